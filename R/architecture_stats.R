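# Gene-architecture statistics: expression quartiles, positional binning
# along the CDS, intron density, CDS length, inter-intron and gene-tail
# distances, and the association tests used to compare strata.

#' Analysis configuration
#'
#' @param n_bins Number of equal-width CDS bins (default 10).
#' @param prevalent_range Prevalent intron size range (nt).
#' @param tail_window Width of the gene-tail region (bp, default 200).
#' @param midpoint_binning Bin features by their interval midpoint instead
#'   of their 5'-most CDS coordinate.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(n_bins = 10L, prevalent_range = c(21L, 30L),
                            tail_window = 200L, midpoint_binning = FALSE) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (tail_window <= 0L) stop("tail_window must be positive")
  structure(list(n_bins = n_bins,
                 prevalent_range = as.integer(prevalent_range),
                 tail_window = as.integer(tail_window),
                 midpoint_binning = midpoint_binning),
            class = "analysis_config")
}

#' Assign genes to expression quartiles
#'
#' Quartile boundaries come from the empirical distribution of
#' log2-transformed expression (rank-based, hence invariant to any monotone
#' transform). Genes with zero expression are excluded (log2 undefined) with
#' a message. Ties are broken toward the lower quartile; with distinct
#' values every quartile is within one gene of `n/4`. Q1 is the weakly
#' expressed class, Q4 the highly expressed class.
#'
#' @param expression Named numeric vector of non-negative expression
#'   values.
#' @return Named factor with levels `Q1` to `Q4` (zero-expression genes
#'   dropped).
#' @export
assign_expression_quartiles <- function(expression) {
  if (any(expression < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  x <- expression[!is.na(expression)]
  zero <- x == 0
  if (any(zero)) {
    message(sum(zero), " gene(s) with zero expression excluded from ",
            "quartile assignment")
    x <- x[!zero]
  }
  if (length(x) < 4L) stop("need at least 4 genes with positive expression")
  if (stats::sd(x) == 0) {
    warning("all expression values equal; all genes assigned to Q1")
    return(stats::setNames(factor(rep("Q1", length(x)),
                                  levels = paste0("Q", 1:4)), names(x)))
  }
  r <- rank(log2(x), ties.method = "min")
  q <- floor((r - 1) * 4 / length(x)) + 1L
  stats::setNames(factor(paste0("Q", q), levels = paste0("Q", 1:4)),
                  names(x))
}

#' Bin a CDS position into equal-width bins
#'
#' `bin = floor(position * n_bins / cds_length) + 1`. Positions are
#' transcription-order CDS offsets (0-based); features are conventionally
#' located by their 5'-most CDS coordinate. Vectorised.
#'
#' @param position CDS coordinate(s), `0 <= position < cds_length`.
#' @param cds_length CDS length(s) in nt.
#' @param n_bins Number of bins.
#' @return Integer bin index in `1..n_bins`.
#' @export
bin_cds_position <- function(position, cds_length, n_bins = 10L) {
  if (any(position < 0 | position >= cds_length))
    stop("position out of range [0, cds_length)")
  as.integer(floor(position * n_bins / cds_length)) + 1L
}

#' Architecture metrics of a single gene
#'
#' @param gene A `GeneModel`.
#' @return List with `cds_length` (nt), `n_introns`, `intron_density`
#'   (introns per kb of CDS), `inter_intron_distances` (exonic nt between
#'   consecutive introns, transcription order), and `tail_distance`
#'   (CDS-coordinate distance from the last intron's 3'ss to the CDS end;
#'   `NA` for intronless genes). All quantities are strand-invariant.
#' @export
gene_architecture_metrics <- function(gene) {
  ex <- exons_tx(gene)
  lens <- ex[, 2L] - ex[, 1L]
  cds_length <- sum(lens)
  n_introns <- nrow(ex) - 1L
  list(cds_length = as.integer(cds_length),
       n_introns = as.integer(n_introns),
       intron_density = n_introns / (cds_length / 1000),
       inter_intron_distances = if (n_introns >= 2L)
         as.integer(lens[2:(n_introns)]) else integer(0),
       tail_distance = if (n_introns >= 1L)
         as.integer(lens[length(lens)]) else NA_integer_)
}

#' Architecture metrics for a gene set
#'
#' @param genes List of `GeneModel` objects.
#' @return List with `genes` (one row per gene: `gene_id`, `cds_length`,
#'   `n_introns`, `intron_density`, `tail_distance`, `expression`) and
#'   `inter_intron` (long data.frame: `gene_id`, `intron_index`,
#'   `distance_to_next`, the exonic distance from each intron's 3'ss to the
#'   next downstream intron's 5'ss).
#' @export
architecture_table <- function(genes) {
  per_gene <- lapply(genes, function(g) {
    m <- gene_architecture_metrics(g)
    data.frame(gene_id = g$gene_id, cds_length = m$cds_length,
               n_introns = m$n_introns, intron_density = m$intron_density,
               tail_distance = m$tail_distance,
               expression = g$expression, stringsAsFactors = FALSE)
  })
  inter <- lapply(genes, function(g) {
    m <- gene_architecture_metrics(g)
    d <- m$inter_intron_distances
    if (length(d) == 0L) return(NULL)
    data.frame(gene_id = g$gene_id, intron_index = seq_along(d),
               distance_to_next = d, stringsAsFactors = FALSE)
  })
  inter_df <- bind_rows_list(inter)
  if (is.null(inter_df))
    inter_df <- data.frame(gene_id = character(0), intron_index = integer(0),
                           distance_to_next = integer(0))
  list(genes = bind_rows_list(per_gene), inter_intron = inter_df)
}

#' Run a batch of association tests
#'
#' Each request is a named list with a `type` and its inputs:
#' \describe{
#'   \item{`two_proportion`}{`x` (2 successes), `n` (2 totals): two-sided
#'     two-proportion chi-square test without continuity correction.}
#'   \item{`chisq_uniform`}{`counts`: chi-square goodness-of-fit against the
#'     uniform distribution (`df = length(counts) - 1`).}
#'   \item{`pearson`}{`x`, `y`: Pearson correlation test.}
#'   \item{`wilcoxon`}{`x`, `y`: two-sample Wilcoxon rank-sum test.}
#' }
#' All tests are two-sided. Degenerate inputs (zero totals, zero variance)
#' are flagged rather than fatal.
#'
#' @param tests Named list of request lists.
#' @param correction `"bonferroni"` (`p_adjusted = min(1, p * n_tests)`) or
#'   `"none"`.
#' @return data.frame: `name`, `type`, `statistic`, `df`, `estimate`,
#'   `p_value`, `p_adjusted`, `degenerate`.
#' @export
association_tests <- function(tests, correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  if (is.null(names(tests)) || any(!nzchar(names(tests))))
    names(tests) <- paste0("test", seq_along(tests))
  row <- function(name, type, statistic = NA_real_, df = NA_real_,
                  estimate = NA_real_, p_value = NA_real_,
                  degenerate = FALSE) {
    data.frame(name = name, type = type, statistic = statistic, df = df,
               estimate = estimate, p_value = p_value,
               degenerate = degenerate, stringsAsFactors = FALSE)
  }
  rows <- lapply(names(tests), function(nm) {
    tq <- tests[[nm]]
    switch(tq$type,
      two_proportion = {
        if (any(tq$n == 0)) return(row(nm, tq$type, degenerate = TRUE))
        pt <- stats::prop.test(tq$x, tq$n, alternative = "two.sided",
                               correct = FALSE)
        row(nm, tq$type, unname(pt$statistic), unname(pt$parameter),
            diff(-pt$estimate), pt$p.value)
      },
      chisq_uniform = {
        if (sum(tq$counts) == 0) return(row(nm, tq$type, degenerate = TRUE))
        ct <- suppressWarnings(stats::chisq.test(tq$counts))
        row(nm, tq$type, unname(ct$statistic), unname(ct$parameter),
            NA_real_, ct$p.value)
      },
      pearson = {
        if (stats::sd(tq$x) == 0 || stats::sd(tq$y) == 0)
          return(row(nm, tq$type, degenerate = TRUE))
        ct <- stats::cor.test(tq$x, tq$y, method = "pearson")
        row(nm, tq$type, unname(ct$statistic), unname(ct$parameter),
            unname(ct$estimate), ct$p.value)
      },
      wilcoxon = {
        if (length(tq$x) == 0 || length(tq$y) == 0)
          return(row(nm, tq$type, degenerate = TRUE))
        wt <- suppressWarnings(stats::wilcox.test(tq$x, tq$y,
                                                  alternative = "two.sided"))
        row(nm, tq$type, unname(wt$statistic), NA_real_, NA_real_,
            wt$p.value)
      },
      stop("unknown test type: ", tq$type))
  })
  out <- bind_rows_list(rows)
  out$p_adjusted <- if (correction == "bonferroni")
    pmin(1, out$p_value * nrow(out)) else out$p_value
  out
}

#' Intron boundary-signal frequencies by expression quartile
#'
#' For each expression quartile, the percentage of introns with the optimal
#' GTA 5' splice site, the optimal TAG 3' splice site, and both
#' simultaneously.
#'
#' @param introns data.frame from [derive_intron_records()].
#' @param quartiles Named factor from [assign_expression_quartiles()].
#' @return data.frame: `quartile`, `n`, `pct_gta_tag`, `pct_gta5`,
#'   `pct_tag3`.
#' @export
intron_signal_by_quartile <- function(introns, quartiles) {
  q <- quartiles[introns$gene_id]
  keep <- !is.na(q)
  d <- introns[keep, , drop = FALSE]
  q <- droplevels(factor(q[keep], levels = levels(quartiles)))
  rows <- lapply(levels(q), function(lev) {
    di <- d[q == lev, , drop = FALSE]
    data.frame(quartile = lev, n = nrow(di),
               pct_gta_tag = 100 * mean(di$gta5 & di$tag3),
               pct_gta5 = 100 * mean(di$gta5),
               pct_tag3 = 100 * mean(di$tag3),
               stringsAsFactors = FALSE)
  })
  bind_rows_list(rows)
}
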