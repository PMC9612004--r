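# DNA strand asymmetry (DSA).
#
# Under a neutral model, a motif and its reverse complement occur at equal
# rates on the two DNA strands, so the asymmetry score
#   S = (Ns - Na) / (Ns + Na)
# is centred on zero; negative S indicates sense-strand under-representation
# and is read as purifying selection against the motif on the sense strand.

#' DSA score
#'
#' `S = (Ns - Na) / (Ns + Na)`: the normalised difference between a sense-
#' and antisense-strand count. Vectorised.
#'
#' @param Ns Sense-strand count(s), non-negative.
#' @param Na Antisense-strand count(s), non-negative.
#' @return Numeric score(s) in `[-1, 1]`; `NA` where `Ns + Na == 0`.
#' @export
dsa_score <- function(Ns, Na) {
  if (any(Ns < 0, na.rm = TRUE) || any(Na < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  tot <- Ns + Na
  ifelse(tot > 0, (Ns - Na) / tot, NA_real_)
}

#' Per-size DSA profile of a segment table
#'
#' Counts sense and antisense GT|AG segments per size class, optionally
#' restricted to a stratum (signal class, length-mod-3 class, exon position
#' class, expression class), and scores each size with [dsa_score()].
#'
#' @param segments data.frame from [segment_table()].
#' @param params An [enumeration_params()] object (defines the size range).
#' @param signal,mod3,position Optional stratum filters; each a character
#'   vector of admitted classes (`NULL` = no filter).
#' @param size_range Optional length-2 vector restricting segment lengths
#'   (inclusive).
#' @return data.frame with columns `size`, `Ns`, `Na`, `S` (one row per
#'   size in the window; `S` is `NA` where both counts are zero).
#' @export
dsa_size_profile <- function(segments, params = enumeration_params(),
                             signal = NULL, mod3 = NULL, position = NULL,
                             size_range = NULL) {
  seg <- filter_segments(segments, signal, mod3, position, size_range)
  sizes <- params$min_len:params$max_len
  Ns <- tabulate_sizes(seg$length[seg$strand == "sense"], sizes)
  Na <- tabulate_sizes(seg$length[seg$strand == "antisense"], sizes)
  data.frame(size = sizes, Ns = Ns, Na = Na, S = dsa_score(Ns, Na))
}

filter_segments <- function(segments, signal = NULL, mod3 = NULL,
                            position = NULL, size_range = NULL) {
  keep <- rep(TRUE, nrow(segments))
  if (!is.null(signal)) keep <- keep & segments$signal_class %in% signal
  if (!is.null(mod3)) keep <- keep & segments$mod3_class %in% mod3
  if (!is.null(position)) keep <- keep & segments$position_class %in% position
  if (!is.null(size_range))
    keep <- keep & segments$length >= size_range[1L] &
      segments$length <= size_range[2L]
  segments[keep, , drop = FALSE]
}

tabulate_sizes <- function(lengths, sizes) {
  if (length(lengths) == 0L) return(integer(length(sizes)))
  as.integer(table(factor(lengths, levels = sizes)))
}

#' Bootstrap parameters for gene-level DSA resampling
#'
#' @param genes_per_draw Genes sampled (without replacement) per replicate.
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer seed making the resampling reproducible.
#' @return List of class `bootstrap_params`.
#' @export
bootstrap_params <- function(genes_per_draw = 500L, replicates = 1000L,
                             seed = 1L) {
  structure(list(genes_per_draw = as.integer(genes_per_draw),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "bootstrap_params")
}

#' Gene-bootstrap distribution of the DSA score
#'
#' The gene, not the exon or the segment, is the resampling unit. Each
#' replicate draws `genes_per_draw` genes uniformly without replacement from
#' the group, sums sense and antisense segment counts of the selected
#' stratum over the drawn genes, and applies [dsa_score()]. Genes with no
#' segments in the stratum contribute zero counts.
#'
#' @param segments data.frame from [segment_table()].
#' @param gene_ids Character vector: the gene universe of the group.
#' @param params A [bootstrap_params()] object.
#' @param signal,mod3,position,size_range Stratum filters as in
#'   [dsa_size_profile()].
#' @param group Group label used in error messages.
#' @return Numeric vector of `replicates` DSA scores.
#' @export
bootstrap_group_dsa <- function(segments, gene_ids,
                                params = bootstrap_params(),
                                signal = NULL, mod3 = NULL, position = NULL,
                                size_range = NULL, group = "group") {
  gene_ids <- unique(gene_ids)
  if (length(gene_ids) < params$genes_per_draw)
    stop("group '", group, "' has ", length(gene_ids),
         " genes; need at least ", params$genes_per_draw)
  seg <- filter_segments(segments, signal, mod3, position, size_range)
  seg <- seg[seg$gene_id %in% gene_ids, , drop = FALSE]
  f <- factor(seg$gene_id, levels = gene_ids)
  ns <- as.numeric(table(f[seg$strand == "sense"]))
  na <- as.numeric(table(f[seg$strand == "antisense"]))
  set.seed(params$seed)
  vapply(seq_len(params$replicates), function(i) {
    idx <- sample.int(length(gene_ids), params$genes_per_draw,
                      replace = FALSE)
    dsa_score(sum(ns[idx]), sum(na[idx]))
  }, numeric(1))
}

#' Pairwise comparison of bootstrap DSA distributions
#'
#' Two-sided two-sample t-tests between every pair of groups, with
#' Bonferroni correction (`p_adjusted = min(1, p * n_pairs)`). Pairs where
#' both distributions have zero variance are flagged as degenerate with an
#' undefined p-value.
#'
#' @param dists Named list of at least two numeric score vectors.
#' @param correction `"bonferroni"` or `"none"`.
#' @return data.frame with one row per pair: group labels, group means,
#'   t statistic, degrees of freedom, raw and corrected p-values, and a
#'   `degenerate` flag.
#' @export
compare_bootstrap_groups <- function(dists, correction = c("bonferroni",
                                                           "none")) {
  correction <- match.arg(correction)
  if (length(dists) < 2L) stop("need at least two groups")
  if (is.null(names(dists))) names(dists) <- paste0("group", seq_along(dists))
  pairs <- utils::combn(names(dists), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- dists[[pairs[1L, j]]]; b <- dists[[pairs[2L, j]]]
    degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0
    if (degenerate) {
      data.frame(group1 = pairs[1L, j], group2 = pairs[2L, j],
                 mean1 = mean(a), mean2 = mean(b),
                 statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                 degenerate = TRUE, stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(a, b, alternative = "two.sided")
      data.frame(group1 = pairs[1L, j], group2 = pairs[2L, j],
                 mean1 = mean(a), mean2 = mean(b),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 degenerate = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- bind_rows_list(rows)
  out$p_adjusted <- if (correction == "bonferroni")
    pmin(1, out$p_value * nrow(out)) else out$p_value
  out
}

#' Per-offset DSA of a trinucleotide in splice-site flank windows
#'
#' For each offset `d` from the splice site (offset 1 = the motif's nearest
#' base is adjacent to the splice site), counts motif occurrences at that
#' offset on the sense strand across all windows (`Ns`) and occurrences at
#' the mirrored offset on the reverse complement of each window (`Na`), so
#' the distance to the splice site is preserved on both strands, then scores
#' each offset with [dsa_score()].
#'
#' @param windows Character vector of exonic flank windows, 5' to 3' on the
#'   sense strand, as produced by [intron_flank_windows()] (`upstream`
#'   windows end at the 5'ss; `downstream` windows start at the 3'ss).
#' @param motif Trinucleotide, e.g. `"GTA"` or `"TAG"`.
#' @param side `"upstream"` (windows abut the 5'ss on their right) or
#'   `"downstream"` (windows abut the 3'ss on their left).
#' @param width Nominal window width; offsets 1 .. `width - 2` are scored.
#' @return data.frame with columns `offset`, `Ns`, `Na`, `S`.
#' @export
flank_motif_dsa <- function(windows, motif, side = c("upstream",
                                                     "downstream"),
                            width = 15L) {
  side <- match.arg(side)
  if (nchar(motif) != 3L) stop("motif must be a trinucleotide")
  rc <- revcomp(windows)
  L <- nchar(windows)
  offsets <- seq_len(width - 2L)
  rows <- lapply(offsets, function(d) {
    valid <- L >= d + 2L
    if (side == "upstream") {
      sense_tri <- substring(windows[valid], L[valid] - d - 1L,
                             L[valid] - d + 1L)
      anti_tri <- substring(rc[valid], d, d + 2L)
    } else {
      sense_tri <- substring(windows[valid], d, d + 2L)
      anti_tri <- substring(rc[valid], L[valid] - d - 1L, L[valid] - d + 1L)
    }
    Ns <- sum(sense_tri == motif)
    Na <- sum(anti_tri == motif)
    data.frame(offset = d, Ns = Ns, Na = Na, S = dsa_score(Ns, Na))
  })
  bind_rows_list(rows)
}
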