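# Quantification of splicing, intron retention and alternative splice-site
# usage per locus (annotated intron or cryptic GT|AG segment), from splice
# junction tables and either raw read intervals or pre-aggregated counts.

#' Quantification parameters
#'
#' @param min_reads Minimum total analysed reads for a locus to count as
#'   covered (default 10).
#' @return List of class `quant_params`.
#' @export
quant_params <- function(min_reads = 10L) {
  min_reads <- as.integer(min_reads)
  if (min_reads < 1L) stop("min_reads must be >= 1")
  structure(list(min_reads = min_reads), class = "quant_params")
}

#' Cluster junctions into alternative-splicing groups
#'
#' Two junctions are linked iff they share the donor or the acceptor but
#' not both (junctions with identical coordinates are the same junction);
#' clusters are the connected components of this relation.
#'
#' @param junctions data.frame with `donor` and `acceptor` columns
#'   (one chromosome/strand at a time).
#' @return The input with an integer `cluster` column (junctions with equal
#'   coordinates get the same cluster id).
#' @export
group_alternative_junctions <- function(junctions) {
  if (nrow(junctions) == 0L) {
    junctions$cluster <- integer(0)
    return(junctions)
  }
  key <- paste(junctions$donor, junctions$acceptor)
  uk <- unique(key)
  idx <- match(key, uk)
  ud <- junctions$donor[match(uk, key)]
  ua <- junctions$acceptor[match(uk, key)]
  parent <- seq_along(uk)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  link_by <- function(values) {
    for (grp in split(seq_along(values), values)) {
      if (length(grp) > 1L)
        for (j in grp[-1L]) union2(grp[1L], j)
    }
  }
  link_by(ud)
  link_by(ua)
  roots <- vapply(seq_along(uk), find, integer(1))
  junctions$cluster <- as.integer(factor(roots[idx],
                                         levels = unique(roots)))
  junctions
}

#' Count reads supporting retention of a locus
#'
#' A read supports retention iff its contiguous alignment interval contains
#' the locus interval entirely. When both mates of a pair support the same
#' locus, a single retention event is counted (aligning the counting with
#' how junction-spanning reads are counted once per fragment).
#'
#' @param read_intervals data.frame with columns `start`, `end` (0-based
#'   half-open genomic intervals of uniquely mapped reads), `read_id` and
#'   optionally `pair_id` (mates share a `pair_id`; `NA` means unpaired).
#' @param locus List or one-row data.frame with `start` and `end`.
#' @return Integer retention count.
#' @export
count_retention <- function(read_intervals, locus) {
  if (nrow(read_intervals) == 0L) return(0L)
  spans <- read_intervals$start <= locus$start &
    read_intervals$end >= locus$end
  if (!any(spans)) return(0L)
  unit <- if ("pair_id" %in% names(read_intervals)) {
    ifelse(is.na(read_intervals$pair_id),
           paste0("r:", read_intervals$read_id),
           paste0("p:", read_intervals$pair_id))
  } else read_intervals$read_id
  length(unique(unit[spans]))
}

#' Splicing profile of a single locus
#'
#' Spliced reads are the unique reads of the junction matching the locus
#' boundaries exactly; alternative reads are the unique reads of junctions
#' in the same connected component (sharing a donor or an acceptor, possibly
#' transitively); retained reads come from `count_retention()` or a
#' pre-aggregated count. Levels are proportions of the three categories out
#' of all analysed reads.
#'
#' @param locus List with `locus_id`, `chrom`, `start` (donor), `end`
#'   (acceptor).
#' @param junctions Junction data.frame (see [read_junction_table()]).
#' @param read_intervals Optional read-interval data.frame for
#'   [count_retention()].
#' @param retained_count Optional pre-aggregated retention count (used when
#'   `read_intervals` is `NULL`).
#' @param params A [quant_params()] object.
#' @return One-row data.frame: `locus_id`, `spliced`, `retained`, `alt`,
#'   `total`, `splicing_level`, `retention_level`, `alt_usage`, `covered`.
#' @export
compute_locus_profile <- function(locus, junctions, read_intervals = NULL,
                                  retained_count = NULL,
                                  params = quant_params()) {
  j <- junctions[junctions$chrom == locus$chrom, , drop = FALSE]
  spliced <- sum(j$unique_reads[j$donor == locus$start &
                                  j$acceptor == locus$end])
  # cluster with a virtual zero-read junction at the locus coordinates so
  # alternative junctions are found even when the canonical one is absent
  virt <- data.frame(chrom = locus$chrom, donor = locus$start,
                     acceptor = locus$end, unique_reads = 0L,
                     stringsAsFactors = FALSE)
  jj <- rbind(j[, c("chrom", "donor", "acceptor", "unique_reads")], virt)
  cl <- group_alternative_junctions(jj)
  own <- cl$cluster[nrow(cl)]
  in_cluster <- cl$cluster == own
  exact <- cl$donor == locus$start & cl$acceptor == locus$end
  alt <- sum(cl$unique_reads[in_cluster & !exact])
  retained <- if (!is.null(read_intervals))
    count_retention(read_intervals, locus)
  else as.integer(retained_count %||% 0L)
  total <- spliced + retained + alt
  data.frame(locus_id = locus$locus_id,
             spliced = as.integer(spliced),
             retained = as.integer(retained),
             alt = as.integer(alt),
             total = as.integer(total),
             splicing_level = if (total > 0) spliced / total else NA_real_,
             retention_level = if (total > 0) retained / total else NA_real_,
             alt_usage = if (total > 0) alt / total else NA_real_,
             covered = total >= params$min_reads,
             stringsAsFactors = FALSE)
}

#' Splicing profiles from a pre-aggregated count table
#'
#' The count path: per-locus spliced/retained/alternative read counts are
#' turned into the same `SplicingProfile` rows as the junction/interval
#' path.
#'
#' @param counts data.frame with columns `locus_id`, `spliced`, `retained`,
#'   `alt`.
#' @param params A [quant_params()] object.
#' @return data.frame with one profile row per locus (see
#'   [compute_locus_profile()]).
#' @export
profiles_from_counts <- function(counts, params = quant_params()) {
  total <- counts$spliced + counts$retained + counts$alt
  data.frame(locus_id = counts$locus_id,
             spliced = as.integer(counts$spliced),
             retained = as.integer(counts$retained),
             alt = as.integer(counts$alt),
             total = as.integer(total),
             splicing_level = ifelse(total > 0, counts$spliced / total,
                                     NA_real_),
             retention_level = ifelse(total > 0, counts$retained / total,
                                      NA_real_),
             alt_usage = ifelse(total > 0, counts$alt / total, NA_real_),
             covered = total >= params$min_reads,
             stringsAsFactors = FALSE)
}

#' Match novel junctions to enumerated GT|AG segments
#'
#' A cryptic segment is matched by a junction iff the junction is
#' non-annotated and its donor and acceptor equal the segment's genomic
#' boundaries exactly. Reads of junctions from multiple replicates matching
#' the same segment are summed; evidence in any replicate suffices for a
#' segment to count as spliced.
#'
#' @param segments data.frame from [segment_table()] (sense segments with
#'   genomic coordinates are used).
#' @param junctions Junction data.frame (possibly several replicates
#'   concatenated).
#' @return The sense segments that match at least one novel junction, with
#'   an added `junction_reads` column (summed unique reads).
#' @export
match_novel_junctions_to_segments <- function(segments, junctions) {
  sense <- segments[segments$strand == "sense" & !is.na(segments$g_start), ,
                    drop = FALSE]
  skey <- paste(sense$chrom, sense$g_start, sense$g_end)
  novel <- junctions[!junctions$annotated, , drop = FALSE]
  if (nrow(novel) > 0L && anyDuplicated(skey)) {
    jkey <- paste(novel$chrom, novel$donor, novel$acceptor)
    dup <- skey[duplicated(skey)]
    if (any(jkey %in% dup))
      stop("a junction matches multiple identical segments; ",
           "deduplicate the segment table first")
  }
  if (nrow(novel) == 0L) {
    out <- sense[integer(0), , drop = FALSE]
    out$junction_reads <- integer(0)
    return(out)
  }
  jkey <- paste(novel$chrom, novel$donor, novel$acceptor)
  reads <- tapply(novel$unique_reads, jkey, sum)
  hit <- skey %in% names(reads)
  out <- sense[hit, , drop = FALSE]
  out$junction_reads <- as.integer(reads[skey[hit]])
  rownames(out) <- NULL
  out
}

#' Summary of loci by splicing-level class
#'
#' Bins covered loci with non-zero splicing level into ten equal-width
#' splicing-level classes ((0, 0.1], (0.1, 0.2], ..., (0.9, 1]) and reports,
#' per bin, the fraction of loci, the fraction of 3n loci and the mean AT
#' content, plus Pearson correlations of bin index against the 3n fraction
#' and against AT content (over non-empty bins).
#'
#' @param profiles Profile data.frame with `splicing_level` and `covered`
#'   columns plus `mod3_class` and `at` (AT content) per locus.
#' @param n_bins Number of equal-width bins (default 10).
#' @return List with `bins` (data.frame: `bin`, `lower`, `upper`, `n`,
#'   `fraction`, `fraction_3n`, `mean_at`) and `correlations` (data.frame
#'   with Pearson r and p for 3n fraction and AT content vs bin index).
#' @export
splicing_level_class_summary <- function(profiles, n_bins = 10L) {
  use <- profiles[profiles$covered & !is.na(profiles$splicing_level) &
                    profiles$splicing_level > 0, , drop = FALSE]
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  empty_bins <- data.frame(bin = seq_len(n_bins),
                           lower = breaks[-(n_bins + 1L)],
                           upper = breaks[-1L],
                           n = 0L, fraction = NA_real_,
                           fraction_3n = NA_real_, mean_at = NA_real_)
  if (nrow(use) == 0L)
    return(list(bins = empty_bins[integer(0), ],
                correlations = data.frame(variable = character(0),
                                          r = numeric(0), p = numeric(0))))
  b <- as.integer(cut(use$splicing_level, breaks = breaks, right = TRUE,
                      include.lowest = FALSE))
  bins <- empty_bins
  tab <- table(factor(b, levels = seq_len(n_bins)))
  bins$n <- as.integer(tab)
  bins$fraction <- bins$n / nrow(use)
  is3n <- use$mod3_class == "3n"
  bins$fraction_3n <- as.numeric(tapply(is3n, factor(b, seq_len(n_bins)),
                                        mean))
  bins$mean_at <- as.numeric(tapply(use$at, factor(b, seq_len(n_bins)),
                                    mean))
  cor_row <- function(variable, y) {
    ok <- !is.na(y)
    if (sum(ok) < 3L || stats::sd(y[ok]) == 0)
      return(data.frame(variable = variable, r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(bins$bin[ok], y[ok], method = "pearson")
    data.frame(variable = variable, r = unname(ct$estimate), p = ct$p.value)
  }
  list(bins = bins,
       correlations = rbind(cor_row("fraction_3n", bins$fraction_3n),
                            cor_row("mean_at", bins$mean_at)))
}
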