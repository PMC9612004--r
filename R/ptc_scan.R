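# Premature termination codon (PTC) scanning under the ciliate nuclear
# genetic code (NCBI translation table 6), in which TAA and TAG encode
# glutamine and TGA is the only stop codon. A retained intron introduces a
# PTC iff, reading the retained transcript in frame, some codon
# intersecting the intron equals TGA.

#' Reading-frame phase of an intron
#'
#' The phase is the number of nucleotides of the interrupted codon already
#' emitted upstream of the intron: the sum of upstream CDS exon lengths
#' (transcription order) modulo 3.
#'
#' @param gene A `GeneModel`.
#' @param intron_index Intron index in transcription order.
#' @return Integer phase in `{0, 1, 2}`.
#' @export
intron_phase <- function(gene, intron_index) {
  n <- nrow(gene$exons)
  if (intron_index < 1L || intron_index > n - 1L)
    stop("intron index out of range for gene ", gene$gene_id)
  ex <- exons_tx(gene)
  lens <- ex[, 2L] - ex[, 1L]
  as.integer(sum(lens[seq_len(intron_index)]) %% 3L)
}

#' Detect a premature termination codon in a retained intron
#'
#' Reads the retained transcript in frame across the intron and reports
#' whether any codon intersecting the intron is TGA (the only stop codon
#' under translation table 6). Codons spanning the exon-intron boundaries
#' are included by default and require flanking exonic context nucleotides;
#' `include_boundary = FALSE` restricts the scan to codons lying fully
#' inside the intron.
#'
#' @param intron_sequence Intron sequence, transcription sense.
#' @param phase Intron phase from [intron_phase()].
#' @param upstream_context Up to 2 nt of exonic sequence immediately 5' of
#'   the intron (at least `phase` nt are required when
#'   `include_boundary = TRUE`).
#' @param downstream_context Up to 2 nt of exonic sequence immediately 3'
#'   of the intron (required when the last intron-intersecting codon is
#'   incomplete).
#' @param include_boundary Scan codons spanning the exon-intron boundaries
#'   (default `TRUE`).
#' @return `TRUE` iff a TGA codon intersects the intron.
#' @export
detect_ptc <- function(intron_sequence, phase, upstream_context = "",
                       downstream_context = "", include_boundary = TRUE) {
  phase <- as.integer(phase)
  if (!phase %in% 0:2) stop("phase must be 0, 1 or 2")
  len <- nchar(intron_sequence)
  if (len < 1L) return(FALSE)
  if (include_boundary) {
    need_up <- phase
    need_down <- (3L - (phase + len) %% 3L) %% 3L
    if (nchar(upstream_context) < need_up)
      stop("phase ", phase, " intron needs ", need_up,
           " nt of upstream exonic context")
    if (nchar(downstream_context) < need_down)
      stop("intron needs ", need_down, " nt of downstream exonic context")
    up <- if (need_up > 0L)
      substr(upstream_context, nchar(upstream_context) - need_up + 1L,
             nchar(upstream_context)) else ""
    down <- if (need_down > 0L) substr(downstream_context, 1L, need_down)
      else ""
    s <- paste0(up, intron_sequence, down)
    starts <- seq.int(1L, nchar(s) - 2L, by = 3L)
    any(substring(s, starts, starts + 2L) == "TGA")
  } else {
    first_codon_start <- (3L - phase) %% 3L + 1L
    if (len - first_codon_start + 1L < 3L) return(FALSE)
    starts <- seq.int(first_codon_start, len - 2L, by = 3L)
    any(substring(intron_sequence, starts, starts + 2L) == "TGA")
  }
}

#' Build the annotated-intron table of a gene set
#'
#' Derives one record per annotated intron: genomic interval, transcription
#' -sense sequence, length-mod-3 class, boundary signal class, positional
#' class, phase and PTC flag (boundary-spanning codons included). Introns
#' not bounded by GT..AG are flagged non-canonical (signal class `NA`)
#' rather than rejected.
#'
#' @param genes List of `GeneModel` objects.
#' @param sequences Named character vector of chromosome sequences.
#' @param include_boundary Passed to [detect_ptc()].
#' @return data.frame with columns `gene_id`, `intron_index`, `n_introns`,
#'   `chrom`, `start`, `end`, `strand`, `length`, `sequence`, `phase`,
#'   `mod3_class`, `signal_class`, `position_class`, `gta5` (5'ss is GTA),
#'   `tag3` (3'ss is TAG), `canonical`, `ptc`, `expression`.
#' @export
derive_intron_records <- function(genes, sequences,
                                  include_boundary = TRUE) {
  rows <- lapply(genes, function(g) {
    n_ex <- nrow(g$exons)
    if (n_ex < 2L) return(NULL)
    chrom_seq <- sequences[[g$chromosome]]
    if (is.null(chrom_seq) || is.na(chrom_seq))
      stop("chromosome ", g$chromosome, " not present in sequences")
    gaps <- gene_introns(g)                       # genomic order
    n_int <- nrow(gaps)
    exs <- extract_coding_exons(list(g), sequences)
    out <- lapply(seq_len(n_int), function(i) {
      # transcription-order intron i <-> genomic gap index
      gi <- if (g$strand == "+") i else n_int - i + 1L
      seqg <- substr(chrom_seq, gaps[gi, 1L] + 1L, gaps[gi, 2L])
      seqs <- if (g$strand == "-") revcomp(seqg) else seqg
      len <- nchar(seqs)
      canonical <- len >= 6L && substr(seqs, 1L, 2L) == "GT" &&
        substr(seqs, len - 1L, len) == "AG"
      signal <- if (canonical) classify_segment(seqs)$signal_class
        else NA_character_
      ph <- intron_phase(g, i)
      up_ex <- exs$sequence[i]
      down_ex <- exs$sequence[i + 1L]
      up_ctx <- substr(up_ex, max(1L, nchar(up_ex) - 1L), nchar(up_ex))
      down_ctx <- substr(down_ex, 1L, min(2L, nchar(down_ex)))
      pos <- if (n_int == 1L) "single" else if (i == 1L) "first"
        else if (i == n_int) "last" else "internal"
      data.frame(gene_id = g$gene_id, intron_index = i, n_introns = n_int,
                 chrom = g$chromosome,
                 start = gaps[gi, 1L], end = gaps[gi, 2L],
                 strand = g$strand, length = len, sequence = seqs,
                 phase = ph,
                 mod3_class = c("3n", "3n+1", "3n+2")[len %% 3L + 1L],
                 signal_class = signal,
                 position_class = pos,
                 gta5 = substr(seqs, 1L, 3L) == "GTA",
                 tag3 = len >= 3L &&
                   substr(seqs, len - 2L, len) == "TAG",
                 canonical = canonical,
                 ptc = detect_ptc(seqs, ph, up_ctx, down_ctx,
                                  include_boundary = include_boundary),
                 expression = g$expression,
                 stringsAsFactors = FALSE)
    })
    bind_rows_list(out)
  })
  out <- bind_rows_list(rows)
  if (is.null(out)) stop("no multi-exon genes: no introns to derive")
  out
}

#' PTC enrichment by stratum
#'
#' Computes the fraction of PTC-containing introns per stratum and
#' two-sided two-proportion tests (chi-square without continuity
#' correction) between requested strata pairs.
#'
#' @param introns data.frame from [derive_intron_records()] (must carry a
#'   logical `ptc` column and the stratifying column).
#' @param by Name of the stratifying column (e.g. `"mod3_class"`,
#'   `"position_class"`).
#' @param pairs Optional 2-column character matrix of strata pairs to test;
#'   default all pairs.
#' @return List with `fractions` (stratum, n, n_ptc, fraction) and `tests`
#'   (pairwise proportion tests: statistic, df, p_value).
#' @export
ptc_enrichment <- function(introns, by = "mod3_class", pairs = NULL) {
  if (!by %in% names(introns)) stop("no column '", by, "' in intron table")
  strata <- split(introns$ptc, introns[[by]])
  fractions <- data.frame(
    stratum = names(strata),
    n = vapply(strata, length, integer(1)),
    n_ptc = vapply(strata, sum, integer(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE, row.names = NULL)
  fractions$fraction <- ifelse(fractions$n > 0,
                               fractions$n_ptc / fractions$n, NA_real_)
  if (is.null(pairs)) {
    if (nrow(fractions) < 2L)
      return(list(fractions = fractions,
                  tests = data.frame(stratum1 = character(0),
                                     stratum2 = character(0),
                                     statistic = numeric(0),
                                     df = numeric(0),
                                     p_value = numeric(0))))
    pairs <- t(utils::combn(fractions$stratum, 2L))
  }
  tests <- lapply(seq_len(nrow(pairs)), function(j) {
    a <- fractions[fractions$stratum == pairs[j, 1L], ]
    b <- fractions[fractions$stratum == pairs[j, 2L], ]
    pt <- suppressWarnings(
      stats::prop.test(c(a$n_ptc, b$n_ptc), c(a$n, b$n),
                       alternative = "two.sided", correct = FALSE))
    data.frame(stratum1 = pairs[j, 1L], stratum2 = pairs[j, 2L],
               statistic = unname(pt$statistic),
               df = unname(pt$parameter), p_value = pt$p.value,
               stringsAsFactors = FALSE)
  })
  list(fractions = fractions, tests = bind_rows_list(tests))
}
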