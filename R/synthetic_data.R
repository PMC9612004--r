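# Synthetic genomes, annotations, expression and junction tables with
# known planted structure, for parameter-recovery testing of every
# pipeline stage.
#
# The generator emulates the salient features of the P. tetraurelia
# macronuclear genome: many short genes, ~25 bp introns concentrated in the
# 21-30 bp range, AT-rich exons (~72%) and introns (~80%), a configurable
# fraction of introns with the optimal GTA...TAG boundaries, and lognormal
# expression. Exon sequences are iid nucleotides (no codon model): under
# iid generation the DSA baseline is symmetric, which is exactly what the
# recovery tests need.

#' Simulation parameters
#'
#' Defaults reflect the architecture of intron-containing
#' *P. tetraurelia* genes: a mean of 2.9 introns per gene, lognormal exon
#' lengths with median 194 bp (mean ~354 bp), intron lengths concentrated
#' in 21-30 nt, 72% AT exons, 80% AT introns, and 69% of introns carrying
#' GTA...TAG boundaries.
#'
#' @param n_genes Number of genes.
#' @param mean_introns Poisson mean of the per-gene intron count.
#' @param exon_len_meanlog,exon_len_sdlog Lognormal parameters of exon
#'   length (nt).
#' @param min_exon_len,max_exon_len Exon length clamp (nt).
#' @param intron_sizes,intron_size_weights Support and weights of the
#'   intron length distribution (default: 95% of mass uniform on 21-30 nt,
#'   5% on the rest of 15-40 nt).
#' @param exon_at,intron_at Target AT fractions.
#' @param gta_tag_intron_fraction Fraction of introns with GTA...TAG
#'   boundaries.
#' @param expr_meanlog,expr_sdlog Lognormal parameters of expression.
#' @param genes_per_chrom Genes placed per chromosome.
#' @param intergenic_len Mean intergenic spacer length (nt).
#' @param seed Integer seed.
#' @return List of class `simulation_params`.
#' @export
simulation_params <- function(n_genes = 2000L, mean_introns = 2.9,
                              exon_len_meanlog = log(194),
                              exon_len_sdlog = 1.1,
                              min_exon_len = 30L, max_exon_len = 5000L,
                              intron_sizes = 15:40,
                              intron_size_weights = NULL,
                              exon_at = 0.72, intron_at = 0.80,
                              gta_tag_intron_fraction = 0.69,
                              expr_meanlog = 3, expr_sdlog = 1.5,
                              genes_per_chrom = 50L,
                              intergenic_len = 200L, seed = 1L) {
  if (is.null(intron_size_weights)) {
    w <- ifelse(intron_sizes >= 21L & intron_sizes <= 30L,
                0.95 / sum(intron_sizes >= 21L & intron_sizes <= 30L),
                0.05 / sum(intron_sizes < 21L | intron_sizes > 30L))
    intron_size_weights <- w / sum(w)
  }
  stopifnot(length(intron_size_weights) == length(intron_sizes),
            all(intron_size_weights >= 0),
            exon_at >= 0, exon_at <= 1, intron_at >= 0, intron_at <= 1,
            gta_tag_intron_fraction >= 0, gta_tag_intron_fraction <= 1,
            min_exon_len >= 6L)
  structure(list(n_genes = as.integer(n_genes),
                 mean_introns = mean_introns,
                 exon_len_meanlog = exon_len_meanlog,
                 exon_len_sdlog = exon_len_sdlog,
                 min_exon_len = as.integer(min_exon_len),
                 max_exon_len = as.integer(max_exon_len),
                 intron_sizes = as.integer(intron_sizes),
                 intron_size_weights = intron_size_weights,
                 exon_at = exon_at, intron_at = intron_at,
                 gta_tag_intron_fraction = gta_tag_intron_fraction,
                 expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
                 genes_per_chrom = as.integer(genes_per_chrom),
                 intergenic_len = as.integer(intergenic_len),
                 seed = as.integer(seed)),
            class = "simulation_params")
}

random_dna <- function(n, at) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

random_intron <- function(len, at, gta_tag_prob) {
  v <- strsplit(random_dna(len, at), "")[[1]]
  v[1:2] <- c("G", "T")
  v[(len - 1L):len] <- c("A", "G")
  if (stats::runif(1) < gta_tag_prob) {
    v[3L] <- "A"
    v[len - 2L] <- "T"
  } else {
    # at least one of the two signal positions is suboptimal
    repeat {
      b3 <- sample(c("A", "T", "G", "C"), 1L,
                   prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
      bt <- sample(c("A", "T", "G", "C"), 1L,
                   prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
      if (!(b3 == "A" && bt == "T")) break
    }
    v[3L] <- b3
    v[len - 2L] <- bt
  }
  paste(v, collapse = "")
}

#' Simulate a genome with annotation, expression and planted truth
#'
#' Generates `n_genes` genes placed on chromosomes of `genes_per_chrom`
#' genes each, separated by intergenic spacers, each gene with iid
#' nucleotide exons at the target AT fraction and introns drawn from the
#' configured length distribution, the configured fraction carrying
#' GTA...TAG boundaries. Fully reproducible from `params$seed`.
#'
#' @param params A [simulation_params()] object.
#' @return List with `genome` (named character vector), `genes` (list of
#'   `GeneModel`), `expression` (named numeric vector), and `truth` (list
#'   with per-gene and per-intron data.frames recording every planted
#'   property).
#' @export
simulate_genome <- function(params = simulation_params()) {
  set.seed(params$seed)
  n <- params$n_genes
  n_introns <- stats::rpois(n, params$mean_introns)
  expression <- stats::rlnorm(n, params$expr_meanlog, params$expr_sdlog)
  gene_ids <- sprintf("g%05d", seq_len(n))
  strands <- sample(c("+", "-"), n, replace = TRUE)

  chrom_parts <- list()
  chrom_lens <- integer(0)
  genes <- vector("list", n)
  intron_truth <- vector("list", n)
  cur_chrom <- 0L
  pos <- 0L

  for (i in seq_len(n)) {
    if ((i - 1L) %% params$genes_per_chrom == 0L) {
      cur_chrom <- cur_chrom + 1L
      pos <- 0L
      chrom_parts[[cur_chrom]] <- list()
    }
    chrom_name <- sprintf("chr%03d", cur_chrom)
    ni <- n_introns[i]
    n_ex <- ni + 1L
    ex_lens <- pmin(pmax(round(stats::rlnorm(n_ex, params$exon_len_meanlog,
                                             params$exon_len_sdlog)),
                         params$min_exon_len), params$max_exon_len)
    ex_lens <- as.integer(ex_lens)
    in_lens <- if (ni > 0L)
      sample(params$intron_sizes, ni, replace = TRUE,
             prob = params$intron_size_weights) else integer(0)
    ex_seqs <- vapply(ex_lens, random_dna, character(1), at = params$exon_at)
    in_seqs <- vapply(in_lens, random_intron, character(1),
                      at = params$intron_at,
                      gta_tag_prob = params$gta_tag_intron_fraction)
    # interleave exons and introns in transcription order
    piece_seq <- character(2L * ni + 1L)
    piece_len <- integer(2L * ni + 1L)
    piece_seq[seq(1L, 2L * ni + 1L, by = 2L)] <- ex_seqs
    piece_len[seq(1L, 2L * ni + 1L, by = 2L)] <- ex_lens
    if (ni > 0L) {
      piece_seq[seq(2L, 2L * ni, by = 2L)] <- in_seqs
      piece_len[seq(2L, 2L * ni, by = 2L)] <- in_lens
    }
    tx_seq <- paste(piece_seq, collapse = "")
    gene_len <- sum(piece_len)
    offsets <- cumsum(c(0L, piece_len[-length(piece_len)]))  # tx coords

    spacer_len <- params$intergenic_len +
      sample.int(params$intergenic_len, 1L)
    spacer <- random_dna(spacer_len, (params$exon_at + params$intron_at) / 2)
    gene_start <- pos + spacer_len                             # 0-based
    genomic_seq <- if (strands[i] == "-") revcomp(tx_seq) else tx_seq

    ex_idx <- seq(1L, 2L * ni + 1L, by = 2L)
    if (strands[i] == "+") {
      ex_start <- gene_start + offsets[ex_idx]
    } else {
      ex_start <- gene_start + gene_len -
        (offsets[ex_idx] + piece_len[ex_idx])
    }
    ex_end <- ex_start + piece_len[ex_idx]
    ord <- order(ex_start)
    genes[[i]] <- gene_model(gene_ids[i], chrom_name, strands[i],
                             cbind(ex_start[ord], ex_end[ord]),
                             expression = expression[i])
    if (ni > 0L) {
      intron_truth[[i]] <- data.frame(
        gene_id = gene_ids[i], intron_index = seq_len(ni),
        length = in_lens,
        gta_tag = substr(in_seqs, 1L, 3L) == "GTA" &
          substr(in_seqs, in_lens - 2L, in_lens) == "TAG",
        stringsAsFactors = FALSE)
    }
    chrom_parts[[cur_chrom]][[length(chrom_parts[[cur_chrom]]) + 1L]] <-
      paste0(spacer, genomic_seq)
    pos <- gene_start + gene_len
  }

  genome <- vapply(chrom_parts, function(p) paste(unlist(p), collapse = ""),
                   character(1))
  names(genome) <- sprintf("chr%03d", seq_along(genome))
  names(genes) <- gene_ids
  gene_truth <- data.frame(gene_id = gene_ids,
                           chrom = vapply(genes, `[[`, "", "chromosome"),
                           strand = strands, n_introns = n_introns,
                           expression = expression,
                           stringsAsFactors = FALSE, row.names = NULL)
  list(genome = genome, genes = genes,
       expression = stats::setNames(expression, gene_ids),
       truth = list(genes = gene_truth,
                    introns = bind_rows_list(intron_truth)))
}

#' Write a simulated dataset to disk in the standard formats
#'
#' Emits exactly the formats the I/O layer reads: FASTA genome, GFF3
#' annotation, expression TSV, plus truth-table TSVs.
#'
#' @param sim Result of [simulate_genome()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fasta"),
             annotation = file.path(dir, "annotation.gff3"),
             expression = file.path(dir, "expression.tsv"),
             truth_genes = file.path(dir, "truth_genes.tsv"),
             truth_introns = file.path(dir, "truth_introns.tsv"))
  write_fasta(sim$genome, paths["genome"])
  write_gene_models_gff3(sim$genes, paths["annotation"])
  write_tsv_file(data.frame(gene_id = names(sim$expression),
                            expression = unname(sim$expression)),
                 paths["expression"])
  write_tsv_file(sim$truth$genes, paths["truth_genes"])
  if (!is.null(sim$truth$introns))
    write_tsv_file(sim$truth$introns, paths["truth_introns"])
  invisible(paths)
}

#' Plant sense-strand depletion of a segment stratum
#'
#' Emulates purifying selection: every sense-strand GT|AG segment of the
#' selected stratum is independently disrupted with probability `delta` by
#' a single point mutation -- the A of its GTA or the T of its TAG (chosen
#' at random) is changed to C -- so segment length distributions are
#' otherwise preserved. Antisense counts are untouched in expectation.
#'
#' @param sequences Character vector of exon (sense-strand) sequences.
#' @param delta Depletion probability in `[0, 1]`.
#' @param stratum List with `signal`, `mod3`, `size_range` selecting the
#'   depleted stratum (defaults: GTA|TAG, 3n, 21-30 nt).
#' @param params An [enumeration_params()] object.
#' @param seed Integer seed.
#' @return Edited character vector; the edit log (data.frame
#'   `seq_index`, `pos` 0-based, `from`, `to`) is attached as attribute
#'   `"edits"`.
#' @export
apply_strand_depletion <- function(sequences, delta,
                                   stratum = list(signal = "GTA|TAG",
                                                  mod3 = "3n",
                                                  size_range = c(21L, 30L)),
                                   params = enumeration_params(),
                                   seed = 1L) {
  if (delta < 0 || delta > 1) stop("delta must be in [0, 1]")
  set.seed(seed)
  edits <- list()
  out <- sequences
  for (i in seq_along(sequences)) {
    seg <- enumerate_gt_ag_segments(sequences[i], params, "sense")
    seg <- filter_segments(seg, signal = stratum$signal,
                           mod3 = stratum$mod3,
                           size_range = stratum$size_range)
    if (nrow(seg) == 0L) next
    hit <- stats::runif(nrow(seg)) < delta
    if (!any(hit)) next
    v <- strsplit(out[i], "")[[1]]
    for (k in which(hit)) {
      use_gta <- stats::runif(1) < 0.5
      pos0 <- if (use_gta) seg$start[k] + 2L else seg$end[k] - 3L
      if (v[pos0 + 1L] == "C") next   # already disrupted by an earlier edit
      edits[[length(edits) + 1L]] <- data.frame(
        seq_index = i, pos = pos0, from = v[pos0 + 1L], to = "C",
        stringsAsFactors = FALSE)
      v[pos0 + 1L] <- "C"
    }
    out[i] <- paste(v, collapse = "")
  }
  log_df <- bind_rows_list(edits)
  if (is.null(log_df))
    log_df <- data.frame(seq_index = integer(0), pos = integer(0),
                         from = character(0), to = character(0))
  attr(out, "edits") <- log_df
  out
}

#' Plant sense-strand depletion directly in a simulated genome
#'
#' Runs [apply_strand_depletion()] on the coding exons of a simulated
#' dataset and maps the edits back onto the chromosome sequences
#' (complementing edited bases for minus-strand genes), so the depletion
#' survives a round trip through the on-disk FASTA/GFF3 representation.
#'
#' @param sim Result of [simulate_genome()].
#' @param delta,stratum,params,seed As in [apply_strand_depletion()].
#' @return `sim` with an edited `genome` and the edit log in
#'   `sim$depletion_edits`.
#' @export
deplete_genome <- function(sim, delta,
                           stratum = list(signal = "GTA|TAG", mod3 = "3n",
                                          size_range = c(21L, 30L)),
                           params = enumeration_params(), seed = 1L) {
  exons <- extract_coding_exons(sim$genes, sim$genome)
  edited <- apply_strand_depletion(exons$sequence, delta, stratum, params,
                                   seed)
  edits <- attr(edited, "edits")
  if (nrow(edits) > 0L) {
    ex <- exons[edits$seq_index, , drop = FALSE]
    plus <- ex$strand == "+"
    gpos <- ifelse(plus, ex$start + edits$pos, ex$end - 1L - edits$pos)
    base <- ifelse(plus, edits$to, chartr("ACGT", "TGCA", edits$to))
    for (chrom in unique(ex$chrom)) {
      sel <- ex$chrom == chrom
      v <- strsplit(sim$genome[[chrom]], "")[[1]]
      v[gpos[sel] + 1L] <- base[sel]
      sim$genome[[chrom]] <- paste(v, collapse = "")
    }
  }
  sim$depletion_edits <- edits
  sim
}

#' Expected DSA under planted depletion
#'
#' Under equal baseline sense/antisense rates, removing a fraction `delta`
#' of sense-strand segments gives
#' `S = ((1 - delta) - 1) / ((1 - delta) + 1) = -delta / (2 - delta)`.
#'
#' @param delta Depletion probability in `[0, 1]`.
#' @return Expected DSA score.
#' @export
expected_dsa <- function(delta) {
  if (any(delta < 0 | delta > 1)) stop("delta must be in [0, 1]")
  -delta / (2 - delta)
}

#' Simulate junction and per-locus count tables at planted splicing levels
#'
#' Per locus, reads are drawn multinomially at the true (splicing,
#' retention, alternative-usage) levels at the given depth. Spliced reads
#' become a junction-table row at the locus boundaries; alternative reads
#' become a row sharing the donor with the acceptor shifted 3 nt
#' downstream; retained reads appear only in the count table.
#'
#' @param loci data.frame with columns `locus_id`, `chrom`, `start`, `end`,
#'   `level_spliced`, `level_retained`, `level_alt` (summing to 1 per
#'   locus), `depth`, and optionally `annotated` (logical, default FALSE).
#' @param seed Integer seed.
#' @return List with `counts` (locus_id, spliced, retained, alt),
#'   `junctions` (internal junction representation, see
#'   [read_junction_table()]) and `truth` (the input levels).
#' @export
simulate_junction_counts <- function(loci, seed = 1L) {
  lev <- cbind(loci$level_spliced, loci$level_retained, loci$level_alt)
  if (any(abs(rowSums(lev) - 1) > 1e-8))
    stop("per-locus levels must sum to 1")
  if (any(lev < 0)) stop("levels must be non-negative")
  set.seed(seed)
  counts <- t(vapply(seq_len(nrow(loci)), function(i)
    as.integer(stats::rmultinom(1L, loci$depth[i], lev[i, ])),
    integer(3)))
  count_df <- data.frame(locus_id = loci$locus_id,
                         spliced = counts[, 1L], retained = counts[, 2L],
                         alt = counts[, 3L], stringsAsFactors = FALSE)
  annotated <- if ("annotated" %in% names(loci)) loci$annotated
    else rep(FALSE, nrow(loci))
  jrows <- list()
  for (i in seq_len(nrow(loci))) {
    if (counts[i, 1L] > 0L)
      jrows[[length(jrows) + 1L]] <- data.frame(
        chrom = loci$chrom[i], donor = loci$start[i],
        acceptor = loci$end[i], strand = "+", motif = 1L,
        annotated = annotated[i], unique_reads = counts[i, 1L],
        multi_reads = 0L, overhang = 30L, stringsAsFactors = FALSE)
    if (counts[i, 3L] > 0L)
      jrows[[length(jrows) + 1L]] <- data.frame(
        chrom = loci$chrom[i], donor = loci$start[i],
        acceptor = loci$end[i] + 3L, strand = "+", motif = 1L,
        annotated = FALSE, unique_reads = counts[i, 3L],
        multi_reads = 0L, overhang = 30L, stringsAsFactors = FALSE)
  }
  junctions <- bind_rows_list(jrows)
  if (is.null(junctions))
    junctions <- data.frame(chrom = character(0), donor = integer(0),
                            acceptor = integer(0), strand = character(0),
                            motif = integer(0), annotated = logical(0),
                            unique_reads = integer(0),
                            multi_reads = integer(0), overhang = integer(0),
                            stringsAsFactors = FALSE)
  list(counts = count_df, junctions = junctions, truth = loci)
}
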