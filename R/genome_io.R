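# Reading and validating the standard formats the pipeline touches, and the
# gene-model container used throughout.
#
# All internal coordinates are 0-based half-open. GFF3 (1-based inclusive)
# and the STAR SJ.out.tab junction dialect (1-based inclusive intron
# coordinates) are converted at the boundary, in both directions.

#' Construct a gene model
#'
#' A `GeneModel` holds a gene's chromosome, strand, ordered CDS exon
#' intervals and (optionally) an expression value. It is the unit of
#' bootstrap resampling in the strand-asymmetry analysis. Exon intervals are
#' stored 0-based half-open in genomic order; transcription order is exposed
#' through [exons_tx()].
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome/scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of CDS exon intervals,
#'   0-based half-open, sorted by start, pairwise non-overlapping.
#' @param expression Non-negative expression value, or `NA`.
#' @return An object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, chromosome, strand, exons,
                       expression = NA_real_) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for gene ", gene_id)
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("gene ", gene_id, " has no CDS exons")
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("gene ", gene_id, ": exon end must exceed start")
  if (is.unsorted(exons[, 1L]))
    stop("gene ", gene_id, ": exons must be sorted by start")
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("gene ", gene_id, ": overlapping CDS exons")
  if (!is.na(expression) && expression < 0)
    stop("gene ", gene_id, ": negative expression value")
  structure(list(gene_id = gene_id, chromosome = chromosome,
                 strand = strand, exons = exons,
                 expression = as.numeric(expression)),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s%s): %d CDS exon(s), %d intron(s)\n",
              x$gene_id, x$chromosome, x$strand, nrow(x$exons),
              nrow(x$exons) - 1L))
  invisible(x)
}

#' Exons of a gene in transcription order
#'
#' @param gene A `GeneModel`.
#' @return Exon interval matrix ordered 5' to 3' along the transcript
#'   (genomically last exon first for minus-strand genes).
#' @export
exons_tx <- function(gene) {
  if (gene$strand == "-") gene$exons[rev(seq_len(nrow(gene$exons))), ,
                                     drop = FALSE]
  else gene$exons
}

#' Introns of a gene (genomic order)
#'
#' Introns are the gaps between consecutive CDS exons.
#'
#' @param gene A `GeneModel`.
#' @return Two-column matrix of 0-based half-open intron intervals in
#'   genomic order (zero rows for single-exon genes).
#' @export
gene_introns <- function(gene) {
  n <- nrow(gene$exons)
  if (n < 2L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = gene$exons[-n, 2L], end = gene$exons[-1L, 1L])
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercased sequences, one per record.
#'   Record ids are the first whitespace-delimited token of each header.
#'   Duplicate ids are an error; characters outside A/C/G/T/N trigger a
#'   warning but are passed through.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  if (any(grepl("[^ACGTN]", seqs)))
    warning("FASTA contains characters outside A/C/G/T/N; passed through")
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = 70L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 annotation (1-based inclusive coordinates) and returns one
#' [gene_model()] per gene, with coordinates converted to the internal
#' 0-based half-open convention. Only `CDS` features define exons; CDS rows
#' are attached to genes directly or through their parent mRNA. CDS features
#' whose parent gene cannot be resolved are skipped with a warning;
#' overlapping CDS within one gene is an error.
#'
#' @param path Path to a GFF3 file.
#' @param expression Optional named numeric vector (as returned by
#'   [read_expression_table()]) joined to genes by id.
#' @return List of `GeneModel` objects, named by gene id.
#' @export
read_gff3_gene_models <- function(path, expression = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else
    rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p)[1L]
           else NA_character_, character(1))
  } else rep(NA_character_, length(gr))

  gene_idx <- which(type == "gene")
  gene_ids <- ids[gene_idx]
  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  mrna_to_gene <- stats::setNames(parents[mrna_idx], ids[mrna_idx])

  cds_idx <- which(type == "CDS")
  cds_gene <- parents[cds_idx]
  via_mrna <- cds_gene %in% names(mrna_to_gene)
  cds_gene[via_mrna] <- mrna_to_gene[cds_gene[via_mrna]]
  known <- cds_gene %in% gene_ids
  if (any(!known)) {
    warning(sum(!known), " CDS feature(s) without a resolvable parent gene; ",
            "skipped")
    cds_idx <- cds_idx[known]
    cds_gene <- cds_gene[known]
  }
  if (length(cds_idx) == 0L) return(list())

  cds <- data.frame(
    gene_id = cds_gene,
    chrom = as.character(GenomicRanges::seqnames(gr))[cds_idx],
    start = GenomicRanges::start(gr)[cds_idx] - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr)[cds_idx],
    strand = as.character(GenomicRanges::strand(gr))[cds_idx],
    stringsAsFactors = FALSE)

  out <- lapply(split(cds, cds$gene_id), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (length(unique(d$chrom)) != 1L)
      stop("gene ", d$gene_id[1L], ": CDS on multiple chromosomes")
    if (length(unique(d$strand)) != 1L || !d$strand[1L] %in% c("+", "-"))
      stop("gene ", d$gene_id[1L], ": inconsistent or missing strand")
    expr <- if (!is.null(expression) && d$gene_id[1L] %in% names(expression))
      unname(expression[d$gene_id[1L]]) else NA_real_
    gene_model(d$gene_id[1L], d$chrom[1L], d$strand[1L],
               cbind(d$start, d$end), expression = expr)
  })
  out[order(names(out))]
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and CDS rows (1-based inclusive coordinates) such that
#' [read_gff3_gene_models()] reproduces the input intervals exactly.
#'
#' @param genes List of `GeneModel` objects.
#' @param path Output path.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    n <- nrow(g$exons)
    span <- c(min(g$exons[, 1L]), max(g$exons[, 2L]))
    ex <- exons_tx(g)
    lens <- ex[, 2L] - ex[, 1L]
    phase_tx <- (3L - cumsum(c(0L, lens[-n])) %% 3L) %% 3L
    phase <- if (g$strand == "-") rev(phase_tx) else phase_tx
    data.frame(
      chrom = g$chromosome,
      start = c(span[1L], span[1L], g$exons[, 1L]) + 1L,
      end = c(span[2L], span[2L], g$exons[, 2L]),
      strand = g$strand,
      type = c("gene", "mRNA", rep("CDS", n)),
      phase = c(NA_integer_, NA_integer_, phase),
      ID = c(g$gene_id, paste0(g$gene_id, ".t1"),
             paste0(g$gene_id, ".cds", seq_len(n))),
      Parent = c(NA_character_, g$gene_id, rep(paste0(g$gene_id, ".t1"), n)),
      stringsAsFactors = FALSE)
  })
  tab <- bind_rows_list(rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand)
  S4Vectors::mcols(gr)$type <- tab$type
  S4Vectors::mcols(gr)$phase <- tab$phase
  S4Vectors::mcols(gr)$ID <- tab$ID
  plist <- lapply(tab$Parent, function(p) if (is.na(p)) character(0) else p)
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(plist)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a splice-junction table (STAR SJ.out.tab dialect)
#'
#' The dialect has nine tab-separated columns: chromosome, intron first base
#' (1-based), intron last base (1-based), strand code (0 undefined, 1 `+`,
#' 2 `-`), motif code, annotated flag (0/1), unique-read count,
#' multimapping-read count, maximum overhang. Coordinates are converted to
#' the internal 0-based half-open convention: `donor` is the first intronic
#' base, `acceptor` one past the last.
#'
#' @param path Path to the junction table.
#' @param dialect Currently only `"star-sj"`.
#' @return data.frame with columns `chrom`, `donor`, `acceptor`, `strand`,
#'   `motif`, `annotated` (logical), `unique_reads`, `multi_reads`,
#'   `overhang`.
#' @export
read_junction_table <- function(path, dialect = "star-sj") {
  dialect <- match.arg(dialect, "star-sj")
  if (!file.exists(path)) stop("junction table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(chrom = character(0), donor = integer(0),
                      acceptor = integer(0), strand = character(0),
                      motif = integer(0), annotated = logical(0),
                      unique_reads = integer(0), multi_reads = integer(0),
                      overhang = integer(0), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed junction row at line ", which(nf != 9L)[1L],
         ": expected 9 tab-separated columns, found ", nf[nf != 9L][1L])
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, 2:9, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, ncol = 8L)
  if (anyNA(num))
    stop("malformed junction row at line ",
         which(apply(num, 1L, anyNA))[1L], ": non-numeric field")
  strand <- c("*", "+", "-")[num[, 3L] + 1L]
  if (anyNA(strand)) stop("invalid strand code in junction table")
  out <- data.frame(chrom = m[, 1L],
                    donor = as.integer(num[, 1L]) - 1L,
                    acceptor = as.integer(num[, 2L]),
                    strand = strand,
                    motif = as.integer(num[, 4L]),
                    annotated = num[, 5L] == 1,
                    unique_reads = as.integer(num[, 6L]),
                    multi_reads = as.integer(num[, 7L]),
                    overhang = as.integer(num[, 8L]),
                    stringsAsFactors = FALSE)
  if (any(out$acceptor <= out$donor))
    stop("junction with acceptor <= donor at line ",
         which(out$acceptor <= out$donor)[1L])
  if (any(out$unique_reads < 0))
    stop("negative unique-read count in junction table")
  out
}

#' Write a junction table in the STAR SJ.out.tab dialect
#'
#' Inverse of [read_junction_table()].
#'
#' @param junctions data.frame as returned by [read_junction_table()].
#' @param path Output path.
#' @export
write_junction_table <- function(junctions, path) {
  strand_code <- match(junctions$strand, c("*", "+", "-")) - 1L
  m <- cbind(junctions$chrom,
             junctions$donor + 1L,
             junctions$acceptor,
             strand_code,
             junctions$motif,
             as.integer(junctions$annotated),
             junctions$unique_reads,
             junctions$multi_reads,
             junctions$overhang)
  utils::write.table(m, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a gene expression table
#'
#' Two-column TSV (gene id, linear-scale expression value), with or without
#' a header line. Negative values and duplicated gene ids are errors. Zero
#' values are retained (they are excluded later from log2-based quartile
#' analyses, see [assign_expression_quartiles()]).
#'
#' @param path Path to the TSV.
#' @return Named numeric vector of expression values.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (ncol(raw) < 2L) stop("expression table must have two columns")
  # tolerate a header line
  if (is.na(suppressWarnings(as.numeric(raw[1L, 2L]))))
    raw <- raw[-1L, , drop = FALSE]
  vals <- suppressWarnings(as.numeric(raw[[2L]]))
  if (anyNA(vals)) stop("non-numeric expression value at row ",
                        which(is.na(vals))[1L])
  if (any(vals < 0)) stop("negative expression value for gene ",
                          raw[[1L]][which(vals < 0)[1L]])
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated gene id in expression table: ",
         ids[duplicated(ids)][1L])
  stats::setNames(vals, ids)
}
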