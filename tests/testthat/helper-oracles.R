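# Independent oracles and small fixture builders used across tests.

# Exhaustive O(L^2) oracle: every GT start crossed with every AG end whose
# total length falls in the size window. Kept deliberately naive and
# independent of the package's enumerator.
brute_force_segments <- function(seq, min_len = 15L, max_len = 40L) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  gts <- which(v[-n] == "G" & v[-1] == "T")          # 1-based start
  ags <- which(v[-n] == "A" & v[-1] == "G") + 1L     # 1-based end
  rows <- list()
  for (s in gts) {
    for (e in ags) {
      L <- e - s + 1L
      if (L >= min_len && L <= max_len)
        rows[[length(rows) + 1L]] <- c(start = s - 1L, end = e, length = L)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  df <- as.data.frame(do.call(rbind, rows))
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

random_dna_str <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# A small two-chromosome gene set with known structure, built in code.
# chrA: g1 plus-strand, exons [0,10) and [20,30) (intron [10,20));
#       g2 plus-strand single exon [40, 70).
# chrB: g3 minus-strand, exons [5,15) and [25,40).
tiny_gene_set <- function() {
  chrA <- paste0("GTAAGCCTAA", "GTATTTTTAG", "CCCCCCCCCC",
                 strrep("T", 10), random_dna_str(30), strrep("A", 10))
  chrB <- paste0(strrep("C", 5), random_dna_str(10), strrep("G", 10),
                 random_dna_str(15), strrep("T", 10))
  genes <- list(
    g1 = gene_model("g1", "chrA", "+", rbind(c(0L, 10L), c(20L, 30L)),
                    expression = 8),
    g2 = gene_model("g2", "chrA", "+", rbind(c(40L, 70L)), expression = 2),
    g3 = gene_model("g3", "chrB", "-", rbind(c(5L, 15L), c(25L, 40L)),
                    expression = 0.5))
  list(genome = c(chrA = chrA, chrB = chrB), genes = genes)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
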