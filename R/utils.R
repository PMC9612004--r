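# Internal helpers shared across modules.

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that works
#' on plain character vectors. Input must use the DNA alphabet (IUPAC codes
#' allowed).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' AT content of DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Numeric vector: fraction of A/T bases per sequence (NA for empty
#'   strings).
#' @export
at_content <- function(x) {
  n <- nchar(x)
  at <- nchar(gsub("[^ATat]", "", x))
  ifelse(n > 0L, at / n, NA_real_)
}

# Deterministic per-stage seed derived from a master seed. Kept below 2^31
# so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483587)
}

# Write a data.frame as TSV with a header line; stable byte-level output.
write_tsv_file <- function(df, path) {
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     na = "NA")
  invisible(path)
}

read_tsv_file <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# rbind a list of data.frames fast; returns a plain data.frame.
bind_rows_list <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (length(lst) == 0L) return(NULL)
  out <- data.table::rbindlist(lst)
  data.table::setDF(out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
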