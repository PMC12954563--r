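#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement matchPDict PDict startIndex
#' @importFrom IRanges IRanges reduce start end width
#' @importFrom stats rbinom rnbinom rnorm rpois runif rbeta setNames
#'   quantile prcomp wilcox.test sd median
#' @importFrom utils write.table read.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character strings. `N` maps to
#' `N`; any other symbol is an error.
#'
#' @param x character vector of DNA strings over \{A,C,G,T,N\}.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) stop("non-ACGTN symbol in DNA string")
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

## normalise a reference (named character vector / DNAStringSet / file path)
## to a named uppercase character vector
as_reference <- function(ref) {
  if (inherits(ref, "DNAStringSet")) {
    out <- as.character(ref)
  } else if (is.character(ref) && length(ref) == 1 && is.null(names(ref)) &&
             file.exists(ref)) {
    out <- as.character(readDNAStringSet(ref))
  } else if (is.character(ref)) {
    out <- ref
  } else {
    stop("reference must be a DNAStringSet, a named character vector or a FASTA path")
  }
  out <- toupper(out)
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    names(out) <- paste0("seq", seq_along(out))
  }
  if (anyDuplicated(names(out))) stop("duplicate sequence ids in reference")
  if (any(nchar(out) == 0)) stop("empty sequence in reference")
  out
}

#' Generate a random DNA string
#'
#' @param n length in bases.
#' @return a single character string over \{A,C,G,T\}.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}
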