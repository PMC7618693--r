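# Shared low-level helpers. Sequences are plain uppercase DNA character
# strings everywhere internally (T, not U); RNA spelling appears only at
# export.

#' Reverse complement of a DNA character string
#' @param x character vector of DNA strings (A/C/G/T)
#' @return character vector of reverse complements
#' @export
revcompDna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' DNA to RNA spelling (T -> U)
#' @param x character vector of DNA strings
#' @return the same sequences spelled with U
#' @export
dnaToRna <- function(x) chartr("T", "U", x)

#' Hamming distance between two equal-length strings
#' @param a,b character scalars of equal length
#' @return integer number of differing positions
#' @export
hammingDist <- function(a, b) {
  ia <- utf8ToInt(a); ib <- utf8ToInt(b)
  if (length(ia) != length(ib)) stop("hammingDist: unequal lengths")
  sum(ia != ib)
}

# Hamming distance of one string against a list of pre-encoded integer
# vectors (utf8ToInt); used in the selection inner loop.
hammingToEncoded <- function(x, encoded) {
  ix <- utf8ToInt(x)
  vapply(encoded, function(e) sum(ix != e), integer(1))
}

gcFraction <- function(x) {
  v <- strsplit(x, "", fixed = TRUE)
  vapply(v, function(ch) mean(ch %in% c("G", "C")), numeric(1))
}

maxHomopolymer <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    r <- rle(ch)
    max(r$lengths)
  }, integer(1))
}

assertDna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T}: %s", what,
                 paste(head(which(bad), 5), collapse = ", ")))
  }
  invisible(x)
}

# stage-count logging to stderr
logStage <- function(fmt, ...) {
  message(sprintf(paste0("[phyloAmiR] ", fmt), ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
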