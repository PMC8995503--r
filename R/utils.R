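# Internal sequence helpers.  The package works in DNA space (ACGT); the
# thermodynamic layer converts to RNA (T -> U) when an RNA parameter set is
# in force.

.DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")
.RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; accepts upper-case ACGT only.
#'
#' @param x character vector of DNA sequences (may include empty strings).
#' @return character vector of reverse complements.
#' @examples
#' revcomp("GCGGCCG")
#' @export
revcomp <- function(x) {
  assert_dna(x)
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# complement of a single-character vector, in the given alphabet
.comp_chars <- function(ch, kind = c("DNA", "RNA")) {
  kind <- match.arg(kind)
  tab <- if (kind == "DNA") .DNA_COMP else .RNA_COMP
  out <- unname(tab[ch])
  if (anyNA(out)) stop("invalid base in sequence: ",
                       paste(unique(ch[is.na(out)]), collapse = ", "))
  out
}

assert_dna <- function(x, what = "sequence") {
  if (!is.character(x)) stop(what, " must be a character vector")
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("invalid ", what, ": non-ACGT characters in ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  }
  invisible(x)
}

# split a single string into a character vector of bases
.chars <- function(s) strsplit(s, "")[[1]]

# Watson-Crick check for a 2-character pair code in DNA or RNA space
.is_wc <- function(pair, kind = c("DNA", "RNA")) {
  kind <- match.arg(kind)
  wc <- if (kind == "DNA") c("AT", "TA", "GC", "CG") else c("AU", "UA", "GC", "CG")
  pair %in% wc
}

# convert DNA-space strings/pair codes into the model alphabet
.to_alphabet <- function(x, kind) {
  if (kind == "RNA") chartr("T", "U", x) else chartr("U", "T", x)
}
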