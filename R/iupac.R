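# IUPAC nucleotide ambiguity handling for degenerate-primer matching.

# allowed plain bases for each IUPAC symbol
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_ALPHABET <- names(IUPAC_SETS)

# 15 x 4 logical lookup: does IUPAC symbol (row) admit plain base (col)?
.iupac_admits <- local({
  m <- matrix(FALSE, nrow = length(IUPAC_SETS), ncol = 4,
              dimnames = list(names(IUPAC_SETS), c("A", "C", "G", "T")))
  for (s in names(IUPAC_SETS)) m[s, IUPAC_SETS[[s]]] <- TRUE
  m
})

.check_acgt <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  if (nchar(x) > 0L && grepl("[^ACGT]", x))
    stop(what, " contains characters outside A/C/G/T", call. = FALSE)
  invisible(x)
}

.check_iupac <- function(x, what = "primer") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(what, " must be a non-empty character string", call. = FALSE)
  if (grepl(sprintf("[^%s]", paste(IUPAC_ALPHABET, collapse = "")), x))
    stop(what, " contains characters outside the IUPAC nucleotide alphabet",
         call. = FALSE)
  invisible(x)
}

#' Match a degenerate primer window against a plain-base target window
#'
#' Position-wise comparison of an IUPAC degenerate primer window with an
#' A/C/G/T target window of the same length. A position mismatches when the
#' target base is outside the set of bases admitted by the primer's IUPAC
#' symbol (e.g. `R` admits A and G).
#'
#' @param primer_window IUPAC string (may contain ambiguity codes).
#' @param target_window plain A/C/G/T string of the same length.
#' @param max_mismatch maximum number of mismatching positions tolerated.
#'
#' @return `TRUE` when the number of mismatching positions is at most
#'   `max_mismatch`, otherwise `FALSE`.
#'
#' @examples
#' iupac_match("AR", "AG") # TRUE: R admits G
#' iupac_match("AR", "AC") # FALSE
#' @export
iupac_match <- function(primer_window, target_window, max_mismatch = 0L) {
  .check_iupac(primer_window, "primer_window")
  .check_acgt(target_window, "target_window")
  if (nchar(primer_window) != nchar(target_window))
    stop("primer and target windows must have equal length", call. = FALSE)
  p <- strsplit(primer_window, "", fixed = TRUE)[[1L]]
  t <- strsplit(target_window, "", fixed = TRUE)[[1L]]
  mism <- sum(!.iupac_admits[cbind(p, t)])
  mism <= max_mismatch
}

#' Reverse complement of an IUPAC (possibly degenerate) sequence
#'
#' Degenerate symbols are complemented symbol-wise (R to Y, K to M, ...).
#'
#' @param x IUPAC nucleotide string.
#' @return the reverse-complemented string.
#' @examples
#' revcomp("TTRGGCTKAGGAATCKCT")
#' @export
revcomp <- function(x) {
  .check_iupac(x, "sequence")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
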