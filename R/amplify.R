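# Virtual PCR with degenerate primers and Class I / Class II calling.

#' Kinase-domain classification primers
#'
#' Returns the packaged degenerate primer set targeting the SRK kinase
#' domain (exons 4-7): the Class I pair KD(I)-F/R (expected product about
#' 1200 bp) and the Class II pair KD4/KD7 (about 1000 bp). The set is read
#' from a TSV under `inst/extdata/` and can be swapped for any other primer
#' system with the same columns.
#'
#' @param path optional path to an alternative primer TSV with columns
#'   `name`, `si_class`, `role`, `sequence`, `expected_length`.
#' @return data frame of primers, one row per oligo.
#' @export
kd_primers <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "kd_primers.tsv", package = "stype",
                        mustWork = TRUE)
  pr <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("name", "si_class", "role", "sequence",
                  "expected_length") %in% names(pr)))
  for (s in pr$sequence) .check_iupac(s, "primer sequence")
  pr
}

#' Build a primer pair from a primer table
#'
#' @param primers primer data frame as returned by [kd_primers()].
#' @param si_class `"class_I"` or `"class_II"`.
#' @return list with `forward`, `reverse` (one-row data frames),
#'   `expected_length`, `si_class` and `pair_name`.
#' @export
primer_pair <- function(primers, si_class = c("class_I", "class_II")) {
  si_class <- match.arg(si_class)
  sel <- primers[primers$si_class == si_class, , drop = FALSE]
  fwd <- sel[sel$role == "forward", , drop = FALSE]
  rev <- sel[sel$role == "reverse", , drop = FALSE]
  if (nrow(fwd) != 1L || nrow(rev) != 1L)
    stop("primer table must contain exactly one forward and one reverse ",
         si_class, " primer", call. = FALSE)
  list(forward = fwd, reverse = rev,
       expected_length = fwd$expected_length,
       si_class = si_class,
       pair_name = paste(fwd$name, rev$name, sep = "/"))
}

#' Find binding sites of a degenerate primer on a template
#'
#' Forward-role primers are matched on the top strand as written; reverse-
#' role primers are matched where the top strand contains the primer's
#' reverse complement (degenerate codes complemented symbol-wise). With
#' `max_mismatch > 0` the three bases at the primer's 3' end must still
#' match exactly, since polymerase extension requires a paired 3' terminus.
#'
#' @param primer IUPAC primer sequence (character).
#' @param template plain A/C/G/T template string.
#' @param role `"forward"` or `"reverse"`.
#' @param max_mismatch mismatches tolerated outside the 3'-terminal 3 bases.
#' @return data frame with `offset` (0-based top-strand offset of the
#'   matched window) and `strand` (`"top"`/`"bottom"`), ascending by offset.
#' @export
find_binding_sites <- function(primer, template,
                               role = c("forward", "reverse"),
                               max_mismatch = 0L) {
  role <- match.arg(role)
  .check_iupac(primer, "primer")
  .check_acgt(template, "template")
  if (nchar(template) < nchar(primer))
    return(data.frame(offset = integer(), strand = character()))
  pat <- if (role == "forward") primer else revcomp(primer)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                   Biostrings::DNAString(template),
                                   max.mismatch = max_mismatch,
                                   fixed = c(pattern = FALSE, subject = TRUE))
  off <- BiocGenerics::start(hits) - 1L
  if (max_mismatch > 0L && length(off)) {
    # exact-match constraint on the 3'-terminal 3 bases
    k <- min(3L, nchar(primer))
    keep <- vapply(off, function(o) {
      win <- substr(template, o + 1L, o + nchar(pat))
      if (role == "forward")
        iupac_match(substr(pat, nchar(pat) - k + 1L, nchar(pat)),
                    substr(win, nchar(win) - k + 1L, nchar(win)), 0L)
      else
        # on the top strand the reverse primer's 3' end is the window start
        iupac_match(substr(pat, 1L, k), substr(win, 1L, k), 0L)
    }, logical(1))
    off <- off[keep]
  }
  data.frame(offset = sort(off),
             strand = rep(if (role == "forward") "top" else "bottom",
                          length(off)),
             stringsAsFactors = FALSE)
}

#' Predict PCR products of a primer pair on a template
#'
#' Pairs every forward binding site with every downstream reverse binding
#' site whose product length falls inside `size_window`, emitting one
#' amplicon per admissible pairing. PCR is strand-symmetric, so both
#' orientations are enumerated: the forward primer priming the top strand
#' with the reverse primer downstream on the bottom strand
#' (`orientation = "FR"`), and the mirror arrangement with the reverse
#' primer on the top strand (`"RF"`). Pairings in which the primer
#' footprints would overlap are discarded as physically unamplifiable.
#' Coordinates are 0-based half-open on the top strand.
#'
#' @param template plain A/C/G/T template string.
#' @param pair primer pair from [primer_pair()].
#' @param size_window length-2 numeric `(min, max)` of admissible product
#'   lengths; default is the pair's expected length +/- 20%.
#' @param max_mismatch per-primer mismatch tolerance (see
#'   [find_binding_sites()]).
#' @param template_id identifier recorded in the output.
#' @return data frame of amplicons (`template_id`, `pair_name`, `start`,
#'   `end`, `length`, `orientation`), sorted by (start, end); zero rows
#'   when no product.
#' @export
virtual_pcr <- function(template, pair, size_window = NULL,
                        max_mismatch = 0L, template_id = "template") {
  .check_acgt(template, "template")
  if (is.null(size_window))
    size_window <- c(floor(0.8 * pair$expected_length),
                     ceiling(1.2 * pair$expected_length))
  stopifnot(length(size_window) == 2L, size_window[1L] <= size_window[2L])
  len_f <- nchar(pair$forward$sequence)
  len_r <- nchar(pair$reverse$sequence)
  empty <- data.frame(template_id = character(), pair_name = character(),
                      start = integer(), end = integer(),
                      length = integer(), orientation = character())
  pair_sites <- function(starts, ends_excl, len5, len3, orientation) {
    out <- list()
    for (f in starts) for (r in ends_excl) {
      if (r - f < size_window[1L] || r - f > size_window[2L]) next
      if (r - f <= len5 + len3) next # overlapping footprints
      out[[length(out) + 1L]] <- data.frame(
        template_id = template_id, pair_name = pair$pair_name,
        start = f, end = r, length = r - f, orientation = orientation,
        stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else empty
  }
  # orientation FR: forward primer on the top strand, reverse downstream
  fw_top <- find_binding_sites(pair$forward$sequence, template, "forward",
                               max_mismatch)
  rv_bot <- find_binding_sites(pair$reverse$sequence, template, "reverse",
                               max_mismatch)
  amp <- pair_sites(fw_top$offset, rv_bot$offset + len_r, len_f, len_r,
                    "FR")
  # orientation RF: the mirror product (reverse primer priming the top
  # strand, forward primer on the bottom strand)
  rv_top <- find_binding_sites(pair$reverse$sequence, template, "forward",
                               max_mismatch)
  fw_bot <- find_binding_sites(pair$forward$sequence, template, "reverse",
                               max_mismatch)
  amp <- rbind(amp, pair_sites(rv_top$offset, fw_bot$offset + len_f,
                               len_r, len_f, "RF"))
  if (nrow(amp) == 0L) return(empty)
  amp <- amp[!duplicated(amp[, c("start", "end")]), , drop = FALSE]
  amp <- amp[order(amp$start, amp$end), ]
  rownames(amp) <- NULL
  amp
}

#' Extract the top-strand sequence of an amplicon
#'
#' @param template template string the amplicon was predicted on.
#' @param amplicon one row of a [virtual_pcr()] result.
#' @return the amplicon sequence (character).
#' @export
amplicon_sequence <- function(template, amplicon) {
  substr(template, amplicon$start + 1L, amplicon$end)
}

#' Call the self-incompatibility class of a genotype from its PCR products
#'
#' Both primer pairs productive: Class I/II heterozygote; only the Class I
#' pair: Class I; only the Class II pair: Class II; neither: no call.
#'
#' @param genotype_id identifier.
#' @param class_I_products,class_II_products amplicon data frames from
#'   [virtual_pcr()] with the Class I and Class II pairs.
#' @return data frame with `genotype_id` and `call` (one of `"class_I"`,
#'   `"class_II"`, `"class_I_II"`, `"none"`).
#' @export
call_class <- function(genotype_id, class_I_products, class_II_products) {
  has1 <- nrow(class_I_products) > 0L
  has2 <- nrow(class_II_products) > 0L
  call <- if (has1 && has2) "class_I_II"
          else if (has1) "class_I"
          else if (has2) "class_II"
          else "none"
  data.frame(genotype_id = genotype_id, call = call, stringsAsFactors = FALSE)
}
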