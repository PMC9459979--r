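# Identity-based S-haplotype assignment against a reference panel,
# novel-allele flagging, and frequency tabulation.

.SUBMAT <- NULL # memoised +1/-1 nucleotide substitution matrix

.submat <- function() {
  if (is.null(.SUBMAT))
    utils::assignInMyNamespace(".SUBMAT",
      Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1))
  .SUBMAT
}

#' Percent identity between two nucleotide sequences
#'
#' Global (Needleman-Wunsch) alignment with match +1, mismatch -1 and a
#' linear gap cost of 2 per base; identity is 100 x matches / aligned
#' columns, where columns consisting of a terminal gap (an unaligned
#' overhang of either sequence) are excluded from the denominator. The
#' measure is symmetric and is 100 for identical sequences.
#'
#' @param a,b non-empty A/C/G/T strings.
#' @return percent identity in `[0, 100]`.
#' @examples
#' percent_identity("ACGT", "ACGT") # 100
#' percent_identity("ACGT", "ACGA") # 75
#' @export
percent_identity <- function(a, b) {
  .check_acgt(a, "a"); .check_acgt(b, "b")
  .identity_batch(a, b)[1L]
}

# identity of one query against many references in a single alignment
# call; the alignment's match/mismatch/indel tallies cover exactly the
# non-terminal-gap columns, so identity = matches / (matches + mismatches
# + internal gap columns)
.identity_batch <- function(query, refs) {
  if (nchar(query) == 0L || any(nchar(refs) == 0L))
    stop("sequences must be non-empty", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(refs), Biostrings::DNAString(query),
    type = "global", substitutionMatrix = .submat(),
    gapOpening = 0, gapExtension = 2)
  nm <- Biostrings::nmatch(aln)
  cols <- nm + Biostrings::nmismatch(aln) +
    sum(BiocGenerics::width(Biostrings::insertion(aln))) +
    sum(BiocGenerics::width(Biostrings::deletion(aln)))
  ifelse(cols == 0L, 0, 100 * nm / cols)
}

#' Assign a query sequence to its S haplotype
#'
#' Computes percent identity of the query to every reference in the panel.
#' The call is `known` when the best identity reaches `threshold`, `novel`
#' when every reference falls below it, and `ambiguous` when references of
#' two different unified haplotypes tie at the maximum within
#' `ambiguity_margin` percentage points.
#'
#' @param query plain A/C/G/T query sequence.
#' @param panel data frame of references with columns `nau_name`,
#'   `si_class`, `sequence`.
#' @param threshold same-haplotype identity threshold in percent
#'   (default 98.5, just below the smallest published within-haplotype
#'   similarity of 98.7%).
#' @param query_id identifier carried into the call.
#' @param ambiguity_margin tie margin in percentage points (default 0.1).
#' @return data frame (one row) with `query_id`, `best_hit`,
#'   `identity_pct`, `status`.
#' @export
assign_haplotype <- function(query, panel, threshold = 98.5,
                             query_id = "query", ambiguity_margin = 0.1) {
  if (!is.data.frame(panel) || nrow(panel) == 0L)
    stop("reference panel is empty", call. = FALSE)
  .check_acgt(query, "query")
  ids <- .identity_batch(query, panel$sequence)
  best <- which.max(ids)
  tied <- unique(panel$nau_name[ids >= ids[best] - ambiguity_margin])
  status <- if (ids[best] < threshold) "novel"
            else if (length(tied) > 1L) "ambiguous"
            else "known"
  data.frame(query_id = query_id,
             best_hit = if (status == "novel") NA_character_
                        else panel$nau_name[best],
             identity_pct = ids[best], status = status,
             stringsAsFactors = FALSE)
}

# half-up rounding to 2 decimals (printed-table convention)
.round2 <- function(x) floor(x * 100 + 0.5) / 100

#' Tabulate S-haplotype frequencies
#'
#' @param calls data frame of resolved calls with a `nau_name` column (use
#'   the `best_hit` of known calls or the registered name of novel ones);
#'   any `NA` entry is an unresolved call and an error.
#' @return data frame (`nau_name`, `occurrences`, `frequency_pct`) sorted
#'   by descending occurrences then name, with attribute `denominator`.
#'   Frequencies are percentages rounded half-up to 2 decimals.
#' @export
tally_frequencies <- function(calls) {
  stopifnot(is.data.frame(calls), "nau_name" %in% names(calls))
  if (anyNA(calls$nau_name))
    stop("unresolved calls present: register or drop them first",
         call. = FALSE)
  if (nrow(calls) == 0L) {
    out <- data.frame(nau_name = character(), occurrences = integer(),
                      frequency_pct = numeric())
    attr(out, "denominator") <- 0L
    return(out)
  }
  counts <- table(calls$nau_name)
  out <- data.frame(nau_name = names(counts),
                    occurrences = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$frequency_pct <- .round2(100 * out$occurrences / nrow(calls))
  out <- out[order(-out$occurrences, out$nau_name), ]
  rownames(out) <- NULL
  attr(out, "denominator") <- nrow(calls)
  out
}

#' Resolve a Class I/II heterozygote from its two per-class calls
#'
#' @param genotype_id identifier.
#' @param class_I_call,class_II_call one-row call data frames from
#'   [assign_haplotype()] (or with a registered novel name in `best_hit`);
#'   both must be resolved, and the two haplotypes must differ.
#' @return an `s_genotype` (see [s_genotype()]) with one haplotype per
#'   class.
#' @export
heterozygote_resolve <- function(genotype_id, class_I_call, class_II_call) {
  for (cl in list(class_I_call, class_II_call))
    if (is.na(cl$best_hit) || cl$status == "ambiguous")
      stop("unresolved call for genotype ", genotype_id, call. = FALSE)
  if (class_I_call$best_hit == class_II_call$best_hit)
    stop("genotype ", genotype_id,
         ": a Class I/II heterozygote cannot carry one haplotype twice",
         call. = FALSE)
  s_genotype(genotype_id,
             nau_names = c(class_I_call$best_hit, class_II_call$best_hit),
             si_classes = c("class_I", "class_II"))
}
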