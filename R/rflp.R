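# In-silico restriction digestion, gel band-pattern simulation and
# profile matching (PCR-RFLP of Class I amplicons).

#' Packaged restriction enzyme definitions
#'
#' HinfI (recognition `GANTC`, top-strand cut after the G) is the enzyme
#' used throughout; the TSV under `inst/extdata/` makes other enzymes
#' pluggable.
#'
#' @param name enzyme name to select, or `NULL` for the full table.
#' @param path optional alternative TSV (`name`, `recognition`,
#'   `cut_offset`).
#' @return one-row data frame (when `name` given) or the full table.
#' @export
restriction_enzyme <- function(name = "HinfI", path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "enzymes.tsv", package = "stype",
                        mustWork = TRUE)
  enz <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("name", "recognition", "cut_offset") %in% names(enz)))
  if (is.null(name)) return(enz)
  hit <- enz[enz$name == name, , drop = FALSE]
  if (nrow(hit) != 1L) stop("unknown enzyme: ", name, call. = FALSE)
  if (hit$cut_offset < 0 || hit$cut_offset > nchar(hit$recognition))
    stop("cut_offset outside the recognition window", call. = FALSE)
  hit
}

#' Find restriction cut positions on the top strand
#'
#' Scans the sequence for the enzyme's (possibly degenerate) recognition
#' window and reports top-strand cut positions (window offset plus the
#' enzyme's cut offset), ascending and deduplicated. A single-strand scan
#' suffices for palindromic sites such as HinfI's `GANTC`, which is its own
#' reverse complement. Cuts falling on the sequence boundary are dropped
#' since they release no fragment.
#'
#' @param sequence plain A/C/G/T string.
#' @param enzyme one-row enzyme data frame from [restriction_enzyme()].
#' @return integer vector of 0-based cut positions.
#' @export
find_cut_sites <- function(sequence, enzyme = restriction_enzyme("HinfI")) {
  .check_acgt(sequence, "sequence")
  if (nchar(sequence) < nchar(enzyme$recognition)) return(integer())
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(enzyme$recognition),
    Biostrings::DNAString(sequence),
    fixed = c(pattern = FALSE, subject = TRUE))
  cuts <- sort(unique(BiocGenerics::start(hits) - 1L + enzyme$cut_offset))
  cuts[cuts > 0L & cuts < nchar(sequence)]
}

#' Digest a sequence into restriction fragments
#'
#' @inheritParams find_cut_sites
#' @param source_id identifier carried into the result.
#' @return object of class `fragment_set`: list with `source_id` and
#'   `fragment_lengths` (5' to 3' along the top strand; sums to the
#'   sequence length; one more fragment than cut sites).
#' @export
digest_sequence <- function(sequence, enzyme = restriction_enzyme("HinfI"),
                            source_id = "sequence") {
  cuts <- find_cut_sites(sequence, enzyme)
  structure(list(source_id = source_id,
                 fragment_lengths = diff(c(0L, cuts, nchar(sequence)))),
            class = "fragment_set")
}

#' Simulate the gel band pattern of a fragment set
#'
#' Models a resolution-limited gel lane: fragments below the detection
#' limit are dropped, the rest are sorted by decreasing length, and
#' fragments within `resolution_pct` percent of the current band's length
#' are merged into it (the band keeps the longest member's length), as
#' co-migrating fragments are indistinguishable on a gel.
#'
#' @param fragments a `fragment_set` from [digest_sequence()], or a numeric
#'   vector of fragment lengths.
#' @param resolution_pct relative co-migration tolerance in percent
#'   (default 2, the approximate resolving power of 6% PAGE with silver
#'   staining).
#' @param min_detect smallest visible fragment in nucleotides (default 50;
#'   shorter fragments run off the gel).
#' @return object of class `gel_profile`: list with `bands` (strictly
#'   descending lengths), `resolution_pct`, `min_detect`.
#' @export
gel_profile <- function(fragments, resolution_pct = 2, min_detect = 50) {
  stopifnot(resolution_pct >= 0, min_detect >= 1)
  lens <- if (inherits(fragments, "fragment_set"))
    fragments$fragment_lengths else fragments
  lens <- sort(lens[lens >= min_detect], decreasing = TRUE)
  bands <- numeric()
  for (l in lens) {
    if (length(bands) == 0L ||
        (bands[length(bands)] - l) / bands[length(bands)] * 100 > resolution_pct)
      bands <- c(bands, l)
    # else: co-migrates with the current (longer) band; absorbed
  }
  structure(list(bands = bands, resolution_pct = resolution_pct,
                 min_detect = min_detect),
            class = "gel_profile")
}

#' @export
print.gel_profile <- function(x, ...) {
  cat("gel profile:", if (length(x$bands)) paste(x$bands, collapse = ", ")
      else "(no visible band)",
      sprintf("[resolution %.3g%%, min %d nt]\n", x$resolution_pct,
              as.integer(x$min_detect)))
  invisible(x)
}

#' Are two gel profiles indistinguishable?
#'
#' Profiles match when they show the same number of bands and each
#' corresponding band pair differs by at most the co-migration tolerance.
#' Comparing profiles taken under different gel settings is an error.
#'
#' @param a,b `gel_profile` objects with identical settings.
#' @return `TRUE` or `FALSE`.
#' @export
profiles_equal <- function(a, b) {
  stopifnot(inherits(a, "gel_profile"), inherits(b, "gel_profile"))
  if (a$resolution_pct != b$resolution_pct || a$min_detect != b$min_detect)
    stop("profiles were taken under different gel settings", call. = FALSE)
  if (length(a$bands) != length(b$bands)) return(FALSE)
  if (length(a$bands) == 0L) return(TRUE)
  rel <- abs(a$bands - b$bands) / pmax(a$bands, b$bands) * 100
  all(rel <= a$resolution_pct)
}

#' Group amplicons by gel profile
#'
#' Digests every amplicon, builds its gel profile, and groups profiles by
#' indistinguishability. Because band-level equality is not transitive at
#' tolerance boundaries, grouping uses single-linkage (connected components
#' of the pairwise-equality graph), which is deterministic and independent
#' of input order; profile ids are numbered by first appearance.
#'
#' @param panel data frame with columns `genotype_id` and `sequence`
#'   (amplicon top-strand sequences).
#' @inheritParams gel_profile
#' @param enzyme enzyme definition from [restriction_enzyme()].
#' @return list with `n_profiles` (distinct profile count), `assignments`
#'   (data frame `genotype_id`, `profile_id`) and `profiles` (list of
#'   `gel_profile`, one representative per id).
#' @export
profile_table <- function(panel, enzyme = restriction_enzyme("HinfI"),
                          resolution_pct = 2, min_detect = 50) {
  stopifnot(is.data.frame(panel),
            all(c("genotype_id", "sequence") %in% names(panel)))
  n <- nrow(panel)
  if (n == 0L)
    return(list(n_profiles = 0L,
                assignments = data.frame(genotype_id = character(),
                                         profile_id = integer()),
                profiles = list()))
  profs <- lapply(seq_len(n), function(i)
    gel_profile(digest_sequence(panel$sequence[i], enzyme,
                                panel$genotype_id[i]),
                resolution_pct, min_detect))
  edges <- list()
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    if (profiles_equal(profs[[i]], profs[[j]]))
      edges[[length(edges) + 1L]] <- c(i, j)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, unlist(edges))
  comp <- igraph::components(g)$membership
  # renumber components by first appearance in the input
  id_map <- stats::setNames(seq_along(unique(comp)), unique(comp))
  profile_id <- unname(id_map[as.character(comp)])
  reps <- profs[match(seq_along(id_map), profile_id)]
  list(n_profiles = length(id_map),
       assignments = data.frame(genotype_id = panel$genotype_id,
                                profile_id = profile_id,
                                stringsAsFactors = FALSE),
       profiles = reps)
}
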