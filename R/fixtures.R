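# Accessors for the packaged example data.

#' Path to a packaged example file
#'
#' @param file file name under the package's `extdata` directory; `NULL`
#'   lists the available files.
#' @return a file path (or a character vector of file names).
#' @export
stype_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "stype")))
  system.file("extdata", file, package = "stype", mustWork = TRUE)
}

#' The published radish S-haplotype registry
#'
#' Loads the packaged alias cross-reference of all published radish
#' S-haplotype names (four naming schools: Okamoto, Lim, Kim D and other
#' groups) and unifies it into the non-redundant `NAU-S` registry of 52
#' classes.
#'
#' @return an `s_registry` (see [unify_haplotypes()]).
#' @examples
#' reg <- radish_registry()
#' reg$n_classes
#' s_lookup(reg, "okamoto", "S30")
#' @export
radish_registry <- function() {
  unify_haplotypes(load_alias_table(stype_example("radish_s_aliases.tsv")))
}

#' Published pollination trials
#'
#' The packaged table of field pollination trials among typed radish lines:
#' reciprocal and one-way crosses within and between S haplotypes plus
#' selfed controls, with the published compatibility index, pod setting
#' rate and printed compatibility label for each combination. Raw
#' flower/pod/seed counts were not published, so this table carries the
#' derived quantities.
#'
#' @return data frame with one row per pollination combination.
#' @export
pollination_trials <- function() {
  utils::read.delim(stype_example("radish_pollination_trials.tsv"),
                    stringsAsFactors = FALSE)
}

#' Build homozygous-line genotypes and predictions for pollination trials
#'
#' Interprets the haplotype annotations of a pollination-trial table (all
#' parents are Class I homozygous lines) and predicts each cross from
#' shared expressed haplotypes.
#'
#' @param trials data frame from [pollination_trials()] (columns
#'   `female_id`, `male_id`, `female_haplotypes`, `male_haplotypes`).
#' @return data frame of predictions, one row per trial (see
#'   [predict_cross()]).
#' @export
predict_trials <- function(trials) {
  do.call(rbind, lapply(seq_len(nrow(trials)), function(i) {
    f_h <- strsplit(trials$female_haplotypes[i], ",", fixed = TRUE)[[1L]]
    m_h <- strsplit(trials$male_haplotypes[i], ",", fixed = TRUE)[[1L]]
    f <- s_genotype(trials$female_id[i], f_h, rep("class_I", length(f_h)))
    m <- s_genotype(trials$male_id[i], m_h, rep("class_I", length(m_h)))
    predict_cross(f, m, "flower")
  }))
}
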