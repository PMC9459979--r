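# Sporophytic self-incompatibility genetics: expressed-haplotype dominance,
# cross prediction, compatibility index and concordance scoring.

#' Construct a diploid S-locus genotype
#'
#' @param genotype_id identifier.
#' @param nau_names one (homozygote) or two (heterozygote, distinct) unified
#'   haplotype names.
#' @param si_classes matching vector of `"class_I"` / `"class_II"` labels.
#' @return object of class `s_genotype`.
#' @export
s_genotype <- function(genotype_id, nau_names, si_classes) {
  stopifnot(length(nau_names) %in% 1:2,
            length(si_classes) == length(nau_names),
            all(si_classes %in% c("class_I", "class_II")))
  if (length(nau_names) == 2L && nau_names[1L] == nau_names[2L])
    stop("a heterozygote must carry two distinct haplotypes", call. = FALSE)
  structure(list(genotype_id = genotype_id,
                 haplotypes = data.frame(nau_name = nau_names,
                                         si_class = si_classes,
                                         stringsAsFactors = FALSE)),
            class = "s_genotype")
}

#' @export
print.s_genotype <- function(x, ...) {
  cat(x$genotype_id, "{",
      paste(sprintf("%s (%s)", x$haplotypes$nau_name,
                    sub("class_", "", x$haplotypes$si_class)),
            collapse = ", "), "}\n")
  invisible(x)
}

#' Haplotypes phenotypically expressed by a genotype
#'
#' Applies the Class I over Class II dominance model of sporophytic
#' self-incompatibility, identically on the stigma and pollen sides:
#' homozygotes express their single haplotype; Class I / Class I and
#' Class II / Class II heterozygotes express both (co-dominance); a
#' Class I / Class II heterozygote expresses only its Class I haplotype.
#'
#' @param g an `s_genotype`.
#' @return character vector of expressed `NAU-S` names (never empty).
#' @export
expressed_haplotypes <- function(g) {
  stopifnot(inherits(g, "s_genotype"))
  h <- g$haplotypes
  if (nrow(h) == 1L || length(unique(h$si_class)) == 1L) return(h$nau_name)
  h$nau_name[h$si_class == "class_I"]
}

#' Predict the compatibility of a cross
#'
#' At the flowering stage a cross is incompatible when the two parents share
#' at least one expressed S haplotype (the shared haplotype triggers pollen
#' rejection on the stigma); the prediction is symmetric in the parents.
#' Bud-stage pollination bypasses the self-incompatibility response and is
#' always compatible.
#'
#' @param female,male `s_genotype` objects.
#' @param stage `"flower"` or `"bud"`.
#' @return data frame with `female_id`, `male_id`, `stage`, `predicted`
#'   (`"incompatible"`/`"compatible"`) and `shared_expressed`
#'   (comma-collapsed shared haplotypes, `""` when none).
#' @export
predict_cross <- function(female, male, stage = c("flower", "bud")) {
  stage <- match.arg(stage)
  stopifnot(inherits(female, "s_genotype"), inherits(male, "s_genotype"))
  shared <- intersect(expressed_haplotypes(female),
                      expressed_haplotypes(male))
  predicted <- if (stage == "bud") "compatible"
               else if (length(shared)) "incompatible" else "compatible"
  data.frame(female_id = female$genotype_id, male_id = male$genotype_id,
             stage = stage, predicted = predicted,
             shared_expressed = paste(sort(shared), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Compatibility index of a pollination test
#'
#' Seeds per pollinated flower.
#'
#' @param n_seeds,n_flowers counts; `n_flowers` must be at least 1.
#' @return the index (numeric, >= 0).
#' @export
compatibility_index <- function(n_seeds, n_flowers) {
  stopifnot(all(n_seeds >= 0))
  if (any(n_flowers < 1)) stop("n_flowers must be >= 1", call. = FALSE)
  n_seeds / n_flowers
}

#' Pod setting rate of a pollination test
#'
#' Pods per pollinated flower, as a percentage.
#'
#' @param n_pods,n_flowers counts; pods cannot exceed flowers.
#' @return percentage in `[0, 100]`.
#' @export
pod_rate <- function(n_pods, n_flowers) {
  if (any(n_flowers < 1)) stop("n_flowers must be >= 1", call. = FALSE)
  if (any(n_pods > n_flowers))
    stop("n_pods cannot exceed n_flowers", call. = FALSE)
  100 * n_pods / n_flowers
}

#' Classify a compatibility index
#'
#' Field-pollination convention: an index below 0.5 indicates strong
#' self-incompatibility, above 2.0 compatibility, and the closed interval
#' `[0.5, 2.0]` weak self-incompatibility.
#'
#' @param ci compatibility index (vectorised, non-negative).
#' @return character vector: `"strong_incompatible"`,
#'   `"weak_incompatible"` or `"compatible"`.
#' @examples
#' classify_index(c(0.47, 0.88, 3.76))
#' @export
classify_index <- function(ci) {
  if (any(is.na(ci)) || any(ci < 0))
    stop("compatibility index must be non-negative", call. = FALSE)
  ifelse(ci < 0.5, "strong_incompatible",
         ifelse(ci <= 2.0, "weak_incompatible", "compatible"))
}

#' Summarise a pollination experiment
#'
#' Computes the compatibility index, pod rate and observed class for each
#' record of a pollination table.
#'
#' @param records data frame with `female_id`, `male_id`, `n_flowers`,
#'   `n_pods`, `n_seeds`.
#' @return the records with `compatibility_index`, `pod_rate_pct` and
#'   `observed_class` columns appended.
#' @export
score_pollination <- function(records) {
  stopifnot(all(c("female_id", "male_id", "n_flowers", "n_pods",
                  "n_seeds") %in% names(records)))
  records$compatibility_index <-
    compatibility_index(records$n_seeds, records$n_flowers)
  records$pod_rate_pct <- pod_rate(records$n_pods, records$n_flowers)
  records$observed_class <- classify_index(records$compatibility_index)
  records
}

#' Concordance of cross predictions with pollination outcomes
#'
#' Pairs each prediction with the observed outcome of the same cross
#' (matched on female and male ids). Observed strong and weak
#' incompatibility both collapse to "incompatible" for scoring, since the
#' binary shared-haplotype model cannot distinguish them.
#'
#' @param predictions data frame from [predict_cross()] rows.
#' @param outcomes data frame with `female_id`, `male_id` and
#'   `observed_class` (e.g. from [score_pollination()]).
#' @return list with `n` (crosses scored), `n_agree`, `agreement` (fraction,
#'   `NA` when no crosses) and `discordant` (data frame of mismatching
#'   crosses with both labels).
#' @export
concordance <- function(predictions, outcomes) {
  if (nrow(predictions) == 0L && nrow(outcomes) == 0L)
    return(list(n = 0L, n_agree = 0L, agreement = NA_real_,
                discordant = data.frame(female_id = character(),
                                        male_id = character(),
                                        predicted = character(),
                                        observed_class = character())))
  key_p <- paste(predictions$female_id, predictions$male_id, sep = "\r")
  key_o <- paste(outcomes$female_id, outcomes$male_id, sep = "\r")
  if (!setequal(key_p, key_o) || anyDuplicated(key_p) || anyDuplicated(key_o))
    stop("predictions and outcomes do not match one-to-one", call. = FALSE)
  m <- match(key_p, key_o)
  observed <- ifelse(outcomes$observed_class[m] == "compatible",
                     "compatible", "incompatible")
  agree <- observed == predictions$predicted
  disc <- data.frame(female_id = predictions$female_id[!agree],
                     male_id = predictions$male_id[!agree],
                     predicted = predictions$predicted[!agree],
                     observed_class = outcomes$observed_class[m][!agree],
                     stringsAsFactors = FALSE)
  list(n = length(agree), n_agree = sum(agree),
       agreement = mean(agree), discordant = disc)
}
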