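# Synthetic kinase-domain panel generator: reference haplotypes carrying
# intact degenerate-primer binding sites and planted HinfI site maps,
# genotype panels with truth labels, and noisy pollination counts.

.BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Bundles all tunable parameters of the synthetic-data generator. The
#' defaults emulate the study panel this package was validated against:
#' 23 reference haplotypes (19 Class I, 4 Class II) of 1400 nt, a panel of
#' 79 genotypes (48 homozygous Class I, 13 homozygous Class II, 17
#' Class I/II heterozygotes), about 10% divergence between haplotypes and
#' at most 0.5% within a haplotype, and pollination counts whose
#' compatibility indices centre on 0.2 (incompatible) and 3.0 (compatible)
#' seeds per flower with pod rates near 20% and 75%.
#'
#' @param n_haplotypes number of reference haplotypes.
#' @param seq_length template length in nucleotides.
#' @param class_I_fraction fraction of references that are Class I.
#' @param between_divergence substitution fraction separating any haplotype
#'   from the panel ancestor (pairwise divergence is roughly twice this).
#' @param within_divergence substitution fraction applied when a genotype's
#'   allele copy of a reference is emitted.
#' @param n_hinfI_sites length-2 integer range of planted HinfI sites per
#'   Class I haplotype.
#' @param panel_size number of genotypes in the simulated panel.
#' @param heterozygote_fraction fraction of genotypes that are Class I/II
#'   heterozygous.
#' @param unclassified_fraction fraction of genotypes carrying an S locus
#'   amplifiable by neither primer pair (the study panel contained one such
#'   line among 79: its class partition lists 48 + 13 + 17 = 78 typed
#'   genotypes but class frequencies use the 79-line denominator).
#' @param hom_class_I_fraction fraction of classifiable homozygous
#'   genotypes that are Class I.
#' @param class_I_counts,class_II_counts optional explicit multiplicities
#'   (one per reference of that class, summing to the homozygote count);
#'   when `NULL` and the panel matches the study composition (19 references
#'   for 48 Class I homozygotes, 4 for 13 Class II) the study tallies
#'   `8,7,5,4,4,3,3,2,2,1x10` and `5,4,3,1` are used, otherwise counts are
#'   spread as evenly as possible.
#' @param n_flowers_per_cross pollinated flowers per cross.
#' @param seed_means named numeric: mean seeds per flower for
#'   `incompatible` and `compatible` crosses.
#' @param pod_probs named numeric: per-flower pod probability for the two
#'   outcomes.
#' @param gel_resolution_pct,gel_min_detect gel model used to guarantee
#'   planted Class I site maps are distinguishable.
#' @param noise logical; `FALSE` switches the pollination counts to their
#'   deterministic expectations (zero-variance mode).
#' @param rng_seed integer seed; all outputs are reproducible from it.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_haplotypes = 23L,
                       seq_length = 1400L,
                       class_I_fraction = 19 / 23,
                       between_divergence = 0.10,
                       within_divergence = 0.005,
                       n_hinfI_sites = c(2L, 5L),
                       panel_size = 79L,
                       heterozygote_fraction = 17 / 79,
                       unclassified_fraction = 1 / 79,
                       hom_class_I_fraction = 48 / 61,
                       class_I_counts = NULL,
                       class_II_counts = NULL,
                       n_flowers_per_cross = 30L,
                       seed_means = c(incompatible = 0.2, compatible = 3.0),
                       pod_probs = c(incompatible = 0.20, compatible = 0.75),
                       gel_resolution_pct = 2,
                       gel_min_detect = 50,
                       noise = TRUE,
                       rng_seed = 1L) {
  cfg <- list(n_haplotypes = as.integer(n_haplotypes),
              seq_length = as.integer(seq_length),
              class_I_fraction = class_I_fraction,
              between_divergence = between_divergence,
              within_divergence = within_divergence,
              n_hinfI_sites = as.integer(n_hinfI_sites),
              panel_size = as.integer(panel_size),
              heterozygote_fraction = heterozygote_fraction,
              unclassified_fraction = unclassified_fraction,
              hom_class_I_fraction = hom_class_I_fraction,
              class_I_counts = class_I_counts,
              class_II_counts = class_II_counts,
              n_flowers_per_cross = as.integer(n_flowers_per_cross),
              seed_means = seed_means, pod_probs = pod_probs,
              gel_resolution_pct = gel_resolution_pct,
              gel_min_detect = gel_min_detect,
              noise = isTRUE(noise), rng_seed = as.integer(rng_seed))
  stopifnot(cfg$n_haplotypes >= 1L, cfg$seq_length >= 1L,
            cfg$panel_size >= 1L, cfg$n_flowers_per_cross >= 1L,
            cfg$within_divergence < cfg$between_divergence,
            cfg$class_I_fraction >= 0, cfg$class_I_fraction <= 1,
            cfg$heterozygote_fraction >= 0, cfg$heterozygote_fraction <= 1,
            cfg$unclassified_fraction >= 0, cfg$unclassified_fraction <= 1,
            cfg$hom_class_I_fraction >= 0, cfg$hom_class_I_fraction <= 1,
            length(cfg$n_hinfI_sites) == 2L,
            cfg$n_hinfI_sites[1L] >= 1L,
            cfg$n_hinfI_sites[1L] <= cfg$n_hinfI_sites[2L],
            all(c("incompatible", "compatible") %in% names(cfg$seed_means)),
            all(c("incompatible", "compatible") %in% names(cfg$pod_probs)))
  structure(cfg, class = "sim_config")
}

# one concrete A/C/G/T realization of an IUPAC string
.realize_iupac <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  paste(vapply(chars, function(s) {
    set <- IUPAC_SETS[[s]]
    if (length(set) == 1L) set else sample(set, 1L)
  }, character(1)), collapse = "")
}

.random_seq <- function(n) sample(.BASES, n, replace = TRUE)

# substitute the given 1-based positions with a different random base
.mutate_at <- function(chars, positions) {
  for (p in positions)
    chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
  chars
}

# remove accidental GANTC occurrences outside protected positions by
# re-drawing the leading G; loops because a fix can expose a new window
.scrub_gantc <- function(chars, protected) {
  for (pass in 1:25) {
    seq <- paste(chars, collapse = "")
    hits <- BiocGenerics::start(Biostrings::matchPattern(
      Biostrings::DNAString("GANTC"), Biostrings::DNAString(seq),
      fixed = c(pattern = FALSE, subject = TRUE)))
    fixable <- hits[vapply(hits, function(h)
      !any((h:(h + 4L)) %in% protected), logical(1))]
    if (length(fixable) == 0L) return(chars)
    for (h in fixable) chars[h] <- sample(c("A", "C", "T"), 1L)
  }
  stop("failed to scrub accidental restriction sites", call. = FALSE)
}

# fixed template layout for one class: forward primer at offset 100,
# product length near the pair's expected size
.sim_layout <- function(pair, seq_length) {
  amp_len <- pair$expected_length
  len_f <- nchar(pair$forward$sequence)
  len_r <- nchar(pair$reverse$sequence)
  if (seq_length < 100L + amp_len + 50L)
    stop("seq_length too short for the ", pair$si_class,
         " amplicon layout", call. = FALSE)
  list(amp_start = 100L, amp_end = 100L + amp_len, amp_len = amp_len,
       fwd_pos = 101:(100L + len_f),
       rev_pos = (100L + amp_len - len_r + 1L):(100L + amp_len),
       len_f = len_f, len_r = len_r)
}

#' Simulate a reference S-haplotype panel
#'
#' Generates `n_haplotypes` kinase-domain-like templates. Every template
#' embeds, intact, one realization of its class's degenerate primer pair at
#' fixed offsets (forward site at offset 100; product length 1200 nt for
#' Class I, 1000 nt for Class II). Cores diverge from a common ancestor by
#' `between_divergence` substitutions. Each Class I haplotype is planted
#' with a distinct HinfI cut-site map: explicit `GANTC` motifs written at
#' lattice positions inside the amplicon, accidental motifs scrubbed
#' elsewhere, and site maps re-drawn until all planted haplotypes yield
#' pairwise-distinguishable gel profiles under the configured gel model.
#' (One HinfI site is constitutive in the Class I reverse-primer footprint
#' and is shared by every Class I amplicon.)
#'
#' @param config a [sim_config()].
#' @return list with `panel` (data frame `nau_name`, `si_class`,
#'   `sequence`) and `truth` (data frame with amplicon coordinates and the
#'   realised cut-position set per haplotype, cut positions relative to the
#'   amplicon start, semicolon-collapsed).
#' @export
simulate_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  primers <- kd_primers()
  pairs <- list(class_I = primer_pair(primers, "class_I"),
                class_II = primer_pair(primers, "class_II"))
  layouts <- lapply(pairs, .sim_layout, seq_length = config$seq_length)
  enz <- restriction_enzyme("HinfI")

  n_I <- round(config$n_haplotypes * config$class_I_fraction)
  classes <- rep(c("class_I", "class_II"),
                 c(n_I, config$n_haplotypes - n_I))
  ancestor <- .random_seq(config$seq_length)

  # lattice of candidate GANTC window offsets within the Class I amplicon
  lay_I <- layouts$class_I
  lattice <- seq(60L, lay_I$amp_len - lay_I$len_r - 65L, by = 60L)
  if (length(lattice) < config$n_hinfI_sites[2L])
    stop("seq_length leaves too few lattice positions for the requested ",
         "number of restriction sites", call. = FALSE)

  panel <- vector("list", config$n_haplotypes)
  truth <- vector("list", config$n_haplotypes)
  accepted_profiles <- list()
  for (i in seq_len(config$n_haplotypes)) {
    cls <- classes[i]
    lay <- layouts[[cls]]
    pair <- pairs[[cls]]
    chars <- ancestor
    chars[lay$fwd_pos] <-
      strsplit(.realize_iupac(pair$forward$sequence), "")[[1L]]
    chars[lay$rev_pos] <-
      strsplit(revcomp(.realize_iupac(pair$reverse$sequence)), "")[[1L]]
    protected <- c(lay$fwd_pos, lay$rev_pos)
    mutable <- setdiff(seq_len(config$seq_length), protected)
    chars <- .mutate_at(chars, sample(mutable,
      round(config$between_divergence * length(mutable))))

    if (cls == "class_I") {
      base_chars <- chars
      for (try in 1:200) {
        chars <- base_chars
        n_sites <- sample(seq(config$n_hinfI_sites[1L],
                              config$n_hinfI_sites[2L]), 1L)
        rel <- sort(sample(lattice, n_sites))
        site_pos <- integer()
        for (r in rel) {
          win <- lay$amp_start + r + 1:5 # 1-based template window
          chars[win] <- c("G", "A", sample(.BASES, 1L), "T", "C")
          site_pos <- c(site_pos, win)
        }
        chars <- .scrub_gantc(chars, c(protected, site_pos))
        amp <- substr(paste(chars, collapse = ""), lay$amp_start + 1L,
                      lay$amp_end)
        prof <- gel_profile(digest_sequence(amp, enz),
                            config$gel_resolution_pct, config$gel_min_detect)
        clash <- any(vapply(accepted_profiles, profiles_equal, logical(1),
                            a = prof))
        if (!clash) break
        if (try == 200L)
          stop("could not draw a distinguishable restriction-site map for ",
               "haplotype ", i, "; relax n_hinfI_sites or the gel model",
               call. = FALSE)
      }
      accepted_profiles[[length(accepted_profiles) + 1L]] <- prof
    } else {
      chars <- .scrub_gantc(chars, protected)
    }

    seq <- paste(chars, collapse = "")
    amp_seq <- substr(seq, lay$amp_start + 1L, lay$amp_end)
    cuts <- find_cut_sites(amp_seq, enz)
    panel[[i]] <- data.frame(
      nau_name = sprintf("SYN-S%02d", i), si_class = cls, sequence = seq,
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      nau_name = sprintf("SYN-S%02d", i), si_class = cls,
      amp_start = lay$amp_start, amp_length = lay$amp_len,
      n_cut_sites = length(cuts),
      cut_positions = paste(cuts, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  list(panel = do.call(rbind, panel), truth = do.call(rbind, truth))
}

# positions that must survive within-haplotype mutation: primer footprints
# plus every remaining GANTC window of the reference template
.protected_positions <- function(sequence, si_class, config) {
  primers <- kd_primers()
  lay <- .sim_layout(primer_pair(primers, si_class), config$seq_length)
  hits <- BiocGenerics::start(Biostrings::matchPattern(
    Biostrings::DNAString("GANTC"), Biostrings::DNAString(sequence),
    fixed = c(pattern = FALSE, subject = TRUE)))
  c(lay$fwd_pos, lay$rev_pos, unlist(lapply(hits, function(h) h:(h + 4L))))
}

#' Simulate a genotype panel from a reference panel
#'
#' Draws `panel_size` genotypes: homozygotes carry one reference haplotype,
#' heterozygotes one Class I plus one Class II haplotype. Each carried
#' allele is an imperfect copy of its reference, re-mutated at
#' `within_divergence` outside the primer footprints and restriction-site
#' windows (so the diagnostic features a real allele of that haplotype
#' would retain are retained), and emitted as one sequence record per
#' allele.
#'
#' @param references result of [simulate_reference_panel()].
#' @param config the same [sim_config()].
#' @return list with `sequences` (data frame `seq_id`, `genotype_id`,
#'   `nau_name_true`, `si_class`, `sequence`) and `truth` (data frame
#'   `genotype_id`, `class_truth`, `hap_class_I`, `hap_class_II`; for
#'   homozygotes the off-class slot is `NA`).
#' @export
simulate_genotype_panel <- function(references, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 1L)
  panel <- references$panel
  refs_I <- panel[panel$si_class == "class_I", , drop = FALSE]
  refs_II <- panel[panel$si_class == "class_II", , drop = FALSE]

  n_het <- round(config$panel_size * config$heterozygote_fraction)
  n_none <- round(config$panel_size * config$unclassified_fraction)
  n_hom <- config$panel_size - n_het - n_none
  n_hom_I <- round(n_hom * config$hom_class_I_fraction)
  n_hom_II <- n_hom - n_hom_I
  if (n_het > 0L && (nrow(refs_I) == 0L || nrow(refs_II) == 0L))
    stop("heterozygotes requested but a class has no references",
         call. = FALSE)
  if (n_hom_I > 0L && nrow(refs_I) == 0L)
    stop("Class I homozygotes requested but no Class I references",
         call. = FALSE)
  if (n_hom_II > 0L && nrow(refs_II) == 0L)
    stop("Class II homozygotes requested but no Class II references",
         call. = FALSE)

  counts_for <- function(counts, n_refs, n_slots, study_default) {
    if (!is.null(counts)) {
      stopifnot(length(counts) == n_refs, sum(counts) == n_slots)
      return(as.integer(counts))
    }
    if (!is.null(study_default) && n_refs == length(study_default) &&
        n_slots == sum(study_default)) return(study_default)
    base <- rep(n_slots %/% n_refs, n_refs)
    base[seq_len(n_slots %% n_refs)] <- base[seq_len(n_slots %% n_refs)] + 1L
    base
  }
  cI <- counts_for(config$class_I_counts, nrow(refs_I), n_hom_I,
                   c(8L, 7L, 5L, 4L, 4L, 3L, 3L, 2L, 2L, rep(1L, 10L)))
  cII <- counts_for(config$class_II_counts, nrow(refs_II), n_hom_II,
                    c(5L, 4L, 3L, 1L))

  # ordered draw plan: Class I homozygotes, Class II homozygotes, hets
  hom_I <- rep(refs_I$nau_name, cI)
  hom_II <- rep(refs_II$nau_name, cII)
  seqs <- list(); truth <- list()
  emit_allele <- function(gid, idx, ref_row) {
    chars <- strsplit(ref_row$sequence, "", fixed = TRUE)[[1L]]
    protected <- .protected_positions(ref_row$sequence, ref_row$si_class,
                                      config)
    mutable <- setdiff(seq_along(chars), protected)
    n_mut <- round(config$within_divergence * length(mutable))
    if (n_mut > 0L) chars <- .mutate_at(chars, sample(mutable, n_mut))
    chars <- .scrub_gantc(chars, protected)
    data.frame(seq_id = paste0(gid, "|a", idx), genotype_id = gid,
               nau_name_true = ref_row$nau_name,
               si_class = ref_row$si_class,
               sequence = paste(chars, collapse = ""),
               stringsAsFactors = FALSE)
  }
  gid_i <- 0L
  for (h in hom_I) {
    gid_i <- gid_i + 1L; gid <- sprintf("GEN-%03d", gid_i)
    seqs[[length(seqs) + 1L]] <-
      emit_allele(gid, 1L, refs_I[refs_I$nau_name == h, ])
    truth[[length(truth) + 1L]] <- data.frame(
      genotype_id = gid, class_truth = "class_I", hap_class_I = h,
      hap_class_II = NA_character_, stringsAsFactors = FALSE)
  }
  for (h in hom_II) {
    gid_i <- gid_i + 1L; gid <- sprintf("GEN-%03d", gid_i)
    seqs[[length(seqs) + 1L]] <-
      emit_allele(gid, 1L, refs_II[refs_II$nau_name == h, ])
    truth[[length(truth) + 1L]] <- data.frame(
      genotype_id = gid, class_truth = "class_II",
      hap_class_I = NA_character_, hap_class_II = h,
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(n_het)) {
    gid_i <- gid_i + 1L; gid <- sprintf("GEN-%03d", gid_i)
    rI <- refs_I[sample(nrow(refs_I), 1L), ]
    rII <- refs_II[sample(nrow(refs_II), 1L), ]
    seqs[[length(seqs) + 1L]] <- emit_allele(gid, 1L, rI)
    seqs[[length(seqs) + 1L]] <- emit_allele(gid, 2L, rII)
    truth[[length(truth) + 1L]] <- data.frame(
      genotype_id = gid, class_truth = "class_I_II",
      hap_class_I = rI$nau_name, hap_class_II = rII$nau_name,
      stringsAsFactors = FALSE)
  }
  # unclassifiable lines: an S locus diverged beyond both primer systems,
  # emitted as a random template carrying neither binding site
  primers <- kd_primers()
  for (k in seq_len(n_none)) {
    gid_i <- gid_i + 1L; gid <- sprintf("GEN-%03d", gid_i)
    repeat {
      seq <- paste(.random_seq(config$seq_length), collapse = "")
      amplifies <- any(vapply(c("class_I", "class_II"), function(cl)
        nrow(virtual_pcr(seq, primer_pair(primers, cl))) > 0L, logical(1)))
      if (!amplifies) break
    }
    seqs[[length(seqs) + 1L]] <- data.frame(
      seq_id = paste0(gid, "|a1"), genotype_id = gid,
      nau_name_true = NA_character_, si_class = "none", sequence = seq,
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      genotype_id = gid, class_truth = "none",
      hap_class_I = NA_character_, hap_class_II = NA_character_,
      stringsAsFactors = FALSE)
  }
  list(sequences = do.call(rbind, seqs), truth = do.call(rbind, truth))
}

# s_genotype objects from a genotype truth table (unclassified lines
# carry no haplotype and cannot enter crosses)
.truth_genotypes <- function(truth) {
  truth <- truth[truth$class_truth != "none", , drop = FALSE]
  out <- lapply(seq_len(nrow(truth)), function(i) {
    row <- truth[i, ]
    haps <- c(row$hap_class_I, row$hap_class_II)
    cls <- c("class_I", "class_II")[!is.na(haps)]
    s_genotype(row$genotype_id, haps[!is.na(haps)], cls)
  })
  stats::setNames(out, truth$genotype_id)
}

#' Simulate pollination counts for a set of crosses
#'
#' Ground-truth compatibility of each cross is computed with
#' [predict_cross()] from the planted genotypes. Seed counts are Poisson
#' with mean `n_flowers x seed_means[state]`; pods are Binomial with the
#' per-flower pod probability of the state. With `noise = FALSE` in the
#' config, counts equal their rounded expectations.
#'
#' @param truth genotype truth table from [simulate_genotype_panel()].
#' @param crosses data frame with `female_id`, `male_id` and optionally
#'   `stage` (default `"flower"`) and `n_flowers`.
#' @param config a [sim_config()].
#' @return data frame with the cross, `stage`, counts, and
#'   `true_state` (the generating compatibility state).
#' @export
simulate_pollination <- function(truth, crosses, config) {
  stopifnot(inherits(config, "sim_config"),
            all(c("female_id", "male_id") %in% names(crosses)))
  set.seed(config$rng_seed + 2L)
  gts <- .truth_genotypes(truth)
  unknown <- setdiff(unique(c(crosses$female_id, crosses$male_id)),
                     names(gts))
  if (length(unknown))
    stop("unknown genotype id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(crosses$stage)) crosses$stage <- "flower"
  if (is.null(crosses$n_flowers))
    crosses$n_flowers <- config$n_flowers_per_cross
  out <- lapply(seq_len(nrow(crosses)), function(i) {
    cr <- crosses[i, ]
    pred <- predict_cross(gts[[cr$female_id]], gts[[cr$male_id]], cr$stage)
    state <- pred$predicted
    mu_seed <- cr$n_flowers * config$seed_means[[state]]
    p_pod <- config$pod_probs[[state]]
    if (config$noise) {
      n_seeds <- stats::rpois(1L, mu_seed)
      n_pods <- stats::rbinom(1L, cr$n_flowers, p_pod)
    } else {
      n_seeds <- round(mu_seed)
      n_pods <- round(cr$n_flowers * p_pod)
    }
    data.frame(female_id = cr$female_id, male_id = cr$male_id,
               stage = cr$stage, n_flowers = cr$n_flowers,
               n_pods = n_pods, n_seeds = n_seeds, true_state = state,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a sequence table as FASTA
#'
#' @param sequences data frame with an id column and a `sequence` column.
#' @param path output file path.
#' @param id_col name of the id column (default the first column).
#' @return `path`, invisibly.
#' @export
write_panel_fasta <- function(sequences, path, id_col = names(sequences)[1L]) {
  set <- Biostrings::DNAStringSet(
    stats::setNames(sequences$sequence, sequences[[id_col]]))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
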