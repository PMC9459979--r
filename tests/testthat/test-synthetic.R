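# Synthetic panel generator: determinism, planted structure, noise model.

test_that("configuration invariants are enforced", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(within_divergence = 0.2,
                          between_divergence = 0.1))
  expect_error(sim_config(n_hinfI_sites = c(4L, 2L)))
  expect_error(sim_config(class_I_fraction = 1.2))
})

test_that("reference generation is byte-deterministic", {
  cfg <- sim_config(n_haplotypes = 6L, class_I_fraction = 4 / 6,
                    rng_seed = 31L)
  r1 <- simulate_reference_panel(cfg)
  r2 <- simulate_reference_panel(cfg)
  expect_identical(r1, r2)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_panel_fasta(r1$panel, f1, "nau_name")
  write_panel_fasta(r2$panel, f2, "nau_name")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("references embed intact primer sites and divergent cores", {
  cfg <- sim_config(n_haplotypes = 19L, class_I_fraction = 1.0,
                    rng_seed = 7L)
  refs <- simulate_reference_panel(cfg)
  expect_equal(nrow(refs$panel), 19L)
  pair <- primer_pair(kd_primers(), "class_I")
  for (i in seq_len(19L)) {
    amp <- virtual_pcr(refs$panel$sequence[i], pair)
    expect_equal(nrow(amp), 1L)
    expect_equal(amp$length, 1200L)
  }
  # pairwise identity well below the same-haplotype range
  ids <- combn(19L, 2L, function(ij)
    percent_identity(refs$panel$sequence[ij[1L]],
                     refs$panel$sequence[ij[2L]]))
  expect_lte(max(ids), 95)
  # planted Class I cut maps are recoverable and pairwise distinct as gels
  tr <- refs$truth
  profs <- lapply(seq_len(19L), function(i) {
    amp_seq <- substr(refs$panel$sequence[i], tr$amp_start[i] + 1L,
                      tr$amp_start[i] + tr$amp_length[i])
    cuts <- find_cut_sites(amp_seq)
    expect_equal(cuts, as.integer(strsplit(tr$cut_positions[i], ";")[[1L]]))
    gel_profile(digest_sequence(amp_seq))
  })
  for (i in 1:18) for (j in (i + 1):19)
    expect_false(profiles_equal(profs[[i]], profs[[j]]))
})

test_that("single-haplotype and infeasible configurations behave", {
  one <- simulate_reference_panel(sim_config(n_haplotypes = 1L,
                                             class_I_fraction = 1,
                                             rng_seed = 1L))
  expect_equal(nrow(one$panel), 1L)
  expect_error(simulate_reference_panel(
    sim_config(n_haplotypes = 2L, class_I_fraction = 1,
               seq_length = 1400L, n_hinfI_sites = c(30L, 40L),
               rng_seed = 1L)), "lattice")
})

test_that("genotype panels honour composition and divergence settings", {
  panel <- small_panel()
  expect_equal(as.vector(table(panel$gen$truth$class_truth)[
    c("class_I", "class_II", "class_I_II")]), c(4L, 2L, 2L))
  # zero within-divergence: alleles identical to their reference
  cfg0 <- sim_config(n_haplotypes = 4L, class_I_fraction = 0.5,
                     panel_size = 4L, heterozygote_fraction = 0,
                     unclassified_fraction = 0, within_divergence = 0,
                     hom_class_I_fraction = 0.5, rng_seed = 13L)
  refs0 <- simulate_reference_panel(cfg0)
  gen0 <- simulate_genotype_panel(refs0, cfg0)
  refmap <- stats::setNames(refs0$panel$sequence, refs0$panel$nau_name)
  expect_true(all(gen0$sequences$sequence ==
                    refmap[gen0$sequences$nau_name_true]))
  # heterozygotes need both classes
  cfg_bad <- sim_config(n_haplotypes = 3L, class_I_fraction = 1,
                        panel_size = 4L, heterozygote_fraction = 0.5,
                        unclassified_fraction = 0, rng_seed = 1L)
  refs_bad <- simulate_reference_panel(cfg_bad)
  expect_error(simulate_genotype_panel(refs_bad, cfg_bad), "class")
})

test_that("within-haplotype copies stay inside the identity threshold", {
  panel <- small_panel()
  refmap <- stats::setNames(panel$refs$panel$sequence,
                            panel$refs$panel$nau_name)
  hom <- panel$gen$sequences[!is.na(panel$gen$sequences$nau_name_true), ]
  ids <- vapply(seq_len(nrow(hom)), function(i)
    percent_identity(hom$sequence[i], refmap[[hom$nau_name_true[i]]]),
    numeric(1))
  expect_true(all(ids >= 98.5))
  expect_true(all(ids < 100 | panel$cfg$within_divergence == 0))
})

test_that("pollination counts track the generating compatibility state", {
  panel <- small_panel()
  truth <- panel$gen$truth
  hom <- truth[truth$class_truth == "class_I", ]
  crosses <- data.frame(
    female_id = hom$genotype_id[c(1L, 1L, 2L)],
    male_id = hom$genotype_id[c(2L, 1L, 3L)],
    stage = c("flower", "flower", "flower"))
  # zero-variance mode: the index equals the configured mean exactly
  cfg0 <- panel$cfg
  cfg0$noise <- FALSE
  out0 <- simulate_pollination(truth, crosses, cfg0)
  sc0 <- score_pollination(out0)
  expect_true(all(sc0$compatibility_index[sc0$true_state == "compatible"]
                  == 3.0))
  expect_true(all(sc0$compatibility_index[sc0$true_state == "incompatible"]
                  == 0.2))
  # bud-stage self is compatible regardless of shared haplotypes
  bud <- simulate_pollination(truth,
                              data.frame(female_id = hom$genotype_id[1L],
                                         male_id = hom$genotype_id[1L],
                                         stage = "bud"), cfg0)
  expect_equal(bud$true_state, "compatible")
  # law of large numbers at many flowers: index converges on the mean
  cfg_big <- panel$cfg
  cfg_big$n_flowers_per_cross <- 10000L
  out_big <- simulate_pollination(truth, crosses, cfg_big)
  sc <- score_pollination(out_big)
  inc <- sc[sc$true_state == "incompatible", ]
  expect_true(all(abs(inc$compatibility_index - 0.2) < 0.05))
  expect_true(all(inc$observed_class == "strong_incompatible"))
  expect_error(simulate_pollination(truth,
    data.frame(female_id = "nope", male_id = hom$genotype_id[1L]),
    panel$cfg), "unknown")
})
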