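# Alignment identity, haplotype assignment and frequency tables.

test_that("percent identity matches hand-computed cases", {
  expect_equal(percent_identity("ACGT", "ACGT"), 100)
  expect_equal(percent_identity("ACGT", "ACGA"), 75)
  set.seed(21)
  a <- random_acgt(1000)
  b <- a
  for (p in c(100, 900)) # two substitutions
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"),
                               substr(a, p, p))[1L]
  expect_equal(percent_identity(a, b), 99.8)
  expect_error(percent_identity("", "ACGT"), "non-empty")
})

test_that("identity is symmetric, reflexive, and strand-consistent", {
  # symmetry and strand invariance are asserted on diverged copies (the
  # typing regime, where the optimal alignment is unique); for unrelated
  # sequences co-optimal alignments can decompose score into different
  # match/gap mixes, leaving identity tie-dependent
  set.seed(22)
  for (trial in 1:10) {
    a <- random_acgt(sample(200:400, 1L))
    expect_equal(percent_identity(a, a), 100)
    ch <- strsplit(a, "")[[1L]]
    pos <- sample(length(ch), round(0.05 * length(ch)))
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1L]
    b <- paste(ch, collapse = "")
    expect_equal(percent_identity(a, b), 100 - 100 * length(pos) / length(ch))
    expect_equal(percent_identity(a, b), percent_identity(b, a))
    expect_equal(percent_identity(revcomp(a), revcomp(b)),
                 percent_identity(a, b))
  }
})

test_that("terminal overhangs do not count against identity", {
  core <- "ACGTACGTACGTACGTACGT"
  expect_equal(percent_identity(paste0(core, "GGGGG"), core), 100)
  expect_equal(percent_identity(paste0("GGGGG", core), core), 100)
})

test_that("assignment separates known, novel and ambiguous calls", {
  set.seed(23)
  base <- random_acgt(1000)
  mutate_frac <- function(s, frac) {
    pos <- sample(nchar(s), round(frac * nchar(s)))
    ch <- strsplit(s, "")[[1L]]
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1L]
    paste(ch, collapse = "")
  }
  panel <- data.frame(nau_name = c("NAU-S16", "NAU-S25", "NAU-S17"),
                      si_class = "class_I",
                      sequence = c(base, mutate_frac(base, 0.08),
                                   mutate_frac(base, 0.16)),
                      stringsAsFactors = FALSE)
  exact <- assign_haplotype(base, panel, 98.5, "q0")
  expect_equal(exact$status, "known")
  expect_equal(exact$best_hit, "NAU-S16")
  expect_equal(exact$identity_pct, 100)
  near <- assign_haplotype(mutate_frac(base, 0.009), panel, 98.5, "q1")
  expect_equal(near$status, "known")
  expect_equal(near$best_hit, "NAU-S16")
  far <- assign_haplotype(mutate_frac(base, 0.10), panel, 98.5, "q2")
  expect_equal(far$status, "novel")
  expect_true(is.na(far$best_hit))
  # two references of different classes tied at the max
  tie_panel <- data.frame(nau_name = c("NAU-A", "NAU-B"),
                          si_class = "class_I",
                          sequence = c(base, base), stringsAsFactors = FALSE)
  expect_equal(assign_haplotype(base, tie_panel, 98.5)$status, "ambiguous")
  expect_error(assign_haplotype(base, panel[0, ], 98.5), "empty")
})

test_that("frequency tables reproduce planted tallies", {
  class_I_calls <- data.frame(nau_name = rep(
    c("NAU-S16", "NAU-S25", "NAU-S17", "NAU-S15", "NAU-S51", "NAU-S04",
      "NAU-S44", "NAU-S02", "NAU-S14", paste0("NAU-X", 1:10)),
    c(8, 7, 5, 4, 4, 3, 3, 2, 2, rep(1, 10))))
  tab <- tally_frequencies(class_I_calls)
  expect_equal(attr(tab, "denominator"), 48L)
  expect_equal(sum(tab$occurrences), 48L)
  expect_equal(tab$frequency_pct[tab$nau_name == "NAU-S16"], 16.67)
  expect_equal(tab$frequency_pct[tab$nau_name == "NAU-S25"], 14.58)
  expect_equal(tab$frequency_pct[tab$nau_name == "NAU-S17"], 10.42)
  expect_equal(tab$frequency_pct[tab$nau_name == "NAU-S51"], 8.33)
  expect_equal(tab$nau_name[1L], "NAU-S16") # sorted by occurrences
  expect_lt(abs(sum(tab$frequency_pct) - 100), 0.2)

  class_II_calls <- data.frame(nau_name = rep(
    c("NAU-S39", "NAU-S52", "NAU-S43", "NAU-S38"), c(5, 4, 3, 1)))
  tab2 <- tally_frequencies(class_II_calls)
  expect_equal(tab2$frequency_pct, c(38.46, 30.77, 23.08, 7.69))
  single <- tally_frequencies(data.frame(nau_name = "NAU-S1"))
  expect_equal(single$frequency_pct, 100)
  expect_error(tally_frequencies(data.frame(nau_name = c("a", NA))),
               "unresolved")
})

test_that("heterozygote resolution pairs one call per class", {
  call_I <- data.frame(query_id = "g|a1", best_hit = "NAU-S17",
                       identity_pct = 99.5, status = "known")
  call_II <- data.frame(query_id = "g|a2", best_hit = "NAU-S39",
                        identity_pct = 99.9, status = "known")
  g <- heterozygote_resolve("NAU-Rs49", call_I, call_II)
  expect_s3_class(g, "s_genotype")
  expect_setequal(g$haplotypes$nau_name, c("NAU-S17", "NAU-S39"))
  dup <- call_I; dup$best_hit <- "NAU-S17"
  bad_II <- call_II; bad_II$best_hit <- "NAU-S17"
  expect_error(heterozygote_resolve("g", call_I, bad_II), "twice")
  unres <- call_II; unres$best_hit <- NA_character_; unres$status <- "novel"
  expect_error(heterozygote_resolve("g", call_I, unres), "unresolved")
})
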