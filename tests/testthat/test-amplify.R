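# Degenerate-primer matching, binding-site search and virtual PCR.

test_that("degenerate window matching follows the IUPAC sets", {
  expect_true(iupac_match("AR", "AG"))
  expect_false(iupac_match("AR", "AC"))
  expect_true(iupac_match("AR", "AC", max_mismatch = 1L))
  expect_true(iupac_match("GAACTTCCATTGATAGAGTTRG",
                          "GAACTTCCATTGATAGAGTTAG"))
  expect_true(iupac_match("N", "T"))
  expect_error(iupac_match("AR", "AGG"), "equal length")
  expect_error(iupac_match("AZ", "AG"), "IUPAC")
  expect_error(iupac_match("AR", "AU"), "A/C/G/T")
})

test_that("binding sites are found on the written and complementary strand", {
  expect_equal(find_binding_sites("AAA", "TTAAATT", "forward")$offset, 2L)
  rv <- find_binding_sites("AAA", "TTTTTGG", "reverse")
  expect_equal(rv$offset, c(0L, 1L, 2L))
  expect_true(all(rv$strand == "bottom"))
  expect_equal(find_binding_sites("AR", "AAAG", "forward")$offset, 0:2)
  expect_equal(nrow(find_binding_sites("AAAA", "GGGG", "forward")), 0L)
})

test_that("binding-site search agrees with the sliding-window oracle", {
  primers <- kd_primers()
  set.seed(101)
  for (trial in 1:6) {
    template <- random_acgt(sample(500:3000, 1L))
    # plant a couple of realized degenerate sites to guarantee hits
    pr <- primers[sample(nrow(primers), 1L), ]
    pat <- if (pr$role == "forward") pr$sequence else revcomp(pr$sequence)
    pat <- chartr("RYSWKMBDHVN", "ACCAGACAAAA", pat) # one fixed realization
    pos <- sample(nchar(template) - nchar(pat), 2L)
    substr(template, pos[1L], pos[1L] + nchar(pat) - 1L) <- pat
    substr(template, pos[2L], pos[2L] + nchar(pat) - 1L) <- pat
    got <- find_binding_sites(pr$sequence, template, pr$role)
    expect_equal(got$offset,
                 naive_binding_sites(pr$sequence, template, pr$role))
    expect_gte(nrow(got), 1L)
  }
})

test_that("virtual PCR emits in-window products with matching primer ends", {
  primers <- kd_primers()
  pair <- primer_pair(primers, "class_I")
  set.seed(5)
  fwd <- chartr("R", "G", pair$forward$sequence)
  rev_tail <- revcomp(chartr("RK", "AG", pair$reverse$sequence))
  template <- random_acgt(1500)
  substr(template, 101, 100 + nchar(fwd)) <- fwd
  substr(template, 1300 - nchar(rev_tail) + 1, 1300) <- rev_tail
  amp <- virtual_pcr(template, pair, size_window = c(900, 1500))
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, 1200L)
  expect_equal(c(amp$start, amp$end), c(100L, 1300L))
  # the product starts with a forward-primer realization and ends with the
  # reverse complement of a reverse-primer realization
  seq <- amplicon_sequence(template, amp[1L, ])
  expect_true(iupac_match(pair$forward$sequence,
                          substr(seq, 1, nchar(fwd))))
  expect_true(iupac_match(pair$reverse$sequence,
                          revcomp(substr(seq, nchar(seq) - 17, nchar(seq)))))
  # out-of-window: no product
  expect_equal(nrow(virtual_pcr(template, pair, size_window = c(100, 200))),
               0L)
})

test_that("multiple compatible sites pair combinatorially", {
  primers <- kd_primers()
  pair <- primer_pair(primers, "class_II")
  fwd <- pair$forward$sequence
  rev_tail <- revcomp(pair$reverse$sequence)
  set.seed(6)
  template <- random_acgt(3000)
  for (p in c(101, 401)) substr(template, p, p + nchar(fwd) - 1) <- fwd
  for (p in c(1200, 1400))
    substr(template, p - nchar(rev_tail) + 1, p) <- rev_tail
  amp <- virtual_pcr(template, pair, size_window = c(500, 1500))
  expect_equal(nrow(amp), 4L) # 2 forward x 2 reverse
  expect_equal(amp$length, c(1100L, 1300L, 800L, 1000L))
  expect_false(is.unsorted(amp$start))
})

test_that("reverse-complementing the template mirrors sites and amplicons", {
  primers <- kd_primers()
  pair <- primer_pair(primers, "class_I")
  panel <- small_panel()
  refs_I <- panel$refs$panel[panel$refs$panel$si_class == "class_I", ]
  for (i in seq_len(nrow(refs_I))) {
    tpl <- refs_I$sequence[i]
    L <- nchar(tpl)
    rc <- revcomp(tpl)
    a <- virtual_pcr(tpl, pair)
    b <- virtual_pcr(rc, pair)
    expect_equal(nrow(a), nrow(b))
    expect_setequal(a$length, b$length)
    expect_setequal(paste(L - a$end, L - a$start), paste(b$start, b$end))
    # a top-strand forward site becomes a bottom-strand site of the same
    # primer on the reverse complement, at the mirrored offset
    fw_top <- find_binding_sites(pair$forward$sequence, tpl, "forward")
    fw_rc <- find_binding_sites(pair$forward$sequence, rc, "reverse")
    k <- nchar(pair$forward$sequence)
    expect_equal(sort(L - k - fw_top$offset), fw_rc$offset)
  }
})

test_that("mismatch tolerance still requires an exact 3' terminus", {
  # forward primer ACGTACGT: internal mismatch tolerated, 3'-end not
  template <- paste0("TTTT", "ACGAACGT", "TTTT") # mismatch at position 4
  expect_equal(nrow(find_binding_sites("ACGTACGT", template, "forward", 0L)),
               0L)
  expect_equal(find_binding_sites("ACGTACGT", template, "forward", 1L)$offset,
               4L)
  template2 <- paste0("TTTT", "ACGTACGA", "TTTT") # mismatch at 3' base
  expect_equal(nrow(find_binding_sites("ACGTACGT", template2, "forward", 1L)),
               0L)
})

test_that("class calls follow the two-pair product logic", {
  amp <- data.frame(template_id = "g", pair_name = "p", start = 0L,
                    end = 1200L, length = 1200L)
  none <- amp[0L, ]
  expect_equal(call_class("g", amp, none)$call, "class_I")
  expect_equal(call_class("g", none, amp)$call, "class_II")
  expect_equal(call_class("g", amp, amp)$call, "class_I_II")
  expect_equal(call_class("g", none, none)$call, "none")
})
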