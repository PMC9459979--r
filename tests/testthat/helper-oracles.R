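# Independent brute-force oracles and shared fixtures.

random_acgt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                 collapse = "")

# all-offsets sliding-window scan for a degenerate pattern on the top
# strand; returns 0-based window offsets (independent of matchPattern)
naive_iupac_scan <- function(pattern, template, max_mismatch = 0L) {
  k <- nchar(pattern)
  L <- nchar(template)
  if (L < k) return(integer())
  offs <- integer()
  for (i in seq_len(L - k + 1L))
    if (iupac_match(pattern, substr(template, i, i + k - 1L), max_mismatch))
      offs <- c(offs, i - 1L)
  offs
}

# primer binding-site oracle: forward as written, reverse via its
# reverse complement on the top strand
naive_binding_sites <- function(primer, template, role) {
  pat <- if (role == "forward") primer else revcomp(primer)
  naive_iupac_scan(pat, template)
}

# HinfI cut-position oracle (0-based cut positions, boundaries dropped)
naive_cut_sites <- function(sequence, recognition = "GANTC",
                            cut_offset = 1L) {
  cuts <- naive_iupac_scan(recognition, sequence) + cut_offset
  cuts <- sort(unique(cuts))
  cuts[cuts > 0L & cuts < nchar(sequence)]
}

# breadth-first connected components over an edge list of node labels;
# returns membership partition as a list of sorted node vectors
bfs_components <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- character()
  comps <- list()
  for (n in nodes) {
    if (n %in% seen) next
    queue <- n; comp <- character()
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# build an alias_table programmatically (bypasses the loader so link
# structures beyond row-disjoint cliques can be exercised)
make_alias_table <- function(rows) {
  recs <- do.call(rbind, lapply(seq_along(rows), function(i) {
    parts <- strsplit(rows[[i]], ":", fixed = TRUE)
    data.frame(row = i,
               team = vapply(parts, `[`, "", 1L),
               label = vapply(parts, `[`, "", 2L),
               is_synonym = FALSE, stringsAsFactors = FALSE)
  }))
  structure(list(records = recs,
                 similarities = data.frame(),
                 n_rows = length(rows)),
            class = "alias_table")
}

# memoised simulated study panel + full workflow run (expensive; built
# once per test session)
.study_env <- new.env(parent = emptyenv())
study_panel <- function() {
  if (is.null(.study_env$fixture)) {
    cfg <- sim_config(rng_seed = 7L)
    refs <- simulate_reference_panel(cfg)
    gen <- simulate_genotype_panel(refs, cfg)
    run <- suppressMessages(run_typing_workflow(gen$sequences, refs$panel))
    .study_env$fixture <- list(cfg = cfg, refs = refs, gen = gen, run = run)
  }
  .study_env$fixture
}

# tiny synthetic panel for fast smoke paths
small_panel <- function(seed = 11L) {
  cfg <- sim_config(n_haplotypes = 5L, class_I_fraction = 3 / 5,
                    panel_size = 8L, heterozygote_fraction = 2 / 8,
                    unclassified_fraction = 0,
                    hom_class_I_fraction = 4 / 6, rng_seed = seed)
  refs <- simulate_reference_panel(cfg)
  gen <- simulate_genotype_panel(refs, cfg)
  list(cfg = cfg, refs = refs, gen = gen)
}
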