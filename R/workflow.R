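# End-to-end orchestration: virtual PCR -> class partition -> RFLP
# profiles -> haplotype typing -> frequency tables -> cross concordance.

.read_seq_table <- function(x, id_col = "seq_id") {
  if (is.character(x) && length(x) == 1L) {
    set <- Biostrings::readDNAStringSet(x)
    x <- data.frame(seq_id = names(set), sequence = as.character(set),
                    stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x), "sequence" %in% names(x))
  if (!"genotype_id" %in% names(x))
    x$genotype_id <- sub("\\|.*$", "", x[[id_col]])
  if (!"seq_id" %in% names(x)) x$seq_id <- x[[id_col]]
  x
}

.read_reference_panel <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    set <- Biostrings::readDNAStringSet(x)
    parts <- strsplit(names(set), "|", fixed = TRUE)
    x <- data.frame(nau_name = vapply(parts, `[`, "", 1L),
                    si_class = vapply(parts, `[`, "", 2L),
                    sequence = as.character(set), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x),
            all(c("nau_name", "si_class", "sequence") %in% names(x)))
  x
}

#' Run the full S-haplotype typing workflow
#'
#' Executes, in order: virtual PCR with the Class I and Class II primer
#' pairs and class calling for every genotype; HinfI PCR-RFLP gel profiling
#' of the Class I homozygotes; identity-based haplotype assignment of every
#' amplifying allele against the reference panel (Class I alleles against
#' Class I references, Class II against Class II), with novel-allele
#' registration when a registry is supplied; per-class frequency tables
#' over the homozygous materials; a heterozygote table; and, when
#' pollination records are supplied, compatibility-index scoring and a
#' prediction/outcome concordance report. A machine-readable run manifest
#' records the parameters and per-stage row counts.
#'
#' A genotype may contribute several sequence records (one per allele);
#' records are named `<genotype>|<allele>` in FASTA input.
#'
#' @param queries query sequences: FASTA path or data frame with `seq_id`
#'   (or `genotype_id`) and `sequence`.
#' @param references reference panel: FASTA path (headers
#'   `>name|class_I`) or data frame `nau_name`, `si_class`, `sequence`.
#' @param registry optional `s_registry` used to name novel haplotypes;
#'   without one, novel alleles are labelled `NOVEL-<seq_id>`.
#' @param pollination optional data frame of pollination counts
#'   (`female_id`, `male_id`, `n_flowers`, `n_pods`, `n_seeds`) whose
#'   crosses reference typed genotypes.
#' @param threshold same-haplotype identity threshold (see
#'   [assign_haplotype()]).
#' @param max_mismatch primer mismatch tolerance (see [virtual_pcr()]).
#' @param resolution_pct,min_detect gel model (see [gel_profile()]).
#' @param outdir optional directory; when given, TSV reports and a JSON
#'   manifest are written there.
#' @return list of class `stype_run` with elements `class_calls`,
#'   `partition`, `rflp`, `calls`, `freq_class_I`, `freq_class_II`,
#'   `het_table`, `genotypes`, `cross_report` (or `NULL`), `registry`,
#'   `manifest`.
#' @export
run_typing_workflow <- function(queries, references, registry = NULL,
                                pollination = NULL, threshold = 98.5,
                                max_mismatch = 0L, resolution_pct = 2,
                                min_detect = 50, outdir = NULL) {
  seqs <- .read_seq_table(queries)
  refs <- .read_reference_panel(references)
  primers <- kd_primers()
  pair_I <- primer_pair(primers, "class_I")
  pair_II <- primer_pair(primers, "class_II")
  enz <- restriction_enzyme("HinfI")
  genotype_ids <- unique(seqs$genotype_id)
  message(sprintf("stype: %d sequence record(s), %d genotype(s)",
                  nrow(seqs), length(genotype_ids)))

  # stage 1: virtual PCR and class calls -------------------------------
  per_gen <- list()
  class_calls <- list()
  for (g in genotype_ids) {
    recs <- seqs[seqs$genotype_id == g, , drop = FALSE]
    prod_I <- list(); prod_II <- list()
    for (j in seq_len(nrow(recs))) {
      amp_I <- virtual_pcr(recs$sequence[j], pair_I,
                           max_mismatch = max_mismatch,
                           template_id = recs$seq_id[j])
      amp_II <- virtual_pcr(recs$sequence[j], pair_II,
                            max_mismatch = max_mismatch,
                            template_id = recs$seq_id[j])
      if (nrow(amp_I)) prod_I[[length(prod_I) + 1L]] <- amp_I
      if (nrow(amp_II)) prod_II[[length(prod_II) + 1L]] <- amp_II
    }
    prod_I <- if (length(prod_I)) do.call(rbind, prod_I) else
      data.frame(template_id = character(), pair_name = character(),
                 start = integer(), end = integer(), length = integer())
    prod_II <- if (length(prod_II)) do.call(rbind, prod_II) else
      data.frame(template_id = character(), pair_name = character(),
                 start = integer(), end = integer(), length = integer())
    per_gen[[g]] <- list(records = recs, prod_I = prod_I, prod_II = prod_II)
    class_calls[[g]] <- call_class(g, prod_I, prod_II)
  }
  class_calls <- do.call(rbind, class_calls)
  rownames(class_calls) <- NULL
  lv <- c("class_I", "class_II", "class_I_II", "none")
  counts <- table(factor(class_calls$call, levels = lv))
  partition <- data.frame(call = lv, n = as.integer(counts),
                          frequency_pct =
                            .round2(100 * as.integer(counts) /
                                      max(1L, nrow(class_calls))),
                          stringsAsFactors = FALSE)
  message(sprintf("stype: class partition I=%d II=%d I/II=%d none=%d",
                  counts[1L], counts[2L], counts[3L], counts[4L]))

  # stage 2: PCR-RFLP of Class I homozygotes ---------------------------
  amp_seq_of <- function(g, which = c("prod_I", "prod_II")) {
    which <- match.arg(which)
    prod <- per_gen[[g]][[which]][1L, ] # first admissible product
    rec <- per_gen[[g]]$records
    template <- rec$sequence[rec$seq_id == prod$template_id][1L]
    list(seq = amplicon_sequence(template, prod),
         template = template, seq_id = prod$template_id)
  }
  hom_I <- class_calls$genotype_id[class_calls$call == "class_I"]
  rflp <- if (length(hom_I)) {
    amps <- data.frame(genotype_id = hom_I,
                       sequence = vapply(hom_I, function(g)
                         amp_seq_of(g, "prod_I")$seq, character(1)),
                       stringsAsFactors = FALSE)
    profile_table(amps, enz, resolution_pct, min_detect)
  } else profile_table(data.frame(genotype_id = character(),
                                  sequence = character()), enz,
                       resolution_pct, min_detect)
  message(sprintf("stype: %d gel profile(s) among %d Class I genotype(s)",
                  rflp$n_profiles, length(hom_I)))

  # stage 3: haplotype typing ------------------------------------------
  refs_I <- refs[refs$si_class == "class_I", , drop = FALSE]
  refs_II <- refs[refs$si_class == "class_II", , drop = FALSE]
  type_allele <- function(g, which) {
    x <- amp_seq_of(g, which)
    panel <- if (which == "prod_I") refs_I else refs_II
    assign_haplotype(x$template, panel, threshold, query_id = x$seq_id)
  }
  resolve_name <- function(call) {
    if (call$status != "novel") return(list(name = call$best_hit))
    if (!is.null(registry)) {
      reg <- register_novel(registry, call$query_id)
      registry <<- reg$registry
      list(name = reg$nau_name)
    } else list(name = paste0("NOVEL-", call$query_id))
  }
  calls <- list(); genotypes <- list()
  hom_II <- class_calls$genotype_id[class_calls$call == "class_II"]
  hets <- class_calls$genotype_id[class_calls$call == "class_I_II"]
  for (g in hom_I) {
    cl <- type_allele(g, "prod_I")
    cl$nau_name <- resolve_name(cl)$name
    cl$genotype_id <- g; calls[[length(calls) + 1L]] <- cl
    genotypes[[g]] <- s_genotype(g, cl$nau_name, "class_I")
  }
  for (g in hom_II) {
    cl <- type_allele(g, "prod_II")
    cl$nau_name <- resolve_name(cl)$name
    cl$genotype_id <- g; calls[[length(calls) + 1L]] <- cl
    genotypes[[g]] <- s_genotype(g, cl$nau_name, "class_II")
  }
  het_rows <- list()
  for (g in hets) {
    clI <- type_allele(g, "prod_I")
    clI$nau_name <- resolve_name(clI)$name
    clII <- type_allele(g, "prod_II")
    clII$nau_name <- resolve_name(clII)$name
    clI$genotype_id <- g; clII$genotype_id <- g
    calls[[length(calls) + 1L]] <- clI
    calls[[length(calls) + 1L]] <- clII
    clI$best_hit <- clI$nau_name; clII$best_hit <- clII$nau_name
    genotypes[[g]] <- heterozygote_resolve(g, clI, clII)
    het_rows[[g]] <- data.frame(genotype_id = g,
                                hap_class_I = clI$nau_name,
                                hap_class_II = clII$nau_name,
                                stringsAsFactors = FALSE)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(query_id = character(), best_hit = character(),
               identity_pct = numeric(), status = character(),
               nau_name = character(), genotype_id = character())
  rownames(calls) <- NULL
  het_table <- if (length(het_rows)) do.call(rbind, het_rows) else
    data.frame(genotype_id = character(), hap_class_I = character(),
               hap_class_II = character())
  rownames(het_table) <- NULL
  freq_I <- tally_frequencies(calls[calls$genotype_id %in% hom_I, ,
                                    drop = FALSE])
  freq_II <- tally_frequencies(calls[calls$genotype_id %in% hom_II, ,
                                     drop = FALSE])
  message(sprintf("stype: typed %d allele(s); %d novel",
                  nrow(calls), sum(calls$status == "novel")))

  # stage 4: cross concordance (optional) ------------------------------
  cross_report <- NULL
  if (!is.null(pollination) && nrow(pollination)) {
    missing_g <- setdiff(unique(c(pollination$female_id,
                                  pollination$male_id)), names(genotypes))
    if (length(missing_g))
      stop("pollination stage: cross references untyped genotype(s): ",
           paste(missing_g, collapse = ", "), call. = FALSE)
    stage <- if (is.null(pollination$stage)) "flower" else pollination$stage
    preds <- do.call(rbind, lapply(seq_len(nrow(pollination)), function(i)
      predict_cross(genotypes[[pollination$female_id[i]]],
                    genotypes[[pollination$male_id[i]]],
                    if (length(stage) == 1L) stage else stage[i])))
    outcomes <- score_pollination(pollination)
    cross_report <- list(predictions = preds, outcomes = outcomes,
                         concordance = concordance(preds, outcomes))
    message(sprintf("stype: cross concordance %d/%d",
                    cross_report$concordance$n_agree,
                    cross_report$concordance$n))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("stype")),
    parameters = list(threshold = threshold, max_mismatch = max_mismatch,
                      resolution_pct = resolution_pct,
                      min_detect = min_detect),
    counts = list(n_sequences = nrow(seqs),
                  n_genotypes = length(genotype_ids),
                  partition = stats::setNames(as.list(as.integer(counts)),
                                              lv),
                  n_profiles = rflp$n_profiles,
                  n_typed_alleles = nrow(calls),
                  n_crosses = if (is.null(cross_report)) 0L else
                    cross_report$concordance$n))

  out <- list(class_calls = class_calls, partition = partition,
              rflp = rflp, calls = calls, freq_class_I = freq_I,
              freq_class_II = freq_II, het_table = het_table,
              genotypes = genotypes, cross_report = cross_report,
              registry = registry, manifest = manifest)
  class(out) <- "stype_run"
  if (!is.null(outdir)) .write_run(out, outdir)
  out
}

.write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(run$class_calls, "class_calls.tsv")
  wt(run$partition, "class_partition.tsv")
  wt(run$rflp$assignments, "rflp_profiles.tsv")
  wt(run$calls, "haplotype_calls.tsv")
  wt(run$freq_class_I, "frequencies_class_I.tsv")
  wt(run$freq_class_II, "frequencies_class_II.tsv")
  wt(run$het_table, "heterozygotes.tsv")
  if (!is.null(run$cross_report)) {
    wt(run$cross_report$outcomes, "pollination_outcomes.tsv")
    wt(run$cross_report$predictions, "cross_predictions.tsv")
  }
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.stype_run <- function(x, ...) {
  cat("S-haplotype typing run\n")
  cat("  genotypes:", x$manifest$counts$n_genotypes,
      sprintf("(I=%d, II=%d, I/II=%d, none=%d)\n",
              x$manifest$counts$partition$class_I,
              x$manifest$counts$partition$class_II,
              x$manifest$counts$partition$class_I_II,
              x$manifest$counts$partition$none))
  cat("  gel profiles among Class I:", x$rflp$n_profiles, "\n")
  cat("  typed alleles:", nrow(x$calls),
      sprintf("(%d novel)\n", sum(x$calls$status == "novel")))
  if (!is.null(x$cross_report))
    cat(sprintf("  cross concordance: %d/%d\n",
                x$cross_report$concordance$n_agree,
                x$cross_report$concordance$n))
  invisible(x)
}
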