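# The two end-to-end workflows: a vaccine-panel analysis of a single tumor
# (relaxed threshold, per-mutation counting, no loci scaling) and a
# cohort-level burden analysis (high-affinity threshold, per-peptide
# counting, x3 loci scaling). A thin command-line wrapper lives in
# inst/cli/neoburden.R.

#' Default parameters for the vaccine-panel workflow
#'
#' Per-mutation counting at the relaxed 1500 nM cutoff with no loci scaling
#' (the typed alleles are the organism's full complement).
#'
#' @return A [burden_params()].
#' @export
panel_params <- function() {
  burden_params(counting_mode = "per_mutation", threshold_nM = 1500,
                loci_scale = 1)
}

#' Run the vaccine-panel workflow on one tumor
#'
#' Filters the mutation table through the funnel, enumerates 8-11mer
#' candidate windows for every retained mutation, reduces the binding calls
#' to the best epitope per mutation, applies the binder threshold, and
#' designs a long vaccine peptide for every predicted binder. The returned
#' funnel appends the binder count to the filter audit:
#' input -> transcribed -> eligible class -> predicted binders.
#'
#' @param mutations Mutation data.frame (see [read_mutation_table()]).
#' @param proteome Named list of [protein_record()]s.
#' @param alleles An [allele_set()] or character vector of allele names.
#' @param calls Binding calls covering every window-allele pair.
#' @param params A [burden_params()]; defaults to [panel_params()].
#' @param flank Vaccine-peptide flank length (default 14, giving 29mers).
#' @param out_dir Optional directory; when given, the audit, the
#'   per-mutation affinity table, the binder panel and a provenance record
#'   are written there.
#' @return Object of class `panel_result`: `funnel` (named counts), `audit`
#'   (the `funnel_audit`), `mutation_summary` (best affinity per retained
#'   mutation), `panel` (binders only, with vaccine peptides), `params`.
#' @export
run_panel <- function(mutations, proteome, alleles, calls,
                      params = panel_params(), flank = 14L, out_dir = NULL) {
  stopifnot(inherits(params, "burden_params"))
  filt <- filter_mutations(mutations)
  kept <- filt$mutations
  missing <- setdiff(unique(kept$protein_id), names(proteome))
  if (length(missing)) {
    stop("proteome is missing protein(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- vector("list", nrow(kept))
  for (i in seq_len(nrow(kept))) {
    ctx <- apply_mutation(proteome[[kept$protein_id[i]]], kept[i, ])
    w <- enumerate_class1_windows(ctx)
    best <- best_affinity_per_mutation(calls, w, alleles)
    substitution <- if (kept$variant_class[i] == "missense") {
      paste0(kept$ref_aa[i], kept$position[i], kept$alt_aa[i])
    } else {
      paste0(kept$position[i], "_", kept$variant_class[i])
    }
    rows[[i]] <- data.frame(
      sample_id = kept$sample_id[i], gene = kept$gene[i],
      substitution = substitution, variant_class = kept$variant_class[i],
      epitope = best$peptide, ic50_nM = best$ic50_nM, allele = best$allele,
      rna_reads_ref = kept$rna_reads_ref[i],
      rna_reads_alt = kept$rna_reads_alt[i],
      vaccine_peptide = design_vaccine_peptide(ctx, flank = flank),
      stringsAsFactors = FALSE)
  }
  mutation_summary <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(mutation_summary)) {
    panel <- NULL
  } else {
    panel <- mutation_summary[classify_binder(mutation_summary$ic50_nM,
                                              params$threshold_nM), ,
                              drop = FALSE]
    rownames(panel) <- NULL
  }
  n_binders <- if (is.null(panel)) 0L else nrow(panel)
  if (n_binders == 0L) {
    warning("no mutation carries a predicted binder below ",
            params$threshold_nM, " nM; the vaccine panel is empty")
  }
  funnel <- c(n_input = filt$audit$n_input,
              n_transcribed = filt$audit$n_after_expression,
              n_class = filt$audit$n_after_class,
              n_binders = n_binders)
  res <- structure(list(funnel = funnel, audit = filt$audit,
                        mutation_summary = mutation_summary, panel = panel,
                        params = params), class = "panel_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(data.frame(stage = names(as.integer(filt$audit)),
                                  count = as.integer(filt$audit)),
                       file.path(out_dir, "funnel_audit.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(mutation_summary)) {
      utils::write.table(mutation_summary,
                         file.path(out_dir, "mutation_affinities.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(panel)) {
      utils::write.table(panel, file.path(out_dir, "vaccine_panel.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_provenance(file.path(out_dir, "provenance.json"),
                     workflow = "panel", params = params)
  }
  res
}

#' @export
print.panel_result <- function(x, ...) {
  cat("Vaccine panel workflow\n")
  cat("  funnel:", paste(sprintf("%s=%d", names(x$funnel), x$funnel),
                         collapse = " -> "), "\n")
  cat("  threshold:", x$params$threshold_nM, "nM;",
      if (is.null(x$panel)) 0L else nrow(x$panel), "peptides designed\n")
  invisible(x)
}

#' Run the cohort burden workflow
#'
#' For every sample with an unambiguous allele call: filter its mutations,
#' enumerate candidate windows, count predicted neoantigens at the typed
#' loci, extrapolate across loci (from the allele set's typed/total counts),
#' and apply the authenticity model. Samples with ambiguous allele calls are
#' dropped with a message.
#'
#' @param mutations Cohort mutation data.frame.
#' @param proteome Named list of [protein_record()]s.
#' @param allele_sets Named list of [allele_set()]s (one per sample).
#' @param calls Binding calls; a `sample_id` column restricts lookups per
#'   sample.
#' @param params A [burden_params()].
#' @param out_dir Optional directory for the burden table, summary JSON,
#'   rank table and provenance record.
#' @return Object of class `cohort_result`: `burdens` (per-sample table),
#'   `summary` (a `cohort_summary`), `n_ambiguous`.
#' @export
run_cohort <- function(mutations, proteome, allele_sets, calls,
                       params = burden_params(), out_dir = NULL) {
  stopifnot(inherits(params, "burden_params"))
  ok <- vapply(allele_sets, function(a) a$unambiguous, logical(1))
  n_ambiguous <- sum(!ok)
  if (n_ambiguous > 0L) {
    message("dropping ", n_ambiguous, " sample(s) with ambiguous allele calls")
  }
  allele_sets <- allele_sets[ok]
  if (length(allele_sets) == 0L) {
    stop("no samples with unambiguous allele calls remain", call. = FALSE)
  }
  has_sample_col <- !is.null(calls) && "sample_id" %in% names(calls)
  burdens <- vector("list", length(allele_sets))
  for (s in seq_along(allele_sets)) {
    aset <- allele_sets[[s]]
    m <- mutations[mutations$sample_id == aset$sample_id, , drop = FALSE]
    pre <- m[m$somatic & !m$in_dbsnp & m$variant_class != "synonymous", ,
             drop = FALSE]
    n_total <- nrow(pre)
    n_transcribed <- sum(pre$rna_reads_alt >= 1L)
    filt <- filter_mutations(m)
    w <- mutant_windows(filt$mutations, proteome)
    sample_calls <- if (has_sample_col) {
      calls[calls$sample_id == aset$sample_id, , drop = FALSE]
    } else calls
    n_pred <- count_predicted_neoantigens(w, sample_calls, aset, params)
    N <- scale_loci(n_pred, aset$typed_loci, aset$total_loci)
    burdens[[s]] <- data.frame(
      sample_id = aset$sample_id, n_total = n_total,
      n_transcribed = n_transcribed, n_predicted_raw = n_pred, N = N,
      E = expected_authentic(N, params$authenticity_rate),
      P = prob_at_least_one(N, params$authenticity_rate),
      stringsAsFactors = FALSE)
  }
  burdens <- do.call(rbind, burdens)
  summary <- summarize_cohort(burdens, params)
  res <- structure(list(burdens = summary$samples, summary = summary,
                        n_ambiguous = n_ambiguous, params = params),
                   class = "cohort_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_burden_table(summary$samples, file.path(out_dir, "sample_burden.tsv"))
    write_cohort_summary(summary, file.path(out_dir, "cohort_summary.json"))
    rank_tab <- cbind(rank = seq_len(nrow(summary$samples)),
                      summary$samples[, c("sample_id", "n_total",
                                          "n_transcribed", "N", "P")])
    utils::write.table(rank_tab, file.path(out_dir, "rank_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_provenance(file.path(out_dir, "provenance.json"),
                     workflow = "cohort", params = params)
  }
  res
}

#' @export
print.cohort_result <- function(x, ...) {
  print(x$summary)
  if (x$n_ambiguous > 0L) {
    cat("  (", x$n_ambiguous, " ambiguous sample(s) dropped)\n", sep = "")
  }
  invisible(x)
}

#' Simulate a cohort and write its input files
#'
#' Generates a proteome (unless one is supplied), simulates the cohort, and
#' writes every file dialect the pipeline consumes — mutation TSV, protein
#' FASTA, allele TSV, binding-call TSV — plus a truth JSON and a provenance
#' record. The outputs round-trip through [run_cohort()].
#'
#' @param config A [cohort_sim_config()].
#' @param out_dir Output directory.
#' @param proteome Optional named list of [protein_record()]s; by default
#'   500 proteins of 100-300 residues are generated from the config seed.
#' @return The `cohort_sim` object, invisibly.
#' @export
run_simulate <- function(config, out_dir, proteome = NULL) {
  stopifnot(inherits(config, "cohort_sim_config"))
  if (is.null(proteome)) {
    proteome <- simulate_proteome(500L, c(100L, 300L), seed = config$seed)
  }
  sim <- simulate_cohort(config, proteome)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_mutation_table(sim$mutations, file.path(out_dir, "mutations.tsv"))
  write_protein_fasta(sim$proteome, file.path(out_dir, "proteome.fasta"))
  allele_tab <- do.call(rbind, lapply(sim$allele_sets, function(a) {
    data.frame(sample_id = a$sample_id, allele = a$alleles,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(allele_tab, file.path(out_dir, "alleles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$calls)) {
    utils::write.table(sim$calls, file.path(out_dir, "binding_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(file.path(out_dir, "provenance.json"),
                   workflow = "simulate",
                   params = unclass(config))
  invisible(sim)
}

# Machine-readable record of how an output directory was produced.
#' @keywords internal
write_provenance <- function(path, workflow, params) {
  jsonlite::write_json(
    list(workflow = workflow,
         params = unclass(params),
         package = "neoburden",
         package_version = as.character(utils::packageVersion("neoburden")),
         r_version = paste(R.version$major, R.version$minor, sep = ".")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
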