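# The binomial authenticity model and cohort-level neoantigen-burden
# statistics.
#
# Of peptides predicted to bind MHC class I with high affinity, empirically
# only a fraction a (default 0.08) prove to be authentic epitopes —
# naturally processed, presented, and recognized by autologous T cells.
# Treating a sample's N predicted neoantigens as independent trials, the
# chance that none is authentic is (1 - a)^N, hence
# P(at least one authentic) = 1 - (1 - a)^N.

#' Burden-model parameters
#'
#' Bundles the tunable parameters of the neoantigen-burden analysis.
#'
#' @param authenticity_rate Fraction `a` of predicted high-affinity binders
#'   that are authentic epitopes (default 0.08, a literature-derived
#'   constant; exposed for sensitivity sweeps).
#' @param loci_scale Factor extrapolating counts from typed loci to the full
#'   class I complement (default 3: one typed HLA-A locus of three).
#' @param threshold_nM IC50 threshold below which a peptide counts as a
#'   predicted binder (default 100 nM, high affinity).
#' @param counting_mode `"per_peptide"` counts distinct sub-threshold window
#'   sequences (cohort burden analysis); `"per_mutation"` counts mutations
#'   with at least one such window (vaccine panel analysis).
#' @param likelihood_cutoff Probability cutoff used when reporting the
#'   fraction of a cohort likely to harbor an authentic neoantigen
#'   (default 0.90).
#' @return An object of class `burden_params`.
#' @export
burden_params <- function(authenticity_rate = 0.08, loci_scale = 3,
                          counting_mode = c("per_peptide", "per_mutation"),
                          threshold_nM = 100, likelihood_cutoff = 0.90) {
  counting_mode <- match.arg(counting_mode)
  if (authenticity_rate <= 0 || authenticity_rate >= 1) {
    stop("authenticity_rate must lie in (0, 1)", call. = FALSE)
  }
  if (loci_scale <= 0) stop("loci_scale must be positive", call. = FALSE)
  if (threshold_nM <= 0) stop("threshold_nM must be positive", call. = FALSE)
  if (likelihood_cutoff <= 0 || likelihood_cutoff >= 1) {
    stop("likelihood_cutoff must lie in (0, 1)", call. = FALSE)
  }
  structure(list(authenticity_rate = authenticity_rate,
                 loci_scale = loci_scale, threshold_nM = threshold_nM,
                 counting_mode = counting_mode,
                 likelihood_cutoff = likelihood_cutoff),
            class = "burden_params")
}

#' @export
print.burden_params <- function(x, ...) {
  cat("<burden_params> a =", x$authenticity_rate,
      "| loci scale =", x$loci_scale,
      "| threshold =", x$threshold_nM, "nM",
      "| counting =", x$counting_mode,
      "| likelihood cutoff =", x$likelihood_cutoff, "\n")
  invisible(x)
}

#' Expected number of authentic neoantigens
#'
#' `E = a * N`: the predicted neoantigen count discounted by the
#' authenticity rate.
#'
#' @param N Scaled predicted-neoantigen count (may be fractional);
#'   vectorized.
#' @param a Authenticity rate in (0, 1).
#' @return `a * N`.
#' @examples
#' expected_authentic(6, 0.08)   # 0.48
#' expected_authentic(27, 0.08)  # 2.16
#' @export
expected_authentic <- function(N, a = 0.08) {
  if (length(a) != 1L || is.na(a) || a <= 0 || a >= 1) {
    stop("authenticity rate a must lie in (0, 1)", call. = FALSE)
  }
  if (any(N < 0)) stop("N must be nonnegative", call. = FALSE)
  a * N
}

#' Probability of harboring at least one authentic neoantigen
#'
#' `P = 1 - (1 - a)^N`. With the default `a = 0.08` this is
#' `1 - 0.92^N`; N may be non-integer because counts extrapolated across
#' loci are real-valued.
#'
#' @inheritParams expected_authentic
#' @return Probability in `[0, 1]`; vectorized over `N`.
#' @examples
#' prob_at_least_one(6, 0.08)   # ~0.39
#' prob_at_least_one(27, 0.08)  # ~0.89
#' @export
prob_at_least_one <- function(N, a = 0.08) {
  if (length(a) != 1L || is.na(a) || a <= 0 || a >= 1) {
    stop("authenticity rate a must lie in (0, 1)", call. = FALSE)
  }
  if (any(N < 0)) stop("N must be nonnegative", call. = FALSE)
  1 - (1 - a)^N
}

#' Smallest predicted-neoantigen count reaching a likelihood cutoff
#'
#' The minimum integer `N` with `prob_at_least_one(N, a) >= cutoff`
#' (28 at the defaults `a = 0.08`, `cutoff = 0.90`).
#'
#' @param a Authenticity rate in (0, 1).
#' @param cutoff Likelihood cutoff in (0, 1).
#' @return Integer threshold on `N`.
#' @export
min_n_for_likelihood <- function(a = 0.08, cutoff = 0.90) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)", call. = FALSE)
  as.integer(ceiling(log(1 - cutoff) / log(1 - a)))
}

#' Extrapolate neoantigen counts across class I loci
#'
#' Counts obtained from a subset of typed loci are scaled to the organism's
#' full class I complement: `n_typed * total_loci / typed_loci`. With one
#' typed locus of three (HLA-A of A/B/C) this is the x3 rule; fractional
#' results are admitted.
#'
#' @param n_typed Count of predicted neoantigens at the typed loci.
#' @param typed_loci Number of loci the predictions cover (>= 1).
#' @param total_loci Total class I loci in the organism.
#' @return Scaled (possibly fractional) count.
#' @examples
#' scale_loci(9, 1, 3)  # 27
#' @export
scale_loci <- function(n_typed, typed_loci, total_loci) {
  if (any(typed_loci < 1) || any(typed_loci > total_loci)) {
    stop("typed_loci must satisfy 1 <= typed_loci <= total_loci", call. = FALSE)
  }
  if (any(n_typed < 0)) stop("n_typed must be nonnegative", call. = FALSE)
  n_typed * total_loci / typed_loci
}

#' Count predicted neoantigens for one sample
#'
#' Applies the threshold to the best (minimum over alleles) predicted
#' affinity of every candidate window. In `per_peptide` mode the count is
#' the number of distinct sub-threshold window sequences; in `per_mutation`
#' mode it is the number of mutations carrying at least one sub-threshold
#' window.
#'
#' @param windows Window data.frame from [mutant_windows()] for the sample's
#'   filtered mutations.
#' @param calls Binding calls covering every window-allele pair.
#' @param alleles An [allele_set()] or character vector of allele names.
#' @param params A [burden_params()] (supplies threshold and counting mode).
#' @return Integer count of predicted neoantigens at the typed loci.
#' @export
count_predicted_neoantigens <- function(windows, calls, alleles,
                                        params = burden_params()) {
  stopifnot(inherits(params, "burden_params"))
  allele_names <- if (inherits(alleles, "allele_set")) alleles$alleles else alleles
  if (nrow(windows) == 0L) return(0L)
  peptides <- unique(windows$sequence)
  grid <- expand.grid(peptide = peptides, allele = allele_names,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(paste(grid$peptide, grid$allele, sep = "\r"),
               paste(calls$peptide, calls$allele, sep = "\r"))
  if (anyNA(idx)) {
    gaps <- unique(paste0(grid$peptide[is.na(idx)], " x ",
                          grid$allele[is.na(idx)]))
    stop("missing binding calls for ", length(gaps), " window-allele pair(s): ",
         paste(utils::head(gaps, 5L), collapse = "; "),
         if (length(gaps) > 5L) " ...", call. = FALSE)
  }
  best <- tapply(calls$ic50_nM[idx], grid$peptide, min)
  is_binder <- classify_binder(as.numeric(best), params$threshold_nM)
  binder_peptides <- names(best)[is_binder]
  if (params$counting_mode == "per_peptide") {
    length(binder_peptides)
  } else {
    length(unique(windows$mutation_idx[windows$sequence %in% binder_peptides]))
  }
}

#' Assemble a per-sample burden record
#'
#' Combines the funnel counts with the scaled predicted-neoantigen count and
#' the authenticity model: `N = n_predicted_raw * loci_scale`,
#' `E = a * N`, `P = 1 - (1 - a)^N`.
#'
#' @param sample_id Sample identifier.
#' @param n_total All somatic non-synonymous mutations.
#' @param n_transcribed Those with RNA-seq support for the mutant allele.
#' @param n_predicted_raw Predicted neoantigens at the typed loci.
#' @param params A [burden_params()].
#' @return One-row data.frame: `sample_id`, `n_total`, `n_transcribed`,
#'   `n_predicted_raw`, `N`, `E`, `P`.
#' @export
sample_burden <- function(sample_id, n_total, n_transcribed, n_predicted_raw,
                          params = burden_params()) {
  stopifnot(inherits(params, "burden_params"))
  N <- n_predicted_raw * params$loci_scale
  data.frame(sample_id = sample_id, n_total = n_total,
             n_transcribed = n_transcribed,
             n_predicted_raw = n_predicted_raw, N = N,
             E = expected_authentic(N, params$authenticity_rate),
             P = prob_at_least_one(N, params$authenticity_rate),
             stringsAsFactors = FALSE)
}

#' Summarize neoantigen burden over a cohort
#'
#' Rank-orders samples by total mutation count (descending, ties by sample
#' id), takes the median of the scaled predicted-neoantigen counts `N`
#' (midpoint convention for even cohorts), and reports the fraction of
#' samples whose probability of at least one authentic neoantigen reaches
#' the likelihood cutoff.
#'
#' @param burdens data.frame of per-sample burden rows
#'   (see [sample_burden()]).
#' @param params A [burden_params()].
#' @return An object of class `cohort_summary`: `samples` (rank-ordered
#'   burden table), `median_N`, `frac_above_cutoff`, `n_samples`, `params`.
#' @export
summarize_cohort <- function(burdens, params = burden_params()) {
  stopifnot(inherits(params, "burden_params"))
  if (is.null(burdens) || nrow(burdens) == 0L) {
    stop("cohort is empty", call. = FALSE)
  }
  ord <- order(-burdens$n_total, burdens$sample_id)
  samples <- burdens[ord, , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(
    samples = samples,
    median_N = stats::median(samples$N),
    frac_above_cutoff = mean(samples$P >= params$likelihood_cutoff),
    n_samples = nrow(samples),
    params = params), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort neoantigen burden (", x$n_samples, " samples)\n", sep = "")
  cat("  median scaled predicted neoantigens N:", x$median_N, "\n")
  cat("  expected authentic at median N:",
      expected_authentic(x$median_N, x$params$authenticity_rate), "\n")
  cat("  P(>=1 authentic) at median N: ",
      percent_round(prob_at_least_one(x$median_N, x$params$authenticity_rate)),
      "%\n", sep = "")
  cat("  fraction with P >= ", x$params$likelihood_cutoff, ": ",
      sprintf("%.3f", x$frac_above_cutoff), "\n", sep = "")
  invisible(x)
}

#' Round a probability to a whole percentage (half-up)
#'
#' Reporting convention for probabilities: half-up rounding to integer
#' percent, so 0.3936 prints as 39 and 0.8948 as 89.
#'
#' @param p Probability in `[0, 1]`; vectorized.
#' @return Integer percentage.
#' @export
percent_round <- function(p) {
  as.integer(floor(p * 100 + 0.5))
}

#' Write a per-sample burden table as TSV
#'
#' @param burdens Burden data.frame ([sample_burden()] rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_burden_table <- function(burdens, path) {
  utils::write.table(burdens, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a cohort summary as JSON
#'
#' Emits `median_N`, `frac_above_cutoff`, `n_samples` and an echo of the
#' model parameters.
#'
#' @param summary A `cohort_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(summary, path) {
  stopifnot(inherits(summary, "cohort_summary"))
  jsonlite::write_json(list(median_N = summary$median_N,
                            frac_above_cutoff = summary$frac_above_cutoff,
                            n_samples = summary$n_samples,
                            params = unclass(summary$params)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
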