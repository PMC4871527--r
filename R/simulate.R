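# Seeded generators emulating the statistical structure of an ID8-like
# mouse tumor mutanome and of human tumor cohorts with intermediate
# (HGSC-like) or high (lung-like) mutation burden. Everything a generator
# emits is paired with a truth record so recovery tests can compare the
# pipeline's output against the planted composition exactly.

#' Simulate a random proteome
#'
#' Proteins with residues drawn uniformly from the 20-letter alphabet,
#' deterministic for a fixed seed. Lengths below 30 are rejected so every
#' protein admits a full 29mer vaccine peptide.
#'
#' @param n_proteins Number of proteins (0 gives an empty proteome).
#' @param length_range Two-element integer range of protein lengths.
#' @param seed Integer seed.
#' @return Named list of [protein_record()]s (`P0001`, `P0002`, ...).
#' @export
simulate_proteome <- function(n_proteins, length_range = c(100L, 300L), seed) {
  if (any(length_range < 30L)) {
    stop("protein lengths must be >= 30 to admit a full 29mer design",
         call. = FALSE)
  }
  if (n_proteins == 0L) return(stats::setNames(list(), character(0)))
  set.seed(seed)
  lens <- sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
  ids <- sprintf("P%04d", seq_len(n_proteins))
  out <- lapply(seq_len(n_proteins), function(i) {
    protein_record(ids[i], paste(sample(AA_STANDARD, lens[i], replace = TRUE),
                                 collapse = ""))
  })
  names(out) <- ids
  out
}

#' Configuration for a simulated tumor cohort
#'
#' Per-sample somatic non-synonymous mutation counts are drawn from an
#' overdispersed count distribution; each mutation is independently
#' transcribed (at least one RNA-seq read supporting the mutant allele) with
#' probability `transcribed_prob`, and each transcribed mutation
#' independently harbors one sub-threshold binding window at the typed locus
#' with probability `binder_prob`.
#'
#' Two presets pin the generator to the study conditions the package
#' emulates: `hgsc_like` (negative binomial, size 10, mean 45; median ~43
#' mutations, a narrow burden range) and `lung_like` (negative binomial,
#' size 1.2, mean 270; median ~200 with a spread over orders of magnitude).
#' Both use `transcribed_prob = 42/92` and `binder_prob = 0.10`, calibrated
#' once so the analytic median of the loci-scaled predicted-neoantigen count
#' is 6 (hgsc_like) and 27 (lung_like); see `cohort_analytics()`.
#'
#' @param n_samples Number of samples (>= 1).
#' @param burden_dist Distribution of per-sample mutation counts: a list
#'   with `family` (`"negative_binomial"` or `"log_normal"`) and its
#'   parameters (`size`/`mu`, or `meanlog`/`sdlog`; log-normal draws are
#'   rounded to counts).
#' @param transcribed_prob Per-mutation probability of RNA support, in (0,1).
#' @param binder_prob Per-transcribed-mutation probability of a planted
#'   sub-threshold window, in `[0, 1)` (0 gives a cohort with no predicted
#'   neoantigens).
#' @param preset `"hgsc_like"` or `"lung_like"`; mutually exclusive with an
#'   explicit `burden_dist`.
#' @param seed Integer seed.
#' @param background_ic50_range Background affinity range for non-planted
#'   windows; its floor sits above the binder threshold so that the planted
#'   windows are exactly the sub-threshold set (the truth record then
#'   matches the recounted data without sampling noise from the background).
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_samples, burden_dist = NULL,
                              transcribed_prob = 42 / 92,
                              binder_prob = 0.10,
                              preset = NULL, seed = 1L,
                              background_ic50_range = c(150, 50000)) {
  if (!is.null(preset) && !is.null(burden_dist)) {
    stop("give either a preset or an explicit burden_dist, not both",
         call. = FALSE)
  }
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("hgsc_like", "lung_like"))
    burden_dist <- switch(preset,
      hgsc_like = list(family = "negative_binomial", size = 10, mu = 45),
      lung_like = list(family = "negative_binomial", size = 1.2, mu = 270))
  }
  if (is.null(burden_dist)) {
    burden_dist <- list(family = "negative_binomial", size = 10, mu = 45)
  }
  if (!burden_dist$family %in% c("negative_binomial", "log_normal")) {
    stop("burden_dist$family must be 'negative_binomial' or 'log_normal'",
         call. = FALSE)
  }
  if (n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  if (transcribed_prob <= 0 || transcribed_prob >= 1) {
    stop("transcribed_prob must lie in (0, 1)", call. = FALSE)
  }
  if (binder_prob < 0 || binder_prob >= 1) {
    stop("binder_prob must lie in [0, 1)", call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples), burden_dist = burden_dist,
                 transcribed_prob = transcribed_prob,
                 binder_prob = binder_prob, preset = preset,
                 seed = as.integer(seed),
                 background_ic50_range = background_ic50_range),
            class = "cohort_sim_config")
}

# Draw per-sample mutation counts under the configured burden distribution.
#' @keywords internal
draw_burden <- function(config, n) {
  d <- config$burden_dist
  if (d$family == "negative_binomial") {
    stats::rnbinom(n, size = d$size, mu = d$mu)
  } else {
    pmax(0L, as.integer(round(stats::rlnorm(n, d$meanlog, d$sdlog))))
  }
}

# Marginal pmf of the per-sample mutation count on 0..nmax.
#' @keywords internal
burden_pmf <- function(config, nmax) {
  d <- config$burden_dist
  n <- 0:nmax
  if (d$family == "negative_binomial") {
    stats::dnbinom(n, size = d$size, mu = d$mu)
  } else {
    stats::plnorm(n + 0.5, d$meanlog, d$sdlog) -
      stats::plnorm(pmax(n - 0.5, 0), d$meanlog, d$sdlog)
  }
}

#' Analytic burden summaries implied by a simulation configuration
#'
#' Under the generative model, the raw (typed-locus) predicted-neoantigen
#' count of a sample with `n` mutations is Binomial(`n`, q) with
#' `q = transcribed_prob * binder_prob`. Marginalizing over the burden
#' distribution gives the exact median of the scaled count
#' `N = loci_scale * raw` and the exact fraction of samples with
#' `P(at least one authentic) >= likelihood_cutoff` — the values the
#' empirical cohort statistics converge to, used in parameter-recovery
#' tests.
#'
#' @param config A [cohort_sim_config()].
#' @param params A [burden_params()].
#' @param loci_scale Scaling from typed to total loci (default 3).
#' @return List with `median_N`, `frac_above_cutoff`, `raw_threshold` (the
#'   smallest raw count reaching the cutoff).
#' @export
cohort_analytics <- function(config, params = burden_params(),
                             loci_scale = 3) {
  stopifnot(inherits(config, "cohort_sim_config"))
  q <- config$transcribed_prob * config$binder_prob
  d <- config$burden_dist
  nmax <- if (d$family == "negative_binomial") {
    stats::qnbinom(1 - 1e-12, size = d$size, mu = d$mu)
  } else {
    as.integer(stats::qlnorm(1 - 1e-12, d$meanlog, d$sdlog)) + 1L
  }
  pmf <- burden_pmf(config, nmax)
  n <- 0:nmax
  marg_cdf <- function(k) sum(pmf * stats::pbinom(k, n, q))
  k <- 0L
  while (marg_cdf(k) < 0.5) k <- k + 1L
  median_raw <- k
  # P >= cutoff  <=>  N = loci_scale * raw >= log(1-cutoff)/log(1-a)
  raw_thr <- ceiling(log(1 - params$likelihood_cutoff) /
                       log(1 - params$authenticity_rate) / loci_scale)
  frac <- sum(pmf * (1 - stats::pbinom(raw_thr - 1, n, q)))
  list(median_N = median_raw * loci_scale, frac_above_cutoff = frac,
       raw_threshold = as.integer(raw_thr))
}

#' Simulate a tumor cohort with planted neoantigens
#'
#' Per sample: draw the somatic non-synonymous mutation count from the
#' burden distribution; place each mutation as a missense substitution at a
#' distinct random proteome position; mark it transcribed (mutant-allele
#' RNA reads >= 1, drawn from a geometric-like tail) with
#' `transcribed_prob`; among transcribed mutations, plant a sub-threshold
#' binding window with `binder_prob` by adding one 11mer mutant window to
#' the synthetic predictor's anchor-motif list. Affinities for every
#' candidate window of every expressed mutation are emitted via
#' [synthetic_predict()]; each sample gets two HLA-A alleles (one typed
#' locus of three).
#'
#' @param config A [cohort_sim_config()].
#' @param proteome Named list of [protein_record()]s.
#' @return List of class `cohort_sim`: `mutations` (one table for the whole
#'   cohort), `allele_sets` (named list of [allele_set()]), `calls` (binding
#'   calls with a `sample_id` column), `truth` (per-sample planted counts
#'   and motifs), `proteome`, `config`.
#' @export
simulate_cohort <- function(config, proteome) {
  stopifnot(inherits(config, "cohort_sim_config"), length(proteome) > 0L)
  set.seed(config$seed)
  ns <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(ns))
  hla_pool <- c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01",
                "HLA-A*11:01", "HLA-A*24:02")
  prot_ids <- names(proteome)
  prot_len <- vapply(proteome, function(p) nchar(p$sequence), integer(1))

  n_total <- draw_burden(config, ns)
  mut_list <- vector("list", ns)
  call_list <- vector("list", ns)
  allele_sets <- vector("list", ns)
  truth_rows <- vector("list", ns)
  truth_motifs <- vector("list", ns)

  for (s in seq_len(ns)) {
    alle <- sample(hla_pool, 2L, replace = TRUE)
    allele_sets[[s]] <- allele_set(sample_ids[s], unique(alle),
                                   typed_loci = 1L, total_loci = 3L)
    nm <- n_total[s]
    if (nm == 0L) {
      mut_list[[s]] <- NULL
      truth_rows[[s]] <- data.frame(sample_id = sample_ids[s], n_total = 0L,
                                    n_transcribed = 0L, n_binders = 0L,
                                    stringsAsFactors = FALSE)
      truth_motifs[[s]] <- character(0)
      next
    }
    # distinct (protein, position) pairs per sample
    pidx <- sample(length(proteome), nm, replace = TRUE)
    pos <- 1L + as.integer(floor(stats::runif(nm) * prot_len[pidx]))
    key <- paste(pidx, pos)
    while (anyDuplicated(key)) {
      dup <- duplicated(key)
      pidx[dup] <- sample(length(proteome), sum(dup), replace = TRUE)
      pos[dup] <- 1L + as.integer(floor(stats::runif(sum(dup)) * prot_len[pidx[dup]]))
      key <- paste(pidx, pos)
    }
    ref <- substring(vapply(proteome[pidx], `[[`, character(1), "sequence"),
                     pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(AA_STANDARD, r), 1L),
                  character(1), USE.NAMES = FALSE)
    transcribed <- stats::runif(nm) < config$transcribed_prob
    reads_alt <- ifelse(transcribed,
                        pmin(stats::rgeom(nm, 0.02) + 1L, 2000L), 0L)
    reads_ref <- pmin(stats::rgeom(nm, 0.02), 2000L)
    binder <- transcribed & stats::runif(nm) < config$binder_prob
    m <- data.frame(sample_id = sample_ids[s], gene = prot_ids[pidx],
                    protein_id = prot_ids[pidx], variant_class = "missense",
                    position = pos, ref_aa = ref, alt_aa = alt,
                    rna_reads_ref = as.integer(reads_ref),
                    rna_reads_alt = as.integer(reads_alt),
                    in_dbsnp = FALSE, somatic = TRUE,
                    stringsAsFactors = FALSE)
    mut_list[[s]] <- m

    kept <- m[m$rna_reads_alt >= 1L, , drop = FALSE]
    motifs <- character(0)
    for (i in which(binder & transcribed)) {
      ctx <- apply_mutation(proteome[[pidx[i]]], m[i, ])
      L <- nchar(ctx$mut_sequence)
      start <- min(max(1L, pos[i] - 5L), L - 10L)
      motifs <- c(motifs, substr(ctx$mut_sequence, start, start + 10L))
    }
    truth_motifs[[s]] <- motifs
    truth_rows[[s]] <- data.frame(sample_id = sample_ids[s],
                                  n_total = nm,
                                  n_transcribed = sum(transcribed),
                                  n_binders = sum(binder),
                                  stringsAsFactors = FALSE)
    if (nrow(kept)) {
      w <- mutant_windows(kept, proteome)
      calls <- synthetic_predict(unique(w$sequence),
                                 allele_sets[[s]]$alleles,
                                 seed = config$seed,
                                 strong_motifs = motifs,
                                 ic50_range = config$background_ic50_range)
      calls$sample_id <- sample_ids[s]
      call_list[[s]] <- calls
    }
  }

  mutations <- do.call(rbind, mut_list[!vapply(mut_list, is.null, logical(1))])
  if (is.null(mutations)) {
    mutations <- data.frame(sample_id = character(0), gene = character(0),
                            protein_id = character(0),
                            variant_class = character(0), position = integer(0),
                            ref_aa = character(0), alt_aa = character(0),
                            rna_reads_ref = integer(0),
                            rna_reads_alt = integer(0), in_dbsnp = logical(0),
                            somatic = logical(0), stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, call_list[!vapply(call_list, is.null, logical(1))])
  names(allele_sets) <- sample_ids
  structure(list(mutations = mutations, allele_sets = allele_sets,
                 calls = calls,
                 truth = list(samples = do.call(rbind, truth_rows),
                              motifs = stats::setNames(truth_motifs, sample_ids)),
                 proteome = proteome, config = config),
            class = "cohort_sim")
}

#' Seeded single-sample fixture with a planted filtering funnel
#'
#' Builds a mouse-style tumor mutanome whose composition is planted by
#' construction: 92 somatic tumor-specific mutations, of which 42 carry at
#' least one RNA-seq read supporting the mutant allele, 39 of those are
#' missense/indel/frameshift (3 transcribed nonsense mutations are planted),
#' and 17 harbor a candidate window with predicted IC50 in the intermediate
#' 103-1160 nM range (all other windows sit above 1500 nM, so the panel at a
#' relaxed 1500 nM cutoff has exactly 17 members and the high-affinity count
#' at 100 nM is zero). Running the real filtering, enumeration and
#' classification pipeline on the fixture must recover these planted counts;
#' the fixture tests the pipeline's logic, not tumor biology.
#'
#' @param seed Integer seed; outputs are byte-identical for equal seeds.
#' @return List of class `id8_fixture`: `mutations`, `proteome`, `alleles`
#'   (an [allele_set()] with the two H-2 alleles), `calls`, and `truth`
#'   (planted funnel counts and binder motifs).
#' @export
make_id8_fixture <- function(seed = 8L) {
  set.seed(seed)
  proteome <- simulate_proteome(92L, c(80L, 200L), seed = seed + 1L)
  set.seed(seed + 2L)
  ids <- names(proteome)
  lens <- vapply(proteome, function(p) nchar(p$sequence), integer(1))

  # planted composition: rows 1..42 transcribed (rows 1..39 eligible class,
  # rows 40..42 nonsense), rows 43..92 untranscribed
  n <- 92L
  transcribed <- c(rep(TRUE, 42L), rep(FALSE, 50L))
  vclass <- rep("missense", n)
  vclass[40:42] <- "nonsense"
  vclass[sample(43:92, 4L)] <- "nonsense"   # some untranscribed nonsense too
  vclass[38L] <- "frameshift"
  vclass[39L] <- "inframe_indel"
  binder_rows <- sort(c(sample(1:37, 16L), 38L))  # 16 missense + the frameshift

  pos <- 15L + as.integer(floor(stats::runif(n) * (lens - 29L)))
  ref <- substring(vapply(proteome, `[[`, character(1), "sequence"), pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(AA_STANDARD, r), 1L),
                character(1), USE.NAMES = FALSE)
  alt[vclass == "nonsense"] <- "*"
  ref[vclass == "frameshift"] <- ""
  alt[vclass == "frameshift"] <- paste(sample(AA_STANDARD, 12L, replace = TRUE),
                                       collapse = "")
  i_ind <- which(vclass == "inframe_indel")
  ref[i_ind] <- substring(proteome[[i_ind]]$sequence, pos[i_ind], pos[i_ind] + 1L)
  alt[i_ind] <- ""

  reads_alt <- ifelse(transcribed, pmin(stats::rgeom(n, 0.02) + 1L, 2000L), 0L)
  reads_ref <- pmin(stats::rgeom(n, 0.02), 2000L)
  reads_ref[sample(which(transcribed), 3L)] <- 0L  # mutant-only expression

  mutations <- data.frame(sample_id = "ID8_G7", gene = ids, protein_id = ids,
                          variant_class = vclass, position = pos,
                          ref_aa = ref, alt_aa = alt,
                          rna_reads_ref = as.integer(reads_ref),
                          rna_reads_alt = as.integer(reads_alt),
                          in_dbsnp = FALSE, somatic = TRUE,
                          stringsAsFactors = FALSE)

  alleles <- allele_set("ID8_G7", c("H-2-Kb", "H-2-Db"),
                        typed_loci = 2L, total_loci = 2L)

  kept <- filter_mutations(mutations)$mutations
  motifs <- character(0)
  for (i in binder_rows) {
    ctx <- apply_mutation(proteome[[mutations$protein_id[i]]], mutations[i, ])
    novel <- min(ctx$novel_positions)
    L <- nchar(ctx$mut_sequence)
    start <- min(max(1L, novel - 5L), L - 10L)
    motifs <- c(motifs, substr(ctx$mut_sequence, start, start + 10L))
  }
  w <- mutant_windows(kept, proteome)
  calls <- synthetic_predict(unique(w$sequence), alleles$alleles, seed = seed,
                             strong_motifs = motifs,
                             ic50_range = c(1600, 50000),
                             motif_range = c(103, 1160))
  calls$sample_id <- "ID8_G7"

  structure(list(mutations = mutations, proteome = proteome,
                 alleles = alleles, calls = calls,
                 truth = list(funnel = c(n_input = 92L, n_transcribed = 42L,
                                         n_class = 39L, n_binders = 17L),
                              binder_rows = binder_rows, motifs = motifs)),
            class = "id8_fixture")
}
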