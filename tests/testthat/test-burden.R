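# The authenticity probability model and cohort burden statistics.

test_that("expected authentic count is a*N and linear in N", {
  expect_equal(expected_authentic(6, 0.08), 0.48)
  expect_equal(expected_authentic(27, 0.08), 2.16)
  expect_equal(expected_authentic(0, 0.08), 0)
  set.seed(1)
  n1 <- runif(20, 0, 50); n2 <- runif(20, 0, 50)
  expect_equal(expected_authentic(n1 + n2, 0.3),
               expected_authentic(n1, 0.3) + expected_authentic(n2, 0.3))
  expect_error(expected_authentic(5, 1), "\\(0, 1\\)")
  expect_error(expected_authentic(-1, 0.08), "nonnegative")
})

test_that("probability of at least one authentic neoantigen follows 1-(1-a)^N", {
  expect_equal(prob_at_least_one(6, 0.08), 1 - 0.92^6)
  expect_equal(prob_at_least_one(27, 0.08), 1 - 0.92^27)
  expect_equal(percent_round(prob_at_least_one(6, 0.08)), 39L)
  expect_equal(percent_round(prob_at_least_one(27, 0.08)), 89L)
  expect_equal(prob_at_least_one(0, 0.4), 0)
  # closed-form identity and strict monotonicity in N and a
  N <- seq(0, 60, by = 0.5)
  expect_equal(prob_at_least_one(N, 0.08), 1 - exp(N * log(0.92)))
  expect_true(all(diff(prob_at_least_one(N, 0.08)) > 0))
  a_grid <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(vapply(a_grid, prob_at_least_one, numeric(1), N = 7)) > 0))
  expect_error(prob_at_least_one(5, 0), "\\(0, 1\\)")
  expect_error(prob_at_least_one(-2, 0.08), "nonnegative")
})

test_that("the likelihood threshold on N matches brute-force search", {
  brute <- function(a, cutoff) {
    for (n in 1:1000) if (prob_at_least_one(n, a) >= cutoff) return(n)
    NA_integer_
  }
  expect_equal(min_n_for_likelihood(0.08, 0.90), brute(0.08, 0.90))
  expect_equal(min_n_for_likelihood(0.08, 0.90), 28L)
  for (a in c(0.02, 0.05, 0.08, 0.2, 0.5)) {
    for (cutoff in c(0.5, 0.8, 0.9, 0.95)) {
      expect_equal(min_n_for_likelihood(a, cutoff), brute(a, cutoff))
    }
  }
})

test_that("loci scaling extrapolates typed counts to the full complement", {
  expect_equal(scale_loci(9, 1, 3), 27)
  expect_equal(scale_loci(9, 3, 3), 9)   # fully typed: no extrapolation
  expect_equal(scale_loci(5, 2, 3), 7.5) # fractional counts admitted
  expect_error(scale_loci(5, 0, 3), "typed_loci")
  expect_error(scale_loci(-1, 1, 3), "nonnegative")
})

test_that("counting modes agree with their definitions", {
  # one mutation, windows with exactly 2 sub-threshold sequences
  w <- data.frame(mutation_idx = 1L,
                  sequence = sprintf("PEPTIDE%02d", 1:38),
                  start = 1:38, length = 9L, stringsAsFactors = FALSE)
  ic <- rep(5000, 38); ic[c(4, 20)] <- c(50, 80)
  calls <- data.frame(peptide = w$sequence, allele = "A1", ic50_nM = ic,
                      stringsAsFactors = FALSE)
  expect_equal(count_predicted_neoantigens(w, calls, "A1",
                 burden_params(counting_mode = "per_peptide")), 2L)
  expect_equal(count_predicted_neoantigens(w, calls, "A1",
                 burden_params(counting_mode = "per_mutation")), 1L)
  # no sub-threshold windows: zero in both modes
  calls$ic50_nM <- 5000
  expect_equal(count_predicted_neoantigens(w, calls, "A1",
                 burden_params(counting_mode = "per_peptide")), 0L)
  expect_equal(count_predicted_neoantigens(w, calls, "A1",
                 burden_params(counting_mode = "per_mutation")), 0L)
})

test_that("planted binder fixture recounts correctly in both modes", {
  # 10 mutations x 5 windows; binders planted in mutations 2, 5, 9 with
  # 4 + 1 + 1 sub-threshold windows respectively
  set.seed(53)
  w <- data.frame(mutation_idx = rep(1:10, each = 5),
                  sequence = replicate(50, random_protein_seq(9)),
                  start = rep(1:5, 10), length = 9L, stringsAsFactors = FALSE)
  ic <- runif(50, 200, 40000)
  planted <- c(which(w$mutation_idx == 2)[1:4],
               which(w$mutation_idx == 5)[3],
               which(w$mutation_idx == 9)[2])
  ic[planted] <- runif(6, 1, 99)
  calls <- data.frame(peptide = w$sequence, allele = "A1", ic50_nM = ic,
                      stringsAsFactors = FALSE)
  per_pep <- count_predicted_neoantigens(w, calls, "A1",
               burden_params(counting_mode = "per_peptide"))
  per_mut <- count_predicted_neoantigens(w, calls, "A1",
               burden_params(counting_mode = "per_mutation"))
  # brute-force recount straight off the call table
  sub <- calls$peptide[calls$ic50_nM < 100]
  expect_equal(per_pep, length(unique(sub)))
  expect_equal(per_mut, length(unique(w$mutation_idx[w$sequence %in% sub])))
  expect_equal(per_pep, 6L)
  expect_equal(per_mut, 3L)
  expect_gte(per_pep, per_mut)
})

test_that("per-peptide counts always dominate per-mutation counts", {
  set.seed(59)
  for (i in 1:15) {
    n_mut <- sample(2:6, 1)
    w <- data.frame(mutation_idx = rep(seq_len(n_mut), each = 4),
                    sequence = replicate(4 * n_mut, random_protein_seq(9)),
                    start = 1L, length = 9L, stringsAsFactors = FALSE)
    calls <- data.frame(peptide = w$sequence, allele = "A1",
                        ic50_nM = 10^runif(nrow(w), 0, 4.7),
                        stringsAsFactors = FALSE)
    pp <- count_predicted_neoantigens(w, calls, "A1",
            burden_params(counting_mode = "per_peptide"))
    pm <- count_predicted_neoantigens(w, calls, "A1",
            burden_params(counting_mode = "per_mutation"))
    expect_gte(pp, pm)
  }
})

test_that("sample burden rows combine scaling and the authenticity model", {
  params <- burden_params()  # a = 0.08, x3 loci
  b <- sample_burden("s1", n_total = 40L, n_transcribed = 18L,
                     n_predicted_raw = 2L, params)
  expect_equal(b$N, 6)
  expect_equal(b$E, 0.48)
  expect_equal(percent_round(b$P), 39L)
  b2 <- sample_burden("s2", 300L, 140L, 9L, params)
  expect_equal(b2$N, 27)
  expect_equal(percent_round(b2$P), 89L)
})

test_that("cohort summary takes the median of N and the cutoff fraction", {
  params <- burden_params()
  b <- rbind(sample_burden("a", 10L, 5L, 0L, params),
             sample_burden("b", 40L, 18L, 2L, params),
             sample_burden("c", 300L, 140L, 9L, params))
  s <- summarize_cohort(b, params)
  expect_equal(s$median_N, 6)
  # N = 27 gives P = 0.894 < 0.90 (threshold N is 28), so no sample qualifies
  expect_equal(s$frac_above_cutoff, 0)
  expect_equal(s$n_samples, 3L)
  # rank order: n_total descending
  expect_equal(s$samples$sample_id, c("c", "b", "a"))

  one <- summarize_cohort(b[3, , drop = FALSE], params)
  expect_equal(one$median_N, 27)
  expect_true(one$frac_above_cutoff %in% c(0, 1))

  same <- rbind(sample_burden("z", 40L, 18L, 2L, params),
                sample_burden("y", 40L, 18L, 2L, params))
  s2 <- summarize_cohort(same, params)
  expect_equal(s2$median_N, 6)
  expect_equal(s2$samples$sample_id, c("y", "z"))  # ties break by sample id

  expect_error(summarize_cohort(b[0, ], params), "empty")
})

test_that("even-sized cohorts use the midpoint median convention", {
  params <- burden_params()
  b <- rbind(sample_burden("a", 1L, 1L, 1L, params),
             sample_burden("b", 2L, 2L, 2L, params),
             sample_burden("c", 3L, 3L, 3L, params),
             sample_burden("d", 4L, 4L, 4L, params))
  expect_equal(summarize_cohort(b, params)$median_N, (6 + 9) / 2)
})

test_that("burden parameter validation rejects out-of-range values", {
  expect_error(burden_params(authenticity_rate = 0), "\\(0, 1\\)")
  expect_error(burden_params(authenticity_rate = 1), "\\(0, 1\\)")
  expect_error(burden_params(loci_scale = 0), "positive")
  expect_error(burden_params(threshold_nM = -100), "positive")
  expect_error(burden_params(likelihood_cutoff = 1.2), "\\(0, 1\\)")
  expect_error(burden_params(counting_mode = "per_sample"))
})
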