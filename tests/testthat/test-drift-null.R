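test_that("ancestor-proxy generation adjustment matches the sampling design", {
  expect_equal(adjust_generations(57, "cold"), 60)
  expect_equal(adjust_generations(59, "cold"), 62)
  expect_equal(adjust_generations(67, "hot"), 64)
  expect_equal(adjust_generations(69, "hot"), 66)
  expect_equal(adjust_generations(3, "hot"), 0)
  expect_error(adjust_generations(2, "hot"), "proxy")
  expect_error(adjust_generations(10, "warm"), "regime")
})

test_that("drift coefficient F: closed form, limits, and exact inversion", {
  expect_equal(inbreeding_coefficient(100, 0), 0)
  expect_equal(inbreeding_coefficient(100, 10),
               1 - (1 - 1 / 200)^10)
  expect_lt(abs(inbreeding_coefficient(100, 10) - 0.04889), 5e-6)
  expect_lt(inbreeding_coefficient(1e12, 100), 1e-9)
  expect_error(inbreeding_coefficient(0.4, 10), "ne")
  ## round trip through the inversion used by the Ne estimator
  for (ne in c(50, 100, 215.4, 500)) {
    expect_equal(invert_inbreeding(inbreeding_coefficient(ne, 60), 60), ne,
                 tolerance = 1e-10)
  }
})

test_that("beta drift null: symmetry, central value, monotonicity, and errors", {
  ## allele-label symmetry
  expect_equal(drift_null_pvalue(0.3, 0.5, 50, 20),
               drift_null_pvalue(0.7, 0.5, 50, 20))
  ## the null median gets p ~ 1
  f <- inbreeding_coefficient(50, 20)
  med <- qbeta(0.5, 0.5 * (1 - f) / f + 0.001, 0.5 * (1 - f) / f + 0.001)
  expect_gt(drift_null_pvalue(0.5, med, 50, 20), 0.999)
  ## monotone decreasing in |pt - p0|
  pt <- seq(0.5, 0.99, by = 0.01)
  p <- drift_null_pvalue(rep(0.5, length(pt)), pt, 50, 20)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0 & p <= 1))
  expect_error(drift_null_pvalue(0.5, 0.6, Inf, 10), "finite")
  expect_error(drift_null_pvalue(0.5, 0.6, 100, 0), "t")
})

test_that("beta drift null approximates brute-force Wright-Fisher tails", {
  ## Independent oracle: direct WF simulation.  The beta approximation's
  ## tails deviate from the exact process by up to ~30% in relative terms at
  ## these cutoffs; assert it tracks the oracle within that known quality.
  set.seed(31)
  n <- 2e5; ne <- 50; t <- 20; p0 <- 0.5
  pt <- simulate_wf_trajectory(rep(p0, n), ne, 0, t, seed = 31)
  f <- inbreeding_coefficient(ne, t)
  a <- p0 * (1 - f) / f + 0.001
  for (dp in c(0.2, 0.3, 0.4)) {
    wf_tail <- mean(pt >= p0 + dp)
    beta_tail <- 1 - pbeta(p0 + dp, a, a)
    expect_lt(abs(beta_tail - wf_tail) / wf_tail, 0.30)
  }
})

test_that("temporal Ne estimator recovers simulated values and flags no-drift input", {
  ## parameter recovery oracle: WF + pool-seq simulation
  n <- 1e4; ne <- 100; t <- 10
  p0 <- runif_seeded <- withr::with_seed(8, runif(n, 0.1, 0.9))
  pt <- simulate_wf_trajectory(p0, ne, 0, t, seed = 9)
  o0 <- sample_poolseq(p0, 60, 100, seed = 10)
  ot <- sample_poolseq(pt, 60, 100, seed = 11)
  fit <- estimate_ne(o0$freq, ot$freq, o0$depth, ot$depth, 60, t)
  expect_lt(abs(fit$ne - ne) / ne, 0.15)

  ## halving Ne roughly doubles the corrected temporal variance
  pt2 <- simulate_wf_trajectory(p0, ne / 2, 0, t, seed = 12)
  ot2 <- sample_poolseq(pt2, 60, 100, seed = 13)
  fit2 <- estimate_ne(o0$freq, ot2$freq, o0$depth, ot2$depth, 60, t)
  expect_lt(abs(fit2$f_hat / fit$f_hat - 2), 0.35)

  ## no change at all -> corrected F <= 0 -> flagged infinite estimate
  fit3 <- estimate_ne(p0, p0, 1e6, 1e6, 60, t)
  expect_true(fit3$no_drift)
  expect_identical(fit3$ne, Inf)

  expect_error(estimate_ne(rep(0.5, 10), rep(0.5, 10), 50, 50, 60, 10),
               "informative")
})

test_that("logit-slope selection estimator: exact values, clamping, recovery", {
  expect_equal(estimate_selection_coefficient(0.4, 0.4, 10)$s, 0)
  est <- estimate_selection_coefficient(0.5, 0.62, 10)
  expect_lt(abs(est$s - log(0.62 / 0.38) / 10), 1e-12)
  expect_lt(abs(est$s - 0.0490), 5e-4)
  expect_false(est$clamped)
  expect_true(estimate_selection_coefficient(0, 0.5, 10)$clamped)

  ## deterministic-limit oracle: near-infinite Ne trajectory at s = 0.05
  pt <- simulate_wf_trajectory(0.3, 1e7, 0.05, 30, seed = 14)
  expect_lt(abs(estimate_selection_coefficient(0.3, pt, 30)$s - 0.05), 0.005)
})

test_that("sampling-aware nulls are calibrated under neutral evolution", {
  ## desk-scale version of the calibration property: 1e5 loci, full pipeline
  exp <- scenario_neutral(n_snps = 1e5, seed = 17, ne = 200,
                          backgrounds = "B1", differentiation = 0,
                          generation_cold = 57, generation_hot = 63)
  scan <- drift_scan(exp, seed = 4)
  expect_true(all(abs(scan$ne$ne - 200) / 200 < 0.1))
  for (q in c(1e-2, 1e-3)) {
    rates <- tail_rates(scan$records, q)
    band <- 3 * sqrt(q * (1 - q) / rates$n)
    expect_true(all(abs(rates$lower - q) < band),
                label = paste("lower tail at q =", q))
    expect_true(all(abs(rates$upper - q) < band),
                label = paste("upper tail at q =", q))
  }
})

test_that("exact null p-values are deterministic given a seed and mid-p without one", {
  exp <- scenario_neutral(n_snps = 2000, seed = 23, backgrounds = "B1")
  s1 <- drift_scan(exp, seed = 5)
  s2 <- drift_scan(exp, seed = 5)
  expect_identical(s1$records, s2$records)
  s3 <- drift_scan(exp, seed = 6)
  expect_false(identical(s1$records$pvalue, s3$records$pvalue))
})

test_that("candidate detection flags per-tail exceedances and unions over lines", {
  rec <- tibble::tibble(
    locus = c(1, 1, 2, 3), line_id = c("A", "B", "A", "B"),
    p_tail = c(1e-5, 0.4, 0.5, 5e-3), direction = c(1, 1, 0, -1)
  )
  out <- detect_candidates(rec, 1e-4)
  expect_equal(out$locus, 1)
  expect_equal(out$lines, "A")
  out2 <- detect_candidates(rec, 1e-2)
  expect_setequal(out2$locus, c(1, 3))
  ## all p-values at 1 -> empty set
  rec$p_tail <- 0.5
  expect_equal(nrow(detect_candidates(rec, 1e-4)), 0)
  expect_error(detect_candidates(rec, 0.7), "per_tail")
})
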