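test_that("mean scaling divides by ancestral grand means, per temperature, idempotently", {
  traits <- tibble::tibble(
    line_id = rep(c("anc1", "anc2", "ev1"), each = 2),
    background = "B1", regime = c("hot", "hot", "hot", "hot", "hot", "hot"),
    replicate = 1, role = rep(c("ancestor", "ancestor", "evolved"), each = 2),
    assay_temp = rep(c(23, 35), 3), trait = "lrs",
    mean = c(1.5, 4, 2.5, 4, 3.0, 6.0), se = c(0.1, 0.2, 0.1, 0.2, 0.2, 0.4),
    n = 30
  )
  scaled <- mean_scale_traits(traits)
  ## ancestral grand means: 2.0 at 23 C, 4.0 at 35 C
  expect_equal(scaled$mean[scaled$line_id == "ev1" & scaled$assay_temp == 23],
               1.5)
  expect_equal(scaled$se[scaled$line_id == "ev1" & scaled$assay_temp == 23],
               0.1)
  expect_equal(scaled$mean[scaled$line_id == "ev1" & scaled$assay_temp == 35],
               1.5)
  ## temperatures scale independently: perturbing 35 C leaves 23 C as-is
  traits2 <- traits
  traits2$mean[traits2$assay_temp == 35] <- traits2$mean[traits2$assay_temp == 35] * 7
  scaled2 <- mean_scale_traits(traits2)
  expect_equal(scaled2$mean[scaled2$assay_temp == 23],
               scaled$mean[scaled$assay_temp == 23])
  ## second pass is the identity (grand mean is 1 after the first)
  rescaled <- mean_scale_traits(scaled)
  expect_equal(rescaled$mean, scaled$mean)
  traits$mean[traits$role == "ancestor"] <- 0
  expect_error(mean_scale_traits(traits), "zero")
})

test_that("change vectors subtract ancestors and carry errors unchanged", {
  cv <- change_vector(c(1, 2), c(1, 2), anc_se = c(0.1, 0.2), t = 10)
  expect_equal(cv$values, c(0, 0))
  expect_equal(cv$anc_errors, c(0.1, 0.2))
  expect_error(change_vector(1:3, 1:2), "dimension")
})

test_that("evolutionary rates follow the norm-over-time definition", {
  r <- evolutionary_rate(c(0.3, 0.4), t = 50)
  expect_equal(r$raw_rate, 0.01)
  expect_equal(evolutionary_rate(c(0.3, 0.4), 50, dataset_max = 0.01)$scaled_rate, 1)
  expect_equal(evolutionary_rate(c(0, 0), 10)$raw_rate, 0)
})

test_that("pairwise angles: canonical geometry and the documented correction", {
  a <- c(1, 0, 0)
  expect_equal(pairwise_angle(a, a)$theta, 0)
  expect_equal(pairwise_angle(a, c(0, 1, 0))$theta, 90)
  expect_equal(pairwise_angle(a, -a)$theta, 180)
  expect_error(pairwise_angle(a, c(0, 0, 0)), "zero-length")

  ## worked numerator correction: a.b = 2, error sum 0.5, norms sqrt(2):
  ## cos = (2 - 0.5) / 2 = 0.75
  aa <- bb <- c(1, 1)
  res <- pairwise_angle(aa, bb, shared_anc_se = c(0.5, 0.5))
  expect_equal(res$theta, acos(0.75) * 180 / pi, tolerance = 1e-9)
  expect_lt(abs(res$theta - 41.41), 0.01)
  ## overwhelming shared error -> undefined
  res2 <- pairwise_angle(aa, bb, shared_anc_se = c(3, 3))
  expect_true(is.na(res2$theta))
  expect_equal(res2$undefined_reason, "error exceeds signal")
})

test_that("uncorrected cosine equals a brute-force loop on random cases", {
  withr::with_seed(44, {
    for (k in 1:100) {
      a <- rnorm(7); b <- rnorm(7)
      num <- 0; na <- 0; nb <- 0
      for (i in 1:7) {
        num <- num + a[i] * b[i]; na <- na + a[i]^2; nb <- nb + b[i]^2
      }
      expect_equal(pairwise_angle(a, b)$theta,
                   acos(max(-1, min(1, num / sqrt(na * nb)))) * 180 / pi)
    }
  })
})

test_that("numerator correction removes the shared-ancestor bias at a known 45-degree angle", {
  a_true <- c(1, rep(0, 6))
  b_true <- c(cos(pi / 4), sin(pi / 4), rep(0, 5))
  sigma <- 0.05
  corr <- uncorr <- numeric(1000)
  withr::with_seed(46, {
    for (i in 1:1000) {
      e <- rnorm(7, 0, sigma)
      a <- a_true - e; b <- b_true - e
      corr[i] <- pairwise_angle(a, b, shared_anc_se = rep(sigma, 7))$theta
      uncorr[i] <- pairwise_angle(a, b, correct = FALSE)$theta
    }
  })
  expect_lt(abs(mean(corr) - 45), 2)
  expect_lt(mean(uncorr), 45)          # biased low
  expect_lt(mean(uncorr), mean(corr))
})

test_that("divergence: arithmetic, the floor rule, and rotation invariance", {
  d <- divergence(c(0, 0), c(1, 0), c(0, 0), c(1, 0))
  expect_equal(d$div, 0)
  d2 <- divergence(c(0, 0), c(1, 0), c(0, 0), c(1.5, 0), scale = 2)
  expect_equal(d2$div_scaled, 0.25)
  ## shared-ancestor floor: (a - b)^2 = 0.04 < se^2 sum = 0.09
  d3 <- divergence(c(0), c(0), c(0), c(0.2), se_a = 0.2, se_b = sqrt(0.05),
                   shared_ancestor = TRUE)
  expect_equal(d3$E_d, 0)
  expect_true(d3$floored)

  ## E_d - S_d invariant under a global rotation of trait space
  withr::with_seed(47, {
    vals <- matrix(rnorm(24), 4, 6,
                   dimnames = list(c("a", "b", "c", "d"), NULL))
    anc <- matrix(rnorm(24), 4, 6, dimnames = dimnames(vals))
    cv <- make_cv(vals, rep("B1", 4), c("cold", "cold", "hot", "hot"),
                  anc_value = anc)
    q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
    cv_rot <- make_cv(t(q %*% t(anc + vals)) - t(q %*% t(anc)),
                      rep("B1", 4), c("cold", "cold", "hot", "hot"),
                      anc_value = t(q %*% t(anc)))
    d1 <- divergence_pairs(cv, correct = FALSE)
    d2 <- divergence_pairs(cv_rot, correct = FALSE)
    expect_equal(d1$div, d2$div, tolerance = 1e-10)
    expect_equal(d1$div_scaled, d2$div_scaled, tolerance = 1e-10)
  })
})

test_that("random-angle null is centred at 90 degrees with dimension-dependent spread", {
  null7 <- random_angle_null(7, iterations = 1e5, seed = 48)
  expect_lt(abs(mean(null7$draws) - 90), 0.2)
  null2 <- random_angle_null(2, iterations = 2e4, seed = 49)
  expect_lt(abs(mean(null2$draws) - 90), 1)
  expect_gt(sd(null2$draws), sd(null7$draws))
  ## observed at the null median -> p ~ 1
  null_p <- random_angle_null(7, iterations = 2e4,
                              observed = median(null7$draws), seed = 50)
  expect_gt(null_p$p, 0.9)
  expect_error(random_angle_null(1), "dim")
})

test_that("permutation regime test: degenerate and strong-effect cases", {
  ## identical vectors for all lines -> difference 0 -> p = 1
  vals <- matrix(rep(c(1, 0, 0), each = 8), 8, 3,
                 dimnames = list(paste0("l", 1:8), NULL))
  cv <- make_cv(vals, rep(c("B1", "B2"), each = 4),
                rep(c("cold", "cold", "hot", "hot"), 2))
  res <- permutation_regime_test(cv, "angle", iterations = 199, seed = 51)
  expect_equal(res$p_value, 1)

  ## hot collinear, cold mutually orthogonal (4 backgrounds for resolution)
  vals <- matrix(0, 16, 16, dimnames = list(paste0("l", 1:16), NULL))
  hot <- rep(c(FALSE, FALSE, TRUE, TRUE), 4)
  vals[hot, 1] <- 1
  vals[!hot, ] <- diag(16)[which(!hot), ]
  cv <- make_cv(vals, rep(paste0("B", 1:4), each = 4),
                ifelse(hot, "hot", "cold"))
  res <- permutation_regime_test(cv, "angle", iterations = 1999, seed = 52)
  expect_lt(res$p_value, 0.01)
  expect_lt(res$observed, -80)
})

test_that("permutation regime test is calibrated under label noise", {
  withr::with_seed(53, {
    p <- replicate(200, {
      vals <- matrix(rnorm(12 * 7), 12, 7,
                     dimnames = list(paste0("l", 1:12), NULL))
      cv <- make_cv(vals, rep(c("B1", "B2", "B3"), each = 4),
                    rep(c("cold", "cold", "hot", "hot"), 3))
      permutation_regime_test(cv, "angle", iterations = 99)$p_value
    })
  })
  expect_gt(mean(p <= 0.05), 0.005)
  expect_lt(mean(p <= 0.05), 0.11)
})

test_that("within-background genomic angles beat between-background ones under private architectures", {
  exp <- scenario_background_private(n_snps = 8000, n_private = 150, seed = 54)
  scan <- drift_scan(exp, seed = 3)
  cv <- genomic_change_vectors(scan)
  ang <- pairwise_angles(cv, correct = FALSE)
  expect_lt(mean(ang$theta[ang$group == "within"]),
            mean(ang$theta[ang$group == "between"]))
})
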