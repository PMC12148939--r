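test_that("laboratory fitness is the offspring-per-day ratio", {
  expect_equal(laboratory_fitness(80, 28), 80 / 28)
  expect_lt(abs(laboratory_fitness(80, 28) - 2.857), 1e-3)
  expect_equal(laboratory_fitness(0, 28), 0)
  expect_equal(laboratory_fitness(160, 56), laboratory_fitness(80, 28))
  expect_error(laboratory_fitness(80, 0), "dev_time")
})

test_that("reference selection takes the fittest line with a lexicographic tie-break", {
  yem <- tibble::tibble(line_id = c("Yemen_7", "Yemen_8"),
                        fitness = c(2.88, 3.65))
  ref <- select_reference(yem)
  expect_equal(ref$line_id, "Yemen_8")
  expect_equal(ref$fitness, 3.65)
  expect_false(ref$tie)
  expect_equal(select_reference(yem[1, ])$line_id, "Yemen_7")
  tie <- select_reference(tibble::tibble(line_id = c("b", "a"),
                                         fitness = c(1, 1)))
  expect_equal(tie$line_id, "a")
  expect_true(tie$tie)
  expect_error(select_reference(yem[0, ]), "no candidate")
})

test_that("reference candidate sets take the smallest p-value quantile with ties flagged", {
  pv <- tibble::tibble(locus = 1:1000, pvalue = (1:1000) / 1000, s = 0.1)
  cand <- reference_candidate_set(pv, 0.01)
  expect_equal(nrow(cand), 10)
  expect_equal(sort(cand$locus), 1:10)
  expect_false(attr(cand, "ties"))
  expect_true(all(cand$weight == 0.1))
  ## all p-values equal: whole table returned, tie flag set
  pv$pvalue <- 0.5
  all_tied <- reference_candidate_set(pv, 0.001)
  expect_equal(nrow(all_tied), 1000)
  expect_true(attr(all_tied, "ties"))
  expect_error(reference_candidate_set(pv[0, ], 0.01), "empty")
})

test_that("planted strong-selection loci land inside the reference quantile set", {
  ## strong, detectable sweeps: s = 0.25 over ~20 generations from
  ## intermediate frequencies where a sweep is far outside the drift null
  design <- experiment_design(backgrounds = "B1", ne_cold = 200,
                              ne_hot = 200, generation_cold = 17,
                              generation_hot = 23)
  n <- 20000
  pool <- draw_ancestral_frequencies(n, "B1", differentiation = 0,
                                     common_range = c(0.1, 0.35), seed = 71)
  arch <- assign_architecture(n, seed = 71)
  planted <- 1:100
  arch$class[planted] <- "private_hot"
  arch$s_hot[planted] <- 0.25
  exp <- generate_experiment(design, pool, arch, seed = 71)
  scan <- drift_scan(exp, ne = 200, seed = 9)
  rec <- scan$records |> dplyr::filter(line_id == "B1_hot_1")
  cand <- reference_candidate_set(
    dplyr::select(rec, locus, pvalue, s), 0.01)   # 200-SNP candidate set
  expect_gte(mean(planted %in% cand$locus), 0.9)
})

test_that("genomic offset is a weighted L1 distance with the documented identities", {
  expect_equal(genomic_offset(c(0.8, 0.2), c(0.6, 0.2), c(0.1, 0.05)), 0.02)
  expect_equal(genomic_offset(c(0.5, 0.5), c(0.5, 0.5), 1), 0)
  expect_equal(genomic_offset(c(0.8, 0.2), c(0.6, 0.2), 2 * c(0.1, 0.05)),
               2 * genomic_offset(c(0.8, 0.2), c(0.6, 0.2), c(0.1, 0.05)))
  ## symmetry and triangle inequality on random triples
  withr::with_seed(72, {
    for (i in 1:50) {
      w <- runif(5); a <- runif(5); b <- runif(5); c <- runif(5)
      expect_equal(genomic_offset(a, b, w), genomic_offset(b, a, w))
      expect_lte(genomic_offset(a, c, w),
                 genomic_offset(a, b, w) + genomic_offset(b, c, w) + 1e-12)
    }
  })
  expect_error(genomic_offset(c(0.1, 0.2), 0.1), "SNP set")
})

test_that("phenotypic and fitness offsets behave as distances and ratios", {
  expect_equal(phenotypic_offset(c(1, 1), c(1, 1)), 0)
  expect_equal(phenotypic_offset(c(0, 0, 1), c(0.3, 0.4, 1)), 0.5)
  expect_equal(phenotypic_offset(c(0.3, 0.4, 1), c(0, 0, 1)),
               phenotypic_offset(c(1, 0.4, 0.3), c(1, 0, 0)))
  expect_equal(fitness_offset(3.65, 3.65), 1)
  expect_lt(abs(fitness_offset(2.88, 3.65) - 0.789), 1e-3)
  expect_equal(fitness_offset(2 * 2.88, 2 * 3.65), fitness_offset(2.88, 3.65))
  expect_error(fitness_offset(1, 0), "reference")
})

test_that("self-offsets are (0, 0, 1) and offset tables label groups correctly", {
  exp <- scenario_background_private(n_snps = 5000, n_private = 100,
                                     backgrounds = c("B1", "B2", "B3"),
                                     seed = 73)
  scan <- drift_scan(exp, seed = 10)
  ot <- offset_table(exp, scan, quantile_fraction = 0.02,
                     include_self = TRUE)
  self <- ot[ot$line_id == ot$reference, ]
  expect_equal(nrow(self), 3)
  expect_true(all(self$genomic_offset == 0))
  expect_true(all(self$phenotypic_offset == 0))
  expect_true(all(self$fitness_offset == 1))
  expect_true(all(self$group == "within"))
  expect_setequal(unique(ot$group), c("within", "between"))
  ## 18 lines per reference including self
  expect_equal(nrow(ot), 3 * 18)
})

test_that("between-background offsets shrink when selected loci are fixed toward the reference", {
  ## constructed case: reference swept its selected loci to ~1; the other
  ## background is already fixed at 1 there, its own lines vary in fitness
  ref_freq <- c(rep(0.95, 20), 0.5)
  test_same_bg <- c(rep(0.30, 20), 0.5)    # still polymorphic, far from ref
  test_other_bg <- c(rep(1, 20), 0.45)     # fixed in the reference direction
  w <- rep(1, 21)
  expect_gt(genomic_offset(ref_freq, test_same_bg, w),
            genomic_offset(ref_freq, test_other_bg, w))
})

test_that("offset correlations separate predictive within- from flat between-background patterns", {
  withr::with_seed(74, {
    gen <- function(n, slope, noise) {
      g <- runif(n, 1, 3)
      tibble::tibble(genomic_offset = g,
                     phenotypic_offset = slope * g + rnorm(n, 0, noise),
                     fitness_offset = 2 - slope * g + rnorm(n, 0, noise))
    }
    ot <- dplyr::bind_rows(
      within = dplyr::mutate(gen(12, 1, 0.05), reference = rep(c("r1", "r2"), 6)),
      between = dplyr::mutate(gen(24, 0, 0.6), reference = rep(c("r1", "r2"), 12)),
      .id = "group"
    )
  })
  oc <- offset_correlation(ot)
  gl <- glance(oc)
  expect_gt(gl$r_pheno[gl$group == "within"], 0.9)
  expect_lt(gl$r_fit[gl$group == "within"], -0.9)
  expect_lt(abs(gl$r_fit[gl$group == "between"]), 0.5)
  expect_true(all(c("F_interaction", "p_value") %in% names(oc$ancova)))
  ## perfectly collinear points give |r| = 1
  ot2 <- tibble::tibble(
    group = rep(c("within", "between"), each = 4), reference = "r",
    genomic_offset = rep(1:4, 2), phenotypic_offset = rep(2 * (1:4), 2),
    fitness_offset = rep(4:1, 2)
  )
  oc2 <- offset_correlation(ot2)
  expect_equal(glance(oc2)$r_pheno, c(1, 1))
  expect_equal(glance(oc2)$r_fit, c(-1, -1))
  ## constant genomic offset -> undefined correlation, flagged
  ot2$genomic_offset <- 1
  expect_warning(oc3 <- offset_correlation(ot2), "degenerate")
  expect_true(all(is.na(oc3$by_group$r_pheno)))
})

test_that("random-SNP controls are reproducible and degenerate at n = total", {
  exp <- scenario_background_private(n_snps = 3000, n_private = 60,
                                     backgrounds = c("B1", "B2", "B3"),
                                     seed = 75)
  r1 <- random_snp_offsets(exp, "B1_hot_1", n = 100, iterations = 5,
                           seed = 76)
  r2 <- random_snp_offsets(exp, "B1_hot_1", n = 100, iterations = 5,
                           seed = 76)
  expect_identical(r1$offsets, r2$offsets)
  ## n = total loci: every iteration uses the same (full) set
  rall <- random_snp_offsets(exp, "B1_hot_1", n = 3000, iterations = 3,
                             seed = 77)
  per_iter <- split(rall$offsets$genomic_offset, rall$offsets$iteration)
  expect_equal(per_iter[[1]], per_iter[[2]])
  expect_equal(per_iter[[1]], per_iter[[3]])
  expect_error(random_snp_offsets(exp, "B1_hot_1", n = 3001), "exceeds")
})
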