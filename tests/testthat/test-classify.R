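## Build scan-like records for one background: p_tail / direction per
## line x locus.
records_for <- function(p_cold1, p_cold2, p_hot1, p_hot2,
                        d_cold1 = 1, d_cold2 = 1, d_hot1 = 1, d_hot2 = 1) {
  n <- length(p_cold1)
  tibble::tibble(
    locus = rep(seq_len(n), 4),
    background = "B1",
    line_id = rep(c("c1", "c2", "h1", "h2"), each = n),
    regime = rep(c("cold", "cold", "hot", "hot"), each = n),
    replicate = rep(c(1, 2, 1, 2), each = n),
    p_tail = c(p_cold1, p_cold2, p_hot1, p_hot2),
    direction = c(rep_len(d_cold1, n), rep_len(d_cold2, n),
                  rep_len(d_hot1, n), rep_len(d_hot2, n))
  )
}

test_that("SNP classes follow the replicate-concordance rules", {
  sig <- 1e-4; ns <- 0.5
  rec <- records_for(
    p_cold1 = c(sig, sig, sig, ns, sig),
    p_cold2 = c(sig, sig, sig, ns, ns),
    p_hot1  = c(sig, sig, ns, sig, ns),
    p_hot2  = c(sig, sig, ns, sig, ns),
    d_cold1 = c(1, 1, 1, 0, 1), d_cold2 = c(1, 1, 1, 0, -1),
    d_hot1  = c(1, -1, 1, 1, 0), d_hot2 = c(1, -1, -1, 1, 0)
  )
  calls <- classify_snps(rec, 1e-2)
  expect_equal(calls$class[order(calls$locus)],
               c("SP",            # both regimes up
                 "AP",            # cold up, hot down
                 "private_cold",  # hot lines not significant
                 "private_hot",   # cold lines not significant
                 "none"))         # one cold replicate only / discordant
  ## exclusivity: one class per locus x background
  expect_equal(nrow(calls), dplyr::n_distinct(calls$locus))
})

test_that("relabelling regimes swaps the private classes and fixes SP/AP", {
  sig <- 1e-4; ns <- 0.5
  rec <- records_for(
    p_cold1 = c(sig, sig, sig, ns), p_cold2 = c(sig, sig, sig, ns),
    p_hot1  = c(sig, sig, ns, sig), p_hot2  = c(sig, sig, ns, sig),
    d_cold1 = 1, d_cold2 = 1,
    d_hot1 = c(1, -1, 1, 1), d_hot2 = c(1, -1, 1, 1)
  )
  calls <- classify_snps(rec, 1e-2)
  swapped <- rec
  swapped$regime <- ifelse(rec$regime == "cold", "hot", "cold")
  calls_sw <- classify_snps(swapped, 1e-2)
  map <- c(SP = "SP", AP = "AP", private_cold = "private_hot",
           private_hot = "private_cold", none = "none")
  expect_equal(unname(map[calls$class[order(calls$locus)]]),
               calls_sw$class[order(calls_sw$locus)])
})

test_that("neutral concordant-hit rate per regime is about 2 q^2", {
  exp <- scenario_neutral(n_snps = 1e5, seed = 61, backgrounds = "B1",
                          differentiation = 0)
  scan <- drift_scan(exp, seed = 7)
  q <- 0.05    # raised threshold so 2 q^2 * n gives a testable count
  calls <- classify_snps(scan, q)
  n_hit <- sum(calls$class != "none")
  ## two regimes, each with concordant-pair probability ~ 2 q^2
  expected <- 2 * 2 * q^2 * 1e5
  expect_lt(abs(n_hit - expected), 4 * sqrt(expected))
})

test_that("SNP-to-gene mapping honours inclusive bounds and overlapping genes", {
  skip_if_not_installed("rtracklayer")
  genes <- read_gene_annotation(write_test_gff3())
  expect_setequal(genes$gene_id, c("geneA", "geneB", "geneD", "geneE"))

  calls <- tibble::tibble(
    locus = 1:6, background = "B1", class = "private_hot",
    scaffold = c("scf1", "scf1", "scf1", "scf1", "scf1", "scf2"),
    pos = c(100, 500, 750, 1450, 99, 90)
  )
  gs <- map_snps_to_genes(calls, genes)
  expect_true(all(c("geneA", "geneB", "geneD", "geneE") %in% gs$gene_id))
  ## gene start and end are inside; between-gene SNP maps nowhere
  got <- dplyr::inner_join(calls, genes,
    by = dplyr::join_by(scaffold, between(x$pos, y$start, y$end)))
  expect_setequal(got$pos[got$gene_id == "geneA"], c(100, 500))
  expect_equal(sort(got$gene_id[got$pos == 1450]), c("geneB", "geneD"))
  expect_false(99 %in% got$pos)
  expect_true("geneE" %in% got$gene_id)   # SNP at gene end, other scaffold
  expect_error(map_snps_to_genes(calls,
    tibble::tibble(gene_id = "x", scaffold = "scf1", start = 10, end = 5)),
    "malformed")
})

test_that("jaccard index covers the degenerate and textbook cases", {
  expect_equal(as.numeric(jaccard(c("a", "b"), c("a", "b"))), 1)
  expect_equal(as.numeric(jaccard("a", "b")), 0)
  expect_equal(as.numeric(jaccard(c("g1", "g2", "g3"), c("g2", "g3", "g4"))),
               0.5)
  empty <- jaccard(character(0), character(0))
  expect_equal(as.numeric(empty), 0)
  expect_true(attr(empty, "both_empty"))
})

test_that("overlap counts respect inclusion-exclusion on constructed sets", {
  gs <- tibble::tibble(
    background = rep(c("B1", "B2", "B3"), times = c(2, 2, 1)),
    class = "private_hot",
    gene_id = c("a", "b", "b", "c", "b")
  )
  ov <- overlap_counts(gs)
  expect_equal(ov$shared$shared_all, 1)                  # {b}
  cmb <- ov$combinations
  expect_equal(cmb$n[cmb$combo == "B1&B2&B3"], 1)
  expect_equal(sum(cmb$n), 3)                            # a, b, c exclusive cells
  ## identical sets -> full intersection only
  gs2 <- tidyr::expand_grid(background = c("B1", "B2", "B3"),
                            gene_id = c("x", "y")) |>
    dplyr::mutate(class = "SP")
  ov2 <- overlap_counts(gs2)
  expect_equal(ov2$shared$shared_all, 2)
  expect_true(all(ov2$jaccard$jaccard == 1))
  ## pairwise-disjoint sets -> no multi-way intersections
  gs3 <- tibble::tibble(background = c("B1", "B2", "B3"), class = "SP",
                        gene_id = c("u", "v", "w"))
  ov3 <- overlap_counts(gs3)
  expect_equal(ov3$shared$shared_all, 0)
  expect_true(all(ov3$combinations$degree == 1))
})

test_that("drift-expected overlap: trivial p-value and strong-effect excess", {
  design <- experiment_design(generation_cold = 17, generation_hot = 23,
                              ne_cold = 200, ne_hot = 200)
  pool <- draw_ancestral_frequencies(3000, unique(design$background),
                                     differentiation = 0, seed = 62)
  ## observed count of 0 -> p = 1
  null0 <- expected_overlap_by_drift(pool, design, class = "private_hot",
                                     iterations = 20,
                                     snps_per_iteration = 500,
                                     observed = 0, seed = 63)
  expect_equal(null0$p_value, 1)

  ## planted shared SP targets produce far more sharing than drift
  arch <- assign_architecture(3000, c(SP = 0.05), s_magnitude = 0.2,
                              seed = 64)
  exp <- generate_experiment(design, pool, arch, seed = 64)
  scan <- drift_scan(exp, ne = 200, seed = 8)
  calls <- classify_snps(scan)
  shared_sp <- calls |>
    dplyr::filter(class == "SP") |>
    dplyr::count(locus) |>
    dplyr::filter(n == 3) |>
    nrow()
  expect_gt(shared_sp, 5)
  null_sp <- expected_overlap_by_drift(pool, design, class = "SP",
                                       iterations = 99,
                                       snps_per_iteration = 1000,
                                       observed = shared_sp, seed = 65)
  expect_lt(null_sp$p_value, 0.011)
  expect_lt(null_sp$expected, shared_sp)
})
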