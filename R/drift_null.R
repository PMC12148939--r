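#' Ancestor-proxy adjustment of divergence times
#'
#' The sequenced "ancestors" are early-generation samples of the hot lines
#' (taken at the proxy generation, by default 3).  Divergence between a
#' proxy and an evolved line therefore spans the line's sampling generation
#' plus the proxy age for cold lines (independent branches), and minus the
#' proxy age for hot lines (the proxy lies on the same branch).
#'
#' @param nominal_t Sampling generation(s) of the evolved line.
#' @param regime `"cold"` or `"hot"` (vectorised).
#' @param proxy_offset Proxy generation (default 3).
#' @return Adjusted generations of divergence.
#' @export
#' @examples
#' adjust_generations(57, "cold")  # 60
#' adjust_generations(67, "hot")   # 64
adjust_generations <- function(nominal_t, regime, proxy_offset = 3) {
  if (!all(regime %in% c("cold", "hot"))) {
    abort("`regime` must be \"cold\" or \"hot\"")
  }
  n <- max(length(nominal_t), length(regime))
  nominal_t <- rep_len(nominal_t, n)
  regime <- rep_len(regime, n)
  if (any(regime == "hot" & nominal_t < proxy_offset)) {
    abort("hot lines need `nominal_t` >= `proxy_offset`")
  }
  out <- ifelse(regime == "cold", nominal_t + proxy_offset,
                nominal_t - proxy_offset)
  if (any(out < 0)) abort("adjusted generations would be negative")
  out
}

#' Cumulative drift coefficient of Wright-Fisher drift
#'
#' `F = 1 - (1 - 1/(2 Ne))^t`: the expected variance of allele-frequency
#' change after `t` generations of drift is `p0 (1 - p0) F`.
#'
#' @param ne Effective population size (diploids), `> 0.5`.
#' @param t Generations, `>= 0`.
#' @return `F` in `[0, 1)`.
#' @export
inbreeding_coefficient <- function(ne, t) {
  if (any(!is.na(ne) & ne <= 0.5)) abort("`ne` must be > 0.5")
  if (any(t < 0)) abort("`t` must be >= 0")
  1 - (1 - 1 / (2 * ne))^t
}

#' Invert the drift coefficient for the effective population size
#'
#' Exact inverse of [inbreeding_coefficient()] in `ne`.
#'
#' @param f Cumulative drift coefficient in `(0, 1)`.
#' @param t Generations, `>= 1`.
#' @return Effective population size.
#' @export
invert_inbreeding <- function(f, t) {
  if (any(f <= 0 | f >= 1)) abort("`f` must be in (0, 1)")
  assert_scalar_count(t)
  1 / (2 * (1 - (1 - f)^(1 / t)))
}

#' Temporal (variance) estimate of the effective population size
#'
#' Estimates Ne from allele-frequency change between two pool-seq samples.
#' Per locus, the squared change is corrected by unbiased estimates of the
#' two-stage sampling variance at each time point (pool of diploids, then
#' finite read depth), the corrected numerators and `p0(1-p0)` denominators
#' are each summed over loci (a ratio-of-sums temporal F), and
#' `F = 1 - (1 - 1/(2 Ne))^t` is inverted.  The construction makes the
#' numerator conditionally unbiased for `p0 (1 - p0) F` under binomial
#' sampling, so no small-F approximation is involved.
#'
#' @param p0,pt Observed allele frequencies at the two time points.
#' @param depth0,deptht Read depths (vectors recycled against loci).
#' @param pool_size Diploid individuals per pool.
#' @param t Generations between samples (after proxy adjustment), or — when
#'   `t_anc > 0` — generations on the evolved branch only.
#' @param t_anc Generations of drift on the ancestor-sample branch.  When
#'   the two samples sit on diverging branches (a proxy ancestor), the
#'   temporal variance is the *sum* of the two branches' `F`, and the
#'   inversion solves `F(ne, t) + F(ne, t_anc) = F_hat` instead of the
#'   single-chain formula.
#' @param min_loci Minimum number of informative loci (`0 < p0 < 1`).
#' @return Object of class `er_ne`: list with `ne` (``Inf`` and
#'   `no_drift = TRUE` when the corrected F is non-positive), `f_hat`,
#'   `t` and `n_loci`.  See [glance.er_ne()].
#' @export
estimate_ne <- function(p0, pt, depth0, deptht, pool_size, t,
                        t_anc = 0, min_loci = 100) {
  assert_scalar_count(t)
  assert_scalar_count(t_anc, min = 0)
  keep <- p0 > 0 & p0 < 1
  if (sum(keep) < min_loci) {
    abort(sprintf("need >= %d informative loci (0 < p0 < 1), got %d",
                  min_loci, sum(keep)))
  }
  depth0 <- rep_len(depth0, length(p0))[keep]
  deptht <- rep_len(deptht, length(p0))[keep]
  p0 <- p0[keep]; pt <- pt[keep]
  n0 <- poolseq_n_eff(pool_size, depth0)
  nt <- poolseq_n_eff(pool_size, deptht)
  num <- (p0 - pt)^2 - p0 * (1 - p0) / (n0 - 1) - pt * (1 - pt) / (nt - 1)
  den <- p0 * (1 - p0) / (1 - 1 / n0)
  f_hat <- sum(num) / sum(den)
  no_drift <- f_hat <= 0
  ne <- if (no_drift) {
    Inf
  } else if (t_anc == 0) {
    invert_inbreeding(min(f_hat, 1 - 1e-12), t)
  } else {
    f <- min(f_hat, 1 - 1e-12)
    y <- stats::uniroot(function(y) 2 - y^t - y^t_anc - f,
                        c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    1 / (2 * (1 - y))
  }
  structure(list(ne = ne, f_hat = f_hat, t = t + t_anc, n_loci = length(p0),
                 no_drift = no_drift),
            class = "er_ne")
}

#' @export
print.er_ne <- function(x, ...) {
  cat(sprintf("Temporal Ne estimate: %s (F_c = %.5g, t = %d, %d loci)%s\n",
              format(round(x$ne, 1)), x$f_hat, x$t, x$n_loci,
              if (x$no_drift) " [no detectable drift]" else ""))
  invisible(x)
}

#' @rdname estimate_ne
#' @param x An `er_ne` object.
#' @param ... Unused.
#' @export
glance.er_ne <- function(x, ...) {
  tibble(ne = x$ne, f_hat = x$f_hat, t = x$t, n_loci = x$n_loci,
         no_drift = x$no_drift)
}

#' Beta-approximation drift null p-value
#'
#' Two-sided tail probability of an observed allele-frequency change under
#' pure Wright-Fisher drift, using the classical beta approximation
#' `p_t | p_0 ~ beta(alpha + 0.001, beta + 0.001)` with
#' `alpha = p0 (1-F)/F`, `beta = (1-p0)(1-F)/F` and
#' `F = 1 - (1 - 1/(2 Ne))^t`.  The small offsets keep the density
#' integrable at the boundaries, mimicking the fixation atoms of the
#' discrete process.  This null ignores pool-seq sampling noise; see
#' [poolseq_null_pvalue()] for the observation-aware version used by the
#' detection pipeline.
#'
#' @param p0,pt Start and end allele frequencies (vectors).
#' @param ne Effective population size (finite).
#' @param t Generations (`>= 1`).
#' @return Numeric vector of two-sided p-values in `(0, 1]`.
#' @export
drift_null_pvalue <- function(p0, pt, ne, t) {
  assert_prob(p0); assert_prob(pt)
  if (any(!is.finite(ne))) abort("`ne` must be finite")
  if (any(t < 1)) abort("`t` must be >= 1")
  f <- inbreeding_coefficient(ne, t)
  if (any(f == 0)) abort("F = 0: no drift elapsed, p-value undefined")
  alpha <- p0 * (1 - f) / f + 0.001
  beta_ <- (1 - p0) * (1 - f) / f + 0.001
  lo <- pbeta(pt, alpha, beta_)
  pmax(pmin(1, 2 * pmin(lo, 1 - lo)), .Machine$double.xmin)
}

## Beta-binomial tail probabilities, grouped by read depth.  Returns the
## lower cumulative P(R <= r) and point mass P(R = r) of
## R ~ BetaBinomial(depth, a, b), row-normalised for numerical safety.
betabinom_tails <- function(r, depth, a, b, chunk = 50000L) {
  n <- length(r)
  lo <- eq <- numeric(n)
  for (d in unique(depth)) {
    idx <- which(depth == d)
    ks <- 0:d
    lch <- lchoose(d, ks)
    tri <- upper.tri(diag(d + 1), diag = TRUE) * 1  # col j: sum over k <= j
    for (st in seq(1, length(idx), by = chunk)) {
      ix <- idx[st:min(st + chunk - 1L, length(idx))]
      lp <- matrix(lch, length(ix), d + 1, byrow = TRUE) +
        lbeta(outer(a[ix], ks, "+"), outer(b[ix], d - ks, "+")) -
        lbeta(a[ix], b[ix])
      pm <- exp(lp)
      pm <- pm / rowSums(pm)
      cs <- pm %*% tri
      sel <- cbind(seq_along(ix), r[ix] + 1L)
      eq[ix] <- pm[sel]
      lo[ix] <- cs[sel]
    }
  }
  list(lo = lo, eq = eq)
}

#' Sampling-aware drift null for pool-seq read counts
#'
#' Refines the beta drift null to the full observation process, so that
#' candidate detection is calibrated at extreme tails even with noisy,
#' discrete pool-seq data.  The ancestral frequency is given a uniform-prior
#' posterior reflecting its own two-stage sampling noise; drift
#' (`F = 1 - (1 - 1/(2 Ne))^t`) and pool sampling are composed onto it by
#' moment matching of beta stages; and the final read count is evaluated
#' against the exact beta-binomial mixture, with mid-p tail probabilities to
#' undo the conservativeness of the discrete test.
#'
#' @param p0 Observed ancestral (proxy) allele frequency.
#' @param reads_t Reads carrying the tracked allele in the evolved sample.
#' @param depth0,deptht Read depths of the two samples.
#' @param pool_size Diploid individuals per pool.
#' @param ne Effective population size of the line.
#' @param t Generations of divergence (after proxy adjustment).
#' @param offset Boundary offset added to the mixing-beta parameters
#'   (default 0.001, as in the plain beta null).
#' @return Tibble with one row per locus: `p_lower`, `p_upper` (one-sided
#'   mid-p), `p_tail` (smaller of the two), `pvalue` (two-sided, capped at
#'   1) and `direction` (`sign(freq_t - p0)`).
#' @export
poolseq_null_pvalue <- function(p0, reads_t, depth0, deptht, pool_size,
                                ne, t, offset = 0.001) {
  assert_prob(p0)
  if (any(t < 1)) abort("`t` must be >= 1")
  if (any(!is.finite(ne))) abort("`ne` must be finite")
  depth0 <- rep_len(depth0, length(p0))
  deptht <- rep_len(deptht, length(p0))
  n_eff0 <- poolseq_n_eff(pool_size, depth0)

  ## posterior of the true ancestral frequency (uniform prior)
  a0 <- p0 * n_eff0 + 1
  b0 <- (1 - p0) * n_eff0 + 1
  m <- a0 / (a0 + b0)
  v <- m * (1 - m) / (a0 + b0 + 1)
  ## compose drift, then pool sampling, by moment matching
  fd <- inbreeding_coefficient(ne, t)
  v <- v + (m * (1 - m) - v) * fd
  v <- v + (m * (1 - m) - v) / (2 * pool_size)
  cc <- m * (1 - m) / v - 1
  a <- m * cc + offset
  b <- (1 - m) * cc + offset

  tl <- betabinom_tails(as.integer(reads_t), as.integer(deptht), a, b)
  p_lower <- pmax(tl$lo - 0.5 * tl$eq, .Machine$double.xmin)
  p_upper <- pmax(1 - tl$lo + 0.5 * tl$eq, .Machine$double.xmin)
  tibble(
    p_lower = p_lower, p_upper = p_upper,
    p_tail = pmin(p_lower, p_upper),
    pvalue = pmin(1, 2 * pmin(p_lower, p_upper)),
    direction = sign(reads_t / deptht - p0)
  )
}

#' Logit-slope selection coefficient from two time points
#'
#' `s = (logit(pt) - logit(p0)) / t`, the deterministic-selection slope on
#' the logit scale.  Boundary frequencies are clamped into the interval
#' `[1/(20 pool_size), 1 - 1/(20 pool_size)]` (a tenth of the smallest
#' resolvable pool frequency) rather than erroring, because pooled data
#' frequently hit 0 or 1 by sampling.
#'
#' @param p0,pt Allele frequencies (vectors).
#' @param t Generations (`>= 1`).
#' @param pool_size Diploid pool size determining the clamping bound.
#' @return Tibble with `s` and `clamped` (whether any clamping occurred for
#'   that locus).
#' @export
estimate_selection_coefficient <- function(p0, pt, t, pool_size = 60) {
  assert_prob(p0); assert_prob(pt)
  if (any(t < 1)) abort("`t` must be >= 1")
  bound <- 1 / (2 * pool_size * 10)
  clamp <- function(p) pmin(pmax(p, bound), 1 - bound)
  clamped <- p0 <= 0 | p0 >= 1 | pt <= 0 | pt >= 1
  tibble(s = (logit(clamp(pt)) - logit(clamp(p0))) / t, clamped = clamped)
}

#' Per-SNP drift-null scan of an experiment
#'
#' For every evolved line, pairs its pool-seq frequencies with its
#' ancestor-proxy sample, adjusts the divergence time ([adjust_generations()]),
#' estimates the line's effective population size ([estimate_ne()]) unless
#' supplied, computes per-SNP drift-null p-values (sampling-aware
#' [poolseq_null_pvalue()] by default, or the plain beta null), and
#' estimates logit-slope selection coefficients.
#'
#' @param x An `er_experiment`, or a long SNP tibble with columns `locus`,
#'   `sample_id`, `freq`, `reads`, `depth` (plus optional `scaffold`, `pos`).
#' @param design The design sheet (taken from `x` when it is an
#'   experiment).
#' @param ne `NULL` to estimate per line; or a single number; or a tibble
#'   with columns `line_id`, `ne`.
#' @param q_detect Per-tail probability of the strict detection threshold.
#' @param q_class Per-tail probability of the relaxed classification
#'   threshold.
#' @param method `"exact"` (default, [wf_exact_null()]), `"sampling"`
#'   ([poolseq_null_pvalue()]) or `"beta"` ([drift_null_pvalue()]).
#' @param proxy_offset Ancestor-proxy age in generations.
#' @param min_loci Passed to [estimate_ne()].
#' @param seed Seed of the randomized tail probabilities of the exact null
#'   (per-line substreams are derived from it).
#'
#' @return Object of class `er_scan`: list with `records` (locus x line test
#'   records with `p0`, `pt`, `direction`, `pvalue`, `p_tail`, `s`,
#'   `candidate_detect`, `candidate_class`), `ne` (per-line estimates), and
#'   `params`.
#' @export
drift_scan <- function(x, design = NULL, ne = NULL,
                       q_detect = 1e-4, q_class = 1e-2,
                       method = c("exact", "sampling", "beta"),
                       proxy_offset = 3, min_loci = 100, seed = 1) {
  method <- match.arg(method)
  if (inherits(x, "er_experiment")) {
    design <- x$design
    snp <- x$snp
  } else {
    snp <- x
    if (is.null(design)) abort("`design` is required with a raw SNP table")
  }
  if (!all(q_detect > 0, q_detect < 0.5, q_class > 0, q_class < 0.5)) {
    abort("detection thresholds must lie in (0, 0.5)")
  }

  loci_meta <- if (all(c("scaffold", "pos") %in% names(snp))) {
    distinct(snp, .data$locus, .data$scaffold, .data$pos)
  } else {
    distinct(snp, .data$locus)
  }

  evolved <- design[design$role == "evolved", ]
  ne_tbl <- NULL
  if (!is.null(ne) && !is.data.frame(ne)) {
    ne_tbl <- tibble(line_id = evolved$line_id, ne = ne)
  } else if (is.data.frame(ne)) {
    ne_tbl <- ne
  }

  per_line <- purrr::map(seq_len(nrow(evolved)), function(i) {
    row <- evolved[i, ]
    ev <- snp[snp$sample_id == row$sample_id, ]
    an <- snp[snp$sample_id == row$anc_sample_id, ]
    d <- inner_join(
      select(ev, "locus", pt = "freq", reads_t = "reads", deptht = "depth"),
      select(an, "locus", p0 = "freq", depth0 = "depth"),
      by = "locus"
    )
    t_adj <- adjust_generations(row$generation, row$regime, proxy_offset)
    cold <- row$regime == "cold"
    t_evo <- if (cold) row$generation else row$generation - proxy_offset
    t_anc <- if (cold) proxy_offset else 0
    if (is.null(ne_tbl)) {
      fit <- estimate_ne(d$p0, d$pt, d$depth0, d$deptht, row$pool_size,
                         t = if (method == "exact") t_evo else t_adj,
                         t_anc = if (method == "exact") t_anc else 0,
                         min_loci = min_loci)
      line_ne <- fit$ne
      ne_row <- glance(fit) |> mutate(line_id = row$line_id, .before = 1)
    } else {
      line_ne <- ne_tbl$ne[match(row$line_id, ne_tbl$line_id)]
      ne_row <- tibble(line_id = row$line_id, ne = line_ne, f_hat = NA_real_,
                       t = t_adj, n_loci = nrow(d), no_drift = FALSE)
    }
    if (!is.finite(line_ne)) {
      abort(sprintf("line %s: no detectable drift, cannot form a null",
                    row$line_id))
    }
    pv <- if (method == "exact") {
      ## cold lines branch off t_anc = proxy_offset generations before their
      ## proxy was sampled; hot lines carry the proxy on their own branch
      wf_exact_null(round(d$p0 * d$depth0), d$depth0, d$reads_t, d$deptht,
                    row$pool_size, line_ne, t = t_evo, t_anc = t_anc,
                    seed = if (is.null(seed)) NULL
                           else substream_seed(seed, row$line_id))
    } else if (method == "sampling") {
      poolseq_null_pvalue(d$p0, d$reads_t, d$depth0, d$deptht,
                          row$pool_size, line_ne, t_adj)
    } else {
      p2 <- drift_null_pvalue(d$p0, d$pt, line_ne, t_adj)
      tibble(p_lower = NA_real_, p_upper = NA_real_, p_tail = p2 / 2,
             pvalue = p2, direction = sign(d$pt - d$p0))
    }
    sel <- estimate_selection_coefficient(d$p0, d$pt, t_adj, row$pool_size)
    rec <- tibble(
      locus = d$locus, line_id = row$line_id, background = row$background,
      regime = row$regime, replicate = row$replicate,
      p0 = d$p0, pt = d$pt, depth0 = d$depth0, deptht = d$deptht,
      direction = pv$direction, pvalue = pv$pvalue, p_tail = pv$p_tail,
      s = sel$s, s_clamped = sel$clamped,
      candidate_detect = pv$p_tail < q_detect & pv$direction != 0,
      candidate_class = pv$p_tail < q_class & pv$direction != 0
    )
    list(rec = rec, ne = ne_row)
  })

  structure(
    list(records = bind_rows(purrr::map(per_line, "rec")),
         ne = bind_rows(purrr::map(per_line, "ne")),
         loci = loci_meta,
         params = list(q_detect = q_detect, q_class = q_class,
                       method = method, proxy_offset = proxy_offset)),
    class = "er_scan"
  )
}

#' @export
print.er_scan <- function(x, ...) {
  cat("Drift-null scan (", x$params$method, " null)\n", sep = "")
  cat("  lines:", nrow(x$ne), " loci:", dplyr::n_distinct(x$records$locus), "\n")
  cat("  candidates (q =", x$params$q_detect, "):",
      dplyr::n_distinct(x$records$locus[x$records$candidate_detect]), "\n")
  invisible(x)
}

#' @rdname drift_scan
#' @param x An `er_scan`.
#' @param ... Unused.
#' @export
tidy.er_scan <- function(x, ...) x$records

#' @rdname drift_scan
#' @export
glance.er_scan <- function(x, ...) {
  x$records |>
    group_by(.data$line_id) |>
    summarise(n_loci = n(),
              n_detect = sum(.data$candidate_detect),
              n_class = sum(.data$candidate_class)) |>
    left_join(select(x$ne, "line_id", "ne", "f_hat", "no_drift"),
              by = "line_id")
}

#' Union candidate set across lines
#'
#' Flags SNP x line records whose one-sided tail probability falls below
#' `per_tail_probability` in the recorded direction, and returns the union
#' of flagged loci over lines with the contributing lines listed.
#'
#' @param records Scan records (an `er_scan` or its `records` tibble).
#' @param per_tail_probability Per-tail threshold `q` in `(0, 0.5)`;
#'   the strict detection default is `1e-4`, the relaxed classification
#'   threshold is `1e-2`.
#' @return Tibble with `locus`, `n_lines` and `lines` (comma-separated
#'   contributing line ids).
#' @export
detect_candidates <- function(records, per_tail_probability = 1e-4) {
  if (inherits(records, "er_scan")) records <- records$records
  q <- per_tail_probability
  if (q <= 0 || q >= 0.5) abort("`per_tail_probability` must be in (0, 0.5)")
  records |>
    filter(.data$p_tail < q, .data$direction != 0) |>
    group_by(.data$locus) |>
    summarise(n_lines = n(),
              lines = paste(sort(.data$line_id), collapse = ","))
}
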