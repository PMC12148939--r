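## Exact discrete drift-plus-sampling null.
##
## The observation model per locus: an unknown branch-point frequency p0
## (prior over a frequency grid); on the *observation* branch, t_anc
## generations of Wright-Fisher drift (zero when the ancestor sample sits on
## the evolved line's own trajectory) followed by two-stage pool-seq
## sampling of the ancestor pool; on the *evolved* branch, t generations of
## drift followed by the same two-stage sampling.  Every stage after the
## prior is an exact finite transition (binomial first generation onto the
## 2Ne-chromosome grid, transition-matrix powers, binomial pool and read
## sampling), so the conditional distribution of the evolved read count
## given the ancestor read count is exact up to the prior.  The prior itself
## is estimated from the genome-wide ancestor read counts by nonparametric
## maximum likelihood (EM over the grid).
##
## With `randomize = TRUE` the point mass at the observed count enters the
## tail with a uniform weight, which makes null p-values exactly
## Uniform(0,1) despite read-count discreteness.

## M^k by binary powering.
matrix_power <- function(M, k) {
  if (k == 0) return(diag(nrow(M)))
  R <- NULL
  while (k > 0) {
    if (k %% 2 == 1) R <- if (is.null(R)) M else R %*% M
    M <- M %*% M
    k <- k %/% 2
  }
  R
}

#' Exact Wright-Fisher drift null for pool-seq read counts
#'
#' Computes, for every locus, the exact conditional distribution of the
#' evolved sample's read count given the ancestor sample's read count under
#' pure drift, and returns tail probabilities.  The branch-point frequency
#' gets a genome-wide empirical prior (nonparametric MLE from the ancestor
#' read counts; or a uniform prior); drift on both branches is the exact
#' `2 Ne`-chromosome Wright-Fisher chain (`t_anc` generations between the
#' branch point and the ancestor sample — 3 for lines whose "ancestor" is an
#' early proxy on a sibling branch, 0 when the proxy lies on the line's own
#' trajectory — and `t` generations to the evolved sample); two-stage
#' pool-seq sampling of both samples is modelled exactly.  Tail
#' probabilities are randomized (the observed count's probability mass
#' enters with a uniform draw), so null p-values are exactly uniform; set
#' `randomize = FALSE` for deterministic mid-p values instead.
#'
#' @param r0,depth0 Ancestor-sample reads of the tracked allele and depth.
#' @param rt,deptht Evolved-sample reads and depth.
#' @param pool_size Diploid individuals per pool.
#' @param ne Effective population size of the line (used as `round(2 ne)`
#'   chromosomes; must give at most `max_chromosomes`).
#' @param t Generations of drift on the evolved branch (`>= 1`).
#' @param t_anc Generations of drift on the observation branch (default 0).
#' @param prior `"empirical"` (default) or `"uniform"`.
#' @param grid_size Frequency-grid resolution for the prior/posterior.
#' @param em_iterations EM iterations of the prior fit.
#' @param randomize Randomized (exactly uniform) versus mid-p tails.
#' @param max_chromosomes Guard on the transition-matrix size.
#' @param seed Optional integer seed for the randomized tails.
#' @return Tibble with `p_lower`, `p_upper`, `p_tail`, `pvalue` (two-sided)
#'   and `direction`, one row per locus.
#' @export
wf_exact_null <- function(r0, depth0, rt, deptht, pool_size, ne, t,
                          t_anc = 0,
                          prior = c("empirical", "uniform"),
                          grid_size = 1024, em_iterations = 300,
                          randomize = TRUE, max_chromosomes = 4000,
                          seed = NULL) {
  prior <- match.arg(prior)
  if (!is.finite(ne)) abort("`ne` must be finite")
  if (t < 1) abort("`t` must be >= 1")
  if (t_anc < 0) abort("`t_anc` must be >= 0")
  n2 <- round(2 * ne)
  if (n2 > max_chromosomes) {
    abort(sprintf("2*ne = %d exceeds `max_chromosomes`; use the \"sampling\" null",
                  n2))
  }
  r0 <- as.integer(r0); rt <- as.integer(rt)
  depth0 <- rep_len(as.integer(depth0), length(r0))
  deptht <- rep_len(as.integer(deptht), length(r0))

  grid <- (seq_len(grid_size) - 0.5) / grid_size
  states <- 0:n2
  K <- 2 * pool_size

  B <- outer(grid, states, function(p, j) dbinom(j, n2, p))    # grid -> states
  pool_from_grid <- outer(grid, 0:K, function(p, k) dbinom(k, K, p))
  pool_from_states <- outer(states, 0:K, function(i, k) dbinom(k, K, i / n2))
  M <- outer(states, states, function(i, j) dbinom(j, n2, i / n2))

  ## observation-branch operator: grid -> pool-chromosome counts
  obs_to_pool <- if (t_anc == 0) {
    pool_from_grid
  } else {
    B %*% (matrix_power(M, t_anc - 1) %*% pool_from_states)
  }

  ## likelihood of each unique (r0, depth0) cell under each grid frequency
  cells <- dplyr::count(tibble(r = r0, d = depth0), .data$r, .data$d)
  L <- matrix(0, grid_size, nrow(cells))
  for (d in unique(cells$d)) {
    j <- which(cells$d == d)
    reads <- outer(0:K, 0:d, function(k, r) dbinom(r, d, k / K))
    L[, j] <- (obs_to_pool %*% reads)[, cells$r[j] + 1L, drop = FALSE]
  }

  ## prior over the grid: NPMLE by EM, or uniform
  w <- rep(1 / grid_size, grid_size)
  if (prior == "empirical") {
    for (i in seq_len(em_iterations)) {
      mix <- as.numeric(crossprod(L, w))
      w <- w * as.numeric(L %*% (cells$n / mix)) / sum(cells$n)
    }
  }
  W <- L * w
  W <- sweep(W, 2, colSums(W), "/")              # grid x cell posterior
  V0 <- crossprod(W, B)                          # cell x states (1st WF gen)
  V0 <- V0 / rowSums(V0)

  Mt <- matrix_power(M, t - 1)
  cell_id <- match(paste(r0, depth0), paste(cells$r, cells$d))
  lo <- eq <- numeric(length(r0))
  for (d in unique(deptht)) {
    rows <- which(deptht == d)
    reads_tr <- outer(0:K, 0:d, function(k, r) dbinom(r, d, k / K))
    S <- Mt %*% (pool_from_states %*% reads_tr)  # states x (d+1)
    Dm <- V0 %*% S                               # cell x (d+1)
    Dm <- Dm / rowSums(Dm)
    CS <- Dm %*% (upper.tri(diag(d + 1), diag = TRUE) * 1)
    sel <- cbind(cell_id[rows], rt[rows] + 1L)
    eq[rows] <- Dm[sel]
    lo[rows] <- CS[sel]
  }

  frac <- if (randomize) {
    with_substream(seed, "exact_null", runif(length(r0)))
  } else {
    rep(0.5, length(r0))
  }
  ## complementary randomized tails: p_lower + p_upper = 1 exactly
  p_lower <- pmax(lo - frac * eq, .Machine$double.xmin)
  p_upper <- pmax(1 - lo + frac * eq, .Machine$double.xmin)
  tibble(
    p_lower = p_lower, p_upper = p_upper,
    p_tail = pmin(p_lower, p_upper),
    pvalue = pmin(1, 2 * pmin(p_lower, p_upper)),
    direction = sign(rt / deptht - r0 / depth0)
  )
}
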