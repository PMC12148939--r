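#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange summarise group_by ungroup
#'   left_join inner_join join_by across n bind_rows distinct rename pull
#'   row_number if_else
#' @importFrom stats pbeta rbinom rnorm runif quantile cor lm anova setNames
#'   median sd qlogis plogis
#' @importFrom utils head
NULL

## Deterministic sub-stream seeds: fold a master seed and a text key through
## a 31-ary hash modulo the Mersenne prime 2^31 - 1.  All intermediates stay
## below 2^53, so the arithmetic is exact in doubles on every platform.
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  m <- 2147483647
  x <- abs(as.numeric(seed)) %% m
  for (c in utf8ToInt(key)) x <- (x * 31 + c) %% m
  as.integer(x)
}

with_substream <- function(seed, key, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(substream_seed(seed, key), code)
}

## Effective number of chromosomes behind one pool-seq frequency estimate:
## Var(p_obs) = p(1-p) / n_eff with two-stage binomial sampling
## (2*pool_size chromosomes, then `depth` reads).
poolseq_n_eff <- function(pool_size, depth) {
  1 / (1 / (2 * pool_size) + (1 - 1 / (2 * pool_size)) / depth)
}

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

assert_prob <- function(x, name = deparse(substitute(x))) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be in [0, 1]", name))
  }
  invisible(x)
}

assert_scalar_count <- function(x, name = deparse(substitute(x)), min = 1) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s", name, min))
  }
  invisible(x)
}

#' The seven life-history traits of the experimental design
#'
#' Trait identifiers used throughout the package, in canonical order:
#' lifetime offspring production (`lrs`), adult weight, juvenile development
#' time, weight loss, water loss, early fecundity and mass-specific
#' metabolic rate.
#'
#' @return Character vector of length 7.
#' @export
trait_names <- function() {
  c("lrs", "adult_weight", "dev_time", "weight_loss", "water_loss",
    "early_fecundity", "metabolic_rate")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
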