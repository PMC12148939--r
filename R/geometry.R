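#' Mean-scale a trait panel by ancestral grand means
#'
#' Divides every trait mean and standard error by the grand mean of that
#' trait across all ancestor lines measured at the same assay temperature,
#' yielding unitless traits whose changes read as proportions of the
#' ancestral value.  The two assay temperatures are scaled independently.
#'
#' @param traits Long trait panel with columns `trait`, `assay_temp`,
#'   `mean`, `se` and `role` (rows with `role == "ancestor"` define the
#'   scaling).
#' @return The panel with `mean` and `se` rescaled and attribute
#'   `mean_scaled = TRUE`.
#' @export
mean_scale_traits <- function(traits) {
  need <- c("trait", "assay_temp", "mean", "se", "role")
  if (!all(need %in% names(traits))) {
    abort(paste("`traits` must have columns:", toString(need)))
  }
  grand <- traits |>
    filter(.data$role == "ancestor") |>
    group_by(.data$trait, .data$assay_temp) |>
    summarise(grand_mean = mean(.data$mean), .groups = "drop")
  if (any(grand$grand_mean == 0)) {
    abort("zero ancestral grand mean: trait cannot be mean-scaled")
  }
  out <- traits |>
    left_join(grand, by = c("trait", "assay_temp")) |>
    mutate(mean = .data$mean / .data$grand_mean,
           se = .data$se / abs(.data$grand_mean)) |>
    select(-"grand_mean")
  attr(out, "mean_scaled") <- TRUE
  out
}

#' Change vector between an ancestor and an evolved sample
#'
#' @param anc_mean,evo_mean Matched numeric vectors of per-dimension means.
#' @param anc_se,evo_se Standard errors (recycled; carried through unchanged
#'   for later bias corrections).
#' @param t Generations separating the samples.
#' @param ancestor_id Optional identifier of the shared ancestor.
#' @return List with `values` (`evo_mean - anc_mean`), `anc_errors`,
#'   `evo_errors`, `t`, `ancestor_id`.
#' @export
change_vector <- function(anc_mean, evo_mean, anc_se = 0, evo_se = 0,
                          t = 1, ancestor_id = NULL) {
  if (length(anc_mean) != length(evo_mean)) {
    abort("ancestor and evolved vectors must have equal dimension")
  }
  list(values = evo_mean - anc_mean,
       anc_errors = rep_len(anc_se, length(anc_mean)),
       evo_errors = rep_len(evo_se, length(anc_mean)),
       t = t, ancestor_id = ancestor_id)
}

## Pool the (independent) ancestor lines of each background into one shared
## ancestral estimate: mean of means, se of the mean.
pool_ancestors <- function(traits) {
  traits |>
    filter(.data$role == "ancestor") |>
    group_by(.data$background, .data$assay_temp, .data$trait) |>
    summarise(anc_value = mean(.data$mean),
              anc_se = sqrt(sum(.data$se^2)) / n(),
              .groups = "drop")
}

#' Per-line phenotypic change vectors
#'
#' Builds, for every evolved line, the vector of mean-scaled trait change
#' from its background's pooled ancestor, measured at the line's local assay
#' temperature (cold lines at 23, hot at 35) or at a fixed temperature.
#'
#' @param traits A mean-scaled trait panel (see [mean_scale_traits()]).
#' @param design Optional design sheet; when given, each line's divergence
#'   time `t` is attached via [adjust_generations()].
#' @param assay `"local"`, `23` or `35`.
#' @param proxy_offset Ancestor-proxy age for the time adjustment.
#' @return Long tibble: `line_id`, `background`, `regime`, `replicate`,
#'   `assay_temp`, `dim`, `value`, `anc_value`, `anc_se`, `evo_se`,
#'   `ancestor_id`, `t`.
#' @export
change_vectors <- function(traits, design = NULL, assay = "local",
                           proxy_offset = 3) {
  anc <- pool_ancestors(traits)
  ev <- filter(traits, .data$role == "evolved")
  if (identical(assay, "local")) {
    ev <- filter(ev, (.data$regime == "cold") == (.data$assay_temp == 23))
  } else {
    ev <- filter(ev, .data$assay_temp == as.numeric(assay))
  }
  out <- ev |>
    inner_join(anc, by = c("background", "assay_temp", "trait")) |>
    mutate(dim = .data$trait, value = .data$mean - .data$anc_value,
           evo_se = .data$se,
           ancestor_id = paste0(.data$background, "_anc")) |>
    select("line_id", "background", "regime", "replicate", "assay_temp",
           "dim", "value", "anc_value", "anc_se", "evo_se", "ancestor_id")
  if (!is.null(design)) {
    gen <- design |>
      filter(.data$role == "evolved") |>
      mutate(t = adjust_generations(.data$generation, .data$regime,
                                    proxy_offset)) |>
      select("line_id", "t")
    out <- left_join(out, gen, by = "line_id")
  } else {
    out$t <- NA_real_
  }
  out
}

#' Per-line genomic change vectors over a candidate SNP set
#'
#' Allele-frequency change vectors (`pt - p0`) per line, restricted to a set
#' of loci (by default the union candidate set at the scan's detection
#' threshold).  No shared-ancestor error correction is attached: each line
#' has its own sequenced ancestor proxy.
#'
#' @param scan An `er_scan`.
#' @param loci Optional integer vector of loci; default
#'   `detect_candidates(scan)$locus`.
#' @return Tibble in the same shape as [change_vectors()] (with
#'   `assay_temp = NA`, `anc_se = NA`).
#' @export
genomic_change_vectors <- function(scan, loci = NULL) {
  loci <- loci %||% detect_candidates(scan, scan$params$q_detect)$locus
  scan$records |>
    filter(.data$locus %in% loci) |>
    left_join(select(scan$ne, "line_id", "t"), by = "line_id") |>
    mutate(dim = as.character(.data$locus), value = .data$pt - .data$p0,
           anc_value = .data$p0, anc_se = NA_real_, evo_se = NA_real_,
           ancestor_id = paste0(.data$line_id, "_anc"),
           assay_temp = NA_real_) |>
    select("line_id", "background", "regime", "replicate", "assay_temp",
           "dim", "value", "anc_value", "anc_se", "evo_se", "ancestor_id",
           "t")
}

#' Evolutionary rate of a change vector
#'
#' Euclidean norm of the change vector per generation, optionally scaled by
#' the maximum rate in the dataset.
#'
#' @param values Numeric change vector.
#' @param t Generations (`>= 1`).
#' @param dataset_max Optional maximum raw rate used for scaling.
#' @return List with `raw_rate` and `scaled_rate` (`NA` without
#'   `dataset_max`).
#' @export
evolutionary_rate <- function(values, t, dataset_max = NULL) {
  if (t < 1) abort("`t` must be >= 1")
  raw <- sqrt(sum(values^2)) / t
  list(raw_rate = raw,
       scaled_rate = if (is.null(dataset_max)) NA_real_ else raw / dataset_max)
}

#' @rdname evolutionary_rate
#' @param cv Change-vector tibble from [change_vectors()] or
#'   [genomic_change_vectors()].
#' @return For `evolutionary_rates()`: per-line tibble with `raw_rate` and
#'   `scaled_rate` (scaled by the dataset maximum).
#' @export
evolutionary_rates <- function(cv) {
  out <- cv |>
    group_by(.data$line_id, .data$background, .data$regime,
             .data$replicate) |>
    summarise(raw_rate = sqrt(sum(.data$value^2)) / .data$t[1],
              .groups = "drop")
  mutate(out, scaled_rate = .data$raw_rate / max(.data$raw_rate))
}

#' Angle between two change vectors with shared-ancestor correction
#'
#' The uncorrected angle is the arccosine of the normalised dot product
#' (vector correlation through the origin).  When both vectors were computed
#' against the same measured ancestor, the ancestor's measurement error adds
#' `sum(anc_se^2)` to the expected dot product; with `correct = TRUE` this
#' error component is subtracted from the numerator.  The denominator is
#' left at the observed norms by default; `denominator_correction = TRUE`
#' additionally subtracts the error from each squared norm.  When the
#' corrected cosine is impossible (magnitude beyond 1, or a corrected
#' squared norm non-positive), the angle is undefined with reason
#' `"error exceeds signal"`.
#'
#' @param a,b Numeric change vectors of equal dimension and non-zero norm.
#' @param shared_anc_se Per-dimension standard errors of the shared
#'   ancestor, or `NULL` for independently measured ancestors.
#' @param correct Apply the numerator correction when an ancestor is shared.
#' @param denominator_correction Also correct the norms (off by default).
#' @param centered Use centred (Pearson) rather than raw cosine.
#' @return List with `theta` (degrees in `[0, 180]`, `NA` when undefined),
#'   `corrected`, `undefined_reason`.
#' @export
pairwise_angle <- function(a, b, shared_anc_se = NULL, correct = TRUE,
                           denominator_correction = FALSE, centered = FALSE) {
  if (length(a) != length(b)) abort("vectors must have equal dimension")
  if (centered) { a <- a - mean(a); b <- b - mean(b) }
  na2 <- sum(a^2); nb2 <- sum(b^2)
  if (na2 == 0 || nb2 == 0) abort("zero-length change vector")
  num <- sum(a * b)
  corrected <- FALSE
  if (!is.null(shared_anc_se) && correct) {
    err2 <- sum(shared_anc_se^2)
    num <- num - err2
    corrected <- TRUE
    if (denominator_correction) {
      na2 <- na2 - err2; nb2 <- nb2 - err2
      if (na2 <= 0 || nb2 <= 0) {
        return(list(theta = NA_real_, corrected = TRUE,
                    undefined_reason = "error exceeds signal"))
      }
    }
  }
  cosv <- num / sqrt(na2 * nb2)
  if (abs(cosv) > 1 + 1e-12) {
    if (corrected) {
      return(list(theta = NA_real_, corrected = TRUE,
                  undefined_reason = "error exceeds signal"))
    }
    cosv <- sign(cosv)
  }
  cosv <- pmin(1, pmax(-1, cosv))
  list(theta = acos(cosv) * 180 / pi, corrected = corrected,
       undefined_reason = NA_character_)
}

## Spread a change-vector tibble into aligned matrices.
cv_matrices <- function(cv) {
  dims <- sort(unique(cv$dim))
  lines <- distinct(cv, .data$line_id, .data$background, .data$regime,
                    .data$replicate, .data$ancestor_id, .data$t)
  shape <- function(col) {
    w <- tidyr::pivot_wider(cv, id_cols = "line_id", names_from = "dim",
                            values_from = dplyr::all_of(col))
    m <- as.matrix(w[, dims, drop = FALSE])
    rownames(m) <- w$line_id
    m[lines$line_id, , drop = FALSE]
  }
  list(lines = lines, values = shape("value"), anc_value = shape("anc_value"),
       anc_se = shape("anc_se"), evo_se = shape("evo_se"))
}

#' All pairwise angles between line change vectors
#'
#' Computes [pairwise_angle()] for every unordered pair of lines, applying
#' the shared-ancestor correction to pairs that share an `ancestor_id` (when
#' `correct = TRUE` and ancestor errors are available), and annotates each
#' pair as a within- or between-background comparison.
#'
#' @inheritParams pairwise_angle
#' @param cv Change-vector tibble ([change_vectors()] /
#'   [genomic_change_vectors()]).
#' @return Tibble per pair: line ids, regimes, backgrounds, `group`
#'   (`"within"`/`"between"`), `shared_ancestor`, `theta`,
#'   `undefined_reason`.
#' @export
pairwise_angles <- function(cv, correct = TRUE,
                            denominator_correction = FALSE,
                            centered = FALSE) {
  mm <- cv_matrices(cv)
  ln <- mm$lines
  pairs <- utils::combn(nrow(ln), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    shared <- !is.na(ln$ancestor_id[i]) &&
      identical(ln$ancestor_id[i], ln$ancestor_id[j]) &&
      !anyNA(mm$anc_se[i, ])
    ang <- pairwise_angle(
      mm$values[i, ], mm$values[j, ],
      shared_anc_se = if (shared) mm$anc_se[i, ] else NULL,
      correct = correct, denominator_correction = denominator_correction,
      centered = centered
    )
    tibble(line_a = ln$line_id[i], line_b = ln$line_id[j],
           regime_a = ln$regime[i], regime_b = ln$regime[j],
           background_a = ln$background[i], background_b = ln$background[j],
           group = if_else(ln$background[i] == ln$background[j],
                           "within", "between"),
           shared_ancestor = shared, theta = ang$theta,
           corrected = ang$corrected,
           undefined_reason = ang$undefined_reason)
  })
}

#' Start/end distance and divergence of two lineages
#'
#' `S_d` is the Euclidean distance between the two ancestors, `E_d` between
#' the two evolved lines.  When the evolved lines share a measured ancestor,
#' the summed squared standard errors of the evolved lines are subtracted
#' under the square root of `E_d`; a negative corrected square is floored at
#' zero (`floored = TRUE`).  `div = E_d - S_d` is positive for divergence,
#' negative for convergence; `div_scaled` divides by `scale`.
#'
#' @param anc_a,anc_b Ancestor position vectors.
#' @param evo_a,evo_b Evolved position vectors.
#' @param se_a,se_b Evolved-line standard errors (used only when
#'   `shared_ancestor`).
#' @param shared_ancestor Do the evolved lines share one measured ancestor?
#' @param scale Optional scaling distance (the most differentiated ancestor
#'   pair in the dataset).
#' @return List with `S_d`, `E_d`, `div`, `div_scaled`, `floored`.
#' @export
divergence <- function(anc_a, anc_b, evo_a, evo_b, se_a = 0, se_b = 0,
                       shared_ancestor = FALSE, scale = NULL) {
  if (length(evo_a) != length(evo_b)) abort("dimension mismatch")
  s_d <- sqrt(sum((anc_a - anc_b)^2))
  e2 <- sum((evo_a - evo_b)^2)
  floored <- FALSE
  if (shared_ancestor) {
    e2 <- e2 - sum(rep_len(se_a, length(evo_a))^2) -
      sum(rep_len(se_b, length(evo_b))^2)
    if (e2 < 0) { e2 <- 0; floored <- TRUE }
  }
  e_d <- sqrt(e2)
  div <- e_d - s_d
  list(S_d = s_d, E_d = e_d, div = div,
       div_scaled = if (is.null(scale)) NA_real_ else div / scale,
       floored = floored)
}

#' Pairwise divergence of all line pairs
#'
#' Applies [divergence()] to every unordered pair of lines in a
#' change-vector tibble (evolved position = ancestor + change), scaling by
#' the distance between the two most differentiated ancestors.
#'
#' @param cv Change-vector tibble.
#' @param correct Apply the shared-ancestor error correction.
#' @return Tibble per pair with `S_d`, `E_d`, `div`, `div_scaled`,
#'   `floored`, plus pair annotation as in [pairwise_angles()].
#' @export
divergence_pairs <- function(cv, correct = TRUE) {
  mm <- cv_matrices(cv)
  ln <- mm$lines
  evo <- mm$anc_value + mm$values
  pairs <- utils::combn(nrow(ln), 2)
  anc_d <- apply(pairs, 2, function(ij) {
    sqrt(sum((mm$anc_value[ij[1], ] - mm$anc_value[ij[2], ])^2))
  })
  scale <- max(anc_d)
  if (scale == 0) abort("all ancestors are identical: no divergence scale")
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    shared <- correct && !is.na(ln$ancestor_id[i]) &&
      identical(ln$ancestor_id[i], ln$ancestor_id[j]) &&
      !anyNA(mm$evo_se[i, ])
    d <- divergence(mm$anc_value[i, ], mm$anc_value[j, ],
                    evo[i, ], evo[j, ],
                    se_a = mm$evo_se[i, ], se_b = mm$evo_se[j, ],
                    shared_ancestor = shared, scale = scale)
    tibble(line_a = ln$line_id[i], line_b = ln$line_id[j],
           regime_a = ln$regime[i], regime_b = ln$regime[j],
           background_a = ln$background[i], background_b = ln$background[j],
           group = if_else(ln$background[i] == ln$background[j],
                           "within", "between"),
           S_d = d$S_d, E_d = d$E_d, div = d$div, div_scaled = d$div_scaled,
           floored = d$floored)
  })
}

#' Monte-Carlo null distribution of random angles
#'
#' Draws pairs of isotropic random unit vectors (independent standard-normal
#' components, normalised) in `dim` dimensions and records the mean pairwise
#' angle per iteration.  An observed mean angle can be tested two-sidedly
#' against this null.
#'
#' @param dim Dimensionality (`>= 2`).
#' @param n_pairs Pairs averaged per iteration.
#' @param iterations Monte-Carlo iterations.
#' @param observed Optional observed mean angle (degrees).
#' @param seed Optional integer seed.
#' @return Object of class `er_angle_null` with `draws`, `observed` and
#'   two-sided `p` (when `observed` is given).
#' @export
random_angle_null <- function(dim, n_pairs = 1, iterations = 1e5,
                              observed = NULL, seed = NULL) {
  if (dim < 2) abort("`dim` must be >= 2")
  if (iterations < 1000) abort("use at least 1000 iterations")
  draws <- with_substream(seed, "angle_null", {
    n <- n_pairs * iterations
    a <- matrix(rnorm(n * dim), n, dim)
    b <- matrix(rnorm(n * dim), n, dim)
    cosv <- rowSums(a * b) /
      sqrt(rowSums(a^2) * rowSums(b^2))
    theta <- acos(pmin(1, pmax(-1, cosv))) * 180 / pi
    rowMeans(matrix(theta, iterations, n_pairs))
  })
  p <- if (is.null(observed)) NA_real_ else {
    min(1, 2 * min(mean(draws <= observed), mean(draws >= observed)))
  }
  structure(list(draws = draws, dim = dim, n_pairs = n_pairs,
                 observed = observed, p = p),
            class = "er_angle_null")
}

#' @export
print.er_angle_null <- function(x, ...) {
  cat(sprintf("Random-angle null (dim %d): mean %.2f deg, sd %.2f\n",
              x$dim, mean(x$draws), sd(x$draws)))
  if (!is.null(x$observed)) {
    cat(sprintf("  observed %.2f deg, two-sided p = %.4g\n", x$observed, x$p))
  }
  invisible(x)
}

#' @rdname random_angle_null
#' @param x An `er_angle_null`.
#' @param ... Unused.
#' @export
tidy.er_angle_null <- function(x, ...) tibble(mean_angle = x$draws)

#' @rdname random_angle_null
#' @export
glance.er_angle_null <- function(x, ...) {
  tibble(dim = x$dim, n_pairs = x$n_pairs, iterations = length(x$draws),
         null_mean = mean(x$draws), null_sd = sd(x$draws),
         observed = x$observed %||% NA_real_, p_value = x$p)
}

#' Permutation test of a regime difference in repeatability statistics
#'
#' Tests whether hot and cold lines differ in mean pairwise angle, mean
#' pairwise divergence, or mean evolutionary rate.  The observed statistic
#' is the hot-minus-cold difference; the null permutes regime labels across
#' lines *within each genetic background* (preserving background structure)
#' and recomputes the statistic.  Two-sided p-value with the add-one
#' correction `(k + 1) / (n + 1)`.
#'
#' @param cv Change-vector tibble ([change_vectors()] or
#'   [genomic_change_vectors()]), all lines of both regimes.
#' @param statistic `"angle"`, `"divergence"` or `"rate"`.
#' @param iterations Number of label permutations.
#' @param correct Shared-ancestor corrections for angle/divergence.
#' @param seed Optional integer seed.
#' @return Object of class `er_perm` with `observed`, `null` draws,
#'   `p_value`, `statistic`.
#' @export
permutation_regime_test <- function(cv,
                                    statistic = c("angle", "divergence",
                                                  "rate"),
                                    iterations = 999, correct = TRUE,
                                    seed = NULL) {
  statistic <- match.arg(statistic)
  lines <- distinct(cv, .data$line_id, .data$background, .data$regime)
  if (any(table(lines$regime) < 2)) abort("need >= 2 lines per regime")

  if (statistic == "rate") {
    per_line <- evolutionary_rates(cv)
    value_of <- setNames(per_line$raw_rate, per_line$line_id)
    stat_fun <- function(regime) {
      mean(value_of[lines$line_id[regime == "hot"]]) -
        mean(value_of[lines$line_id[regime == "cold"]])
    }
  } else {
    pairs <- if (statistic == "angle") {
      pairwise_angles(cv, correct = correct) |>
        rename(value = "theta")
    } else {
      divergence_pairs(cv, correct = correct) |>
        rename(value = "div_scaled")
    }
    pairs <- filter(pairs, !is.na(.data$value))
    ia <- match(pairs$line_a, lines$line_id)
    ib <- match(pairs$line_b, lines$line_id)
    stat_fun <- function(regime) {
      same <- regime[ia] == regime[ib]
      hot <- same & regime[ia] == "hot"
      cold <- same & regime[ia] == "cold"
      mean(pairs$value[hot]) - mean(pairs$value[cold])
    }
  }

  observed <- stat_fun(lines$regime)
  null <- with_substream(seed, "perm", {
    vapply(seq_len(iterations), function(i) {
      perm <- lines$regime
      for (b in unique(lines$background)) {
        idx <- which(lines$background == b)
        perm[idx] <- sample(perm[idx])
      }
      stat_fun(perm)
    }, numeric(1))
  })
  p <- (sum(abs(null) >= abs(observed) - 1e-12) + 1) / (iterations + 1)
  structure(list(observed = observed, null = null, p_value = p,
                 statistic = statistic, iterations = iterations),
            class = "er_perm")
}

#' @export
print.er_perm <- function(x, ...) {
  cat(sprintf("Permutation regime test (%s): hot - cold = %.4g, p = %.4g\n",
              x$statistic, x$observed, x$p_value))
  invisible(x)
}

#' @rdname permutation_regime_test
#' @param x An `er_perm`.
#' @param ... Unused.
#' @export
tidy.er_perm <- function(x, ...) tibble(null_statistic = x$null)

#' @rdname permutation_regime_test
#' @export
glance.er_perm <- function(x, ...) {
  tibble(statistic = x$statistic, observed = x$observed,
         iterations = x$iterations, p_value = x$p_value)
}
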