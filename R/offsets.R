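#' Laboratory fitness: offspring per unit generation time
#'
#' Lifetime adult offspring per mating couple divided by egg-to-adult
#' development time — a proxy for the intrinsic population growth rate.
#'
#' @param lrs Lifetime reproductive success (adult offspring per couple).
#' @param dev_time Egg-to-adult development time (days, `> 0`).
#' @return Fitness (offspring per day).
#' @export
laboratory_fitness <- function(lrs, dev_time) {
  if (any(dev_time <= 0)) abort("`dev_time` must be > 0")
  if (any(lrs < 0)) abort("`lrs` must be >= 0")
  lrs / dev_time
}

#' Per-line laboratory fitness from a raw trait panel
#'
#' @param traits Raw (unscaled) trait panel.
#' @param assay_temp Assay temperature at which fitness is taken.
#' @return Tibble per line: `line_id`, `background`, `regime`, `replicate`,
#'   `role`, `lrs`, `dev_time`, `fitness`.
#' @export
fitness_table <- function(traits, assay_temp = 35) {
  if (isTRUE(attr(traits, "mean_scaled"))) {
    warn("fitness should be computed from the raw (unscaled) trait panel")
  }
  traits |>
    filter(.data$assay_temp == !!assay_temp,
           .data$trait %in% c("lrs", "dev_time")) |>
    tidyr::pivot_wider(id_cols = c("line_id", "background", "regime",
                                   "replicate", "role"),
                       names_from = "trait", values_from = "mean") |>
    mutate(fitness = laboratory_fitness(.data$lrs, .data$dev_time))
}

#' Select the reference line of a background x regime cell
#'
#' The reference is the line with the highest laboratory fitness at the
#' temperature to which it has been adapting.  Exact ties resolve to the
#' lexicographically first line id, with `tie = TRUE`.
#'
#' @param fitness Tibble with `line_id` and `fitness` for the candidate
#'   lines.
#' @return List with `line_id`, `fitness`, `tie`.
#' @export
select_reference <- function(fitness) {
  if (nrow(fitness) == 0) abort("no candidate lines")
  ord <- order(-fitness$fitness, fitness$line_id)
  best <- fitness[ord[1], ]
  tie <- sum(fitness$fitness == best$fitness) > 1
  list(line_id = best$line_id, fitness = best$fitness, tie = tie)
}

#' Reference candidate SNP set by empirical p-value quantile
#'
#' The smallest `quantile_fraction` of the reference line's empirical
#' p-value distribution, ties at the cut included (and flagged).  Each SNP
#' carries the absolute selection coefficient estimated in the reference
#' line as its offset weight.
#'
#' @param pvalues Tibble with `locus`, `pvalue` and `s` for the reference
#'   line (e.g. the line's scan records).
#' @param quantile_fraction Fraction of SNPs to keep (default 0.001).
#' @return Tibble `locus`, `pvalue`, `weight` (`|s|`), with attribute
#'   `ties`.
#' @export
reference_candidate_set <- function(pvalues, quantile_fraction = 0.001) {
  if (nrow(pvalues) == 0) abort("empty p-value table")
  if (quantile_fraction <= 0 || quantile_fraction >= 1) {
    abort("`quantile_fraction` must be in (0, 1)")
  }
  k <- ceiling(quantile_fraction * nrow(pvalues))
  cut <- sort(pvalues$pvalue, partial = k)[k]
  keep <- pvalues$pvalue <= cut
  out <- pvalues[keep, ] |>
    mutate(weight = abs(.data$s)) |>
    select("locus", "pvalue", "weight")
  attr(out, "ties") <- sum(keep) > k
  out
}

#' Genomic offset between two lines
#'
#' Weighted L1 distance in allele-frequency space over a candidate SNP set:
#' `sum(|p_ref - p_test| * |s_ref|)`.  Frequencies must be aligned to the
#' same loci in the same allele orientation.
#'
#' @param ref_freqs,test_freqs Allele frequencies over the same loci.
#' @param weights Non-negative weights (`|s|` from the reference line; 1 for
#'   random-SNP controls).
#' @return Scalar offset.
#' @export
genomic_offset <- function(ref_freqs, test_freqs, weights = 1) {
  if (length(ref_freqs) != length(test_freqs)) {
    abort("reference and test frequencies cover different SNP sets")
  }
  if (anyNA(ref_freqs) || anyNA(test_freqs)) abort("missing SNP frequencies")
  sum(abs(ref_freqs - test_freqs) * rep_len(weights, length(ref_freqs)))
}

#' Phenotypic offset between two lines
#'
#' Euclidean distance in mean-scaled trait space.
#'
#' @param ref_traits,test_traits Scaled trait vectors of equal dimension.
#' @return Scalar distance.
#' @export
phenotypic_offset <- function(ref_traits, test_traits) {
  if (length(ref_traits) != length(test_traits)) abort("dimension mismatch")
  sqrt(sum((ref_traits - test_traits)^2))
}

#' Relative fitness offset
#'
#' @param test_fitness,ref_fitness Laboratory fitness of test and reference
#'   (reference `> 0`).
#' @return `test_fitness / ref_fitness`.
#' @export
fitness_offset <- function(test_fitness, ref_fitness) {
  if (any(ref_fitness <= 0)) abort("reference fitness must be > 0")
  test_fitness / ref_fitness
}

## Per-sample data needed by the offset machinery: frequency matrix over all
## loci, plus trait/fitness metadata per line at the assay temperature.
offset_inputs <- function(x, assay_temp) {
  freq <- tidyr::pivot_wider(x$snp, id_cols = "locus",
                             names_from = "sample_id",
                             values_from = "freq")
  scaled <- mean_scale_traits(x$traits) |>
    filter(.data$assay_temp == !!assay_temp) |>
    tidyr::pivot_wider(id_cols = c("line_id", "background", "regime",
                                   "replicate", "role"),
                       names_from = "trait", values_from = "mean")
  fit <- fitness_table(x$traits, assay_temp)
  list(freq = freq, scaled = scaled, fitness = fit)
}

#' Reference-anchored offset table of an experiment
#'
#' For each genetic background, selects the reference line
#' ([select_reference()]: highest laboratory fitness among that background's
#' lines of `regime` at `assay_temp`), takes the reference's candidate SNP
#' set ([reference_candidate_set()]), and computes for every other sequenced
#' line the genomic offset (weighted by the reference's `|s|`), the
#' phenotypic offset in mean-scaled trait space, and the relative fitness
#' offset — each labelled as a within- or between-background comparison.
#'
#' @param x An `er_experiment`.
#' @param scan The matching `er_scan`.
#' @param assay_temp Assay temperature of the phenotypic/fitness offsets.
#' @param regime Regime from which references are drawn (`"hot"` at 35).
#' @param quantile_fraction Candidate-set fraction per reference.
#' @param include_self Keep the reference's zero self-offset rows.
#' @return Tibble of class `er_offsets`: `reference`, `line_id`,
#'   `background`, `group`, `genomic_offset`, `phenotypic_offset`,
#'   `fitness_offset`, `n_candidates`.
#' @export
offset_table <- function(x, scan, assay_temp = 35, regime = "hot",
                         quantile_fraction = 0.001, include_self = FALSE) {
  inp <- offset_inputs(x, assay_temp)
  refs <- inp$fitness |>
    filter(.data$role == "evolved", .data$regime == !!regime)
  traits7 <- trait_names()

  out <- purrr::map_dfr(unique(refs$background), function(bg) {
    ref <- select_reference(filter(refs, .data$background == bg))
    rec <- scan$records |> filter(.data$line_id == ref$line_id)
    cand <- reference_candidate_set(select(rec, "locus", "pvalue", "s"),
                                    quantile_fraction)
    idx <- match(cand$locus, inp$freq$locus)
    ref_freq <- inp$freq[[ref$line_id]][idx]
    ref_traits <- unlist(inp$scaled[inp$scaled$line_id == ref$line_id,
                                    traits7])
    ref_fit <- inp$fitness$fitness[inp$fitness$line_id == ref$line_id]

    tests <- inp$scaled$line_id
    if (!include_self) tests <- setdiff(tests, ref$line_id)
    purrr::map_dfr(tests, function(tl) {
      meta <- inp$scaled[inp$scaled$line_id == tl, ]
      tibble(
        reference = ref$line_id,
        line_id = tl,
        background = meta$background,
        regime = meta$regime,
        role = meta$role,
        group = if_else(meta$background == bg, "within", "between"),
        genomic_offset = genomic_offset(ref_freq, inp$freq[[tl]][idx],
                                        cand$weight),
        phenotypic_offset = phenotypic_offset(ref_traits,
                                              unlist(meta[, traits7])),
        fitness_offset = fitness_offset(
          inp$fitness$fitness[inp$fitness$line_id == tl], ref_fit),
        n_candidates = nrow(cand)
      )
    })
  })
  attr(out, "assay_temp") <- assay_temp
  attr(out, "quantile_fraction") <- quantile_fraction
  class(out) <- c("er_offsets", class(out))
  out
}

#' Correlation of genomic offsets with phenotypic and fitness offsets
#'
#' Pearson correlations between the genomic offset and each of the
#' phenotypic and fitness offsets, computed separately for within- and
#' between-background comparisons — pooled across references and averaged
#' over per-reference correlations.  The within/between difference is tested
#' by analysis of covariance: a linear model of each response on
#' `genomic_offset * group`, reporting the interaction F and p.
#'
#' @param offsets An `er_offsets` table.
#' @return Object of class `er_offset_cor` with `by_group`, `by_reference`
#'   and `ancova` tibbles.
#' @export
offset_correlation <- function(offsets) {
  groups <- split(offsets, offsets$group)
  if (any(vapply(groups, nrow, 1L) < 3)) {
    abort("need >= 3 offset pairs per group")
  }
  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) {
      warn("degenerate variance: correlation undefined")
      return(NA_real_)
    }
    cor(x, y)
  }
  by_reference <- offsets |>
    group_by(.data$reference, .data$group) |>
    summarise(n = n(),
              r_pheno = safe_cor(.data$genomic_offset,
                                 .data$phenotypic_offset),
              r_fit = safe_cor(.data$genomic_offset, .data$fitness_offset),
              .groups = "drop")
  by_group <- offsets |>
    group_by(.data$group) |>
    summarise(n = n(),
              r_pheno = safe_cor(.data$genomic_offset,
                                 .data$phenotypic_offset),
              r_fit = safe_cor(.data$genomic_offset, .data$fitness_offset),
              .groups = "drop") |>
    left_join(
      by_reference |>
        group_by(.data$group) |>
        summarise(mean_r_pheno = mean(.data$r_pheno, na.rm = TRUE),
                  mean_r_fit = mean(.data$r_fit, na.rm = TRUE)),
      by = "group"
    )
  ancova <- purrr::map_dfr(
    c(phenotypic = "phenotypic_offset", fitness = "fitness_offset"),
    .id = "response",
    function(resp) {
      fit <- lm(offsets[[resp]] ~ offsets$genomic_offset * offsets$group)
      tab <- anova(fit)
      k <- grep(":", rownames(tab))
      tibble(F_interaction = tab$`F value`[k], df1 = tab$Df[k],
             df2 = tab$Df[nrow(tab)], p_value = tab$`Pr(>F)`[k])
    })
  structure(list(by_group = by_group, by_reference = by_reference,
                 ancova = ancova),
            class = "er_offset_cor")
}

#' @export
print.er_offset_cor <- function(x, ...) {
  cat("Offset correlations (genomic vs phenotypic / fitness)\n")
  print(x$by_group)
  invisible(x)
}

#' @rdname offset_correlation
#' @param x An `er_offset_cor`.
#' @param ... Unused.
#' @export
tidy.er_offset_cor <- function(x, ...) x$by_reference

#' @rdname offset_correlation
#' @export
glance.er_offset_cor <- function(x, ...) x$by_group

#' Random-SNP control offsets
#'
#' Repeatedly samples `n` loci uniformly without replacement, computes
#' unit-weight genomic offsets from the given reference to every other line,
#' and records their correlation with the fitness offsets within and
#' between backgrounds.  Random SNP sets carry no selection-coefficient
#' weights, so weights are 1 by construction.
#'
#' @param x An `er_experiment`.
#' @param reference Reference `line_id`.
#' @param n SNPs per control set (`<=` total loci).
#' @param iterations Number of control sets.
#' @param assay_temp Assay temperature for fitness offsets.
#' @param seed Optional integer seed.
#' @return Object of class `er_random_offsets`: `r` (tibble `iteration`,
#'   `group`, `r_fit`), `offsets` (iteration x line tibble).
#' @export
random_snp_offsets <- function(x, reference, n, iterations = 100,
                               assay_temp = 35, seed = NULL) {
  inp <- offset_inputs(x, assay_temp)
  n_loci <- nrow(inp$freq)
  if (n > n_loci) abort("`n` exceeds the number of SNPs")
  ref_bg <- inp$scaled$background[inp$scaled$line_id == reference]
  ref_fit <- inp$fitness$fitness[inp$fitness$line_id == reference]
  tests <- setdiff(inp$scaled$line_id, reference)
  meta <- inp$scaled[match(tests, inp$scaled$line_id), ]
  fit_off <- fitness_offset(
    inp$fitness$fitness[match(tests, inp$fitness$line_id)], ref_fit)
  group <- if_else(meta$background == ref_bg, "within", "between")

  res <- with_substream(seed, "random_offsets", {
    purrr::map_dfr(seq_len(iterations), function(it) {
      idx <- sample.int(n_loci, n)
      go <- vapply(tests, function(tl) {
        genomic_offset(inp$freq[[reference]][idx], inp$freq[[tl]][idx])
      }, numeric(1))
      tibble(iteration = it, line_id = tests, group = group,
             genomic_offset = go, fitness_offset = fit_off)
    })
  })
  r <- res |>
    group_by(.data$iteration, .data$group) |>
    summarise(r_fit = cor(.data$genomic_offset, .data$fitness_offset),
              .groups = "drop")
  structure(list(r = r, offsets = res, reference = reference, n = n),
            class = "er_random_offsets")
}

#' @export
print.er_random_offsets <- function(x, ...) {
  cat(sprintf("Random-SNP control offsets (reference %s, %d SNPs/set)\n",
              x$reference, x$n))
  print(x$r |> group_by(.data$group) |>
          summarise(mean_r_fit = mean(.data$r_fit)))
  invisible(x)
}
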