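#' Lay out an evolve-and-resequence sampling design
#'
#' Builds the sample sheet for a replicated thermal-selection experiment:
#' each genetic background contributes `replicates` lines per regime (cold,
#' hot), every line is pool-sequenced once at its sampling generation, and
#' the early generation of each hot line doubles as a sequenced proxy for
#' the (unsampled) ancestor of its background.  Generation defaults follow a
#' design in which cold lines are sampled at generation 57 and hot lines at
#' 67, with the ancestor proxy taken at generation 3, so that
#' ancestor-to-evolved divergence spans 60 (cold) and 64 (hot) generations
#' after the proxy adjustment (see [adjust_generations()]).
#'
#' @param backgrounds Character vector of genetic-background labels.
#' @param replicates Lines per background x regime cell.
#' @param generation_cold,generation_hot Sampling generation of evolved
#'   lines, per regime.
#' @param proxy_generation Generation at which the ancestor-proxy pool is
#'   taken from each hot line.
#' @param pool_size Diploid individuals per sequencing pool.
#' @param mean_depth Expected read depth per SNP.
#' @param ne_cold,ne_hot True effective population sizes used when
#'   simulating lines of each regime.
#'
#' @return A tibble of samples (class `er_design`) with one row per
#'   sequenced pool: `sample_id`, `line_id`, `background`, `regime`,
#'   `replicate`, `role` (`"ancestor"` or `"evolved"`), `generation`
#'   (of sampling), `ne`, `pool_size`, `mean_depth` and, for evolved rows,
#'   `anc_sample_id` linking each line to its ancestor-proxy pool.
#' @export
experiment_design <- function(backgrounds = c("California", "Brazil", "Yemen"),
                              replicates = 2,
                              generation_cold = 57,
                              generation_hot = 67,
                              proxy_generation = 3,
                              pool_size = 60,
                              mean_depth = 50,
                              ne_cold = 240,
                              ne_hot = 190) {
  assert_scalar_count(replicates)
  assert_scalar_count(generation_cold)
  assert_scalar_count(generation_hot)
  assert_scalar_count(proxy_generation, min = 0)
  assert_scalar_count(pool_size)
  if (mean_depth < 1) abort("`mean_depth` must be >= 1")
  if (generation_hot < proxy_generation) {
    abort("hot lines must be sampled at or after the ancestor-proxy generation")
  }

  cells <- tidyr::expand_grid(
    background = backgrounds,
    regime = c("cold", "hot"),
    replicate = seq_len(replicates)
  )
  evolved <- cells |>
    mutate(
      line_id = paste(.data$background, .data$regime, .data$replicate, sep = "_"),
      sample_id = .data$line_id,
      role = "evolved",
      generation = if_else(.data$regime == "cold", generation_cold, generation_hot),
      ne = if_else(.data$regime == "cold", ne_cold, ne_hot),
      anc_sample_id = paste(.data$background, "anc", .data$replicate, sep = "_")
    )
  ancestors <- tidyr::expand_grid(
    background = backgrounds,
    replicate = seq_len(replicates)
  ) |>
    mutate(
      regime = "hot",           # proxies are early samples of the hot lines
      line_id = paste(.data$background, "anc", .data$replicate, sep = "_"),
      sample_id = .data$line_id,
      role = "ancestor",
      generation = proxy_generation,
      ne = ne_hot,
      anc_sample_id = NA_character_
    )
  out <- bind_rows(evolved, ancestors) |>
    mutate(pool_size = pool_size, mean_depth = mean_depth) |>
    select("sample_id", "line_id", "background", "regime", "replicate",
           "role", "generation", "ne", "pool_size", "mean_depth",
           "anc_sample_id")
  attr(out, "proxy_generation") <- proxy_generation
  class(out) <- c("er_design", class(out))
  out
}

#' Draw differentiated ancestral allele frequencies
#'
#' Simulates standing variation in several geographic backgrounds that
#' descend from a common ancestral population.  A common frequency is drawn
#' per locus, each background's frequency is drawn around it from a
#' Balding-Nichols beta kernel whose spread is controlled by
#' `differentiation` (an F_ST-like parameter), and a finite founder pool is
#' then sampled so that strongly diverged loci can fix for alternative
#' alleles in different backgrounds.  With `differentiation = 0` all
#' backgrounds carry the common frequency exactly.
#'
#' @param n_snps Number of loci.
#' @param backgrounds Character vector of background labels (or a count).
#' @param differentiation F_ST-like divergence parameter, `>= 0` and `< 1`.
#' @param founders Diploid founders per background; fixation can only arise
#'   through this finite-sampling step.
#' @param common_range Range of the uniform distribution of the common
#'   ancestral frequency.
#' @param seed Optional integer seed (deterministic output for equal seeds).
#'
#' @return Tibble with columns `locus`, `background`, `p0` and `shared`
#'   (`TRUE` where the locus is polymorphic in every background), plus a
#'   `differentiation` attribute.
#' @export
draw_ancestral_frequencies <- function(n_snps,
                                       backgrounds = c("California", "Brazil", "Yemen"),
                                       differentiation = 0.15,
                                       founders = 350,
                                       common_range = c(0.05, 0.95),
                                       seed = NULL) {
  assert_scalar_count(n_snps)
  if (is.numeric(backgrounds)) backgrounds <- paste0("B", seq_len(backgrounds))
  if (!is.finite(differentiation) || differentiation < 0 || differentiation >= 1) {
    abort("`differentiation` must be in [0, 1)")
  }
  assert_scalar_count(founders)

  with_substream(seed, "ancestral", {
    common <- runif(n_snps, common_range[1], common_range[2])
    per_bg <- lapply(backgrounds, function(b) {
      if (differentiation == 0) {
        p <- common
      } else {
        cc <- (1 - differentiation) / differentiation
        p <- stats::rbeta(n_snps, common * cc, (1 - common) * cc)
        p <- rbinom(n_snps, 2 * founders, p) / (2 * founders)
      }
      tibble(locus = seq_len(n_snps), background = b, p0 = p)
    })
    out <- bind_rows(per_bg) |>
      group_by(.data$locus) |>
      mutate(shared = all(.data$p0 > 0 & .data$p0 < 1)) |>
      ungroup()
    attr(out, "differentiation") <- differentiation
    out
  })
}

snp_classes <- function() c("SP", "AP", "private_cold", "private_hot")

#' Default trait loadings of selected alleles
#'
#' Relative per-trait loadings of the additive trait effects carried by
#' selected SNPs.  Signs encode the direction that improves laboratory
#' fitness in the regime where the allele is favoured: offspring production
#' and early fecundity rise, development time falls.
#'
#' @return Named numeric vector over [trait_names()].
#' @export
default_trait_loadings <- function() {
  c(lrs = 1, adult_weight = 0.4, dev_time = -0.6, weight_loss = 0.4,
    water_loss = 0.3, early_fecundity = 0.8, metabolic_rate = -0.3)
}

## Shared constructor: per-locus class labels -> architecture tibble.
architecture_from_classes <- function(class, s_magnitude, trait_loadings,
                                      effect_size, seed = NULL) {
  n <- length(class)
  stopifnot(all(class %in% c(snp_classes(), "neutral")))
  with_substream(seed, "architecture", {
    sign <- ifelse(class == "neutral", 0,
                   sample(c(-1, 1), n, replace = TRUE))
    s_cold <- s_magnitude * sign *
      (class %in% c("SP", "private_cold") | class == "AP")
    s_hot <- s_magnitude * sign *
      ((class %in% c("SP", "private_hot")) - (class == "AP"))
    tau <- trait_loadings[trait_names()]
    eff <- outer(as.numeric(class != "neutral") * effect_size, tau)
    colnames(eff) <- paste0("eff_", trait_names())
    out <- tibble(locus = seq_len(n), class = class,
                  s_cold = s_cold, s_hot = s_hot)
    bind_cols_quiet(out, as_tibble(eff))
  })
}

bind_cols_quiet <- function(x, y) dplyr::bind_cols(x, y, .name_repair = "minimal")

#' Assign a selection architecture over loci
#'
#' Labels loci as synergistically pleiotropic (`SP`: selected in the same
#' direction in both thermal regimes), antagonistically pleiotropic (`AP`:
#' opposite directions), private to one regime (`private_cold`,
#' `private_hot`), or `neutral`, and assigns per-regime selection
#' coefficients and additive trait effects accordingly.
#'
#' @param n_snps Number of loci.
#' @param class_fractions Named numeric vector over a subset of
#'   `c("SP", "AP", "private_cold", "private_hot")`; fractions must be
#'   non-negative and sum to at most 1 (the remainder is neutral).
#' @param s_magnitude Absolute per-generation selection coefficient given to
#'   every non-neutral locus.
#' @param eligible Optional integer or logical index of loci allowed to be
#'   non-neutral (e.g. loci polymorphic in all backgrounds).
#' @param trait_loadings Named per-trait loadings, see
#'   [default_trait_loadings()].
#' @param effect_size Proportional trait change per unit allele-frequency
#'   change per selected locus (scales `trait_loadings`).
#' @param seed Optional integer seed.
#'
#' @return Tibble with `locus`, `class`, `s_cold`, `s_hot` and seven
#'   `eff_<trait>` columns (zero for neutral loci).
#' @export
assign_architecture <- function(n_snps,
                                class_fractions = NULL,
                                s_magnitude = 0.1,
                                eligible = NULL,
                                trait_loadings = default_trait_loadings(),
                                effect_size = 0.004,
                                seed = NULL) {
  assert_scalar_count(n_snps)
  class_fractions <- class_fractions %||% numeric(0)
  if (length(class_fractions)) {
    bad <- setdiff(names(class_fractions), snp_classes())
    if (length(bad)) abort(paste("unknown SNP classes:", toString(bad)))
    if (any(class_fractions < 0)) abort("class fractions must be >= 0")
    if (sum(class_fractions) > 1) abort("class fractions must sum to <= 1")
    if (sum(class_fractions) > 0 && s_magnitude <= 0) {
      abort("`s_magnitude` must be > 0 when non-neutral classes are requested")
    }
  }
  counts <- floor(class_fractions * n_snps)
  if (is.logical(eligible)) eligible <- which(eligible)
  eligible <- eligible %||% seq_len(n_snps)
  if (sum(counts) > length(eligible)) {
    abort("not enough eligible loci for the requested class fractions")
  }
  class <- rep("neutral", n_snps)
  with_substream(seed, "classes", {
    chosen <- sample(eligible, sum(counts))
    class[chosen] <- rep(names(counts), counts)
    architecture_from_classes(class, s_magnitude, trait_loadings, effect_size,
                              seed = if (is.null(seed)) NULL else seed + 1L)
  })
}

#' Simulate a Wright-Fisher allele-frequency trajectory
#'
#' Iterates `t` generations of deterministic selection
#' `p' = p(1+s) / (1+ps)` followed by binomial genetic drift with `2*ne`
#' chromosomes.  Frequencies 0 and 1 are absorbing.  Vectorised over loci
#' (`p0` and `s` are recycled against each other).
#'
#' @param p0 Starting allele frequency (vector).
#' @param ne Effective population size (diploid individuals, `>= 1`).
#' @param s Per-generation selection coefficient (vector).
#' @param t Number of generations (`>= 0`).
#' @param seed Optional integer seed.
#' @return Vector of frequencies at generation `t`.
#' @export
simulate_wf_trajectory <- function(p0, ne, s = 0, t, seed = NULL) {
  assert_prob(p0)
  if (!is.finite(ne) || ne < 1) abort("`ne` must be finite and >= 1")
  assert_scalar_count(t, min = 0)
  n2 <- round(2 * ne)
  p <- rep_len(p0, max(length(p0), length(s)))
  s <- rep_len(s, length(p))
  with_substream(seed, "wf", {
    for (g in seq_len(t)) {
      p <- p * (1 + s) / (1 + p * s)
      p <- rbinom(length(p), n2, p) / n2
    }
    p
  })
}

#' Two-stage pool-seq sampling of an allele frequency
#'
#' Emulates pooled sequencing: `k ~ Binom(2 * pool_size, p_true)`
#' chromosomes enter the pool, then `reads ~ Binom(depth, k / (2 pool_size))`
#' reads carry the tracked allele.
#'
#' @param p_true True allele frequency (vector).
#' @param pool_size Diploid individuals in the pool.
#' @param depth Read depth (scalar or per-locus vector).
#' @param seed Optional integer seed.
#' @return Tibble with `freq` (`reads/depth`), `reads` and `depth`.
#' @export
sample_poolseq <- function(p_true, pool_size, depth, seed = NULL) {
  assert_prob(p_true)
  assert_scalar_count(pool_size)
  if (any(depth < 1)) abort("`depth` must be >= 1")
  depth <- rep_len(depth, length(p_true))
  with_substream(seed, "poolseq", {
    k <- rbinom(length(p_true), 2 * pool_size, p_true)
    r <- rbinom(length(p_true), depth, k / (2 * pool_size))
    tibble(freq = r / depth, reads = r, depth = depth)
  })
}

#' Baseline trait means of the ancestral populations
#'
#' Illustrative ancestral means for the seven traits at the two assay
#' temperatures, on raw measurement scales (offspring counts, mg, days,
#' eggs, ml CO2 min^-1 mg^-1).
#'
#' @return Tibble with `trait`, `assay_temp`, `mean`.
#' @export
ancestral_trait_means <- function() {
  tibble(
    trait = rep(trait_names(), each = 2),
    assay_temp = rep(c(23, 35), times = 7),
    mean = c(
      60, 75,      # lrs
      5.5, 5.0,    # adult_weight (mg)
      35, 21,      # dev_time (days)
      0.6, 0.9,    # weight_loss
      0.4, 0.6,    # water_loss
      25, 40,      # early_fecundity
      0.8, 1.3     # metabolic_rate
    )
  )
}

#' Generate a complete synthetic evolve-and-resequence experiment
#'
#' Evolves every line of `design` forward from its background's ancestral
#' frequencies under the regime-appropriate selection coefficients of
#' `arch`, takes the ancestor-proxy samples from the hot lines at the proxy
#' generation, applies two-stage pool-seq sampling (Poisson read depth
#' around `mean_depth`) to every sequenced pool, and builds a seven-trait
#' panel at both assay temperatures.  Trait means follow a linear-additive
#' map: the proportional change of trait j at assay temperature T is the sum
#' over loci of `eff_j * sign(s_T) * dp`, where `dp` is the line's true
#' allele-frequency change, so alleles favoured in a regime improve
#' regime-appropriate trait values.  Reported standard errors equal
#' `trait_noise * |ancestral mean|` and the realised means include Gaussian
#' error of that magnitude.
#'
#' @param design An [experiment_design()] sheet.
#' @param pool Ancestral frequencies from [draw_ancestral_frequencies()].
#' @param arch Architecture from [assign_architecture()].
#' @param trait_noise Relative measurement error of trait means (0 disables
#'   noise and reports zero standard errors).
#' @param n_assay Individuals behind each trait mean.
#' @param seed Master seed; per-line and per-stage substreams are derived
#'   deterministically from it, so equal seeds give bit-identical output.
#'
#' @return List of class `er_experiment` with elements `snp` (locus x sample
#'   observed frequencies, reads, depth), `traits` (long trait panel
#'   including ancestor lines), `design`, `arch`, `pool`, and `truth`
#'   (per-line true final frequencies).
#' @export
generate_experiment <- function(design, pool, arch,
                                trait_noise = 0.02,
                                n_assay = 30,
                                seed = 1) {
  backgrounds <- unique(design$background)
  n_snps <- max(pool$locus)
  if (nrow(arch) != n_snps) {
    abort("`pool` and `arch` describe different numbers of loci")
  }
  if (!all(backgrounds %in% unique(pool$background))) {
    abort("`pool` lacks ancestral frequencies for some design backgrounds")
  }
  proxy_gen <- attr(design, "proxy_generation") %||% 3

  p0_by_bg <- lapply(setNames(backgrounds, backgrounds), function(b) {
    pool$p0[pool$background == b][order(pool$locus[pool$background == b])]
  })

  evolved <- design[design$role == "evolved", ]
  truth <- list()      # per sample_id: true frequency at sampling
  for (i in seq_len(nrow(evolved))) {
    row <- evolved[i, ]
    s <- if (row$regime == "cold") arch$s_cold else arch$s_hot
    p <- p0_by_bg[[row$background]]
    with_substream(seed, paste0("wf_", row$line_id), {
      n2 <- round(2 * row$ne)
      for (g in seq_len(row$generation)) {
        p <- p * (1 + s) / (1 + p * s)
        p <- rbinom(length(p), n2, p) / n2
        if (row$regime == "hot" && g == proxy_gen && !is.na(row$anc_sample_id)) {
          truth[[row$anc_sample_id]] <- p
        }
      }
      truth[[row$sample_id]] <- p
    })
  }

  snp <- purrr::map_dfr(design$sample_id, function(sid) {
    drow <- design[design$sample_id == sid, ]
    p <- truth[[sid]]
    obs <- with_substream(seed, paste0("pool_", sid), {
      depth <- pmax(1L, stats::rpois(length(p), drow$mean_depth))
      sample_poolseq(p, drow$pool_size, depth)
    })
    tibble(locus = seq_along(p), sample_id = sid,
           freq = obs$freq, reads = obs$reads, depth = obs$depth)
  })

  ## trait panel ------------------------------------------------------------
  anc_means <- ancestral_trait_means()
  eff <- as.matrix(arch[, paste0("eff_", trait_names())])
  sgn <- list(`23` = sign(arch$s_cold), `35` = sign(arch$s_hot))

  trait_rows <- purrr::map_dfr(design$sample_id, function(sid) {
    drow <- design[design$sample_id == sid, ]
    dp <- truth[[sid]] - p0_by_bg[[drow$background]]
    purrr::map_dfr(c(23, 35), function(temp) {
      prop <- unname(colSums(eff * (sgn[[as.character(temp)]] * dp)))
      base <- anc_means$mean[anc_means$assay_temp == temp][
        match(trait_names(), anc_means$trait[anc_means$assay_temp == temp])]
      se <- trait_noise * abs(base)
      err <- with_substream(seed, paste0("trait_", sid, "_", temp),
                            rnorm(length(base), 0, se))
      tibble(line_id = drow$line_id, background = drow$background,
             regime = drow$regime, replicate = drow$replicate,
             role = drow$role, assay_temp = temp, trait = trait_names(),
             mean = base * (1 + prop) + err, se = se, n = n_assay)
    })
  })

  structure(
    list(snp = snp, traits = trait_rows, design = design, arch = arch,
         pool = pool, truth = truth, seed = seed),
    class = "er_experiment"
  )
}

#' @export
print.er_experiment <- function(x, ...) {
  cat("Synthetic evolve-and-resequence experiment\n")
  cat("  backgrounds:", toString(unique(x$design$background)), "\n")
  cat("  samples:", nrow(x$design), " loci:", max(x$snp$locus), "\n")
  cat("  non-neutral loci:", sum(x$arch$class != "neutral"), "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Canned scenarios used by tests and the worked examples.

#' Neutral scenario: drift and sampling noise only
#'
#' @param n_snps Number of loci.
#' @param seed Master seed.
#' @param ne Effective size of every line.
#' @param differentiation Ancestral F_ST-like divergence between
#'   backgrounds.
#' @param trait_noise Relative trait measurement error (see
#'   [generate_experiment()]).
#' @param common_range Range of the common ancestral frequency.
#' @param ... Passed to [experiment_design()].
#' @return An `er_experiment`.
#' @export
scenario_neutral <- function(n_snps = 10000, seed = 1, ne = 200,
                             differentiation = 0.15, trait_noise = 0.02,
                             common_range = c(0.05, 0.95), ...) {
  design <- experiment_design(ne_cold = ne, ne_hot = ne, ...)
  pool <- draw_ancestral_frequencies(n_snps, unique(design$background),
                                     differentiation = differentiation,
                                     common_range = common_range,
                                     seed = seed)
  arch <- assign_architecture(n_snps, seed = seed)
  generate_experiment(design, pool, arch, trait_noise = trait_noise,
                      seed = seed)
}

#' Planted-classes scenario for classification recovery
#'
#' Plants equal fractions of SP, AP, private-cold and private-hot loci
#' (default 5% each, `s = 0.1`, Ne = 200) among loci polymorphic in all
#' backgrounds, leaving the rest neutral.
#'
#' @param n_snps Number of loci.
#' @param fraction Fraction of loci per non-neutral class.
#' @param s_magnitude Selection coefficient of planted loci.
#' @param ne Effective size of every line.
#' @param seed Master seed.
#' @param ... Passed to [experiment_design()].
#' @return An `er_experiment`.
#' @export
scenario_planted_classes <- function(n_snps = 10000, fraction = 0.05,
                                     s_magnitude = 0.1, ne = 200,
                                     seed = 1, ...) {
  design <- experiment_design(ne_cold = ne, ne_hot = ne, ...)
  pool <- draw_ancestral_frequencies(n_snps, unique(design$background),
                                     seed = seed)
  interior <- pool |>
    group_by(.data$locus) |>
    summarise(ok = all(.data$p0 >= 0.05 & .data$p0 <= 0.95)) |>
    filter(.data$ok) |>
    pull("locus")
  arch <- assign_architecture(
    n_snps,
    class_fractions = setNames(rep(fraction, 4), snp_classes()),
    s_magnitude = s_magnitude, eligible = interior, seed = seed
  )
  generate_experiment(design, pool, arch, seed = seed)
}

#' Background-private scenario for offset prediction
#'
#' Draws strongly differentiated ancestral backgrounds (few founders, high
#' F_ST) and plants selected loci only where a locus is polymorphic in
#' exactly one background and fixed in the others, so each background adapts
#' through its own private loci.  Half of each background's planted loci are
#' private-hot, half private-cold.
#'
#' @param n_snps Number of loci.
#' @param n_private Planted loci per background (capped by availability).
#' @param s_magnitude Selection coefficient of planted loci.
#' @param differentiation,founders Passed to
#'   [draw_ancestral_frequencies()]; defaults give substantial differential
#'   fixation.
#' @param seed Master seed.
#' @param ... Passed to [experiment_design()].
#' @return An `er_experiment`.
#' @export
scenario_background_private <- function(n_snps = 20000, n_private = 250,
                                        s_magnitude = 0.1,
                                        differentiation = 0.5, founders = 100,
                                        seed = 1, ...) {
  design <- experiment_design(...)
  backgrounds <- unique(design$background)
  pool <- draw_ancestral_frequencies(n_snps, backgrounds,
                                     differentiation = differentiation,
                                     founders = founders, seed = seed)
  wide <- tidyr::pivot_wider(pool, id_cols = "locus",
                             names_from = "background", values_from = "p0")
  pm <- as.matrix(wide[, backgrounds])
  interior <- pm >= 0.05 & pm <= 0.95
  fixed <- pm == 0 | pm == 1
  class <- rep("neutral", n_snps)
  withr::with_seed(substream_seed(seed, "private_pick"), {
    for (b in seq_along(backgrounds)) {
      private <- which(interior[, b] & rowSums(fixed[, -b, drop = FALSE]) ==
                         length(backgrounds) - 1 & class == "neutral")
      take <- sample(private, min(n_private, length(private)))
      class[take] <- rep_len(c("private_hot", "private_cold"), length(take))
    }
  })
  arch <- architecture_from_classes(class, s_magnitude,
                                    default_trait_loadings(),
                                    effect_size = 0.004,
                                    seed = substream_seed(seed, "arch"))
  generate_experiment(design, pool, arch, seed = seed)
}
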