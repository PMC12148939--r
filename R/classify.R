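#' Classify candidate SNPs by pleiotropy across thermal regimes
#'
#' For each locus and genetic background, a regime scores a "hit" when both
#' of its replicate lines change beyond the per-tail threshold `q` *in the
#' same direction*.  Loci are then classified: `SP` (synergistic pleiotropy)
#' when both regimes hit in the same direction, `AP` (antagonistic) when
#' both hit in opposite directions, `private_cold`/`private_hot` when
#' exactly one regime hits, `none` otherwise.  Classes are mutually
#' exclusive per locus x background.
#'
#' @param records Scan records (`er_scan` or its `records` tibble) with
#'   exactly two replicates per regime per background.
#' @param per_tail_probability Relaxed classification threshold `q`
#'   (default `1e-2`).
#' @return Tibble with `locus`, `background`, `class`, and the concordant
#'   regime directions `dir_cold`, `dir_hot` (0 when the regime did not
#'   hit).
#' @export
classify_snps <- function(records, per_tail_probability = 1e-2) {
  if (inherits(records, "er_scan")) records <- records$records
  q <- per_tail_probability
  if (q <= 0 || q >= 0.5) abort("`per_tail_probability` must be in (0, 0.5)")
  reps <- records |>
    distinct(.data$background, .data$regime, .data$line_id) |>
    dplyr::count(.data$background, .data$regime)
  if (any(reps$n != 2)) {
    abort("classification requires exactly 2 replicate lines per regime per background")
  }
  regime_hits <- records |>
    mutate(hit = .data$p_tail < q & .data$direction != 0) |>
    group_by(.data$locus, .data$background, .data$regime) |>
    summarise(
      concordant = all(.data$hit) && dplyr::n_distinct(.data$direction) == 1,
      dir = if_else(concordant, .data$direction[1], 0),
      .groups = "drop"
    ) |>
    rename(hit = "concordant")
  wide <- tidyr::pivot_wider(regime_hits, id_cols = c("locus", "background"),
                             names_from = "regime",
                             values_from = c("hit", "dir"))
  wide |>
    mutate(class = dplyr::case_when(
      .data$hit_cold & .data$hit_hot &
        .data$dir_cold == .data$dir_hot ~ "SP",
      .data$hit_cold & .data$hit_hot ~ "AP",
      .data$hit_cold ~ "private_cold",
      .data$hit_hot ~ "private_hot",
      .default = "none"
    )) |>
    select("locus", "background", "class",
           dir_cold = "dir_cold", dir_hot = "dir_hot")
}

#' Map classified SNPs to protein-coding genes
#'
#' A SNP is assigned to every gene whose protein-coding span contains its
#' position (1-based inclusive bounds at both ends); genes inherit the SNP's
#' class per background.  A SNP between genes maps nowhere; overlapping
#' genes both receive it.
#'
#' @param calls Classification calls from [classify_snps()], joined with
#'   locus coordinates (columns `scaffold`, `pos`); calls with
#'   `class == "none"` are dropped.
#' @param genes Gene annotation tibble from [read_gene_annotation()] (or any
#'   tibble with `gene_id`, `scaffold`, `start`, `end`).
#' @return Tibble of gene sets: `background`, `class`, `gene_id`, `n_snps`.
#' @export
map_snps_to_genes <- function(calls, genes) {
  need <- c("gene_id", "scaffold", "start", "end")
  if (!all(need %in% names(genes))) {
    abort(paste("`genes` must have columns:", toString(need)))
  }
  if (any(genes$end < genes$start)) abort("malformed gene interval: end < start")
  if (!all(c("scaffold", "pos") %in% names(calls))) {
    abort("`calls` must carry `scaffold` and `pos` coordinates")
  }
  calls |>
    filter(.data$class != "none") |>
    inner_join(genes,
               by = join_by("scaffold",
                            between(x$pos, y$start, y$end))) |>
    group_by(.data$background, .data$class, .data$gene_id) |>
    summarise(n_snps = n(), .groups = "drop")
}

#' Jaccard index of two sets
#'
#' `|A intersect B| / |A union B|`; defined as 0 when both sets are empty
#' (flagged via the `"both_empty"` attribute).
#'
#' @param a,b Vectors interpreted as sets.
#' @return Scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(structure(0, both_empty = TRUE))
  length(intersect(a, b)) / u
}

#' Cross-background overlap counts of gene (or SNP) sets
#'
#' Counts, for one class at a time, how many set members fall in each
#' exclusive combination of backgrounds (upset-style), together with the
#' all-background intersection and pairwise Jaccard indices.
#'
#' @param gene_sets Tibble with columns `background`, `class` and a member
#'   column (default `gene_id`).
#' @param class Class to compare (default: each class separately, stacked).
#' @param member Name of the member column.
#' @return List of class `er_overlap` with `combinations` (tibble: `class`,
#'   `combo`, `degree`, `n`), `shared` (all-background intersection size per
#'   class) and `jaccard` (pairwise tibble).
#' @export
overlap_counts <- function(gene_sets, class = NULL, member = "gene_id") {
  if (!is.null(class)) gene_sets <- gene_sets[gene_sets$class %in% class, ]
  backgrounds <- sort(unique(gene_sets$background))
  per_class <- split(gene_sets, gene_sets$class)
  combos <- purrr::map_dfr(per_class, function(gs) {
    membership <- gs |>
      distinct(.data$background, member = .data[[member]]) |>
      group_by(.data$member) |>
      summarise(combo = paste(sort(unique(.data$background)), collapse = "&"),
                degree = dplyr::n_distinct(.data$background),
                .groups = "drop")
    membership |>
      dplyr::count(.data$combo, .data$degree, name = "n") |>
      mutate(class = gs$class[1], .before = 1)
  })
  shared <- purrr::map_dfr(per_class, function(gs) {
    sets <- lapply(backgrounds, function(b) unique(gs[[member]][gs$background == b]))
    tibble(class = gs$class[1],
           shared_all = length(Reduce(intersect, sets)))
  })
  jac <- purrr::map_dfr(per_class, function(gs) {
    prs <- utils::combn(backgrounds, 2)
    purrr::map_dfr(seq_len(ncol(prs)), function(k) {
      a <- unique(gs[[member]][gs$background == prs[1, k]])
      b <- unique(gs[[member]][gs$background == prs[2, k]])
      tibble(class = gs$class[1], background_a = prs[1, k],
             background_b = prs[2, k], jaccard = as.numeric(jaccard(a, b)))
    })
  })
  structure(list(combinations = combos, shared = shared, jaccard = jac,
                 backgrounds = backgrounds),
            class = "er_overlap")
}

#' @export
print.er_overlap <- function(x, ...) {
  cat("Cross-background overlap across", length(x$backgrounds),
      "backgrounds\n")
  print(x$shared)
  invisible(x)
}

#' Expected cross-background overlap under pure drift
#'
#' Forward drift simulations of the classification pipeline: each iteration
#' samples loci from the ancestral frequencies, evolves every line neutrally
#' under its own Ne and divergence time, re-applies pool-seq sampling and
#' the sampling-aware null, classifies SNPs, and records how many loci of
#' the focal class are shared by all backgrounds.  The expectation is the
#' mean over iterations; `p = (k + 1) / (n + 1)` where `k` counts iterations
#' with shared count `>=` the observed one.
#'
#' @param pool Ancestral frequencies ([draw_ancestral_frequencies()]).
#' @param design Design sheet giving per-line `ne`, generations and pool
#'   size (the same conditions as the observed data).
#' @param class Focal class (default `"private_hot"`).
#' @param per_tail_probability Classification threshold `q`.
#' @param iterations,snps_per_iteration Simulation size (defaults 1000 x
#'   10000).
#' @param observed Observed shared count to be tested (optional).
#' @param seed Optional integer seed.
#' @return Object of class `er_overlap_null` with `expected`, `p_value`,
#'   `draws`.
#' @export
expected_overlap_by_drift <- function(pool, design, class = "private_hot",
                                      per_tail_probability = 1e-2,
                                      iterations = 1000,
                                      snps_per_iteration = 10000,
                                      observed = NULL, seed = NULL) {
  if (iterations < 1) abort("`iterations` must be >= 1")
  backgrounds <- unique(design$background)
  wide <- tidyr::pivot_wider(pool, id_cols = "locus",
                             names_from = "background", values_from = "p0")
  evolved <- design[design$role == "evolved", ]
  proxy_gen <- attr(design, "proxy_generation") %||% 3

  draws <- with_substream(seed, "overlap_null", {
    n_tot <- iterations * snps_per_iteration
    pick <- sample.int(nrow(wide), n_tot, replace = TRUE)
    iter_id <- rep(seq_len(iterations), each = snps_per_iteration)

    evolve <- function(p, ne, t) {
      n2 <- round(2 * ne)
      for (g in seq_len(t)) p <- rbinom(n_tot, n2, p) / n2
      p
    }
    ## ancestor proxies: early samples of the hot lines, mirroring the design
    per_line <- purrr::map_dfr(seq_len(nrow(evolved)), function(i) {
      row <- evolved[i, ]
      p0 <- wide[[row$background]][pick]
      hot_ne <- evolved$ne[evolved$background == row$background &
                             evolved$regime == "hot" &
                             evolved$replicate == row$replicate][1]
      anc <- evolve(p0, hot_ne, proxy_gen)
      if (row$regime == "hot") {
        p <- evolve(anc, row$ne, row$generation - proxy_gen)
        t_evo <- row$generation - proxy_gen
        t_anc <- 0
      } else {
        p <- evolve(p0, row$ne, row$generation)
        t_evo <- row$generation
        t_anc <- proxy_gen
      }
      d0 <- pmax(1L, stats::rpois(n_tot, row$mean_depth))
      dt <- pmax(1L, stats::rpois(n_tot, row$mean_depth))
      o0 <- sample_poolseq(anc, row$pool_size, d0)
      ot <- sample_poolseq(p, row$pool_size, dt)
      pv <- wf_exact_null(o0$reads, o0$depth, ot$reads, ot$depth,
                          row$pool_size, row$ne, t = t_evo, t_anc = t_anc)
      tibble(locus = seq_len(n_tot), line_id = row$line_id,
             background = row$background, regime = row$regime,
             replicate = row$replicate,
             p_tail = pv$p_tail, direction = pv$direction)
    })

    calls <- classify_snps(per_line, per_tail_probability)
    hits <- calls |>
      filter(.data$class == !!class) |>
      group_by(.data$locus) |>
      summarise(n_bg = dplyr::n_distinct(.data$background))
    shared_loci <- hits$locus[hits$n_bg == length(backgrounds)]
    tabulate(iter_id[shared_loci], nbins = iterations)
  })

  p <- if (is.null(observed)) NA_real_ else {
    (sum(draws >= observed) + 1) / (iterations + 1)
  }
  structure(list(expected = mean(draws), draws = draws, p_value = p,
                 observed = observed, class = class,
                 iterations = iterations,
                 snps_per_iteration = snps_per_iteration),
            class = "er_overlap_null")
}

#' @export
print.er_overlap_null <- function(x, ...) {
  cat(sprintf("Drift-expected shared %s count: %.3g (%d iterations x %d SNPs)\n",
              x$class, x$expected, x$iterations, x$snps_per_iteration))
  if (!is.null(x$observed)) {
    cat(sprintf("  observed %d, p = %.4g\n", x$observed, x$p_value))
  }
  invisible(x)
}

#' @rdname expected_overlap_by_drift
#' @param x An `er_overlap_null`.
#' @param ... Unused.
#' @export
glance.er_overlap_null <- function(x, ...) {
  tibble(class = x$class, expected = x$expected,
         observed = x$observed %||% NA_integer_, p_value = x$p_value,
         iterations = x$iterations)
}

#' Recovery of a planted selection architecture
#'
#' Compares classification calls with the generator's ground truth,
#' restricted to planted loci whose true allele-frequency responses are
#' detectable in principle: every replicate line of the class-relevant
#' regime(s) must show a true `|dp|` exceeding `sd_mult` standard deviations
#' of the drift-plus-sampling null at that locus (antagonistic responses at
#' intermediate frequencies rarely clear this bar at moderate Ne over ~60
#' generations; see the methods vignette).  Also reports the SP/AP
#' confusion rate among *all* planted loci.
#'
#' @param x The `er_experiment` carrying the ground truth.
#' @param calls Classification calls from [classify_snps()].
#' @param sd_mult Detectability multiple (default 3).
#' @return List with `by_class` (per background x class recovery among
#'   eligible loci), `overall` (pooled recovery), `confusion_sp_ap`
#'   (fraction of all planted SP/AP loci called as the other), and `table`.
#' @export
classification_recovery <- function(x, calls, sd_mult = 3) {
  design <- x$design
  ev <- design[design$role == "evolved", ]
  p0w <- tidyr::pivot_wider(x$pool, id_cols = "locus",
                            names_from = "background", values_from = "p0")
  n_eff <- poolseq_n_eff(ev$pool_size[1], ev$mean_depth[1])
  truth <- x$arch[, c("locus", "class")]

  rows <- purrr::map_dfr(unique(ev$background), function(bg) {
    cl <- calls[calls$background == bg, ]
    m <- inner_join(rename(truth, true = "class"), cl, by = "locus")
    p0 <- p0w[[bg]]
    detectable <- function(lines) {
      ok <- rep(TRUE, nrow(p0w))
      for (i in which(ev$background == bg & ev$line_id %in% lines)) {
        t_adj <- adjust_generations(ev$generation[i], ev$regime[i], 3)
        f <- inbreeding_coefficient(ev$ne[i], t_adj)
        sd_i <- sqrt(pmax(p0 * (1 - p0), 1e-12) * (f + 2 / n_eff))
        dp <- abs(x$truth[[ev$sample_id[i]]] - p0)
        ok <- ok & dp > sd_mult * sd_i
      }
      ok
    }
    rc <- detectable(ev$line_id[ev$background == bg & ev$regime == "cold"])
    rh <- detectable(ev$line_id[ev$background == bg & ev$regime == "hot"])
    eligible <- dplyr::case_when(
      m$true %in% c("SP", "AP") ~ rc[m$locus] & rh[m$locus],
      m$true == "private_cold" ~ rc[m$locus],
      m$true == "private_hot" ~ rh[m$locus],
      .default = FALSE
    )
    tibble(background = bg, locus = m$locus, true = m$true, call = m$class,
           eligible = eligible)
  })

  planted <- filter(rows, .data$true != "neutral")
  elig <- filter(planted, .data$eligible)
  by_class <- elig |>
    group_by(.data$background, .data$true) |>
    summarise(n_eligible = n(),
              n_correct = sum(.data$true == .data$call),
              recovery = mean(.data$true == .data$call),
              .groups = "drop")
  sp_ap <- filter(planted, .data$true %in% c("SP", "AP"))
  confusion <- if (nrow(sp_ap)) {
    mean((sp_ap$true == "SP" & sp_ap$call == "AP") |
           (sp_ap$true == "AP" & sp_ap$call == "SP"))
  } else NA_real_
  list(by_class = by_class,
       overall = mean(elig$true == elig$call),
       confusion_sp_ap = confusion,
       table = table(truth = planted$true, call = planted$call))
}
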