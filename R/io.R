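#' Read a PoPoolation2 sync file
#'
#' Parses the tab-separated sync interchange format: scaffold, 1-based
#' position, reference base, then per sample a colon-separated base-count
#' sextet `A:T:C:G:N:del`.  Malformed lines (ragged rows, non-integer
#' counts, sextets of the wrong length) are rejected with their line
#' numbers.  Depth for frequency purposes excludes the `N` and `del`
#' counts.
#'
#' @param path Sync file path.
#' @param sample_ids Optional sample names (default `S1`, `S2`, ...).
#' @return Long tibble of class `er_sync`: `scaffold`, `pos`, `ref`,
#'   `sample_id`, `A`, `T`, `C`, `G`, `N`, `del`, `depth`.
#' @export
read_sync <- function(path, sample_ids = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warn("empty sync file")
    return(structure(tibble(scaffold = character(), pos = integer(),
                            ref = character(), sample_id = character(),
                            A = integer(), T = integer(), C = integer(),
                            G = integer(), N = integer(), del = integer(),
                            depth = integer()),
                     class = c("er_sync", class(tibble()))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 4)) {
    abort(paste("sync rows with fewer than 4 columns at line(s):",
                toString(head(which(n_col < 4), 5))))
  }
  if (length(unique(n_col)) != 1) {
    abort(paste("ragged sync rows at line(s):",
                toString(head(which(n_col != n_col[1]), 5))))
  }
  n_samples <- n_col[1] - 3L
  sample_ids <- sample_ids %||% paste0("S", seq_len(n_samples))
  if (length(sample_ids) != n_samples) {
    abort("`sample_ids` length does not match the number of sample columns")
  }
  mat <- do.call(rbind, fields)
  pos <- suppressWarnings(as.integer(mat[, 2]))
  if (anyNA(pos)) {
    abort(paste("non-integer positions at line(s):",
                toString(head(which(is.na(pos)), 5))))
  }
  out <- purrr::map_dfr(seq_len(n_samples), function(j) {
    sext <- strsplit(mat[, 3 + j], ":", fixed = TRUE)
    if (any(lengths(sext) != 6)) {
      abort(paste("malformed count sextet at line(s):",
                  toString(head(which(lengths(sext) != 6), 5))))
    }
    cnt <- suppressWarnings(matrix(as.integer(unlist(sext)), ncol = 6,
                                   byrow = TRUE))
    if (anyNA(cnt) || any(cnt < 0)) {
      abort(paste("non-integer counts at line(s):",
                  toString(head(which(rowSums(is.na(cnt)) > 0), 5))))
    }
    tibble(scaffold = mat[, 1], pos = pos, ref = mat[, 3],
           sample_id = sample_ids[j],
           A = cnt[, 1], T = cnt[, 2], C = cnt[, 3], G = cnt[, 4],
           N = cnt[, 5], del = cnt[, 6],
           depth = cnt[, 1] + cnt[, 2] + cnt[, 3] + cnt[, 4])
  })
  class(out) <- c("er_sync", class(out))
  out
}

#' Write a PoPoolation2 sync file
#'
#' Inverse of [read_sync()] (canonical files round-trip bit-exactly, sextet
#' order `A:T:C:G:N:del`).
#'
#' @param sync An `er_sync` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(sync, path) {
  samples <- unique(sync$sample_id)
  wide <- sync |>
    mutate(sextet = paste(.data$A, .data$T, .data$C, .data$G, .data$N,
                          .data$del, sep = ":")) |>
    tidyr::pivot_wider(id_cols = c("scaffold", "pos", "ref"),
                       names_from = "sample_id", values_from = "sextet")
  lines <- do.call(paste, c(wide[, c("scaffold", "pos", "ref", samples)],
                            sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Tracked-allele frequencies from sync counts
#'
#' Resolves the tracked allele per locus as the *minor* allele of the
#' ancestral samples (the two most frequent bases overall are taken as the
#' segregating alleles) and returns per-sample frequencies and depths.
#' Orientation uses all ancestor samples jointly (`"global_ancestor"`,
#' required for cross-background offsets) or each background's own ancestors
#' (`"background_ancestor"`).  Without a design sheet, all samples
#' orient the allele.
#'
#' @param sync An `er_sync` tibble.
#' @param design Optional design sheet mapping `sample_id` to `role` and
#'   `background`.
#' @param orient `"global_ancestor"` or `"background_ancestor"`.
#' @return Tibble: `locus`, `scaffold`, `pos`, `sample_id`, `freq`, `reads`,
#'   `depth`.
#' @export
sync_frequencies <- function(sync, design = NULL,
                             orient = c("global_ancestor",
                                        "background_ancestor")) {
  orient <- match.arg(orient)
  bases <- c("A", "T", "C", "G")
  key <- sync |>
    distinct(.data$scaffold, .data$pos) |>
    arrange(.data$scaffold, .data$pos) |>
    mutate(locus = row_number())
  sync <- left_join(sync, key, by = c("scaffold", "pos"))
  if (!is.null(design)) {
    sync <- left_join(sync,
                      select(design, "sample_id", "role", "background"),
                      by = "sample_id")
  } else {
    sync$role <- "ancestor"      # orient on all samples
    sync$background <- "all"
  }

  totals <- sync |>
    group_by(.data$locus) |>
    summarise(across(dplyr::all_of(bases), sum), .groups = "drop")
  cnt <- as.matrix(totals[, bases])
  top2 <- t(apply(cnt, 1, function(z) order(z, decreasing = TRUE)[1:2]))

  anc_scope <- if (orient == "global_ancestor") {
    sync |> filter(.data$role == "ancestor") |>
      group_by(.data$locus) |>
      summarise(across(dplyr::all_of(bases), sum), .groups = "drop") |>
      mutate(background = "all")
  } else {
    sync |> filter(.data$role == "ancestor") |>
      group_by(.data$locus, .data$background) |>
      summarise(across(dplyr::all_of(bases), sum), .groups = "drop")
  }
  anc_cnt <- as.matrix(anc_scope[, bases])
  li <- match(anc_scope$locus, totals$locus)
  a1 <- anc_cnt[cbind(seq_len(nrow(anc_scope)), top2[li, 1])]
  a2 <- anc_cnt[cbind(seq_len(nrow(anc_scope)), top2[li, 2])]
  ## tracked = the rarer of the two segregating alleles in the ancestors
  anc_scope$tracked <- ifelse(a2 <= a1, top2[li, 2], top2[li, 1])

  joined <- if (orient == "global_ancestor") {
    left_join(sync, select(anc_scope, "locus", "tracked"), by = "locus")
  } else {
    left_join(sync, select(anc_scope, "locus", "background", "tracked"),
              by = c("locus", "background"))
  }
  smat <- as.matrix(joined[, bases])
  joined |>
    mutate(reads = smat[cbind(seq_len(nrow(joined)), .data$tracked)],
           freq = if_else(.data$depth > 0, .data$reads / .data$depth,
                          NA_real_)) |>
    select("locus", "scaffold", "pos", "sample_id", "freq", "reads",
           "depth")
}

trait_table_columns <- function() {
  c("line_id", "background", "regime", "replicate", "role", "assay_temp",
    "trait", "mean", "se", "n")
}

#' Read a long-format trait table
#'
#' Validates a tab-separated trait panel (`line_id`, `background`, `regime`,
#' `replicate`, `role`, `assay_temp`, `trait`, `mean`, `se`, `n`): missing
#' columns and duplicate cells are errors, unknown trait names are errors,
#' and missing line x temperature x trait cells are reported.
#'
#' @param path TSV path.
#' @param traits Expected trait set.
#' @return Trait panel tibble.
#' @export
read_trait_table <- function(path, traits = trait_names()) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  missing <- setdiff(trait_table_columns(), names(tbl))
  if (length(missing)) {
    abort(paste("trait table lacks column(s):", toString(missing)))
  }
  unknown <- setdiff(unique(tbl$trait), traits)
  if (length(unknown)) {
    abort(paste("unknown trait name(s):", toString(unknown)))
  }
  dup <- tbl |>
    dplyr::count(.data$line_id, .data$assay_temp, .data$trait) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste("duplicate trait cells, e.g.",
                paste(dup$line_id[1], dup$assay_temp[1], dup$trait[1])))
  }
  full <- tidyr::expand_grid(line_id = unique(tbl$line_id),
                             assay_temp = unique(tbl$assay_temp),
                             trait = traits)
  miss <- dplyr::anti_join(full, tbl,
                           by = c("line_id", "assay_temp", "trait"))
  if (nrow(miss)) {
    warn(sprintf("%d missing trait cells (e.g. %s %s %s)", nrow(miss),
                 miss$line_id[1], miss$assay_temp[1], miss$trait[1]))
  }
  tbl
}

#' Write a trait table
#' @param traits Trait panel tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  readr::write_tsv(traits[, trait_table_columns()], path)
  invisible(path)
}

#' Read protein-coding gene intervals from a GFF3 annotation
#'
#' Imports a GFF3 file and returns the protein-coding gene spans
#' (1-based inclusive, GFF3 convention): genes owning at least one CDS
#' feature (directly or through an mRNA).  With `feature = "cds"`, the
#' individual CDS intervals are returned instead (exon-resolved mode).
#'
#' @param path GFF3 path.
#' @param feature `"gene"` (whole CDS-bearing gene span) or `"cds"`.
#' @return Tibble: `gene_id`, `scaffold`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path, feature = c("gene", "cds")) {
  feature <- match.arg(feature)
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p)) as.character(p[[1]]) else NA_character_
  }, character(1))
  typ <- tolower(as.character(df$type))
  cds <- df[typ == "cds", ]
  mrna <- df[typ %in% c("mrna", "transcript"), ]
  gene <- df[typ == "gene", ]
  ## resolve each CDS to its gene: parent may be an mRNA or the gene itself
  via_mrna <- mrna$Parent[match(cds$Parent, mrna$ID)]
  cds_gene <- ifelse(cds$Parent %in% gene$ID, cds$Parent, via_mrna)
  if (feature == "cds") {
    out <- tibble(gene_id = cds_gene, scaffold = as.character(cds$seqnames),
                  start = cds$start, end = cds$end,
                  strand = as.character(cds$strand))
    return(filter(out, !is.na(.data$gene_id)))
  }
  coding <- gene[gene$ID %in% cds_gene, ]
  tibble(gene_id = coding$ID, scaffold = as.character(coding$seqnames),
         start = coding$start, end = coding$end,
         strand = as.character(coding$strand))
}

#' Rolling -log10 p-value track with its outlier threshold
#'
#' Rolling average of `-log10(p)` in windows of `window` SNPs, never
#' spanning scaffold boundaries (each scaffold contributes
#' `max(0, n - window + 1)` windows), plus the empirical threshold marking
#' the top `quantile_fraction` of window means.
#'
#' @param pvalues Tibble with `scaffold`, `pos` (sorted within scaffold) and
#'   `pvalue`.
#' @param window Window size in SNPs (default 20).
#' @param quantile_fraction Upper-tail fraction defining the threshold
#'   (default 0.001).
#' @return Tibble of class `er_rolling`: `scaffold`, `pos` (window centre),
#'   `value`; attribute `threshold`.
#' @export
rolling_log10p <- function(pvalues, window = 20, quantile_fraction = 0.001) {
  assert_scalar_count(window)
  if (any(pvalues$pvalue <= 0 | pvalues$pvalue > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  unsorted <- pvalues |>
    group_by(.data$scaffold) |>
    summarise(ok = !is.unsorted(.data$pos), .groups = "drop")
  if (any(!unsorted$ok)) {
    abort(paste("positions unsorted within scaffold(s):",
                toString(unsorted$scaffold[!unsorted$ok])))
  }
  out <- pvalues |>
    group_by(.data$scaffold) |>
    filter(n() >= window) |>
    ungroup() |>
    dplyr::reframe(pos = zoo::rollmean(.data$pos, window),
                   value = zoo::rollmean(-log10(.data$pvalue), window),
                   .by = "scaffold")
  attr(out, "threshold") <- as.numeric(
    quantile(out$value, 1 - quantile_fraction, names = FALSE))
  class(out) <- c("er_rolling", class(out))
  out
}
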