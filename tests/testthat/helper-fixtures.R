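## Shared fixtures, all generated in code.

## A tiny two-gene GFF3 annotation: geneA (coding, via mRNA), geneB (coding,
## CDS parented directly), geneC (non-coding), geneD overlapping geneB.
write_test_gff3 <- function(path = tempfile(fileext = ".gff3")) {
  lines <- c(
    "##gff-version 3",
    "scf1\tsrc\tgene\t100\t500\t.\t+\t.\tID=geneA",
    "scf1\tsrc\tmRNA\t100\t500\t.\t+\t.\tID=mrnaA;Parent=geneA",
    "scf1\tsrc\tCDS\t150\t450\t.\t+\t0\tID=cdsA;Parent=mrnaA",
    "scf1\tsrc\tgene\t1000\t1500\t.\t-\t.\tID=geneB",
    "scf1\tsrc\tCDS\t1000\t1500\t.\t-\t0\tID=cdsB;Parent=geneB",
    "scf1\tsrc\tgene\t2000\t2200\t.\t+\t.\tID=geneC",
    "scf1\tsrc\tgene\t1400\t1800\t.\t+\t.\tID=geneD",
    "scf1\tsrc\tmRNA\t1400\t1800\t.\t+\t.\tID=mrnaD;Parent=geneD",
    "scf1\tsrc\tCDS\t1400\t1800\t.\t+\t0\tID=cdsD;Parent=mrnaD",
    "scf2\tsrc\tgene\t10\t90\t.\t+\t.\tID=geneE",
    "scf2\tsrc\tmRNA\t10\t90\t.\t+\t.\tID=mrnaE;Parent=geneE",
    "scf2\tsrc\tCDS\t10\t90\t.\t+\t0\tID=cdsE;Parent=mrnaE"
  )
  writeLines(lines, path)
  path
}

## Minimal change-vector tibble: one line per row of `values` (a matrix with
## named rows), all with independent ancestors unless ancestor ids repeat.
make_cv <- function(values, background, regime, anc_value = 0 * values,
                    anc_se = NA_real_, evo_se = NA_real_, t = 1,
                    ancestor_id = NULL) {
  lines <- rownames(values)
  ancestor_id <- ancestor_id %||% paste0(lines, "_anc")
  purrr::map_dfr(seq_along(lines), function(i) {
    tibble::tibble(
      line_id = lines[i], background = background[i], regime = regime[i],
      replicate = i, assay_temp = NA_real_,
      dim = paste0("d", seq_len(ncol(values))),
      value = values[i, ], anc_value = anc_value[i, ],
      anc_se = anc_se, evo_se = evo_se,
      ancestor_id = ancestor_id[i], t = t
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Per-line per-tail flag rates from scan records.
tail_rates <- function(records, q) {
  records |>
    dplyr::group_by(.data$line_id) |>
    dplyr::summarise(lower = mean(.data$p_tail < q & .data$direction < 0),
                     upper = mean(.data$p_tail < q & .data$direction > 0),
                     n = dplyr::n(), .groups = "drop")
}
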