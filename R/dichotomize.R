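#' Fit expression thresholds that proxy promoter hypermethylation
#'
#' From a cohort with both methylation and expression, learns per-gene
#' expression statistics of the hypermethylated versus non-hypermethylated
#' strata. To be robust to multi-region sampling, one region per tumor is
#' drawn uniformly at random and the stratum mean and 25th/50th/75th
#' percentiles are computed; the draw is repeated `n_bootstrap` times
#' (default 100) and the statistics averaged across replicates.
#' Per-replicate Q3 values are retained for confidence intervals. With a
#' single region per tumor every replicate is identical, so the bootstrap
#' variance is exactly zero.
#'
#' @param expression Long expression tibble over tumor samples.
#' @param hyper_status Tibble with `gene_id`, `sample_id` and logical
#'   `hyper` (promoter hypermethylated in that region).
#' @param samples Sample sheet.
#' @param n_bootstrap Number of region-resampling replicates (default 100).
#' @param seed Seed for the resampling.
#' @param min_per_stratum Minimum tumors per stratum over the full data
#'   (default 5); genes below it are skipped, with reasons in the
#'   `"skip_report"` attribute.
#' @return Tibble of class `"expression_thresholds"`: per gene and stratum,
#'   aggregated `mean`, `q25`, `q50`, `q75`, `n_tumors`, plus a `q75_reps`
#'   list-column of per-replicate values.
#' @export
fit_expression_thresholds <- function(expression, hyper_status, samples,
                                      n_bootstrap = 100, seed,
                                      min_per_stratum = 5) {
  if (missing(seed)) abort("a seed is required for the bootstrap")
  assert_columns(expression, c("gene_id", "sample_id", "value"))
  assert_columns(hyper_status, c("gene_id", "sample_id", "hyper"))
  samples <- validate_samples(samples)
  tum <- filter(samples, .data$tissue == "tumor")

  df <- expression |>
    inner_join(hyper_status, by = c("gene_id", "sample_id")) |>
    inner_join(select(tum, dplyr::all_of(c("sample_id", "patient_id"))),
               by = "sample_id")

  eligible <- df |>
    distinct(.data$gene_id, .data$patient_id, .data$hyper) |>
    count(.data$gene_id, .data$hyper) |>
    tidyr::pivot_wider(names_from = "hyper", values_from = "n",
                       values_fill = 0L, names_prefix = "h")
  ok_genes <- eligible$gene_id[
    (eligible$hTRUE %||% 0) >= min_per_stratum &
      (eligible$hFALSE %||% 0) >= min_per_stratum
  ]
  skipped <- setdiff(unique(df$gene_id), ok_genes)
  df <- filter(df, .data$gene_id %in% ok_genes)

  regions <- tum |>
    semi_join(df, by = "sample_id") |>
    select(dplyr::all_of(c("sample_id", "patient_id")))
  by_patient <- split(regions$sample_id, regions$patient_id)

  set.seed(substream_seed(seed, "bootstrap"))
  reps <- purrr::map(seq_len(n_bootstrap), function(r) {
    chosen <- purrr::map_chr(by_patient, function(ids) {
      if (length(ids) == 1) ids else sample(ids, 1)
    })
    df |>
      filter(.data$sample_id %in% chosen) |>
      group_by(.data$gene_id, .data$hyper) |>
      summarise(
        mean = mean(.data$value),
        q25 = quantile(.data$value, 0.25, names = FALSE),
        q50 = quantile(.data$value, 0.50, names = FALSE),
        q75 = quantile(.data$value, 0.75, names = FALSE),
        n_tumors = n(),
        .groups = "drop"
      ) |>
      mutate(replicate = r)
  })
  reps <- bind_rows(reps)
  out <- reps |>
    group_by(.data$gene_id, .data$hyper) |>
    summarise(
      mean = mean(.data$mean), q25 = mean(.data$q25), q50 = mean(.data$q50),
      q75_reps = list(.data$q75), q75 = mean(.data$q75),
      n_tumors = as.integer(round(mean(.data$n_tumors))),
      n_bootstrap = n(),
      .groups = "drop"
    )
  attr(out, "skip_report") <- tibble(
    gene_id = skipped, reason = rep("stratum_too_small", length(skipped))
  )
  class(out) <- c("expression_thresholds", class(out))
  out
}

#' Predict promoter hypermethylation status from expression alone
#'
#' Transfers fitted thresholds to an expression-only cohort: a region is
#' labeled `low` (hypermethylation-dependent reduced expression) when its
#' expression is strictly below the aggregated Q3 threshold of the chosen
#' stratum (default: the hypermethylated stratum), and `high` otherwise
#' (values exactly at the threshold are `high`). At the tumor level, a
#' tumor with any `low` region is classified as having
#' hypermethylation-dependent reduced expression; disagreeing regions are
#' flagged as conflicts.
#'
#' @param expression Long expression tibble for the target cohort.
#' @param thresholds Output of [fit_expression_thresholds()].
#' @param samples Sample sheet for the target cohort.
#' @param stratum Which stratum's Q3 to use as the threshold:
#'   `"hyper"` (default) or `"not_hyper"`.
#' @return Tibble with `gene_id`, `sample_id`, `patient_id`, `label`,
#'   `tumor_label`, `region_conflict`.
#' @export
predict_methylation_status <- function(expression, thresholds, samples,
                                       stratum = c("hyper", "not_hyper")) {
  stratum <- match.arg(stratum)
  assert_columns(expression, c("gene_id", "sample_id", "value"))
  assert_columns(thresholds, c("gene_id", "hyper", "q75"))
  samples <- validate_samples(samples)
  tum <- filter(samples, .data$tissue == "tumor")
  thr <- thresholds |>
    filter(.data$hyper == (stratum == "hyper")) |>
    select(dplyr::all_of(c("gene_id", "q75")))
  out <- expression |>
    inner_join(select(tum, dplyr::all_of(c("sample_id", "patient_id"))),
               by = "sample_id") |>
    inner_join(thr, by = "gene_id") |>
    mutate(label = if_else(.data$value < .data$q75, "low", "high")) |>
    group_by(.data$gene_id, .data$patient_id) |>
    mutate(
      tumor_label = if_else(any(.data$label == "low"), "low", "high"),
      region_conflict = n_distinct(.data$label) > 1
    ) |>
    ungroup() |>
    select(dplyr::all_of(c("gene_id", "sample_id", "patient_id", "label",
                           "tumor_label", "region_conflict")))
  out
}
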