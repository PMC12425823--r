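#' Call differentially methylated regions (DMRs) from DMP records
#'
#' CpGs are binned into neighborhoods by chaining: consecutive covered CpGs
#' within `gap` bp (default 100) of one another share a bin. Within each bin
#' the run structure of same-direction DMPs is evaluated over the sequence
#' of adjacent covered CpGs (missing-coverage CpGs are simply absent from
#' the series and do not break runs). A bin is a hyper-DMR when it contains
#' four or more consecutive hyper DMPs and at least five hyper DMPs in
#' total; hypo-DMRs analogously.
#'
#' @param dmps DMP tibble with `chrom`, `pos`, `status` and a grouping
#'   column (default `sample_id`; pass `group = NULL` for cohort-level
#'   records).
#' @param gap Maximum distance between neighboring CpGs in one bin.
#' @param min_run Minimum consecutive same-direction DMPs (default 4).
#' @param min_total Minimum total same-direction DMPs in the bin (default 5).
#' @param group Name of the grouping column, or `NULL`.
#' @return Tibble with one row per bin and group: `chrom`, `start`, `end`,
#'   `n_cpgs`, per-direction DMP counts and maximum runs, and
#'   `status` in `hyper` / `hypo` / `both` / `ns`.
#' @export
call_dmrs <- function(dmps, gap = 100, min_run = 4, min_total = 5,
                      group = "sample_id") {
  assert_columns(dmps, c("chrom", "pos", "status"))
  if (!is.null(group)) assert_columns(dmps, group)
  df <- dmps
  if (is.null(group)) {
    df$..group <- "all"
  } else {
    df$..group <- df[[group]]
  }
  df <- arrange(df, .data$..group, .data$chrom, .data$pos)
  df <- df |>
    group_by(.data$..group, .data$chrom) |>
    mutate(new_bin = is.na(lag(.data$pos)) | .data$pos - lag(.data$pos) > gap,
           bin = cumsum(.data$new_bin)) |>
    ungroup()

  max_run <- function(x) {
    if (!any(x)) return(0L)
    r <- rle(x)
    max(r$lengths[r$values])
  }
  out <- df |>
    group_by(.data$..group, .data$chrom, .data$bin) |>
    summarise(
      start = min(.data$pos), end = max(.data$pos), n_cpgs = n(),
      n_hyper = sum(.data$status == "hyper"),
      n_hypo = sum(.data$status == "hypo"),
      max_run_hyper = max_run(.data$status == "hyper"),
      max_run_hypo = max_run(.data$status == "hypo"),
      .groups = "drop"
    ) |>
    mutate(
      is_hyper = .data$max_run_hyper >= min_run & .data$n_hyper >= min_total,
      is_hypo = .data$max_run_hypo >= min_run & .data$n_hypo >= min_total,
      status = dplyr::case_when(
        .data$is_hyper & .data$is_hypo ~ "both",
        .data$is_hyper ~ "hyper",
        .data$is_hypo ~ "hypo",
        TRUE ~ "ns"
      )
    ) |>
    select(-"is_hyper", -"is_hypo")
  if (is.null(group)) {
    select(out, -"..group")
  } else {
    rename(out, !!group := "..group")
  }
}

#' Summarize promoter methylation status per gene and sample
#'
#' A gene is `hyper` in a sample when at least one hyper-DMR overlaps its
#' promoter window, `hypo` analogously; a promoter overlapping qualifying
#' DMRs of both directions is recorded as `both` with a conflict flag.
#' Genes whose promoter has covered CpGs but no qualifying DMR are `none`;
#' genes with zero covered promoter CpGs in a sample are reported with
#' status `NA` (missing, not "none").
#'
#' @param dmrs Output of [call_dmrs()] (per sample).
#' @param promoters Promoter window tibble.
#' @param meth Methylation observations used to establish coverage
#'   (`chrom`, `pos`, `sample_id`), typically the deconvolution input.
#' @return Tibble with `gene_id`, `sample_id`, `status`, `conflict`,
#'   `n_covered_cpgs`.
#' @export
promoter_methylation_status <- function(dmrs, promoters, meth) {
  assert_columns(dmrs, c("sample_id", "chrom", "start", "end", "status"))
  assert_columns(promoters, c("gene_id", "chrom", "window_start", "window_end"))
  assert_columns(meth, c("chrom", "pos", "sample_id"))

  covered <- map_cpgs_to_promoters(
    distinct(meth, .data$chrom, .data$pos, .data$sample_id), promoters
  ) |>
    count(.data$gene_id, .data$sample_id, name = "n_covered_cpgs")

  hits <- inner_join(
    filter(dmrs, .data$status %in% c("hyper", "hypo", "both")),
    select(promoters, dplyr::all_of(c("gene_id", "chrom", "window_start",
                                      "window_end"))),
    by = join_by(chrom, overlaps(start, end, window_start, window_end)),
    relationship = "many-to-many"
  ) |>
    group_by(.data$gene_id, .data$sample_id) |>
    summarise(
      has_hyper = any(.data$status %in% c("hyper", "both")),
      has_hypo = any(.data$status %in% c("hypo", "both")),
      .groups = "drop"
    )

  covered |>
    left_join(hits, by = c("gene_id", "sample_id")) |>
    mutate(
      has_hyper = tidyr::replace_na(.data$has_hyper, FALSE),
      has_hypo = tidyr::replace_na(.data$has_hypo, FALSE),
      status = dplyr::case_when(
        has_hyper & has_hypo ~ "both",
        has_hyper ~ "hyper",
        has_hypo ~ "hypo",
        TRUE ~ "none"
      ),
      conflict = .data$has_hyper & .data$has_hypo
    ) |>
    select(dplyr::all_of(c("gene_id", "sample_id", "status", "conflict",
                           "n_covered_cpgs")))
}

#' Compute event ubiquity (clonality) across regions of each patient
#'
#' For every feature and patient, counts the regions in which an event is
#' present among the regions where the feature is assessable. An event is
#' `ubiquitous` (clonal) when present in all of at least two assessable
#' regions and `subclonal` otherwise; clonality is missing for patients
#' with fewer than two assessable regions (the fraction is still reported).
#'
#' @param events Tibble with a feature column, `sample_id` and a logical
#'   `event` column (`NA` = not assessable in that region).
#' @param samples Sample sheet (used to map samples to patients; normals
#'   are ignored).
#' @param feature Name of the feature column (default `"gene_id"`).
#' @return Tibble with feature, `patient_id`, `n_regions_with_event`,
#'   `n_regions_assessable`, `fraction`, `clonality`.
#' @export
compute_ubiquity <- function(events, samples, feature = "gene_id") {
  assert_columns(events, c(feature, "sample_id", "event"))
  samples <- validate_samples(samples)
  tum <- filter(samples, .data$tissue == "tumor")
  events |>
    select(dplyr::all_of(c(feature, "sample_id", "event"))) |>
    inner_join(select(tum, dplyr::all_of(c("sample_id", "patient_id"))),
               by = "sample_id") |>
    group_by(.data[[feature]], .data$patient_id) |>
    summarise(
      n_regions_with_event = sum(.data$event, na.rm = TRUE),
      n_regions_assessable = sum(!is.na(.data$event)),
      .groups = "drop"
    ) |>
    filter(.data$n_regions_assessable > 0) |>
    mutate(
      fraction = .data$n_regions_with_event / .data$n_regions_assessable,
      clonality = dplyr::case_when(
        .data$n_regions_assessable < 2 ~ NA_character_,
        .data$n_regions_with_event == 0 ~ NA_character_,
        .data$fraction == 1 ~ "ubiquitous",
        TRUE ~ "subclonal"
      )
    )
}
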