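#' Intratumor / intertumor methylation distance (ITMD)
#'
#' Pairwise Pearson distance (`1 - r`, range \[0, 2\]) between the CpG
#' methylation-rate vectors of tumor regions, computed over the CpGs
#' covered in both members of each pair. `scope = "intra"` returns all
#' region pairs within a patient, `scope = "inter"` all cross-patient
#' region pairs. Pairs whose shared feature count falls below
#' `min_features`, or where a rate vector has zero variance (correlation
#' undefined), are skipped with a warning.
#'
#' @param rates Tibble with `chrom`, `pos`, `sample_id` and a rate column
#'   (default `m_t_hat`; use `rate` for bulk rates).
#' @param samples Sample sheet.
#' @param scope `"intra"` or `"inter"`.
#' @param value Name of the rate column.
#' @param min_features Minimum shared CpGs per pair (default 5000; lower it
#'   for small simulated cohorts).
#' @return Tibble of class `"itmd"` with one row per region pair:
#'   `patient_a`, `patient_b`, `sample_a`, `sample_b`, `distance`,
#'   `n_features`, `scope`.
#' @export
compute_itmd <- function(rates, samples, scope = c("intra", "inter"),
                         value = "m_t_hat", min_features = 5000) {
  scope <- match.arg(scope)
  assert_columns(rates, c("chrom", "pos", "sample_id", value))
  samples <- validate_samples(samples)
  tum <- filter(samples, .data$tissue == "tumor")
  if (scope == "intra") {
    n_reg <- count(tum, .data$patient_id)
    if (all(n_reg$n < 2)) {
      abort("intra-patient ITMD needs at least 2 regions for some patient",
            class = "methevolve_config_error")
    }
  }
  wide <- rates |>
    semi_join(tum, by = "sample_id") |>
    select(dplyr::all_of(c("chrom", "pos", "sample_id", value))) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = dplyr::all_of(value))
  mat <- as.matrix(wide[, -(1:2), drop = FALSE])
  ids <- colnames(mat)
  cors <- suppressWarnings(cor(mat, use = "pairwise.complete.obs"))
  nf <- crossprod(!is.na(mat))
  pat <- tum$patient_id[match(ids, tum$sample_id)]

  pairs <- which(upper.tri(cors), arr.ind = TRUE)
  dist_vals <- 1 - cors[pairs]
  # identical vectors must be at distance exactly 0 (and anticorrelated at
  # 2); zap sub-ulp correlation round-off at the boundaries
  dist_vals[abs(dist_vals) < 1e-12] <- 0
  dist_vals[abs(dist_vals - 2) < 1e-12] <- 2
  out <- tibble(
    sample_a = ids[pairs[, 1]], sample_b = ids[pairs[, 2]],
    patient_a = pat[pairs[, 1]], patient_b = pat[pairs[, 2]],
    distance = dist_vals,
    n_features = as.integer(nf[pairs]),
    scope = if_else(pat[pairs[, 1]] == pat[pairs[, 2]], "intra", "inter")
  ) |>
    filter(.data$scope == !!scope)
  bad <- is.na(out$distance) | out$n_features < min_features
  if (any(bad)) {
    warn(sprintf("%d region pair(s) skipped (zero variance or < %d shared CpGs)",
                 sum(bad), min_features))
    out <- out[!bad, , drop = FALSE]
  }
  class(out) <- c("itmd", class(out))
  out
}

#' Per-patient mean of pairwise heterogeneity distances
#'
#' Intra-patient pairs are averaged per patient; inter-patient pairs per
#' patient pair.
#'
#' @param pairs Output of [compute_itmd()] (or any tibble with `patient_a`,
#'   `patient_b`, `distance`).
#' @return Tibble with `patient_a`, `patient_b`, `mean_distance`, `n_pairs`.
#' @export
itmd_patient_means <- function(pairs) {
  assert_columns(pairs, c("patient_a", "patient_b", "distance"))
  pairs |>
    group_by(.data$patient_a, .data$patient_b) |>
    summarise(mean_distance = mean(.data$distance), n_pairs = n(),
              .groups = "drop")
}

#' Intratumor expression distance (ITED)
#'
#' Expression is normalized as `log2(x + 1)` followed by a per-gene z-score
#' across the cohort; the ITED of a tumor region is the mean correlation
#' distance (`1 - r`) against every sibling region of the same tumor.
#'
#' @param expression Long expression tibble (`gene_id`, `sample_id`,
#'   `value`).
#' @param samples Sample sheet.
#' @return Tibble with `sample_id`, `patient_id`, `ited`, `n_pairs`,
#'   `n_genes`.
#' @export
compute_ited <- function(expression, samples) {
  assert_columns(expression, c("gene_id", "sample_id", "value"))
  samples <- validate_samples(samples)
  tum <- filter(samples, .data$tissue == "tumor")
  n_reg <- count(tum, .data$patient_id)
  if (all(n_reg$n < 2)) {
    abort("ITED needs at least 2 regions for some patient",
          class = "methevolve_config_error")
  }
  norm <- expression |>
    semi_join(tum, by = "sample_id") |>
    mutate(logv = log2(.data$value + 1)) |>
    group_by(.data$gene_id) |>
    mutate(z = (.data$logv - mean(.data$logv)) /
             ifelse(sd(.data$logv) > 0, sd(.data$logv), 1)) |>
    ungroup()
  wide <- tidyr::pivot_wider(
    select(norm, dplyr::all_of(c("gene_id", "sample_id", "z"))),
    names_from = "sample_id", values_from = "z"
  )
  mat <- as.matrix(wide[, -1, drop = FALSE])
  ids <- colnames(mat)
  cors <- suppressWarnings(cor(mat, use = "pairwise.complete.obs"))
  pat <- tum$patient_id[match(ids, tum$sample_id)]
  purrr::map_dfr(seq_along(ids), function(i) {
    sib <- which(pat == pat[i] & seq_along(ids) != i)
    if (length(sib) == 0) return(NULL)
    tibble(
      sample_id = ids[i], patient_id = pat[i],
      ited = mean(1 - cors[i, sib]),
      n_pairs = length(sib),
      n_genes = nrow(mat)
    )
  })
}
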