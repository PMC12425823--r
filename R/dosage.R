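#' Mean promoter methylation per gene and sample
#'
#' Averages a methylation-rate column over the covered promoter CpGs of
#' each gene, the per-gene summary consumed by the dosage-compensation and
#' chromatin-transition scans.
#'
#' @param rates Tibble with `chrom`, `pos`, `sample_id` and the rate column.
#' @param promoters Promoter windows.
#' @param value Rate column name (default `m_t_hat`; use `rate` for bulk
#'   or normal rates).
#' @return Tibble with `gene_id`, `sample_id`, `mean_meth`, `n_cpgs`.
#' @export
promoter_mean_meth <- function(rates, promoters, value = "m_t_hat") {
  assert_columns(rates, c("chrom", "pos", "sample_id", value))
  map_cpgs_to_promoters(rates, promoters) |>
    filter(!is.na(.data[[value]])) |>
    group_by(.data$gene_id, .data$sample_id) |>
    summarise(mean_meth = mean(.data[[value]]), n_cpgs = n(), .groups = "drop")
}

#' Scan genes for methylation-dependent dosage compensation
#'
#' For every gene with enough amplified and non-amplified tumor regions,
#' computes the difference in median promoter methylation between the two
#' strata; a difference above 0.2 flags the gene as increasing promoter
#' methylation when amplified. Expression is classified by a two-sample
#' t-test on `log2(value + 1)` between strata: `scaling` when expression is
#' significantly higher when amplified, `antiscaling` when significantly
#' lower, `buffered` otherwise. A flagged, buffered gene is the
#' dosage-compensation signature: extra copies silenced by promoter
#' methylation with expression held at baseline.
#'
#' @param meth_promoter Output of [promoter_mean_meth()].
#' @param expression Long expression tibble.
#' @param events Output of [classify_gene_events()] (provides the
#'   amplification stratum).
#' @param min_per_stratum Minimum regions per stratum (default 3).
#' @param delta_threshold Methylation-difference flag threshold (0.2).
#' @param alpha Expression t-test significance level (0.05).
#' @return Tibble with `gene_id`, `delta_median_meth`, `expression_class`,
#'   `flagged`, `n_amplified`, `n_not_amplified`, `p_expression`.
#' @export
dosage_compensation_scan <- function(meth_promoter, expression, events,
                                     min_per_stratum = 3,
                                     delta_threshold = 0.2, alpha = 0.05) {
  assert_columns(meth_promoter, c("gene_id", "sample_id", "mean_meth"))
  assert_columns(expression, c("gene_id", "sample_id", "value"))
  assert_columns(events, c("gene_id", "sample_id", "amplification"))
  strata <- select(events, dplyr::all_of(c("gene_id", "sample_id",
                                           "amplification")))
  df <- meth_promoter |>
    inner_join(strata, by = c("gene_id", "sample_id")) |>
    inner_join(select(expression, dplyr::all_of(c("gene_id", "sample_id",
                                                  "value"))),
               by = c("gene_id", "sample_id")) |>
    mutate(logv = log2(.data$value + 1))
  df |>
    group_by(.data$gene_id) |>
    summarise(
      n_amplified = sum(.data$amplification),
      n_not_amplified = sum(!.data$amplification),
      delta_median_meth = median(.data$mean_meth[.data$amplification]) -
        median(.data$mean_meth[!.data$amplification]),
      p_expression = if (sum(.data$amplification) >= min_per_stratum &&
                         sum(!.data$amplification) >= min_per_stratum) {
        tryCatch(
          t.test(.data$logv[.data$amplification],
                 .data$logv[!.data$amplification])$p.value,
          error = function(e) 1
        )
      } else NA_real_,
      mean_diff = mean(.data$logv[.data$amplification]) -
        mean(.data$logv[!.data$amplification]),
      .groups = "drop"
    ) |>
    filter(.data$n_amplified >= min_per_stratum,
           .data$n_not_amplified >= min_per_stratum) |>
    mutate(
      expression_class = dplyr::case_when(
        .data$p_expression < alpha & .data$mean_diff > 0 ~ "scaling",
        .data$p_expression < alpha & .data$mean_diff < 0 ~ "antiscaling",
        TRUE ~ "buffered"
      ),
      flagged = .data$delta_median_meth > delta_threshold
    ) |>
    select(dplyr::all_of(c("gene_id", "delta_median_meth", "expression_class",
                           "flagged", "n_amplified", "n_not_amplified",
                           "p_expression")))
}

#' Retain only large copy-number events and classify them against ploidy
#'
#' Keeps segments spanning at least `min_span` bp (default 50 Mb), the
#' scale at which copy-number calls from methylation data are reliable,
#' and labels each as `gain` or `loss` relative to the sample's ploidy
#' (`neutral` otherwise).
#'
#' @param segments Copy-number segments.
#' @param samples Sample sheet (provides ploidy).
#' @param min_span Minimum segment span in bp (default 5e7).
#' @return Filtered segments with a `cna_class` column.
#' @export
filter_cnas_for_allchat <- function(segments, samples, min_span = 5e7) {
  segments <- validate_segments(segments)
  samples <- validate_samples(samples)
  segments |>
    filter(.data$end - .data$start + 1 >= min_span) |>
    inner_join(select(samples, dplyr::all_of(c("sample_id", "ploidy"))),
               by = "sample_id") |>
    mutate(cna_class = dplyr::case_when(
      .data$n_t > .data$ploidy ~ "gain",
      .data$n_t < .data$ploidy ~ "loss",
      TRUE ~ "neutral"
    ))
}

#' Enumerate candidate oncogene-passenger pairs within a shared amplicon
#'
#' Pairs each annotated oncogene with every other gene within `max_dist`
#' bp on the same chromosome (default 20 Mb), the distance within which
#' both genes can be assumed to sit under the same copy-number event.
#'
#' @param oncogenes Character vector of oncogene ids.
#' @param genes Gene tibble with `gene_id`, `chrom`, `tss`.
#' @param max_dist Maximum TSS distance in bp (default 2e7).
#' @return Tibble with `oncogene_id`, `passenger_id`, `distance_bp`.
#' @export
make_allchat_pairs <- function(oncogenes, genes, max_dist = 2e7) {
  assert_columns(genes, c("gene_id", "chrom", "tss"))
  onco <- filter(genes, .data$gene_id %in% oncogenes) |>
    select(oncogene_id = "gene_id", "chrom", onco_tss = "tss")
  partners <- select(genes, passenger_id = "gene_id", "chrom", pass_tss = "tss")
  inner_join(onco, partners, by = "chrom", relationship = "many-to-many") |>
    mutate(distance_bp = abs(.data$onco_tss - .data$pass_tss)) |>
    filter(.data$passenger_id != .data$oncogene_id,
           !.data$passenger_id %in% oncogenes,
           .data$distance_bp <= max_dist) |>
    select(dplyr::all_of(c("oncogene_id", "passenger_id", "distance_bp")))
}

#' Normalize histone TSS-window signals against the normal average
#'
#' Divides each tumor sample's window sum by the average window sum of the
#' normal samples for the same gene and mark (pseudocount 1 on both sides)
#' and log-transforms the ratio.
#'
#' @param histone Tibble with `gene_id`, `sample_id`, `mark`, `window_sum`.
#' @param samples Sample sheet.
#' @return Tumor rows with a `log_ratio` column added.
#' @export
normalize_histone <- function(histone, samples) {
  assert_columns(histone, c("gene_id", "sample_id", "mark", "window_sum"))
  samples <- validate_samples(samples)
  norm_ids <- samples$sample_id[samples$tissue == "normal"]
  norm_avg <- histone |>
    filter(.data$sample_id %in% norm_ids) |>
    group_by(.data$gene_id, .data$mark) |>
    summarise(normal_mean = mean(.data$window_sum), .groups = "drop")
  histone |>
    filter(!.data$sample_id %in% norm_ids) |>
    inner_join(norm_avg, by = c("gene_id", "mark")) |>
    mutate(log_ratio = log((.data$window_sum + 1) / (.data$normal_mean + 1)))
}

#' Tumor-minus-normal differential promoter methylation per sample
#'
#' Averages a rate column over promoter CpGs per gene and sample, then
#' subtracts each patient's matched-normal promoter mean from every tumor
#' region's mean.
#'
#' @param rates Methylation-rate tibble covering tumor and normal samples
#'   (`chrom`, `pos`, `sample_id` and the rate column).
#' @param samples Sample sheet.
#' @param promoters Promoter windows.
#' @param value Rate column (default `"rate"`).
#' @return Tibble with `gene_id`, `sample_id`, `patient_id`, `meth_diff`.
#' @export
promoter_meth_diff <- function(rates, samples, promoters, value = "rate") {
  samples <- validate_samples(samples)
  pm <- promoter_mean_meth(rates, promoters, value = value)
  tum <- filter(samples, .data$tissue == "tumor")
  nor <- filter(samples, .data$tissue == "normal")
  pm_n <- pm |>
    semi_join(nor, by = "sample_id") |>
    inner_join(select(nor, dplyr::all_of(c("sample_id", "patient_id"))),
               by = "sample_id") |>
    select(dplyr::all_of(c("gene_id", "patient_id")), normal_mean = "mean_meth")
  pm |>
    semi_join(tum, by = "sample_id") |>
    inner_join(select(tum, dplyr::all_of(c("sample_id", "patient_id"))),
               by = "sample_id") |>
    inner_join(pm_n, by = c("gene_id", "patient_id")) |>
    mutate(meth_diff = .data$mean_meth - .data$normal_mean) |>
    select(dplyr::all_of(c("gene_id", "sample_id", "patient_id", "meth_diff")))
}

one_sided_less_p <- function(a, b) {
  # H1: mean(a) < mean(b); Welch t
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  tryCatch(t.test(a, b, alternative = "less")$p.value,
           error = function(e) NA_real_)
}

#' Detect oncogene-passenger chromatin transitions at co-amplified loci
#'
#' For each candidate pair, tumor samples are stratified by whether the
#' oncogene locus is gained or amplified. The divergence signature is a
#' battery of one-sided t-tests: within the gained stratum, tumor-normal
#' differential promoter methylation at the oncogene must be lower than at
#' the passenger, the H3K4me3 tumor/normal log-ratio higher, and the
#' H3K27me3 log-ratio lower (each at `alpha`). Within the non-gained
#' stratum the oncogene must *not* diverge: with
#' `non_gained = "nonsig"` (default) each gained-direction test must be
#' non-significant (a no-divergence check, since a reverse one-sided test
#' cannot succeed when the profiles are genuinely equal); with
#' `non_gained = "reverse"` a significant reverse-direction test is
#' required. The verdict is true only when every stratum test passes; with
#' histone data absent the methylation tests alone decide and the verdict
#' is marked partial.
#'
#' @param pairs Candidate pairs from [make_allchat_pairs()].
#' @param meth_diff Tibble with `gene_id`, `sample_id`, `meth_diff`
#'   (tumor-minus-normal promoter methylation per sample).
#' @param events Output of [classify_gene_events()] (gain/amplification
#'   strata at the oncogene).
#' @param histone Normalized histone tibble from [normalize_histone()], or
#'   `NULL` for methylation-only mode.
#' @param alpha One-sided test level for the gained-stratum tests (0.05).
#' @param alpha_non_gained Rejection level for the non-gained no-divergence
#'   checks (default 0.01). Because a candidate pair must clear three
#'   independent no-divergence checks, rejecting each at `alpha` would
#'   discard truly divergent pairs at rate `3 * alpha` by chance alone; a
#'   stricter level balances the two error rates while still excluding
#'   pairs whose divergence is locus-intrinsic rather than
#'   copy-number-driven (those reject at far smaller p).
#' @param min_per_stratum Minimum samples per stratum (default 3).
#' @param non_gained `"nonsig"` or `"reverse"` (see Details).
#' @return Tibble of class `"allchat"`: one row per pair with stratum
#'   sizes, each test p-value, `verdict` and `partial`.
#' @export
detect_allchat <- function(pairs, meth_diff, events, histone = NULL,
                           alpha = 0.05, alpha_non_gained = 0.01,
                           min_per_stratum = 3,
                           non_gained = c("nonsig", "reverse")) {
  non_gained <- match.arg(non_gained)
  assert_columns(pairs, c("oncogene_id", "passenger_id"))
  assert_columns(meth_diff, c("gene_id", "sample_id", "meth_diff"))
  assert_columns(events, c("gene_id", "sample_id", "gain", "amplification"))
  strata <- events |>
    mutate(gained = .data$gain | .data$amplification) |>
    select(dplyr::all_of(c("gene_id", "sample_id", "gained")))

  use_histone <- !is.null(histone)
  if (use_histone) {
    assert_columns(histone, c("gene_id", "sample_id", "mark", "log_ratio"))
  }

  eval_pair <- function(onco, pass) {
    st <- filter(strata, .data$gene_id == onco)
    gained_ids <- st$sample_id[st$gained]
    other_ids <- st$sample_id[!st$gained]
    md <- filter(meth_diff, .data$gene_id %in% c(onco, pass))
    get_vec <- function(d, g, ids, col) {
      d[[col]][d$gene_id == g & d$sample_id %in% ids]
    }
    p_meth_g <- one_sided_less_p(get_vec(md, onco, gained_ids, "meth_diff"),
                                 get_vec(md, pass, gained_ids, "meth_diff"))
    p_meth_n <- one_sided_less_p(get_vec(md, onco, other_ids, "meth_diff"),
                                 get_vec(md, pass, other_ids, "meth_diff"))
    res <- tibble(
      oncogene_id = onco, passenger_id = pass,
      n_gained = length(gained_ids), n_not_gained = length(other_ids),
      p_meth_gained = p_meth_g, p_meth_not_gained = p_meth_n
    )
    if (use_histone) {
      h <- filter(histone, .data$gene_id %in% c(onco, pass))
      k4 <- filter(h, .data$mark == "H3K4me3")
      k27 <- filter(h, .data$mark == "H3K27me3")
      # H1 within gained: K4(onco) > K4(pass)  <=>  K4(pass) < K4(onco)
      res$p_k4_gained <- one_sided_less_p(
        get_vec(k4, pass, gained_ids, "log_ratio"),
        get_vec(k4, onco, gained_ids, "log_ratio"))
      res$p_k4_not_gained <- one_sided_less_p(
        get_vec(k4, pass, other_ids, "log_ratio"),
        get_vec(k4, onco, other_ids, "log_ratio"))
      res$p_k27_gained <- one_sided_less_p(
        get_vec(k27, onco, gained_ids, "log_ratio"),
        get_vec(k27, pass, gained_ids, "log_ratio"))
      res$p_k27_not_gained <- one_sided_less_p(
        get_vec(k27, onco, other_ids, "log_ratio"),
        get_vec(k27, pass, other_ids, "log_ratio"))
    }
    res
  }

  out <- purrr::map2_dfr(pairs$oncogene_id, pairs$passenger_id, eval_pair)
  gained_cols <- intersect(c("p_meth_gained", "p_k4_gained", "p_k27_gained"),
                           names(out))
  other_cols <- intersect(c("p_meth_not_gained", "p_k4_not_gained",
                            "p_k27_not_gained"), names(out))
  pass_gained <- rowSums(as.matrix(out[gained_cols]) >= alpha) == 0 &
    !apply(as.matrix(out[gained_cols]), 1, anyNA)
  other_mat <- as.matrix(out[other_cols])
  pass_other <- if (non_gained == "nonsig") {
    rowSums(other_mat < alpha_non_gained, na.rm = TRUE) == 0 &
      !apply(other_mat, 1, anyNA)
  } else {
    rowSums((1 - other_mat) >= alpha) == 0 & !apply(other_mat, 1, anyNA)
  }
  enough <- out$n_gained >= min_per_stratum &
    out$n_not_gained >= min_per_stratum
  out$verdict <- enough & pass_gained & pass_other
  out$partial <- !use_histone
  if ("distance_bp" %in% names(pairs)) {
    out <- left_join(out, pairs, by = c("oncogene_id", "passenger_id"))
  }
  class(out) <- c("allchat", class(out))
  out
}
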