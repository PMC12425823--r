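#' Compute the differentially hypermethylated cytosine ratio (DHcR) per gene
#'
#' The DHcR of a gene in a sample is the number of hypermethylated cytosines
#' among the profiled CpGs of its promoter, divided by that profiled count.
#' Hypermethylation calls come from the chi-squared / 15% FDR caller
#' ([call_dmps_methsig()]); for normal samples the same caller can be run
#' against the element-wise median normal profile (see
#' [median_normal_reference()]). Genes with zero profiled promoter CpGs in a
#' sample are excluded and counted in the `"skip_report"` attribute.
#'
#' @param calls Per-(CpG, sample) tibble with `chrom`, `pos`, `sample_id`
#'   and logical `hyper`; every row counts as a profiled CpG.
#' @param promoters Promoter window tibble.
#' @return Tibble with `gene_id`, `sample_id`, `n_hyper`, `n_profiled`,
#'   `dhcr`.
#' @export
compute_dhcr <- function(calls, promoters) {
  assert_columns(calls, c("chrom", "pos", "sample_id", "hyper"))
  mapped <- map_cpgs_to_promoters(calls, promoters)
  out <- mapped |>
    group_by(.data$gene_id, .data$sample_id) |>
    summarise(
      n_hyper = sum(.data$hyper),
      n_profiled = n(),
      .groups = "drop"
    ) |>
    mutate(dhcr = .data$n_hyper / .data$n_profiled)
  skipped <- setdiff(unique(promoters$gene_id), unique(out$gene_id))
  attr(out, "skip_report") <- tibble(
    gene_id = skipped,
    reason = rep("no_profiled_promoter_cpgs", length(skipped))
  )
  out
}

#' Median normal methylation reference profile
#'
#' Element-wise median methylation rate across the normal samples of a
#' cohort, used as the comparator when computing normal-sample DHcR and as
#' the normal-methylation covariate of [methsig_rank()].
#'
#' @param meth Long methylation tibble.
#' @param samples Sample sheet.
#' @return Tibble with `chrom`, `pos`, `median_rate`, plus pseudo-counts
#'   `meth`/`total` rescaled to the median coverage for count-based tests.
#' @export
median_normal_reference <- function(meth, samples) {
  samples <- validate_samples(samples)
  norm <- filter(samples, .data$tissue == "normal")
  meth |>
    semi_join(norm, by = "sample_id") |>
    group_by(.data$chrom, .data$pos) |>
    summarise(
      median_rate = median(.data$meth / .data$total),
      total = as.integer(round(median(.data$total))),
      .groups = "drop"
    ) |>
    mutate(meth = as.integer(round(.data$median_rate * .data$total)))
}

#' Select the highest-purity tumor sample per patient
#'
#' Deterministic: ties are broken by lexicographic sample id.
#'
#' @param samples Sample sheet.
#' @return The selected tumor sample rows.
#' @export
highest_purity_samples <- function(samples) {
  samples <- validate_samples(samples)
  samples |>
    filter(.data$tissue == "tumor") |>
    arrange(.data$patient_id, dplyr::desc(.data$purity), .data$sample_id) |>
    group_by(.data$patient_id) |>
    slice(1) |>
    ungroup()
}

#' Rank candidate methylation driver genes by observed versus expected DHcR
#'
#' For each selected tumor sample (the highest-purity region per patient), a
#' beta regression models the expected promoter DHcR of every gene from
#' nuisance covariates that predict background hypermethylation propensity
#' (deconvolved promoter PDR, normal promoter methylation, normal
#' expression, promoter CpG count). Each gene then receives a one-sided
#' p-value for its observed DHcR exceeding the fitted expectation under the
#' estimated beta distribution; per-gene p-values are combined across
#' samples with Stouffer's method (equal weights) and adjusted with
#' Benjamini-Hochberg. Genes whose promoter is unprofiled in every sample
#' or with no expression in normal tissue (mean normal counts < 1) are
#' filtered out beforehand.
#'
#' @param dhcr Output of [compute_dhcr()] for tumor samples.
#' @param covariates Per-gene tibble of covariates; column `gene_id` plus
#'   any numeric covariate columns (e.g. `pdr`, `normal_meth`,
#'   `normal_expr`, `n_cpgs`).
#' @param samples Sample sheet; used to select one region per patient.
#' @param normal_expr_filter Genes with `normal_expr` below this value are
#'   filtered out (default 1); set `NULL` to skip.
#' @param fdr FDR threshold recorded on the object (default 0.1).
#' @return Object of class `"methsig"`: a list with `results` (per-gene
#'   tibble with `expected_dhcr`, `observed_dhcr`, `p_combined`, `q`),
#'   `samples_used`, `covariates` and `failed_samples` (beta-regression
#'   non-convergence, flagged not dropped).
#' @export
methsig_rank <- function(dhcr, covariates, samples,
                         normal_expr_filter = 1, fdr = 0.1) {
  assert_columns(dhcr, c("gene_id", "sample_id", "dhcr", "n_profiled"))
  assert_columns(covariates, "gene_id")
  sel <- highest_purity_samples(samples)
  df <- dhcr |>
    semi_join(sel, by = "sample_id") |>
    inner_join(covariates, by = "gene_id")
  if (!is.null(normal_expr_filter) && "normal_expr" %in% names(df)) {
    df <- filter(df, .data$normal_expr >= normal_expr_filter)
  }
  covar_cols <- setdiff(names(covariates), "gene_id")
  if (length(covar_cols) == 0) {
    abort("at least one covariate column is required",
          class = "methevolve_config_error")
  }
  fml <- stats::as.formula(
    paste("dhcr_sq ~", paste(covar_cols, collapse = " + "))
  )

  fit_one <- function(d) {
    # squeeze to the open unit interval for the beta likelihood
    n <- nrow(d)
    d$dhcr_sq <- (d$dhcr * (n - 1) + 0.5) / n
    fit <- tryCatch(
      mgcv::gam(fml, family = mgcv::betar(link = "logit"), data = d),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit)) return(NULL)
    mu <- as.numeric(predict(fit, type = "response"))
    phi <- fit$family$getTheta(TRUE)
    p_one <- 1 - pbeta(d$dhcr_sq, mu * phi, (1 - mu) * phi)
    tibble(gene_id = d$gene_id, sample_id = d$sample_id,
           expected = mu, observed = d$dhcr, p = pmin(pmax(p_one, 1e-15), 1))
  }

  per_sample <- df |>
    dplyr::group_split(.data$sample_id) |>
    purrr::map(fit_one)
  failed <- unique(df$sample_id)[purrr::map_lgl(per_sample, is.null)]
  per_sample <- bind_rows(per_sample)
  if (nrow(per_sample) == 0) {
    abort("beta regression failed in every sample", class = "methevolve_fit_error")
  }
  results <- per_sample |>
    group_by(.data$gene_id) |>
    summarise(
      expected_dhcr = mean(.data$expected),
      observed_dhcr = mean(.data$observed),
      n_samples = n(),
      p_combined = 1 - pnorm(sum(qnorm(1 - .data$p)) / sqrt(n())),
      .groups = "drop"
    ) |>
    mutate(
      p_combined = pmin(pmax(.data$p_combined, .Machine$double.xmin), 1),
      q = p.adjust(.data$p_combined, "BH")
    ) |>
    arrange(.data$q, .data$p_combined)
  structure(
    list(results = results, samples_used = sel$sample_id,
         covariates = covar_cols, failed_samples = failed, fdr = fdr),
    class = "methsig"
  )
}

#' @export
print.methsig <- function(x, ...) {
  cat("<methsig> ", nrow(x$results), " genes, ", length(x$samples_used),
      " samples, ", sum(x$results$q < x$fdr), " significant at q < ",
      x$fdr, "\n", sep = "")
  invisible(x)
}

#' Tidy a methsig driver ranking
#' @param x A `"methsig"` object.
#' @param ... Unused.
#' @return The per-gene results tibble.
#' @export
tidy.methsig <- function(x, ...) x$results

#' One-row summary of a methsig driver ranking
#' @param x A `"methsig"` object.
#' @param ... Unused.
#' @return A one-row tibble with gene/sample counts and significant genes.
#' @export
glance.methsig <- function(x, ...) {
  tibble(
    n_genes = nrow(x$results),
    n_samples = length(x$samples_used),
    n_failed_samples = length(x$failed_samples),
    n_significant = sum(x$results$q < x$fdr),
    fdr = x$fdr
  )
}

#' Assemble the standard covariate table for [methsig_rank()]
#'
#' Builds per-gene covariates: mean deconvolved promoter PDR, mean normal
#' promoter methylation, mean normal expression and profiled promoter CpG
#' count.
#'
#' @param pdr_t Deconvolved PDR tibble (`gene_id`, `pdr_t_hat`), or `NULL`.
#' @param meth Long methylation tibble (for normal methylation).
#' @param samples Sample sheet.
#' @param promoters Promoter windows.
#' @param expression Long expression tibble.
#' @return Covariate tibble keyed by `gene_id`.
#' @export
methsig_covariates <- function(pdr_t, meth, samples, promoters, expression) {
  samples <- validate_samples(samples)
  norm <- filter(samples, .data$tissue == "normal")
  norm_meth <- meth |>
    semi_join(norm, by = "sample_id") |>
    map_cpgs_to_promoters(promoters) |>
    group_by(.data$gene_id) |>
    summarise(normal_meth = mean(.data$meth / .data$total),
              n_cpgs = n_distinct(.data$pos), .groups = "drop")
  norm_expr <- expression |>
    semi_join(norm, by = "sample_id") |>
    group_by(.data$gene_id) |>
    summarise(normal_expr = mean(.data$value), .groups = "drop")
  out <- inner_join(norm_meth, norm_expr, by = "gene_id")
  if (!is.null(pdr_t)) {
    pdr_mean <- pdr_t |>
      group_by(.data$gene_id) |>
      summarise(pdr = mean(.data$pdr_t_hat, na.rm = TRUE), .groups = "drop")
    out <- left_join(out, pdr_mean, by = "gene_id") |>
      mutate(pdr = tidyr::replace_na(.data$pdr, 0))
  }
  out
}
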