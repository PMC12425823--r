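#' Assign promoter DMP CpGs a regulatory / nonregulatory status
#'
#' Across the cohort, a promoter CpG that is hypermethylated in at least
#' one tumor sample is characterized by whether its hypermethylation is
#' associated with reduced expression of the cognate gene: a two-sample
#' t-test compares `log2(expression + 1)` between tumor samples where the
#' CpG is hyper and tumor samples where it is covered but not hyper.
#' The CpG is regulatory when p < `alpha` and the hyper group's mean
#' expression is lower; otherwise nonregulatory. CpGs whose groups are
#' smaller than `min_group` receive a missing assignment and are excluded
#' from downstream denominators.
#'
#' @param dmps Per-sample DMP records ([call_dmps()] output); `status ==
#'   "hyper"` defines hypermethylation events.
#' @param expression Long expression tibble over the same tumor samples.
#' @param promoters Promoter windows (defines the cognate gene of each CpG).
#' @param alpha Significance threshold for the expression t-test (0.05).
#' @param min_group Minimum samples per group (default 2).
#' @return Tibble with `gene_id`, `chrom`, `pos`, `n_hyper_samples`,
#'   `n_covered_samples`, `t_statistic`, `p_value`, `regulatory`
#'   (logical; `NA` when groups are too small).
#' @export
assign_cpg_regulatory_status <- function(dmps, expression, promoters,
                                         alpha = 0.05, min_group = 2) {
  assert_columns(dmps, c("chrom", "pos", "sample_id", "status"))
  assert_columns(expression, c("gene_id", "sample_id", "value"))
  prom_dmps <- map_cpgs_to_promoters(dmps, promoters)
  expr <- mutate(expression, logv = log2(.data$value + 1))

  df <- prom_dmps |>
    inner_join(select(expr, dplyr::all_of(c("gene_id", "sample_id", "logv"))),
               by = c("gene_id", "sample_id")) |>
    mutate(is_hyper = .data$status == "hyper")

  df |>
    group_by(.data$gene_id, .data$chrom, .data$pos) |>
    summarise(
      n_hyper_samples = sum(.data$is_hyper),
      n_covered_samples = n(),
      t_statistic = {
        a <- .data$logv[.data$is_hyper]; b <- .data$logv[!.data$is_hyper]
        if (length(a) >= min_group && length(b) >= min_group) {
          tryCatch(unname(t.test(a, b)$statistic),
                   error = function(e) NA_real_)
        } else NA_real_
      },
      p_value = {
        a <- .data$logv[.data$is_hyper]; b <- .data$logv[!.data$is_hyper]
        if (length(a) >= min_group && length(b) >= min_group) {
          # near-constant data (e.g. identical expression in both groups)
          # carries no regulatory signal
          tryCatch(t.test(a, b)$p.value, error = function(e) 1)
        } else NA_real_
      },
      mean_diff = mean(.data$logv[.data$is_hyper]) -
        mean(.data$logv[!.data$is_hyper]),
      .groups = "drop"
    ) |>
    filter(.data$n_hyper_samples > 0) |>
    mutate(
      regulatory = dplyr::case_when(
        is.na(.data$p_value) ~ NA,
        .data$p_value < alpha & .data$mean_diff < 0 ~ TRUE,
        TRUE ~ FALSE
      )
    )
}

#' Compute the per-gene M_R / M_N regulatory-selection ratio
#'
#' For each gene, hypermethylation events are counted over all covered
#' (CpG, sample) pairs at its promoter DMPs, split by the CpG's
#' regulatory status, and pseudocounted:
#' \deqn{M_R = \frac{\sum H_i R_i + 1}{\sum R_i + 1}, \qquad
#'       M_N = \frac{\sum H_i (1-R_i) + 1}{n - \sum R_i + 1}}
#' where `i` ranges over covered (CpG, sample) pairs, `H_i` indicates a
#' hypermethylation event and `R_i` the CpG's regulatory status. A ratio
#' above 1 suggests preferential hypermethylation of regulatory CpGs
#' (selection for functional silencing). With `mode = "cpg"`, `i` ranges
#' over CpGs and `H_i` indicates hypermethylation in at least one sample.
#' Genes lacking either a regulatory or a nonregulatory CpG are
#' `non_calculable` (ratio missing).
#'
#' @param assignments Output of [assign_cpg_regulatory_status()].
#' @param dmps Per-sample DMP records (provides covered (CpG, sample)
#'   pairs and hyper events).
#' @param mode `"pair"` (default; events indexed by covered (CpG, sample)
#'   pairs) or `"cpg"`.
#' @param subtype Optional label recorded on every row.
#' @return Tibble of class `"mrmn"` with per-gene event counts, `m_r`,
#'   `m_n_ratio`, `ratio`, `log2_ratio`, `calculable`.
#' @export
compute_mrmn <- function(assignments, dmps, mode = c("pair", "cpg"),
                         subtype = NA_character_) {
  mode <- match.arg(mode)
  assert_columns(assignments, c("gene_id", "chrom", "pos", "regulatory"))
  assert_columns(dmps, c("chrom", "pos", "sample_id", "status"))
  asg <- filter(assignments, !is.na(.data$regulatory))
  ev <- dmps |>
    inner_join(select(asg, dplyr::all_of(c("gene_id", "chrom", "pos", "regulatory"))),
               by = c("chrom", "pos"), relationship = "many-to-many") |>
    mutate(h = .data$status == "hyper")
  if (mode == "cpg") {
    ev <- ev |>
      group_by(.data$gene_id, .data$chrom, .data$pos, .data$regulatory) |>
      summarise(h = any(.data$h), .groups = "drop")
  }
  out <- ev |>
    group_by(.data$gene_id) |>
    summarise(
      sum_h_r = sum(.data$h & .data$regulatory),
      sum_r = sum(.data$regulatory),
      sum_h_n = sum(.data$h & !.data$regulatory),
      sum_n = sum(!.data$regulatory),
      .groups = "drop"
    ) |>
    mutate(
      calculable = .data$sum_r > 0 & .data$sum_n > 0,
      m_r = (.data$sum_h_r + 1) / (.data$sum_r + 1),
      m_n_ratio = (.data$sum_h_n + 1) / (.data$sum_n + 1),
      ratio = if_else(.data$calculable, .data$m_r / .data$m_n_ratio, NA_real_),
      log2_ratio = log2(.data$ratio),
      subtype = subtype
    )
  class(out) <- c("mrmn", class(out))
  out
}

#' Test per-gene M_R / M_N deviation from 1
#'
#' An exact conditional test (Fisher) on the 2x2 table of
#' \[hyper, not-hyper\] x \[regulatory, nonregulatory\] event counts, with
#' Benjamini-Hochberg correction across calculable genes (per subtype when
#' present). Genes are classed `gt1` / `lt1` by the direction of the
#' pseudocounted ratio at `q < q_threshold`, `ns` otherwise, and
#' `non_calculable` genes pass through with their class set.
#'
#' @param records Output of [compute_mrmn()].
#' @param q_threshold FDR threshold (default 0.05).
#' @return The records with `p_value`, `q` and
#'   `class` (`gt1` / `lt1` / `ns` / `non_calculable`) added; class
#'   `"mrmn"` preserved.
#' @export
test_mrmn_deviation <- function(records, q_threshold = 0.05) {
  assert_columns(records, c("gene_id", "sum_h_r", "sum_r", "sum_h_n",
                            "sum_n", "ratio", "calculable"))
  calc <- records$calculable
  p <- rep(NA_real_, nrow(records))
  p[calc] <- fisher_2x2_p(
    records$sum_h_r[calc], records$sum_r[calc],
    records$sum_h_n[calc], records$sum_n[calc]
  )
  out <- records
  out$p_value <- p
  grp <- if ("subtype" %in% names(out)) out$subtype else rep(NA, nrow(out))
  out$q <- NA_real_
  for (g in unique(grp)) {
    rows <- (is.na(grp) & is.na(g)) | (!is.na(grp) & !is.na(g) & grp == g)
    rows <- rows & calc
    out$q[rows] <- p.adjust(out$p_value[rows], "BH")
  }
  out$class <- dplyr::case_when(
    !out$calculable ~ "non_calculable",
    out$q < q_threshold & out$ratio > 1 ~ "gt1",
    out$q < q_threshold & out$ratio < 1 ~ "lt1",
    TRUE ~ "ns"
  )
  class(out) <- c("mrmn", class(records))
  out
}

#' Tidy an M_R / M_N result table
#' @param x An `"mrmn"` tibble.
#' @param ... Unused.
#' @return A plain tibble of the per-gene records.
#' @export
tidy.mrmn <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mrmn")
  as_tibble(out)
}

#' One-row summary of an M_R / M_N analysis
#' @param x An `"mrmn"` tibble (after [test_mrmn_deviation()]).
#' @param ... Unused.
#' @return One-row tibble: gene counts per class and the median ratio.
#' @export
glance.mrmn <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_calculable = sum(x$calculable),
    n_gt1 = if ("class" %in% names(x)) sum(x$class == "gt1") else NA_integer_,
    n_lt1 = if ("class" %in% names(x)) sum(x$class == "lt1") else NA_integer_,
    median_ratio = median(x$ratio, na.rm = TRUE)
  )
}

#' Evaluate transfer of regulatory assignments to a validation cohort
#'
#' Assignments discovered in one cohort are frozen and re-evaluated in a
#' second: CpGs whose expression t-test is strictly significant in the
#' discovery cohort (p < `p_strict`, default 1e-4) in either direction
#' (significantly regulatory: lower expression when hyper; significantly
#' nonregulatory: higher) are intersected with the validation cohort and
#' the direction of the validation mean difference is tabulated against
#' the discovery direction.
#'
#' @param discovery Output of [assign_cpg_regulatory_status()] on the
#'   discovery cohort.
#' @param validation Same, on the validation cohort.
#' @param p_strict Strict significance threshold for selecting discovery
#'   CpGs (default 1e-4).
#' @return List with `confusion` (2x2 table of discovery vs validation
#'   direction) and `cpgs` (the per-CpG comparison tibble).
#' @export
mrmn_transfer_report <- function(discovery, validation, p_strict = 1e-4) {
  assert_columns(discovery, c("chrom", "pos", "p_value", "mean_diff"))
  assert_columns(validation, c("chrom", "pos", "mean_diff"))
  strict <- discovery |>
    filter(!is.na(.data$p_value), .data$p_value < p_strict) |>
    mutate(discovery_direction = if_else(.data$mean_diff < 0,
                                         "reduced", "increased")) |>
    select(dplyr::all_of(c("chrom", "pos", "discovery_direction")))
  comp <- strict |>
    inner_join(
      validation |>
        mutate(validation_direction = if_else(.data$mean_diff < 0,
                                              "reduced", "increased")) |>
        select(dplyr::all_of(c("chrom", "pos", "validation_direction"))),
      by = c("chrom", "pos")
    )
  confusion <- table(
    discovery = factor(comp$discovery_direction, c("reduced", "increased")),
    validation = factor(comp$validation_direction, c("reduced", "increased"))
  )
  list(confusion = confusion, cpgs = comp)
}
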