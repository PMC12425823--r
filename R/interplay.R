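#' Build the per-gene, per-region event matrix
#'
#' Combines promoter methylation status with copy-number state at each
#' gene's TSS: relative to sample ploidy, `loss` is `n_t < round(ploidy)`,
#' `amplification` is `n_t >= ploidy + amp_gain` (default gain of 2) and
#' `gain` is anything above `round(ploidy)` that is not an amplification.
#' Genes whose promoter window spans a segment boundary take the copy
#' number at the TSS and are flagged. Optional mutation calls are merged
#' as an additional event column.
#'
#' @param status Promoter status tibble from
#'   [promoter_methylation_status()].
#' @param segments Copy-number segments.
#' @param samples Sample sheet.
#' @param promoters Promoter windows (provides TSS coordinates).
#' @param mutations Optional tibble with `gene_id`, `sample_id` of mutated
#'   genes.
#' @param amp_gain Copies above ploidy defining amplification (default 2).
#' @return Tibble with `gene_id`, `sample_id`, `patient_id` and logical
#'   event columns `hyper`, `hypo`, `loss`, `gain`, `amplification`,
#'   `mutation`, plus `n_t` and `cn_boundary`.
#' @export
classify_gene_events <- function(status, segments, samples, promoters,
                                 mutations = NULL, amp_gain = 2) {
  assert_columns(status, c("gene_id", "sample_id", "status"))
  samples <- validate_samples(samples)
  tum <- filter(samples, .data$tissue == "tumor")
  segments <- validate_segments(segments)

  tss <- select(promoters, dplyr::all_of(c("gene_id", "chrom", "tss",
                                           "window_start", "window_end")))
  df <- status |>
    inner_join(select(tum, dplyr::all_of(c("sample_id", "patient_id", "ploidy"))),
               by = "sample_id") |>
    inner_join(tss, by = "gene_id") |>
    rename(pos = "tss") |>
    lookup_segment_cn(segments)

  # does the promoter window cross the covering segment's boundary?
  seg_at_tss <- status |>
    inner_join(tss, by = "gene_id") |>
    rename(pos = "tss") |>
    inner_join(segments, by = join_by(sample_id, chrom,
                                      between(pos, start, end))) |>
    mutate(cn_boundary = .data$window_start < .data$start |
             .data$window_end > .data$end) |>
    select(dplyr::all_of(c("gene_id", "sample_id", "cn_boundary")))

  df |>
    left_join(seg_at_tss, by = c("gene_id", "sample_id")) |>
    mutate(
      cn_boundary = tidyr::replace_na(.data$cn_boundary, FALSE),
      hyper = .data$status %in% c("hyper", "both"),
      hypo = .data$status %in% c("hypo", "both"),
      loss = !is.na(.data$n_t) & .data$n_t < round(.data$ploidy),
      amplification = !is.na(.data$n_t) & .data$n_t >= .data$ploidy + amp_gain,
      gain = !is.na(.data$n_t) & .data$n_t > round(.data$ploidy) &
        !.data$amplification,
      mutation = if (is.null(mutations)) FALSE else {
        paste(.data$gene_id, .data$sample_id) %in%
          paste(mutations$gene_id, mutations$sample_id)
      }
    ) |>
    select(dplyr::all_of(c("gene_id", "sample_id", "patient_id", "hyper",
                           "hypo", "loss", "gain", "amplification",
                           "mutation", "n_t", "cn_boundary")))
}

#' Classify hypermethylation / copy-number-loss interplay per gene and tumor
#'
#' `double_hit`: promoter hypermethylation and CN loss co-occur in at least
#' one region. `parallel`: hypermethylation and loss each occur in the
#' tumor but never in the same region. `single_mechanism`: only one of the
#' two mechanisms occurs. `other`: events occur (gains, amplifications,
#' mutations, hypomethylation) but neither hypermethylation nor loss.
#' `none`: no events at all. The five categories partition every
#' (gene, patient). The concordant fraction counts regions with
#' hypermethylation + loss, or hypomethylation + gain/amplification, among
#' regions with any event.
#'
#' @param events Output of [classify_gene_events()].
#' @return Tibble with `gene_id`, `patient_id`, `category`,
#'   `concordant_fraction`, `n_regions`.
#' @export
classify_interplay <- function(events) {
  assert_columns(events, c("gene_id", "patient_id", "hyper", "hypo", "loss",
                           "gain", "amplification", "mutation"))
  events |>
    mutate(
      any_event = .data$hyper | .data$hypo | .data$loss | .data$gain |
        .data$amplification | .data$mutation,
      concordant = (.data$hyper & .data$loss) |
        (.data$hypo & (.data$gain | .data$amplification))
    ) |>
    group_by(.data$gene_id, .data$patient_id) |>
    summarise(
      n_regions = n(),
      same_region = any(.data$hyper & .data$loss),
      any_hyper = any(.data$hyper),
      any_loss = any(.data$loss),
      any_other = any(.data$any_event),
      concordant_fraction = if (any(.data$any_event)) {
        sum(.data$concordant) / sum(.data$any_event)
      } else NA_real_,
      .groups = "drop"
    ) |>
    mutate(
      category = dplyr::case_when(
        .data$same_region ~ "double_hit",
        .data$any_hyper & .data$any_loss ~ "parallel",
        xor(.data$any_hyper, .data$any_loss) ~ "single_mechanism",
        .data$any_other ~ "other",
        TRUE ~ "none"
      )
    ) |>
    select(dplyr::all_of(c("gene_id", "patient_id", "category",
                           "concordant_fraction", "n_regions")))
}

#' Time clonal versus subclonal co-occurrence of hypermethylation and loss
#'
#' Uses multi-region ubiquity: for each gene and tumor where both
#' hypermethylation and CN loss occur, the pattern is
#' `clonal_hyper_subclonal_loss` when hypermethylation is ubiquitous
#' (present in every assessable region) while loss is not, and vice versa;
#' `both_clonal` / `both_subclonal` otherwise. Requires at least two
#' assessable regions.
#'
#' @param events Output of [classify_gene_events()].
#' @param samples Sample sheet.
#' @return Tibble with `gene_id`, `patient_id`, `pattern`.
#' @export
call_event_timing <- function(events, samples) {
  assert_columns(events, c("gene_id", "sample_id", "hyper", "loss"))
  ub_h <- compute_ubiquity(
    rename(events, event = "hyper"), samples, feature = "gene_id"
  ) |>
    select(dplyr::all_of(c("gene_id", "patient_id")),
           hyper_frac = "fraction", n_assess = "n_regions_assessable")
  ub_l <- compute_ubiquity(
    rename(events, event = "loss"), samples, feature = "gene_id"
  ) |>
    select(dplyr::all_of(c("gene_id", "patient_id")), loss_frac = "fraction")
  inner_join(ub_h, ub_l, by = c("gene_id", "patient_id")) |>
    mutate(
      pattern = dplyr::case_when(
        .data$n_assess < 2 | .data$hyper_frac == 0 | .data$loss_frac == 0 ~ "na",
        .data$hyper_frac == 1 & .data$loss_frac < 1 ~ "clonal_hyper_subclonal_loss",
        .data$loss_frac == 1 & .data$hyper_frac < 1 ~ "clonal_loss_subclonal_hyper",
        .data$hyper_frac == 1 & .data$loss_frac == 1 ~ "both_clonal",
        TRUE ~ "both_subclonal"
      )
    ) |>
    select(dplyr::all_of(c("gene_id", "patient_id", "pattern")))
}

#' Compare event-timing patterns between two gene sets
#'
#' Tabulates clonal-hypermethylation-first versus clonal-loss-first event
#' counts for two named gene sets and tests the 2x2 table with a
#' chi-squared test without continuity correction, switching to Fisher's
#' exact test (with a message) when any expected cell is below 5.
#'
#' @param timing Output of [call_event_timing()].
#' @param gene_sets Named list of two character vectors of gene ids.
#' @return List of class `"timing_test"`: `table`, `statistic`, `p_value`,
#'   `method`.
#' @export
timing_contingency <- function(timing, gene_sets) {
  if (!is.list(gene_sets) || length(gene_sets) != 2 || is.null(names(gene_sets))) {
    abort("gene_sets must be a named list of two gene-id vectors",
          class = "methevolve_config_error")
  }
  assert_columns(timing, c("gene_id", "pattern"))
  keep <- c("clonal_hyper_subclonal_loss", "clonal_loss_subclonal_hyper")
  counts <- purrr::map(gene_sets, function(gs) {
    t0 <- filter(timing, .data$gene_id %in% gs, .data$pattern %in% keep)
    c(sum(t0$pattern == keep[1]), sum(t0$pattern == keep[2]))
  })
  tab <- matrix(c(counts[[1]], counts[[2]]), nrow = 2, byrow = TRUE,
                dimnames = list(set = names(gene_sets),
                                pattern = c("clonal_hyper_first",
                                            "clonal_loss_first")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    message("expected cell below 5; using Fisher's exact test")
    ft <- stats::fisher.test(tab)
    res <- list(table = tab, statistic = NA_real_, p_value = ft$p.value,
                method = "fisher")
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    res <- list(table = tab, statistic = unname(ct$statistic),
                p_value = ct$p.value, method = "chisq")
  }
  structure(res, class = "timing_test")
}

#' @export
print.timing_test <- function(x, ...) {
  cat("<timing_test>", x$method, "p =", format(x$p_value, digits = 3), "\n")
  print(x$table)
  invisible(x)
}

#' Tidy a timing contingency test
#' @param x A `"timing_test"` object.
#' @param ... Unused.
#' @return One-row tibble with statistic, p-value and method.
#' @export
tidy.timing_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, method = x$method)
}
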