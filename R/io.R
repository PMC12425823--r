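#' Read a Bismark-style coverage file of CpG methylation counts
#'
#' Parses the six-column Bismark coverage dialect (`chrom`, `start`, `end`,
#' percent methylated, methylated count, unmethylated count). The methylation
#' rate is always recomputed from the two count columns; the percent column is
#' ignored, because rounded percentages cannot be trusted to reproduce the
#' counts. Coordinates are 1-based inclusive throughout the package; 0-based
#' half-open input (BED-style starts) is converted here, at the parser
#' boundary, and nowhere else.
#'
#' @param path Path to a tab- or space-separated coverage file. Lines starting
#'   with `#` are treated as comments.
#' @param sample_id Sample identifier attached to every observation.
#' @param zero_based If `TRUE`, interpret the start column as 0-based and add
#'   1 to obtain the CpG cytosine position.
#' @return A tibble with columns `chrom`, `pos`, `sample_id`, `meth`, `total`
#'   and `rate`, one row per CpG.
#' @export
read_bismark_cov <- function(path, sample_id, zero_based = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("file '%s' does not exist", path), class = "methevolve_io_error")
  }
  raw <- suppressWarnings(readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "pct", "meth", "unmeth"),
    col_types = "ciidii",
    comment = "#",
    progress = FALSE
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(
      sprintf("malformed row at line %d of '%s': expected %s",
              probs$row[1], path, probs$expected[1]),
      class = "methevolve_parse_error"
    )
  }
  if (anyNA(raw$meth) || anyNA(raw$unmeth) || any(raw$meth < 0) || any(raw$unmeth < 0)) {
    bad <- which(is.na(raw$meth) | is.na(raw$unmeth) | raw$meth < 0 | raw$unmeth < 0)[1]
    abort(sprintf("invalid counts at line %d of '%s'", bad, path),
          class = "methevolve_validation_error")
  }
  out <- tibble(
    chrom = raw$chrom,
    pos = if (zero_based) raw$start + 1L else raw$start,
    sample_id = sample_id,
    meth = raw$meth,
    total = raw$meth + raw$unmeth
  )
  if (any(out$total < 1)) {
    abort("rows with zero total reads are not valid coverage records",
          class = "methevolve_validation_error")
  }
  if (any(out$pos < 1)) {
    abort("CpG positions must be >= 1", class = "methevolve_validation_error")
  }
  dup <- duplicated(out[, c("chrom", "pos")])
  if (any(dup)) {
    d <- out[dup, ][1, ]
    abort(sprintf("duplicate CpG %s:%d within sample '%s'",
                  d$chrom, d$pos, sample_id),
          class = "methevolve_validation_error")
  }
  mutate(out, rate = .data$meth / .data$total)
}

#' Write methylation observations as a Bismark-style coverage file
#'
#' Inverse of [read_bismark_cov()]: counts round-trip bit-exactly because the
#' rate is derived, not stored.
#'
#' @param meth Tibble with `chrom`, `pos`, `meth`, `total` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bismark_cov <- function(meth, path) {
  assert_columns(meth, c("chrom", "pos", "meth", "total"))
  n_meth <- as.integer(meth$meth)
  n_unmeth <- as.integer(meth$total - meth$meth)
  out <- tibble(
    chrom = meth$chrom,
    start = as.integer(meth$pos),
    end = as.integer(meth$pos),
    pct = 100 * meth$meth / meth$total,
    meth = n_meth,
    unmeth = n_unmeth
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a copy-number segment table
#'
#' Expects tab-separated columns `sample_id`, `chrom`, `start`, `end`, `n_t`
#' and optionally `n_n` (defaults to 2). Coordinates are 1-based inclusive.
#' Segments must be non-overlapping within a sample and chromosome; abutting
#' segments and gaps are allowed, as is `n_t = 0` (homozygous deletion).
#'
#' @param path Path to the segment file (header line required).
#' @return A tibble of segments sorted by sample, chromosome and start.
#' @export
read_segments <- function(path) {
  seg <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  assert_columns(seg, c("sample_id", "chrom", "start", "end", "n_t"), arg = path)
  if (!"n_n" %in% names(seg)) seg$n_n <- 2L
  validate_segments(seg)
}

#' Validate an in-memory segment table
#'
#' @param seg Tibble with `sample_id`, `chrom`, `start`, `end`, `n_t`
#'   (and optionally `n_n`).
#' @return The validated, sorted tibble.
#' @export
validate_segments <- function(seg) {
  assert_columns(seg, c("sample_id", "chrom", "start", "end", "n_t"))
  if (!"n_n" %in% names(seg)) seg$n_n <- 2L
  if (any(seg$start > seg$end)) {
    abort("segment with start > end", class = "methevolve_validation_error")
  }
  if (any(seg$n_t < 0)) {
    abort("tumor copy number n_t must be >= 0", class = "methevolve_validation_error")
  }
  seg <- arrange(seg, .data$sample_id, .data$chrom, .data$start)
  overlap <- seg |>
    group_by(.data$sample_id, .data$chrom) |>
    mutate(prev_end = lag(.data$end), prev_start = lag(.data$start)) |>
    ungroup() |>
    filter(!is.na(.data$prev_end), .data$start <= .data$prev_end)
  if (nrow(overlap) > 0) {
    o <- overlap[1, ]
    abort(
      sprintf("overlapping segments in sample '%s' on %s: [%d, %d] and [%d, %d]",
              o$sample_id, o$chrom, o$prev_start, o$prev_end, o$start, o$end),
      class = "methevolve_validation_error"
    )
  }
  select(seg, dplyr::all_of(c("sample_id", "chrom", "start", "end", "n_t", "n_n")))
}

#' Read a gene-by-sample expression matrix into long form
#'
#' @param path Tab-separated file whose first column is `gene_id` and whose
#'   remaining columns are samples.
#' @param unit Expression unit label (`"counts"`, `"TPM"` or `"RSEM"`),
#'   recorded as an attribute.
#' @return A long tibble with `gene_id`, `sample_id`, `value`.
#' @export
read_expression <- function(path, unit = c("counts", "TPM", "RSEM")) {
  unit <- match.arg(unit)
  wide <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (names(wide)[1] != "gene_id") names(wide)[1] <- "gene_id"
  long <- tidyr::pivot_longer(wide, -"gene_id",
                              names_to = "sample_id", values_to = "value")
  if (any(long$value < 0, na.rm = TRUE)) {
    abort("expression values must be non-negative",
          class = "methevolve_validation_error")
  }
  attr(long, "unit") <- unit
  long
}

#' Read a sample metadata sheet
#'
#' Expects columns `sample_id`, `patient_id`, `region_id`, `tissue`
#' (`tumor`/`normal`), `purity`, `ploidy` and optionally `histology`. Purity
#' must lie in (0, 1] for tumor samples and may be missing for normals; at
#' most one normal sample per patient is permitted (it serves as the
#' matched-normal reference).
#'
#' @param path Tab-separated file with a header.
#' @return A validated tibble.
#' @export
read_samples <- function(path) {
  s <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  validate_samples(s)
}

#' Validate an in-memory sample sheet
#' @param samples Sample metadata tibble; see [read_samples()].
#' @return The validated tibble.
#' @export
validate_samples <- function(samples) {
  assert_columns(samples, c("sample_id", "patient_id", "region_id", "tissue",
                            "purity", "ploidy"))
  if (!all(samples$tissue %in% c("tumor", "normal"))) {
    abort("tissue must be 'tumor' or 'normal'", class = "methevolve_validation_error")
  }
  tum <- samples[samples$tissue == "tumor", ]
  if (anyNA(tum$purity) || any(tum$purity <= 0 | tum$purity > 1)) {
    abort("tumor purity must lie in (0, 1]", class = "methevolve_validation_error")
  }
  n_norm <- samples |>
    filter(.data$tissue == "normal") |>
    count(.data$patient_id)
  if (any(n_norm$n > 1)) {
    abort(sprintf("patient '%s' has more than one normal reference sample",
                  n_norm$patient_id[which(n_norm$n > 1)[1]]),
          class = "methevolve_validation_error")
  }
  samples
}

#' Compute strand-aware promoter windows around TSS coordinates
#'
#' The promoter of a gene spans 2,500 bp upstream through 250 bp downstream
#' of its TSS in transcription orientation, so every window is exactly
#' 2,751 bp long: `[tss - 2500, tss + 250]` on the plus strand and
#' `[tss - 250, tss + 2500]` on the minus strand.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `tss`, `strand`.
#' @param upstream,downstream Window extent in bp (defaults 2500 and 250).
#' @return The input with `window_start`, `window_end` columns added.
#' @export
promoter_windows <- function(genes, upstream = 2500, downstream = 250) {
  assert_columns(genes, c("gene_id", "chrom", "tss", "strand"))
  if (anyNA(genes$strand) || !all(genes$strand %in% c("+", "-"))) {
    abort("every promoter needs a strand of '+' or '-'",
          class = "methevolve_validation_error")
  }
  genes |>
    mutate(
      window_start = if_else(.data$strand == "+",
                             .data$tss - upstream, .data$tss - downstream),
      window_end = if_else(.data$strand == "+",
                           .data$tss + downstream, .data$tss + upstream)
    )
}

#' Read TSS annotation from a BED6 file and derive promoter windows
#'
#' BED is 0-based half-open; the TSS is taken as `start + 1` on the plus
#' strand and `end` on the minus strand, converting to the package's 1-based
#' inclusive convention at this boundary.
#'
#' @param path BED6 file (`chrom`, `start`, `end`, `name`, `score`, `strand`).
#' @inheritParams promoter_windows
#' @return A promoter tibble with `gene_id`, `chrom`, `tss`, `strand`,
#'   `window_start`, `window_end`.
#' @export
read_promoters <- function(path, upstream = 2500, downstream = 250) {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicnc", comment = "#", progress = FALSE
  )
  genes <- tibble(
    gene_id = bed$name,
    chrom = bed$chrom,
    tss = if_else(bed$strand == "+", bed$start + 1L, as.integer(bed$end)),
    strand = bed$strand
  )
  promoter_windows(genes, upstream = upstream, downstream = downstream)
}

#' Assign CpG sites to the promoter windows that contain them
#'
#' A CpG is assigned to every promoter whose window covers its position, so a
#' site inside two overlapping windows appears under both genes.
#'
#' @param sites Tibble with `chrom`, `pos` (additional columns carried along).
#' @param promoters Promoter tibble from [promoter_windows()] or
#'   [read_promoters()].
#' @return `sites` joined with `gene_id` (one row per site-promoter pair).
#' @export
map_cpgs_to_promoters <- function(sites, promoters) {
  assert_columns(sites, c("chrom", "pos"))
  assert_columns(promoters, c("gene_id", "chrom", "window_start", "window_end"))
  if (!"strand" %in% names(promoters) || anyNA(promoters$strand)) {
    abort("promoters must carry strand information",
          class = "methevolve_validation_error")
  }
  inner_join(
    sites,
    select(promoters, dplyr::all_of(c("gene_id", "chrom", "window_start", "window_end"))),
    by = join_by(chrom, between(pos, window_start, window_end)),
    relationship = "many-to-many"
  ) |>
    select(-"window_start", -"window_end") |>
    relocate("gene_id")
}

#' Drop CpG observations below a minimum read depth
#'
#' @param meth Methylation tibble with a `total` column.
#' @param min_total Minimum total read count (default 10) for a CpG to enter
#'   downstream statistics.
#' @return The filtered tibble; the number of dropped rows is recorded in the
#'   `"n_dropped"` attribute so no row disappears silently.
#' @export
filter_coverage <- function(meth, min_total = 10) {
  assert_columns(meth, "total")
  keep <- meth$total >= min_total
  out <- meth[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
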