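# internal validation helpers shared across modules

assert_columns <- function(df, cols, arg = deparse(substitute(df))) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    abort(
      sprintf(
        "`%s` is missing required column%s: %s",
        arg, if (length(missing_cols) > 1) "s" else "",
        paste0("`", missing_cols, "`", collapse = ", ")
      ),
      class = "methevolve_missing_columns"
    )
  }
  invisible(df)
}

assert_probability <- function(x, name, allow_na = FALSE) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (!allow_na && anyNA(x)) {
    abort(sprintf("`%s` contains missing values", name))
  }
  if (any(bad)) {
    abort(sprintf("`%s` must lie in [0, 1]", name),
          class = "methevolve_range_error")
  }
  invisible(x)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number", name))
  }
  invisible(x)
}

clamp01 <- function(x, eps = 0) pmin(pmax(x, eps), 1 - eps)

# deterministic per-stage substream: one global seed, stages regenerable
# independently; kept below 2^31 so it is a valid integer seed
substream_seed <- function(seed, stage) {
  offsets <- c(
    layout = 11L, rates = 23L, events = 37L, cn = 53L, coverage = 71L,
    counts = 89L, expression = 107L, pdr = 131L, reads = 151L,
    amplicon = 173L, histone = 197L, bootstrap = 211L, samples = 229L
  )
  if (!stage %in% names(offsets)) {
    abort(sprintf("unknown simulation stage '%s'", stage))
  }
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

# two-sided two-proportion z-test without continuity correction, vectorized;
# identical to the 1-df chi-squared test on the 2x2 count table
prop_z_p <- function(x1, n1, x2, n2) {
  p_pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  z <- (x1 / n1 - x2 / n2) / se
  p <- 2 * pnorm(-abs(z))
  # degenerate pooled rate (all 0 or all 1): no evidence against the null
  p[!is.finite(z)] <- 1
  p
}

# vectorized two-sided Fisher exact p for 2x2 tables (minimum-likelihood
# definition, matching stats::fisher.test); deduplicates repeated tables
fisher_2x2_p <- function(x1, n1, x2, n2) {
  if (length(x1) == 0) return(numeric(0))
  key <- paste(x1, n1, x2, n2)
  u <- !duplicated(key)
  ux1 <- x1[u]; un1 <- n1[u]; ux2 <- x2[u]; un2 <- n2[u]
  m <- ux1 + ux2              # first-column margin
  lo <- pmax(0L, m - un2)
  hi <- pmin(un1, m)
  p_obs <- dhyper(ux1, un1, un2, m)
  tol <- 1 + 1e-7
  p <- numeric(length(ux1))
  kmax <- max(hi - lo)
  for (step in 0:kmax) {
    k <- lo + step
    idx <- which(k <= hi)
    if (length(idx) == 0) break
    dk <- dhyper(k[idx], un1[idx], un2[idx], m[idx])
    add <- idx[dk <= p_obs[idx] * tol]
    p[add] <- p[add] + dk[dk <= p_obs[idx] * tol]
  }
  p <- pmin(1, p)
  p[match(key, key[u])]
}

# choose the exact path when any expected cell of the 2x2 is small
small_expected_cells <- function(x1, n1, x2, n2, threshold = 5) {
  m1 <- x1 + x2
  m0 <- (n1 - x1) + (n2 - x2)
  tot <- n1 + n2
  e11 <- n1 * m1 / tot
  e12 <- n1 * m0 / tot
  e21 <- n2 * m1 / tot
  e22 <- n2 * m0 / tot
  pmin(e11, e12, e21, e22) < threshold
}

# tumor-normal count test used by the DMP callers: z-test with exact fallback
tumor_normal_count_p <- function(x1, n1, x2, n2, exact_threshold = 5) {
  p <- prop_z_p(x1, n1, x2, n2)
  ex <- small_expected_cells(x1, n1, x2, n2, exact_threshold)
  if (any(ex)) {
    p[ex] <- fisher_2x2_p(x1[ex], n1[ex], x2[ex], n2[ex])
  }
  p
}
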