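#' Build a 3x3 response contingency table
#'
#' Cross-tabulates paired PERCIST classes from two algorithms over the
#' ordered labels (PMD, SMD, PMR).
#'
#' @param pairs data frame holding the two class columns.
#' @param a,b column names (unquoted) of the row and column classifications;
#'   defaults `response_pe` and `response_lc`, matching [percist_compare()].
#' @param row_method,col_method tags naming the two algorithms.
#' @return A 3x3 integer matrix of class `contingency3` with label dimnames
#'   and `row_method`/`col_method` attributes.
#' @export
build_contingency <- function(pairs, a = response_pe, b = response_lc,
                              row_method = "PE", col_method = "LC") {
  if (nrow(pairs) == 0) abort("`pairs` must be non-empty")
  a <- as_response(rlang::eval_tidy(rlang::enquo(a), pairs))
  b <- as_response(rlang::eval_tidy(rlang::enquo(b), pairs))
  counts <- table(a, b)
  m <- matrix(as.integer(counts), 3, 3,
              dimnames = list(response_levels, response_levels))
  as_contingency(m, row_method = row_method, col_method = col_method)
}

#' Wrap a printed 3x3 table as a contingency object
#'
#' @param counts 3x3 non-negative integer matrix, rows and columns ordered
#'   (PMD, SMD, PMR).
#' @param row_method,col_method algorithm tags.
#' @return A `contingency3` matrix.
#' @export
as_contingency <- function(counts, row_method = "PE", col_method = "LC") {
  counts <- as.matrix(counts)
  if (!identical(dim(counts), c(3L, 3L)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    abort("`counts` must be a 3x3 matrix of non-negative integers")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(response_levels, response_levels)
  structure(counts, class = c("contingency3", "matrix", "array"),
            row_method = row_method, col_method = col_method)
}

#' @export
print.contingency3 <- function(x, ...) {
  cat(sprintf("<contingency3> rows: %s, columns: %s, n = %d\n",
              attr(x, "row_method"), attr(x, "col_method"), sum(x)))
  print(unclass_contingency(x))
  invisible(x)
}

unclass_contingency <- function(x) {
  attr(x, "row_method") <- NULL
  attr(x, "col_method") <- NULL
  class(x) <- NULL
  x
}

#' @export
tidy.contingency3 <- function(x, ...) {
  m <- unclass_contingency(x)
  tibble(
    row_class = rep(rownames(m), times = 3),
    col_class = rep(colnames(m), each = 3),
    n = as.integer(m)
  )
}

#' Cohen's kappa for a 3x3 contingency table
#'
#' Chance-corrected agreement `kappa = (Po - Pe) / (1 - Pe)` with
#' `Po = trace/total` and `Pe = sum_i row_i * col_i / total^2`. Unweighted by
#' default; linear weights are available behind `weighted` for ordinal use.
#'
#' @param t a `contingency3` (or plain 3x3 matrix, rows/columns in the same
#'   label order).
#' @param weighted use linear disagreement weights.
#' @return The kappa value; `NaN` with a warning when expected agreement is
#'   1 (all mass in one cell).
#' @export
#' @examples
#' cohens_kappa(as_contingency(diag(c(10, 10, 10))))  # 1
cohens_kappa <- function(t, weighted = FALSE) {
  m <- unclass_contingency(as_contingency(t))
  total <- sum(m)
  if (total == 0) abort("empty table")
  rm_ <- rowSums(m); cm_ <- colSums(m)
  if (!weighted) {
    po <- sum(diag(m)) / total
    pe <- sum(rm_ * cm_) / total^2
    if (1 - pe < .Machine$double.eps * 8) {
      warn("expected agreement is 1; kappa undefined")
      return(NaN)
    }
    return((po - pe) / (1 - pe))
  }
  k <- nrow(m)
  wd <- abs(outer(seq_len(k), seq_len(k), `-`)) / (k - 1)
  obs <- sum(wd * m) / total
  exp_ <- sum(wd * outer(rm_, cm_)) / total^2
  if (exp_ < .Machine$double.eps * 8) {
    warn("expected disagreement is 0; weighted kappa undefined")
    return(NaN)
  }
  1 - obs / exp_
}

#' Wilcoxon signed-rank test on paired ordinal codes
#'
#' Signed-rank test on the differences `b - a` of ordinal response codes
#' (PMD = 1, SMD = 2, PMR = 3). Zero differences are discarded by default;
#' the Pratt policy ranks them first and then drops their ranks. The normal
#' approximation applies the tie correction and no continuity correction;
#' exact mode enumerates all 2^n sign assignments (discard policy only,
#' n <= 25). The policy used is always recorded in the output.
#'
#' @param a,b integer ordinal codes (or PMD/SMD/PMR factors/strings).
#' @param zero_policy `"discard"` (default) or `"pratt"`.
#' @param mode `"normal"` (tie-corrected approximation, default) or
#'   `"exact"`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A one-row tibble: `statistic` (W+, the positive-rank sum), `z`
#'   (normal mode), `p_value`, `n_used`, `n_zero`, `zero_policy`, `mode`,
#'   `alternative`, `note`.
#' @export
wilcoxon_ordinal <- function(a, b, zero_policy = c("discard", "pratt"),
                             mode = c("normal", "exact"),
                             alternative = c("two.sided", "less", "greater")) {
  zero_policy <- match.arg(zero_policy)
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  a <- code_ordinal(a); b <- code_ordinal(b)
  if (length(a) != length(b) || length(a) < 1) {
    abort("`a` and `b` must be equal-length, non-empty")
  }
  d <- b - a
  n_zero <- sum(d == 0)
  if (all(d == 0) && zero_policy == "discard") {
    return(tibble(statistic = NA_real_, z = NA_real_, p_value = 1,
                  n_used = 0L, n_zero = n_zero, zero_policy = zero_policy,
                  mode = mode, alternative = alternative,
                  note = "all differences zero"))
  }
  if (zero_policy == "discard") {
    dnz <- d[d != 0]
    r <- rank(abs(dnz))
    wpos <- sum(r[dnz > 0])
    n <- length(dnz)
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
  } else {
    r <- rank(abs(d))
    wpos <- sum(r[d > 0])
    n <- length(d)
    z0 <- n_zero
    mu <- (n * (n + 1) - z0 * (z0 + 1)) / 4
    ties <- table(r[d != 0])
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      z0 * (z0 + 1) * (2 * z0 + 1) / 24 -
      sum(ties^3 - ties) / 48
  }
  if (mode == "exact") {
    if (zero_policy != "discard") {
      abort("exact mode supports the discard policy only")
    }
    dnz <- d[d != 0]
    n <- length(dnz)
    if (n > 25) abort("exact mode limited to n <= 25 nonzero differences")
    r <- rank(abs(dnz))
    dist <- exact_signed_rank_dist(r)
    p_ge <- sum(dist$prob[dist$w >= wpos - 1e-9])
    p_le <- sum(dist$prob[dist$w <= wpos + 1e-9])
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_ge, p_le)),
      greater = p_ge,
      less = p_le
    )
    return(tibble(statistic = wpos, z = NA_real_, p_value = p,
                  n_used = as.integer(n), n_zero = n_zero,
                  zero_policy = zero_policy, mode = mode,
                  alternative = alternative, note = NA_character_))
  }
  if (sigma2 <= 0) {
    return(tibble(statistic = wpos, z = NA_real_, p_value = 1,
                  n_used = as.integer(n), n_zero = n_zero,
                  zero_policy = zero_policy, mode = mode,
                  alternative = alternative,
                  note = "zero variance after ties/zeros"))
  }
  z <- (wpos - mu) / sqrt(sigma2)
  p <- switch(alternative,
    two.sided = 2 * pnorm(-abs(z)),
    greater = pnorm(z, lower.tail = FALSE),
    less = pnorm(z)
  )
  tibble(statistic = wpos, z = z, p_value = min(1, p),
         n_used = as.integer(n), n_zero = n_zero,
         zero_policy = zero_policy, mode = mode, alternative = alternative,
         note = NA_character_)
}

code_ordinal <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  as.numeric(as_response(x))
}

# Exact null distribution of the positive-rank sum for given ranks: all 2^n
# equiprobable sign assignments, accumulated by convolution.
exact_signed_rank_dist <- function(ranks) {
  w <- 0
  prob <- 1
  for (r in ranks) {
    w2 <- c(w, w + r)
    p2 <- c(prob, prob) / 2
    agg <- tapply(p2, w2, sum)
    w <- as.numeric(names(agg))
    prob <- as.numeric(agg)
  }
  list(w = w, prob = prob)
}

#' Concordance report for a response contingency table
#'
#' Summarises agreement between two PERCIST classifications: observed and
#' expected agreement, Cohen's kappa, discordant counts, and the
#' signed-rank test on the paired ordinal classes reconstructed from the
#' table cells.
#'
#' @param t a `contingency3`.
#' @param ... passed to [wilcoxon_ordinal()] (e.g. `zero_policy`).
#' @return A one-row tibble: `n`, `kappa`, `observed_agreement`,
#'   `expected_agreement`, `discordant_n`, `discordant_pct`, `wilcoxon_z`,
#'   `wilcoxon_p`, `wilcoxon_policy`.
#' @export
concordance_report <- function(t, ...) {
  t <- as_contingency(t)
  m <- unclass_contingency(t)
  total <- sum(m)
  po <- sum(diag(m)) / total
  pe <- sum(rowSums(m) * colSums(m)) / total^2
  # expand cells back to pair-level ordinal codes for the signed-rank test
  idx <- which(m > 0, arr.ind = TRUE)
  codes_a <- rep(idx[, 1], times = m[idx])
  codes_b <- rep(idx[, 2], times = m[idx])
  wx <- wilcoxon_ordinal(codes_a, codes_b, ...)
  disc <- total - sum(diag(m))
  tibble(
    n = total,
    kappa = cohens_kappa(t),
    observed_agreement = po,
    expected_agreement = pe,
    discordant_n = as.integer(disc),
    discordant_pct = 100 * disc / total,
    wilcoxon_z = wx$z,
    wilcoxon_p = wx$p_value,
    wilcoxon_policy = paste(wx$zero_policy, wx$mode, sep = "/")
  )
}

#' Paired t comparison of two LBM series
#'
#' Standard two-sided paired t test, as used to compare each LBM algorithm
#' against the whole-body CT reference.
#'
#' @param a,b equal-length numeric vectors (kg).
#' @return A one-row tibble: `mean_diff`, `t`, `df`, `p_value`, `n`.
#' @export
paired_comparison <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    abort("`a` and `b` must be equal-length with n >= 2")
  }
  d <- a - b
  if (sd(d) == 0) {
    abort("zero-variance differences: paired t undefined",
          class = "lbmct_degenerate_error")
  }
  tt <- t.test(a, b, paired = TRUE)
  tibble(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         n = length(a))
}

#' Bland-Altman agreement analysis
#'
#' Differences `method - reference` summarised as bias (mean difference) and
#' 95% limits of agreement `bias +/- 1.96 * SD` (sample SD), the universal
#' convention for method-comparison plots.
#'
#' @param method,reference equal-length numeric vectors (kg).
#' @return An object of class `bland_altman`: list with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, and `$data` (per-pair means and
#'   differences, for plotting). [tidy()], [glance()] and [autoplot()]
#'   methods apply.
#' @export
bland_altman <- function(method, reference) {
  if (length(method) != length(reference) || length(method) < 2) {
    abort("`method` and `reference` must be equal-length with n >= 2")
  }
  d <- method - reference
  bias <- mean(d)
  s <- sd(d)
  structure(
    list(bias = bias, sd_diff = s,
         loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         n = length(d),
         data = tibble(mean = (method + reference) / 2, diff = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d; bias %.3f; limits of agreement [%.3f, %.3f]\n",
    x$n, x$bias, x$loa_low, x$loa_high
  ))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) x$data

#' @export
glance.bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high, n = x$n)
}

#' Discordance concentration near the response threshold
#'
#' PERCIST discordance between two LBM algorithms can only arise where the
#' percent change sits close to the +/-30% decision boundary, because the
#' two SUL scales differ by a bounded LBM ratio. This analysis counts, for
#' each half-width `w`, the patients whose percent change (under the
#' reference algorithm) lies within `w` points of either threshold
#' (`| |pc| - threshold | <= w`, edges inclusive), and the discordant
#' fraction among them; consecutive half-widths also yield shell (annulus)
#' rows.
#'
#' @param results data frame with `percent_change_pe` and either a logical
#'   `discordant` column or both `response_pe` and `response_lc` (as from
#'   [percist_compare()]).
#' @param band_half_widths positive half-widths in percent-points;
#'   default `c(5, 10)`.
#' @param threshold_pct the classification threshold; default 30.
#' @return A tibble with one row per band and shell: `band`, `half_width`,
#'   `n_in_band`, `n_discordant`, `discordant_fraction` (percent).
#' @export
threshold_band_analysis <- function(results, band_half_widths = c(5, 10),
                                    threshold_pct = 30) {
  if (any(band_half_widths <= 0)) abort("half-widths must be positive")
  if (!"percent_change_pe" %in% names(results)) {
    abort("`results` needs a `percent_change_pe` column")
  }
  disc <- if ("discordant" %in% names(results)) {
    results$discordant
  } else if (all(c("response_pe", "response_lc") %in% names(results))) {
    as_response(results$response_pe) != as_response(results$response_lc)
  } else {
    abort("`results` needs `discordant` or both response columns")
  }
  dist <- abs(abs(results$percent_change_pe) - threshold_pct)
  ws <- sort(unique(band_half_widths))
  band_row <- function(label, width, inside) {
    n <- sum(inside)
    k <- sum(inside & disc)
    tibble(band = label, half_width = width, n_in_band = as.integer(n),
           n_discordant = as.integer(k),
           discordant_fraction = if (n > 0) 100 * k / n else 0)
  }
  rows <- purrr::map2(ws, seq_along(ws), function(w, i) {
    band_row(sprintf("within_%g", w), w, dist <= w)
  })
  shells <- purrr::map(seq_along(ws)[-1], function(i) {
    band_row(sprintf("shell_%g_%g", ws[i - 1], ws[i]), ws[i],
             dist > ws[i - 1] & dist <= ws[i])
  })
  bind_rows(c(rows, shells))
}

#' Summary fractions from printed band counts
#'
#' Turns externally tabulated band counts (n patients in a band, n of them
#' discordant) into the same report rows as [threshold_band_analysis()].
#'
#' @param bands data frame with columns `band`, `n_in_band`, `n_discordant`.
#' @return The input with a `discordant_fraction` column (percent).
#' @export
band_fractions <- function(bands) {
  if (any(bands$n_discordant > bands$n_in_band)) {
    abort("`n_discordant` cannot exceed `n_in_band`")
  }
  mutate(bands, discordant_fraction = ifelse(
    .data$n_in_band > 0, 100 * .data$n_discordant / .data$n_in_band, 0
  ))
}
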