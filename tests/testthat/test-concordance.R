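# 3x3 response table published for the 241-patient dual-algorithm comparison
published_counts <- matrix(c(41, 6, 0,
                             12, 65, 5,
                             0, 4, 108), 3, 3, byrow = TRUE)

expand_pairs <- function(counts) {
  idx <- which(counts > 0, arr.ind = TRUE)
  tibble::tibble(
    response_pe = rep(c("PMD", "SMD", "PMR")[idx[, 1]], counts[idx]),
    response_lc = rep(c("PMD", "SMD", "PMR")[idx[, 2]], counts[idx])
  )
}

test_that("contingency construction counts pairs with correct margins", {
  pairs <- expand_pairs(published_counts)
  tab <- build_contingency(pairs)
  expect_equal(unclass(tab)[1:9], as.vector(published_counts))
  expect_equal(unname(rowSums(tab)), c(47, 82, 112))
  expect_equal(unname(colSums(tab)), c(53, 75, 113))
  expect_equal(sum(tab), 241)

  all_same <- tibble::tibble(response_pe = c("PMR", "PMR"),
                             response_lc = c("PMR", "PMR"))
  t2 <- build_contingency(all_same)
  expect_equal(sum(diag(t2)), 2)
  expect_equal(sum(t2) - sum(diag(t2)), 0)

  one <- build_contingency(tibble::tibble(response_pe = "PMR",
                                          response_lc = "PMD"))
  expect_equal(unclass(one)["PMR", "PMD"], 1L)
  expect_equal(sum(one), 1)
})

test_that("Cohen's kappa handles perfect, chance and degenerate agreement", {
  expect_equal(cohens_kappa(as_contingency(diag(c(10, 10, 10)))), 1.0)
  expect_equal(cohens_kappa(as_contingency(matrix(4, 3, 3))), 0.0)
  expect_warning(
    k <- cohens_kappa(as_contingency(matrix(c(5, rep(0, 8)), 3, 3))),
    "undefined"
  )
  expect_true(is.nan(k))
})

test_that("kappa matches a first-principles oracle on random tables", {
  oracle_kappa <- function(m) {
    total <- sum(m)
    po <- 0; pe <- 0
    for (i in 1:3) {
      po <- po + m[i, i] / total
      pe <- pe + (sum(m[i, ]) / total) * (sum(m[, i]) / total)
    }
    (po - pe) / (1 - pe)
  }
  set.seed(14)
  for (rep in 1:50) {
    m <- matrix(rpois(9, 3), 3, 3)
    if (sum(m) == 0) next
    pe <- sum(rowSums(m) * colSums(m)) / sum(m)^2
    if (pe >= 1 - 1e-12) next
    expect_equal(cohens_kappa(as_contingency(m)), oracle_kappa(m),
                 tolerance = 1e-12)
  }
})

test_that("kappa is invariant to transposition and simultaneous relabeling", {
  set.seed(15)
  for (rep in 1:10) {
    m <- matrix(rpois(9, 4) + 1, 3, 3)
    k <- cohens_kappa(as_contingency(m))
    expect_equal(cohens_kappa(as_contingency(t(m))), k, tolerance = 1e-12)
    p <- sample(3)
    expect_equal(cohens_kappa(as_contingency(m[p, p])), k,
                 tolerance = 1e-12)
  }
})

test_that("weighted kappa is available and degrades to sensible values", {
  expect_equal(cohens_kappa(as_contingency(diag(c(5, 5, 5))),
                            weighted = TRUE), 1.0)
  # one-step disagreements are penalised less than two-step ones
  near <- as_contingency(matrix(c(8, 2, 0, 2, 8, 2, 0, 2, 8), 3, 3))
  far <- as_contingency(matrix(c(8, 0, 2, 0, 8, 2, 2, 2, 8), 3, 3))
  expect_gt(cohens_kappa(near, weighted = TRUE),
            cohens_kappa(far, weighted = TRUE))
})

test_that("signed-rank normal approximation matches the hand computation for
           the published discordance pattern", {
  # 11 upgrades (+1), 16 downgrades (-1), 214 ties
  a <- c(rep(1, 11), rep(2, 16), rep(1, 214))
  b <- c(rep(2, 11), rep(1, 16), rep(1, 214))
  res <- wilcoxon_ordinal(a, b)
  # W+ = 11 * 14 (all |d| = 1 share mean rank 14 of 27)
  expect_equal(res$statistic, 11 * 14)
  mu <- 27 * 28 / 4
  sigma2 <- 27 * 28 * 55 / 24 - (27^3 - 27) / 48
  expect_equal(res$z, (154 - mu) / sqrt(sigma2), tolerance = 1e-12)
  expect_equal(res$z, -0.9623, tolerance = 1e-4)
  expect_equal(res$p_value, 2 * pnorm(res$z), tolerance = 1e-12)
  expect_equal(res$n_used, 27L)
  expect_identical(res$zero_policy, "discard")
})

test_that("exact signed-rank mode reproduces closed-form and enumerated
           distributions", {
  res <- wilcoxon_ordinal(rep(1, 5), rep(2, 5), mode = "exact",
                          alternative = "greater")
  expect_equal(res$p_value, 1 / 32)

  # full 2^n sign enumeration oracle, n <= 10, tie-free magnitudes
  set.seed(16)
  for (rep in 1:6) {
    n <- sample(4:10, 1)
    d <- sample(c(-1, 1), n, replace = TRUE) * sample(seq_len(20), n)
    a <- rep(0, n); b <- d
    res <- wilcoxon_ordinal(a, b, mode = "exact")
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- signs %*% r
    p_ge <- mean(w_all >= w_obs); p_le <- mean(w_all <= w_obs)
    expect_equal(res$p_value, min(1, 2 * min(p_ge, p_le)))
    # and against the standard exact implementation on tie-free data
    ref <- stats::wilcox.test(b, a, paired = TRUE, exact = TRUE)
    expect_equal(res$p_value, ref$p.value)
  }
})

test_that("degenerate signed-rank inputs are reported, not crashed", {
  res <- wilcoxon_ordinal(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$p_value, 1)
  expect_identical(res$note, "all differences zero")
  prat <- wilcoxon_ordinal(c(1, 2, 3), c(1, 2, 3), zero_policy = "pratt")
  expect_equal(prat$p_value, 1)
})

test_that("the concordance report ties the pieces together", {
  tab <- as_contingency(published_counts)
  rep_ <- concordance_report(tab)
  expect_equal(rep_$n, 241L)
  expect_equal(rep_$discordant_n, 27L)
  expect_equal(rep_$discordant_pct, 100 * 27 / 241)
  expect_equal(rep_$observed_agreement, (41 + 65 + 108) / 241)
  expect_equal(rep_$kappa, cohens_kappa(tab))
  expect_equal(rep_$wilcoxon_z, -0.9623, tolerance = 1e-4)
  expect_identical(rep_$wilcoxon_policy, "discard/normal")
})

test_that("paired t comparison matches the closed form and rejects zero
           variance", {
  expect_error(paired_comparison(c(1, 2, 3), c(1, 2, 3)),
               class = "lbmct_degenerate_error")
  expect_error(paired_comparison(c(2, 3, 4, 5), c(1, 2, 3, 4)),
               class = "lbmct_degenerate_error")
  d <- c(-1, 0, 1, 2)
  res <- paired_comparison(d, rep(0, 4))
  s <- sqrt(sum((d - 0.5)^2) / 3)
  t_exp <- 0.5 / (s / 2)
  expect_equal(res$t, t_exp, tolerance = 1e-10)
  expect_equal(res$t, 0.7746, tolerance = 1e-4)
  expect_equal(res$df, 3)
  expect_equal(res$p_value, 2 * pt(-t_exp, 3), tolerance = 1e-10)
})

test_that("Bland-Altman bias and limits follow the 1.96 SD convention", {
  ba <- bland_altman(c(-1, 0, 1), c(0, 0, 0))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)

  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$bias, 0); expect_equal(same$loa_high, 0)

  off <- bland_altman(c(3, 4, 5), c(1, 2, 3))
  expect_equal(off$bias, 2)
  expect_equal(c(off$loa_low, off$loa_high), c(2, 2))

  # antisymmetry and limits width
  set.seed(17)
  x <- rnorm(30, 42, 8); y <- x + rnorm(30, 0.5, 1.5)
  expect_equal(bland_altman(x, y)$bias, -bland_altman(y, x)$bias)
  g <- glance(bland_altman(x, y))
  expect_equal(g$loa_high - g$loa_low, 3.92 * g$sd_diff)
})

test_that("threshold-band membership and monotonicity behave as specified", {
  res <- tibble::tibble(
    percent_change_pe = c(-33, -36, -41, 28, 44),
    discordant = c(TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  bands <- threshold_band_analysis(res)
  w5 <- bands[bands$band == "within_5", ]
  w10 <- bands[bands$band == "within_10", ]
  shell <- bands[bands$band == "shell_5_10", ]
  expect_equal(w5$n_in_band, 2L)            # -33 (|3|) and 28 (|2|)
  expect_equal(w10$n_in_band, 3L)           # plus -36 (|6|)
  expect_equal(shell$n_in_band, 1L)
  expect_equal(w5$n_discordant, 1L)
  expect_equal(shell$n_discordant, 1L)
  expect_equal(w5$discordant_fraction, 50)
  # -41 (|11|) is outside both bands
  expect_equal(w10$n_in_band + 2L, nrow(res))
  # band counts monotone in half-width
  many <- threshold_band_analysis(res, band_half_widths = c(2, 5, 8, 12))
  within <- many[startsWith(many$band, "within"), ]
  expect_true(all(diff(within$n_in_band) >= 0))

  none <- threshold_band_analysis(
    tibble::tibble(percent_change_pe = c(-31, 29), discordant = FALSE)
  )
  expect_true(all(none$discordant_fraction == 0))
})
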