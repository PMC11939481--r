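make_metrics_table <- function(n = 60, seed = 1) {
  withr::with_seed(seed, {
    latent <- rnorm(n)
    data.frame(
      fix_time_pct = plogis(0.5 + 0.8 * latent + rnorm(n, 0, 0.3)),
      sacc_time_pct = plogis(-0.5 - 0.6 * latent + rnorm(n, 0, 0.3)),
      blink_per_min = exp(2 - 0.4 * latent + rnorm(n, 0, 0.2)),
      pupil_mean_mm = 4 + 0.3 * latent + rnorm(n, 0, 0.2),
      avg_fixation_ms = 300 + 80 * latent + rnorm(n, 0, 40),
      avg_saccade_ms = 80 - 10 * latent + rnorm(n, 0, 8),
      lane_fix_share = plogis(1 + 0.7 * latent + rnorm(n, 0, 0.4))
    )
  })
}

test_that("standardization centers, scales, and inverts exactly", {
  tab <- make_metrics_table()
  std <- standardize_indicators(tab)
  for (cl in attr(std, "standardized")) {
    expect_lt(abs(mean(std[[cl]])), 1e-12)
    expect_equal(sd(std[[cl]]), 1)
  }
  back <- unstandardize_indicators(std)
  expect_equal(as.data.frame(back), tab, tolerance = 1e-12)
  ## idempotence: standardizing a standardized table changes nothing
  std2 <- standardize_indicators(as.data.frame(std))
  expect_equal(as.data.frame(std2), as.data.frame(std), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("zero-variance indicator columns are dropped with a warning", {
  tab <- make_metrics_table(n = 20)
  tab$constant <- 5
  expect_warning(std <- standardize_indicators(tab), "constant")
  expect_false("constant" %in% names(std))
})

test_that("perfectly correlated indicators collapse to one component", {
  withr::with_seed(3, x <- rnorm(50))
  tab <- data.frame(fix_time_pct = x, avg_fixation_ms = 2 * x + 5)
  pca <- pca_composite_score(tab, indicators = names(tab))
  expect_equal(length(pca$retained), 1L)
  z <- (x - mean(x)) / sd(x)
  expect_equal(cor(pca$composite, z), 1, tolerance = 1e-10)
})

test_that("composite is invariant to column order and indicator units", {
  tab <- make_metrics_table()
  pca <- pca_composite_score(tab)
  perm <- rev(names(tab))
  pca_perm <- pca_composite_score(tab[perm],
                                  indicators = rev(pca$indicators))
  expect_equal(pca_perm$composite, pca$composite, tolerance = 1e-8)
  ## correlation-matrix PCA ignores units
  rescaled <- tab
  rescaled$avg_fixation_ms <- rescaled$avg_fixation_ms * 1000
  rescaled$blink_per_min <- rescaled$blink_per_min / 60
  pca_resc <- pca_composite_score(rescaled)
  expect_equal(pca_resc$composite, pca$composite, tolerance = 1e-10)
})

test_that("retained components correlate positively with fixation time", {
  tab <- make_metrics_table(seed = 9)
  pca <- pca_composite_score(tab)
  Z <- scale(as.matrix(tab[pca$indicators]))
  scores <- Z %*% pca$loadings
  for (r in seq_along(pca$retained)) {
    expect_gt(cor(scores[, r], tab$fix_time_pct), 0)
  }
  expect_gt(cor(pca$composite, tab$fix_time_pct), 0)
})

test_that("independent noise indicators give near-unit eigenvalues", {
  withr::with_seed(11, {
    tab <- as.data.frame(matrix(rnorm(2000 * 4), ncol = 4))
  })
  names(tab) <- c("fix_time_pct", "a", "b", "c")
  pca <- pca_composite_score(tab, indicators = names(tab))
  expect_true(all(abs(pca$eigenvalues - 1) < 0.2))
  ## uncorrelated component scores: composite variance is exactly
  ## sum of weight^2 x eigenvalue
  ev <- pca$eigenvalues[pca$retained]
  expect_equal(var(pca$composite), sum(pca$weights^2 * ev), tolerance = 1e-10)
})

test_that("re-applied scoring parameters reproduce the fitted composites", {
  tab <- make_metrics_table(seed = 13)
  pca <- pca_composite_score(tab)
  expect_equal(apply_attention_pca(pca, tab), pca$composite, tolerance = 1e-12)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scoring_params(pca, path, cuts = c(-0.5, 0.5))
  pca2 <- read_scoring_params(path)
  expect_equal(apply_attention_pca(pca2, tab), pca$composite, tolerance = 1e-6)
})

test_that("equal-frequency categorization balances levels and respects order", {
  expect_equal(as.integer(categorize_attention(1:9)), rep(1:3, each = 3))
  withr::with_seed(4, x <- rnorm(97))
  lev <- categorize_attention(x)
  expect_equal(as.integer(table(lev)), c(33L, 32L, 32L))
  ## higher composite, higher level
  expect_true(all(x[lev == 3] > max(x[lev == 1])))
  ## rank invariance under monotone transformation
  expect_equal(as.integer(categorize_attention(exp(x))), as.integer(lev))
  ## stored cuts re-apply consistently on distinct values
  cuts <- attr(lev, "cuts")
  expect_equal(as.integer(categorize_attention(x, cuts = cuts)),
               as.integer(lev))
})

test_that("heavy ties at tertile boundaries are broken deterministically", {
  x <- rep(c(1, 2), c(5, 4))
  expect_warning(lev <- categorize_attention(x), "ties")
  expect_equal(length(lev), 9L)
  expect_equal(as.integer(table(lev)), c(3L, 3L, 3L))
  expect_identical(suppressWarnings(categorize_attention(x)), lev)
})

test_that("one-way ANOVA screening equals the squared t test for two groups", {
  withr::with_seed(5, {
    tab <- data.frame(
      composite = c(rnorm(15, 0), rnorm(15, 0.8)),
      grp = rep(c("a", "b"), each = 15)
    )
  })
  res <- screen_factors_anova(tab, "grp")
  tt <- t.test(composite ~ grp, data = tab, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA screening has nominal size and good power", {
  reject_null <- vapply(1:400, function(s) {
    withr::with_seed(1000 + s, {
      tab <- data.frame(composite = rnorm(30), grp = rep(c("a", "b", "c"), 10))
    })
    screen_factors_anova(tab, "grp")$p < 0.05
  }, logical(1))
  expect_gt(mean(reject_null), 0.02)
  expect_lt(mean(reject_null), 0.09)

  reject_alt <- vapply(1:150, function(s) {
    withr::with_seed(5000 + s, {
      tab <- data.frame(composite = c(rnorm(20, 0), rnorm(20, 2)),
                        grp = rep(c("a", "b"), each = 20))
    })
    screen_factors_anova(tab, "grp")$p < 0.05
  }, logical(1))
  expect_gt(mean(reject_alt), 0.9)
})

test_that("degenerate ANOVA inputs are rejected or flagged", {
  tab <- data.frame(composite = rnorm(6), grp = "a")
  expect_error(screen_factors_anova(tab, "grp"), "two groups")
  tab2 <- data.frame(composite = rep(c(1, 2), each = 3),
                     grp = rep(c("a", "b"), each = 3))
  expect_warning(screen_factors_anova(tab2, "grp"), "undefined")
})
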