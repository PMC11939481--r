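small_hier_trials <- function(seed = 17, n_cyclists = 6) {
  sim_study(seed = seed, n_cyclists = n_cyclists, attrition_rate = 0)
}

test_that("with alpha = 0 and B = 0 the likelihood reduces to the plain cumulative logit", {
  tr <- small_hier_trials()
  hd <- prepare_hier_data(tr)
  gamma <- c(-0.7, 0.9)
  beta <- c(1.1, 0.4, 1.9)
  params <- list(gamma = gamma, beta = beta, alpha = c(0, 0),
                 B = rep(0, length(hd$groups)))
  plain <- cumlogit_loglik(gamma, beta, hd$y, hd$X)
  expect_equal(hier_loglik(params, hd), plain, tolerance = 1e-12)
})

test_that("hier likelihood matches a naive direct-formula evaluation", {
  tr <- small_hier_trials(seed = 23)
  hd <- prepare_hier_data(tr)
  withr::with_seed(99, {
    for (rep in 1:5) {
      params <- list(
        gamma = sort(rnorm(2, 0, 2)),
        beta = rnorm(3),
        alpha = rnorm(2),
        B = rnorm(length(hd$groups), 0, 0.7)
      )
      naive <- naive_hier_loglik(
        list(gamma = params$gamma, beta = params$beta, alpha = params$alpha,
             B = params$B),
        tr
      )
      expect_equal(hier_loglik(params, hd), naive, tolerance = 1e-12)
    }
  })
})

test_that("a trial whose utility sits on its first threshold has P(F<=1) = 1/2", {
  expect_equal(cumlogit_logprob(1L, matrix(c(0, 3), nrow = 1)), log(0.5),
               tolerance = 1e-12)
})

test_that("non-increasing thresholds yield -Inf with a diagnostic", {
  tr <- small_hier_trials(seed = 29)
  hd <- prepare_hier_data(tr)
  params <- list(gamma = c(1, -1), beta = rep(0, 3), alpha = c(0, 0),
                 B = rep(0, length(hd$groups)))
  ll <- hier_loglik(params, hd)
  expect_identical(as.numeric(ll), -Inf)
  expect_match(attr(ll, "diagnostic"), "thresholds")
})

test_that("a common shift of thresholds and utility leaves probabilities unchanged", {
  withr::with_seed(31, {
    theta <- rnorm(20)
    shift <- rnorm(20, 0, 3)
  })
  g <- c(-1, 0.7)
  p0 <- ordinal_category_probs(theta, g)
  p1 <- ordinal_category_probs(theta + shift, cbind(g[1] + shift, g[2] + shift))
  expect_equal(p1, p0, tolerance = 1e-12)
})

test_that("the tau update's conjugate Gamma posterior matches numerical integration", {
  withr::with_seed(41, B <- rnorm(8, 0, 0.5))
  a0 <- 0.01
  b0 <- 0.01
  J <- length(B)
  ## unnormalized posterior: Gamma(a0, b0) prior x Normal(0, 1/tau) likelihood
  log_post <- function(tau) {
    (a0 - 1) * log(tau) - b0 * tau + sum(dnorm(B, 0, 1 / sqrt(tau), log = TRUE))
  }
  taus <- seq(0.01, 60, by = 0.01)
  dens <- exp(vapply(taus, log_post, numeric(1)))
  dens <- dens / sum(dens * 0.01)
  conj <- dgamma(taus, shape = a0 + J / 2, rate = b0 + sum(B^2) / 2)
  expect_equal(dens, conj, tolerance = 1e-4)
})

test_that("MCMC draws are reproducible under a fixed seed and chain count", {
  tr <- small_hier_trials(seed = 37, n_cyclists = 4)
  f1 <- suppressWarnings(fit_hier_mcmc(tr, n_iter = 80, n_warmup = 80, n_chains = 2, seed = 5))
  f2 <- suppressWarnings(fit_hier_mcmc(tr, n_iter = 80, n_warmup = 80, n_chains = 2, seed = 5))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_hier_mcmc(tr, n_iter = 80, n_warmup = 80, n_chains = 2, seed = 6))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("every retained draw keeps thresholds ordered and tau positive", {
  tr <- small_hier_trials(seed = 43)
  fit <- suppressWarnings(
    fit_hier_mcmc(tr, n_iter = 300, n_warmup = 300, n_chains = 2, seed = 9)
  )
  all_draws <- do.call(rbind, fit$draws)
  expect_true(all(all_draws[, "gamma_2"] > all_draws[, "gamma_1"]))
  expect_true(all(all_draws[, "tau"] > 0))
})

test_that("cyclist thresholds share a common shift: constant spacing, linear in z", {
  tr <- small_hier_trials(seed = 47)
  fit <- suppressWarnings(
    fit_hier_mcmc(tr, n_iter = 200, n_warmup = 200, n_chains = 1, seed = 3)
  )
  all_draws <- do.call(rbind, fit$draws)
  spacing <- all_draws[, "gamma_2"] - all_draws[, "gamma_1"]
  th0 <- threshold_for_cyclist(fit, tr$cyclist[1],
                               z = c(lane_fix_share = 0.5, pupil_cv = 0.1))
  d0 <- attr(th0, "draws")
  expect_equal(unname(d0[, 2] - d0[, 1]), unname(spacing), tolerance = 1e-12)
  ## raising lane fixation by dz shifts both thresholds by alpha * dz per draw
  th1 <- threshold_for_cyclist(fit, tr$cyclist[1],
                               z = c(lane_fix_share = 0.7, pupil_cv = 0.1))
  d1 <- attr(th1, "draws")
  expect_equal(unname(d1[, 1] - d0[, 1]),
               unname(all_draws[, "alpha_lane_fix_share"] * 0.2),
               tolerance = 1e-10)
  ## z = 0 and B = 0 reduce to the base thresholds
  zero <- threshold_for_cyclist(fit, tr$cyclist[1])
  expect_equal(unname(attr(zero, "draws")[, 1] -
                        all_draws[, paste0("B_", tr$cyclist[1])]),
               unname(all_draws[, "gamma_1"]), tolerance = 1e-12)
  expect_error(threshold_for_cyclist(fit, "nobody"), "unknown cyclist")
})

test_that("hier predictions are proper probabilities and flag unseen cyclists", {
  tr <- small_hier_trials(seed = 53)
  fit <- suppressWarnings(
    fit_hier_mcmc(tr, n_iter = 200, n_warmup = 200, n_chains = 1, seed = 4)
  )
  pr <- predict_category_hier(fit, tr)
  expect_true(all(abs(rowSums(pr$probs) - 1) < 1e-12))
  expect_true(all(pr$level %in% 1:3))
  new_trial <- tr[1, ]
  new_trial$cyclist <- 999L
  expect_warning(pr_new <- predict_category_hier(fit, new_trial), "not in fit")
  expect_equal(sum(pr_new$probs), 1, tolerance = 1e-12)
  ## posterior-averaged probabilities also normalise
  pr_post <- predict_category_hier(fit, tr[1:3, ], type = "posterior")
  expect_true(all(abs(rowSums(pr_post$probs) - 1) < 1e-10))
})

test_that("MCMC warns on degenerate inputs", {
  tr <- small_hier_trials(seed = 59)
  tr$attention <- 2L
  expect_error(fit_hier_mcmc(tr, n_iter = 10, n_warmup = 10, n_chains = 1, seed = 1),
               "two observed|degenerate")
  tr2 <- small_hier_trials(seed = 61)
  tr2 <- tr2[tr2$cyclist == tr2$cyclist[1], ]
  expect_error(fit_hier_mcmc(tr2, n_iter = 10, n_warmup = 10, n_chains = 1, seed = 1),
               "two cyclists")
  expect_error(fit_hier_mcmc(small_hier_trials(seed = 63), n_iter = 10,
                             n_warmup = 10, n_chains = 1),
               "seed")
})

test_that("with strong heterogeneity the hierarchical model beats the baseline in-sample", {
  wins <- vapply(1:10, function(r) {
    tr <- sim_study(seed = 800 + r, n_cyclists = 9, attrition_rate = 0,
                    params = true_params(tau = 0.25))
    fit_h <- suppressWarnings(
      fit_hier_mcmc(tr, n_iter = 300, n_warmup = 300, n_chains = 1,
                    seed = 900 + r)
    )
    fit_o <- fit_ordered_logit(tr)
    levs <- sort(unique(tr$attention))
    acc_h <- accuracy(cross_table(tr$attention,
                                  predict_category_hier(fit_h, tr)$level,
                                  levels = levs))
    acc_o <- accuracy(cross_table(tr$attention,
                                  predict_category(fit_o, tr)$level,
                                  levels = levs))
    acc_h > acc_o
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
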