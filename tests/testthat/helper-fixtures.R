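# Shared fixture builders. All synthetic, generated at test time.

# A gaze stream from explicit event runs at a constant sampling interval.
# runs: data.frame(event, n, aoi); pupil values recycled over non-blink samples.
stream_from_runs <- function(runs, dt_ms = 20, pupil = 4) {
  ev <- rep(runs$event, runs$n)
  aoi <- rep(runs$aoi, runs$n)
  n <- length(ev)
  p <- rep_len(pupil, n)
  p[ev == "blink"] <- NA_real_
  data.frame(
    time_ms = (seq_len(n) - 1) * dt_ms,
    event = ev,
    pupil_mm = p,
    aoi = aoi
  )
}

# Small simulated study, defaults shrunk for speed.
sim_study <- function(seed, n_cyclists = 9, attrition_rate = 11 / 108,
                      params = true_params(), moderate_fraction = 0.25) {
  spec <- design_spec(n_cyclists = n_cyclists, attrition_rate = attrition_rate,
                      moderate_fraction = moderate_fraction)
  simulate_trials(generate_design(spec, seed = seed), params, seed = seed + 1L)
}

# Direct simulation from a plain cumulative-logit model (no hierarchy),
# used as truth for parameter-recovery tests.
sim_cumlogit <- function(n, gamma, beta, seed) {
  withr::with_seed(seed, {
    style <- sample(c("aggressive", "conservative"), n, replace = TRUE)
    dens <- sample(c("dense", "sparse", "moderate"), n, replace = TRUE)
    theta <- beta[1] * (style == "conservative") +
      beta[2] * (dens == "sparse") + beta[3] * (dens == "moderate")
    u <- runif(n)
    y <- 1L + (u > plogis(gamma[1] - theta)) + (u > plogis(gamma[2] - theta))
    data.frame(riding_style = style, traffic_density = dens, attention = y)
  })
}

# Naive, independent re-implementation of the hierarchical log-likelihood
# (plain probability-scale arithmetic; the implementation under test works in
# log space).
naive_hier_loglik <- function(params, trials,
                              covariates = c("lane_fix_share", "pupil_cv")) {
  total <- 0
  groups <- sort(unique(trials$cyclist))
  for (i in seq_len(nrow(trials))) {
    r <- trials[i, ]
    theta <- params$beta[1] * (r$riding_style == "conservative") +
      params$beta[2] * (r$traffic_density == "moderate") +
      params$beta[3] * (r$traffic_density == "sparse")
    shift <- sum(params$alpha * unlist(r[covariates])) +
      params$B[match(r$cyclist, groups)]
    g1 <- params$gamma[1] + shift
    g2 <- params$gamma[2] + shift
    p <- c(
      plogis(g1 - theta),
      plogis(g2 - theta) - plogis(g1 - theta),
      1 - plogis(g2 - theta)
    )[r$attention]
    total <- total + log(p)
  }
  total
}
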