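## Hierarchical ordered logistic model with cyclist-specific thresholds:
##
##   logit P(F_ij <= k) = gamma_kj - theta_ij
##   gamma_kj = gamma_k + sum_q alpha_q z_qij + B_j,   B_j ~ N(0, 1/tau)
##   theta_ij = sum_p beta_p x_pij
##
## Both thresholds receive the same covariate + random-effect shift, so their
## ordering (and spacing) is preserved for every cyclist. Estimation is
## Bayesian: vague Normal(0, 10^3) priors on gamma, beta, alpha;
## tau ~ Gamma(0.01, 0.01). Sampling is Metropolis-within-Gibbs: random-walk
## Metropolis blocks for (gamma), (beta), (alpha) and each B_j (the B update
## is vectorised over cyclists, whose full conditionals are independent),
## with step sizes adapted during warmup toward a 0.25-0.45 acceptance rate,
## and a conjugate Gibbs draw for tau given B.

#' Prepare trial records for the hierarchical model
#'
#' Builds the response, dummy-coded fixed-effect design, threshold-covariate
#' matrix and cyclist grouping used by [hier_loglik()] and
#' [fit_hier_mcmc()].
#'
#' @param data data.frame of trial records.
#' @param response ordinal response column (levels `1..K`).
#' @param predictors fixed-effect columns (dummy-coded against `ref`).
#' @param covariates threshold-covariate columns (default lane fixation share
#'   and pupil diameter coefficient of variation).
#' @param group cyclist identifier column.
#' @param ref named list of reference levels for factor predictors.
#' @return an object of class `hier_data`.
#' @export
prepare_hier_data <- function(data,
                              response = "attention",
                              predictors = c("riding_style", "traffic_density"),
                              covariates = c("lane_fix_share", "pupil_cv"),
                              group = "cyclist",
                              ref = list(riding_style = "aggressive",
                                         traffic_density = "dense")) {
  need <- c(response, covariates, group)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  yraw <- data[[response]]
  levels_y <- sort(unique(yraw))
  K <- length(levels_y)
  if (K < 2L) {
    stop("degenerate data: response must have at least two observed categories",
         call. = FALSE)
  }
  if (length(unique(data[[group]])) < 2L) {
    stop("need at least two cyclists", call. = FALSE)
  }
  des <- build_design(data, predictors, ref)
  Z <- as.matrix(data[covariates])
  if (anyNA(Z)) stop("threshold covariates contain missing values", call. = FALSE)
  groups <- sort(unique(data[[group]]))
  structure(
    list(
      y = match(yraw, levels_y),
      X = des$X,
      Z = Z,
      j = match(data[[group]], groups),
      groups = groups,
      K = K,
      response_levels = levels_y,
      predictors = predictors,
      covariates = covariates,
      group = group,
      ref = ref,
      xlevels = des$xlevels
    ),
    class = "hier_data"
  )
}

#' Hierarchical ordered-logit log-likelihood
#'
#' Log-likelihood of trial records under the hierarchical model at a given
#' parameter point, computed with log-space guards so extreme shifts do not
#' underflow; returns `-Inf` (with a diagnostic attribute) if any category
#' probability is non-positive.
#'
#' @param params list with elements `gamma` (increasing `K - 1` vector),
#'   `beta` (matching the design columns of `data`), `alpha` (one per
#'   threshold covariate) and `B` (one per cyclist).
#' @param data a `hier_data` object from [prepare_hier_data()] (or a raw trial
#'   data.frame, which is prepared with default columns).
#' @return scalar log-likelihood.
#' @export
hier_loglik <- function(params, data) {
  if (!inherits(data, "hier_data")) data <- prepare_hier_data(data)
  K <- data$K
  gamma <- params$gamma
  if (length(gamma) != K - 1L) stop("gamma must have K - 1 elements", call. = FALSE)
  if (K > 2L && any(diff(gamma) <= 0)) {
    out <- -Inf
    attr(out, "diagnostic") <- "non-increasing base thresholds"
    return(out)
  }
  if (length(params$B) != length(data$groups)) {
    stop("B must have one element per cyclist", call. = FALSE)
  }
  if (length(params$alpha) != ncol(data$Z)) stop("alpha dimension mismatch", call. = FALSE)
  theta <- drop(data$X %*% params$beta)
  shift <- drop(data$Z %*% params$alpha) + params$B[data$j]
  eta <- matrix(gamma, nrow = length(theta), ncol = K - 1L, byrow = TRUE) +
    shift - theta
  sum(cumlogit_logprob(data$y, eta))
}

## per-cyclist log-likelihood contributions (vector of length J)
hier_loglik_by_group <- function(gamma, beta, alpha, B, hd) {
  theta <- drop(hd$X %*% beta)
  shift <- drop(hd$Z %*% alpha) + B[hd$j]
  eta <- matrix(gamma, nrow = length(theta), ncol = hd$K - 1L, byrow = TRUE) +
    shift - theta
  lp <- cumlogit_logprob(hd$y, eta)
  as.numeric(rowsum(lp, hd$j, reorder = TRUE))
}

## adapt a random-walk scale toward the 0.25-0.45 acceptance window
adapt_scale <- function(scale, rate) {
  factor <- ifelse(rate < 0.10, 0.5,
            ifelse(rate < 0.25, 0.8,
            ifelse(rate > 0.60, 1.6,
            ifelse(rate > 0.45, 1.25, 1))))
  pmax(scale * factor, 1e-6)
}

run_hier_chain <- function(hd, n_iter, n_warmup, seed, init, prior, thin_adapt = 50L) {
  K <- hd$K
  p <- ncol(hd$X)
  Q <- ncol(hd$Z)
  J <- length(hd$groups)
  prior_var <- prior$normal_var
  a0 <- prior$tau_shape
  b0 <- prior$tau_rate

  ## Internal reparameterization: the sampler works with mean-centered
  ## threshold covariates (gamma_c = gamma + alpha' zbar), which decorrelates
  ## the threshold and covariate blocks; draws are stored on the original
  ## scale. The prior is always evaluated on the original-scale parameters.
  zbar <- colMeans(hd$Z)
  hdc <- hd
  hdc$Z <- sweep(hd$Z, 2, zbar)

  beta <- init$beta
  alpha <- init$alpha
  gamma <- init$gamma + sum(alpha * zbar)
  B <- init$B
  tau <- init$tau

  lp_prior1 <- function(v) -sum(v^2) / (2 * prior_var)
  lp_prior <- function(gamma_c, beta, alpha) {
    lp_prior1(gamma_c - sum(alpha * zbar)) + lp_prior1(beta) + lp_prior1(alpha)
  }
  ll_groups <- hier_loglik_by_group(gamma, beta, alpha, B, hdc)
  ll <- sum(ll_groups)

  s_gamma <- 0.2
  s_beta <- 0.2
  s_alpha <- 0.2
  s_B <- rep(0.3, J)
  acc <- list(gamma = 0L, beta = 0L, alpha = 0L, B = rep(0L, J))
  acc_batch <- list(gamma = 0L, beta = 0L, alpha = 0L, B = rep(0L, J))

  total <- n_warmup + n_iter
  nm <- c(paste0("gamma_", seq_len(K - 1)), colnames(hd$X),
          paste0("alpha_", colnames(hd$Z)),
          paste0("B_", hd$groups), "tau")
  draws <- matrix(NA_real_, n_iter, length(nm), dimnames = list(NULL, nm))

  set.seed(seed)
  for (it in seq_len(total)) {
    ## gamma block
    prop <- gamma + stats::rnorm(K - 1, 0, s_gamma)
    if (K == 2L || all(diff(prop) > 0)) {
      llg <- hier_loglik_by_group(prop, beta, alpha, B, hdc)
      lr <- sum(llg) - ll + lp_prior(prop, beta, alpha) -
        lp_prior(gamma, beta, alpha)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        gamma <- prop; ll_groups <- llg; ll <- sum(llg)
        acc$gamma <- acc$gamma + 1L; acc_batch$gamma <- acc_batch$gamma + 1L
      }
    }
    ## beta block
    prop <- beta + stats::rnorm(p, 0, s_beta)
    llg <- hier_loglik_by_group(gamma, prop, alpha, B, hdc)
    lr <- sum(llg) - ll + lp_prior(gamma, prop, alpha) -
      lp_prior(gamma, beta, alpha)
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      beta <- prop; ll_groups <- llg; ll <- sum(llg)
      acc$beta <- acc$beta + 1L; acc_batch$beta <- acc_batch$beta + 1L
    }
    ## alpha block
    prop <- alpha + stats::rnorm(Q, 0, s_alpha)
    llg <- hier_loglik_by_group(gamma, beta, prop, B, hdc)
    lr <- sum(llg) - ll + lp_prior(gamma, beta, prop) -
      lp_prior(gamma, beta, alpha)
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      alpha <- prop; ll_groups <- llg; ll <- sum(llg)
      acc$alpha <- acc$alpha + 1L; acc_batch$alpha <- acc_batch$alpha + 1L
    }
    ## B: full conditionals are independent across cyclists -> vectorised
    propB <- B + stats::rnorm(J, 0, s_B)
    llgB <- hier_loglik_by_group(gamma, beta, alpha, propB, hdc)
    lrB <- (llgB - ll_groups) +
      (stats::dnorm(propB, 0, 1 / sqrt(tau), log = TRUE) -
       stats::dnorm(B, 0, 1 / sqrt(tau), log = TRUE))
    take <- is.finite(lrB) & log(stats::runif(J)) < lrB
    if (any(take)) {
      B[take] <- propB[take]
      ll_groups[take] <- llgB[take]
      ll <- sum(ll_groups)
      acc$B <- acc$B + take
      acc_batch$B <- acc_batch$B + take
    }
    ## tau: conjugate Gibbs given B
    tau <- stats::rgamma(1, shape = a0 + J / 2, rate = b0 + sum(B^2) / 2)

    ## warmup adaptation
    if (it <= n_warmup && it %% thin_adapt == 0L) {
      s_gamma <- adapt_scale(s_gamma, acc_batch$gamma / thin_adapt)
      s_beta <- adapt_scale(s_beta, acc_batch$beta / thin_adapt)
      s_alpha <- adapt_scale(s_alpha, acc_batch$alpha / thin_adapt)
      s_B <- adapt_scale(s_B, acc_batch$B / thin_adapt)
      acc_batch <- list(gamma = 0L, beta = 0L, alpha = 0L, B = rep(0L, J))
    }
    if (it > n_warmup) {
      draws[it - n_warmup, ] <- c(gamma - sum(alpha * zbar), beta, alpha, B, tau)
    }
  }

  list(
    draws = draws,
    acceptance = c(
      gamma = acc$gamma / total, beta = acc$beta / total,
      alpha = acc$alpha / total, B = mean(acc$B) / total
    ),
    scales = list(gamma = s_gamma, beta = s_beta, alpha = s_alpha, B = s_B)
  )
}

## split-chain potential scale reduction factor
split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n <- length(ch)
    h <- n %/% 2
    halves <- c(halves, list(ch[seq_len(h)], ch[(n - h + 1):n]))
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  Bv <- n * stats::var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + Bv / n) / W)
}

## crude initial-sequence effective sample size
ess_basic <- function(chains) {
  x <- unlist(chains)
  n <- length(x)
  v <- stats::var(x)
  if (v <= 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(200L, n - 1L), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  cutoff <- if (length(pos)) pos[1] - 1L else length(ac)
  denom <- 1 + 2 * sum(ac[seq_len(cutoff)])
  max(n / max(denom, 1), 1)
}

#' Fit the hierarchical ordered logistic model by MCMC
#'
#' Metropolis-within-Gibbs sampling of the hierarchical attention model:
#' random-walk Metropolis blocks for the base thresholds, fixed effects,
#' threshold-covariate coefficients and each cyclist's random effect (with
#' step sizes adapted during warmup), and a conjugate
#' `Gamma(0.01 + J/2, 0.01 + sum(B^2)/2)` Gibbs update for the random-effect
#' precision. Draws are reproducible given `seed` and `n_chains`.
#'
#' @param data trial records data.frame, or a prepared `hier_data`.
#' @param n_iter retained iterations per chain (default 5000).
#' @param n_warmup warmup (adaptation) iterations per chain (default 5000).
#' @param n_chains number of chains (default 4).
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param prior list: `normal_var` (prior variance of gamma/beta/alpha,
#'   default `10^3`), `tau_shape`, `tau_rate` (default 0.01, 0.01).
#' @param init optional named list overriding the default initial values
#'   (cumulative-logit fit for gamma/beta; alpha = 0, B = 0, tau = 1).
#' @inheritParams prepare_hier_data
#' @return an object of class `hier_fit`: `draws` (list of per-chain
#'   matrices), `summary` (posterior mean, SD, 2.5/97.5 percentiles, split
#'   Rhat and effective sample size per parameter), `acceptance`, plus the
#'   prepared data description.
#' @export
fit_hier_mcmc <- function(data,
                          response = "attention",
                          predictors = c("riding_style", "traffic_density"),
                          covariates = c("lane_fix_share", "pupil_cv"),
                          group = "cyclist",
                          ref = list(riding_style = "aggressive",
                                     traffic_density = "dense"),
                          n_iter = 5000, n_warmup = 5000, n_chains = 4,
                          seed,
                          prior = list(normal_var = 1e3, tau_shape = 0.01,
                                       tau_rate = 0.01),
                          init = NULL) {
  hd <- if (inherits(data, "hier_data")) data else
    prepare_hier_data(data, response, predictors, covariates, group, ref)
  J <- length(hd$groups)
  if (J < 2L) stop("need at least two cyclists", call. = FALSE)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)

  ## default inits from the non-hierarchical fit
  base_init <- tryCatch({
    df <- data.frame(.y = hd$response_levels[hd$y], check.names = FALSE)
    for (cn in colnames(hd$X)) df[[cn]] <- hd$X[, cn]
    f0 <- fit_ordered_logit(df, response = ".y", predictors = colnames(hd$X),
                            ref = list())
    list(gamma = unname(f0$gamma), beta = unname(f0$beta))
  }, error = function(e) {
    list(gamma = stats::qlogis(seq_len(hd$K - 1) / hd$K), beta = rep(0, ncol(hd$X)))
  })
  init0 <- list(
    gamma = init$gamma %||% base_init$gamma,
    beta = init$beta %||% base_init$beta,
    alpha = init$alpha %||% rep(0, ncol(hd$Z)),
    B = init$B %||% rep(0, J),
    tau = init$tau %||% 1
  )

  chains <- vector("list", n_chains)
  for (c_i in seq_len(n_chains)) {
    ## deterministic jitter so chains start apart but runs are reproducible
    jit <- init0
    if (c_i > 1) {
      jig <- with_seed(seed * 1000L + c_i, stats::rnorm(length(init0$gamma) +
        length(init0$beta) + length(init0$alpha), 0, 0.3))
      k1 <- length(init0$gamma); k2 <- length(init0$beta)
      jit$gamma <- sort(init0$gamma + jig[seq_len(k1)])
      if (hd$K > 2L && any(diff(jit$gamma) <= 0)) jit$gamma <- init0$gamma
      jit$beta <- init0$beta + jig[k1 + seq_len(k2)]
      jit$alpha <- init0$alpha + jig[k1 + k2 + seq_along(init0$alpha)]
    }
    chains[[c_i]] <- run_hier_chain(hd, n_iter, n_warmup,
                                    seed = seed + c_i - 1L,
                                    init = jit, prior = prior)
  }

  draws <- lapply(chains, `[[`, "draws")
  nm <- colnames(draws[[1]])
  all_draws <- do.call(rbind, draws)
  summ <- data.frame(
    term = nm,
    mean = colMeans(all_draws),
    sd = apply(all_draws, 2, stats::sd),
    q2.5 = apply(all_draws, 2, stats::quantile, probs = 0.025),
    q97.5 = apply(all_draws, 2, stats::quantile, probs = 0.975),
    rhat = vapply(nm, function(v) split_rhat(lapply(draws, function(d) d[, v])),
                  numeric(1)),
    ess = vapply(nm, function(v) ess_basic(lapply(draws, function(d) d[, v])),
                 numeric(1)),
    row.names = NULL
  )
  if (any(is.finite(summ$rhat) & summ$rhat > 1.1)) {
    warning("possible non-convergence: split Rhat > 1.1 for ",
            paste(summ$term[is.finite(summ$rhat) & summ$rhat > 1.1],
                  collapse = ", "), call. = FALSE)
  }

  structure(
    list(
      draws = draws,
      summary = summ,
      acceptance = lapply(chains, `[[`, "acceptance"),
      data = hd,
      n_iter = n_iter, n_warmup = n_warmup, n_chains = n_chains, seed = seed,
      prior = prior,
      call = match.call()
    ),
    class = "hier_fit"
  )
}

#' @export
print.hier_fit <- function(x, ...) {
  cat("Hierarchical ordered logistic model (", x$data$K, " levels, n = ",
      length(x$data$y), ", ", length(x$data$groups), " cyclists)\n", sep = "")
  cat(x$n_chains, "chains x", x$n_iter, "retained draws (warmup ",
      x$n_warmup, ")\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' @export
summary.hier_fit <- function(object, ...) object$summary

#' @rdname wald_inference
#' @export
wald_inference.hier_fit <- function(x, z = 1.96, ...) {
  s <- x$summary
  keep <- !grepl("^B_", s$term) & s$term != "tau"
  wald_inference.default(s$mean[keep], s$sd[keep], z = z, term = s$term[keep])
}

#' Posterior thresholds for one cyclist
#'
#' Per-draw cyclist-specific thresholds `gamma_kj = gamma_k + alpha'z + B_j`
#' at a given covariate row, summarised by posterior mean and 95% interval.
#' Because both thresholds share the same shift, their spacing equals
#' `gamma_2 - gamma_1` in every draw.
#'
#' @param fit a `hier_fit`.
#' @param cyclist a cyclist identifier present in the fit.
#' @param z named numeric vector of threshold covariates (defaults to zeros).
#' @return data.frame with one row per threshold: mean, sd, 2.5% and 97.5%
#'   quantiles; per-draw values attached as attribute `"draws"`.
#' @export
threshold_for_cyclist <- function(fit, cyclist, z = NULL) {
  stopifnot(inherits(fit, "hier_fit"))
  hd <- fit$data
  idx <- match(cyclist, hd$groups)
  if (is.na(idx)) stop("unknown cyclist: ", cyclist, call. = FALSE)
  if (is.null(z)) z <- stats::setNames(rep(0, ncol(hd$Z)), colnames(hd$Z))
  z <- z[colnames(hd$Z)]
  if (anyNA(z)) stop("z must name every threshold covariate", call. = FALSE)
  all_draws <- do.call(rbind, fit$draws)
  K <- hd$K
  gcols <- paste0("gamma_", seq_len(K - 1))
  acols <- paste0("alpha_", colnames(hd$Z))
  bcol <- paste0("B_", hd$groups[idx])
  shift <- drop(all_draws[, acols, drop = FALSE] %*% as.numeric(z)) +
    all_draws[, bcol]
  th <- all_draws[, gcols, drop = FALSE] + shift
  out <- data.frame(
    threshold = gcols,
    mean = colMeans(th),
    sd = apply(th, 2, stats::sd),
    q2.5 = apply(th, 2, stats::quantile, probs = 0.025),
    q97.5 = apply(th, 2, stats::quantile, probs = 0.975),
    row.names = NULL
  )
  attr(out, "draws") <- th
  out
}

#' Predict attention categories from a hierarchical fit
#'
#' Plug-in prediction at the posterior means of `(gamma, beta, alpha, B_j)`
#' (the in-sample protocol used for the model accuracy cross-tables), or
#' posterior-averaged category probabilities over all retained draws.
#'
#' @param fit a `hier_fit`.
#' @param newdata trial records; cyclists not present in the fit receive
#'   `B = 0` with a warning.
#' @param type `"plugin"` (default) or `"posterior"` (average probabilities
#'   over draws; slower).
#' @return list with `level` (modal category on the original response coding)
#'   and `probs` (rows sum to 1).
#' @export
predict_category_hier <- function(fit, newdata, type = c("plugin", "posterior")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "hier_fit"))
  hd <- fit$data
  des <- build_design(newdata, hd$predictors, hd$ref, xlevels = hd$xlevels)
  X <- des$X[, colnames(hd$X), drop = FALSE]
  Z <- as.matrix(newdata[hd$covariates])
  jn <- match(newdata[[hd$group]], hd$groups)
  if (anyNA(jn)) {
    warning("cyclist(s) not in fit: random effect set to 0", call. = FALSE)
  }
  K <- hd$K
  gcols <- paste0("gamma_", seq_len(K - 1))
  acols <- paste0("alpha_", colnames(hd$Z))
  bcols <- paste0("B_", hd$groups)

  prob_at <- function(gamma, beta, alpha, B) {
    Bv <- ifelse(is.na(jn), 0, B[ifelse(is.na(jn), 1L, jn)])
    theta <- drop(X %*% beta)
    shift <- drop(Z %*% alpha) + Bv
    thr <- matrix(gamma, nrow = nrow(X), ncol = K - 1, byrow = TRUE) + shift
    ordinal_category_probs(theta, thr)
  }

  if (type == "plugin") {
    s <- fit$summary
    m <- stats::setNames(s$mean, s$term)
    probs <- prob_at(m[gcols], m[colnames(hd$X)], m[acols], m[bcols])
  } else {
    all_draws <- do.call(rbind, fit$draws)
    probs <- 0
    for (i in seq_len(nrow(all_draws))) {
      d <- all_draws[i, ]
      probs <- probs + prob_at(d[gcols], d[colnames(hd$X)], d[acols], d[bcols])
    }
    probs <- probs / nrow(all_draws)
  }
  idx <- max.col(probs, ties.method = "first")
  list(level = hd$response_levels[idx], probs = probs)
}
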