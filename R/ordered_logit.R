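## Standard cumulative-logit (proportional-odds) model, fitted by maximum
## likelihood. Parameterization: logit P(F <= k) = gamma_k - theta with
## theta = sum_p beta_p x_p, so a positive beta pushes probability mass
## toward higher (more focused) attention levels and exp(beta) is the odds
## ratio of higher attention. Thresholds are kept ordered during optimization
## through gamma_k = gamma_1 + cumsum(exp(delta)); the covariance matrix is
## the inverse observed information in the natural (gamma, beta)
## parameterization.

## Build the dummy-coded design matrix (no intercept: location is carried by
## the thresholds). Character/factor predictors are releveled to the supplied
## reference; numeric predictors enter as-is. Dummy columns are named
## "predictor=level".
build_design <- function(data, predictors, ref = list(), xlevels = NULL) {
  cols <- list()
  out_xlevels <- list()
  for (p in predictors) {
    if (!p %in% names(data)) stop("missing predictor column: ", p, call. = FALSE)
    v <- data[[p]]
    if (is.numeric(v)) {
      cols[[p]] <- matrix(v, ncol = 1, dimnames = list(NULL, p))
    } else {
      if (!is.null(xlevels)) {
        levs <- xlevels[[p]]
        if (!all(v %in% levs)) {
          stop("unseen level in predictor ", p, ": ",
               paste(setdiff(unique(v), levs), collapse = ", "), call. = FALSE)
        }
      } else {
        levs <- sort(unique(as.character(v)))
        r <- ref[[p]]
        if (!is.null(r)) {
          if (!r %in% levs) stop("reference level ", r, " absent from ", p, call. = FALSE)
          levs <- c(r, setdiff(levs, r))
        }
      }
      f <- base::factor(as.character(v), levels = levs)
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(p, "=", levs[-1])
      cols[[p]] <- mm
      out_xlevels[[p]] <- levs
    }
  }
  list(X = do.call(cbind, cols), xlevels = out_xlevels)
}

## Log-likelihood and analytic gradient in the natural parameterization
## (gamma_1..gamma_{K-1}, beta).
cumlogit_loglik <- function(gamma, beta, y, X) {
  theta <- if (length(beta)) drop(X %*% beta) else numeric(nrow(X))
  eta <- outer(-theta, rep(1, length(gamma))) +
    matrix(gamma, nrow = length(theta), ncol = length(gamma), byrow = TRUE)
  sum(cumlogit_logprob(y, eta))
}

cumlogit_grad <- function(gamma, beta, y, X) {
  n <- length(y)
  K <- length(gamma) + 1L
  theta <- if (length(beta)) drop(X %*% beta) else numeric(n)
  gmat <- matrix(gamma, n, K - 1, byrow = TRUE)
  eta <- gmat - theta
  Fmat <- cbind(0, stats::plogis(eta), 1)
  fmat <- cbind(0, stats::dlogis(eta), 0)
  p <- Fmat[cbind(seq_len(n), y + 1L)] - Fmat[cbind(seq_len(n), y)]
  p <- pmax(p, .Machine$double.xmin)
  fu <- fmat[cbind(seq_len(n), y + 1L)] # density at upper threshold
  fl <- fmat[cbind(seq_len(n), y)]      # density at lower threshold
  ## d loglik / d gamma_k: +f(eta_k)/p when k == y, -f(eta_k)/p when k == y-1
  dg <- numeric(K - 1)
  for (k in seq_len(K - 1)) {
    dg[k] <- sum(fu[y == k] / p[y == k]) - sum(fl[y == k + 1L] / p[y == k + 1L])
  }
  db <- if (length(beta)) drop(crossprod(X, -(fu - fl) / p)) else numeric(0)
  c(dg, db)
}

#' Fit the standard cumulative-logit attention model
#'
#' Maximum-likelihood fit of the proportional-odds model
#' `logit P(F <= k) = gamma_k - theta`, `theta = sum beta_p x_p`, the
#' non-hierarchical baseline for the attention analysis. Factors are
#' dummy-coded against configurable reference levels (defaults: aggressive
#' riding style and dense traffic carry coefficient 0).
#'
#' @param data data.frame of trial records.
#' @param response name of the ordinal response column (integer levels
#'   `1..K`; default `"attention"`).
#' @param predictors names of predictor columns (default riding style and
#'   traffic density).
#' @param ref named list of reference levels for factor predictors.
#' @param control list: `maxit`, `reltol` for the quasi-Newton optimizer.
#' @return an object of class `ordered_fit` with components `gamma`
#'   (thresholds), `beta`, `coefficients` (both, named), `vcov`, `se`,
#'   `loglik`, `n`, `K`, `xlevels`, `ref`, `converged`, `grad_norm`.
#' @export
fit_ordered_logit <- function(data,
                              response = "attention",
                              predictors = c("riding_style", "traffic_density"),
                              ref = list(riding_style = "aggressive",
                                         traffic_density = "dense"),
                              control = list(maxit = 200, reltol = 1e-12)) {
  if (!response %in% names(data)) stop("missing response column: ", response, call. = FALSE)
  yraw <- data[[response]]
  levels_y <- sort(unique(yraw))
  K <- length(levels_y)
  if (K < 2L) stop("response must have at least two observed categories", call. = FALSE)
  y <- match(yraw, levels_y)

  des <- build_design(data, predictors, ref)
  X <- des$X
  p <- ncol(X)
  if (p < 1) stop("need at least one predictor column", call. = FALSE)
  if (qr(cbind(1, X))$rank < p + 1) stop("design matrix is rank-deficient", call. = FALSE)

  ## start: empirical cumulative logits, beta = 0
  cum <- cumsum(tabulate(y, K) / length(y))[seq_len(K - 1)]
  g0 <- stats::qlogis(pmin(pmax(cum, 1e-3), 1 - 1e-3))
  g0 <- cummax(g0 + seq_len(K - 1) * 1e-6) # enforce strict order
  par0 <- c(g0[1], log(pmax(diff(g0), 1e-3)), rep(0, p))

  unpack <- function(par) {
    gamma <- if (K == 2L) par[1] else par[1] + c(0, cumsum(exp(par[2:(K - 1)])))
    beta <- if (p > 0) par[K:(K - 1 + p)] else numeric(0)
    list(gamma = gamma, beta = beta)
  }
  negll <- function(par) {
    th <- unpack(par)
    -cumlogit_loglik(th$gamma, th$beta, y, X)
  }
  neggr <- function(par) {
    th <- unpack(par)
    g <- cumlogit_grad(th$gamma, th$beta, y, X)
    ## chain rule to (gamma_1, delta_2.., beta)
    dgam <- g[seq_len(K - 1)]
    out <- numeric(length(par))
    out[1] <- sum(dgam)
    if (K > 2L) {
      for (m in 2:(K - 1)) {
        out[m] <- sum(dgam[m:(K - 1)]) * exp(par[m])
      }
    }
    if (p > 0) out[K:(K - 1 + p)] <- g[K:(K - 1 + p)]
    -out
  }

  opt <- stats::optim(par0, negll, neggr, method = "BFGS",
                      control = list(maxit = control$maxit %||% 200,
                                     reltol = control$reltol %||% 1e-12))
  th <- unpack(opt$par)
  gamma <- th$gamma
  beta <- stats::setNames(th$beta, colnames(X))

  ## observed information in the natural parameterization
  natural <- c(gamma, beta)
  nll_nat <- function(v) -cumlogit_loglik(v[seq_len(K - 1)], v[K:(K - 1 + p)], y, X)
  gr_nat <- function(v) -cumlogit_grad(v[seq_len(K - 1)], v[K:(K - 1 + p)], y, X)
  H <- stats::optimHess(natural, nll_nat, gr_nat)
  vcov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(natural), length(natural)))
  grad_norm <- max(abs(gr_nat(natural)))
  converged <- opt$convergence == 0 && is.finite(grad_norm) && grad_norm < 1e-4 * (1 + abs(opt$value))
  if (!converged) {
    warning("possible non-convergence or separation: gradient sup-norm ",
            format(grad_norm, digits = 3), call. = FALSE)
  }
  nm <- c(paste0("threshold_", seq_len(K - 1)), names(beta))
  dimnames(vcov) <- list(nm, nm)

  structure(
    list(
      gamma = stats::setNames(gamma, nm[seq_len(K - 1)]),
      beta = beta,
      coefficients = stats::setNames(natural, nm),
      vcov = vcov,
      se = stats::setNames(sqrt(diag(vcov)), nm),
      loglik = -opt$value,
      n = length(y),
      K = K,
      response_levels = levels_y,
      predictors = predictors,
      xlevels = des$xlevels,
      ref = ref,
      converged = converged,
      grad_norm = grad_norm,
      call = match.call()
    ),
    class = "ordered_fit"
  )
}

#' @export
print.ordered_fit <- function(x, ...) {
  cat("Cumulative-logit attention model (", x$K, " levels, n = ", x$n, ")\n",
      sep = "")
  print(wald_inference(x), digits = 4)
  cat("log-likelihood:", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' @export
logLik.ordered_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients), class = "logLik")
}

#' @export
vcov.ordered_fit <- function(object, ...) object$vcov

#' @export
coef.ordered_fit <- function(object, ...) object$coefficients

#' Wald statistics, p-values and confidence intervals
#'
#' For each parameter computes the Wald statistic `(estimate/se)^2` referred
#' to chi-square with 1 df, and the 95% interval `estimate +/- z * se`
#' (`z = 1.96`).
#'
#' @param x an `ordered_fit`, a `hier_fit` (posterior mean/SD parity), or a
#'   numeric vector of estimates.
#' @param ... further arguments passed to methods.
#' @return data.frame with `term`, `estimate`, `se`, `wald`, `p`, `ci_lower`,
#'   `ci_upper`.
#' @examples
#' wald_inference(1.234, 0.402) # CI (0.446, 2.022)
#' @export
wald_inference <- function(x, ...) UseMethod("wald_inference")

#' @rdname wald_inference
#' @param se standard errors (numeric method).
#' @param z critical value for the confidence interval (default 1.96).
#' @param term optional parameter names.
#' @export
wald_inference.default <- function(x, se, z = 1.96, term = names(x), ...) {
  est <- as.numeric(x)
  se <- as.numeric(se)
  if (length(se) != length(est)) stop("estimate/se length mismatch", call. = FALSE)
  if (any(is.finite(se) & se < 0)) stop("standard errors must be non-negative", call. = FALSE)
  w <- (est / se)^2
  w[se == 0] <- Inf
  data.frame(
    term = term %||% paste0("par", seq_along(est)),
    estimate = est,
    se = se,
    wald = w,
    p = stats::pchisq(w, df = 1, lower.tail = FALSE),
    ci_lower = est - z * se,
    ci_upper = est + z * se,
    row.names = NULL
  )
}

#' @rdname wald_inference
#' @export
wald_inference.ordered_fit <- function(x, z = 1.96, ...) {
  if (any(!is.finite(x$se))) {
    warning("covariance matrix not positive definite: inference flagged", call. = FALSE)
  }
  wald_inference.default(x$coefficients, x$se, z = z,
                         term = names(x$coefficients))
}

#' Predict attention category probabilities from a cumulative-logit fit
#'
#' @param fit an `ordered_fit`.
#' @param newdata data.frame of covariate rows (factor levels must have been
#'   seen at fit time).
#' @return list with `level` (predicted modal category, on the original
#'   response coding) and `probs` (matrix of category probabilities, one row
#'   per input row; rows sum to 1).
#' @export
predict_category <- function(fit, newdata) {
  stopifnot(inherits(fit, "ordered_fit"))
  des <- build_design(newdata, fit$predictors, fit$ref, xlevels = fit$xlevels)
  X <- des$X[, names(fit$beta), drop = FALSE]
  theta <- drop(X %*% fit$beta)
  probs <- ordinal_category_probs(theta, unname(fit$gamma))
  idx <- max.col(probs, ties.method = "first")
  list(level = fit$response_levels[idx], probs = probs)
}
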