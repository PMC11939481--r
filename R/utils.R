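#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## log(1 + exp(x)) without overflow/underflow.
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  mid <- x > 18 & x <= 33
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

#' Log-probabilities of ordinal categories under a cumulative-logit model
#'
#' Computes `log P(Y = y)` for a cumulative (ordered) logit model in which
#' `logit P(Y <= k) = eta_k`, with `eta` the matrix of threshold-minus-utility
#' values. Written in log space so extreme linear predictors do not underflow.
#'
#' @param y integer vector of observed categories in `1:K`.
#' @param eta numeric matrix with one row per observation and `K - 1` columns,
#'   column `k` holding `gamma_k - theta` for that observation. Columns must be
#'   non-decreasing left to right within each row.
#' @return numeric vector of log-probabilities; `-Inf` where a category
#'   probability is non-positive (non-increasing thresholds).
#' @export
cumlogit_logprob <- function(y, eta) {
  eta <- as.matrix(eta)
  n <- nrow(eta)
  K <- ncol(eta) + 1L
  if (length(y) != n) stop("length(y) must equal nrow(eta)", call. = FALSE)
  if (any(y < 1L | y > K)) stop("categories outside 1..K", call. = FALSE)
  out <- numeric(n)
  i1 <- y == 1L
  out[i1] <- -log1pexp(-eta[i1, 1L])
  iK <- y == K
  out[iK] <- -log1pexp(eta[iK, K - 1L])
  mid <- !(i1 | iK)
  if (any(mid)) {
    a <- eta[cbind(which(mid), y[mid] - 1L)]
    b <- eta[cbind(which(mid), y[mid])]
    d <- b - a
    lp <- ifelse(d > 0, a + log(expm1(d)) - log1pexp(a) - log1pexp(b), -Inf)
    out[mid] <- lp
  }
  out
}

#' Category probabilities of a cumulative-logit model
#'
#' @param theta numeric vector of linear predictors (latent utilities).
#' @param thresholds increasing numeric vector of `K - 1` thresholds; may also
#'   be a matrix with one row per observation for observation-specific
#'   thresholds.
#' @return matrix with one row per observation and `K` columns of category
#'   probabilities summing to 1.
#' @export
ordinal_category_probs <- function(theta, thresholds) {
  n <- length(theta)
  if (is.matrix(thresholds)) {
    if (nrow(thresholds) != n) stop("threshold matrix must have one row per observation", call. = FALSE)
    g <- thresholds
  } else {
    g <- matrix(thresholds, nrow = n, ncol = length(thresholds), byrow = TRUE)
  }
  cum <- stats::plogis(g - theta)
  p <- cbind(cum, 1)
  p[, -1] <- p[, -1, drop = FALSE] - cum
  colnames(p) <- paste0("p", seq_len(ncol(p)))
  p
}
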