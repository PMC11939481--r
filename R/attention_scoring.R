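## Composite attention scoring.
##
## The trial-level indicator vectors have incommensurate units (proportions,
## milliseconds, counts/min, mm), so dimension reduction works on the
## correlation matrix: indicators are standardized, principal components with
## eigenvalue > 1 are retained (Kaiser rule), and the composite score is the
## eigenvalue-proportional weighted sum of the retained component scores,
## each component oriented so it correlates positively with fixation time
## share (higher composite = more focused). The composite is then cut into
## three equal-frequency ordered levels: 1 Distracted, 2 Scattered, 3 Focused.

ATTENTION_LEVELS <- c("Distracted", "Scattered", "Focused")

#' Standardize indicator columns to zero mean and unit variance
#'
#' @param table data.frame of trial metrics.
#' @param cols columns to standardize; default: all numeric columns.
#' @return the table with standardized columns; the centering/scaling vectors
#'   are attached as attributes `"center"` and `"scale"`, and any
#'   zero-variance columns are dropped with a warning (attribute `"dropped"`).
#' @seealso [unstandardize_indicators()] for the inverse transform.
#' @export
standardize_indicators <- function(table, cols = NULL) {
  if (!is.data.frame(table) || nrow(table) < 2L) {
    stop("need at least two rows to standardize", call. = FALSE)
  }
  if (is.null(cols)) cols <- names(table)[vapply(table, is.numeric, logical(1))]
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("unknown columns: ", paste(miss, collapse = ", "), call. = FALSE)
  ctr <- vapply(table[cols], mean, numeric(1))
  scl <- vapply(table[cols], stats::sd, numeric(1))
  dropped <- cols[scl == 0 | is.na(scl)]
  if (length(dropped)) {
    warning("dropping zero-variance columns: ", paste(dropped, collapse = ", "),
            call. = FALSE)
    cols <- setdiff(cols, dropped)
    ctr <- ctr[cols]
    scl <- scl[cols]
  }
  out <- table
  for (cl in cols) out[[cl]] <- (table[[cl]] - ctr[[cl]]) / scl[[cl]]
  out[dropped] <- NULL
  structure(out, center = ctr, scale = scl, dropped = dropped,
            standardized = cols)
}

#' @rdname standardize_indicators
#' @param std a table produced by [standardize_indicators()].
#' @export
unstandardize_indicators <- function(std) {
  ctr <- attr(std, "center")
  scl <- attr(std, "scale")
  if (is.null(ctr) || is.null(scl)) {
    stop("input lacks stored scaling parameters", call. = FALSE)
  }
  out <- std
  for (cl in names(ctr)) out[[cl]] <- std[[cl]] * scl[[cl]] + ctr[[cl]]
  attr(out, "center") <- attr(out, "scale") <- attr(out, "dropped") <- NULL
  attr(out, "standardized") <- NULL
  out
}

#' PCA composite attention score
#'
#' Eigendecomposes the correlation matrix of the selected indicators, retains
#' components with eigenvalue above 1 (falling back to the first component if
#' none qualifies), orients each retained component to correlate positively
#' with `orient_by`, and combines the component scores with
#' eigenvalue-proportional weights into a single composite per trial.
#'
#' @param table data.frame holding the indicator columns (raw scale; the
#'   function standardizes internally, so the composite is invariant to the
#'   units of each indicator).
#' @param indicators character vector of indicator column names; the default
#'   is the seven attention indicators (fixation and saccade time shares,
#'   blinks per minute, mean pupil diameter, mean fixation and saccade
#'   durations, and the lane fixation share as the fixation-time distribution
#'   measure).
#' @param orient_by indicator used to fix component signs (default fixation
#'   time share, so higher composite means more focused).
#' @param retain `"kaiser"` (eigenvalue > 1) or `"first"`.
#' @return an object of class `attention_pca` with elements `composite`
#'   (numeric vector, one score per row), `eigenvalues`, `loadings`,
#'   `weights`, `retained`, `center`, `scale` and `signs`.
#' @export
pca_composite_score <- function(table,
                                indicators = c(
                                  "fix_time_pct", "sacc_time_pct", "blink_per_min",
                                  "pupil_mean_mm", "avg_fixation_ms",
                                  "avg_saccade_ms", "lane_fix_share"
                                ),
                                orient_by = "fix_time_pct",
                                retain = c("kaiser", "first")) {
  retain <- match.arg(retain)
  indicators <- intersect(indicators, names(table))
  if (length(indicators) < 2L) {
    stop("need at least two indicator columns present in the table", call. = FALSE)
  }
  if (!orient_by %in% indicators) {
    stop("orient_by must be one of the indicators", call. = FALSE)
  }
  X <- as.matrix(table[indicators])
  if (anyNA(X)) stop("indicators contain missing values", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) {
    stop("zero-variance indicator: ",
         paste(indicators[scl == 0], collapse = ", "),
         "; drop it (see standardize_indicators)", call. = FALSE)
  }
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  eig <- eigen(stats::cor(X), symmetric = TRUE)
  keep <- if (retain == "kaiser") which(eig$values > 1) else 1L
  if (length(keep) == 0L) keep <- 1L
  scores <- Z %*% eig$vectors[, keep, drop = FALSE]
  ## Orient: each retained component correlates positively with orient_by.
  ref <- Z[, orient_by]
  signs <- vapply(seq_along(keep), function(r) {
    s <- sign(stats::cov(scores[, r], ref))
    if (s == 0) 1 else s
  }, numeric(1))
  scores <- sweep(scores, 2, signs, "*")
  ev <- eig$values[keep]
  w <- ev / sum(ev)
  structure(
    list(
      composite = drop(scores %*% w),
      eigenvalues = eig$values,
      loadings = sweep(eig$vectors[, keep, drop = FALSE], 2, signs, "*"),
      weights = w,
      retained = keep,
      center = ctr,
      scale = scl,
      signs = signs,
      indicators = indicators
    ),
    class = "attention_pca"
  )
}

#' @export
print.attention_pca <- function(x, ...) {
  cat("PCA composite attention score over", length(x$indicators), "indicators\n")
  cat("Eigenvalues:", paste(format(x$eigenvalues, digits = 3), collapse = ", "), "\n")
  cat("Retained components:", paste(x$retained, collapse = ", "),
      "with weights", paste(format(x$weights, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' Re-apply a fitted composite scoring to new indicator rows
#'
#' @param pca an `attention_pca` fit.
#' @param table data.frame containing the fit's indicator columns.
#' @return numeric composite scores for the new rows, on the fitted scale.
#' @export
apply_attention_pca <- function(pca, table) {
  miss <- setdiff(pca$indicators, names(table))
  if (length(miss)) stop("table lacks indicators: ", paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(table[pca$indicators])
  Z <- sweep(sweep(X, 2, pca$center), 2, pca$scale, "/")
  drop(Z %*% pca$loadings %*% pca$weights)
}

#' Cut composite scores into three ordered attention levels
#'
#' With `cuts = NULL`, uses equal-frequency (tertile) intervals: trials are
#' ranked (stable first-occurrence order breaks ties deterministically) and
#' split into three groups as near-equal in size as `n` allows, with lower
#' groups taking the extra trial. Higher composite scores map to higher
#' levels: 1 Distracted, 2 Scattered, 3 Focused. The realised interval
#' boundaries are attached as attribute `"cuts"` for re-application to new
#' scores.
#'
#' @param composites numeric vector of composite scores (length >= 3 when
#'   fitting cuts).
#' @param cuts optional numeric vector of two fixed boundaries `c(c1, c2)`;
#'   a score `x` maps to level `1 + (x > c1) + (x > c2)`.
#' @return integer vector of levels in `{1, 2, 3}` with attribute `"cuts"`.
#' @examples
#' categorize_attention(1:9) # 1 1 1 2 2 2 3 3 3
#' @export
categorize_attention <- function(composites, cuts = NULL) {
  if (!is.null(cuts)) {
    if (length(cuts) != 2L || diff(cuts) < 0) {
      stop("cuts must be two non-decreasing boundaries", call. = FALSE)
    }
    lev <- 1L + (composites > cuts[1]) + (composites > cuts[2])
    return(structure(as.integer(lev), cuts = cuts))
  }
  n <- length(composites)
  if (n < 3L) stop("need at least three scores to fit tertiles", call. = FALSE)
  r <- rank(composites, ties.method = "first")
  lev <- 1L + as.integer(floor(3 * (r - 1) / n))
  ## boundary values realised by the grouping
  c1 <- max(composites[lev == 1L])
  c2 <- max(composites[lev == 2L])
  dup_vals <- unique(composites[duplicated(composites)])
  if (any(c(c1, c2) %in% dup_vals)) {
    warning("ties at tertile boundaries broken by stable input order",
            call. = FALSE)
  }
  structure(lev, cuts = c(c1, c2))
}

#' One-way ANOVA screening of a candidate factor
#'
#' Classical one-way analysis of variance of a response (by default the
#' composite attention score) across the levels of one factor, used to screen
#' which design factors plausibly influence attention before modelling.
#'
#' @param table data.frame of trials.
#' @param factor name of the grouping column (at least two groups, each with
#'   at least two observations).
#' @param response name of the numeric response column.
#' @return a one-row data.frame with `F`, `df1`, `df2`, `p`.
#' @export
screen_factors_anova <- function(table, factor, response = "composite") {
  if (!factor %in% names(table) || !response %in% names(table)) {
    stop("factor and response must be columns of the table", call. = FALSE)
  }
  g <- base::factor(table[[factor]])
  y <- table[[response]]
  counts <- table(g)
  if (length(counts) < 2L) stop("factor must have at least two groups", call. = FALSE)
  if (any(counts < 2L)) stop("every group needs at least two observations", call. = FALSE)
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  out <- data.frame(
    F = tab[["F value"]][1],
    df1 = tab[["Df"]][1],
    df2 = tab[["Df"]][2],
    p = tab[["Pr(>F)"]][1]
  )
  ms <- tab[["Mean Sq"]]
  if (!is.finite(out$F) || ms[2] <= 1e-12 * max(ms[1], .Machine$double.eps)) {
    warning("F statistic undefined (zero within-group variance)", call. = FALSE)
    out$F <- NaN
    out$p <- NaN
  }
  out
}

#' Save / load composite scoring parameters
#'
#' Serializes the loadings, weights, scaling and (optionally) the attention
#' cut points of a fitted scoring to a YAML sidecar so the same scoring can
#' be re-applied to new data.
#'
#' @param pca an `attention_pca` fit.
#' @param path file path for the YAML sidecar.
#' @param cuts optional attention level boundaries to store alongside.
#' @return `read_scoring_params()` returns an `attention_pca` object.
#' @export
write_scoring_params <- function(pca, path, cuts = NULL) {
  obj <- list(
    indicators = pca$indicators,
    center = as.list(pca$center),
    scale = as.list(pca$scale),
    loadings = apply(pca$loadings, 2, identity, simplify = FALSE),
    weights = as.numeric(pca$weights),
    eigenvalues = as.numeric(pca$eigenvalues),
    retained = as.integer(pca$retained),
    signs = as.numeric(pca$signs),
    cuts = if (!is.null(cuts)) as.numeric(cuts)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scoring_params
#' @export
read_scoring_params <- function(path) {
  obj <- yaml::read_yaml(path)
  pca <- structure(
    list(
      composite = NULL,
      eigenvalues = as.numeric(obj$eigenvalues),
      loadings = do.call(cbind, lapply(obj$loadings, as.numeric)),
      weights = as.numeric(obj$weights),
      retained = as.integer(obj$retained),
      center = unlist(obj$center),
      scale = unlist(obj$scale),
      signs = as.numeric(obj$signs),
      indicators = obj$indicators
    ),
    class = "attention_pca"
  )
  attr(pca, "cuts") <- if (!is.null(obj$cuts)) as.numeric(obj$cuts)
  pca
}
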