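## Model evaluation: observed-vs-predicted cross tables, overall accuracy,
## model comparison in percentage points, and odds-ratio analysis with
## reference-level recoding via the treatment-contrast identity.

#' Observed-vs-predicted attention cross table
#'
#' @param observed integer vector of observed attention levels.
#' @param predicted integer vector of predicted levels (same length).
#' @param levels the admissible ordinal levels (default `1:3`).
#' @return a `cross_table`: a K x K count matrix (rows = observed, columns =
#'   predicted) with row/column/grand totals available via [accuracy()] and
#'   the print method.
#' @export
cross_table <- function(observed, predicted, levels = 1:3) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (!all(observed %in% levels) || !all(predicted %in% levels)) {
    stop("levels outside ", paste(range(levels), collapse = ".."), call. = FALSE)
  }
  tab <- table(
    observed = base::factor(observed, levels = levels),
    predicted = base::factor(predicted, levels = levels)
  )
  structure(unclass(tab), class = "cross_table", levels = levels)
}

#' Build a cross table directly from counts
#'
#' Convenience constructor for externally reported cross tables (e.g.
#' published model-accuracy tables), given the count matrix itself.
#'
#' @param counts K x K matrix of counts, rows = observed, columns = predicted.
#' @param levels ordinal level values (default `1:nrow(counts)`).
#' @return a `cross_table`.
#' @export
as_cross_table <- function(counts, levels = seq_len(nrow(counts))) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  dimnames(counts) <- list(observed = levels, predicted = levels)
  structure(counts, class = "cross_table", levels = levels)
}

#' @export
print.cross_table <- function(x, ...) {
  m <- unclass(x)
  full <- rbind(cbind(m, Total = rowSums(m)),
                Total = c(colSums(m), sum(m)))
  cat("Observed (rows) vs predicted (columns) attention levels\n")
  print(full)
  cat(sprintf("Predictive accuracy: %.2f%%\n", accuracy(x)))
  invisible(x)
}

#' Overall prediction accuracy of a cross table
#'
#' `100 * sum(diagonal) / grand total`: the percentage of trials whose
#' predicted attention level equals the observed one.
#'
#' @param table a `cross_table` (or a plain square count matrix).
#' @return accuracy as a percentage in `[0, 100]`.
#' @export
accuracy <- function(table) {
  m <- unclass(as_cross_table_like(table))
  total <- sum(m)
  if (total <= 0) stop("empty cross table", call. = FALSE)
  100 * sum(diag(m)) / total
}

as_cross_table_like <- function(x) {
  if (inherits(x, "cross_table")) return(x)
  if (is.matrix(x) || is.table(x)) return(as_cross_table(as.matrix(unclass(x))))
  stop("expected a cross_table or count matrix", call. = FALSE)
}

#' Accuracy difference between two models
#'
#' `accuracy(a) - accuracy(b)` in percentage points, for predictions made on
#' the identical trial set (checked through the row totals, which are the
#' observed level counts).
#'
#' @param a,b `cross_table`s (or count matrices) of the two models.
#' @return difference in percentage points.
#' @export
compare_models <- function(a, b) {
  a <- as_cross_table_like(a)
  b <- as_cross_table_like(b)
  if (!identical(dim(a), dim(b)) ||
      !isTRUE(all.equal(unname(rowSums(unclass(a))),
                        unname(rowSums(unclass(b)))))) {
    stop("cross tables are not over identical trial sets", call. = FALSE)
  }
  accuracy(a) - accuracy(b)
}

#' Odds ratios with optional reference-level recoding
#'
#' Exponentiates model coefficients into odds ratios of higher attention.
#' With `recode_reference`, re-expresses a factor's coefficients relative to
#' a new reference level using the treatment-contrast identity
#' `beta'_l = beta_l - beta_newref` (exact for maximum-likelihood estimates;
#' the old reference appears with coefficient `-beta_newref`).
#'
#' @param x an `ordered_fit`, `hier_fit`, or a data.frame with columns
#'   `term` and `estimate`, terms of factor dummies named `"factor=level"`.
#' @param recode_reference optional named character, e.g.
#'   `c(traffic_density = "sparse")`.
#' @param old_reference optional named character giving each recoded factor's
#'   original reference level, used to label its row in the output (taken
#'   from the fit when available).
#' @param ... passed to methods.
#' @return data.frame with `term`, `estimate`, `odds_ratio`.
#' @examples
#' tab <- data.frame(
#'   term = c("riding_style=conservative", "traffic_density=sparse",
#'            "traffic_density=moderate"),
#'   estimate = c(1.133, 2.031, 0.862)
#' )
#' odds_ratios(tab) # 3.105, 7.622, 2.368
#' odds_ratios(tab, recode_reference = c(traffic_density = "sparse"),
#'             old_reference = c(traffic_density = "dense"))
#' @export
odds_ratios <- function(x, recode_reference = NULL, ...) UseMethod("odds_ratios")

#' @rdname odds_ratios
#' @export
odds_ratios.data.frame <- function(x, recode_reference = NULL,
                                   old_reference = NULL, ...) {
  if (!all(c("term", "estimate") %in% names(x))) {
    stop("need columns term and estimate", call. = FALSE)
  }
  tab <- x[, c("term", "estimate")]
  ## keep only slope-like terms (skip thresholds)
  tab <- tab[!grepl("^threshold_|^gamma_", tab$term), , drop = FALSE]
  if (!is.null(recode_reference)) {
    for (fac in names(recode_reference)) {
      new_ref <- recode_reference[[fac]]
      in_fac <- grepl(paste0("^", fac, "="), tab$term)
      lev <- sub(paste0("^", fac, "="), "", tab$term[in_fac])
      if (!new_ref %in% lev) {
        stop("unknown level ", new_ref, " for factor ", fac, call. = FALSE)
      }
      b_new <- tab$estimate[in_fac][lev == new_ref]
      tab$estimate[in_fac] <- tab$estimate[in_fac] - b_new
      ## old reference gains an explicit row at -b_new
      old <- old_reference[[fac]]
      if (!is.null(old)) {
        tab <- rbind(tab, data.frame(term = paste0(fac, "=", old),
                                     estimate = -b_new))
      }
      ## the new reference row (now exactly 0) is dropped
      tab <- tab[!(grepl(paste0("^", fac, "="), tab$term) &
                   sub(paste0("^", fac, "="), "", tab$term) == new_ref), ,
                 drop = FALSE]
    }
  }
  tab$odds_ratio <- exp(tab$estimate)
  rownames(tab) <- NULL
  tab
}

#' @rdname odds_ratios
#' @export
odds_ratios.ordered_fit <- function(x, recode_reference = NULL, ...) {
  tab <- data.frame(term = names(x$beta), estimate = unname(x$beta))
  old_ref <- vapply(names(recode_reference), function(f) x$xlevels[[f]][1],
                    character(1))
  odds_ratios.data.frame(tab, recode_reference, old_reference = old_ref)
}

#' @rdname odds_ratios
#' @export
odds_ratios.hier_fit <- function(x, recode_reference = NULL, ...) {
  s <- x$summary
  keep <- !grepl("^gamma_|^B_", s$term) & s$term != "tau"
  tab <- data.frame(term = s$term[keep], estimate = s$mean[keep])
  old_ref <- vapply(names(recode_reference), function(f) x$data$xlevels[[f]][1],
                    character(1))
  odds_ratios.data.frame(tab, recode_reference, old_reference = old_ref)
}
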