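## Synthetic study generator.
##
## Emulates the campus cycling study design: J cyclists ride three road
## sections in both directions during peak and off-peak periods (J x 3 x 2 x 2
## design cells), a small fraction of trials is lost to recording attrition,
## riding style is assigned by comparing trial speed with the grand mean
## speed, and the ordinal attention level is drawn from the hierarchical
## ordered logistic model under known true parameters so that every
## downstream stage can be tested against a known truth.

default_sections <- function() {
  data.frame(
    section = c("A", "B", "C"),
    length_m = c(104, 90, 120),
    grade_pct = c(7.9, 4.4, 0)
  )
}

#' Study design specification
#'
#' Describes the factorial trial design: cyclists x road sections x
#' directions x time periods, plus the attrition probability and how period
#' maps to traffic density.
#'
#' @param n_cyclists number of participants (default 9).
#' @param sections data.frame with columns `section`, `length_m`, `grade_pct`;
#'   default: three campus road sections of 104 m at 7.9% grade, 90 m at
#'   4.4%, and a level 120 m section.
#' @param n_directions number of riding directions per section (default 2).
#' @param periods labels of the surveyed time periods (default
#'   `c("peak", "offpeak")`).
#' @param attrition_rate probability in `[0, 1)` that a recorded trial is lost
#'   (signal interruption, transmission error); default `11/108`, giving on
#'   average 97 valid trials out of 108.
#' @param period_density_map named character vector mapping each period to a
#'   traffic density label; campus flows are tidal, so peak hours are dense
#'   and off-peak hours sparse by default.
#' @param moderate_fraction fraction of design cells relabelled to "moderate"
#'   density so that all three printed density levels occur (default 0.25).
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(n_cyclists = 9,
                        sections = default_sections(),
                        n_directions = 2,
                        periods = c("peak", "offpeak"),
                        attrition_rate = 11 / 108,
                        period_density_map = c(peak = "dense", offpeak = "sparse"),
                        moderate_fraction = 0.25) {
  if (!is.numeric(n_cyclists) || n_cyclists < 1 || n_cyclists != round(n_cyclists)) {
    stop("n_cyclists must be a positive integer", call. = FALSE)
  }
  if (!is.data.frame(sections) || nrow(sections) < 1 ||
      !all(c("section", "length_m", "grade_pct") %in% names(sections))) {
    stop("sections must be a data.frame with section, length_m, grade_pct", call. = FALSE)
  }
  if (!is.numeric(n_directions) || n_directions < 1 || n_directions != round(n_directions)) {
    stop("n_directions must be a positive integer", call. = FALSE)
  }
  if (length(periods) < 1) stop("need at least one period", call. = FALSE)
  if (!is.numeric(attrition_rate) || attrition_rate < 0 || attrition_rate >= 1) {
    stop("attrition_rate must lie in [0, 1)", call. = FALSE)
  }
  if (!all(periods %in% names(period_density_map))) {
    stop("period_density_map must cover every period", call. = FALSE)
  }
  if (moderate_fraction < 0 || moderate_fraction > 1) {
    stop("moderate_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      n_cyclists = as.integer(n_cyclists),
      sections = sections,
      n_directions = as.integer(n_directions),
      periods = periods,
      attrition_rate = attrition_rate,
      period_density_map = period_density_map,
      moderate_fraction = moderate_fraction
    ),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cells <- x$n_cyclists * nrow(x$sections) * x$n_directions * length(x$periods)
  cat("Study design:", x$n_cyclists, "cyclists x", nrow(x$sections),
      "sections x", x$n_directions, "directions x", length(x$periods),
      "periods =", cells, "trials\n")
  cat("Attrition rate:", format(x$attrition_rate, digits = 4), "\n")
  invisible(x)
}

#' True parameters for the hierarchical attention simulator
#'
#' Parameters of the data-generating hierarchical ordered logistic model and
#' of the covariate and speed distributions. Defaults use published-magnitude
#' fixed effects (conservative style 1.133; sparse 2.031 and moderate 0.862
#' vs dense traffic) and threshold-covariate coefficients of 10.5 per unit of
#' lane fixation share (0.105 per percentage point) and -9.56 per unit of
#' pupil diameter coefficient of variation; base thresholds are set so the
#' three attention levels are realised in near-balanced proportions.
#'
#' @param gamma two strictly increasing base thresholds.
#' @param beta named coefficients for the `conservative` riding-style dummy
#'   and the `sparse`/`moderate` traffic-density dummies (aggressive and
#'   dense are the references).
#' @param alpha named threshold-covariate coefficients for `lane_fix_share`
#'   (per unit proportion) and `pupil_cv`.
#' @param tau precision of the cyclist random effect `B_j ~ N(0, 1/tau)`.
#' @param covariate_dists distributions of the simulated covariates:
#'   `lane_fix_share` a Beta with given mean and concentration, `pupil_cv` a
#'   Normal truncated at 0.
#' @param speed_dists cycling speed (m/s): per-cyclist base speed
#'   `N(mean, between_sd)` plus per-trial `N(0, within_sd)` variation.
#' @param gaze_targets distributions of per-trial gaze-stream targets used by
#'   [simulate_gaze_stream()]: fixation time share (Beta) and mean pupil
#'   diameter in mm (Normal).
#' @return an object of class `true_params`.
#' @export
true_params <- function(gamma = c(-4.5, -3.1),
                        beta = c(conservative = 1.133, sparse = 2.031, moderate = 0.862),
                        alpha = c(lane_fix_share = 10.5, pupil_cv = -9.56),
                        tau = 4,
                        covariate_dists = list(
                          lane_fix_share = list(mean = 0.65, concentration = 20),
                          pupil_cv = list(mean = 0.15, sd = 0.05)
                        ),
                        speed_dists = list(mean = 4.0, between_sd = 0.6, within_sd = 0.3),
                        gaze_targets = list(
                          fix_time_pct = list(mean = 0.55, concentration = 40),
                          pupil_mean_mm = list(mean = 4.0, sd = 0.3)
                        )) {
  if (length(gamma) != 2 || diff(gamma) <= 0) {
    stop("gamma must be two strictly increasing thresholds", call. = FALSE)
  }
  if (!all(c("conservative", "sparse", "moderate") %in% names(beta))) {
    stop("beta must name conservative, sparse and moderate effects", call. = FALSE)
  }
  if (!all(c("lane_fix_share", "pupil_cv") %in% names(alpha))) {
    stop("alpha must name lane_fix_share and pupil_cv effects", call. = FALSE)
  }
  if (!is.numeric(tau) || tau <= 0) stop("tau must be positive", call. = FALSE)
  if (covariate_dists$pupil_cv$sd <= 0 || speed_dists$between_sd <= 0 ||
      speed_dists$within_sd <= 0) {
    stop("distribution SDs must be positive", call. = FALSE)
  }
  structure(
    list(
      gamma = gamma, beta = beta, alpha = alpha, tau = tau,
      covariate_dists = covariate_dists, speed_dists = speed_dists,
      gaze_targets = gaze_targets
    ),
    class = "true_params"
  )
}

#' Generate the factorial trial skeletons of a study design
#'
#' Expands the design into one skeleton row per design cell and assigns
#' traffic density from the period (tidal campus flows), optionally
#' relabelling a random fraction of cells "moderate".
#'
#' @param spec a [design_spec()].
#' @param seed integer seed; output is deterministic given the seed.
#' @return a data.frame with one row per design cell: `trial_id`, `cyclist`,
#'   `section`, `direction`, `period`, `traffic_density`; the design's
#'   attrition rate is attached as an attribute for [simulate_trials()].
#' @examples
#' d <- generate_design(design_spec(), seed = 1)
#' nrow(d) # 108
#' @export
generate_design <- function(spec, seed) {
  if (!inherits(spec, "design_spec")) stop("spec must be a design_spec", call. = FALSE)
  grid <- expand.grid(
    cyclist = seq_len(spec$n_cyclists),
    section = spec$sections$section,
    direction = c("outbound", "return", paste0("dir", seq_len(max(0, spec$n_directions - 2)) + 2))[seq_len(spec$n_directions)],
    period = spec$periods,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$traffic_density <- unname(spec$period_density_map[grid$period])
  n <- nrow(grid)
  with_seed(seed, {
    n_mod <- floor(spec$moderate_fraction * n)
    if (n_mod > 0) {
      grid$traffic_density[sample.int(n, n_mod)] <- "moderate"
    }
  })
  out <- cbind(trial_id = seq_len(n), grid)
  attr(out, "attrition_rate") <- spec$attrition_rate
  out
}

## Normal truncated at zero (left), by rejection.
rtnorm_pos <- function(n, mean, sd) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw > 0
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

rbeta_mc <- function(n, mean, concentration) {
  stats::rbeta(n, mean * concentration, (1 - mean) * concentration)
}

#' Simulate trial records from the hierarchical attention model
#'
#' Fills the design skeletons with simulated speeds, riding styles, gaze
#' covariates and ordinal attention levels drawn from the hierarchical
#' ordered logistic model: each cyclist receives a random threshold shift
#' `B_j ~ N(0, 1/tau)`, trial covariates shift both thresholds through
#' `alpha`, the fixed effects act through the latent utility, and the
#' attention level is sampled from the implied three-category distribution.
#' Riding style is "aggressive" when the trial speed strictly exceeds the
#' grand mean speed of all simulated trials, otherwise "conservative".
#'
#' @param skeletons output of [generate_design()].
#' @param params a [true_params()] object.
#' @param seed integer seed.
#' @param attrition_rate probability that each trial is independently dropped;
#'   defaults to the rate attached by [generate_design()].
#' @return a data.frame of trial records (one per surviving trial) with the
#'   design columns plus `speed_mps`, `riding_style`, `fix_time_pct`,
#'   `pupil_mean_mm`, `pupil_sd_mm`, `lane_fix_share`, `pupil_cv` and the
#'   ordinal `attention` level in `{1, 2, 3}`. The cyclist random effects used
#'   are attached as attribute `"B"`.
#' @export
simulate_trials <- function(skeletons, params, seed,
                            attrition_rate = attr(skeletons, "attrition_rate") %||% 0) {
  if (!inherits(params, "true_params")) stop("params must be a true_params", call. = FALSE)
  need <- c("cyclist", "traffic_density")
  if (!all(need %in% names(skeletons))) {
    stop("skeletons must carry cyclist and traffic_density columns", call. = FALSE)
  }
  n <- nrow(skeletons)
  cyclists <- sort(unique(skeletons$cyclist))
  j <- match(skeletons$cyclist, cyclists)

  with_seed(seed, {
    B <- stats::rnorm(length(cyclists), 0, 1 / sqrt(params$tau))
    base_speed <- stats::rnorm(length(cyclists), params$speed_dists$mean,
                               params$speed_dists$between_sd)
    speed <- base_speed[j] + stats::rnorm(n, 0, params$speed_dists$within_sd)
    style <- ifelse(speed > mean(speed), "aggressive", "conservative")

    cd <- params$covariate_dists
    lane <- rbeta_mc(n, cd$lane_fix_share$mean, cd$lane_fix_share$concentration)
    pcv <- rtnorm_pos(n, cd$pupil_cv$mean, cd$pupil_cv$sd)

    gt <- params$gaze_targets
    fixp <- rbeta_mc(n, gt$fix_time_pct$mean, gt$fix_time_pct$concentration)
    pmean <- rtnorm_pos(n, gt$pupil_mean_mm$mean, gt$pupil_mean_mm$sd)

    theta <- params$beta[["conservative"]] * (style == "conservative") +
      params$beta[["sparse"]] * (skeletons$traffic_density == "sparse") +
      params$beta[["moderate"]] * (skeletons$traffic_density == "moderate")
    shift <- params$alpha[["lane_fix_share"]] * lane +
      params$alpha[["pupil_cv"]] * pcv + B[j]
    g <- cbind(params$gamma[1] + shift, params$gamma[2] + shift)
    if (any(!is.finite(g))) stop("numerical overflow in threshold computation", call. = FALSE)
    cum1 <- stats::plogis(g[, 1] - theta)
    cum2 <- stats::plogis(g[, 2] - theta)
    u <- stats::runif(n)
    attention <- 1L + (u > cum1) + (u > cum2)

    keep <- stats::runif(n) >= attrition_rate
  })

  out <- cbind(
    skeletons,
    data.frame(
      speed_mps = speed, riding_style = style,
      fix_time_pct = fixp, pupil_mean_mm = pmean,
      pupil_sd_mm = pcv * pmean,
      lane_fix_share = lane, pupil_cv = pcv,
      attention = attention
    )
  )
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "B") <- stats::setNames(B, cyclists)
  attr(out, "attrition_rate") <- attrition_rate
  out
}

#' Simulate a labelled gaze-sample stream matching trial-level targets
#'
#' Emits a fixed-rate stream of fixation/saccade/blink samples whose
#' recomputed [compute_trial_metrics()] reproduce the trial's target fixation
#' time share, lane fixation share, and pupil mean/SD. Pupil diameters are
#' drawn from a Normal and then affinely rescaled so the realised mean and
#' population SD match the targets exactly; blink samples carry a missing
#' pupil diameter. Deterministic lane-quota assignment keeps the recomputed
#' lane share within one sample of the target.
#'
#' @param trial a one-row data.frame (or list) with `fix_time_pct`,
#'   `lane_fix_share`, `pupil_mean_mm`, `pupil_sd_mm`.
#' @param seed integer seed.
#' @param duration_s stream length in seconds (default 60).
#' @param hz sampling frequency (default 50, the wearable tracker's rate).
#' @param blink_per_min target blink rate (default 12 blinks/min).
#' @return a gaze stream data.frame (see [compute_trial_metrics()]).
#' @export
simulate_gaze_stream <- function(trial, seed, duration_s = 60, hz = 50,
                                 blink_per_min = 12) {
  need <- c("fix_time_pct", "lane_fix_share", "pupil_mean_mm", "pupil_sd_mm")
  miss <- setdiff(need, names(trial))
  if (length(miss)) stop("trial lacks targets: ", paste(miss, collapse = ", "), call. = FALSE)
  f <- trial$fix_time_pct
  share <- trial$lane_fix_share
  pm <- trial$pupil_mean_mm
  ps <- trial$pupil_sd_mm
  if (f < 0 || f > 1 || share < 0 || share > 1) {
    stop("target shares must lie in [0, 1]", call. = FALSE)
  }
  if (pm <= 0 || ps < 0) stop("pupil targets must be non-negative with positive mean", call. = FALSE)

  n <- round(duration_s * hz)
  if (n < 2L) stop("stream too short", call. = FALSE)
  dt <- 1000 / hz

  n_fix <- round(f * n)
  n_blink_runs <- max(0L, round(blink_per_min * duration_s / 60))
  blink_len <- 8L # 160 ms at 50 Hz
  while (n_blink_runs * blink_len + n_fix > n && blink_len > 1L) blink_len <- blink_len - 1L
  if (n_blink_runs * blink_len + n_fix > n) n_blink_runs <- (n - n_fix) %/% max(blink_len, 1L)
  n_blink <- n_blink_runs * blink_len
  n_sacc <- n - n_fix - n_blink

  ## Interleave cycles of fixation / saccade / blink runs.
  n_cycles <- max(1L, n_blink_runs)
  split_even <- function(total, k) {
    base <- total %/% k
    extra <- total %% k
    base + (seq_len(k) <= extra)
  }
  fix_runs <- split_even(n_fix, n_cycles)
  sacc_runs <- split_even(n_sacc, n_cycles)
  blink_runs <- if (n_blink_runs > 0) rep(blink_len, n_blink_runs) else rep(0L, n_cycles)
  events <- unlist(lapply(seq_len(n_cycles), function(i) {
    c(rep("fixation", fix_runs[i]), rep("saccade", sacc_runs[i]),
      rep("blink", blink_runs[i]))
  }))
  stopifnot(length(events) == n)

  ## Lane quota: i-th fixation sample is on-lane when floor(i*share) advances,
  ## spreading floor(n_fix*share) lane samples evenly through fixation time.
  aoi <- rep("none", n)
  fix_idx <- which(events == "fixation")
  if (length(fix_idx)) {
    i <- seq_along(fix_idx)
    on_lane <- floor(i * share) > floor((i - 1) * share)
    side <- rep_len(c("left", "right"), sum(!on_lane))
    aoi[fix_idx[on_lane]] <- "lane"
    aoi[fix_idx[!on_lane]] <- side
  }

  pupil <- rep(NA_real_, n)
  present <- events != "blink"
  np <- sum(present)
  with_seed(seed, {
    raw <- stats::rnorm(np)
  })
  if (np >= 2L && ps > 0) {
    raw_sd <- stats::sd(raw) * sqrt((np - 1) / np)
    vals <- pm + (raw - mean(raw)) / raw_sd * ps
  } else {
    vals <- rep(pm, np)
  }
  if (any(vals <= 0)) stop("pupil targets imply non-positive diameters", call. = FALSE)
  pupil[present] <- vals

  data.frame(
    time_ms = (seq_len(n) - 1L) * dt,
    event = events,
    pupil_mm = pupil,
    aoi = aoi
  )
}
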