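# Model-based BOLD prediction: module activity traces are discretized to
# binary demand functions D(t), convolved with a gamma hemodynamic
# response H(t) = m (t/s)^alpha exp(-t/s), sampled at the TR, expressed as
# percent change from a rest-block baseline, and summarized as the area
# under the curve across the task block.

#' Gamma hemodynamic response parameters
#'
#' @param m Magnitude (dimensionless scaling; fit per region of interest).
#'   The default, together with the unit baseline offset used by
#'   [percent_change()], yields sub-percent signal changes typical of
#'   block-design fMRI.
#' @param s Time scale in seconds.
#' @param alpha Shape; the response peaks at `t = alpha * s`.
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(m = 1e-4, s = 0.75, alpha = 6) {
  if (m <= 0 || s <= 0 || alpha <= 0) {
    stop("hrf parameters m, s, alpha must all be positive", call. = FALSE)
  }
  structure(list(m = m, s = s, alpha = alpha), class = "hrf_params")
}

#' Gamma hemodynamic response function
#'
#' `H(t) = m * (t/s)^alpha * exp(-t/s)` for `t >= 0`, 0 for `t < 0`.
#' Its peak is at `alpha * s` and its integral is `m * s * gamma(alpha + 1)`.
#'
#' @param t Time in seconds (vectorized).
#' @param p An [hrf_params()] object.
#' @return Response values, same length as `t`.
#' @export
hrf <- function(t, p = hrf_params()) {
  out <- numeric(length(t))
  pos <- t > 0
  tt <- t[pos] / p$s
  out[pos] <- p$m * tt^p$alpha * exp(-tt)
  out
}

#' Discretize a module trace into a binary demand function
#'
#' D(t) is 1 exactly on the union of the module's event intervals
#' (half-open, `[onset, onset + duration)`), discretized on a fine grid by
#' the cell-midpoint rule.
#'
#' @param trace A trace: list or data.frame with `module`, `onset`,
#'   `duration` (onsets in block-local seconds).
#' @param module Which module's demand to extract.
#' @param grid_dt Grid resolution in seconds (default 0.010).
#' @param window Numeric `c(start, end)` of the demand window in the same
#'   time base as the trace.
#' @return A `demand_function`: list with `grid_dt`, `t0`, `values`,
#'   `module`.
#' @export
trace_to_demand <- function(trace, module, grid_dt = 0.010,
                            window = c(0, 62)) {
  stopifnot(length(window) == 2L, window[2] > window[1], grid_dt > 0)
  sel <- trace$module == module
  onset <- trace$onset[sel]
  dur <- trace$duration[sel]
  if (length(onset) > 1L) {
    o <- order(onset)
    onset <- onset[o]; dur <- dur[o]
    if (any(onset[-1L] < onset[-length(onset)] + dur[-length(dur)] - 1e-9)) {
      stop("overlapping events for module '", module, "'", call. = FALSE)
    }
  }
  n <- round((window[2] - window[1]) / grid_dt)
  values <- numeric(n)
  for (k in seq_along(onset)) {
    # cells whose midpoint falls inside [onset, onset + duration)
    lo <- ceiling((onset[k] - window[1]) / grid_dt + 0.5)
    hi <- ceiling((onset[k] + dur[k] - window[1]) / grid_dt + 0.5) - 1L
    lo <- max(lo, 1L); hi <- min(hi, n)
    if (hi >= lo) values[lo:hi] <- 1
  }
  structure(list(grid_dt = grid_dt, t0 = window[1], values = values,
                 module = module),
            class = "demand_function")
}

#' Predict a raw BOLD timecourse from a demand function
#'
#' Discrete convolution of the binary demand with the gamma response on the
#' fine grid (a Riemann sum), then sampled at TR boundaries.  The
#' prediction is linear in the magnitude `m` and additive over disjoint
#' demand segments.
#'
#' @param d A `demand_function`.
#' @param p An [hrf_params()] object.
#' @param tr Repetition time in seconds (default 2, the acquisition TR);
#'   must be an integer multiple of `d$grid_dt`.
#' @param hrf_span Length of hemodynamic response support used in the
#'   convolution, seconds.
#' @param keep_fine Keep the full fine-grid convolution as element `fine`
#'   (list with `times`, `values`)?  Useful for quadrature checks.
#' @return A `bold_series`: list with `tr`, `t0`, `times`, `values`,
#'   `kind = "raw"`, `module`.
#' @export
predict_bold <- function(d, p = hrf_params(), tr = 2, hrf_span = 30,
                         keep_fine = FALSE) {
  stopifnot(inherits(d, "demand_function"))
  ratio <- tr / d$grid_dt
  if (abs(ratio - round(ratio)) > 1e-8) {
    stop("grid_dt must divide tr", call. = FALSE)
  }
  # kernel sampled so each demand cell contributes H(t - cell_midpoint):
  # midpoint-rule quadrature in tau, error O(grid_dt^2)
  h <- hrf(seq(0, hrf_span, by = d$grid_dt) - d$grid_dt / 2, p)
  n <- length(d$values)
  conv <- stats::convolve(c(d$values, numeric(length(h) - 1L)),
                          rev(h), type = "open")
  # conv[k] = sum_j d[j] h[k - j + 1]; keep the causal part on the grid
  fine <- conv[seq_len(n + length(h) - 1L)] * d$grid_dt
  times <- seq(ceiling(d$t0 / tr) * tr, d$t0 + (n - 1L) * d$grid_dt, by = tr)
  idx <- round((times - d$t0) / d$grid_dt) + 1L
  out <- structure(list(tr = tr, t0 = times[1L], times = times,
                        values = fine[idx], kind = "raw", module = d$module),
                   class = "bold_series")
  if (keep_fine) {
    out$fine <- list(times = d$t0 + (seq_along(fine) - 1L) * d$grid_dt,
                     values = fine)
  }
  out
}

#' Percent signal change against the rest baseline
#'
#' The baseline is the mean of 7 scans of the rest period preceding the
#' task block and the last 8 scans of the rest period following it.  For a
#' model-predicted raw series (which is 0 at rest) an additive offset
#' representing baseline signal is applied first.
#'
#' @param raw A `bold_series` with `kind == "raw"`.
#' @param pre_rest,post_rest Number of baseline scans taken from the start
#'   and from the end of the series (defaults 7 and 8).
#' @param baseline_offset Additive offset representing baseline MR signal
#'   (default 1 unit; use 0 for data that already carries its baseline).
#' @return A `bold_series` with `kind = "percent_change"`.
#' @export
percent_change <- function(raw, pre_rest = 7L, post_rest = 8L,
                           baseline_offset = 1) {
  stopifnot(inherits(raw, "bold_series"))
  v <- raw$values + baseline_offset
  n <- length(v)
  if (n < pre_rest + post_rest) {
    stop("series too short for ", pre_rest, " + ", post_rest,
         " baseline scans", call. = FALSE)
  }
  b <- mean(c(v[seq_len(pre_rest)], v[seq.int(n - post_rest + 1L, n)]))
  if (b == 0) stop("degenerate baseline: mean baseline signal is 0", call. = FALSE)
  out <- raw
  out$values <- 100 * (v - b) / b
  out$kind <- "percent_change"
  out
}

#' Area under the BOLD curve across the task block
#'
#' Trapezoidal integral of the (percent-change) series between the start
#' and the end of the task block, window edges snapped to the nearest scan.
#'
#' @param series A `bold_series`.
#' @param window Numeric `c(start, end)` in the series' time base.
#' @return Area in percent * seconds (for a percent-change input).
#' @export
bold_auc <- function(series, window = c(2, 32)) {
  stopifnot(inherits(series, "bold_series"))
  if (length(window) != 2L || window[2] <= window[1]) {
    stop("empty AUC window", call. = FALSE)
  }
  i0 <- which.min(abs(series$times - window[1]))
  i1 <- which.min(abs(series$times - window[2]))
  if (i1 <= i0) stop("AUC window contains fewer than two scans", call. = FALSE)
  idx <- seq.int(i0, i1)
  v <- series$values[idx]
  t <- series$times[idx]
  sum(diff(t) * (v[-length(v)] + v[-1L]) / 2)
}

#' Predicted percent-change BOLD for one simulated block
#'
#' Convenience wrapper: builds the module demand over the padded block
#' window (7 pre-task rest scans, the 2 s cue, the 30 s task and the 30 s
#' rest), predicts raw BOLD, converts to percent change and computes the
#' task-window AUC.
#'
#' @param block_result A `block_result` from [run_block()].
#' @param module Module whose demand to use (`"declarative"`,
#'   `"problem_state"`, ...).
#' @param p An [hrf_params()] object.
#' @param tr,grid_dt Sampling parameters.
#' @param noise_sd Optional additive Gaussian scan noise on the raw series
#'   (used by the synthetic-participant generator).
#' @param baseline_offset Passed to [percent_change()].
#' @return List with `raw`, `pc` (both `bold_series`) and `auc`.
#' @export
block_bold <- function(block_result, module, p = hrf_params(), tr = 2,
                       grid_dt = 0.010, noise_sd = 0, baseline_offset = 1) {
  stopifnot(inherits(block_result, "block_result"))
  b <- block_result$block
  t_end <- b$cue_duration + b$task_duration + b$rest_duration
  window <- c(-7 * tr, t_end)
  d <- trace_to_demand(block_result$trace, module, grid_dt, window)
  raw <- predict_bold(d, p, tr)
  if (noise_sd > 0) raw$values <- raw$values + stats::rnorm(length(raw$values), 0, noise_sd)
  pc <- percent_change(raw, baseline_offset = baseline_offset)
  list(raw = raw, pc = pc,
       auc = bold_auc(pc, c(b$cue_duration, b$cue_duration + b$task_duration)))
}

#' Task-window AUC per block and module of an experiment
#'
#' @param experiment An `experiment_result`.
#' @param modules Modules to predict (default the declarative and
#'   problem-state modules, the regions of interest of the ROI analysis).
#' @param p An [hrf_params()] object.
#' @param ... Passed to [block_bold()].
#' @return A data.frame: run, block, condition, module, auc.
#' @export
auc_by_condition <- function(experiment,
                             modules = c("declarative", "problem_state"),
                             p = hrf_params(), ...) {
  stopifnot(inherits(experiment, "experiment_result"))
  rows <- list()
  for (r in seq_along(experiment$runs)) {
    run <- experiment$runs[[r]]
    for (b in seq_along(run$blocks)) {
      br <- run$blocks[[b]]
      for (m in modules) {
        rows[[length(rows) + 1L]] <- data.frame(
          run = r, block = b, condition = br$block$condition, module = m,
          auc = block_bold(br, m, p, ...)$auc, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
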