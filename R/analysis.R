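# Behavioral summaries, repeated-measures comparisons, and grid-search
# calibration of the engine's two free timing parameters.

#' Summarize behavioral performance per condition
#'
#' Mean reaction time over answered (non-timed-out) trials, accuracy over
#' all presented trials (a timed-out trial counts as an error), and the
#' mean and SD of completed trials per 30 s block.
#'
#' @param x An `experiment_result`, or a list with elements `trials` and
#'   `blocks` shaped like [experiment_trials()] / [experiment_blocks()]
#'   output.
#' @return A data.frame with one row per condition: `condition`,
#'   `mean_rt`, `accuracy`, `trials_per_block`, `trials_per_block_sd`,
#'   `n_blocks`.
#' @export
summarize_behavior <- function(x) {
  if (inherits(x, "experiment_result")) {
    trials <- experiment_trials(x)
    blocks <- experiment_blocks(x)
  } else if (is.list(x) && all(c("trials", "blocks") %in% names(x))) {
    trials <- x$trials
    blocks <- x$blocks
  } else {
    stop("`x` must be an experiment_result or a list(trials=, blocks=)",
         call. = FALSE)
  }
  conds <- sort(unique(blocks$condition))
  out <- lapply(conds, function(cc) {
    tr <- trials[trials$condition == cc, , drop = FALSE]
    bl <- blocks[blocks$condition == cc, , drop = FALSE]
    if (nrow(bl) == 0L) stop("no blocks for condition ", cc, call. = FALSE)
    data.frame(
      condition = cc,
      mean_rt = mean(tr$rt[!tr$timed_out]),
      accuracy = mean(tr$correct & !tr$timed_out),
      trials_per_block = mean(bl$n_completed),
      trials_per_block_sd = stats::sd(bl$n_completed),
      n_blocks = nrow(bl),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' One-way repeated-measures ANOVA
#'
#' Classical subject-by-condition repeated-measures F test with
#' `(k - 1, (k - 1)(n - 1))` degrees of freedom, computed through
#' [stats::aov()] with a subject error stratum.  No sphericity correction
#' is applied.
#'
#' @param tab A numeric matrix or data.frame, one row per subject and one
#'   column per condition; no missing cells.
#' @return List with elements `F`, `df` (length 2), `p`.
#' @export
repeated_measures_anova <- function(tab) {
  tab <- as.matrix(tab)
  if (!is.numeric(tab) || anyNA(tab)) {
    stop("`tab` must be a complete numeric subject x condition table",
         call. = FALSE)
  }
  n <- nrow(tab); k <- ncol(tab)
  if (n < 2L || k < 2L) {
    stop("need at least 2 subjects and 2 conditions", call. = FALSE)
  }
  long <- data.frame(
    value = as.vector(tab),
    condition = factor(rep(seq_len(k), each = n)),
    subject = factor(rep(seq_len(n), times = k))
  )
  fit <- stats::aov(value ~ condition + Error(subject), data = long)
  within <- summary(fit)[["Error: Within"]][[1L]]
  ss_cond <- within["condition", "Sum Sq"]
  f <- within["condition", "F value"]
  df <- c(k - 1L, (k - 1L) * (n - 1L))
  # a numerically-zero condition effect is an exact zero, even when the
  # residual is itself zero to rounding error
  ss_scale <- sum((tab - mean(tab))^2)
  if (ss_cond <= 1e-10 * max(ss_scale, .Machine$double.xmin)) {
    f <- 0
  } else if (!is.finite(f)) {
    f <- Inf
  }
  p <- stats::pf(f, df[1L], df[2L], lower.tail = FALSE)
  list(F = f, df = df, p = p)
}

#' Compare task-window AUC between conditions per module/ROI
#'
#' Runs a repeated-measures F test on the subject-by-condition AUC table
#' of each module and reports the direction of the reasoning-minus-
#' calculation difference.
#'
#' @param auc_table A data.frame with columns `subject`, `condition`,
#'   `module`, `auc` (one value per subject x condition x module; repeats
#'   are averaged).
#' @return A data.frame per module: `module`, `F`, `df1`, `df2`, `p`,
#'   `rea_minus_cal`, `direction`.
#' @export
compare_auc <- function(auc_table) {
  need <- c("subject", "condition", "module", "auc")
  if (!all(need %in% names(auc_table))) {
    stop("auc_table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(unique(auc_table$module), function(m) {
    d <- auc_table[auc_table$module == m, , drop = FALSE]
    agg <- stats::aggregate(auc ~ subject + condition, d, mean)
    wide <- stats::reshape(agg, idvar = "subject", timevar = "condition",
                           direction = "wide")
    tab <- as.matrix(wide[, -1L, drop = FALSE])
    colnames(tab) <- sub("^auc\\.", "", colnames(tab))
    res <- repeated_measures_anova(tab)
    diff <- if (all(c("Rea", "Cal") %in% colnames(tab))) {
      mean(tab[, "Rea"]) - mean(tab[, "Cal"])
    } else {
      NA_real_
    }
    data.frame(module = m, F = res$F, df1 = res$df[1L], df2 = res$df[2L],
               p = res$p, rea_minus_cal = diff,
               direction = if (is.na(diff)) NA_character_ else
                 if (diff > 0) "Rea>Cal" else "Cal>Rea",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Calibrate the latency factor and problem-state change by grid search
#'
#' Simulates the experiment at every grid point and minimizes the summed
#' squared error between simulated and target per-condition mean RT and
#' trials per block.  Both measures are z-scaled by the spread of the
#' target values across conditions so that they contribute equally.  Ties
#' are broken toward the smaller latency factor, then the smaller
#' problem-state change.
#'
#' @param targets A data.frame with columns `condition`, `mean_rt`,
#'   `trials_per_block` (e.g. [summarize_behavior()] output).
#' @param grid_F,grid_dt Numeric vectors of candidate latency factors and
#'   problem-state change durations (seconds).
#' @param params Baseline [engine_params()]; each grid point replaces its
#'   `latency_factor` and `problem_state_dt`.
#' @param n_reps Simulated experiments per grid point.
#' @param n_runs Runs per simulated experiment.
#' @param seed Seed used (identically) for every grid point, making the
#'   search deterministic and comparisons use common random numbers.
#' @return A `fit_result` list: `latency_factor`, `problem_state_dt`,
#'   `activation`, `loss`, and the full `grid` of losses.
#' @export
fit_parameters <- function(targets, grid_F = seq(0.2, 0.6, by = 0.1),
                           grid_dt = seq(0.2, 0.6, by = 0.1),
                           params = engine_params(), n_reps = 1L,
                           n_runs = 2L, seed = 1L) {
  if (length(grid_F) == 0L || length(grid_dt) == 0L) {
    stop("empty parameter grid", call. = FALSE)
  }
  need <- c("condition", "mean_rt", "trials_per_block")
  if (!all(need %in% names(targets))) {
    stop("targets must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  targets <- targets[order(targets$condition), , drop = FALSE]
  s_rt <- stats::sd(targets$mean_rt)
  s_tpb <- stats::sd(targets$trials_per_block)
  if (!is.finite(s_rt) || s_rt == 0) s_rt <- 1
  if (!is.finite(s_tpb) || s_tpb == 0) s_tpb <- 1

  grid <- expand.grid(latency_factor = sort(grid_F),
                      problem_state_dt = sort(grid_dt))
  grid$loss <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p <- params
    p$latency_factor <- grid$latency_factor[i]
    p$problem_state_dt <- grid$problem_state_dt[i]
    set.seed(seed)
    sims <- lapply(seq_len(n_reps), function(r) {
      summarize_behavior(run_experiment(p, n_runs = n_runs))
    })
    sim <- Reduce(`+`, lapply(sims, function(s) {
      as.matrix(s[order(s$condition), c("mean_rt", "trials_per_block")])
    })) / n_reps
    grid$loss[i] <- sum(((sim[, "mean_rt"] - targets$mean_rt) / s_rt)^2 +
                        ((sim[, "trials_per_block"] - targets$trials_per_block) / s_tpb)^2)
  }
  ord <- order(grid$loss, grid$latency_factor, grid$problem_state_dt)
  best <- grid[ord[1L], ]
  structure(list(latency_factor = best$latency_factor,
                 problem_state_dt = best$problem_state_dt,
                 activation = params$activation,
                 loss = best$loss, grid = grid),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> latency_factor = %.3g, problem_state_dt = %.3g, loss = %.4g\n",
              x$latency_factor, x$problem_state_dt, x$loss))
  invisible(x)
}
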