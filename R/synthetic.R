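# Virtual-participant datasets with known ground truth: each subject is
# one simulated experiment, given subject-level RT jitter, response flips
# and additive Gaussian scan noise on the raw BOLD signal.

#' Specification of a synthetic participant sample
#'
#' @param n_subjects Number of participants (default 15, the study sample).
#' @param rt_noise_sd SD (log scale) of the lognormal multiplicative
#'   subject-level RT factor; the factor has mean 1.
#' @param accuracy_flip_prob Probability that a trial's recorded
#'   correctness is flipped.
#' @param bold_noise_sd SD of additive Gaussian scan noise on the raw BOLD
#'   series (raw signal units, i.e. same scale as the convolved
#'   prediction).
#' @param seed Optional integer seed for the whole dataset.
#' @return A `participant_spec` list.
#' @export
participant_spec <- function(n_subjects = 15L, rt_noise_sd = 0.1,
                             accuracy_flip_prob = 0.02,
                             bold_noise_sd = 0.002, seed = NULL) {
  if (accuracy_flip_prob < 0 || accuracy_flip_prob > 1) {
    stop("accuracy_flip_prob must be in [0, 1]", call. = FALSE)
  }
  if (rt_noise_sd < 0 || bold_noise_sd < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 rt_noise_sd = rt_noise_sd,
                 accuracy_flip_prob = accuracy_flip_prob,
                 bold_noise_sd = bold_noise_sd, seed = seed),
            class = "participant_spec")
}

#' Simulate a synthetic participant sample
#'
#' Each subject is one model [run_experiment()]; recorded RTs are scaled by
#' a subject-level lognormal factor (mean 1), trial correctness is flipped
#' with `accuracy_flip_prob`, and (optionally) per-block ROI BOLD series
#' are predicted from the subject's own traces with additive Gaussian scan
#' noise applied to the raw signal before percent change.
#'
#' @param params True [engine_params()] generating the behavior.
#' @param hrf True [hrf_params()] generating the BOLD signal.
#' @param spec A [participant_spec()].
#' @param n_runs Runs per subject.
#' @param modules Modules/ROIs for which BOLD is generated.
#' @param bold Generate BOLD series and AUCs?  (Behavior-only datasets are
#'   much faster and sufficient for parameter recovery.)
#' @param shared_design If `TRUE`, all subjects run the identical stimulus
#'   design and engine simulation (useful for isolating measurement
#'   noise); by default every subject gets an independent simulation.
#' @return A `participant_data` list: `spec`, `behavior` (subject x
#'   condition summaries), `auc` (subject x condition x module) and
#'   `bold` (long percent-change timecourses), the latter two `NULL` when
#'   `bold = FALSE`.
#' @export
simulate_participants <- function(params = engine_params(),
                                  hrf = hrf_params(),
                                  spec = participant_spec(),
                                  n_runs = 2L,
                                  modules = c("declarative", "problem_state"),
                                  bold = TRUE,
                                  shared_design = FALSE) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  shared <- if (shared_design) run_experiment(params, n_runs = n_runs) else NULL

  behav <- list(); aucs <- list(); curves <- list()
  for (s in seq_len(spec$n_subjects)) {
    ex <- if (shared_design) shared else run_experiment(params, n_runs = n_runs)
    f <- if (spec$rt_noise_sd > 0) {
      stats::rlnorm(1, meanlog = -spec$rt_noise_sd^2 / 2, sdlog = spec$rt_noise_sd)
    } else 1
    trials <- experiment_trials(ex)
    trials$rt <- trials$rt * f
    if (spec$accuracy_flip_prob > 0) {
      flip <- stats::runif(nrow(trials)) < spec$accuracy_flip_prob
      trials$correct <- xor(trials$correct, flip)
    }
    sm <- summarize_behavior(list(trials = trials, blocks = experiment_blocks(ex)))
    sm$subject <- s
    behav[[s]] <- sm

    if (bold) {
      for (r in seq_along(ex$runs)) {
        for (b in seq_along(ex$runs[[r]]$blocks)) {
          br <- ex$runs[[r]]$blocks[[b]]
          for (m in modules) {
            bb <- block_bold(br, m, hrf, noise_sd = spec$bold_noise_sd)
            aucs[[length(aucs) + 1L]] <- data.frame(
              subject = s, run = r, block = b,
              condition = br$block$condition, module = m, auc = bb$auc,
              stringsAsFactors = FALSE
            )
            curves[[length(curves) + 1L]] <- data.frame(
              subject = s, run = r, block = b,
              condition = br$block$condition, module = m,
              time_s = bb$pc$times, value = bb$pc$values,
              kind = "percent_change", stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  structure(list(
    spec = spec,
    behavior = do.call(rbind, behav),
    auc = if (bold) do.call(rbind, aucs) else NULL,
    bold = if (bold) do.call(rbind, curves) else NULL
  ), class = "participant_data")
}

#' Parameter-recovery harness
#'
#' Repeatedly generates synthetic behavioral datasets at known
#' `(latency_factor, problem_state_dt)` and refits both parameters by
#' [fit_parameters()], reporting the recovery error in grid steps.
#'
#' @param n_replicates Number of synthetic datasets.
#' @param true_F,true_dt Generating parameter values.
#' @param spec A [participant_spec()] (its `seed` is ignored; per-replicate
#'   seeds derive from `seed`).
#' @param grid_F,grid_dt Search grids passed to [fit_parameters()].
#' @param params Baseline [engine_params()].
#' @param n_runs Runs per subject.
#' @param n_reps Simulated experiments per grid point in the refit
#'   (averaging over stimulus compositions sharpens the loss surface).
#' @param seed Master seed.
#' @return A data.frame with one row per replicate: the true and fitted
#'   values, the loss, and absolute errors expressed in grid steps.
#' @export
recovery_harness <- function(n_replicates = 20L, true_F = 0.4, true_dt = 0.4,
                             spec = participant_spec(),
                             grid_F = seq(0.2, 0.6, by = 0.1),
                             grid_dt = seq(0.2, 0.6, by = 0.1),
                             params = engine_params(), n_runs = 2L,
                             n_reps = 1L, seed = 1L) {
  step_F <- if (length(grid_F) > 1L) min(diff(sort(grid_F))) else 1
  step_dt <- if (length(grid_dt) > 1L) min(diff(sort(grid_dt))) else 1
  true_params <- params
  true_params$latency_factor <- true_F
  true_params$problem_state_dt <- true_dt
  rows <- lapply(seq_len(n_replicates), function(i) {
    sp <- spec
    sp$seed <- seed + i
    dat <- simulate_participants(true_params, spec = sp, n_runs = n_runs,
                                 bold = FALSE)
    tgt <- stats::aggregate(cbind(mean_rt, trials_per_block) ~ condition,
                            dat$behavior, mean)
    fit <- fit_parameters(tgt, grid_F = grid_F, grid_dt = grid_dt,
                          params = params, n_runs = n_runs, n_reps = n_reps,
                          seed = seed + 10000L + i)
    data.frame(replicate = i, true_F = true_F, true_dt = true_dt,
               fit_F = fit$latency_factor, fit_dt = fit$problem_state_dt,
               loss = fit$loss,
               err_F_steps = abs(fit$latency_factor - true_F) / step_F,
               err_dt_steps = abs(fit$problem_state_dt - true_dt) / step_dt)
  })
  do.call(rbind, rows)
}
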