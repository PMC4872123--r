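# Plain-text readers/writers (events TSV, trace TSV, BOLD CSV), YAML
# configuration, and the deterministic end-to-end pipeline.

format_stimulus <- function(stim) {
  if (stim$condition == "Cal") {
    paste(stim$elements[1], stim$operators[1], stim$elements[2],
          stim$operators[2], stim$elements[3])
  } else {
    paste(stim$elements, collapse = ":")
  }
}

# block onset within a run, seconds from run start
block_offset <- function(block, index) {
  (index - 1) * (block$cue_duration + block$task_duration + block$rest_duration)
}

#' Events table of one simulated run
#'
#' One row per presented trial, BIDS-events style: `onset` (s, 0 at run
#' start), `duration` (stimulus phase, i.e. RT or the timeout), then
#' `trial_type`, `stimulus`, `response`, `response_time`, `accuracy`.
#'
#' @param run One element of `experiment_result$runs`.
#' @return A data.frame.
#' @export
run_events <- function(run) {
  rows <- list()
  for (b in seq_along(run$blocks)) {
    br <- run$blocks[[b]]
    off <- block_offset(br$block, b)
    for (trial in br$trials) {
      rows[[length(rows) + 1L]] <- data.frame(
        onset = off + trial$onset,
        duration = if (trial$timed_out) br$block$timeout else trial$rt,
        trial_type = br$block$condition,
        stimulus = format_stimulus(trial$stimulus),
        response = if (trial$timed_out) "n/a" else
          if (trial$correct) trial$stimulus$correct_side else
            setdiff(c("left", "right"), trial$stimulus$correct_side),
        response_time = if (trial$timed_out) NA_real_ else trial$rt,
        accuracy = as.integer(trial$correct && !trial$timed_out),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Write / read an events TSV
#'
#' @param events A data.frame as returned by [run_events()].
#' @param path File path.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns the data.frame.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  read_checked(path, sep = "\t",
               cols = c("onset", "duration", "trial_type", "stimulus",
                        "response", "response_time", "accuracy"))
}

#' Write / read a module trace TSV
#'
#' Columns `module`, `onset`, `duration`, `label`.
#'
#' @param trace A trace (list or data.frame with those fields).
#' @param path File path.
#' @export
write_trace_tsv <- function(trace, path) {
  df <- data.frame(module = trace$module, onset = trace$onset,
                   duration = trace$duration, label = trace$label,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  read_checked(path, sep = "\t",
               cols = c("module", "onset", "duration", "label"))
}

#' Write / read a BOLD timecourse CSV
#'
#' Long format: `time_s`, `value`, `kind`, `module`, `condition` (plus any
#' extra columns present).
#'
#' @param df The timecourse data.frame.
#' @param path File path.
#' @export
write_bold_csv <- function(df, path) {
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bold_csv
#' @export
read_bold_csv <- function(path) {
  read_checked(path, sep = ",",
               cols = c("time_s", "value", "kind", "module", "condition"))
}

# shared checked reader: header must contain the expected columns and every
# row must have the full field count (reports the offending line)
read_checked <- function(path, sep, cols) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  header <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  missing <- setdiff(cols, header)
  if (length(missing) > 0L) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  nf <- lengths(strsplit(lines, sep, fixed = TRUE))
  bad <- which(nf != length(header))
  if (length(bad) > 0L) {
    stop("malformed row at line ", bad[1L], " of ", path,
         " (expected ", length(header), " fields, found ", nf[bad[1L]], ")",
         call. = FALSE)
  }
  utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Collects the master seed, engine/HRF parameter overrides, the design
#' constants (2 runs of 9 blocks; 2 s cue, 30 s task, 30 s rest, 2 s ISI,
#' 10 s timeout; TR 2 s) and synthetic-sample settings into one validated
#' list.  `pipeline_config_from_yaml()` reads the same structure from a
#' YAML file and rejects unknown keys.
#'
#' @param seed Master seed; per-stage child seeds are derived as
#'   `seed + 1000` (experiment), `seed + 2000` (synthetic sample) and
#'   `seed + 3000` (fit), so stages can be rerun in isolation.
#' @param n_runs,tr Design constants.
#' @param engine,hrf Named lists of overrides for [engine_params()] /
#'   [hrf_params()].
#' @param participants Named list of overrides for [participant_spec()].
#' @param fit `NULL` to skip calibration, or a named list with optional
#'   `grid_F`, `grid_dt`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_runs = 2L, tr = 2,
                            engine = list(), hrf = list(),
                            participants = list(), fit = NULL) {
  cfg <- list(seed = as.integer(seed), n_runs = as.integer(n_runs), tr = tr,
              engine = engine, hrf = hrf, participants = participants,
              fit = fit)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML file.
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config YAML must be a mapping", call. = FALSE)
  known <- c("seed", "n_runs", "tr", "engine", "hrf", "participants", "fit")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

validate_config <- function(cfg) {
  if (!is.finite(cfg$seed)) stop("config key 'seed' must be an integer", call. = FALSE)
  if (cfg$n_runs < 1L) stop("config key 'n_runs' must be >= 1", call. = FALSE)
  if (cfg$tr <= 0) stop("config key 'tr' must be positive", call. = FALSE)
  for (key in c("engine", "hrf", "participants")) {
    val <- cfg[[key]]
    if (!is.list(val)) stop("config key '", key, "' must be a mapping", call. = FALSE)
    allowed <- names(formals(switch(key, engine = engine_params,
                                    hrf = hrf_params,
                                    participants = participant_spec)))
    unknown <- setdiff(names(val), allowed)
    if (length(unknown) > 0L) {
      stop("unknown config key(s) under '", key, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Run the full pipeline
#'
#' generate -> simulate -> predict BOLD -> analyze (-> optionally fit),
#' writing every artifact into `out_dir`: per-run events and trace TSVs,
#' per-module percent-change timecourse and AUC CSVs, a behavioral summary
#' CSV, the AUC comparison CSV, an optional fit report YAML, and a
#' plain-text log.  Fully deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the main in-memory results and the
#'   written paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline_log.txt")
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, paste0(...))

  params <- do.call(engine_params, config$engine)
  hp <- do.call(hrf_params, config$hrf)
  say("stage simulate: seed ", config$seed + 1000L, ", n_runs ", config$n_runs,
      ", latency_factor ", params$latency_factor,
      ", problem_state_dt ", params$problem_state_dt)
  ex <- run_experiment(params, n_runs = config$n_runs,
                       seed = config$seed + 1000L)

  paths <- character(0)
  for (r in seq_along(ex$runs)) {
    run <- ex$runs[[r]]
    ep <- file.path(out_dir, sprintf("events_run-%02d.tsv", r))
    write_events_tsv(run_events(run), ep)
    tr_all <- list(module = character(0), onset = numeric(0),
                   duration = numeric(0), label = character(0))
    for (b in seq_along(run$blocks)) {
      br <- run$blocks[[b]]
      off <- block_offset(br$block, b)
      tr_all$module <- c(tr_all$module, br$trace$module)
      tr_all$onset <- c(tr_all$onset, off + br$trace$onset)
      tr_all$duration <- c(tr_all$duration, br$trace$duration)
      tr_all$label <- c(tr_all$label, br$trace$label)
    }
    tp <- file.path(out_dir, sprintf("trace_run-%02d.tsv", r))
    write_trace_tsv(tr_all, tp)
    paths <- c(paths, ep, tp)
  }

  say("stage predict-bold: hrf m ", hp$m, ", s ", hp$s, ", alpha ", hp$alpha)
  modules <- c("declarative", "problem_state")
  curves <- list()
  for (r in seq_along(ex$runs)) {
    for (b in seq_along(ex$runs[[r]]$blocks)) {
      br <- ex$runs[[r]]$blocks[[b]]
      for (m in modules) {
        bb <- block_bold(br, m, hp, tr = config$tr)
        curves[[length(curves) + 1L]] <- data.frame(
          time_s = bb$pc$times, value = bb$pc$values,
          kind = "percent_change", module = m,
          condition = br$block$condition, run = r, block = b,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  bp <- file.path(out_dir, "bold_timecourses.csv")
  write_bold_csv(do.call(rbind, curves), bp)
  auc <- auc_by_condition(ex, modules, hp, tr = config$tr)
  ap <- file.path(out_dir, "bold_auc.csv")
  utils::write.table(auc, ap, sep = ",", quote = FALSE, row.names = FALSE)

  say("stage analyze")
  behav <- summarize_behavior(ex)
  sp <- file.path(out_dir, "behavior_summary.csv")
  utils::write.table(behav, sp, sep = ",", quote = FALSE, row.names = FALSE)
  paths <- c(paths, bp, ap, sp)

  fit <- NULL
  if (!is.null(config$fit)) {
    say("stage fit: seed ", config$seed + 3000L)
    fit_args <- config$fit
    fit <- fit_parameters(behav,
                          grid_F = fit_args$grid_F %||% seq(0.3, 0.5, by = 0.1),
                          grid_dt = fit_args$grid_dt %||% seq(0.3, 0.5, by = 0.1),
                          params = params, n_runs = config$n_runs,
                          seed = config$seed + 3000L)
    fp <- file.path(out_dir, "fit_report.yaml")
    yaml::write_yaml(list(latency_factor = fit$latency_factor,
                          problem_state_dt = fit$problem_state_dt,
                          loss = fit$loss), fp)
    paths <- c(paths, fp)
  }

  writeLines(log_lines, log_path)
  invisible(list(experiment = ex, behavior = behav, auc = auc, fit = fit,
                 paths = c(paths, log_path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
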