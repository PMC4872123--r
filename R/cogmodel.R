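# A minimal ACT-R-style discrete-event engine.  Cognition is simulated as a
# serial critical path of module events (visual encoding, declarative
# retrieval, problem-state updates, production firings, motor presses);
# each strategy below realizes one condition's solution path and emits the
# per-module activity trace that later becomes the BOLD demand function.

#' Engine timing and activation parameters
#'
#' Durations follow the architecture's published defaults (50 ms production
#' firing, 85 ms visual encoding shift, 260 ms button press); the latency
#' factor and problem-state change duration default to the values estimated
#' from behavior (0.4 and 400 ms).  Activation levels per fact class are
#' the engine's calibrated defaults: rote arithmetic facts and number-order
#' (direction) facts are high-activation, deliberate relation/calculation
#' facts are lower, so that retrieval latencies F*exp(-A) produce the
#' observed task-speed ordering.
#'
#' @param latency_factor Latency factor F in seconds.
#' @param problem_state_dt Duration of a problem-state change (s).
#' @param visual_encode_dt Duration of one visual encoding (s).
#' @param production_dt Duration of one production firing (s).
#' @param motor_dt Duration of a button press (s).
#' @param activation Named numeric vector of activation per fact class
#'   (`instruction`, `direction`, `relation`, `rote`, `calc`).
#' @param activation_noise_sd SD of Gaussian noise added to activation on
#'   each retrieval (affects latency).  Setting it to 0 makes the engine
#'   fully deterministic and disables all error processes.
#' @param retrieval_threshold,error_scale Location and scale of the
#'   logistic mis-retrieval probability `plogis((threshold - A)/scale)`.
#' @param slip_prob Per-trial probability of a response slip unrelated to
#'   retrieval (active only when `activation_noise_sd > 0`).
#' @return An object of class `engine_params`.
#' @export
engine_params <- function(latency_factor = 0.4,
                          problem_state_dt = 0.4,
                          visual_encode_dt = 0.085,
                          production_dt = 0.05,
                          motor_dt = 0.26,
                          activation = c(instruction = 1.0,
                                         direction = 0.98,
                                         relation = -0.20,
                                         rote = 0.69,
                                         calc = -0.56),
                          activation_noise_sd = 0.25,
                          retrieval_threshold = -2.2,
                          error_scale = 0.8,
                          slip_prob = 0.01) {
  p <- list(latency_factor = latency_factor,
            problem_state_dt = problem_state_dt,
            visual_encode_dt = visual_encode_dt,
            production_dt = production_dt,
            motor_dt = motor_dt,
            activation = activation,
            activation_noise_sd = activation_noise_sd,
            retrieval_threshold = retrieval_threshold,
            error_scale = error_scale,
            slip_prob = slip_prob)
  durs <- c(p$latency_factor, p$problem_state_dt, p$visual_encode_dt,
            p$production_dt, p$motor_dt)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    stop("all engine durations must be positive", call. = FALSE)
  }
  if (p$activation_noise_sd < 0) stop("activation_noise_sd must be >= 0", call. = FALSE)
  need <- c("instruction", "direction", "relation", "rote", "calc")
  if (!all(need %in% names(p$activation))) {
    stop("activation must name the classes: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  class(p) <- "engine_params"
  p
}

#' Declarative retrieval latency
#'
#' Retrieval time decreases exponentially with the activation of the
#' retrieved fact: `F * exp(-A)`.
#'
#' @param A Activation of the fact.
#' @param F Latency factor in seconds.
#' @return Retrieval latency in seconds.
#' @examples
#' retrieval_time(0, 0.4)      # 0.4
#' retrieval_time(-log(2), 0.4) # 0.8
#' @export
retrieval_time <- function(A, F = 0.4) {
  stopifnot(F > 0)
  F * exp(-A)
}

# -- trace accumulation -------------------------------------------------

new_trace_state <- function(params) {
  e <- new.env(parent = emptyenv())
  e$mod <- character(0)
  e$dur <- numeric(0)
  e$lab <- character(0)
  e$err <- FALSE
  e$p <- params
  e
}

add_event <- function(st, module, duration, label) {
  st$mod <- c(st$mod, module)
  st$dur <- c(st$dur, duration)
  st$lab <- c(st$lab, label)
}

# one visual encoding, preceded by the production that requests it
enc <- function(st, label) {
  add_event(st, "procedural", st$p$production_dt, paste0("request-", label))
  add_event(st, "visual", st$p$visual_encode_dt, label)
}

# one declarative retrieval; records a mis-retrieval on st$err
retr <- function(st, class, label) {
  p <- st$p
  A <- p$activation[[class]]
  noise <- if (p$activation_noise_sd > 0) stats::rnorm(1, 0, p$activation_noise_sd) else 0
  add_event(st, "procedural", p$production_dt, paste0("request-", label))
  add_event(st, "declarative", retrieval_time(A + noise, p$latency_factor), label)
  failed <- if (p$activation_noise_sd > 0) {
    stats::runif(1) < stats::plogis((p$retrieval_threshold - A) / p$error_scale)
  } else {
    A < p$retrieval_threshold
  }
  if (failed) st$err <- TRUE
}

ps_update <- function(st, label) {
  add_event(st, "procedural", st$p$production_dt, paste0("request-", label))
  add_event(st, "problem_state", st$p$problem_state_dt, label)
}

compare <- function(st, label) add_event(st, "procedural", st$p$production_dt, label)

press <- function(st, label) {
  add_event(st, "procedural", st$p$production_dt, paste0("request-", label))
  add_event(st, "motor", st$p$motor_dt, label)
}

finish_trace <- function(st) {
  onset <- c(0, cumsum(st$dur))[seq_along(st$dur)]
  list(module = st$mod, onset = onset, duration = st$dur, label = st$lab,
       total = sum(st$dur), err = st$err)
}

# -- condition strategies -----------------------------------------------

rea_trace <- function(stimulus, params) {
  st <- new_trace_state(params)
  enc(st, "number-1"); enc(st, "number-2")
  retr(st, "direction", "direction-1")
  ps_update(st, "store-direction-1")
  retr(st, "relation", "relation-1")
  ps_update(st, "store-relation-1")
  enc(st, "number-3")
  retr(st, "direction", "direction-2")
  compare(st, "compare-directions")
  d1 <- stimulus$elements[2L] - stimulus$elements[1L]
  d2 <- stimulus$elements[3L] - stimulus$elements[2L]
  if (sign(d1) == sign(d2)) {
    retr(st, "relation", "relation-2")
    compare(st, "compare-relations")
  }
  ps_update(st, "represent-answer")
  press(st, "respond")
  finish_trace(st)
}

cal_trace <- function(stimulus, params) {
  st <- new_trace_state(params)
  for (lab in c("number-1", "operator-1", "number-2", "operator-2", "number-3")) {
    enc(st, lab)
  }
  retr(st, "rote", "intermediate-result")
  ps_update(st, "store-intermediate")
  retr(st, "calc", "final-result")
  ps_update(st, "represent-answer")
  press(st, "respond")
  finish_trace(st)
}

jud_trace <- function(stimulus, params) {
  st <- new_trace_state(params)
  for (k in 1:3) {
    enc(st, paste0("number-", k))
    if (stimulus$elements[k] == 10L) break
  }
  ps_update(st, "represent-answer")
  press(st, "respond")
  finish_trace(st)
}

# option-selection phase: encode the two options, pick the matching side
option_trace <- function(params) {
  st <- new_trace_state(params)
  enc(st, "options")
  press(st, "select")
  finish_trace(st)
}

#' Simulate one trial
#'
#' Runs the condition-specific solution strategy on one stimulus and
#' returns the reaction time (stimulus onset to first button press), the
#' response correctness, the option-selection-phase duration and the full
#' module activity trace (onsets relative to stimulus onset; the trace
#' spans both the stimulus and the option phase).
#'
#' @param stimulus An `actr_stimulus`.
#' @param params An [engine_params()] object.
#' @param timeout Stimulus timeout in seconds (default 10); an unanswered
#'   stimulus disappears and the trial is marked timed out.
#' @return A `trial_result` list with fields `stimulus`, `rt`, `correct`,
#'   `timed_out`, `option_phase_dt` and `trace`.
#' @export
simulate_trial <- function(stimulus, params = engine_params(), timeout = 10) {
  stopifnot(inherits(stimulus, "actr_stimulus"))
  tr <- switch(stimulus$condition,
               Rea = rea_trace(stimulus, params),
               Cal = cal_trace(stimulus, params),
               Jud = jud_trace(stimulus, params))
  if (tr$total > timeout) {
    keep <- tr$onset < timeout
    dur <- tr$duration[keep]
    onset <- tr$onset[keep]
    dur[length(dur)] <- min(dur[length(dur)], timeout - onset[length(onset)])
    return(structure(list(
      stimulus = stimulus, rt = NA_real_, correct = FALSE, timed_out = TRUE,
      option_phase_dt = 0,
      trace = list(module = tr$module[keep], onset = onset, duration = dur,
                   label = tr$label[keep])
    ), class = "trial_result"))
  }
  opt <- option_trace(params)
  slip <- params$activation_noise_sd > 0 && stats::runif(1) < params$slip_prob
  correct <- !tr$err && !slip
  structure(list(
    stimulus = stimulus, rt = tr$total, correct = correct, timed_out = FALSE,
    option_phase_dt = opt$total,
    trace = list(module = c(tr$module, opt$module),
                 onset = c(tr$onset, tr$total + opt$onset),
                 duration = c(tr$duration, opt$duration),
                 label = c(tr$label, opt$label))
  ), class = "trial_result")
}

# cue processing at block start: encode the cue, represent the task in the
# problem state, retrieve the task instruction
cue_trace <- function(params) {
  st <- new_trace_state(params)
  enc(st, "cue")
  ps_update(st, "represent-task")
  retr(st, "instruction", "retrieve-instruction")
  finish_trace(st)
}

#' Run one self-paced block
#'
#' Executes trials back to back (stimulus phase up to the first press, then
#' the option-selection phase, then the 2 s ISI) until the 30 s task window
#' closes.  A trial whose option-phase press has not occurred when the
#' window closes is truncated and not counted.  Block-local time 0 is cue
#' onset; trials start at `cue_duration`.
#'
#' @param block A `block_design` from [build_block()].
#' @param params An [engine_params()] object.
#' @return A `block_result` list: `block`, `trials` (completed and
#'   timed-out trials), `n_completed`, and the merged module `trace`
#'   clipped to the cue+task window (the rest period holds no events).
#' @export
run_block <- function(block, params = engine_params()) {
  stopifnot(inherits(block, "block_design"))
  task_start <- block$cue_duration
  task_end <- block$cue_duration + block$task_duration

  cue <- cue_trace(params)
  mod <- list(cue$module); ons <- list(cue$onset); dur <- list(cue$duration)
  lab <- list(cue$label)

  trials <- list()
  n_completed <- 0L
  t <- task_start
  i <- 1L
  while (t < task_end) {
    if (i > length(block$stimuli)) {
      stop("stimulus pool exhausted; increase pool_size", call. = FALSE)
    }
    trial <- simulate_trial(block$stimuli[[i]], params, timeout = block$timeout)
    consumed <- if (trial$timed_out) block$timeout else trial$rt + trial$option_phase_dt
    if (t + consumed > task_end) {
      # window closed mid-trial: clip its events into the trace, drop the trial
      keep <- t + trial$trace$onset < task_end
      if (any(keep)) {
        o <- trial$trace$onset[keep]; d <- trial$trace$duration[keep]
        d[length(d)] <- min(d[length(d)], task_end - t - o[length(o)])
        mod <- c(mod, list(trial$trace$module[keep]))
        ons <- c(ons, list(t + o)); dur <- c(dur, list(d))
        lab <- c(lab, list(trial$trace$label[keep]))
      }
      break
    }
    mod <- c(mod, list(trial$trace$module))
    ons <- c(ons, list(t + trial$trace$onset))
    dur <- c(dur, list(trial$trace$duration))
    lab <- c(lab, list(trial$trace$label))
    trial$onset <- t   # block-local stimulus onset, for the events writer
    trials[[length(trials) + 1L]] <- trial
    if (!trial$timed_out) n_completed <- n_completed + 1L
    t <- t + consumed + block$isi
    i <- i + 1L
  }

  structure(list(
    block = block,
    trials = trials,
    n_completed = n_completed,
    trace = list(module = unlist(mod), onset = unlist(ons),
                 duration = unlist(dur), label = unlist(lab))
  ), class = "block_result")
}

#' Run a full simulated experiment
#'
#' Builds `n_runs` runs of 9 blocks (3 per condition) and simulates every
#' block with the given engine parameters.  Deterministic given `seed`.
#'
#' @param params An [engine_params()] object.
#' @param n_runs Number of runs (default 2, the scanning design).
#' @param seed Optional integer seed.
#' @param ... Passed to [build_run()] (e.g. `pool_size`).
#' @return An `experiment_result`: list of runs, each holding the
#'   `run_design` and its `block_result`s, plus the engine params.
#' @export
run_experiment <- function(params = engine_params(), n_runs = 2L,
                           seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  runs <- lapply(seq_len(n_runs), function(r) {
    design <- build_run(run_index = r, ...)
    results <- lapply(design$blocks, run_block, params = params)
    list(design = design, blocks = results)
  })
  structure(list(runs = runs, params = params), class = "experiment_result")
}

# flatten an experiment into one trial-level data.frame
#' Trial-level table of an experiment
#'
#' @param experiment An `experiment_result`.
#' @return A data.frame with one row per presented trial: run, block index,
#'   condition, rt, correct, timed_out, option_phase_dt.
#' @export
experiment_trials <- function(experiment) {
  stopifnot(inherits(experiment, "experiment_result"))
  rows <- list()
  for (r in seq_along(experiment$runs)) {
    run <- experiment$runs[[r]]
    for (b in seq_along(run$blocks)) {
      br <- run$blocks[[b]]
      for (trial in br$trials) {
        rows[[length(rows) + 1L]] <- data.frame(
          run = r, block = b, condition = br$block$condition,
          rt = trial$rt, correct = trial$correct,
          timed_out = trial$timed_out,
          option_phase_dt = trial$option_phase_dt,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Per-block completion counts of an experiment
#'
#' @param experiment An `experiment_result`.
#' @return A data.frame with run, block, condition, n_completed.
#' @export
experiment_blocks <- function(experiment) {
  stopifnot(inherits(experiment, "experiment_result"))
  rows <- list()
  for (r in seq_along(experiment$runs)) {
    run <- experiment$runs[[r]]
    for (b in seq_along(run$blocks)) {
      br <- run$blocks[[b]]
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, block = b, condition = br$block$condition,
        n_completed = br$n_completed, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
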