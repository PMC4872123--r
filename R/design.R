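# Block and run construction under the scanning design: 2 runs x 9 blocks
# (3 per condition), 2 s cue + 30 s self-paced task + 30 s rest per block,
# 2 s ISI, 10 s stimulus timeout.

CONDITIONS <- c("Rea", "Cal", "Jud")

#' Build one task block
#'
#' Pre-generates a shuffled stimulus pool large enough that the self-paced
#' 30 s task window can never exhaust it.  Condition-specific constraints:
#' a Rea pool contains exactly one invalid series (random position), with
#' rule signs counterbalanced among the valid ones; a Cal pool
#' counterbalances the four operator pairs; a Jud pool has the target "10"
#' present in half the items with its position counterbalanced.
#'
#' @param condition `"Rea"`, `"Cal"` or `"Jud"`.
#' @param pool_size Number of stimuli pre-generated (default 12).
#' @param foil_distances Passed to [cal_problem()].
#' @param cue_duration,task_duration,rest_duration,isi,timeout Block timing
#'   constants in seconds.
#' @return A `block_design` list.
#' @export
build_block <- function(condition = c("Rea", "Cal", "Jud"), pool_size = 12L,
                        foil_distances = 1:2, cue_duration = 2,
                        task_duration = 30, rest_duration = 30, isi = 2,
                        timeout = 10) {
  condition <- match.arg(condition)
  stopifnot(pool_size >= 4L)
  pool <- switch(condition,
    Rea = {
      n_valid <- pool_size - 1L
      signs <- sample(rep_len(c("+", "-"), n_valid))
      items <- lapply(signs, function(s) rea_problem(valid = TRUE, rule_sign = s))
      inv <- rea_problem(valid = FALSE, rule_sign = sample(c("+", "-"), 1L))
      append(items, list(inv), after = sample.int(n_valid + 1L, 1L) - 1L)
    },
    Cal = {
      combos <- expand.grid(c("+", "-"), c("+", "-"), stringsAsFactors = FALSE)
      idx <- sample(rep_len(seq_len(4L), pool_size))
      lapply(idx, function(i) {
        cal_problem(ops = unlist(combos[i, ], use.names = FALSE),
                    foil_distances = foil_distances)
      })
    },
    Jud = {
      n_present <- pool_size %/% 2L
      positions <- rep_len(1:3, n_present)
      items <- c(
        lapply(positions, function(p) jud_problem(TRUE, target_position = p)),
        lapply(seq_len(pool_size - n_present), function(i) jud_problem(FALSE))
      )
      sample(items)
    }
  )
  structure(
    list(condition = condition, cue_duration = cue_duration,
         task_duration = task_duration, rest_duration = rest_duration,
         isi = isi, timeout = timeout, stimuli = pool),
    class = "block_design"
  )
}

# Condition order for one run: 3 blocks of each condition, randomized with
# the constraint that no three consecutive blocks share a condition.
sample_block_order <- function(max_tries = 1000L) {
  base <- rep(CONDITIONS, each = 3L)
  for (i in seq_len(max_tries)) {
    ord <- sample(base)
    runs <- rle(ord)$lengths
    if (all(runs <= 2L)) return(ord)
  }
  stop("failed to find an admissible block order", call. = FALSE)
}

#' Build one run of 9 blocks
#'
#' @param run_index Integer label for the run.
#' @param ... Passed to [build_block()].
#' @return A `run_design` list with `blocks` and `run_index`.
#' @export
build_run <- function(run_index = 1L, ...) {
  ord <- sample_block_order()
  blocks <- lapply(ord, function(cond) build_block(cond, ...))
  structure(list(blocks = blocks, run_index = as.integer(run_index)),
            class = "run_design")
}

#' @export
print.run_design <- function(x, ...) {
  cat(sprintf("<run_design %d> blocks: %s\n", x$run_index,
              paste(vapply(x$blocks, `[[`, "", "condition"), collapse = " ")))
  invisible(x)
}
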