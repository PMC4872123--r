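#' Rule underlying a three-number series
#'
#' A three-number series such as 5:11:17 follows a rule when the two
#' successive differences are identical and non-zero; the rule is that
#' common signed difference (here +6).  A series like 19:14:17 (differences
#' -5 and +3) has no rule.
#'
#' @param triple Integer vector of length 3.
#' @return The signed integer rule, or `NA_integer_` when the two
#'   differences disagree or are zero.
#' @examples
#' series_rule(c(5, 11, 17))   # 6
#' series_rule(c(19, 14, 17))  # NA
#' @export
series_rule <- function(triple) {
  if (length(triple) != 3L || any(is.na(triple)) || !is.numeric(triple) ||
      any(triple != round(triple))) {
    stop("`triple` must be three non-missing integers", call. = FALSE)
  }
  d1 <- triple[2L] - triple[1L]
  d2 <- triple[3L] - triple[2L]
  if (d1 == d2 && d1 != 0) as.integer(d1) else NA_integer_
}

new_stimulus <- function(condition, elements, operators = NULL, rule = NA_integer_,
                         correct_answer, options, correct_side) {
  structure(
    list(
      condition = condition, elements = as.integer(elements),
      operators = operators, rule = rule, correct_answer = correct_answer,
      options = options, correct_side = correct_side
    ),
    class = "actr_stimulus"
  )
}

#' @export
print.actr_stimulus <- function(x, ...) {
  body <- if (x$condition == "Cal") {
    paste(x$elements[1], x$operators[1], x$elements[2], x$operators[2],
          x$elements[3])
  } else {
    paste(x$elements, collapse = ":")
  }
  cat(sprintf("<%s> %s  answer: %s  options: [%s | %s]\n", x$condition, body,
              x$correct_answer, x$options[1], x$options[2]))
  invisible(x)
}

# Random side assignment shared by all three generators: the correct answer
# is shown left or right with equal probability.
assign_side <- function(correct, foil) {
  if (stats::runif(1) < 0.5) {
    list(options = c(correct, foil), correct_side = "left")
  } else {
    list(options = c(foil, correct), correct_side = "right")
  }
}

#' Generate a number-series reasoning (Rea) problem
#'
#' Elements are three integers in 1-50.  A valid series has a common signed
#' difference (the rule); an invalid one has two different differences.  The
#' response options are the validity labels, side-randomized.
#'
#' @param valid Logical; should the series follow a single rule?
#' @param rule_sign `"+"` or `"-"`; sign of the rule for valid series (for
#'   invalid series, of the first difference).
#' @param rule_range Integer vector of admissible rule magnitudes.
#' @return An `actr_stimulus`.
#' @export
rea_problem <- function(valid = TRUE, rule_sign = c("+", "-"),
                        rule_range = 2:9) {
  rule_sign <- match.arg(rule_sign)
  sgn <- if (rule_sign == "+") 1L else -1L
  if (valid) {
    d <- sgn * sample(rule_range, 1L)
    lo <- max(1L, 1L - 2L * d)
    hi <- min(50L, 50L - 2L * d)
    a <- sample(seq.int(lo, hi), 1L)
    el <- c(a, a + d, a + 2L * d)
    stim <- new_stimulus("Rea", el, rule = d, correct_answer = "valid",
                         options = NULL, correct_side = NA)
    return(label_options(stim, c("valid", "invalid")))
  }
  # invalid: two different non-zero differences, first with the requested sign
  for (i in 1:1000) {
    d1 <- sgn * sample(rule_range, 1L)
    d2 <- sample(c(-rule_range, rule_range), 1L)
    if (d2 == d1) next
    lo <- max(1L, 1L - d1, 1L - d1 - d2)
    hi <- min(50L, 50L - d1, 50L - d1 - d2)
    if (lo > hi) next
    a <- sample(seq.int(lo, hi), 1L)
    el <- c(a, a + d1, a + d1 + d2)
    stim <- new_stimulus("Rea", el, rule = NA_integer_,
                         correct_answer = "invalid",
                         options = NULL, correct_side = NA)
    return(label_options(stim, c("valid", "invalid")))
  }
  stop("could not generate an invalid series under the element constraints",
       call. = FALSE)
}

# Rea/Jud options are category labels; attach them with a random side.
# (Done outside new_stimulus so the generators above stay readable.)
label_options <- function(stim, labels) {
  correct <- stim$correct_answer
  foil <- setdiff(labels, correct)
  side <- assign_side(correct, foil)
  stim$options <- side$options
  stim$correct_side <- side$correct_side
  stim
}

#' Generate a three-term calculation (Cal) problem
#'
#' An expression `a op1 b op2 c` with operators drawn from `{+, -}`; the
#' intermediate result and the final answer both stay in 1-50.  The foil
#' answer option differs from the correct answer by 1 or 2 (configurable).
#'
#' @param ops Optional character vector of two operators (`"+"`/`"-"`); if
#'   `NULL` they are drawn at random (block builders pass balanced sets).
#' @param foil_distances Integer vector the |foil - correct| distance is
#'   drawn from.
#' @return An `actr_stimulus`.
#' @export
cal_problem <- function(ops = NULL, foil_distances = 1:2) {
  if (is.null(ops)) ops <- sample(c("+", "-"), 2L, replace = TRUE)
  stopifnot(length(ops) == 2L, all(ops %in% c("+", "-")))
  apply_op <- function(x, op, y) if (op == "+") x + y else x - y
  repeat {
    el <- sample.int(50L, 3L, replace = TRUE)
    mid <- apply_op(el[1L], ops[1L], el[2L])
    if (mid < 1L || mid > 50L) next
    ans <- apply_op(mid, ops[2L], el[3L])
    if (ans < 1L || ans > 50L) next
    break
  }
  foil <- ans + sample(c(-1L, 1L), 1L) * sample(foil_distances, 1L)
  side <- assign_side(ans, foil)
  new_stimulus("Cal", el, operators = ops, correct_answer = ans,
               options = side$options, correct_side = side$correct_side)
}

#' Generate a perceptual judgment (Jud) problem
#'
#' Three integers in 1-50; the task is to detect whether the digit pair
#' "10" occurs in the sequence.
#'
#' @param contains_ten Logical; should 10 appear?
#' @param target_position Position (1-3) of the 10 when present.
#' @return An `actr_stimulus`.
#' @export
jud_problem <- function(contains_ten = TRUE,
                        target_position = sample.int(3L, 1L)) {
  others <- sample(setdiff(1:50, 10L), 3L, replace = TRUE)
  el <- others
  if (contains_ten) el[target_position] <- 10L
  stim <- new_stimulus("Jud", el, correct_answer = if (contains_ten) "present" else "absent",
                       options = NULL, correct_side = NA)
  label_options(stim, c("present", "absent"))
}
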