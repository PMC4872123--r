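# Independent oracles used across the suite.  These re-derive quantities
# from first principles (textbook formulas, brute-force loops) and must not
# call the package functions they check.

# Textbook one-way repeated-measures ANOVA from raw sums of squares.
rm_anova_ss <- function(tab) {
  tab <- as.matrix(tab)
  n <- nrow(tab); k <- ncol(tab)
  grand <- mean(tab)
  ss_cond <- n * sum((colMeans(tab) - grand)^2)
  ss_subj <- k * sum((rowMeans(tab) - grand)^2)
  ss_tot <- sum((tab - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  f <- (ss_cond / df1) / (ss_err / df2)
  if (!is.finite(f) && ss_cond < 1e-12) f <- 0
  list(F = f, df = c(df1, df2), p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Deterministic (noise-free) critical-path reaction time for one stimulus,
# assembled by hand from the engine's timing constants.
oracle_rt <- function(stim, p) {
  enc <- p$production_dt + p$visual_encode_dt
  ps <- p$production_dt + p$problem_state_dt
  mot <- p$production_dt + p$motor_dt
  rt_of <- function(class) p$production_dt + p$latency_factor * exp(-p$activation[[class]])
  switch(stim$condition,
    Jud = {
      pos <- match(10L, stim$elements)
      k <- if (is.na(pos)) 3L else pos
      k * enc + ps + mot
    },
    Cal = 5 * enc + rt_of("rote") + ps + rt_of("calc") + ps + mot,
    Rea = {
      d1 <- stim$elements[2] - stim$elements[1]
      d2 <- stim$elements[3] - stim$elements[2]
      base <- 3 * enc + 2 * rt_of("direction") + rt_of("relation") +
        3 * ps + p$production_dt + mot
      if (sign(d1) == sign(d2)) base + rt_of("relation") + p$production_dt else base
    }
  )
}

# Option-selection phase duration (noise-free), assembled by hand.
oracle_option_dt <- function(p) {
  (p$production_dt + p$visual_encode_dt) + (p$production_dt + p$motor_dt)
}

# Brute-force step-through of a self-paced block: walks the stimulus pool
# trial by trial using oracle_rt() and counts trials whose option press
# completes inside the task window.
oracle_block_count <- function(block, p) {
  task_end <- block$cue_duration + block$task_duration
  t <- block$cue_duration
  n <- 0L
  for (stim in block$stimuli) {
    rt <- oracle_rt(stim, p)
    done <- t + rt + oracle_option_dt(p)
    if (done > task_end) break
    n <- n + 1L
    t <- done + block$isi
  }
  n
}

# Deterministic engine: the default parameter set with all stochastic
# components switched off.
quiet_params <- function(...) {
  engine_params(activation_noise_sd = 0, ...)
}
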