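test_that("retrieval time follows F*exp(-A) and decreases with activation", {
  expect_equal(retrieval_time(0, 0.4), 0.4)
  expect_equal(retrieval_time(-log(2), 0.4), 0.8)
  A <- sort(runif(20, -2, 2))
  expect_true(all(diff(retrieval_time(A, 0.4)) < 0))
})

test_that("deterministic reaction times equal the hand-computed critical path", {
  p <- quiet_params()
  set.seed(31)
  cases <- list(
    rea_problem(valid = TRUE, rule_sign = "+"),
    rea_problem(valid = FALSE, rule_sign = "-"),
    cal_problem(),
    jud_problem(TRUE, target_position = 2),
    jud_problem(FALSE)
  )
  for (stim in cases) {
    tr <- simulate_trial(stim, p)
    expect_equal(tr$rt, oracle_rt(stim, p), tolerance = 1e-12)
    expect_equal(tr$option_phase_dt, oracle_option_dt(p), tolerance = 1e-12)
    # rt is the end of the stimulus-phase critical path in the trace
    stim_phase <- tr$trace$onset < tr$rt - 1e-9
    expect_equal(sum(tr$trace$duration[stim_phase]), tr$rt, tolerance = 1e-12)
  }
})

test_that("reasoning strategy branches on direction mismatch", {
  p <- quiet_params()
  set.seed(37)
  # opposite-direction invalid series: only one relation retrieval
  repeat {
    s <- rea_problem(valid = FALSE)
    d <- diff(s$elements)
    if (sign(d[1]) != sign(d[2])) break
  }
  tr <- simulate_trial(s, p)
  labs <- tr$trace$label[tr$trace$module == "declarative"]
  expect_identical(sum(grepl("^relation", labs)), 1L)
  expect_identical(sum(grepl("^direction", labs)), 2L)

  v <- rea_problem(valid = TRUE)
  trv <- simulate_trial(v, p)
  labsv <- trv$trace$label[trv$trace$module == "declarative"]
  expect_identical(sum(grepl("^relation", labsv)), 2L)
  expect_identical(sum(grepl("^direction", labsv)), 2L)
  expect_gt(trv$rt, tr$rt)
})

test_that("calculation strategy makes exactly two declarative retrievals", {
  p <- quiet_params()
  set.seed(41)
  tr <- simulate_trial(cal_problem(), p)
  expect_identical(sum(tr$trace$module == "declarative"), 2L)
})

test_that("judgment strategy halts at the target and is position-monotone", {
  p <- quiet_params()
  set.seed(43)
  enc_count <- function(pos) {
    s <- jud_problem(TRUE, target_position = pos)
    tr <- simulate_trial(s, p)
    sum(grepl("^number", tr$trace$label[tr$trace$module == "visual"]))
  }
  expect_identical(enc_count(1), 1L)
  expect_identical(enc_count(3), 3L)
  s0 <- jud_problem(FALSE)
  tr0 <- simulate_trial(s0, p)
  expect_identical(sum(grepl("^number", tr0$trace$label[tr0$trace$module == "visual"])), 3L)
  expect_identical(sum(tr0$trace$module == "declarative"), 0L)
  rt1 <- simulate_trial(jud_problem(TRUE, 1), p)$rt
  rt3 <- simulate_trial(jud_problem(TRUE, 3), p)$rt
  expect_lt(rt1, rt3)
})

test_that("trials are deterministic and accurate when the engine noise is off", {
  p <- quiet_params()
  set.seed(47)
  stim <- cal_problem()
  t1 <- simulate_trial(stim, p)
  t2 <- simulate_trial(stim, p)
  expect_identical(t1$rt, t2$rt)
  set.seed(47)
  ex <- run_experiment(p, n_runs = 1, seed = 47)
  trials <- experiment_trials(ex)
  expect_true(all(trials$correct))
  expect_true(all(trials$rt[!trials$timed_out] <= 10))
})

test_that("very low activation forces a timeout and the trial is truncated", {
  p <- quiet_params()
  p$activation[] <- -4  # retrievals of ~22 s each
  set.seed(53)
  tr <- simulate_trial(cal_problem(), p, timeout = 10)
  expect_true(tr$timed_out)
  expect_true(is.na(tr$rt))
  ends <- tr$trace$onset + tr$trace$duration
  expect_lte(max(ends), 10 + 1e-9)
})

test_that("per-module events never overlap in a block trace", {
  set.seed(59)
  ex <- run_experiment(engine_params(), n_runs = 1, seed = 59)
  for (br in ex$runs[[1]]$blocks) {
    for (m in unique(br$trace$module)) {
      sel <- br$trace$module == m
      o <- br$trace$onset[sel]; d <- br$trace$duration[sel]
      ord <- order(o)
      o <- o[ord]; d <- d[ord]
      if (length(o) > 1) {
        expect_true(all(o[-1] >= o[-length(o)] + d[-length(d)] - 1e-9))
      }
    }
  }
})

test_that("block completion counts match a brute-force step-through oracle", {
  p <- quiet_params()
  set.seed(61)
  for (cond in c("Rea", "Cal", "Jud")) {
    for (i in 1:5) {
      b <- build_block(cond)
      br <- run_block(b, p)
      expect_identical(br$n_completed, oracle_block_count(b, p))
    }
  }
})

test_that("declarative demand per trial orders Rea > Cal > Jud", {
  p <- quiet_params()
  set.seed(67)
  decl_time <- function(stim) {
    tr <- simulate_trial(stim, p)
    sum(tr$trace$duration[tr$trace$module == "declarative"])
  }
  rea <- mean(replicate(20, decl_time(rea_problem(valid = TRUE))))
  cal <- mean(replicate(20, decl_time(cal_problem())))
  jud <- mean(replicate(20, decl_time(jud_problem(TRUE))))
  expect_gt(rea, cal)
  expect_gt(cal, jud)
})

test_that("experiments are reproducible under a fixed seed", {
  e1 <- run_experiment(engine_params(), n_runs = 1, seed = 71)
  e2 <- run_experiment(engine_params(), n_runs = 1, seed = 71)
  expect_identical(experiment_trials(e1), experiment_trials(e2))
  expect_identical(experiment_blocks(e1), experiment_blocks(e2))
})
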