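test_that("gamma response is zero at onset, peaks at alpha*s, integrates to m*s*gamma(alpha+1)", {
  p <- hrf_params(m = 2, s = 0.75, alpha = 6)
  expect_identical(hrf(0, p), 0)
  expect_identical(hrf(-1, p), 0)
  # peak location vs a 1 ms grid search
  tg <- seq(0, 20, by = 0.001)
  expect_lt(abs(tg[which.max(hrf(tg, p))] - p$alpha * p$s), 0.001 + 1e-9)
  # integral vs adaptive quadrature and the closed form
  quad <- stats::integrate(hrf, 0, Inf, p = p, rel.tol = 1e-10)$value
  closed <- p$m * p$s * gamma(p$alpha + 1)
  expect_lt(abs(quad - closed) / closed, 1e-6)
})

test_that("demand discretization covers exactly the event intervals", {
  d0 <- trace_to_demand(list(module = character(0), onset = numeric(0),
                             duration = numeric(0)),
                        "declarative", 0.01, c(0, 10))
  expect_true(all(d0$values == 0))
  d1 <- trace_to_demand(list(module = "declarative", onset = 1.0, duration = 0.4),
                        "declarative", 0.01, c(0, 10))
  expect_identical(sum(d1$values), 40)
  expect_true(all(d1$values %in% c(0, 1)))
  # conservation for non-overlapping grid-aligned events
  tr <- list(module = c("declarative", "declarative"),
             onset = c(0.5, 3.25), duration = c(1.0, 0.75))
  d2 <- trace_to_demand(tr, "declarative", 0.01, c(0, 10))
  expect_equal(sum(d2$values) * 0.01, 1.75, tolerance = 1e-12)
  # overlap is rejected
  bad <- list(module = c("declarative", "declarative"),
              onset = c(1, 1.2), duration = c(0.5, 0.1))
  expect_error(trace_to_demand(bad, "declarative"), "overlap")
})

test_that("convolution matches a brute-force Riemann sum at 1 ms", {
  p <- hrf_params(m = 1, s = 0.75, alpha = 6)
  dt <- 0.001
  tr <- list(module = "declarative", onset = 1, duration = 1)
  d <- trace_to_demand(tr, "declarative", dt, c(0, 16))
  b <- predict_bold(d, p, tr = 2, hrf_span = 20)
  tau_mid <- d$t0 + (seq_along(d$values) - 0.5) * dt
  direct <- vapply(b$times, function(t) {
    sum(d$values * hrf(t - tau_mid, p)) * dt
  }, 0)
  expect_lt(max(abs(b$values - direct)) / max(direct), 1e-6)
})

test_that("prediction is linear in m and additive over disjoint demand", {
  p1 <- hrf_params(m = 1)
  p2 <- hrf_params(m = 2)
  tr <- list(module = "declarative", onset = c(1, 6), duration = c(1, 0.5))
  d <- trace_to_demand(tr, "declarative", 0.01, c(0, 30))
  b1 <- predict_bold(d, p1)
  b2 <- predict_bold(d, p2)
  expect_equal(b2$values, 2 * b1$values, tolerance = 1e-12)

  single <- function(onset, duration) {
    di <- trace_to_demand(list(module = "declarative", onset = onset,
                               duration = duration),
                          "declarative", 0.01, c(0, 30))
    predict_bold(di, p1)$values
  }
  expect_equal(b1$values, single(1, 1) + single(6, 0.5), tolerance = 1e-12)
  # zero demand predicts zero signal
  z <- trace_to_demand(list(module = "visual", onset = 1, duration = 1),
                       "declarative", 0.01, c(0, 30))
  expect_true(all(predict_bold(z, p1)$values == 0))
})

test_that("total raw signal equals HRF integral times demand seconds", {
  p <- hrf_params(m = 1, s = 0.75, alpha = 6)
  set.seed(73)
  onsets <- cumsum(runif(10, 0.5, 2))
  durs <- runif(10, 0.05, 0.6)
  tr <- list(module = "declarative", onset = onsets, duration = durs)
  d <- trace_to_demand(tr, "declarative", 0.01, c(0, 80))
  b <- predict_bold(d, p, hrf_span = 40, keep_fine = TRUE)
  lhs <- sum(b$fine$values) * 0.01
  rhs <- p$m * p$s * gamma(p$alpha + 1) * sum(d$values) * 0.01
  expect_lt(abs(lhs - rhs) / rhs, 1e-3)
})

test_that("halving the grid leaves TR-sampled values unchanged to 1e-4 of scale", {
  p <- hrf_params()
  tr <- list(module = "declarative", onset = c(2, 10.5), duration = c(1, 2))
  v <- lapply(c(0.01, 0.005), function(dt) {
    d <- trace_to_demand(tr, "declarative", dt, c(0, 40))
    predict_bold(d, p)$values
  })
  expect_lt(max(abs(v[[1]] - v[[2]])) / max(abs(v[[1]])), 1e-4)
})

test_that("percent change uses the 7+8 rest-scan baseline", {
  mk <- function(values) {
    structure(list(tr = 2, t0 = -14, times = seq(-14, by = 2, length.out = length(values)),
                   values = values, kind = "raw", module = "declarative"),
              class = "bold_series")
  }
  # constant series -> all zeros
  pc <- percent_change(mk(rep(0.5, 38)))
  expect_true(all(abs(pc$values) < 1e-12))
  # v = 1.01 against baseline 1.00 -> 1 percent
  v <- rep(0, 38); v[12] <- 0.01
  pc <- percent_change(mk(v), baseline_offset = 1)
  expect_equal(pc$values[12], 100 * (1.01 - 1) / 1, tolerance = 1e-9)
  # baseline means first 7 and last 8 scans
  v2 <- rep(0, 38); v2[1:7] <- 0.1; v2[31:38] <- 0.1
  pc2 <- percent_change(mk(v2), baseline_offset = 1)
  expect_equal(pc2$values[12], 100 * (1 - 1.1) / 1.1, tolerance = 1e-9)
  # offset applied inside equals offset applied to the data
  v3 <- runif(38)
  a <- percent_change(mk(v3), baseline_offset = 2)
  b <- percent_change(mk(v3 + 2), baseline_offset = 0)
  expect_equal(a$values, b$values, tolerance = 1e-9)
  # degenerate baseline errors out
  expect_error(percent_change(mk(rep(0, 38)), baseline_offset = 0), "baseline")
})

test_that("AUC is the trapezoidal area over the task window", {
  s <- structure(list(tr = 2, t0 = -14, times = seq(-14, 60, by = 2),
                      values = rep(1, 38), kind = "percent_change",
                      module = "declarative"),
                 class = "bold_series")
  expect_equal(bold_auc(s, c(2, 32)), 30, tolerance = 1e-12)
  expect_error(bold_auc(s, c(10, 10)), "empty")
  # doubling m doubles the raw-series AUC
  tr <- list(module = "declarative", onset = 5, duration = 2)
  d <- trace_to_demand(tr, "declarative", 0.01, c(-14, 62))
  r1 <- predict_bold(d, hrf_params(m = 1))
  r2 <- predict_bold(d, hrf_params(m = 2))
  expect_equal(bold_auc(r2, c(2, 32)), 2 * bold_auc(r1, c(2, 32)),
               tolerance = 1e-12)
})

test_that("predicted task AUC is larger for reasoning than calculation blocks", {
  set.seed(79)
  p <- engine_params()
  auc <- do.call(rbind, lapply(1:6, function(i) auc_by_condition(run_experiment(p))))
  m <- aggregate(auc ~ condition + module, auc, mean)
  for (mod in c("declarative", "problem_state")) {
    v <- m[m$module == mod, ]
    expect_gt(v$auc[v$condition == "Rea"], v$auc[v$condition == "Cal"])
    expect_gt(v$auc[v$condition == "Cal"], v$auc[v$condition == "Jud"])
  }
})
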