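test_that("clean manoeuvre matches the analytic profile and conserves volume", {
  p <- maneuver_params(fvc = 4, pef = 8, rise_time = 0.1, decay_tau = 0.6,
                       duration = 6)
  m <- simulate_maneuver(p)
  expect_identical(m$volume[1], 0)
  expect_equal(m$time[which.max(m$flow)], 0.1)
  expect_lt(abs(max(m$volume) - 4), 1e-3)
  # FEV1 analog strictly below FVC
  v1 <- m$volume[which.min(abs(m$time - 1))]
  expect_lt(v1, max(m$volume))
  # whole volume trajectory against the fine-grid quadrature oracle
  vo <- oracle_volume_trajectory(4, 8, 0.1, 0.6, 6, m$time)
  expect_lt(max(abs(m$volume - vo)), 1e-3)
  # clean manoeuvre: non-negative flow, non-decreasing volume
  expect_true(all(m$flow >= 0))
  expect_true(all(diff(m$volume) >= 0))
})

test_that("mass balance holds across random parameter draws", {
  set.seed(99)
  for (i in 1:8) {
    fvc <- runif(1, 2, 6); pef <- runif(1, 4, 11)
    tau <- runif(1, 0.3, 0.9)
    m <- simulate_maneuver(maneuver_params(fvc = fvc, pef = pef,
                                           rise_time = runif(1, 0.05, 0.2),
                                           decay_tau = tau,
                                           duration = 6 * tau))
    expect_lt(abs(max(m$volume) - fvc), 1e-3)
    # volume is the cumulative quadrature of flow (per-step identity)
    expect_lt(max(abs(diff(m$volume) -
                        (head(m$flow, -1) + tail(m$flow, -1)) / 2 *
                        diff(m$time))), 1e-6)
  }
})

test_that("invalid manoeuvre parameters are rejected", {
  expect_error(maneuver_params(fvc = -1), "fvc")
  expect_error(maneuver_params(pef = 0), "pef")
  expect_error(maneuver_params(duration = 1, decay_tau = 0.6), "duration")
})

test_that("cough perturbs the flow only inside its annotated window", {
  clean <- simulate_maneuver(maneuver_params())
  pp <- maneuver_params(artifact = "cough",
                        artifact_params = list(onset = 2.5, width = 0.08,
                                               amplitude = 4))
  m <- inject_artifact(clean, pp)
  expect_identical(m$label, "unacceptable")
  out <- m$time < 2.5 - 3 * 0.08 | m$time > 2.5 + 3 * 0.08
  expect_identical(m$flow[out], clean$flow[out])
  expect_false(identical(m$flow[!out], clean$flow[!out]))
  expect_equal(m$artifact_annotation$t_start, 2.5 - 0.24)
})

test_that("early termination truncates at the requested volume fraction", {
  clean <- simulate_maneuver(maneuver_params(fvc = 4))
  pp <- maneuver_params(fvc = 4, artifact = "early_termination",
                        artifact_params = list(truncation_fraction = 0.7))
  m <- inject_artifact(clean, pp)
  expect_lt(abs(max(m$volume) / 4 - 0.7), 0.01)
  expect_lt(max(m$time), max(clean$time))
  expect_error(inject_artifact(clean, maneuver_params(
    artifact = "early_termination",
    artifact_params = list(truncation_fraction = 0.95))), "0.9")
})

test_that("submaximal effort lowers and flattens the peak", {
  clean <- simulate_maneuver(maneuver_params())
  pp <- maneuver_params(artifact = "submaximal",
                        artifact_params = list(scale = 0.6))
  m <- inject_artifact(clean, pp)
  expect_lt(max(m$flow), 0.8 * max(clean$flow))
})

test_that("extra breath inserts a negative-flow interval", {
  clean <- simulate_maneuver(maneuver_params())
  pp <- maneuver_params(artifact = "extra_breath", seed = 3)
  m <- inject_artifact(clean, pp)
  expect_lt(min(m$flow), 0)
  a <- m$artifact_annotation
  out <- m$time < a$t_start | m$time > a$t_end
  expect_identical(m$flow[out], clean$flow[out])
})

test_that("artifact injection guards its preconditions", {
  clean <- simulate_maneuver(maneuver_params())
  expect_error(inject_artifact(clean, maneuver_params(artifact = "none")),
               "none")
  pp <- maneuver_params(artifact = "cough")
  withcough <- inject_artifact(clean, pp)
  expect_error(inject_artifact(withcough, pp), "already")
})
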