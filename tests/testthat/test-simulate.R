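# Synthetic two-compartment tracer experiment: simulator, estimator and
# scenario draws.

sim_args <- list(volume_a = 1000, volume_b = 1000, contact_area = 50,
                 wall_thickness = 0.18)
# closed-form decay time for these dimensions at D_eff = 0.41
tau_for <- function(d_eff, a = sim_args) {
  p <- d_eff / a$wall_thickness
  1 / (p * a$contact_area * (1 / a$volume_a + 1 / a$volume_b))
}

test_that("simulated traces follow the closed-form exponential and conserve mass", {
  tau <- tau_for(0.41)
  tr <- do.call(simulate_equilibration,
                c(list(d_eff = 0.41, duration = 3 * tau, dt = tau / 20,
                       seed = 1), sim_args))
  delta <- tr$concentrations_a - tr$concentrations_b
  # Delta(tau)/Delta(0) = exp(-1)
  i_tau <- which.min(abs(tr$times - tau))
  expect_equal(delta[i_tau] / delta[1], exp(-(tr$times[i_tau]) / tau),
               tolerance = 1e-12)
  # total tracer conserved to relative 1e-12 (equal volumes: plain mean)
  total <- tr$concentrations_a * 1000 + tr$concentrations_b * 1000
  expect_lt(diff(range(total)) / mean(total), 1e-12)
  # long-run limit: both compartments at total/(V_a + V_b)
  tr_long <- do.call(simulate_equilibration,
                     c(list(d_eff = 0.41, duration = 50 * tau, dt = tau,
                            seed = 1), sim_args))
  expect_equal(tail(tr_long$concentrations_a, 1), 0.5, tolerance = 1e-9)
  expect_equal(tail(tr_long$concentrations_b, 1), 0.5, tolerance = 1e-9)
})

test_that("degenerate simulator inputs behave as specified", {
  # D_eff = 0: both traces constant
  tr0 <- do.call(simulate_equilibration,
                 c(list(d_eff = 0, duration = 10, dt = 1, seed = 1), sim_args))
  expect_true(all(tr0$concentrations_a == 1))
  expect_true(all(tr0$concentrations_b == 0))
  # identical seed -> identical trace; different seed -> different noise
  mk <- function(seed) do.call(simulate_equilibration,
    c(list(d_eff = 0.41, duration = 10, dt = 0.5, noise_sd = 0.05,
           seed = seed), sim_args))
  expect_identical(mk(42), mk(42))
  expect_false(identical(mk(42)$concentrations_a, mk(43)$concentrations_a))
  # seed is mandatory; invalid geometry errors name the field
  expect_error(simulate_equilibration(0.41, 1000, 1000, 50, 0.18), "seed")
  expect_error(do.call(simulate_equilibration,
                       c(list(d_eff = 0.41, seed = 1),
                         modifyList(sim_args, list(volume_a = -1)))),
               "volume_a")
})

test_that("noise-free simulate -> estimate roundtrip recovers D_eff to 1e-6", {
  for (d_true in c(0.05, 0.41, 2.0)) {
    tau <- tau_for(d_true)
    tr <- do.call(simulate_equilibration,
                  c(list(d_eff = d_true, duration = 3 * tau, dt = tau / 20,
                         seed = 1), sim_args))
    est <- estimate_deff(tr)
    expect_equal(est$d_eff, d_true, tolerance = 1e-6)
  }
})

test_that("noisy recovery: median of 50 seeded replicates within 10% of truth", {
  tau <- tau_for(0.41)
  ests <- vapply(1:50, function(i) {
    tr <- do.call(simulate_equilibration,
                  c(list(d_eff = 0.41, duration = 3 * tau, dt = tau / 20,
                         noise_sd = 0.02, seed = 1000 + i), sim_args))
    estimate_deff(tr)$d_eff
  }, numeric(1))
  expect_lt(abs(median(ests) / 0.41 - 1), 0.10)
})

test_that("estimator bias at 2% noise is below 3% over 200 seeded replicates", {
  tau <- tau_for(0.73)
  ests <- vapply(1:200, function(i) {
    tr <- do.call(simulate_equilibration,
                  c(list(d_eff = 0.73, duration = 3 * tau, dt = tau / 15,
                         noise_sd = 0.02, seed = 5000 + i), sim_args))
    estimate_deff(tr)$d_eff
  }, numeric(1))
  expect_lt(abs(mean(ests) / 0.73 - 1), 0.03)
})

test_that("the estimator rejects non-decaying input", {
  tr0 <- do.call(simulate_equilibration,
                 c(list(d_eff = 0, duration = 10, dt = 1, seed = 1), sim_args))
  expect_error(estimate_deff(tr0), "fit failure")
  # no positive initial difference
  tr_eq <- do.call(simulate_equilibration,
                   c(list(d_eff = 0.41, c0_a = 1, c0_b = 1, duration = 10,
                          dt = 1, seed = 1), sim_args))
  expect_error(estimate_deff(tr_eq), "fit failure")
  short <- do.call(simulate_equilibration,
                   c(list(d_eff = 0.41, duration = 2, dt = 1, seed = 1),
                     sim_args))
  expect_error(estimate_deff(short), "time points")
})

test_that("scenario draws are reproducible, positive and mean-preserving", {
  params <- data.frame(name = c("r_suc", "r_raf"), base = c(4.38, 5.37),
                       cv = c(0.02, 0.02))
  d1 <- generate_scenarios(params, 1000, seed = 11)
  d2 <- generate_scenarios(params, 1000, seed = 11)
  expect_identical(d1, d2)
  expect_true(all(d1$r_suc > 0) && all(d1$r_raf > 0))
  expect_equal(mean(d1$r_suc), 4.38, tolerance = 0.01)
  # cv = 0 reproduces the base exactly
  d0 <- generate_scenarios(data.frame(name = "x", base = 2, cv = 0), 10,
                           seed = 1)
  expect_true(all(d0$x == 2))
  expect_error(generate_scenarios(data.frame(name = "x", base = 2, cv = -1),
                                  10, seed = 1), "cv")
})

test_that("near-cutoff channel hindrance is highly sensitive to radius noise", {
  # 2% radius noise at lambda ~ 0.85 spreads H by more than 2-fold
  draws <- generate_scenarios(
    data.frame(name = "r", base = 0.85 * 6.4, cv = 0.02), 1000, seed = 21)
  h <- hindrance_channel(pmin(draws$r / 6.4, 2))
  q <- quantile(h[h > 0], c(0.05, 0.95))
  expect_gt(q[[2]] / q[[1]], 2)
})

test_that("trace files roundtrip through delimited text with metadata", {
  tr <- do.call(simulate_equilibration,
                c(list(d_eff = 0.41, duration = 10, dt = 0.5, noise_sd = 0.01,
                       seed = 9), sim_args))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$times, tr$times)
  expect_equal(back$concentrations_a, tr$concentrations_a, tolerance = 1e-12)
  expect_equal(back$seed, tr$seed)
  expect_equal(back$wall_thickness, tr$wall_thickness)
})
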