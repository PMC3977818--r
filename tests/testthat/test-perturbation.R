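test_that("perturbations are pure, reversible edits", {
  m <- cached_default_model()
  kd <- perturbation("knockdown", "A20", 10)
  m2 <- apply_perturbation(m, kd)
  expect_equal(get_coefficients(m)[["mdeg_A20"]], 1)
  expect_equal(get_coefficients(m2)[["mdeg_A20"]], 10)
  # resetting the edited coefficient reproduces the original exactly
  m3 <- set_coefficients(m2, c(mdeg_A20 = 1))
  expect_equal(get_coefficients(m3), get_coefficients(m))
  # multiplier 1 is the identity
  m4 <- apply_perturbation(m, perturbation("knockdown", "RelA", 1))
  expect_equal(get_coefficients(m4), get_coefficients(m))
  expect_error(apply_perturbation(m, perturbation("knockdown", "GAPDH")),
               "valid targets")
})

test_that("knockout removes both copies of every gene state", {
  m <- cached_default_model()
  ko <- apply_perturbation(m, perturbation("knockout", "IRF7"))
  gs <- grep("^G_IRF7", ko$species$name)
  expect_true(all(ko$species$initial_count[gs] == 0))
  # other genes untouched
  expect_equal(sum(ko$species$initial_count), sum(m$species$initial_count) - 2)
  # no IRF7 mRNA at the knocked-out steady state
  ss <- steady_state(ko)
  expect_lt(ss[["mIRF7"]], 1e-9)
})

test_that("lognormal dose sampler has the stated mean and CV", {
  spec <- dose_ensemble_spec(mean_molecules = 2e4, cv = 3, n_cells = 1e5,
                             seed = 123)
  set.seed(spec$seed)
  d <- draw_doses(spec)
  # the moment estimator of the CV of a CV-3 lognormal is heavy-tailed
  # (its own sampling error exceeds the tolerance), so mean and CV are
  # checked through the lognormal MLE, which estimates them to ~0.2%
  m <- mean(log(d)); s <- sd(log(d))
  implied_mean <- exp(m + s^2 / 2)
  implied_cv <- sqrt(exp(s^2) - 1)
  expect_lt(abs(implied_mean / 2e4 - 1), 0.02)
  expect_lt(abs(implied_cv / 3 - 1), 0.02)
})

test_that("ensemble bands collapse in the deterministic small-noise limit", {
  m <- cached_default_model()
  sch <- schedule(horizon = 1, output_grid = c(0, 0.5, 1))
  spec <- dose_ensemble_spec(cv = 1e-6, n_cells = 5, seed = 4)
  ens <- run_dose_ensemble(m, spec, sch, mode = "ode")
  for (i in 2:5)
    expect_equal(ens$trajectories[[i]]$counts, ens$trajectories[[1]]$counts,
                 tolerance = 1e-4)
  width <- ens$band_high - ens$band_low
  expect_lt(max(width / pmax(ens$mean, 1)), 1e-3)
})

test_that("ensemble summary matches an independent mean/SE computation", {
  m <- cached_default_model()
  sch <- schedule(horizon = 2, output_grid = c(0, 1, 2))
  spec <- dose_ensemble_spec(n_cells = 8, seed = 11)
  ens <- run_dose_ensemble(m, spec, sch, mode = "ode")
  arr <- simplify2array(lapply(ens$trajectories, function(t) t$counts))
  for (sp in c("NFkBn", "mA20", "IRF3an")) {
    v <- arr[, sp, ]
    mu <- rowMeans(v)
    se <- apply(v, 1, sd) / sqrt(8)
    expect_equal(unname(ens$mean[, sp]), unname(mu))
    expect_equal(unname(ens$band_high[, sp]), unname(mu + 1.96 * se))
    expect_equal(unname(ens$band_low[, sp]), unname(mu - 1.96 * se))
  }
  expect_true(all(ens$band_low <= ens$mean & ens$mean <= ens$band_high))
})

test_that("dose response covers the design and is anchored at zero dose", {
  m <- cached_default_model()
  dr <- dose_response(m, doses_ug = c(0, 1, 5), readouts = c("mA20", "mIkBa"),
                      readout_hr = 6, n_cells = 3, mode = "ode", seed = 2)
  expect_equal(nrow(dr), 3)
  expect_equal(dr$dose_molecules[1], 0)
  ss <- cached_steady_state()
  expect_equal(dr$mA20[1], unname(ss["mA20"]), tolerance = 1e-6)
  # responses increase with dose over this range
  expect_true(all(diff(dr$mA20) > 0))
  expect_true(all(diff(dr$mIkBa) > 0))
})

test_that("fold-change table self-normalizes the control", {
  m <- cached_default_model()
  tab <- kd_foldchange_table(m, list(control = list()),
                             readouts = c("RelA", "A20", "IFNb"))
  ctrl0 <- tab[tab$time == "0h", ]
  expect_equal(ctrl0$fold_change[ctrl0$readout == "RelA"], 1)
  expect_equal(ctrl0$fold_change[ctrl0$readout == "A20"], 1)
  # zero-baseline genes have undefined fold changes
  expect_true(is.na(ctrl0$fold_change[ctrl0$readout == "IFNb"]))
  # stimulation induces A20 in the control
  ctrl6 <- tab[tab$time == "6h", ]
  expect_gt(ctrl6$fold_change[ctrl6$readout == "A20"], 5)
})
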