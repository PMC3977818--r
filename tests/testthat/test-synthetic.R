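test_that("noise-free synthetic data reproduce the generator exactly", {
  spec <- synthetic_spec(rel_noise = 1e-9, scale_range = c(1, 1), seed = 1,
                         times = c(0, 1, 2))
  out <- generate_timeseries(spec)
  fs <- fit_score(out$measurements, out$truth$trajectory)
  expect_lt(fs$score, 1e-6)
  expect_true(all(abs(fs$scales - 1) < 1e-6))
})

test_that("synthetic datasets are reproducible by seed", {
  s1 <- generate_timeseries(synthetic_spec(seed = 5, times = c(0, 1)))
  s2 <- generate_timeseries(synthetic_spec(seed = 5, times = c(0, 1)))
  expect_identical(s1$measurements$data, s2$measurements$data)
  s3 <- generate_timeseries(synthetic_spec(seed = 6, times = c(0, 1)))
  expect_false(identical(s1$measurements$data, s3$measurements$data))
})

test_that("replicate noise realizes the 10% design", {
  out <- generate_timeseries(synthetic_spec(seed = 2))
  d <- out$measurements$data
  cvs <- tapply(d$value, interaction(d$series, d$time_hr), function(v) {
    if (mean(v) <= 0) return(NA_real_)
    sd(v) / mean(v)
  })
  cvs <- cvs[is.finite(cvs)]
  # triplicate CVs scatter widely; their aggregate sits near 10% (within 2
  # percentage points)
  expect_lt(abs(sqrt(mean(cvs^2)) - 0.10), 0.02)
})

test_that("scoring synthetic data at design noise gives the expected level", {
  # replicates enter the score as their mean, so the expected relative
  # deviation is E|mean of 3 LN(1, 10%) - 1| ~ 0.8 * 0.10 / sqrt(3) ~ 0.046,
  # minus a little absorbed by the per-series scale fit
  scores <- vapply(1:3, function(s) {
    out <- generate_timeseries(synthetic_spec(seed = s))
    fit_score(out$measurements, out$truth$trajectory)$score
  }, numeric(1))
  expect_gt(mean(scores), 0.025)
  expect_lt(mean(scores), 0.07)
})

test_that("parameter recovery closes the synthetic loop", {
  # generator: default model with one kinetic coefficient perturbed x5
  # (mRNA degradation changes the curve shape, so the per-series scale
  # cannot absorb it); refinement against the generator-made data must
  # move the coefficient back toward 5x
  truth <- set_coefficients(cached_default_model(), c(mdeg_ISG56 = 5))
  spec <- synthetic_spec(model = truth, rel_noise = 0.05,
                         series_map = c(sISG56 = "mISG56", sA20 = "mA20"),
                         seed = 3)
  out <- generate_timeseries(spec)
  sch <- schedule()
  sim <- function(m) run_ode(m, sch, state0 = cached_steady_state())
  start <- cached_default_model()   # coefficient 1 (wrong by x5)
  ref <- refine_coefficients(start, out$measurements,
                             stages = list("mdeg_ISG56"), simulate = sim,
                             grid = 10^seq(-1, 1, by = 0.25))
  expect_true(all(diff(ref$trace) <= 1e-12))
  expect_lt(ref$score, fit_score(out$measurements, sim(start))$score)
  expect_lt(abs(log10(ref$coefficients[["mdeg_ISG56"]] / 5)), 0.26)
})

test_that("knockdown dataset carries constructed effects through the model", {
  spec <- synthetic_spec(seed = 8)
  kd <- generate_kd_dataset(
    spec,
    perturbations = list(control = list(),
                         RelA = perturbation("knockdown", "RelA", 25)),
    readouts = c("RelA", "A20"))
  expect_true(all(c("perturbation", "readout", "time", "replicate",
                    "fold_change") %in% names(kd)))
  ctrl0 <- kd$fold_change[kd$perturbation == "control" & kd$time == "0h" &
                            kd$readout == "RelA"]
  expect_equal(mean(ctrl0), 1, tolerance = 0.25)
  # RelA knockdown suppresses stimulated A20 induction (Welch-significant)
  a20_ctrl <- kd$fold_change[kd$perturbation == "control" & kd$time == "6h" &
                               kd$readout == "A20"]
  a20_kd <- kd$fold_change[kd$perturbation == "RelA" & kd$time == "6h" &
                             kd$readout == "A20"]
  wt <- welch_test(a20_kd, a20_ctrl)
  expect_lt(wt$p, 0.05)
  expect_equal(wt$sign, -1)
})

test_that("IRF3/IRF7 double knockout silences RIG-I induction", {
  spec <- synthetic_spec(seed = 9)
  kd <- generate_kd_dataset(
    spec,
    perturbations = list(
      control = list(),
      dko = list(perturbation("knockout", "IRF3"),
                 perturbation("knockout", "IRF7"))),
    readouts = c("RIGI"))
  ctrl6 <- mean(kd$fold_change[kd$perturbation == "control" &
                                 kd$time == "6h"])
  dko6 <- mean(kd$fold_change[kd$perturbation == "dko" & kd$time == "6h"])
  dko0 <- mean(kd$fold_change[kd$perturbation == "dko" & kd$time == "0h"])
  expect_gt(ctrl6, 5)            # strong induction in the control
  expect_lt(dko6 / dko0, 1.3)    # induction abolished in the double KO
})

test_that("unstimulated imaging series are flat", {
  series <- generate_single_cell_imaging(n_cells = 2, dose_ug = 0,
                                         duration_hr = 2, seed = 1)
  for (rs in series) {
    expect_lt(diff(range(rs$values)) / mean(rs$values), 0.05)
  }
})
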