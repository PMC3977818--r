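test_that("telegraph gene matches the two-state occupancy law", {
  tg <- telegraph_model()
  # kon*TF = 1e-5 * 1000 = 1e-2 = koff -> active fraction 1/2
  sch <- toy_schedule(8, seq(0, 8, by = 1 / 120), species = "TF")
  x0 <- c(G_X = 1, G_X_a = 0, TF = 1000)
  tr <- run_hybrid(tg, sch, seed = 5, state0 = x0)
  frac <- mean(tr$counts[, "G_X_a"])
  # effective samples ~ T / (2 * correlation time), tau = 1/(kon TF + koff)
  tau <- 1 / 2e-2
  se <- sqrt(0.25 * 2 * tau / (8 * 3600))
  expect_lt(abs(frac - 0.5), 3 * se)
  # copy number conserved throughout
  expect_equal(unname(tr$counts[, "G_X"] + tr$counts[, "G_X_a"]),
               rep(1, nrow(tr$counts)))
})

test_that("hybrid reduces to the ODE when gene switching is off", {
  tg <- set_coefficients(telegraph_model(), c(act_gene_X = 0))
  sch <- toy_schedule(4, c(0, 1, 2, 4), species = "TF")
  x0 <- c(G_X = 1, G_X_a = 0, TF = 1000)
  trh <- run_hybrid(tg, sch, seed = 1, state0 = x0)
  tro <- run_ode(tg, sch, state0 = x0)
  expect_equal(trh$counts, tro$counts, tolerance = 1e-8)
})

test_that("compiled and reference hybrid engines agree statistically", {
  tg <- telegraph_model()
  sch <- toy_schedule(4, seq(0, 4, by = 1 / 60), species = "TF")
  x0 <- c(G_X = 1, G_X_a = 0, TF = 1000)
  frac <- function(engine, seed)
    mean(run_hybrid(tg, sch, seed = seed, state0 = x0,
                    engine = engine)$counts[, "G_X_a"])
  fc <- vapply(1:4, function(s) frac("cpp", s), numeric(1))
  fr <- vapply(1:4, function(s) frac("r", s), numeric(1))
  # both unbiased estimates of 1/2; compare cross-engine means loosely
  expect_lt(abs(mean(fc) - 0.5), 0.12)
  expect_lt(abs(mean(fr) - 0.5), 0.12)
  expect_lt(abs(mean(fc) - mean(fr)), 0.2)
})

test_that("hybrid runs are reproducible and integer-valued on genes", {
  tg <- telegraph_model()
  sch <- toy_schedule(2, seq(0, 2, by = 0.05), species = "TF")
  x0 <- c(G_X = 1, G_X_a = 0, TF = 1000)
  t1 <- run_hybrid(tg, sch, seed = 9, state0 = x0)
  t2 <- run_hybrid(tg, sch, seed = 9, state0 = x0)
  expect_identical(t1$counts, t2$counts)
  expect_equal(t1$counts[, "G_X_a"], round(t1$counts[, "G_X_a"]))
  expect_true(all(t1$counts >= 0))
})

test_that("hybrid default-model trajectories show gene-state jitter", {
  m <- cached_default_model()
  ss <- cached_steady_state()
  sch <- schedule(horizon = 2, output_grid = seq(0, 2, by = 0.05))
  tr <- run_hybrid(m, sch, seed = 21, state0 = ss)
  # gene states move on {0, 1, 2}
  ga <- tr$counts[, "G_A20_a"]
  expect_true(all(ga %in% 0:2))
  expect_gt(length(unique(ga)), 1)   # switching actually happened
  # per-module copies conserved
  gsp <- grep("^G_A20", colnames(tr$counts), value = TRUE)
  expect_equal(unname(rowSums(tr$counts[, gsp])), rep(2, nrow(tr$counts)))
})
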