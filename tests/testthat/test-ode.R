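test_that("pure decay follows the closed form", {
  m <- iir_model(c(A = 0),
                 list(reaction("dec", c(A = 1), numeric(0),
                               "prot_unreg_degr_r", 1)))  # 1e-4 /s
  sch <- toy_schedule(6, c(0, 1, 2, 4, 6))
  tr <- run_ode(m, sch, state0 = c(A = 1000))
  expect_equal(unname(tr$counts[, "A"]),
               1000 * exp(-1e-4 * sch$output_grid * 3600), tolerance = 1e-6)
  # absorbing steady state is all-zero
  expect_equal(unname(steady_state(m)), 0)
})

test_that("birth-death steady state equals k/gamma", {
  expect_equal(unname(steady_state(birth_death_model())["A"]), 100,
               tolerance = 1e-8)
})

test_that("unstimulated default model stays at its steady state", {
  m <- cached_default_model()
  ss <- cached_steady_state()
  sch <- schedule(stimulus_count = 0)
  tr <- run_ode(m, sch, state0 = ss)
  drift <- abs(sweep(tr$counts, 2, ss)) / pmax(rep(ss, each = 6), 1)
  expect_lt(max(drift), 1e-5)
})

test_that("basal transcription keeps every regulated mRNA positive", {
  ss <- cached_steady_state()
  mrnas <- mrna_species(setdiff(iir_genes(), c("IFNb", "ISG56")))
  expect_true(all(ss[mrnas] > 0))
  # IFNb and ISG56 are the zero-baseline genes (no basal transcription)
  expect_lt(max(ss[c("mIFNb", "mISG56")]), 1e-6)
})

test_that("stimulated nuclear RelA reaches a sustained plateau by 2-4 hr", {
  tr <- cached_stimulated_run()
  relan <- tr$counts[, "NFkBn"]
  names(relan) <- tr$times
  expect_lt(relan[["0"]], 0.1 * relan[["6"]])   # low basal
  expect_gt(relan[["2"]], 0.5 * relan[["6"]])   # mostly there by 2 hr
  expect_gt(relan[["4"]], 0.8 * relan[["6"]])   # sustained through 4-6 hr
})

test_that("dsRNA drives sensor depletion then resynthesis", {
  tr <- cached_stimulated_run()
  rigi <- tr$counts[, "RIGI"]
  expect_lt(min(rigi[2:4]), 0.5 * rigi[1])   # < half within 2 hr
  expect_gt(rigi[6], rigi[1])                # above control at 6 hr
  mavs <- tr$counts[, "MAVS"]
  expect_lt(min(mavs[2:4]), 0.6 * mavs[1])
})

test_that("gene copies are conserved along deterministic trajectories", {
  tr <- cached_stimulated_run()
  m <- cached_default_model()
  gene_sp <- m$species$name[grepl("^G_", m$species$name)]
  gene_of <- sub("^G_([A-Za-z0-9]+).*$", "\\1", gene_sp)
  for (g in unique(gene_of)) {
    tot <- rowSums(tr$counts[, gene_sp[gene_of == g], drop = FALSE])
    expect_equal(unname(tot), rep(2, nrow(tr$counts)), tolerance = 1e-6)
  }
})
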