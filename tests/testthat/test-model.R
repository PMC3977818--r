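test_that("default model passes conformance validation", {
  v <- validate_model(cached_default_model(), conformance = TRUE)
  expect_equal(v$n_species, 83L)
  expect_equal(v$n_reactions, 150L)
  expect_true(v$conformance_ok)
  expect_length(v$orphans, 0)
  expect_length(v$order_violations, 0)
  expect_length(v$gene_violations, 0)
  expect_true(v$ok)
})

test_that("gene species start with 2 free copies, all else at zero", {
  m <- cached_default_model()
  free <- m$species[m$species$role == "gene-free", ]
  expect_equal(length(iir_genes()), 11L)
  expect_equal(nrow(free), 11L)
  expect_true(all(free$initial_count == 2))
  other <- m$species[m$species$role != "gene-free", ]
  expect_true(all(other$initial_count == 0))
})

test_that("all reactions are mass action of order at most two", {
  orders <- vapply(cached_default_model()$reactions, reaction_order,
                   integer(1))
  expect_true(all(orders <= 2))
  # the constructor refuses a third-order reaction outright
  expect_error(reaction("bad", c(A = 2, B = 1), c(C = 1), "prot_bind_r"),
               "order > 2")
})

test_that("validator reports constructed defects", {
  m <- telegraph_model()
  # an unused species becomes an orphan
  m2 <- m
  m2$species <- rbind(m2$species,
                      data.frame(name = "unused", compartment = "cytoplasm",
                                 role = "protein-inactive",
                                 initial_count = 0))
  expect_identical(validate_model(m2)$orphans, "unused")
  expect_false(validate_model(m2)$ok)
  # a hand-built order-3 reaction (bypassing the constructor) is flagged
  m3 <- m
  bad <- structure(list(id = "tri", reactants = c(TF = 3),
                        products = c(TF = 3), bcr = "prot_bind_r", coef = 1),
                   class = "iir_reaction")
  m3$reactions <- c(m3$reactions, list(bad))
  expect_identical(validate_model(m3)$order_violations, "tri")
  # a reaction consuming a gene without producing one is flagged
  m4 <- m
  leak <- structure(list(id = "leak", reactants = c(G_X = 1),
                         products = numeric(0), bcr = "prot_degr_r",
                         coef = 1),
                    class = "iir_reaction")
  m4$reactions <- c(m4$reactions, list(leak))
  expect_identical(validate_model(m4)$gene_violations, "leak")
})

test_that("effective rates are BCR x coefficient with the unit switch", {
  rates <- bcr_table()
  deg <- reaction("deg", c(A = 1), numeric(0), "prot_degr_r", 1)
  expect_identical(effective_rate(deg, rates), 1e-5)
  off <- reaction("off", c(A = 1), numeric(0), "prot_degr_r", 0)
  expect_identical(effective_rate(off, rates), 0)
  bind <- reaction("bind", c(A = 1, B = 1), c(C = 1), "prot_bind_r", 1)
  expect_identical(effective_rate(bind, rates), 1e-7)
  expect_identical(
    effective_rate(bind, rates, divide_second_order_by_prot_avg = TRUE),
    1e-7 / 1e5)
  expect_error(effective_rate(reaction("x", c(A = 1), numeric(0),
                                       "nonexistent_r"), rates),
               "nonexistent_r")
})

test_that("rate assignment table reconstructs every rate bit-exactly", {
  m <- cached_default_model()
  ra <- rate_assignment(m)
  expect_equal(nrow(ra), 150L)
  recon <- unlist(m$rate_table[ra$bcr]) * ra$coef
  expect_identical(unname(recon), ra$rate)
})

test_that("stimulus reaches every acceptance readout species", {
  m <- cached_default_model()
  # undirected reachability over the species-reaction graph from dsRNA
  edges <- list()
  for (r in m$reactions) {
    sp <- unique(c(names(r$reactants), names(r$products)))
    if (length(sp) > 1) edges[[length(edges) + 1L]] <- sp
  }
  reach <- "dsRNA"
  repeat {
    grew <- FALSE
    for (e in edges) {
      if (any(e %in% reach) && !all(e %in% reach)) {
        reach <- union(reach, e); grew <- TRUE
      }
    }
    if (!grew) break
  }
  readouts <- c("mIFNb", "mA20", "NFkBn", "IRF3an", "IKK1a", "IKK2a",
                "RIGI", "MAVS")
  expect_true(all(readouts %in% reach))
})

test_that("copy-number scaling multiplies the deterministic solution", {
  m <- cached_default_model()
  m10 <- scale_copy_numbers(m, 10, scale_gene_switching = FALSE)
  sch <- schedule(horizon = 2, output_grid = c(0, 1, 2))
  ss1 <- cached_steady_state()
  tr1 <- run_ode(m, sch, state0 = ss1)
  gene <- grepl("^G_", m$species$name)
  ss10 <- ss1
  ss10[!gene] <- ss1[!gene] * 10
  sch10 <- sch
  sch10$stimulus_count <- sch$stimulus_count * 10
  tr10 <- run_ode(m10, sch10, state0 = ss10)
  # exact up to TF sequestration at the (unscaled) gene copies, which
  # holds back O(1) molecules of 1e5-scale pools; compare the main
  # readouts at a tolerance far below any dynamic effect
  readouts <- c("mA20", "mIkBa", "NFkBn", "IRF3an", "IKK1a", "IKK2a",
                "RIGI", "MAVS")
  rel <- abs(tr10$counts[, readouts] - 10 * tr1$counts[, readouts]) /
    pmax(10 * tr1$counts[, readouts], 10)
  expect_lt(max(rel), 1e-3)
  expect_equal(tr10$counts[, gene], tr1$counts[, gene], tolerance = 1e-3)
})

test_that("coefficient edits are pure and validated", {
  m <- telegraph_model()
  m2 <- set_coefficients(m, c(act_gene_X = 7))
  expect_equal(get_coefficients(m)[["act_gene_X"]], 100)
  expect_equal(get_coefficients(m2)[["act_gene_X"]], 7)
  expect_error(set_coefficients(m, c(nope = 1)), "unknown reaction")
})
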