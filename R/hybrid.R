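# Hybrid simulation: stochastic gene states over a deterministic bulk.
#
# Gene activation/inactivation events (TF binding and unbinding at gene
# copies) are simulated as a jump process whose propensities follow the
# current continuous species abundances; between events every non-gene
# species evolves by the mass-action ODE flow. Event times are exact: the
# integrated total gene-event hazard is carried as an auxiliary state and a
# unit-exponential threshold is located by the solver's root finder.

# channels that change a gene state: the multiset of gene species on the
# reactant side differs from the product side
gene_channel_ids <- function(model) {
  gene_sp <- model$species$name[grepl("^G_", model$species$name)]
  is_switch <- vapply(model$reactions, function(r) {
    rg <- as.character(names(r$reactants)[names(r$reactants) %in% gene_sp])
    pg <- as.character(names(r$products)[names(r$products) %in% gene_sp])
    !identical(sort(rg), sort(pg))
  }, logical(1))
  reaction_ids(model)[is_switch]
}

#' Hybrid stochastic/deterministic simulation
#'
#' Gene-state switching (the source of intrinsic transcriptional noise) is
#' simulated stochastically, with each gene's active copy number moving on
#' {0, 1, 2}; all other species follow the deterministic mass-action flow
#' between switching events. With all gene-activation rates zero the result
#' coincides with [run_ode()].
#'
#' Two engines are provided: a compiled adaptive Runge-Kutta stepper with
#' exact integrated-hazard event location (the default), and a reference R
#' implementation on deSolve's lsodar root-finder, used to cross-validate
#' the compiled path.
#'
#' @inheritParams run_ssa
#' @param engine "cpp" (compiled stepper) or "r" (lsodar reference)
#' @param h_max step size of the implicit stepper in seconds (cpp engine)
#' @param rtol,atol error control of the deterministic flow (r engine)
#' @return an \code{iir_trajectory} with \code{mode = "hybrid"}
#' @export
run_hybrid <- function(model, sched = schedule(), seed = 1L, state0 = NULL,
                       engine = c("cpp", "r"), h_max = 5, rtol = 1e-6,
                       atol = 1e-3,
                       divide_second_order_by_prot_avg = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(sched, "iir_schedule"))
  mm <- model_matrices(model, divide_second_order_by_prot_avg)
  ids <- reaction_ids(model)
  gch <- match(gene_channel_ids(model), ids)
  det <- setdiff(seq_along(ids), gch)

  # deterministic sub-network closures
  sub <- function(cols) {
    Ssub <- mm$S[, cols, drop = FALSE]; Rsub <- mm$R[, cols, drop = FALSE]
    ksub <- mm$k[cols]
    nr <- length(cols)
    i1 <- integer(nr); i2 <- integer(nr); same <- logical(nr)
    for (j in seq_len(nr)) {
      idx <- which(Rsub[, j] > 0)
      if (length(idx) == 0) next
      if (length(idx) == 1 && Rsub[idx, j] == 1) i1[j] <- idx
      else if (length(idx) == 1) { i1[j] <- idx; i2[j] <- idx; same[j] <- TRUE }
      else { i1[j] <- idx[1]; i2[j] <- idx[2] }
    }
    list(S = Ssub, k = ksub, i1 = i1, i2 = i2, same = same)
  }
  dpart <- sub(det); gpart <- sub(gch)
  prop <- function(part, x) {
    v <- numeric(length(part$k))
    z0 <- part$i1 == 0
    v[z0] <- part$k[z0]
    o1 <- part$i1 > 0 & part$i2 == 0
    v[o1] <- part$k[o1] * x[part$i1[o1]]
    o2 <- part$i2 > 0
    v[o2] <- part$k[o2] * x[part$i1[o2]] * x[part$i2[o2]]
    v[o2 & part$same] <- part$k[o2 & part$same] *
      x[part$i1[o2 & part$same]] * pmax(x[part$i1[o2 & part$same]] - 1, 0) / 2
    pmax(v, 0)
  }
  ns <- nrow(mm$S)
  rhs <- function(t, y, parms) {
    x <- pmax(y[seq_len(ns)], 0)
    dx <- as.vector(dpart$S %*% prop(dpart, x))
    list(c(dx, sum(prop(gpart, x))))
  }

  if (is.null(state0)) {
    state0 <- steady_state(
      model,
      equilibration_hr = sched$stimulus_time - sched$equilibration_start,
      divide_second_order_by_prot_avg = divide_second_order_by_prot_avg)
  }
  x <- pmax(state0, 0)
  gene_sp <- grepl("^G_", model$species$name)
  x[gene_sp] <- round(x[gene_sp])
  # put rounded gene copies back on the conservation manifold (2 per module)
  x[sched$stimulus_species] <- x[sched$stimulus_species] + sched$stimulus_count

  grid_s <- sched$output_grid * .HR
  if (engine == "cpp") {
    as_int <- function(M) matrix(as.integer(round(M)), nrow = nrow(M))
    set.seed(seed)
    grid_c <- grid_s
    if (grid_c[1] > sched$stimulus_time * .HR)
      grid_c <- c(sched$stimulus_time * .HR, grid_c)
    counts <- hybrid_cpp(as_int(dpart$S), dpart$i1 - 1L, dpart$i2 - 1L,
                         dpart$same, dpart$k,
                         as_int(gpart$S), gpart$i1 - 1L, gpart$i2 - 1L,
                         gpart$same, gpart$k,
                         x, grid_c, h_max)
    colnames(counts) <- model$species$name
    keep <- match(grid_s, grid_c)
    return(new_trajectory(times = sched$output_grid,
                          counts = counts[keep, , drop = FALSE],
                          mode = "hybrid", seed = seed))
  }
  set.seed(seed)
  t_cur <- sched$stimulus_time * .HR
  out <- matrix(NA_real_, length(grid_s), ns,
                dimnames = list(NULL, model$species$name))
  gi <- 1L
  while (grid_s[gi] <= t_cur && gi <= length(grid_s)) {
    out[gi, ] <- x; gi <- gi + 1L
    if (gi > length(grid_s)) break
  }
  threshold <- stats::rexp(1)
  while (gi <= length(grid_s)) {
    times <- unique(c(t_cur, grid_s[grid_s > t_cur]))
    y0 <- c(x, 0)
    root_fn <- function(t, y, parms) y[ns + 1] - threshold
    sol <- deSolve::lsodar(y = y0, times = times, func = rhs, parms = NULL,
                           rootfunc = root_fn, rtol = rtol, atol = atol,
                           maxsteps = 100000)
    t_reached <- sol[nrow(sol), 1]
    troot <- attr(sol, "troot")
    # record grid points reached in this segment (lsodar stops at the root,
    # so rows beyond it are simply absent)
    got <- sol[-1, , drop = FALSE]
    for (r in seq_len(nrow(got))) {
      if (gi <= length(grid_s) && abs(got[r, 1] - grid_s[gi]) < 1e-6) {
        out[gi, ] <- pmax(got[r, 1 + seq_len(ns)], 0)
        gi <- gi + 1L
      }
    }
    if (!is.null(troot) && length(troot)) {
      # a gene-switching event fired at troot
      xr <- pmax(sol[nrow(sol), 1 + seq_len(ns)], 0)
      a <- prop(gpart, xr)
      if (sum(a) > 0) {
        j <- sample.int(length(a), 1, prob = a)
        xr <- pmax(xr + gpart$S[, j], 0)
      }
      x <- xr
      t_cur <- troot[length(troot)]
      threshold <- stats::rexp(1)
    } else {
      x <- pmax(sol[nrow(sol), 1 + seq_len(ns)], 0)
      t_cur <- t_reached
      if (gi > length(grid_s) || t_cur >= grid_s[length(grid_s)]) break
    }
  }
  new_trajectory(times = sched$output_grid, counts = out, mode = "hybrid",
                 seed = seed)
}
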