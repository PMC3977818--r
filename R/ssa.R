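# Stochastic simulation (Gillespie direct method and tau-leaping).

ssa_prep <- function(model, divide_second_order_by_prot_avg = FALSE) {
  mm <- model_matrices(model, divide_second_order_by_prot_avg)
  nr <- ncol(mm$S)
  i1 <- integer(nr); i2 <- integer(nr); same <- logical(nr)
  for (j in seq_len(nr)) {
    idx <- which(mm$R[, j] > 0)
    if (length(idx) == 0) { i1[j] <- 0L; i2[j] <- 0L }
    else if (length(idx) == 1 && mm$R[idx, j] == 1) { i1[j] <- idx; i2[j] <- 0L }
    else if (length(idx) == 1) { i1[j] <- idx; i2[j] <- idx; same[j] <- TRUE }
    else { i1[j] <- idx[1]; i2[j] <- idx[2] }
  }
  list(S = matrix(as.integer(round(mm$S)), nrow = nrow(mm$S),
                  dimnames = dimnames(mm$S)),
       i1 = i1 - 1L, i2 = i2 - 1L, same = same, k = mm$k)
}

#' Stochastic simulation (Gillespie SSA)
#'
#' Samples an exact trajectory of the chemical master equation with the
#' direct method, or an approximate one by fixed-step tau-leaping (the
#' appropriate path at the network's physiological copy numbers, where exact
#' event-by-event simulation is many orders of magnitude more work).
#'
#' The pre-stimulus state is the deterministic steady state with counts
#' rounded to integers (the stochastic equivalent of the long equilibration
#' segment); the stimulus is added at the stimulus time and the system is
#' sampled on the output grid (piecewise-constant interpolation of the jump
#' process). Reproducible for a given \code{seed}.
#'
#' @param model an \code{iir_model}
#' @param sched an [schedule()]
#' @param seed integer seed
#' @param method "exact" or "tau"
#' @param tau leap size in seconds (tau-leaping only)
#' @param state0 optional pre-equilibrated state
#' @param max_events guard on the exact-method event count
#' @param divide_second_order_by_prot_avg unit-convention switch
#' @return an \code{iir_trajectory}
#' @export
run_ssa <- function(model, sched = schedule(), seed = 1L,
                    method = c("exact", "tau"), tau = 1,
                    state0 = NULL, max_events = 5e7,
                    divide_second_order_by_prot_avg = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(sched, "iir_schedule"))
  prep <- ssa_prep(model, divide_second_order_by_prot_avg)
  if (is.null(state0)) {
    state0 <- steady_state(
      model,
      equilibration_hr = sched$stimulus_time - sched$equilibration_start,
      divide_second_order_by_prot_avg = divide_second_order_by_prot_avg)
  }
  x <- round(pmax(state0, 0))
  if (!sched$stimulus_species %in% names(x))
    stop("unknown stimulus species: ", sched$stimulus_species)
  x[sched$stimulus_species] <- x[sched$stimulus_species] +
    round(sched$stimulus_count)
  grid_s <- sched$output_grid * .HR
  if (grid_s[1] > sched$stimulus_time * .HR)
    grid_s <- c(sched$stimulus_time * .HR, grid_s)
  set.seed(seed)
  counts <- if (method == "exact") {
    ssa_exact_cpp(prep$S, prep$i1, prep$i2, prep$same, prep$k, x, grid_s,
                  max_events)
  } else {
    ssa_tau_cpp(prep$S, prep$i1, prep$i2, prep$same, prep$k, x, grid_s, tau)
  }
  colnames(counts) <- names(x)
  keep <- match(sched$output_grid * .HR, grid_s)
  new_trajectory(times = sched$output_grid,
                 counts = counts[keep, , drop = FALSE],
                 mode = "ssa", seed = seed)
}
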