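# Synthetic pseudo-experimental data with the statistical structure the
# analysis assumes: triplicate series on the measurement grid with ~10%
# multiplicative noise and arbitrary per-series reporting units, knockdown
# fold-change tables, and single-cell imaging-style N/C ratio series.

#' Default series selection: the 4 mRNA and 10 protein readouts
#'
#' The measurement design: four mRNA species and ten (phospho)protein
#' abundances across cytoplasm and nucleus, 14 series in total.
#'
#' @return named character vector mapping series name to model species
#' @export
default_series_map <- function() {
  c(mRNA_TNFAIP3 = "mA20", mRNA_IkBa = "mIkBa", mRNA_RIGI = "mRIGI",
    mRNA_IFNb = "mIFNb",
    RIGI_cyt = "RIGI", MAVS_cyt = "MAVS", IKK1a_cyt = "IKK1a",
    IKK2a_cyt = "IKK2a", RelA_cyt = "NFkB", RelA_nuc = "NFkBn",
    IkBa_cyt = "IkBa", IkBa_nuc = "IkBan", IRF3_cyt = "IRF3i",
    IRF3_nuc = "IRF3an")
}

#' Synthetic-data specification
#'
#' @param model generator model (default the calibrated network)
#' @param series_map named map series -> species (default
#'   [default_series_map()])
#' @param times measurement grid in hours
#' @param replicates replicates per point (default 3)
#' @param rel_noise relative (lognormal, CV) measurement noise, default 0.10
#' @param scale_range per-series reporting-unit factors are drawn
#'   log-uniformly from this range, mimicking arbitrary assay units
#' @param seed integer seed
#' @export
synthetic_spec <- function(model = NULL, series_map = default_series_map(),
                           times = c(0, 0.5, 1, 2, 4, 6), replicates = 3,
                           rel_noise = 0.10, scale_range = c(1e-3, 1e3),
                           seed = 1L) {
  stopifnot(rel_noise > 0, replicates >= 2, all(scale_range > 0))
  structure(list(model = model, series_map = series_map, times = times,
                 replicates = replicates, rel_noise = rel_noise,
                 scale_range = scale_range, seed = seed),
            class = "synthetic_spec")
}

# lognormal multiplicative noise with mean 1 and the requested CV
rlnoise <- function(n, cv) {
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic time-series measurement set
#'
#' Simulates the generator model deterministically on the measurement grid,
#' applies a per-series reporting scale (arbitrary assay units) and
#' multiplicative lognormal noise per replicate, and returns the
#' measurement set together with a ground-truth bundle (true trajectory,
#' scales, seed).
#'
#' @param spec a [synthetic_spec()]
#' @param sched stimulation schedule (default [schedule()] over the grid)
#' @return list: \code{measurements} (a [measurement_set()]),
#'   \code{truth} (list: trajectory, scales, seed)
#' @export
generate_timeseries <- function(spec = synthetic_spec(), sched = NULL) {
  model <- spec$model
  if (is.null(model)) model <- build_default_model()
  if (is.null(sched))
    sched <- schedule(horizon = max(spec$times), output_grid = spec$times)
  tr <- run_ode(model, sched)
  set.seed(spec$seed)
  scales <- stats::setNames(
    exp(stats::runif(length(spec$series_map), log(spec$scale_range[1]),
                     log(spec$scale_range[2]))),
    names(spec$series_map))
  rows <- list()
  for (nm in names(spec$series_map)) {
    truth <- tr$counts[, spec$series_map[[nm]]]
    for (r in seq_len(spec$replicates)) {
      noise <- rlnoise(length(spec$times), spec$rel_noise)
      rows[[length(rows) + 1L]] <- data.frame(
        series = nm, time_hr = spec$times, replicate = r,
        value = truth * scales[[nm]] * noise)
    }
  }
  data <- do.call(rbind, rows)
  list(measurements = measurement_set(data, mapping = spec$series_map),
       truth = list(trajectory = tr, scales = scales, seed = spec$seed))
}

#' Generate a synthetic knockdown fold-change dataset
#'
#' Simulates each perturbed generator model, forms fold changes against the
#' unperturbed unstimulated control, and adds triplicate 10% relative
#' noise: the synthetic analogue of the knockdown bar charts, suitable for
#' [welch_test()] and for comparison with [kd_foldchange_table()].
#'
#' @param spec a [synthetic_spec()]
#' @param perturbations named list as in [kd_foldchange_table()]
#' @param readouts readout genes
#' @return data frame: perturbation, readout, time, replicate, fold_change
#' @export
generate_kd_dataset <- function(spec = synthetic_spec(),
                                perturbations = list(control = list()),
                                readouts = c("RelA", "IRF3", "RIGI",
                                             "A20", "IkBa", "ISG56")) {
  model <- spec$model
  if (is.null(model)) model <- build_default_model()
  tab <- kd_foldchange_table(model, perturbations, readouts = readouts)
  set.seed(spec$seed)
  out <- tab[rep(seq_len(nrow(tab)), each = spec$replicates), ]
  out$replicate <- rep(seq_len(spec$replicates), nrow(tab))
  out$fold_change <- out$fold_change * rlnoise(nrow(out), spec$rel_noise)
  rownames(out) <- NULL
  out[, c("perturbation", "readout", "time", "replicate", "fold_change")]
}

#' Generate synthetic single-cell imaging series
#'
#' Hybrid-mode per-cell simulations with lognormal doses, reported as
#' nuclear/cytoplasmic RelA ratio series at imaging cadence — the synthetic
#' analogue of live-cell translocation quantifications.
#'
#' @param model generator model (default the calibrated network)
#' @param n_cells number of cells
#' @param dose_ug dose on the ug scale (default 5, the low-dose imaging
#'   condition)
#' @param cadence_min imaging cadence in minutes (default 6)
#' @param duration_hr imaging duration in hours (default 12)
#' @param cv extrinsic dose CV (default 3)
#' @param seed integer seed
#' @param nuclear_species,cytoplasmic_species ratio readout (defaults:
#'   total nuclear RelA over total cytoplasmic RelA)
#' @return list of [ratio_series()] (length \code{n_cells}), with the dose
#'   vector as attribute \code{"doses"}
#' @export
generate_single_cell_imaging <- function(model = NULL, n_cells = 20,
                                         dose_ug = 5, cadence_min = 6,
                                         duration_hr = 12, cv = 3, seed = 1L,
                                         nuclear_species = c("NFkBn",
                                                             "NFkBn_IkBan"),
                                         cytoplasmic_species =
                                           c("NFkB", "NFkB_IkBa",
                                             "poolNFkB")) {
  if (is.null(model)) model <- build_default_model()
  # n frames spanning exactly duration_hr (n * dt = T), the standard
  # periodogram convention, so Fourier periods fall at T/k
  dt <- cadence_min / 60
  grid <- seq(0, duration_hr - dt, by = dt)
  sched <- schedule(horizon = duration_hr, output_grid = grid)
  mols <- ug_to_molecules(dose_ug)
  state0 <- steady_state(model)
  set.seed(seed)
  doses <- if (mols > 0)
    draw_doses(dose_ensemble_spec(mean_molecules = max(mols, 1e-12), cv = cv,
                                  n_cells = n_cells))
  else rep(0, n_cells)
  cell_seeds <- sample.int(.Machine$integer.max, n_cells)
  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    si <- sched; si$stimulus_count <- doses[i]
    tr <- run_hybrid(model, si, seed = cell_seeds[i], state0 = state0)
    out[[i]] <- nc_ratio(tr, nuclear_species, cytoplasmic_species)
  }
  attr(out, "doses") <- doses
  out
}
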