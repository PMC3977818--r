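#' Simulation schedule
#'
#' The experiment protocol: equilibrate from zero initial conditions (free
#' gene copies excepted) starting at \code{equilibration_start}, apply an
#' instantaneous dsRNA stimulus at \code{stimulus_time}, then follow the
#' response to \code{horizon}. All times are in hours; rate constants are
#' per second internally.
#'
#' @param equilibration_start start of the pre-stimulus equilibration (hr,
#'   default -500)
#' @param stimulus_time time of the dsRNA electroporation pulse (hr, default 0)
#' @param stimulus_species species receiving the pulse (default "dsRNA")
#' @param stimulus_count number of molecules inserted (default 2e4, the
#'   working per-cell count for the reference 4 ug dose)
#' @param horizon end of the recorded response (hr, default 6)
#' @param output_grid times at which the state is recorded (hr); defaults to
#'   the measurement grid 0, 0.5, 1, 2, 4, 6 scaled to the horizon
#' @return a list of class \code{"iir_schedule"}
#' @export
schedule <- function(equilibration_start = -500,
                     stimulus_time = 0,
                     stimulus_species = "dsRNA",
                     stimulus_count = 2e4,
                     horizon = 6,
                     output_grid = NULL) {
  stopifnot(equilibration_start < stimulus_time, stimulus_time < horizon,
            stimulus_count >= 0)
  if (is.null(output_grid)) {
    output_grid <- c(0, 0.5, 1, 2, 4, 6)
    output_grid <- unique(sort(c(output_grid[output_grid <= horizon], horizon)))
  }
  stopifnot(all(diff(output_grid) > 0), all(output_grid >= stimulus_time),
            all(output_grid <= horizon))
  structure(list(equilibration_start = equilibration_start,
                 stimulus_time = stimulus_time,
                 stimulus_species = stimulus_species,
                 stimulus_count = stimulus_count,
                 horizon = horizon,
                 output_grid = output_grid),
            class = "iir_schedule")
}

new_trajectory <- function(times, counts, mode, seed = NULL) {
  structure(list(times = times, counts = counts, mode = mode, seed = seed),
            class = "iir_trajectory")
}

#' @export
print.iir_trajectory <- function(x, ...) {
  cat("iir_trajectory (", x$mode, "): ", length(x$times), " time points x ",
      ncol(x$counts), " species, t in [", min(x$times), ", ", max(x$times),
      "] hr\n", sep = "")
  invisible(x)
}

#' Extract one species' series from a trajectory
#' @param traj an \code{iir_trajectory}
#' @param species species name
#' @return numeric vector along \code{traj$times}
#' @export
species_series <- function(traj, species) {
  if (!species %in% colnames(traj$counts))
    stop("no species '", species, "' in trajectory")
  traj$counts[, species]
}
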