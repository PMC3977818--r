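# Single-cell nucleus/cytoplasm ratio analysis: cubic detrending and
# Fourier periodogram, the translocation-oscillation readout.

#' Nucleus/cytoplasm ratio series from a trajectory
#'
#' @param traj an \code{iir_trajectory} on a uniform time grid
#' @param nuclear_species,cytoplasmic_species species names (counts are
#'   summed when several are given, e.g. free plus complexed nuclear RelA)
#' @param volume_corrected multiply by the cytoplasmic-to-nuclear volume
#'   ratio so the ratio is concentration-like rather than count-like
#' @param cyto_to_nuc_ratio volume ratio used when \code{volume_corrected}
#' @param eps_floor small count floor applied to the cytoplasmic series; set
#'   to 0 to error on zero cytoplasmic counts instead
#' @return a list of class \code{"ratio_series"} with \code{times} (hr) and
#'   \code{values}
#' @export
nc_ratio <- function(traj, nuclear_species, cytoplasmic_species,
                     volume_corrected = FALSE, cyto_to_nuc_ratio = 5,
                     eps_floor = 1e-9) {
  nuc <- rowSums(traj$counts[, nuclear_species, drop = FALSE])
  cyt <- rowSums(traj$counts[, cytoplasmic_species, drop = FALSE])
  if (any(cyt <= 0)) {
    if (eps_floor <= 0)
      stop("cytoplasmic counts reach zero; set eps_floor > 0 to floor them")
    cyt <- pmax(cyt, eps_floor)
  }
  v <- nuc / cyt
  if (volume_corrected) v <- v * cyto_to_nuc_ratio
  ratio_series(traj$times, v)
}

#' Construct a ratio series
#' @param times uniform time grid (hr)
#' @param values positive dimensionless ratios
#' @export
ratio_series <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 2)
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-6)
    stop("ratio series requires a uniform time grid (tolerance 1e-6)")
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "ratio_series")
}

#' Read / write a two-column (time, ratio) CSV
#' @param path file path
#' @export
read_ratio_series <- function(path) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("expected a two-column (time, ratio) CSV")
  ratio_series(d[[1]], d[[2]])
}

#' @rdname read_ratio_series
#' @param series a [ratio_series()]
#' @export
write_ratio_series <- function(series, path) {
  utils::write.csv(data.frame(time_hr = series$times, ratio = series$values),
                   path, row.names = FALSE)
}

#' Third-order polynomial detrending
#'
#' Fits a cubic in time by least squares and returns the residual series
#' (mean zero by construction) together with the trend coefficients.
#'
#' @param series a [ratio_series()] with at least 5 points
#' @return list with \code{detrended} (a \code{ratio_series}-shaped list;
#'   residuals may be negative), \code{trend} (fitted values) and
#'   \code{coefficients} (intercept, t, t^2, t^3)
#' @export
detrend_poly3 <- function(series) {
  t <- series$times; y <- series$values
  if (length(t) < 5)
    stop("cubic detrending needs at least 5 points, got ", length(t))
  fit <- stats::lm(y ~ stats::poly(t, 3, raw = TRUE))
  res <- stats::residuals(fit)
  names(res) <- NULL
  list(detrended = structure(list(times = t, values = res),
                             class = "ratio_series"),
       trend = as.numeric(stats::fitted(fit)),
       coefficients = stats::setNames(as.numeric(stats::coef(fit)),
                                      c("c0", "c1", "c2", "c3")))
}

#' Discrete Fourier periodogram
#'
#' Raw (unsmoothed, untapered) periodogram of a detrended, uniformly
#' sampled series. One-sided power at the Fourier frequencies
#' k/(n dt), k = 1..floor(n/2), normalized so that the total returned power
#' equals the sum of squares of the (mean-removed) series (Parseval).
#' The dominant period is the period of maximum power inside a search band;
#' exact power ties resolve to the lowest frequency.
#'
#' @param series a detrended series (uniform grid, times in hours)
#' @param band period search band in hours (default 0.5 to 5)
#' @return a list of class \code{"iir_periodogram"}: \code{frequencies}
#'   (1/hr), \code{power}, \code{periods} (hr), \code{dominant_period} (hr),
#'   \code{total_power}
#' @export
periodogram <- function(series, band = c(0.5, 5)) {
  t <- series$times; y <- series$values
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-6)
    stop("periodogram requires a uniform grid; resample the series first")
  dt <- dt[1]
  n <- length(y)
  y <- y - mean(y)
  X <- stats::fft(y)
  kmax <- floor(n / 2)
  k <- seq_len(kmax)
  pw <- Mod(X[k + 1])^2 / n
  # double interior bins so one-sided power satisfies Parseval
  double <- rep(2, kmax)
  if (n %% 2 == 0) double[kmax] <- 1
  pw <- pw * double
  freq <- k / (n * dt)                    # 1/hr
  periods <- 1 / freq
  sel <- which(periods >= band[1] & periods <= band[2])
  dominant <- if (length(sel)) {
    best <- sel[pw[sel] == max(pw[sel])]
    periods[min(best)]                    # ties: lowest frequency wins
  } else NA_real_
  structure(list(frequencies = freq, power = pw, periods = periods,
                 dominant_period = dominant, total_power = sum(pw)),
            class = "iir_periodogram")
}
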