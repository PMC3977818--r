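# Fit-score machinery: per-series scaling of empirical data onto the
# simulation's absolute scale, the average relative absolute difference
# score, staged coefficient refinement, and the Welch test used for
# knockdown significance calls.

#' Measurement set
#'
#' Empirical-style data: named series measured in triplicate on the common
#' time grid. Only relative values within a series are considered
#' trustworthy (assay units are arbitrary), which is why scoring rescales
#' each series onto the simulation.
#'
#' @param data data frame with columns \code{series}, \code{time_hr},
#'   \code{replicate}, \code{value}
#' @param mapping named character vector mapping series name to the model
#'   species it reads out
#' @return a list of class \code{"measurement_set"}
#' @export
measurement_set <- function(data, mapping = NULL) {
  stopifnot(all(c("series", "time_hr", "replicate", "value") %in% names(data)))
  if (any(data$value < 0)) stop("measurement values must be >= 0")
  grids <- tapply(data$time_hr, data$series, function(t) sort(unique(t)))
  g1 <- grids[[1]]
  if (!all(vapply(grids, function(g) identical(g, g1), logical(1))))
    stop("all series must share the same time grid")
  structure(list(data = data, mapping = mapping, times = g1),
            class = "measurement_set")
}

#' Read / write the measurement CSV schema (series,time_hr,replicate,value)
#' @param path file path
#' @param mapping optional series-to-species mapping
#' @export
read_measurements <- function(path, mapping = NULL)
  measurement_set(utils::read.csv(path), mapping = mapping)

#' @rdname read_measurements
#' @param ms a [measurement_set()]
#' @export
write_measurements <- function(ms, path)
  utils::write.csv(ms$data, path, row.names = FALSE)

# replicate means per (series, time), as a named list of vectors on ms$times
replicate_means <- function(ms) {
  ag <- stats::aggregate(value ~ series + time_hr, data = ms$data, FUN = mean)
  split_means <- split(ag, ag$series)
  lapply(split_means, function(d) d$value[order(d$time_hr)])
}

#' Optimal per-series scale
#'
#' Finds the factor a minimizing sum_j |a e_j - s_j| / s_j, the series'
#' contribution to the fit score. The objective is piecewise linear in a
#' with breakpoints s_j / e_j, so the exact minimizer is a weighted median
#' of those ratios with weights e_j / s_j.
#'
#' @param empirical,simulated positive numeric vectors of equal length
#' @param floor denominator floor (molecules) guarding near-zero simulated
#'   values
#' @return the optimal scale (a scalar)
#' @export
scale_series <- function(empirical, simulated, floor = 1) {
  stopifnot(length(empirical) == length(simulated))
  s <- pmax(simulated, floor)
  keep <- empirical > 0
  if (!any(keep))
    stop("all-zero empirical series: scale undefined")
  e <- empirical[keep]; s <- s[keep]
  r <- s / e; w <- e / s
  o <- order(r)
  r <- r[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  r[which(cw >= 0.5)[1]]
}

#' Fit score: average relative absolute difference
#'
#' Scales every empirical series onto the simulation with its optimal
#' factor, then averages |a_i e_ij - s_ij| / s_ij over all series i and
#' times j. Replicates enter through their mean. A score of zero means the
#' simulation matches every series exactly up to per-series units.
#'
#' @param ms a [measurement_set()] whose mapping covers every series
#' @param traj an \code{iir_trajectory} (or any object with \code{times} and
#'   a counts matrix) simulated on the measurement time grid
#' @param denominator which reference the relative difference is taken
#'   against: the simulated value (default), the scaled empirical value, or
#'   their mean
#' @param floor denominator floor in molecules
#' @return a list of class \code{"fit_score"}: \code{score}, \code{scales},
#'   \code{contributions} (per-series mean relative difference)
#' @export
fit_score <- function(ms, traj, denominator = c("simulated",
                                                "scaled_empirical", "mean"),
                      floor = 1) {
  denominator <- match.arg(denominator)
  if (is.null(ms$mapping))
    stop("measurement set has no series-to-species mapping")
  means <- replicate_means(ms)
  idx <- match(ms$times, traj$times)
  if (any(is.na(idx)))
    stop("trajectory does not cover the measurement time grid")
  scales <- numeric(0); contrib <- numeric(0); total <- 0; ncell <- 0
  for (nm in names(means)) {
    if (!nm %in% names(ms$mapping))
      stop("no species mapping for series '", nm, "'")
    s <- traj$counts[idx, ms$mapping[[nm]]]
    e <- means[[nm]]
    a <- scale_series(e, s, floor = floor)
    den <- switch(denominator,
                  simulated = pmax(s, floor),
                  scaled_empirical = pmax(a * e, floor),
                  mean = pmax((a * e + s) / 2, floor))
    d <- abs(a * e - s) / den
    scales[nm] <- a
    contrib[nm] <- mean(d)
    total <- total + sum(d); ncell <- ncell + length(d)
  }
  structure(list(score = total / ncell, scales = scales,
                 contributions = contrib),
            class = "fit_score")
}

#' @export
print.fit_score <- function(x, ...) {
  cat("fit score:", format(x$score, digits = 4),
      "(", length(x$scales), "series )\n")
  invisible(x)
}

#' Staged coefficient refinement
#'
#' Coordinate-wise search over per-reaction coefficients, in stages. Each
#' stage names a group of reaction ids; every coefficient in the group is
#' moved across a multiplicative grid around its current value (all other
#' coefficients held fixed) and kept at the grid point minimizing the fit
#' score. The score trace is non-increasing by construction and the whole
#' procedure is deterministic.
#'
#' @param model an \code{iir_model}
#' @param ms a [measurement_set()] with species mapping
#' @param stages list of character vectors of reaction ids
#' @param simulate function(model) returning the trajectory to score
#'   (defaults to an ODE run on the measurement grid with the default
#'   schedule)
#' @param grid multiplicative search grid (default 10^seq(-1, 1, by = 0.25))
#' @param sweeps passes through each stage (default 1)
#' @return list: \code{model} (with refined coefficients),
#'   \code{coefficients}, \code{trace} (score after each stage),
#'   \code{score}
#' @export
refine_coefficients <- function(model, ms, stages,
                                simulate = NULL,
                                grid = 10^seq(-1, 1, by = 0.25),
                                sweeps = 1) {
  if (is.null(simulate)) {
    sch <- schedule(output_grid = ms$times,
                    horizon = max(ms$times))
    simulate <- function(m) run_ode(m, sch)
  }
  score_of <- function(m) fit_score(ms, simulate(m))$score
  cur <- score_of(model)
  trace <- cur
  if (length(stages)) {
    ids <- reaction_ids(model)
    for (sw in seq_len(sweeps)) {
      for (stage in stages) {
        bad <- setdiff(stage, ids)
        if (length(bad))
          stop("unknown reaction id(s) in stage: ", paste(bad, collapse = ", "))
        for (rid in stage) {
          co <- get_coefficients(model)[[rid]]
          cand <- co * grid
          for (cc in cand) {
            m2 <- set_coefficients(model, stats::setNames(cc, rid))
            s2 <- score_of(m2)
            if (s2 < cur - 1e-12) { cur <- s2; model <- m2 }
          }
        }
        trace <- c(trace, cur)
      }
    }
  }
  list(model = model, coefficients = get_coefficients(model), trace = trace,
       score = cur)
}

#' Welch two-sample t-test with direction sign
#'
#' Two-sided Welch (unequal-variance) t-test on two replicate groups; the
#' returned sign is negative when group A has the smaller mean, matching
#' the convention of reporting down-regulation as a signed p-value.
#'
#' @param a,b numeric replicate vectors (length >= 2)
#' @return list with \code{t}, \code{p}, \code{sign}, \code{df}
#' @export
welch_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, sign = 0, df = NA_real_))
    stop("zero variance in both groups with unequal means: t undefined")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value,
       sign = if (mean(a) < mean(b)) -1 else if (mean(a) > mean(b)) 1 else 0,
       df = unname(ht$parameter))
}
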