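# Converting trajectory ensembles into cellular-decision readouts.
#
# A trajectory "chooses" a gene program when its running maximum for that
# protein reaches a molecule threshold at any point before the horizon; the
# fraction of an ensemble crossing the threshold is the fraction of cells
# exhibiting that response.

#' Fraction of trajectories whose running maximum crosses a threshold
#'
#' Ties count as crossing (`max >= threshold`), so `threshold = 0` always
#' gives 1 and the fraction is non-increasing in the threshold.
#'
#' @param ensemble an [run_ensemble()] result.
#' @param species species name (usually `"I"` or `"A"`).
#' @param threshold molecule count, >= 0.
#' @return Fraction in \[0, 1\].
#' @examples
#' ens <- run_ensemble(rate_parameters(k_deg_T = 1), n = 20, t_end = 500,
#'                     master_seed = 1)
#' crossing_fraction(ens, "I", 100)
#' @export
crossing_fraction <- function(ensemble, species, threshold) {
  stopifnot(inherits(ensemble, "ssa_ensemble"), threshold >= 0,
            ensemble$n >= 1)
  if (!species %in% colnames(ensemble$max)) stop("unknown species: ", species)
  mean(ensemble$max[, species] >= threshold)
}

#' Histogram of molecule counts at a fixed time
#'
#' @param ensemble an [run_ensemble()] result.
#' @param species species name.
#' @param t time (minutes).  Defaults to the ensemble horizon; other times
#'   require the ensemble to have been run with `record = "grid"`.
#' @return Data frame with columns `count` and `n` (`sum(n)` equals the
#'   ensemble size).
#' @examples
#' ens <- run_ensemble(rate_parameters(), n = 20, t_end = 500, master_seed = 1)
#' endpoint_histogram(ens, "A")
#' @export
endpoint_histogram <- function(ensemble, species, t = ensemble$t_end) {
  stopifnot(inherits(ensemble, "ssa_ensemble"))
  if (!species %in% colnames(ensemble$final)) stop("unknown species: ", species)
  if (t == ensemble$t_end) {
    v <- ensemble$final[, species]
  } else {
    if (is.null(ensemble$trajectories))
      stop("counts at t < t_end require record = \"grid\"")
    tr1 <- ensemble$trajectories[[1]]
    idx <- match(t, tr1$time)
    if (is.na(idx)) stop("t is not on the recording grid")
    v <- vapply(ensemble$trajectories,
                function(tr) tr$counts[idx, species], numeric(1))
  }
  tab <- table(factor(v, levels = sort(unique(v))))
  data.frame(count = as.numeric(names(tab)), n = as.integer(tab))
}

#' Default log-spaced grid for the signal degradation rate
#'
#' @param from,to grid limits (per minute).
#' @param per_decade points per decade (>= 5 recommended).
#' @param include_zero prepend the exactly-sustained point `k_deg_T = 0`.
#' @return Numeric vector, ascending.
#' @examples
#' kdeg_grid(1e-4, 1e-1)
#' @export
kdeg_grid <- function(from = 1e-4, to = 10, per_decade = 5,
                      include_zero = FALSE) {
  g <- 10^seq(log10(from), log10(to), by = 1 / per_decade)
  if (include_zero) g <- c(0, g)
  g
}

#' Decision curve: threshold-crossing fractions across signal durations
#'
#' For every signal degradation rate on the grid, runs an ensemble and
#' records the fraction of trajectories whose running maximum of I crosses
#' `theta_I` (inflammatory response) and of A crosses `theta_A`
#' (anti-inflammatory response).  Grid point `i` uses master seed
#' `master_seed + (i - 1) * 1e6`, so two curves computed with the same
#' `master_seed` (e.g. at different amplitudes) share per-trajectory seeds
#' point by point.
#'
#' @param params a [rate_parameters()] object (its `k_deg_T` is overridden by
#'   the grid).
#' @param variant a [model_variant()] object.
#' @param grid ascending vector of `k_deg_T` values (0 allowed).
#' @param theta_I,theta_A molecule thresholds for I and A.
#' @param n trajectories per grid point.
#' @param t_end horizon (minutes).
#' @param master_seed integer master seed.
#' @return An object of class `decision_curve`: a data frame with columns
#'   `k_deg_T`, `frac_I`, `frac_A`, `n`, with thresholds, amplitude and seed
#'   as attributes.
#' @examples
#' \donttest{
#' dc <- decision_curve(rate_parameters(), grid = kdeg_grid(1e-3, 1e-1, 2),
#'                      n = 50, master_seed = 1)
#' dc
#' }
#' @export
decision_curve <- function(params = rate_parameters(),
                           variant = model_variant(),
                           grid = kdeg_grid(), theta_I = 100, theta_A = 20,
                           n = 1000, t_end = 2000, master_seed) {
  stopifnot(length(grid) >= 1, !is.unsorted(grid), !missing(master_seed))
  rows <- lapply(seq_along(grid), function(i) {
    p <- set_parameters(params, k_deg_T = grid[i])
    ens <- run_ensemble(p, variant, t_end = t_end, n = n,
                        master_seed = point_seed(master_seed, i))
    data.frame(k_deg_T = grid[i],
               frac_I = crossing_fraction(ens, "I", theta_I),
               frac_A = crossing_fraction(ens, "A", theta_A),
               n = n)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("decision_curve", "data.frame"),
            theta_I = theta_I, theta_A = theta_A,
            amplitude = params$pSTAT3_0, t_end = t_end,
            master_seed = master_seed)
}

# seed offset per grid point; 1e6 exceeds any plausible ensemble size, so
# per-trajectory seeds never collide across grid points
point_seed <- function(master_seed, i) master_seed + (i - 1) * 1e6

#' @export
print.decision_curve <- function(x, ...) {
  cat(sprintf(
    "Decision curve: amplitude %d, thresholds I >= %g / A >= %g, %d points\n",
    as.integer(attr(x, "amplitude")), attr(x, "theta_I"), attr(x, "theta_A"),
    nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.decision_curve <- function(x, ...) {
  k <- x$k_deg_T
  pos <- k > 0
  graphics::plot(k[pos], 100 * x$frac_I[pos], log = "x", type = "b", pch = 16,
                 ylim = c(0, 100), xlab = expression(k["deg,T"] ~ (min^-1)),
                 ylab = "% trajectories crossing threshold", col = "firebrick",
                 ...)
  graphics::lines(k[pos], 100 * x$frac_A[pos], type = "b", pch = 16,
                  col = "steelblue")
  graphics::legend("right", legend = c("I (inflammatory)",
                                       "A (anti-inflammatory)"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' Crossover point of the two decision curves
#'
#' The signal degradation rate at which the inflammatory (I) and
#' anti-inflammatory (A) crossing-fraction curves intersect, located by
#' log-linear interpolation of `frac_I - frac_A` between the bracketing
#' positive grid points (an exact zero at a grid point is returned as is).
#'
#' @param curve a [decision_curve()].
#' @return The interpolated `k_deg_T` (per minute).
#' @examples
#' syn <- structure(data.frame(k_deg_T = c(0.005, 0.01, 0.02),
#'                             frac_I = c(0, 0.5, 1),
#'                             frac_A = c(1, 0.5, 0), n = 10),
#'                  class = c("decision_curve", "data.frame"))
#' crossover_point(syn)  # 0.01
#' @export
crossover_point <- function(curve) {
  stopifnot(inherits(curve, "decision_curve"))
  cc <- curve[curve$k_deg_T > 0, ]
  d <- cc$frac_I - cc$frac_A
  if (any(d == 0)) return(cc$k_deg_T[which(d == 0)[1]])
  sgn <- sign(d)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(flip)) stop("no crossover on grid")
  i <- flip[1]
  lx1 <- log(cc$k_deg_T[i]); lx2 <- log(cc$k_deg_T[i + 1])
  exp(lx1 + (0 - d[i]) * (lx2 - lx1) / (d[i + 1] - d[i]))
}

#' Onset of stochastic bistability along the signal degradation rate
#'
#' For transient signals a trajectory may fail to ignite the positive
#' feedback loop before the signal dies, leaving its running maximum of I at
#' exactly zero while other trajectories rise — stochastic bistability.
#' This scans ascending `k_deg_T` values and reports the first at which the
#' zero-I-trajectory fraction exceeds `eps`.
#'
#' @param params a [rate_parameters()] object.
#' @param variant a [model_variant()] object.
#' @param scan ascending vector of `k_deg_T` values.
#' @param n trajectories per scan point.
#' @param eps bimodality criterion on the zero fraction (0 < eps < 0.5).
#' @param t_end horizon (minutes).
#' @param master_seed integer master seed (per-point seeds as in
#'   [decision_curve()]).
#' @return An object of class `bistability_report`: list with `onset` (the
#'   smallest scanned `k_deg_T` whose zero fraction exceeds `eps`, or `NA` if
#'   never reached) and `report`, a data frame with `k_deg_T`, `zero_frac`,
#'   `bimodal` and `n`.
#' @examples
#' \donttest{
#' bistability_onset(rate_parameters(), scan = c(0.2, 0.4, 0.8), n = 100,
#'                   master_seed = 1)
#' }
#' @export
bistability_onset <- function(params = rate_parameters(),
                              variant = model_variant(),
                              scan, n = 300, eps = 0.02, t_end = 2000,
                              master_seed) {
  stopifnot(!is.unsorted(scan), eps > 0, eps < 0.5, !missing(master_seed))
  zero_frac <- vapply(seq_along(scan), function(i) {
    p <- set_parameters(params, k_deg_T = scan[i])
    ens <- run_ensemble(p, variant, t_end = t_end, n = n,
                        master_seed = point_seed(master_seed, i))
    mean(ens$max[, "I"] == 0)
  }, numeric(1))
  report <- data.frame(k_deg_T = scan, zero_frac = zero_frac,
                       bimodal = zero_frac > eps & zero_frac < 1 - eps, n = n)
  hit <- which(zero_frac > eps)
  structure(list(onset = if (length(hit)) scan[hit[1]] else NA_real_,
                 report = report, eps = eps, master_seed = master_seed),
            class = "bistability_report")
}

#' @export
print.bistability_report <- function(x, ...) {
  if (is.na(x$onset))
    cat(sprintf("Bistability (zero-I fraction > %g) not reached on scan\n",
                x$eps))
  else
    cat(sprintf("Bistability onset: zero-I fraction first exceeds %g at k_deg_T = %g min^-1\n",
                x$eps, x$onset))
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Write a decision curve as CSV
#'
#' Columns: `k_deg_T`, `frac_I`, `frac_A`, `n`, `theta_I`, `theta_A`,
#' `amplitude`, `master_seed`.
#'
#' @param curve a [decision_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decision_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "decision_curve"))
  df <- as.data.frame(curve)
  df$theta_I <- attr(curve, "theta_I")
  df$theta_A <- attr(curve, "theta_A")
  df$amplitude <- attr(curve, "amplitude")
  df$master_seed <- attr(curve, "master_seed")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
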