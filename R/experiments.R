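# The network's in silico experiments, packaged as reproducible scenarios.
# Every comparison reuses identical per-trajectory seeds across conditions
# (paired seeds), so reported differences are not resampling noise.

qualitative_call <- function(frac_I, frac_A, rule = 0.5) {
  if (frac_I >= rule && frac_A >= rule) "both"
  else if (frac_I >= rule) "inflammatory"
  else if (frac_A >= rule) "anti-inflammatory"
  else "none"
}

scenario_result <- function(label, params, variant, frac_I, frac_A,
                            theta_I, theta_A, n, master_seed, extra = list()) {
  structure(c(list(label = label, params = params, variant = variant,
                   k_deg_T = params$k_deg_T, amplitude = params$pSTAT3_0,
                   frac_I = frac_I, frac_A = frac_A,
                   theta_I = theta_I, theta_A = theta_A, n = n,
                   master_seed = master_seed,
                   call = qualitative_call(frac_I, frac_A)),
              extra),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("%s  (k_deg_T = %g, amplitude = %d, n = %d)\n",
              x$label, x$k_deg_T, as.integer(x$amplitude), x$n))
  cat(sprintf("  I >= %g crossed by %.1f%%; A >= %g crossed by %.1f%%  ->  %s\n",
              x$theta_I, 100 * x$frac_I, x$theta_A, 100 * x$frac_A, x$call))
  invisible(x)
}

#' In silico feedback-knockout panel
#'
#' Runs the full network and the three feedback knockouts (positive loop
#' removed, negative loop removed, both removed) under a sustained and a
#' transient signal each, with paired per-trajectory seeds, and reports
#' threshold-crossing fractions, endpoint means and the qualitative call for
#' each of the eight scenarios.
#'
#' Expected qualitative outcomes: removing the positive loop leaves the
#' sustained (anti-inflammatory) response intact but abolishes any response
#' to transient signals; removing the negative loop leaves the transient
#' (inflammatory) response intact while sustained signals now produce both
#' proteins in quantity; removing both loops makes both genes purely
#' signal-dependent.
#'
#' @param params a [rate_parameters()] object.
#' @param t_end horizon (minutes).
#' @param n trajectories per scenario.
#' @param master_seed integer master seed (shared across scenarios: paired).
#' @param kdeg_sustained,kdeg_transient the two signal regimes (per minute).
#' @param theta_I,theta_A decision thresholds (molecules).
#' @return An object of class `knockout_panel`: named list of eight
#'   `scenario_result`s (`full`, `posKO`, `negKO`, `doubleKO` x
#'   `sustained`/`transient`).
#' @examples
#' \donttest{
#' knockout_panel(rate_parameters(), n = 100, master_seed = 1)
#' }
#' @export
knockout_panel <- function(params = rate_parameters(), t_end = 2000, n = 1000,
                           master_seed, kdeg_sustained = 0,
                           kdeg_transient = 1.0,
                           theta_I = 100, theta_A = 20) {
  stopifnot(!missing(master_seed))
  variants <- list(
    full = model_variant(),
    posKO = model_variant(positive_feedback = FALSE),
    negKO = model_variant(negative_feedback = FALSE),
    doubleKO = model_variant(positive_feedback = FALSE,
                             negative_feedback = FALSE))
  regimes <- c(sustained = kdeg_sustained, transient = kdeg_transient)
  out <- list()
  for (vn in names(variants)) for (rn in names(regimes)) {
    p <- set_parameters(params, k_deg_T = regimes[[rn]])
    ens <- run_ensemble(p, variants[[vn]], t_end = t_end, n = n,
                        master_seed = master_seed)
    out[[paste(vn, rn, sep = ".")]] <- scenario_result(
      paste(vn, rn), p, variants[[vn]],
      crossing_fraction(ens, "I", theta_I),
      crossing_fraction(ens, "A", theta_A),
      theta_I, theta_A, n, master_seed,
      extra = list(mean_final_I = mean(ens$final[, "I"]),
                   mean_final_A = mean(ens$final[, "A"])))
  }
  structure(out, class = "knockout_panel")
}

#' @export
print.knockout_panel <- function(x, ...) {
  cat("Feedback knockout panel\n")
  for (s in x) print(s)
  invisible(x)
}

#' Decision curves at several signal amplitudes
#'
#' One [decision_curve()] per initial pSTAT3 amount, all computed with the
#' same master seed so that per-trajectory seeds are paired across
#' amplitudes.  Lowering the amplitude shifts both curves toward smaller
#' `k_deg_T` without changing their shape.
#'
#' @param params a [rate_parameters()] object (its `pSTAT3_0` is overridden).
#' @param amplitudes initial pSTAT3 counts.
#' @param grid `k_deg_T` grid passed to [decision_curve()].
#' @param theta_I,theta_A decision thresholds.
#' @param n trajectories per grid point.
#' @param t_end horizon (minutes).
#' @param master_seed integer master seed.
#' @return An object of class `amplitude_sweep`: named list of
#'   `decision_curve`s (names = amplitudes).
#' @export
amplitude_sweep <- function(params = rate_parameters(),
                            amplitudes = c(10, 20, 50, 100),
                            grid = kdeg_grid(), theta_I = 100, theta_A = 20,
                            n = 1000, t_end = 2000, master_seed) {
  stopifnot(all(amplitudes > 0), !missing(master_seed))
  out <- lapply(amplitudes, function(a)
    decision_curve(set_parameters(params, pSTAT3_0 = a), grid = grid,
                   theta_I = theta_I, theta_A = theta_A, n = n, t_end = t_end,
                   master_seed = master_seed))
  names(out) <- as.character(amplitudes)
  structure(out, class = "amplitude_sweep")
}

#' @export
print.amplitude_sweep <- function(x, ...) {
  cat("Amplitude sweep of decision curves\n")
  for (a in names(x)) {
    cat(sprintf("-- amplitude %s --\n", a))
    print(x[[a]])
  }
  invisible(x)
}

#' Predicted inflammatory response of WT and SOCS3-knockout macrophages
#'
#' Models the IL-6 + LPS experiment on SOCS3-deficient macrophages.  SOCS3
#' cannot shut down IL-6 signalling in the knockout, so the normally
#' transient pSTAT3 signal (WT, `k_deg_T = 0.1`) becomes sustained
#' (`k_deg_T = 0.003`); the question is what fraction of LPS-stimulated
#' cells stays inflammatory as the pSTAT3 amplitude (IL-6 dose) rises.
#'
#' LPS keeps cells inflammatory on its own, so cells only leave the
#' inflammatory pool when A's negative feedback actively suppresses
#' I-threshold crossing.  Suppression is measured against a paired-seed
#' negative-feedback-knockout control:
#' `% inflammatory = 100 - 100 * max(0, frac_I(negKO) - frac_I(full))`.
#' A failure to ignite the positive loop (low amplitude) therefore does not
#' masquerade as an anti-inflammatory response.
#'
#' @param params a [rate_parameters()] object.
#' @param amplitudes initial pSTAT3 counts to scan (IL-6 dose proxy).
#' @param kdeg_wt,kdeg_ko signal degradation rates for WT and SOCS3-/-.
#' @param theta_I inflammatory threshold (molecules).
#' @param n trajectories per condition/amplitude.
#' @param t_end horizon (minutes).
#' @param master_seed integer master seed (paired across all cells).
#' @return An object of class `socs3_prediction`: data frame with columns
#'   `condition`, `k_deg_T`, `amplitude`, `frac_I_full`, `frac_I_negKO`,
#'   `percent_inflammatory`.
#' @examples
#' \donttest{
#' socs3_prediction(rate_parameters(), amplitudes = c(10, 100), n = 100,
#'                  master_seed = 1)
#' }
#' @export
socs3_prediction <- function(params = rate_parameters(),
                             amplitudes = c(1, 2, 5, 10, 20, 50, 100),
                             kdeg_wt = 0.1, kdeg_ko = 0.003,
                             theta_I = 100, n = 1000, t_end = 2000,
                             master_seed) {
  stopifnot(all(amplitudes > 0), !missing(master_seed))
  conditions <- c(WT = kdeg_wt, `SOCS3-/-` = kdeg_ko)
  negko <- model_variant(negative_feedback = FALSE)
  rows <- list()
  for (cn in names(conditions)) for (a in amplitudes) {
    p <- set_parameters(params, k_deg_T = conditions[[cn]], pSTAT3_0 = a)
    full <- run_ensemble(p, model_variant(), t_end = t_end, n = n,
                         master_seed = master_seed)
    ko <- run_ensemble(p, negko, t_end = t_end, n = n,
                       master_seed = master_seed)
    fI <- crossing_fraction(full, "I", theta_I)
    fK <- crossing_fraction(ko, "I", theta_I)
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cn, k_deg_T = conditions[[cn]], amplitude = a,
      frac_I_full = fI, frac_I_negKO = fK,
      percent_inflammatory = 100 - 100 * max(0, fK - fI))
  }
  structure(do.call(rbind, rows),
            class = c("socs3_prediction", "data.frame"),
            theta_I = theta_I, n = n, master_seed = master_seed)
}

#' @export
print.socs3_prediction <- function(x, ...) {
  cat("Predicted % inflammatory cells (LPS + cytokine)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Long-horizon breakdown check
#'
#' A is purely signal-dependent, so for any non-zero signal decay it
#' eventually vanishes and the few surviving I molecules re-ignite the
#' positive feedback loop: observed out to 5000 min with a slowly decaying
#' signal, I dominates.  Slowing A's turnover (`k_deg_A = 1e-4`) keeps the
#' negative loop active and restores the anti-inflammatory decision at the
#' same horizon.
#'
#' @param params a [rate_parameters()] object.
#' @param variant a [model_variant()] object.
#' @param t_end horizon (minutes), > 2000.
#' @param kdeg signal degradation rate (per minute).
#' @param n trajectories.
#' @param theta_I,theta_A decision thresholds (molecules).
#' @param k_deg_A optional override of A's removal rate.
#' @param master_seed integer master seed.
#' @return A `scenario_result`.
#' @examples
#' \donttest{
#' long_time_check(rate_parameters(), n = 100, master_seed = 1)
#' long_time_check(rate_parameters(), k_deg_A = 1e-4, theta_A = 20,
#'                 n = 100, master_seed = 1)
#' }
#' @export
long_time_check <- function(params = rate_parameters(),
                            variant = model_variant(),
                            t_end = 5000, kdeg = 0.002, n = 300,
                            theta_I = 100, theta_A = 100,
                            k_deg_A = NULL, master_seed) {
  stopifnot(t_end > 2000, !missing(master_seed))
  p <- set_parameters(params, k_deg_T = kdeg)
  if (!is.null(k_deg_A)) p <- set_parameters(p, k_deg_A = k_deg_A)
  ens <- run_ensemble(p, variant, t_end = t_end, n = n,
                      master_seed = master_seed)
  scenario_result(
    sprintf("long-time check (t_end = %g, k_deg_A = %g)", t_end, p$k_deg_A),
    p, variant,
    crossing_fraction(ens, "I", theta_I),
    crossing_fraction(ens, "A", theta_A),
    theta_I, theta_A, n, master_seed,
    extra = list(mean_final_I = mean(ens$final[, "I"]),
                 mean_final_A = mean(ens$final[, "A"])))
}
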