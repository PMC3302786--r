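# Exact stochastic simulation (Gillespie direct method) of the network.
#
# Seed discipline: a trajectory is fully determined by (params, variant, seed).
# run_ensemble() gives trajectory j the seed master_seed + j, so ensembles are
# bit-reproducible and comparisons across conditions can reuse identical
# per-trajectory seeds ("paired seeds").  Seeds are whitened through
# splitmix64 inside the C++ engine before seeding its mt19937-64 generator.

#' Simulate one exact stochastic trajectory
#'
#' Samples one realization of the chemical master equation with the Gillespie
#' direct method: exponential waiting times from the total propensity, channel
#' choice proportional to propensity.  Running maxima of every species are
#' tracked at event resolution (not just at recording times), because the
#' decision analyses compare the maximum of a trajectory to a threshold.
#'
#' @param params a [rate_parameters()] object.
#' @param variant a [model_variant()] object.
#' @param t_end simulation horizon (minutes).
#' @param grid_step recording interval (minutes); the state is recorded at
#'   `seq(0, t_end, by = grid_step)`.
#' @param seed integer seed; same inputs give a bit-identical trajectory.
#' @param record if `FALSE`, skip grid recording (running maxima and the final
#'   state are still returned) — much lighter for large ensembles.
#' @return An object of class `ssa_trajectory`: list with `time`, `counts`
#'   (time x species matrix, if recorded), `max` (named per-species running
#'   maxima), `final` (state at `t_end`), `n_events`, `seed`, `params`,
#'   `variant`.
#' @examples
#' tr <- simulate_trajectory(rate_parameters(k_deg_T = 1), t_end = 200, seed = 1)
#' tr$max["I"]
#' @export
simulate_trajectory <- function(params = rate_parameters(),
                                variant = model_variant(),
                                t_end = 2000, grid_step = 1,
                                seed, record = TRUE) {
  stopifnot(t_end > 0, grid_step > 0, !missing(seed))
  net <- reaction_network(params, variant)
  simulate_from_network(net, t_end, grid_step, seed, record)
}

# internal: run the C++ engine from a prebuilt reaction table
simulate_from_network <- function(net, t_end, grid_step, seed, record = TRUE) {
  grid <- if (record) seq(0, t_end, by = grid_step) else numeric(0)
  init <- initial_state(net$params)
  res <- ssa_run_cpp(unname(init), net$rates, net$reactants, net$stoich,
                     grid, t_end, as.double(seed), record)
  counts <- NULL
  if (record) {
    counts <- res$counts
    colnames(counts) <- net$species
  }
  structure(list(time = if (record) grid else NULL,
                 counts = counts,
                 max = stats::setNames(res$max, net$species),
                 final = stats::setNames(res$final, net$species),
                 n_events = res$n_events, seed = seed,
                 params = net$params, variant = net$variant),
            class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat(sprintf("SSA trajectory: %s events, seed %s\n",
              format(x$n_events, big.mark = ","), format(x$seed)))
  cat("running maxima (free molecules):\n")
  print(x$max[c("T", "I", "A")])
  cat("final state:\n")
  print(x$final[c("T", "I", "A", "Im", "Am")])
  invisible(x)
}

#' @export
as.data.frame.ssa_trajectory <- function(x, ...) {
  if (is.null(x$counts)) stop("trajectory was simulated with record = FALSE")
  data.frame(time_min = rep(x$time, times = ncol(x$counts)),
             species = rep(colnames(x$counts), each = length(x$time)),
             count = as.vector(x$counts))
}

#' @export
plot.ssa_trajectory <- function(x, species = c("I", "A"), ...) {
  if (is.null(x$counts)) stop("trajectory was simulated with record = FALSE")
  graphics::matplot(x$time, x$counts[, species, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (min)", ylab = "molecules", ...)
  graphics::legend("topleft", legend = species, col = seq_along(species),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Simulate a seeded ensemble of independent trajectories
#'
#' Runs `n` independent trajectories; trajectory `j` uses seed
#' `master_seed + j`, so the ensemble is bit-reproducible from
#' `(params, variant, master_seed, n)` and experiments that compare
#' conditions can pair trajectories by reusing the same master seed.
#'
#' @inheritParams simulate_trajectory
#' @param n number of trajectories.
#' @param master_seed integer master seed.
#' @param record `"maxima"` (default) keeps per-trajectory running maxima and
#'   final states only; `"grid"` additionally keeps every recorded
#'   trajectory.
#' @return An object of class `ssa_ensemble`: list with `max` (n x species
#'   matrix of running maxima), `final` (n x species matrix of states at
#'   `t_end`), `trajectories` (list of `ssa_trajectory` or `NULL`), `n`,
#'   `t_end`, `master_seed`, `params`, `variant`.
#' @examples
#' ens <- run_ensemble(rate_parameters(k_deg_T = 1), n = 20, t_end = 500,
#'                     master_seed = 1)
#' mean(ens$max[, "I"] >= 100)
#' @export
run_ensemble <- function(params = rate_parameters(),
                         variant = model_variant(),
                         t_end = 2000, grid_step = 1, n,
                         master_seed, record = c("maxima", "grid")) {
  stopifnot(n >= 1, !missing(master_seed))
  record <- match.arg(record)
  net <- reaction_network(params, variant)
  keep <- record == "grid"
  trajs <- vector("list", n)
  mx <- matrix(0, n, 15, dimnames = list(NULL, net$species))
  fin <- mx
  for (j in seq_len(n)) {
    tr <- simulate_from_network(net, t_end, grid_step, master_seed + j,
                                record = keep)
    mx[j, ] <- tr$max
    fin[j, ] <- tr$final
    if (keep) trajs[[j]] <- tr
  }
  structure(list(max = mx, final = fin,
                 trajectories = if (keep) trajs else NULL,
                 n = n, t_end = t_end, grid_step = grid_step,
                 master_seed = master_seed,
                 params = params, variant = variant),
            class = "ssa_ensemble")
}

#' @export
print.ssa_ensemble <- function(x, ...) {
  cat(sprintf("SSA ensemble: %d trajectories to %g min (master seed %s)\n",
              x$n, x$t_end, format(x$master_seed)))
  cat(sprintf("k_deg_T = %g, amplitude = %d\n",
              x$params$k_deg_T, as.integer(x$params$pSTAT3_0)))
  s <- rbind(`mean final` = colMeans(x$final[, c("T", "I", "A"), drop = FALSE]),
             `mean max` = colMeans(x$max[, c("T", "I", "A"), drop = FALSE]))
  print(round(s, 2))
  invisible(x)
}

#' @export
summary.ssa_ensemble <- function(object, ...) {
  sp <- c("T", "I", "A", "Im", "Am")
  out <- data.frame(species = sp,
                    mean_final = colMeans(object$final[, sp, drop = FALSE]),
                    sd_final = apply(object$final[, sp, drop = FALSE], 2, stats::sd),
                    mean_max = colMeans(object$max[, sp, drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Export trajectories as tidy CSV with a JSON metadata sidecar
#'
#' Writes one row per (trajectory, time, species) with columns
#' `trajectory_id`, `time_min`, `species`, `count`, plus `<path>.meta.json`
#' holding the parameter set, variant flags and seeds needed to re-run the
#' exact computation.
#'
#' @param x an `ssa_ensemble` simulated with `record = "grid"`, or an
#'   `ssa_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(x, path) {
  if (inherits(x, "ssa_trajectory")) {
    df <- as.data.frame(x)
    df <- cbind(trajectory_id = 1L, df)
    meta <- list(kind = "ssa_trajectory", seed = x$seed,
                 params = unclass(x$params), variant = unclass(x$variant))
  } else if (inherits(x, "ssa_ensemble")) {
    if (is.null(x$trajectories))
      stop("ensemble was simulated with record = \"maxima\"; rerun with record = \"grid\"")
    dfs <- lapply(seq_along(x$trajectories), function(j)
      cbind(trajectory_id = j, as.data.frame(x$trajectories[[j]])))
    df <- do.call(rbind, dfs)
    meta <- list(kind = "ssa_ensemble", n = x$n, master_seed = x$master_seed,
                 seed_rule = "trajectory j uses master_seed + j",
                 t_end = x$t_end, grid_step = x$grid_step,
                 params = unclass(x$params), variant = unclass(x$variant))
  } else stop("x must be an ssa_trajectory or ssa_ensemble")
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
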