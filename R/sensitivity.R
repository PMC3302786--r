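# Factorial parameter-sensitivity scaffold: the varied rate parameters are
# partitioned into nine classes, each taking a low / mid / high level, and
# every one of the 3^9 = 19,683 combinations can be screened for the
# duration-decoding phenotype (A dominates under a sustained signal, I under
# a transient one).  The positive-result criteria are configurable and are
# echoed into all outputs.

#' Partition of the rate parameters into level classes
#'
#' Default partition (nine classes): association rates; dissociation rates
#' other than A's slow unbinding from gene I; that slow unbinding
#' `k_off_A_I` on its own; gene-I transcription rates; gene-A transcription;
#' translation rates; protein removal; mRNA removal; initial signal amount.
#' The mid level of every class is the reference value; low/high
#' bracket it by a factor of 10.  `k_deg_m` has reference value 0, which
#' cannot be bracketed multiplicatively, so its low and mid levels are both 0
#' and its high level probes non-zero mRNA turnover.  Not varied: `k_deg_T`
#' (the scanned control variable), `k_trx_I_A` (kept at full repression) and
#' the gene copy numbers (structural constants).
#'
#' @param base a [rate_parameters()] object supplying the mid levels.
#' @param classes optional replacement partition: a named list, each element
#'   a list with `fields` (character) and `levels` (list of three named
#'   numeric vectors `low`, `mid`, `high` over those fields).
#' @return An object of class `parameter_class_grid`.
#' @examples
#' g <- parameter_class_grid()
#' grid_size(g)  # 19683
#' @export
parameter_class_grid <- function(base = rate_parameters(), classes = NULL) {
  if (is.null(classes)) {
    mk <- function(fields, low = NULL, mid = NULL, high = NULL) {
      midv <- if (is.null(mid)) unlist(base[fields]) else mid
      list(fields = fields,
           levels = list(low = if (is.null(low)) midv / 10 else low,
                         mid = midv,
                         high = if (is.null(high)) midv * 10 else high))
    }
    classes <- list(
      on_rates = mk(c("k_on_T_I", "k_on_T_A", "k_on_I_I", "k_on_A_I")),
      off_rates = mk(c("k_off_T_I", "k_off_T_A", "k_off_I_I")),
      k_off_A_I = mk("k_off_A_I"),
      k_trx_I = mk(c("k_trx_I_T", "k_trx_I_I")),
      k_trx_A = mk("k_trx_A_T"),
      translation = mk(c("k_trl_I", "k_trl_A")),
      protein_deg = mk(c("k_deg_I", "k_deg_A")),
      mrna_deg = mk("k_deg_m", low = c(k_deg_m = 0), high = c(k_deg_m = 0.01)),
      initial_amount = mk("pSTAT3_0"))
  }
  fields <- unlist(lapply(classes, `[[`, "fields"), use.names = FALSE)
  if (anyDuplicated(fields))
    stop("a parameter field appears in more than one class")
  structure(list(classes = classes, base = base),
            class = "parameter_class_grid")
}

#' @export
print.parameter_class_grid <- function(x, ...) {
  cat(sprintf("Parameter class grid: %d classes, %d combinations\n",
              length(x$classes), grid_size(x)))
  for (nm in names(x$classes))
    cat(sprintf("  %-15s %s\n", nm,
                paste(x$classes[[nm]]$fields, collapse = ", ")))
  invisible(x)
}

#' @rdname parameter_class_grid
#' @param grid a `parameter_class_grid`.
#' @export
grid_size <- function(grid) {
  stopifnot(inherits(grid, "parameter_class_grid"))
  3L^length(grid$classes)
}

#' Level assignment and parameter set for one grid index
#'
#' Combinations are ordered by base-3 digits of `index - 1`, the first class
#' varying fastest (digit 0 = low, 1 = mid, 2 = high).
#'
#' @param grid a [parameter_class_grid()].
#' @param index integer in `1:grid_size(grid)`.
#' @return `grid_levels` returns a named character vector of levels per
#'   class; `grid_parameters` the corresponding [rate_parameters()] object.
#' @examples
#' g <- parameter_class_grid()
#' grid_levels(g, 1)                       # all classes low
#' all_mid <- sum(3^(0:8)) + 1             # index with every class at mid
#' identical(grid_parameters(g, all_mid), rate_parameters())
#' @export
grid_levels <- function(grid, index) {
  stopifnot(inherits(grid, "parameter_class_grid"),
            index >= 1, index <= grid_size(grid))
  k <- length(grid$classes)
  digits <- integer(k)
  x <- index - 1
  for (j in seq_len(k)) { digits[j] <- x %% 3; x <- x %/% 3 }
  stats::setNames(c("low", "mid", "high")[digits + 1L], names(grid$classes))
}

#' @rdname grid_levels
#' @export
grid_parameters <- function(grid, index) {
  lv <- grid_levels(grid, index)
  p <- grid$base
  for (nm in names(grid$classes)) {
    cl <- grid$classes[[nm]]
    vals <- cl$levels[[lv[[nm]]]]
    p[cl$fields] <- as.list(unname(vals[cl$fields]))
  }
  validate_rate_parameters(p)
  structure(p, class = "rate_parameters")
}

#' Enumerate (index, parameter set) pairs of a class grid
#'
#' @param grid a [parameter_class_grid()].
#' @param indices which combinations to emit (default: all).
#' @return List of `list(index =, levels =, params =)`, in index order.
#' @examples
#' g <- parameter_class_grid()
#' e <- enumerate_grid(g, indices = 1:3)
#' e[[2]]$levels
#' @export
enumerate_grid <- function(grid, indices = seq_len(grid_size(grid))) {
  lapply(indices, function(i)
    list(index = i, levels = grid_levels(grid, i),
         params = grid_parameters(grid, i)))
}

#' Criteria defining successful duration decoding
#'
#' A parameter set decodes signal duration when, at the stated thresholds,
#' the anti-inflammatory response dominates under the sustained signal
#' (A-fraction high, I-fraction low) and the inflammatory response dominates
#' under the transient signal (I-fraction high, A-fraction low).  The exact
#' fraction requirements are configurable; defaults require 0.8 / 0.2 under
#' the sustained regime and 0.5 / 0.2 under the transient regime — at the
#' transient reference `k_deg_T = 1` a minority of trajectories lawfully
#' stays at zero I (stochastic bistability), so demanding 0.8 there would
#' reject the reference parameter set itself.
#'
#' @param kdeg_sustained,kdeg_transient the two signal regimes (per minute).
#' @param theta_I,theta_A decision thresholds (molecules).
#' @param sustained_A_min,sustained_I_max required fractions, sustained
#'   regime.
#' @param transient_I_min,transient_A_max required fractions, transient
#'   regime.
#' @param n trajectories per regime evaluation.
#' @param t_end horizon (minutes).
#' @return An object of class `duration_decoding_criteria`.
#' @examples
#' duration_decoding_criteria()
#' @export
duration_decoding_criteria <- function(kdeg_sustained = 0, kdeg_transient = 1,
                                       theta_I = 100, theta_A = 20,
                                       sustained_A_min = 0.8,
                                       sustained_I_max = 0.2,
                                       transient_I_min = 0.5,
                                       transient_A_max = 0.2,
                                       n = 100, t_end = 2000) {
  structure(as.list(environment()), class = "duration_decoding_criteria")
}

#' @export
print.duration_decoding_criteria <- function(x, ...) {
  cat("Duration-decoding criteria\n")
  cat(sprintf("  sustained (k_deg_T = %g): frac(A >= %g) >= %g and frac(I >= %g) <= %g\n",
              x$kdeg_sustained, x$theta_A, x$sustained_A_min, x$theta_I,
              x$sustained_I_max))
  cat(sprintf("  transient (k_deg_T = %g): frac(I >= %g) >= %g and frac(A >= %g) <= %g\n",
              x$kdeg_transient, x$theta_I, x$transient_I_min, x$theta_A,
              x$transient_A_max))
  cat(sprintf("  n = %d trajectories per regime, horizon %g min\n", x$n, x$t_end))
  invisible(x)
}

#' Classify one parameter set for duration decoding
#'
#' @param params a [rate_parameters()] object.
#' @param criteria a [duration_decoding_criteria()] object.
#' @param variant a [model_variant()] object.
#' @param master_seed integer master seed.
#' @return List with `positive` (logical) and the four measured fractions.
#' @examples
#' \donttest{
#' classify_parameters(rate_parameters(), master_seed = 1)$positive  # TRUE
#' }
#' @export
classify_parameters <- function(params,
                                criteria = duration_decoding_criteria(),
                                variant = model_variant(), master_seed) {
  stopifnot(inherits(criteria, "duration_decoding_criteria"),
            !missing(master_seed))
  ps <- set_parameters(params, k_deg_T = criteria$kdeg_sustained)
  pt <- set_parameters(params, k_deg_T = criteria$kdeg_transient)
  es <- run_ensemble(ps, variant, t_end = criteria$t_end, n = criteria$n,
                     master_seed = master_seed)
  et <- run_ensemble(pt, variant, t_end = criteria$t_end, n = criteria$n,
                     master_seed = master_seed + 5e5)
  sI <- crossing_fraction(es, "I", criteria$theta_I)
  sA <- crossing_fraction(es, "A", criteria$theta_A)
  tI <- crossing_fraction(et, "I", criteria$theta_I)
  tA <- crossing_fraction(et, "A", criteria$theta_A)
  list(positive = sA >= criteria$sustained_A_min &&
         sI <= criteria$sustained_I_max &&
         tI >= criteria$transient_I_min &&
         tA <= criteria$transient_A_max,
       sustained_frac_I = sI, sustained_frac_A = sA,
       transient_frac_I = tI, transient_frac_A = tA)
}

#' Screen (part of) a class grid for duration decoding
#'
#' Evaluates [classify_parameters()] for each requested grid index and
#' returns one row per parameter set.  With `csv` set, rows are appended as
#' they complete, so long sweeps are resumable by passing the remaining
#' indices.
#'
#' @param grid a [parameter_class_grid()].
#' @param criteria a [duration_decoding_criteria()] object.
#' @param indices grid indices to evaluate (default: all 19,683).
#' @param master_seed integer master seed; set `i` uses `master_seed` offset
#'   by its index.
#' @param csv optional path to stream results to.
#' @return Data frame with `index`, one level column per class, the four
#'   fractions and `positive`.
#' @export
sensitivity_sweep <- function(grid = parameter_class_grid(),
                              criteria = duration_decoding_criteria(),
                              indices = seq_len(grid_size(grid)),
                              master_seed, csv = NULL) {
  stopifnot(!missing(master_seed))
  rows <- vector("list", length(indices))
  for (k in seq_along(indices)) {
    i <- indices[k]
    res <- classify_parameters(grid_parameters(grid, i), criteria,
                               master_seed = master_seed + (i - 1) * 2e6)
    row <- cbind(data.frame(index = i),
                 as.data.frame(as.list(grid_levels(grid, i))),
                 as.data.frame(res[c("sustained_frac_I", "sustained_frac_A",
                                     "transient_frac_I", "transient_frac_A")]),
                 data.frame(positive = res$positive))
    rows[[k]] <- row
    if (!is.null(csv))
      utils::write.table(row, csv, append = file.exists(csv), sep = ",",
                         col.names = !file.exists(csv), row.names = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "criteria") <- criteria
  out
}

#' Level composition of the positive parameter sets
#'
#' For each parameter class, the fraction of positive (duration-decoding)
#' parameter sets carrying its low, mid and high level; fractions sum to 1
#' per class.
#'
#' @param results a [sensitivity_sweep()] result (or any data frame with one
#'   level column per class and a logical `positive` column).
#' @return Data frame with columns `class`, `low`, `mid`, `high`.
#' @examples
#' df <- data.frame(a = c("low", "low", "high"), b = c("mid", "mid", "mid"),
#'                  positive = c(TRUE, TRUE, FALSE))
#' summarize_levels(df)
#' @export
summarize_levels <- function(results) {
  stopifnot("positive" %in% names(results))
  pos <- results[results$positive, , drop = FALSE]
  if (!nrow(pos)) stop("no positive parameter sets to summarize")
  cls <- setdiff(names(results),
                 c("index", "positive", "sustained_frac_I", "sustained_frac_A",
                   "transient_frac_I", "transient_frac_A"))
  out <- do.call(rbind, lapply(cls, function(cn) {
    f <- table(factor(pos[[cn]], levels = c("low", "mid", "high"))) / nrow(pos)
    data.frame(class = cn, low = as.numeric(f["low"]),
               mid = as.numeric(f["mid"]), high = as.numeric(f["high"]))
  }))
  rownames(out) <- NULL
  out
}
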