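#' Rate parameters of the two-gene duration-decoding network
#'
#' Constructs the full parameter set of the network: promoter association and
#' dissociation rates for the shared transcription factor (pSTAT3 dimer, "T"),
#' the inflammatory protein I and the anti-inflammatory protein A;
#' transcription and translation rates; first-order removal rates; and initial
#' molecule/gene-copy numbers.  Defaults are the reference parameter set of
#' the network (Model 1).
#'
#' The signal degradation rate `k_deg_T` is the duration knob of the model:
#' `k_deg_T = 0` is a fully sustained signal, large values are transient
#' signals.  It defaults to 0 and is normally set per experiment.
#'
#' Protein removal is parameterised as separate `k_deg_I` and `k_deg_A`
#' (both defaulting to the common `k_deg`), so that the long-time behaviour of
#' the network can be probed by slowing only A's turnover.
#'
#' @param k_on_T_I,k_on_T_A association rate of T with the promoters of genes
#'   I and A (per molecule per minute).
#' @param k_on_I_I association rate of protein I with its own promoter
#'   (positive feedback loop).
#' @param k_on_A_I association rate of protein A with gene I's promoter
#'   (negative feedback loop).
#' @param k_off_T_I,k_off_T_A,k_off_I_I,k_off_A_I corresponding dissociation
#'   rates (per minute).
#' @param k_trx_I_T,k_trx_I_I transcription rate of gene I when activated by
#'   bound T or by bound I (per minute per gene copy).  When both activators
#'   are bound the larger of the two applies.
#' @param k_trx_I_A transcription rate of gene I while A is bound (repressed
#'   rate; 0 = complete repression).
#' @param k_trx_A_T transcription rate of gene A when activated by bound T.
#' @param k_trl_I,k_trl_A translation rates (per minute per mRNA).
#' @param k_deg_T signal (pSTAT3) degradation rate (per minute).
#' @param k_deg common protein deactivation/degradation rate; convenience
#'   default for `k_deg_I` and `k_deg_A`.
#' @param k_deg_I,k_deg_A protein-specific removal rates (per minute).
#' @param k_deg_m mRNA degradation rate (per minute).
#' @param pSTAT3_0 initial number of free pSTAT3 dimers (molecules).
#' @param I_g,A_g gene copy numbers.
#'
#' @return An object of class `rate_parameters` (a named list of numeric
#'   scalars).
#' @examples
#' p <- rate_parameters()            # reference parameter set, sustained signal
#' p$k_trx_A_T                       # 0.1
#' rate_parameters(k_deg_T = 1)      # transient signal
#' @export
rate_parameters <- function(k_on_T_I = 0.015, k_on_T_A = 0.015,
                            k_on_I_I = 0.015, k_on_A_I = 0.015,
                            k_off_T_I = 0.5, k_off_T_A = 0.5,
                            k_off_I_I = 0.5, k_off_A_I = 0.01,
                            k_trx_I_T = 1.0, k_trx_A_T = 0.1,
                            k_trx_I_I = 1.0, k_trx_I_A = 0,
                            k_trl_I = 0.5, k_trl_A = 0.5,
                            k_deg_T = 0,
                            k_deg = 0.001, k_deg_I = k_deg, k_deg_A = k_deg,
                            k_deg_m = 0,
                            pSTAT3_0 = 100, I_g = 2, A_g = 2) {
  p <- list(k_on_T_I = k_on_T_I, k_on_T_A = k_on_T_A,
            k_on_I_I = k_on_I_I, k_on_A_I = k_on_A_I,
            k_off_T_I = k_off_T_I, k_off_T_A = k_off_T_A,
            k_off_I_I = k_off_I_I, k_off_A_I = k_off_A_I,
            k_trx_I_T = k_trx_I_T, k_trx_A_T = k_trx_A_T,
            k_trx_I_I = k_trx_I_I, k_trx_I_A = k_trx_I_A,
            k_trl_I = k_trl_I, k_trl_A = k_trl_A,
            k_deg_T = k_deg_T, k_deg_I = k_deg_I, k_deg_A = k_deg_A,
            k_deg_m = k_deg_m,
            pSTAT3_0 = pSTAT3_0, I_g = I_g, A_g = A_g)
  validate_rate_parameters(p)
  structure(p, class = "rate_parameters")
}

#' @rdname rate_parameters
#' @export
default_parameters <- function() rate_parameters()

validate_rate_parameters <- function(p) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("parameter '", nm, "' must be non-negative", call. = FALSE)
  }
  for (nm in c("pSTAT3_0", "I_g", "A_g"))
    if (p[[nm]] != round(p[[nm]]))
      stop("parameter '", nm, "' must be a non-negative integer", call. = FALSE)
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced; all invariants
#' are re-checked.
#'
#' @param params a [rate_parameters()] object.
#' @param ... named replacements, e.g. `k_deg_T = 0.2`.
#' @return A `rate_parameters` object.
#' @examples
#' set_parameters(rate_parameters(), k_deg_T = 0.2, pSTAT3_0 = 10)
#' @export
set_parameters <- function(params, ...) {
  stopifnot(inherits(params, "rate_parameters"))
  repl <- list(...)
  if (length(repl)) {
    bad <- setdiff(names(repl), names(params))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    params[names(repl)] <- repl
  }
  validate_rate_parameters(params)
  structure(params, class = "rate_parameters")
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("Rate parameters (two-gene duration-decoding network)\n")
  v <- unlist(x)
  out <- data.frame(value = v)
  print(out)
  invisible(x)
}

#' Write / read a parameter set as a flat key-value file
#'
#' One `key = value` line per field, full double precision; reading back
#' reproduces the parameter set exactly.
#'
#' @param params a [rate_parameters()] object.
#' @param path file path.
#' @return `read_parameters` returns a `rate_parameters` object;
#'   `write_parameters` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".cfg")
#' write_parameters(rate_parameters(), f)
#' identical(read_parameters(f), rate_parameters())
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "rate_parameters"))
  lines <- vapply(names(params), function(nm)
    sprintf("%s = %s", nm, format(params[[nm]], digits = 17)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, character(1), 2L)))
  do.call(rate_parameters, as.list(stats::setNames(vals, keys)))
}

#' Model variant flags
#'
#' The network comes in two variants that differ in what happens to
#' promoter-bound activators when a transcription reaction fires:
#' in Model 1 the bound activators (T on either gene, I on gene I) dissociate
#' back to the free pools with every transcript made; in Model 2 they remain
#' bound.  A bound repressor A is never released by transcription.
#'
#' Feedback knockouts remove whole loops for in silico knockout experiments:
#' `positive_feedback = FALSE` deletes all binding of protein I to its own
#' promoter, `negative_feedback = FALSE` deletes all binding of protein A to
#' gene I's promoter.
#'
#' @param model 1 or 2; shorthand for `dissociate_on_transcription`.
#' @param dissociate_on_transcription logical; `TRUE` = Model 1.
#' @param positive_feedback keep the I autoregulatory loop?
#' @param negative_feedback keep A's repression of gene I?
#' @param degrade_bound may promoter-bound T/I/A be removed (vacating the
#'   site) at their free-pool rates?  Default `TRUE`.
#' @param catalytic_translation if `TRUE`, translation leaves the mRNA intact
#'   (`mRNA -> mRNA + protein`); by default translation consumes its mRNA,
#'   which with the default `k_deg_m = 0` is what limits protein production to
#'   the transcriptional output.
#' @return An object of class `model_variant`.
#' @examples
#' model_variant()                       # Model 1, all loops intact
#' model_variant(model = 2)
#' model_variant(negative_feedback = FALSE)
#' @export
model_variant <- function(model = 1,
                          dissociate_on_transcription = (model == 1),
                          positive_feedback = TRUE,
                          negative_feedback = TRUE,
                          degrade_bound = TRUE,
                          catalytic_translation = FALSE) {
  if (!model %in% c(1, 2)) stop("model must be 1 or 2")
  structure(list(dissociate_on_transcription = isTRUE(dissociate_on_transcription),
                 positive_feedback = isTRUE(positive_feedback),
                 negative_feedback = isTRUE(negative_feedback),
                 degrade_bound = isTRUE(degrade_bound),
                 catalytic_translation = isTRUE(catalytic_translation)),
            class = "model_variant")
}

#' @export
print.model_variant <- function(x, ...) {
  cat(sprintf("Model %d (%s)\n", if (x$dissociate_on_transcription) 1L else 2L,
              if (x$dissociate_on_transcription)
                "activators dissociate on transcription"
              else "activators stay bound on transcription"))
  cat(sprintf("  positive feedback: %s\n  negative feedback: %s\n",
              if (x$positive_feedback) "intact" else "knocked out",
              if (x$negative_feedback) "intact" else "knocked out"))
  cat(sprintf("  bound-molecule degradation: %s\n  translation: %s\n",
              if (x$degrade_bound) "allowed" else "forbidden",
              if (x$catalytic_translation) "catalytic" else "consumes mRNA"))
  invisible(x)
}
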