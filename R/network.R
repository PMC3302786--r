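#' @useDynLib sigdecode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- state-space layout ------------------------------------------------------
#
# The chemical-master-equation state is a vector of 15 non-negative integers:
#   1 T     free pSTAT3 dimers (the signal)
#   2 I     free inflammatory protein
#   3 A     free anti-inflammatory protein
#   4 Im    I mRNA
#   5 Am    A mRNA
#   6..13   I-gene copies per promoter micro-state; gene I carries three
#           independent sites (T-site, I-site, A-site), giving 8 occupancy
#           combinations.  Bin index = 6 + t + 2*i + 4*a.
#   14 Ag   A-gene copies with an empty promoter
#   15 AgT  A-gene copies with T bound
#
# Genes never decay, so bins 6..13 always sum to I_g and 14..15 to A_g.

SPECIES_T  <- 1L; SPECIES_I <- 2L; SPECIES_A <- 3L
SPECIES_Im <- 4L; SPECIES_Am <- 5L
IG_BINS <- 6:13
AG_BINS <- 14:15

ig_bin_index <- function(t, i, a) 6L + t + 2L * i + 4L * a

#' The 8 promoter micro-states of gene I
#'
#' Gene I's promoter carries three independent binding sites: one for the
#' signal T (pSTAT3), one for protein I (positive feedback) and one for the
#' repressor A (negative feedback).  Each gene copy is in one of the
#' \eqn{2^3 = 8} occupancy combinations.
#'
#' @return A data frame with logical columns `t_site`, `i_site`, `a_site`, one
#'   row per micro-state in state-vector order, row names matching the species
#'   names used throughout the package.
#' @examples
#' promoter_states()
#' @export
promoter_states <- function() {
  g <- expand.grid(t_site = c(FALSE, TRUE), i_site = c(FALSE, TRUE),
                   a_site = c(FALSE, TRUE))
  rownames(g) <- paste0("Ig",
                        ifelse(g$t_site, "T", ""),
                        ifelse(g$i_site, "I", ""),
                        ifelse(g$a_site, "A", ""))
  rownames(g)[1] <- "Ig"
  g
}

#' Species names of the state vector
#'
#' @return Character vector of length 15 naming every coordinate of the
#'   chemical-master-equation state: free `T`, `I`, `A`, the mRNAs `Im`, `Am`,
#'   the eight gene-I promoter bins and the two gene-A bins.
#' @examples
#' species_names()
#' @export
species_names <- function() {
  c("T", "I", "A", "Im", "Am", rownames(promoter_states()), "Ag", "AgT")
}

#' Transcription rate of gene I in a given promoter micro-state
#'
#' The repressor dominates: while A is bound, gene I transcribes at the
#' repressed rate `k_trx_I_A` (0 by default) regardless of activator
#' occupancy.  Otherwise the bound activator sets the rate, and when both T
#' and I are bound the larger of `k_trx_I_T` and `k_trx_I_I` applies.  With no
#' activator bound there is no transcription.
#'
#' @param t_site,i_site,a_site logicals (may be vectors): site occupancy.
#' @param params a [rate_parameters()] object.
#' @return Transcription rate(s), per minute per gene copy.
#' @examples
#' p <- rate_parameters()
#' transcription_rate_I(TRUE, TRUE, FALSE, p)   # max(k_trx_I_T, k_trx_I_I) = 1
#' transcription_rate_I(TRUE, TRUE, TRUE, p)    # repressed: 0
#' @export
transcription_rate_I <- function(t_site, i_site, a_site, params) {
  stopifnot(inherits(params, "rate_parameters"))
  both <- pmax(params$k_trx_I_T, params$k_trx_I_I)
  act <- ifelse(t_site & i_site, both,
                ifelse(t_site, params$k_trx_I_T,
                       ifelse(i_site, params$k_trx_I_I, 0)))
  ifelse(a_site, params$k_trx_I_A, act)
}

#' Initial state of a simulation
#'
#' The simulation starts at the moment the signal peaks and begins to decay:
#' all pSTAT3 is free, every gene copy has an empty promoter, and no mRNA or
#' protein has been made.
#'
#' @param params a [rate_parameters()] object.
#' @return Named numeric vector over [species_names()].
#' @examples
#' initial_state(rate_parameters())
#' @export
initial_state <- function(params) {
  stopifnot(inherits(params, "rate_parameters"))
  s <- stats::setNames(numeric(15), species_names())
  s["T"] <- params$pSTAT3_0
  s["Ig"] <- params$I_g
  s["Ag"] <- params$A_g
  s
}

# ---- reaction table ----------------------------------------------------------

#' Enumerate the complete reaction set of the network
#'
#' Builds the full list of elementary reaction channels for a parameter set
#' and model variant.  Every channel is mass-action over the 15-coordinate
#' state (the promoter micro-state bins are explicit species, so the
#' "whichever activator rate is greater" transcription rule becomes a
#' per-bin rate constant).  The same table drives the exact stochastic
#' simulator and, as its first-moment closure, the mean-field ODEs.
#'
#' Channel groups:
#' \itemize{
#'   \item binding/unbinding of T to gene I's T-site and gene A's promoter;
#'   \item binding/unbinding of I to its own promoter (dropped when
#'     `positive_feedback = FALSE`) and of A to gene I's A-site (dropped when
#'     `negative_feedback = FALSE`);
#'   \item transcription of I mRNA per gene-I bin at
#'     [transcription_rate_I()], and of A mRNA from T-bound gene-A copies;
#'     under Model 1 each transcription event returns the bound activators to
#'     the free pools (a bound repressor A stays bound);
#'   \item translation (consuming the mRNA unless
#'     `catalytic_translation = TRUE`);
#'   \item first-order removal of free T, I, A and the mRNAs, and (when
#'     `degrade_bound = TRUE`) of promoter-bound T, I and A, which vacates
#'     the site.
#' }
#' Channels whose rate constant is zero are omitted.
#'
#' @param params a [rate_parameters()] object.
#' @param variant a [model_variant()] object.
#' @return An object of class `reaction_network`: a list with `species`
#'   (names), `labels`, `rates` (rate constants), `reactants` (nchan x 2
#'   matrix of species indices, 0 = unused) and `stoich` (15 x nchan matrix).
#' @examples
#' net <- reaction_network(rate_parameters(), model_variant())
#' net
#' @export
reaction_network <- function(params = rate_parameters(),
                             variant = model_variant()) {
  stopifnot(inherits(params, "rate_parameters"),
            inherits(variant, "model_variant"))
  ps <- promoter_states()

  labels <- character(0); rates <- numeric(0)
  reactants <- matrix(integer(0), ncol = 2)
  stoich <- matrix(0L, nrow = 15, ncol = 0)

  add <- function(label, k, r, dv) {
    if (k <= 0) return(invisible())
    labels[[length(labels) + 1L]] <<- label
    rates[[length(rates) + 1L]] <<- k
    reactants <<- rbind(reactants, as.integer(c(r, rep(0L, 2 - length(r)))))
    col <- integer(15); col[as.integer(names(dv))] <- as.integer(dv)
    stoich <<- cbind(stoich, col)
    invisible()
  }
  dvec <- function(...) {
    x <- c(...)
    stats::setNames(as.integer(x), names(x))
  }

  for (b in seq_len(8)) {
    t <- ps$t_site[b]; i <- ps$i_site[b]; a <- ps$a_site[b]
    bin <- IG_BINS[b]
    nm <- rownames(ps)[b]
    # T-site
    if (!t) {
      to <- ig_bin_index(1L, i, a)
      add(paste0("T binds ", nm), params$k_on_T_I, c(SPECIES_T, bin),
          dvec(structure(c(-1, -1, 1), names = c(SPECIES_T, bin, to))))
    } else {
      to <- ig_bin_index(0L, i, a)
      add(paste0("T unbinds ", nm), params$k_off_T_I, bin,
          dvec(structure(c(1, -1, 1), names = c(SPECIES_T, bin, to))))
      if (variant$degrade_bound && params$k_deg_T > 0)
        add(paste0("bound T degraded on ", nm), params$k_deg_T, bin,
            dvec(structure(c(-1, 1), names = c(bin, to))))
    }
    # I-site (positive feedback loop)
    if (variant$positive_feedback) {
      if (!i) {
        to <- ig_bin_index(t, 1L, a)
        add(paste0("I binds ", nm), params$k_on_I_I, c(SPECIES_I, bin),
            dvec(structure(c(-1, -1, 1), names = c(SPECIES_I, bin, to))))
      } else {
        to <- ig_bin_index(t, 0L, a)
        add(paste0("I unbinds ", nm), params$k_off_I_I, bin,
            dvec(structure(c(1, -1, 1), names = c(SPECIES_I, bin, to))))
        if (variant$degrade_bound && params$k_deg_I > 0)
          add(paste0("bound I degraded on ", nm), params$k_deg_I, bin,
              dvec(structure(c(-1, 1), names = c(bin, to))))
      }
    }
    # A-site (negative feedback loop)
    if (variant$negative_feedback) {
      if (!a) {
        to <- ig_bin_index(t, i, 1L)
        add(paste0("A binds ", nm), params$k_on_A_I, c(SPECIES_A, bin),
            dvec(structure(c(-1, -1, 1), names = c(SPECIES_A, bin, to))))
      } else {
        to <- ig_bin_index(t, i, 0L)
        add(paste0("A unbinds ", nm), params$k_off_A_I, bin,
            dvec(structure(c(1, -1, 1), names = c(SPECIES_A, bin, to))))
        if (variant$degrade_bound && params$k_deg_A > 0)
          add(paste0("bound A degraded on ", nm), params$k_deg_A, bin,
              dvec(structure(c(-1, 1), names = c(bin, to))))
      }
    }
    # transcription of I from this bin
    ktrx <- transcription_rate_I(t, i, a, params)
    if (ktrx > 0) {
      if (variant$dissociate_on_transcription && (t || i)) {
        to <- ig_bin_index(0L, 0L, a)  # activators released; bound A stays
        d <- c(1, -1, 1)
        names(d) <- c(SPECIES_Im, bin, to)
        if (t) d <- c(d, structure(1, names = SPECIES_T))
        if (i) d <- c(d, structure(1, names = SPECIES_I))
        add(paste0("transcription of Im from ", nm), ktrx, bin, dvec(d))
      } else {
        add(paste0("transcription of Im from ", nm), ktrx, bin,
            dvec(structure(1, names = SPECIES_Im)))
      }
    }
  }

  # gene A: empty <-> T-bound, transcription, bound-T degradation
  add("T binds Ag", params$k_on_T_A, c(SPECIES_T, AG_BINS[1]),
      dvec(structure(c(-1, -1, 1), names = c(SPECIES_T, AG_BINS[1], AG_BINS[2]))))
  add("T unbinds Ag", params$k_off_T_A, AG_BINS[2],
      dvec(structure(c(1, 1, -1), names = c(SPECIES_T, AG_BINS[1], AG_BINS[2]))))
  if (variant$degrade_bound && params$k_deg_T > 0)
    add("bound T degraded on Ag", params$k_deg_T, AG_BINS[2],
        dvec(structure(c(1, -1), names = c(AG_BINS[1], AG_BINS[2]))))
  if (variant$dissociate_on_transcription) {
    add("transcription of Am", params$k_trx_A_T, AG_BINS[2],
        dvec(structure(c(1, 1, 1, -1),
                       names = c(SPECIES_Am, SPECIES_T, AG_BINS[1], AG_BINS[2]))))
  } else {
    add("transcription of Am", params$k_trx_A_T, AG_BINS[2],
        dvec(structure(1, names = SPECIES_Am)))
  }

  # translation
  if (variant$catalytic_translation) {
    add("translation of I", params$k_trl_I, SPECIES_Im,
        dvec(structure(1, names = SPECIES_I)))
    add("translation of A", params$k_trl_A, SPECIES_Am,
        dvec(structure(1, names = SPECIES_A)))
  } else {
    add("translation of I", params$k_trl_I, SPECIES_Im,
        dvec(structure(c(1, -1), names = c(SPECIES_I, SPECIES_Im))))
    add("translation of A", params$k_trl_A, SPECIES_Am,
        dvec(structure(c(1, -1), names = c(SPECIES_A, SPECIES_Am))))
  }

  # first-order removal of free species
  add("T decay", params$k_deg_T, SPECIES_T, dvec(structure(-1, names = SPECIES_T)))
  add("I decay", params$k_deg_I, SPECIES_I, dvec(structure(-1, names = SPECIES_I)))
  add("A decay", params$k_deg_A, SPECIES_A, dvec(structure(-1, names = SPECIES_A)))
  add("Im decay", params$k_deg_m, SPECIES_Im, dvec(structure(-1, names = SPECIES_Im)))
  add("Am decay", params$k_deg_m, SPECIES_Am, dvec(structure(-1, names = SPECIES_Am)))

  rownames(stoich) <- species_names()
  structure(list(species = species_names(), labels = labels, rates = rates,
                 reactants = reactants, stoich = stoich,
                 params = params, variant = variant),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Reaction network: %d species, %d channels\n",
              length(x$species), length(x$rates)))
  df <- data.frame(rate = x$rates, row.names = x$labels)
  print(df)
  invisible(x)
}

#' Propensities of every channel in a given state
#'
#' Mass-action propensity `k * x1 [* x2]` per channel.  All channels of this
#' network are unimolecular or hetero-bimolecular, so no combinatorial
#' corrections arise.
#'
#' @param network a [reaction_network()].
#' @param state numeric state vector over [species_names()].
#' @return Named numeric vector of propensities (per minute).
#' @examples
#' net <- reaction_network(rate_parameters(), model_variant())
#' propensities(net, initial_state(rate_parameters()))
#' @export
propensities <- function(network, state) {
  stopifnot(inherits(network, "reaction_network"), length(state) == 15)
  r1 <- network$reactants[, 1]; r2 <- network$reactants[, 2]
  p <- network$rates * state[r1]
  has2 <- r2 > 0
  p[has2] <- p[has2] * state[r2[has2]]
  stats::setNames(p, network$labels)
}

#' Apply one reaction to a state
#'
#' Adds the channel's stoichiometry vector and checks that no count goes
#' negative and that gene-copy totals are conserved.
#'
#' @param state numeric state vector over [species_names()].
#' @param network a [reaction_network()].
#' @param channel channel index or label.
#' @return The updated state vector.
#' @examples
#' net <- reaction_network(rate_parameters(), model_variant())
#' s <- initial_state(rate_parameters())
#' apply_reaction(s, net, "T binds Ig")
#' @export
apply_reaction <- function(state, network, channel) {
  stopifnot(inherits(network, "reaction_network"))
  if (is.character(channel)) channel <- match(channel, network$labels)
  if (is.na(channel) || channel < 1 || channel > ncol(network$stoich))
    stop("unknown reaction channel")
  new <- state + network$stoich[, channel]
  if (any(new < 0)) stop("reaction would produce a negative count")
  if (sum(new[IG_BINS]) != sum(state[IG_BINS]) ||
      sum(new[AG_BINS]) != sum(state[AG_BINS]))
    stop("reaction would change a gene-copy total")
  new
}
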