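---
title: "Decoding transcription-factor signal duration: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding transcription-factor signal duration: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`sigdecode` simulates a minimal two-gene transcriptional network in which a
single transcription factor — the pSTAT3 dimer, written T — drives both an
inflammatory gene I and an anti-inflammatory gene A, and the *duration* of
the T signal selects which program wins.  The biological context is IL-6
versus IL-10 signalling in macrophages: both cytokines activate STAT3, but
SOCS3 terminates only IL-6 signalling, so IL-6 yields a transient and IL-10 a
sustained pSTAT3 signal.  The simulation starts at the moment the signal
peaks and SOCS3-mediated shutdown begins: `pSTAT3_0` free T molecules at time
zero, every promoter empty, no mRNA or protein, and T decaying at the
first-order rate `k_deg_T` (min⁻¹) — the single knob that encodes duration
(`0` = fully sustained; around `1` = strongly transient).

Each gene is present in a fixed number of copies (2 by default; gene copies
never decay).  Gene I's promoter carries three *independent* sites:

* a T site (association `k_on_T_I`, dissociation `k_off_T_I`),
* an I site — the autoregulatory positive feedback loop (`k_on_I_I`,
  `k_off_I_I`),
* an A site — the negative feedback loop (`k_on_A_I`, `k_off_A_I`).

A gene-I copy transcribes its mRNA at a rate set by its occupancy: 0 with no
activator; `k_trx_I_T` or `k_trx_I_I` with one activator bound; the *larger*
of the two when both are bound; and the repressed rate `k_trx_I_A` (default
0, i.e. complete repression) whenever A is bound, regardless of activators.
Gene A has a single T site (`k_on_T_A`, `k_off_T_A`) and transcribes at
`k_trx_A_T`; it has no feedback of its own, which is what makes its product
a faithful reporter of signal duration.  mRNAs are translated at `k_trl_I`,
`k_trl_A`; proteins are deactivated/degraded at `k_deg_I`, `k_deg_A`
(a common default `k_deg = 0.001`), mRNA at `k_deg_m` (default 0).

The default rate constants (per-molecule per-minute for associations, min⁻¹
otherwise) are the network's reference parameter set: all association rates
0.015, all dissociations 0.5 except A's slow release from gene I
(`k_off_A_I = 0.01`), `k_trx_I_T = k_trx_I_I = 1`, `k_trx_A_T = 0.1`,
translation 0.5, protein removal 0.001, 100 initial T, two copies of each
gene.  They were chosen to display the phenomenon cleanly, not fitted to a
specific system; the sensitivity module (below) probes robustness around
them.

**Model 1 vs Model 2.** In Model 1 (the default) every transcription event
releases the bound activator(s) on that copy back to the free pools; in
Model 2 they remain bound.  A bound repressor is never released by
transcription (it is not part of the transcribing complex).  Both variants
decode duration with the default parameters; Model 2's transient reference
point is `k_deg_T = 0.1` rather than 1.

**Why two solvers.** With two gene copies, occupancy fluctuations are order
one and decide individual cell fates, so the chemical master equation is
sampled exactly with the Gillespie direct method.  The mean-field ODE
counterpart is kept for comparison: it shows, for example, that a
deterministic treatment caps I below a 50-molecule signalling threshold under
a sustained signal while an appreciable fraction of exact trajectories cross
it — fluctuation-driven threshold crossing that motivates the whole
stochastic apparatus — and, conversely, under bistability it tracks only the
ignited subpopulation, sitting well above the all-trajectory mean.

## Interpretive choices where the scheme is silent

* **Translation consumes its mRNA** (`mRNA -> protein`).  With immortal
  mRNA (`k_deg_m = 0`) and catalytic translation, protein production could
  never stop, contradicting the early peak and decline of I under sustained
  signalling; consuming translation makes protein output equal
  transcriptional output and renders the (zero) mRNA decay rate irrelevant.
  `model_variant(catalytic_translation = TRUE)` restores the catalytic
  variant for exploration.
* **The three gene-I sites are independent**: T and I can be co-bound (the
  max rule requires it) and A binds regardless of activator occupancy.  No
  competition for overlapping sites is modelled.
* **Degradation of promoter-bound molecules** is allowed by default
  (`degrade_bound = TRUE`), removing the molecule and vacating the site; the
  alternative (bound molecules protected) is available as a flag.
* **"Amount of I" always means free protein I** in every analysis; bound
  copies are at most the gene copy number (2) and negligible.
* **The A gene follows the same Model-1 dissociate-on-transcription rule**
  as gene I; the release rule is treated as generic.

## The stochastic engine

The reaction set is built in R (`reaction_network()`) as a mass-action
table: because each of the 8 gene-I promoter micro-states (and 2 gene-A
states) is an explicit species, every channel — including the max-rule
transcription — is a plain product `k × x₁ [× x₂]`, and the same table
drives the SSA and the ODEs.  With all loops intact and a non-zero signal
decay the network has ~50 active channels over a 15-coordinate state.

The C++ core implements the classic direct method (waiting time exponential
in the total propensity; channel chosen proportionally), with incremental
propensity updates over a species→channel dependency map and a periodic full
re-summation to cancel floating-point drift.  *Running maxima are updated at
every event*, because the decision rule compares the trajectory maximum to a
threshold and grid sampling could miss an excursion.  The recording grid
defaults to 1-min steps out to `t_end = 2000` min (about 1.5 days — long
enough that the decision has been made at every signal duration of
interest, short enough that the long-horizon breakdown discussed below does
not intrude).

Randomness comes from `std::mt19937_64`, whose output sequence is specified
by the C++ standard, with explicit uniform/exponential transforms —
trajectories are therefore bit-reproducible across platforms.  Trajectory
`j` of an ensemble uses seed `master_seed + j` (whitened through splitmix64
before seeding the engine), so ensembles are reproducible from four scalars
and *paired-seed* comparisons across conditions (knockout vs full model,
amplitude vs amplitude) reuse identical randomness, removing resampling
noise from reported differences.  Grid point `i` of a decision curve uses
`master_seed + (i-1)·10⁶`.

## The mean-field counterpart

The ODEs are the naive first-moment closure of the same reaction table:
each channel contributes rate × product of its reactant coordinates times
its stoichiometry, with the ten promoter bins carried as continuous
occupancies (gene conservation is then built into the stoichiometry).
Covariances between occupancy and free counts are ignored, as usual.
Integration uses `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`, and
maxima are taken over a dense 0.5-min reporting grid; the headline
mean-field result (max I ≈ 39.7 < 50 under a sustained signal) is unchanged
at tolerances three orders of magnitude looser, and the closure is pinned by
that ceiling plus the large-copy-number agreement test (50× copy numbers
with associations scaled by 1/50: ensemble means track the ODE to ~1%,
tested at 5%).

## Decision readouts

* **Crossing** is inclusive (`running max ≥ threshold`) — stable for integer
  counts and exact at threshold 0.
* **Decision curves** default to thresholds I ≥ 100, A ≥ 20 (I can reach
  several-fold higher maxima than A, so a common threshold has biological
  meaning only in the "no response in the crossover window" variant, also
  reproduced at θ = 90/90); grids are log-spaced with ≥5 points per decade,
  with `k_deg_T = 0` handled as a separate exact point.
* **The crossover point** is read off by log-linear interpolation of
  `frac_I − frac_A` between the bracketing grid points; with the defaults it
  falls near 0.01 min⁻¹ at amplitude 100 and shifts to ~0.0012 min⁻¹ at
  amplitude 10 (the whole curve slides left at lower amplitude because a
  weaker signal can be partially compensated by a longer one).
* **Stochastic bistability** is quantified by the fraction of trajectories
  whose I maximum is exactly 0 (the loop never ignited).  The onset reported
  by `bistability_onset()` is the first scanned `k_deg_T` where this
  fraction exceeds ε = 0.02 — there is no canonical criterion, so ε is an
  explicit argument; with the defaults the onset lands at 0.4 min⁻¹ on a
  0.05-step scan.

## The packaged experiments

* `knockout_panel()` deletes whole loops structurally (the corresponding
  binding channels are removed from the reaction table, verified by
  inspection of the generated network).
* `socs3_prediction()` models the LPS + IL-6 experiment: WT macrophages get
  `k_deg_T = 0.1`, SOCS3-deficient ones `0.003` (IL-10-like).  Because LPS
  alone keeps cells inflammatory, the reported
  `% inflammatory = 100 − 100·max(0, frac_I(negKO) − frac_I(full))` with
  paired seeds: only suppression attributable to A's negative feedback —
  not a failure to ignite the positive loop at low amplitude — can pull
  cells out of the inflammatory pool.  This is our operationalization of
  the verbal "LPS floor" assumption; the knockout control makes it exact at
  every amplitude, and it is identically 100 whenever the negative loop is
  absent.
* `long_time_check()` exposes a real limitation: A is purely
  signal-dependent, so for any non-zero `k_deg_T` it eventually decays and
  the surviving I molecules re-ignite their loop — at a 5000-min horizon
  with `k_deg_T = 0.002` the decision flips to I.  Splitting the common
  protein decay into `k_deg_I`/`k_deg_A` (a deliberate refinement of the
  single common `k_deg`, both defaulting to 0.001) allows the
  documented rescue: `k_deg_A = 10⁻⁴` keeps the negative loop alive and
  restores A dominance at the same horizon.

## Sensitivity scaffold

`parameter_class_grid()` partitions the varied rates into nine classes
(association rates; dissociation rates except `k_off_A_I`; `k_off_A_I`;
gene-I transcription; gene-A transcription; translation; protein removal;
mRNA removal; initial signal amount), each at low/mid/high levels — mid is
the reference value, low/high bracket it by ×/÷10.  Exceptions: `k_deg_m`'s
reference is 0, which cannot be bracketed multiplicatively, so its levels
are {0, 0, 0.01}; `k_deg_T` (the scanned control variable), `k_trx_I_A`
(kept at complete repression) and the gene copy numbers are not varied.
There is no canonical choice of level values for such a screen, so these
defaults are the package's own and are echoed into all outputs.

`classify_parameters()` calls a set positive when the sustained regime
(`k_deg_T = 0`) gives `frac_A ≥ 0.8` and `frac_I ≤ 0.2` *and* the transient
regime (`k_deg_T = 1`) gives `frac_I ≥ 0.5` and `frac_A ≤ 0.2` (100
trajectories per regime by default).  The transient requirement is
deliberately 0.5 rather than 0.8: at `k_deg_T = 1` roughly a third of
trajectories lawfully never ignite the positive loop (that is the
bistability, not a decoding failure), so a 0.8 requirement would reject the
reference parameter set itself.  All criteria are arguments and are stored
with the results.

## What the simulations do and do not emulate

Inputs are entirely synthetic — the model *is* the object of study, and the
parameter set defines the study conditions; there is no external data.  The
simulations abstract away: receptor/JAK kinetics and explicit SOCS3
biochemistry (the signal simply starts at its peak and decays), other STATs
and heterodimers, the multiplicity of real inflammatory/anti-inflammatory
genes (one coarse-grained representative each), nuclear transport and space,
and cell-to-cell variation in anything but reaction timing.  Passing tests
therefore validate the duration-decoding *mechanism* under idealized
conditions; they do not calibrate it to measured transcript counts, and the
positive feedback loop on inflammatory genes remains an experimentally
unverified ingredient.

## Problem sizes and numerical notes

The test suite and the acceptance script size their ensembles to keep total
runtime around a minute while leaving every stochastic assertion ≥3 standard
errors wide: 1000 trajectories for headline fractions, 300 per grid point
for curve scans (500 and 10 points/decade for the reported crossovers, whose
interpolation is the most noise-sensitive readout), 2000 for the two
amplitude percentages, 10⁴ endpoint samples for the Poisson stationarity
check.  Degenerate networks (all rates zero) freeze cleanly because a zero
total propensity terminates the event loop; propensity underflow is guarded
by a periodic full re-summation; counts are carried as doubles (exact
integers well past any reachable copy number).
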