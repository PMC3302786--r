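# Degenerate parameter sets used by the analytic-oracle tests: start from an
# all-zero network and switch on only the channels under study.
params_zero <- function(...) {
  base <- list(k_on_T_I = 0, k_on_T_A = 0, k_on_I_I = 0, k_on_A_I = 0,
               k_off_T_I = 0, k_off_T_A = 0, k_off_I_I = 0, k_off_A_I = 0,
               k_trx_I_T = 0, k_trx_A_T = 0, k_trx_I_I = 0, k_trx_I_A = 0,
               k_trl_I = 0, k_trl_A = 0,
               k_deg_T = 0, k_deg_I = 0, k_deg_A = 0, k_deg_m = 0,
               pSTAT3_0 = 0, I_g = 0, A_g = 0)
  do.call(rate_parameters, utils::modifyList(base, list(...)))
}

# hand-built ensemble stub for brute-force decision oracles
fake_ensemble <- function(max_I, max_A = rep(0, length(max_I)),
                          final_I = max_I, final_A = max_A) {
  n <- length(max_I)
  mx <- matrix(0, n, 15, dimnames = list(NULL, sigdecode::species_names()))
  fin <- mx
  mx[, "I"] <- max_I; mx[, "A"] <- max_A
  fin[, "I"] <- final_I; fin[, "A"] <- final_A
  structure(list(max = mx, final = fin, trajectories = NULL, n = n,
                 t_end = 2000, grid_step = 1, master_seed = 0,
                 params = rate_parameters(), variant = model_variant()),
            class = "ssa_ensemble")
}

ig_bin_cols <- function() 6:13
ag_bin_cols <- function() 14:15
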