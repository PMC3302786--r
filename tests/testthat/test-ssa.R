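test_that("a network with no active channels stays frozen", {
  p <- params_zero(pSTAT3_0 = 7, I_g = 2, A_g = 2)
  tr <- simulate_trajectory(p, t_end = 50, grid_step = 5, seed = 1)
  expect_equal(tr$n_events, 0)
  expect_true(all(tr$counts[, "T"] == 7))
  expect_equal(unname(tr$max), unname(tr$counts[1, ]))
  expect_equal(unname(tr$final["T"]), 7)
})

test_that("trajectories are bit-reproducible and ensembles derive their seeds", {
  p <- rate_parameters(k_deg_T = 0.5)
  a <- simulate_trajectory(p, t_end = 300, seed = 11)
  b <- simulate_trajectory(p, t_end = 300, seed = 11)
  expect_identical(a, b)
  c <- simulate_trajectory(p, t_end = 300, seed = 12)
  expect_false(identical(a$counts, c$counts))
  # trajectory j of an ensemble uses master_seed + j
  ens <- run_ensemble(p, t_end = 300, n = 3, master_seed = 10,
                      record = "grid")
  tr2 <- simulate_trajectory(p, t_end = 300, seed = 12)
  expect_identical(ens$trajectories[[2]]$counts, tr2$counts)
  expect_identical(ens$max[2, ], tr2$max)
  # whole-ensemble rerun is identical
  ens2 <- run_ensemble(p, t_end = 300, n = 3, master_seed = 10,
                       record = "grid")
  expect_identical(ens, ens2)
})

test_that("isolated signal decay matches the linear death process mean", {
  # only T decays: E[T(t)] = 100 exp(-t)
  p <- params_zero(pSTAT3_0 = 100, k_deg_T = 1)
  n <- 1500
  ens <- run_ensemble(p, t_end = 5, grid_step = 1, n = n, master_seed = 31,
                      record = "grid")
  counts <- sapply(ens$trajectories, function(tr) tr$counts[, "T"])
  for (t in c(1, 2, 5)) {
    x <- counts[t + 1, ]
    se <- stats::sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - 100 * exp(-t)), 3 * se + 1e-9)
  }
})

test_that("single-copy promoter occupancy matches the two-state chain", {
  # one A-gene copy flipping against a pool of 100 T:
  # P(bound) = k_on*T0 / (k_on*T0 + k_off) = 1.5/2 = 0.75
  p <- params_zero(pSTAT3_0 = 100, A_g = 1, k_on_T_A = 0.015, k_off_T_A = 0.5)
  tr <- simulate_trajectory(p, t_end = 50000, grid_step = 1, seed = 17)
  occ <- mean(tr$counts[tr$time > 100, "AgT"])
  expect_lt(abs(occ - 0.75), 0.02)
})

test_that("a constant-birth/death species reaches its Poisson stationary law", {
  # Model 2, both A-gene copies permanently T-bound (k_off = 0, fast on):
  # Am is born at 2 * k_trx_A_T = 0.2/min and dies at k_deg_m = 0.02/min,
  # so stationary Am ~ Poisson(10).
  p <- params_zero(pSTAT3_0 = 2, A_g = 2, k_on_T_A = 50,
                   k_trx_A_T = 0.1, k_deg_m = 0.02)
  ens <- run_ensemble(p, model_variant(model = 2), t_end = 400, n = 10000,
                      master_seed = 53)
  x <- ens$final[, "Am"]
  lambda <- 10
  kmax <- max(x)
  obs <- tabulate(x + 1, nbins = kmax + 1)
  expe <- length(x) * stats::dpois(0:kmax, lambda)
  expe[kmax + 1] <- expe[kmax + 1] + length(x) * stats::ppois(kmax, lambda,
                                                             lower.tail = FALSE)
  # merge tail bins until every expected count is >= 5
  while (length(expe) > 2 && expe[length(expe)] < 5) {
    k <- length(expe)
    expe[k - 1] <- expe[k - 1] + expe[k]; expe <- expe[-k]
    obs[k - 1] <- obs[k - 1] + obs[k]; obs <- obs[-k]
  }
  while (length(expe) > 2 && expe[1] < 5) {
    expe[2] <- expe[2] + expe[1]; expe <- expe[-1]
    obs[2] <- obs[2] + obs[1]; obs <- obs[-1]
  }
  chi2 <- sum((obs - expe)^2 / expe)
  pval <- stats::pchisq(chi2, df = length(expe) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("gene copies are conserved and maxima dominate the grid", {
  for (kdeg in c(0, 1)) {
    tr <- simulate_trajectory(rate_parameters(k_deg_T = kdeg), t_end = 500,
                              seed = 7 + kdeg)
    expect_true(all(rowSums(tr$counts[, ig_bin_cols()]) == 2))
    expect_true(all(rowSums(tr$counts[, ag_bin_cols()]) == 2))
    expect_true(all(tr$counts >= 0))
    # event-resolution running maxima bound every recorded value
    expect_true(all(apply(tr$counts, 2, max) <= tr$max + 1e-12))
  }
})

test_that("the SSA mean approaches the mean-field limit at large copy number", {
  # 50x all copy numbers with association rates scaled by 1/50 preserves the
  # deterministic rates; the ensemble mean must track the ODE within 5%.
  f <- 50
  p <- rate_parameters()
  pl <- set_parameters(p, pSTAT3_0 = p$pSTAT3_0 * f, I_g = p$I_g * f,
                       A_g = p$A_g * f,
                       k_on_T_I = p$k_on_T_I / f, k_on_T_A = p$k_on_T_A / f,
                       k_on_I_I = p$k_on_I_I / f, k_on_A_I = p$k_on_A_I / f)
  mf <- integrate_meanfield(pl, t_end = 500, grid_step = 1)
  ens <- run_ensemble(pl, t_end = 500, grid_step = 1, n = 40,
                      master_seed = 19, record = "grid")
  sel <- mf$time >= 50  # compare once molecule numbers are appreciable
  for (sp in c("I", "A")) {
    m <- rowMeans(sapply(ens$trajectories, function(tr) tr$counts[, sp]))
    rel <- abs(m[sel] - mf$counts[sel, sp]) / pmax(mf$counts[sel, sp], 1)
    expect_lt(max(rel), 0.05)
  }
})

test_that("sustained signals favour A and transient signals exclude it", {
  # sustained: distribution of A at the horizon dominates I's
  ens <- run_ensemble(rate_parameters(), t_end = 2000, n = 200,
                      master_seed = 23)
  expect_gt(stats::median(ens$final[, "A"]), 5 * stats::median(ens$final[, "I"]))
  expect_equal(crossing_fraction(ens, "A", 20), 1)
  # transient: A stays at or around zero in every trajectory
  enst <- run_ensemble(rate_parameters(k_deg_T = 1), t_end = 2000, n = 200,
                       master_seed = 24)
  expect_lte(crossing_fraction(enst, "A", 20), 0.02)
  expect_lt(stats::median(enst$final[, "A"]), 1)
})

test_that("tidy CSV export round-trips counts and writes metadata", {
  ens <- run_ensemble(rate_parameters(k_deg_T = 1), t_end = 50, grid_step = 10,
                      n = 2, master_seed = 3, record = "grid")
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectories_csv(ens, f)
  df <- utils::read.csv(f)
  expect_named(df, c("trajectory_id", "time_min", "species", "count"))
  expect_equal(nrow(df), 2 * 6 * 15)
  got <- df$count[df$trajectory_id == 2 & df$species == "T"]
  expect_equal(got, unname(ens$trajectories[[2]]$counts[, "T"]))
  meta <- jsonlite::read_json(paste0(f, ".meta.json"))
  expect_equal(meta$master_seed, 3)
  expect_equal(meta$params$pSTAT3_0, 100)
})
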