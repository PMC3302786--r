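p_ref <- rate_parameters()

test_that("gene-I transcription rate follows the repressor/max-activator rule", {
  # repressor bound: repressed rate regardless of activators
  for (t in c(FALSE, TRUE)) for (i in c(FALSE, TRUE))
    expect_equal(transcription_rate_I(t, i, TRUE, p_ref), 0)
  # both activators: whichever rate constant is greater
  expect_equal(transcription_rate_I(TRUE, TRUE, FALSE, p_ref), 1.0)
  pa <- set_parameters(p_ref, k_trx_I_I = 2.5)
  expect_equal(transcription_rate_I(TRUE, TRUE, FALSE, pa), 2.5)
  # single activator, no activator
  expect_equal(transcription_rate_I(TRUE, FALSE, FALSE, p_ref), p_ref$k_trx_I_T)
  expect_equal(transcription_rate_I(FALSE, TRUE, FALSE, p_ref), p_ref$k_trx_I_I)
  expect_equal(transcription_rate_I(FALSE, FALSE, FALSE, p_ref), 0)
  # partial repression passes through
  pr <- set_parameters(p_ref, k_trx_I_A = 0.05)
  expect_equal(transcription_rate_I(TRUE, TRUE, TRUE, pr), 0.05)
})

test_that("initial-state propensities are the mass-action products", {
  net <- reaction_network(p_ref, model_variant())
  pr <- propensities(net, initial_state(p_ref))
  expect_equal(unname(pr["T binds Ig"]), 0.015 * 100 * 2)
  expect_equal(unname(pr["T binds Ag"]), 0.015 * 100 * 2)
  expect_true(all(pr >= 0))
  # with no signal, every T-binding propensity vanishes
  s0 <- initial_state(p_ref)
  s0["T"] <- 0
  pr0 <- propensities(net, s0)
  expect_true(all(pr0[grepl("^T binds", names(pr0))] == 0))
})

test_that("every channel conserves gene-copy totals and keeps counts valid", {
  variants <- list(model_variant(), model_variant(model = 2),
                   model_variant(positive_feedback = FALSE),
                   model_variant(negative_feedback = FALSE),
                   model_variant(degrade_bound = FALSE),
                   model_variant(catalytic_translation = TRUE))
  for (v in variants) {
    net <- reaction_network(set_parameters(p_ref, k_deg_T = 0.5,
                                           k_deg_m = 0.01), v)
    ig <- colSums(net$stoich[ig_bin_cols(), , drop = FALSE])
    ag <- colSums(net$stoich[ag_bin_cols(), , drop = FALSE])
    expect_true(all(ig == 0))
    expect_true(all(ag == 0))
  }
})

test_that("applying reactions updates stoichiometry and guards invariants", {
  net <- reaction_network(p_ref, model_variant())
  s <- initial_state(p_ref)
  s2 <- apply_reaction(s, net, "T binds Ig")
  expect_equal(unname(s2["T"]), 99)
  expect_equal(unname(s2["Ig"]), 1)
  expect_equal(unname(s2["IgT"]), 1)
  # Model 1 transcription from a T-bound copy releases the activator
  s3 <- apply_reaction(s2, net, "transcription of Im from IgT")
  expect_equal(unname(s3["Im"]), 1)
  expect_equal(unname(s3["T"]), 100)
  expect_equal(unname(s3["IgT"]), 0)
  expect_equal(unname(s3["Ig"]), 2)
  # Model 2: the copy stays bound
  net2 <- reaction_network(p_ref, model_variant(model = 2))
  s4 <- apply_reaction(s2, net2, "transcription of Im from IgT")
  expect_equal(unname(s4["Im"]), 1)
  expect_equal(unname(s4["T"]), 99)
  expect_equal(unname(s4["IgT"]), 1)
  # applying an impossible reaction signals corruption
  expect_error(apply_reaction(initial_state(p_ref), net, "T unbinds IgT"),
               "negative")
  expect_error(apply_reaction(s, net, "no such channel"), "unknown")
})

test_that("feedback knockouts remove whole loops structurally", {
  # positive KO: nothing depends on free protein I except its own decay
  net <- reaction_network(p_ref, model_variant(positive_feedback = FALSE))
  dep_I <- net$labels[net$reactants[, 1] == 2 | net$reactants[, 2] == 2]
  expect_identical(dep_I, "I decay")
  # negative KO: the only channel consuming free A is its decay
  net <- reaction_network(p_ref, model_variant(negative_feedback = FALSE))
  consumes_A <- net$labels[net$stoich["A", ] < 0]
  expect_identical(consumes_A, "A decay")
  # double KO: I and A never appear in the same channel (independent given T)
  net <- reaction_network(p_ref, model_variant(positive_feedback = FALSE,
                                               negative_feedback = FALSE))
  touches <- function(sp) net$stoich[sp, ] != 0 |
    net$reactants[, 1] == match(sp, species_names()) |
    net$reactants[, 2] == match(sp, species_names())
  expect_false(any((touches("I") | touches("Im")) &
                   (touches("A") | touches("Am"))))
})

test_that("propensities stay non-negative over random valid states", {
  net <- reaction_network(set_parameters(p_ref, k_deg_T = 0.3),
                          model_variant())
  set.seed(42)
  for (rep in 1:25) {
    s <- initial_state(p_ref)
    s[c("T", "I", "A", "Im", "Am")] <- sample(0:500, 5, replace = TRUE)
    bins <- stats::rmultinom(1, p_ref$I_g, rep(1, 8))[, 1]
    s[ig_bin_cols()] <- bins
    s[ag_bin_cols()] <- stats::rmultinom(1, p_ref$A_g, rep(1, 2))[, 1]
    expect_true(all(propensities(net, s) >= 0))
  }
})
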