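test_that("the default class grid partitions the varied parameters", {
  g <- parameter_class_grid()
  expect_length(g$classes, 9)
  expect_equal(grid_size(g), 19683)
  fields <- unlist(lapply(g$classes, `[[`, "fields"), use.names = FALSE)
  expect_false(anyDuplicated(fields) > 0)
  # mid level of every class is the reference value
  for (cl in g$classes)
    expect_equal(unname(cl$levels$mid[cl$fields]),
                 unname(unlist(rate_parameters()[cl$fields])))
  # overlapping classes are rejected
  bad <- list(a = list(fields = "k_trl_I",
                       levels = list(low = c(k_trl_I = 0.1),
                                     mid = c(k_trl_I = 0.5),
                                     high = c(k_trl_I = 1))),
              b = list(fields = c("k_trl_I", "k_trl_A"),
                       levels = list(low = c(k_trl_I = 0.1, k_trl_A = 0.1),
                                     mid = c(k_trl_I = 0.5, k_trl_A = 0.5),
                                     high = c(k_trl_I = 1, k_trl_A = 1))))
  expect_error(parameter_class_grid(classes = bad), "more than one class")
})

test_that("a toy two-class grid enumerates all nine combinations in order", {
  classes <- list(
    trl = list(fields = "k_trl_I",
               levels = list(low = c(k_trl_I = 0.05), mid = c(k_trl_I = 0.5),
                             high = c(k_trl_I = 5))),
    amp = list(fields = "pSTAT3_0",
               levels = list(low = c(pSTAT3_0 = 10), mid = c(pSTAT3_0 = 100),
                             high = c(pSTAT3_0 = 1000))))
  g <- parameter_class_grid(classes = classes)
  expect_equal(grid_size(g), 9L)
  e <- enumerate_grid(g)
  expect_length(e, 9)
  # first class varies fastest
  lv <- t(vapply(e, function(x) unname(x$levels), character(2)))
  expect_equal(lv[, 1], rep(c("low", "mid", "high"), 3))
  expect_equal(lv[, 2], rep(c("low", "mid", "high"), each = 3))
  # each combination is distinct and consistent with its levels
  tuples <- vapply(e, function(x)
    paste(x$params$k_trl_I, x$params$pSTAT3_0), character(1))
  expect_equal(anyDuplicated(tuples), 0L)
  expect_equal(e[[6]]$params$k_trl_I, 5)      # index 6: (high, mid)
  expect_equal(e[[6]]$params$pSTAT3_0, 100)
})

test_that("the all-mid combination is the reference parameter set", {
  g <- parameter_class_grid()
  all_mid <- sum(3^(0:8)) + 1
  expect_identical(grid_levels(g, all_mid),
                   stats::setNames(rep("mid", 9), names(g$classes)))
  expect_identical(grid_parameters(g, all_mid), rate_parameters())
})

test_that("level summaries among positives match a brute-force tally", {
  df <- data.frame(c1 = c("low", "low", "high", "mid"),
                   c2 = c("mid", "mid", "mid", "high"),
                   positive = c(TRUE, TRUE, TRUE, FALSE))
  s <- summarize_levels(df)
  expect_equal(s$class, c("c1", "c2"))
  expect_equal(unlist(s[1, c("low", "mid", "high")], use.names = FALSE),
               c(2 / 3, 0, 1 / 3))
  expect_equal(unlist(s[2, c("low", "mid", "high")], use.names = FALSE),
               c(0, 1, 0))
  expect_equal(rowSums(s[, c("low", "mid", "high")]), c(1, 1))
  expect_error(summarize_levels(data.frame(c1 = "low", positive = FALSE)),
               "no positive")
})

test_that("the reference parameter set decodes duration; broken sets do not", {
  res <- classify_parameters(rate_parameters(), master_seed = 71)
  expect_true(res$positive)
  expect_gte(res$sustained_frac_A, 0.8)
  expect_lte(res$sustained_frac_I, 0.2)
  # reruns are reproducible
  res2 <- classify_parameters(rate_parameters(), master_seed = 71)
  expect_identical(res, res2)
  # no transcription at all: nothing is produced in either regime
  p0 <- set_parameters(rate_parameters(), k_trx_I_T = 0, k_trx_I_I = 0,
                       k_trx_A_T = 0)
  expect_false(classify_parameters(p0, master_seed = 72)$positive)
  # dead negative loop: I is not suppressed under sustained signalling
  pn <- set_parameters(rate_parameters(), k_on_A_I = 0)
  resn <- classify_parameters(pn, master_seed = 73)
  expect_false(resn$positive)
  expect_gt(resn$sustained_frac_I, 0.2)
})

test_that("a sweep over a few grid indices streams rows with level columns", {
  g <- parameter_class_grid()
  csv <- withr::local_tempfile(fileext = ".csv")
  crit <- duration_decoding_criteria(n = 30)
  res <- sensitivity_sweep(g, crit, indices = c(1, sum(3^(0:8)) + 1),
                           master_seed = 74, csv = csv)
  expect_equal(res$index, c(1, 9842))
  expect_equal(unname(unlist(res[1, names(g$classes)])), rep("low", 9))
  expect_true(all(c("sustained_frac_A", "transient_frac_I", "positive")
                  %in% names(res)))
  ondisk <- utils::read.csv(csv)
  expect_equal(nrow(ondisk), 2)
  expect_equal(ondisk$positive, res$positive)
})
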