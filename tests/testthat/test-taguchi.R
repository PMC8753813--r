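# full-precision preliminary-test SNR values recomputed from the runs;
# they round to the published eta column (asserted below)
prelim_etas <- function() {
  s <- summarize_run_table(screening_runs())
  s <- s[s$dataset == "preliminary_test", ]
  s$eta[order(s$experiment_id)]
}

test_that("the smaller-the-better SNR has its closed form and monotonicity", {
  expect_equal(snr_stb(c(0.9, 0.9, 0.9)), 20)
  expect_equal(snr_stb(0.99), 40)
  # strictly decreasing in |ybar - m| on a grid
  ybar <- seq(0.5, 0.999, by = 0.007)
  eta <- vapply(ybar, snr_stb, numeric(1))
  expect_true(all(diff(eta) > 0))
  expect_error(snr_stb(1), "undefined")
})

test_that("run summaries reproduce the published per-experiment statistics", {
  runs <- screening_runs()
  got <- summarize_run_table(runs)
  ref <- published$summary
  key <- paste(ref$experiment_id, ref$dataset)
  got <- got[match(key, paste(got$experiment_id, got$dataset)), ]
  expect_equal(round(got$mean, 4), ref$mean)
  expect_equal(round(got$sd, 4), ref$sd)
  expect_equal(round(got$eta, 4), ref$eta, tolerance = 1e-8)
})

test_that("single-experiment summaries behave at the edges", {
  r <- summarize_runs(3, "d", c(0.9, 0.9, 0.9))
  expect_equal(r$sd, 0)
  expect_equal(r$eta, 20)
  r1 <- summarize_runs(1, "d", 0.85)
  expect_equal(r1$n, 1L)
  expect_equal(r1$sd, 0)
  expect_error(summarize_runs(4, "d", c(1, 1)), "experiment 4")
  expect_error(summarize_runs(1, "d", c(0.5, 1.6)), "\\[0, 1\\]")
})

test_that("the response table reproduces the published level averages", {
  rt <- response_table(l9_oa(), prelim_etas())
  expect_equal(round(unname(rt$E), 4), unname(published$response_E),
               tolerance = 1e-8)
  expect_equal(round(unname(rt$effect), 4),
               unname(published$response_effect))
  expect_identical(rt$best_level, unname(published$best_level))
})

test_that("response-table identities hold: constant input and grand-mean averaging", {
  rt <- suppressWarnings(response_table(l9_oa(), rep(7.5, 9)))
  expect_true(all(rt$E == 7.5))
  expect_true(all(rt$effect == 0))
  # within every factor, the mean of the three level averages is the
  # grand mean (each level average covers 3 of the 9 runs exactly once)
  etas <- prelim_etas()
  rt2 <- response_table(l9_oa(), etas)
  expect_equal(unname(colMeans(rt2$E)), rep(mean(etas), 4))
  expect_error(response_table(l9_oa(), etas[-1]), "9 SNR values")
  expect_error(response_table(l9_oa(), c(etas[-1], NaN)), "finite")
})

test_that("additive objectives are recovered: best level matches the known constants", {
  # construct eta_i = a(A_i) + b(B_i) + c(C_i) + d(D_i) with known
  # per-level constants, then check argmax recovery per factor
  oa <- l9_oa()
  consts <- list(a = c(2, 5, 1), b = c(0, 3, 4), c = c(6, 2, 2),
                 d = c(1, 1.5, 9))
  etas <- vapply(1:9, function(i) {
    sum(vapply(1:4, function(f) consts[[f]][oa[i, f]], numeric(1)))
  }, numeric(1))
  rt <- response_table(oa, etas)
  expect_identical(rt$best_level,
                   vapply(consts, which.max, integer(1), USE.NAMES = FALSE))
  # and the selected combination is the exhaustive argmax over all 81
  grid <- expand.grid(1:3, 1:3, 1:3, 1:3)
  obj <- apply(grid, 1, function(lv) {
    sum(vapply(1:4, function(f) consts[[f]][lv[f]], numeric(1)))
  })
  expect_identical(unname(unlist(grid[which.max(obj), ])),
                   as.integer(rt$best_level))
  # additive input is fitted exactly: zero residuals
  fit <- taguchi(etas)
  expect_equal(unname(residuals(fit)), rep(0, 9), tolerance = 1e-12)
})

test_that("best-combination selection reproduces the published winner and breaks ties low", {
  sp <- table3_space()
  rt <- response_table(l9_oa(), prelim_etas())
  best <- select_best_combination(rt, sp)
  expect_identical(best$Optimizer, "adam")
  expect_equal(best$MiniBatchSize, 65)
  expect_equal(best$MaxEpochs, 12)
  expect_equal(best$InitialLearnRate, 1e-4)
  expect_identical(unname(attr(best, "levels")), c(1L, 2L, 3L, 1L))
  expect_warning(rt_tie <- response_table(l9_oa(), rep(1, 9)), "tie")
  tied <- select_best_combination(rt_tie, sp)
  expect_identical(unname(attr(tied, "levels")), rep(1L, 4))
})

test_that("the Taguchi ANOVA reproduces the published decomposition", {
  av <- taguchi_anova(l9_oa(), prelim_etas())
  fac <- av[1:4, ]
  expect_equal(round(fac$ss, 4), published$anova$ss, tolerance = 1e-8)
  expect_equal(round(fac$variance, 4), published$anova$variance,
               tolerance = 1e-8)
  expect_equal(round(fac$expected_ss, 4), published$anova$ss,
               tolerance = 1e-8)
  expect_equal(round(fac$pct_contribution, 2), published$anova$pct)
  expect_identical(fac$df, rep(2L, 4))
  err <- av[av$term == "Error", ]
  expect_equal(err$ss, 0, tolerance = 1e-9)
  expect_identical(err$df, 0L)
  tot <- av[av$term == "Total", ]
  expect_equal(round(tot$ss, 4), published$total_ss, tolerance = 1e-8)
  expect_identical(tot$df, 8L)
})

test_that("sums of squares are conserved and contributions sum to 100", {
  for (s in 1:100) {
    etas <- with(list(), {set.seed(s); rnorm(9, 12, 3)})
    av <- taguchi_anova(l9_oa(), etas)
    s_t <- av$ss[av$term == "Total"]
    expect_equal(sum(av$ss[1:4]), s_t, tolerance = 1e-9)
    expect_equal(sum(av$pct_contribution[1:5]), 100, tolerance = 1e-6)
  }
  # zero-effect factor contributes exactly zero under noise-free input
  oa <- l9_oa()
  etas <- c(3, 1, 2)[oa[, 2]] + c(0, 5, 1)[oa[, 4]]
  av0 <- taguchi_anova(oa, etas)
  expect_equal(av0$ss[av0$term == "A"], 0, tolerance = 1e-12)
  expect_equal(av0$ss[av0$term == "C"], 0, tolerance = 1e-12)
  # all-constant input: every SS zero
  avc <- suppressWarnings(taguchi_anova(oa, rep(4, 9)))
  expect_true(all(abs(avc$ss) < 1e-12))
})

test_that("the taguchi() model object is coherent end to end", {
  runs <- screening_runs()
  fit <- taguchi(runs, space = table3_space())
  expect_s3_class(fit, "taguchi")
  expect_equal(round(fit$grand_mean, 4),
               round(mean(prelim_etas()), 4))
  expect_identical(unname(fit$best_level), c(1L, 2L, 3L, 1L))
  expect_identical(fit$best_combination$Optimizer, "adam")
  # coef returns the level-average matrix
  expect_equal(round(unname(coef(fit)), 4), unname(published$response_E),
               tolerance = 1e-8)
  # the additive prediction at the best combination beats every
  # prediction for the nine runs actually performed
  expect_true(predict(fit) >= max(fitted(fit)) - 1e-12)
  # residuals decompose: fitted + residuals = etas
  expect_equal(fitted(fit) + residuals(fit), fit$etas)
  # analysing the training split gives a different (larger) grand mean
  fit_tr <- taguchi(runs, space = table3_space(), dataset = "training")
  expect_gt(fit_tr$grand_mean, fit$grand_mean)
  expect_error(taguchi(runs, dataset = "nope"), "no rows")
})
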