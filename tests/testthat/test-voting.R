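test_that("majority voting matches a brute-force count and its invariants", {
  # one model: identity
  v1 <- matrix(c("ALL", "Normal", "ALL"), nrow = 1)
  expect_identical(majority_vote(v1), c("ALL", "Normal", "ALL"))
  # strict majority of three
  v3 <- matrix(c("ALL", "ALL", "Normal"), ncol = 1)
  expect_identical(majority_vote(v3), "ALL")
  # random 9 x 500 matrix vs independent per-image counting oracle
  set.seed(42)
  votes <- matrix(sample(c("ALL", "Normal"), 9 * 500, replace = TRUE),
                  nrow = 9)
  oracle <- apply(votes, 2, function(col) {
    names(which.max(table(col)))
  })
  got <- majority_vote(votes)
  expect_identical(got, unname(oracle))
  # odd model count never ties; permutation of models never matters
  for (s in 1:10) {
    set.seed(s)
    v <- matrix(sample(c("ALL", "Normal"), 7 * 40, replace = TRUE), 7)
    expect_silent(majority_vote(v))  # a tie would warn
    expect_identical(majority_vote(v), majority_vote(v[sample(7), ]))
  }
  # even tie breaks toward ALL with a warning
  v2 <- matrix(c("ALL", "Normal"), nrow = 2)
  expect_warning(tie <- majority_vote(v2), "tied")
  expect_identical(tie, "ALL")
  expect_error(majority_vote(matrix(character(0), 0, 0)), "non-empty")
})

test_that("confusion matrices use the predicted-rows x actual-columns convention", {
  pred <- c(rep("ALL", 10), rep("Normal", 5))
  cm <- confusion(pred, pred)
  expect_equal(cm["ALL", "ALL"], 10)
  expect_equal(cm["Normal", "Normal"], 5)
  expect_equal(cm["ALL", "Normal"] + cm["Normal", "ALL"], 0)
  # reconstructed published ensemble counts
  lb <- labels_from_counts(1118, 177, 101, 471)
  cm9 <- confusion(lb$predicted, lb$actual)
  expect_equal(unname(as.vector(cm9)), c(1118, 101, 177, 471))
  # conservation on random labelings
  set.seed(7)
  for (i in 1:5) {
    n <- sample(50:200, 1)
    p <- sample(c("ALL", "Normal"), n, replace = TRUE)
    a <- sample(c("ALL", "Normal"), n, replace = TRUE)
    expect_equal(sum(confusion(p, a)), n)
  }
  expect_error(confusion(c("ALL"), c("ALL", "Normal")), "equal length")
  expect_error(confusion("blast", "ALL"), "unknown class")
})

test_that("metrics reproduce every published table value at 4 decimals", {
  fix <- confusion_fixture()
  for (i in seq_len(nrow(fix))) {
    cm <- confusion_counts(fix$tp[i], fix$fp[i], fix$fn[i], fix$tn[i])
    got <- classification_metrics(cm)
    expect_equal(round(unname(unclass(got)), 4),
                 unname(published$metrics[fix$model[i], ]),
                 info = fix$model[i])
  }
})

test_that("metric edge cases: perfect classifier, swapped convention, zero denominators", {
  expect_equal(unname(unclass(
    classification_metrics(confusion_counts(12, 0, 0, 30)))),
    rep(1, 5))
  # swapping the positive-class convention swaps precision with the
  # negative predictive value and recall with specificity
  set.seed(11)
  p <- sample(c("ALL", "Normal"), 300, replace = TRUE, prob = c(.6, .4))
  a <- sample(c("ALL", "Normal"), 300, replace = TRUE, prob = c(.6, .4))
  m <- classification_metrics(confusion(p, a))
  swap <- function(x) ifelse(x == "ALL", "Normal", "ALL")
  ms <- classification_metrics(confusion(swap(p), swap(a)))
  cm <- confusion(p, a)
  npv <- cm["Normal", "Normal"] / (cm["Normal", "Normal"] +
                                     cm["Normal", "ALL"])
  expect_equal(unname(ms["precision"]), unname(npv))
  expect_equal(unname(ms["recall"]), unname(m["specificity"]))
  expect_equal(unname(ms["specificity"]), unname(m["recall"]))
  # zero denominator reported as NaN with a warning
  w <- testthat::capture_warnings(
    z <- classification_metrics(confusion_counts(0, 0, 5, 5)))
  expect_match(w, "undefined", all = TRUE)
  expect_true(is.nan(z["precision"]))
  expect_error(classification_metrics(confusion_counts(0, 0, 0, 0)),
               "empty")
})

test_that("growing ensembles are evaluated over the first k models", {
  # models 1-3 perfect, 4-9 always wrong: k = 3 perfect, k = 9 all wrong
  actual <- rep(c("ALL", "Normal"), each = 10)
  wrong <- ifelse(actual == "ALL", "Normal", "ALL")
  votes <- rbind(matrix(rep(actual, 3), 3, byrow = TRUE),
                 matrix(rep(wrong, 6), 6, byrow = TRUE))
  ev <- suppressWarnings(ensemble_evaluate(votes, actual, c(3, 9)))
  expect_equal(unname(ev[["ensemble-3"]]$metrics["accuracy"]), 1)
  expect_equal(unname(ev[["ensemble-9"]]$metrics["accuracy"]), 0)
  # k = 1 equals the single model's own confusion matrix
  set.seed(5)
  v <- matrix(sample(c("ALL", "Normal"), 5 * 60, replace = TRUE), 5)
  a <- sample(c("ALL", "Normal"), 60, replace = TRUE)
  e1 <- ensemble_evaluate(v, a, 1)[[1]]
  expect_equal(unclass(e1$confusion), unclass(confusion(v[1, ], a)))
  # unanimity: all models identical -> ensemble equals the individual
  vu <- matrix(rep(v[1, ], 5), 5, byrow = TRUE)
  e5 <- ensemble_evaluate(vu, a, 5)[[1]]
  expect_equal(e5$metrics, classification_metrics(confusion(v[1, ], a)))
  expect_error(ensemble_evaluate(v, a, 7), "between 1 and")
})

test_that("error profiles count wrong votes per image and sum to the ensemble errors", {
  # all models correct: empty profile
  a <- rep(c("ALL", "Normal"), 5)
  v <- matrix(rep(a, 3), 3, byrow = TRUE)
  prof <- error_profile(v, a)
  expect_identical(nrow(prof$errors), 0L)
  # random votes: per-image multiplicity equals a brute-force count, and
  # bucket totals match the ensemble confusion errors
  set.seed(9)
  v <- matrix(sample(c("ALL", "Normal"), 9 * 120, replace = TRUE,
                     prob = c(.55, .45)), 9)
  colnames(v) <- sprintf("im%03d", 1:120)
  a <- sample(c("ALL", "Normal"), 120, replace = TRUE)
  ens <- majority_vote(v)
  prof <- error_profile(v, a, ens)
  brute <- sapply(seq_len(120), function(j) sum(v[, j] != a[j]))
  for (r in seq_len(nrow(prof$errors))) {
    j <- match(prof$errors$image_id[r], colnames(v))
    expect_equal(prof$errors$n_wrong[r], brute[j])
  }
  cm <- confusion(ens, a)
  fn <- cm["Normal", "ALL"]; fp <- cm["ALL", "Normal"]
  bk <- prof$buckets
  expect_equal(sum(bk$n_images[bk$actual == "ALL"]), fn)
  expect_equal(sum(bk$n_images[bk$actual == "Normal"]), fp)
  # every ensemble-missed image has at least a strict majority wrong
  expect_true(all(prof$errors$n_wrong >= 5))
  expect_error(error_profile(v, a[-1]), "disagree")
})

test_that("vote matrices round-trip through CSV", {
  set.seed(2)
  v <- matrix(sample(c("ALL", "Normal"), 3 * 8, replace = TRUE), 3,
              dimnames = list(paste0("m", 1:3), paste0("img", 1:8)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_votes_csv(v, path)
  expect_identical(read_votes_csv(path), v)
})
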