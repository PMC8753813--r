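# Published reference values used as frozen oracles across the suite.
# The run-level accuracies live in inst/extdata/screening_runs.csv; the
# summary statistics below are the printed per-experiment results they
# must reproduce at 4 decimal places.

published <- new.env()

published$summary <- data.frame(
  experiment_id = rep(1:9, each = 2),
  dataset = rep(c("training", "preliminary_test"), 9),
  mean = c(0.9788, 0.8013, 0.9862, 0.7970, 0.9215, 0.7481,
           0.7891, 0.6508, 0.9535, 0.7793, 0.8642, 0.6900,
           0.9859, 0.8011, 0.9059, 0.7311, 0.9819, 0.7795),
  sd = c(0.0010, 0.0075, 0.0011, 0.0071, 0.0004, 0.0003,
         0.0003, 0.0000, 0.0003, 0.0014, 0.0004, 0.0011,
         0.0016, 0.0046, 0.0004, 0.0038, 0.0020, 0.0205),
  eta = c(33.4870, 14.0346, 37.2024, 13.8487, 22.1026, 11.9754,
          13.5185, 9.1385, 26.6572, 13.1253, 17.3420, 10.1737,
          37.0156, 14.0288, 20.5282, 11.4082, 34.8624, 13.1318)
)

published$response_E <- matrix(
  c(13.2862, 10.8125, 12.8563,
    12.4006, 12.7940, 11.7603,
    11.8722, 12.0397, 13.0432,
    13.4306, 12.6837, 10.8407),
  nrow = 3, dimnames = list(level = as.character(1:3),
                            factor = c("A", "B", "C", "D")))
published$response_effect <- c(A = 2.4737, B = 1.0337, C = 1.1710,
                               D = 2.5898)
published$best_level <- c(A = 1L, B = 2L, C = 3L, D = 1L)

published$anova <- data.frame(
  term = c("A", "B", "C", "D"),
  ss = c(10.4812, 1.6333, 2.4063, 10.6617),
  variance = c(5.2406, 0.8167, 1.2031, 5.3309),
  pct = c(41.62, 6.49, 9.56, 42.34))
published$total_ss <- 25.1825

published$confirmation <- list(mean = 0.8209, sd = 0.0136,
                               eta = 14.9359, train_mean = 0.9860,
                               train_sd = 0.0025, train_eta = 37.0637)

# accuracy, precision, recall, specificity, f1 per model / ensemble
published$metrics <- rbind(
  `model-8249(#1)` = c(0.8249, 0.8436, 0.8983, 0.6867, 0.8701),
  `model-8184(#2)` = c(0.8184, 0.8624, 0.8589, 0.7423, 0.8607),
  `model-8452(#3)` = c(0.8452, 0.8582, 0.9139, 0.7160, 0.8852),
  `model-8125(#4)` = c(0.8125, 0.8376, 0.8843, 0.6775, 0.8603),
  `model-8061(#5)` = c(0.8061, 0.8562, 0.8450, 0.7330, 0.8505),
  `model-8281(#6)` = c(0.8281, 0.8376, 0.9139, 0.6667, 0.8741),
  `model-8307(#7)` = c(0.8307, 0.8536, 0.8942, 0.7114, 0.8734),
  `model-8002(#8)` = c(0.8002, 0.8473, 0.8466, 0.7130, 0.8469),
  `model-8216(#9)` = c(0.8216, 0.8377, 0.9016, 0.6713, 0.8684),
  `ensemble-3` = c(0.8409, 0.8585, 0.9057, 0.7191, 0.8814),
  `ensemble-5` = c(0.8436, 0.8641, 0.9024, 0.7330, 0.8828),
  `ensemble-7` = c(0.8506, 0.8638, 0.9155, 0.7284, 0.8889),
  `ensemble-9` = c(0.8511, 0.8633, 0.9171, 0.7269, 0.8894))
colnames(published$metrics) <- c("accuracy", "precision", "recall",
                                 "specificity", "f1")

table3_space <- function() {
  factor_space(
    Optimizer        = c("adam", "sgdm", "adam"),
    MiniBatchSize    = c(60, 65, 70),
    MaxEpochs        = c(8, 10, 12),
    InitialLearnRate = c(1e-4, 1e-5, 1e-6)
  )
}

screening_runs <- function() read_runs_csv(example_table("screening_runs"))

confusion_fixture <- function() {
  utils::read.csv(example_table("confusion_matrices"),
                  stringsAsFactors = FALSE)
}

# reconstruct label vectors realising a given confusion matrix
labels_from_counts <- function(tp, fp, fn, tn) {
  actual <- c(rep("ALL", tp + fn), rep("Normal", fp + tn))
  predicted <- c(rep("ALL", tp), rep("Normal", fn),
                 rep("ALL", fp), rep("Normal", tn))
  list(predicted = predicted, actual = actual)
}

tiny_imgset <- function(n = 2, size = 16, seed = 1) {
  synthetic_cells(n, image_size = size, seed = seed)
}
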