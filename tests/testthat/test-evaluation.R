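# Wrap prescribed assignments in a minimal classification_result.
fake_result <- function(assigned, labels, probabilities = NULL) {
  assigned <- factor(assigned, levels = labels)
  n <- length(assigned)
  if (is.null(probabilities)) {
    probabilities <- matrix(1 / length(labels), n, length(labels),
                            dimnames = list(NULL, labels))
    probabilities[cbind(seq_len(n), as.integer(assigned))] <- 0.9
    probabilities <- probabilities / rowSums(probabilities)
  }
  structure(list(probabilities = probabilities, assigned_class = assigned,
                 class_counts = table(assigned), class_labels = labels,
                 source_sample = "test"),
            class = "classification_result")
}

test_that("confusion metrics match hand arithmetic on a 2x2 table", {
  # C = [[90, 10], [30, 70]]: recall 90%/70%, precision 75%/87.5%
  truth <- rep(c("x", "y"), c(100, 100))
  pred <- c(rep("x", 90), rep("y", 10), rep("x", 30), rep("y", 70))
  met <- confusion_and_metrics(truth, fake_result(pred, c("x", "y")))
  expect_equal(unname(met$confusion), rbind(c(90, 10), c(30, 70)))
  expect_equal(unname(met$recall), c(90, 70))
  expect_equal(unname(met$precision), c(75, 87.5))
  expect_equal(met$mean_accuracy, 80)
  expect_equal(met$overall_accuracy, 80)
})

test_that("a perfect classifier yields a diagonal confusion matrix", {
  truth <- rep(c("x", "y", "z"), c(5, 3, 2))
  met <- confusion_and_metrics(truth, fake_result(truth, c("x", "y", "z")))
  expect_equal(unname(diag(met$confusion)), c(5, 3, 2))
  expect_equal(sum(met$confusion) - sum(diag(met$confusion)), 0)
  expect_equal(unname(met$recall), rep(100, 3))
  expect_equal(unname(met$precision), rep(100, 3))
})

test_that("confusion rows conserve evaluated event counts", {
  set.seed(42)
  labels <- c("a", "b", "c", "d")
  truth <- sample(labels, 500, replace = TRUE)
  pred <- sample(labels, 500, replace = TRUE)
  met <- confusion_and_metrics(truth, fake_result(pred, labels))
  expect_equal(unname(rowSums(met$confusion)),
               as.vector(table(factor(truth, labels))))
  # overall accuracy is the count-weighted mean of recall
  w <- rowSums(met$confusion) / sum(met$confusion)
  expect_equal(met$overall_accuracy, sum(w * met$recall))
})

test_that("a never-predicted class reports precision 0 with a warning", {
  truth <- c("x", "x", "y")
  expect_warning(
    met <- confusion_and_metrics(truth, fake_result(c("x", "x", "x"),
                                                    c("x", "y"))),
    "never predicted")
  expect_equal(unname(met$precision[2]), 0)
})

test_that("misaligned or unknown truth labels raise errors", {
  res <- fake_result(c("x", "y"), c("x", "y"))
  expect_error(confusion_and_metrics(c("x"), res), "aligned")
  expect_error(confusion_and_metrics(c("x", "zzz"), res), "zzz")
})

test_that("ROC area is 1 for perfect separation and 0.5 for ties", {
  truth <- c(rep(TRUE, 5), rep(FALSE, 5))
  perfect <- roc_curve(truth, c(rep(0.9, 5), rep(0.1, 5)))
  expect_equal(perfect$auc, 1)
  flat <- roc_curve(truth, rep(0.5, 10))
  expect_equal(flat$auc, 0.5)
  expect_equal(perfect$points$fpr[1], 0)
  expect_equal(perfect$points$tpr[nrow(perfect$points)], 1)
})

test_that("random scores give chance-level ROC area", {
  set.seed(7)
  truth <- rep(c(TRUE, FALSE), each = 5000)
  scores <- runif(10000)
  expect_equal(roc_curve(truth, scores)$auc, 0.5, tolerance = 0.02)
})

test_that("ROC area agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  truth <- runif(300) > 0.6
  scores <- runif(300) + truth * 0.4
  ours <- roc_curve(truth, scores)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("single-class truth is rejected for ROC", {
  expect_error(roc_curve(rep(TRUE, 5), runif(5)), "positive")
})

test_that("in-silico mixing preserves events bit-exactly with truth labels", {
  specs <- two_class_specs()
  bg <- generate_standard(specs$A, seed = 1, n_events = 5039)
  spike <- generate_standard(specs$B, seed = 2, n_events = 8000)
  mix <- in_silico_mix(list(list(data = bg, label = "unknown"),
                            list(data = spike, n = 5000)), seed = 3)
  expect_equal(nrow(mix$events$events), 10039)
  expect_equal(sum(mix$truth == "unknown"), 5039)
  expect_equal(sum(mix$truth == "B"), 5000)
  # every mixed B event is literally a row of the spike dataset
  key <- function(m) apply(m, 1, paste, collapse = "|")
  expect_true(all(key(mix$events$events[mix$truth == "B", ]) %in%
                  key(spike$events)))
  # deterministic under the seed
  mix2 <- in_silico_mix(list(list(data = bg, label = "unknown"),
                             list(data = spike, n = 5000)), seed = 3)
  expect_identical(mix$events$events, mix2$events$events)
  expect_identical(mix$truth, mix2$truth)
})

test_that("mixing with n above availability takes all events with a warning", {
  sp <- two_class_specs()$A
  small <- generate_standard(sp, seed = 4, n_events = 100)
  expect_warning(mix <- in_silico_mix(list(list(data = small, n = 500)),
                                      seed = 1), "100")
  expect_equal(nrow(mix$events$events), 100)
})

test_that("CPC is definitional arithmetic and may exceed 100%", {
  assigned <- c(A = 4000, B = 100, C = 0)
  expect_equal(correct_predicted_classification(assigned, 5000, "A"), 80)
  expect_equal(correct_predicted_classification(c(A = 6600), 5000, "A"), 132)
  expect_equal(correct_predicted_classification(assigned, 5000, "C"), 0)
  # group targets sum over classes (e.g. all subpopulations of one strain)
  expect_equal(correct_predicted_classification(assigned, 5000, c("A", "B")),
               82)
  expect_error(correct_predicted_classification(assigned, 5000, "zzz"),
               "zzz")
})

test_that("CPC is exactly 100% for a pure standard under perfect assignment", {
  truth <- rep("A", 250)
  res <- fake_result(truth, c("A", "B"))
  expect_equal(correct_predicted_classification(res$class_counts, 250, "A"),
               100)
})
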