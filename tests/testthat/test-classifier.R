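# Hand-built model with prescribed weights (zeros by default).
make_model <- function(labels, H = 4, W1 = NULL, b1 = NULL, W2 = NULL,
                       b2 = NULL) {
  K <- length(labels)
  lo <- log10(filter_spec()$lower)
  hi <- log10(filter_spec()$upper)
  structure(list(
    W_hidden = if (is.null(W1)) matrix(0, 7, H) else W1,
    b_hidden = if (is.null(b1)) rep(0, H) else b1,
    W_out = if (is.null(W2)) matrix(0, H, K) else W2,
    b_out = if (is.null(b2)) rep(0, K) else b2,
    class_labels = labels, scaling = list(min = lo, max = hi),
    hidden_nodes = H, seed = 0, optimizer = "none",
    training_log = list()), class = "classifier_model")
}

log_events <- function(m) event_table(m, scale = "log10")

test_that("softmax rows sum to one and zero weights give uniform 1/K", {
  model <- make_model(c("a", "b", "c"))
  ev <- log_events(raw_events(10, value = 4.2))
  res <- forward_pass(model, ev)
  expect_equal(unname(rowSums(res$probabilities)), rep(1, 10),
               tolerance = 1e-9)
  expect_equal(unname(res$probabilities[1, ]), rep(1 / 3, 3))
  # exact tie: assignment goes to the lowest class index
  expect_true(all(res$assigned_class == "a"))
})

test_that("events outside the scaling range are clipped with a warning", {
  model <- make_model(c("a", "b"))
  ev <- log_events(raw_events(2, value = 9.5))  # above log10(1e7)
  expect_warning(res <- forward_pass(model, ev), "clipped")
  expect_equal(nrow(res$probabilities), 2)
})

test_that("well-separated standards are learned to near-perfect recall", {
  fit <- small_two_class_fit()
  specs <- fit$specs
  # fresh held-out events, never seen in training
  ev_a <- generate_standard(specs$A, seed = 901, n_events = 600)
  ev_b <- generate_standard(specs$B, seed = 902, n_events = 600)
  mixed <- bind_events(ev_a, ev_b)
  truth <- rep(c("A", "B"), each = 600)

  # independent oracle: nearest-centroid classification at 8-SD separation
  oracle_pred <- nearest_centroid_predict(fit$standards, mixed$events)
  oracle_recall <- sapply(c("A", "B"), function(k)
    mean(oracle_pred[truth == k] == k))
  expect_true(all(oracle_recall >= 0.99))

  met <- confusion_and_metrics(truth, forward_pass(fit$model, mixed))
  expect_true(all(met$recall >= 99))
})

test_that("identically distributed classes are classified at chance", {
  sp <- synthetic_standard_spec("S", rep(4.5, 7), sd = 0.2)
  accs <- sapply(1:5, function(s) {
    stds <- lapply(1:2, function(k) {
      d <- generate_standard(sp, seed = 50 * s + k, n_events = 800)
      as_standard_dataset(log_events(d$events), c("C1", "C2")[k])
    })
    asm <- assemble_training_set(stds, 800, seed = s)
    train_classifier(asm, training_config(seed = s))$training_log$test_accuracy
  })
  expect_equal(mean(accs), 0.5, tolerance = 0.05)
})

test_that("flat validation loss triggers the early-stopping rule", {
  sp <- synthetic_standard_spec("S", rep(4.5, 7), sd = 0.2)
  stds <- lapply(1:2, function(k) {
    d <- generate_standard(sp, seed = 100 + k, n_events = 600)
    as_standard_dataset(log_events(d$events), c("C1", "C2")[k])
  })
  asm <- assemble_training_set(stds, 600, seed = 21)
  model <- train_classifier(asm, training_config(seed = 21))
  expect_identical(model$training_log$stop_reason, "validation")
  expect_lt(model$training_log$cycles, 1000)
})

test_that("accuracy agrees with an independently trained reference network", {
  skip_if_not_installed("nnet")
  fit <- small_two_class_fit()
  asm <- fit$assembly
  Xtr <- asm$X[asm$split$train, ]
  ytr <- factor(asm$class_labels[asm$y[asm$split$train]])
  ref <- nnet::nnet(Xtr, nnet::class.ind(ytr), size = 20, softmax = TRUE,
                    maxit = 200, trace = FALSE)
  Xte <- asm$X[asm$split$test, ]
  yte <- asm$class_labels[asm$y[asm$split$test]]
  keep <- !asm$anchor_mask[asm$split$test]
  ref_acc <- mean(colnames(ref$fitted.values)[
    max.col(predict(ref, Xte))] [keep] == yte[keep])
  expect_equal(fit$model$training_log$test_accuracy, ref_acc,
               tolerance = 0.02)
})

test_that("ensembles hold the requested replicates with shared labels", {
  stds <- gen_standards(two_class_specs(), 500, seed = 31)
  ens <- train_ensemble(stds, 500, training_config(seed = 31),
                        n_replicates = 3)
  expect_length(ens$models, 3)
  labs <- lapply(ens$models, `[[`, "class_labels")
  expect_true(all(vapply(labs, identical, logical(1), labs[[1]])))
  # members differ: independent subsample/split/init seeds
  expect_false(identical(ens$models[[1]]$W_hidden, ens$models[[2]]$W_hidden))

  ev <- generate_standard(two_class_specs()$A, seed = 99, n_events = 200)
  results <- classify_events(ens, ev)
  expect_length(results, 3)
  for (r in results) expect_equal(sum(r$class_counts), 200)
  sm <- summarize_counts(results)
  expect_equal(sum(sm$mean_count), 200)
})

test_that("classification is event-wise: batch composition is irrelevant", {
  fit <- small_two_class_fit()
  ev_a <- generate_standard(fit$specs$A, seed = 71, n_events = 150)
  ev_b <- generate_standard(fit$specs$B, seed = 72, n_events = 150)
  sep_a <- forward_pass(fit$model, ev_a)$probabilities
  sep_b <- forward_pass(fit$model, ev_b)$probabilities
  joint <- forward_pass(fit$model, bind_events(ev_a, ev_b))$probabilities
  expect_equal(unname(joint), unname(rbind(sep_a, sep_b)))
})

test_that("an empty event table yields all-zero counts", {
  model <- make_model(c("a", "b"))
  m <- matrix(numeric(0), 0, 7, dimnames = list(NULL, FCM_PARAMETERS))
  res <- forward_pass(model, log_events(m))
  expect_equal(sum(res$class_counts), 0)
  expect_equal(nrow(res$probabilities), 0)
})

test_that("models and ensembles reload bit-exactly from JSON", {
  fit <- small_two_class_fit()
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(fit$model, path)
  back <- load_classifier(path)
  expect_identical(back$W_hidden, fit$model$W_hidden)
  expect_identical(back$b_out, fit$model$b_out)
  expect_identical(back$class_labels, fit$model$class_labels)
  expect_equal(back$scaling, fit$model$scaling)

  ev <- generate_standard(fit$specs$A, seed = 5, n_events = 50)
  expect_identical(forward_pass(back, ev)$probabilities,
                   forward_pass(fit$model, ev)$probabilities)
})
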