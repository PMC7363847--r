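#' Training hyperparameters
#'
#' Defaults reproduce the reference training regime: up to 1000 cycles of
#' full-batch scaled-conjugate-gradient minimization of categorical
#' cross-entropy, stopping early when the gradient norm drops below 1e-6 or
#' when the validation cross-entropy fails to improve on 6 consecutive
#' cycles; the weights from the best validation point are returned.
#'
#' @param max_cycles Maximum training cycles (epochs).
#' @param min_gradient Gradient-norm stopping threshold.
#' @param max_validation_failures Consecutive cycles without validation
#'   improvement tolerated before stopping.
#' @param hidden_nodes Hidden-layer width.
#' @param performance_goal Cross-entropy at which training stops (0 = never).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `training_config`.
#' @export
training_config <- function(max_cycles = 1000, min_gradient = 1e-6,
                            max_validation_failures = 6, hidden_nodes = 20,
                            performance_goal = 0, seed = 1) {
  stopifnot(max_cycles >= 1, min_gradient > 0, max_validation_failures >= 1,
            hidden_nodes >= 1, performance_goal >= 0)
  structure(list(max_cycles = max_cycles, min_gradient = min_gradient,
                 max_validation_failures = max_validation_failures,
                 hidden_nodes = hidden_nodes,
                 performance_goal = performance_goal, seed = seed),
            class = "training_config")
}

# ---- network internals -----------------------------------------------------

unpack_weights <- function(w, n_in, n_hid, n_out) {
  i <- 0
  W1 <- matrix(w[i + seq_len(n_in * n_hid)], n_in, n_hid); i <- i + n_in * n_hid
  b1 <- w[i + seq_len(n_hid)]; i <- i + n_hid
  W2 <- matrix(w[i + seq_len(n_hid * n_out)], n_hid, n_out)
  i <- i + n_hid * n_out
  b2 <- w[i + seq_len(n_out)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

logistic <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(A) {
  A <- A - apply(A, 1, max)
  E <- exp(A)
  E / rowSums(E)
}

net_forward <- function(wts, X) {
  Z <- logistic(sweep(X %*% wts$W1, 2, wts$b1, "+"))
  P <- softmax_rows(sweep(Z %*% wts$W2, 2, wts$b2, "+"))
  list(Z = Z, P = P)
}

# mean categorical cross-entropy; Y is a one-hot matrix
net_loss <- function(wts, X, Y) {
  P <- net_forward(wts, X)$P
  -sum(Y * log(pmax(P, 1e-300))) / nrow(X)
}

net_gradient <- function(wts, X, Y) {
  fw <- net_forward(wts, X)
  dA <- (fw$P - Y) / nrow(X)
  dW2 <- crossprod(fw$Z, dA)
  db2 <- colSums(dA)
  dZ <- dA %*% t(wts$W2) * fw$Z * (1 - fw$Z)
  dW1 <- crossprod(X, dZ)
  db1 <- colSums(dZ)
  c(as.vector(dW1), db1, as.vector(dW2), db2)
}

one_hot <- function(y, k) {
  Y <- matrix(0, length(y), k)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

# ---- training --------------------------------------------------------------

#' Train one classifier on an assembled training set
#'
#' Fits the 7-input / `hidden_nodes`-hidden / K-output network (logistic
#' hidden layer, softmax output) by full-batch scaled conjugate gradient on
#' the training block, evaluating the validation block once per cycle.
#' Training stops at `max_cycles`, when the gradient norm falls below
#' `min_gradient`, or after `max_validation_failures` consecutive cycles
#' without a new validation best; the returned weights are those of the best
#' validation point. Anchor rows participate in training and scaling but are
#' excluded from the reported test-block accuracy.
#'
#' @param assembly A [assemble_training_set()] result.
#' @param config A [training_config()].
#' @return A `classifier_model` with weights, class labels, scaling constants
#'   and a `training_log` (cycles run, stop reason, losses, test accuracy).
#' @export
train_classifier <- function(assembly, config = training_config()) {
  stopifnot(inherits(assembly, "training_assembly"),
            inherits(config, "training_config"))
  K <- length(assembly$class_labels)
  if (K < 2) stop("training requires at least two classes", call. = FALSE)
  n_in <- ncol(assembly$X)
  H <- config$hidden_nodes

  Xtr <- assembly$X[assembly$split$train, , drop = FALSE]
  Ytr <- one_hot(assembly$y[assembly$split$train], K)
  Xva <- assembly$X[assembly$split$validation, , drop = FALSE]
  Yva <- one_hot(assembly$y[assembly$split$validation], K)

  n_par <- n_in * H + H + H * K + K
  w0 <- with_seed(config$seed, stats::runif(n_par, -0.5, 0.5))

  fn <- function(w) {
    L <- net_loss(unpack_weights(w, n_in, H, K), Xtr, Ytr)
    if (!is.finite(L)) stop("non-finite training loss; check input scaling",
                            call. = FALSE)
    L
  }
  gr <- function(w) net_gradient(unpack_weights(w, n_in, H, K), Xtr, Ytr)

  best <- list(w = w0, val = Inf, cycle = 0)
  fails <- 0
  stop_early <- NULL
  cb <- function(k, w, fval, gnorm) {
    val <- net_loss(unpack_weights(w, n_in, H, K), Xva, Yva)
    if (val < best$val) {
      best <<- list(w = w, val = val, cycle = k)
      fails <<- 0
    } else {
      fails <<- fails + 1
      if (fails >= config$max_validation_failures) {
        stop_early <<- "validation"
        return(FALSE)
      }
    }
    if (config$performance_goal > 0 && fval <= config$performance_goal) {
      stop_early <<- "performance_goal"
      return(FALSE)
    }
    TRUE
  }

  fit <- scg_minimize(w0, fn, gr, max_cycles = config$max_cycles,
                      min_gradient = config$min_gradient, callback = cb)
  stop_reason <- if (!is.null(stop_early)) stop_early else fit$stop_reason
  if (!is.finite(best$val)) best <- list(w = fit$par, val = NA_real_,
                                         cycle = fit$iterations)

  wts <- unpack_weights(best$w, n_in, H, K)
  model <- structure(
    list(W_hidden = wts$W1, b_hidden = wts$b1, W_out = wts$W2,
         b_out = wts$b2, class_labels = assembly$class_labels,
         scaling = assembly$scaling, hidden_nodes = H, seed = config$seed,
         optimizer = "scaled conjugate gradient"),
    class = "classifier_model")

  Xte <- assembly$X[assembly$split$test, , drop = FALSE]
  yte <- assembly$y[assembly$split$test]
  te_anch <- assembly$anchor_mask[assembly$split$test]
  Pte <- net_forward(wts, Xte)$P
  pred <- max.col(Pte, ties.method = "first")
  te_acc <- mean(pred[!te_anch] == yte[!te_anch])
  te_ce <- -sum(one_hot(yte, K) * log(pmax(Pte, 1e-300))) / length(yte)

  model$training_log <- list(
    cycles = fit$iterations, stop_reason = stop_reason,
    best_validation_cycle = best$cycle,
    train_cross_entropy = fit$value, validation_cross_entropy = best$val,
    test_cross_entropy = te_ce, test_accuracy = te_acc,
    optimizer = model$optimizer)
  model
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf(
    "<classifier_model> %d classes, %d hidden nodes; %d cycles (%s), test accuracy %.3f\n",
    length(x$class_labels), x$hidden_nodes, x$training_log$cycles,
    x$training_log$stop_reason, x$training_log$test_accuracy))
  invisible(x)
}

# ---- prediction ------------------------------------------------------------

#' Classify events with one trained model
#'
#' Applies the stored min-max scaling, the logistic hidden layer and the
#' softmax output to every event, assigning each to the class with the
#' highest probability (ties go to the lowest class index). Scaled values
#' outside [-1, 1] are clipped, with the affected event count reported.
#'
#' @param model A `classifier_model`.
#' @param events A log10-scale [event_table()] (or `standard_dataset`).
#' @return A `classification_result`: `probabilities` (N x K matrix),
#'   `assigned_class` (factor of length N), `class_counts` (named K-vector)
#'   and `source_sample`.
#' @export
forward_pass <- function(model, events) {
  stopifnot(inherits(model, "classifier_model"),
            inherits(events, "event_table"))
  if (events$scale != "log10") stop("events must be on the log10 scale",
                                    call. = FALSE)
  X <- events$events[, FCM_PARAMETERS, drop = FALSE]
  lo <- model$scaling$min
  hi <- model$scaling$max
  Xs <- sweep(sweep(X, 2, lo), 2, (hi - lo) / 2, "/") - 1
  n_clip <- sum(Xs < -1 | Xs > 1)
  if (n_clip > 0) {
    warning(n_clip, " scaled value(s) outside [-1, 1] clipped", call. = FALSE)
    Xs[Xs < -1] <- -1
    Xs[Xs > 1] <- 1
  }
  K <- length(model$class_labels)
  if (nrow(Xs) == 0) {
    P <- matrix(numeric(0), 0, K, dimnames = list(NULL, model$class_labels))
    assigned <- factor(character(0), levels = model$class_labels)
  } else {
    P <- net_forward(list(W1 = model$W_hidden, b1 = model$b_hidden,
                          W2 = model$W_out, b2 = model$b_out), Xs)$P
    colnames(P) <- model$class_labels
    assigned <- factor(model$class_labels[max.col(P, ties.method = "first")],
                       levels = model$class_labels)
  }
  structure(
    list(probabilities = P, assigned_class = assigned,
         class_counts = table(assigned), class_labels = model$class_labels,
         source_sample = events$sample_id),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s: %d events over %d classes\n",
              x$source_sample, nrow(x$probabilities), length(x$class_labels)))
  invisible(x)
}

# ---- ensemble --------------------------------------------------------------

#' Train an ensemble of replicate classifiers
#'
#' Repeats subsampling, anchoring, splitting and training `n_replicates`
#' times with independent seeds derived from `config$seed`, yielding slightly
#' different classifiers whose spread quantifies training variability.
#' Downstream summaries report mean +/- SD over the replicates.
#'
#' @param standards List of `standard_dataset` objects.
#' @param n_per_standard Subsample size per standard.
#' @param config A [training_config()]; `config$seed` seeds replicate 1.
#' @param n_replicates Number of replicate classifiers (default 5).
#' @param spec [filter_spec()] defining anchors/scaling.
#' @return A `classifier_ensemble` (list of `classifier_model`s).
#' @export
train_ensemble <- function(standards, n_per_standard = 10000,
                           config = training_config(), n_replicates = 5,
                           spec = filter_spec()) {
  stopifnot(n_replicates >= 1)
  models <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    seed_r <- config$seed + 1000003L * (r - 1L)
    asm <- assemble_training_set(standards, n_per_standard, spec = spec,
                                 seed = seed_r)
    cfg_r <- config
    cfg_r$seed <- seed_r
    models[[r]] <- train_classifier(asm, cfg_r)
  }
  structure(list(models = models), class = "classifier_ensemble")
}

#' @export
print.classifier_ensemble <- function(x, ...) {
  acc <- vapply(x$models, function(m) m$training_log$test_accuracy, numeric(1))
  cat(sprintf("<classifier_ensemble> %d replicate models, test accuracy %.3f +/- %.3f\n",
              length(x$models), mean(acc), stats::sd(acc)))
  invisible(x)
}

#' Classify events with every ensemble member
#'
#' @param ensemble A `classifier_ensemble`.
#' @param events A log10-scale [event_table()].
#' @return List of [forward_pass()] results, one per member.
#' @export
classify_events <- function(ensemble, events) {
  stopifnot(inherits(ensemble, "classifier_ensemble"))
  lapply(ensemble$models, forward_pass, events = events)
}

#' Summarize per-class counts over ensemble replicates
#'
#' @param results List of `classification_result`s from [classify_events()].
#' @return Data frame with class, mean count, SD, and mean relative abundance.
#' @export
summarize_counts <- function(results) {
  stopifnot(length(results) >= 1)
  counts <- sapply(results, function(r) as.numeric(r$class_counts))
  counts <- matrix(counts, ncol = length(results))
  labels <- results[[1]]$class_labels
  mu <- rowMeans(counts)
  sdv <- if (ncol(counts) > 1) apply(counts, 1, stats::sd) else rep(0, nrow(counts))
  total <- sum(mu)
  data.frame(class = labels, mean_count = mu, sd_count = sdv,
             relative_abundance = if (total > 0) mu / total else 0 * mu,
             row.names = NULL)
}

# ---- serialization ---------------------------------------------------------

#' Save / load classifier models and ensembles as JSON
#'
#' Weights, scaling constants, labels and the training log are written at
#' full precision so a reload is bit-exact.
#'
#' @param x A `classifier_model` or `classifier_ensemble`.
#' @param path Output file path.
#' @return `path` (for save) or the reconstructed object (for load).
#' @export
save_classifier <- function(x, path) {
  # doubles are written as %.17g strings, which round-trip bit-exactly
  ser_num <- function(v) sprintf("%.17g", v)
  ser_mat <- function(m) list(dim = dim(m), data = ser_num(as.vector(m)))
  to_ser <- function(m) {
    list(W_hidden = ser_mat(m$W_hidden), b_hidden = ser_num(m$b_hidden),
         W_out = ser_mat(m$W_out), b_out = ser_num(m$b_out),
         class_labels = m$class_labels,
         scaling = list(min = ser_num(unname(m$scaling$min)),
                        max = ser_num(unname(m$scaling$max))),
         hidden_nodes = m$hidden_nodes, seed = m$seed,
         optimizer = m$optimizer, training_log = m$training_log)
  }
  obj <- if (inherits(x, "classifier_ensemble")) {
    list(type = "ensemble", models = lapply(x$models, to_ser))
  } else if (inherits(x, "classifier_model")) {
    list(type = "model", models = list(to_ser(x)))
  } else stop("not a classifier model or ensemble", call. = FALSE)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(v) vapply(v, as.numeric, numeric(1))
  des_mat <- function(m) matrix(num(m$data), nrow = m$dim[[1]], ncol = m$dim[[2]])
  from_ser <- function(m) {
    mod <- list(
      W_hidden = des_mat(m$W_hidden), b_hidden = num(m$b_hidden),
      W_out = des_mat(m$W_out), b_out = num(m$b_out),
      class_labels = vapply(m$class_labels, as.character, character(1)),
      scaling = list(
        min = stats::setNames(num(m$scaling$min), FCM_PARAMETERS),
        max = stats::setNames(num(m$scaling$max), FCM_PARAMETERS)),
      hidden_nodes = m$hidden_nodes, seed = m$seed, optimizer = m$optimizer,
      training_log = m$training_log)
    class(mod) <- "classifier_model"
    mod
  }
  if (identical(obj$type, "ensemble")) {
    structure(list(models = lapply(obj$models, from_ser)),
              class = "classifier_ensemble")
  } else {
    from_ser(obj$models[[1]])
  }
}
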