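#' Confusion matrix and per-class performance metrics
#'
#' Cross-tabulates true standard labels against predicted classes and derives
#' per-class recall (row-normalized diagonal) and precision
#' (column-normalized diagonal), both in percent, plus two overall summaries:
#' the mean per-class recall and the overall accuracy (diagonal over total).
#' A class never predicted gets precision 0 with a warning.
#'
#' @param truth Vector of true class labels, one per event (anchors must
#'   already be excluded). Levels absent from the classifier are not allowed.
#' @param result A `classification_result` from [forward_pass()].
#' @return List with `confusion` (K x K count matrix, rows = truth),
#'   `recall`, `precision` (named percent vectors), `mean_accuracy`,
#'   `overall_accuracy` (percent scalars).
#' @export
confusion_and_metrics <- function(truth, result) {
  stopifnot(inherits(result, "classification_result"))
  labels <- result$class_labels
  if (length(truth) != nrow(result$probabilities)) {
    stop("truth labels and classified events are not aligned", call. = FALSE)
  }
  unknown <- setdiff(unique(as.character(truth)), labels)
  if (length(unknown) > 0) {
    stop("truth contains labels absent from the classifier: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  tr <- factor(as.character(truth), levels = labels)
  C <- table(truth = tr, predicted = result$assigned_class)
  C <- unclass(C)
  rs <- rowSums(C)
  cs <- colSums(C)
  diagC <- diag(C)
  recall <- ifelse(rs > 0, 100 * diagC / rs, NA_real_)
  if (any(cs == 0 & rs > 0)) {
    warning("class(es) never predicted; precision reported as 0: ",
            paste(labels[cs == 0 & rs > 0], collapse = ", "), call. = FALSE)
  }
  precision <- ifelse(cs > 0, 100 * diagC / cs, 0)
  present <- rs > 0
  list(confusion = C,
       recall = recall, precision = precision,
       mean_accuracy = mean(recall[present]),
       overall_accuracy = 100 * sum(diagC) / sum(C))
}

#' Per-class metrics averaged over an ensemble
#'
#' Applies [confusion_and_metrics()] to every replicate's result and reports
#' mean and SD of recall, precision and the two accuracy summaries over the
#' replicates (never pooling counts across replicates).
#'
#' @param truth True labels (shared by all replicates).
#' @param results List of `classification_result`s, one per replicate.
#' @return List with `per_class` data frame (recall/precision mean and SD)
#'   and `summary` data frame (mean accuracy, overall accuracy; mean and SD).
#' @export
ensemble_metrics <- function(truth, results) {
  mets <- lapply(results, function(r) confusion_and_metrics(truth, r))
  labels <- results[[1]]$class_labels
  rec <- sapply(mets, `[[`, "recall")
  pre <- sapply(mets, `[[`, "precision")
  rec <- matrix(rec, ncol = length(mets))
  pre <- matrix(pre, ncol = length(mets))
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  per_class <- data.frame(
    class = labels,
    recall_mean = rowMeans(rec), recall_sd = apply(rec, 1, sd0),
    precision_mean = rowMeans(pre), precision_sd = apply(pre, 1, sd0),
    row.names = NULL)
  ma <- vapply(mets, `[[`, numeric(1), "mean_accuracy")
  oa <- vapply(mets, `[[`, numeric(1), "overall_accuracy")
  summary <- data.frame(
    metric = c("mean_accuracy", "overall_accuracy"),
    mean = c(mean(ma), mean(oa)), sd = c(sd0(ma), sd0(oa)))
  list(per_class = per_class, summary = summary)
}

#' One-vs-rest ROC curve by threshold sweep
#'
#' Sweeps a decision threshold over the unique scores and reports the false
#' and true positive rates at each, with the trapezoidal area under the
#' curve. Endpoints (0,0) and (1,1) are always included.
#'
#' @param truth Logical (or 0/1) per-event indicator for the class.
#' @param scores That class's assignment probability per event.
#' @return List with `points` data frame (threshold, fpr, tpr) and `auc`.
#' @export
roc_curve <- function(truth, scores) {
  truth <- as.logical(truth)
  stopifnot(length(truth) == length(scores))
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs at least one positive and one negative event",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  # cumulative counts at each distinct score cut ("score >= cut" is positive)
  cut_idx <- cumsum(rle(s)$lengths)
  tp <- cumsum(t)[cut_idx]
  fp <- cumsum(!t)[cut_idx]
  tpr <- c(0, tp / n_pos, 1)
  fpr <- c(0, fp / n_neg, 1)
  thr <- c(Inf, s[cut_idx], -Inf)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Merge datasets in silico with per-event truth labels
#'
#' Subsamples each component to its requested size, concatenates and shuffles
#' the events, and keeps a truth label per event. Background communities
#' (plain event tables, or a part explicitly labelled) receive the label
#' `"unknown"`; standards carry their class name. Parameter values pass
#' through bit-exactly.
#'
#' @param parts List of parts; each part is either a `standard_dataset` /
#'   [event_table()] or a `list(data =, n =, label =)` with `n` the subsample
#'   size (default: all events) and `label` overriding the truth label.
#' @param seed Integer seed for subsampling and the final shuffle.
#' @return List with `events` (a log10 [event_table()]) and `truth`
#'   (character vector aligned with the rows).
#' @export
in_silico_mix <- function(parts, seed = 1) {
  stopifnot(length(parts) >= 1)
  pieces <- list()
  labels <- character(0)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (inherits(p, "event_table")) p <- list(data = p)
    d <- p$data
    stopifnot(inherits(d, "event_table"))
    if (nrow(d$events) == 0) stop("empty mixture component", call. = FALSE)
    lab <- if (!is.null(p$label)) p$label
           else if (!is.null(d$standard_name)) d$standard_name else "unknown"
    if (!is.null(p$n)) {
      d <- subsample_events(d, p$n, seed = seed + i)
    }
    if (!is.null(d$anchor) && any(d$anchor)) {
      d <- subset_events(d, !d$anchor)
    }
    pieces[[length(pieces) + 1]] <- d$events
    labels <- c(labels, rep(lab, nrow(d$events)))
  }
  m <- do.call(rbind, pieces)
  perm <- with_seed(seed, sample.int(nrow(m)))
  ev <- event_table(m[perm, , drop = FALSE], scale = "log10",
                    sample_id = "in-silico mixture")
  list(events = ev, truth = labels[perm])
}

#' Correct predicted classification (CPC)
#'
#' The number of events attributed to a target class (or group of classes,
#' e.g. all subpopulations of one strain) as a percentage of the number of
#' events expected (spiked). Over-attribution of background events to the
#' target classes can push the value above 100%.
#'
#' @param assigned Named per-class assigned counts (e.g.
#'   `result$class_counts`).
#' @param expected Expected (spiked) event count (> 0).
#' @param target_classes Class label(s) counted as correct.
#' @return CPC in percent.
#' @export
correct_predicted_classification <- function(assigned, expected,
                                             target_classes) {
  stopifnot(expected > 0)
  assigned <- c(assigned)
  bad <- setdiff(target_classes, names(assigned))
  if (length(bad) > 0) {
    stop("unknown target class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  100 * sum(as.numeric(assigned[target_classes])) / expected
}
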