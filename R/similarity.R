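#' Class attribution profile of a classified sample
#'
#' Summarizes a `classification_result` into per-class counts, relative
#' abundances, the mean winning probability of the events assigned to each
#' class, and a fixed-width histogram of those winning probabilities on
#' [0, 1]. The winning probability is the softmax maximum, so it is always
#' at least 1/K.
#'
#' @param result A `classification_result` with at least one event.
#' @param bins Number of equal-width probability histogram bins (default 50).
#' @return A `class_attribution_profile`: list with `class_counts`,
#'   `relative_abundance`, `mean_probability` (NA for empty classes),
#'   `probability_histogram` (bins x K matrix), `breaks`, `source_sample`.
#' @export
attribution_profile <- function(result, bins = 50) {
  stopifnot(inherits(result, "classification_result"), bins >= 1)
  n <- nrow(result$probabilities)
  if (n == 0) stop("cannot profile an empty classification result",
                   call. = FALSE)
  labels <- result$class_labels
  win_p <- result$probabilities[cbind(seq_len(n),
                                      as.integer(result$assigned_class))]
  counts <- as.numeric(result$class_counts)
  names(counts) <- labels
  breaks <- seq(0, 1, length.out = bins + 1)
  hist_m <- matrix(0L, bins, length(labels),
                   dimnames = list(NULL, labels))
  mean_p <- rep(NA_real_, length(labels))
  names(mean_p) <- labels
  for (k in seq_along(labels)) {
    pk <- win_p[as.integer(result$assigned_class) == k]
    if (length(pk) > 0) {
      mean_p[k] <- mean(pk)
      hist_m[, k] <- tabulate(pmin(findInterval(pk, breaks,
                                                rightmost.closed = TRUE),
                                   bins), bins)
    }
  }
  structure(
    list(class_counts = counts, relative_abundance = counts / sum(counts),
         mean_probability = mean_p, probability_histogram = hist_m,
         breaks = breaks, source_sample = result$source_sample),
    class = "class_attribution_profile")
}

#' @export
print.class_attribution_profile <- function(x, ...) {
  cat(sprintf("<class_attribution_profile> %s: %d events, %d occupied classes\n",
              x$source_sample, sum(x$class_counts),
              sum(x$class_counts > 0)))
  invisible(x)
}

#' Classification similarity score
#'
#' The ratio, in percent, of a query population's mean winning assignment
#' probability in a class to the mean winning probability of the true
#' standard's own cells in that class. Identical populations score 100%;
#' unknown cells attributed to a class they merely resemble score lower.
#'
#' @param attributed_mean_p Mean winning probability of the query cells
#'   assigned to the class, in (0, 1].
#' @param standard_mean_p Mean winning probability of the standard's own
#'   cells in that class, in (0, 1].
#' @return List with `score` (full precision, percent) and `rounded`
#'   (nearest whole percent).
#' @export
classification_similarity_score <- function(attributed_mean_p,
                                            standard_mean_p) {
  if (!is.numeric(attributed_mean_p) || attributed_mean_p <= 0 ||
      attributed_mean_p > 1) {
    stop("attributed_mean_p must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(standard_mean_p) || standard_mean_p <= 0 ||
      standard_mean_p > 1) {
    stop("standard_mean_p must lie in (0, 1]", call. = FALSE)
  }
  score <- 100 * attributed_mean_p / standard_mean_p
  list(score = score, rounded = round(score))
}

#' Chance-level accuracy of a K-class classifier
#'
#' @param k Number of classes (>= 1).
#' @return List with `percent` (100 / k) and `rounded` (whole percent).
#' @export
chance_accuracy <- function(k) {
  if (!is.numeric(k) || k < 1) stop("k must be a class count >= 1",
                                    call. = FALSE)
  p <- 100 / k
  list(percent = p, rounded = round(p))
}

#' Shannon index of a count or abundance vector (natural log)
#'
#' @param counts Non-negative class counts or abundances.
#' @return Entropy in nats; 0 * log(0) is treated as 0.
#' @export
shannon_index <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("Shannon index undefined for an all-zero profile",
                       call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity between two count profiles
#'
#' `1 - 2 * sum(min(a, b)) / sum(a + b)` on counts; 0 for identical
#' profiles, 1 for profiles with no shared classes.
#'
#' @param a,b Non-negative count vectors over the same ordered classes.
#' @return Dissimilarity in [0, 1].
#' @export
bray_curtis <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0))
  tot <- sum(a) + sum(b)
  if (tot == 0) stop("Bray-Curtis undefined for two empty profiles",
                     call. = FALSE)
  1 - 2 * sum(pmin(a, b)) / tot
}

#' Diversity summary over a set of community profiles
#'
#' Computes, per profile, the class richness (number of classes whose
#' relative abundance exceeds `richness_threshold`) and the Shannon index,
#' plus the pairwise Bray-Curtis dissimilarity matrix on counts.
#'
#' @param profiles List of `class_attribution_profile`s sharing class order.
#' @param richness_threshold Relative-abundance cut-off for counting a class
#'   as present (default 0.0005, i.e. classes above 0.05%).
#' @return A `diversity_summary`: list with `richness`, `shannon` (vectors,
#'   one entry per profile) and `bray_curtis` (symmetric matrix, zero
#'   diagonal).
#' @export
diversity_summary <- function(profiles, richness_threshold = 0.0005) {
  stopifnot(length(profiles) >= 1)
  stopifnot(all(vapply(profiles, inherits, logical(1),
                       "class_attribution_profile")))
  labels <- names(profiles[[1]]$class_counts)
  for (p in profiles) {
    if (!identical(names(p$class_counts), labels)) {
      stop("profiles must share the same class label order", call. = FALSE)
    }
  }
  nm <- vapply(profiles, `[[`, character(1), "source_sample")
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  richness <- vapply(profiles, function(p)
    sum(p$relative_abundance > richness_threshold), numeric(1))
  shannon <- vapply(profiles, function(p) shannon_index(p$class_counts),
                    numeric(1))
  np <- length(profiles)
  bc <- matrix(0, np, np, dimnames = list(nm, nm))
  if (np > 1) {
    for (i in 1:(np - 1)) for (j in (i + 1):np) {
      bc[i, j] <- bc[j, i] <- bray_curtis(profiles[[i]]$class_counts,
                                          profiles[[j]]$class_counts)
    }
  }
  names(richness) <- names(shannon) <- nm
  structure(list(richness = richness, shannon = shannon, bray_curtis = bc,
                 richness_threshold = richness_threshold),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("<diversity_summary> %d profile(s); richness threshold %.4f\n",
              length(x$richness), x$richness_threshold))
  print(data.frame(richness = x$richness, shannon = round(x$shannon, 4)))
  invisible(x)
}
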