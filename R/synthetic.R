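#' Specification of a synthetic flow-cytometry standard
#'
#' Synthetic standards are (mixtures of) multivariate Gaussians in log10
#' intensity space, truncated to the filter bounds by rejection sampling;
#' this emulates the ellipsoidal per-standard clusters seen on log-scaled
#' cytograms, including standards composed of several subpopulations.
#'
#' @param name Standard class name.
#' @param center Length-7 mean vector in log10 space; every coordinate must
#'   lie inside the log10 filter bounds.
#' @param sd Scalar or length-7 per-parameter standard deviation, or a 7x7
#'   covariance matrix.
#' @param n_events Default number of events to generate.
#' @param subpopulations Optional list of subcomponents, each a
#'   `list(weight =, center =, sd =)`; weights must sum to 1 and override
#'   the top-level center/sd.
#' @param spec [filter_spec()] defining the admissible intensity range.
#' @return A `synthetic_standard_spec`.
#' @export
synthetic_standard_spec <- function(name, center, sd = 0.15, n_events = 10000,
                                    subpopulations = NULL,
                                    spec = filter_spec()) {
  lo <- log10(spec$lower)
  hi <- log10(spec$upper)
  as_cov <- function(s) {
    if (is.matrix(s)) {
      if (!all(dim(s) == c(7, 7)) || any(abs(s - t(s)) > 1e-12)) {
        stop("covariance must be a symmetric 7x7 matrix", call. = FALSE)
      }
      ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-10) stop("covariance must be positive semi-definite",
                                 call. = FALSE)
      s
    } else diag(rep_len(s, 7)^2)
  }
  check_center <- function(ctr) {
    ctr <- as.numeric(ctr)
    if (length(ctr) != 7) stop("center must have 7 coordinates", call. = FALSE)
    if (any(ctr <= lo) || any(ctr >= hi)) {
      stop("center of '", name, "' lies outside the log10 filter bounds",
           call. = FALSE)
    }
    ctr
  }
  if (is.null(subpopulations)) {
    comps <- list(list(weight = 1, center = check_center(center),
                       cov = as_cov(sd)))
  } else {
    w <- vapply(subpopulations, `[[`, numeric(1), "weight")
    if (abs(sum(w) - 1) > 1e-9) {
      stop("subpopulation weights must sum to 1", call. = FALSE)
    }
    comps <- lapply(subpopulations, function(sp) {
      list(weight = sp$weight, center = check_center(sp$center),
           cov = as_cov(if (is.null(sp$sd)) sd else sp$sd))
    })
  }
  structure(list(name = name, components = comps, n_events = n_events,
                 bounds = list(lower = lo, upper = hi)),
            class = "synthetic_standard_spec")
}

# Truncated multivariate normal draws by rejection sampling.
rmvnorm_truncated <- function(n, center, covm, lo, hi, max_tries = 1000) {
  R <- chol(covm + diag(1e-12, 7))
  out <- matrix(NA_real_, n, 7)
  need <- n
  filled <- 0
  for (i in seq_len(max_tries)) {
    if (need == 0) break
    Z <- matrix(stats::rnorm(need * 7), need, 7)
    X <- Z %*% R + matrix(center, need, 7, byrow = TRUE)
    ok <- rowSums(sweep(X, 2, lo, "<") | sweep(X, 2, hi, ">")) == 0
    nok <- sum(ok)
    if (nok > 0) {
      out[filled + seq_len(nok), ] <- X[ok, , drop = FALSE]
      filled <- filled + nok
      need <- need - nok
    }
  }
  if (need > 0) {
    stop("rejection sampling failed; cluster mass lies outside the filter bounds",
         call. = FALSE)
  }
  out
}

#' Generate a synthetic standard dataset
#'
#' @param spec A [synthetic_standard_spec()].
#' @param seed Integer seed; the draw is fully reproducible.
#' @param n_events Number of events (default from the spec).
#' @return A log10-scale `standard_dataset` named after the spec.
#' @export
generate_standard <- function(spec, seed = 1, n_events = spec$n_events) {
  stopifnot(inherits(spec, "synthetic_standard_spec"), n_events >= 0)
  lo <- spec$bounds$lower
  hi <- spec$bounds$upper
  m <- with_seed(seed, {
    if (n_events == 0) {
      matrix(numeric(0), 0, 7)
    } else {
      w <- vapply(spec$components, `[[`, numeric(1), "weight")
      comp <- sample.int(length(w), n_events, replace = TRUE, prob = w)
      out <- matrix(NA_real_, n_events, 7)
      for (k in seq_along(w)) {
        idx <- which(comp == k)
        if (length(idx) > 0) {
          out[idx, ] <- rmvnorm_truncated(length(idx),
                                          spec$components[[k]]$center,
                                          spec$components[[k]]$cov, lo, hi)
        }
      }
      out
    }
  })
  colnames(m) <- FCM_PARAMETERS
  ev <- event_table(m, scale = "log10", sample_id = spec$name)
  as_standard_dataset(ev, spec$name)
}

#' Generate a synthetic mixed community with per-event truth
#'
#' Events are drawn component-wise with multinomially distributed sizes,
#' pooled and shuffled. Components flagged as background carry the truth
#' label `"unknown"`.
#'
#' @param components List of `list(spec =, weight =, background = FALSE)`
#'   entries; weights must sum to 1.
#' @param total_events Total number of events.
#' @param seed Integer seed.
#' @return List with `events` (log10 [event_table()]) and `truth` (character
#'   vector; standard names, or `"unknown"` for background).
#' @export
generate_community <- function(components, total_events, seed = 1) {
  stopifnot(length(components) >= 1, total_events >= 0)
  w <- vapply(components, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) stop("component weights must sum to 1",
                                   call. = FALSE)
  if (total_events == 0) {
    m <- matrix(numeric(0), 0, 7, dimnames = list(NULL, FCM_PARAMETERS))
    return(list(events = event_table(m, scale = "log10",
                                     sample_id = "synthetic community"),
                truth = character(0)))
  }
  sizes <- with_seed(seed, as.integer(stats::rmultinom(1, total_events, w)))
  pieces <- vector("list", length(components))
  labels <- character(0)
  for (k in seq_along(components)) {
    comp <- components[[k]]
    ds <- generate_standard(comp$spec, seed = seed + 7919L * k,
                            n_events = sizes[k])
    lab <- if (isTRUE(comp$background)) "unknown" else comp$spec$name
    pieces[[k]] <- ds$events
    labels <- c(labels, rep(lab, sizes[k]))
  }
  m <- do.call(rbind, pieces)
  perm <- with_seed(seed + 1L, sample.int(nrow(m)))
  list(events = event_table(m[perm, , drop = FALSE], scale = "log10",
                            sample_id = "synthetic community"),
       truth = labels[perm])
}

#' Five-standard demonstration fixture
#'
#' A canned set of five well-separated synthetic standards emulating the
#' three-species proof-of-concept community (one Acinetobacter-like class
#' and two classes each for an E. coli-like and a Pseudomonas-like strain
#' with two FCM subpopulations apiece). Centers sit well inside the default
#' filter bounds and mutual separations exceed 6 pooled SDs.
#'
#' @param sd Per-parameter standard deviation in log10 space (default 0.15).
#' @param n_events Default events per standard.
#' @return Named list of five [synthetic_standard_spec()]s.
#' @export
demo_standard_specs <- function(sd = 0.15, n_events = 10000) {
  centers <- rbind(
    AJH  = c(3.0, 3.2, 4.0, 3.8, 3.5, 3.3, 4.5),
    ECL1 = c(4.2, 4.4, 4.6, 4.4, 4.0, 3.9, 4.6),
    ECL2 = c(4.8, 5.0, 4.2, 4.0, 4.6, 4.5, 4.4),
    PVR1 = c(3.6, 3.8, 5.2, 5.0, 4.8, 4.7, 5.0),
    PVR2 = c(5.4, 5.6, 5.6, 5.4, 5.2, 5.1, 5.2))
  out <- lapply(rownames(centers), function(nm) {
    synthetic_standard_spec(nm, centers[nm, ], sd = sd, n_events = n_events)
  })
  names(out) <- rownames(centers)
  out
}

#' Recall as a function of cluster separation
#'
#' Builds, for each requested separation, a two-standard problem whose
#' cluster centers lie that many pooled standard deviations apart (Euclidean
#' distance in log10 space), trains a classifier, and reports per-class
#' recall on freshly generated held-out events. Separation 0 puts both
#' classes on the same distribution (chance level); large separations should
#' approach perfect recall.
#'
#' @param base A [synthetic_standard_spec()] with a single component; its
#'   center and SD anchor the sweep.
#' @param separations Non-negative separations in pooled-SD units.
#' @param config [training_config()] used for every fit.
#' @param n_per_standard Training events per standard.
#' @param n_eval Held-out evaluation events per standard.
#' @param seed Integer seed.
#' @return Data frame with columns `separation`, `recall_A`, `recall_B`,
#'   `mean_recall` (percent).
#' @export
separability_sweep <- function(base, separations, config = training_config(),
                               n_per_standard = 2000, n_eval = 1000,
                               seed = 1) {
  stopifnot(inherits(base, "synthetic_standard_spec"),
            length(base$components) == 1, all(separations >= 0))
  ctr <- base$components[[1]]$center
  pooled_sd <- sqrt(mean(diag(base$components[[1]]$cov)))
  u <- rep(1 / sqrt(7), 7)
  rows <- vector("list", length(separations))
  for (i in seq_along(separations)) {
    sep <- separations[i]
    ctr_b <- ctr + sep * pooled_sd * u
    spec_a <- synthetic_standard_spec("A", ctr, sd = sqrt(diag(base$components[[1]]$cov)))
    spec_b <- synthetic_standard_spec("B", ctr_b, sd = sqrt(diag(base$components[[1]]$cov)))
    std_a <- generate_standard(spec_a, seed = seed + 2L * i,
                               n_events = n_per_standard)
    std_b <- generate_standard(spec_b, seed = seed + 2L * i + 1L,
                               n_events = n_per_standard)
    cfg <- config
    cfg$seed <- seed + 100L * i
    asm <- assemble_training_set(list(std_a, std_b), n_per_standard,
                                 seed = cfg$seed)
    model <- train_classifier(asm, cfg)
    ev_a <- generate_standard(spec_a, seed = seed + 5000L + i,
                              n_events = n_eval)
    ev_b <- generate_standard(spec_b, seed = seed + 6000L + i,
                              n_events = n_eval)
    mixed <- bind_events(ev_a, ev_b)
    truth <- rep(c("A", "B"), each = n_eval)
    met <- confusion_and_metrics(truth, forward_pass(model, mixed))
    rows[[i]] <- data.frame(separation = sep,
                            recall_A = met$recall[["A"]],
                            recall_B = met$recall[["B"]],
                            mean_recall = met$mean_accuracy)
  }
  do.call(rbind, rows)
}
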