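#' Per-parameter intensity filter bounds
#'
#' Events are kept only when every one of the seven parameters lies within
#' `[lower, upper]` on the raw intensity scale. The lower bound defaults to
#' 100 on every parameter; the upper bound defaults to 1e7 and is typically
#' set between 1e5 and 1e7 depending on the instrument range.
#'
#' @param lower Scalar or length-7 vector of lower raw-intensity bounds (> 0).
#' @param upper Scalar or length-7 vector of upper bounds (> lower).
#' @return An object of class `filter_spec` with per-parameter named bounds.
#' @export
filter_spec <- function(lower = 100, upper = 1e7) {
  lower <- rep_len(as.numeric(lower), 7L)
  upper <- rep_len(as.numeric(upper), 7L)
  names(lower) <- names(upper) <- FCM_PARAMETERS
  if (any(lower <= 0)) stop("lower filter bounds must be positive",
                            call. = FALSE)
  if (any(upper <= lower)) stop("upper filter bounds must exceed lower bounds",
                                call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "filter_spec")
}

#' Filter and log10-transform a raw event table
#'
#' Keeps only events whose values lie within the filter bounds on all seven
#' parameters, then log10-transforms the retained intensities. Acquisition
#' metadata is preserved. An empty result is returned with a warning, never an
#' error, so batch pipelines can continue.
#'
#' @param raw A raw-scale [event_table()].
#' @param spec A [filter_spec()].
#' @return A log10-scale [event_table()].
#' @export
preprocess <- function(raw, spec = filter_spec()) {
  stopifnot(inherits(raw, "event_table"), inherits(spec, "filter_spec"))
  if (raw$scale != "raw") stop("preprocess() expects a raw-scale table",
                               call. = FALSE)
  m <- raw$events
  keep <- rep(TRUE, nrow(m))
  for (j in seq_len(ncol(m))) {
    keep <- keep & m[, j] >= spec$lower[j] & m[, j] <= spec$upper[j]
  }
  if (!any(keep) && nrow(m) > 0) {
    warning("all events removed by filtering", call. = FALSE)
  }
  out <- raw
  out$events <- log10(m[keep, , drop = FALSE])
  out$scale <- "log10"
  out
}

#' Rectangular gate in the three height parameters
#'
#' A gate box selects a subpopulation of a standard by inclusive lower/upper
#' log10 bounds on FITC-H, SSC-H and FSC-H.
#'
#' @param label Subpopulation / standard class name.
#' @param bounds Named list mapping each of `"FITC-H"`, `"SSC-H"`, `"FSC-H"`
#'   to a `c(lower, upper)` pair on the log10 scale. Axes omitted from the
#'   list are unconstrained.
#' @param min_fraction Minimum share of the input events the gate is expected
#'   to capture (default 0.05, the threshold for treating a subpopulation as
#'   real); a smaller captured fraction triggers a warning.
#' @return An object of class `gate_box`.
#' @export
gate_box <- function(label, bounds, min_fraction = 0.05) {
  if (length(bounds) == 0) stop("gate needs at least one bounded axis",
                                call. = FALSE)
  bad <- setdiff(names(bounds), GATE_PARAMETERS)
  if (length(bad) > 0) {
    stop("gate axes must be among ", paste(GATE_PARAMETERS, collapse = ", "),
         "; got: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (ax in names(bounds)) {
    b <- bounds[[ax]]
    if (length(b) != 2 || !is.numeric(b) || b[1] >= b[2]) {
      stop("gate bounds for ", ax, " must be an increasing (lower, upper) pair",
           call. = FALSE)
    }
  }
  if (min_fraction <= 0 || min_fraction >= 1) {
    stop("min_fraction must lie in (0, 1)", call. = FALSE)
  }
  structure(list(label = label, bounds = bounds,
                 min_fraction = min_fraction), class = "gate_box")
}

#' Gate a log10 event table into a standard dataset
#'
#' Events inside the box (inclusive on both bounds) become the gated standard
#' dataset; the captured fraction is recorded, and a warning is issued when it
#' falls below `gate$min_fraction`.
#'
#' @param data A log10-scale [event_table()].
#' @param gate A [gate_box()].
#' @param replicate_of Optional parent strain/bead label.
#' @return A `standard_dataset`: an [event_table()] with `standard_name`,
#'   `gate_fraction`, `replicate_of` and an `anchor` flag vector.
#' @export
apply_gate <- function(data, gate, replicate_of = gate$label) {
  stopifnot(inherits(data, "event_table"), inherits(gate, "gate_box"))
  if (data$scale != "log10") stop("apply_gate() expects a log10-scale table",
                                  call. = FALSE)
  m <- data$events
  keep <- rep(TRUE, nrow(m))
  for (ax in names(gate$bounds)) {
    b <- gate$bounds[[ax]]
    keep <- keep & m[, ax] >= b[1] & m[, ax] <= b[2]
  }
  frac <- if (nrow(m) > 0) mean(keep) else NA_real_
  if (!is.na(frac) && frac < gate$min_fraction) {
    warning(sprintf("gate '%s' captured %.1f%% of events (< %.0f%% threshold)",
                    gate$label, 100 * frac, 100 * gate$min_fraction),
            call. = FALSE)
  }
  out <- data
  out$events <- m[keep, , drop = FALSE]
  out$standard_name <- gate$label
  out$replicate_of <- replicate_of
  out$gate_fraction <- frac
  out$anchor <- rep(FALSE, sum(keep))
  class(out) <- c("standard_dataset", "event_table")
  out
}

#' Promote a log10 event table to a standard dataset without gating
#'
#' Used when a standard has a single population and needs no subpopulation
#' separation (or for synthetic data generated directly per class).
#'
#' @param data A log10-scale [event_table()].
#' @param name Standard class name.
#' @param replicate_of Optional parent label.
#' @return A `standard_dataset`.
#' @export
as_standard_dataset <- function(data, name, replicate_of = name) {
  stopifnot(inherits(data, "event_table"))
  if (data$scale != "log10") stop("standard datasets are log10 scale",
                                  call. = FALSE)
  out <- data
  out$standard_name <- name
  out$replicate_of <- replicate_of
  out$gate_fraction <- 1
  out$anchor <- rep(FALSE, nrow(data$events))
  class(out) <- c("standard_dataset", "event_table")
  out
}

#' @export
print.standard_dataset <- function(x, ...) {
  cat(sprintf("<standard_dataset> %s: %d events (%d anchors)\n",
              x$standard_name, nrow(x$events), sum(x$anchor)))
  invisible(x)
}

#' Randomly subsample a standard dataset without replacement
#'
#' @param data A `standard_dataset` (or any [event_table()]).
#' @param n Target event count; when fewer events are available all are
#'   returned with a warning.
#' @param seed Integer seed making the draw reproducible.
#' @return Object of the same class with `min(n, available)` events.
#' @export
subsample_events <- function(data, n = 10000, seed = 1) {
  stopifnot(inherits(data, "event_table"), n >= 1)
  nav <- nrow(data$events)
  if (nav == 0) {
    warning("subsampling an empty dataset", call. = FALSE)
    return(data)
  }
  if (nav < n) {
    warning(sprintf("only %d events available for requested %d; returning all",
                    nav, n), call. = FALSE)
    return(data)
  }
  idx <- with_seed(seed, sample.int(nav, n))
  subset_events(data, sort(idx))
}

#' Append range anchors to the first training standard
#'
#' Two synthetic events pin the per-parameter range of the concatenated
#' training matrix to the log10 filter bounds: one event with every parameter
#' at `log10(lower)` and one at `log10(upper)`. Min-max scaling to [-1, 1]
#' is then fixed by the filter configuration rather than by the biological
#' data, so different samples share identical scaling constants. Anchors
#' carry the dataset's class label but are flagged and excluded from all
#' reported performance metrics. Calling twice is a no-op with a warning.
#'
#' @param data A log10-scale `standard_dataset`.
#' @param spec The [filter_spec()] whose bounds define the anchors.
#' @return The dataset with two anchor rows appended and flagged.
#' @export
add_anchors <- function(data, spec = filter_spec()) {
  stopifnot(inherits(data, "standard_dataset"), inherits(spec, "filter_spec"))
  if (any(data$anchor)) {
    warning("anchors already present; not adding again", call. = FALSE)
    return(data)
  }
  lo <- log10(spec$lower)
  hi <- log10(spec$upper)
  anchors <- rbind(lo, hi)
  dimnames(anchors) <- list(NULL, FCM_PARAMETERS)
  data$events <- rbind(data$events, anchors)
  data$anchor <- c(data$anchor, TRUE, TRUE)
  data
}

# Run code under a local RNG seed without disturbing the global stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
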