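#' Assemble an anchored, scaled, split multi-standard training set
#'
#' Each standard is subsampled to `n_per_standard` events; two range anchors
#' are appended to the first standard; the datasets are concatenated, min-max
#' scaled per parameter to [-1, 1] (the anchors guarantee the scaling
#' constants equal the log10 filter bounds), and randomly partitioned into
#' training (50%), validation (25%) and test (25%) blocks.
#'
#' @param standards List of non-empty log10-scale `standard_dataset` objects
#'   with unique names; at least two.
#' @param n_per_standard Subsample size per standard (default 10000).
#' @param spec [filter_spec()] whose bounds define the anchors and scaling.
#' @param seed Integer seed governing subsampling and the random split.
#' @param split Train/validation/test proportions (must sum to 1).
#' @return A `training_assembly`: list with scaled matrix `X` (rows x 7),
#'   integer class vector `y`, `class_labels`, `split` index sets,
#'   `scaling` (per-parameter min/max), and logical `anchor_mask`.
#' @export
assemble_training_set <- function(standards, n_per_standard = 10000,
                                  spec = filter_spec(), seed = 1,
                                  split = c(train = 0.5, validation = 0.25,
                                            test = 0.25)) {
  stopifnot(is.list(standards), length(standards) >= 2)
  stopifnot(all(vapply(standards, inherits, logical(1), "standard_dataset")))
  labels <- unname(vapply(standards, `[[`, character(1), "standard_name"))
  if (anyDuplicated(labels)) {
    stop("duplicate standard names: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(vapply(standards, function(s) nrow(s$events) == 0, logical(1)))) {
    stop("every standard must contain events", call. = FALSE)
  }
  if (abs(sum(split) - 1) > 1e-9) stop("split proportions must sum to 1",
                                       call. = FALSE)

  sub <- vector("list", length(standards))
  for (k in seq_along(standards)) {
    sub[[k]] <- subsample_events(standards[[k]], n_per_standard,
                                 seed = seed + k)
  }
  sub[[1]] <- add_anchors(sub[[1]], spec)

  X <- do.call(rbind, lapply(sub, `[[`, "events"))
  y <- rep(seq_along(sub), vapply(sub, function(s) nrow(s$events), integer(1)))
  anchor_mask <- unlist(lapply(sub, `[[`, "anchor"), use.names = FALSE)

  lo <- log10(spec$lower)
  hi <- log10(spec$upper)
  Xs <- sweep(sweep(X, 2, lo), 2, (hi - lo) / 2, "/") - 1

  n <- nrow(Xs)
  perm <- with_seed(seed, sample.int(n))
  n_train <- round(split[[1]] * n)
  n_val <- round(split[[2]] * n)
  idx <- list(train = perm[seq_len(n_train)],
              validation = perm[n_train + seq_len(n_val)],
              test = perm[(n_train + n_val + 1):n])

  structure(
    list(X = Xs, y = y, class_labels = labels, split = idx,
         scaling = list(min = lo, max = hi), anchor_mask = anchor_mask,
         seed = seed),
    class = "training_assembly")
}

#' @export
print.training_assembly <- function(x, ...) {
  cat(sprintf(
    "<training_assembly> %d events x %d classes (train %d / val %d / test %d, %d anchors)\n",
    nrow(x$X), length(x$class_labels), length(x$split$train),
    length(x$split$validation), length(x$split$test), sum(x$anchor_mask)))
  invisible(x)
}
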