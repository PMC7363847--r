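# Shared fixtures: small synthetic standards and a raw event matrix builder.

# Raw-scale event matrix with all 7 parameters set to `value` except
# overrides given as name = vector pairs.
raw_events <- function(n, value = 1000, ...) {
  m <- matrix(value, n, 7, dimnames = list(NULL, FCM_PARAMETERS))
  over <- list(...)
  for (nm in names(over)) m[, nm] <- over[[nm]]
  m
}

# Two well-separated single-population specs (>= 8 pooled SD apart).
two_class_specs <- function(sd = 0.15, sep_sd = 8) {
  ctr <- rep(4, 7)
  off <- sep_sd * sd / sqrt(7)
  list(A = synthetic_standard_spec("A", ctr, sd = sd),
       B = synthetic_standard_spec("B", ctr + off, sd = sd))
}

# Generate a list of standard datasets from specs with per-class seeds.
gen_standards <- function(specs, n, seed = 1) {
  out <- lapply(seq_along(specs), function(i) {
    generate_standard(specs[[i]], seed = seed + i, n_events = n)
  })
  names(out) <- names(specs)
  out
}

# Nearest-centroid classifier: the independent oracle for separability
# checks. Returns predicted labels for rows of `X` given training data.
nearest_centroid_predict <- function(train_list, X) {
  centroids <- t(vapply(train_list, function(s) colMeans(s$events),
                        numeric(7)))
  labels <- vapply(train_list, `[[`, character(1), "standard_name")
  d2 <- sapply(seq_len(nrow(centroids)), function(k) {
    rowSums(sweep(X, 2, centroids[k, ])^2)
  })
  labels[max.col(-matrix(d2, nrow = nrow(X)), ties.method = "first")]
}

# A small trained two-class model, built once and reused across tests.
.fixture_env <- new.env(parent = emptyenv())
small_two_class_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    specs <- two_class_specs()
    stds <- gen_standards(specs, 2000, seed = 11)
    asm <- assemble_training_set(stds, 2000, seed = 11)
    model <- train_classifier(asm, training_config(seed = 11))
    .fixture_env$fit <- list(specs = specs, standards = stds,
                             assembly = asm, model = model)
  }
  .fixture_env$fit
}
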