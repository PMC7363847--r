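#' Read a standards manifest
#'
#' A manifest is a YAML (or JSON) document describing the standard library:
#' optional `filter` bounds (`lower`, `upper`), and a `standards` list whose
#' entries give `name`, the source `file` of raw events, an optional
#' `replicate_of` parent label, and an optional `gate` mapping the gating
#' axes (FITC-H, SSC-H, FSC-H) to `[lower, upper]` log10 pairs.
#'
#' @param path Path to the manifest file.
#' @return List with `filter` (a [filter_spec()]) and `standards` (list of
#'   entries with `name`, `file`, `replicate_of`, `gate`).
#' @export
read_standards_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc$standards) || length(doc$standards) == 0) {
    stop("manifest defines no standards", call. = FALSE)
  }
  fl <- doc$filter
  spec <- filter_spec(
    lower = if (!is.null(fl$lower)) as.numeric(unlist(fl$lower)) else 100,
    upper = if (!is.null(fl$upper)) as.numeric(unlist(fl$upper)) else 1e7)
  standards <- lapply(doc$standards, function(s) {
    if (is.null(s$name)) stop("manifest standard without a name",
                              call. = FALSE)
    gate <- NULL
    if (!is.null(s$gate)) {
      bounds <- lapply(s$gate, function(b) as.numeric(unlist(b)))
      gate <- gate_box(s$name, bounds)
    }
    list(name = s$name, file = s$file,
         replicate_of = if (is.null(s$replicate_of)) s$name else s$replicate_of,
         gate = gate)
  })
  list(filter = spec, standards = standards)
}

#' Load, preprocess and gate every standard named in a manifest
#'
#' Reads each standard's raw event file (paths resolved relative to the
#' manifest), filters and log10-transforms it with the manifest's filter
#' bounds, and applies the standard's gate where one is given.
#'
#' @param manifest A [read_standards_manifest()] result or a manifest path.
#' @param base_dir Directory against which relative file paths are resolved.
#' @return List of `standard_dataset` objects, named by standard.
#' @export
load_standards <- function(manifest, base_dir = ".") {
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- read_standards_manifest(manifest)
  }
  out <- lapply(manifest$standards, function(s) {
    path <- s$file
    if (!file.exists(path)) path <- file.path(base_dir, s$file)
    raw <- read_event_table(path, sample_id = s$name)
    logd <- preprocess(raw, manifest$filter)
    if (!is.null(s$gate)) {
      apply_gate(logd, s$gate, replicate_of = s$replicate_of)
    } else {
      as_standard_dataset(logd, s$name, replicate_of = s$replicate_of)
    }
  })
  names(out) <- vapply(manifest$standards, `[[`, character(1), "name")
  out
}
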