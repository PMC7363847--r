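#' Allometric biovolume-to-dry-mass conversion
#'
#' Converts a cell biovolume V (um^3) to dry-weight biomass in femtograms
#' using the allometric power law m_b = 435 * V^0.86.
#'
#' @param V Biovolume(s) in cubic micrometres (>= 0).
#' @return Dry-weight biomass in fg, same length as `V`.
#' @export
allometric_biomass <- function(V) {
  if (!is.numeric(V) || any(V < 0)) {
    stop("biovolume must be non-negative", call. = FALSE)
  }
  435 * V^0.86
}

#' Per-standard biomass conversion table
#'
#' From per-standard mean biovolumes and their standard deviations, derives
#' the dry mass (allometric power law) and per-cell carbon mass (dry mass
#' halved), with lower/upper bounds obtained by pushing mean -/+ SD through
#' the same conversion.
#'
#' @param standard Character vector of standard class names.
#' @param V_mean Mean biovolume per cell, um^3.
#' @param V_sd Standard deviation of the biovolume (default 0).
#' @param is_bead Logical; bead standards are excluded from biomass sums by
#'   default (polystyrene is not biomass).
#' @return A `biomass_standard_table` data frame with dry mass and carbon
#'   mass (fg) columns `mass_mean`, `mass_lower`, `mass_upper`,
#'   `carbon_mean`, `carbon_lower`, `carbon_upper`.
#' @export
biomass_standard_table <- function(standard, V_mean, V_sd = 0,
                                   is_bead = FALSE) {
  stopifnot(length(V_mean) == length(standard))
  V_sd <- rep_len(V_sd, length(standard))
  is_bead <- rep_len(is_bead, length(standard))
  if (any(V_mean < 0) || any(V_sd < 0)) {
    stop("biovolumes and SDs must be non-negative", call. = FALSE)
  }
  lo <- pmax(V_mean - V_sd, 0)
  hi <- V_mean + V_sd
  out <- data.frame(
    standard = as.character(standard),
    V_mean = V_mean, V_sd = V_sd, is_bead = is_bead,
    mass_mean = allometric_biomass(V_mean),
    mass_lower = allometric_biomass(lo),
    mass_upper = allometric_biomass(hi),
    stringsAsFactors = FALSE)
  out$carbon_mean <- out$mass_mean / 2
  out$carbon_lower <- out$mass_lower / 2
  out$carbon_upper <- out$mass_upper / 2
  class(out) <- c("biomass_standard_table", "data.frame")
  out
}

#' Read a biomass conversion table from a delimited file
#'
#' Expects columns `standard`, `V_mean` and optionally `V_sd`, `is_bead`.
#'
#' @param path Path to a comma-delimited file.
#' @return A [biomass_standard_table()].
#' @export
read_biomass_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("standard", "V_mean"), colnames(df))
  if (length(need) > 0) {
    stop("biomass table missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  biomass_standard_table(df$standard, df$V_mean,
                         V_sd = if ("V_sd" %in% colnames(df)) df$V_sd else 0,
                         is_bead = if ("is_bead" %in% colnames(df))
                           as.logical(df$is_bead) else FALSE)
}

#' Community carbon biomass from classified counts
#'
#' Multiplies the (mean) classified event count of every standard class by
#' that standard's per-cell carbon mass and sums over classes, propagating
#' the biovolume-derived lower/upper mass bounds. Bead classes are excluded
#' unless `include_beads = TRUE`, in which case their allometric pseudo-mass
#' is used and flagged in the output.
#'
#' @param counts Named per-class event counts (means over an ensemble are
#'   typical).
#' @param table A [biomass_standard_table()].
#' @param include_beads Include bead classes in the totals (default FALSE).
#' @return A `community_biomass` list: `per_class` data frame (class, count,
#'   carbon fg with bounds, excluded flag) and `total` (named vector mean /
#'   lower / upper, fg C).
#' @export
community_biomass <- function(counts, table, include_beads = FALSE) {
  stopifnot(inherits(table, "biomass_standard_table"))
  counts <- c(counts)
  cls <- names(counts)
  if (is.null(cls)) stop("counts must be named by standard class",
                         call. = FALSE)
  idx <- match(cls, table$standard)
  counted <- counts > 0
  excluded <- rep(FALSE, length(cls))
  if (!include_beads) {
    bead <- !is.na(idx) & table$is_bead[idx]
    excluded <- excluded | bead
  }
  missing <- counted & is.na(idx) & !excluded
  if (any(missing)) {
    stop("no biomass entry for counted class(es): ",
         paste(cls[missing], collapse = ", "), call. = FALSE)
  }
  use <- !excluded & !is.na(idx)
  per_class <- data.frame(
    class = cls,
    count = as.numeric(counts),
    carbon_mean = ifelse(use, as.numeric(counts) * table$carbon_mean[idx], 0),
    carbon_lower = ifelse(use, as.numeric(counts) * table$carbon_lower[idx], 0),
    carbon_upper = ifelse(use, as.numeric(counts) * table$carbon_upper[idx], 0),
    excluded = excluded | (is.na(idx) & !counted),
    is_bead = !is.na(idx) & table$is_bead[idx],
    stringsAsFactors = FALSE)
  total <- c(mean = sum(per_class$carbon_mean),
             lower = sum(per_class$carbon_lower),
             upper = sum(per_class$carbon_upper))
  structure(list(per_class = per_class, total = total,
                 include_beads = include_beads),
            class = "community_biomass")
}

#' @export
print.community_biomass <- function(x, ...) {
  cat(sprintf("<community_biomass> total %.4g fg C [%.4g, %.4g]%s\n",
              x$total["mean"], x$total["lower"], x$total["upper"],
              if (x$include_beads) " (beads included)" else ""))
  invisible(x)
}

#' Biomass yield on added substrate carbon
#'
#' The produced biomass carbon (end minus start; negative production is
#' floored at zero with a warning) divided by the added substrate carbon.
#' Any mass unit may be used as long as numerator and denominator share it.
#'
#' @param biomass_produced Net biomass carbon produced (g C, or any unit).
#' @param substrate_added Substrate carbon added (> 0, same unit).
#' @return Yield in g/g.
#' @export
biomass_yield <- function(biomass_produced, substrate_added) {
  if (!is.numeric(substrate_added) || substrate_added <= 0) {
    stop("substrate_added must be positive", call. = FALSE)
  }
  if (biomass_produced < 0) {
    warning("negative biomass production floored at 0", call. = FALSE)
    biomass_produced <- 0
  }
  biomass_produced / substrate_added
}

#' Absolute cell density from volumetric counting
#'
#' @param events Number of counted events (>= 0).
#' @param analyzed_volume Acquired volume in microlitres (> 0).
#' @param dilution_factor Dilution applied before acquisition (>= 1).
#' @return Cell density in cells per ml.
#' @export
absolute_density <- function(events, analyzed_volume, dilution_factor = 1) {
  if (!is.numeric(analyzed_volume) || analyzed_volume <= 0) {
    stop("analyzed_volume must be positive (microlitres)", call. = FALSE)
  }
  if (dilution_factor < 1) stop("dilution_factor must be >= 1", call. = FALSE)
  stopifnot(events >= 0)
  events / (analyzed_volume / 1000) * dilution_factor
}
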