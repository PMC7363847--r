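#' The seven recorded flow-cytometry parameters
#'
#' Column order is fixed throughout the package: FITC area/height (SYBR Green I
#' fluorescence), forward and side scatter area/height, and pulse width.
#'
#' @format Character vector of length 7.
#' @export
FCM_PARAMETERS <- c("FITC-A", "FITC-H", "FSC-A", "FSC-H", "SSC-A", "SSC-H",
                    "Width")

#' The three parameters used for rectangular subpopulation gating
#' @format Character vector of length 3.
#' @export
GATE_PARAMETERS <- c("FITC-H", "SSC-H", "FSC-H")

#' Construct an event table
#'
#' An `event_table` holds one row per detected particle and exactly the seven
#' optical parameters in [FCM_PARAMETERS] order, together with acquisition
#' metadata needed for absolute cell-density calculations.
#'
#' @param events Numeric matrix (or data frame) with the 7 parameter columns.
#'   Extra columns are dropped; columns are reordered to the canonical order.
#' @param scale Either `"raw"` (instrument intensities) or `"log10"`.
#' @param analyzed_volume Acquired sample volume in microlitres (> 0).
#' @param dilution_factor Dilution applied before acquisition (>= 1).
#' @param sample_id Label carried through the pipeline.
#' @return An object of class `event_table`.
#' @export
event_table <- function(events, scale = c("raw", "log10"),
                        analyzed_volume = 20, dilution_factor = 1,
                        sample_id = "sample") {
  scale <- match.arg(scale)
  if (is.data.frame(events)) events <- as.matrix(events)
  if (is.null(dim(events))) events <- matrix(events, nrow = 1)
  cn <- colnames(events)
  missing <- setdiff(FCM_PARAMETERS, cn)
  if (length(missing) > 0) {
    stop("event table is missing required parameter column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  events <- events[, FCM_PARAMETERS, drop = FALSE]
  storage.mode(events) <- "double"
  if (scale == "log10" && nrow(events) > 0 && any(!is.finite(events))) {
    stop("log10-scale event values must be finite", call. = FALSE)
  }
  if (!is.numeric(analyzed_volume) || analyzed_volume <= 0) {
    stop("analyzed_volume must be a positive volume in microlitres",
         call. = FALSE)
  }
  if (!is.numeric(dilution_factor) || dilution_factor < 1) {
    stop("dilution_factor must be >= 1", call. = FALSE)
  }
  structure(
    list(events = events, scale = scale,
         analyzed_volume = as.numeric(analyzed_volume),
         dilution_factor = as.numeric(dilution_factor),
         sample_id = as.character(sample_id)),
    class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %s: %d events, %s scale, %g ul analyzed, dilution %g\n",
              x$sample_id, nrow(x$events), x$scale, x$analyzed_volume,
              x$dilution_factor))
  invisible(x)
}

#' @export
dim.event_table <- function(x) dim(x$events)

n_events <- function(x) nrow(x$events)

#' Read an event table from a delimited file
#'
#' Reads a comma- (or otherwise) delimited export with a header row naming the
#' seven parameters. Extra columns are ignored. Events carrying a negative
#' value on any parameter are dropped (cytometer artefacts), with a message
#' reporting the count.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator (default comma).
#' @param analyzed_volume,dilution_factor,sample_id Acquisition metadata; see
#'   [event_table()]. `sample_id` defaults to the file name.
#' @return A raw-scale [event_table()].
#' @export
read_event_table <- function(path, sep = ",", analyzed_volume = 20,
                             dilution_factor = 1, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          comment.char = "")
  if (nrow(df) == 0) stop("empty event file: ", path, call. = FALSE)
  missing <- setdiff(FCM_PARAMETERS, colnames(df))
  if (length(missing) > 0) {
    stop("file ", path, " is missing required parameter column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, FCM_PARAMETERS, drop = FALSE])
  storage.mode(m) <- "double"
  neg <- rowSums(m < 0 | !is.finite(m)) > 0
  if (any(neg)) {
    message(sum(neg), " event(s) with negative or non-finite values dropped")
    m <- m[!neg, , drop = FALSE]
  }
  if (is.null(sample_id)) sample_id <- basename(path)
  event_table(m, scale = "raw", analyzed_volume = analyzed_volume,
              dilution_factor = dilution_factor, sample_id = sample_id)
}

#' Write an event table to a delimited file
#'
#' Values are written at full double precision so a write/read round trip
#' reproduces them.
#'
#' @param x An [event_table()].
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "event_table"))
  df <- as.data.frame(x$events, check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bind event tables row-wise
#'
#' All tables must share the same scale; metadata is taken from the first.
#' @param ... `event_table` objects.
#' @return A single [event_table()].
#' @export
bind_events <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !inherits(xs[[1]], "event_table"))
    xs <- xs[[1]]
  stopifnot(all(vapply(xs, inherits, logical(1), "event_table")))
  scales <- unique(vapply(xs, `[[`, character(1), "scale"))
  if (length(scales) != 1) stop("cannot bind tables on different scales",
                                call. = FALSE)
  out <- xs[[1]]
  out$events <- do.call(rbind, lapply(xs, `[[`, "events"))
  out
}

subset_events <- function(x, i) {
  x$events <- x$events[i, , drop = FALSE]
  if (!is.null(x$anchor)) x$anchor <- x$anchor[i]
  x
}
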