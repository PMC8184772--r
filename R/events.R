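#' Single-sample event table
#'
#' The FCS-like container used throughout: an `n_cells x n_channels` matrix
#' of nonnegative raw intensities plus sample metadata (donor, gravity
#' condition, stimulation, timepoint) and the panel it was acquired with.
#'
#' @param values numeric matrix, cells in rows, channels in columns; column
#'   names must exactly match the panel's marker names.
#' @param meta list with `donor_id`, `gravity` ("1G" or "uG"), `stimulation`
#'   ("unstim" or "ConA/anti-CD28"), `timepoint_h`, optional
#'   `barcode_key_index`.
#' @param panel the `panel_config` the channels belong to.
#' @param truth_labels optional character vector of generative subset labels
#'   (synthetic data only); carried for ground-truth recovery checks.
#' @return An `event_table` (a matrix with metadata attributes).
#' @export
event_table <- function(values, meta, panel, truth_labels = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (nrow(values) < 1) stop("event table needs at least one cell",
                             call. = FALSE)
  if (!all(is.finite(values)) || any(values < 0)) {
    stop("event intensities must be finite and nonnegative", call. = FALSE)
  }
  if (!identical(colnames(values), panel$markers$name)) {
    stop("channel names must exactly match the panel marker names",
         call. = FALSE)
  }
  meta <- validate_sample_meta(meta)
  if (!is.null(truth_labels)) stopifnot(length(truth_labels) == nrow(values))
  structure(values, class = c("event_table", class(values)),
            meta = meta, panel = panel, cofactor = panel$cofactor,
            truth_labels = truth_labels)
}

validate_sample_meta <- function(meta) {
  stopifnot(is.list(meta))
  need <- c("donor_id", "gravity", "stimulation", "timepoint_h")
  if (!all(need %in% names(meta))) {
    stop("sample meta needs donor_id, gravity, stimulation, timepoint_h",
         call. = FALSE)
  }
  if (!meta$gravity %in% c("1G", "uG")) {
    stop("gravity must be '1G' or 'uG'", call. = FALSE)
  }
  if (!meta$stimulation %in% c("unstim", "ConA/anti-CD28")) {
    stop("stimulation must be 'unstim' or 'ConA/anti-CD28'", call. = FALSE)
  }
  if (meta$timepoint_h == 0 && meta$stimulation != "unstim") {
    stop("timepoint 0 h implies the unstimulated condition", call. = FALSE)
  }
  meta
}

#' @export
print.event_table <- function(x, ...) {
  m <- attr(x, "meta")
  cat("<event_table> ", nrow(x), " cells x ", ncol(x), " channels | donor ",
      m$donor_id, ", ", m$gravity, ", ", m$stimulation, ", t = ",
      m$timepoint_h, " h\n", sep = "")
  invisible(x)
}

event_values <- function(x) {
  v <- unclass(x)
  attributes(v) <- attributes(v)[c("dim", "dimnames")]
  v
}

#' Write / read event tables as CSV with a JSON metadata sidecar
#'
#' `write_event_table()` writes `<path>.csv` (header = channel names, one row
#' per cell) and `<path>.json` (sample metadata). `read_event_table()` loads
#' the pair back against a panel.
#'
#' @param x an `event_table`.
#' @param path file stem (without extension).
#' @param panel `panel_config` used when reading.
#' @return `read_event_table()` returns an `event_table`;
#'   `write_event_table()` returns `path` invisibly.
#' @export
write_event_table <- function(x, path) {
  utils::write.csv(as.data.frame(event_values(x)),
                   paste0(path, ".csv"), row.names = FALSE)
  meta <- attr(x, "meta")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path, panel) {
  values <- as.matrix(utils::read.csv(paste0(path, ".csv"),
                                      check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  event_table(values, meta, panel)
}
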