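#' Arcsinh transform for mass cytometry intensities
#'
#' `asinh(x / cofactor)`, the variance-stabilizing transform applied to raw
#' ion counts before any median or gating computation.
#'
#' @param x nonnegative numeric vector.
#' @param cofactor positive scale factor (mass-cytometry convention: 5).
#' @return Transformed values; strictly increasing in `x`.
#' @export
arcsinh_transform <- function(x, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 ||
      !is.finite(cofactor) || cofactor <= 0) {
    stop("`cofactor` must be a single positive number", call. = FALSE)
  }
  if (any(x < 0, na.rm = TRUE)) {
    stop("raw intensities must be nonnegative", call. = FALSE)
  }
  asinh(x / cofactor)
}

#' Median arcsinh marker intensity of one gated subset
#'
#' @param events an `event_table`.
#' @param labels per-event subset labels from [apply_gating()].
#' @param subset leaf name.
#' @param marker functional marker name.
#' @param cofactor arcsinh cofactor (defaults to the panel's).
#' @param min_cells minimum number of subset events for the median to be
#'   considered stable; below this the feature is flagged missing (`NA`),
#'   never silently zero.
#' @return Median of arcsinh-transformed intensities, or `NA_real_`.
#' @export
median_intensity <- function(events, labels, subset, marker,
                             cofactor = NULL, min_cells = 20) {
  values <- event_values(events)
  if (!marker %in% colnames(values)) {
    stop("marker '", marker, "' not in event table", call. = FALSE)
  }
  if (is.null(cofactor)) cofactor <- attr(events, "cofactor") %||% 5
  sel <- labels == subset
  if (sum(sel) < min_cells) return(NA_real_)
  stats::median(arcsinh_transform(values[sel, marker], cofactor))
}

#' Stimulation-response feature ("asinh ratio")
#'
#' Difference of arcsinh-scale median intensities between the stimulated and
#' unstimulated condition of one subset/marker; the asinh-scale analogue of
#' a log fold change.
#'
#' @param median_stim,median_unstim arcsinh-scale medians; `NA` propagates.
#' @return `median_stim - median_unstim`.
#' @export
response_feature <- function(median_stim, median_unstim) {
  median_stim - median_unstim
}

#' Build a samples-by-features immune feature matrix
#'
#' Converts gated event tables into one of the three feature families:
#' \describe{
#'   \item{response}{per (donor, gravity): stimulated-minus-unstimulated
#'     difference of arcsinh median intensities for every (subset,
#'     functional marker) pair; 18 x 14 = 252 columns with the defaults.}
#'   \item{basal}{arcsinh median intensities of the unstimulated samples.}
#'   \item{abundance}{gated leaf frequencies of the unstimulated samples.}
#' }
#'
#' @param tables list of `event_table`s (all samples of the experiment).
#' @param labels_list list of label vectors parallel to `tables`.
#' @param hierarchy `gating_hierarchy` (defines subset order).
#' @param panel `panel_config` (defines functional marker order).
#' @param mode `"response"`, `"basal"` or `"abundance"`.
#' @param min_cells stability floor per (sample, subset); see
#'   [median_intensity()].
#' @param stim_timepoint_h stimulated timepoint used in response mode.
#' @return A `feature_matrix`: numeric matrix, rows = `donor|gravity` units,
#'   columns = `subset|marker|mode` (or `subset||abundance`), with
#'   `row_meta` and `col_meta` data.frame attributes.
#' @export
build_feature_matrix <- function(tables, labels_list, hierarchy, panel,
                                 mode = c("response", "basal", "abundance"),
                                 min_cells = 20, stim_timepoint_h = 4) {
  mode <- match.arg(mode)
  stopifnot(length(tables) == length(labels_list))
  meta <- lapply(tables, attr, "meta")
  donor <- vapply(meta, `[[`, "", "donor_id")
  gravity <- vapply(meta, `[[`, "", "gravity")
  stim <- vapply(meta, `[[`, "", "stimulation")
  tp <- vapply(meta, function(m) as.numeric(m$timepoint_h), 0)
  units <- unique(data.frame(donor = donor, gravity = gravity,
                             stringsAsFactors = FALSE))
  units <- units[order(units$donor, units$gravity), , drop = FALSE]
  rownames(units) <- NULL
  fn <- panel_markers(panel, "functional")
  leaves <- hierarchy$leaves

  if (mode == "abundance") {
    col_meta <- data.frame(subset = leaves, marker = "", mode = mode,
                           stringsAsFactors = FALSE)
  } else {
    col_meta <- data.frame(subset = rep(leaves, each = length(fn)),
                           marker = rep(fn, length(leaves)), mode = mode,
                           stringsAsFactors = FALSE)
  }
  cols <- paste(col_meta$subset, col_meta$marker, col_meta$mode, sep = "|")
  X <- matrix(NA_real_, nrow(units), length(cols),
              dimnames = list(paste(units$donor, units$gravity, sep = "|"),
                              cols))

  find_one <- function(d, g, want_stim) {
    sel <- which(donor == d & gravity == g &
                   if (want_stim) stim != "unstim" & tp == stim_timepoint_h
                   else stim == "unstim")
    if (length(sel) != 1) {
      stop("unit ", d, "/", g, " lacks a unique ",
           if (want_stim) "stimulated" else "unstimulated",
           " sample", call. = FALSE)
    }
    sel
  }

  subset_medians <- function(i) {
    # all (subset, marker) medians of one sample in one pass
    v <- arcsinh_transform(event_values(tables[[i]])[, fn, drop = FALSE],
                           attr(tables[[i]], "cofactor") %||% 5)
    lab <- labels_list[[i]]
    out <- matrix(NA_real_, length(leaves), length(fn),
                  dimnames = list(leaves, fn))
    for (s in leaves) {
      sel <- lab == s
      if (sum(sel) >= min_cells) {
        out[s, ] <- apply(v[sel, , drop = FALSE], 2, stats::median)
      }
    }
    out
  }

  for (u in seq_len(nrow(units))) {
    d <- units$donor[u]; g <- units$gravity[u]
    if (mode == "abundance") {
      i <- find_one(d, g, want_stim = FALSE)
      f <- compute_frequencies(labels_list[[i]], hierarchy)
      X[u, ] <- f[leaves]
    } else if (mode == "basal") {
      i <- find_one(d, g, want_stim = FALSE)
      X[u, ] <- as.vector(t(subset_medians(i)))
    } else {
      i0 <- find_one(d, g, want_stim = FALSE)
      i1 <- find_one(d, g, want_stim = TRUE)
      X[u, ] <- as.vector(t(response_feature(subset_medians(i1),
                                             subset_medians(i0))))
    }
  }
  structure(X, class = c("feature_matrix", class(X)),
            row_meta = units, col_meta = col_meta, mode = mode)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x), " sample units x ", ncol(x), " ",
      attr(x, "mode"), " features (", sum(is.na(x)), " missing)\n",
      sep = "")
  invisible(x)
}

#' Median-impute missing features
#'
#' Features flagged missing (too few gated cells) are filled with the
#' per-column median across sample units so the elastic net sees a complete
#' matrix; the imputation mask is recorded in the `imputed` attribute.
#' Columns missing in every unit are dropped.
#'
#' @param fm a `feature_matrix`.
#' @return Imputed `feature_matrix`.
#' @export
impute_features <- function(fm) {
  X <- fm
  all_na <- colSums(!is.na(X)) == 0
  if (any(all_na)) {
    warning(sum(all_na), " feature(s) missing in every unit; dropped")
    cm <- attr(X, "col_meta")[!all_na, , drop = FALSE]
    rm_ <- attr(X, "row_meta"); md <- attr(X, "mode")
    X <- X[, !all_na, drop = FALSE]
    attr(X, "col_meta") <- cm; attr(X, "row_meta") <- rm_
    attr(X, "mode") <- md
    class(X) <- c("feature_matrix", "matrix", "array")
  }
  mask <- is.na(X)
  if (any(mask)) {
    med <- apply(X, 2, stats::median, na.rm = TRUE)
    for (j in which(colSums(mask) > 0)) X[mask[, j], j] <- med[j]
  }
  attr(X, "imputed") <- mask
  X
}

#' Write / read a feature matrix as CSV
#'
#' Row metadata (donor, gravity) is stored as leading columns; feature
#' columns keep their `subset|marker|mode` names.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV file path.
#' @export
write_feature_matrix <- function(fm, path) {
  rm_ <- attr(fm, "row_meta")
  df <- cbind(rm_, as.data.frame(unclass(fm), check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  rm_ <- df[, c("donor", "gravity")]
  X <- as.matrix(df[, setdiff(names(df), c("donor", "gravity")),
                    drop = FALSE])
  rownames(X) <- paste(rm_$donor, rm_$gravity, sep = "|")
  parts <- strsplit(colnames(X), "|", fixed = TRUE)
  col_meta <- data.frame(
    subset = vapply(parts, `[`, "", 1),
    marker = vapply(parts, function(p) if (length(p) >= 2) p[2] else "", ""),
    mode = vapply(parts, function(p) p[length(p)], ""),
    stringsAsFactors = FALSE)
  structure(X, class = c("feature_matrix", "matrix", "array"),
            row_meta = rm_, col_meta = col_meta, mode = col_meta$mode[1])
}
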