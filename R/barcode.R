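#' Combinatorial palladium barcoding scheme
#'
#' Enumerates every sample key that is positive for exactly `k_positive` of
#' `n_isotopes` barcode isotopes. With 3-of-6 palladium keys this gives
#' `choose(6, 3) = 20` pooled samples, the standard doublet-filtering
#' barcoding design for mass cytometry.
#'
#' @param n_isotopes number of barcode isotope channels (<= 16).
#' @param k_positive number of positive channels per key.
#' @return A `barcode_scheme`: list with `n_isotopes`, `k_positive` and
#'   `keys`, a `choose(n, k) x n` 0/1 matrix in lexicographic order of the
#'   binary masks.
#' @examples
#' make_barcode_scheme(6, 3)  # 20 keys
#' @export
make_barcode_scheme <- function(n_isotopes, k_positive) {
  if (!is.numeric(n_isotopes) || !is.numeric(k_positive) ||
      length(n_isotopes) != 1 || length(k_positive) != 1 ||
      n_isotopes != round(n_isotopes) || k_positive != round(k_positive) ||
      k_positive < 1 || n_isotopes < k_positive || n_isotopes > 16) {
    stop("need 1 <= k_positive <= n_isotopes <= 16", call. = FALSE)
  }
  combs <- utils::combn(n_isotopes, k_positive)
  keys <- matrix(0L, ncol(combs), n_isotopes)
  for (j in seq_len(ncol(combs))) keys[j, combs[, j]] <- 1L
  # lexicographic order on the masks themselves (leftmost channel most
  # significant); combn is lexicographic on positive positions, which is the
  # reverse order of the masks, so flip.
  ord <- do.call(order, as.data.frame(keys))
  keys <- keys[ord, , drop = FALSE]
  structure(list(n_isotopes = as.integer(n_isotopes),
                 k_positive = as.integer(k_positive),
                 keys = keys),
            class = "barcode_scheme")
}

#' @export
print.barcode_scheme <- function(x, ...) {
  cat("<barcode_scheme> ", nrow(x$keys), " keys: ", x$k_positive, " of ",
      x$n_isotopes, " isotopes positive\n", sep = "")
  invisible(x)
}

#' Deconvolve a pooled, barcoded event table
#'
#' Assigns each event of a pooled table back to a barcode key. An event is
#' assigned to key `j` iff its `k_positive` highest barcode channels (on the
#' arcsinh scale) are exactly key `j`'s positive set *and* the gap between the
#' lowest positive and the highest negative channel exceeds `margin`;
#' otherwise the event stays unassigned (0). Events whose top-k set is
#' ambiguous because of ties across the k-th boundary are unassigned.
#'
#' @param pooled an `event_table` containing all barcode channels of `scheme`.
#' @param scheme a [make_barcode_scheme()] result.
#' @param margin minimum arcsinh-scale separation between the weakest
#'   positive and strongest negative barcode channel (default 1.0).
#' @param cofactor arcsinh cofactor used to transform the raw barcode
#'   intensities; defaults to the panel cofactor recorded in the table.
#' @return Integer vector, one entry per event: the key index in
#'   `scheme$keys`, or 0 for unassigned.
#' @export
pool_and_debarcode <- function(pooled, scheme, margin = 1.0,
                               cofactor = NULL) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  values <- event_values(pooled)
  bc_names <- barcode_channel_names(pooled, scheme)
  if (is.null(cofactor)) cofactor <- attr(pooled, "cofactor") %||% 5
  bc <- asinh(values[, bc_names, drop = FALSE] / cofactor)
  k <- scheme$k_positive
  n <- scheme$n_isotopes

  # rank channels per event; top-k set must match a key exactly with margin
  assign_one <- function(v) {
    ord <- order(v, decreasing = TRUE)
    kth <- v[ord[k]]
    rest <- if (k < n) v[ord[k + 1]] else -Inf
    if (kth - rest <= margin) return(0L)
    mask <- integer(n)
    mask[ord[seq_len(k)]] <- 1L
    hit <- which(colSums(abs(t(scheme$keys) - mask)) == 0)
    if (length(hit) == 1) hit else 0L
  }
  as.integer(apply(bc, 1, assign_one))
}

barcode_channel_names <- function(table, scheme) {
  values <- event_values(table)
  panel <- attr(table, "panel")
  bc <- if (!is.null(panel)) panel_markers(panel, "barcode") else
    grep("^Pd", colnames(values), value = TRUE)
  if (length(bc) != scheme$n_isotopes || !all(bc %in% colnames(values))) {
    stop("pooled table does not carry the scheme's ", scheme$n_isotopes,
         " barcode channels", call. = FALSE)
  }
  bc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
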