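#' Construct a mass cytometry panel configuration
#'
#' A panel is the channel inventory of a CyTOF experiment: phenotyping
#' ("surface") markers used by the gating hierarchy, functional readouts
#' (phospho-proteins and activation markers), and palladium barcode channels,
#' together with the arcsinh cofactor used for all transformed-scale work.
#'
#' @param markers data.frame with columns `name`, `channel`, `class`
#'   (each class one of `"surface"`, `"functional"`, `"barcode"`).
#' @param cofactor positive scale factor of the arcsinh transform
#'   (`asinh(x / cofactor)`); 5 is the mass-cytometry convention.
#' @return An object of class `panel_config`.
#' @seealso [default_panel()]
#' @export
panel_config <- function(markers, cofactor = 5) {
  stopifnot(is.data.frame(markers))
  required <- c("name", "channel", "class")
  if (!all(required %in% names(markers))) {
    stop("`markers` must have columns name, channel, class", call. = FALSE)
  }
  markers <- as.data.frame(markers[, required], stringsAsFactors = FALSE)
  if (anyDuplicated(markers$name)) {
    stop("marker names must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(markers$class), c("surface", "functional", "barcode"))
  if (length(bad)) {
    stop("unknown marker class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(cofactor) || length(cofactor) != 1 || !is.finite(cofactor) ||
      cofactor <= 0) {
    stop("`cofactor` must be a single positive number", call. = FALSE)
  }
  structure(list(markers = markers, cofactor = cofactor),
            class = "panel_config")
}

#' Default 41-channel immune profiling panel
#'
#' 21 surface markers sufficient to gate all major PBMC lineages, 14
#' functional markers (JAK/STAT, MAPK and NF-kB pathway phospho-epitopes plus
#' the activation markers CD25 and CD69), and 6 palladium barcode channels.
#'
#' @param cofactor arcsinh cofactor, default 5.
#' @return A `panel_config`.
#' @export
default_panel <- function(cofactor = 5) {
  surface <- c("CD45", "CD66", "CD7", "CD3", "CD4", "CD8", "TCRgd",
               "CD45RA", "CCR7", "FoxP3", "CD127", "CD19", "CD27", "CD56",
               "CD16", "CD14", "CD11c", "HLA-DR", "CD123", "CD38", "CD20")
  functional <- c("CD25", "CD69", "pSTAT1", "pSTAT3", "pSTAT4", "pSTAT5",
                  "pNFkB", "IkB", "pMAPKAPK2", "pP38", "prpS6", "pERK12",
                  "pCREB", "pSTAT6")
  barcode <- c("Pd102", "Pd104", "Pd105", "Pd106", "Pd108", "Pd110")
  markers <- data.frame(
    name    = c(surface, functional, barcode),
    channel = c(sprintf("Sf%02d", seq_along(surface)),
                sprintf("Fn%02d", seq_along(functional)),
                barcode),
    class   = rep(c("surface", "functional", "barcode"),
                  c(length(surface), length(functional), length(barcode))),
    stringsAsFactors = FALSE
  )
  panel_config(markers, cofactor = cofactor)
}

#' @export
print.panel_config <- function(x, ...) {
  tab <- table(factor(x$markers$class,
                      levels = c("surface", "functional", "barcode")))
  cat("<panel_config> ", nrow(x$markers), " channels (",
      tab[["surface"]], " surface, ", tab[["functional"]], " functional, ",
      tab[["barcode"]], " barcode), cofactor = ", x$cofactor, "\n", sep = "")
  invisible(x)
}

panel_markers <- function(panel, class) {
  panel$markers$name[panel$markers$class == class]
}
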