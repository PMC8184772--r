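#' Gating hierarchies: threshold-rule trees over surface markers
#'
#' A gating hierarchy is a tree of nodes, each carrying marker-threshold
#' rules on the arcsinh scale. Events descend from the root while exactly one
#' child's rules are satisfied; the label is the deepest *leaf* reached,
#' otherwise the event is unassigned. This is the programmatic surrogate for
#' manual flow-cytometry gating: 1-D rectangular gates only, one tree path
#' per event.
#'
#' @param node nested list: `list(name=, rules=list(list(marker=, polarity=,
#'   threshold=), ...), children=list(...))`; leaves have no children.
#' @param panel optional `panel_config`; if given, every rule marker must be
#'   a surface channel of the panel.
#' @return A `gating_hierarchy` with fields `root` and `leaves` (ordered
#'   depth-first).
#' @export
gating_hierarchy <- function(node, panel = NULL) {
  validate_node(node, panel)
  leaves <- collect_leaves(node)
  if (anyDuplicated(leaves)) stop("leaf names must be unique", call. = FALSE)
  structure(list(root = node, leaves = leaves), class = "gating_hierarchy")
}

validate_node <- function(node, panel) {
  stopifnot(is.list(node), !is.null(node$name))
  for (r in node$rules %||% list()) {
    stopifnot(!is.null(r$marker), r$polarity %in% c("positive", "negative"),
              is.numeric(r$threshold))
    if (!is.null(panel) && !(r$marker %in% panel_markers(panel, "surface"))) {
      stop("gate rule references marker '", r$marker,
           "' which is not a surface channel of the panel", call. = FALSE)
    }
  }
  kids <- node$children %||% list()
  if (length(kids) > 1) check_sibling_exclusivity(kids, node$name)
  for (ch in kids) validate_node(ch, panel)
  invisible(TRUE)
}

# every sibling pair must be separable on at least one shared marker
check_sibling_exclusivity <- function(kids, parent) {
  for (i in seq_along(kids)) for (j in seq_len(i - 1L)) {
    ri <- kids[[i]]$rules; rj <- kids[[j]]$rules
    ok <- FALSE
    for (a in ri) for (b in rj) {
      if (a$marker != b$marker) next
      if (a$polarity != b$polarity) {
        pos <- if (a$polarity == "positive") a else b
        neg <- if (a$polarity == "positive") b else a
        if (pos$threshold >= neg$threshold) ok <- TRUE
      }
    }
    if (!ok) {
      stop("children '", kids[[i]]$name, "' and '", kids[[j]]$name,
           "' of node '", parent,
           "' are not mutually exclusive on any shared marker",
           call. = FALSE)
    }
  }
}

collect_leaves <- function(node) {
  kids <- node$children %||% list()
  if (!length(kids)) return(node$name)
  unlist(lapply(kids, collect_leaves), use.names = FALSE)
}

#' @export
print.gating_hierarchy <- function(x, ...) {
  cat("<gating_hierarchy> ", length(x$leaves), " leaf subsets\n", sep = "")
  invisible(x)
}

rule <- function(marker, polarity, threshold) {
  list(marker = marker, polarity = polarity, threshold = threshold)
}

#' Default 18-subset PBMC gating hierarchy
#'
#' Threshold gates on the arcsinh scale resolving the major innate and
#' adaptive PBMC compartments into 18 leaf subsets: classical, intermediate
#' and non-classical monocytes; mDC and pDC; naive and memory B cells;
#' CD56dim CD16+ and CD56bright CD16- NK cells; NKT; gamma-delta T; naive
#' and memory CD4 and CD8 T cells; naive and memory Tregs; and a
#' basophil-like lineage-negative remainder. The default threshold sits
#' midway between the positive and negative surface population means of the
#' synthetic generator.
#'
#' @param panel a `panel_config` carrying the required surface markers.
#' @param threshold arcsinh-scale gate position used for every rule.
#' @return A `gating_hierarchy` with 18 leaves.
#' @export
build_default_hierarchy <- function(panel = default_panel(),
                                    threshold = default_gate_threshold()) {
  t <- threshold
  pos <- function(m) rule(m, "positive", t)
  neg <- function(m) rule(m, "negative", t)
  node <- function(name, rules, ...) {
    kids <- list(...)
    c(list(name = name, rules = rules),
      if (length(kids)) list(children = kids))
  }
  tree <- node(
    "Leukocytes", list(pos("CD45")),
    node("T cells", list(pos("CD3")),
      node("gd T", list(pos("TCRgd"))),
      node("ab T", list(neg("TCRgd")),
        node("NKT", list(pos("CD56"))),
        node("conv T", list(neg("CD56")),
          node("CD4 T", list(pos("CD4")),
            node("Treg", list(pos("FoxP3")),
              node("Treg naive", list(pos("CD45RA"))),
              node("Treg memory", list(neg("CD45RA")))),
            node("CD4 conv", list(neg("FoxP3")),
              node("CD4 T naive", list(pos("CD45RA"))),
              node("CD4 T memory", list(neg("CD45RA"))))),
          node("CD8 T", list(neg("CD4"), pos("CD8")),
            node("CD8 T naive", list(pos("CD45RA"))),
            node("CD8 T memory", list(neg("CD45RA"))))))),
    node("non-T", list(neg("CD3")),
      node("B cells", list(pos("CD19")),
        node("B memory", list(pos("CD27"))),
        node("B naive", list(neg("CD27")))),
      node("non-B", list(neg("CD19")),
        node("NK", list(pos("CD56")),
          node("NK CD56dim CD16+", list(pos("CD16"))),
          node("NK CD56bright CD16-", list(neg("CD16")))),
        node("non-NK", list(neg("CD56")),
          node("CD14+ MC", list(pos("CD14")),
            node("intermediate MC", list(pos("CD16"))),
            node("classical MC", list(neg("CD16")))),
          node("CD14- cells", list(neg("CD14")),
            node("non-classical MC", list(pos("CD16"))),
            node("CD16- cells", list(neg("CD16")),
              node("DC", list(pos("HLA-DR")),
                node("mDC", list(pos("CD11c"))),
                node("pDC", list(neg("CD11c"), pos("CD123")))),
              node("basophil-like Lin-",
                   list(neg("HLA-DR"), pos("CD123")))))))))
  h <- gating_hierarchy(tree, panel)
  stopifnot(length(h$leaves) == 18L)
  h
}

#' @rdname build_default_hierarchy
#' @export
default_gate_threshold <- function() {
  s <- surface_band_defaults()
  (s$pos_mean + s$neg_mean) / 2
}

# generator-side surface bands; the default gate threshold is their midpoint
surface_band_defaults <- function() {
  list(pos_mean = 4.0, pos_sd = 0.5, neg_mean = 0.5, neg_sd = 0.3)
}

#' Gate every event of a sample through a hierarchy
#'
#' Evaluates rules on arcsinh-transformed intensities. An event descends
#' while exactly one child's rule set is fully satisfied; events stopping at
#' an internal node (no child matches, or the node fails the root rule) are
#' `"unassigned"`.
#'
#' @param events an `event_table`.
#' @param hierarchy a `gating_hierarchy`.
#' @param cofactor arcsinh cofactor; defaults to the table's panel cofactor.
#' @return Character vector of leaf labels (or `"unassigned"`), one per
#'   event.
#' @export
apply_gating <- function(events, hierarchy, cofactor = NULL) {
  stopifnot(inherits(hierarchy, "gating_hierarchy"))
  values <- event_values(events)
  if (is.null(cofactor)) cofactor <- attr(events, "cofactor") %||% 5
  markers <- gate_markers(hierarchy$root)
  missing <- setdiff(markers, colnames(values))
  if (length(missing)) {
    stop("events lack gated channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tv <- asinh(values[, markers, drop = FALSE] / cofactor)
  labels <- rep("unassigned", nrow(values))
  rules_ok <- function(node, idx) {
    ok <- rep(TRUE, length(idx))
    for (r in node$rules %||% list()) {
      v <- tv[idx, r$marker]
      ok <- ok & if (r$polarity == "positive") v > r$threshold
                 else v <= r$threshold
    }
    ok
  }
  descend <- function(node, idx) {
    if (!length(idx)) return(invisible(NULL))
    kids <- node$children %||% list()
    if (!length(kids)) {
      labels[idx] <<- node$name
      return(invisible(NULL))
    }
    match_count <- integer(length(idx))
    match_which <- integer(length(idx))
    for (k in seq_along(kids)) {
      ok <- rules_ok(kids[[k]], idx)
      match_count <- match_count + ok
      match_which[ok] <- k
    }
    for (k in seq_along(kids)) {
      sel <- match_count == 1L & match_which == k
      descend(kids[[k]], idx[sel])
    }
    invisible(NULL)
  }
  root_ok <- rules_ok(hierarchy$root, seq_len(nrow(values)))
  descend(hierarchy$root, which(root_ok))
  labels
}

gate_markers <- function(node) {
  own <- vapply(node$rules %||% list(), `[[`, "", "marker")
  unique(c(own, unlist(lapply(node$children %||% list(), gate_markers))))
}

#' Per-sample subset frequencies
#'
#' @param labels output of [apply_gating()].
#' @param hierarchy the `gating_hierarchy` defining leaf order.
#' @return Named numeric vector over the leaves plus `"unassigned"`,
#'   summing to 1.
#' @export
compute_frequencies <- function(labels, hierarchy) {
  if (!length(labels)) stop("no events to tabulate", call. = FALSE)
  lv <- c(hierarchy$leaves, "unassigned")
  counts <- table(factor(labels, levels = lv))
  f <- as.numeric(counts) / length(labels)
  names(f) <- lv
  f
}

#' Serialize / load a gating hierarchy as YAML
#'
#' @param hierarchy a `gating_hierarchy`.
#' @param path file path.
#' @param panel optional panel to validate against when reading.
#' @export
write_hierarchy <- function(hierarchy, path) {
  yaml::write_yaml(hierarchy$root, path)
  invisible(path)
}

#' @rdname write_hierarchy
#' @export
read_hierarchy <- function(path, panel = NULL) {
  gating_hierarchy(yaml::read_yaml(path), panel)
}
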