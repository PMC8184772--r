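#' Bonferroni-thresholded Spearman correlation network
#'
#' Computes Spearman rho and a two-sided p-value for every feature pair
#' across all sample rows (both gravity conditions pooled), and keeps an
#' edge iff `p * C(n_nodes, 2) < 0.05` (Bonferroni over all pairs).
#' Constant features are undefined under rank correlation and are excluded
#' with a warning. P-values use the exact permutation tail for 8 or fewer
#' rows and the t approximation otherwise, matching [spearman_rho_p()].
#'
#' @param features a `feature_matrix` (or plain matrix), >= 4 rows.
#' @param alpha familywise error level for the edge criterion
#'   (default 0.05).
#' @return A `corr_network`: `nodes`, `rho` and `p` (symmetric matrices),
#'   `adjacency` (logical, empty diagonal), `m_pairs`, `alpha`,
#'   `n_samples`, `dropped` (excluded constant features).
#' @export
build_network <- function(features, alpha = 0.05) {
  X <- as.matrix(unclass(features))
  if (nrow(X) < 4) stop("need at least 4 sample rows", call. = FALSE)
  if (ncol(X) < 2) stop("need at least 2 features", call. = FALSE)
  if (any(is.na(X))) stop("impute missing features first", call. = FALSE)
  const <- apply(X, 2, stats::sd) == 0
  dropped <- colnames(X)[const]
  if (any(const)) {
    warning(sum(const), " constant feature(s) excluded from the network: ",
            "rank correlation undefined")
    X <- X[, !const, drop = FALSE]
  }
  n <- nrow(X); p <- ncol(X)
  if (p < 2) stop("fewer than 2 non-constant features", call. = FALSE)
  R <- apply(X, 2, rank)
  rho <- stats::cor(R)
  if (n <= 8) {
    P <- matrix(NA_real_, p, p, dimnames = dimnames(rho))
    # the permutation null of rho depends only on the two columns' rank
    # multisets (tie patterns), so one enumeration is shared across all
    # pairs with the same pattern pair
    pat <- apply(R, 2, function(r) paste(sort(r), collapse = ","))
    null_cache <- new.env(parent = emptyenv())
    get_null <- function(i, j) {
      key <- paste(sort(c(pat[i], pat[j])), collapse = ";")
      val <- null_cache[[key]]
      if (is.null(val)) {
        val <- sort(abs(spearman_perm_null(R[, i], R[, j])))
        null_cache[[key]] <- val
      }
      val
    }
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      null_abs <- get_null(i, j)
      m_null <- length(null_abs)
      P[i, j] <- P[j, i] <-
        (m_null - findInterval(abs(rho[i, j]) - 1e-12, null_abs)) / m_null
    }
  } else {
    r2 <- pmin(abs(rho), 1)
    tt <- r2 * sqrt((n - 2) / pmax(1 - r2^2, .Machine$double.eps))
    P <- 2 * stats::pt(-tt, n - 2)
    P[r2 >= 1] <- 0
    dimnames(P) <- dimnames(rho)
  }
  diag(P) <- NA_real_
  m_pairs <- choose(p, 2)
  adjacency <- P * m_pairs < alpha
  adjacency[is.na(adjacency)] <- FALSE
  diag(adjacency) <- FALSE
  structure(list(nodes = colnames(X), rho = rho, p = P,
                 adjacency = adjacency, m_pairs = m_pairs, alpha = alpha,
                 n_samples = n, dropped = dropped),
            class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  cat("<corr_network> ", length(x$nodes), " nodes, ",
      sum(x$adjacency) / 2, " Bonferroni-significant edges (alpha = ",
      x$alpha, " over ", x$m_pairs, " pairs)\n", sep = "")
  invisible(x)
}

net_graph <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(
    net$adjacency * abs(net$rho), mode = "undirected", weighted = TRUE,
    diag = FALSE)
  igraph::set_vertex_attr(g, "name", value = net$nodes)
}

#' Detect communities of correlated immune features
#'
#' Greedy modularity maximization (weighted by `|rho|`) on the significant-
#' edge graph. Isolated nodes become singleton communities. The algorithm
#' is deterministic; `seed` is accepted for interface uniformity and set
#' before clustering.
#'
#' @param net a `corr_network`.
#' @param seed integer seed.
#' @return Named integer vector of community labels (one per node).
#' @export
detect_communities <- function(net, seed = 1L) {
  set.seed(seed)
  g <- net_graph(net)
  if (igraph::ecount(g) == 0) {
    labels <- seq_along(net$nodes)
    names(labels) <- net$nodes
    return(labels)
  }
  cl <- igraph::cluster_fast_greedy(g)
  labels <- igraph::membership(cl)
  out <- as.integer(labels)
  names(out) <- net$nodes
  out
}

#' Annotate communities by their dominant functional attribute
#'
#' Each community is named after the functional marker that appears most
#' frequently among its member features; ties are broken alphabetically
#' and flagged.
#'
#' @param labels community labels from [detect_communities()]; names must
#'   be `subset|marker|mode` feature ids.
#' @return data.frame: community, attribute, n_members, tie.
#' @export
annotate_communities <- function(labels) {
  parts <- strsplit(names(labels), "|", fixed = TRUE)
  marker <- vapply(parts, function(p) if (length(p) >= 2) p[2] else p[1], "")
  out <- lapply(sort(unique(labels)), function(cm) {
    tab <- sort(table(marker[labels == cm]), decreasing = TRUE)
    top <- tab[tab == tab[1]]
    data.frame(community = cm,
               attribute = sort(names(top))[1],
               n_members = sum(labels == cm),
               tie = length(top) > 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' 2-D t-SNE layout of the correlation network
#'
#' Embeds the nodes with t-SNE on the distance `1 - |rho|`. Perplexity
#' defaults to `min(30, (n - 1) / 3)`; for graphs too small for a valid
#' perplexity (< 10 nodes) classical metric scaling of the same distance is
#' used instead, which is deterministic and preserves the close-pair
#' ordering the layout is meant to convey. A single node is placed at the
#' origin.
#'
#' @param net a `corr_network`.
#' @param seed integer seed (t-SNE initialization).
#' @param perplexity optional t-SNE perplexity override.
#' @return Numeric matrix `n_nodes x 2` with node-name rownames; all
#'   coordinates finite.
#' @export
layout_2d <- function(net, seed = 1L, perplexity = NULL) {
  n <- length(net$nodes)
  if (n == 1) {
    return(matrix(0, 1, 2, dimnames = list(net$nodes, c("x", "y"))))
  }
  D <- 1 - abs(net$rho)
  D[D < 0] <- 0
  diag(D) <- 0
  if (is.null(perplexity)) perplexity <- min(30, (n - 1) / 3)
  set.seed(seed)
  if (n < 10 || perplexity < 1) {
    xy <- stats::cmdscale(stats::as.dist(D), k = 2)
    if (ncol(xy) < 2) xy <- cbind(xy, 0)
  } else {
    xy <- Rtsne::Rtsne(D, is_distance = TRUE, dims = 2,
                       perplexity = perplexity, theta = 0.0,
                       pca = FALSE, max_iter = 500)$Y
  }
  xy[!is.finite(xy)] <- 0
  dimnames(xy) <- list(net$nodes, c("x", "y"))
  xy
}

#' Export a correlation network
#'
#' Writes `<stem>.graphml` (GraphML with rho edge weights, community and
#' layout node attributes), `<stem>_edges.tsv` (node1, node2, rho, p,
#' significant over all pairs) and `<stem>_nodes.tsv` (node, community,
#' x, y).
#'
#' @param net a `corr_network`.
#' @param stem output path stem.
#' @param communities,layout optional results of [detect_communities()]
#'   and [layout_2d()].
#' @return Invisibly, the vector of files written.
#' @export
export_network <- function(net, stem, communities = NULL, layout = NULL) {
  g <- net_graph(net)
  if (!is.null(communities)) {
    g <- igraph::set_vertex_attr(g, "community",
                                 value = communities[net$nodes])
  }
  if (!is.null(layout)) {
    g <- igraph::set_vertex_attr(g, "x", value = layout[net$nodes, "x"])
    g <- igraph::set_vertex_attr(g, "y", value = layout[net$nodes, "y"])
  }
  graphml <- paste0(stem, ".graphml")
  igraph::write_graph(g, graphml, format = "graphml")

  iu <- which(upper.tri(net$rho), arr.ind = TRUE)
  edges <- data.frame(
    node1 = net$nodes[iu[, 1]], node2 = net$nodes[iu[, 2]],
    rho = net$rho[iu], p = net$p[iu],
    significant = net$adjacency[iu], stringsAsFactors = FALSE)
  edge_file <- paste0(stem, "_edges.tsv")
  utils::write.table(edges, edge_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  node_file <- paste0(stem, "_nodes.tsv")
  nodes <- data.frame(node = net$nodes,
                      community = if (!is.null(communities))
                        communities[net$nodes] else NA_integer_,
                      x = if (!is.null(layout)) layout[net$nodes, "x"]
                          else NA_real_,
                      y = if (!is.null(layout)) layout[net$nodes, "y"]
                          else NA_real_,
                      stringsAsFactors = FALSE)
  utils::write.table(nodes, node_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(graphml, edge_file, node_file))
}
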