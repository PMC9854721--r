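# Median-joining haplotype networks (Bandelt-style iteration over the
# minimum spanning network, adding majority-consensus median vectors).

# bottleneck (minimax path) distances via the MST of a complete graph
bottleneck_distances <- function(d) {
  n <- nrow(d)
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g, algorithm = "prim")
  bn <- matrix(0, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) {
    paths <- igraph::shortest_paths(mst, from = i, to = (i + 1):n,
                                    output = "epath")$epath
    for (k in seq_along(paths)) {
      w <- igraph::E(mst)$weight[as.integer(paths[[k]])]
      bn[i, i + k] <- bn[i + k, i] <- max(w)
    }
  }
  bn
}

# minimum spanning network at tolerance eps: edge (u,v) kept iff
# d(u,v) <= bottleneck(u,v) + eps
msn_edges <- function(d, eps = 0) {
  bn <- bottleneck_distances(d)
  keep <- which(d <= bn + eps & upper.tri(d), arr.ind = TRUE)
  data.frame(from = rownames(d)[keep[, 1]], to = rownames(d)[keep[, 2]],
             weight = d[keep], stringsAsFactors = FALSE)
}

# majority-consensus median of three state vectors; ties resolved to the
# first vector (nodes are supplied in the deterministic global order)
median_state <- function(a, b, c) {
  vapply(seq_along(a), function(i) {
    s <- c(a[i], b[i], c[i])
    tb <- sort(table(s), decreasing = TRUE)
    if (tb[1] >= 2) names(tb)[1] else a[i]
  }, "")
}

mst_total_weight <- function(d) {
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  sum(igraph::E(igraph::mst(g, algorithm = "prim"))$weight)
}

#' Median-joining haplotype network
#'
#' Builds the minimum spanning network (MSN) over the observed haplotypes
#' at tolerance `epsilon`, then iterates: for every triplet of nodes
#' connected through MSN links, the majority-consensus (median) vector is a
#' candidate inferred haplotype; the candidate whose addition most reduces
#' the minimum spanning weight of the node set is added (inferred median
#' vectors represent likely extant but unsampled sequences), the MSN is
#' rebuilt, and median vectors that end up with fewer than three links are
#' pruned. The iteration runs to a fixed point. All characters carry equal
#' weight; ties are broken by lexicographic node name (observed) or state
#' string (medians), so the result is invariant to input order.
#'
#' @param m a [variable_site_matrix()] or a `sequence_set`.
#' @param epsilon non-negative integer MSN tolerance (default 0, the
#'   algorithm's conventional default).
#' @return Object of class `"haplotype_network"`: `nodes` data frame
#'   (name, type observed/median, frequency, lineage, states string) and
#'   `edges` data frame (from, to, weight = Hamming distance).
#' @export
median_joining_network <- function(m, epsilon = 0) {
  if (inherits(m, "variable_site_matrix")) {
    freq <- rowSums(m$region_counts)
    lineage <- m$lineage
    states <- m$states
  } else if (inherits(m, "sequence_set")) {
    tb <- table(m$records$haplotype)
    states <- m$states[names(tb), , drop = FALSE]
    freq <- setNames(as.integer(tb), names(tb))
    lineage <- vapply(names(tb), function(h)
      m$records$lineage[match(h, m$records$haplotype)], "")
  } else stop_wreckpop("need a variable_site_matrix or sequence_set")
  if (nrow(states) < 2) stop_wreckpop("need at least 2 haplotypes")
  epsilon <- as.integer(epsilon)
  if (epsilon < 0) stop_wreckpop("epsilon must be >= 0")

  ord <- order(rownames(states))
  states <- states[ord, , drop = FALSE]
  freq <- freq[rownames(states)]
  node_states <- states
  node_type <- rep("observed", nrow(states))
  rejected <- character(0)  # pruned median keys, never re-added
  mv_id <- 0L

  for (iter in 1:100) {
    d <- hamming_matrix(node_states)$d
    edges <- msn_edges(d, epsilon)
    # prune median vectors with < 3 links
    deg <- table(factor(c(edges$from, edges$to),
                        levels = rownames(node_states)))
    drop <- names(deg)[deg < 3 & node_type == "median"]
    if (length(drop)) {
      rejected <- union(rejected,
                        apply(node_states[drop, , drop = FALSE], 1,
                              paste, collapse = ""))
      keep <- !(rownames(node_states) %in% drop)
      node_states <- node_states[keep, , drop = FALSE]
      node_type <- node_type[keep]
      next
    }
    # candidate medians from triplets with >= 2 connecting links
    adj <- matrix(FALSE, nrow(d), ncol(d), dimnames = dimnames(d))
    for (r in seq_len(nrow(edges)))
      adj[edges$from[r], edges$to[r]] <- adj[edges$to[r], edges$from[r]] <- TRUE
    nm <- rownames(node_states)
    existing <- apply(node_states, 1, paste, collapse = "")
    cand <- list()
    if (length(nm) >= 3) {
      trip <- combn(seq_along(nm), 3)
      for (tcol in seq_len(ncol(trip))) {
        u <- trip[1, tcol]; v <- trip[2, tcol]; w <- trip[3, tcol]
        if (adj[u, v] + adj[u, w] + adj[v, w] < 2) next
        ms <- median_state(node_states[u, ], node_states[v, ],
                           node_states[w, ])
        key <- paste(ms, collapse = "")
        if (key %in% existing || key %in% rejected) next
        cand[[key]] <- ms
      }
    }
    if (!length(cand)) break
    base_w <- mst_total_weight(d)
    keys <- sort(names(cand))
    red <- vapply(keys, function(key) {
      ns <- rbind(node_states, cand[[key]])
      rownames(ns)[nrow(ns)] <- "candidate"
      base_w - mst_total_weight(hamming_matrix(ns)$d)
    }, numeric(1))
    best <- keys[which.max(red)]
    if (red[best] <= 0) break
    mv_id <- mv_id + 1L
    node_states <- rbind(node_states, cand[[best]])
    rownames(node_states)[nrow(node_states)] <- sprintf("mv%d", mv_id)
    node_type <- c(node_type, "median")
  }

  d <- hamming_matrix(node_states)$d
  edges <- msn_edges(d, epsilon)
  nodes <- data.frame(
    name = rownames(node_states), type = node_type,
    frequency = ifelse(node_type == "observed",
                       freq[rownames(node_states)], 0L),
    lineage = ifelse(node_type == "observed",
                     lineage[rownames(node_states)], NA_character_),
    states = apply(node_states, 1, paste, collapse = ""),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = nodes, edges = edges, epsilon = epsilon),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("Median-joining network: %d observed + %d median nodes, %d edges (eps = %d)\n",
              sum(x$nodes$type == "observed"), sum(x$nodes$type == "median"),
              nrow(x$edges), x$epsilon))
  e <- x$edges
  for (r in seq_len(nrow(e)))
    cat(sprintf("  %s -- %s  (%d steps)\n", e$from[r], e$to[r], e$weight[r]))
  invisible(x)
}

#' Convert a haplotype network to an igraph object
#'
#' @param x a `haplotype_network`.
#' @return An `igraph` graph with node attributes `type`, `frequency`,
#'   `lineage` and edge attribute `weight`.
#' @export
as_igraph <- function(x) {
  stopifnot(inherits(x, "haplotype_network"))
  igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                vertices = x$nodes)
}

#' Write a haplotype network to GraphML and a TSV edge list
#'
#' @param x a `haplotype_network`.
#' @param graphml,edges_tsv output paths (either may be `NULL` to skip).
#' @return Invisible list of written paths.
#' @export
write_network <- function(x, graphml = NULL, edges_tsv = NULL) {
  g <- as_igraph(x)
  if (!is.null(graphml)) igraph::write_graph(g, graphml, format = "graphml")
  if (!is.null(edges_tsv))
    write.table(x$edges, edges_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(list(graphml = graphml, edges_tsv = edges_tsv))
}

#' Weighted shortest-path steps between node sets of a network
#'
#' Minimum total mutational steps along network paths between any node of
#' `from` and any node of `to`; used e.g. to check that a putative hybrid
#' haplotype attaches between its parental clusters.
#'
#' @param x a `haplotype_network`.
#' @param from,to character vectors of node names.
#' @return Numeric scalar.
#' @export
network_steps <- function(x, from, to) {
  g <- as_igraph(x)
  min(igraph::distances(g, v = from, to = to, weights = igraph::E(g)$weight))
}

#' Plot a haplotype network
#'
#' Convenience layout: observed nodes scaled by frequency, median vectors
#' as small squares, edges labelled with mutational steps.
#'
#' @param x a `haplotype_network`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.haplotype_network <- function(x, ...) {
  g <- as_igraph(x)
  obs <- igraph::V(g)$type == "observed"
  sz <- ifelse(obs, 8 + 4 * sqrt(as.numeric(igraph::V(g)$frequency)), 4)
  igraph::plot.igraph(
    g, vertex.size = sz,
    vertex.shape = ifelse(obs, "circle", "square"),
    vertex.color = ifelse(obs, "steelblue", "tomato"),
    edge.label = igraph::E(g)$weight, ...)
  invisible(x)
}
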