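# Per-frame residue interaction networks and Girvan-Newman community
# decomposition.
#
# One node per amino-acid residue (CB bead; CA for glycine) plus one node per
# ligand-candidate HETATM residue (its configured node atom, C2 by default).
# An undirected edge joins two nodes when their node atoms lie within the
# distance cutoff; no self-loops. Communities are obtained divisively by
# repeatedly deleting the single highest edge-betweenness edge (deterministic
# lexicographic tie-break) until the graph falls apart into at least `omega`
# connected components. Betweenness scores are computed with Brandes'
# algorithm as implemented in igraph; an exhaustive shortest-path oracle in
# the test suite checks the wrapper independently.

#' Residue-network configuration
#'
#' @param cutoff contact distance between node atoms, Angstrom (default 6.7).
#' @param ligand_node_atom atom name used as the ligand node (default "C2").
#' @param omega target community count for Girvan-Newman (default 6).
#' @param n_select number of equally spaced frames analyzed by
#'   [partition_series()] (default 10).
#' @param window_ns when the trajectory has frame times, analyze one frame
#'   per `spacing_ns` over the final `window_ns` (defaults 100 and 10 ns).
#' @param spacing_ns see `window_ns`.
#' @return a `network_config` list.
#' @export
network_config <- function(cutoff = 6.7, ligand_node_atom = "C2", omega = 6L,
                           n_select = 10L, window_ns = 100, spacing_ns = 10) {
  stopifnot(cutoff > 0, omega >= 1L, n_select >= 1L)
  structure(list(cutoff = cutoff, ligand_node_atom = ligand_node_atom,
                 omega = as.integer(omega), n_select = as.integer(n_select),
                 window_ns = window_ns, spacing_ns = spacing_ns),
            class = "network_config")
}

node_labels <- function(topology, idx) {
  a <- topology$atoms
  one <- AA3TO1[a$residue_name[idx]]
  lab <- ifelse(a$is_het[idx], a$residue_name[idx],
                paste0(ifelse(is.na(one), paste0(a$residue_name[idx], "-"), one),
                       a$residue_seq[idx],
                       ifelse(nzchar(a$icode[idx]), a$icode[idx], "")))
  if (anyDuplicated(lab)) {
    dup <- duplicated(lab) | duplicated(lab, fromLast = TRUE)
    lab[dup] <- paste0(lab[dup], "/", a$chain[idx][dup], a$residue_seq[idx][dup])
  }
  lab
}

#' Build the residue network of one frame
#'
#' @param frame `n_atoms x 3` coordinate matrix.
#' @param topology the `md_structure`.
#' @param config a [network_config()].
#' @return a `residue_graph`: list with `nodes` (character vector of labels
#'   such as `"I94"`), `edges` (two-column character matrix, each row an
#'   unordered pair with `from < to` lexicographically) and `node_atoms`
#'   (atom indices backing the nodes).
#' @export
build_residue_network <- function(frame, topology, config = network_config()) {
  idx <- select_atoms(topology, list(network_node = TRUE,
                                     ligand_node_atom = config$ligand_node_atom))
  res <- residues(topology)
  covered <- residue_uid(topology$atoms$chain[idx], topology$atoms$residue_seq[idx],
                         topology$atoms$icode[idx])
  protein <- res[!res$is_het, , drop = FALSE]
  missing <- setdiff(protein$uid, covered)
  if (length(missing) > 0L) {
    stop("residues missing their network-node atom (CB, or CA for GLY): ",
         paste(utils::head(missing, 10L), collapse = ", "))
  }
  lig <- res[res$is_het & !(res$residue_name %in% SOLVENT_RESNAMES), , drop = FALSE]
  missing_lig <- setdiff(lig$uid, covered)
  if (length(missing_lig) > 0L) {
    stop("ligand residue(s) missing node atom '", config$ligand_node_atom,
         "': ", paste(missing_lig, collapse = ", "))
  }
  labels <- node_labels(topology, idx)
  xyz <- frame[idx, , drop = FALSE]
  n <- length(idx)
  edges <- NULL
  if (n >= 2L) {
    d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
    hit <- which(upper.tri(d2) & d2 <= config$cutoff^2, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      a <- labels[hit[, 1]]; b <- labels[hit[, 2]]
      edges <- cbind(pmin(a, b), pmax(a, b))
      edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    }
  }
  if (is.null(edges)) edges <- matrix(character(0), ncol = 2L)
  colnames(edges) <- c("from", "to")
  structure(list(nodes = labels, edges = edges, node_atoms = idx),
            class = "residue_graph")
}

#' Construct a residue graph directly from nodes and edges
#'
#' @param nodes character vector of node ids.
#' @param edges two-column matrix/data.frame of node pairs (undirected).
#' @return a `residue_graph`.
#' @export
residue_graph <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  stopifnot(!anyDuplicated(nodes))
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    if (!all(edges %in% nodes)) stop("edge endpoints must be listed nodes")
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  colnames(edges) <- c("from", "to")
  structure(list(nodes = nodes, edges = edges), class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("<residue_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    as.data.frame(g$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE)
  )
}

#' Shortest-path edge betweenness of a residue graph
#'
#' Unit edge weights; node pairs in different components contribute nothing;
#' multiple shortest paths split their contribution equally. Each unordered
#' pair is counted once.
#'
#' @param g a `residue_graph`.
#' @return data.frame with columns `from`, `to`, `betweenness`, ordered as
#'   `g$edges`.
#' @export
edge_betweenness <- function(g) {
  stopifnot(inherits(g, "residue_graph"))
  if (nrow(g$edges) == 0L) {
    return(data.frame(from = character(0), to = character(0),
                      betweenness = numeric(0), stringsAsFactors = FALSE))
  }
  ig <- as_igraph(g)
  eb <- igraph::edge_betweenness(ig, directed = FALSE)
  data.frame(from = g$edges[, 1], to = g$edges[, 2], betweenness = eb,
             stringsAsFactors = FALSE)
}

components_partition <- function(g) {
  ig <- as_igraph(g)
  comp <- igraph::components(ig)
  stats::setNames(as.integer(comp$membership), igraph::V(ig)$name)[g$nodes]
}

#' Girvan-Newman community partition
#'
#' Repeatedly recomputes edge betweenness on the current graph and removes
#' the single highest-betweenness edge (ties, including floating-point ties
#' within 1e-9 relative, broken by lexicographically smallest edge) until the
#' number of connected components reaches `omega`. If the input graph already
#' has at least `omega` components it is returned unchanged.
#'
#' @param g a `residue_graph`.
#' @param omega target number of communities.
#' @return a `community_partition`: list with `membership` (named integer,
#'   labels numbered by first node appearance), `n_communities`, and
#'   `removed_edges` (matrix of deleted edges in removal order).
#' @export
girvan_newman_partition <- function(g, omega = 6L) {
  stopifnot(inherits(g, "residue_graph"))
  if (omega > length(g$nodes)) stop("omega exceeds the number of nodes")
  cur <- g
  removed <- matrix(character(0), ncol = 2L)
  repeat {
    membership <- components_partition(cur)
    if (max(membership) >= omega || nrow(cur$edges) == 0L) break
    eb <- edge_betweenness(cur)
    top <- max(eb$betweenness)
    tied <- which(eb$betweenness >= top - 1e-9 * max(1, abs(top)))
    pick <- tied[order(eb$from[tied], eb$to[tied])][1]
    removed <- rbind(removed, c(eb$from[pick], eb$to[pick]))
    keep <- rep(TRUE, nrow(cur$edges))
    keep[pick] <- FALSE
    cur <- structure(list(nodes = cur$nodes,
                          edges = cur$edges[keep, , drop = FALSE]),
                     class = "residue_graph")
  }
  # renumber labels by first appearance in node order
  first <- membership[!duplicated(membership)]
  relabel <- stats::setNames(seq_along(first), first)
  membership <- stats::setNames(relabel[as.character(membership)], names(membership))
  structure(list(membership = membership,
                 n_communities = max(membership),
                 removed_edges = removed),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d nodes in %d communities\n",
              length(x$membership), x$n_communities))
  invisible(x)
}

select_network_frames <- function(traj, config) {
  nf <- n_frames(traj)
  if (!is.null(traj$frame_times)) {
    t_end <- traj$frame_times[nf]
    wanted <- t_end - rev(seq_len(config$n_select) - 1L) * config$spacing_ns
    if (min(wanted) < traj$frame_times[1]) {
      stop("configured analysis window extends before the first frame")
    }
    vapply(wanted, function(w) which.min(abs(traj$frame_times - w)), integer(1))
  } else {
    if (nf < config$n_select) stop("trajectory shorter than requested frame count")
    unique(round(seq(1L, nf, length.out = config$n_select)))
  }
}

#' Community partitions over selected trajectory frames
#'
#' With frame times present, one frame per `spacing_ns` over the final
#' `window_ns`; otherwise `n_select` equally spaced frames spanning the
#' trajectory.
#'
#' @param traj an `md_trajectory`.
#' @param config a [network_config()].
#' @return list of [girvan_newman_partition()] results in frame order, with
#'   attribute `frames` giving the analyzed frame indices.
#' @export
partition_series <- function(traj, config = network_config()) {
  frames <- select_network_frames(traj, config)
  parts <- lapply(frames, function(i) {
    g <- build_residue_network(frame_coords(traj, i), traj$topology, config)
    girvan_newman_partition(g, config$omega)
  })
  attr(parts, "frames") <- frames
  parts
}

#' Write a residue graph as an edge-list TSV
#' @param g a `residue_graph`.
#' @param path output file.
#' @export
write_edgelist_tsv <- function(g, path) {
  utils::write.table(as.data.frame(g$edges, stringsAsFactors = FALSE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a partition series as TSV (frame, node, community)
#' @param parts result of [partition_series()] (or list of partitions).
#' @param path output file.
#' @export
write_partitions_tsv <- function(parts, path) {
  frames <- attr(parts, "frames") %||% seq_along(parts)
  rows <- do.call(rbind, lapply(seq_along(parts), function(i) {
    m <- parts[[i]]$membership
    data.frame(frame = frames[i], node = names(m), community = unname(m),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
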