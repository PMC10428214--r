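# Independent oracles and fixture builders. Everything here is deliberately
# brute-force and shares no code with the implementation it checks.

# Exhaustive shortest-path edge betweenness: enumerate every shortest path of
# every unordered node pair by BFS layering + recursive path expansion.
oracle_edge_betweenness <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  score <- stats::setNames(rep(0, nrow(edges)),
                           paste(pmin(edges[, 1], edges[, 2]),
                                 pmax(edges[, 1], edges[, 2]), sep = "|"))
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  bfs_dist <- function(s) {
    d <- stats::setNames(rep(Inf, length(nodes)), nodes)
    d[s] <- 0
    q <- s
    while (length(q) > 0L) {
      v <- q[1]; q <- q[-1]
      for (u in adj[[v]]) if (is.infinite(d[u])) { d[u] <- d[v] + 1; q <- c(q, u) }
    }
    d
  }
  all_paths <- function(d, t, s) {
    if (t == s) return(list(s))
    preds <- adj[[t]][d[adj[[t]]] == d[t] - 1]
    out <- list()
    for (p in preds) {
      for (pp in all_paths(d, p, s)) out <- c(out, list(c(pp, t)))
    }
    out
  }
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (j <= i) next
      s <- nodes[i]; t <- nodes[j]
      d <- bfs_dist(s)
      if (is.infinite(d[t])) next
      paths <- all_paths(d, t, s)
      w <- 1 / length(paths)
      for (p in paths) {
        for (k in seq_len(length(p) - 1L)) {
          key <- paste(min(p[k], p[k + 1]), max(p[k], p[k + 1]), sep = "|")
          score[key] <- score[key] + w
        }
      }
    }
  }
  score
}

random_test_graph <- function(n, p_edge, seed, connected = FALSE) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  repeat {
    keep <- stats::runif(nrow(pairs)) < p_edge
    if (connected) {
      # add a random spanning path to force connectivity
      perm <- sample(nodes)
      extra <- cbind(perm[-n], perm[-1])
      edges <- unique(rbind(pairs[keep, , drop = FALSE],
                            t(apply(extra, 1L, sort))))
    } else {
      edges <- pairs[keep, , drop = FALSE]
    }
    if (nrow(edges) >= 1L) return(residue_graph(nodes, edges))
  }
}

# direct geometric hydrogen-bond evaluation for one D/H/A triplet
oracle_hbond <- function(d, h, a, max_dist = 3.2, max_dev = 20) {
  da <- sqrt(sum((d - a)^2))
  v1 <- d - h; v2 <- a - h
  ang <- acos(min(1, max(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  (da <= max_dist) && ((180 - ang) <= max_dev)
}

# minimal hand-built structure: one row per atom
make_structure <- function(names, resnames, resseq, xyz, chain = "A",
                           element = NULL, is_het = FALSE) {
  n <- length(names)
  if (is.null(element)) element <- toupper(substr(names, 1, 1))
  mdlens:::new_structure(data.frame(
    serial = seq_len(n), name = names, altloc = "", residue_name = resnames,
    chain = rep_len(chain, n), residue_seq = resseq, icode = "",
    occupancy = 1, element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    is_het = rep_len(is_het, n), stringsAsFactors = FALSE
  ))
}

# 3*sigma sampling bound on the occupancy estimate of the planted two-state
# chain, using the effective sample size under lag-1 autocorrelation r
markov_occupancy_bound <- function(p, r, n) {
  n_eff <- n * (1 - r) / (1 + r)
  3 * sqrt(p * (1 - p) / n_eff)
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), nrow = 3, byrow = TRUE)
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# synthetic protein of `n_res` residues (CB beads, CA for the glycines) plus
# one HETATM ligand residue carrying atom C2, spread on a loose 3-D grid
make_protein_with_ligand <- function(n_res = 159L, gly_at = c(5L, 50L, 120L),
                                     ligand_name = "TMP") {
  k <- ceiling(n_res^(1 / 3))
  pos <- as.matrix(expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k)))[seq_len(n_res), ] * 4.0
  resn <- rep("ALA", n_res); resn[gly_at] <- "GLY"
  atom <- ifelse(resn == "GLY", "CA", "CB")
  prot <- data.frame(
    serial = seq_len(n_res), name = atom, altloc = "", residue_name = resn,
    chain = "A", residue_seq = seq_len(n_res), icode = "", occupancy = 1,
    element = "C", x = pos[, 1], y = pos[, 2], z = pos[, 3], is_het = FALSE,
    stringsAsFactors = FALSE
  )
  lig <- data.frame(
    serial = n_res + 1L, name = "C2", altloc = "", residue_name = ligand_name,
    chain = "A", residue_seq = n_res + 1L, icode = "", occupancy = 1,
    element = "C", x = mean(pos[, 1]), y = mean(pos[, 2]), z = mean(pos[, 3]) + 2,
    is_het = TRUE, stringsAsFactors = FALSE
  )
  mdlens:::new_structure(rbind(prot, lig))
}

# hand-built community partition from a membership vector
make_partition <- function(membership) {
  structure(list(membership = membership,
                 n_communities = length(unique(membership)),
                 removed_edges = matrix(character(0), ncol = 2)),
            class = "community_partition")
}
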