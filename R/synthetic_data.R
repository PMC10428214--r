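# Synthetic trajectory generators with planted ground truth.
#
# Each generator emits regular md_structure/md_trajectory objects carrying
# ordinary residue metadata (ALA residues with a CB bead by default), so every
# downstream selection, network and detector runs on them unchanged. All
# generators are deterministic given their seed.

#' Specification for a planted-community bead trajectory
#'
#' Beads are laid out as `n_blocks` compact cubic-grid clusters with bead
#' spacing `intra_contact_distance`, so each block is densely internally
#' connected (many parallel shortest paths). Consecutive clusters are
#' separated by `inter_block_separation` so that no direct inter-block
#' contact exists at typical network cutoffs; each gap receives `n_bridges`
#' donated bead pairs ~`bridge_distance` apart forming the only inter-block
#' contacts, which therefore carry maximal edge betweenness. Frames add
#' isotropic Gaussian jitter of standard deviation `jitter_sd` per
#' coordinate.
#'
#' @param n_blocks number of planted communities (>= 1).
#' @param block_sizes integer vector (recycled) of beads per block, all >= 3.
#' @param intra_contact_distance bead spacing within a block, Angstrom.
#' @param inter_block_separation gap between consecutive blocks, Angstrom.
#' @param n_bridges bridge pairs per adjacent-block gap.
#' @param bridge_distance separation of a bridge pair, Angstrom.
#' @param jitter_sd per-coordinate Gaussian jitter per frame, Angstrom.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return a `planted_community_spec` list.
#' @export
planted_community_spec <- function(n_blocks = 3L, block_sizes = 8L,
                                   intra_contact_distance = 5.0,
                                   inter_block_separation = 15.0,
                                   n_bridges = 1L, bridge_distance = 6.0,
                                   jitter_sd = 0.0, n_frames = 10L,
                                   seed = 1L) {
  block_sizes <- rep_len(as.integer(block_sizes), n_blocks)
  if (any(block_sizes < 3L)) stop("all block sizes must be >= 3")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (!(bridge_distance < inter_block_separation)) {
    stop("bridge_distance must be smaller than inter_block_separation")
  }
  if (n_blocks > 1L && n_bridges >= 1L &&
      any(block_sizes < 3L + 2L * n_bridges)) {
    stop("blocks too small to donate bridge beads; increase block_sizes")
  }
  structure(list(n_blocks = as.integer(n_blocks), block_sizes = block_sizes,
                 intra_contact_distance = intra_contact_distance,
                 inter_block_separation = inter_block_separation,
                 n_bridges = as.integer(n_bridges),
                 bridge_distance = bridge_distance,
                 jitter_sd = jitter_sd, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "planted_community_spec")
}

bead_structure <- function(xyz, residue_name = "ALA", atom_name = "CB",
                           chain = "A") {
  n <- nrow(xyz)
  new_structure(data.frame(
    serial = seq_len(n), name = atom_name, altloc = "",
    residue_name = residue_name, chain = chain, residue_seq = seq_len(n),
    icode = "", occupancy = 1, element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], is_het = FALSE,
    stringsAsFactors = FALSE
  ))
}

#' Generate a bead trajectory with planted community structure
#'
#' @param spec a [planted_community_spec()].
#' @return list with `trajectory` (an `md_trajectory`), `labels` (integer
#'   block label per bead) and `base_coords` (the jitter-free frame).
#' @export
make_planted_community_trajectory <- function(spec) {
  stopifnot(inherits(spec, "planted_community_spec"))
  d <- spec$intra_contact_distance
  gap <- spec$inter_block_separation
  nb <- spec$n_bridges
  # Each block core is a compact cubic-grid cluster (spacing d), giving dense
  # internal connectivity with many parallel shortest paths, so inter-block
  # bridge edges dominate the edge betweenness. Consecutive clusters are
  # separated by `gap` along x; bridge beads donated by the flanking blocks
  # sit inside the gap, chained along y at 4 A spacing, each within contact
  # range of its own cluster, while only the n_bridges A-B pairs cross.
  donated <- rep.int(0L, spec$n_blocks)
  if (spec$n_blocks > 1L && nb > 0L) {
    donated <- rep.int(2L * nb, spec$n_blocks)
    donated[c(1L, spec$n_blocks)] <- nb
  }
  core_sizes <- spec$block_sizes - donated
  grid_cluster <- function(n) {
    # x-layers of a k x k grid, filled y-fastest; layer sizes balanced so the
    # first and last layer always hold >= 2 beads, giving every bridge bead
    # two anchor contacts on the cluster face
    k <- ceiling(n^(1 / 3))
    n_layers <- ceiling(n / (k * k))
    sz <- rep.int(n %/% n_layers, n_layers)
    if (n %% n_layers > 0L) sz[seq_len(n %% n_layers)] <- sz[1L] + 1L
    do.call(rbind, lapply(seq_len(n_layers), function(l) {
      j <- seq_len(sz[l]) - 1L
      cbind(x = (l - 1L), y = j %% k, z = j %/% k) * d
    }))
  }
  xyz <- NULL
  labels <- integer(0)
  core_end <- numeric(spec$n_blocks)
  x0 <- 0
  for (b in seq_len(spec$n_blocks)) {
    cl <- grid_cluster(core_sizes[b])
    cl[, 1] <- cl[, 1] + x0
    xyz <- rbind(xyz, cl)
    labels <- c(labels, rep.int(b, core_sizes[b]))
    core_end[b] <- max(cl[, 1])
    x0 <- core_end[b] + gap
  }
  if (spec$n_blocks > 1L && nb > 0L) {
    half <- (gap - spec$bridge_distance) / 2
    for (b in seq_len(spec$n_blocks - 1L)) {
      e <- core_end[b]
      for (k in seq_len(nb)) {
        yk <- d / 2 + (k - 1L) * 4.0   # straddles the two face anchors
        xyz <- rbind(xyz, c(e + half, yk, 0), c(e + half + spec$bridge_distance, yk, 0))
        labels <- c(labels, b, b + 1L)
      }
    }
  }
  # reorder beads so labels are grouped by block (stable residue numbering)
  ord <- order(labels, seq_along(labels))
  xyz <- xyz[ord, , drop = FALSE]
  labels <- labels[ord]
  base <- unname(as.matrix(xyz))
  set.seed(spec$seed)
  frames <- lapply(seq_len(spec$n_frames), function(i) {
    base + matrix(stats::rnorm(length(base), sd = spec$jitter_sd),
                  ncol = 3L)
  })
  traj <- new_trajectory(bead_structure(base), frames,
                         frame_times = NULL)
  list(trajectory = traj, labels = labels, base_coords = base)
}

# ---------------------------------------------------------------------------

#' Specification for a two-state hydrogen-bond trajectory
#'
#' Each donor-hydrogen-acceptor triplet switches between a bonded geometry
#' (collinear D-H...A, D-A = `bonded_distance`) and a broken one
#' (D-A = `broken_distance`) following a two-state Markov chain whose
#' stationary bonded probability equals `occupancy`. `mean_dwell` is the mean
#' dwell time of the bonded state in frames; the broken-state dwell is derived
#' from the stationary occupancy.
#'
#' @param n_triplets number of independent triplets.
#' @param occupancy target occupancy per triplet (recycled), in `[0, 1]`.
#' @param mean_dwell mean bonded dwell, frames (>= 1).
#' @param bonded_distance,broken_distance donor-acceptor heavy-atom
#'   distances, Angstrom (`bonded < 3.2 < broken`).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return an `hbond_series_spec` list.
#' @export
hbond_series_spec <- function(n_triplets = 1L, occupancy = 0.5,
                              mean_dwell = 10, bonded_distance = 2.9,
                              broken_distance = 4.5, n_frames = 500L,
                              seed = 1L) {
  occupancy <- rep_len(occupancy, n_triplets)
  if (any(occupancy < 0 | occupancy > 1)) stop("occupancies must lie in [0, 1]")
  if (mean_dwell < 1) stop("mean_dwell must be at least 1 frame")
  if (!(bonded_distance < 3.2 && 3.2 < broken_distance)) {
    stop("need bonded_distance < 3.2 < broken_distance")
  }
  structure(list(n_triplets = as.integer(n_triplets), occupancy = occupancy,
                 mean_dwell = mean_dwell, bonded_distance = bonded_distance,
                 broken_distance = broken_distance,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "hbond_series_spec")
}

simulate_two_state <- function(p, mean_dwell, n) {
  if (p <= 0) return(rep.int(0L, n))
  if (p >= 1) return(rep.int(1L, n))
  # bonded dwell geometric with mean d_b => exit prob 1/d_b;
  # broken dwell d_u = d_b (1-p)/p so the stationary bonded fraction is p
  p_exit_b <- min(1, 1 / mean_dwell)
  d_u <- mean_dwell * (1 - p) / p
  p_exit_u <- min(1, 1 / d_u)
  s <- integer(n)
  s[1] <- as.integer(stats::runif(1) < p)
  for (t in seq_len(n - 1L)) {
    flip <- stats::runif(1) < (if (s[t] == 1L) p_exit_b else p_exit_u)
    s[t + 1L] <- if (flip) 1L - s[t] else s[t]
  }
  s
}

#' Lag-1 autocorrelation of the planted two-state chain
#'
#' Used to form an effective sample size `n * (1 - r) / (1 + r)` for sampling
#' bounds on recovered occupancies.
#'
#' @param spec an [hbond_series_spec()].
#' @param which triplet index.
#' @return numeric autocorrelation (the chain's second eigenvalue).
#' @export
hbond_chain_autocorrelation <- function(spec, which = 1L) {
  p <- spec$occupancy[which]
  if (p <= 0 || p >= 1) return(0)
  p_exit_b <- min(1, 1 / spec$mean_dwell)
  d_u <- spec$mean_dwell * (1 - p) / p
  p_exit_u <- min(1, 1 / d_u)
  1 - p_exit_b - p_exit_u
}

#' Generate a trajectory of switching hydrogen-bond triplets
#'
#' Triplets are laid out 50 Angstrom apart so no cross-triplet bond can form.
#' The donor residue carries atoms `N` and `H`; the acceptor residue carries
#' atom `O`. In the bonded state the geometry is exactly collinear with
#' D-A = `bonded_distance`; in the broken state the acceptor moves out to
#' `broken_distance`.
#'
#' @param spec an [hbond_series_spec()].
#' @return list with `trajectory`, `occupancy` (true per-triplet stationary
#'   occupancy), `states` (`n_frames x n_triplets` 0/1 matrix) and `keys`
#'   (the `donor->acceptor` key each triplet produces when bonded).
#' @export
make_hbond_trajectory <- function(spec) {
  stopifnot(inherits(spec, "hbond_series_spec"))
  k <- spec$n_triplets
  atoms <- do.call(rbind, lapply(seq_len(k), function(i) {
    ox <- (i - 1L) * 50.0
    data.frame(
      serial = (i - 1L) * 3L + 1:3,
      name = c("N", "H", "O"), altloc = "",
      residue_name = "ALA", chain = "A",
      residue_seq = c(2L * i - 1L, 2L * i - 1L, 2L * i),
      icode = "", occupancy = 1,
      element = c("N", "H", "O"),
      x = c(ox, ox + 1.0, ox + spec$bonded_distance),
      y = 0, z = 0, is_het = FALSE, stringsAsFactors = FALSE
    )
  }))
  topo <- new_structure(atoms)
  set.seed(spec$seed)
  states <- vapply(seq_len(k), function(i) {
    simulate_two_state(spec$occupancy[i], spec$mean_dwell, spec$n_frames)
  }, integer(spec$n_frames))
  states <- matrix(states, nrow = spec$n_frames, ncol = k)
  base <- coords(topo)
  frames <- lapply(seq_len(spec$n_frames), function(t) {
    f <- base
    broken <- which(states[t, ] == 0L)
    # move the acceptor O out along +x in broken frames
    f[(broken - 1L) * 3L + 3L, 1] <-
      (broken - 1L) * 50.0 + spec$broken_distance
    f
  })
  keys <- sprintf("A:%d:ALA:N->A:%d:ALA:O", 2L * seq_len(k) - 1L, 2L * seq_len(k))
  list(trajectory = new_trajectory(topo, frames),
       occupancy = spec$occupancy, states = states, keys = keys)
}

# ---------------------------------------------------------------------------

#' Generate a trajectory of atoms with planted displacement correlations
#'
#' Atom `i` is displaced along `modes[i, ]` (a unit 3-vector) by amplitude
#' `a_i(t)`, where the amplitude vectors are i.i.d. multivariate normal with
#' the given covariance. The cross-correlation of atoms `i` and `j`
#' converges to `cov[i,j] * (modes_i . modes_j) / sqrt(cov[i,i] cov[j,j])`.
#'
#' @param covariance `k x k` symmetric positive-semidefinite matrix of
#'   amplitude covariances (Angstrom^2).
#' @param modes optional `k x 3` matrix of unit displacement directions
#'   (default: all along x, giving correlation = normalized covariance).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param spacing bead spacing, Angstrom (default 50, avoids contacts).
#' @return an `md_trajectory` of `k` CB beads.
#' @export
make_correlated_trajectory <- function(covariance, modes = NULL,
                                       n_frames = 1000L, seed = 1L,
                                       spacing = 50.0) {
  covariance <- as.matrix(covariance)
  k <- nrow(covariance)
  stopifnot(ncol(covariance) == k)
  if (max(abs(covariance - t(covariance))) > 1e-10) {
    stop("covariance must be symmetric")
  }
  ev <- eigen(covariance, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values))) {
    stop("covariance must be positive semidefinite")
  }
  if (is.null(modes)) modes <- matrix(rep(c(1, 0, 0), each = k), ncol = 3L)
  stopifnot(nrow(modes) == k, ncol(modes) == 3L)
  root <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  base <- cbind((seq_len(k) - 1L) * spacing, 0, 0)
  set.seed(seed)
  amp <- matrix(stats::rnorm(n_frames * k), nrow = n_frames) %*% root
  frames <- lapply(seq_len(n_frames), function(t) base + amp[t, ] * modes)
  new_trajectory(bead_structure(base), frames)
}

# ---------------------------------------------------------------------------

#' Specification for Crooks-consistent Gaussian work samples
#'
#' Forward and backward potential-energy differences are drawn from Gaussians
#' obeying the Crooks fluctuation relation: forward mean
#' `true_dF + sigma^2 / (2RT)` and backward mean `-true_dF + sigma^2 / (2RT)`
#' with common standard deviation `work_sd`, so Zwanzig, BAR and MBAR all
#' converge to the analytic `true_dF`.
#'
#' @param true_dF analytic free-energy difference, kcal/mol.
#' @param work_sd standard deviation of the work distributions, kcal/mol (> 0).
#' @param temperature Kelvin.
#' @param n_forward,n_backward sample counts (>= 2).
#' @param seed RNG seed.
#' @return a `gaussian_work_spec` list.
#' @export
gaussian_work_spec <- function(true_dF = -3.0, work_sd = 1.0,
                               temperature = 300, n_forward = 1000L,
                               n_backward = 1000L, seed = 1L) {
  if (work_sd <= 0) stop("work_sd must be > 0")
  if (n_forward < 2L || n_backward < 2L) stop("need >= 2 samples per direction")
  structure(list(true_dF = true_dF, work_sd = work_sd,
                 temperature = temperature,
                 n_forward = as.integer(n_forward),
                 n_backward = as.integer(n_backward), seed = as.integer(seed)),
            class = "gaussian_work_spec")
}

#' Draw Crooks-consistent Gaussian FEP samples
#'
#' @param spec a [gaussian_work_spec()].
#' @return an object of class `fep_samples`: list with `forward`, `backward`
#'   (kcal/mol), `temperature` and `true_dF`.
#' @export
make_fep_samples <- function(spec) {
  stopifnot(inherits(spec, "gaussian_work_spec"))
  rt <- GAS_CONSTANT_KCAL * spec$temperature
  shift <- spec$work_sd^2 / (2 * rt)
  set.seed(spec$seed)
  fwd <- stats::rnorm(spec$n_forward, mean = spec$true_dF + shift,
                      sd = spec$work_sd)
  bwd <- stats::rnorm(spec$n_backward, mean = -spec$true_dF + shift,
                      sd = spec$work_sd)
  structure(list(forward = fwd, backward = bwd,
                 temperature = spec$temperature, true_dF = spec$true_dF),
            class = "fep_samples")
}
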