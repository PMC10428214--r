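# Superposition-based motion statistics: Kabsch alignment, RMSD time series,
# per-node RMSF and the normalized dynamic cross-correlation map (DCCM).

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares proper rotation and translation mapping `mobile` onto
#' `reference`; reflections are prevented by the usual determinant sign
#' correction on the smallest singular vector.
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`.
#' @return a `superposition` list: `rotation` (3x3, det +1), `translation`
#'   (length-3), `rmsd` (Angstrom), and `transform(x)` applying the fit.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference))
  if (nrow(mobile) < 3L) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  a <- sweep(mobile, 2L, cm); b <- sweep(reference, 2L, cr)
  h <- t(a) %*% b
  sv <- svd(h)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300)) {
    stop("degenerate point set (collinear or coincident); superposition undefined")
  }
  s <- sign(det(sv$v %*% t(sv$u)))
  d <- diag(c(1, 1, s))
  rot <- sv$v %*% d %*% t(sv$u)
  fitted <- a %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - b)^2)))
  trans <- cr - as.vector(rot %*% cm)
  structure(list(rotation = rot, translation = trans, rmsd = rmsd,
                 transform = function(x) sweep(as.matrix(x) %*% t(rot), 2L,
                                               trans, "+")),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

resolve_selection <- function(traj, selection) {
  idx <- if (is.null(selection)) {
    sel <- select_atoms(traj$topology, list(network_node = TRUE))
    if (length(sel) == 0L) seq_len(n_atoms(traj$topology)) else sel
  } else if (is.numeric(selection)) {
    as.integer(selection)
  } else {
    select_atoms(traj$topology, selection)
  }
  if (length(idx) == 0L) stop("empty atom selection")
  idx
}

#' Per-frame RMSD to a reference frame
#'
#' Each frame is superposed onto the reference over the selection and the
#' RMSD is reported over the same selection.
#'
#' @param traj an `md_trajectory`.
#' @param reference_frame frame index used as reference (default 1).
#' @param selection `NULL` (network-node atoms, falling back to all atoms),
#'   an integer index vector, or a [select_atoms()] spec list.
#' @return numeric vector of per-frame RMSD, Angstrom.
#' @export
rmsd_series <- function(traj, reference_frame = 1L, selection = NULL) {
  idx <- resolve_selection(traj, selection)
  ref <- frame_coords(traj, reference_frame)[idx, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(i) {
    kabsch_superpose(frame_coords(traj, i)[idx, , drop = FALSE], ref)$rmsd
  }, numeric(1))
}

aligned_selection_coords <- function(traj, idx, superpose = TRUE) {
  nf <- n_frames(traj)
  xs <- lapply(seq_len(nf), function(i) frame_coords(traj, i)[idx, , drop = FALSE])
  if (!superpose) return(xs)
  # two-pass: align everything to frame 1, take the mean, re-align to the mean
  ref <- xs[[1]]
  once <- lapply(xs, function(x) kabsch_superpose(x, ref)$transform(x))
  mean1 <- Reduce(`+`, once) / nf
  lapply(xs, function(x) kabsch_superpose(x, mean1)$transform(x))
}

#' Per-node root-mean-square fluctuation
#'
#' Frames are superposed onto the mean structure (align to frame 1, average,
#' re-align to the mean), then
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)`. With `superpose = FALSE` the
#' raw frames are used (for absolute-frame motions). `n_blocks > 1` returns
#' the mean of per-block RMSF over contiguous equal chunks.
#'
#' @param traj an `md_trajectory` with >= 2 frames.
#' @param selection as in [rmsd_series()].
#' @param superpose align frames before measuring (default TRUE).
#' @param n_blocks number of contiguous blocks to average over (default 1).
#' @return named numeric vector of per-node RMSF, Angstrom.
#' @export
rmsf <- function(traj, selection = NULL, superpose = TRUE, n_blocks = 1L) {
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  idx <- resolve_selection(traj, selection)
  rmsf_of <- function(xs) {
    m <- Reduce(`+`, xs) / length(xs)
    sq <- Reduce(`+`, lapply(xs, function(x) rowSums((x - m)^2))) / length(xs)
    sqrt(sq)
  }
  xs <- aligned_selection_coords(traj, idx, superpose)
  out <- if (n_blocks <= 1L) {
    rmsf_of(xs)
  } else {
    nf <- length(xs)
    base <- floor(nf / n_blocks)
    if (base < 2L) stop("blocks need at least 2 frames each")
    block_of <- pmin(ceiling(seq_len(nf) / base), n_blocks)
    vals <- vapply(seq_len(n_blocks),
                   function(b) rmsf_of(xs[block_of == b]),
                   numeric(length(idx)))
    rowMeans(vals)
  }
  stats::setNames(out, node_labels_or_index(traj$topology, idx))
}

node_labels_or_index <- function(topology, idx) {
  tryCatch(node_labels(topology, idx), error = function(e) as.character(idx))
}

#' Dynamic cross-correlation map
#'
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` with `dr` the
#' displacement from each node's mean position after superposition onto the
#' mean structure.
#'
#' @param traj an `md_trajectory` with >= 2 frames.
#' @param selection as in [rmsd_series()].
#' @param superpose align frames first (default TRUE).
#' @return symmetric `correlation_matrix` (plain matrix with unit diagonal),
#'   dimnames = node labels.
#' @export
dccm <- function(traj, selection = NULL, superpose = TRUE) {
  if (n_frames(traj) < 2L) stop("DCCM needs at least 2 frames")
  idx <- resolve_selection(traj, selection)
  xs <- aligned_selection_coords(traj, idx, superpose)
  nf <- length(xs)
  m <- Reduce(`+`, xs) / nf
  dx <- lapply(xs, function(x) x - m)
  n <- length(idx)
  cov_ij <- matrix(0, n, n)
  for (t in seq_len(nf)) cov_ij <- cov_ij + dx[[t]] %*% t(dx[[t]])
  cov_ij <- cov_ij / nf
  v <- diag(cov_ij)
  zero <- which(v <= 0 | v < 1e-300)
  if (length(zero) > 0L) {
    labs <- node_labels_or_index(traj$topology, idx)
    stop("zero-variance node(s) make the DCCM undefined: ",
         paste(labs[zero], collapse = ", "))
  }
  cc <- cov_ij / sqrt(outer(v, v))
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  cc[cc > 1] <- 1; cc[cc < -1] <- -1
  labs <- node_labels_or_index(traj$topology, idx)
  dimnames(cc) <- list(labs, labs)
  cc
}
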