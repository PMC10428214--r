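# Hydrogen-bond detection, occupancies and occupancy-difference fingerprints.
#
# A hydrogen bond is reported between a donor heavy atom D (N or O carrying at
# least one covalent hydrogen, assigned by a 1.2 A distance rule) and an
# acceptor heavy atom A (N or O in a different residue) when the D-A distance
# is at most `max_da_distance` and, for at least one hydrogen on D, the
# D-H...A angle deviates from linearity by at most `max_angle_deviation`.

#' Hydrogen-bond geometric criteria
#'
#' @param max_da_distance donor-acceptor heavy-atom distance cutoff,
#'   Angstrom (default 3.2).
#' @param max_angle_deviation allowed deviation from a linear D-H...A
#'   arrangement, degrees (default 20).
#' @param equilibration_discard initial trajectory time discarded before
#'   computing occupancies, ns (default 10; applied only when the trajectory
#'   carries frame times).
#' @param angle_convention `"dha_linearity"` (default: angle at the hydrogen,
#'   deviation from 180 degrees) or `"da_dh"` (angle between the D->H and
#'   D->A vectors, must be at most `max_angle_deviation`).
#' @return an `hbond_criteria` list.
#' @export
hbond_criteria <- function(max_da_distance = 3.2, max_angle_deviation = 20,
                           equilibration_discard = 10,
                           angle_convention = c("dha_linearity", "da_dh")) {
  if (max_da_distance <= 0) stop("max_da_distance must be positive")
  if (max_angle_deviation <= 0 || max_angle_deviation > 90) {
    stop("max_angle_deviation must lie in (0, 90]")
  }
  structure(list(max_da_distance = max_da_distance,
                 max_angle_deviation = max_angle_deviation,
                 equilibration_discard = equilibration_discard,
                 angle_convention = match.arg(angle_convention)),
            class = "hbond_criteria")
}

#' Fingerprint selection thresholds
#'
#' @param min_abs_difference minimum absolute occupancy change, percentage
#'   points (default 20).
#' @param sigma_multiplier_select a change must exceed this multiple of the
#'   standard deviation of all changes (default 3).
#' @param sigma_multiplier_stability the per-chunk change estimates must
#'   fluctuate by less than this multiple of sigma (default 2).
#' @param n_chunks number of contiguous trajectory chunks used for the
#'   stability estimate (default 5).
#' @return a `fingerprint_config` list.
#' @export
fingerprint_config <- function(min_abs_difference = 20,
                               sigma_multiplier_select = 3,
                               sigma_multiplier_stability = 2,
                               n_chunks = 5L) {
  stopifnot(min_abs_difference > 0, sigma_multiplier_select > 0,
            sigma_multiplier_stability > 0, n_chunks >= 1L)
  structure(list(min_abs_difference = min_abs_difference,
                 sigma_multiplier_select = sigma_multiplier_select,
                 sigma_multiplier_stability = sigma_multiplier_stability,
                 n_chunks = as.integer(n_chunks)),
            class = "fingerprint_config")
}

atom_key <- function(atoms, idx) {
  paste0(residue_uid(atoms$chain[idx], atoms$residue_seq[idx], atoms$icode[idx]),
         ":", atoms$residue_name[idx], ":", atoms$name[idx])
}

# donor/acceptor bookkeeping shared across frames of one topology
hbond_topology_info <- function(topology) {
  a <- topology$atoms
  heavy_na_o <- which(a$element %in% c("N", "O"))
  hydrogens <- which(a$element == "H")
  if (length(hydrogens) == 0L) {
    stop("topology contains no hydrogens; hydrogen-bond detection requires ",
         "explicit hydrogens (inferred-hydrogen mode is not supported)")
  }
  list(heavy = heavy_na_o, hydrogens = hydrogens,
       res_uid = residue_uid(a$chain, a$residue_seq, a$icode),
       keys = vapply(seq_len(nrow(a)), function(i) atom_key(a, i), character(1)))
}

#' Detect hydrogen bonds in a single frame
#'
#' @param frame `n_atoms x 3` coordinate matrix.
#' @param topology the `md_structure` shared by the trajectory.
#' @param criteria an [hbond_criteria()].
#' @return character vector of bond keys `"donor->acceptor"`, where each side
#'   is `chain:resseq:resname:atomname`; sorted, unique.
#' @export
detect_hbonds_frame <- function(frame, topology, criteria = hbond_criteria()) {
  info <- hbond_topology_info(topology)
  detect_hbonds_frame_impl(frame, info, criteria)
}

detect_hbonds_frame_impl <- function(frame, info, criteria) {
  heavy <- info$heavy
  hyd <- info$hydrogens
  if (length(heavy) < 2L) return(character(0))
  hx <- frame[hyd, , drop = FALSE]
  px <- frame[heavy, , drop = FALSE]
  # covalent assignment: each hydrogen belongs to the nearest N/O within 1.2 A
  d_hp <- outer(rowSums(hx^2), rowSums(px^2), "+") - 2 * hx %*% t(px)
  d_hp[d_hp < 0] <- 0
  d_hp <- sqrt(d_hp)
  parent <- apply(d_hp, 1L, which.min)
  attached <- d_hp[cbind(seq_along(hyd), parent)] <= 1.2
  donors_idx <- unique(parent[attached])      # positions within `heavy`
  if (length(donors_idx) == 0L) return(character(0))
  dd <- px[donors_idx, , drop = FALSE]
  d_da <- outer(rowSums(dd^2), rowSums(px^2), "+") - 2 * dd %*% t(px)
  d_da[d_da < 0] <- 0
  d_da <- sqrt(d_da)
  out <- character(0)
  for (di in seq_along(donors_idx)) {
    d_heavy <- donors_idx[di]
    d_atom <- heavy[d_heavy]
    cand <- which(d_da[di, ] <= criteria$max_da_distance)
    cand <- cand[heavy[cand] != d_atom &
                   info$res_uid[heavy[cand]] != info$res_uid[d_atom]]
    if (length(cand) == 0L) next
    hs <- which(attached & parent == d_heavy)
    for (ai in cand) {
      a_atom <- heavy[ai]
      ok <- FALSE
      for (h in hs) {
        if (criteria$angle_convention == "dha_linearity") {
          v1 <- frame[d_atom, ] - hx[h, ]
          v2 <- frame[a_atom, ] - hx[h, ]
        } else {
          v1 <- hx[h, ] - frame[d_atom, ]
          v2 <- frame[a_atom, ] - frame[d_atom, ]
        }
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        dev <- if (criteria$angle_convention == "dha_linearity") 180 - ang else ang
        if (dev <= criteria$max_angle_deviation) { ok <- TRUE; break }
      }
      if (ok) out <- c(out, paste0(info$keys[d_atom], "->", info$keys[a_atom]))
    }
  }
  sort(unique(out))
}

analysis_frames <- function(traj, criteria) {
  nf <- n_frames(traj)
  if (!is.null(traj$frame_times) && !is.null(criteria$equilibration_discard) &&
      criteria$equilibration_discard > 0) {
    keep <- which(traj$frame_times > criteria$equilibration_discard)
    if (length(keep) == 0L) stop("no frames remain after equilibration discard")
    return(keep)
  }
  seq_len(nf)
}

#' Hydrogen-bond occupancy table of a trajectory
#'
#' Occupancy of a bond is the fraction of analyzed frames in which it
#' satisfies the geometric criteria. Frames are additionally split into
#' `n_chunks` contiguous chunks (equal sizes; remainder frames go to the last
#' chunk) and per-chunk occupancies are recorded for stability estimates.
#'
#' @param traj an `md_trajectory` with explicit hydrogens.
#' @param criteria an [hbond_criteria()].
#' @param n_chunks number of chunks (default 5).
#' @return an `occupancy_table`: list with `occupancy` (named numeric),
#'   `chunk_occupancy` (matrix, bonds x chunks), `n_frames`, `n_chunks`.
#' @export
occupancy_table <- function(traj, criteria = hbond_criteria(), n_chunks = 5L) {
  frames <- analysis_frames(traj, criteria)
  nf <- length(frames)
  if (nf < n_chunks) stop("fewer analyzed frames than chunks")
  info <- hbond_topology_info(traj$topology)
  per_frame <- lapply(frames, function(i) {
    detect_hbonds_frame_impl(frame_coords(traj, i), info, criteria)
  })
  keys <- sort(unique(unlist(per_frame)))
  base <- floor(nf / n_chunks)
  chunk_of <- pmin(ceiling(seq_len(nf) / base), n_chunks)
  occ <- stats::setNames(numeric(length(keys)), keys)
  chunk_occ <- matrix(0, nrow = length(keys), ncol = n_chunks,
                      dimnames = list(keys, NULL))
  if (length(keys) > 0L) {
    for (t in seq_len(nf)) {
      hit <- per_frame[[t]]
      if (length(hit) > 0L) {
        occ[hit] <- occ[hit] + 1
        chunk_occ[hit, chunk_of[t]] <- chunk_occ[hit, chunk_of[t]] + 1
      }
    }
    occ <- occ / nf
    chunk_occ <- sweep(chunk_occ, 2L, tabulate(chunk_of, n_chunks), "/")
  }
  structure(list(occupancy = occ, chunk_occupancy = chunk_occ,
                 n_frames = nf, n_chunks = as.integer(n_chunks),
                 chunk_sizes = tabulate(chunk_of, n_chunks)),
            class = "occupancy_table")
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat(sprintf("<occupancy_table> %d bond(s) over %d frames in %d chunks\n",
              length(x$occupancy), x$n_frames, x$n_chunks))
  invisible(x)
}

#' Per-frame residue contact barcode
#'
#' For each frame, 1 when at least one hydrogen bond (either direction) exists
#' between any atom of the two residues, else 0. Multiple simultaneous bonds
#' in one frame still score 1.
#'
#' @param traj an `md_trajectory`.
#' @param residue_uid_a,residue_uid_b residue identifiers `"chain:seq"` (with
#'   insertion code appended when present).
#' @param criteria an [hbond_criteria()].
#' @return integer 0/1 vector over analyzed frames.
#' @export
residue_contact_barcode <- function(traj, residue_uid_a, residue_uid_b,
                                    criteria = hbond_criteria()) {
  uids <- residues(traj)$uid
  for (u in c(residue_uid_a, residue_uid_b)) {
    if (!(u %in% uids)) stop("unknown residue id: ", u)
  }
  info <- hbond_topology_info(traj$topology)
  frames <- analysis_frames(traj, criteria)
  atoms <- traj$topology$atoms
  uid_of_key <- function(keys) {
    # bond key format chain:seq[:icode]:resname:atom -> residue uid is field 1:2
    vapply(strsplit(keys, ":", fixed = TRUE),
           function(p) paste(p[1:2], collapse = ":"), character(1))
  }
  vapply(frames, function(i) {
    bonds <- detect_hbonds_frame_impl(frame_coords(traj, i), info, criteria)
    if (length(bonds) == 0L) return(0L)
    sides <- strsplit(bonds, "->", fixed = TRUE)
    don <- uid_of_key(vapply(sides, `[`, character(1), 1L))
    acc <- uid_of_key(vapply(sides, `[`, character(1), 2L))
    hit <- (don == residue_uid_a & acc == residue_uid_b) |
      (don == residue_uid_b & acc == residue_uid_a)
    as.integer(any(hit))
  }, integer(1))
}

#' Occupancy-difference fingerprint between two systems
#'
#' Differences are `alternate - reference` in percentage points per bond
#' (bonds absent from one table count as occupancy 0). With `sigma` the
#' standard deviation of all differences, a bond is selected when
#' `|delta| >= min_abs_difference`, `|delta| > sigma_multiplier_select * sigma`
#' and the standard deviation of its per-chunk differences is below
#' `sigma_multiplier_stability * sigma`.
#'
#' @param reference,alternate [occupancy_table()] objects built with the same
#'   criteria and chunk count.
#' @param config a [fingerprint_config()].
#' @return data.frame sorted by `|delta|` descending (ties: bond key) with
#'   columns `bond`, `delta` (points), `chunk_sd` (points), `selected`,
#'   `direction` (`"increase"`/`"decrease"`), plus attribute `sigma`.
#' @export
occupancy_fingerprint <- function(reference, alternate,
                                  config = fingerprint_config()) {
  stopifnot(inherits(reference, "occupancy_table"),
            inherits(alternate, "occupancy_table"))
  if (reference$n_chunks != alternate$n_chunks) {
    stop("chunk-count mismatch between tables")
  }
  keys <- sort(union(names(reference$occupancy), names(alternate$occupancy)))
  get_occ <- function(tab, keys) {
    out <- stats::setNames(numeric(length(keys)), keys)
    hit <- intersect(keys, names(tab$occupancy))
    out[hit] <- tab$occupancy[hit]
    out
  }
  get_chunks <- function(tab, keys) {
    out <- matrix(0, nrow = length(keys), ncol = tab$n_chunks,
                  dimnames = list(keys, NULL))
    hit <- intersect(keys, rownames(tab$chunk_occupancy))
    out[hit, ] <- tab$chunk_occupancy[hit, , drop = FALSE]
    out
  }
  delta <- 100 * (get_occ(alternate, keys) - get_occ(reference, keys))
  chunk_delta <- 100 * (get_chunks(alternate, keys) - get_chunks(reference, keys))
  sigma <- if (length(delta) > 1L) stats::sd(delta) else 0
  chunk_sd <- if (length(keys) > 0L) apply(chunk_delta, 1L, stats::sd) else numeric(0)
  selected <- abs(delta) >= config$min_abs_difference &
    abs(delta) > config$sigma_multiplier_select * sigma &
    chunk_sd < config$sigma_multiplier_stability * sigma
  out <- data.frame(bond = keys, delta = unname(delta),
                    chunk_sd = unname(chunk_sd), selected = unname(selected),
                    direction = ifelse(delta >= 0, "increase", "decrease"),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$delta), out$bond), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sigma") <- sigma
  out
}

#' Write an occupancy table as TSV
#' @param tab an [occupancy_table()] result.
#' @param path output file.
#' @export
write_occupancy_tsv <- function(tab, path) {
  df <- data.frame(bond = names(tab$occupancy), occupancy = unname(tab$occupancy),
                   stringsAsFactors = FALSE)
  ch <- as.data.frame(tab$chunk_occupancy)
  names(ch) <- paste0("chunk", seq_len(ncol(ch)))
  df <- cbind(df, ch)
  rownames(df) <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_frames=%d n_chunks=%d", tab$n_frames, tab$n_chunks), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an occupancy table written by [write_occupancy_tsv()]
#' @param path TSV file.
#' @export
read_occupancy_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- regmatches(header, gregexpr("[0-9]+", header))[[1]]
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  chunk_cols <- grep("^chunk", names(df))
  chunk <- as.matrix(df[, chunk_cols, drop = FALSE])
  dimnames(chunk) <- list(df$bond, NULL)
  structure(list(occupancy = stats::setNames(df$occupancy, df$bond),
                 chunk_occupancy = chunk,
                 n_frames = as.integer(meta[1]), n_chunks = as.integer(meta[2]),
                 chunk_sizes = NULL),
            class = "occupancy_table")
}
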