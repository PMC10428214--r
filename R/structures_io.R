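# Fixed-column PDB structure / multi-model trajectory I/O and atom selection.
#
# No R PDB reader ships with the supported environment, so the parser is
# implemented here against the PDB v3.3 fixed-column layout for ATOM/HETATM
# and MODEL/ENDMDL records. Residue numbering is preserved exactly as printed
# in the file (crystal-structure numbering); insertion codes are part of the
# residue identity.

#' Construct a structure object
#'
#' @param atoms data.frame with columns `serial`, `name`, `altloc`,
#'   `residue_name`, `chain`, `residue_seq`, `icode`, `occupancy`, `element`,
#'   `x`, `y`, `z`, `is_het`.
#' @return object of class `md_structure`.
#' @keywords internal
new_structure <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms) > 0L) {
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
      stop("all atom coordinates must be finite")
    }
    if (any(!nzchar(atoms$name))) stop("atom names must be non-empty")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "md_structure")
}

#' Number of atoms in a structure
#' @param x an `md_structure`.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "md_trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' Residue table of a structure
#'
#' One row per residue in file order: `chain`, `residue_seq`, `icode`,
#' `residue_name`, `is_het`, plus a unique `uid` string.
#'
#' @param x an `md_structure` or `md_trajectory`.
#' @return data.frame.
#' @export
residues <- function(x) {
  if (inherits(x, "md_trajectory")) x <- x$topology
  a <- x$atoms
  uid <- residue_uid(a$chain, a$residue_seq, a$icode)
  keep <- !duplicated(uid)
  data.frame(
    chain = a$chain[keep], residue_seq = a$residue_seq[keep],
    icode = a$icode[keep], residue_name = a$residue_name[keep],
    is_het = a$is_het[keep], uid = uid[keep],
    stringsAsFactors = FALSE
  )
}

residue_uid <- function(chain, seq, icode) {
  paste0(chain, ":", seq, ifelse(nzchar(icode), icode, ""))
}

#' Coordinates of one structure as an n x 3 matrix
#' @param x an `md_structure`.
#' @export
coords <- function(x) {
  cbind(x = x$atoms$x, y = x$atoms$y, z = x$atoms$z)
}

#' @export
print.md_structure <- function(x, ...) {
  r <- residues(x)
  cat(sprintf(
    "<md_structure> %d atoms, %d residues (%d HETATM ligand-candidate residue(s))\n",
    n_atoms(x), nrow(r), sum(r$is_het & !(r$residue_name %in% SOLVENT_RESNAMES))
  ))
  invisible(x)
}

#' Construct a trajectory object
#'
#' @param topology an `md_structure` shared by all frames.
#' @param frames list of `n_atoms x 3` coordinate matrices (Angstrom).
#' @param frame_times optional numeric vector of frame times in ns,
#'   strictly increasing.
#' @return object of class `md_trajectory` with fields `topology`,
#'   `coords` (array `n_atoms x 3 x n_frames`) and `frame_times`.
#' @export
new_trajectory <- function(topology, frames, frame_times = NULL) {
  stopifnot(inherits(topology, "md_structure"))
  if (length(frames) == 0L) stop("a trajectory needs at least one frame")
  na <- n_atoms(topology)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || nrow(f) != na || ncol(f) != 3L) {
      stop(sprintf("frame %d does not have %d x 3 coordinates", i, na))
    }
  }
  if (!is.null(frame_times)) {
    if (length(frame_times) != length(frames)) {
      stop("frame_times length must equal the number of frames")
    }
    if (any(diff(frame_times) <= 0)) {
      stop("frame_times must be strictly increasing")
    }
  }
  arr <- array(unlist(frames, use.names = FALSE), dim = c(na, 3L, length(frames)))
  structure(list(topology = topology, coords = arr, frame_times = frame_times),
            class = "md_trajectory")
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3L]

#' Coordinates of one trajectory frame
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  traj$coords[, , i, drop = TRUE]
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d atoms x %d frames%s\n",
              n_atoms(x$topology), n_frames(x),
              if (is.null(x$frame_times)) "" else
                sprintf(", t = %.3g..%.3g ns", min(x$frame_times), max(x$frame_times))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Parsing

parse_pdb_atoms <- function(lines, line_numbers) {
  rec <- substr(lines, 1, 6)
  sel <- rec %in% c("ATOM  ", "HETATM") | trimws(rec) %in% c("ATOM", "HETATM")
  lines <- lines[sel]
  line_numbers <- line_numbers[sel]
  if (length(lines) == 0L) {
    return(data.frame(
      serial = integer(), name = character(), altloc = character(),
      residue_name = character(), chain = character(), residue_seq = integer(),
      icode = character(), occupancy = double(), element = character(),
      x = double(), y = double(), z = double(), is_het = logical(),
      stringsAsFactors = FALSE
    ))
  }
  num_field <- function(from, to, what) {
    raw <- substr(lines, from, to)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & nzchar(trimws(raw)) | !nzchar(trimws(raw)) & what != "occupancy")
    if (what != "occupancy" && length(bad) > 0L) {
      stop(sprintf("malformed %s field '%s' at line %d",
                   what, trimws(raw[bad[1]]), line_numbers[bad[1]]))
    }
    val
  }
  x <- num_field(31, 38, "x coordinate")
  y <- num_field(39, 46, "y coordinate")
  z <- num_field(47, 54, "z coordinate")
  occ <- suppressWarnings(as.numeric(substr(lines, 55, 60)))
  occ[is.na(occ)] <- 1
  element <- trimws(substr(lines, 77, 78))
  name <- trimws(substr(lines, 13, 16))
  # infer element from the atom name when column 77-78 is blank
  blank <- !nzchar(element)
  element[blank] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", name[blank])
  data.frame(
    serial = suppressWarnings(as.integer(substr(lines, 7, 11))),
    name = name,
    altloc = trimws(substr(lines, 17, 17)),
    residue_name = trimws(substr(lines, 18, 21)),
    chain = trimws(substr(lines, 22, 22)),
    residue_seq = as.integer(num_field(23, 26, "residue number")),
    icode = trimws(substr(lines, 27, 27)),
    occupancy = occ,
    element = toupper(element),
    x = x, y = y, z = z,
    is_het = trimws(rec[sel]) == "HETATM",
    stringsAsFactors = FALSE
  )
}

resolve_altlocs <- function(atoms) {
  if (nrow(atoms) == 0L || all(!nzchar(atoms$altloc))) return(atoms)
  key <- paste(atoms$chain, atoms$residue_seq, atoms$icode, atoms$name, sep = "\r")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    # highest occupancy wins; ties resolved to the first encountered
    best <- idx[which.max(atoms$occupancy[idx])]
    keep[setdiff(idx, best)] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

#' Read a PDB structure from text
#'
#' Parses fixed-column `ATOM`/`HETATM` records. Alternate locations are
#' resolved to the highest-occupancy conformer (ties: first encountered);
#' `HETATM` records are retained and flagged as ligand candidates unless the
#' residue name is a common solvent/ion.
#'
#' @param text a single string or character vector of PDB lines.
#' @return an `md_structure`.
#' @export
read_pdb <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  atoms <- parse_pdb_atoms(lines, seq_along(lines))
  atoms <- resolve_altlocs(atoms)
  if (nrow(atoms) == 0L) stop("no ATOM/HETATM records found (empty input)")
  key <- paste(atoms$chain, atoms$residue_seq, atoms$icode, atoms$name, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate atom identity after altloc resolution: ",
         key[duplicated(key)][1])
  }
  new_structure(atoms)
}

#' Read a multi-model PDB as a trajectory
#'
#' One frame per `MODEL`/`ENDMDL` block; the topology is taken from the first
#' model. A file without `MODEL` records yields a single-frame trajectory.
#'
#' @param text a single string or character vector of PDB lines.
#' @param frame_times optional frame times in ns.
#' @return an `md_trajectory`.
#' @export
read_multimodel_pdb <- function(text, frame_times = NULL) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) {
    s <- read_pdb(lines)
    return(new_trajectory(s, list(coords(s)), frame_times = frame_times))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts)) {
    stop("unbalanced MODEL/ENDMDL records")
  }
  topology <- NULL
  frames <- vector("list", length(model_starts))
  for (m in seq_along(model_starts)) {
    block <- lines[model_starts[m]:model_ends[m]]
    atoms <- parse_pdb_atoms(block, model_starts[m] - 1L + seq_along(block))
    if (m == 1L) {
      topology <- new_structure(atoms)
      if (n_atoms(topology) == 0L) stop("model 1 contains no atoms")
    } else if (nrow(atoms) != n_atoms(topology)) {
      stop(sprintf("model %d has %d atoms but model 1 has %d (topology mismatch)",
                   m, nrow(atoms), n_atoms(topology)))
    } else if (!identical(atoms$name, topology$atoms$name)) {
      stop(sprintf("model %d atom ordering differs from model 1", m))
    }
    frames[[m]] <- cbind(atoms$x, atoms$y, atoms$z)
  }
  new_trajectory(topology, frames, frame_times = frame_times)
}

# ---------------------------------------------------------------------------
# Writing

format_atom_lines <- function(atoms, xyz) {
  if (any(abs(xyz) >= 1e4)) {
    stop("coordinate magnitude >= 10^4 Angstrom cannot be represented in PDB columns")
  }
  name4 <- ifelse(nchar(atoms$name) < 4L, paste0(" ", atoms$name), atoms$name)
  sprintf("%-6s%5d %-4s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(atoms$is_het, "HETATM", "ATOM"),
          atoms$serial %% 100000L, name4, atoms$altloc,
          atoms$residue_name, atoms$chain, atoms$residue_seq, atoms$icode,
          xyz[, 1], xyz[, 2], xyz[, 3], atoms$occupancy, 0, atoms$element)
}

#' Write a structure as PDB text
#'
#' Round-trips through [read_pdb()] with coordinates preserved to 3 decimals.
#'
#' @param x an `md_structure`.
#' @return a single PDB-format string.
#' @export
write_pdb <- function(x) {
  stopifnot(inherits(x, "md_structure"))
  if (n_atoms(x) == 0L) stop("cannot write a structure with no atoms")
  paste(c(format_atom_lines(x$atoms, coords(x)), "END", ""), collapse = "\n")
}

#' Write a trajectory as multi-model PDB text
#'
#' @param traj an `md_trajectory`.
#' @return a single PDB-format string with one `MODEL` block per frame.
#' @export
write_multimodel_pdb <- function(traj) {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- n_frames(traj)
  if (nf == 0L) stop("cannot write a trajectory with no frames")
  blocks <- character(nf)
  for (i in seq_len(nf)) {
    blocks[i] <- paste(c(sprintf("MODEL     %4d", i),
                         format_atom_lines(traj$topology$atoms, frame_coords(traj, i)),
                         "ENDMDL"), collapse = "\n")
  }
  paste(c(blocks, "END", ""), collapse = "\n")
}

# ---------------------------------------------------------------------------
# Selection

#' Select atom indices by predicate conjunction
#'
#' `spec` is a named list of predicates combined with AND:
#' \describe{
#'   \item{chain}{character vector of chain identifiers}
#'   \item{residue_seq}{integer vector of residue numbers}
#'   \item{residue_range}{length-2 integer `c(lo, hi)`, inclusive}
#'   \item{residue_name}{character vector of residue names}
#'   \item{name}{character vector of atom names}
#'   \item{element}{character vector of element symbols}
#'   \item{network_node}{`TRUE` to select the residue-network node atoms:
#'     CB per amino acid (CA for glycine) plus the ligand node atom on
#'     ligand-candidate HETATM residues}
#'   \item{ligand_node_atom}{atom name used as the ligand node
#'     (default `"C2"`); only meaningful with `network_node`}
#' }
#'
#' @param x an `md_structure` or `md_trajectory`.
#' @param spec named list of predicates (see Details).
#' @return integer vector of atom indices in topology order (possibly empty).
#' @export
select_atoms <- function(x, spec) {
  if (inherits(x, "md_trajectory")) x <- x$topology
  stopifnot(inherits(x, "md_structure"), is.list(spec))
  known <- c("chain", "residue_seq", "residue_range", "residue_name",
             "name", "element", "network_node", "ligand_node_atom")
  bad <- setdiff(names(spec), known)
  if (length(bad) > 0L) {
    stop("unknown selection predicate key(s): ", paste(bad, collapse = ", "))
  }
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(spec$chain)) keep <- keep & a$chain %in% spec$chain
  if (!is.null(spec$residue_seq)) keep <- keep & a$residue_seq %in% spec$residue_seq
  if (!is.null(spec$residue_range)) {
    stopifnot(length(spec$residue_range) == 2L)
    keep <- keep & a$residue_seq >= spec$residue_range[1] &
      a$residue_seq <= spec$residue_range[2]
  }
  if (!is.null(spec$residue_name)) keep <- keep & a$residue_name %in% spec$residue_name
  if (!is.null(spec$name)) keep <- keep & a$name %in% spec$name
  if (!is.null(spec$element)) keep <- keep & a$element %in% toupper(spec$element)
  if (isTRUE(spec$network_node)) {
    lig_atom <- spec$ligand_node_atom %||% "C2"
    protein_node <- !a$is_het &
      ((a$name == "CB" & a$residue_name != "GLY") |
         (a$name == "CA" & a$residue_name == "GLY"))
    ligand_node <- a$is_het & !(a$residue_name %in% SOLVENT_RESNAMES) &
      a$name == lig_atom
    keep <- keep & (protein_node | ligand_node)
  }
  which(keep)
}
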