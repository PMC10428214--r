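# RGB projection of dynamic community co-membership.
#
# Three reference nodes are fixed; for every analyzed frame, each node whose
# community contains a reference node gets that reference's color channel
# incremented. Counts are normalized to the 0..256 scale (round half-up), so
# a node always sharing a community with the red reference scores (256,0,0)
# and one splitting its time evenly between red and blue scores (128,0,128).
# References may share a community in a frame, in which case both channels
# are incremented for that community's members (no exclusivity).

#' Reference nodes for RGB accumulation
#'
#' Defaults follow the DHFR study this scheme comes from: I94 -> red,
#' N142 -> blue, S64 -> green.
#'
#' @param red_node,green_node,blue_node distinct node ids.
#' @return a `reference_set` list.
#' @export
reference_set <- function(red_node = "I94", green_node = "S64",
                          blue_node = "N142") {
  ids <- c(red_node, green_node, blue_node)
  if (anyDuplicated(ids)) stop("reference nodes must be distinct")
  structure(list(red = red_node, green = green_node, blue = blue_node),
            class = "reference_set")
}

#' Accumulate community co-membership into an RGB profile
#'
#' @param partitions list of `community_partition` objects (e.g. from
#'   [partition_series()]).
#' @param refs a [reference_set()].
#' @return an `rgb_profile`: list with `rgb` (n_nodes x 3 integer matrix in
#'   `[0, 256]`, rownames = node ids, columns r/g/b) and `n_frames`.
#' @export
rgb_accumulate <- function(partitions, refs = reference_set()) {
  stopifnot(length(partitions) > 0L, inherits(refs, "reference_set"))
  nodes <- names(partitions[[1]]$membership)
  counts <- matrix(0L, nrow = length(nodes), ncol = 3L,
                   dimnames = list(nodes, c("r", "g", "b")))
  ref_ids <- c(refs$red, refs$green, refs$blue)
  for (f in seq_along(partitions)) {
    m <- partitions[[f]]$membership
    for (ch in 1:3) {
      ref <- ref_ids[ch]
      if (!(ref %in% names(m))) {
        stop(sprintf("reference node '%s' missing from partition %d", ref, f))
      }
      share <- names(m)[m == m[[ref]]]
      counts[share, ch] <- counts[share, ch] + 1L
    }
  }
  rgb <- matrix(as.integer(round_half_up(counts * 256 / length(partitions))),
                nrow = nrow(counts), dimnames = dimnames(counts))
  structure(list(rgb = rgb, n_frames = length(partitions)),
            class = "rgb_profile")
}

#' @export
print.rgb_profile <- function(x, ...) {
  cat(sprintf("<rgb_profile> %d nodes over %d frames\n",
              nrow(x$rgb), x$n_frames))
  invisible(x)
}

rgb_hex <- function(rgb) {
  # 256 is the full-score value on the accumulation scale; clamp to 255 only
  # for the 8-bit hex rendering
  cl <- pmin(rgb, 255L)
  sprintf("#%02X%02X%02X", cl[, 1], cl[, 2], cl[, 3])
}

#' Export an RGB profile as a color table and viewer script
#'
#' Writes a TSV (`node`, `r`, `g`, `b`, `hex`; channel values kept on the
#' 0..256 scale, hex clamped to 8 bits) and a plain-text coloring script with
#' one `color <node> <r> <g> <b>` command per node using 0..1 channel values,
#' consumable by common molecular viewers after trivial adaptation.
#'
#' @param profile an [rgb_accumulate()] result.
#' @param tsv_path,script_path output files (`NULL` to skip either).
#' @param structure optional `md_structure`; nodes not mappable onto its
#'   residues trigger a warning but are still written.
#' @return data.frame of the color table, invisibly.
#' @export
export_rgb <- function(profile, tsv_path = NULL, script_path = NULL,
                       structure = NULL) {
  stopifnot(inherits(profile, "rgb_profile"))
  df <- data.frame(node = rownames(profile$rgb),
                   r = profile$rgb[, 1], g = profile$rgb[, 2],
                   b = profile$rgb[, 3], hex = rgb_hex(profile$rgb),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (!is.null(structure)) {
    idx <- select_atoms(structure, list(network_node = TRUE))
    known <- node_labels(structure, idx)
    unmapped <- setdiff(df$node, known)
    if (length(unmapped) > 0L) {
      warning("node(s) not mappable onto the structure: ",
              paste(unmapped, collapse = ", "))
    }
  }
  if (!is.null(tsv_path)) {
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(script_path)) {
    writeLines(sprintf("color %s %.4f %.4f %.4f", df$node,
                       pmin(df$r, 255) / 255, pmin(df$g, 255) / 255,
                       pmin(df$b, 255) / 255),
               script_path)
  }
  invisible(df)
}
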