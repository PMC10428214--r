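make_triplet_structure <- function() {
  # donor N (res 1, with H), acceptor O (res 2)
  make_structure(c("N", "H", "O"), c("ALA", "ALA", "SER"), c(1L, 1L, 2L),
                 matrix(0, 3, 3), element = c("N", "H", "O"))
}

triplet_frame <- function(da, h_offset = c(1, 0, 0)) {
  rbind(c(0, 0, 0), h_offset, c(da, 0, 0))
}

test_that("distance and angle cutoffs act as specified", {
  s <- make_triplet_structure()
  crit <- hbond_criteria()
  expect_equal(detect_hbonds_frame(triplet_frame(3.0), s, crit),
               "A:1:ALA:N->A:2:SER:O")
  expect_equal(detect_hbonds_frame(triplet_frame(3.3), s, crit), character(0))
  # move the acceptor so the D-H...A deviation from linearity is exactly `deg`
  bend <- function(deg) {
    rad <- deg * pi / 180
    rbind(c(0, 0, 0), c(1, 0, 0),
          c(1 + 2 * cos(rad), 2 * sin(rad), 0))
  }
  expect_length(detect_hbonds_frame(bend(19), s, crit), 1L)
  expect_length(detect_hbonds_frame(bend(21), s, crit), 0L)
  # alternative convention measures the D->H vs D->A angle
  alt <- hbond_criteria(angle_convention = "da_dh")
  expect_length(detect_hbonds_frame(bend(21), s, alt), 1L)
})

test_that("topologies without hydrogens are rejected explicitly", {
  s <- make_structure(c("N", "O"), c("ALA", "SER"), c(1L, 2L),
                      matrix(0, 2, 3), element = c("N", "O"))
  expect_error(detect_hbonds_frame(matrix(0, 2, 3), s, hbond_criteria()),
               "no hydrogens")
})

test_that("detection matches the brute-force geometric oracle on random triplets", {
  n <- 500L
  set.seed(33)
  rows <- vector("list", n)
  truth <- logical(n)
  for (i in seq_len(n)) {
    off <- c((i - 1) * 50, 0, 0)
    d <- off + stats::rnorm(3, sd = 0.5)
    hdir <- stats::rnorm(3); hdir <- hdir / sqrt(sum(hdir^2))
    h <- d + hdir
    adir <- stats::rnorm(3); adir <- adir / sqrt(sum(adir^2))
    a <- d + adir * stats::runif(1, 2.5, 4.0)
    truth[i] <- oracle_hbond(d, h, a)
    rows[[i]] <- rbind(d, h, a)
  }
  xyz <- do.call(rbind, rows)
  s <- make_structure(rep(c("N", "H", "O"), n), rep("ALA", 3 * n),
                      rep(seq_len(2 * n), rep(c(2L, 1L), n)), xyz,
                      element = rep(c("N", "H", "O"), n))
  found <- detect_hbonds_frame(coords(s), s, hbond_criteria())
  donors <- sprintf("A:%d:ALA:N->A:%d:ALA:O", 2 * seq_len(n) - 1L, 2 * seq_len(n))
  expect_setequal(found, donors[truth])
})

test_that("detection is invariant under rigid motion of the frame", {
  gen <- make_hbond_trajectory(hbond_series_spec(n_triplets = 3L,
                                                 occupancy = c(1, 0.5, 0.2),
                                                 n_frames = 20L, seed = 6L))
  crit <- hbond_criteria()
  rot <- random_rotation(99)
  for (i in c(1L, 7L, 20L)) {
    f <- frame_coords(gen$trajectory, i)
    moved <- f %*% t(rot) + matrix(c(5, -3, 11), nrow(f), 3, byrow = TRUE)
    expect_identical(detect_hbonds_frame(moved, gen$trajectory$topology, crit),
                     detect_hbonds_frame(f, gen$trajectory$topology, crit))
  }
})

test_that("occupancies count frames and chunks consistently", {
  # 10 frames, bonded in frames 1-5 only
  gen <- make_hbond_trajectory(hbond_series_spec(occupancy = 1, n_frames = 2L))
  base <- frame_coords(gen$trajectory, 1L)     # bonded geometry
  broken <- base
  broken[3L, 1] <- 4.5                          # acceptor pulled out
  states <- c(rep(1L, 5L), rep(0L, 5L))
  frames <- lapply(states, function(s) if (s == 1L) base else broken)
  traj <- new_trajectory(gen$trajectory$topology, frames)
  tab <- occupancy_table(traj, hbond_criteria(), n_chunks = 5L)
  expect_equal(unname(tab$occupancy[gen$keys[1]]), 0.5)
  # equal-size chunk means reproduce the global occupancy exactly
  expect_equal(mean(tab$chunk_occupancy[gen$keys[1], ]), 0.5, tolerance = 1e-12)
  expect_true(all(tab$occupancy >= 0 & tab$occupancy <= 1))
  expect_error(occupancy_table(new_trajectory(traj$topology, frames[1:3]),
                               hbond_criteria(), n_chunks = 5L),
               "fewer analyzed frames than chunks")
})

test_that("equilibration discard honours frame times", {
  spec <- hbond_series_spec(occupancy = 1, n_frames = 20L)
  gen <- make_hbond_trajectory(spec)
  traj <- gen$trajectory
  traj$frame_times <- seq_len(20L)  # ns
  tab <- occupancy_table(traj, hbond_criteria(equilibration_discard = 10),
                         n_chunks = 5L)
  expect_equal(tab$n_frames, 10L)
})

test_that("residue contact barcodes collapse multiple bonds to one", {
  gen <- make_hbond_trajectory(hbond_series_spec(occupancy = 0.6,
                                                 n_frames = 200L, seed = 12L))
  bc <- residue_contact_barcode(gen$trajectory, "A:1", "A:2")
  expect_true(all(bc %in% c(0L, 1L)))
  expect_equal(bc, unname(gen$states[, 1]))
  tab <- occupancy_table(gen$trajectory, hbond_criteria(), n_chunks = 5L)
  expect_equal(mean(bc), unname(tab$occupancy[[gen$keys]]))
  expect_error(residue_contact_barcode(gen$trajectory, "A:1", "B:9"),
               "unknown residue id")

  # a frame with two simultaneous bonds between the same residue pair: donor
  # residue with two N-H groups hitting two acceptor O atoms of one residue
  s <- make_structure(c("N", "H", "ND", "HD", "O", "OX"),
                      c("ASN", "ASN", "ASN", "ASN", "GLU", "GLU"),
                      c(1L, 1L, 1L, 1L, 2L, 2L),
                      rbind(c(0, 0, 0), c(1, 0, 0), c(0, 8, 0), c(1, 8, 0),
                            c(3, 0, 0), c(3, 8, 0)),
                      element = c("N", "H", "N", "H", "O", "O"))
  traj2 <- new_trajectory(s, list(coords(s), coords(s)))
  expect_length(detect_hbonds_frame(coords(s), s, hbond_criteria()), 2L)
  expect_equal(residue_contact_barcode(traj2, "A:1", "A:2"), c(1L, 1L))
})

test_that("fingerprint selection finds the planted shift and nothing else", {
  occ_ref <- c(0.9, 0.5, 0.3, 0.8, 0.2, 0.6, 0.4, 0.7, 0.35, 0.65, 0.55, 0.45)
  occ_alt <- occ_ref
  occ_alt[1] <- 0.5  # planted 40-point drop
  n <- 2000L
  ref <- make_hbond_trajectory(hbond_series_spec(n_triplets = 12L,
                                                 occupancy = occ_ref,
                                                 n_frames = n, seed = 101L))
  alt <- make_hbond_trajectory(hbond_series_spec(n_triplets = 12L,
                                                 occupancy = occ_alt,
                                                 n_frames = n, seed = 202L))
  crit <- hbond_criteria()
  tab_ref <- occupancy_table(ref$trajectory, crit, n_chunks = 5L)
  tab_alt <- occupancy_table(alt$trajectory, crit, n_chunks = 5L)
  fp <- occupancy_fingerprint(tab_ref, tab_alt, fingerprint_config())
  expect_equal(fp$bond[fp$selected], ref$keys[1])
  expect_equal(fp$direction[fp$selected], "decrease")
  expect_lt(fp$delta[fp$selected], -20)
  # self-fingerprint is empty; swapping the tables negates every delta
  self <- occupancy_fingerprint(tab_ref, tab_ref, fingerprint_config())
  expect_false(any(self$selected))
  expect_true(all(self$delta == 0))
  swapped <- occupancy_fingerprint(tab_alt, tab_ref, fingerprint_config())
  m <- match(fp$bond, swapped$bond)
  expect_equal(swapped$delta[m], -fp$delta)
  expect_equal(swapped$direction[swapped$bond == ref$keys[1]], "increase")
})

test_that("fingerprint validates chunk compatibility and sorts by |delta|", {
  gen <- make_hbond_trajectory(hbond_series_spec(n_triplets = 2L,
                                                 occupancy = c(0.8, 0.4),
                                                 n_frames = 100L, seed = 7L))
  a <- occupancy_table(gen$trajectory, hbond_criteria(), n_chunks = 5L)
  b <- occupancy_table(gen$trajectory, hbond_criteria(), n_chunks = 4L)
  expect_error(occupancy_fingerprint(a, b), "chunk-count mismatch")
  fp <- occupancy_fingerprint(a, a)
  expect_equal(order(-abs(fp$delta), fp$bond), seq_len(nrow(fp)))
})

test_that("occupancy tables round-trip through TSV", {
  gen <- make_hbond_trajectory(hbond_series_spec(n_triplets = 2L,
                                                 occupancy = c(0.8, 0.4),
                                                 n_frames = 100L, seed = 7L))
  tab <- occupancy_table(gen$trajectory, hbond_criteria(), n_chunks = 5L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_occupancy_tsv(tab, path)
  back <- read_occupancy_tsv(path)
  expect_equal(back$occupancy, tab$occupancy)
  expect_equal(unname(back$chunk_occupancy), unname(tab$chunk_occupancy))
  expect_equal(back$n_frames, tab$n_frames)
})
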