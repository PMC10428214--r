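RT300 <- 1.98720425e-3 * 300

test_that("ki_to_dg reproduces standard-state limits and propagates error", {
  expect_equal(ki_to_dg(1e9, 300), 0)             # 1 M == standard state
  expect_gt(ki_to_dg(10), ki_to_dg(1))            # strictly increasing in Ki
  expect_equal(dg_to_ki(ki_to_dg(37.3, 285), 285), 37.3, tolerance = 1e-10)
  out <- ki_to_dg(4.2, 300, ki_err_nM = 0.5)
  expect_equal(out$dG_err, RT300 * 0.5 / 4.2, tolerance = 1e-12)
  expect_error(ki_to_dg(-1), "positive")
  expect_error(ki_to_dg(1, temperature = 0), "positive")
})

test_that("a 301 K conversion uniquely reproduces the bundled binding table", {
  # at 300 K the fourth entry lands on -10.2468 and rounds to -10.2; 301 K is
  # the only integer temperature whose conversion matches all four printed
  # values at 1 decimal place
  ki <- c(4.2, 5.1, 65.0, 34.3)
  expect_equal(round(ki_to_dg(ki, 301), 1), c(-11.5, -11.4, -9.9, -10.3))
  expect_equal(round(ki_to_dg(ki, 300), 1), c(-11.5, -11.4, -9.9, -10.2))
})

test_that("cycle_ddg computes experimental and alchemical differences", {
  # printed binding table edges and computed alchemical edges
  cyc <- thermo_cycle(dg_bind_A_1 = -11.5, dg_bind_A_2 = -9.9,
                      dg_bind_B_1 = -11.4, dg_bind_B_2 = -10.3,
                      dg_alch_1 = -3.2, dg_alch_2 = -3.4,
                      err = c(bind_A_1 = 0.1, alch_1 = 0.3, alch_2 = 0.4))
  res <- cycle_ddg(cyc)
  expect_equal(res$ddG_exp, 0.5, tolerance = 1e-12)
  expect_equal(res$ddG_alch, 0.2, tolerance = 1e-12)
  expect_equal(res$closure, 0.3, tolerance = 1e-12)
  expect_equal(res$ddG_alch_err, sqrt(0.09 + 0.16), tolerance = 1e-12)

  # identical ligands: every output zero; a fully consistent cycle closes
  same <- cycle_ddg(thermo_cycle(-10, -9, -10, -9, dg_alch_1 = 0, dg_alch_2 = 0))
  expect_equal(same$ddG_exp, 0)
  expect_equal(same$closure, 0, tolerance = 1e-12)
  consistent <- cycle_ddg(thermo_cycle(-11, -9.5, -10.2, -8.4,
                                       dg_alch_1 = 0.8, dg_alch_2 = 1.1))
  expect_equal(consistent$closure, (( -9.5 + 11) - (-8.4 + 10.2)) - (0.8 - 1.1),
               tolerance = 1e-12)

  expect_error(cycle_ddg(thermo_cycle(-11.5, NA, -11.4, -10.3)),
               "bind_A_2")
})

test_that("zwanzig handles constants, Gaussians, and extreme samples", {
  expect_equal(zwanzig(rep(1.7, 100)), 1.7, tolerance = 1e-12)
  set.seed(14)
  du <- stats::rnorm(2e5, mean = 2, sd = 1)
  expect_equal(zwanzig(du, 300), 2 - 1 / (2 * RT300), tolerance = 0.05)
  expect_true(is.finite(zwanzig(c(-1e4, -1e4 + 1, 0), 300)))
  expect_error(zwanzig(numeric(0)), "no samples")
})

test_that("bar solves the symmetric case exactly and is antisymmetric", {
  f <- rep(1.3, 50); b <- rep(-1.3, 50)
  est <- bar(f, b)
  expect_equal(est$dF, 1.3, tolerance = 1e-8)
  fs <- make_fep_samples(gaussian_work_spec(true_dF = -2, work_sd = 0.8,
                                            n_forward = 4000L,
                                            n_backward = 4000L, seed = 15L))
  fwd_est <- bar(fs$forward, fs$backward)
  swp_est <- bar(fs$backward, fs$forward)
  expect_equal(swp_est$dF, -fwd_est$dF, tolerance = 1e-8)
  expect_error(bar(1, rep(0, 5)), "at least 2 samples")
})

test_that("mbar obeys identity, shift-invariance, and the harmonic ladder", {
  # identical potentials at every state: all free energies zero
  u <- matrix(stats::rnorm(300), nrow = 3, ncol = 100, byrow = TRUE)
  u <- rbind(u[1, ], u[1, ], u[1, ])
  res <- mbar(u, counts = c(34, 33, 33))
  expect_equal(res$dF, rep(0, 3), tolerance = 1e-9)

  # adding a constant to one state's reduced potential shifts its dF by RT*c
  fs <- make_fep_samples(gaussian_work_spec(true_dF = -1, work_sd = 0.7,
                                            n_forward = 2000L,
                                            n_backward = 2000L, seed = 16L))
  inp <- mbar_input_from_bidirectional(fs$forward, fs$backward)
  base <- mbar(inp$u_kn, inp$counts)
  shifted_u <- inp$u_kn
  shifted_u[2, ] <- shifted_u[2, ] + 2.5
  shifted <- mbar(shifted_u, inp$counts)
  expect_equal(shifted$dF[2] - base$dF[2], 2.5 * RT300, tolerance = 1e-8)

  # harmonic ladder: dF between widths s_a, s_b is RT ln(s_a/s_b) per step
  set.seed(17)
  s_width <- c(1, 0.7, 0.5)
  n_per <- 4000L
  x <- unlist(lapply(s_width, function(s) stats::rnorm(n_per, sd = s)))
  u_kn <- t(vapply(s_width, function(s) x^2 / (2 * s^2), numeric(length(x))))
  res2 <- mbar(u_kn, counts = rep(n_per, 3))
  analytic <- RT300 * log(s_width[1] / s_width)
  expect_lt(max(abs(res2$dF - analytic)), 0.02)
})

test_that("zwanzig estimates bracket BAR in expectation (Crooks data)", {
  zf <- zb <- bb <- numeric(50)
  for (i in 1:50) {
    fs <- make_fep_samples(gaussian_work_spec(true_dF = -1.5, work_sd = 2,
                                              n_forward = 200L,
                                              n_backward = 200L,
                                              seed = 400L + i))
    zf[i] <- zwanzig(fs$forward)
    zb[i] <- -zwanzig(fs$backward)
    bb[i] <- bar(fs$forward, fs$backward)$dF
  }
  # forward exponential averaging is biased up, negated backward biased down
  expect_gt(mean(zf), mean(bb))
  expect_lt(mean(zb), mean(bb))
})

test_that("stitch_windows sums estimates and variances", {
  one <- stitch_windows(-0.37, 0.02)
  expect_equal(one$dF, -0.37)
  expect_equal(one$se, 0.02)
  expect_equal(stitch_windows(rep(-0.1, 32))$dF, -3.2, tolerance = 1e-12)
  both <- stitch_windows(c(-1, 2), c(0.3, 0.4))
  expect_equal(both$se, 0.5)
  expect_error(stitch_windows(numeric(0)), "at least one window")
})

test_that("FEP sample tables round-trip through TSV", {
  windows <- list(list(forward = c(1.1, 1.2), backward = c(-1.0, -1.3)),
                  list(forward = c(0.4, 0.5, 0.6), backward = c(-0.4, -0.5)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fep_samples_tsv(windows, path)
  back <- read_fep_samples_tsv(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$forward, windows[[1]]$forward)
  expect_equal(back[[2]]$backward, windows[[2]]$backward)
})
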