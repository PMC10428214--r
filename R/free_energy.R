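# Binding free energies from inhibition constants, thermodynamic-cycle
# bookkeeping, and alchemical free-energy estimators (Zwanzig exponential
# averaging, Bennett acceptance ratio, multistate BAR).
#
# Conventions: energies in kcal/mol, temperatures in Kelvin, Ki in nM against
# a 1 M standard state. R = 1.98720425e-3 kcal mol^-1 K^-1.

#' Convert an inhibition constant to a binding free energy
#'
#' `dG = RT ln(Ki / 1 M)` with Ki supplied in nM (equivalently
#' `-RT ln(1 M / Ki)`): tighter binding (smaller Ki) gives a more negative
#' binding free energy. Uncertainty is propagated linearly:
#' `d(dG) = RT * dKi / Ki`.
#'
#' @param ki_nM inhibition constant, nM (> 0); vectorized.
#' @param temperature Kelvin (default 300).
#' @param ki_err_nM optional uncertainty on Ki, nM.
#' @return numeric dG in kcal/mol, or (when `ki_err_nM` is given) a
#'   data.frame with columns `dG` and `dG_err`.
#' @export
ki_to_dg <- function(ki_nM, temperature = 300, ki_err_nM = NULL) {
  if (any(ki_nM <= 0) || temperature <= 0) {
    stop("Ki and temperature must be positive")
  }
  rt <- GAS_CONSTANT_KCAL * temperature
  dg <- rt * log(ki_nM * 1e-9)
  if (is.null(ki_err_nM)) return(dg)
  data.frame(dG = dg, dG_err = rt * ki_err_nM / ki_nM)
}

#' Inverse of [ki_to_dg()]
#' @param dg binding free energy, kcal/mol.
#' @param temperature Kelvin.
#' @return Ki in nM.
#' @export
dg_to_ki <- function(dg, temperature = 300) {
  exp(dg / (GAS_CONSTANT_KCAL * temperature)) * 1e9
}

#' Double thermodynamic cycle for two proteins x two ligands
#'
#' Vertical (experimental) edges are binding free energies of ligands A and B
#' to proteins 1 and 2; horizontal (computed) edges are the alchemical A->B
#' transformation free energies in each protein. All kcal/mol; `*_err` are
#' 1-sigma uncertainties (0 when unknown).
#'
#' @param dg_bind_A_1,dg_bind_A_2,dg_bind_B_1,dg_bind_B_2 binding edges
#'   (ligand A/B to protein 1/2).
#' @param dg_alch_1,dg_alch_2 alchemical A->B edges in proteins 1 and 2
#'   (optional, `NA` when absent).
#' @param err named numeric of uncertainties for any of the six edges.
#' @return a `thermo_cycle` list.
#' @export
thermo_cycle <- function(dg_bind_A_1, dg_bind_A_2, dg_bind_B_1, dg_bind_B_2,
                         dg_alch_1 = NA_real_, dg_alch_2 = NA_real_,
                         err = NULL) {
  edges <- c(bind_A_1 = dg_bind_A_1, bind_A_2 = dg_bind_A_2,
             bind_B_1 = dg_bind_B_1, bind_B_2 = dg_bind_B_2,
             alch_1 = dg_alch_1, alch_2 = dg_alch_2)
  errs <- stats::setNames(rep(0, length(edges)), names(edges))
  if (!is.null(err)) errs[names(err)] <- err
  structure(list(edges = edges, err = errs), class = "thermo_cycle")
}

#' Relative binding free energies from a thermodynamic cycle
#'
#' `ddG_exp  = (dG_bind_A_2 - dG_bind_A_1) - (dG_bind_B_2 - dG_bind_B_1)`
#' compares how the protein change affects the two ligands from experimental
#' binding edges; `ddG_alch = dg_alch_1 - dg_alch_2` is the same quantity from
#' the alchemical edges. `closure = ddG_exp - ddG_alch` vanishes for a
#' consistent cycle. Uncertainties add in quadrature.
#'
#' @param cycle a [thermo_cycle()].
#' @return list with `ddG_exp`, `ddG_alch`, `closure`, and `*_err` fields
#'   (alchemical entries `NA` when those edges are absent).
#' @export
cycle_ddg <- function(cycle) {
  stopifnot(inherits(cycle, "thermo_cycle"))
  e <- cycle$edges; s <- cycle$err
  need <- c("bind_A_1", "bind_A_2", "bind_B_1", "bind_B_2")
  miss <- need[is.na(e[need])]
  if (length(miss) > 0L) stop("missing cycle edge(s): ", paste(miss, collapse = ", "))
  ddg_exp <- (e[["bind_A_2"]] - e[["bind_A_1"]]) -
    (e[["bind_B_2"]] - e[["bind_B_1"]])
  ddg_exp_err <- sqrt(sum(s[need]^2))
  if (any(is.na(e[c("alch_1", "alch_2")]))) {
    ddg_alch <- NA_real_; ddg_alch_err <- NA_real_
    closure <- NA_real_; closure_err <- NA_real_
  } else {
    ddg_alch <- e[["alch_1"]] - e[["alch_2"]]
    ddg_alch_err <- sqrt(sum(s[c("alch_1", "alch_2")]^2))
    closure <- ddg_exp - ddg_alch
    closure_err <- sqrt(ddg_exp_err^2 + ddg_alch_err^2)
  }
  list(ddG_exp = ddg_exp, ddG_exp_err = ddg_exp_err,
       ddG_alch = ddg_alch, ddG_alch_err = ddg_alch_err,
       closure = closure, closure_err = closure_err)
}

#' Zwanzig exponential-averaging free-energy estimate
#'
#' `dF = -RT ln < exp(-dU / RT) >`, evaluated with log-sum-exp so arbitrarily
#' large negative samples cannot overflow.
#'
#' @param du potential-energy difference samples, kcal/mol.
#' @param temperature Kelvin.
#' @return dF in kcal/mol.
#' @export
zwanzig <- function(du, temperature = 300) {
  if (length(du) == 0L) stop("no samples")
  rt <- GAS_CONSTANT_KCAL * temperature
  -rt * (logsumexp(-du / rt) - log(length(du)))
}

#' Bennett acceptance ratio free-energy estimate
#'
#' Solves the self-consistent BAR equation
#' `sum_F logistic(-(ln(nF/nB) + beta (W_F - dF))) =
#'  sum_B logistic(-(ln(nB/nF) + beta (W_B + dF)))`
#' for `dF` by bracketed root finding to 1e-10 kcal/mol, with the bracket
#' grown from the two one-sided Zwanzig estimates. The asymptotic standard
#' error is the standard Bennett variance estimate.
#'
#' @param forward samples of `U1 - U0` drawn at state 0, kcal/mol.
#' @param backward samples of `U0 - U1` drawn at state 1, kcal/mol.
#' @param temperature Kelvin.
#' @return list with `dF` and `se`, kcal/mol.
#' @export
bar <- function(forward, backward, temperature = 300) {
  if (length(forward) < 2L || length(backward) < 2L) {
    stop("need at least 2 samples in each direction")
  }
  rt <- GAS_CONSTANT_KCAL * temperature
  lnf <- log(length(forward) / length(backward))
  h <- function(df) {
    lhs <- sum(stats::plogis(-(lnf + (forward - df) / rt)))
    rhs <- sum(stats::plogis(-(-lnf + (backward + df) / rt)))
    lhs - rhs
  }
  z_f <- zwanzig(forward, temperature)
  z_b <- -zwanzig(backward, temperature)
  lo <- min(z_f, z_b) - 1; hi <- max(z_f, z_b) + 1
  for (i in 1:60) {
    if (h(lo) <= 0 && h(hi) >= 0) break
    span <- hi - lo
    if (h(lo) > 0) lo <- lo - span
    if (h(hi) < 0) hi <- hi + span
    if (i == 60L) stop("BAR bracket expansion failed to enclose a root")
  }
  df <- stats::uniroot(h, c(lo, hi), tol = 1e-10)$root
  # Bennett variance estimate from the Fermi-weighted overlap samples
  ff <- stats::plogis(-(lnf + (forward - df) / rt))
  fb <- stats::plogis(-(-lnf + (backward + df) / rt))
  var_beta2 <- (mean(ff^2) / mean(ff)^2 - 1) / length(forward) +
    (mean(fb^2) / mean(fb)^2 - 1) / length(backward)
  list(dF = df, se = rt * sqrt(max(var_beta2, 0)))
}

#' Multistate Bennett acceptance ratio (MBAR)
#'
#' Damped self-consistent iteration of the MBAR estimating equations
#' `f_k = -ln sum_n exp(-u_kn - ln sum_l N_l exp(f_l - u_ln))`
#' on reduced (dimensionless) potentials, to a relative tolerance of 1e-10
#' on the dimensionless free energies.
#'
#' @param u_kn `K x N` matrix of reduced potentials: `u_kn[k, n]` is the
#'   potential of configuration `n` evaluated at state `k`, in units of kT.
#' @param counts integer vector of length `K`, samples drawn from each state
#'   (`sum(counts) == N`).
#' @param temperature Kelvin (used only to convert the output to kcal/mol).
#' @param tol convergence tolerance on the dimensionless free energies.
#' @param max_iter iteration cap.
#' @return list with `dF` (length-K vector, kcal/mol, `dF[1] == 0`), `f`
#'   (dimensionless), `iterations`.
#' @export
mbar <- function(u_kn, counts, temperature = 300, tol = 1e-12,
                 max_iter = 100000L) {
  u_kn <- as.matrix(u_kn)
  k <- nrow(u_kn); n <- ncol(u_kn)
  stopifnot(k >= 2L, length(counts) == k, sum(counts) == n)
  log_n <- log(counts)
  f <- numeric(k)
  for (it in seq_len(max_iter)) {
    # log denominator per sample: ln sum_l N_l exp(f_l - u_ln)
    m <- log_n + f - u_kn              # K x N (column recycling over samples)
    tm <- t(m)
    mx <- tm[cbind(seq_len(n), max.col(tm, ties.method = "first"))]
    log_denom <- mx + log(colSums(exp(m - rep(mx, each = k))))
    a <- -u_kn - rep(log_denom, each = k)
    amx <- apply(a, 1L, max)
    f_new <- -(amx + log(rowSums(exp(a - amx))))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol * max(1, max(abs(f)))) {
      return(list(dF = f * GAS_CONSTANT_KCAL * temperature, f = f,
                  iterations = it))
    }
  }
  stop(sprintf("MBAR failed to converge in %d iterations (residual %.3g)",
               max_iter, delta))
}

#' Build an MBAR input from two-state forward/backward samples
#'
#' Forward samples (from state 0) contribute columns with `u_0 = 0`,
#' `u_1 = dU_f / RT`; backward samples (from state 1) contribute `u_1 = 0`,
#' `u_0 = dU_b / RT`.
#'
#' @param forward,backward kcal/mol samples as in [bar()].
#' @param temperature Kelvin.
#' @return list with `u_kn` and `counts` ready for [mbar()].
#' @export
mbar_input_from_bidirectional <- function(forward, backward, temperature = 300) {
  rt <- GAS_CONSTANT_KCAL * temperature
  u_kn <- rbind(c(rep(0, length(forward)), backward / rt),
                c(forward / rt, rep(0, length(backward))))
  list(u_kn = u_kn, counts = c(length(forward), length(backward)))
}

#' Combine per-window free-energy estimates
#'
#' Windows are treated as independent: the total is the sum of the window
#' estimates and the variance the sum of the window variances.
#'
#' @param dF numeric vector of per-window free energies, kcal/mol.
#' @param se optional vector of per-window standard errors.
#' @return list with `dF` and `se`.
#' @export
stitch_windows <- function(dF, se = NULL) {
  if (length(dF) == 0L) stop("need at least one window")
  if (is.null(se)) se <- rep(0, length(dF))
  stopifnot(length(se) == length(dF))
  list(dF = sum(dF), se = sqrt(sum(se^2)))
}

#' Read a Ki table from TSV
#'
#' Expected columns: `protein`, `inhibitor`, `ki_nM`, optional `ki_err_nM`.
#'
#' @param path TSV file.
#' @param temperature Kelvin for the derived dG column.
#' @return data.frame with appended `dG` (and `dG_err`) columns.
#' @export
read_ki_table <- function(path, temperature = 300) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("protein", "inhibitor", "ki_nM") %in% names(df)))
  if ("ki_err_nM" %in% names(df)) {
    conv <- ki_to_dg(df$ki_nM, temperature, df$ki_err_nM)
    df$dG <- conv$dG; df$dG_err <- conv$dG_err
  } else {
    df$dG <- ki_to_dg(df$ki_nM, temperature)
  }
  df
}

#' Read per-window FEP samples from TSV
#'
#' Expected columns: `window` (integer), `direction` (`"forward"` or
#' `"backward"`), `dU` (kcal/mol).
#'
#' @param path TSV file.
#' @return named list per window with `forward` and `backward` vectors.
#' @export
read_fep_samples_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("window", "direction", "dU") %in% names(df)))
  lapply(split(df, df$window), function(w) {
    list(forward = w$dU[w$direction == "forward"],
         backward = w$dU[w$direction == "backward"])
  })
}

#' Write per-window FEP samples as TSV
#' @param windows list as returned by [read_fep_samples_tsv()].
#' @param path output file.
#' @export
write_fep_samples_tsv <- function(windows, path) {
  rows <- do.call(rbind, lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    data.frame(window = i,
               direction = c(rep("forward", length(w$forward)),
                             rep("backward", length(w$backward))),
               dU = c(w$forward, w$backward))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
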