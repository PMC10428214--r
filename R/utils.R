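# Shared constants and small numerical helpers.

# Gas constant in kcal mol^-1 K^-1
GAS_CONSTANT_KCAL <- 1.98720425e-3

# Three-letter -> one-letter amino-acid codes used for residue node labels.
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", HSD = "H", HSE = "H",
  HSP = "H", ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F",
  PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# Residue names never treated as ligand candidates even when stored as HETATM.
SOLVENT_RESNAMES <- c(
  "HOH", "WAT", "TIP", "TIP3", "TIP4", "SPC", "SOL",
  "NA", "CL", "K", "MG", "CA", "ZN", "SOD", "CLA", "POT"
)

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector.
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to label permutation), ~0 for random ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# round-half-up to integer (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
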