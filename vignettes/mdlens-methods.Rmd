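---
title: "mdlens: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mdlens: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdlens)
```

mdlens packages the trajectory-analysis layer used in comparative
enzyme–inhibitor MD studies: hydrogen-bond occupancy fingerprinting between
two systems, per-frame residue-network community decomposition with RGB
co-membership projection, superposition-based motion statistics, and a
free-energy layer from inhibition constants and alchemical window samples.
This vignette records the models, the tunable parameters with their
defaults and units, the design decisions that were genuinely open, and what
the synthetic generators do and do not establish.

## Hydrogen bonds and occupancy fingerprints

A hydrogen bond is declared between a donor heavy atom D (N or O carrying at
least one hydrogen, assigned covalently by a 1.2 Å nearest-neighbour rule)
and an acceptor heavy atom A (N or O in a different residue) when

* the D–A heavy-atom distance is ≤ `max_da_distance` (default **3.2 Å**), and
* for at least one hydrogen on D, the D–H···A angle deviates from linearity
  by ≤ `max_angle_deviation` (default **20°**).

The angle convention was an open point: "a bond angle of 20°" is used by
different tools either as the deviation from a linear D–H···A arrangement
(vertex at H) or as the angle between the D→H and D→A vectors (vertex at D).
The default is the D–H···A linearity reading — the stricter and more common
convention — and `hbond_criteria(angle_convention = "da_dh")` switches to the
other. Donors and acceptors are elected purely by element (N, O); no
chemistry perception is attempted, matching the heavy-atom character of the
criteria. Multiple hydrogens on one donor reaching the same acceptor count
once per frame: occupancy is a presence fraction.

Occupancy is the fraction of analyzed frames in which a bond exists. Frames
before `equilibration_discard` (default **10 ns**) are dropped when the
trajectory carries frame times; index-only trajectories are used in full.
The trajectory is additionally split into `n_chunks` (default **5**)
contiguous, equal-size chunks (remainder frames join the last chunk), and
per-chunk occupancies feed the stability filter below. Bonds are keyed at
atom-pair level (`chain:resseq:resname:atom -> ...`); residue-level views
(`residue_contact_barcode`) are aggregations of these keys.

The fingerprint between a reference and an alternate system takes
Δ = alternate − reference in percentage points per bond (a bond absent from
one table counts as occupancy 0), sets σ to the standard deviation of all Δ
values — σ is always recomputed from the data at hand, never treated as a
constant — and selects bonds with

* |Δ| ≥ `min_abs_difference` (default **20 points**, read as absolute
  percentage points, the only reading consistent with quoting σ on the same
  scale),
* |Δ| > 3σ (`sigma_multiplier_select`), and
* per-chunk Δ standard deviation < 2σ (`sigma_multiplier_stability`).

Output is sorted by |Δ| descending with lexicographic tie-break, carries an
increase/decrease direction label, and the self-fingerprint is empty by
construction (all Δ = 0 gives σ = 0 and the 20-point floor fails).

## Residue networks and Girvan–Newman communities

One node per amino-acid residue — its Cβ atom, Cα for glycine — plus one
node per ligand-candidate HETATM residue (node atom `C2` by default, the
conventional choice for trimethoprim-like ligands). An undirected edge joins
nodes whose atoms lie within `cutoff` (default **6.7 Å**); no self-loops.
Waters and common ions are never ligand candidates; cofactors present in the
topology are excluded from the node set by default (a 159-residue protein
plus one inhibitor yields exactly 160 nodes) but any HETATM residue can be
targeted via `ligand_node_atom`.

Communities are found divisively: recompute shortest-path edge betweenness
(unit weights, equal splitting over degenerate shortest paths; Brandes'
algorithm via igraph, cross-checked in the test suite against an exhaustive
hand-written path enumerator) and delete the single highest-betweenness
edge until the number of connected components reaches Ω (default **6**).
Scores tied within 1e-9 relative are broken by lexicographically smallest
edge, making the removal sequence platform-independent. Betweenness is
recomputed from scratch after every removal — at 160 nodes correctness is
cheap. The stop rule is component count ≥ Ω, the standard divisive reading;
modularity-based stopping is out of scope. Since deleting one edge can split
a component into at most two, the final community count is exactly
max(Ω, initial component count).

`partition_series` analyzes one frame per `spacing_ns` (default 10 ns) over
the final `window_ns` (default 100 ns) when frame times exist — i.e. 10
frames ending at the last frame, the "ten frames" reading of an ambiguous
10-or-11 window description; `n_select` makes the count explicit. Without
times, `n_select` equally spaced frames span the trajectory.

## RGB co-membership projection

Three reference nodes are fixed (defaults I94 → red, N142 → blue,
S64 → green). For each analyzed frame, every node sharing a community with a
reference gets that channel incremented; counts are normalized to 0…256
(round half-up). A node always with red scores (256,0,0); half red / half
blue scores (128,0,128); a node never co-member with any reference stays
(0,0,0) and renders black. The source study's Methods and its figure caption
disagree on which of N142/S64 is blue versus green; the default follows the
Methods because the worked magenta example (128,0,128 from I94 + N142) is
only consistent with N142 = blue. The mapping is fully configurable in
`reference_set()`. When two references share a community in a frame, both
channels are incremented — the accumulation rule has no exclusivity clause —
so the invariant r+g+b ≤ 256 holds only while references occupy pairwise
distinct communities. TSV export keeps the 0…256 scale; only the 8-bit hex
rendering clamps 256 to 255.

## Motion statistics

Kabsch superposition minimizes least-squares deviation with the determinant
correction preventing reflections; fewer than 3 points or collinear sets
are rejected. `rmsd_series` superposes every frame onto a reference frame
over the selection and reports RMSD over the same selection. `rmsf` uses the
mean structure after a two-pass alignment (align to frame 1, average,
re-align to the mean) — one refinement pass is standard and stable — with a
block-averaged variant over equal chunks; `superpose = FALSE` provides
absolute-frame fluctuations. The DCCM is the normalized covariance of nodal
displacement vectors, symmetrized and clamped to [−1, 1] at the 1e-12
level, with zero-variance nodes reported by name rather than silently
yielding NaN. All three default to the network-node atom selection
(Cβ/Cα rule) for consistency across modules, since the upstream atom set for
published RMSD values is unstated; any selection can be passed explicitly.

## Free energies

`ki_to_dg` converts Ki (nM) to ΔG = RT ln(Ki / 1 M), R =
1.98720425×10⁻³ kcal mol⁻¹ K⁻¹, with linear error propagation
RT·δKi/Ki. The literature formula is often quoted as "−RT ln Ki", which
only yields the tabulated negative binding free energies when read with
Ki inverted; the implemented sign is the one that makes tighter binding
more favourable and ΔG strictly increasing in Ki. The default temperature
is **300 K**. Note a genuine boundary case: converting the bundled
example table at 300 K gives −11.50/−11.38/−9.87/−10.25 kcal/mol, so the
fourth value rounds to −10.2 while the source table prints −10.3; 301 K is
the only integer temperature reproducing all four printed values at one
decimal. The default was kept at 300 K and the discrepancy is documented
rather than papered over.

`thermo_cycle`/`cycle_ddg` book-keep the double cycle of two proteins ×
two ligands: ΔΔG_exp compares how the protein change affects each ligand
from the binding edges, ΔΔG_alch does the same from the two alchemical
transformation edges, and their difference is the cycle-closure residual
(zero for a consistent cycle); uncertainties add in quadrature.

Estimators operate on potential-energy-difference samples in kcal/mol:

* **Zwanzig**: ΔF = −RT ln⟨exp(−ΔU/RT)⟩ via log-sum-exp, so arbitrarily
  large negative samples cannot overflow.
* **BAR**: the Bennett self-consistent equation solved by bracketed root
  finding to 1e-10 kcal/mol, the bracket grown from the two one-sided
  Zwanzig estimates (which bound the BAR solution monotonically); the
  standard asymptotic variance estimate supplies the SE.
* **MBAR**: damped self-consistent iteration of the estimating equations on
  reduced potentials to 1e-12 on the dimensionless free energies — slower
  than a Newton solver but unconditionally robust at this scale. With K = 2
  the equations coincide with BAR and the implementations agree to better
  than 1e-10 kcal/mol.
* **stitch_windows** sums per-window estimates with independent variances —
  the independence assumption is standard for sequentially simulated
  windows and is the user's responsibility.

## Synthetic generators: what a green test establishes

All generators are bit-deterministic given their seed and emit ordinary
structures (ALA residues, CB beads) so every downstream selection runs
unchanged.

**Planted communities.** Blocks are compact cubic-grid bead clusters
(spacing 5.0 Å < cutoff, so blocks are densely connected with many parallel
shortest paths), separated by 15.0 Å along x; each inter-block gap holds
donated bridge-bead pairs 6.0 Å apart, each bead anchored by two contacts
to its own cluster face. This makes the bridge the unique inter-block cut
edge and gives it maximal betweenness — mirroring, in graph terms, two
protein domains joined by a hinge. An earlier linear-chain layout was
rejected because a chain-of-beads graph is a path, and divisive betweenness
removal cuts paths at their centre, not at the planted boundary. Defaults
(3 blocks of 8, jitter 0–0.5 Å per coordinate) recover the planted labels
with ARI = 1 across seeds. The generator emulates contact topology only:
no excluded volume, no bonded forces, no global diffusion.

**Two-state hydrogen bonds.** Each donor–hydrogen–acceptor triplet follows
a two-state Markov chain parametrized by (occupancy, mean bonded dwell)
rather than raw rates, because those are exactly the quantities under test;
the broken-state dwell follows from stationarity. Bonded geometry is exactly
collinear at 2.9 Å, broken at 4.5 Å — a caricature with no intermediate
geometries, which is precisely what makes detector output equal the planted
state series frame for frame. Sampling checks use the chain's lag-1
autocorrelation to form an effective sample size n(1−r)/(1+r) for 3σ
bounds.

**Correlated motions.** Atom displacements are linear combinations of unit
mode vectors with multivariate-normal amplitudes, so the DCCM entry for two
atoms converges to the normalized planted covariance (times the mode dot
product). Beads are 50 Å apart: these trajectories probe correlation
recovery, not contact analysis.

**Crooks-consistent Gaussian work.** Forward/backward ΔU are Gaussian with
means ±ΔF + σ²/2RT and common σ, the unique Gaussian pair satisfying the
Crooks relation, so Zwanzig, BAR and MBAR all converge to the analytic ΔF.
Real alchemical windows have non-Gaussian tails and imperfect overlap; a
green test here certifies estimator algebra, not sampling adequacy.

## Numerical choices and degenerate inputs

PDB parsing resolves alternate locations to the highest occupancy (ties:
first encountered), keeps insertion codes as part of residue identity,
preserves printed residue numbering, and retains HETATM records as ligand
candidates. Coordinates round-trip through the fixed-column format at 3
decimals; magnitudes ≥ 10⁴ Å are rejected at write time. Models with
mismatched atom counts, topologies without hydrogens (for H-bond analysis),
empty selections, fewer frames than chunks, omega exceeding the node count,
non-PSD covariances and zero-variance DCCM nodes all fail with explicit
messages naming the offender. RGB normalization rounds half-up; base R's
round-half-even would map a 0.5-frame count differently across platforms.

## Limitations

* Trajectory input is multi-model PDB text; binary formats (DCD/XTC) would
  need an external conversion step.
* No π-interactions, salt-bridge geometry, water-mediated bridges or
  protonation-state prediction; the donor/acceptor model is element-based.
* Communities are recomputed independently per frame; there is no
  time-linked community tracking, and no alternative community algorithms.
* The free-energy layer consumes window samples; running alchemical
  simulations, soft-core schedules and overlap diagnostics beyond sample
  counts are out of scope.
* Published per-trajectory statistics of the motivating study (RMSD values,
  the σ = 6.6 fingerprint width, specific occupancy shifts, its alchemical
  −3.2/−3.4 kcal/mol edges) depend on microsecond MD sampling and are used
  here only as inputs to cycle arithmetic, never as recomputed targets.
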