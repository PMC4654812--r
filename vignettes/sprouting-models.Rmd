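---
title: "Cellular Potts models of angiogenic sprouting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cellular Potts models of angiogenic sprouting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`sproutcpm` simulates the collective migration of endothelial cells out of
a spheroid with a two-dimensional Cellular Potts (Glazier–Graner–Hogeweg)
model. Space is a square lattice of 2 µm sites; each cell is a connected
patch of sites sharing an identifier σ, and σ = 0 is extracellular matrix
(ECM). A Hamiltonian

$$H = \sum_{(\vec x,\vec x')} J\big(\tau(\sigma(\vec x)),
      \tau(\sigma(\vec x'))\big)\,\big(1-\delta_{\sigma(\vec x),
      \sigma(\vec x')}\big)
      + \lambda_{\text{size}} \sum_\sigma (A(\sigma)-a(\sigma))^2 + H'$$

balances interfacial energies `J` (summed once over every unordered pair
of 2nd-order — Moore — neighbor sites) against a quadratic area
constraint; `H'` collects the optional cell-length constraint
$\lambda_\text{length}(L-l)^2$ and a large connectivity penalty for copies
that would locally fragment a cell. Dynamics are Metropolis copy attempts:
per Monte Carlo step (MCS, 30 s) as many attempts are made as there are
lattice sites; a random site copies its identifier into a random Moore
neighbor, always accepted when the energy drops and with Boltzmann
probability $e^{-\Delta H/\mu}$ ($\mu = 1$) otherwise. The lattice border
is a frozen ECM frame.

Cells secrete a chemoattractant that diffuses and decays in the ECM,

$$\partial_t c = \alpha\,[\text{cell}] - \varepsilon\,[\text{ECM}]\,c
  + D\nabla^2 c,$$

solved by explicit forward Euler (5-point Laplacian, zero-flux
boundaries, 15 steps of Δt = 2 s per MCS; the stability bound
$D\,\Delta t/\Delta x^2 \le 1/4$ is asserted at construction). Copy
attempts gain a chemotactic bias $\lambda_c\,(c(\vec x)-c(\vec x'))$ so
fluctuations toward higher concentration are favored.

Two sprouting variants are provided:

* **contact inhibition** — the bias acts only where a cell meets the ECM
  (cell–cell copies feel none), and
* **cell elongation** — the bias acts everywhere and cells additionally
  carry the length constraint, with the length measured from the cell's
  inertia tensor.

## Cell length convention

The length of a site patch is $l = 4\sqrt{\lambda_{\max}/a}$ with
$\lambda_{\max}$ the largest eigenvalue of the summed second-moment
tensor about the centroid — exact for ellipses (four standard deviations
along the major axis). Each site contributes an extra 1/12 to the
diagonal moments (a unit square's own moment), so a single site has the
extent of one site and an $n \times n$ square measures $4n/\sqrt{12}$.
Note the convention overestimates a perfect rectangle's side by
$2/\sqrt 3 \approx 1.15$; it is a convention, applied consistently.
Moment sums are integers maintained exactly and incrementally, so no
periodic recomputation is needed and incremental energies agree with full
re-evaluation to machine precision (this is tested).

## Connectivity

A copy that would split the retracting cell *locally* — the cell's sites
within the Moore neighborhood of the target site fall into more than one
8-connected component — incurs `connectivity_penalty` (default 1e5). The
test suite verifies cells remain globally connected over long runs; the
local test is the standard inexpensive surrogate for a global component
search.

# VEGF–Dll4–Notch signaling

Each cell carries five levels: Dll4 ($D_i$), Notch ($N_i$), NICD
($S_i$), VEGFR2 ($R_i$) and VEGF activity ($A_i$). Notch binds Dll4 of
contacting cells (trans-activation, producing NICD), Dll4 and Notch
mutually deactivate within a cell (cis-inhibition), NICD represses Dll4
and VEGFR2 production, VEGF activity — a saturating function of
$R_i V_{\text{ext}}$ under the uniform external VEGF field
($V_{\text{ext}} = 1$) — feeds back onto Dll4 production. Trans terms
are weighted by the shared-membrane factor $|P_{ij}|^2/(|P_i||P_j|)$,
where membrane and contact sizes are counted as 4-neighborhood boundary
links (symmetric, and a cell's summed contacts can never exceed its
membrane). *Vegfr2*^+/-^ cells have both VEGFR2 production terms halved.

Integration is forward Euler, 10 substeps of Δt = 3 s per MCS, with the
contact map frozen within an MCS. Negative Euler overshoots are clipped
at zero and counted. Accuracy is validated against a high-order adaptive
integrator (`deSolve::lsoda`) with the global error halving as the step
halves.

A cell differentiates to **tip** when $S_i$ is below `nicd_threshold`
(boundary value → stalk), re-evaluated after each MCS's substeps; the
tip/stalk kinds feed back into the `J` and $\lambda_c$ lookups.

## Parameter calibration

The rate constants are not fixed by first principles here; they were
calibrated once, before any acceptance measurement, to the qualitative
targets the biology dictates: (i) a perturbed pair of identical cells in
contact diverges to one high-Dll4/low-NICD and one low-Dll4/high-NICD
cell; (ii) even rings of cells settle into perfectly alternating
(salt-and-pepper) phenotypes, odd rings keep at least one frustrated
pair; (iii) with VEGF, Dll4 and VEGFR2 levels are strongly positively
correlated across cells; and (iv) in mixed populations wild-type cells
adopt the tip fate more often than *Vegfr2*^+/-^ cells. All rates are
per second with decay constants 0.002 s⁻¹ (≈ 8 min half-life, a
transcriptional timescale); the NICD production gain and its Hill
midpoint (`alpha_S = 0.008`, `k_S = 0.01`, both Hill exponents 2) set
the lateral-inhibition loop gain above the bistability threshold at
lattice-typical contact weights. `nicd_threshold = 1` sits in the valley
between the two NICD modes those defaults produce;
`calibrate_nicd_threshold()` recomputes it as the midpoint of the
optimal two-cluster split of measured steady-state NICD levels and
fails loudly on unimodal input.

# Potts parameter calibration and the sprouting regime

The interfacial energies and chemotactic strengths of the two variants
are calibration choices (on the µ = 1 scale). Transcribing the published
energy *ratios* of the prior contact-inhibition and elongation models did
not destabilize a compact spheroid in this implementation — with the
unsaturated chemotaxis term the self-secreted field compresses the rim
(retractions up-gradient are favored, extensions penalized), and the
spheroid stays round. The calibrated regime instead supplies cohesion
through chemotaxis rather than adhesion:

* contact inhibition: `J_cc = 1.2`, `J_cE = 0.4` (cell–cell contact
  energetically unfavorable), `lambda_c = 5`. The spheroid develops a
  branched star of blunt sprouts.
* cell elongation: `J_cc = 0.8`, `J_cE = 0.4`, `lambda_length = 1`,
  `L = 40` sites (80 µm), `lambda_c = 10`. Long thin sprouts of aligned
  elongated cells radiate from the spheroid, and cells slide along one
  another at multi-cellular sprout tips — the configuration in which tip
  overtaking is frequent.

The field parameters are the published ones from the cited prior models:
α = ε = 1.8 × 10⁻⁴ s⁻¹ and D = 10⁻¹³ m²/s, giving a diffusion length
$\sqrt{D/\varepsilon} = 24$ µm (about one to two cell diameters).

The printed differential tip/stalk parameter sets are installed verbatim
by `apply_behavior_mode()`: reduced tip adhesion
(`J_ss = 0.2, J_tt = J_st = 0.8, J_cell,ECM = 1`) or reduced tip
chemosensitivity (`lambda_c` 5 for tips vs 10 for stalks with uniform
`J` 0.4/0.6). Under the differential-adhesion energies the desk-scale
aggregate remains compact with transient bumps; tip-occupancy statistics
then rest on few sprout records per seed, which the binomial test
accommodates through its small n.

# Sprout detection and analysis

Per sampled frame (every 20 MCS) the cell mask is closed with a disk of
radius `r`, thinned to a one-site skeleton (Zhang–Suen), terminal
branches shorter than `p` are pruned and nodes within `m` sites merged
(`r = 4, t = 4, p = 10, m = 10` for the contact model;
`r = 2, t = 5, p = 25, m = 15` for the elongation model). Because full
topology-preserving thinning subsumes any fixed number of safe thinning
passes, the `t` parameter is carried for provenance but does not change
the skeleton. A sprout is an edge from a branch node `B` to an end node
`E`; at reduced scale the skeleton is frequently a single branchless
segment, whose two ends are both scored as tips (each against the
opposite end) — without this the desk preset would carry no sprout
records on most frames.

The leader cell is found geometrically: first guess `G` = the cell
containing `E` (or the dominant cell among its neighbors when `E` is in
the ECM); the tip site `T` = the farthest cell site along the ray from
`B` through `E` followed by at least five consecutive ECM sites (rays
are Bresenham-rasterized; if no site qualifies, the farthest cell site
on the ray); cells on the perpendicular through `T` that neighbor `G`
(8-neighborhood) are candidates, filtered by requiring their shortest
cell-adjacency path to `B`'s cell (unit-weight Dijkstra via igraph) to
be at least `G`'s; the candidate owning the site farthest (Euclidean)
from `B` wins, ties to the smaller id. Distances are Euclidean rather
than along-path, and exact rasterized line membership is required — both
choices where the geometric construction leaves room.

Sprout identity over time is by member-set overlap
(|∩| / min(|A|,|B|) ≥ 0.5 against recently seen sprouts, with a
two-frame grace before an identity closes). Members are the leader plus
up to ten nearest neighbors by layered contact expansion ordered by
contact size.

## Kinetics

* **Overtakes**: a leader change where both outgoing and incoming leader
  persist ≥ 80 consecutive MCS (40 min); shorter tenures are protrusion
  flicker and produce no event. Rates are events per sprout per
  20,000 MCS over the analysis window.
* **Lifetimes**: all contiguous leader tenures, in minutes, with
  birth/death-truncated tenures flagged.
* **Coordination / motility**: per-20-MCS displacement angles against
  the sprout axis (start→end of the mean branch/tip positions at the
  sprout's first and last frames); displacements under 0.5 sites are
  "stopped".
* **MSD**: positions projected on the axis, squared displacement from
  each track's start, averaged per lag and fitted with
  $\mathrm{MSD}(t) = 2Dt + (vt)^2$ by non-negative least squares on the
  equivalent straight line $\mathrm{MSD}/t = 2D + v^2 t$ — the division
  by $t$ stabilizes the variance so that drift-dominated long lags do
  not swamp the dispersion coefficient (verified by parameter-recovery
  simulation: at 10⁴ synthetic tracks D is recovered within 10 % and v
  within 5 %).

# Scale, problem sizes, and what the tests show

The `paper` preset mirrors the source conditions (400 × 400 lattice,
spheroid radius 45, 30,000 MCS, window 10,000–30,000; batches of 15–30
seeds are hour-scale). Development, testing and the acceptance script
use the `desk` preset (200 × 200, radius 25, 6,000 MCS, window
2,000–6,000) and the `mini` preset (140 × 140, radius 18, 3,000 MCS) —
sizes chosen so a seed completes in tens of seconds on one core. At
these scales a spheroid holds ~25–40 cells and sprouts are a few cells
long; consequences, stated plainly:

* overtake rates and especially mean tip lifetimes sit well below the
  full-scale values, because blunt few-cell tips make the geometric
  leader assignment flicker between two or three near-equivalent cells,
  fragmenting tenures;
* dispersion coefficients are an order of magnitude below full-scale
  values (shorter sprouts constrain axial excursions);
* directional contrasts survive the scale reduction and are what the
  acceptance tests assert: the elongation model overtakes more than the
  contact model, wild-type cells out-differentiate and out-occupy
  haploids, and occupancy falls with the mixing ratio.

The synthetic-data generators used by the tests (handcrafted label
lattices, drift+diffusion track generators, ring/grid contact graphs)
emulate the *structure* of simulator output, not its correlations: real
sprout tracks have correlated displacements and sprouts share cells,
which the independent-track generators ignore. Passing tests therefore
validate the estimators and the machinery, not the biological realism of
any particular parameter set.

# Degenerate inputs and numerical guards

Vacuous copies (equal labels) signal a no-op; an empty site set has no
length; empty masks give empty graphs; a ray through pure ECM gives an
undefined leader and the sprout is skipped; occupancy with zero sprouts
and MSD fits with fewer than three usable lags raise errors rather than
returning numbers. Signaling levels are clipped at zero with a count of
clips. All stochastic draws — Potts dynamics, genotype assignment,
signaling noise — come from R's global RNG, so `set.seed()` makes every
run bit-reproducible (tested).
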