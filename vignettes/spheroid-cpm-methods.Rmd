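---
title: "Methods: a Cellular Potts Model of chondrocyte spheroid formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Cellular Potts Model of chondrocyte spheroid formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological question

Primary chondrocytes isolated from the surface (SZ), middle (MZ) and deep
(DZ) longitudinal depth zones of articular cartilage self-organize into
strikingly different structures when 1,000 cells are seeded into a
round-bottom low-adhesion well: SZ cells form a single large spheroid with a
cell-rich rim and matrix-rich core, MZ cells fragment into many small, tight
cell clusters with little internal matrix, and DZ cells fall in between.
This package implements a 3D Cellular Potts Model (CPM) in which those
differences emerge from a handful of zone-specific parameters — adhesion
energies, extracellular-matrix (ECM) secretion probabilities and an ECM
decay speed — several of which are linear translations of relative
gene-expression levels (RT-qPCR RQ values) measured during spheroid
formation.

## The model

### State

The simulation state is a 3D integer lattice in which each voxel carries the
id $\sigma$ of the compartment occupying it. A compartment is one simulated
object: a cell, a blob of *structural* ECM (ECMst: collagen-I-like,
cell-binding), a blob of *volumetric* ECM (ECMv: aggrecan / collagen-II /
hyaluronan-like, water-retaining, non-cell-binding), or the culture medium.
The medium is a single compartment with id 0. Each non-medium compartment
has a realized volume $V_\sigma$ (its voxel count, maintained exactly) and a
target volume $V_{target}(\sigma)$.

### Hamiltonian

The energy of a configuration is

$$H = H_{contact} + H_{volume},$$

$$H_{contact} = \sum_{\vec i, \vec j\ \mathrm{neighbors}}
  J\big(\tau(\sigma_{\vec i}), \tau(\sigma_{\vec j})\big)
  \big(1 - \delta_{\sigma_{\vec i}, \sigma_{\vec j}}\big), \qquad
H_{volume} = \sum_{\sigma} \lambda_{vol} \big(V_\sigma -
  V_{target}(\sigma)\big)^2 .$$

$J(\tau, \tau')$ is the contact energy per boundary bond between voxels of
compartments of types $\tau, \tau'$; lower $J$ between cells means stronger
effective adhesion. Each unordered neighbor pair is counted once, so the
printed $J$ values act directly as bond energies and the local energy change
of a move is exactly antisymmetric under its reverse. Pairs inside one
compartment contribute nothing (the $1-\delta$ factor), and the medium
carries no volume term. The volume constraint applies to cells and (by
default) to ECM compartments; `ecm_constrained = FALSE` switches the ECM
volume term off, for users who prefer the alternative reading of the
parameter table's empty ECM-target entry.

Under the default fixed-medium boundary, sites outside the lattice behave as
medium: they contribute medium bonds at the walls and can act as copy
sources, which models the open culture medium around the spheroid. A
periodic boundary is available for calibration tests.

### Dynamics

The state advances by Metropolis index-copy dynamics. One attempt samples a
target voxel uniformly, then a source site uniformly among its neighbors
(order-2 neighborhood by default, 18 neighbors); if the two labels differ,
the local energy change $\Delta H$ is computed and the copy is accepted with
probability $\min(1, e^{-\Delta H / T_m})$, with domain temperature
$T_m = 37$. One Monte Carlo Step (MCS) is one attempt per lattice voxel
(configurable), followed by the lifecycle sweep below. The clock is
calibrated as 1 MCS = 6 min, 240 MCS = 1 culture day, with MCS 0
representing culture day 1 (so MCS 720 is day 4 and MCS 3120 is day 14).

The acceptance rule's functional form and the one-sweep-per-MCS convention
are the standard CPM choices; both are config-exposed because the day
calibration depends on them.

### Lifecycle

Once per MCS, every compartment is updated in freshly randomized order
(avoiding id-order artifacts):

* **Cells** grow their *target* volume by $v_g$ per MCS — the realized
  volume follows through the volume constraint, which is the only mechanism
  in the model that moves realized volumes. A cell whose realized volume
  exceeds $V_{Death} = 60$ is deleted (voxels become medium; rare in
  practice, counted). A cell whose realized volume exceeds the action
  threshold $V_A = 20$ draws its stochastic actions: mitosis with $P(M) =
  1\%$ per MCS, and — unless a division fired (division pre-empts secretion
  that MCS; a config flag makes the draws fully independent) — ECMst
  secretion with $P(ECMst)$ and ECMv secretion with $P(ECMv)$, two
  independent draws, so a cell may secrete both kinds in one MCS.
* **Mitosis** splits the cell with a random-orientation plane. Voxels are
  ordered by their projection on a random unit normal and cut at the median:
  the plane passes through the centroid for symmetric bodies and the halves
  differ by at most one voxel. (A literal plane through the centroid can
  produce an 18/9 split on a 3-voxel cube — an axis-aligned plane through
  the middle layer — so the median cut is used, which is also the common CPM
  mitosis implementation.) Parent and daughter both get target volume
  $V_{Cell}/2 = 15$, below $V_A$, so offspring are quiescent until they
  regrow.
* **Secretion** creates a new ECM compartment at medium voxels face-adjacent
  to the cell: a uniformly chosen adjacent medium voxel anchors an (up to)
  2×2×2 seed block (the block position holding the most medium is chosen,
  ties broken by RNG), and the volume constraint grows the newborn toward
  $V_{ECMInit} = 30$. Placement is the minimal assumption consistent with
  pericellular deposition. A fully enclosed cell secretes nothing (the draw
  is counted as blocked) — this self-limits ECM production to cells with
  medium contact and is what stops the matrix content from growing without
  bound.
* **ECM** compartments decay their target volume by $v_d$ per MCS (there is
  no fixed ECM target: the decaying target *is* the ECM volume law). When an
  ECM compartment's realized volume falls below $V_{Delete} = 3$, it is
  deleted and replaced by medium.

### Parameters

`build_parameter_set(zone)` returns the full parameter column for a zone.
Volumes are in voxel³, speeds in voxel³/MCS, probabilities in %/MCS,
energies per neighbor bond. The zone-specific entries are:

| parameter | SZ | MZ | DZ | meaning |
|---|---|---|---|---|
| `v_g` | +0.080 | +0.060 | +0.060 | cell target-volume growth speed |
| `P_ECMst` | 3.2 | 0.67 | 3.0 | ECMst secretion probability |
| `P_ECMv` | 3.2 | 9.3 | 8.3 | ECMv secretion probability |
| `v_d` | 0.003 | 0.027 | 0.097 | ECM decay speed (32-fold DZ/SZ) |
| `J_cell_cell` | 5.0 | 2.5 | 2.5 | cell-cell contact energy |
| `J_medium_ECM` | 20 | 2.5 | 2.5 | medium-ECM contact energy |

All other entries are zone-independent: $V_{Cell} = 30$, $V_{CellInit} =
27$, $V_A = 20$, $P(M) = 1.0$, $V_{parent} = V_{daughter} = V_{Cell}/2$,
$V_{Death} = 60$, $V_{ECMInit} = 30$, $V_{Delete} = 3.0$, $\lambda_{vol} =
10$, $T_m = 37$, $J$(medium-medium) $= 0$, $J$(medium-cell) $= 5.0$,
$J$(cell-ECM) $= J$(ECM-ECM) $= 10$. Two wrinkles are worth noting. First,
the parameter table and the running text disagree on $P(ECMst)$ for SZ (3.2
vs 3.3 %/MCS); the table value 3.2 is the default. Second, although the
cell-cell energy is described as set "lower than the others",
$J$(SZ cell-SZ cell) equals $J$(medium-cell); the table values are used
verbatim. The single medium-ECM row applies to both ECM classes. Simulations
are single-zone, so cross-zone contact never arises under the defaults.

The very high SZ medium-ECM energy (20 vs 2.5 elsewhere) is the engine of
the SZ core-shell morphology: ECM exposed to medium is costly, so ECM blobs
are engulfed into the aggregate's interior while cells (medium-cell = 5)
coat the surface.

### Gene-expression translation

Five parameters are anchored linear rescalings of day-7 RQ values measured
relative to SZ: proportional for Col1a1 → `P_ECMst`, Col2a1 → `P_ECMv`,
Mmp13 → `v_d`, Pcna → `v_g`, ItgaV → `J_cell_ECM`, and *inverse* for Cdh2 →
`J_cell_cell` (more cadherin ⇒ stronger adhesion ⇒ lower contact energy; the
direction choices reproduce the ordering of the zone columns).
`rq_to_parameter()` implements the map, `translate_parameters()` applies a
whole RQ table. The exact functional form is not published; anchored linear
scaling is this package's choice, validated by the round-trip test that the
back-solved RQ table reproduces every translated zone value to 2 significant
figures. The packaged RQ table (`default_rq_table()`) is itself *derived* by
back-solving the parameter columns, because the numeric day-7 RQ values are
published only graphically; it is a provenance path, not a dependency — the
defaults are the literal parameter values.

## Initialization

`seed_zone()` builds the 0-MCS state: 1,000 cells plus ECMst/ECMv at ratios
8:1:1 (SZ) or 4:4:3 (MZ, DZ), every compartment a 3×3×3 block (27 voxel³),
placed on random non-overlapping slots of a cylinder resting on the
substrate plane $z = 0$ (cells start at $V_{target} = V_{Cell} = 30$, ECM at
$V_{ECMInit} = 30$).

The printed cylinder dimensions (diameter 36/84/84, height 5/3/3 for
SZ/MZ/DZ) cannot literally hold 1,000 cells of 27 voxels: a 36 × 5 voxel
cylinder has ≈5,089 voxels but the SZ seeding needs 1,250 × 27 = 33,750.
The default `unit_mode = "cell-slot"` therefore reads those dimensions in
*cell-slot* units of 3 voxels (SZ cylinder 108 × 15 voxels ≈ 5,089 slots ≥
1,250 compartments), which preserves the published aspect ratios and
cell-count-to-area relationships; `unit_mode = "voxel"` honors the literal
text and fails with a capacity report. Placement samples distinct slots
uniformly, which guarantees non-overlap without rejection loops.

Lattice dimensions are not published; the default derives them from the
seeding geometry (XY = 1.5× the cylinder diameter, Z = cylinder height plus
half a diameter of headroom, at least 16 voxels), configurable. The
substrate is the flat fixed-medium plane below $z = 1$ — the model has no
wall compartment class, so a curved-well mask is out of scope.

Reduced cultures (`n_cells` below 1,000) rescale the cylinder diameter by
$\sqrt{n/1000}$, preserving seeding density, and keep the height.

## Morphometrics

* `find_clusters()` labels face-connected (order-1) components of the voxel
  lattice — *all-matter* mode (cells + ECM) defines a "spheroid",
  *cells-only* mode defines "cell clusters"; both notions are used because
  the two ECM classes blur the boundary between one spheroid and many cell
  clusters. Compartments are assigned to the component holding the majority
  of their voxels. Note that a pure-ECM cluster exists in all-matter mode
  but not in cells-only mode, so the two counts are not ordered in general;
  cells-only clusters refine the cell-containing all-matter clusters.
* The spheroid **diameter** is the XY-projected equivalent circular diameter
  $2\sqrt{A/\pi}$ of the cluster footprint, matching how diameters are read
  off inverted-microscope images; the equivalent-sphere diameter
  $(6V/\pi)^{1/3}$ is reported alongside. `diameter_ratio()` compares the
  largest cluster (by voxel count, ties broken toward the substrate) across
  two snapshots — the day-14 / day-1 growth readout.
* `radial_profile()` reports voxel-type fractions in concentric equal-width
  shells around a cluster centroid (medium included, so shell fractions sum
  to 1) — the core-shell readout.

## Numerical conventions and degenerate cases

* Bond counting: once per unordered pair; each bond from an in-lattice voxel
  to a virtual out-of-lattice medium site counts once.
* $\Delta H$ is computed locally (target voxel's bonds plus the two affected
  volume terms) and equals the full-Hamiltonian difference to $10^{-9}$ —
  the randomized oracle test — *except* for moves that annihilate a
  compartment: the penalty $\lambda V_{target}^2$ is paid in the
  annihilating $\Delta H$, after which the registry drops the compartment
  (so it stops contributing to later totals). Annihilations are counted.
* Same-label draws count as attempts but trigger no energy evaluation.
* A division of a 1-voxel cell is impossible and skipped with a log entry;
  secretion with no adjacent medium is blocked and counted.
* Realized volumes sit slightly below target because shrinking also removes
  boundary bonds; for a lone decaying ECM blob this advances deletion
  relative to the ideal $(V_{ECMInit} - V_{Delete})/v_d$ by ≈6–10% at
  neighborhood order 1 and ≈13–16% at order 2. The lifetime test uses
  order 1.
* All randomness — sweeps, lifecycle draws, division planes, placement —
  flows through R's global RNG, so `set.seed()` fixes an entire trajectory,
  and snapshots archive the RNG state so a resumed run is bit-identical to
  an uninterrupted one.

## What the reduced-scale experiments do and do not show

Full-scale cultures (1,000 cells, 3,120 MCS, ≈2.6M-voxel lattice for SZ)
reproduce the 14-day experiment but cost hours per seed. The packaged tests
and the acceptance script therefore run a *reduced surrogate*: 100 cells on
a $\sqrt{1/10}$-rescaled cylinder for 720 MCS (the day-4 mark, where
aggregation into 3D structures is established), with 5 seeds per condition
in the test-suite and 3 in the acceptance script. At this
scale the machinery is identical and the qualitative zone contrasts are
robust: the SZ largest-spheroid diameter ratio exceeds 1, MZ cultures show
more cells-only clusters than SZ, the SZ spheroid core is ECMv-enriched
while its rim is cell-enriched, and raising the decay speed `v_d` from the
SZ to the DZ value lowers total ECM content. What the reduced scale does
*not* establish is quantitative day-14 magnitudes, nor long-horizon
phenomena such as late cluster merging. Two further caveats apply to any
scale. The diameter ratio is dominated by the day-1 reference: the seeded
cylinder occupies only ~25% of its slots, below the face-percolation
threshold, so the largest day-1 cluster is a small island and ratios are
large; measuring the whole seeded territory instead would give much smaller
ratios. And at the default per-MCS proliferation and secretion rates, matter
grows fast enough that long runs become domain-limited on any fixed lattice
— not unphysical for a bounded culture well (the fixed-medium boundary plays
the well wall), but lattice size then shapes late-time diameters.

The generator also idealizes the biology: phenotypes are fixed at their
day-7 translation for the whole run (no dynamic gene regulation), the
medium is passive (no convection, nutrients or signaling fields), cells do
not migrate actively, and the substrate is flat rather than U-shaped.
Passing tests validate the model's internal consistency and its qualitative
morphogenesis, not those excluded mechanisms.

## Known limitations

* Compartments may fragment under CPM dynamics; no connectivity constraint
  is enforced (none is defined in the model).
* Cross-zone co-culture is not exercised by any default; the contact table
  is typed, not zone-pair-typed, so mixing zones in one state would need a
  custom `J`.
* The day calibration (240 MCS/day) is tied to the one-attempt-per-voxel
  sweep convention; changing `attempts_per_mcs` rescales simulated time.
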