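---
title: "Methods: juxtamembrane lipid-interaction fingerprints from synthetic membrane trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: juxtamembrane lipid-interaction fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-pass receptor tyrosine kinases (RTKs) carry, immediately C-terminal
of the transmembrane (TM) helix, a short juxtamembrane (JM) segment that is
enriched in basic residues across the whole 58-member human family. Those
basic clusters interact electrostatically with the anionic lipids of the
inner plasma-membrane leaflet — phosphatidylserine (PS, net charge −1) and
especially phosphatidylinositol-4,5-bisphosphate (PIP₂, a multiply charged
headgroup) — drawing them into annular shells around the receptor. `jmlipid`
implements the complete analysis stack for quantifying that behaviour from
membrane trajectories: per-residue contact matrices, occupancy fractions,
mean residence times, unit-area-normalized lateral radial distribution
functions (RDFs), occupancy density maps, clustering propensities, and
family-wide positional aggregation; plus a seeded synthetic trajectory
generator so every stage is testable without large-scale coarse-grained MD
data.

## The synthetic membrane emulator

### Model

The emulator is deliberately minimal: a two-dimensional square periodic box
represents the inner-leaflet surface, each lipid is a single headgroup bead,
and the protein is a fixed set of anchor beads — one TM anchor at the box
centre plus one anchor per JM residue at spacing 3.5 Å along a fixed
direction, encoding the surface-lying pose of the JM arm. All analyses in
scope are lateral (contacts near the membrane surface, in-plane density,
annular shells), so a 3D bilayer would add cost without adding anything the
analyses could detect; dimensionality is the first deliberate simplification.

Lipids follow overdamped Langevin (Brownian) dynamics:

\[ \Delta x_i = -\frac{D_i}{k_BT}\,\nabla U\,\Delta t \;+\;
   \sqrt{2 D_i \Delta t}\,\eta, \qquad \eta \sim \mathcal N(0,1) \]

with the potential

\[ U = \sum_{\text{pairs}} U_{\mathrm{WCA}}(r) \;+\;
   \sum_{\substack{\text{charged anchor,}\\ \text{charged lipid}}}
   \epsilon_{\mathrm{elec}}\, q_{\mathrm{res}} q_{\mathrm{lip}}
   \frac{e^{-r/\lambda_D}}{r}. \]

The WCA (purely repulsive Lennard-Jones) term acts on all lipid–lipid and
lipid–anchor pairs and provides excluded volume; the screened-Coulomb
(Yukawa) term acts only between charged residues and charged lipid
headgroups. Lipid–lipid electrostatics are omitted: the phenomenon of
interest is protein-driven sequestration, and leaving inter-lipid repulsion
out keeps the single free parameter interpretable.

### Parameters, units and defaults

Lengths are in Å, energies in units of \(k_BT\), and time in an arbitrary
unit \(\tau\) fixed by the uniform lateral diffusion coefficient
\(D = 1\;\text{Å}^2/\tau\) (no per-species diffusion data are available for
the systems emulated, so all species share \(D\); this is documented rather
than hidden).

| parameter | default | why |
|---|---|---|
| box edge | 160 Å | the 20-residue arm (70 Å) must stay under half the box |
| lipids | 400 | ≈64 Å² per lipid, a realistic headgroup area |
| bead radius | 2.35 Å | contact distance 4.7 Å, so the first shell sits near 5 Å |
| charges | PC/PE/CHOL 0, PS/GM3 −1, PIP₂ −4 | only the relative anionic strength is dictated by the biology; −4 is a MARTINI-like net headgroup charge |
| Debye length | 7.8 Å | 0.15 M NaCl screening |
| timestep | 0.005 τ | stability margin for the stiff WCA core (see below) |
| frames × stride | 600 × 100 | 300 τ of production per replicate |
| equilibration | 20 000 steps | 100 τ, enough for the first shell to populate from a uniform start |
| replicates | 3 | mirrors triplicate production runs with different seeds |
| ε_elec | calibrated, see below | the one free parameter |

Composition handling is exact bookkeeping: lipid counts are apportioned by
largest remainder with ties broken by species-name order, so an 80:10:10
PC:PS:PIP₂ leaflet of 200 lipids is 160/20/20 deterministically. Initial
positions are rejection-sampled with a hard-core minimum distance of one
bead diameter, also keeping clear of the protein anchors (otherwise a lipid
placed on top of an anchor makes the first step violent).

### Calibration of the electrostatic coupling

Everything except \(\epsilon_{\mathrm{elec}}\) is fixed a priori.
`calibrate_affinity()` scans a geometric grid of couplings, runs short
replicate simulations at each, and returns the smallest value whose mean
first-interaction-shell PIP₂ count (beads within 6 Å of the anchor set)
falls in the 4–6 window reported for JM-bearing receptor systems. The
shipped default, `default_epsilon_elec()`, was fixed once by this procedure
for the INSR-like reference layout in the 80:10:10 leaflet, and the scan is
shipped as `inst/extdata/calibration_log.csv`. The mean first-shell count
is monotone in the coupling (a property the test suite asserts), so the
calibration is well posed.

### Numerical choices

* **Integration** is explicit Euler–Maruyama. The WCA core is stiff; at a
  timestep of 0.005 τ the linearized stability bound is respected for the
  compressions that occur at the calibrated coupling, and as a guard the
  deterministic drift per step is capped at a quarter of the contact
  distance (standard Brownian-dynamics force capping). A bead displaced
  more than half the box in one step raises an instability error advising
  a smaller timestep rather than wrapping silently.
* **Determinism**: every stochastic operation takes an explicit seed;
  replicate \(r\) of a run seeded \(s\) uses \(s + r\) for both its initial
  placement and its noise stream, and identical seeds give bit-identical
  trajectories (asserted in the tests).
* **Minimum image** on the square periodic box is used for every distance;
  RDF range is capped at half the box edge so annuli are complete.
* **Contact boundary** is inclusive (≤ 6 Å).

## The analyses

* `count_contacts()` — per-residue × per-frame counts of species beads
  within the cutoff; replicates concatenate along the frame axis but event
  statistics never bridge the seam.
* `mean_contacts()`, `occupancy_fraction()` — time averages per residue.
* `residence_time()` — occupancy time divided by the number of association
  events, where an event is a maximal run of consecutive occupied frames in
  the binarized series. This is the literal per-residue formula; tracking
  individual lipid dwell times is a documented alternative that the package
  does not make the default (a residue statistic, not a lipid statistic).
  A `gap_tolerance` option can merge short vacancies, but the default is 0
  (no smoothing is described for the source analysis).
* `lateral_rdf()` — minimum distance from each bead to the whole anchor set
  (TM + JM; the distance reference is a design choice the source leaves
  open — anchor-set minimum distance is used because the JM arm, not the
  receptor centre of mass, organizes the shells), annulus-area
  normalization, then rescaling to unit area under the curve. The unit-area
  convention removes dimensional prefactors, which is also why a lateral
  (2D) RDF is directly comparable with a spherical one after this
  rescaling. `first_peak()` finds the first strict local maximum.
* `density_map()` — per-cell fraction of frames with ≥1 bead of the
  species in the cell (a VolMap-style occupancy surface on a 2D grid).
* `rmsf()` — per-label RMS fluctuation about the time-mean position, no
  alignment (anchors are fixed by construction; alignment of ingested
  external tracks is the ingesting adapter's responsibility).
* `clustering_propensity()` — the mean per-frame fraction of a species'
  population within 6 Å of the protein divided by the species' leaflet mole
  fraction. This is the literal published formula; note that under it, a
  completely non-interacting species has a baseline value equal to the
  accessible shell-area fraction divided by the leaflet fraction (the test
  suite computes that geometric baseline by direct integration), so
  propensities should be compared between systems or species, not read as
  absolute enrichment factors. An alternative reading — shell composition
  relative to leaflet composition, which equals 1 for no enrichment — is
  deliberately not the implementation, because the module contract fixes
  the per-population form. For complex leaflets the denominator is the mole
  percent among *all* inner-leaflet species, cholesterol included.
* `positional_mean_contacts()`, `positional_residue_probability()` — the
  family view: per-JM-position mean contacts (sum over receptors divided by
  the receptor count) and per-position residue-class/amino-acid
  probabilities (the numeric content of a sequence logo; rendering is out
  of scope).
* `charge_propensity_correlation()` — Pearson (default; Spearman optional)
  correlation between propensity and net JM charge, restricted by default
  to receptors with net positive JM charge. Saturation of the propensity at
  high charge is reported descriptively by the scan output, not tested
  inferentially — there is no statistical model for it in the source
  analysis.

Net JM charge counts R/K as +1 and D/E as −1. Histidine is counted neutral
and polar: only Arg and Lys act as the basic contact drivers, and no
protonation model is in scope. Glycine and proline are classed non-polar so
that exactly four classes cover all 20 residues. Termini are uncharged
(models are mid-protein fragments).

## What the synthetic generator does and does not show

The emulator reproduces the *statistical structure* the analyses assume:
annular shells at multiples of the contact distance, the preference
ordering PIP₂ > PS > PC in the first shell, competition (PS clustering
rises when PIP₂ is removed), loss of clustering in basic→Leu mutants and in
TM-only controls, and a positive charge–propensity relationship with
saturation. It does **not** emulate: headgroup chemistry beyond a point
charge, lipid acyl-chain packing or cholesterol ordering, membrane
curvature or undulation, protein conformational dynamics (anchors are
immobile), inter-lipid electrostatics, or outer-leaflet species dynamics
(GM3/cholesterol enter composition bookkeeping only). Passing tests
therefore validate the analysis pipeline and the qualitative electrostatic
mechanism, not quantitative agreement with any particular force field.

## Problem sizes

Default production runs (3 × 600 frames of a 400-lipid box) complete in a
few minutes on one CPU; the comparative suites (mutant, competition, family
scan) use the same geometry with 300-frame replicates, and small-box
systems (60 Å, 56 lipids, short JM arms) serve the purely numerical
properties. These sizes were chosen so the full pipeline is routinely
re-runnable at a desk, and they are stated here so results can be
reproduced at exactly the same scale.

## Worked example

```r
library(jmlipid)

model <- insr_like_model()
comp  <- leaflet_composition(PC = 0.8, PS = 0.1, PIP2 = 0.1)
cfg   <- sim_config(seed = 1)
trajs <- simulate_replicates(model, comp, cfg, n_replicates = 3)

first_shell_count(trajs, "PIP2")          # mean first-shell PIP2 count
first_peak(lateral_rdf(trajs, "PIP2"))    # first RDF peak (Å)
cm <- count_contacts(trajs, "PIP2")
head(sort(mean_contacts(cm), decreasing = TRUE))
residence_time(cm)[c("JM1", "JM5")]
clustering_propensity(trajs, "PIP2", comp)
```

## Known limitations

* The 2D single-bead representation cannot express headgroup orientation
  or partial burial; the 6 Å shell is a proxy validated only against the
  emulator's own geometry.
* Residence times depend on the frame interval (a vacancy shorter than one
  frame is invisible); compare residence times only between runs with the
  same interval.
* The text trajectory format stores labels and coordinates only; residue
  classes and charges of anchors are not round-tripped (use the rds medium
  when full metadata must survive).
* `calibrate_affinity()` calibrates against one window statistic; systems
  with very different anchor layouts may need re-calibration.
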