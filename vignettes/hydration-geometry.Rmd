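---
title: "Hydration-shell geometry of crystalline proteins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydration-shell geometry of crystalline proteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model behind
each analysis, the tunable parameters and their defaults, what the
synthetic generators do and do not emulate, and the numerical and design
choices a maintainer would want written down.

## The system and its representation

A crystalline protein at hydration level h (grams of water per gram of
protein) is represented as a `wat_structure`: a tibble of atoms with an
orthorhombic periodic box and metadata carried as attributes, so
structures flow through dplyr verbs without losing their cell. A
trajectory is an ordered list of coordinate frames over one topology.
Only rectangular cells are supported; the supported space groups are P1
and P4₁ (the tetragonal 4₁ screw group, four operators), which cover
triclinic reference cells and the classic tetragonal lysozyme/nuclease
crystal forms. P4₁ expansion refuses cells with a ≠ b, since a 90°
rotation in fractional coordinates of a non-square cell would distort
distances. Wrapping into the unit cell is by *molecular centroid* — each
water, ion, or whole protein chain moves as a unit — so no molecule is
ever split across a boundary.

Atoms are partitioned into exactly five classes: `water`, `ion`,
`main_chain` (backbone N, CA, C, O, OXT and their hydrogens), and
hydrophobic or hydrophilic side chains. The hydrophobic set defaults to
{ALA, VAL, LEU, ILE, PRO, PHE, MET, TRP, GLY} — a standard
Kyte–Doolittle-style binary split; the analysis only ever needs the
binary distinction, and the set is an argument everywhere it matters.
Unknown residues fall back to hydrophilic with a warning rather than an
error, because HETATM ligands should not abort a hydration profile.
Hydrogens count as protein atoms in all surface-distance calculations.

## The hydrogen-bond criterion

A donor–acceptor pair is bonded when the donor-heavy to acceptor
distance is strictly below 3.5 Å *and* θ = 180° − ∠(D–H···A) is at most
60° for at least one donor hydrogen. Two boundary conventions are fixed
and tested: a pair at exactly 3.5 Å is *not* bonded (strict inequality),
and a D–H···A angle of exactly 120° *is* (the angle window [120°, 180°]
is closed at its lower edge; whether that edge is open is not decidable
from the usual statement of the criterion, so the inclusive reading was
chosen and documented). Donors are water and protein O–H and N–H groups;
acceptors are water oxygens, protein oxygens, and protein nitrogens
bearing no hydrogen. Hydrogen-to-heavy-atom attachment is by nearest
heavy atom within the same residue at a 1.2 Å covalent cutoff, because
PDB inputs carry no bond records for waters. Nitrogen acceptors are
computed but flagged by element, so O-only maps are reproducible.

Bond counts per water average over waters within a frame and then over
frames. For systems where every frame has the same water count the order
of averaging is immaterial; per-frame-then-overall was chosen so frames
with transiently displaced waters cannot be over-weighted.

## Geometry maps and their scoring gate

The distance–angle map histograms (r, θ) for donor-hydrogen/acceptor
pairs, where r is the hydrogen-to-acceptor-oxygen distance. Maps must
show *more* than the bonded population: the informative feature of bulk
water is a band at r > 3.0 Å, 60° < θ < 90° — first-shell neighbours
whose hydrogens point elsewhere, close but not bonded. The scoring gate
is therefore the *distance criterion only*: every donor-H/acceptor pair
with heavy-atom separation under 3.5 Å is scored, at any angle. An
alternative gate on the hydrogen–acceptor distance (`gate = "hydrogen"`,
4.0 Å) is available, but it is not the default: scoring by H···O
distance admits the full second-shell phase space, whose raw-count
volume factor (∝ r² sin θ) swamps the hydrogen-bond peak and moves the
map maximum into the non-bonded band. Under the distance gate the map
maximum is the hydrogen-bond peak, and the non-bonded band remains
visible, which matches how these maps are read in the field.

Default bins are 0.1 Å × 5°, from 1.2–4.0 Å and 0–90°. Bins are
half-open `[lo, hi)` with a 10⁻⁹ snap tolerance so a geometry
constructed exactly on an edge lands in the upper bin instead of being
at the mercy of `sqrt` rounding. Out-of-range geometries (mostly
θ > 90°) are dropped and counted in a spill register, so
`binned + spilled = scored` is a testable conservation law. `map_peak()`
reports the maximal bin's center, breaking ties toward smaller r, then
smaller θ.

On the bulk-water sample the maximal bin sits at r = 1.85 Å,
θ = 17.5° (bin centers), stable across seeds at 440 molecules and 100
frames. The r location deserves a note: the first intermolecular O–H
peak of three-site water models lies at 1.8–1.9 Å, and the raw-count
histogram keeps it there; the value conventionally quoted from colormap
readings of such maps is ~2.0 Å. The package reports what it computes.

## Hydration profiles

For every water oxygen, the distance to the protein surface is the
minimum over *all* protein atoms, hydrogens included, under the minimum
image. Class profiles use the minimum over atoms of that class only —
each water contributes once per class histogram — rather than
attributing each water to its single nearest class; "waters around
hydrophilic residues" is a per-class question, and the per-class minimum
answers it directly. Counts are averaged over frames and divided by the
number of protein chains, giving waters per protein. Defaults: 0.1 Å
bins to 6 Å; trend curves probe the bins containing 1.8 Å (hydrogen
bond) and 2.5 Å (van der Waals contact); the hydration-shell membership
cutoff for ring queries is 4 Å.

## Ring perception

The water network is an undirected simple graph (igraph) on water
molecules with water–water bonds as edges; parallel bonds collapse. For
each edge, the shortest cycles through it are enumerated by deleting the
edge and taking all shortest paths between its endpoints; cycles up to
`max_size` (default 6 — pentagons and hexagons are the motifs of
interest) are canonicalised under rotation and reflection and
deduplicated. On a cube graph this returns all six faces, matching
exhaustive enumeration; on trees, nothing.

## Crystal-structure entry sets

The analogous analysis over experimental hydrogen-containing structures
reads a manifest (entry id, method, resolution) plus PDB files, filters
by method ∈ {neutron} and resolution ≤ 2.0 Å — the "resolution above
2.0 Å" phrase is read as *numerically at most* 2.0 Å, i.e. better
quality, and that reading is deliberately prominent because the phrase
is ambiguous — and sums per-entry maps (additivity is tested). Waters
modelled without hydrogens cannot donate and are *skipped and counted*,
never given inferred hydrogens: fabricating hydrogen positions would
fabricate the very geometry under study. With symmetry expansion
enabled, acceptor environments include symmetry mates of the whole cell
while donors stay in the original copy, so each unique geometry is
counted once; for P1 entries expansion is a no-op, which is tested.
Occupancies do not weight counts; alternate locations resolve to the
highest-occupancy conformer (ties to altloc "A") at parse time.

## Crystal-system construction

Water insertion is rejection sampling: uniform position, uniform random
orientation (quaternion), accepted when the new oxygen is at least
2.4 Å from every heavy atom and previously placed oxygen under the
minimum image. The 2.4 Å default sits just below the water–water
hydrogen-bond O···O distance: it forbids overlap yet permits first-shell
placement. After 10,000 failed attempts for one molecule the builder
stops with a capacity error reporting how many were placed.
Neutralisation computes the net formal charge from residue rules
(ASP/GLU −1, LYS/ARG +1, HIS neutral by default with protonated
variants available — protonation states are a configurable choice, not
an observable of this package) plus one cancelling (+1, −1) terminus
pair per chain and unit charges of ions already present, then adds that
many Cl⁻ (or Na⁺) at non-clashing random positions. The operation is
idempotent by construction.

## The synthetic generators

The generators exist so that every analysis is exercised end to end
without downloads or a simulation engine; they emulate *structure*, not
dynamics.

* **Ice-rule lattice**: oxygens on a cubic-ice-like diamond lattice
  (nearest O–O 2.76 Å) in a periodic box; protons assigned by orienting
  an Eulerian circuit of the 4-regular neighbour graph, which satisfies
  the ice rules exactly for any circuit, so a seeded random vertex
  permutation gives a random valid assignment with identical bond
  counts. Jitter displaces each molecule rigidly (hydrogens ride with
  their oxygen), the way static positional disorder perturbs a lattice;
  jittering atoms independently would stretch covalent O–H bonds, which
  is not disorder but a broken molecule.
* **Ring fixtures**: regular planar n-gons of waters, each donating
  along one edge, closing the hydrogen-bond cycle; the second hydrogen
  points out of plane so it cannot short-circuit the ring.
* **Toy surfaces**: isolated amide (N–H) sites with a water exactly
  1.8 Å above the hydrogen in a collinear, bond-competent arrangement,
  and hydrophobic carbon sites with a water exactly 2.5 Å above; 16 Å
  site spacing guarantees each water's nearest protein atom is its own
  site's. These pin the profile bins by construction.
* **Bulk-water sampler**: Metropolis Monte Carlo of rigid three-site
  waters (O–H 0.9572 Å, H–O–H 104.52°, charges −0.834/+0.417 e,
  oxygen Lennard-Jones σ = 3.1507 Å, ε = 0.1521 kcal/mol) at 300 K and
  1.0 g/cm³, single-molecule translation+rotation moves, all-site
  Coulomb and O–O Lennard-Jones under a 10 Å spherical cutoff on the
  O–O distance, with the minimum-image shift applied per molecule so
  molecules never split. Electrostatics are deliberately cutoff-based,
  not Ewald: the quantity of interest is local hydrogen-bond geometry,
  which is insensitive to the long-range treatment, and the sampler
  stays minutes-scale at 216–440 molecules. Move sizes auto-tune toward
  ~40 % acceptance during the first half of equilibration only, so
  production sampling satisfies detailed balance. Equilibration is
  accepted when the last two quarters of the energy trace agree within
  1 % (and is extended up to three times otherwise); the run records
  its energy trace, acceptance rate and plateau flag on the returned
  trajectory. All randomness flows through R's RNG, so a single
  `set.seed` makes runs bit-reproducible.

What the generators do *not* emulate — and therefore what green tests do
not show about real data: conformational flexibility of the protein,
water exchange dynamics and residence times, long-range electrostatic
ordering, NPT cell relaxation with hydration level, and experimental
disorder beyond a single alternate-location choice. Quantities that
require production molecular dynamics of the full crystal (absolute
hydration-profile magnitudes across h, lattice constants vs h) are out
of scope by design.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use a 216-water ice lattice
(3³ cells), 64-water random boxes for oracle equivalence (20 seeds), and
440-water Monte Carlo runs with 2000 equilibration and 2000 production
sweeps sampling 100 frames — sizes chosen so the whole suite runs in
minutes on one core while leaving every estimate comfortably inside its
statistical tolerance (the map peak location is bin-stable across
seeds at this size).

## Known limitations

* Only orthorhombic cells and the P1/P4₁ operator sets; no mmCIF.
* Bifurcated bonds are reported as two geometries, not merged.
* No solvent-density 3D maps, dipole-orientation analysis, or kernel
  smoothing of maps — histograms are raw by design.
* PDB serial/residue-number wrapping above 99,999/9,999 is modular, so
  round trips of very large systems preserve order but not literal ids.
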