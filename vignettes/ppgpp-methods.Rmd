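---
title: "Conformational and interaction analysis of (p)ppGpp: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational and interaction analysis of (p)ppGpp: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgpp)
```

## Scope

ppGpp (guanosine 5'-diphosphate-3'-diphosphate) and pppGpp (its
5'-triphosphate homolog) are the alarmone nucleotides of the bacterial
stringent response. They bind dozens of structurally unrelated proteins
— synthetases, nucleotide-metabolic enzymes, translational GTPases, RNA
polymerase — and the chemistry of each binding site leaves a readable
signature in the geometry of the ligand (sugar pucker, glycosidic
angle) and in the inventory of non-covalent contacts. This package
implements that analysis as a tested pipeline: nucleotide conformational
descriptors, geometric contact typing, corpus-level aggregation, and a
synthetic-structure generator that replaces downloaded PDB entries with
ground-truth fixtures.

## Ribose pseudorotation

The furanose ring is described by its five endocyclic torsions
$\nu_0\ldots\nu_4$. We use the classical single-parameter treatment:

$$\tan P = \frac{(\nu_4 + \nu_1) - (\nu_3 + \nu_0)}
                {2\,\nu_2\,(\sin 36^\circ + \sin 72^\circ)},
\qquad \nu_{max} = \frac{\nu_2}{\cos P},$$

adding $180^\circ$ to $P$ when $\nu_2 < 0$ and wrapping to $[0, 360)$.
The pucker class is the 36-degree bin of $P$ (C3'-endo on $[0,36)$,
then C4'-exo, O4'-endo, C1'-exo, C2'-endo, C3'-exo, C4'-endo, O4'-exo,
C1'-endo, C2'-exo); the northern hemisphere is
$P \in [270,360) \cup [0,90)$. Numerical edge cases: at $\nu_2 = 0$ the
phase sits on the $P = 90/270$ meridian and is resolved by the sign of
the numerator, with $\nu_{max}$ taken from the numerator magnitude; an
all-zero (planar) ring is an error. This is the variant used by the
standard pseudorotation web services, and the curated reference
conformers shipped in `inst/extdata/reference_torsions.tsv` (unbound
energy-minimised ppGpp/pppGpp plus bound conformers from PDB entries
6EX0, 5VSW, 6G14 and 6GFM) reproduce their published $P$ and
$\nu_{max}$ to better than $0.02^\circ$:

```{r}
pucker_table(system.file("extdata", "reference_torsions.tsv",
                         package = "ppgpp"))[,
  c("id", "P", "nu_max", "pucker_class", "hemisphere",
    "glycosidic_class")]
```

Note that the conventional hemisphere label for the unbound conformers
($P \approx 186\text{--}188^\circ$, C3'-exo) is *south*; we report the
convention-derived hemisphere throughout and do not attempt to
reconcile it with looser textual usages of "north".

## Torsion conventions

`dihedral()` uses the standard IUPAC convention: looking from the
second to the third atom, clockwise rotation of the far bond is
positive, and the angle is invariant under reversal of the atom order
(a mirror image negates it). The glycosidic angle $\chi$ is
O4'-C1'-N9-C4; $\gamma$ is O5'-C5'-C4'-C3'. Classification is *anti*
for $\chi \bmod 360 \in [90, 270)$ and *syn* otherwise, with the
boundaries half-open exactly as stated (90 is anti, 270 is syn).

## Contact typing

Contacts are typed inside a 5 A environment of the ligand using
explicit, config-overridable criteria
(see `interaction_criteria()`):

* hydrogen bond: donor-acceptor distance 2.8-3.5 A and angle
  120-180 degrees;
* weak hydrogen bond: shorter than 2.8 A with angle below 120 degrees;
* polar / weak polar: remaining donor-acceptor pairs within 3.5 A /
  4.0 A regardless of angle;
* ionic: cation-anion pairs within 4.0 A; metal coordination: metal to
  ligand N/O within 3.0 A; aromatic: ring-centroid distance within
  4.5 A, subclassed parallel (inter-normal angle <= 30 degrees) or
  T-shaped (>= 60);
* van der Waals contact / clash: remaining heavy-atom pairs within the
  Bondi radius sum (+0.1 A slack), a clash when the overlap exceeds
  0.4 A.

Only the hydrogen-bond thresholds and the 5 A cutoff are fixed by the
protocol this reproduces; the ionic, metal, aromatic and polar
distances follow the conventions of the structural interaction
databases these tools descend from, and every one of them is exposed in
the YAML config.

Crystal structures usually lack hydrogens, so the D-H...A angle is
replaced by the antecedent proxy: the angle at the donor between its
bonded heavy atom and the acceptor. Donors without a locatable
antecedent (isolated waters) pass the angle criterion. This choice is
documented, switchable in the sense that explicit criteria can be
supplied, and not asserted to be the choice of any upstream tool.

Assignment per atom pair is hierarchical: metal > ionic > hydrogen bond
> weak hydrogen bond > polar > weak polar > clash > van der Waals. The
hierarchy makes the marginal counts well defined (each pair contributes
to exactly one category) and treats charge-assisted hydrogen bonds as
ionic. Water-mediated hydrogen bonds (water bonded to both ligand and
protein) are reported as a separate bridge list rather than inside the
nine-category counts, and the metal detector additionally reports
protein-side partners of each coordinated metal (bridging). Two
definitional points deserve note: the weak-hydrogen-bond rule is the
conjunctive one (short *and* bent); and although the upstream protocol
both removes "clashes" during cleanup and lists them among its nine
parameters, we detect clashes and let aggregation include or exclude
them.

## Aggregation

Counts are raw occurrences, exact marginals of the contact lists, and
conserved across every level (category, atom, moiety, functional
class); the aggregation functions assert this rather than assume it. A
per-complex-normalised mode exists because real corpora mix class sizes
(eight RNA polymerase entries against three synthetases). The bundled
`class_map.tsv` assigns the known complex entries to synthetase,
nucleotide-metabolic, GTPase, RNA polymerase, riboswitch or other;
riboswitch entries (RNA receptors) are excluded from protein-class
profiles by default. Corpus membership is configuration, not code.

## The synthetic generator

The generator defines the study conditions; it is not a tuning knob.

**Ligands.** `build_ribose()` starts from a planar pentagon displaced
along the pseudorotation mode and refines all fifteen coordinates by
least squares against the ideal torsions
$\nu_j = \nu_{max}\cos(P + 144^\circ(j-2))$ and target bond lengths
(C-C 1.528 A, C-O 1.43 A). A closed five-ring cannot satisfy the ideal
torsions exactly; the residual is below one degree in practice and a
2-degree recovery tolerance is declared, not silent. Guanine is a rigid
planar template (idealized 9-substituted guanine geometry) attached at
the requested $\chi$; substituent torsion offsets measured on an
idealized guanosine fix the D-ribose/beta-anomer chirality; phosphate
chains are grown from ideal internal coordinates in extended
conformations. A built ppGpp carries exactly 5 nitrogen and 17 oxygen
hydrogen-bond-capable atoms — every polar N and O of the molecule,
including the glycosidic N9 and the ester bridges, matching the
whole-molecule census used in the field.

**Sites.** `build_site()` places one partner fragment per requested
contact at geometry strictly inside the category's thresholds (margins
at least 0.1 A / 5 degrees), searches candidate directions ranked by
clearance, and verifies that the partner forms *exactly* the intended
contact with the whole ligand — otherwise it errors rather than emit an
ambiguous fixture. Edge-on (T-shaped) aromatic plants are the one
exception: their rim atoms inherently graze the base's van der Waals
envelope, so incidental vdW side contacts are permitted there.
Decoys are placed beyond the environment cutoff. Class recipes encode
the distinguishing patterns of the four protein classes (tyrosine
stacking and arginine/magnesium anchoring in synthetases and
nucleotide-metabolic enzymes, neither stacking nor metals in GTPases,
phosphate-centred contacts in RNA polymerase).

**Ensembles.** Glycosidic ensembles are von Mises mixtures
(Best-Fisher sampler, written here because no circular-statistics
package is available in the stack) with a 70% syn default occupancy.
The mode centers (syn $45^\circ$, anti $-150^\circ$, $\kappa = 12$) sit
deep inside their classification windows so that the mixture weight is
identifiable from range occupancy — with centers near the $\pm 90^\circ$
boundaries the weight-recovery property would be false by construction,
independent of sample size. Coordinate ensembles for descriptor tests
add isotropic Gaussian noise to a built conformer.

What the generator does *not* emulate: force-field energetics,
solvation, correlated internal motions, crystallographic disorder, or
the true conformational coupling between pucker and backbone. Passing
tests therefore demonstrate that the analysis operations are correct on
structures with known truth, not that any biological conclusion about
real complexes follows.

## Ensemble descriptors

RMSF is computed on the coordinates as supplied (no implicit
superposition — ligand-only trajectories are typically pre-centred;
an optional flag Kabsch-fits each frame first), against the ensemble
mean or the first frame. SASA is Shrake-Rupley with a deterministic
golden-spiral point set (960 points by default), so values are exactly
reproducible; an isolated atom reproduces $4\pi(r+1.4)^2$ within 1%.
Exactly coincident equal spheres are a degenerate input; the shared
surface is counted once. Intramolecular hydrogen bonds reuse the
contact criteria with a three-covalent-bond separation filter over the
canonical ligand topology. Superposition is the SVD-based Kabsch
procedure restricted to proper rotations.

## Problem sizes and determinism

The test suite and the analysis scripts run at desk scale by design:
corpora of eight complexes (~60-100 atoms each), torsion ensembles of
10,000 frames, SASA at 120-960 sphere points, ten-seed recall sweeps.
These sizes were chosen so the whole suite completes in a couple of
minutes while every statistical check retains comfortable margins
(e.g. the binomial standard error of a 0.7 weight at n = 10,000 is
0.5%, against a 2-point band). All randomness flows through explicit
integer seeds; generator functions restore the global RNG state on
exit, and fixture generation is byte-identical per seed.

## Known limitations

* The rotatable-bond counter uses a simple exposed convention (acyclic
  heavy-atom single bonds with non-terminal ends) and is deliberately
  not pinned to any published bond count.
* Trajectory-scale observables (RMSF/rGyr/SASA magnitudes of long
  enhanced-sampling runs) are not reproducible at desk scale; the
  descriptor operations are validated by their analytic cases instead.
* The contact detectors assume a single conformation per atom (highest
  occupancy wins at parse time) and do not model alternate-conformer
  ambiguity.
* mmCIF, symmetry mates and assembly generation are out of scope; the
  PDB reader covers ATOM/HETATM/MODEL records only.
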