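---
title: "Methods: pose triage and enantioselectivity analysis for aldoxime dehydratases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pose triage and enantioselectivity analysis for aldoxime dehydratases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxdock)
```

## The scientific problem

Aldoxime dehydratases (Oxd) convert aldoximes (R–CH=N–OH) to nitriles at a
heme center, assisted by a Ser/His/Arg catalytic triad, without any cofactor.
Acting on a racemic aldoxime they behave as kinetic-resolution catalysts, and
OxdRE shows an unusual control rule: the enantiopreference tracks the C=N
double-bond geometry of the substrate rather than the configuration of its
stereocenter — the *E*-racemate is resolved toward the (*S*)-nitrile, the
*Z*-racemate toward the (*R*)-nitrile.

Docking studies rationalize this behavior: each enantiomer of each E/Z isomer
is docked into the closed-conformation active site, catalytically productive
poses are recognized by a geometric binding motif, and the binding-energy gap
between the two enantiomers of one isomer predicts both the preferred product
configuration and the degree of selectivity.  oxdock implements the
post-processing side of that workflow — everything downstream of the docking
engine — together with the statistics that connect docking output to wet-lab
resolution data, and a synthetic-data generator that makes every stage
testable with known ground truth.

## The pharmacophore filter

A productive pose is defined by five internal coordinates tying the oxime
function to the catalytic machinery:

| descriptor          | meaning                                     | reference | tolerance |
|---------------------|---------------------------------------------|-----------|-----------|
| `fe_n_dist`         | heme Fe – oxime N coordination, Å           | 2.5       | ±0.5      |
| `o_ser_dist`        | oxime O – Ser219 OG hydrogen bond, Å        | 2.8       | ±0.5      |
| `o_his_dist`        | oxime O – His320 donor N hydrogen bond, Å   | 2.7       | ±0.5      |
| `his_o_ser_angle`   | His–O–Ser angle at the oxime O, degrees     | 115       | ±15       |
| `c_n_o_o_dihedral`  | C–N–O–O torsion of the oxime plane, degrees | 85        | ±25       |

The reference values come from the n-propanal oxime co-crystal redock; they
are quoted as approximate, so the tolerances are this package's own choice:
wide enough that a correctly redocked co-crystal pose passes, tight enough
that a pose violating any one criterion by twice its tolerance is always
rejected.  A criterion passes iff `|observed − reference| ≤ tolerance`; the
pose passes iff all five do.  Matching is monotone in the tolerances by
construction (shrinking tolerances can only convert pass → fail).

Two conventions are configurable because the underlying reports leave them
open.  First, the C–N–O–O torsion is matched on its absolute value by default
(`abs_dihedral = TRUE`): the motif is quoted without sign, and a signed match
would silently exclude mirror-related poses.  Second, the fourth atom of that
torsion (`PARTNER_O`) defaults to Ser219-OG, the only other motif oxygen; the
atom map lets users rebind it if their receptor suggests otherwise.  Likewise
the His donor is taken as the heavy NE2 nitrogen rather than its hydrogen,
since hydrogens are routinely absent from structure files.

Among poses of one ligand that pass the filter, the pipeline keeps the one
with the lowest (most negative) binding energy; exact ties are broken by
lexicographic pose id so results never depend on input order.

### Numerical choices

Angles clamp the normalized dot product to [−1, 1] before `acos()`, so
numerically collinear arms cannot produce `NaN`.  Torsions follow the IUPAC
sign convention and were cross-checked against `bio3d::torsion.xyz()`.
Degenerate geometry (zero-length arms, collinear torsion frames) is an error,
not a silent value.  Pose construction from internal coordinates uses NeRF
placement; measuring any specified internal coordinate on the built pose
reproduces it to better than 1e-6 (Å / degrees), which is the round-trip
property the test suite asserts.

## Stereochemical bookkeeping

E/Z is read off the torsion of the heavy substituent around the C=N bond: Z
when its absolute value is below 90°, E otherwise, with exactly 90° assigned
E as a deterministic tie-break.  R/S uses the signed volume of the three
highest-priority substituent vectors from the stereocenter: with a
right-handed frame and the lowest priority pointing away, the center is R
exactly when the triple product is negative.  This sign was validated against
full CIP assignments of reference tetrahedral centers (e.g. (R)-CHFClBr) —
note that "positive volume = R" claims found in some informal descriptions
have the opposite, incorrect sign.  Substituent priorities are declared by
the user in the atom map ("CIP-lite") because the ligand set is small and
fixed; a full CIP implementation is out of scope.  Centers whose tetrahedron
volume falls below 0.1 ų are rejected as near-planar rather than labelled
arbitrarily.

## From binding energies to E-values

Within one E/Z isomer, the docking-based selectivity proxy is the
binding-energy difference of the two enantiomers,
`ΔΔG = |ΔG_R − ΔG_S|` (kcal/mol); the predicted product configuration is the
enantiomer bound more tightly (lower ΔG).  Transition-state theory converts
the gap into an enantiomeric ratio

$$E = \exp\!\left(\frac{\Delta\Delta G}{R\,T}\right),$$

with R = 1.98720425×10⁻³ kcal mol⁻¹ K⁻¹.  The default temperature is
303.15 K (30 °C, a typical whole-cell biotransformation temperature), but
every conversion takes an explicit `temperature` argument and result tables
record the value used — the temperature behind published ΔΔG↔E conversions
for this system is not stated, and back-calculation from the printed tables
is not consistent with any single temperature, so the package never hides
this choice.  For the same reason the finite published mutant E-values are
not treated as exact reproduction targets; only parameter-free statements
(monotonicity, and that ΔΔG ≥ 3.65 kcal/mol exceeds E = 200 at any
temperature in 288–310 K) are asserted.

Experimental selectivities come from single-endpoint measurements of an
irreversible kinetic resolution via the Chen–Sih product-ee relation

$$E = \frac{\ln\left[1 - c\,(1 + ee_p)\right]}{\ln\left[1 - c\,(1 - ee_p)\right]},$$

where `c` is the conversion and `ee_p` the product enantiomeric excess (both
fractions).  This is the standard estimator for this reaction class, and it
reproduces five of the six bundled wild-type reference entries exactly at
printed precision; the remaining entry (45 % conversion, 96 % ee) recomputes
to E ≈ 118 against a published 112, most plausibly because the published
value was derived from unrounded raw data.  The package reports its own
computation and flags the discrepancy rather than reconciling it.  Rows
violating the mass balance `c (1 + ee_p) < 1` are flagged infeasible, not
fatal.  The inverse (`ee_from_conversion_e()`) is solved by bracketed
root-finding to 1e-10 on `[0, min(1, 1/c − 1))`; at conversions above 50 %
with very large E the root collapses onto the mass-balance ceiling faster
than double precision can represent, and that situation is reported as an
explicit error.

E-values are reported raw, rounded, and capped at 200 side by side.  The cap
is purely a reporting convention (chiral analytics cannot distinguish larger
ratios, hence "> 200"); no internal computation ever caps.

## The synthetic-data generator

The simulator is first-class code, not a test fixture: it defines the
conditions under which the pipeline is validated.

**Kinetic resolutions.**  The model is the minimal one under which the
Chen–Sih relation is exact: two parallel irreversible pseudo-first-order
consumptions with rate ratio `true_e`, equal initial enantiomer amounts, no
product inhibition, no E/Z interconversion, no Michaelis–Menten saturation.
Eliminating time gives `fast = slow^E`; the closed-form mode solves this per
conversion grid point by bracketed root-finding (tolerance 1e-12, Newton
polishing to machine precision — necessary because for E near 10⁶ the
residual slope amplifies bracket error).  An independent route integrates the
rate equations with `deSolve::lsoda` (rtol 1e-12) and locates grid
conversions by root-finding in time; the two routes agree to better than
1e-8 in product ee, and mass balance holds to 1e-10 at every point.
Noise-free trajectories return their true E through the Chen–Sih formula to
1e-6 relative error, which is the simulator↔formula consistency the tests
assert.

**Measurement noise.**  Observations are trajectory points perturbed by
independent Gaussian noise on conversion and product ee (defaults 0.01
absolute on each, a realistic scale for GC/HPLC determination of conversion
and ee), clipped to the feasible domain, under a single seeded generator per
call.  The default validation uses conversions in 0.3–0.4, where endpoint
sampling of a resolution is informative.  What the noise model does *not*
emulate: correlated errors between c and ee (both derive from the same
chromatogram in practice), systematic calibration bias, or enzyme
deactivation — so passing recovery tests show robustness to random
measurement error only.

**Docking tables and pose ensembles.**  Fabricated score tables give the
preferred enantiomer a base ΔG and the other `base ΔG + ΔΔG`, so the
selectivity engine must recover the design exactly.  Pose ensembles place
valid poses by jittering every descriptor uniformly within half its
tolerance and decoys by displacing one descriptor (cycled through all five)
by twice its tolerance, each pose in a random rigid frame; ground truth is
recorded alongside.  These ensembles test the filter's bookkeeping and
invariances, not docking realism: real decoys fail gradually and
correlatedly, while these are constructed to be unambiguous.

## Problem sizes and determinism

The validation suite runs trajectories of 5–25 points, ensembles of ten
poses, and 1000-observation recovery experiments; these sizes were chosen so
that every property under test (invariance at 1e-9, round-trips at 1e-6,
median recovery within 10 %) is exercised with comfortable margin while the
whole suite stays interactive.  Every stochastic component takes an explicit
seed, seeded generators are local to the call (`withr::local_seed`), and
generated artifacts — including multi-model PDB output — are byte-identical
under a fixed seed.

## Known limitations

* The pipeline post-processes docking output; it does not dock, prepare
  proteins, or model mutations, and it never scores interactions beyond the
  five-descriptor motif (no π-stacking, no energy terms).
* PDB support covers ATOM/HETATM/MODEL/ENDMDL with single-conformer altloc
  handling; mmCIF is out of scope.
* CIP-lite requires the user to state substituent priorities; it does not
  detect when declared priorities contradict full CIP rules.
* The experimental E-value estimator assumes an irreversible resolution with
  the stated minimal kinetics; substrate-ee-based or reversible estimators
  are not provided.
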