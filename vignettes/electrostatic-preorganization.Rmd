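---
title: "Quantifying electrostatic preorganization in enzyme active sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying electrostatic preorganization in enzyme active sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preorg)
```

## The scientific question

Enzymes are thought to accelerate chemistry in large part by holding a
*preorganized* arrangement of charges around the reacting atoms: the folded
scaffold pays the reorganization cost once, at folding time, and the
resulting electrostatic potential then stabilizes the transition state for
free. `preorg` packages the computational bookkeeping needed to interrogate
that hypothesis for a multi-step covalent reaction in a protease active
site:

1. decompose the classical electrostatic potential at an active-site probe
   into per-residue contributions;
2. engineer *charge variants* of the force field — switch the environment
   off, restore selected residues, mutate a position electrostatically,
   or scale one residue's charges continuously;
3. book-keep stationary-point free-energy profiles across variants,
   identify the rate-determining step, and convert barriers to rates with
   transition-state theory (TST);
4. reconstruct potentials of mean force (PMF) from umbrella-sampling
   windows by WHAM, with spline high-level corrections and grid-level
   stationary-point analysis;
5. count first-hydration-shell waters and hydrogen bonds around a leaving
   anion.

The package's worked system is the inactivation of the three catalytic
β-subunits of the 20S proteasome (chymotrypsin-, trypsin- and caspase-like)
by a β-lactone natural product: three active sites of ~30% sequence
identity, sitting in electrostatically very different environments, that
catalyze the same three-step chemistry at nearly the same rate.

## The potential model

The potential at a probe point $r$ is the bare Coulomb sum over fixed
partial charges,

$$V(r) = f_C \sum_i \frac{q_i}{|r - r_i|},$$

with $q_i$ in units of the elementary charge, distances in ångström, and
$f_C = N_A e^2 / (4\pi\varepsilon_0)$ evaluated from CODATA 2018 constants
(`physical_constants$f_coulomb` ≈ 1389.3546 kJ mol⁻¹ Å e⁻²), so potentials
come out in kJ mol⁻¹ e⁻¹ — the interaction energy of a unit probe charge.
Three deliberate modelling choices:

* **No cutoff, no switching function.** Nonbonded cutoffs belong to the
  MD engine that generated the coordinates, not to the potential being
  analyzed; the decomposition is the exact Coulomb sum. An optional
  uniform relative dielectric (default 1, vacuum) is exposed for
  sensitivity checks only.
* **Distance-shell profiles are cumulative**, accumulating residues whose
  backbone Cα lies within a growing radius of the probe (default 7–24 Å in
  1 Å steps). The Cα convention means waters, ions and the substrate are
  excluded from profiles (they have no Cα) while still appearing as their
  own groups in decompositions.
* **Contributor ranking** classifies residues against an absolute
  threshold, default 60 kJ mol⁻¹ e⁻¹, as positive / negative / negligible,
  sorted by |contribution|.

Because the sum is linear in the charges, three exact invariants anchor the
test suite: scaling all charges scales every entry; potentials of disjoint
structures superpose; and per-residue entries sum to the total to 1e-8
relative. These are verified against a brute-force atom-loop oracle on
hundreds of random toy structures.

## Charge variants

All perturbation experiments are *charge-only*: coordinates, atom
identities and Lennard-Jones parameters are never touched, which mirrors
the in-silico design where only the force field's charge table is edited.
The recipe algebra composes in a fixed order —
atrophy → restore → mutate → scale:

* `apply_atrophy()` zeroes every charge except a catalytic keep-list and
  the substrate (the species in the quantum region keep their charges).
  The default keep-list is the whole-residue catalytic pair
  (the nucleophile Thr1 and its activator Lys33) plus substrate; the exact
  atom set of a QM region is system-specific, so keep-lists are fully
  user-configurable.
* `restore_residues()` copies original charges back for selected residues,
  with `"waters"`/`"ions"` keywords; restoring everything reproduces the
  original bit-exactly.
* `mutate_charges()` swaps one residue's charges for a library template
  matched by atom name; template atoms absent from the structure are
  ignored, structure atoms absent from the template are zeroed. This
  deliberately neglects any conformational consequence of the mutation —
  it isolates the electrostatic component and is documented as such a
  limitation.
* `scale_residue()` multiplies one residue's charges by λ ≥ 0; the
  conventional scan grid is `lambda_grid()` = 0, 0.2, …, 1.4 (λ > 1 models
  an unnatural charge amplification). By linearity, the residue's
  potential contribution obeys V(λ) = λ·V(1) exactly, which the tests
  assert at machine precision.

The shipped charge library is a **simplified, AMBER-flavoured stand-in**
(TIP3P water is exact): per-residue atom charges that sum exactly to the
formal charge of each of the 20 standard residues, plus deprotonated
cysteine (CYM) and monovalent ions. The published source system's actual
per-atom charge table is not public; every library is therefore
user-replaceable, sums are validated to 1e-6 e at load, and no acceptance
check depends on the specific values.

## Profiles, the energetic span, and TST

A `fe_profile()` is the ordered list of stationary points of the
multi-step reaction — for the worked system
E:SalA → TS1 → E-I1 → TS2 → E-I2 → TS3 → E-PC — with cumulative Gibbs free
energies (kcal/mol) relative to the Michaelis complex. The shipped fixture
`inst/extdata/table1_profiles.csv` transcribes the published profiles for
the three subunits under three electrostatic conditions (unperturbed,
atrophied, single-aspartate-restored).

**The rate-determining barrier uses the energetic-span convention**: for
each TS, the span is its energy minus the lowest *preceding* minimum, and
the rate-determining barrier is the maximal span (ties to the earliest
TS). This definition matters: in the caspase-like subunit the first
single-step rise (19.4 kcal/mol) exceeds the third (13.0), yet the third
TS sits 22.8 kcal/mol above the Michaelis complex because the intervening
intermediates are shallow — the span rule charges TS3 against E:SalA and
correctly identifies the cyclization step as rate-determining, where a
naive per-step maximum would not.

TST conversions use $k = (k_BT/h)\,e^{-\Delta G^\ddagger/RT}$ with exact
SI constants and a default temperature of 310 K (the temperature of the
experimental inactivation rates). `retardation_factor()` reports the rate
ratio of two barriers and its nearest power of ten; for the trypsin-like
subunit, atrophy (20.5 → 70.0 kcal/mol) gives a ~10³⁵-fold slowdown.

One published table cell (chymotrypsin-like subunit, unperturbed last-step
barrier relative to E-I2: 8.9 kcal/mol) is inconsistent with its own
profile arithmetic (18.8 − 9.1 = 9.7); `run_reproduce_tables()` annotates
it as excluded rather than reproducing or failing it, and the discrepancy
is left visible in the reference fixture. Columns derived from
water-restored surfaces have no tabulated profile and are reported as
reference-only.

## WHAM

`wham()` implements the standard self-consistent unbiasing of overlapping
harmonic umbrella windows. Numerical choices:

* Histogram binning **is** the PMF grid (bin centers are grid nodes); no
  second binning layer.
* The published convergence criterion names a 1e-3 density tolerance but
  not the metric; here the metric is the maximum relative change of the
  unbiased density between successive iterations. Because plain direct
  iteration approaches the fixed point slowly enough that a loose
  tolerance can stop it early, the solver first minimizes the convex dual
  of the WHAM equations over the window free-energy shifts (BFGS with
  analytic gradient), then applies direct iteration until the density
  criterion holds. For a single unbiased window the estimator reduces
  exactly to the histogram PMF.
* PMFs are min-shifted to zero; unsampled nodes are masked `NA`, never
  interpolated.
* Uncertainty comes from a **moving-block bootstrap** (default 50 seeded
  replicates, block length ≈ √n per window): umbrella samples from
  Metropolis or MD are autocorrelated, and a plain iid bootstrap
  understates the stitching error of the window free energies.
* Energies are kJ/mol internally and kcal/mol (÷4.184) in every report.

The spline correction mirrors the interpolated high-minus-low-level
energy scheme: `correction_spline()` holds ΔE = E_HL − E_LL at coarse
nodes; corrected(r) = E_LL(r) + S(ΔE)(r). In 1D, S is a natural cubic
spline; in 2D a bilinear interpolant. Both pass through the nodes exactly
(so corrected values at coarse nodes equal the high-level values),
reproduce any linear field exactly, and refuse to extrapolate beyond the
node hull.

`locate_stationary_points()` works at grid level: minima are nodes not
above any neighbour (8-connectivity in 2D, plateau ties to the lowest node
index), and the saddle energy between two minima is the exact minimax path
cost, computed by merging nodes in ascending energy with union–find — the
energy at which the two basins first connect. Masked gaps that disconnect
minima are an error, not a guess. On noisy reconstructed PMFs every
statistical dimple is a legitimate grid minimum; the locator is meant for
exact or smoothed surfaces, and the analysis drivers use it that way.

## Synthetic ground truth

The generators in this package are first-class, tested code — they define
the conditions under which correctness is certified:

* `make_toy_protein()` places point-charge "residues" with Cα atoms at
  *exactly* prescribed distances from an origin probe on quasi-uniform
  (Fibonacci-sphere) directions, satellite atoms jittered nearby, and
  per-residue net charges distributed randomly but renormalized exactly.
  Shell profiles of the result step at exactly the prescribed radii. It
  emulates the geometry of a buried probe surrounded by alternating
  charged shells; it does **not** emulate real protein connectivity,
  secondary structure, or realistic charge densities — so passing tests
  certify the arithmetic of decomposition and variant algebra, not any
  biological claim.
* `sample_umbrella_windows()` draws seeded Metropolis samples from
  U(x) + k/2 (x − x₀)² at temperature T, with the proposal step auto-tuned
  toward 30–60% acceptance during a discarded burn-in (10% of the
  production length), then thinned (default: keep every 5th step). The
  default force constant is 2500 kJ mol⁻¹ Å⁻², matching the umbrella
  restraint of the source study's PMFs.
* `make_toy_fes()` evaluates closed-form potentials (flat; harmonic;
  double-well $b(x^2-c^2)^2/c^4$ with minima ±c and saddle b; 2D Gaussian
  wells) on a grid together with their declared stationary points.
* `make_water_shell()` builds TIP3P water shells with oxygens exactly at
  the shell radius and an orientation rule that makes hydrogen-bond counts
  exact by construction (one ideal 180° donor per inner water for
  `"H-toward-center"`, none for `"H-away"`).

Every generator is a pure function of (spec, seed) and leaves the caller's
RNG state untouched.

**Certification problem sizes.** The WHAM checks use 71 windows at 0.04 Å
spacing on [−1.4, 1.4] Å, 400 production samples per window, a 0.02 Å
PMF grid and 50 bootstrap replicates — chosen so the double-well barrier
(20 kJ/mol ≈ 4.78 kcal/mol) is recovered well within 3 bootstrap standard
errors (typically ±0.2 kcal/mol) and a flat potential reconstructs flat at
every node within 3 SE. The electrostatics oracle comparison runs 100
random structures of 3–10 residues. These sizes make the whole suite run
in about a minute; the real QM/MM free-energy landscapes behind the
transcribed profiles used >40,000 windows and are far beyond desk scale,
which is exactly why WHAM correctness is certified on synthetic ground
truth instead.

## Hydration-shell analysis

`coordination_number()` counts waters whose oxygen lies within the shell
cutoff of a central atom; `count_hbonds()` counts O–H groups with H within
the H-cutoff and an O–H···center angle above the minimum. The defaults
(3.9 Å, 2.9 Å, 150°) follow standard chloride-hydration conventions; the
published counts for the real system come from structures that are not
distributed, so the defaults are config-exposed and nothing in acceptance
depends on them. Counts are invariant under rigid motions and satisfy
hbonds ≤ 2 × coordination by construction.

## Design decisions that were genuinely open

* **Energetic span vs per-step maximum** for the rate-determining barrier:
  span, because it reproduces all three published ΔG‡ values including the
  late-TS case (see above).
* **PDB/PQR I/O**: PDB parsing is delegated to `bio3d` (altloc: highest
  occupancy, ties first; insertion codes folded into the residue key);
  PQR is read and written by the package as whitespace-delimited records
  with charges at 1e-8 e so that structures round-trip inside the
  1e-3 Å / 1e-4 e contract and total charge is preserved to 1e-6 e.
* **WHAM convergence metric** (see above): density-change metric with a
  convex-dual pre-solve, because the named tolerance alone does not pin
  down a stopping rule.
* **2D corrections are bilinear**, not bicubic: the contract (node
  exactness, linear-field reproduction, no extrapolation) does not require
  higher order, and bilinear interpolation cannot overshoot between nodes.
* **Bootstrap over blocks**, not iid samples, for PMF errors (see above).
* **Mixed Table-cell policy**: arithmetic-consistent cells are reproduced
  and checked to 0.05 kcal/mol (transcription rounding); the single
  inconsistent cell is excluded and flagged rather than silently matched.

## Known limitations

* The charge library is a documented stand-in; per-residue decompositions
  of real structures are only as good as the charges supplied.
* Electrostatic-only mutation ignores side-chain rebuilding; it quantifies
  the field change, not the full mutational effect.
* `wham()` supports 1D and 2D coordinates; reaction coordinates are
  treated as abstract scalars (the antisymmetric bond combinations of the
  source study are not enumerated).
* No periodic boundary conditions, Poisson–Boltzmann screening, or
  field-vector analysis — the package computes potentials of fixed point
  charges, nothing more.

## Reproducing the analysis

The numbered drivers under `analysis/` run the full workflow
(`01_reproduce_tables.R`, `02_field_scan.R`, `03_wham_recovery.R`,
`04_chloride_hydration.R`), writing CSV reports and manifests under
`results/`. `scripts/acceptance.R --seed <int> --out <path>` recomputes
the headline rate-determining barriers from the shipped profile fixtures
and writes them as JSON.
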