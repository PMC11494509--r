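# preorg — electrostatic preorganization analysis for enzyme active sites

`preorg` is an R package for asking, quantitatively, *what the charges
around an enzyme active site do for catalysis*. It targets the workflow
used to dissect multi-step covalent chemistry in the three catalytic
β-subunits of the 20S proteasome — three proteases of ~30% sequence
identity whose electrostatically very different active sites catalyze the
same reaction at nearly the same rate — but every component works on any
charged structure and any stationary-point free-energy profile.

The package provides:

* **Per-residue Coulomb decomposition.** The classical potential
  $V(r) = f_C \sum_i q_i/|r-r_i|$ at an active-site probe (e.g. the
  substrate's electrophilic carbon), decomposed by residue, with
  cumulative Cα distance-shell profiles (7–24 Å) and contributor ranking
  at a 60 kJ mol⁻¹ e⁻¹ labelling threshold. $f_C$ is computed from CODATA
  constants; potentials are in kJ mol⁻¹ e⁻¹.
* **Charge-variant engineering.** Charge atrophy (zero everything except a
  catalytic keep-set and substrate), selective restoration, mutation at a
  position by library template (charge-only), and continuous λ-scaling of
  one residue — composable recipes with canonical labels such as
  `Velec(OFF)`, `Velec(D17&WAT)`, `D17A`, `lambda=0.8`.
* **Profile bookkeeping and TST kinetics.** Stationary-point free-energy
  profiles (E:SalA → TS1 → … → E-PC), step-barrier tables relative to a
  reference intermediate, rate-determining-step identification by the
  *energetic span* (max rise from any preceding minimum to a TS), Eyring
  rate ↔ barrier conversion at 310 K, and rate retardation factors.
* **Umbrella sampling + WHAM.** PMF reconstruction from biased windows
  (default force constant 2500 kJ mol⁻¹ Å⁻², 1e-3 density tolerance) with
  moving-block bootstrap errors, spline high-level corrections that are
  exact at nodes, and exact minimax saddle location on FES grids.
* **Hydration-shell counting.** First-shell waters and donated hydrogen
  bonds around a leaving anion under standard geometric criteria.
* **Synthetic ground truth.** Seeded generators for toy charged proteins
  with exactly prescribed Cα distances, Metropolis samples from known 1D
  potentials, toy FES grids with closed-form saddles, and oriented water
  shells — the fixtures against which everything above is certified.

## Worked example

Regenerate the step-barrier arithmetic, rate-determining steps and
retardation factors from the shipped profile transcription:

```r
library(preorg)
res <- run_reproduce_tables()
res$rds_table
#>   subunit    variant barrier  ts    ref       rate_s
#> 1   beta1 Velec(D17)    28.9 TS3 E:SalA 2.729679e-08
#> 2   beta1 Velec(OFF)    62.0 TS3 E:SalA 1.262105e-31
#> 3   beta1  Velec(ON)    22.8 TS3 E:SalA 5.451580e-04
#> 4   beta2 Velec(D17)    29.5 TS3 E:SalA 1.030672e-08
#> 5   beta2 Velec(OFF)    70.0 TS3 E:SalA 2.892095e-37
#> 6   beta2  Velec(ON)    20.5 TS1 E:SalA 2.280283e-02
#> 7   beta5 Velec(D17)    27.5 TS3 E:SalA 2.649056e-07
#> 8   beta5 Velec(OFF)    66.5 TS3 E:SalA 8.485187e-35
#> 9   beta5  Velec(ON)    20.4 TS1 E:SalA 2.682176e-02
res$retardation
#>   subunit barrier_on barrier_off log10_factor power10
#> 1   beta1       22.8        62.0     27.63543      28
#> 2   beta2       20.5        70.0     34.89678      35
#> 3   beta5       20.4        66.5     32.49983      32
```

Reading the output: with intact electrostatics the three subunits share
rate-determining barriers of 20.4–22.8 kcal/mol (Eyring rates of
10⁻² – 10⁻⁴ s⁻¹ at 310 K, i.e. the observed seconds-to-minutes
inactivation). Note the caspase-like subunit (β1): its rate-determining
step is the *third* TS by the energetic-span rule, even though its first
single-step rise is larger. Zeroing every environment charge except the
catalytic Thr1/Lys33 pair (`Velec(OFF)`) lifts all three barriers to
62–70 kcal/mol at the cyclization step — a rate retardation of up to
~10³⁵-fold — and restoring the single active-site aspartate (`Velec(D17)`)
recovers most of the first two steps but not the last.

The same algebra on structures:

```r
s   <- make_toy_protein(toy_protein_spec(data.frame(
         name = c("LYS", "ASP"), net_charge = c(1, -1),
         ca_distance = c(8, 10.5))), seed = 1)
dec <- decompose_by_residue(s, c(0, 0, 0))
rank_contributors(dec, threshold = 60)
off <- apply_atrophy(s, keep_list = "A:1")      # zero all but residue A:1
scale_residue(s, "A:2", 0.6)                     # lambda = 0.6 on A:2
```

The numbered drivers under `analysis/` run the full workflow and write
CSV reports plus manifests under `results/`:

```sh
Rscript analysis/01_reproduce_tables.R    # profile arithmetic + kinetics
Rscript analysis/02_field_scan.R          # per-residue field scan + variants
Rscript analysis/03_wham_recovery.R       # WHAM on synthetic ground truth
Rscript analysis/04_chloride_hydration.R  # hydration-shell counting
```

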