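#!/usr/bin/env Rscript
# Step 1 — profile arithmetic and kinetics.
#
# From the transcribed cumulative free-energy profiles of the three
# catalytic proteasome subunits (unperturbed, charge-atrophied and
# Asp17-restored electrostatics), regenerate the last-step barrier /
# product-stabilization table relative to E-I2, identify the
# rate-determining step by the energetic-span rule, convert the barriers
# to Eyring rates at 310 K, and compute the unperturbed-vs-atrophy rate
# retardation per subunit.

suppressMessages(library(preorg))

out_dir <- "results/tables"
res <- run_reproduce_tables(out_dir = out_dir)

cat("== Step-barrier table (relative to E-I2) ==\n")
print(res$step_table, digits = 3)
n_pass <- sum(res$step_table$status == "pass")
n_fail <- sum(res$step_table$status == "FAIL")
cat(sprintf("\n%d/%d checked cells reproduce the published values", n_pass,
            n_pass + n_fail),
    "(excluded: the one published cell inconsistent with its own profile",
    "arithmetic, and water-restored columns that have no tabulated",
    "profile).\n\n")

cat("== Rate-determining (energetic-span) barriers ==\n")
print(res$rds_table, digits = 4)
cat("\nUnder intact electrostatics the three subunits share barriers of",
    "20.4-22.8 kcal/mol (seconds-to-minutes chemistry at 310 K); full",
    "charge atrophy lifts all three to 62-70 kcal/mol at the cyclization",
    "step.\n\n")

cat("== Retardation: field OFF vs ON ==\n")
print(res$retardation, digits = 4)
cat("\nSwitching the environment's charges off slows the trypsin-like",
    sprintf("subunit by ~10^%d-fold.\n", res$retardation$power10[
      res$retardation$subunit == "beta2"]))
cat("\nReports written under", out_dir, "\n")
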