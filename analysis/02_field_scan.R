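#!/usr/bin/env Rscript
# Step 2 — per-residue electrostatic field scan on a synthetic active site.
#
# Builds a toy globular point-charge protein emulating the alternating
# positive/negative distance shells seen around a buried electrophile,
# then runs the decomposition pipeline: total potential at the probe,
# cumulative Calpha-shell profile (7-24 A), contributor ranking at the
# 60 kJ/mol/e labelling threshold, and a lambda scan of the dominant
# anionic residue. Finally it demonstrates the charge-variant algebra:
# atrophy, selective restoration and electrostatic-only mutation.

suppressMessages(library(preorg))

seed <- 101
out_dir <- "results/field_scan"

# inner shell positive (backbone amides / Lys), then an anionic belt
# (Asp/Glu), then a neutralizing outer shell — the shell pattern the
# cumulative profile is designed to resolve
spec <- toy_protein_spec(data.frame(
  name        = c("LYS", "THR", "ASP", "GLU", "ASP", "ARG", "LYS", "SER"),
  net_charge  = c(1, 0, -1, -1, -1, 1, 1, 0),
  ca_distance = c(8, 9, 10.5, 11.5, 12.5, 17.5, 18.5, 21),
  n_atoms     = 5L), n_waters = 12, n_ions = 2)
s <- make_toy_protein(spec, seed = seed)

probe <- c(0, 0, 0)  # the toy electrophile position
res <- run_field_scan(s, probe, lambda_residue = "A:3",
                      out_dir = out_dir, seed = seed)

cat("== Total potential at the probe ==\n")
cat(sprintf("V_elec = %+.1f kJ mol^-1 e^-1 over %d residues/groups\n\n",
            res$decomposition$total, nrow(res$decomposition$per_group)))

cat("== Cumulative shell profile (Calpha convention) ==\n")
print(as.data.frame(res$profile), digits = 3)
cat("\n== Ranked contributors (|V| > 60 labelled) ==\n")
print(res$ranking[, c("key", "residue_name", "ca_distance",
                      "contribution", "sign_class")], digits = 3)

cat("\n== Lambda scan of the dominant anion (A:3) ==\n")
print(res$lambda_scan, digits = 4)
fit <- lm(contribution ~ lambda, data = res$lambda_scan)
cat(sprintf("slope %.3f kJ mol^-1 e^-1 per lambda, intercept %.2e (exact linearity)\n",
            coef(fit)[2], coef(fit)[1]))

# variant algebra on the same structure
keep <- c("A:1", "A:2")   # the catalytic pair of the toy site
off <- apply_atrophy(s, keep)
d17 <- restore_residues(off, s, "A:3")
cat("\n== Charge-variant potentials at the probe ==\n")
for (v in list(list("Velec(ON)", s), list("Velec(OFF)", off),
               list("Velec(D17)", d17),
               list("Velec(D17&WAT)", restore_residues(d17, s, "waters")))) {
  cat(sprintf("  %-16s V_elec = %+8.1f kJ mol^-1 e^-1\n", v[[1]],
              potential_at_point(v[[2]], probe)))
}

cat("\nReports written under", out_dir, "\n")
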