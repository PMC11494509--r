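# Fixture: a miniature active site with two catalytic residues, a distant
# charged residue, waters, an ion and a substrate group.
make_site <- function() {
  make_structure(
    atom("CA", "THR", 1, c(3, 0, 0), q = 0.1),
    atom("OG1", "THR", 1, c(3.5, 0.8, 0), q = -0.4),
    atom("CA", "LYS", 33, c(0, 4, 0), q = 0.2),
    atom("NZ", "LYS", 33, c(0, 4.9, 0.5), q = 0.8),
    atom("CA", "ASP", 17, c(0, 0, 6), q = -0.1),
    atom("CG", "ASP", 17, c(0.4, 0.3, 6.8), q = 0.7),
    atom("OD1", "ASP", 17, c(1.0, 0.9, 7.3), q = -0.8),
    atom("OD2", "ASP", 17, c(-0.5, 0.2, 7.7), q = -0.8),
    atom("O", "HOH", 101, c(7, 7, 0), q = -0.834, chain = "W"),
    atom("H1", "HOH", 101, c(7.96, 7, 0), q = 0.417, chain = "W"),
    atom("H2", "HOH", 101, c(6.76, 7.93, 0), q = 0.417, chain = "W"),
    atom("NA", "NA", 201, c(-9, 0, 0), q = 1, chain = "I"),
    atom("C1", "SAL", 301, c(1, 1, 1), q = 0.3, chain = "S"),
    atom("O2", "SAL", 301, c(1.9, 1.4, 1.2), q = -0.3, chain = "S"))
}

test_that("atrophy zeroes everything but keep-list and substrate, idempotently", {
  s <- make_site()
  keep <- c("A:1", "A:33")
  off <- apply_atrophy(s, keep)
  kinds <- off$atoms$group_kind
  keys <- residue_key(off)
  # keep-list charges bit-identical, substrate untouched
  expect_identical(off$atoms$charge[keys %in% keep],
                   s$atoms$charge[keys %in% keep])
  expect_identical(off$atoms$charge[kinds == "substrate"],
                   s$atoms$charge[kinds == "substrate"])
  # all other charges exactly zero; geometry untouched
  expect_true(all(off$atoms$charge[!(keys %in% keep) &
                                     kinds != "substrate"] == 0))
  expect_identical(off$atoms[, c("x", "y", "z", "atom_name")],
                   s$atoms[, c("x", "y", "z", "atom_name")])
  expect_identical(apply_atrophy(off, keep)$atoms$charge,
                   off$atoms$charge)
  # environment potential excluding the keep-list vanishes
  expect_equal(potential_at_point(off, c(0, 0, 0),
                                  include = c("protein", "water", "ion"),
                                  exclude_residues = keep), 0)
  # nonzero decomposition entries only on keep-list + substrate
  dec <- decompose_by_residue(off, c(0.2, 0.2, 0.2))
  nz <- dec$per_group$key[abs(dec$per_group$contribution) > 0]
  expect_true(all(nz %in% c(keep, "S:301")))
  expect_error(apply_atrophy(s, "A:999"), "A:999")
})

test_that("restoration returns selected residues to original charges", {
  s <- make_site()
  off <- apply_atrophy(s, c("A:1", "A:33"))
  # restoring everything reproduces the original exactly
  all_keys <- unique(residue_key(s))
  expect_identical(restore_residues(off, s, all_keys)$atoms$charge,
                   s$atoms$charge)
  # restoring Asp17 changes only Asp17 atoms
  r17 <- restore_residues(off, s, "A:17")
  diff_rows <- which(r17$atoms$charge != off$atoms$charge)
  expect_true(all(residue_key(r17)[diff_rows] == "A:17"))
  # sequential restore equals one-shot restore (field-by-field)
  seq2 <- restore_residues(restore_residues(off, s, "A:17"), s, "waters")
  oneshot <- restore_residues(off, s, c("A:17", "waters"))
  expect_identical(seq2$atoms, oneshot$atoms)
  # atom misalignment is an error
  perm <- s
  perm$atoms <- perm$atoms[rev(seq_len(nrow(perm$atoms))), ]
  expect_error(restore_residues(off, perm, "A:17"), "atom-aligned")
})

test_that("electrostatic-only mutation swaps template charges by atom name", {
  lib <- read_charge_library()
  s <- make_structure(
    atom("N", "ASP", 17, c(0, 0, 8)), atom("CA", "ASP", 17, c(1, 0, 8)),
    atom("C", "ASP", 17, c(2, 0.7, 8)), atom("O", "ASP", 17, c(3, 0.4, 8.4)),
    atom("CB", "ASP", 17, c(1, 1.4, 8.6)), atom("CG", "ASP", 17, c(1.6, 2.3, 9.2)),
    atom("OD1", "ASP", 17, c(2.3, 3.0, 8.7)), atom("OD2", "ASP", 17, c(1.4, 2.5, 10.4)))
  s <- assign_charges(s, lib)
  # self-mutation is the identity on charges
  expect_identical(mutate_charges(s, "A:17", "ASP", lib)$atoms$charge,
                   s$atoms$charge)
  # D -> A: shared atoms take ALA charges, Asp-only atoms are zeroed
  d17a <- mutate_charges(s, "A:17", "ALA", lib)
  expect_equal(sum(d17a$atoms$charge), 0 - 0.18 - 0.55 + 0.55 - 0.40 + 0.05,
               tolerance = 1e-9)   # backbone shared + CB; CG/OD zeroed, no HB/H
  expect_true(all(d17a$atoms$charge[d17a$atoms$atom_name %in%
                                      c("CG", "OD1", "OD2")] == 0))
  # D -> E keeps the -1 class: shared heavy atoms CB(+CG? E has CG) follow E
  d17e <- mutate_charges(s, "A:17", "GLU", lib)
  tmpl <- library_template(lib, "GLU")
  for (nm in c("N", "CA", "C", "O", "CB", "CG"))
    expect_equal(d17e$atoms$charge[d17e$atoms$atom_name == nm],
                 unname(tmpl[nm]))
  expect_true(all(d17e$atoms$charge[d17e$atoms$atom_name %in%
                                      c("OD1", "OD2")] == 0))
  # potential change at a probe matches brute-force re-evaluation
  probe <- c(0, 0, 0)
  expect_equal(potential_at_point(d17e, probe),
               sum(oracle_decompose(d17e, probe)), tolerance = 1e-10)
  expect_error(mutate_charges(s, "A:17", "XYZ", lib), "not in charge")
})

test_that("lambda scaling is exactly linear and composes multiplicatively", {
  s <- make_site()
  probe <- c(0.2, 0.1, 0)
  v1 <- decompose_by_residue(s, probe)
  c1 <- v1$per_group$contribution[v1$per_group$key == "A:17"]
  for (lam in lambda_grid()) {
    sl <- scale_residue(s, "A:17", lam)
    d <- decompose_by_residue(sl, probe)
    expect_equal(d$per_group$contribution[d$per_group$key == "A:17"],
                 lam * c1, tolerance = 1e-12)
  }
  # identity and annihilation limits
  expect_identical(scale_residue(s, "A:17", 1)$atoms$charge,
                   s$atoms$charge)
  z <- scale_residue(s, "A:17", 0)
  expect_true(all(z$atoms$charge[residue_key(z) == "A:17"] == 0))
  # composition: lambda1 then lambda2 equals lambda1*lambda2
  expect_equal(scale_residue(scale_residue(s, "A:17", 0.5),
                             "A:17", 0.6)$atoms$charge,
               scale_residue(s, "A:17", 0.3)$atoms$charge,
               tolerance = 1e-15)
  expect_error(scale_residue(s, "A:17", -0.1), "lambda")
})

test_that("variant recipes compose in fixed order with canonical labels", {
  s <- make_site()
  # empty spec is the identity
  id <- build_variant(s, variant_spec())
  expect_identical(id$atoms$charge, s$atoms$charge)
  expect_equal(attr(id, "variant_label"), "Velec(ON)")
  # atrophy + restore reproduces the explicit composition
  spec <- variant_spec(atrophy = TRUE, keep_list = c("A:1", "A:33"),
                       restore_list = "A:17")
  v <- build_variant(s, spec)
  expect_identical(v$atoms$charge,
                   restore_residues(apply_atrophy(s, c("A:1", "A:33")),
                                    s, "A:17")$atoms$charge)
  expect_equal(attr(v, "variant_label"), "Velec(D17)")
  # keep Thr1/Lys33, restore Asp17 + waters: exactly those groups charged
  v2 <- build_variant(s, variant_spec(atrophy = TRUE,
                                      keep_list = c("A:1", "A:33"),
                                      restore_list = c("A:17", "waters")))
  nz <- unique(residue_key(v2)[v2$atoms$charge != 0])
  expect_setequal(nz, c("A:1", "A:33", "A:17", "W:101", "S:301"))
  expect_equal(attr(v2, "variant_label"), "Velec(D17&WAT)")
  expect_equal(attr(build_variant(s, variant_spec(atrophy = TRUE)),
                    "variant_label"), "Velec(OFF)")
  # conflicting directives are rejected up front
  expect_error(variant_spec(restore_list = "A:17",
                            mutations = c("A:17" = "ALA")),
               "both mutated")
  # YAML round-trip preserves the recipe
  f <- withr::local_tempfile(fileext = ".yaml")
  write_variant_spec(spec, f)
  spec2 <- read_variant_spec(f)
  expect_equal(spec2$keep_list, spec$keep_list)
  expect_equal(spec2$restore_list, spec$restore_list)
  expect_true(spec2$atrophy)
})
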