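test_that("potential of a unit charge at 10 A matches the Coulomb factor", {
  s <- make_structure(atom("NA", "NA", 1, c(10, 0, 0), q = 1,
                           chain = "I"))
  v <- potential_at_point(s, c(0, 0, 0))
  expect_equal(v, oracle_f_coulomb() / 10, tolerance = 1e-12)
  expect_equal(v, 138.935, tolerance = 1e-5)
  # uniform dielectric screens linearly
  expect_equal(potential_at_point(s, c(0, 0, 0), dielectric = 4), v / 4)
})

test_that("degenerate scopes: empty scope is zero, symmetry cancels, singularity errs", {
  s <- make_structure(atom("NA", "NA", 1, c(5, 0, 0), q = 1, chain = "I"),
                      atom("CL", "CL", 2, c(-5, 0, 0), q = -1,
                           chain = "I"))
  expect_identical(potential_at_point(s, c(0, 0, 0), include = "protein"),
                   0)
  expect_equal(potential_at_point(s, c(0, 0, 0)), 0, tolerance = 1e-12)
  expect_error(potential_at_point(s, c(5, 0, 0)), "singularity")
  # exclusion by residue key removes that residue's atoms from the sum
  expect_equal(potential_at_point(s, c(0, 0, 0),
                                  exclude_residues = "I:2"),
               oracle_f_coulomb() / 5, tolerance = 1e-12)
})

test_that("per-residue decomposition matches the brute-force atom loop", {
  for (seed in c(5, 17)) {
    s <- make_toy_protein(random_toy_spec(12, seed), seed = seed)
    probe <- c(0, 0, 0)
    dec <- decompose_by_residue(s, probe)
    oracle <- oracle_decompose(s, probe)
    expect_setequal(dec$per_group$key, names(oracle))
    m <- match(dec$per_group$key, names(oracle))
    expect_equal(dec$per_group$contribution, unname(oracle[m]),
                 tolerance = 1e-10)
    # conservation: sum of entries equals the total and the point value
    expect_equal(sum(dec$per_group$contribution), dec$total,
                 tolerance = 1e-8 * max(1, abs(dec$total)))
    expect_equal(dec$total, potential_at_point(s, probe),
                 tolerance = 1e-12)
  }
})

test_that("linearity, superposition and 1/r decay hold", {
  s <- make_toy_protein(random_toy_spec(8, 23), seed = 23)
  probe <- c(0.5, -0.3, 0.2)
  v1 <- potential_at_point(s, probe)
  # scaling all charges by s scales the potential by s
  s3 <- s; s3$atoms$charge <- 3 * s3$atoms$charge
  expect_equal(potential_at_point(s3, probe), 3 * v1, tolerance = 1e-12)
  # superposition over a disjoint union
  s2 <- make_toy_protein(random_toy_spec(5, 29), seed = 29)
  s2$atoms$chain_id <- "B"
  s2$atoms$atom_id <- s2$atoms$atom_id + max(s$atoms$atom_id)
  un <- charged_structure(rbind(s$atoms, s2$atoms))
  expect_equal(potential_at_point(un, probe),
               v1 + potential_at_point(s2, probe), tolerance = 1e-12)
  # doubling all atom-probe distances halves the potential (probe at 0)
  sd2 <- s
  sd2$atoms[, c("x", "y", "z")] <- 2 * sd2$atoms[, c("x", "y", "z")]
  expect_equal(potential_at_point(sd2, c(0, 0, 0)),
               potential_at_point(s, c(0, 0, 0)) / 2, tolerance = 1e-12)
})

test_that("shell profile accumulates at Calpha distances", {
  # single residue with CA at 12 A: contribution enters at radius 12
  s <- make_structure(atom("CA", "GLY", 1, c(12, 0, 0), q = 0),
                      atom("X1", "GLY", 1, c(12.8, 0, 0), q = -1))
  p <- shell_profile(s, c(0, 0, 0))
  expect_equal(p$radius, 7:24)
  c_exp <- potential_at_point(s, c(0, 0, 0))
  expect_true(all(p$cumulative_V[p$radius < 12] == 0))
  expect_true(all(abs(p$cumulative_V[p$radius >= 12] - c_exp) < 1e-12))
  expect_equal(p$cumulative_count, as.integer(p$radius >= 12))
  # counts nondecreasing; final value consistent with the decomposition
  s2 <- make_toy_protein(random_toy_spec(10, 31), seed = 31)
  p2 <- shell_profile(s2, c(0, 0, 0), r_max = 30)
  expect_true(all(diff(p2$cumulative_count) >= 0))
  dec <- decompose_by_residue(s2, c(0, 0, 0), include = "protein")
  expect_equal(p2$cumulative_V[length(p2$cumulative_V)],
               sum(dec$per_group$contribution), tolerance = 1e-10)
  expect_error(shell_profile(s, c(0, 0, 0), r_min = 10, r_max = 5),
               "r_min")
  expect_error(shell_profile(s, c(0, 0, 0), step = 0), "step")
})

test_that("contributor ranking orders by |V| and classifies at the threshold", {
  s <- make_structure(atom("CA", "ASP", 1, c(8, 0, 0), q = -0.6),
                      atom("CA", "LYS", 2, c(0, 9, 0), q = 0.25),
                      atom("CA", "SER", 3, c(0, 0, 14), q = -0.01))
  dec <- decompose_by_residue(s, c(0, 0, 0))
  rk <- rank_contributors(dec, threshold = 60)
  # independent sort oracle
  oracle <- sort(abs(oracle_decompose(s, c(0, 0, 0))), decreasing = TRUE)
  expect_equal(abs(rk$contribution), unname(oracle), tolerance = 1e-10)
  expect_equal(rk$sign_class,
               ifelse(rk$contribution > 60, "positive",
                      ifelse(rk$contribution < -60, "negative",
                             "negligible")))
  # threshold zero: nothing is negligible
  rk0 <- rank_contributors(dec, threshold = 0)
  expect_false(any(rk0$sign_class == "negligible"))
  expect_error(rank_contributors(dec, threshold = -1), "non-negative")
})
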