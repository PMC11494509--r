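test_that("toy proteins are deterministic and honour the declared geometry", {
  spec <- toy_protein_spec(data.frame(
    name = c("ASP", "LYS", "GLY"), net_charge = c(-1, 1, 0),
    ca_distance = c(8, 12, 19), n_atoms = 3L))
  s1 <- make_toy_protein(spec, seed = 7)
  s2 <- make_toy_protein(spec, seed = 7)
  expect_identical(s1$atoms, s2$atoms)   # bit-identical under one seed
  s3 <- make_toy_protein(spec, seed = 8)
  expect_false(identical(s1$atoms$charge, s3$atoms$charge))
  # Calpha atoms exactly at the prescribed distances from the origin
  ca <- s1$atoms[s1$atoms$atom_name == "CA", ]
  expect_equal(sort(sqrt(ca$x^2 + ca$y^2 + ca$z^2)), c(8, 12, 19),
               tolerance = 1e-12)
  # per-residue net charges equal the declared values
  tab <- residue_table(s1)
  expect_equal(tab$net_charge, c(-1, 1, 0), tolerance = 1e-12)
  # shell profile counts step 0 -> 1 -> 2 -> 3 exactly at those radii
  p <- shell_profile(s1, c(0, 0, 0), r_min = 5, r_max = 20)
  expect_equal(p$cumulative_count,
               vapply(p$radius, function(r) sum(c(8, 12, 19) <= r),
                      integer(1)))
  # single-residue spec yields exactly one protein entry
  one <- make_toy_protein(toy_protein_spec(data.frame(
    name = "ASP", net_charge = -1, ca_distance = 10)), seed = 1)
  dec <- decompose_by_residue(one, c(0, 0, 0))
  expect_equal(nrow(dec$per_group), 1L)
  expect_equal(dec$per_group$group_kind, "protein")
})

test_that("overlapping toy geometries are rejected", {
  # two residues crammed within half an angstrom of the origin collide
  spec <- toy_protein_spec(data.frame(
    name = c("GLY", "GLY"), net_charge = c(0, 0),
    ca_distance = c(0.2, 0.2), n_atoms = 2L))
  expect_error(make_toy_protein(spec, seed = 1), "overlap")
  expect_error(toy_protein_spec(data.frame(
    name = "GLY", net_charge = 0, ca_distance = -3)), "positive")
})

test_that("umbrella sampling of a flat potential has the Gaussian variance RT/k", {
  k <- 2500
  fl <- toy_potential_spec("flat")
  ds <- sample_umbrella_windows(fl, centers = 0, force_constant = k,
                                n_samples = 2000, seed = 12)
  x <- as.numeric(ds$windows[[1]]$samples)
  RT <- physical_constants$R_J / 1000 * 310
  v_exp <- RT / k
  # sampling error of a variance: se ~ var * sqrt(2/n_eff); thinned
  # Metropolis chains keep some correlation, allow n_eff = n/5
  se <- v_exp * sqrt(2 / (length(x) / 5))
  expect_lt(abs(var(x) - v_exp), 3 * se)
  # acceptance tuned into the 30-60% band
  expect_gt(attr(ds$windows[[1]], "acceptance"), 0.25)
  expect_lt(attr(ds$windows[[1]], "acceptance"), 0.65)
  # a very stiff bias pins the mean at the window center
  stiff <- sample_umbrella_windows(fl, centers = 0.8,
                                   force_constant = 1e6,
                                   n_samples = 500, seed = 3)
  expect_equal(mean(stiff$windows[[1]]$samples), 0.8, tolerance = 5e-3)
  # identical seeds give identical sample streams
  dsa <- sample_umbrella_windows(fl, centers = 0.3, n_samples = 100,
                                 seed = 5)
  dsb <- sample_umbrella_windows(fl, centers = 0.3, n_samples = 100,
                                 seed = 5)
  expect_identical(dsa$windows[[1]]$samples, dsb$windows[[1]]$samples)
})

test_that("toy FES grids declare their closed-form stationary points", {
  # harmonic: single declared minimum at x0
  h <- make_toy_fes(toy_potential_spec("harmonic", a = 12, x0 = 0.3),
                    grid = seq(-1, 1.5, by = 0.05))
  expect_equal(h$stationary$minima$x, 0.3)
  # double well with c = 1: minima at +-1, saddle at 0 with energy b
  b_kJ <- 18
  dw <- make_toy_fes(toy_potential_spec("double_well", b = b_kJ, c = 1),
                     grid = seq(-1.6, 1.6, by = 0.02))
  expect_equal(sort(dw$stationary$minima$x), c(-1, 1))
  expect_equal(dw$stationary$saddle$G, b_kJ / 4.184, tolerance = 1e-12)
  # grid-level location recovers the declared saddle within one grid-cell
  # energy spacing
  sp <- locate_stationary_points(dw$surface)
  cell <- max(abs(diff(dw$surface$G)))
  expect_lt(abs(sp$saddles$G_saddle[1] - dw$stationary$saddle$G), cell)
  # generators never disturb the caller's RNG state
  set.seed(1234); before <- .Random.seed
  invisible(make_toy_protein(toy_protein_spec(data.frame(
    name = "GLY", net_charge = 0, ca_distance = 9)), seed = 2))
  invisible(sample_umbrella_windows(toy_potential_spec("flat"), 0,
                                    n_samples = 60, seed = 2))
  expect_identical(.Random.seed, before)
})

test_that("oriented water shells give constructed coordination and H-bonds", {
  s <- make_water_shell(n_inner = 5, r_inner = 3.0, seed = 4,
                        orientation = "H-toward-center")
  expect_identical(coordination_number(s, "CL",
                                       shell_criteria(shell_cutoff = 3.9)),
                   5L)
  expect_identical(count_hbonds(s, "CL"), 5L)
  expect_error(make_water_shell(n_inner = 2, r_inner = -1, seed = 1),
               "positive")
  expect_error(make_water_shell(n_inner = 1, r_inner = 5, n_outer = 1,
                                r_outer = 3, seed = 1), "r_inner")
})
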