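test_that("a single unbiased window reduces WHAM to the histogram estimator", {
  x <- c(rep(0.0, 50), rep(0.5, 30), rep(1.0, 20))
  w <- umbrella_window(0, x, force_constant = 0)
  ds <- umbrella_dataset(list(w), temperature = 300)
  s <- wham(ds, grid = c(0, 0.5, 1.0))
  RT <- physical_constants$R_J / 1000 * 300 / physical_constants$kJ_per_kcal
  G_exp <- -RT * log(c(0.5, 0.3, 0.2))
  expect_equal(s$G, G_exp - min(G_exp), tolerance = 1e-9)
  expect_true(all(s$sampled))
})

test_that("WHAM output is invariant to window ordering", {
  dw <- toy_potential_spec("double_well", b = 12, c = 1)
  ds <- sample_umbrella_windows(dw, seq(-1.2, 1.2, by = 0.1),
                                n_samples = 150, seed = 4)
  grid <- seq(-1.2, 1.2, by = 0.05)
  s1 <- wham(ds, grid, tol = 1e-6)
  ds_rev <- umbrella_dataset(rev(ds$windows), ds$temperature)
  s2 <- wham(ds_rev, grid, tol = 1e-6)
  expect_equal(s1$G, s2$G, tolerance = 1e-6)
  # min-shift normalization: minimum over sampled nodes is exactly zero
  expect_equal(min(s1$G, na.rm = TRUE), 0)
})

test_that("unsampled grid regions are masked, never interpolated", {
  w <- umbrella_window(0, rnorm(200, 0, 0.05), force_constant = 2500)
  ds <- umbrella_dataset(list(w))
  s <- wham(ds, grid = seq(-2, 2, by = 0.05))
  expect_true(any(!s$sampled))
  expect_true(all(is.na(s$G[!s$sampled])))
  expect_true(all(is.finite(s$G[s$sampled])))
  # a window whose samples all fall off-grid is an error
  w2 <- umbrella_window(5, rep(5, 10), force_constant = 2500)
  expect_error(wham(umbrella_dataset(list(w2)), grid = seq(-1, 1, 0.1)),
               "empty histogram")
})

test_that("window samples round-trip through manifest files", {
  dw <- toy_potential_spec("harmonic", a = 30)
  ds <- sample_umbrella_windows(dw, c(-0.5, 0, 0.5), n_samples = 50,
                                seed = 2)
  dir <- withr::local_tempdir()
  man <- write_umbrella_dataset(ds, dir)
  ds2 <- read_umbrella_dataset(man, temperature = ds$temperature)
  expect_equal(length(ds2$windows), 3L)
  for (i in 1:3) {
    expect_equal(ds2$windows[[i]]$center, ds$windows[[i]]$center)
    expect_equal(as.numeric(ds2$windows[[i]]$samples),
                 as.numeric(ds$windows[[i]]$samples), tolerance = 1e-12)
  }
})

test_that("spline corrections interpolate node differences exactly", {
  # zero correction leaves the surface unchanged
  fes <- make_toy_fes(toy_potential_spec("double_well", b = 15, c = 1),
                      grid = seq(-1.5, 1.5, by = 0.05))
  surf <- fes$surface
  coarse_idx <- seq(1, nrow(surf$nodes), by = 10)
  nodes <- surf$nodes$x[coarse_idx]   # coarse nodes on the fine grid
  c0 <- correction_spline(nodes, rep(0, length(nodes)))
  expect_equal(spline_correct(surf, c0)$G, surf$G, tolerance = 1e-12)
  # at coarse nodes the corrected surface equals the high-level value
  dE <- sin(nodes)
  cs <- correction_spline(nodes, dE)
  corr <- spline_correct(surf, cs)
  hl_at <- surf$G[coarse_idx] + dE
  shift <- min(surf$G + evaluate_correction(cs, surf$nodes$x))
  expect_equal(corr$G[coarse_idx], hl_at - shift, tolerance = 1e-9)
  # a linear difference field is reproduced exactly everywhere (1D)
  lin <- correction_spline(nodes, 2 * nodes + 1)
  expect_equal(evaluate_correction(lin, surf$nodes$x),
               2 * surf$nodes$x + 1, tolerance = 1e-9)
  # ... and in 2D with the bilinear interpolant
  ax <- seq(-1, 1, by = 0.5)
  dE2 <- outer(ax, ax, function(x, y) 3 * x - 2 * y + 0.5)
  cs2 <- correction_spline(list(ax, ax), dE2)
  q <- expand.grid(x = seq(-1, 1, by = 0.1), y = seq(-1, 1, by = 0.1))
  expect_equal(evaluate_correction(cs2, q), 3 * q$x - 2 * q$y + 0.5,
               tolerance = 1e-9)
  # extrapolation beyond the node hull is refused
  expect_error(evaluate_correction(cs, 2.0), "hull")
  expect_error(evaluate_correction(cs2, cbind(2, 0)), "hull")
})

test_that("grid minima and minimax saddles are located exactly", {
  # 1D double well: saddle equals the maximal node between the minima
  fes <- make_toy_fes(toy_potential_spec("double_well", b = 10, c = 1),
                      grid = seq(-1.5, 1.5, by = 0.1))
  sp <- locate_stationary_points(fes$surface)
  expect_equal(sort(sp$minima$x), c(-1, 1), tolerance = 1e-9)
  expect_equal(nrow(sp$saddles), 1L)
  expect_equal(sp$saddles$G_saddle, 10 / 4.184, tolerance = 1e-9)
  # single-basin paraboloid: one minimum, no saddles
  g2 <- list(seq(-1, 1, 0.25), seq(-1, 1, 0.25))
  nodes <- expand.grid(x = g2[[1]], y = g2[[2]])
  para <- pmf_surface(nodes, nodes$x^2 + nodes$y^2, axes = g2)
  sp2 <- locate_stationary_points(para)
  expect_equal(nrow(sp2$minima), 1L)
  expect_equal(sp2$minima$G, 0)
  expect_equal(nrow(sp2$saddles), 0L)
  # 6x6 grid with a hand-placed ridge: union-find saddle equals the
  # exhaustive simple-path minimax oracle
  set.seed(99)
  nx <- 6L
  ax <- list(seq_len(nx) * 1.0, seq_len(nx) * 1.0)
  G <- matrix(runif(nx * nx, 2, 4), nx, nx)
  G[, 3] <- G[, 3] + 6           # ridge down the middle
  G[2, 1] <- 0; G[5, 6] <- 0.5   # two wells either side
  nodes6 <- expand.grid(x = ax[[1]], y = ax[[2]])
  surf6 <- pmf_surface(nodes6, as.vector(G), axes = ax)
  sp6 <- locate_stationary_points(surf6)
  i1 <- which(surf6$G == 0)
  i2 <- which(abs(surf6$G - 0.5) < 1e-9)
  row6 <- sp6$saddles[(sp6$saddles$min_a == i1 & sp6$saddles$min_b == i2) |
                        (sp6$saddles$min_a == i2 & sp6$saddles$min_b == i1), ]
  expect_equal(nrow(row6), 1L)
  expect_equal(row6$G_saddle,
               oracle_minimax(surf6$G, c(nx, nx), i1, i2),
               tolerance = 1e-12)
  # saddle energy dominates both minima and is symmetric in the pair
  expect_true(all(sp6$saddles$barrier_from_a >= -1e-12))
  expect_true(all(sp6$saddles$barrier_from_b >= -1e-12))
})
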