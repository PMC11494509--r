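# Umbrella-sampling bookkeeping and WHAM reconstruction of potentials of
# mean force, plus spline high-level corrections and grid-level
# stationary-point analysis. Coordinates are abstract 1D or 2D reaction
# coordinates (angstrom or composites); energies are handled in kJ/mol
# internally and reported in kcal/mol.

#' Construct an umbrella window
#'
#' @param center restraint center(s): length 1 (1D) or 2 (2D).
#' @param samples numeric vector (1D) or 2-column matrix (2D) of reaction
#'   coordinate values visited under the bias.
#' @param force_constant harmonic bias force constant, kJ mol^-1 A^-2
#'   (default 2500); scalar or one per dimension.
#' @param n_equil_discard leading samples dropped as equilibration.
#' @return An object of class \code{umbrella_window}.
#' @export
umbrella_window <- function(center, samples, force_constant = 2500,
                            n_equil_discard = 0) {
  if (any(force_constant < 0)) stop("force_constant must be >= 0")
  samples <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1)
  if (n_equil_discard > 0) {
    if (n_equil_discard >= nrow(samples))
      stop("discard leaves no samples")
    samples <- samples[-seq_len(n_equil_discard), , drop = FALSE]
  }
  if (nrow(samples) == 0L) stop("window has no samples")
  if (ncol(samples) != length(center))
    stop("sample dimensionality does not match center")
  structure(list(center = as.numeric(center), samples = samples,
                 force_constant = rep_len(force_constant, length(center))),
            class = "umbrella_window")
}

#' Bundle umbrella windows into a dataset
#'
#' @param windows list of [umbrella_window()]s, all of one dimensionality.
#' @param temperature kelvin.
#' @return An object of class \code{umbrella_dataset}.
#' @export
umbrella_dataset <- function(windows, temperature = 310) {
  if (!length(windows)) stop("need at least one window")
  dims <- vapply(windows, function(w) length(w$center), integer(1))
  if (length(unique(dims)) != 1L)
    stop("windows have inconsistent dimensionality")
  structure(list(windows = windows, dimensionality = dims[1],
                 temperature = temperature),
            class = "umbrella_dataset")
}

.grid_nodes <- function(grid) {
  # grid: list(min=, max=, n=) per dimension, or a numeric vector of node
  # centers (1D), or list of two such vectors (2D)
  expand1 <- function(g) {
    if (is.numeric(g)) return(g)
    seq(g$min, g$max, length.out = g$n)
  }
  if (is.numeric(grid)) return(list(expand1(grid)))
  if (!is.null(grid$min)) return(list(expand1(grid)))
  lapply(grid, expand1)
}

.bias_energy <- function(w, nodes_df) {
  # harmonic bias evaluated at node centers, kJ/mol
  e <- 0
  for (d in seq_along(w$center))
    e <- e + 0.5 * w$force_constant[d] * (nodes_df[[d]] - w$center[d])^2
  e
}

#' WHAM reconstruction of a PMF from umbrella windows
#'
#' Standard self-consistent weighted-histogram iteration: samples of all
#' windows are histogrammed on the PMF grid (bin centers are the grid
#' nodes; no separate binning), and the window free-energy shifts f_i and
#' the unbiased density rho are iterated until the maximum relative change
#' of rho between successive iterations falls below \code{tol}. The PMF is
#' -RT ln(rho), min-shifted to zero; nodes with no samples are masked, not
#' interpolated.
#'
#' @param dataset an [umbrella_dataset()].
#' @param grid PMF grid: \code{list(min=, max=, n=)} (1D), a numeric vector
#'   of node centers, or a list of two of either (2D).
#' @param tol convergence tolerance on the unbiased density (default 1e-3).
#' @param max_iter iteration cap (default 1e5).
#' @return An object of class \code{pmf_surface}: list with \code{nodes}
#'   (data.frame of coordinates), \code{G} (kcal/mol, min-shifted, NA on
#'   masked nodes), \code{sampled} (logical mask), \code{counts},
#'   \code{f} (window shifts, kJ/mol), \code{iterations},
#'   \code{dimensionality}, \code{grid_dims}.
#' @export
wham <- function(dataset, grid, tol = 1e-3, max_iter = 1e5) {
  stopifnot(inherits(dataset, "umbrella_dataset"))
  axes <- .grid_nodes(grid)
  if (length(axes) != dataset$dimensionality)
    stop("grid dimensionality does not match dataset")
  nodes <- if (length(axes) == 1L) data.frame(x = axes[[1]])
           else expand.grid(x = axes[[1]], y = axes[[2]])
  nbin <- nrow(nodes)
  # assign samples to nearest node (equal-width bins around node centers)
  bin_of <- function(v, ax) {
    step <- if (length(ax) > 1) ax[2] - ax[1] else 1
    i <- round((v - ax[1]) / step) + 1
    i[i < 1 | i > length(ax)] <- NA
    i
  }
  H <- numeric(nbin)
  N <- integer(length(dataset$windows))
  for (k in seq_along(dataset$windows)) {
    s <- dataset$windows[[k]]$samples
    i1 <- bin_of(s[, 1], axes[[1]])
    idx <- if (length(axes) == 1L) i1 else {
      i2 <- bin_of(s[, 2], axes[[2]])
      i1 + (i2 - 1L) * length(axes[[1]])
    }
    idx <- idx[!is.na(idx)]
    if (!length(idx))
      stop("window ", k, " has an empty histogram on the grid")
    N[k] <- length(idx)
    tab <- tabulate(idx, nbins = nbin)
    H <- H + tab
  }
  RT <- physical_constants$R_J / 1000 * dataset$temperature  # kJ/mol
  # bias Boltzmann factors at node centers: nwin x nbin
  B <- t(vapply(dataset$windows, function(w)
    exp(-.bias_energy(w, nodes) / RT), numeric(nbin)))
  sampled <- H > 0
  # Solve the convex WHAM dual for the window shifts g_i = ln f_i first
  # (guards against the slow tail of plain direct iteration), then polish
  # with direct iteration until the unbiased density is self-consistent to
  # tol (maximum relative change between successive updates).
  logB <- log(pmax(B, .Machine$double.xmin))
  nll <- function(g) {
    # log denom_j = log sum_i N_i e^{g_i} B_ij, computed stably
    m <- apply(logB + g + log(N), 2, max)
    d <- m + log(colSums(exp(sweep(logB + g + log(N), 2, m))))
    -sum(N * g) + sum(H[sampled] * d[sampled])
  }
  grad <- function(g) {
    m <- apply(logB + g + log(N), 2, max)
    ld <- m + log(colSums(exp(sweep(logB + g + log(N), 2, m))))
    W <- exp(sweep(logB + g + log(N), 2, ld))  # N_i e^g B_ij / denom_j
    -N + as.vector(W[, sampled, drop = FALSE] %*% H[sampled])
  }
  g <- rep(0, length(N))
  if (length(N) > 1L) {
    opt <- stats::optim(g, nll, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    g <- opt$par - opt$par[1]
  }
  f <- exp(g)
  rho <- {
    denom <- as.vector(crossprod(B, N * f))
    r <- ifelse(denom > 0, H / denom, 0)
    r
  }
  rel <- Inf
  for (it in seq_len(max_iter)) {
    f <- 1 / as.vector(B %*% rho)
    denom <- as.vector(crossprod(B, N * f))
    rho_new <- ifelse(denom > 0, H / denom, 0)
    rel <- max(abs(rho_new[sampled] - rho[sampled]) /
                 pmax(rho[sampled], .Machine$double.xmin))
    rho <- rho_new
    if (rel < tol) break
  }
  if (rel >= tol)
    stop("WHAM did not converge in ", max_iter,
         " iterations (residual ", signif(rel, 3), ")")
  G_kJ <- rep(NA_real_, nbin)
  G_kJ[sampled] <- -RT * log(rho[sampled])
  G_kJ <- G_kJ - min(G_kJ, na.rm = TRUE)
  structure(list(nodes = nodes, G = G_kJ / physical_constants$kJ_per_kcal,
                 sampled = sampled, counts = H, f = RT * log(f),
                 iterations = it, dimensionality = length(axes),
                 grid_dims = vapply(axes, length, integer(1)),
                 axes = axes, temperature = dataset$temperature),
            class = "pmf_surface")
}

#' @export
print.pmf_surface <- function(x, ...) {
  cat("pmf_surface:", x$dimensionality, "D,",
      paste(x$grid_dims, collapse = " x "), "nodes,",
      sum(x$sampled), "sampled; G range",
      sprintf("[0, %.2f] kcal/mol", max(x$G, na.rm = TRUE)), "\n")
  invisible(x)
}

#' Construct a PMF surface directly from a grid of energies
#'
#' @param nodes data.frame of node coordinates (columns x, and y in 2D).
#' @param G energies per node, kcal/mol (min-shifted internally).
#' @param axes list of axis node vectors (inferred for regular grids when
#'   omitted).
#' @return A \code{pmf_surface} with all nodes sampled.
#' @export
pmf_surface <- function(nodes, G, axes = NULL) {
  stopifnot(nrow(nodes) == length(G), all(is.finite(G)))
  if (is.null(axes)) {
    axes <- lapply(nodes, function(v) sort(unique(v)))
  }
  structure(list(nodes = nodes, G = G - min(G),
                 sampled = rep(TRUE, length(G)), counts = rep(NA, length(G)),
                 f = NULL, iterations = 0L,
                 dimensionality = length(axes),
                 grid_dims = vapply(axes, length, integer(1)),
                 axes = axes, temperature = NA_real_),
            class = "pmf_surface")
}

#' Bootstrap replicate PMFs
#'
#' Resamples each window's samples with replacement and reruns [wham()],
#' returning the matrix of replicate free energies so any derived
#' statistic (barrier, well depth, flatness deviation) can be given a
#' bootstrap standard error. Resampling is done in moving blocks of
#' consecutive samples (default length ~sqrt(n)) so that the standard
#' error stays honest when the window samples are autocorrelated, as
#' Metropolis or MD trajectories are.
#'
#' @inheritParams wham
#' @param n_boot number of replicates (default 50).
#' @param seed integer seed.
#' @param block_length block size for the moving-block bootstrap;
#'   \code{NULL} = \code{ceiling(sqrt(n))} per window.
#' @return list with \code{G_rep} (nodes x n_boot matrix, kcal/mol,
#'   min-shifted per replicate), \code{se} (per-node standard error) and
#'   the point-estimate \code{surface}.
#' @export
wham_bootstrap <- function(dataset, grid, n_boot = 50, seed = 1,
                           tol = 1e-3, max_iter = 1e5,
                           block_length = NULL) {
  surf <- wham(dataset, grid, tol, max_iter)
  rng <- .seeded_rng(seed)
  G_rep <- matrix(NA_real_, nrow(surf$nodes), n_boot)
  for (b in seq_len(n_boot)) {
    ws <- lapply(dataset$windows, function(w) {
      n <- nrow(w$samples)
      L <- if (is.null(block_length)) ceiling(sqrt(n))
           else min(block_length, n)
      nblk <- ceiling(n / L)
      starts <- as.integer(floor(rng(nblk) * (n - L + 1))) + 1L
      idx <- as.vector(vapply(starts, function(s) s + 0:(L - 1L),
                              integer(L)))[seq_len(n)]
      umbrella_window(w$center, w$samples[idx, , drop = FALSE],
                      w$force_constant)
    })
    sb <- wham(umbrella_dataset(ws, dataset$temperature), grid, tol,
               max_iter)
    G_rep[, b] <- sb$G
  }
  se <- apply(G_rep, 1, stats::sd, na.rm = TRUE)
  list(G_rep = G_rep, se = se, surface = surf)
}

# ---- spline corrections ----------------------------------------------------

#' High-level correction spline
#'
#' Encapsulates the interpolated correction that upgrades a low-level (LL)
#' energy surface with single-point high-minus-low (HL - LL) energy
#' differences evaluated on a coarse grid of nodes: corrected(r) =
#' E_LL(r) + S(dE)(r), with S an interpolant that passes through the nodes
#' exactly.
#'
#' @param nodes coarse node coordinates: numeric vector (1D) or list of two
#'   axis vectors for a regular 2D grid.
#' @param dE HL - LL differences at the nodes: vector (1D) or matrix of
#'   dim (length x-axis, length y-axis) (2D). Units follow the surface
#'   being corrected.
#' @param order interpolation: \code{"cubic"} (natural cubic spline, 1D
#'   only) or \code{"linear"} (1D or bilinear 2D).
#' @return An object of class \code{correction_spline} — callable via
#'   [evaluate_correction()].
#' @export
correction_spline <- function(nodes, dE, order = c("cubic", "linear")) {
  order <- match.arg(order)
  if (is.numeric(nodes)) {
    stopifnot(length(nodes) == length(dE))
    dim <- 1L
  } else {
    stopifnot(is.list(nodes), length(nodes) == 2L, is.matrix(dE),
              nrow(dE) == length(nodes[[1]]), ncol(dE) == length(nodes[[2]]))
    dim <- 2L
    if (order == "cubic") order <- "linear"  # 2D corrections are bilinear
  }
  structure(list(nodes = nodes, dE = dE, order = order, dim = dim),
            class = "correction_spline")
}

#' Evaluate a correction spline
#'
#' @param correction a [correction_spline()].
#' @param x query coordinates: vector (1D) or 2-column matrix /
#'   data.frame (2D). Queries outside the node hull are an error (no
#'   silent extrapolation).
#' @return interpolated dE values.
#' @export
evaluate_correction <- function(correction, x) {
  if (correction$dim == 1L) {
    x <- as.numeric(x)
    rng <- range(correction$nodes)
    if (any(x < rng[1] - 1e-9 | x > rng[2] + 1e-9))
      stop("correction query outside the node hull [", rng[1], ", ",
           rng[2], "]")
    if (correction$order == "cubic")
      stats::splinefun(correction$nodes, correction$dE,
                       method = "natural")(x)
    else stats::approx(correction$nodes, correction$dE, xout = x)$y
  } else {
    x <- as.matrix(x)
    rx <- range(correction$nodes[[1]]); ry <- range(correction$nodes[[2]])
    if (any(x[, 1] < rx[1] - 1e-9 | x[, 1] > rx[2] + 1e-9 |
              x[, 2] < ry[1] - 1e-9 | x[, 2] > ry[2] + 1e-9))
      stop("correction query outside the node hull")
    # interp2 convention: Z is length(y) x length(x)
    pracma::interp2(correction$nodes[[1]], correction$nodes[[2]],
                    t(correction$dE),
                    pmin(pmax(x[, 1], rx[1]), rx[2]),
                    pmin(pmax(x[, 2], ry[1]), ry[2]), method = "linear")
  }
}

#' Apply a spline correction to a low-level surface
#'
#' @param ll_surface a \code{pmf_surface} (or any object with \code{nodes}
#'   and \code{G}).
#' @param correction a [correction_spline()] whose node hull covers the
#'   surface grid.
#' @return A new \code{pmf_surface} with G replaced by
#'   \code{G + S(dE)} (re-min-shifted); at coarse nodes the corrected
#'   energy equals the high-level value exactly.
#' @export
spline_correct <- function(ll_surface, correction) {
  q <- if (correction$dim == 1L) ll_surface$nodes[[1]]
       else as.matrix(ll_surface$nodes[, 1:2])
  corr <- evaluate_correction(correction, q)
  G <- ll_surface$G + corr
  out <- ll_surface
  out$G <- G - min(G, na.rm = TRUE)
  out$correction_applied <- TRUE
  out
}

# ---- stationary points on grids -------------------------------------------

.neighbours <- function(i, dims) {
  # linear indices of grid neighbours: 2 in 1D, 8-connectivity in 2D
  if (length(dims) == 1L) {
    out <- c(i - 1L, i + 1L)
    return(out[out >= 1L & out <= dims[1]])
  }
  nx <- dims[1]; ny <- dims[2]
  ix <- (i - 1L) %% nx + 1L
  iy <- (i - 1L) %/% nx + 1L
  dx <- rep(-1:1, 3); dy <- rep(-1:1, each = 3)
  keep <- !(dx == 0 & dy == 0)
  jx <- ix + dx[keep]; jy <- iy + dy[keep]
  ok <- jx >= 1 & jx <= nx & jy >= 1 & jy <= ny
  jx[ok] + (jy[ok] - 1L) * nx
}

#' Locate minima and minimax saddle energies on a PMF grid
#'
#' Minima are sampled nodes not above any sampled neighbour (8-connectivity
#' in 2D; plateau ties resolved to the lowest node index). The saddle
#' energy between two minima is the minimax path cost — the minimal over
#' connecting paths of the maximal node energy — computed exactly by
#' merging nodes in ascending energy order (union-find): two minima's
#' saddle is the energy at which their basins first connect.
#'
#' @param surface a \code{pmf_surface}.
#' @return list with \code{minima} (data.frame: node index, coordinates,
#'   G) and \code{saddles} (data.frame: minimum pair, saddle energy
#'   \code{G_saddle}, barrier heights from each minimum). Masked gaps that
#'   disconnect two minima are an error.
#' @export
locate_stationary_points <- function(surface) {
  stopifnot(inherits(surface, "pmf_surface"))
  G <- surface$G
  dims <- surface$grid_dims
  sampled <- surface$sampled & !is.na(G)
  is_min <- logical(length(G))
  for (i in which(sampled)) {
    nb <- .neighbours(i, dims)
    nb <- nb[sampled[nb]]
    if (!length(nb)) { is_min[i] <- TRUE; next }
    if (all(G[i] < G[nb])) is_min[i] <- TRUE
    else if (all(G[i] <= G[nb])) {
      # plateau: accept only the lowest-index node of the flat patch
      flat <- nb[G[nb] == G[i]]
      is_min[i] <- all(i < flat)
    }
  }
  mins <- which(is_min)
  minima <- cbind(node = mins, surface$nodes[mins, , drop = FALSE],
                  G = G[mins])
  rownames(minima) <- NULL
  if (length(mins) < 2L)
    return(list(minima = minima,
                saddles = data.frame(min_a = integer(), min_b = integer(),
                                     G_saddle = numeric())))
  # union-find over ascending energies
  parent <- seq_along(G)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  added <- logical(length(G))
  sad <- matrix(NA_real_, length(mins), length(mins))
  pending <- (length(mins) * (length(mins) - 1L)) %/% 2L
  ord <- order(G, seq_along(G))       # deterministic tie-break by index
  ord <- ord[sampled[ord]]
  for (i in ord) {
    added[i] <- TRUE
    for (j in .neighbours(i, dims)) if (added[j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
    # check which minima pairs just merged
    roots <- vapply(mins, find, integer(1))
    for (a in seq_along(mins)) for (b in seq_len(a - 1L)) {
      if (is.na(sad[a, b]) && added[mins[a]] && added[mins[b]] &&
            roots[a] == roots[b]) {
        sad[a, b] <- G[i]
        pending <- pending - 1L
      }
    }
    if (pending == 0L) break
  }
  if (pending > 0L)
    stop("masked gaps disconnect ", pending, " minima pair(s)")
  pairs <- which(lower.tri(sad), arr.ind = TRUE)
  saddles <- data.frame(min_a = mins[pairs[, 2]], min_b = mins[pairs[, 1]],
                        G_saddle = sad[pairs],
                        barrier_from_a = sad[pairs] - G[mins[pairs[, 2]]],
                        barrier_from_b = sad[pairs] - G[mins[pairs[, 1]]])
  list(minima = minima, saddles = saddles)
}

# ---- window-sample I/O -----------------------------------------------------

#' Read an umbrella dataset from a windows manifest
#'
#' The manifest CSV has columns \code{file}, \code{center} (and
#' \code{center2} for 2D), \code{force_constant}, optional
#' \code{n_equil_discard}; each referenced plain-text file holds one sample
#' per line (two whitespace-separated columns in 2D). Paths are relative to
#' the manifest.
#'
#' @param manifest_path CSV path.
#' @param temperature kelvin.
#' @return An [umbrella_dataset()].
#' @export
read_umbrella_dataset <- function(manifest_path, temperature = 310) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  two_d <- "center2" %in% names(man)
  windows <- lapply(seq_len(nrow(man)), function(i) {
    s <- as.matrix(utils::read.table(file.path(base, man$file[i])))
    umbrella_window(
      center = if (two_d) c(man$center[i], man$center2[i]) else man$center[i],
      samples = s,
      force_constant = man$force_constant[i],
      n_equil_discard = if ("n_equil_discard" %in% names(man))
        man$n_equil_discard[i] else 0)
  })
  umbrella_dataset(windows, temperature)
}

#' Write an umbrella dataset as sample files plus manifest
#'
#' @param dataset an \code{umbrella_dataset}.
#' @param dir output directory (created if needed).
#' @return manifest path, invisibly.
#' @export
write_umbrella_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(dataset$windows), function(i) {
    w <- dataset$windows[[i]]
    f <- sprintf("window_%03d.dat", i)
    utils::write.table(w$samples, file.path(dir, f), row.names = FALSE,
                       col.names = FALSE)
    if (length(w$center) == 2L)
      data.frame(file = f, center = w$center[1], center2 = w$center[2],
                 force_constant = w$force_constant[1])
    else data.frame(file = f, center = w$center,
                    force_constant = w$force_constant[1])
  })
  man <- do.call(rbind, rows)
  path <- file.path(dir, "windows.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}
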