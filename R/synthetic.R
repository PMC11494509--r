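# Synthetic-data generators: toy charged structures with prescribed
# residue distances and net charges, Metropolis samples from known 1D/2D
# potentials under harmonic restraints, toy free-energy grids with
# closed-form stationary points, and oriented water shells. Every generator
# is a pure function of (spec, seed); the private RNG stream never touches
# the caller's .Random.seed.

.seeded_rng <- function(seed) {
  state <- NULL
  function(n, kind = c("unif", "norm")) {
    kind <- match.arg(kind)
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = .GlobalEnv)
    out <- if (kind == "unif") stats::runif(n) else stats::rnorm(n)
    state <<- get(".Random.seed", envir = .GlobalEnv)
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, envir = .GlobalEnv)
    out
  }
}

# deterministic quasi-uniform directions (Fibonacci sphere)
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta), y = sin(phi) * sin(theta),
        z = cos(phi))
}

#' Specification of a toy globular point-charge protein
#'
#' @param residues data.frame with columns \code{name} (template name),
#'   \code{net_charge} (e), \code{ca_distance} (angstrom from the origin
#'   probe) and optionally \code{n_atoms} (satellite atoms per residue,
#'   default 4).
#' @param n_waters,water_rmin,water_rmax optional waters (TIP3P charges)
#'   placed at random radii in [rmin, rmax].
#' @param n_ions,ion_charge optional monovalent ions at water-like radii.
#' @return An object of class \code{toy_protein_spec}.
#' @export
toy_protein_spec <- function(residues, n_waters = 0, water_rmin = 10,
                             water_rmax = 20, n_ions = 0, ion_charge = 1) {
  stopifnot(all(c("name", "net_charge", "ca_distance") %in% names(residues)))
  if (any(residues$ca_distance <= 0)) stop("ca_distance must be positive")
  if (is.null(residues$n_atoms)) residues$n_atoms <- 4L
  structure(list(residues = residues, n_waters = n_waters,
                 water_rmin = water_rmin, water_rmax = water_rmax,
                 n_ions = n_ions, ion_charge = ion_charge),
            class = "toy_protein_spec")
}

#' Generate a toy charged structure
#'
#' Places each residue's Calpha exactly at its prescribed distance from the
#' origin along a deterministic quasi-uniform direction, scatters
#' \code{n_atoms} satellite atoms within ~1 angstrom of the Calpha, and
#' distributes the declared net charge over the residue's atoms (random
#' spread, exactly renormalized). The origin is the intended probe site; a
#' massless probe position, not an atom. Deterministic given the seed.
#'
#' @param spec a [toy_protein_spec()].
#' @param seed integer seed.
#' @return A \code{charged_structure}.
#' @export
make_toy_protein <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "toy_protein_spec"))
  rng <- .seeded_rng(seed)
  nres <- nrow(spec$residues)
  dirs <- .fibonacci_sphere(max(nres, 2L))[seq_len(nres), , drop = FALSE]
  rows <- list()
  aid <- 0L
  for (i in seq_len(nres)) {
    r <- spec$residues[i, ]
    ca <- as.numeric(dirs[i, ]) * r$ca_distance
    nat <- r$n_atoms
    # satellites on a small deterministic shell + jitter
    sat <- .fibonacci_sphere(max(nat, 2L))[seq_len(nat), , drop = FALSE]
    jit <- matrix(rng(nat * 3, "norm") * 0.05, ncol = 3)
    pos <- rbind(ca, sweep(sat * 0.9 + jit, 2, ca, `+`))
    q <- rng(nat, "norm") * 0.2
    q <- c(0, q - mean(q) + r$net_charge / nat)  # CA neutral, sum exact
    q[2] <- q[2] + (r$net_charge - sum(q))        # kill rounding residue
    rows[[i]] <- data.frame(
      atom_id = aid + seq_len(nat + 1L),
      atom_name = c("CA", paste0("X", seq_len(nat))),
      residue_name = r$name, residue_seq = i, chain_id = "A",
      x = pos[, 1], y = pos[, 2], z = pos[, 3], charge = q,
      group_kind = "protein", stringsAsFactors = FALSE)
    aid <- aid + nat + 1L
  }
  seq0 <- nres
  if (spec$n_waters > 0) {
    wd <- .fibonacci_sphere(max(spec$n_waters, 2L))[seq_len(spec$n_waters), ,
                                                    drop = FALSE]
    wr <- spec$water_rmin +
      rng(spec$n_waters) * (spec$water_rmax - spec$water_rmin)
    for (i in seq_len(spec$n_waters)) {
      o <- as.numeric(wd[i, ]) * wr[i]
      rows[[length(rows) + 1L]] <- data.frame(
        atom_id = aid + 1:3,
        atom_name = c("O", "H1", "H2"), residue_name = "HOH",
        residue_seq = seq0 + i, chain_id = "W",
        x = o[1] + c(0, 0.9572, -0.24), y = o[2] + c(0, 0, 0.927),
        z = o[3], charge = c(-0.834, 0.417, 0.417),
        group_kind = "water", stringsAsFactors = FALSE)
      aid <- aid + 3L
    }
    seq0 <- seq0 + spec$n_waters
  }
  if (spec$n_ions > 0) {
    id <- .fibonacci_sphere(max(spec$n_ions + 7L, 2L))
    id <- id[seq(nrow(id), by = -1L, length.out = spec$n_ions), ,
             drop = FALSE]
    ir <- spec$water_rmin +
      rng(spec$n_ions) * (spec$water_rmax - spec$water_rmin)
    nm <- if (spec$ion_charge > 0) "NA" else "CL"
    for (i in seq_len(spec$n_ions)) {
      p <- as.numeric(id[i, ]) * ir[i]
      rows[[length(rows) + 1L]] <- data.frame(
        atom_id = aid + 1L, atom_name = nm, residue_name = nm,
        residue_seq = seq0 + i, chain_id = "I",
        x = p[1], y = p[2], z = p[3], charge = spec$ion_charge,
        group_kind = "ion", stringsAsFactors = FALSE)
      aid <- aid + 1L
    }
  }
  atoms <- do.call(rbind, rows)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dmin <- min(stats::dist(xyz))
  if (dmin < 0.5)
    stop("generated atoms overlap (min separation ",
         signif(dmin, 3), " angstrom)")
  charged_structure(atoms, title = sprintf("toy protein (seed %d)", seed))
}

# ---- toy potentials --------------------------------------------------------

#' Specification of a toy 1D/2D potential
#'
#' Functional forms (energies in kJ/mol, coordinates in angstrom):
#' \describe{
#'   \item{flat}{U = 0 on \code{range}.}
#'   \item{harmonic}{U = a (x - x0)^2; minimum at x0.}
#'   \item{double_well}{U = b (x^2 - c^2)^2 / c^4; minima at +-c with
#'     U = 0, saddle at 0 with U = b.}
#'   \item{gaussians2d}{U = -sum_k h_k exp(-|r - m_k|^2 / (2 s_k^2));
#'     wells at the Gaussian centers.}
#' }
#'
#' @param form one of \code{"flat"}, \code{"harmonic"},
#'   \code{"double_well"}, \code{"gaussians2d"}.
#' @param range coordinate range (per dimension for 2D).
#' @param a,x0 harmonic parameters.
#' @param b,c double-well barrier height (kJ/mol) and half-separation
#'   (angstrom).
#' @param centers,heights,widths gaussians2d parameters: k x 2 matrix,
#'   vector, vector.
#' @return An object of class \code{toy_potential_spec} with \code{U}
#'   (vectorized energy function), \code{dimensionality} and
#'   \code{stationary} (closed-form minima/saddles where available).
#' @export
toy_potential_spec <- function(form = c("flat", "harmonic", "double_well",
                                        "gaussians2d"),
                               range = c(-2, 2), a = 10, x0 = 0, b = 20,
                               c = 1, centers = NULL, heights = NULL,
                               widths = NULL) {
  form <- match.arg(form)
  out <- switch(form,
    flat = list(U = function(x) rep(0, NROW(x)), dimensionality = 1L,
                stationary = NULL),
    harmonic = list(U = function(x) a * (x - x0)^2, dimensionality = 1L,
                    stationary = list(minima = data.frame(x = x0, G = 0))),
    double_well = {
      stopifnot(b > 0, c > 0)
      list(U = function(x) b * (x^2 - c^2)^2 / c^4, dimensionality = 1L,
           stationary = list(minima = data.frame(x = c(-c, c), G = 0),
                             saddle = data.frame(x = 0, G = b)))
    },
    gaussians2d = {
      stopifnot(is.matrix(centers), ncol(centers) == 2L,
                length(heights) == nrow(centers),
                length(widths) == nrow(centers))
      list(U = function(x) {
        x <- if (is.matrix(x) || is.data.frame(x)) as.matrix(x)
             else matrix(x, ncol = 2)
        v <- 0
        for (k in seq_len(nrow(centers)))
          v <- v - heights[k] *
            exp(-((x[, 1] - centers[k, 1])^2 +
                    (x[, 2] - centers[k, 2])^2) / (2 * widths[k]^2))
        v
      }, dimensionality = 2L,
      stationary = list(minima = data.frame(x = centers[, 1],
                                            y = centers[, 2])))
    })
  structure(c(out, list(form = form, range = range,
                        params = list(a = a, x0 = x0, b = b, c = c,
                                      centers = centers, heights = heights,
                                      widths = widths))),
            class = "toy_potential_spec")
}

#' Metropolis umbrella sampling of a toy potential
#'
#' Draws seeded Metropolis samples from exp(-(U(x) + bias)/RT) for each
#' window, with the harmonic bias k/2 (x - x0)^2. The proposal step is
#' auto-tuned toward a 30-60 percent acceptance rate during a burn-in of
#' 10 percent of \code{n_samples}, which is then discarded (the
#' equilibrate-then-produce convention).
#'
#' @param potential a [toy_potential_spec()] (1D).
#' @param centers window centers.
#' @param force_constant bias force constant, kJ mol^-1 A^-2 (default
#'   2500).
#' @param n_samples production samples per window.
#' @param temperature kelvin.
#' @param seed integer seed.
#' @param thin keep every \code{thin}-th Metropolis step (default 5) to
#'   reduce autocorrelation.
#' @return An [umbrella_dataset()]; each window carries an
#'   \code{acceptance} attribute.
#' @export
sample_umbrella_windows <- function(potential, centers,
                                    force_constant = 2500,
                                    n_samples = 500, temperature = 310,
                                    seed = 1, thin = 5L) {
  stopifnot(inherits(potential, "toy_potential_spec"),
            potential$dimensionality == 1L)
  rng <- .seeded_rng(seed)
  RT <- physical_constants$R_J / 1000 * temperature
  windows <- vector("list", length(centers))
  for (w in seq_along(centers)) {
    x0 <- centers[w]
    Ub <- function(x) potential$U(x) + 0.5 * force_constant * (x - x0)^2
    step <- 3 * sqrt(RT / max(force_constant, 1))  # ~2-3x biased sd
    n_burn <- max(ceiling(0.1 * n_samples), 100L)
    x <- x0
    ux <- Ub(x)
    acc <- 0L; tried <- 0L
    # burn-in with step tuning every 25 proposals toward 30-60% acceptance
    for (i in seq_len(n_burn)) {
      prop <- x + (rng(1) * 2 - 1) * step
      up <- Ub(prop)
      tried <- tried + 1L
      if (up <= ux || rng(1) < exp(-(up - ux) / RT)) {
        x <- prop; ux <- up; acc <- acc + 1L
      }
      if (tried %% 25L == 0L) {
        rate <- acc / tried
        if (rate < 0.30) step <- step / 1.4
        if (rate > 0.60) step <- step * 1.4
        acc <- 0L; tried <- 0L
      }
    }
    out <- numeric(n_samples)
    acc <- 0L
    ntot <- n_samples * thin
    for (i in seq_len(ntot)) {
      prop <- x + (rng(1) * 2 - 1) * step
      up <- Ub(prop)
      if (up <= ux || rng(1) < exp(-(up - ux) / RT)) {
        x <- prop; ux <- up; acc <- acc + 1L
      }
      if (i %% thin == 0L) out[i %/% thin] <- x
    }
    if (acc == 0L)
      stop("window at ", x0, ": zero Metropolis acceptance; ",
           "reduce the proposal step")
    win <- umbrella_window(x0, out, force_constant)
    attr(win, "acceptance") <- acc / ntot
    windows[[w]] <- win
  }
  umbrella_dataset(windows, temperature)
}

#' Evaluate a toy potential on a grid as a PMF surface
#'
#' @param potential a [toy_potential_spec()].
#' @param grid grid spec as in [wham()].
#' @return list with \code{surface} (a \code{pmf_surface}, energies
#'   converted to kcal/mol and min-shifted) and \code{stationary} (the
#'   declared closed-form stationary points, energies in kcal/mol).
#' @export
make_toy_fes <- function(potential, grid) {
  axes <- .grid_nodes(grid)
  stopifnot(length(axes) == potential$dimensionality)
  nodes <- if (length(axes) == 1L) data.frame(x = axes[[1]])
           else expand.grid(x = axes[[1]], y = axes[[2]])
  U <- potential$U(if (length(axes) == 1L) nodes$x else nodes)
  surf <- pmf_surface(nodes, U / physical_constants$kJ_per_kcal,
                      axes = axes)
  stat <- potential$stationary
  if (!is.null(stat)) {
    if (!is.null(stat$minima$G))
      stat$minima$G <- stat$minima$G / physical_constants$kJ_per_kcal
    if (!is.null(stat$saddle$G))
      stat$saddle$G <- stat$saddle$G / physical_constants$kJ_per_kcal
  }
  list(surface = surf, stationary = stat)
}

# ---- water shells ----------------------------------------------------------

#' Build an oriented water shell around a central ion
#'
#' Places \code{n_inner} TIP3P waters with oxygens exactly at
#' \code{r_inner} from the center (quasi-uniform directions) and
#' \code{n_outer} at \code{r_outer}, plus the central chloride-like anion.
#' The orientation rule fixes the hydrogen-bond geometry: with
#' \code{"H-toward-center"} one O-H bond of each inner water points exactly
#' at the center (an ideal 180-degree hydrogen bond), with
#' \code{"H-away"} both hydrogens point outward (no hydrogen bonds by
#' construction); outer waters always point away.
#'
#' @param center 3-vector position of the anion.
#' @param n_inner,r_inner inner-shell count and radius (angstrom).
#' @param n_outer,r_outer outer-shell count and radius.
#' @param orientation \code{"H-toward-center"}, \code{"H-away"} or
#'   \code{"random"}.
#' @param seed integer seed (used by \code{"random"} orientation and
#'   small azimuthal choices).
#' @param center_name atom/residue name of the central ion (default
#'   \code{"CL"}).
#' @return A \code{charged_structure}.
#' @export
make_water_shell <- function(center = c(0, 0, 0), n_inner = 5,
                             r_inner = 3.0, n_outer = 0, r_outer = 6.0,
                             orientation = c("H-toward-center", "H-away",
                                             "random"),
                             seed = 1, center_name = "CL") {
  orientation <- match.arg(orientation)
  if (r_inner <= 0 || r_outer <= 0) stop("radii must be positive")
  if (n_outer > 0 && r_inner >= r_outer) stop("r_inner must be < r_outer")
  rng <- .seeded_rng(seed)
  b <- 0.9572                       # O-H bond length
  ang <- 104.52 * pi / 180          # H-O-H angle
  rows <- list(data.frame(
    atom_id = 1L, atom_name = center_name, residue_name = center_name,
    residue_seq = 1L, chain_id = "I", x = center[1], y = center[2],
    z = center[3], charge = -1, group_kind = "ion",
    stringsAsFactors = FALSE))
  aid <- 1L
  place <- function(n, r, inward, seq_off) {
    if (n == 0) return(invisible(NULL))
    dirs <- .fibonacci_sphere(max(n, 2L))[seq_len(n), , drop = FALSE]
    for (i in seq_len(n)) {
      u <- as.numeric(dirs[i, ])              # outward unit vector
      o <- center + u * r
      # orthonormal frame at the oxygen
      ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      t1 <- ref - sum(ref * u) * u
      t1 <- t1 / sqrt(sum(t1^2))
      inw <- if (inward) -u else u           # first O-H along +-u
      h1 <- o + b * inw
      # second H at the water angle from the first, tilted off-axis
      h2dir <- cos(ang) * inw + sin(ang) * t1
      h2 <- o + b * h2dir
      rows[[length(rows) + 1L]] <<- data.frame(
        atom_id = aid + 1:3, atom_name = c("O", "H1", "H2"),
        residue_name = "HOH", residue_seq = seq_off + i, chain_id = "W",
        x = c(o[1], h1[1], h2[1]), y = c(o[2], h1[2], h2[2]),
        z = c(o[3], h1[3], h2[3]), charge = c(-0.834, 0.417, 0.417),
        group_kind = "water", stringsAsFactors = FALSE)
      aid <<- aid + 3L
    }
  }
  inner_in <- switch(orientation,
                     "H-toward-center" = rep(TRUE, max(n_inner, 0)),
                     "H-away" = rep(FALSE, max(n_inner, 0)),
                     "random" = rng(max(n_inner, 0)) < 0.5)
  if (n_inner > 0) {
    dirs <- .fibonacci_sphere(max(n_inner, 2L))[seq_len(n_inner), ,
                                                drop = FALSE]
    for (i in seq_len(n_inner)) {
      u <- as.numeric(dirs[i, ])
      o <- center + u * r_inner
      ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      t1 <- ref - sum(ref * u) * u
      t1 <- t1 / sqrt(sum(t1^2))
      inw <- if (inner_in[i]) -u else u
      h1 <- o + b * inw
      h2 <- o + b * (cos(ang) * inw + sin(ang) * t1)
      rows[[length(rows) + 1L]] <- data.frame(
        atom_id = aid + 1:3, atom_name = c("O", "H1", "H2"),
        residue_name = "HOH", residue_seq = 1L + i, chain_id = "W",
        x = c(o[1], h1[1], h2[1]), y = c(o[2], h1[2], h2[2]),
        z = c(o[3], h1[3], h2[3]), charge = c(-0.834, 0.417, 0.417),
        group_kind = "water", stringsAsFactors = FALSE)
      aid <- aid + 3L
    }
  }
  place(n_outer, r_outer, inward = FALSE, seq_off = 1L + n_inner)
  atoms <- do.call(rbind, rows)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(xyz) > 1 && min(stats::dist(xyz)) < 0.5)
    stop("generated atoms overlap")
  charged_structure(atoms, title = "synthetic water shell")
}
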