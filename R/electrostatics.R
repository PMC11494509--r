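# Classical Coulomb potential at active-site probes, decomposed by residue.
#
# V(r) = f_C * sum_i q_i / |r - r_i|, with q_i in e, distances in angstrom
# and the Coulomb factor f_C = N_A e^2 / (4 pi eps0) in kJ mol^-1 A e^-2,
# so potentials come out in kJ mol^-1 e^-1 (the potential energy of a unit
# probe charge). No distance cutoff and no switching function are applied:
# the quantity is the bare electrostatic potential of the fixed partial
# charges, optionally screened by a uniform relative dielectric.

.atom_scope <- function(structure, include, exclude_residues) {
  a <- structure$atoms
  sel <- a$group_kind %in% include
  if (length(exclude_residues))
    sel <- sel & !(residue_key(a) %in% exclude_residues)
  a[sel, , drop = FALSE]
}

.dist_to_probe <- function(atoms, probe) {
  sqrt((atoms$x - probe[1])^2 + (atoms$y - probe[2])^2 +
         (atoms$z - probe[3])^2)
}

#' Electrostatic potential at a point
#'
#' @param structure a \code{charged_structure}.
#' @param probe probe position: numeric 3-vector, [probe_site()] or atom
#'   name (resolved with [resolve_probe()]).
#' @param include group kinds whose atoms contribute; default all four.
#' @param exclude_residues character vector of residue keys
#'   (\code{"chain:seq"}) to leave out of the sum.
#' @param dielectric uniform relative dielectric constant (default 1,
#'   vacuum permittivity).
#' @return Potential in kJ mol^-1 e^-1.
#' @export
potential_at_point <- function(structure, probe,
                               include = c("protein", "water", "ion",
                                           "substrate"),
                               exclude_residues = character(),
                               dielectric = 1) {
  p <- resolve_probe(structure, probe)
  a <- .atom_scope(structure, include, exclude_residues)
  if (nrow(a) == 0L) return(0)
  d <- .dist_to_probe(a, p)
  if (any(d < 1e-6)) {
    at <- a[which(d < 1e-6)[1], ]
    stop("atom ", at$atom_name, " of ", at$residue_name, " ",
         at$chain_id, ":", at$residue_seq,
         " coincides with the probe (singularity)")
  }
  physical_constants$f_coulomb / dielectric * sum(a$charge / d)
}

#' Per-residue decomposition of the potential at a probe
#'
#' Splits the Coulomb potential at the probe into additive per-residue
#' contributions (each residue's atoms summed separately); waters, ions and
#' the substrate appear as their own groups. The per-residue entries sum to
#' [potential_at_point()] on the same scope by construction.
#'
#' @inheritParams potential_at_point
#' @return An object of class \code{potential_decomposition}: list with
#'   \code{total}, \code{per_group} (data.frame: key, chain_id, residue_seq,
#'   residue_name, group_kind, ca_distance, contribution), \code{probe},
#'   \code{include}.
#' @export
decompose_by_residue <- function(structure, probe,
                                 include = c("protein", "water", "ion",
                                             "substrate"),
                                 exclude_residues = character(),
                                 dielectric = 1) {
  p <- resolve_probe(structure, probe)
  a <- .atom_scope(structure, include, exclude_residues)
  if (nrow(a) == 0L) {
    per <- data.frame(key = character(), chain_id = character(),
                      residue_seq = integer(), residue_name = character(),
                      group_kind = character(), ca_distance = numeric(),
                      contribution = numeric(), stringsAsFactors = FALSE)
    return(structure(list(total = 0, per_group = per, probe = p,
                          include = include),
                     class = "potential_decomposition"))
  }
  d <- .dist_to_probe(a, p)
  if (any(d < 1e-6)) {
    at <- a[which(d < 1e-6)[1], ]
    stop("atom ", at$atom_name, " of ", at$residue_name, " ",
         at$chain_id, ":", at$residue_seq,
         " coincides with the probe (singularity)")
  }
  v <- physical_constants$f_coulomb / dielectric * a$charge / d
  key <- residue_key(a)
  contrib <- tapply(v, key, sum)
  idx <- !duplicated(key)
  ord <- match(names(contrib), key[idx])
  ca <- rep(NA_real_, length(contrib))
  is_ca <- a$atom_name == "CA" & a$group_kind == "protein"
  if (any(is_ca)) {
    cad <- .dist_to_probe(a[is_ca, , drop = FALSE], p)
    ca[match(key[is_ca], names(contrib))] <- cad
  }
  per <- data.frame(key = names(contrib),
                    chain_id = a$chain_id[idx][ord],
                    residue_seq = a$residue_seq[idx][ord],
                    residue_name = a$residue_name[idx][ord],
                    group_kind = a$group_kind[idx][ord],
                    ca_distance = ca,
                    contribution = as.numeric(contrib),
                    stringsAsFactors = FALSE)
  per <- per[order(match(per$key, key[idx])), ]  # structure order
  rownames(per) <- NULL
  structure(list(total = sum(v), per_group = per, probe = p,
                 include = include),
            class = "potential_decomposition")
}

#' @export
print.potential_decomposition <- function(x, ...) {
  cat("potential_decomposition: total",
      sprintf("%+.2f kJ mol^-1 e^-1", x$total), "over",
      nrow(x$per_group), "groups\n")
  invisible(x)
}

#' Cumulative distance-shell profile of the potential
#'
#' Accumulates per-residue contributions over growing spheres around the
#' probe using the Calpha-to-probe distance convention: a protein residue
#' enters the profile at the radius that first covers its backbone Calpha.
#' Waters, ions and the substrate carry no Calpha and are excluded; protein
#' residues lacking a Calpha atom are excluded and reported in the
#' \code{excluded} attribute.
#'
#' @inheritParams potential_at_point
#' @param r_min,r_max,step radial grid in angstrom (defaults 7, 24, 1).
#' @return An object of class \code{shell_profile}: data.frame with columns
#'   \code{radius}, \code{cumulative_V} (kJ mol^-1 e^-1),
#'   \code{cumulative_count}.
#' @export
shell_profile <- function(structure, probe, r_min = 7, r_max = 24,
                          step = 1.0, dielectric = 1) {
  if (r_min >= r_max) stop("r_min must be < r_max")
  if (step <= 0) stop("step must be positive")
  dec <- decompose_by_residue(structure, probe, include = "protein",
                              dielectric = dielectric)
  per <- dec$per_group
  excluded <- per$key[is.na(per$ca_distance)]
  per <- per[!is.na(per$ca_distance), , drop = FALSE]
  radii <- seq(r_min, r_max, by = step)
  cumV <- vapply(radii, function(r) sum(per$contribution[per$ca_distance <= r]),
                 numeric(1))
  cumN <- vapply(radii, function(r) sum(per$ca_distance <= r), integer(1))
  out <- data.frame(radius = radii, cumulative_V = cumV,
                    cumulative_count = cumN)
  attr(out, "distance_convention") <- "Calpha-to-probe"
  attr(out, "excluded") <- excluded
  class(out) <- c("shell_profile", "data.frame")
  out
}

#' Rank residues by absolute contribution
#'
#' Orders the decomposition by |contribution| (descending) and classifies
#' each residue against an absolute labelling threshold, by default
#' 60 kJ mol^-1 e^-1: contributions above +threshold are "positive", below
#' -threshold "negative", the rest "negligible".
#'
#' @param decomposition a \code{potential_decomposition}.
#' @param threshold labelling threshold in kJ mol^-1 e^-1 (>= 0).
#' @return data.frame of the decomposition rows plus \code{sign_class},
#'   sorted by absolute contribution.
#' @export
rank_contributors <- function(decomposition, threshold = 60) {
  stopifnot(inherits(decomposition, "potential_decomposition"))
  if (threshold < 0) stop("threshold must be non-negative")
  per <- decomposition$per_group
  if (nrow(per) == 0L) stop("empty decomposition")
  per$sign_class <- ifelse(per$contribution > threshold, "positive",
                           ifelse(per$contribution < -threshold,
                                  "negative", "negligible"))
  per <- per[order(-abs(per$contribution), per$key), ]
  rownames(per) <- NULL
  attr(per, "threshold") <- threshold
  per
}
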