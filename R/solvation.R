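# First-hydration-shell analysis around a chosen ion: coordination number
# by water-oxygen distance, and hydrogen-bond counting with a combined
# distance/angle criterion (the leaving-chloride analysis).

#' Geometric criteria for hydration-shell analysis
#'
#' Defaults follow standard chloride-hydration conventions:
#' Cl...O(water) within 3.9 angstrom defines the first shell, and a
#' hydrogen bond requires Cl...H within 2.9 angstrom with an
#' O-H...Cl angle of at least 150 degrees.
#'
#' @param shell_cutoff first-shell O distance cutoff, angstrom.
#' @param hbond_H_cutoff H distance cutoff, angstrom.
#' @param hbond_angle_min minimal O-H...center angle, degrees (0, 180].
#' @return list of criteria.
#' @export
shell_criteria <- function(shell_cutoff = 3.9, hbond_H_cutoff = 2.9,
                           hbond_angle_min = 150) {
  if (shell_cutoff <= 0 || hbond_H_cutoff <= 0)
    stop("cutoffs must be positive")
  if (hbond_angle_min <= 0 || hbond_angle_min > 180)
    stop("hbond_angle_min must be in (0, 180]")
  list(shell_cutoff = shell_cutoff, hbond_H_cutoff = hbond_H_cutoff,
       hbond_angle_min = hbond_angle_min)
}

.center_pos <- function(structure, center) resolve_probe(structure, center)

.water_oxygens <- function(structure) {
  a <- structure$atoms
  a[a$group_kind == "water" &
      (a$atom_name %in% c("O", "OW", "OH2") |
         grepl("^O", a$atom_name)), , drop = FALSE]
}

#' First-shell water coordination number
#'
#' Counts waters whose oxygen lies within \code{shell_cutoff} of the
#' center atom.
#'
#' @param structure a \code{charged_structure} with water residues.
#' @param center the central atom: a [probe_site()], atom-name string or
#'   3-vector.
#' @param criteria a [shell_criteria()].
#' @return integer count.
#' @export
coordination_number <- function(structure, center,
                                criteria = shell_criteria()) {
  p <- .center_pos(structure, center)
  ox <- .water_oxygens(structure)
  if (nrow(ox) == 0L) return(0L)
  d <- .dist_to_probe(ox, p)
  sum(d <= criteria$shell_cutoff)
}

#' Count water hydrogen bonds to a central anion
#'
#' An O-H group donates a hydrogen bond when its H lies within
#' \code{hbond_H_cutoff} of the center and the O-H...center angle is at
#' least \code{hbond_angle_min} degrees (180 = H exactly between O and the
#' center). Waters must carry explicit hydrogens; waters without any are an
#' error naming them.
#'
#' @inheritParams coordination_number
#' @return integer count of donated hydrogen bonds.
#' @export
count_hbonds <- function(structure, center, criteria = shell_criteria()) {
  p <- .center_pos(structure, center)
  a <- structure$atoms
  w <- a[a$group_kind == "water", , drop = FALSE]
  if (nrow(w) == 0L) return(0L)
  keys <- residue_key(w)
  n <- 0L
  for (k in unique(keys)) {
    res <- w[keys == k, , drop = FALSE]
    o <- res[grepl("^O", res$atom_name), , drop = FALSE]
    h <- res[grepl("^H", res$atom_name), , drop = FALSE]
    if (nrow(h) == 0L)
      stop("water ", k, " lacks explicit hydrogens")
    if (nrow(o) != 1L) stop("water ", k, " has no unique oxygen")
    for (j in seq_len(nrow(h))) {
      hp <- as.numeric(h[j, c("x", "y", "z")])
      dhc <- sqrt(sum((hp - p)^2))
      if (dhc > criteria$hbond_H_cutoff) next
      op <- as.numeric(o[1, c("x", "y", "z")])
      v1 <- op - hp                  # H -> O
      v2 <- p - hp                   # H -> center
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      if (ang >= criteria$hbond_angle_min) n <- n + 1L
    }
  }
  n
}
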