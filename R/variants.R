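# Force-field charge-variant engineering: the in-silico electrostatic
# perturbation experiments. Every operation is charge-only — coordinates,
# atom identities and the residue partition are never touched (Lennard-Jones
# parameters live outside this package and are by definition unchanged).
#
# Variants compose in the fixed order atrophy -> restore -> mutate -> scale.

#' Charge atrophy: zero every charge outside a catalytic keep-set
#'
#' Emulates switching the environment's electrostatic field off: all atom
#' charges of protein residues, waters and counterions are set to zero
#' except those of the keep-list residues and of the substrate group (the
#' reacting species always keeps its charges).
#'
#' @param structure a \code{charged_structure}.
#' @param keep_list character vector of residue keys (\code{"chain:seq"})
#'   that keep their charges (typically the catalytic residues).
#' @return A new \code{charged_structure}; idempotent.
#' @export
apply_atrophy <- function(structure, keep_list = character()) {
  stopifnot(inherits(structure, "charged_structure"))
  .check_residues_exist(structure, keep_list, "keep-list residue")
  a <- structure$atoms
  keep <- residue_key(a) %in% keep_list | a$group_kind == "substrate"
  a$charge[!keep] <- 0
  charged_structure(a, title = structure$title, charges_assigned = TRUE)
}

#' Restore original charges on selected residues
#'
#' The charges of the listed residues are copied back from the reference
#' structure; everything else stays as in the (typically atrophied) input.
#' The keyword \code{"waters"} in \code{restore_list} expands to every
#' water residue; \code{"ions"} to every ion.
#'
#' @param atrophied a \code{charged_structure} (e.g. from
#'   [apply_atrophy()]).
#' @param original the atom-aligned reference \code{charged_structure}.
#' @param restore_list residue keys and/or the keywords \code{"waters"},
#'   \code{"ions"}.
#' @return A new \code{charged_structure}. Restoring every residue
#'   reproduces the original exactly.
#' @export
restore_residues <- function(atrophied, original, restore_list) {
  stopifnot(inherits(atrophied, "charged_structure"),
            inherits(original, "charged_structure"))
  a <- atrophied$atoms
  b <- original$atoms
  if (nrow(a) != nrow(b) ||
      !all(a$atom_name == b$atom_name & a$residue_seq == b$residue_seq &
             a$chain_id == b$chain_id))
    stop("structures are not atom-aligned")
  keys <- residue_key(a)
  sel <- rep(FALSE, nrow(a))
  lit <- setdiff(restore_list, c("waters", "ions"))
  if ("waters" %in% restore_list) sel <- sel | a$group_kind == "water"
  if ("ions" %in% restore_list) sel <- sel | a$group_kind == "ion"
  if (length(lit)) {
    .check_residues_exist(atrophied, lit, "restore-list residue")
    sel <- sel | keys %in% lit
  }
  a$charge[sel] <- b$charge[sel]
  charged_structure(a, title = atrophied$title, charges_assigned = TRUE)
}

#' Electrostatic-only mutation of one residue
#'
#' Replaces the partial charges of one residue by the library template of a
#' target residue, matched by atom name; source atoms absent from the
#' target template are zeroed. Geometry is untouched — the operation models
#' only the change in the charge distribution, deliberately neglecting any
#' conformational consequence of the substitution.
#'
#' @param structure a \code{charged_structure}.
#' @param key residue key (\code{"chain:seq"}) of the residue to mutate.
#' @param target target residue template name in \code{library} (e.g.
#'   \code{"ALA"}, \code{"GLU"}, \code{"CYM"} for deprotonated Cys).
#' @param library a \code{charge_library}.
#' @return A new \code{charged_structure}; the mutated residue's net charge
#'   equals the target template's declared net charge when all template
#'   heavy atoms are present.
#' @export
mutate_charges <- function(structure, key, target, library) {
  stopifnot(inherits(structure, "charged_structure"),
            inherits(library, "charge_library"))
  .check_residues_exist(structure, key)
  tmpl <- library_template(library, target)  # errors if absent
  a <- structure$atoms
  sel <- residue_key(a) == key
  hit <- match(a$atom_name[sel], names(tmpl))
  newq <- ifelse(is.na(hit), 0, tmpl[hit])
  a$charge[sel] <- newq
  a$residue_name[sel] <- toupper(target)
  charged_structure(a, title = structure$title, charges_assigned = TRUE)
}

#' Scale one residue's charges by lambda
#'
#' Multiplies every atom charge of the residue by a factor lambda,
#' continuously modulating its electrostatic contribution (lambda = 0 turns
#' the residue off, lambda > 1 amplifies it). By linearity of the Coulomb
#' sum, the residue's potential contribution at any probe scales exactly as
#' V(lambda) = lambda * V(1).
#'
#' @param structure a \code{charged_structure}.
#' @param key residue key (\code{"chain:seq"}).
#' @param lambda scaling factor, >= 0. The conventional scan grid is
#'   \code{lambda_grid()} = 0, 0.2, ..., 1.4.
#' @return A new \code{charged_structure}.
#' @export
scale_residue <- function(structure, key, lambda) {
  stopifnot(inherits(structure, "charged_structure"))
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be >= 0")
  .check_residues_exist(structure, key)
  a <- structure$atoms
  sel <- residue_key(a) == key
  a$charge[sel] <- a$charge[sel] * lambda
  charged_structure(a, title = structure$title, charges_assigned = TRUE)
}

#' Default lambda scan grid
#'
#' @return numeric vector 0, 0.2, ..., 1.4.
#' @export
lambda_grid <- function() seq(0, 1.4, by = 0.2)

#' Declarative charge-variant recipe
#'
#' @param atrophy logical; zero the environment's charges first.
#' @param keep_list residue keys kept charged under atrophy.
#' @param restore_list residue keys / \code{"waters"} / \code{"ions"} whose
#'   original charges are restored after atrophy.
#' @param mutations named character vector: names are residue keys, values
#'   target template names (electrostatic-only mutation).
#' @param lambda_map named numeric vector: names are residue keys, values
#'   scaling factors.
#' @param label optional canonical variant label; auto-generated when
#'   omitted (e.g. \code{"Velec(OFF)"}, \code{"Velec(D17&WAT)"},
#'   \code{"D17A"}, \code{"lambda=0.8"}).
#' @return An object of class \code{variant_spec}.
#' @export
variant_spec <- function(atrophy = FALSE, keep_list = character(),
                         restore_list = character(),
                         mutations = character(), lambda_map = numeric(),
                         label = NULL) {
  if (length(lambda_map) && any(lambda_map < 0))
    stop("lambda factors must be >= 0")
  clash <- intersect(names(mutations),
                     c(keep_list, setdiff(restore_list, c("waters", "ions"))))
  if (length(clash))
    stop("residue(s) both mutated and kept/restored: ",
         paste(clash, collapse = ", "))
  structure(list(atrophy = atrophy, keep_list = keep_list,
                 restore_list = restore_list, mutations = mutations,
                 lambda_map = lambda_map, label = label),
            class = "variant_spec")
}

.variant_label <- function(spec) {
  if (!is.null(spec$label)) return(spec$label)
  short <- function(k) {
    # "A:17" -> "17"; keep chain only when ambiguity matters to the caller
    sub("^[^:]*:", "", k)
  }
  parts <- character()
  if (spec$atrophy) {
    if (length(spec$restore_list)) {
      nm <- vapply(spec$restore_list, function(k)
        if (k %in% c("waters", "ions")) toupper(substr(k, 1, 3))
        else paste0("D", short(k)), character(1))
      parts <- c(parts, paste0("Velec(", paste(nm, collapse = "&"), ")"))
    } else parts <- c(parts, "Velec(OFF)")
  }
  if (length(spec$mutations))
    parts <- c(parts, paste0(vapply(seq_along(spec$mutations), function(i)
      paste0("D", short(names(spec$mutations)[i]),
             substr(spec$mutations[[i]], 1, 1)), character(1)),
      collapse = ","))
  if (length(spec$lambda_map))
    parts <- c(parts, paste0("lambda=",
                             paste(spec$lambda_map, collapse = ",")))
  if (!length(parts)) parts <- "Velec(ON)"
  paste(parts, collapse = " ")
}

#' Build a charge variant from a recipe
#'
#' Applies the recipe in the fixed order atrophy, restore, mutate, scale,
#' and attaches the canonical variant label and a manifest of the recipe.
#'
#' @param structure the reference \code{charged_structure}.
#' @param spec a [variant_spec()].
#' @param library \code{charge_library} (needed only when the recipe
#'   mutates).
#' @return A \code{charged_structure} with attributes \code{variant_label}
#'   and \code{manifest}.
#' @export
build_variant <- function(structure, spec, library = NULL) {
  stopifnot(inherits(spec, "variant_spec"))
  out <- structure
  if (spec$atrophy) out <- apply_atrophy(out, spec$keep_list)
  if (length(spec$restore_list))
    out <- restore_residues(out, structure, spec$restore_list)
  for (i in seq_along(spec$mutations)) {
    if (is.null(library))
      stop("a charge library is required for mutations")
    out <- mutate_charges(out, names(spec$mutations)[i],
                          spec$mutations[[i]], library)
  }
  for (i in seq_along(spec$lambda_map))
    out <- scale_residue(out, names(spec$lambda_map)[i],
                         spec$lambda_map[[i]])
  attr(out, "variant_label") <- .variant_label(spec)
  attr(out, "manifest") <- list(
    label = .variant_label(spec),
    recipe = unclass(spec),
    n_atoms = nrow(out$atoms),
    total_charge = sum(out$atoms$charge),
    package_version = as.character(utils::packageVersion("preorg")))
  out
}

#' Read / write variant recipes as YAML
#'
#' @param path YAML file.
#' @return [read_variant_spec()]: a \code{variant_spec};
#'   [write_variant_spec()]: \code{path}, invisibly.
#' @export
read_variant_spec <- function(path) {
  y <- yaml::read_yaml(path)
  variant_spec(atrophy = isTRUE(y$atrophy),
               keep_list = as.character(y$keep_list %||% character()),
               restore_list = as.character(y$restore_list %||% character()),
               mutations = unlist(y$mutations) %||% character(),
               lambda_map = unlist(y$lambda_map) %||% numeric(),
               label = y$label)
}

#' @rdname read_variant_spec
#' @param spec a \code{variant_spec}.
#' @export
write_variant_spec <- function(spec, path) {
  stopifnot(inherits(spec, "variant_spec"))
  yaml::write_yaml(Filter(Negate(is.null), unclass(spec)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
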