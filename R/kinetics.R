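# Stationary-point free-energy profiles and transition-state-theory
# kinetics. A profile is the ordered list of stationary points of a
# multi-step reaction (minimum, TS, minimum, ...), with cumulative Gibbs
# free energies in kcal/mol relative to the first point (the Michaelis
# complex). The rate-determining barrier follows the energetic-span
# convention: the largest rise from any preceding minimum to a TS.

#' Construct a free-energy profile
#'
#' @param labels stationary-point labels in reaction order, alternating
#'   minimum / transition state (e.g. \code{"E:SalA", "TS1", "E-I1", "TS2",
#'   "E-I2", "TS3", "E-PC"}).
#' @param G cumulative Gibbs free energies, kcal/mol, relative to the first
#'   point (which must be 0).
#' @param kind \code{"min"}/\code{"ts"} per point; by default inferred from
#'   labels starting with \code{"TS"}.
#' @param variant,subunit bookkeeping strings (e.g. \code{"Velec(ON)"},
#'   \code{"beta5"}).
#' @return An object of class \code{fe_profile} (a data.frame with columns
#'   label, kind, G, and attributes variant/subunit).
#' @export
fe_profile <- function(labels, G, kind = NULL, variant = "", subunit = "") {
  if (length(labels) != length(G)) stop("labels and G differ in length")
  if (!all(is.finite(G))) stop("non-finite free energies")
  if (abs(G[1]) > 1e-12) stop("first point must have G = 0 (cumulative ",
                              "profile relative to the reactant complex)")
  if (is.null(kind)) kind <- ifelse(grepl("^TS", labels), "ts", "min")
  if (!all(kind %in% c("min", "ts"))) stop("kind must be 'min' or 'ts'")
  if (any(kind[-1] == kind[-length(kind)]))
    stop("stationary points must alternate minimum / TS")
  if (kind[1] != "min") stop("profile must start at a minimum")
  out <- data.frame(label = as.character(labels), kind = kind, G = G,
                    stringsAsFactors = FALSE)
  attr(out, "variant") <- variant
  attr(out, "subunit") <- subunit
  class(out) <- c("fe_profile", "data.frame")
  out
}

.profile_G <- function(profile, label) {
  i <- match(label, profile$label)
  if (is.na(i)) stop("unknown stationary point '", label, "'")
  profile$G[i]
}

#' Free-energy difference between two stationary points
#'
#' \code{G(ts_label) - G(ref_label)}: a step barrier when \code{ref}
#' precedes \code{ts}, or a stabilization energy when the target is a
#' minimum (negative = more stable than the reference).
#'
#' @param profile an \code{fe_profile}.
#' @param ts_label,ref_label stationary-point labels.
#' @return kcal/mol.
#' @export
step_barrier <- function(profile, ts_label, ref_label) {
  .profile_G(profile, ts_label) - .profile_G(profile, ref_label)
}

#' Rate-determining barrier (energetic span)
#'
#' For each transition state the span is its free energy minus the lowest
#' preceding minimum; the rate-determining barrier is the maximal span.
#' This reduces to the highest single-step barrier for monotone profiles
#' but correctly charges a late TS against an early deep reference when
#' intermediates lie below it. Ties go to the earliest TS.
#'
#' @param profile an \code{fe_profile} with at least one TS.
#' @return list with \code{barrier} (kcal/mol), \code{ts} (label) and
#'   \code{ref} (the minimum realizing the span).
#' @export
rate_determining_barrier <- function(profile) {
  ts_idx <- which(profile$kind == "ts")
  if (!length(ts_idx)) stop("profile has no transition state")
  spans <- vapply(ts_idx, function(i) {
    mins <- which(profile$kind == "min" & seq_len(nrow(profile)) < i)
    profile$G[i] - min(profile$G[mins])
  }, numeric(1))
  best <- which.max(spans)          # which.max takes the earliest on ties
  i <- ts_idx[best]
  mins <- which(profile$kind == "min" & seq_len(nrow(profile)) < i)
  ref <- mins[which.min(profile$G[mins])]
  list(barrier = spans[best], ts = profile$label[i],
       ref = profile$label[ref])
}

#' Transition-state-theory kinetics context
#'
#' @param temperature kelvin; default 310 K (37 C, the temperature of the
#'   experimental inactivation rates).
#' @return list with \code{T}, \code{R} (kcal mol^-1 K^-1) and
#'   \code{prefactor} = k_B T / h (s^-1).
#' @export
kinetics_context <- function(temperature = 310) {
  if (temperature <= 0) stop("temperature must be positive")
  pc <- physical_constants
  list(T = temperature, R = pc$R_kcal,
       prefactor = pc$k_B * temperature / pc$h)
}

#' Eyring rate from a free-energy barrier
#'
#' k = (k_B T / h) exp(-dG / RT).
#'
#' @param dG activation free energy, kcal/mol.
#' @param ctx a [kinetics_context()].
#' @return rate constant, s^-1.
#' @export
tst_rate <- function(dG, ctx = kinetics_context()) {
  ctx$prefactor * exp(-dG / (ctx$R * ctx$T))
}

#' Free-energy barrier from an Eyring rate
#'
#' dG = RT ln(k_B T / (h k)); inverse of [tst_rate()].
#'
#' @param k rate constant, s^-1 (> 0).
#' @inheritParams tst_rate
#' @return kcal/mol.
#' @export
tst_barrier <- function(k, ctx = kinetics_context()) {
  if (any(k <= 0)) stop("rate must be positive")
  ctx$R * ctx$T * log(ctx$prefactor / k)
}

#' Rate retardation factor between two barriers
#'
#' Ratio of TST rates, exp((dG_slow - dG_fast)/RT): how many fold slower
#' the process with the higher barrier runs.
#'
#' @param dG_fast,dG_slow barriers, kcal/mol.
#' @inheritParams tst_rate
#' @return list with \code{factor}, \code{log10} and \code{power10}
#'   (nearest power of ten).
#' @export
retardation_factor <- function(dG_fast, dG_slow, ctx = kinetics_context()) {
  l10 <- (dG_slow - dG_fast) / (ctx$R * ctx$T) / log(10)
  list(factor = 10^l10, log10 = l10, power10 = round(l10))
}

# ---- profile fixtures and step tables --------------------------------------

#' Read stationary-point profiles from CSV
#'
#' Expects columns \code{subunit, variant, label, kind, G_kcal_mol}; each
#' (subunit, variant) block becomes one [fe_profile()]. The shipped fixture
#' \code{inst/extdata/table1_profiles.csv} transcribes the published
#' cumulative profiles for the three catalytic proteasome subunits under
#' unperturbed, atrophied and Asp17-restored electrostatics.
#'
#' @param path profile CSV; default = shipped transcription.
#' @return named list of \code{fe_profile} objects, names
#'   \code{"<subunit>|<variant>"}.
#' @export
read_profiles <- function(path = system.file("extdata",
                                             "table1_profiles.csv",
                                             package = "preorg")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subunit", "variant", "label", "kind", "G_kcal_mol")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("profile table lacks columns: ", paste(miss, collapse = ", "))
  split_key <- paste(tab$subunit, tab$variant, sep = "|")
  out <- lapply(split(tab, factor(split_key, levels = unique(split_key))),
                function(b) fe_profile(b$label, b$G_kcal_mol, b$kind,
                                       variant = b$variant[1],
                                       subunit = b$subunit[1]))
  out
}

#' Step-barrier / stabilization table relative to a reference minimum
#'
#' For each profile, reports the free energy of the chosen stationary
#' points relative to a common reference minimum — the arithmetic behind
#' last-step barrier and product-stabilization comparisons across variants.
#'
#' @param profiles list of \code{fe_profile}s (e.g. from
#'   [read_profiles()]).
#' @param ref_label reference minimum (default \code{"E-I2"}, the
#'   intermediate preceding the last step).
#' @param points stationary points to tabulate (default \code{"TS3"},
#'   \code{"E-PC"}).
#' @return data.frame: subunit, variant, point, reference, value
#'   (kcal/mol).
#' @export
build_step_table <- function(profiles, ref_label = "E-I2",
                             points = c("TS3", "E-PC")) {
  if (!length(profiles))
    return(data.frame(subunit = character(), variant = character(),
                      point = character(), reference = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  rows <- lapply(profiles, function(p) {
    data.frame(subunit = attr(p, "subunit"), variant = attr(p, "variant"),
               point = points, reference = ref_label,
               value = vapply(points, function(pt)
                 step_barrier(p, pt, ref_label), numeric(1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Compare one step-table entry between two subunits
#'
#' @param table a [build_step_table()] result.
#' @param subunit_a,subunit_b subunit names.
#' @param point stationary-point label.
#' @param variant variant label (default \code{"Velec(ON)"}).
#' @return signed difference a - b, kcal/mol.
#' @export
compare_step_barriers <- function(table, subunit_a, subunit_b, point,
                                  variant = "Velec(ON)") {
  pick <- function(s) {
    v <- table$value[table$subunit == s & table$point == point &
                       table$variant == variant]
    if (length(v) != 1L)
      stop("no unique entry for ", s, " / ", variant, " / ", point)
    v
  }
  pick(subunit_a) - pick(subunit_b)
}
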