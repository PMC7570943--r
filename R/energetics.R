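#' Binding free energy from an inhibition constant
#'
#' Relates an inhibition constant to a binding free energy with the gas
#' constant R = 1.987e-3 kcal/(mol K). Two sign conventions exist in the
#' literature this workflow draws on:
#'
#' * `"as_printed"` (default): `dG = -R T ln(Ki)`, the form printed in the
#'   source methodology. For sub-molar Ki this yields a positive number.
#' * `"thermodynamic"`: `dG = +R T ln(Ki)`, the standard convention in
#'   which a favourable (sub-molar) Ki gives a negative free energy.
#'
#' The two modes are exact negations of each other.
#'
#' @param ki Inhibition constant(s), molar (> 0).
#' @param temperature Absolute temperature in Kelvin (> 0; default 310, body
#'   temperature).
#' @param mode Sign convention, see above.
#' @return Free energy in kcal/mol.
#' @export
#' @examples
#' delta_g_from_ki(310e-9, 310)                       # +9.23 (as printed)
#' delta_g_from_ki(310e-9, 310, mode = "thermodynamic")  # -9.23
delta_g_from_ki <- function(ki, temperature = 310,
                            mode = c("as_printed", "thermodynamic")) {
  mode <- match.arg(mode)
  if (!is.numeric(ki) || anyNA(ki) || any(ki <= 0)) {
    stop("ki must be positive (molar)", call. = FALSE)
  }
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      temperature <= 0) {
    stop("temperature must be a single positive value (K)", call. = FALSE)
  }
  r_gas <- 1.987e-3  # kcal / (mol K)
  dg <- -r_gas * temperature * log(ki)
  if (mode == "thermodynamic") -dg else dg
}

#' MM-GBSA energy-term sets
#'
#' Named energy components (kcal/mol) of one end state of an MM-GBSA
#' calculation: internal (bond/angle/dihedral), electrostatic and van der
#' Waals molecular-mechanics terms, polar (GB) and non-polar solvation
#' terms, and optionally the entropy term `-T dS`. When the entropy term is
#' absent it is treated as 0 and the aggregate is flagged accordingly.
#'
#' @param label System identifier (e.g. ligand or complex name).
#' @param e_internal,e_ele,e_vdw,g_gb,g_np Energy terms, kcal/mol.
#' @param minus_t_ds Optional `-T dS` term, kcal/mol (`NA` = not evaluated).
#' @return An object of class `energy_terms`.
#' @export
energy_terms <- function(label, e_internal = 0, e_ele = 0, e_vdw = 0,
                         g_gb = 0, g_np = 0, minus_t_ds = NA_real_) {
  vals <- c(e_internal = e_internal, e_ele = e_ele, e_vdw = e_vdw,
            g_gb = g_gb, g_np = g_np)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("all energy terms must be finite", call. = FALSE)
  }
  if (!is.na(minus_t_ds) && !is.finite(minus_t_ds)) {
    stop("minus_t_ds must be finite or NA", call. = FALSE)
  }
  structure(list(label = as.character(label), e_internal = e_internal,
                 e_ele = e_ele, e_vdw = e_vdw, g_gb = g_gb, g_np = g_np,
                 minus_t_ds = minus_t_ds),
            class = "energy_terms")
}

#' Read energy-term sets from CSV
#'
#' Expects columns `label`, `e_internal`, `e_ele`, `e_vdw`, `g_gb`, `g_np`
#' and optionally `minus_t_ds`.
#'
#' @param path CSV file.
#' @return Named list of [energy_terms()].
#' @export
read_energy_terms <- function(path) {
  x <- read.csv(path, check.names = FALSE)
  need <- c("label", "e_internal", "e_ele", "e_vdw", "g_gb", "g_np")
  missing_c <- setdiff(need, names(x))
  if (length(missing_c) > 0) {
    stop("energy-term table lacks column(s): ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
  if (!"minus_t_ds" %in% names(x)) x$minus_t_ds <- NA_real_
  out <- lapply(seq_len(nrow(x)), function(i) {
    energy_terms(x$label[i], x$e_internal[i], x$e_ele[i], x$e_vdw[i],
                 x$g_gb[i], x$g_np[i], x$minus_t_ds[i])
  })
  names(out) <- x$label
  out
}

#' MM-GBSA binding free energy from end-state terms
#'
#' Forms the per-term differences `complex - receptor - ligand` and sums
#' them: `dG_bind = dE_internal + dE_ele + dE_vdW + dG_GB + dG_NP + (-T dS)`.
#' The polar and non-polar solvation differences make up `dG_solv`, the
#' molecular-mechanics differences `dE_MM`. An entropy term that is absent
#' (NA) in all three states contributes 0 and the result carries
#' `attr(, "entropy_included") = FALSE`.
#'
#' @param complex,receptor,ligand [energy_terms()] for the three end states.
#' @return Binding free energy (kcal/mol) with attributes `terms` (named
#'   per-term differences) and `entropy_included`.
#' @export
#' @examples
#' cpx <- energy_terms("cpx", -10, -20, -30, 15, -3)
#' zero <- energy_terms("0")
#' mmgbsa_bind(cpx, zero, zero)  # -48
mmgbsa_bind <- function(complex, receptor, ligand) {
  stopifnot(inherits(complex, "energy_terms"),
            inherits(receptor, "energy_terms"),
            inherits(ligand, "energy_terms"))
  term_names <- c("e_internal", "e_ele", "e_vdw", "g_gb", "g_np")
  delta <- vapply(term_names, function(t) {
    complex[[t]] - receptor[[t]] - ligand[[t]]
  }, numeric(1))
  ent <- c(complex$minus_t_ds, receptor$minus_t_ds, ligand$minus_t_ds)
  entropy_included <- !all(is.na(ent))
  d_ent <- if (entropy_included) {
    sum(c(1, -1, -1) * ifelse(is.na(ent), 0, ent))
  } else 0
  delta <- c(delta, minus_t_ds = d_ent)
  structure(sum(delta), terms = delta, entropy_included = entropy_included)
}

#' Per-residue free-energy decomposition bookkeeping
#'
#' Sums, per residue, the van der Waals, electrostatic, polar-solvation and
#' non-polar-solvation contributions of an MM-GBSA decomposition and orders
#' residues most favourable (most negative total) first.
#'
#' @param contribs Data frame with columns `residue`, `e_vdw`, `e_elec`,
#'   `e_pol`, `e_np` (kcal/mol); residues must be unique.
#' @return The table with an added `total` column, sorted ascending by
#'   total.
#' @export
#' @examples
#' decompose_per_residue(data.frame(
#'   residue = c("Arg513", "Tyr385"), e_vdw = c(-1, -0.2),
#'   e_elec = c(-0.5, -0.1), e_pol = c(0.3, 0.05), e_np = c(-0.1, -0.02)
#' ))
decompose_per_residue <- function(contribs) {
  need <- c("residue", "e_vdw", "e_elec", "e_pol", "e_np")
  missing_c <- setdiff(need, names(contribs))
  if (length(missing_c) > 0) {
    stop("contribution table lacks column(s): ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(contribs$residue)) {
    stop("duplicate residue(s): ",
         paste(unique(contribs$residue[duplicated(contribs$residue)]),
               collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(contribs[, c("e_vdw", "e_elec", "e_pol", "e_np")])
  if (any(!is.finite(vals))) {
    stop("all contributions must be finite", call. = FALSE)
  }
  contribs$total <- rowSums(vals)
  out <- contribs[order(contribs$total), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' COX-2/COX-1 selectivity ratio of binding energies
#'
#' Reports both directed ratios of the two binding free energies of one
#' ligand against the two cyclooxygenase isoforms. With both energies
#' negative (favourable), both ratios are positive; a COX-2/COX-1 ratio
#' above 1 indicates a stronger (more negative) COX-2 affinity.
#'
#' @param dg_cox2,dg_cox1 Binding free energies (kcal/mol), nonzero.
#' @return Named numeric vector `c(cox2_over_cox1, cox1_over_cox2)`.
#' @export
#' @examples
#' selectivity_ratio(-8.60, -6.80)
selectivity_ratio <- function(dg_cox2, dg_cox1) {
  if (!is.numeric(dg_cox2) || !is.numeric(dg_cox1) ||
      length(dg_cox2) != 1 || length(dg_cox1) != 1) {
    stop("supply one binding energy per isoform", call. = FALSE)
  }
  if (dg_cox2 == 0 || dg_cox1 == 0) {
    stop("binding energies must be nonzero", call. = FALSE)
  }
  c(cox2_over_cox1 = dg_cox2 / dg_cox1,
    cox1_over_cox2 = dg_cox1 / dg_cox2)
}
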