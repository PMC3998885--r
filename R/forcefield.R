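# Force-field parameters. Defaults follow canonical Go-model ratios
# (angle : dihedral-1 : dihedral-3 : contact = 20 : 1 : 0.5 : 1, scaled to
# k_angle = 6.67 kcal/mol/rad^2); every constant is configurable and the
# resolved values are recorded in run metadata.

#' Force-field parameters of the coarse-grained actomyosin potential
#'
#' All energies in kcal/mol, lengths in Angstrom, angles in radians. The
#' harmonic bonded and ligand terms use `k * x^2`; restraint and umbrella
#' terms use the `1/2 * k * x^2` convention. Short-range spring continuations
#' of the 12-10 contact and 12-6 van der Waals terms switch at the distance
#' where the pair force equals the force of a spring of the documented
#' stiffness anchored at the pair minimum, matching value and slope; the
#' purely repulsive nonnative term (which has no minimum to anchor such a
#' spring) switches to its value-and-slope-matched spring at 0.8 times the
#' excluded-volume diameter.
#'
#' @param k_angle bond-angle stiffness, kcal/mol/rad^2.
#' @param k_dih1,k_dih3 dihedral amplitudes (periodicity 1 and 3), kcal/mol.
#' @param eps_native native-contact well depth, kcal/mol.
#' @param eps_nonnative nonnative repulsion strength, kcal/mol.
#' @param nonnative_C nonnative excluded-volume diameter, Angstrom.
#' @param nonnative_cutoff truncation radius of the nonnative term, Angstrom.
#' @param k_spring_contact spring continuation stiffness of the contact
#'   terms, kcal/mol/A^2.
#' @param k_ligand ligand restraint stiffness, kcal/mol/A^2.
#' @param salt_molar monovalent salt concentration, mol/L (sets the Debye
#'   length; default 25 mM gives 1.9 nm).
#' @param temperature temperature, K.
#' @param eps_r relative permittivity (calibrated default, see
#'   [debye_permittivity()]).
#' @param elec_cutoff electrostatic truncation radius, Angstrom.
#' @param lj_eps,lj_sigma well depth (kcal/mol) and position (Angstrom) of
#'   the interface 12-6 Lennard-Jones term.
#' @param k_spring_lj spring continuation stiffness of the LJ term.
#' @param lj_cutoff truncation radius of the LJ term, Angstrom.
#' @param k_rail curtain-rail stiffness, kcal/mol/A^2.
#' @param k_anchor actin anchor stiffness, kcal/mol/A^2.
#' @param k_umb_z,k_umb_theta umbrella stiffnesses (kcal/mol/A^2,
#'   kcal/mol/rad^2).
#' @return A list of class `forcefield_params`, including the derived
#'   `debye_length_A` and `dh_prefactor` (kcal A/mol).
#' @export
forcefield_params <- function(k_angle = 6.67,
                              k_dih1 = 6.67 / 20,
                              k_dih3 = 6.67 / 40,
                              eps_native = 6.67 / 20,
                              eps_nonnative = 6.67 / 20,
                              nonnative_C = 4.0,
                              nonnative_cutoff = 10.0,
                              k_spring_contact = 1.33,
                              k_ligand = 6.67,
                              salt_molar = 0.025,
                              temperature = 300,
                              eps_r = debye_permittivity(),
                              elec_cutoff = 59.3,
                              lj_eps = 0.015,
                              lj_sigma = 8.0,
                              k_spring_lj = 1.33,
                              lj_cutoff = 24.0,
                              k_rail = 0.2,
                              k_anchor = 1.33,
                              k_umb_z = 0.01,
                              k_umb_theta = 10) {
  p <- list(k_angle = k_angle, k_dih1 = k_dih1, k_dih3 = k_dih3,
            eps_native = eps_native, eps_nonnative = eps_nonnative,
            nonnative_C = nonnative_C, nonnative_cutoff = nonnative_cutoff,
            k_spring_contact = k_spring_contact, k_ligand = k_ligand,
            salt_molar = salt_molar, temperature = temperature,
            eps_r = eps_r, elec_cutoff = elec_cutoff,
            lj_eps = lj_eps, lj_sigma = lj_sigma,
            k_spring_lj = k_spring_lj, lj_cutoff = lj_cutoff,
            k_rail = k_rail, k_anchor = k_anchor,
            k_umb_z = k_umb_z, k_umb_theta = k_umb_theta)
  stopifnot(all(unlist(p[c("k_angle", "k_spring_contact", "k_ligand",
                           "k_rail", "k_anchor", "k_umb_z",
                           "k_umb_theta")]) >= 0))
  p$debye_length_A <- 10 * debye_length(salt_molar, temperature, eps_r)
  p$dh_prefactor <- COULOMB_KCAL_A / eps_r
  class(p) <- "forcefield_params"
  p
}

#' @export
print.forcefield_params <- function(x, ...) {
  cat("forcefield_params:\n")
  flds <- setdiff(names(x), NULL)
  for (f in flds) cat(sprintf("  %-18s %g\n", f, x[[f]]))
  invisible(x)
}

# Switch distance where the 12-10 (or 12-6) pair force equals the force of a
# spring of stiffness k anchored at the pair minimum r0. Returns the switch
# distance; falls back to the curvature-match point if the minimum curvature
# already exceeds the spring stiffness.
.switch_native <- function(r0, eps, k) {
  vapply(r0, function(r0i) {
    g <- function(u) 60 * eps * (u^-13 - u^-11) / r0i - 2 * k * r0i * (1 - u)
    lo <- 0.3; hi <- 1 - 1e-6
    if (g(hi) < 0 && g(lo) > 0) return(r0i * stats::uniroot(g, c(lo, hi))$root)
    # curvature match: d2V/dr2 = 2k
    h <- function(u) 60 * eps * (13 * u^-14 - 11 * u^-12) / r0i^2 - 2 * k
    r0i * stats::uniroot(h, c(0.2, 1))$root
  }, numeric(1))
}

.switch_lj <- function(sigma, eps, k) {
  g <- function(u) 12 * eps * (u^-13 - u^-7) / sigma - 2 * k * sigma * (1 - u)
  lo <- 0.3; hi <- 1 - 1e-6
  if (g(hi) < 0 && g(lo) > 0) return(sigma * stats::uniroot(g, c(lo, hi))$root)
  h <- function(u) 12 * eps * (13 * u^-14 - 7 * u^-8) / sigma^2 - 2 * k
  sigma * stats::uniroot(h, c(0.2, 1))$root
}

.switch_nonnative <- function(C, eps, k) {
  # the purely repulsive term has no minimum to anchor a force-matched
  # spring; the continuation engages well inside the excluded-volume core
  0.8 * C
}
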