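# Energy evaluation wrappers around the compiled engine.

#' Evaluate the potential energy of a configuration
#'
#' Computes every term of the coarse-grained actomyosin potential (bond
#' angles, dihedrals, native 12-10 contacts, nonnative repulsion, ligand
#' restraints, interface Debye-Hueckel electrostatics and 12-6 van der Waals,
#' curtain-rail and anchor restraints, and the umbrella bias when a window is
#' given) and, optionally, the analytic forces.
#'
#' @param sys a [assemble_system()] object.
#' @param X coordinate matrix (n x 3, Angstrom); defaults to the reference
#'   coordinates `sys$X0`.
#' @param window an optional [umbrella_window()] bias.
#' @param forces if `TRUE`, also return the force matrix (-gradient,
#'   kcal/mol/Angstrom).
#' @param use_neighbor_list evaluate the cutoff terms through the Verlet
#'   neighbor list (2 Angstrom skin); results are identical to the
#'   brute-force path.
#' @return A list with `total` (kcal/mol), named `terms`, and optionally
#'   `forces`.
#' @export
energy_terms <- function(sys, X = NULL, window = NULL, forces = FALSE,
                         use_neighbor_list = FALSE) {
  stopifnot(inherits(sys, "cg_system"))
  if (is.null(X)) X <- sys$X0
  X <- as.matrix(X)
  if (nrow(X) != sys$n || ncol(X) != 3) stop("X must be n x 3")
  cg_energy_cpp(X, .cpp_model(sys, window), forces, use_neighbor_list)
}

#' Total energy and forces
#'
#' @inheritParams energy_terms
#' @return list with `energy` (kcal/mol) and `forces` (n x 3).
#' @export
total_energy_forces <- function(sys, X = NULL, window = NULL,
                                use_neighbor_list = FALSE) {
  e <- energy_terms(sys, X, window, forces = TRUE,
                    use_neighbor_list = use_neighbor_list)
  list(energy = e$total, terms = e$terms, forces = e$forces)
}

.term <- function(sys, X, window, name, use_nl = FALSE)
  energy_terms(sys, X, window, use_neighbor_list = use_nl)$terms[[name]]

#' Individual energy terms
#'
#' Convenience accessors for single terms of the potential; each returns an
#' energy in kcal/mol for the given configuration.
#'
#' @inheritParams energy_terms
#' @name energy-terms
NULL

#' @rdname energy-terms
#' @export
angle_energy <- function(sys, X = NULL) .term(sys, X, NULL, "angle")

#' @rdname energy-terms
#' @export
dihedral_energy <- function(sys, X = NULL) .term(sys, X, NULL, "dihedral")

#' @rdname energy-terms
#' @export
native_contact_energy <- function(sys, X = NULL) .term(sys, X, NULL, "native")

#' @rdname energy-terms
#' @export
nonnative_energy <- function(sys, X = NULL, use_neighbor_list = FALSE)
  .term(sys, X, NULL, "nonnative", use_neighbor_list)

#' @rdname energy-terms
#' @export
ligand_energy <- function(sys, X = NULL) .term(sys, X, NULL, "ligand")

#' @rdname energy-terms
#' @export
debye_huckel_energy <- function(sys, X = NULL, use_neighbor_list = FALSE)
  .term(sys, X, NULL, "elec", use_neighbor_list)

#' @rdname energy-terms
#' @export
vdw_energy <- function(sys, X = NULL, use_neighbor_list = FALSE)
  .term(sys, X, NULL, "vdw", use_neighbor_list)

#' @rdname energy-terms
#' @export
restraint_energy <- function(sys, X = NULL) {
  t <- energy_terms(sys, X)$terms
  unname(t["rail"] + t["anchor"])
}

#' @rdname energy-terms
#' @param window an [umbrella_window()].
#' @export
umbrella_energy <- function(sys, window, X = NULL)
  .term(sys, X, window, "umbrella")

#' Numerical gradient of the total energy (central differences)
#'
#' Independent check of the analytic forces; intended for small systems.
#'
#' @inheritParams energy_terms
#' @param h step size, Angstrom.
#' @return n x 3 matrix of -dE/dx.
#' @export
numerical_forces <- function(sys, X = NULL, window = NULL, h = 1e-5) {
  if (is.null(X)) X <- sys$X0
  X <- as.matrix(X)
  G <- matrix(0, nrow(X), 3)
  for (i in seq_len(nrow(X))) {
    for (d in 1:3) {
      Xp <- X; Xp[i, d] <- Xp[i, d] + h
      Xm <- X; Xm[i, d] <- Xm[i, d] - h
      G[i, d] <- -(energy_terms(sys, Xp, window)$total -
                     energy_terms(sys, Xm, window)$total) / (2 * h)
    }
  }
  G
}

#' Write a per-term energy breakdown to TSV
#'
#' @inheritParams energy_terms
#' @param path output file.
#' @return The breakdown data.frame, invisibly.
#' @export
energy_report <- function(sys, X = NULL, window = NULL, path = NULL) {
  e <- energy_terms(sys, X, window)
  df <- data.frame(term = c(names(e$terms), "total"),
                   energy_kcal_mol = c(unname(e$terms), e$total))
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
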