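# Assembly of a simulatable actomyosin system: myosin S1 (with ligands) plus
# the actin filament, interface interaction lists, restraints and umbrella
# bookkeeping, in the form consumed by the compiled energy/dynamics engine.

#' Assemble an actomyosin system for energy evaluation and dynamics
#'
#' Merges the myosin and actin topologies into one particle array, enumerates
#' the interface interaction pairs (Debye-Hueckel electrostatics between
#' charged particles, 12-6 van der Waals between beads), attaches the
#' curtain-rail restraint on the lever-arm tip, harmonic anchors on every
#' actin residue, and precomputes the short-range spring continuations.
#'
#' @param myosin a `cg_topology` for the myosin molecule (may be `NULL` for
#'   an actin-only system).
#' @param actin a `cg_topology` for the actin filament (may be `NULL`).
#' @param params a [forcefield_params()].
#' @param helix the [helical_params()] of the filament (sets the rail twist).
#' @param tip_idx indices (into the myosin beads) of the lever-arm tip
#'   residues restrained to the curtain rail.
#' @param motor_idx indices (into the myosin beads) of the motor domain whose
#'   centroid defines the reaction coordinates `(z, theta)`.
#' @return A list of class `cg_system`; element `X0` holds the reference
#'   coordinates (Angstrom).
#' @export
assemble_system <- function(myosin = NULL, actin = NULL,
                            params = forcefield_params(),
                            helix = helical_params(),
                            tip_idx = integer(), motor_idx = integer()) {
  if (is.null(myosin) && is.null(actin)) stop("need at least one molecule")
  offs <- 0L
  tabs <- list()
  mol_of <- character(0)
  take <- function(topo, mol) {
    tab <- topo$particles
    tab$molecule <- mol
    tab
  }
  nm <- if (is.null(myosin)) 0L else nrow(myosin$particles)
  if (!is.null(myosin)) tabs <- c(tabs, list(take(myosin, "myosin")))
  if (!is.null(actin)) tabs <- c(tabs, list(take(actin, "actin")))
  particles <- do.call(rbind, tabs)
  rownames(particles) <- NULL
  n <- nrow(particles)

  shift <- function(d, cols, by) {
    if (is.null(d)) return(NULL)
    d[cols] <- d[cols] + by
    d
  }
  cat_term <- function(f) {
    a <- if (is.null(myosin)) NULL else myosin[[f]]
    b <- shift(if (is.null(actin)) NULL else actin[[f]],
               intersect(c("i", "j", "k", "l"),
                         names(actin[[f]] %||% data.frame())), nm)
    if (is.null(a)) b else if (is.null(b)) a else rbind(a, b)
  }
  bonds <- cat_term("bonds")
  angles <- cat_term("angles")
  dihedrals <- cat_term("dihedrals")
  native <- cat_term("native")
  nonnative <- cat_term("nonnative")
  ligand_pairs <- cat_term("ligand_pairs")

  # interface pair lists (never part of the native/nonnative partition)
  elec <- vdw <- NULL
  if (!is.null(myosin) && !is.null(actin)) {
    im <- which(particles$molecule == "myosin" & particles$charge != 0)
    ia <- which(particles$molecule == "actin" & particles$charge != 0)
    if (length(im) && length(ia)) {
      g <- expand.grid(i = im, j = ia)
      elec <- data.frame(i = g$i, j = g$j,
                         qq = particles$charge[g$i] * particles$charge[g$j])
    }
    bm <- which(particles$molecule == "myosin" & particles$kind == "bead")
    ba <- which(particles$molecule == "actin" & particles$kind == "bead")
    g <- expand.grid(i = bm, j = ba)
    vdw <- data.frame(i = g$i, j = g$j)
  }

  anchor_idx <- which(particles$molecule == "actin" & particles$kind == "bead")
  X0 <- as.matrix(particles[, c("x", "y", "z")])
  dimnames(X0) <- NULL

  # curtain rail: one helical rail per tip particle through its reference
  # position, twisting net_twist per repeat so the restrained system retains
  # the filament's helical symmetry
  omega <- (helix$net_twist_deg * pi / 180) / (helix$repeat_length_nm * 10)
  if (length(tip_idx) && is.null(myosin)) stop("tip_idx without myosin")

  # spring continuation parameters
  nat_sw <- NULL
  if (!is.null(native)) {
    rsw <- .switch_native(native$r0, params$eps_native, params$k_spring_contact)
    s <- native$r0 / rsw
    v <- params$eps_native * (5 * s^12 - 6 * s^10)
    dv <- -60 * params$eps_native * ((native$r0 / rsw^2) * (s^11 - s^9))
    # V_s = k (r - b)^2 + c matching value and slope at rsw
    b <- rsw - dv / (2 * params$k_spring_contact)
    cc <- v - params$k_spring_contact * (rsw - b)^2
    nat_sw <- cbind(rsw, b, cc)
  }
  nn_rsw <- .switch_nonnative(params$nonnative_C, params$eps_nonnative,
                              params$k_spring_contact)
  nn_v <- params$eps_nonnative * (params$nonnative_C / nn_rsw)^12
  nn_dv <- -12 * nn_v / nn_rsw
  nn_b <- nn_rsw - nn_dv / (2 * params$k_spring_contact)
  nn_c <- nn_v - params$k_spring_contact * (nn_rsw - nn_b)^2
  lj_rsw <- .switch_lj(params$lj_sigma, params$lj_eps, params$k_spring_lj)
  s <- params$lj_sigma / lj_rsw
  lj_v <- params$lj_eps * (s^12 - 2 * s^6)
  lj_dv <- -12 * params$lj_eps * (params$lj_sigma / lj_rsw^2) * (s^11 - s^5)
  lj_b <- lj_rsw - lj_dv / (2 * params$k_spring_lj)
  lj_c <- lj_v - params$k_spring_lj * (lj_rsw - lj_b)^2

  sys <- list(particles = particles, n = n, n_myosin = nm,
              X0 = X0, params = params, helix = helix,
              bonds = bonds, angles = angles, dihedrals = dihedrals,
              native = native, native_switch = nat_sw,
              nonnative = nonnative,
              nonnative_switch = c(nn_rsw, nn_b, nn_c),
              ligand_pairs = ligand_pairs,
              elec = elec, vdw = vdw,
              lj_switch = c(lj_rsw, lj_b, lj_c),
              anchor_idx = anchor_idx,
              tip_idx = as.integer(tip_idx),
              rail_omega = omega,
              motor_idx = as.integer(motor_idx))
  class(sys) <- "cg_system"
  sys
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf(paste0("cg_system: %d particles (%d myosin); %d native, ",
                     "%d nonnative, %d elec, %d vdw pairs; %d anchors, ",
                     "%d tip, %d motor beads\n"),
              x$n, x$n_myosin, nrow(x$native %||% data.frame()),
              nrow(x$nonnative %||% data.frame()),
              nrow(x$elec %||% data.frame()), nrow(x$vdw %||% data.frame()),
              length(x$anchor_idx), length(x$tip_idx), length(x$motor_idx)))
  invisible(x)
}

# Build the plain list handed to the compiled engine. Window may be NULL.
.cpp_model <- function(sys, window = NULL) {
  p <- sys$params
  mat0 <- function(d, cols) {
    if (is.null(d)) matrix(0L, 0, length(cols)) else
      matrix(as.integer(as.matrix(d[cols]) - 1L), ncol = length(cols))
  }
  num <- function(d, col) if (is.null(d)) numeric(0) else as.numeric(d[[col]])
  list(
    n = sys$n,
    bonds = mat0(sys$bonds, c("i", "j")), b0 = num(sys$bonds, "b0"),
    angles = mat0(sys$angles, c("i", "j", "k")),
    theta0 = num(sys$angles, "theta0"),
    dihedrals = mat0(sys$dihedrals, c("i", "j", "k", "l")),
    phi0 = num(sys$dihedrals, "phi0"),
    native = mat0(sys$native, c("i", "j")), r0 = num(sys$native, "r0"),
    native_switch = if (is.null(sys$native_switch))
      matrix(0, 0, 3) else sys$native_switch,
    nonnative = mat0(sys$nonnative, c("i", "j")),
    nonnative_switch = sys$nonnative_switch,
    ligand_pairs = mat0(sys$ligand_pairs, c("i", "j")),
    lr0 = num(sys$ligand_pairs, "r0"),
    elec = mat0(sys$elec, c("i", "j")), qq = num(sys$elec, "qq"),
    vdw = mat0(sys$vdw, c("i", "j")),
    lj_switch = sys$lj_switch,
    anchor_idx = as.integer(sys$anchor_idx - 1L),
    anchor_ref = sys$X0[sys$anchor_idx, , drop = FALSE],
    tip_idx = as.integer(sys$tip_idx - 1L),
    tip_ref = sys$X0[sys$tip_idx, , drop = FALSE],
    rail_omega = sys$rail_omega,
    motor_idx = as.integer(sys$motor_idx - 1L),
    params = unclass(p)[c("k_angle", "k_dih1", "k_dih3", "eps_native",
                          "eps_nonnative", "nonnative_C", "nonnative_cutoff",
                          "k_spring_contact", "k_ligand", "dh_prefactor",
                          "debye_length_A", "elec_cutoff", "lj_eps",
                          "lj_sigma", "k_spring_lj", "lj_cutoff", "k_rail",
                          "k_anchor", "k_umb_z", "k_umb_theta")],
    window = if (is.null(window)) numeric(0) else
      c(window$z_center * 10, window$theta_center)  # nm -> Angstrom
  )
}
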