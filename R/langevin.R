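# Langevin dynamics with constrained virtual bonds and umbrella biasing.

#' Langevin dynamics parameters
#'
#' Reduced units: particle mass 1, time step 0.0175, friction coefficient
#' 0.005 per reduced time; temperature in Kelvin. The mapping from reduced to
#' physical time is left symbolic (physical time enters the analysis only
#' through the Monte Carlo timescale estimate,
#' [estimate_mcs_timescale()]).
#'
#' @param mass particle mass (reduced units).
#' @param temperature temperature, K.
#' @param dt integration time step (reduced units; > 0).
#' @param friction friction coefficient (reduced units; >= 0).
#' @param stride recording stride (steps).
#' @param constraint_tol relative tolerance of the RATTLE iteration.
#' @param blowup per-step displacement (Angstrom) treated as divergence.
#' @param use_neighbor_list use Verlet lists for the cutoff terms.
#' @return list of class `langevin_params`.
#' @export
langevin_params <- function(mass = 1.0, temperature = 300, dt = 0.0175,
                            friction = 0.005, stride = 10L,
                            constraint_tol = 1e-12, blowup = 10,
                            use_neighbor_list = TRUE) {
  stopifnot(dt > 0, friction >= 0, mass > 0)
  structure(list(mass = mass, temperature = temperature, dt = dt,
                 friction = friction, stride = as.integer(stride),
                 constraint_tol = constraint_tol, blowup = blowup,
                 use_neighbor_list = use_neighbor_list),
            class = "langevin_params")
}

#' Umbrella window
#'
#' Harmonic bias `1/2 k_z (zbar - z_center)^2 + 1/2 k_theta
#' wrap(thetabar - theta_center)^2` on the motor-domain centroid; the angular
#' difference is wrapped into `(-pi, pi]`.
#'
#' @param z_center window center along the filament axis, nm.
#' @param theta_center angular window center, rad in `[0, 2*pi)`.
#' @return list of class `umbrella_window`.
#' @export
umbrella_window <- function(z_center, theta_center = 0) {
  stopifnot(is.finite(z_center), is.finite(theta_center))
  structure(list(z_center = z_center,
                 theta_center = wrap_2pi(theta_center)),
            class = "umbrella_window")
}

#' Cylindrical coordinates of the motor-domain centroid
#'
#' @param X coordinate matrix (n x 3, Angstrom) or a `cg_system`.
#' @param motor_idx indices of the motor-domain beads (defaults to the
#'   system's `motor_idx`; residues 1-780 in the full-size myosin model).
#' @return `c(z = <nm>, theta = <rad in [0, 2*pi)>)`.
#' @export
motor_domain_cyl <- function(X, motor_idx = NULL) {
  if (inherits(X, "cg_system")) {
    if (is.null(motor_idx)) motor_idx <- X$motor_idx
    X <- X$X0
  }
  if (is.null(motor_idx) || !length(motor_idx))
    stop("motor_idx must be provided")
  cm <- colMeans(X[motor_idx, , drop = FALSE])
  if (cm[1]^2 + cm[2]^2 < 1e-12)
    stop("motor centroid lies on the filament axis; theta undefined")
  c(z = unname(cm[3]) / 10, theta = wrap_2pi(atan2(cm[2], cm[1])))
}

#' Apply RATTLE position constraints
#'
#' Restores every virtual bond to its reference length (relative tolerance of
#' the squared length 1e-12, i.e. well below 1e-6 Angstrom absolute for
#' 3.8 Angstrom bonds).
#'
#' @param positions proposed coordinates (n x 3, Angstrom).
#' @param prev_positions coordinates satisfying the constraints (the
#'   constraint gradients are taken here).
#' @param bonds data.frame with `i`, `j`, `b0` (see `cg_topology`).
#' @return corrected coordinate matrix.
#' @export
apply_bond_constraints <- function(positions, prev_positions, bonds) {
  rattle_positions_cpp(as.matrix(prev_positions), as.matrix(positions),
                       as.matrix(bonds[, c("i", "j")]), bonds$b0)
}

#' Run Langevin dynamics for one umbrella window
#'
#' Performs `n_replicas` independent runs differing only by seed; the first
#' `discard_fraction` of each recorded series is dropped before analysis, as
#' in the umbrella-sampling protocol (12 replicas, first half discarded).
#'
#' @param sys a [assemble_system()] object.
#' @param window an [umbrella_window()] (or `NULL` for unbiased dynamics).
#' @param n_steps steps per replica (> 0).
#' @param lpar [langevin_params()].
#' @param n_replicas number of independent replicas.
#' @param discard_fraction fraction of each series discarded as equilibration.
#' @param seed base seed; replica r uses `seed + r - 1`.
#' @param X0 starting coordinates (defaults to the reference).
#' @return A list of class `sampler_output`: `samples` (data.frame with
#'   `replica`, `step`, `z_nm`, `theta_rad`, `energy`), `window`, `metadata`.
#' @export
run_window <- function(sys, window, n_steps, lpar = langevin_params(),
                       n_replicas = 12L, discard_fraction = 0.5,
                       seed = 1L, X0 = NULL) {
  stopifnot(inherits(sys, "cg_system"))
  if (n_steps <= 0) stop("n_steps must be positive")
  if (!length(sys$motor_idx)) stop("system has no motor domain defined")
  if (is.null(X0)) X0 <- sys$X0
  model <- .cpp_model(sys, window)
  out <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    lp <- c(unclass(lpar),
            list(n_steps = n_steps, seed = seed + r - 1,
                 use_nlist = lpar$use_neighbor_list))
    run <- run_langevin_cpp(as.matrix(X0), model, lp)
    s <- run$series
    keep <- s[, 1] > discard_fraction * n_steps
    out[[r]] <- data.frame(replica = r, step = s[keep, 1],
                           z_nm = s[keep, 2], theta_rad = s[keep, 3],
                           energy = s[keep, 4])
  }
  samples <- do.call(rbind, out)
  structure(list(samples = samples, window = window,
                 metadata = list(n_steps = n_steps, n_replicas = n_replicas,
                                 discard_fraction = discard_fraction,
                                 seed = seed, lpar = unclass(lpar),
                                 params = unclass(sys$params))),
            class = "sampler_output")
}

#' Low-level Langevin run
#'
#' Single trajectory with full control; returns the recorded motor-domain
#' series and the final phase-space point.
#'
#' @inheritParams run_window
#' @param seed RNG seed (runs with identical seeds are identical).
#' @return list with `series` (matrix: step, z_nm, theta_rad, energy), final
#'   `X`, `V`, and `max_bond_dev` (Angstrom).
#' @export
run_langevin <- function(sys, n_steps, window = NULL,
                         lpar = langevin_params(), seed = 1L, X0 = NULL) {
  stopifnot(inherits(sys, "cg_system"))
  if (n_steps <= 0) stop("n_steps must be positive")
  if (is.null(X0)) X0 <- sys$X0
  lp <- c(unclass(lpar), list(n_steps = n_steps, seed = seed,
                              use_nlist = lpar$use_neighbor_list))
  run <- run_langevin_cpp(as.matrix(X0), .cpp_model(sys, window), lp)
  colnames(run$series) <- c("step", "z_nm", "theta_rad", "energy")
  run
}
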