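# Desk-scale synthetic inputs: a mini actomyosin system that runs the full
# MD -> WHAM path in minutes, and analytic landscape sets with the
# qualitative structure of the computed actomyosin landscapes (periodic
# basins at the actin-subunit repeat, shallow barriers for open-cleft
# states, a global gradient toward the strong-binding site for closed-cleft
# states).

#' Mini-system specification
#'
#' A stand-in for the full S1 + 26-subunit filament system: a short motor
#' bead chain facing a small helical filament, with an acidic patch on each
#' filament subunit and a basic, flexible loop on the motor (emulating
#' loop 2). Geometry is a uniform bead helix with 3.8 Angstrom virtual
#' bonds.
#'
#' @param motor_beads motor chain length (beads).
#' @param n_subunits filament subunits.
#' @param beads_per_subunit beads per filament subunit.
#' @param helix filament [helical_params()] (defaults as the full model).
#' @param motor_loop residue range of the basic flexible loop.
#' @param tip_frac fraction of C-terminal motor beads forming the lever-arm
#'   tip (restrained to the curtain rail).
#' @param motor_domain_frac fraction of N-terminal motor beads whose
#'   centroid defines `(z, theta)`.
#' @param with_ligand include a small ADP+Mg-like ligand cluster.
#' @param jitter coordinate jitter amplitude, Angstrom.
#' @param seed generation seed.
#' @return list of class `mini_system_spec`.
#' @export
mini_system_spec <- function(motor_beads = 40L, n_subunits = 6L,
                             beads_per_subunit = 9L,
                             helix = helical_params(),
                             motor_loop = 18:22, tip_frac = 0.15,
                             motor_domain_frac = 0.75,
                             with_ligand = TRUE, jitter = 0.02,
                             seed = 1L) {
  structure(list(motor_beads = as.integer(motor_beads),
                 n_subunits = as.integer(n_subunits),
                 beads_per_subunit = as.integer(beads_per_subunit),
                 helix = helix, motor_loop = motor_loop,
                 tip_frac = tip_frac, motor_domain_frac = motor_domain_frac,
                 with_ligand = with_ligand, jitter = jitter,
                 seed = as.integer(seed)),
            class = "mini_system_spec")
}

# uniform bead helix with 3.8 A bonds: rise 1.0 A, 100 deg per bead
.bead_helix <- function(n, rise = 1.0, ang_deg = 100) {
  a <- ang_deg * pi / 180
  chord <- sqrt(3.8^2 - rise^2)
  r <- chord / (2 * sin(a / 2))
  k <- seq_len(n) - 1
  cbind(r * cos(k * a), r * sin(k * a), k * rise)
}

#' Generate the mini actomyosin system
#'
#' @param spec a [mini_system_spec()].
#' @param params [forcefield_params()].
#' @param max_retries clash-regeneration attempts (next sub-seed).
#' @return list of class `mini_system`: `myosin`, `subunit`
#'   ([reference_structure()]s), `filament`, `system`
#'   ([assemble_system()]), index sets and the spec. The WHAM periodicity of
#'   the mini system is the two-subunit repeat (`period`, `twist`).
#' @export
make_mini_system <- function(spec = mini_system_spec(),
                             params = forcefield_params(),
                             max_retries = 10L) {
  for (try in seq_len(max_retries)) {
    seed <- spec$seed + (try - 1L) * 1000L
    rng_state <- .mini_rng(seed)
    out <- .mini_build(spec, params, rng_state)
    if (out$min_nonbonded >= 3.8) return(out)
  }
  stop("could not generate a clash-free mini system in ", max_retries,
       " attempts")
}

.mini_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

.mini_build <- function(spec, params, old_rng) {
  on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng, globalenv()))
  hx <- spec$helix
  nb_s <- spec$beads_per_subunit
  sub_xyz <- .bead_helix(nb_s)
  sub_xyz[, 3] <- sub_xyz[, 3] - mean(sub_xyz[, 3])
  sub_xyz[, 1] <- sub_xyz[, 1] + 8  # subunit centroid at 8 A radius
  sub_xyz <- sub_xyz + matrix(stats::runif(3 * nb_s, -spec$jitter,
                                           spec$jitter), ncol = 3)
  resid <- rep("GLY", nb_s)
  resid[1:3] <- "ASP"  # acidic patch
  subunit <- reference_structure(
    data.frame(chain = "F", resno = seq_len(nb_s), resid = resid,
               x = sub_xyz[, 1], y = sub_xyz[, 2], z = sub_xyz[, 3],
               stringsAsFactors = FALSE),
    label = "actin_subunit")
  subunit <- assign_charges(subunit)
  filament <- build_filament(subunit, spec$n_subunits, hx)

  nm <- spec$motor_beads
  mot_xyz <- .bead_helix(nm)
  span <- spec$n_subunits * hx$rise_per_subunit * 10
  mot_xyz[, 3] <- mot_xyz[, 3] - mean(mot_xyz[, 3]) + span / 2
  mot_xyz[, 1] <- mot_xyz[, 1] + 17  # motor helix axis at 17 A radius
  mot_xyz <- mot_xyz + matrix(stats::runif(3 * nm, -spec$jitter,
                                           spec$jitter), ncol = 3)
  mres <- rep("GLY", nm)
  mres[spec$motor_loop] <- "LYS"  # basic loop (loop-2 analog)
  ligand <- NULL
  if (spec$with_ligand) {
    zc <- mot_xyz[10, 3]
    cx <- 17 - 3.5
    ligand <- data.frame(
      atom = c("O1B", "O2B", "O3B", "MG"),
      parent = c("ADP", "ADP", "ADP", "Mg"),
      x = cx + c(0.9, -0.9, 0, 0), y = c(0, 0, 0.9, -0.9),
      z = zc + c(0.5, 0.5, -0.5, -0.5),
      stringsAsFactors = FALSE)
  }
  myosin <- reference_structure(
    data.frame(chain = "M", resno = seq_len(nm), resid = mres,
               x = mot_xyz[, 1], y = mot_xyz[, 2], z = mot_xyz[, 3],
               stringsAsFactors = FALSE),
    ligand = ligand, label = "custom")
  myosin$beads$flexible[spec$motor_loop] <- TRUE
  myosin <- assign_charges(myosin)

  mtopo <- build_topology(myosin)
  atopo <- build_topology(filament)
  motor_idx <- seq_len(round(spec$motor_domain_frac * nm))
  tip_idx <- seq.int(nm - round(spec$tip_frac * nm) + 1L, nm)
  sys <- assemble_system(mtopo, atopo, params, hx, tip_idx, motor_idx)

  # clash check: minimum nonbonded bead-bead distance
  beads <- sys$particles[sys$particles$kind == "bead", ]
  X <- as.matrix(beads[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(X))
  diag(d) <- Inf
  same_chain <- outer(beads$chain, beads$chain, "==")
  adj <- abs(outer(beads$resno, beads$resno, "-")) == 1
  d[same_chain & adj] <- Inf
  min_nb <- min(d)

  # the mini filament's own (two-subunit) repeat for WHAM periodicity
  rep2 <- helical_params(hx$rot_per_subunit, hx$rise_per_subunit, 2L)
  structure(list(myosin = myosin, subunit = subunit, filament = filament,
                 myosin_topo = mtopo, actin_topo = atopo, system = sys,
                 motor_idx = motor_idx, tip_idx = tip_idx,
                 period = rep2$repeat_length_nm,
                 twist = rep2$net_twist_deg * pi / 180,
                 min_nonbonded = min_nb, spec = spec),
            class = "mini_system")
}

#' @export
print.mini_system <- function(x, ...) {
  cat(sprintf(paste0("mini_system: %d-bead motor + %d x %d-bead filament; ",
                     "min nonbonded %.2f A; WHAM repeat %.3f nm / %.2f deg\n"),
              x$spec$motor_beads, x$spec$n_subunits,
              x$spec$beads_per_subunit, x$min_nonbonded,
              x$period, x$twist * 180 / pi))
  invisible(x)
}

# ------------------------------------------------------------------------
#' Synthetic landscape specification
#'
#' Analytic free-energy landscapes emulating the computed actomyosin
#' landscapes. Binding wells sit on the actin subunit helix
#' (`k * rise, k * rot`); an azimuthal confinement band around the slowly
#' twisting rail makes every other subunit accessible, so the effective
#' basin spacing is two subunit rises (5.52 nm, the actin-subunit
#' diameter). Open-cleft states have shallow barriers, broad angular wells
#' and a weak tent ramp toward the weak-binding site; closed-cleft states
#' add the global gradient toward the strong-binding site (an asymmetric
#' tent whose ridge lies `ridge_fraction` of a repeat plus-end-ward of the
#' site) and narrow angular valleys; post-stroke open states are z-shifted
#' by `post_offset`.
#'
#' @param basin_spacing accessible-well spacing, nm (two subunit rises).
#' @param barrier well depth of the open-cleft basins, kT (within the
#'   1-2 kT range of the open-cleft landscapes).
#' @param closed_depth well depth of the closed-cleft basins, kT (strong
#'   binding; deep enough that stepping proceeds by well-to-well hops).
#' @param gradient closed-state gradient, kT per basin.
#' @param gradient_range_basins range of the closed-state gradient: the
#'   descent toward the strong site spans this many basins (the screened
#'   electrostatic attraction is short-ranged); between the rise zone and
#'   the descent zone the ramp plateaus, so the barrier separating periodic
#'   strong-site basins is `gradient * gradient_range_basins` kT.
#' @param open_gradient weak tent gradient of open states, kT per basin.
#' @param ridge_fraction position of the closed-state ridge, fraction of a
#'   repeat plus-end-ward of the strong site.
#' @param weak_site_basins weak-binding site position, basins relative to
#'   the strong site (negative = minus-end-ward).
#' @param post_offset z shift of post-stroke open-state wells, nm.
#' @param sigma_z well width in z, nm.
#' @param sigma_theta_open,sigma_theta_closed angular well widths, rad
#'   (closed-cleft valleys are narrower).
#' @param conf_open,conf_closed width (rad) of the angular confinement band
#'   around the twisting rail; it models the lever-arm rail restraint and is
#'   state-independent by default.
#' @param rot_per_subunit subunit rotation, degrees.
#' @param twist_deg net twist per repeat, degrees.
#' @param nz,ntheta grid size (dz = period / nz).
#' @param strong_site strong-binding site position, nm (repeat origin).
#' @return list of class `synthetic_landscape_spec`; `period = 6.5 *
#'   basin_spacing` (13 subunits).
#' @export
synthetic_landscape_spec <- function(basin_spacing = 2 * 2.759,
                                     barrier = 1.5, closed_depth = 4.0,
                                     gradient = 2.0,
                                     gradient_range_basins = 2.5,
                                     open_gradient = 0.8,
                                     ridge_fraction = 0.2,
                                     weak_site_basins = -1,
                                     post_offset = 1.5,
                                     sigma_z = 0.8,
                                     sigma_theta_open = 0.8,
                                     sigma_theta_closed = 0.6,
                                     conf_open = 0.6, conf_closed = 0.6,
                                     rot_per_subunit = 166.4,
                                     twist_deg = 3.2,
                                     nz = 360L, ntheta = 72L,
                                     strong_site = 0) {
  structure(list(basin_spacing = basin_spacing, barrier = barrier,
                 closed_depth = closed_depth,
                 gradient = gradient,
                 gradient_range_basins = gradient_range_basins,
                 open_gradient = open_gradient,
                 ridge_fraction = ridge_fraction,
                 weak_site_basins = weak_site_basins,
                 post_offset = post_offset, sigma_z = sigma_z,
                 sigma_theta_open = sigma_theta_open,
                 sigma_theta_closed = sigma_theta_closed,
                 conf_open = conf_open, conf_closed = conf_closed,
                 rot_per_subunit = rot_per_subunit, twist_deg = twist_deg,
                 nz = as.integer(nz), ntheta = as.integer(ntheta),
                 strong_site = strong_site,
                 period = 13 * basin_spacing / 2,
                 rise = basin_spacing / 2),
            class = "synthetic_landscape_spec")
}

# state class of each mobile actomyosin state
.state_class <- function(state) {
  switch(state,
         "A.Mpre.ADP.Pi" = "pre", "A.Mpre.ADP" = "pre",
         "A.Mpost.ADP.Pi" = "post", "A.Mpost.ADP" = "post",
         "A.Mpost" = "post",
         "A.Mclosed.ADP" = "closed", "A.Mclosed" = "closed",
         stop("unknown state ", state))
}

#' Evaluate a synthetic landscape analytically
#'
#' @param spec a [synthetic_landscape_spec()].
#' @param state a mobile actomyosin state label.
#' @param z,theta coordinates (nm, rad), recycled.
#' @return free energy, kT (ungauged).
#' @export
synthetic_landscape_F <- function(spec, state, z, theta) {
  n <- max(length(z), length(theta))
  z <- rep_len(z, n); theta <- rep_len(theta, n)
  cls <- .state_class(state)
  L <- spec$period
  rise <- spec$rise
  rot <- spec$rot_per_subunit * pi / 180
  twist <- spec$twist_deg * pi / 180
  omega <- twist / L
  delta <- if (cls == "post") spec$post_offset else 0
  sig_th <- if (cls == "closed") spec$sigma_theta_closed else
    spec$sigma_theta_open
  conf_w <- if (cls == "closed") spec$conf_closed else spec$conf_open
  depth <- if (cls == "closed") spec$closed_depth else spec$barrier

  # wells on the subunit helix, summed over a generous k window
  kmin <- floor((min(z) - delta - 6 * spec$sigma_z) / rise)
  kmax <- ceiling((max(z) - delta + 6 * spec$sigma_z) / rise)
  W <- numeric(n)
  for (k in kmin:kmax) {
    gz <- exp(-(z - (k * rise + delta))^2 / (2 * spec$sigma_z^2))
    gth <- exp(-wrap_pi(theta - k * rot)^2 / (2 * sig_th^2))
    W <- W - depth * gz * gth
  }
  # angular confinement about the twisting rail band
  conf <- wrap_pi(theta - omega * z)^2 / (2 * conf_w^2)
  # z ramp
  if (cls == "closed") {
    # distance (nm) the walker must still travel forward to the next site
    ufwd <- (spec$strong_site - z) %% L
    f <- spec$ridge_fraction
    H <- spec$gradient * spec$gradient_range_basins
    rise <- L - ufwd  # distance past the previous site
    ramp <- ifelse(rise < f * L,
                   H * rise / (f * L),
                   pmin(spec$gradient * ufwd / spec$basin_spacing, H))
  } else {
    zw <- spec$strong_site + spec$weak_site_basins * spec$basin_spacing
    d <- (z - zw) %% L
    d <- pmin(d, L - d)
    ramp <- spec$open_gradient * d / spec$basin_spacing
  }
  W + conf + ramp
}

#' Generate the seven synthetic state landscapes
#'
#' @param spec a [synthetic_landscape_spec()].
#' @param dir optional directory; landscapes are written as
#'   `<state>.tsv` + JSON sidecars.
#' @return named list of [landscape_2d()] for the seven mobile states.
#' @export
make_landscape_set <- function(spec = synthetic_landscape_spec(),
                               dir = NULL) {
  states <- setdiff(actomyosin_states(), "A.Mrigor")
  L <- spec$period
  dz <- L / spec$nz
  zg <- (seq_len(spec$nz) - 1) * dz
  thg <- (seq_len(spec$ntheta) - 1) * 2 * pi / spec$ntheta
  grid <- expand.grid(th = thg, z = zg)
  out <- list()
  for (s in states) {
    Fv <- synthetic_landscape_F(spec, s, grid$z, grid$th)
    Fm <- matrix(Fv, nrow = spec$nz, ncol = spec$ntheta, byrow = TRUE)
    out[[s]] <- landscape_2d(Fm, z0 = 0, dz = dz, period = L,
                             twist = spec$twist_deg * pi / 180,
                             state_label = s, gauge = TRUE)
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (s in states)
      write_landscape(out[[s]], file.path(dir, paste0(s, ".tsv")))
  }
  out
}

#' Synthetic joint (z_motor, z_tip) landscape
#'
#' A single harmonic basin at `(motor_center, motor_center + tip_offset)`,
#' used to exercise the lever-arm bookkeeping.
#'
#' @param motor_center basin position of the motor-domain coordinate, nm.
#' @param tip_offset tip-minus-motor offset of the basin, nm.
#' @param sigma_motor,sigma_tip basin widths, nm.
#' @param z_range,y_range grid ranges (nm).
#' @param n grid points per axis.
#' @return joint landscape list (`F`, `z`, `y`) for [lever_tip_offset()].
#' @export
make_joint_landscape <- function(motor_center, tip_offset,
                                 sigma_motor = 1.5, sigma_tip = 1.0,
                                 z_range = motor_center + c(-8, 8),
                                 y_range = motor_center + tip_offset +
                                   c(-8, 8),
                                 n = 81L) {
  z <- seq(z_range[1], z_range[2], length.out = n)
  y <- seq(y_range[1], y_range[2], length.out = n)
  F <- outer(z, y, function(zm, zt)
    (zm - motor_center)^2 / (2 * sigma_motor^2) +
      (zt - zm - tip_offset)^2 / (2 * sigma_tip^2))
  F <- F - min(F)
  list(F = F, z = z, y = y)
}
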