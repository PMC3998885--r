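# Dynamical-energy-landscape Monte Carlo: lattice Metropolis diffusion of the
# motor-domain point on the current state's free-energy landscape, stochastic
# switching among the actomyosin kinetic states, and absorption into rigor.

#' Actomyosin state labels
#'
#' The seven mobile bound states plus the absorbing rigor state.
#' @export
actomyosin_states <- function() {
  c("A.Mpre.ADP.Pi", "A.Mpost.ADP.Pi", "A.Mpre.ADP", "A.Mpost.ADP",
    "A.Mclosed.ADP", "A.Mpost", "A.Mclosed", "A.Mrigor")
}

# directed edges of the kinetic network: conformational exchange within each
# nucleotide state, irreversible Pi/ADP release, cleft closure, and the
# position-gated rigor entry (handled separately via k_w)
.network_edges <- function() {
  data.frame(
    id = paste0("e", 1:12),
    from = c("A.Mpre.ADP.Pi", "A.Mpost.ADP.Pi", "A.Mpre.ADP.Pi",
             "A.Mpost.ADP.Pi", "A.Mpre.ADP", "A.Mpost.ADP", "A.Mpost.ADP",
             "A.Mclosed.ADP", "A.Mpost.ADP", "A.Mclosed.ADP", "A.Mpost",
             "A.Mclosed"),
    to = c("A.Mpost.ADP.Pi", "A.Mpre.ADP.Pi", "A.Mpre.ADP", "A.Mpost.ADP",
           "A.Mpost.ADP", "A.Mpre.ADP", "A.Mclosed.ADP", "A.Mpost.ADP",
           "A.Mpost", "A.Mclosed", "A.Mclosed", "A.Mpost"),
    stringsAsFactors = FALSE)
}

# fast/slow assignment per preset (which edges are fast); each preset
# lengthens the lifetime of one weak-binding state
.preset_fast <- list(
  main              = c("e2", "e4", "e5", "e7", "e10", "e11"),
  long_pre_adp      = c("e2", "e3", "e6", "e7", "e10", "e11"),
  long_post_adp_pi  = c("e1", "e5", "e7", "e9", "e10", "e11"),
  long_post_adp_pi_wide = c("e1", "e5", "e7", "e9", "e10", "e11"))

#' Kinetic network of actomyosin states
#'
#' Per-MCS transition probabilities among the eight actomyosin states. Each
#' directed edge is tagged fast or slow; the rigor entry from `A.Mclosed` is
#' attempted at rate `k_w` only inside the admissible strong-binding valley.
#' The `main` preset lengthens the lifetime of `A.Mpre.ADP.Pi`; the
#' alternative presets lengthen `A.Mpre.ADP` or `A.Mpost.ADP.Pi`, and the
#' `_wide` variant additionally allows rigor entry from the second-lowest
#' valley.
#'
#' @param preset one of `"main"`, `"long_pre_adp"`, `"long_post_adp_pi"`,
#'   `"long_post_adp_pi_wide"`.
#' @param fast,slow per-MCS probabilities of fast and slow transitions
#'   (must be < 1 and realistically << 1).
#' @param k_w per-MCS rigor-entry probability from the admissible valley.
#' @return object of class `kinetic_network` with the 8 x 8 transition
#'   probability matrix (`$trans`), the edge table, `k_w` and the number of
#'   rigor-entry valleys (`$n_valleys`).
#' @export
kinetic_network <- function(preset = c("main", "long_pre_adp",
                                       "long_post_adp_pi",
                                       "long_post_adp_pi_wide"),
                            fast = 1e-4, slow = 1e-6, k_w = 1e-3) {
  preset <- match.arg(preset)
  stopifnot(fast > 0, fast < 1, slow > 0, slow < 1, k_w > 0, k_w < 1)
  st <- actomyosin_states()
  ed <- .network_edges()
  ed$rate <- ifelse(ed$id %in% .preset_fast[[preset]], fast, slow)
  ed$speed <- ifelse(ed$id %in% .preset_fast[[preset]], "fast", "slow")
  trans <- matrix(0, 8, 8, dimnames = list(st, st))
  for (r in seq_len(nrow(ed))) trans[ed$from[r], ed$to[r]] <- ed$rate[r]
  structure(list(preset = preset, edges = ed, trans = trans,
                 fast = fast, slow = slow, k_w = k_w,
                 n_valleys = if (preset == "long_post_adp_pi_wide") 2L else 1L),
            class = "kinetic_network")
}

#' @export
print.kinetic_network <- function(x, ...) {
  cat(sprintf("kinetic_network <%s>: fast %g, slow %g, k_w %g (%d valley(s))\n",
              x$preset, x$fast, x$slow, x$k_w, x$n_valleys))
  print(x$edges[, c("id", "from", "to", "speed")], row.names = FALSE)
  invisible(x)
}

#' Probability of choosing a z move
#'
#' With lattice steps `dz` along the filament and arc step
#' `s = r_arc * dtheta` around it, isotropic in-plane Brownian motion
#' requires equal mean-square displacement per MCS along both axes, giving
#' `p_z = s^2 / (dz^2 + s^2)`.
#'
#' @param dz z lattice step, nm.
#' @param dtheta angular lattice step, rad.
#' @param r_arc radius converting angular steps to arc length, nm.
#' @return probability in (0, 1).
#' @export
compute_pz <- function(dz, dtheta, r_arc) {
  if (any(c(dz, dtheta, r_arc) <= 0)) stop("all inputs must be positive")
  s <- r_arc * dtheta
  s^2 / (dz^2 + s^2)
}

#' Monte Carlo parameters
#'
#' @param dz,dtheta lattice mesh (nm, rad).
#' @param r_arc mean radial distance of the motor-domain centroid from the
#'   filament axis, nm (converts angular steps to arc length).
#' @param p_z probability of attempting a z move (defaults to the isotropy
#'   value of [compute_pz()]).
#' @param max_steps per-trajectory step budget.
#' @param admissible_halfwidth half-width (nm) of the rigor-entry window
#'   around each strong-binding valley minimum.
#' @return list of class `mc_params`.
#' @export
mc_params <- function(dz = 0.1, dtheta = 2 * pi / 360, r_arc = 4.5,
                      p_z = compute_pz(dz, dtheta, r_arc),
                      max_steps = 5e6, admissible_halfwidth = 0.5) {
  stopifnot(p_z > 0, p_z < 1, max_steps >= 1)
  structure(list(dz = dz, dtheta = dtheta, r_arc = r_arc, p_z = p_z,
                 max_steps = max_steps,
                 admissible_halfwidth = admissible_halfwidth),
            class = "mc_params")
}

#' Locate strong-binding valley minima on the closed-cleft landscape
#'
#' Boltzmann-projects the landscape onto z and finds the periodic local
#' minima; returns the `n_valleys` lowest (the second valley must lie at
#' least `min_sep` nm from the first).
#'
#' @param landscape the `A.Mclosed` [landscape_2d()].
#' @param n_valleys 1 or 2.
#' @param min_sep minimum separation between reported valleys, nm.
#' @return numeric vector of valley z positions (mod period), nm.
#' @export
strong_binding_sites <- function(landscape, n_valleys = 1L, min_sep = 2) {
  p1 <- project_1d(landscape)
  f <- p1$F_kT
  n <- length(f)
  up <- f[c(2:n, 1)]; dn <- f[c(n, 1:(n - 1))]
  locmin <- which(f < up & f < dn & is.finite(f))
  if (!length(locmin)) stop("no valley found on the landscape")
  ord <- locmin[order(f[locmin])]
  sites <- p1$z_nm[ord[1]]
  for (i in ord[-1]) {
    if (length(sites) >= n_valleys) break
    zc <- p1$z_nm[i]
    d <- abs(zc - sites)
    d <- pmin(d, landscape$period - d)
    if (all(d >= min_sep)) sites <- c(sites, zc)
  }
  sites %% landscape$period
}

#' Run landscape-switching Monte Carlo trajectories
#'
#' Each trajectory starts at a random z (uniform over one repeat) on the
#' `A.Mpre.ADP.Pi` landscape with theta on the confinement band, and runs
#' until rigor absorption or `max_steps`. Each MCS attempts, in order, a
#' state switch (position preserved), otherwise one lattice diffusion move
#' accepted by the Metropolis rule on the free-energy difference. The
#' displacement statistic `D` is the unwrapped z displacement from the first
#' entry into `A.Mclosed` to the rigor site.
#'
#' @param landscapes named list of [landscape_2d()] for the seven mobile
#'   states (names as [actomyosin_states()], rigor absent).
#' @param network a [kinetic_network()].
#' @param mcpar a [mc_params()].
#' @param n_traj number of trajectories.
#' @param seed integer seed; trajectory t uses stream `(seed, t)`.
#' @param n_record record full trajectories for the first `n_record`
#'   trajectories.
#' @param record_stride recording stride (MCS).
#' @param start_state initial state label.
#' @return data.frame of class `mc_trajectories` with one row per
#'   trajectory: `D` (nm), `z_entry`, `z_final`, `steps`, `completed`,
#'   `entered`; attributes `transitions` (8 x 8 counts), `sites`,
#'   `rejected_missing`, `trajectories` (recorded paths), `network`,
#'   `mcpar`.
#' @export
run_trajectories <- function(landscapes, network, mcpar = mc_params(),
                             n_traj = 8000L, seed = 1L, n_record = 0L,
                             record_stride = 100L,
                             start_state = "A.Mpre.ADP.Pi") {
  st <- actomyosin_states()
  mobile <- st[-8]
  if (!all(mobile %in% names(landscapes)))
    stop("landscapes must be named for all seven mobile states; missing: ",
         paste(setdiff(mobile, names(landscapes)), collapse = ", "))
  closed <- landscapes[["A.Mclosed"]]
  sites <- strong_binding_sites(closed, network$n_valleys)
  L <- closed$period
  twist <- closed$twist
  lsc <- lapply(mobile, function(s) .lsc_cpp(landscapes[[s]]))
  lsc[[8]] <- list()  # rigor placeholder
  par <- list(dz = mcpar$dz, dtheta = mcpar$dtheta, p_z = mcpar$p_z,
              k_w = network$k_w, max_steps = mcpar$max_steps,
              admissible_z = sites,
              admissible_halfwidth = mcpar$admissible_halfwidth,
              z_start_min = 0, z_start_range = L,
              theta_start_slope = twist / L,
              start_state = match(start_state, st),
              closed_state = match("A.Mclosed", st))
  out <- run_actomyosin_mc_cpp(lsc, network$trans, par, as.integer(n_traj),
                               as.double(seed), as.integer(n_record),
                               as.integer(record_stride))
  df <- data.frame(D = out$D, z_entry = out$z_entry, z_final = out$z_final,
                   steps = out$steps, completed = out$completed,
                   entered = out$entered)
  tc <- out$transitions
  dimnames(tc) <- list(st, st)
  attr(df, "transitions") <- tc
  attr(df, "sites") <- sites
  attr(df, "rejected_missing") <- out$rejected_missing
  attr(df, "trajectories") <- out$trajectories
  attr(df, "network") <- network
  attr(df, "mcpar") <- mcpar
  attr(df, "period") <- L
  class(df) <- c("mc_trajectories", "data.frame")
  df
}

#' Displacement distribution of completed trajectories
#'
#' @param traj a [run_trajectories()] result (or numeric vector of D).
#' @param bin_width histogram bin width, nm.
#' @return list of class `displacement_record`: `D`, histogram `mids` /
#'   `counts`, `n_complete`, `n_incomplete`.
#' @export
displacement_distribution <- function(traj, bin_width = 0.5) {
  D <- if (is.data.frame(traj)) traj$D[traj$completed & traj$entered] else
    traj
  D <- D[is.finite(D)]
  n_inc <- if (is.data.frame(traj)) sum(!traj$completed) else 0L
  if (!length(D)) stop("no completed trajectories")
  lo <- floor(min(D) / bin_width) * bin_width - bin_width
  hi <- ceiling(max(D) / bin_width) * bin_width + bin_width
  br <- seq(lo, hi, by = bin_width)
  h <- hist(D, breaks = br, plot = FALSE)
  structure(list(D = D, mids = h$mids, counts = h$counts,
                 bin_width = bin_width, n_complete = length(D),
                 n_incomplete = n_inc,
                 period = if (is.data.frame(traj))
                   attr(traj, "period") else NA_real_),
            class = "displacement_record")
}

#' Peaks of the displacement distribution
#'
#' Separates the major part (displacements within half a period of the
#' median) from the minor part (trajectories reaching the strong-binding
#' site one helical repeat away), finds the local maxima of the smoothed
#' major-part histogram, and reports the mean spacing of adjacent peaks.
#'
#' @param rec a [displacement_record()] (from
#'   [displacement_distribution()]).
#' @param period helical repeat, nm (defaults to the stored period).
#' @param min_height_frac peak acceptance threshold as a fraction of the
#'   highest peak.
#' @return list with `peaks` (positions, nm), `mean_spacing`, `spacings`,
#'   `n_major`, `n_minor_plus`, `n_minor_minus`, `minor_fraction`.
#' @export
displacement_peaks <- function(rec, period = NULL, min_height_frac = 0.08) {
  if (is.null(period)) period <- rec$period
  if (!is.finite(period)) stop("period required")
  D <- rec$D
  med <- stats::median(D)
  # trajectories absorbed at the strong-binding site one repeat away
  major <- D[abs(D - med) < 0.75 * period]
  minor_plus <- sum(D - med >= 0.75 * period)
  minor_minus <- sum(D - med <= -0.75 * period)
  bw <- rec$bin_width
  br <- seq(floor(min(major) / bw) * bw - 2 * bw,
            ceiling(max(major) / bw) * bw + 2 * bw, by = bw)
  h <- hist(major, breaks = br, plot = FALSE)
  cnt <- as.numeric(stats::filter(h$counts, rep(1 / 3, 3), sides = 2))
  cnt[is.na(cnt)] <- 0
  n <- length(cnt)
  is_peak <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - 2); hi <- min(n, i + 2)
    cnt[i] == max(cnt[lo:hi]) && cnt[i] > 0
  }, logical(1))
  pk <- which(is_peak & cnt >= min_height_frac * max(cnt))
  # merge plateau/adjacent peaks closer than 2 nm, keep the higher
  pos <- h$mids[pk]; hgt <- cnt[pk]
  keep <- rep(TRUE, length(pos))
  if (length(pos) > 1) {
    for (i in seq_along(pos)[-1]) {
      if (keep[i] && any(keep[seq_len(i - 1)] &
                         abs(pos[seq_len(i - 1)] - pos[i]) < 2)) {
        j <- which(keep[seq_len(i - 1)] &
                     abs(pos[seq_len(i - 1)] - pos[i]) < 2)
        if (max(hgt[j]) >= hgt[i]) keep[i] <- FALSE else keep[j] <- FALSE
      }
    }
  }
  pos <- pos[keep]
  # refine each peak position by a local centroid
  pos <- vapply(pos, function(p) {
    sel <- abs(h$mids - p) <= 1.5 * bw
    sum(h$mids[sel] * h$counts[sel]) / max(1, sum(h$counts[sel]))
  }, numeric(1))
  sp <- diff(sort(pos))
  list(peaks = sort(pos), spacings = sp,
       mean_spacing = if (length(sp)) mean(sp) else NA_real_,
       n_major = length(major), n_minor_plus = minor_plus,
       n_minor_minus = minor_minus,
       minor_fraction = (minor_plus + minor_minus) / length(D))
}

#' Physical timescale of one Monte Carlo step
#'
#' Models the free myosin head as a prolate ellipsoid moving sidewise
#' (translation perpendicular to its major axis) with the Perrin friction
#' factor, and equates the lattice mean-square displacement per MCS with
#' `4 D tau`. Because it assumes free diffusion, the estimate is a lower
#' limit of the physical time per MCS.
#'
#' @param semi_major,semi_minor ellipsoid semi-axes, nm.
#' @param viscosity solvent viscosity, pN ns / nm^2 (water: 0.89).
#' @param temperature K.
#' @param mcpar a [mc_params()] (sets the lattice mean-square displacement).
#' @return list with `D_free` (nm^2/ns), `friction` (pN ns/nm),
#'   `msd_per_mcs` (nm^2) and `tau_ns`.
#' @export
estimate_mcs_timescale <- function(semi_major = 8, semi_minor = 2.5,
                                   viscosity = 0.89, temperature = 300,
                                   mcpar = mc_params()) {
  stopifnot(semi_major > 0, semi_minor > 0, viscosity > 0)
  a <- semi_major; b <- semi_minor; eta <- viscosity
  kBT <- 1.380649e-2 * temperature  # pN nm
  if ((a - b) / a < 1e-9) {
    f <- 6 * pi * eta * a  # Stokes sphere
  } else {
    xi <- sqrt(a^2 - b^2)
    S <- 2 / xi * log((a + xi) / b)
    f <- 32 * pi * eta * (a^2 - b^2) / ((2 * a^2 - 3 * b^2) * S + 2 * a)
  }
  Dfree <- kBT / f
  s <- mcpar$r_arc * mcpar$dtheta
  msd <- mcpar$p_z * mcpar$dz^2 + (1 - mcpar$p_z) * s^2
  list(D_free = Dfree, friction = f, msd_per_mcs = msd,
       tau_ns = msd / (4 * Dfree))
}

#' Lever-tip offset from a joint (z_motor, z_tip) landscape
#'
#' Locates the free-energy basin(s) of a joint landscape of the motor-domain
#' and lever-tip z coordinates and reports the tip-minus-motor offset.
#'
#' @param joint a joint landscape: list with `F` (matrix, kT; rows = motor
#'   z grid, cols = tip z grid), `z` (motor grid, nm), `y` (tip grid, nm),
#'   e.g. from [make_joint_landscape()].
#' @return list with `motor`, `tip`, `offset` (nm) at the global basin and a
#'   `minima` table of all local minima.
#' @export
lever_tip_offset <- function(joint) {
  F <- joint$F
  nz <- nrow(F); ny <- ncol(F)
  mins <- NULL
  for (i in seq_len(nz)) for (j in seq_len(ny)) {
    lo_i <- max(1, i - 1); hi_i <- min(nz, i + 1)
    lo_j <- max(1, j - 1); hi_j <- min(ny, j + 1)
    nb <- F[lo_i:hi_i, lo_j:hi_j]
    if (is.finite(F[i, j]) && F[i, j] <= min(nb, na.rm = TRUE) &&
        sum(nb == F[i, j], na.rm = TRUE) == 1)
      mins <- rbind(mins, c(joint$z[i], joint$y[j], F[i, j]))
  }
  if (is.null(mins)) stop("no local minimum found")
  mins <- data.frame(motor = mins[, 1], tip = mins[, 2], F_kT = mins[, 3])
  mins$offset <- mins$tip - mins$motor
  g <- which.min(mins$F_kT)
  list(motor = mins$motor[g], tip = mins$tip[g], offset = mins$offset[g],
       minima = mins[order(mins$F_kT), ])
}

#' Decompose the net lever-tip displacement
#'
#' Between the weak-binding and strong-binding basins, the net tip
#' displacement splits exactly into the biased-Brownian part (motor-domain
#' displacement) and the lever-swing part (change of the tip-minus-motor
#' offset).
#'
#' @param weak,strong joint landscapes (see [lever_tip_offset()]).
#' @return list with `total`, `brownian`, `lever` (nm); `total = brownian +
#'   lever` exactly.
#' @export
lever_swing_decomposition <- function(weak, strong) {
  w <- lever_tip_offset(weak)
  s <- lever_tip_offset(strong)
  list(total = s$tip - w$tip, brownian = s$motor - w$motor,
       lever = s$offset - w$offset)
}
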