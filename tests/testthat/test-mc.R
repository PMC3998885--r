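# Landscape-switching Monte Carlo: move-choice isotropy, detailed balance,
# gradient response, network soundness, displacement bookkeeping, the MCS
# timescale estimate and lever-arm bookkeeping.

test_that("p_z makes the in-plane lattice walk isotropic", {
  expect_equal(compute_pz(0.1, 0.1 / 4.5, 4.5), 0.5)       # s = dz
  expect_equal(compute_pz(0.1, 0.2 / 4.5, 4.5), 0.8)       # s = 2 dz
  expect_error(compute_pz(-1, 0.1, 1), "positive")

  # flat landscape: MSD along z equals MSD along the arc within 3 sigma
  mp <- mc_params()
  F <- matrix(0, 100, 100)
  nrep <- 60
  msd_z <- msd_arc <- numeric(nrep)
  s_arc <- mp$r_arc * mp$dtheta
  for (r in seq_len(nrep)) {
    w <- motorscape:::mc_lattice_walk_cpp(F, mp$p_z, 1e5, 1e5, 1000 + r, 0, 0)
    msd_z[r] <- (w[1, 2] * mp$dz)^2
    msd_arc[r] <- (w[1, 3] * s_arc)^2
  }
  se <- sqrt(var(msd_z) / nrep + var(msd_arc) / nrep)
  expect_lt(abs(mean(msd_z) - mean(msd_arc)), 3 * se)
})

test_that("Metropolis sampling reproduces exact Boltzmann occupancy", {
  # 5-bin periodic landscape; oracle = stationary distribution of the exact
  # transition matrix (enumeration)
  Fv <- c(0, 1.2, 0.4, 2.0, 0.7)
  n <- 5
  P <- matrix(0, n, n)
  for (i in 1:n) for (d in c(-1, 1)) {
    j <- ((i - 1 + d) %% n) + 1
    a <- min(1, exp(-(Fv[j] - Fv[i])))
    P[i, j] <- P[i, j] + 0.5 * a
  }
  diag(P) <- 1 - rowSums(P)
  ev <- Re(eigen(t(P))$vectors[, 1])
  boltz <- ev / sum(ev)
  expect_equal(boltz, exp(-Fv) / sum(exp(-Fv)), tolerance = 1e-9)

  nchain <- 40
  occ <- matrix(0, nchain, n)
  for (c in seq_len(nchain)) {
    cnt <- motorscape:::mc_lattice_sample_cpp(matrix(Fv, ncol = 1), 1.0,
                                              4e4, 5e3, 700 + c, 0, 0)
    occ[c, ] <- cnt[, 1] / sum(cnt)
  }
  m <- colMeans(occ)
  se <- apply(occ, 2, sd) / sqrt(nchain)
  expect_true(all(abs(m - boltz) < 3 * se + 1e-3))

  # Metropolis rule: acceptance of a +1 kT move approaches exp(-1)
  F2 <- matrix(c(0, 1), ncol = 1)
  cnt <- motorscape:::mc_lattice_sample_cpp(F2, 1.0, 2e5, 1e4, 3, 0, 0)
  ratio <- cnt[2, 1] / cnt[1, 1]
  expect_lt(abs(ratio - exp(-1)), 0.03)
})

test_that("drift on a tilted landscape is downhill and grows with slope", {
  mp <- mc_params()
  drifts <- sapply(c(0.05, 0.15, 0.4), function(g) {
    F <- matrix(g * (1:4001), ncol = 1)  # descending toward low index? no:
    # F increases with index, so drift must be toward smaller iz
    mean(sapply(1:20, function(r) {
      w <- motorscape:::mc_lattice_walk_cpp(F, 1.0, 5e3, 5e3, 50 + r,
                                            2000, 0)
      w[1, 2] - 2000
    }))
  })
  expect_true(all(drifts < 0))
  expect_true(all(diff(abs(drifts)) > 0))
})

test_that("state transitions occur only on network edges at their rates", {
  tr <- main_mc_run()
  tc <- attr(tr, "transitions")
  net <- kinetic_network("main")
  allowed <- net$trans > 0
  allowed["A.Mclosed", "A.Mrigor"] <- TRUE
  expect_true(all(tc[!allowed] == 0))
  # rigor is absorbing
  expect_equal(sum(tc["A.Mrigor", ]), 0)
  # relative frequencies of the two exits of A.Mpre.ADP.Pi (both slow)
  # agree within Poisson error, and the fast return from A.Mpost.ADP.Pi
  # dominates its Pi release ~ fast:fast
  n1 <- tc["A.Mpre.ADP.Pi", "A.Mpost.ADP.Pi"]
  n2 <- tc["A.Mpre.ADP.Pi", "A.Mpre.ADP"]
  expect_lt(abs(n1 - n2) / sqrt(n1 + n2), 4)
  # fast vs slow edges out of A.Mpost.ADP: e7 (fast) vs e6+e9 (slow)
  nf <- tc["A.Mpost.ADP", "A.Mclosed.ADP"]
  ns <- tc["A.Mpost.ADP", "A.Mpre.ADP"] + tc["A.Mpost.ADP", "A.Mpost"]
  expect_gt(nf / max(ns, 1), 20)  # rate ratio is 100:2 = 50
})

test_that("edge frequencies match configured per-MCS rates on recorded runs", {
  lset <- landscape_set()
  net <- kinetic_network("main", fast = 2e-3, slow = 2e-5, k_w = 1e-3)
  tr <- run_trajectories(lset, net, mc_params(max_steps = 4e4),
                         n_traj = 12, seed = 9, n_record = 12,
                         record_stride = 1)
  recs <- attr(tr, "trajectories")
  dwell <- setNames(numeric(8), actomyosin_states())
  for (r in recs) {
    st <- table(factor(actomyosin_states()[r[, 2]],
                       levels = actomyosin_states()))
    dwell <- dwell + st
  }
  tc <- attr(tr, "transitions")
  # per-MCS frequency of the pre.ADP.Pi -> post.ADP.Pi (slow) edge
  n <- tc["A.Mpre.ADP.Pi", "A.Mpost.ADP.Pi"]
  T1 <- dwell["A.Mpre.ADP.Pi"]
  expect_gt(T1, 1e5)
  rate <- n / T1
  expect_lt(abs(rate - 2e-5), 4 * sqrt(2e-5 / T1) + 1e-6)
  # and the fast cleft-closure edge out of post.ADP
  n2 <- tc["A.Mpost.ADP", "A.Mclosed.ADP"]
  T2 <- dwell["A.Mpost.ADP"]
  if (T2 > 1e4) {
    rate2 <- n2 / T2
    expect_lt(abs(rate2 - 2e-3), 4 * sqrt(2e-3 / T2) + 2e-4)
  }
})

test_that("trajectories with all rates ~ zero stay put and are flagged", {
  lset <- landscape_set()
  net <- kinetic_network("main", fast = 1e-15, slow = 1e-16, k_w = 1e-15)
  tr <- run_trajectories(lset, net, mc_params(max_steps = 2e3),
                         n_traj = 5, seed = 2)
  expect_true(all(!tr$completed))
  expect_true(all(!tr$entered))
  expect_true(all(is.na(tr$D)))
  expect_error(displacement_distribution(tr), "no completed")
})

test_that("displacement bookkeeping distinguishes periodic sites", {
  rec <- displacement_distribution(c(0, 5.5, 35.867, -1), bin_width = 0.5)
  expect_equal(rec$n_complete, 4L)
  expect_equal(sum(rec$counts), 4L)
  pk <- displacement_peaks(rec, period = 35.867)
  # the trajectory one repeat away is the minor part
  expect_equal(pk$n_minor_plus, 1L)
  expect_equal(pk$n_major, 3L)
})

test_that("identical seeds reproduce the Monte Carlo run exactly", {
  lset <- landscape_set()
  net <- kinetic_network("main")
  a <- run_trajectories(lset, net, mc_params(max_steps = 2e5), 20, seed = 4)
  b <- run_trajectories(lset, net, mc_params(max_steps = 2e5), 20, seed = 4)
  expect_identical(a$D, b$D)
  expect_identical(a$steps, b$steps)
})

test_that("MCS timescale from the sidewise Perrin friction factor", {
  # sphere limit: Stokes drag
  eta <- 0.89
  sph <- estimate_mcs_timescale(semi_major = 4, semi_minor = 4,
                                viscosity = eta)
  kBT <- 1.380649e-2 * 300
  expect_equal(sph$D_free, kBT / (6 * pi * eta * 4), tolerance = 1e-9)
  # near-sphere continuity of the Perrin expression
  near <- estimate_mcs_timescale(semi_major = 4.0001, semi_minor = 4,
                                 viscosity = eta)
  expect_equal(near$D_free, sph$D_free, tolerance = 1e-4)
  # doubling the viscosity halves D and doubles tau
  e1 <- estimate_mcs_timescale()
  e2 <- estimate_mcs_timescale(viscosity = 2 * 0.89)
  expect_equal(e2$D_free, e1$D_free / 2, tolerance = 1e-12)
  expect_equal(e2$tau_ns, e1$tau_ns * 2, tolerance = 1e-12)
  # the 8 x 2.5 nm ellipsoid diffuses more slowly than its circumscribed
  # sphere and faster than a 8 nm sphere; tau is a fraction of a ns
  expect_lt(e1$D_free, estimate_mcs_timescale(2.5, 2.5)$D_free)
  expect_gt(e1$D_free, estimate_mcs_timescale(8, 8)$D_free)
  expect_gt(e1$tau_ns, 0.001)
  expect_lt(e1$tau_ns, 1)
})

test_that("lever-tip bookkeeping: offsets and exact decomposition", {
  j0 <- make_joint_landscape(motor_center = 2, tip_offset = 0)
  expect_equal(lever_tip_offset(j0)$offset, 0, tolerance = 0.2)
  j6 <- make_joint_landscape(motor_center = 2, tip_offset = 6)
  expect_equal(lever_tip_offset(j6)$offset, 6, tolerance = 0.2)
  # weak/strong pair: total tip displacement = Brownian + lever exactly
  weak <- make_joint_landscape(motor_center = 1, tip_offset = 1.5)
  strong <- make_joint_landscape(motor_center = 9.5, tip_offset = 6)
  dec <- lever_swing_decomposition(weak, strong)
  expect_equal(dec$total, dec$brownian + dec$lever, tolerance = 1e-12)
  expect_equal(dec$brownian, 8.5, tolerance = 0.3)
  expect_equal(dec$lever, 4.5, tolerance = 0.3)
})

test_that("strong-binding sites are found on the closed landscape", {
  lset <- landscape_set()
  s1 <- strong_binding_sites(lset[["A.Mclosed"]], 1)
  expect_length(s1, 1L)
  expect_lt(min(abs(c(s1, s1 - 35.867))), 0.3)  # at the repeat origin
  s2 <- strong_binding_sites(lset[["A.Mclosed"]], 2)
  expect_length(s2, 2L)
})
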