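# Potential-energy terms: values at reference/closed-form points, spring
# continuations, screening, forces vs numerical gradients, symmetry.

test_that("Debye screening length matches the printed values", {
  expect_equal(debye_length(0.025), 1.9, tolerance = 1e-9)
  expect_equal(debye_length(0.100), 0.95, tolerance = 1e-9)
  # inverse-square-root law: 4x concentration halves the length
  expect_equal(debye_length(0.4) * 2, debye_length(0.1), tolerance = 1e-12)
  expect_error(debye_length(-1), "positive")
  # calibrated permittivity is physically reasonable for water at 300 K
  expect_true(debye_permittivity() > 60 && debye_permittivity() < 90)
})

test_that("intra terms vanish at the reference structure", {
  ms <- mini()
  e <- energy_terms(ms$system)
  expect_equal(unname(e$terms["angle"]), 0, tolerance = 1e-20)
  expect_equal(unname(e$terms["dihedral"]), 0, tolerance = 1e-20)
  expect_equal(unname(e$terms["ligand"]), 0, tolerance = 1e-20)
  expect_equal(unname(e$terms["rail"]), 0, tolerance = 1e-20)
  expect_equal(unname(e$terms["anchor"]), 0, tolerance = 1e-20)
  # every native pair sits at its minimum: -eps_native each
  expect_equal(unname(e$terms["native"]),
               -ms$system$params$eps_native * nrow(ms$system$native),
               tolerance = 1e-9)
})

test_that("bond-angle term is k (theta - theta0)^2", {
  # 3 beads at a right angle; rotate the arm by 1 rad
  xyz0 <- rbind(c(3.8, 0, 0), c(0, 0, 0), c(0, 3.8, 0))
  sys <- chain_system(xyz0)
  expect_equal(angle_energy(sys), 0, tolerance = 1e-20)
  a <- pi / 2 - 1  # bend by 1 rad
  X <- rbind(c(3.8, 0, 0), c(0, 0, 0), 3.8 * c(cos(a), sin(a), 0))
  expect_equal(angle_energy(sys, X), 6.67, tolerance = 1e-9)
  # random chain: term-by-term oracle
  set.seed(1)
  xyz <- motorscape:::.bead_helix(8)
  sys8 <- chain_system(xyz)
  X <- xyz + matrix(rnorm(24, 0, 0.4), ncol = 3)
  ang <- function(p) {
    u <- p[1, ] - p[2, ]; v <- p[3, ] - p[2, ]
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  expected <- 0
  for (i in 1:6)
    expected <- expected + 6.67 * (ang(X[i + 0:2, ]) - ang(xyz[i + 0:2, ]))^2
  expect_equal(angle_energy(sys8, X), expected, tolerance = 1e-9)
})

test_that("dihedral term follows the 1- and 3-fold cosine form", {
  xyz0 <- rbind(c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(1.5, -1, 0.3))
  p <- forcefield_params(k_dih1 = 0.7, k_dih3 = 0.2)
  sys <- chain_system(xyz0, params = p)
  expect_equal(dihedral_energy(sys), 0, tolerance = 1e-20)
  # rotate the last bead by pi about the central bond: cos terms give 2a+2b
  X <- xyz0
  X[4, ] <- c(1.5, 1, -0.3)
  expect_equal(dihedral_energy(sys, X), 2 * 0.7 + 2 * 0.2,
               tolerance = 1e-9)
  # random quad matches direct evaluation
  set.seed(2)
  X2 <- xyz0 + matrix(rnorm(12, 0, 0.3), ncol = 3)
  dihed <- function(p) {
    b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
    cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])
    n1 <- cr(b1, b2); n2 <- cr(b2, b3); m1 <- cr(n1, b2)
    atan2(sum(m1 * n2) / sqrt(sum(b2^2)), sum(n1 * n2))
  }
  d <- dihed(X2) - dihed(xyz0)
  expect_equal(dihedral_energy(sys, X2),
               0.7 * (1 - cos(d)) + 0.2 * (1 - cos(3 * d)),
               tolerance = 1e-9)
  # degenerate quad errors
  X3 <- xyz0
  X3[1, ] <- c(-1.5, 0, 0)  # beads 1-2-3 collinear
  expect_error(dihedral_energy(sys, X3), "degenerate")
})

test_that("12-10 native contact: minimum, decay and C1 spring switch", {
  p <- forcefield_params()
  eps <- p$eps_native
  # two-bead 'molecules' cannot carry a native pair, so synthesize one
  r0 <- 6.0
  rsw <- motorscape:::.switch_native(r0, eps, p$k_spring_contact)
  V1210 <- function(r) eps * (5 * (r0 / r)^12 - 6 * (r0 / r)^10)
  expect_lt(rsw, r0)
  # value/slope continuity at the switch (finite differences)
  b <- rsw - (-60 * eps * (r0 / rsw^2) * ((r0 / rsw)^11 - (r0 / rsw)^9)) /
    (2 * p$k_spring_contact)
  Vsp <- function(r) p$k_spring_contact * (r - b)^2 +
    (V1210(rsw) - p$k_spring_contact * (rsw - b)^2)
  expect_equal(Vsp(rsw), V1210(rsw), tolerance = 1e-10)
  h <- 1e-6
  expect_equal((Vsp(rsw + h) - Vsp(rsw - h)) / (2 * h),
               (V1210(rsw + h) - V1210(rsw - h)) / (2 * h),
               tolerance = 1e-6)
  # minimum and decay via the assembled mini system
  ms <- mini()
  sys <- ms$system
  expect_equal(native_contact_energy(sys),
               -eps * nrow(sys$native), tolerance = 1e-9)
  # pull the two molecules far apart: all cutoff terms decay to zero
  X <- sys$X0
  myo <- sys$particles$molecule == "myosin"
  X[myo, 1] <- X[myo, 1] + 1e5
  e <- energy_terms(sys, X)$terms
  expect_equal(unname(e["elec"]), 0)
  expect_equal(unname(e["vdw"]), 0)
})

test_that("nonnative repulsion: value at C, truncation, neighbor list", {
  p <- forcefield_params()
  # helical 9-bead chain; fold bead 9 back to distance C from bead 1
  xyz <- motorscape:::.bead_helix(9)
  sys <- chain_system(xyz, params = p)
  X <- xyz
  X[9, ] <- xyz[1, ] + c(p$nonnative_C, 0, 0)
  e9 <- energy_terms(sys, X)$terms
  # pairs (5..9,9) are within |i-j|<4 except (1,9),(2,9)...(5,9):
  # isolate by comparing with eps scaling
  p2 <- p; p2$eps_nonnative <- 2 * p$eps_nonnative
  sys2 <- sys; sys2$params <- p2
  e9b <- energy_terms(sys2, X)$terms
  contrib <- e9b["nonnative"] - e9["nonnative"]  # = eps * sum (C/r)^12
  # direct formula over the enumerated nonnative pairs (the pair list itself
  # is checked against a brute-force oracle in test-structure.R)
  manual <- sum(apply(sys$nonnative, 1, function(q) {
    r <- sqrt(sum((X[q[1], ] - X[q[2], ])^2))
    if (r < p$nonnative_cutoff) (p$nonnative_C / r)^12 else 0
  }))
  expect_gt(manual, 0.9)  # the folded-back pair sits at r = C: (C/r)^12 = 1
  expect_equal(unname(contrib), p$eps_nonnative * manual, tolerance = 1e-9)
  # all pairs far beyond the cutoff -> exactly 0
  zig <- cbind(60 * (0:8), rep(c(0, 3), length.out = 9), 0)
  far <- chain_system(zig, params = p)
  expect_equal(nonnative_energy(far), 0, tolerance = 1e-15)
  # neighbor list equals brute force on a perturbed mini system
  ms <- mini()
  set.seed(3)
  Xp <- ms$system$X0 + matrix(rnorm(3 * ms$system$n, 0, 0.3), ncol = 3)
  e1 <- energy_terms(ms$system, Xp)$terms
  e2 <- energy_terms(ms$system, Xp, use_neighbor_list = TRUE)$terms
  expect_identical(e1, e2)
})

test_that("ligand restraints: reference zero, quadratic, absent when apo", {
  ms <- mini()
  sys <- ms$system
  expect_equal(ligand_energy(sys), 0, tolerance = 1e-20)
  # stretch one ligand pair by 1 A along its axis: k (r - r0)^2 adds k per
  # affected pair; use a synthetic 2-particle check instead
  lp <- sys$ligand_pairs[1, ]
  X <- sys$X0
  d <- X[lp$j, ] - X[lp$i, ]
  X[lp$j, ] <- X[lp$i, ] + d * (1 + 1 / sqrt(sum(d^2)))  # +1 A
  de <- ligand_energy(sys, X) - ligand_energy(sys)
  # other pairs involving particle j also move; recompute expected directly
  expected <- 0
  for (r in seq_len(nrow(sys$ligand_pairs))) {
    q <- sys$ligand_pairs[r, ]
    rr <- sqrt(sum((X[q$j, ] - X[q$i, ])^2))
    expected <- expected + sys$params$k_ligand * (rr - q$r0)^2
  }
  expect_equal(de, expected, tolerance = 1e-9)
  # nucleotide-free system has no ligand term
  apo <- make_mini_system(mini_system_spec(with_ligand = FALSE))
  expect_null(apo$system$ligand_pairs)
  expect_equal(ligand_energy(apo$system), 0)
})

test_that("Debye-Hueckel pair energy has the screened-Coulomb closed form", {
  ms <- mini()
  sys <- ms$system
  p <- sys$params
  # single pair at r = lambda_D: move one charged myosin bead next to one
  # charged actin bead, everything else far away
  ch <- which(sys$particles$charge != 0)
  im <- ch[sys$particles$molecule[ch] == "myosin"][1]
  ia <- ch[sys$particles$molecule[ch] == "actin"][1]
  X <- sys$X0
  # park everyone far apart (all pairwise distances beyond every cutoff)
  X[, 1] <- X[, 1] + 1e6 + 1e3 * seq_len(nrow(X))
  X[im, ] <- c(0, 0, 0)
  X[ia, ] <- c(p$debye_length_A, 0, 0)
  qq <- sys$particles$charge[im] * sys$particles$charge[ia]
  expect_equal(debye_huckel_energy(sys, X),
               p$dh_prefactor * qq * exp(-1) / p$debye_length_A,
               tolerance = 1e-9)
  # magnitude decreases monotonically with r (same sign as qq)
  rs <- seq(5, 50, by = 5)
  vals <- sapply(rs, function(r) {
    X[ia, ] <- c(r, 0, 0)
    debye_huckel_energy(sys, X)
  })
  expect_true(all(diff(abs(vals)) < 0))
  expect_true(all(sign(vals) == sign(qq)))
})

test_that("12-6 interface term: well depth at sigma, C1 switch", {
  ms <- mini()
  sys <- ms$system
  p <- sys$params
  bm <- which(sys$particles$molecule == "myosin" &
                sys$particles$kind == "bead" & sys$particles$charge == 0)[1]
  ba <- which(sys$particles$molecule == "actin" &
                sys$particles$charge == 0)[1]
  X <- sys$X0
  X[, 1] <- X[, 1] + 1e6 + 1e3 * seq_len(nrow(X))
  X[bm, ] <- c(0, 0, 0)
  X[ba, ] <- c(p$lj_sigma, 0, 0)
  expect_equal(vdw_energy(sys, X), -p$lj_eps, tolerance = 1e-12)
  # switch continuity
  rsw <- sys$lj_switch[1]
  f <- function(r) {
    X[ba, ] <- c(r, 0, 0)
    vdw_energy(sys, X)
  }
  h <- 1e-5
  # value continuity of the two branches at the switch
  sgm <- p$lj_sigma
  V126 <- function(r) p$lj_eps * ((sgm / r)^12 - 2 * (sgm / r)^6)
  Vsp <- function(r) p$k_spring_lj * (r - sys$lj_switch[2])^2 +
    sys$lj_switch[3]
  expect_equal(Vsp(rsw), V126(rsw), tolerance = 1e-8)
  expect_equal((Vsp(rsw - h) - Vsp(rsw)) / h, (V126(rsw - h) - V126(rsw)) / h,
               tolerance = 1e-3)
  # one-sided derivatives of the assembled term agree (C1 at the switch)
  expect_lt(abs((f(rsw + h) - f(rsw)) / h - (f(rsw) - f(rsw - h)) / h), 1e-3)
})

test_that("curtain rail: zero on the rail, half-k-x^2 off it, free along it", {
  ms <- mini()
  sys <- ms$system
  expect_equal(restraint_energy(sys), 0, tolerance = 1e-20)
  # displace one tip bead 1 A perpendicular to its rail
  i <- sys$tip_idx[1]
  X <- sys$X0
  r <- sqrt(sum(X[i, 1:2]^2))
  X[i, 1:2] <- X[i, 1:2] * (r + 1) / r
  e <- energy_terms(sys, X)$terms
  expect_equal(unname(e["rail"]), 0.5 * sys$params$k_rail * 1^2,
               tolerance = 1e-9)
  # screw-translate all tip beads along their rails: energy stays zero
  om <- sys$rail_omega
  dz <- 7.3
  X2 <- sys$X0
  for (i in sys$tip_idx) {
    ph <- om * dz
    X2[i, ] <- c(cos(ph) * X2[i, 1] - sin(ph) * X2[i, 2],
                 sin(ph) * X2[i, 1] + cos(ph) * X2[i, 2],
                 X2[i, 3] + dz)
  }
  e2 <- energy_terms(sys, X2)$terms
  expect_equal(unname(e2["rail"]), 0, tolerance = 1e-12)
})

test_that("umbrella bias: center, wrap and the half-k convention", {
  ms <- mini()
  sys <- ms$system
  ref <- motor_domain_cyl(sys)
  w0 <- umbrella_window(ref["z"], ref["theta"])
  expect_equal(umbrella_energy(sys, w0), 0, tolerance = 1e-12)
  # theta offset by 2*pi wraps to zero
  w2 <- umbrella_window(ref["z"], ref["theta"] + 2 * pi)
  expect_equal(umbrella_energy(sys, w2), 0, tolerance = 1e-9)
  # 1 rad offset with k = 10 -> 5 kcal/mol
  w1 <- umbrella_window(ref["z"], ref["theta"] + 1)
  expect_equal(umbrella_energy(sys, w1), 0.5 * 10, tolerance = 1e-6)
})

test_that("analytic forces match central finite differences", {
  ms <- mini()
  sys <- ms$system
  set.seed(2)
  X <- sys$X0 + matrix(rnorm(3 * sys$n, 0, 0.15), ncol = 3)
  w <- umbrella_window(5.5, 0.2)
  a <- energy_terms(sys, X, w, forces = TRUE)$forces
  n <- numerical_forces(sys, X, w, h = 1e-5)
  expect_lt(max(abs(a - n)) / max(abs(a)), 1e-5)
})

test_that("total energy is invariant under the helical screw operation", {
  # anchors pin absolute positions, so release them; every other term,
  # including the helical curtain rail, respects the screw symmetry
  ms <- mini()
  sys <- ms$system
  p <- sys$params
  p$k_anchor <- 0
  sys$params <- p
  set.seed(5)
  X <- sys$X0 + matrix(rnorm(3 * sys$n, 0, 0.1), ncol = 3)
  e0 <- energy_terms(sys, X)$total
  dz <- 11.3
  ph <- sys$rail_omega * dz
  Xs <- cbind(cos(ph) * X[, 1] - sin(ph) * X[, 2],
              sin(ph) * X[, 1] + cos(ph) * X[, 2],
              X[, 3] + dz)
  e1 <- energy_terms(sys, Xs)$total
  expect_equal(e1, e0, tolerance = 1e-9)
})

test_that("energy report writes a per-term TSV", {
  ms <- mini()
  f <- tempfile(fileext = ".tsv")
  energy_report(ms$system, path = f)
  df <- read.table(f, header = TRUE, sep = "\t")
  expect_true(all(c("angle", "elec", "total") %in% df$term))
})
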