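# WHAM: window planning, helical replication, self-consistent solution
# against analytic oracles, projection, landscape I/O.

test_that("plan_windows lays out a regular grid", {
  w <- plan_windows()
  expect_length(w, 60L)
  zc <- sapply(w, `[[`, "z_center")
  expect_equal(length(unique(round(diff(sort(unique(zc))), 9))), 1L)
  expect_equal(sort(unique(round(diff(sort(unique(zc))), 9))),
               13 * 2.759 / 20)
  w1 <- plan_windows(c(2, 8), 1, 1)
  expect_length(w1, 1L)
  expect_equal(w1[[1]]$z_center, 5)
  expect_error(plan_windows(c(5, 5), 2, 1), "empty")
})

test_that("helical replication produces five symmetric copies", {
  s <- data.frame(z_nm = c(1, 2), theta_rad = c(0.3, 0.4), window = c(1, 1))
  wins <- list(umbrella_window(1.5, 0.35))
  rep5 <- replicate_helical(s, wins)
  expect_equal(nrow(rep5$samples), 10L)
  expect_length(rep5$windows, 5L)
  # the n = 0 copy is the input itself
  mid <- rep5$samples[rep5$samples$window == 3, ]
  expect_equal(mid$z_nm, s$z_nm)
  expect_equal(mid$theta_rad, s$theta_rad)
  # applying the symmetry operation maps copy k onto copy k+1 exactly
  L <- 13 * 2.759; tw <- 3.2 * pi / 180
  for (k in 1:4) {
    a <- rep5$samples[rep5$samples$window == k, ]
    b <- rep5$samples[rep5$samples$window == k + 1, ]
    expect_equal(a$z_nm + L, b$z_nm, tolerance = 1e-12)
    expect_equal((a$theta_rad + tw) %% (2 * pi), b$theta_rad,
                 tolerance = 1e-12)
  }
})

# draw exact samples from a known free energy under a known bias
.biased_draw <- function(Ftrue, wins, p, n_per, zg, thg, seed) {
  set.seed(seed)
  kBT <- kT(p$temperature)
  wrap <- motorscape:::wrap_pi
  grid <- expand.grid(z = zg, th = thg)
  out <- NULL
  for (k in seq_along(wins)) {
    w <- wins[[k]]
    B <- (0.5 * p$k_umb_z * (10 * (grid$z - w$z_center))^2 +
            0.5 * p$k_umb_theta * wrap(grid$th - w$theta_center)^2) / kBT
    pr <- exp(-(Ftrue(grid$z, grid$th) + B))
    idx <- sample(nrow(grid), n_per, replace = TRUE, prob = pr / sum(pr))
    out <- rbind(out, data.frame(z_nm = grid$z[idx], theta_rad = grid$th[idx],
                                 window = k))
  }
  out
}

test_that("WHAM recovers an analytic harmonic free energy", {
  wrap <- motorscape:::wrap_pi
  p <- forcefield_params(k_umb_z = 0.012, k_umb_theta = 2)
  zg <- seq(2, 8, by = 0.1) + 0.05
  thg <- seq(0, 2 * pi, length.out = 37)[-37] + pi / 36
  Ftrue <- function(z, th) (z - 5)^2 / (2 * 0.8^2) +
    wrap(th - pi)^2 / (2 * 0.5^2)
  wins <- lapply(c(3.5, 4.5, 5.5, 6.5), umbrella_window, theta_center = pi)
  samples <- .biased_draw(Ftrue, wins, p, 40000, zg, thg, seed = 7)
  h <- wham_histograms(samples, 4, z_edges = seq(2, 8.1, by = 0.1),
                       n_theta_bins = 36)
  lsc <- wham_solve(h, wins, p, tol = 1e-10)
  expect_true(attr(lsc, "converged"))
  # convergence diagnostic decreases
  dh <- attr(lsc, "delta_history")
  expect_lt(dh[length(dh)], dh[1])

  zmid <- lsc$z0 + (seq_len(lsc$nz) - 1) * lsc$dz
  thmid <- (seq_len(lsc$ntheta) - 1) * lsc$dtheta + pi / 36
  Ft <- outer(zmid, thmid, Ftrue)
  cnt <- matrix(colSums(h$counts), nrow = lsc$nz, byrow = TRUE)
  ok <- is.finite(lsc$F) & cnt >= 20
  d <- lsc$F[ok] - Ft[ok]
  d <- d - mean(d)
  expect_lt(sqrt(mean(d^2)), 0.2)

  # permuting window order leaves the landscape unchanged
  perm <- c(3, 1, 4, 2)
  s2 <- samples
  s2$window <- match(s2$window, perm)
  h2 <- wham_histograms(s2, 4, z_edges = seq(2, 8.1, by = 0.1),
                        n_theta_bins = 36)
  l2 <- wham_solve(h2, wins[perm], p, tol = 1e-10)
  expect_equal(l2$F, lsc$F, tolerance = 1e-8)
})

test_that("single unbiased window gives F = -ln(counts) + const", {
  set.seed(11)
  p0 <- forcefield_params(k_umb_z = 0, k_umb_theta = 0)
  s <- data.frame(z_nm = runif(5000, 0, 2), theta_rad = runif(5000, 0, 2 * pi),
                  window = 1L)
  h <- wham_histograms(s, 1, z_edges = seq(0, 2, 0.5), n_theta_bins = 4)
  l <- wham_solve(h, list(umbrella_window(1, 0)), p0)
  cnt <- h$counts[1, ]
  sel <- cnt > 0
  d <- as.vector(t(l$F))[sel] + log(cnt[sel])
  expect_lt(diff(range(d)), 1e-10)
})

test_that("disconnected window sets are rejected with their components", {
  s <- data.frame(z_nm = c(rep(1, 10), rep(50, 10)),
                  theta_rad = 0.1, window = rep(1:2, each = 10))
  h <- wham_histograms(s, 2, z_edges = c(0, 2, 49, 51), n_theta_bins = 4)
  expect_error(wham_solve(h, list(umbrella_window(1, 0),
                                  umbrella_window(50, 0))),
               "disconnected")
})

test_that("Boltzmann projection onto z behaves as the log-sum-exp", {
  # theta-independent landscape: projection equals any slice up to gauge
  F <- matrix(rep(c(0, 1, 0.5, 2), 6), nrow = 4)
  l <- landscape_2d(F, dz = 0.5, gauge = FALSE)
  p1 <- project_1d(l)
  expect_equal(p1$F_kT, c(0, 1, 0.5, 2), tolerance = 1e-12)
  # two theta bins with equal F: projection = F - ln 2 before the gauge
  F2 <- matrix(c(0, 1, 0, 1), nrow = 2)
  l2 <- landscape_2d(F2, dz = 0.5, gauge = FALSE)
  raw <- -log(rowSums(exp(-F2)))
  expect_equal(raw, c(0, 1) - log(2), tolerance = 1e-12)
  expect_equal(project_1d(l2)$F_kT, c(0, 1), tolerance = 1e-12)
  # projection is below the minimum over theta at every z (more states)
  set.seed(3)
  F3 <- matrix(runif(60, 0, 4), nrow = 10)
  raw3 <- -log(rowSums(exp(-F3)))
  expect_true(all(raw3 <= apply(F3, 1, min) + 1e-12))
})

test_that("landscape TSV + JSON round trip and helical evaluation", {
  lset <- landscape_set()
  l <- lset[["A.Mpre.ADP.Pi"]]
  f <- file.path(tempdir(), "pre.tsv")
  write_landscape(l, f)
  back <- read_landscape(f)
  expect_equal(back$F, l$F, tolerance = 1e-12)
  expect_equal(back$period, l$period)
  expect_equal(back$twist, l$twist)
  expect_equal(back$state_label, l$state_label)
  # the evaluator honors the helical wrap: F(z + L, th + twist) = F(z, th)
  set.seed(6)
  z <- runif(100, 0, l$period)
  th <- runif(100, 0, 2 * pi)
  a <- landscape_eval(l, z, th)
  b <- landscape_eval(l, z + l$period, th + l$twist)
  expect_equal(a, b, tolerance = 1e-9)
})
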