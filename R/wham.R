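# WHAM: combine umbrella-biased (z, theta) histograms into an unbiased 2D
# free-energy landscape, with the five-fold helical data replication that
# enforces the periodicity of the entire system.

#' Plan a regular grid of umbrella windows
#'
#' @param z_range numeric length-2, nm (default one helical repeat).
#' @param n_z,n_theta number of window centers along z and theta
#'   (default 20 x 3 = 60 windows).
#' @return list of [umbrella_window()]s (z fastest).
#' @export
plan_windows <- function(z_range = c(0, 13 * 2.759), n_z = 20L,
                         n_theta = 3L) {
  if (diff(z_range) <= 0) stop("empty z range")
  dzw <- diff(z_range) / n_z
  zc <- z_range[1] + (seq_len(n_z) - 0.5) * dzw
  thc <- (seq_len(n_theta) - 1) * 2 * pi / n_theta
  out <- list()
  for (th in thc) for (z in zc)
    out[[length(out) + 1L]] <- umbrella_window(z, th)
  out
}

#' Replicate window samples by the helical symmetry
#'
#' Each sample `(z, theta)` in window `k` generates copies
#' `(z + n L, theta + n twist)` for `n = -(n_copies-1)/2 ... +(n_copies-1)/2`
#' assigned to correspondingly shifted windows, so that the WHAM input (and
#' hence the solved landscape) carries the helical periodicity of the system.
#'
#' @param samples data.frame with `z_nm`, `theta_rad`, `window` (1-based
#'   window index).
#' @param windows list of [umbrella_window()]s the samples refer to.
#' @param period repeat length, nm.
#' @param twist net twist per repeat, rad.
#' @param n_copies odd number of copies (default 5).
#' @return list with augmented `samples` and `windows`.
#' @export
replicate_helical <- function(samples, windows, period = 13 * 2.759,
                              twist = 3.2 * pi / 180, n_copies = 5L) {
  stopifnot(n_copies %% 2 == 1)
  half <- (n_copies - 1L) %/% 2L
  K <- length(windows)
  out_s <- vector("list", n_copies)
  out_w <- vector("list", n_copies * K)
  ci <- 0L
  for (n in -half:half) {
    ci <- ci + 1L
    s <- samples
    s$z_nm <- s$z_nm + n * period
    s$theta_rad <- wrap_2pi(s$theta_rad + n * twist)
    s$window <- s$window + (ci - 1L) * K
    out_s[[ci]] <- s
    for (k in seq_len(K)) {
      w <- windows[[k]]
      out_w[[(ci - 1L) * K + k]] <-
        umbrella_window(w$z_center + n * period,
                        wrap_2pi(w$theta_center + n * twist))
    }
  }
  list(samples = do.call(rbind, out_s), windows = out_w)
}

#' Bin window samples into 2D histograms
#'
#' @param samples data.frame with `z_nm`, `theta_rad`, `window`.
#' @param n_windows number of windows (rows of the count matrix).
#' @param z_edges z bin edges (nm); default 0.1 nm bins covering the samples.
#' @param n_theta_bins number of theta bins tiling `[0, 2*pi)` (default 72).
#' @return list of class `wham_histograms`.
#' @export
wham_histograms <- function(samples, n_windows,
                            z_edges = NULL, n_theta_bins = 72L) {
  if (is.null(z_edges)) {
    lo <- floor(min(samples$z_nm) / 0.1) * 0.1
    hi <- ceiling(max(samples$z_nm) / 0.1) * 0.1
    z_edges <- seq(lo, hi, by = 0.1)
  }
  th_edges <- seq(0, 2 * pi, length.out = n_theta_bins + 1L)
  nz <- length(z_edges) - 1L
  iz <- findInterval(samples$z_nm, z_edges, rightmost.closed = TRUE)
  ith <- findInterval(wrap_2pi(samples$theta_rad), th_edges,
                      rightmost.closed = TRUE)
  ok <- iz >= 1 & iz <= nz
  iz <- iz[ok]; ith <- ith[ok]; win <- samples$window[ok]
  bin <- (iz - 1L) * n_theta_bins + ith
  m <- nz * n_theta_bins
  counts <- matrix(tabulate((bin - 1L) * n_windows + win,
                            nbins = as.double(m) * n_windows),
                   nrow = n_windows, ncol = m)
  zmid <- (z_edges[-1] + z_edges[-length(z_edges)]) / 2
  thmid <- (th_edges[-1] + th_edges[-length(th_edges)]) / 2
  structure(list(counts = counts, z_edges = z_edges, th_edges = th_edges,
                 zmid = zmid, thmid = thmid, nz = nz,
                 ntheta = n_theta_bins),
            class = "wham_histograms")
}

.logsumexp_cols <- function(m) {
  # row-wise log-sum-exp over the columns of a matrix, via vectorized pmax
  mx <- m[, 1]
  for (k in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, k])
  s <- exp(m[, 1] - mx)
  for (k in seq_len(ncol(m))[-1]) s <- s + exp(m[, k] - mx)
  mx + log(s)
}

#' Solve WHAM self-consistently
#'
#' Standard self-consistent solution of the weighted-histogram equations on
#' the 2D `(z, theta)` grid. The bias of window k at a bin center is the
#' umbrella energy evaluated there. Convergence is declared when the maximum
#' change of the window free energies falls below `tol` (kT). Bins with zero
#' counts across all windows are reported missing (`NA`), not extrapolated.
#'
#' @param hist a [wham_histograms()] object.
#' @param windows list of [umbrella_window()]s (possibly replicated).
#' @param params a [forcefield_params()] (umbrella stiffnesses,
#'   temperature).
#' @param tol convergence tolerance on the window free energies, kT.
#' @param max_iter maximum number of iterations.
#' @param period,twist,state_label metadata for the output landscape.
#' @return a [landscape_2d()]; attributes `f_window` (window free energies,
#'   kT), `iterations`, `converged`, `delta_history`.
#' @export
wham_solve <- function(hist, windows, params = forcefield_params(),
                       tol = 1e-6, max_iter = 10000L,
                       period = 13 * 2.759, twist = 3.2 * pi / 180,
                       state_label = "custom") {
  K <- length(windows)
  stopifnot(nrow(hist$counts) == K)
  kBT <- kT(params$temperature)
  # bin centers, flattened (z major, theta minor)
  zc <- rep(hist$zmid, each = hist$ntheta)
  thc <- rep(hist$thmid, times = hist$nz)
  sampled <- which(colSums(hist$counts) > 0L)
  if (!length(sampled)) stop("no sampled bins")
  n_m <- colSums(hist$counts)[sampled]
  N_k <- rowSums(hist$counts)
  if (any(N_k == 0)) stop("window(s) with no samples: ",
                          paste(which(N_k == 0), collapse = ", "))

  # connectivity of the window coverage
  comp <- .window_components(hist$counts[, sampled, drop = FALSE])
  if (max(comp) > 1)
    stop("non-overlapping windows; disconnected components: ",
         paste(vapply(seq_len(max(comp)), function(cc)
           paste0("{", paste(which(comp == cc), collapse = ","), "}"),
           character(1)), collapse = " "))

  # bias matrix (K x Msampled), in kT; a window may carry several helical
  # images (see [periodic_windows()]): its effective bias is the log-mixture
  # -ln mean_i exp(-B_i), which ties the replicated copies' free-energy
  # constants together and hence enforces the helical periodicity of the
  # solved landscape
  B <- matrix(0, K, length(sampled))
  for (k in seq_len(K)) {
    w <- windows[[k]]
    n_img <- length(w$z_center)
    Bi <- matrix(0, length(sampled), n_img)
    for (i in seq_len(n_img)) {
      dzA <- 10 * (zc[sampled] - w$z_center[i])
      dth <- wrap_pi(thc[sampled] - w$theta_center[i])
      Bi[, i] <- (0.5 * params$k_umb_z * dzA^2 +
                    0.5 * params$k_umb_theta * dth^2) / kBT
    }
    if (n_img == 1) B[k, ] <- Bi[, 1]
    else {
      bmin <- do.call(pmin, as.data.frame(Bi))
      B[k, ] <- bmin - log(rowMeans(exp(-(Bi - bmin))))
    }
  }

  lognk <- log(N_k)
  lognm <- log(n_m)
  Bt <- t(B)  # Msampled x K

  # The window constants maximize the WHAM likelihood, a smooth convex
  # problem in f: minimize sum_m n_m log D_m(f) - sum_k N_k f_k with
  # D_m = sum_k exp(log N_k + f_k - B_km). Damped Newton reaches the
  # optimum in a handful of iterations even when the self-consistent map
  # mixes slowly (long replicated window chains); the classical
  # self-consistent iteration then polishes the solution and provides the
  # convergence diagnostic.
  f <- rep(0, K)
  obj <- function(fv) {
    A <- sweep(-Bt, 2, lognk + fv, "+")
    mx <- Reduce(pmax, as.data.frame(A))
    sum(n_m * (mx + log(rowSums(exp(A - mx))))) - sum(N_k * fv)
  }
  F0 <- obj(f)
  for (newton in seq_len(100)) {
    A <- sweep(-Bt, 2, lognk + f, "+")
    mx <- Reduce(pmax, as.data.frame(A))
    E <- exp(A - mx)
    W <- E / rowSums(E)
    g <- colSums(n_m * W) - N_k
    if (max(abs(g)) < 1e-10 * sum(N_k)) break
    WN <- sqrt(n_m) * W
    H <- diag(colSums(n_m * W)) - crossprod(WN)
    step_dir <- rep(0, K)
    d <- try(solve(H[-1, -1, drop = FALSE] +
                     1e-9 * mean(diag(H)) * diag(K - 1),
                   g[-1]), silent = TRUE)
    if (inherits(d, "try-error")) break
    step_dir[-1] <- d
    step <- 1
    repeat {
      f_try <- f - step * step_dir
      F1 <- obj(f_try)
      if (is.finite(F1) && F1 <= F0) { f <- f_try; F0 <- F1; break }
      step <- step / 2
      if (step < 1e-8) break
    }
    if (step < 1e-8) break
  }
  f <- f - f[1]

  sol <- wham_iterate_cpp(lognm, Bt, lognk, tol, as.integer(max_iter), f)
  f <- sol$f
  delta_hist <- sol$delta_history
  converged <- sol$converged
  iter <- sol$iterations
  logP_full <- rep(NA_real_, hist$nz * hist$ntheta)
  logP_full[sampled] <- sol$logP
  Fgrid <- matrix(-logP_full, nrow = hist$nz, ncol = hist$ntheta,
                  byrow = TRUE)
  out <- landscape_2d(Fgrid, z0 = hist$zmid[1],
                      dz = hist$zmid[2] - hist$zmid[1],
                      period = period, twist = twist,
                      state_label = state_label, gauge = TRUE)
  attr(out, "counts") <- matrix(colSums(hist$counts), nrow = hist$nz,
                                ncol = hist$ntheta, byrow = TRUE)
  attr(out, "f_window") <- f
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  attr(out, "delta_history") <- delta_hist
  out
}

# union-find over windows: two windows are connected when they share a
# sampled bin
.window_components <- function(counts) {
  K <- nrow(counts)
  parent <- seq_len(K)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (m in seq_len(ncol(counts))) {
    ks <- which(counts[, m] > 0L)
    if (length(ks) > 1) {
      r <- find(ks[1])
      for (k in ks[-1]) parent[find(k)] <- r
    }
  }
  roots <- vapply(seq_len(K), find, integer(1))
  match(roots, unique(roots))
}

#' Helical image set of a window
#'
#' Attaches the `n_copies` helical images `(z + n L, theta + n twist)` to
#' each window. Used together with helically replicated samples, the images
#' give each window a composite bias that ties the free-energy constants of
#' all copies together, so the solved landscape is periodic by construction
#' (up to the finite number of copies).
#'
#' @param windows list of [umbrella_window()]s.
#' @param period,twist helical periodicity (nm, rad).
#' @param n_copies odd number of images.
#' @return list of windows with vector-valued centers.
#' @export
periodic_windows <- function(windows, period = 13 * 2.759,
                             twist = 3.2 * pi / 180, n_copies = 5L) {
  half <- (n_copies - 1L) %/% 2L
  lapply(windows, function(w) {
    ns <- -half:half
    structure(list(z_center = w$z_center + ns * period,
                   theta_center = wrap_2pi(w$theta_center + ns * twist)),
              class = "umbrella_window")
  })
}

#' Umbrella sampling to landscape, end to end
#'
#' Runs the full pipeline: helical replication of the window samples
#' (5 copies), 2D histogramming and the WHAM solution.
#'
#' @param samples data.frame with `z_nm`, `theta_rad`, `window`.
#' @param windows list of [umbrella_window()]s.
#' @param params [forcefield_params()].
#' @param period,twist helical periodicity (nm, rad).
#' @param n_copies helical replication count (5; 1 disables replication).
#' @param z_edges,n_theta_bins binning, see [wham_histograms()].
#' @param ... passed to [wham_solve()].
#' @return a [landscape_2d()].
#' @export
wham_landscape <- function(samples, windows, params = forcefield_params(),
                           period = 13 * 2.759, twist = 3.2 * pi / 180,
                           n_copies = 5L, z_edges = NULL,
                           n_theta_bins = 72L, ...) {
  if (n_copies > 1) {
    rep <- replicate_helical(samples, windows, period, twist, n_copies)
    # keep the base window identity of each replicated sample: each base
    # window then sees its five data copies under its five helical images
    K <- length(windows)
    rep$samples$window <- ((rep$samples$window - 1L) %% K) + 1L
    samples <- rep$samples
    windows <- periodic_windows(windows, period, twist, n_copies)
  }
  h <- wham_histograms(samples, length(windows), z_edges, n_theta_bins)
  wham_solve(h, windows, params, period = period, twist = twist, ...)
}
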