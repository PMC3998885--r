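# Free-energy landscape container (thermal-energy units, cylindrical grid).

#' Two-dimensional free-energy landscape
#'
#' Free energy (in units of thermal energy) on a regular `(z, theta)` grid
#' with helical periodicity metadata: `F(z + period, theta + twist) =
#' F(z, theta)`. `theta` bins tile `[0, 2*pi)`.
#'
#' @param F numeric matrix `nz x ntheta` (kT units; `NA` marks unsampled
#'   bins).
#' @param z0 z of the first grid column, nm.
#' @param dz z grid spacing, nm.
#' @param period helical repeat length, nm (35.867 by default).
#' @param twist net twist per repeat, rad (3.2 degrees by default).
#' @param state_label actomyosin state the landscape belongs to.
#' @param gauge if `TRUE`, shift so the minimum over the grid is 0.
#' @return object of class `landscape_2d`.
#' @export
landscape_2d <- function(F, z0 = 0, dz = NULL, period = 13 * 2.759,
                         twist = 3.2 * pi / 180, state_label = "custom",
                         gauge = TRUE) {
  F <- as.matrix(F)
  if (is.null(dz)) dz <- period / nrow(F)
  if (gauge && any(is.finite(F))) F <- F - min(F, na.rm = TRUE)
  structure(list(F = F, z0 = z0, dz = dz, period = period, twist = twist,
                 nz = nrow(F), ntheta = ncol(F),
                 dtheta = 2 * pi / ncol(F), state_label = state_label),
            class = "landscape_2d")
}

#' @export
print.landscape_2d <- function(x, ...) {
  cat(sprintf(paste0("landscape_2d <%s>: %d x %d grid, z in [%.3f, %.3f) nm ",
                     "(dz %.4f), period %.3f nm, twist %.2f deg; ",
                     "range %.2f kT, %d unsampled bins\n"),
              x$state_label, x$nz, x$ntheta, x$z0, x$z0 + x$nz * x$dz, x$dz,
              x$period, x$twist * 180 / pi,
              diff(range(x$F, na.rm = TRUE)), sum(!is.finite(x$F))))
  invisible(x)
}

.lsc_cpp <- function(l) list(F = l$F, z0 = l$z0, dz = l$dz,
                             period = l$period, twist = l$twist)

#' Evaluate a landscape at arbitrary coordinates
#'
#' Bilinear interpolation on the grid, periodic in `theta` and helically
#' periodic in z (the grid is assumed to cover exactly one repeat when the
#' helical wrap is exercised). Unsampled bins propagate as `NA`.
#'
#' @param landscape a [landscape_2d()].
#' @param z,theta coordinates (nm, rad); recycled to a common length.
#' @return numeric vector of free energies (kT).
#' @export
landscape_eval <- function(landscape, z, theta) {
  n <- max(length(z), length(theta))
  landscape_eval_cpp(.lsc_cpp(landscape), rep_len(as.numeric(z), n),
                     rep_len(as.numeric(theta), n))
}

#' Boltzmann projection onto the z axis
#'
#' `F(z) = -ln sum_theta exp(-F(z, theta))` up to an additive constant;
#' the gauge sets the minimum to 0. z columns with no sampled bin are
#' returned as `NA`.
#'
#' @param landscape a [landscape_2d()].
#' @return data.frame of class `landscape_1d` with `z_nm` and `F_kT`.
#' @export
project_1d <- function(landscape) {
  F <- landscape$F
  w <- exp(-F)
  s <- rowSums(w, na.rm = TRUE)
  s[!apply(is.finite(F), 1, any)] <- NA
  f1 <- -log(s)
  f1 <- f1 - min(f1, na.rm = TRUE)
  out <- data.frame(z_nm = landscape$z0 + (seq_len(landscape$nz) - 1) *
                      landscape$dz,
                    F_kT = f1)
  class(out) <- c("landscape_1d", "data.frame")
  out
}

#' Helical periodicity residual of a landscape
#'
#' Compares `F(z, theta)` with `F(z + period, theta + twist)` wherever both
#' points lie inside the grid (plain, non-wrapping interpolation), so it is
#' meaningful for landscapes solved on a z range longer than one repeat.
#'
#' @param landscape a [landscape_2d()].
#' @param z_range optional z interval (nm): only compare pairs whose lower
#'   point lies inside it (use the centrally covered region of a landscape
#'   solved on replicated data, where both periodic images are constrained
#'   by data on both sides).
#' @param max_F only compare grid points whose free energy (both images) is
#'   at most `max_F` kT above the minimum; high-lying bins of a sampled
#'   landscape carry few counts and mostly statistical noise.
#' @param min_count only compare grid points carrying at least this many
#'   histogram counts (both images, nearest grid node); requires a `counts`
#'   attribute as attached by [wham_solve()].
#' @return list with `rms` and `max` residual (kT) and the number of
#'   compared grid points.
#' @export
periodicity_residual <- function(landscape, z_range = NULL, max_F = Inf,
                                 min_count = 0) {
  counts <- attr(landscape, "counts")
  if (min_count > 0 && is.null(counts))
    stop("min_count filtering needs a landscape with a 'counts' attribute")
  l <- landscape
  zmax <- l$z0 + (l$nz - 1) * l$dz
  z <- l$z0 + (seq_len(l$nz) - 1) * l$dz
  usable <- which(z + l$period <= zmax + 1e-9)
  if (!is.null(z_range))
    usable <- usable[z[usable] >= z_range[1] & z[usable] <= z_range[2]]
  if (!length(usable))
    stop("grid z range shorter than one period; residual undefined")
  th <- (seq_len(l$ntheta) - 1) * l$dtheta
  diffs <- c()
  for (i in usable) {
    zi <- z[i] + l$period
    xi <- (zi - l$z0) / l$dz
    i0 <- floor(xi); tz <- xi - i0
    i0 <- as.integer(i0) + 1L
    i1 <- min(i0 + 1L, l$nz)
    for (j in seq_len(l$ntheta)) {
      a <- .theta_interp(l, i0, th[j] + l$twist)
      b <- .theta_interp(l, i1, th[j] + l$twist)
      v <- (1 - tz) * a + tz * b
      d <- v - l$F[i, j]
      ok <- is.finite(d) && v <= max_F && l$F[i, j] <= max_F
      if (ok && min_count > 0) {
        i2 <- min(l$nz, max(1L, as.integer(round(xi)) + 1L))
        j2 <- (as.integer(round((((th[j] + l$twist) %% (2 * pi)) /
                                   l$dtheta))) %% l$ntheta) + 1L
        ok <- counts[i, j] >= min_count && counts[i2, j2] >= min_count
      }
      if (ok) diffs <- c(diffs, d)
    }
  }
  if (!length(diffs)) stop("no overlapping sampled bins")
  list(rms = sqrt(mean(diffs^2)), max = max(abs(diffs)),
       n = length(diffs))
}

.theta_interp <- function(l, i, theta) {
  u <- (theta %% (2 * pi)) / l$dtheta
  j0 <- floor(u); t <- u - j0
  j0 <- (as.integer(j0) %% l$ntheta) + 1L
  j1 <- (j0 %% l$ntheta) + 1L
  (1 - t) * l$F[i, j0] + t * l$F[i, j1]
}

#' Write / read a landscape (TSV + JSON sidecar)
#'
#' The TSV carries `z_nm`, `theta_rad`, `F_kT` in grid order; the JSON
#' sidecar carries the grid geometry, periodicity and state label.
#'
#' @param landscape a [landscape_2d()].
#' @param path TSV path; the sidecar is `<path>.json`.
#' @return `write_landscape`: the path, invisibly. `read_landscape`: a
#'   [landscape_2d()].
#' @export
write_landscape <- function(landscape, path) {
  l <- landscape
  grid <- expand.grid(theta_rad = (seq_len(l$ntheta) - 1) * l$dtheta,
                      z_nm = l$z0 + (seq_len(l$nz) - 1) * l$dz)
  df <- data.frame(z_nm = grid$z_nm, theta_rad = grid$theta_rad,
                   F_kT = as.vector(t(l$F)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(nz = l$nz, ntheta = l$ntheta, z0 = l$z0, dz = l$dz,
               period_nm = l$period, twist_rad = l$twist,
               state_label = l$state_label, units = "kT")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.table(path, header = TRUE, sep = "\t")
  F <- matrix(df$F_kT, nrow = meta$nz, ncol = meta$ntheta, byrow = TRUE)
  landscape_2d(F, z0 = meta$z0, dz = meta$dz, period = meta$period_nm,
               twist = meta$twist_rad, state_label = meta$state_label,
               gauge = FALSE)
}
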