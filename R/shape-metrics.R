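#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the selected atoms from
#' their center of mass,
#' \deqn{R_g = \sqrt{\sum_i m_i |r_i - r_{cm}|^2 / \sum_i m_i},}
#' the standard overall size measure for a dendrimer conformation.
#'
#' @param ens A \code{\link{conf_ensemble}}.
#' @param selection Atom indices; default all atoms.
#' @param frame Frame index vector; default all frames.
#' @return Numeric vector of per-frame RoG values (nm).
#' @examples
#' ens <- gen_reference_solids("solid_ball", list(radius = 1), seed = 1)
#' mean(radius_of_gyration(ens))  # ~ sqrt(3/5)
#' @export
radius_of_gyration <- function(ens, selection = seq_len(n_atoms(ens)),
                               frame = seq_len(n_frames(ens))) {
  if (length(selection) == 0L) stop("empty selection")
  m <- ens$masses[selection]
  if (sum(m) <= 0) stop("zero total mass")
  vapply(frame, function(f) {
    xyz <- matrix(ens$coords[selection, , f], ncol = 3L)
    cm <- colSums(xyz * m) / sum(m)
    d2 <- (xyz[, 1L] - cm[1L])^2 + (xyz[, 2L] - cm[2L])^2 +
          (xyz[, 3L] - cm[3L])^2
    sqrt(sum(m * d2) / sum(m))
  }, numeric(1L))
}

#' @keywords internal
.inertia_tensor <- function(xyz, m) {
  cm <- colSums(xyz * m) / sum(m)
  x <- xyz[, 1L] - cm[1L]; y <- xyz[, 2L] - cm[2L]; z <- xyz[, 3L] - cm[3L]
  Ixx <- sum(m * (y^2 + z^2)); Iyy <- sum(m * (x^2 + z^2))
  Izz <- sum(m * (x^2 + y^2))
  Ixy <- -sum(m * x * y); Ixz <- -sum(m * x * z); Iyz <- -sum(m * y * z)
  matrix(c(Ixx, Ixy, Ixz, Ixy, Iyy, Iyz, Ixz, Iyz, Izz), 3L, 3L)
}

#' Principal-inertia shape descriptors
#'
#' Per frame, the mass-weighted inertia tensor about the selection's
#' center of mass is diagonalized and its eigenvalues sorted ascending,
#' \eqn{I_x \le I_y \le I_z} (amu nm^2). From these, two aspect ratios
#' \eqn{I_x/I_y} and \eqn{I_x/I_z} (in (0,1], 1 for a sphere) and the
#' asphericity
#' \deqn{\delta = 1 - 3\langle I_2\rangle / \langle I_1^2\rangle,}
#' with \eqn{I_1 = I_x+I_y+I_z}, \eqn{I_2 = I_xI_y + I_yI_z + I_xI_z}
#' and angle brackets denoting the time average over the analysed frames.
#' \eqn{\delta = 0} for isotropic inertia and reaches 1/4 in the thin-rod
#' limit (\eqn{I_x \to 0}, \eqn{I_y = I_z}).
#'
#' Aspect ratios are reported both as means of the per-frame series (with
#' SD) and the per-frame series themselves; the asphericity is a ratio of
#' time averages, as its definition requires.
#'
#' @param ens A \code{\link{conf_ensemble}}.
#' @param selection Atom indices; default the dendrimer plus core beads.
#' @param frames Frame indices to analyse; default all.
#' @return Object of class \code{"shape_summary"}: per-frame RoG and
#'   moments, per-frame ratio series, time-averaged ratios with SD, and
#'   asphericity \code{delta}.
#' @export
inertia_descriptors <- function(ens,
                                selection = select_atoms(ens, c("core",
                                                                "dendrimer")),
                                frames = seq_len(n_frames(ens))) {
  if (length(selection) == 0L) stop("empty selection")
  m <- ens$masses[selection]
  nf <- length(frames)
  mom <- matrix(NA_real_, nf, 3L,
                dimnames = list(NULL, c("Ix", "Iy", "Iz")))
  degenerate <- FALSE
  for (k in seq_len(nf)) {
    xyz <- matrix(ens$coords[selection, , frames[k]], ncol = 3L)
    ev <- sort(eigen(.inertia_tensor(xyz, m), symmetric = TRUE,
                     only.values = TRUE)$values)
    ev[ev < 0 & ev > -1e-12 * max(abs(ev))] <- 0  # numerical noise
    if (ev[1L] <= 0) degenerate <- TRUE
    mom[k, ] <- ev
  }
  if (degenerate)
    warning("degenerate (collinear) configuration in at least one frame")
  I1 <- rowSums(mom)
  I2 <- mom[, 1L] * mom[, 2L] + mom[, 2L] * mom[, 3L] + mom[, 1L] * mom[, 3L]
  delta <- 1 - 3 * mean(I2) / mean(I1^2)
  rxy <- mom[, 1L] / mom[, 2L]
  rxz <- mom[, 1L] / mom[, 3L]
  structure(list(
    rog = radius_of_gyration(ens, selection, frames),
    moments = mom,
    ratio_xy = rxy, ratio_xz = rxz,
    mean_ratio_xy = mean(rxy), sd_ratio_xy = stats::sd(rxy),
    mean_ratio_xz = mean(rxz), sd_ratio_xz = stats::sd(rxz),
    delta = delta, frames = frames,
    degenerate = degenerate), class = "shape_summary")
}

#' @export
print.shape_summary <- function(x, ...) {
  cat(sprintf("shape_summary over %d frames\n", length(x$frames)))
  cat(sprintf("  RoG      %.4f +/- %.4f nm\n", mean(x$rog), stats::sd(x$rog)))
  cat(sprintf("  Ix/Iy    %.3f +/- %.3f\n", x$mean_ratio_xy, x$sd_ratio_xy))
  cat(sprintf("  Ix/Iz    %.3f +/- %.3f\n", x$mean_ratio_xz, x$sd_ratio_xz))
  cat(sprintf("  delta    %.4f\n", x$delta))
  invisible(x)
}

#' Probability density of a radius-of-gyration series
#'
#' Histogram-based probability density, normalized so that the curve
#' integrates to 1 over its support. A histogram (rather than a kernel
#' estimate) is used so that a constant series yields a single-bin spike
#' that still integrates to 1.
#'
#' @param rog Numeric vector of per-frame RoG values (>= 10 samples).
#' @param bins Number of bins; reduced with a warning when it exceeds
#'   the sample count.
#' @return Data frame with \code{mid}, \code{density}, and attributes
#'   \code{breaks}.
#' @export
rog_pdf <- function(rog, bins = 30L) {
  if (length(rog) < 10L) stop("need at least 10 samples")
  if (bins > length(rog)) {
    warning("more bins than samples; coarsening")
    bins <- max(1L, length(rog) %/% 2L)
  }
  rng <- range(rog)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * max(abs(rng[1L]) * 1e-3, 1e-6)
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  h <- graphics::hist(rog, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE)
  out <- data.frame(mid = h$mids, density = h$density)
  attr(out, "breaks") <- h$breaks
  out
}

#' Mean and SD over an analysis window
#'
#' Trajectory descriptors are averaged over the equilibrated tail of
#' each run; the default window is the last 25\% of frames. Several
#' replica series may be supplied as a list, in which case the selected
#' tail of each replica is concatenated into a single ensemble window
#' before averaging.
#'
#' @param series Numeric vector, or list of numeric vectors (replicas).
#' @param last_fraction Fraction of each series to keep, from the end.
#' @param window Optional explicit number of trailing samples (overrides
#'   \code{last_fraction}).
#' @return List with \code{mean}, \code{sd} (sample SD; \code{0} for a
#'   single sample), \code{n}, and the concatenated \code{values}.
#' @examples
#' window_average(c(1, 2, 3, 4), last_fraction = 0.5)$mean  # 3.5
#' @export
window_average <- function(series, last_fraction = 0.25, window = NULL) {
  if (!is.list(series)) series <- list(series)
  tails <- lapply(series, function(s) {
    n <- length(s)
    k <- if (!is.null(window)) window else max(1L, ceiling(n * last_fraction))
    if (k < 1L || k > n) stop("empty or invalid window")
    s[(n - k + 1L):n]
  })
  v <- unlist(tails)
  list(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
       n = length(v), values = v)
}
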