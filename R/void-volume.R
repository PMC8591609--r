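#' Van der Waals radii (nm) for common elements
#'
#' Bondi radii for the elements these systems contain; bead symbols not
#' in the table fall back to \code{default} (used by the synthetic bead
#' models, which carry their own radii in metadata).
#'
#' @param element Character vector of element/bead symbols.
#' @param default Radius for unknown symbols (nm).
#' @return Numeric vector of radii (nm).
#' @export
vdw_radii <- function(element, default = 0.15) {
  tab <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, P = 0.180,
           S = 0.180, F = 0.147, CL = 0.175, BR = 0.185, I = 0.198,
           NA. = 0.227, K = 0.275)
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  r <- tab[key]
  r[is.na(r)] <- default
  unname(r)
}

#' Volume enclosed by the solvent-accessible surface
#'
#' Atoms are inflated by the probe radius and rasterized on a cubic
#' grid. A grid point counts as enclosed if it lies inside any inflated
#' atom \emph{or} cannot be reached from the box boundary through
#' probe-free space (flood fill over the free points, started from the
#' boundary). Interior pockets that the probe cannot enter therefore
#' count as enclosed volume -- which is what makes the probe-radius sweep
#' of \code{\link{void_volume_estimate}} sensitive to internal cavities.
#'
#' @param xyz N x 3 coordinate matrix (nm) for one frame.
#' @param radii Per-atom van der Waals radii (nm); see
#'   \code{\link{vdw_radii}}.
#' @param probe Probe radius (nm).
#' @param spacing Grid spacing (nm), default 0.05. A spacing coarser
#'   than probe/2 warns.
#' @return Enclosed volume in nm^3, with the grid point count in
#'   attributes.
#' @export
sasa_volume <- function(xyz, radii, probe, spacing = 0.05) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  n <- nrow(xyz)
  if (n == 0L) stop("empty frame")
  if (length(radii) == 1L) radii <- rep(radii, n)
  stopifnot(length(radii) == n, probe >= 0, spacing > 0)
  if (probe > 0 && spacing > probe / 2)
    warning("grid spacing > probe/2; enclosed volume may be inaccurate")
  rinf <- radii + probe
  pad <- 2 * spacing
  lo <- apply(xyz - rinf, 2L, min) - pad
  hi <- apply(xyz + rinf, 2L, max) + pad
  gx <- seq(lo[1L], hi[1L], by = spacing)
  gy <- seq(lo[2L], hi[2L], by = spacing)
  gz <- seq(lo[3L], hi[3L], by = spacing)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  occ <- array(FALSE, dim = c(nx, ny, nz))
  # mark occupied points atom by atom over the atom's bounding sub-block
  for (i in seq_len(n)) {
    ix <- which(gx >= xyz[i, 1L] - rinf[i] & gx <= xyz[i, 1L] + rinf[i])
    iy <- which(gy >= xyz[i, 2L] - rinf[i] & gy <= xyz[i, 2L] + rinf[i])
    iz <- which(gz >= xyz[i, 3L] - rinf[i] & gz <= xyz[i, 3L] + rinf[i])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - xyz[i, 1L])^2
    dy2 <- (gy[iy] - xyz[i, 2L])^2
    dz2 <- (gz[iz] - xyz[i, 3L])^2
    block <- outer(outer(dx2, dy2, "+"), dz2, "+") <= rinf[i]^2
    occ[ix, iy, iz] <- occ[ix, iy, iz] | block
  }
  free <- !occ
  # flood fill reachable free space from the box boundary (6-neighbor)
  reach <- array(FALSE, dim = dim(free))
  reach[c(1L, nx), , ] <- free[c(1L, nx), , ]
  reach[, c(1L, ny), ] <- reach[, c(1L, ny), ] | free[, c(1L, ny), ]
  reach[, , c(1L, nz)] <- reach[, , c(1L, nz)] | free[, , c(1L, nz)]
  repeat {
    grown <- reach
    grown[-1L, , ] <- grown[-1L, , ] | reach[-nx, , ]
    grown[-nx, , ] <- grown[-nx, , ] | reach[-1L, , ]
    grown[, -1L, ] <- grown[, -1L, ] | reach[, -ny, ]
    grown[, -ny, ] <- grown[, -ny, ] | reach[, -1L, ]
    grown[, , -1L] <- grown[, , -1L] | reach[, , -nz]
    grown[, , -nz] <- grown[, , -nz] | reach[, , -1L]
    grown <- grown & free
    if (identical(grown, reach)) break
    reach <- grown
  }
  enclosed <- sum(occ) + sum(free & !reach)
  structure(enclosed * spacing^3,
            n_points = enclosed, spacing = spacing)
}

#' Internal void volume from a probe-radius sweep
#'
#' Enclosed volumes are computed across a set of probe radii. At large
#' probes the probe cannot enter internal cavities, so the enclosed
#' volume includes them; the cube root of the enclosed volume grows
#' almost linearly with probe radius there. A line is fitted to
#' \eqn{V_{sasa}^{1/3}} against probe radius over the radii >=
#' \code{fit_min}, extrapolated down to \code{eval_probe}, converted
#' back to a volume, and the measured enclosed volume at
#' \code{eval_probe} (where the probe does penetrate the cavities) is
#' subtracted. The difference estimates the internal void volume.
#'
#' By default the extrapolated cube root is cubed before subtraction, so
#' the estimate is in nm^3 directly; set
#' \code{deviation = "cuberoot"} to instead take the deviation in
#' cube-root space and cube it.
#'
#' @param xyz N x 3 coordinates (nm) for one frame.
#' @param radii Per-atom radii (nm).
#' @param probes Ascending probe radii (nm); default
#'   \code{seq(0.3, 1.0, 0.1)}.
#' @param fit_min Smallest probe radius included in the linear fit
#'   (default 0.4 nm).
#' @param eval_probe Probe radius at which the deviation is evaluated
#'   (default 0.3 nm).
#' @param spacing Grid spacing (nm).
#' @param deviation \code{"volume"} (default) or \code{"cuberoot"}.
#' @return Object of class \code{"probe_sweep"}: the sweep table,
#'   fit coefficients, and \code{void_volume} (nm^3; negative estimates
#'   are clipped to 0 and flagged via \code{clipped}).
#' @export
void_volume_estimate <- function(xyz, radii, probes = seq(0.3, 1.0, by = 0.1),
                                 fit_min = 0.4, eval_probe = 0.3,
                                 spacing = 0.05,
                                 deviation = c("volume", "cuberoot")) {
  deviation <- match.arg(deviation)
  probes <- sort(unique(c(probes, eval_probe)))
  fit_idx <- which(probes >= fit_min)
  if (length(fit_idx) < 2L) stop("need at least 2 probe radii >= fit_min")
  if (min(probes) > eval_probe) stop("probe set must include eval_probe")
  v <- vapply(probes, function(p) as.numeric(sasa_volume(xyz, radii, p,
                                                         spacing)),
              numeric(1L))
  cr <- v^(1 / 3)
  fit <- stats::lm.fit(cbind(1, probes[fit_idx]), cr[fit_idx])
  a <- fit$coefficients[1L]; b <- fit$coefficients[2L]
  v_eval <- v[which.min(abs(probes - eval_probe))]
  void <- if (deviation == "volume") (a + b * eval_probe)^3 - v_eval
          else ((a + b * eval_probe) - v_eval^(1 / 3))^3
  clipped <- void < 0
  structure(list(probes = probes, v_sasa = v,
                 fit = c(intercept = unname(a), slope = unname(b)),
                 fit_range = range(probes[fit_idx]),
                 eval_probe = eval_probe, deviation = deviation,
                 void_volume = max(0, void), clipped = clipped),
            class = "probe_sweep")
}

#' @export
print.probe_sweep <- function(x, ...) {
  cat("probe sweep (nm, nm^3):\n")
  print(data.frame(probe = x$probes, v_sasa = x$v_sasa), row.names = FALSE)
  cat(sprintf("fit over [%.2f, %.2f]: V^(1/3) = %.4f + %.4f r\n",
              x$fit_range[1L], x$fit_range[2L], x$fit["intercept"],
              x$fit["slope"]))
  cat(sprintf("void volume at probe %.2f nm: %.4f nm^3%s\n", x$eval_probe,
              x$void_volume, if (x$clipped) " (clipped from negative)" else ""))
  invisible(x)
}

#' Mean void volume of an ensemble
#'
#' @param ens A \code{\link{conf_ensemble}}.
#' @param radii Per-atom radii (nm) for the atoms retained; a single
#'   value is recycled.
#' @param selection Atoms to include; default everything except water,
#'   ions and photosensitizer (the neat dendrimer).
#' @param frames Frames to average over; default all.
#' @param ... Passed to \code{\link{void_volume_estimate}}.
#' @return Mean void volume (nm^3) with the per-frame sweeps attached.
#' @export
ensemble_void_volume <- function(ens, radii = 0.15,
                                 selection = select_atoms(ens, c("core",
                                                                 "dendrimer")),
                                 frames = seq_len(n_frames(ens)), ...) {
  if (length(radii) == 1L) radii <- rep(radii, length(selection))
  sweeps <- lapply(frames, function(f)
    void_volume_estimate(ens$coords[selection, , f], radii, ...))
  structure(mean(vapply(sweeps, `[[`, numeric(1L), "void_volume")),
            sweeps = sweeps)
}

#' Void-volume ratio of a complex to the neat dendrimer
#'
#' The paper-level comparison: cavities of the dendrimer within a
#' photosensitizer complex (photosensitizer atoms removed from each
#' snapshot before the sweep, so only structural effects on the
#' dendrimer are measured) relative to the neat dendrimer. A ratio < 1
#' means complexation compacts the dendrimer and closes cavities.
#'
#' @param complex_ens Ensemble containing \code{"RB"}-labelled atoms.
#' @param neat_ens Ensemble of the free dendrimer.
#' @param radii Bead/atom radius or per-atom radii (nm).
#' @param frames Frames to average (applied to both ensembles).
#' @param ... Passed to \code{\link{void_volume_estimate}}.
#' @return List with \code{ratio}, \code{void_complex}, \code{void_neat}.
#' @export
void_ratio <- function(complex_ens, neat_ens, radii = 0.15,
                       frames = NULL, ...) {
  rb <- which(complex_ens$labels == "RB")
  if (length(rb) == 0L)
    warning("no RB atoms in complex ensemble; comparing identical pipelines")
  keep <- select_atoms(complex_ens, c("core", "dendrimer"))
  fc <- if (is.null(frames)) seq_len(n_frames(complex_ens)) else frames
  fn <- if (is.null(frames)) seq_len(n_frames(neat_ens)) else frames
  vc <- ensemble_void_volume(complex_ens, radii, selection = keep,
                             frames = fc, ...)
  vn <- ensemble_void_volume(neat_ens, radii,
                             selection = select_atoms(neat_ens,
                                                      c("core", "dendrimer")),
                             frames = fn, ...)
  list(ratio = as.numeric(vc) / as.numeric(vn),
       void_complex = as.numeric(vc), void_neat = as.numeric(vn))
}
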