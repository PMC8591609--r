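#' Emission spectrum container
#'
#' @param wavelengths Strictly ascending wavelengths (nm).
#' @param intensities Non-negative intensities (arbitrary units).
#' @param ratio Optional titration-point metadata (molar ratio).
#' @return Object of class \code{"emission_spectrum"}.
#' @export
emission_spectrum <- function(wavelengths, intensities, ratio = NA_real_) {
  stopifnot(length(wavelengths) == length(intensities))
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly ascending")
  if (any(intensities < 0)) stop("intensities must be >= 0")
  structure(list(wavelengths = wavelengths, intensities = intensities,
                 ratio = ratio), class = "emission_spectrum")
}

#' Titration series container
#'
#' A monotone sequence of (molar ratio, response) points, the response
#' being either the F564/F575 fluorescence ratio (dimensionless) or a
#' zeta potential (mV).
#'
#' @param x Strictly ascending molar ratios (at least 5 points).
#' @param y Responses.
#' @param kind \code{"fluorescence"} or \code{"zeta"}.
#' @param meta Optional metadata (e.g. generator truth).
#' @return Object of class \code{"titration_series"}.
#' @export
titration_series <- function(x, y, kind = c("fluorescence", "zeta"),
                             meta = list()) {
  kind <- match.arg(kind)
  stopifnot(length(x) == length(y))
  if (length(x) < 5L) stop("need at least 5 titration points")
  if (any(diff(x) <= 0)) stop("molar ratios must be strictly ascending")
  structure(list(x = as.numeric(x), y = as.numeric(y), kind = kind,
                 meta = meta), class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("titration_series (%s): %d points, ratio %.3g..%.3g\n",
              x$kind, length(x$x), min(x$x), max(x$x)))
  invisible(x)
}

#' F564/F575 fluorescence ratio of a spectrum
#'
#' Intensity at 564 nm over intensity at 575 nm, each read off by
#' linear interpolation between the sampled wavelengths. The ratio
#' tracks the red shift of the dye's emission upon binding: free dye
#' peaks near 564 nm (ratio > 1), fully bound dye near 575 nm
#' (ratio < 1).
#'
#' @param spectrum An \code{\link{emission_spectrum}} covering both
#'   wavelengths.
#' @param num,den Numerator and denominator wavelengths (nm).
#' @return Dimensionless ratio.
#' @export
fluorescence_ratio <- function(spectrum, num = 564, den = 575) {
  w <- spectrum$wavelengths
  if (num < w[1L] || den > w[length(w)] || den < w[1L] || num > w[length(w)])
    stop("readout wavelengths outside the sampled range")
  fi <- stats::approx(w, spectrum$intensities, xout = c(num, den))$y
  if (fi[2L] == 0) stop("zero intensity at the denominator wavelength")
  fi[1L] / fi[2L]
}

#' Peak emission wavelength
#'
#' Wavelength of maximum intensity, refined by a 3-point parabolic fit
#' around the sampled maximum when possible. A plateaued maximum
#' (several equal-intensity samples) returns the plateau midpoint with
#' the \code{"plateau"} attribute set.
#'
#' @param spectrum An \code{\link{emission_spectrum}}.
#' @return Peak wavelength (nm).
#' @export
peak_wavelength <- function(spectrum) {
  w <- spectrum$wavelengths; y <- spectrum$intensities
  if (diff(range(y)) == 0) stop("flat spectrum has no peak")
  tops <- which(y == max(y))
  if (length(tops) > 1L) {
    return(structure(mean(range(w[tops])), plateau = TRUE))
  }
  i <- tops
  if (i == 1L || i == length(w)) return(w[i])
  # parabolic refinement on a locally uniform grid
  h1 <- w[i] - w[i - 1L]; h2 <- w[i + 1L] - w[i]
  if (abs(h1 - h2) > 1e-9 * h1) return(w[i])
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (denom >= 0) return(w[i])
  w[i] + 0.5 * h1 * (y[i - 1L] - y[i + 1L]) / denom
}

#' @keywords internal
#' least-squares line through (x, y); returns c(intercept, slope, sse)
.ls_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  b <- if (sxx == 0) 0 else sum((x - mx) * (y - my)) / sxx
  a <- my - b * mx
  c(a, b, sum((y - (a + b * x))^2))
}

#' Binding stoichiometry from a two-regime titration curve
#'
#' The saturation-breakpoint construction the field calls Job's method
#' for these titrations: the response falls (or rises) linearly with
#' the molar ratio while binding sites remain, then switches to a
#' second regime (typically a plateau) once the dendrimer is saturated.
#' Over a grid of candidate breakpoints (every interior ratio and the
#' midpoints between adjacent ratios), one line is fitted to the points
#' at \eqn{x \le c} and one to \eqn{x \ge c}; the candidate minimizing
#' the total SSE wins (ties toward smaller breakpoint), and the
#' stoichiometry n is the x-coordinate of the two lines' intersection.
#'
#' The estimate is invariant under affine rescaling of the response, so
#' arbitrary fluorescence units are fine.
#'
#' @param series A \code{\link{titration_series}} spanning both regimes.
#' @param min_points Minimum points per segment at the optimum
#'   (default 3).
#' @param slope_tol Relative slope-difference threshold below which the
#'   two segments are considered parallel/degenerate.
#' @return Object of class \code{"stoichiometry_estimate"}: \code{n}
#'   (continuous), \code{label} (rounded "1:n" string, half-up),
#'   segment fits and diagnostics. Strictly linear input (no breakpoint)
#'   is returned flagged \code{degenerate = TRUE} with \code{n = NA}.
#' @examples
#' s <- gen_titration(n_true = 27, noise_sd = 0, seed = 1)
#' job_stoichiometry(s)$n  # 27
#' @export
job_stoichiometry <- function(series, min_points = 3L, slope_tol = 1e-8) {
  stopifnot(inherits(series, "titration_series"))
  x <- series$x; y <- series$y
  xs <- sort(unique(x))
  cand <- sort(unique(c(xs[-c(1L, length(xs))],
                        (xs[-1L] + xs[-length(xs)]) / 2)))
  best <- NULL; best_sse <- Inf
  for (cc in cand) {
    li <- x <= cc; ri <- x >= cc
    if (sum(li) < min_points || sum(ri) < min_points) next
    fl <- .ls_line(x[li], y[li]); fr <- .ls_line(x[ri], y[ri])
    sse <- fl[3L] + fr[3L]
    if (!is.finite(best_sse) || sse < best_sse - 1e-12 * max(best_sse, 1)) {
      best_sse <- sse
      best <- list(breakpoint = cc, left = fl, right = fr)
    }
  }
  if (is.null(best)) stop("fewer than ", min_points,
                          " points per segment for every candidate breakpoint")
  fl <- best$left; fr <- best$right
  yr <- diff(range(y))
  slope_scale <- max(abs(fl[2L]), abs(fr[2L]), yr / diff(range(x)))
  degenerate <- abs(fl[2L] - fr[2L]) <= slope_tol * max(slope_scale, 1e-300)
  n <- if (degenerate) NA_real_ else (fr[1L] - fl[1L]) / (fl[2L] - fr[2L])
  if (!degenerate && (n < min(x) || n > max(x))) {
    # intersection escaped the sampled range: fall back to the SSE-optimal
    # breakpoint (plateau onset)
    n <- best$breakpoint
    fallback <- TRUE
  } else fallback <- FALSE
  structure(list(
    n = n,
    label = if (is.na(n)) NA_character_
            else sprintf("1:%d", as.integer(floor(n + 0.5))),
    breakpoint = best$breakpoint, sse = best_sse,
    left = c(intercept = fl[1L], slope = fl[2L]),
    right = c(intercept = fr[1L], slope = fr[2L]),
    degenerate = degenerate, fallback = fallback,
    method = paste0(series$kind, "_job")),
    class = "stoichiometry_estimate")
}

#' @export
print.stoichiometry_estimate <- function(x, ...) {
  if (x$degenerate) {
    cat("stoichiometry_estimate: degenerate (no breakpoint detected)\n")
  } else {
    cat(sprintf("stoichiometry_estimate (%s): n = %.3f (%s)\n",
                x$method, x$n, x$label))
    cat(sprintf("  segments: slope %.4g | %.4g, SSE %.4g\n",
                x$left["slope"], x$right["slope"], x$sse))
  }
  invisible(x)
}

#' Saturation zeta potential
#'
#' The "eventual zeta potential of the fully saturated dendrimer": the
#' post-breakpoint segment of the titration curve, evaluated as the mean
#' of its fitted line over that segment's ratio range. For a saturated
#' plateau this is the plateau level (about -30 mV for rose bengal
#' saturating a cationic dendrimer).
#'
#' @param series A \code{\link{titration_series}} with a plateau regime.
#' @return Zeta potential (mV).
#' @export
zeta_saturation <- function(series) {
  est <- job_stoichiometry(series)
  if (est$degenerate) {
    # flat everywhere is itself a plateau
    sl <- .ls_line(series$x, series$y)
    if (abs(sl[2L]) * diff(range(series$x)) <
        1e-6 * max(abs(diff(range(series$y))), 1))
      return(mean(series$y))
    stop("no plateau detected in titration series")
  }
  xr <- series$x[series$x >= est$breakpoint]
  unname(est$right["intercept"] + est$right["slope"] * mean(xr))
}

#' Singlet-oxygen generation rate relative to a control
#'
#' In the probe-decay assay, the slope of probe fluorescence versus
#' irradiation time measures singlet-oxygen generation. The statistic is
#' the ordinary least-squares slope of the sample series divided by the
#' control's slope, times 100 (percent of control).
#'
#' @param time,fluorescence Sample time series (>= 3 points).
#' @param control_time,control_fluorescence Control series (>= 3
#'   points), overlapping the sample's time range.
#' @return Percent of control (100 = same rate as control).
#' @export
singlet_oxygen_rate <- function(time, fluorescence,
                                control_time, control_fluorescence) {
  stopifnot(length(time) >= 3L, length(control_time) >= 3L)
  if (max(time) < min(control_time) || max(control_time) < min(time))
    stop("sample and control time ranges do not overlap")
  bs <- .ls_line(time, fluorescence)[2L]
  bc <- .ls_line(control_time, control_fluorescence)[2L]
  if (bc == 0) stop("zero control slope")
  100 * bs / bc
}

#' Read a titration CSV
#'
#' Expects columns \code{ratio} and \code{response} (or the first two
#' columns, in that order).
#'
#' @param path CSV path.
#' @param kind \code{"fluorescence"} or \code{"zeta"}.
#' @return A \code{\link{titration_series}}.
#' @export
read_titration_csv <- function(path, kind = c("fluorescence", "zeta")) {
  df <- utils::read.csv(path)
  cols <- intersect(c("ratio", "response"), names(df))
  if (length(cols) == 2L) df <- df[, cols] else df <- df[, 1:2]
  titration_series(df[[1L]], df[[2L]], kind = match.arg(kind),
                   meta = list(source = path))
}
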