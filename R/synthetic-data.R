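#' Generate a two-regime synthetic titration curve
#'
#' Emulates the titration of a cationic dendrimer with an anionic dye:
#' the response (zeta potential in mV, or a fluorescence ratio) falls
#' linearly with the molar ratio while binding sites remain, then holds
#' at the saturation plateau beyond the true stoichiometry
#' \code{n_true}. The defaults mirror a zeta titration: initial +40 mV,
#' plateau -30 mV, ratio grid 1..50. Additive Gaussian noise is drawn
#' from the given seed; all truth parameters are recorded in the series
#' metadata.
#'
#' @param n_true True stoichiometry (ligands per dendrimer); must lie
#'   inside the ratio grid.
#' @param initial Response at the first grid point.
#' @param plateau Saturation response.
#' @param noise_sd Gaussian noise SD (response units).
#' @param ratios Ascending molar-ratio grid.
#' @param kind \code{"zeta"} or \code{"fluorescence"}.
#' @param seed RNG seed.
#' @return A \code{\link{titration_series}} with truth in \code{meta}.
#'   A flat curve (plateau equal to initial) is generated but flagged
#'   \code{degenerate} in the metadata.
#' @examples
#' job_stoichiometry(gen_titration(26, noise_sd = 0, seed = 1))$n  # 26
#' @export
gen_titration <- function(n_true, initial = 40, plateau = -30,
                          noise_sd = 1, ratios = 1:50,
                          kind = c("zeta", "fluorescence"), seed = 1L) {
  kind <- match.arg(kind)
  if (n_true <= min(ratios) || n_true >= max(ratios))
    stop("ratio grid must span n_true")
  if (noise_sd < 0) stop("noise SD must be >= 0")
  slope <- (plateau - initial) / (n_true - min(ratios))
  y <- ifelse(ratios <= n_true,
              initial + slope * (ratios - min(ratios)), plateau)
  degenerate <- plateau == initial
  if (degenerate) warning("plateau equals initial response; flat curve")
  set.seed(seed)
  y <- y + stats::rnorm(length(y), sd = noise_sd)
  titration_series(ratios, y, kind = kind,
                   meta = list(n_true = n_true, initial = initial,
                               plateau = plateau, noise_sd = noise_sd,
                               seed = seed, degenerate = degenerate))
}

#' Generate a titration series of synthetic emission spectra
#'
#' Each spectrum is a weighted sum of a free-dye Gaussian band (peak
#' 564 nm) and a bound-dye band (peak 575 nm); the bound weight follows
#' a saturation binding curve of the dye:dendrimer molar ratio with
#' saturation at \code{n_sat}. Total intensity dips mid-titration
#' (static quenching) and recovers toward the bound state, controlled
#' by \code{quench_depth}.
#'
#' @param ratios Dye:dendrimer molar ratios (one spectrum each).
#' @param n_sat Saturation stoichiometry governing the bound fraction.
#' @param free_peak,bound_peak Band centers (nm).
#' @param width Gaussian SD of both bands (nm).
#' @param quench_depth Fractional intensity dip at half saturation, in
#'   [0, 1).
#' @param wavelengths Sampled wavelength grid (nm).
#' @param noise_sd Additive intensity noise SD.
#' @param seed RNG seed.
#' @return List of \code{\link{emission_spectrum}} objects, with the
#'   generator truth attached as the \code{"truth"} attribute.
#' @export
gen_spectra_series <- function(ratios, n_sat = 27, free_peak = 564,
                               bound_peak = 575, width = 10,
                               quench_depth = 0.5,
                               wavelengths = seq(540, 650, by = 1),
                               noise_sd = 0, seed = 1L) {
  if (free_peak < min(wavelengths) || bound_peak > max(wavelengths))
    stop("band peaks must lie within the sampled wavelengths")
  if (width <= 0) stop("invalid band width")
  if (quench_depth < 0 || quench_depth >= 1) stop("quench_depth in [0, 1)")
  set.seed(seed)
  # bound fraction of dendrimer binding sites vs dye load: for a fixed
  # dendrimer amount, the dye is fully bound below saturation, so the
  # bound fraction OF DYE is min(1, n_sat / ratio); mid-titration mixes
  f_bound <- pmin(1, n_sat / pmax(ratios, .Machine$double.eps))
  out <- lapply(seq_along(ratios), function(i) {
    fb <- f_bound[i]
    amp <- 1 - quench_depth * 4 * fb * (1 - fb)
    inten <- amp * ((1 - fb) * exp(-(wavelengths - free_peak)^2 /
                                     (2 * width^2)) +
                    fb * exp(-(wavelengths - bound_peak)^2 / (2 * width^2)))
    if (noise_sd > 0)
      inten <- pmax(0, inten + stats::rnorm(length(inten), sd = noise_sd))
    emission_spectrum(wavelengths, inten, ratio = ratios[i])
  })
  attr(out, "truth") <- list(n_sat = n_sat, free_peak = free_peak,
                             bound_peak = bound_peak, width = width,
                             quench_depth = quench_depth, seed = seed)
  out
}

#' @keywords internal
#' unit vectors spread over the sphere (golden-spiral lattice)
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Generate a dendrimer-like bead ensemble
#'
#' A geometric stand-in for an MD trajectory of a dendrimer: beads are
#' placed along the branching tree of a \code{\link{build_topology}}
#' layer model, from a core bead outward, each child displaced from its
#' parent by \code{segment} nm in a direction that is its parent's
#' outward direction plus angular noise. Frame-to-frame conformational
#' fluctuation is controlled by \code{stiffness}: each frame perturbs
#' the branch directions and applies a log-normal breathing factor with
#' SD proportional to 1/stiffness, so a high-stiffness model (PPI-like)
#' has a narrow radius-of-gyration distribution and a low-stiffness
#' model (PAMAM-like) a broad one. After generation all frames are
#' scaled by a single factor so the time-mean RoG matches
#' \code{target_rog}.
#'
#' @param topology A \code{\link{dendrimer_topology}} (or a
#'   \code{\link{dendrimer_spec}}, which is built automatically).
#' @param target_rog Target time-mean radius of gyration (nm).
#' @param segment Branch segment length before rescaling (nm).
#' @param stiffness Dimensionless rigidity; large = rigid (narrow RoG
#'   spread), small = floppy. Infinite stiffness gives identical frames.
#' @param bead_radius Bead radius recorded in metadata (nm).
#' @param n_frames Number of frames.
#' @param bead_mass Mass per bead (amu).
#' @param seed RNG seed; generation is fully seed-deterministic.
#' @return A \code{\link{conf_ensemble}} with one \code{"core"} bead and
#'   \code{"dendrimer"} beads, truth parameters in \code{meta}.
#' @examples
#' ens <- gen_dendrimer_ensemble(build_topology("PPI", 3),
#'                               target_rog = 1.284, stiffness = 40,
#'                               n_frames = 20, seed = 1)
#' mean(radius_of_gyration(ens))
#' @export
gen_dendrimer_ensemble <- function(topology, target_rog = 1.5,
                                   segment = 0.35, stiffness = 10,
                                   bead_radius = 0.15, n_frames = 50L,
                                   bead_mass = 1, seed = 1L) {
  if (inherits(topology, "dendrimer_spec")) topology <- build_topology(topology)
  stopifnot(inherits(topology, "dendrimer_topology"))
  if (segment <= 0 || target_rog <= 0 || bead_radius <= 0)
    stop("geometric parameters must be positive")
  if (n_frames < 1L) stop("n_frames >= 1 required")
  set.seed(seed)
  # parent table: core layer is the deepest; walk outward doubling
  counts <- rev(topology$layers$count)       # core -> terminal
  n_beads <- 1L + sum(counts)                # + central core bead
  parent <- integer(n_beads)
  base_dir <- matrix(0, n_beads, 3L)
  idx0 <- 1L                                  # core bead index
  prev <- rep(idx0, counts[1L])
  nxt <- 2L
  layer_of <- integer(n_beads)
  for (li in seq_along(counts)) {
    ids <- nxt:(nxt + counts[li] - 1L)
    if (li == 1L) {
      parent[ids] <- idx0
      base_dir[ids, ] <- .fibonacci_sphere(counts[li])
    } else {
      # each parent in the previous layer spawns two children
      pids <- rep(prev, each = counts[li] %/% length(prev))
      parent[ids] <- pids
      # strong angular decorrelation from the parent keeps the blob
      # near-spherical (real dendrimers have asphericity ~0.01-0.03)
      jitter <- matrix(stats::rnorm(3L * counts[li], sd = 1.5), ncol = 3L)
      d <- base_dir[pids, , drop = FALSE] + jitter
      base_dir[ids, ] <- d / sqrt(rowSums(d^2))
    }
    layer_of[ids] <- li
    prev <- ids
    nxt <- nxt + counts[li]
  }
  sd_dir <- if (is.finite(stiffness)) 1 / stiffness else 0
  sd_breath <- if (is.finite(stiffness)) 0.25 / stiffness else 0
  frames <- array(0, dim = c(n_beads, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    d <- base_dir
    if (sd_dir > 0) {
      d <- d + matrix(stats::rnorm(3L * n_beads, sd = sd_dir), ncol = 3L)
      nrm <- sqrt(rowSums(d^2)); nrm[nrm == 0] <- 1
      d <- d / nrm
    }
    breath <- exp(stats::rnorm(1L, sd = sd_breath))
    xyz <- matrix(0, n_beads, 3L)
    for (i in 2L:n_beads)
      xyz[i, ] <- xyz[parent[i], ] + segment * breath * d[i, ]
    frames[, , f] <- xyz
  }
  labels <- c("core", rep("dendrimer", n_beads - 1L))
  ens <- conf_ensemble(frames, masses = rep(bead_mass, n_beads),
                       labels = labels,
                       element = sprintf("X%d", layer_of))
  scale <- target_rog / mean(radius_of_gyration(ens))
  ens$coords <- ens$coords * scale
  ens$meta <- list(family = topology$spec$family,
                   generation = topology$spec$generation,
                   target_rog = target_rog, segment = segment * scale,
                   stiffness = stiffness, bead_radius = bead_radius,
                   n_frames = n_frames, seed = seed)
  ens
}

#' Add photosensitizer beads to a dendrimer bead ensemble
#'
#' Places \code{n_ligands} ligand beads per frame at radial positions
#' drawn about \code{depth} times the frame's radius of gyration (so
#' the ligands co-move with the dendrimer's breathing), with angular
#' positions spread over the sphere. \code{depth = "internal"} (0.5)
#' emulates encapsulated dye, \code{depth = "surface"} (1.6) dye bound
#' at the periphery. Optionally compacts the dendrimer beads about the
#' core by \code{compaction} (< 1 emulates the cavity-closing response
#' of a flexible dendrimer to complexation).
#'
#' @param base A dendrimer \code{\link{conf_ensemble}}.
#' @param n_ligands Number of ligand beads (default 10, the 1:10
#'   dendrimer:dye ratio used for the complexes).
#' @param depth \code{"internal"}, \code{"surface"}, or a numeric
#'   multiple of the per-frame RoG for the mean placement radius.
#' @param radial_sd SD of the placement radius as a fraction of RoG.
#' @param ligand_mass Mass per ligand bead (amu).
#' @param compaction Scale factor applied to dendrimer beads about the
#'   per-frame core position (default 1 = none).
#' @param seed RNG seed.
#' @return A \code{\link{conf_ensemble}} with added \code{"RB"} beads.
#' @export
gen_complex_ensemble <- function(base, n_ligands = 10L, depth = "internal",
                                 radial_sd = 0.08, ligand_mass = 1,
                                 compaction = 1, seed = 1L) {
  stopifnot(inherits(base, "conf_ensemble"))
  if (n_ligands <= 0L) stop("n_ligands must be positive")
  mult <- if (is.numeric(depth)) depth
          else switch(match.arg(depth, c("internal", "surface")),
                      internal = 0.5, surface = 1.6)
  set.seed(seed)
  n <- n_atoms(base); nf <- n_frames(base)
  dend <- select_atoms(base, c("core", "dendrimer"))
  rog <- radius_of_gyration(base, dend)
  coords <- array(0, dim = c(n + n_ligands, 3L, nf))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(base, f)
    core <- center_of_mass(base, select_atoms(base, "core"), f)
    if (compaction != 1)
      xyz <- sweep(sweep(xyz, 2L, core, "-") * compaction, 2L, core, "+")
    dirs <- .fibonacci_sphere(n_ligands)
    # random rigid rotation of the ligand shell per frame
    q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
    dirs <- dirs %*% q
    rr <- abs(stats::rnorm(n_ligands, mean = mult * rog[f],
                           sd = radial_sd * rog[f]))
    lig <- sweep(dirs * rr, 2L, core, "+")
    coords[, , f] <- rbind(xyz, lig)
  }
  conf_ensemble(coords,
                masses = c(base$masses, rep(ligand_mass, n_ligands)),
                labels = c(base$labels, rep("RB", n_ligands)),
                element = c(if (is.null(base$element))
                              rep("X", n) else base$element,
                            rep("RB", n_ligands)),
                meta = c(base$meta,
                         list(n_ligands = n_ligands, depth = mult,
                              compaction = compaction,
                              ligand_seed = seed)))
}

#' Analytic reference structures for descriptor validation
#'
#' Seed-deterministic point ensembles with closed-form descriptors:
#' \describe{
#'   \item{solid_ball}{\code{n} uniform points in a ball of
#'     \code{radius}; RoG = sqrt(3/5) radius, asphericity 0.}
#'   \item{hollow_shell}{beads of radius \code{bead_radius} densely
#'     covering a sphere of radius \code{shell_radius} (golden-spiral
#'     lattice at spacing \code{bead_spacing}), with one circular
#'     aperture of circumradius \code{aperture}: a probe of radius
#'     < aperture - bead_radius passes, a larger probe is sealed out.
#'     The probe-free interior at probe radius p is a ball of radius
#'     shell_radius - bead_radius - p.}
#'   \item{rod}{\code{n} points uniform on a thin line of
#'     \code{length}; asphericity 1/4.}
#'   \item{isotropic_cloud}{\code{n} isotropic Gaussian points with
#'     \code{sd}; asphericity about 0.}
#' }
#'
#' @param kind One of \code{"solid_ball"}, \code{"hollow_shell"},
#'   \code{"rod"}, \code{"isotropic_cloud"}.
#' @param parameters Named list of the kind's parameters (see above);
#'   sensible defaults are filled in.
#' @param n_frames Number of frames (independent resamples; the shell
#'   is rigid and identical across frames).
#' @param seed RNG seed.
#' @return A \code{\link{conf_ensemble}} (first atom labelled
#'   \code{"core"} at the centroid) with truth in \code{meta}.
#' @export
gen_reference_solids <- function(kind = c("solid_ball", "hollow_shell",
                                          "rod", "isotropic_cloud"),
                                 parameters = list(), n_frames = 1L,
                                 seed = 1L) {
  kind <- match.arg(kind)
  p <- utils::modifyList(switch(kind,
    solid_ball = list(n = 1000L, radius = 1),
    hollow_shell = list(shell_radius = 1.5, bead_radius = 0.2,
                        bead_spacing = 0.25, aperture = 0.56),
    rod = list(n = 1000L, length = 2),
    isotropic_cloud = list(n = 1000L, sd = 1)), parameters)
  set.seed(seed)
  one_frame <- switch(kind,
    solid_ball = function() {
      u <- matrix(stats::rnorm(3L * p$n), ncol = 3L)
      u <- u / sqrt(rowSums(u^2))
      u * p$radius * stats::runif(p$n)^(1 / 3)
    },
    hollow_shell = local({
      nb <- max(12L, round(4 * pi * p$shell_radius^2 /
                             (sqrt(3) / 2 * p$bead_spacing^2)))
      shell <- .fibonacci_sphere(nb) * p$shell_radius
      # carve a circular aperture around +z with the given circumradius
      pole <- c(0, 0, p$shell_radius)
      chord <- sqrt(colSums((t(shell) - pole)^2))
      shell <- shell[chord >= p$aperture, , drop = FALSE]
      function() shell
    }),
    rod = function() cbind(stats::runif(p$n, -p$length / 2, p$length / 2),
                           0, 0),
    isotropic_cloud = function()
      matrix(stats::rnorm(3L * p$n, sd = p$sd), ncol = 3L))
  fr <- lapply(seq_len(n_frames), function(f) {
    xyz <- one_frame()
    rbind(colMeans(xyz), xyz)     # core marker at the centroid
  })
  nb <- nrow(fr[[1L]])
  coords <- array(unlist(fr), dim = c(nb, 3L, n_frames))
  conf_ensemble(coords, labels = c("core", rep("dendrimer", nb - 1L)),
                meta = c(list(kind = kind, seed = seed), p))
}

#' Generate frames with planted hydrogen-bond geometries
#'
#' Builds a small random system whose every frame contains exactly
#' \code{k} planted near-linear donor-hydrogen-acceptor contacts inside
#' the default geometric criteria, with all remaining donor-acceptor
#' pairs pushed outside the distance cutoff. Used to validate
#' detection counts against a known truth.
#'
#' @param n_frames Number of frames.
#' @param k Planted hydrogen bonds per frame.
#' @param n_decoys Additional acceptor atoms placed far from all donors.
#' @param seed RNG seed.
#' @return List with \code{ensemble}, \code{donors} (two-column
#'   matrix), \code{acceptors}.
#' @export
gen_hbond_system <- function(n_frames = 10L, k = 5L, n_decoys = 20L,
                             seed = 1L) {
  set.seed(seed)
  # layout per frame: k donor/hydrogen/acceptor triplets on a wide grid
  # (cells 3 nm apart so cross-pair distances far exceed the cutoff),
  # plus decoy acceptors on a distant shell
  n_atoms <- 1L + 3L * k + n_decoys    # + core marker
  centers <- .fibonacci_sphere(k) * 3
  frames <- array(0, dim = c(n_atoms, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    xyz <- matrix(0, n_atoms, 3L)
    for (j in seq_len(k)) {
      base <- centers[j, ] + stats::rnorm(3L, sd = 0.05)
      dir <- stats::rnorm(3L); dir <- dir / sqrt(sum(dir^2))
      d_da <- stats::runif(1L, 0.26, 0.33)
      row <- 1L + (j - 1L) * 3L
      xyz[row + 1L, ] <- base                       # donor
      xyz[row + 2L, ] <- base + dir * 0.10          # hydrogen (collinear)
      xyz[row + 3L, ] <- base + dir * d_da          # acceptor
    }
    if (n_decoys > 0L)
      xyz[(1L + 3L * k + 1L):n_atoms, ] <-
        .fibonacci_sphere(n_decoys) * 12
    frames[, , f] <- xyz
  }
  donors <- cbind(donor = 1L + (seq_len(k) - 1L) * 3L + 1L,
                  hydrogen = 1L + (seq_len(k) - 1L) * 3L + 2L)
  acceptors <- c(1L + (seq_len(k) - 1L) * 3L + 3L,
                 if (n_decoys > 0L) (1L + 3L * k + 1L):n_atoms)
  labels <- c("core", rep(c("dendrimer", "dendrimer", "dendrimer"), k),
              rep("water", n_decoys))
  ens <- conf_ensemble(frames, labels = labels,
                       meta = list(k_planted = k, seed = seed))
  list(ensemble = ens, donors = donors, acceptors = acceptors)
}
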