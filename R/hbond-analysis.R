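#' Geometric hydrogen-bond criteria
#'
#' The classic geometric definition: a donor-hydrogen-acceptor triplet
#' is a hydrogen bond when the donor-acceptor distance is at most
#' \code{max_distance} and the angle between the donor-to-hydrogen and
#' donor-to-acceptor directions is at most \code{max_angle} (the
#' hydrogen-donor-acceptor deviation angle; 0 is perfectly linear).
#'
#' @param max_distance Donor-acceptor cutoff in nm (default 0.35).
#' @param max_angle Angular cutoff in degrees (default 30).
#' @return Object of class \code{"hbond_criteria"}.
#' @export
hbond_criteria <- function(max_distance = 0.35, max_angle = 30) {
  if (max_distance <= 0) stop("max_distance must be positive")
  if (max_angle <= 0 || max_angle > 90) stop("max_angle must be in (0, 90]")
  structure(list(max_distance = max_distance, max_angle = max_angle,
                 angle_convention = "hydrogen-donor-acceptor deviation"),
            class = "hbond_criteria")
}

#' Detect hydrogen bonds in a conformation ensemble
#'
#' Donor/acceptor typing is input data, not chemical perception: supply
#' a two-column donor table (donor heavy-atom index, bonded hydrogen
#' index) and a vector of acceptor indices. Every donor-acceptor pair
#' (donor != acceptor) in every frame is tested against the geometric
#' criteria; hits are classified from the ensemble's group labels:
#' \code{with_water} if either partner is water, \code{with_RB} if either
#' partner is the photosensitizer, otherwise \code{internal}
#' (dendrimer-dendrimer).
#'
#' @param ens A \code{\link{conf_ensemble}}.
#' @param donors Two-column matrix or data frame: \code{donor} heavy-atom
#'   index and its covalent \code{hydrogen} index.
#' @param acceptors Integer vector of acceptor heavy-atom indices.
#' @param criteria A \code{\link{hbond_criteria}}.
#' @param frames Frames to analyse; default all.
#' @param max_dh Sanity cutoff (nm) on the donor-hydrogen covalent
#'   distance; a hydrogen farther than this from its donor indicates an
#'   inconsistent donor list and raises an error.
#' @return Data frame of class \code{"hbond_records"}: \code{frame},
#'   \code{donor}, \code{hydrogen}, \code{acceptor}, \code{distance}
#'   (nm), \code{angle} (deg), \code{class}. Criteria kept as an
#'   attribute.
#' @export
find_hbonds <- function(ens, donors, acceptors,
                        criteria = hbond_criteria(),
                        frames = seq_len(n_frames(ens)),
                        max_dh = 0.2) {
  stopifnot(inherits(ens, "conf_ensemble"), inherits(criteria, "hbond_criteria"))
  donors <- as.matrix(donors)
  if (ncol(donors) != 2L) stop("'donors' needs columns donor, hydrogen")
  di <- as.integer(donors[, 1L]); hi <- as.integer(donors[, 2L])
  ai <- as.integer(acceptors)
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    xyz <- frame_coords(ens, f)
    dh <- sqrt(rowSums((xyz[hi, , drop = FALSE] -
                        xyz[di, , drop = FALSE])^2))
    if (any(dh > max_dh))
      stop("hydrogen not bonded to its donor (donor-H distance > ",
           max_dh, " nm); check the donor list")
    # donor-acceptor distance matrix, donors x acceptors
    dx <- outer(xyz[di, 1L], xyz[ai, 1L], "-")
    dy <- outer(xyz[di, 2L], xyz[ai, 2L], "-")
    dz <- outer(xyz[di, 3L], xyz[ai, 3L], "-")
    dist <- sqrt(dx^2 + dy^2 + dz^2)
    hit <- which(dist <= criteria$max_distance &
                 outer(di, ai, "!="), arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    d <- di[hit[, 1L]]; h <- hi[hit[, 1L]]; a <- ai[hit[, 2L]]
    vdh <- xyz[h, , drop = FALSE] - xyz[d, , drop = FALSE]
    vda <- xyz[a, , drop = FALSE] - xyz[d, , drop = FALSE]
    cosang <- rowSums(vdh * vda) /
      (sqrt(rowSums(vdh^2)) * sqrt(rowSums(vda^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    keep <- ang <= criteria$max_angle
    if (!any(keep)) next
    lab_d <- ens$labels[d[keep]]; lab_a <- ens$labels[a[keep]]
    cls <- ifelse(lab_d == "water" | lab_a == "water", "with_water",
           ifelse(lab_d == "RB" | lab_a == "RB", "with_RB", "internal"))
    out[[k]] <- data.frame(frame = f, donor = d[keep], hydrogen = h[keep],
                           acceptor = a[keep],
                           distance = dist[hit][keep], angle = ang[keep],
                           class = cls, stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, out)
  if (is.null(rec))
    rec <- data.frame(frame = integer(), donor = integer(),
                      hydrogen = integer(), acceptor = integer(),
                      distance = numeric(), angle = numeric(),
                      class = character(), stringsAsFactors = FALSE)
  attr(rec, "criteria") <- criteria
  attr(rec, "frames") <- frames
  class(rec) <- c("hbond_records", "data.frame")
  rec
}

#' Per-class hydrogen-bond count summary
#'
#' Mean and SD of the per-frame hydrogen-bond count in each class
#' (internal, with_water, with_RB). Frames with no bonds in a class
#' count as zero. Sample SD (n-1 denominator) is used and recorded.
#'
#' @param records Output of \code{\link{find_hbonds}}.
#' @param n_frames Number of frames analysed; defaults to the frame set
#'   stored in \code{records}.
#' @return Data frame: \code{class}, \code{mean}, \code{sd}, with the SD
#'   convention as an attribute.
#' @export
hbond_count_summary <- function(records, n_frames = NULL) {
  if (is.null(n_frames)) n_frames <- length(attr(records, "frames"))
  if (is.null(n_frames) || n_frames == 0L) stop("n_frames must be positive")
  classes <- c("internal", "with_water", "with_RB")
  frames <- attr(records, "frames")
  if (is.null(frames)) frames <- seq_len(n_frames)
  out <- do.call(rbind, lapply(classes, function(cl) {
    cnt <- vapply(frames,
                  function(f) sum(records$frame == f & records$class == cl),
                  numeric(1L))
    data.frame(class = cl, mean = mean(cnt),
               sd = if (length(cnt) > 1L) stats::sd(cnt) else 0,
               stringsAsFactors = FALSE)
  }))
  attr(out, "sd_convention") <- "sample"
  out
}
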