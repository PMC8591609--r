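#' Conformation ensemble container
#'
#' An ordered set of frames of labelled 3D coordinates, the common
#' currency of every descriptor module. Coordinates are stored in nm
#' (GRO convention); readers convert on ingest.
#'
#' @param coords Numeric array \code{N x 3 x n_frames} (nm), or an
#'   \code{N x 3} matrix for a single frame, or a list of such matrices.
#' @param masses Length-N masses (amu); default 1 for bead models.
#' @param labels Length-N character group tags, drawn from
#'   \code{c("core", "dendrimer", "RB", "water", "ion_Na", "ion_Cl",
#'   "other")}. Every atom must be tagged and the ensemble must contain a
#'   \code{"core"} reference group.
#' @param element Optional length-N element/bead symbols.
#' @param charges Optional length-N partial charges (e).
#' @param box Optional 3 x 3 x n_frames (or 3-vector) box vectors (nm).
#' @param meta Optional named list of provenance metadata (generator
#'   parameters, seeds, truth values).
#' @return Object of class \code{"conf_ensemble"}.
#' @examples
#' xyz <- matrix(rnorm(30), 10, 3)
#' ens <- conf_ensemble(xyz, labels = c("core", rep("dendrimer", 9)))
#' n_frames(ens)
#' @export
conf_ensemble <- function(coords, masses = NULL, labels = NULL,
                          element = NULL, charges = NULL, box = NULL,
                          meta = list()) {
  if (is.list(coords) && !is.array(coords))
    coords <- array(unlist(coords), dim = c(dim(coords[[1L]]), length(coords)))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (length(dim(coords)) != 3L || dim(coords)[2L] != 3L)
    stop("'coords' must be an N x 3 x n_frames array")
  n <- dim(coords)[1L]
  if (is.null(masses)) masses <- rep(1, n)
  if (is.null(labels)) labels <- c("core", rep("dendrimer", n - 1L))
  if (length(masses) != n || length(labels) != n)
    stop("masses and labels must have one entry per atom")
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("all masses must be positive and finite")
  known <- c("core", "dendrimer", "RB", "water", "ion_Na", "ion_Cl", "other")
  if (any(!labels %in% known))
    stop("unknown group labels: ",
         paste(unique(labels[!labels %in% known]), collapse = ", "))
  if (!any(labels == "core"))
    stop("ensemble must designate a 'core' reference group")
  if (!is.null(element) && length(element) != n)
    stop("'element' must have one entry per atom")
  if (!is.null(charges) && length(charges) != n)
    stop("'charges' must have one entry per atom")
  structure(list(coords = coords, masses = as.numeric(masses),
                 labels = as.character(labels), element = element,
                 charges = charges, box = box, meta = meta),
            class = "conf_ensemble")
}

#' @rdname conf_ensemble
#' @param x,ens A \code{"conf_ensemble"}.
#' @export
n_frames <- function(ens) dim(ens$coords)[3L]

#' @rdname conf_ensemble
#' @export
n_atoms <- function(ens) dim(ens$coords)[1L]

#' Extract one frame's coordinate matrix
#'
#' @param ens A \code{"conf_ensemble"}.
#' @param frame Frame index (1-based).
#' @return N x 3 numeric matrix (nm).
#' @export
frame_coords <- function(ens, frame) {
  stopifnot(frame >= 1L, frame <= n_frames(ens))
  matrix(ens$coords[, , frame], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf("conf_ensemble: %d atoms x %d frames (nm)\n",
              n_atoms(x), n_frames(x)))
  tab <- table(x$labels)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Select atoms by group tag or predicate
#'
#' Returns a stable, sorted index set; unions and complements compose in
#' the usual way with \code{union()} and \code{setdiff()}.
#'
#' @param ens A \code{"conf_ensemble"}.
#' @param tag Character vector of group tags, or a predicate function of
#'   the label vector returning a logical mask.
#' @return Sorted integer indices. An empty selection warns.
#' @examples
#' ens <- conf_ensemble(matrix(0, 4, 3),
#'                      labels = c("core", "dendrimer", "RB", "RB"))
#' select_atoms(ens, "RB")
#' @export
select_atoms <- function(ens, tag) {
  stopifnot(inherits(ens, "conf_ensemble"))
  idx <- if (is.function(tag)) which(tag(ens$labels))
         else which(ens$labels %in% tag)
  if (length(idx) == 0L) warning("empty selection")
  sort(idx)
}

#' Mass-weighted center of mass of a selection
#'
#' @param ens A \code{"conf_ensemble"}.
#' @param selection Integer atom indices (e.g. from
#'   \code{\link{select_atoms}}); default all atoms.
#' @param frame Frame index.
#' @return 3-vector (nm).
#' @export
center_of_mass <- function(ens, selection = seq_len(n_atoms(ens)), frame = 1L) {
  if (length(selection) == 0L) stop("empty selection")
  m <- ens$masses[selection]
  if (sum(m) <= 0) stop("zero total mass")
  xyz <- matrix(ens$coords[selection, , frame], ncol = 3L)
  colSums(xyz * m) / sum(m)
}
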