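#' Read a multi-frame coordinate file into a conformation ensemble
#'
#' Supported formats: multi-model PDB (parsed with \pkg{bio3d};
#' Angstrom, converted to nm), GRO (nm, one or more concatenated
#' frames) and extended XYZ (Angstrom, concatenated frames). Group tags
#' are assigned through \code{label_map}, a named character vector from
#' residue names (PDB/GRO) or atom symbols (XYZ) to group tags; a
#' \code{".default"} entry catches unmapped names, otherwise an unmapped
#' name is an error.
#'
#' @param path File path.
#' @param format \code{"pdb"}, \code{"gro"} or \code{"xyz"}; guessed
#'   from the extension when missing.
#' @param label_map Named character vector, e.g.
#'   \code{c(COR = "core", DEN = "dendrimer", RB = "RB", SOL = "water",
#'   .default = "other")}. May also be a path to a YAML file with the
#'   same mapping.
#' @param masses Optional length-N masses; by default looked up from the
#'   element symbol (1 amu for unknown bead symbols).
#' @return A \code{\link{conf_ensemble}} in nm, frame order preserved.
#' @export
read_ensemble <- function(path, format = NULL, label_map = NULL,
                          masses = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("pdb", "gro", "xyz"))
  if (is.character(label_map) && length(label_map) == 1L &&
      file.exists(label_map) && is.null(names(label_map)))
    label_map <- unlist(yaml::read_yaml(label_map))
  parsed <- switch(format,
                   pdb = .read_pdb_frames(path),
                   gro = .read_gro_frames(path),
                   xyz = .read_xyz_frames(path))
  labels <- .map_labels(parsed$names, label_map)
  if (is.null(masses)) masses <- .element_masses(parsed$element)
  conf_ensemble(parsed$coords, masses = masses, labels = labels,
                element = parsed$element, box = parsed$box,
                meta = list(source = path, format = format))
}

#' Write a conformation ensemble to a standard coordinate file
#'
#' PDB and XYZ are written in Angstrom, GRO in nm. Group tags are stored
#' as residue names (PDB/GRO), truncated to the format's field width, so
#' a round trip through \code{\link{read_ensemble}} with the identity
#' label map recovers them.
#'
#' @param ens A \code{\link{conf_ensemble}}.
#' @param path Output path.
#' @param format \code{"pdb"}, \code{"gro"} or \code{"xyz"}; guessed
#'   from the extension when missing.
#' @return \code{path}, invisibly.
#' @export
write_ensemble <- function(ens, path, format = NULL) {
  stopifnot(inherits(ens, "conf_ensemble"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("pdb", "gro", "xyz"))
  switch(format,
         pdb = .write_pdb_frames(ens, path),
         gro = .write_gro_frames(ens, path),
         xyz = .write_xyz_frames(ens, path))
  invisible(path)
}

# residue-name field used to carry the group tag in PDB/GRO output
.tag_resname <- c(core = "COR", dendrimer = "DEN", RB = "RB",
                  water = "SOL", ion_Na = "NA", ion_Cl = "CL",
                  other = "OTH")

#' @keywords internal
.map_labels <- function(names, label_map) {
  if (is.null(label_map)) {
    # identity map over the writer's residue-name encoding
    label_map <- stats::setNames(names(.tag_resname), .tag_resname)
  }
  out <- unname(label_map[names])
  if (anyNA(out)) {
    if (".default" %in% names(label_map)) {
      out[is.na(out)] <- label_map[[".default"]]
    } else {
      stop("label_map does not cover name(s): ",
           paste(unique(names[is.na(out)]), collapse = ", "))
    }
  }
  out
}

# standard atomic masses (amu) for the elements these systems contain;
# unrecognized (bead) symbols default to 1
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, NA. = 22.990, CL = 35.45,
                    I = 126.904, K = 39.098)

#' @keywords internal
.element_masses <- function(element) {
  if (is.null(element)) return(NULL)
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- .atomic_masses[key]
  m[is.na(m)] <- 1
  unname(m)
}

#' @keywords internal
.read_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  n <- nrow(pdb$atom)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(n, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) * 0.1  # A -> nm
  elem <- pdb$atom$elesy
  if (all(is.na(elem)) || is.null(elem)) elem <- pdb$atom$elety
  list(coords = coords, names = pdb$atom$resid, element = elem, box = NULL)
}

#' @keywords internal
.write_pdb_frames <- function(ens, path) {
  n <- n_atoms(ens); nf <- n_frames(ens)
  xyz <- matrix(NA_real_, nf, 3L * n)
  for (f in seq_len(nf))
    xyz[f, ] <- as.vector(t(frame_coords(ens, f) * 10))  # nm -> A
  elem <- if (is.null(ens$element)) rep("C", n) else ens$element
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = seq_len(n), resid = .tag_resname[ens$labels],
                   elety = substr(elem, 1L, 4L), elesy = substr(elem, 1L, 2L))
}

#' @keywords internal
.read_gro_frames <- function(path) {
  lines <- readLines(path)
  frames <- list(); names <- NULL; elem <- NULL; boxes <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && (i == length(lines) ||
        !nzchar(trimws(lines[i + 1L])))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) stop("malformed GRO file: bad atom count at line ", i + 1L)
    if (i + 1L + n + 1L > length(lines))
      stop("malformed GRO file: truncated frame")
    body <- lines[(i + 2L):(i + 1L + n)]
    resnm <- trimws(substr(body, 6L, 10L))
    atomnm <- trimws(substr(body, 11L, 15L))
    x <- as.numeric(substr(body, 21L, 28L))
    y <- as.numeric(substr(body, 29L, 36L))
    z <- as.numeric(substr(body, 37L, 44L))
    if (anyNA(c(x, y, z))) stop("malformed GRO coordinates")
    if (is.null(names)) { names <- resnm; elem <- sub("[0-9]+$", "", atomnm) }
    else if (length(resnm) != length(names))
      stop("mixed atom counts across GRO frames")
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
    boxes[[length(boxes) + 1L]] <-
      as.numeric(strsplit(trimws(lines[i + n + 2L]), "\\s+")[[1L]])
    i <- i + n + 3L
  }
  coords <- array(unlist(frames), dim = c(length(names), 3L, length(frames)))
  list(coords = coords, names = names, element = elem, box = boxes)
}

#' @keywords internal
.write_gro_frames <- function(ens, path) {
  n <- n_atoms(ens)
  elem <- if (is.null(ens$element)) rep("X", n) else substr(ens$element, 1L, 5L)
  resnm <- .tag_resname[ens$labels]
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(n_frames(ens))) {
    xyz <- frame_coords(ens, f)
    writeLines(sprintf("dendricomplex ensemble, frame %d", f), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       seq_len(n) %% 100000L, resnm, elem,
                       seq_len(n) %% 100000L,
                       xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
    box <- if (!is.null(ens$box)) ens$box[[min(f, length(ens$box))]]
           else rep(0, 3L)
    writeLines(paste(sprintf("%10.5f", box[1:3]), collapse = ""), con)
  }
}

#' @keywords internal
.read_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list(); names <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ file: bad atom count at line ", i)
    if (i + 1L + n > length(lines)) stop("malformed XYZ file: truncated frame")
    body <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    sym <- vapply(body, `[`, "", 1L)
    xyz <- t(vapply(body, function(b) as.numeric(b[2:4]), numeric(3L)))
    if (anyNA(xyz)) stop("malformed XYZ coordinates")
    if (is.null(names)) names <- sym
    else if (length(sym) != length(names))
      stop("mixed atom counts across XYZ frames")
    frames[[length(frames) + 1L]] <- xyz * 0.1  # A -> nm
    i <- i + n + 2L
  }
  coords <- array(unlist(frames), dim = c(length(names), 3L, length(frames)))
  list(coords = coords, names = names, element = names, box = NULL)
}

#' @keywords internal
.write_xyz_frames <- function(ens, path) {
  n <- n_atoms(ens)
  # XYZ has a single symbol column: carry the group tag there so the
  # label partition round-trips (bead element names are not preserved)
  sym <- .tag_resname[ens$labels]
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(n_frames(ens))) {
    xyz <- frame_coords(ens, f) * 10  # nm -> A
    writeLines(as.character(n), con)
    writeLines(sprintf("frame %d", f), con)
    writeLines(sprintf("%-4s %14.8f %14.8f %14.8f",
                       sym, xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
  }
}
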