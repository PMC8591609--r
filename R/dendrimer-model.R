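#' Dendrimer specification
#'
#' Declare a dendrimer by family and generation. Generations follow the
#' convention used for the commercial polymers studied here: for both
#' families, generation 3 carries 32 terminal primary amines and
#' generation 4 carries 64 (terminal count doubles per generation,
#' \eqn{2^{g+2}}).
#'
#' @param family Character, \code{"PAMAM"} or \code{"PPI"}.
#' @param generation Integer generation number, >= 1.
#' @return An object of class \code{"dendrimer_spec"}.
#' @examples
#' dendrimer_spec("PPI", 4)
#' @export
dendrimer_spec <- function(family, generation) {
  family <- match.arg(toupper(family), c("PAMAM", "PPI"))
  if (length(generation) != 1L || !is.finite(generation) ||
      generation < 1 || generation != round(generation))
    stop("'generation' must be a single integer >= 1")
  structure(list(family = family, generation = as.integer(generation)),
            class = "dendrimer_spec")
}

#' @export
print.dendrimer_spec <- function(x, ...) {
  cat(sprintf("%s generation %d dendrimer\n", x$family, x$generation))
  invisible(x)
}

#' Build the layered amine topology of a dendrimer
#'
#' The dendrimer is modelled as concentric amine layers, indexed by depth
#' from the terminal surface (depth 0 = terminal primary amines). A
#' generation-g dendrimer has \eqn{2^{g+2}} terminal primaries and
#' interior tertiary layers halving in count toward the core
#' (\eqn{2^{g+1}, \ldots, 4, 2}). For PPI the deepest layer (count 2) is
#' the diaminobutane core; its two amines participate in the alternating
#' protonation pattern like any other interior layer. Protonation flags
#' are all unset; see \code{\link{assign_protonation}}.
#'
#' This is a layer-count model, not an atomistic structure: it exists to
#' compute formal charges under a neutral-pH protonation scheme, not to
#' generate coordinates (see \code{\link{gen_dendrimer_ensemble}} for
#' bead-model geometry).
#'
#' @param spec A \code{\link{dendrimer_spec}}, or a family string if
#'   \code{generation} is also given.
#' @param generation Optional generation when \code{spec} is a string.
#' @return An object of class \code{"dendrimer_topology"}: list with
#'   \code{spec}, \code{layers} (data frame: \code{depth},
#'   \code{amine_type}, \code{count}, \code{protonated}) ordered terminal
#'   to core, and \code{terminal_count}.
#' @examples
#' build_topology("PAMAM", 3)$terminal_count  # 32
#' build_topology("PPI", 4)$layers
#' @export
build_topology <- function(spec, generation = NULL) {
  if (!inherits(spec, "dendrimer_spec"))
    spec <- dendrimer_spec(spec, generation)
  g <- spec$generation
  # terminal layer + g+1 interior layers halving down to the 2-amine core
  counts <- as.integer(2^seq(g + 2L, 1L))
  depth <- seq_along(counts) - 1L
  # interior amines (including the two core amines, which are tertiary
  # once both branches are attached) are all tertiary
  amine_type <- c("primary", rep("tertiary", length(counts) - 1L))
  layers <- data.frame(depth = depth, amine_type = amine_type,
                       count = counts, protonated = FALSE,
                       stringsAsFactors = FALSE)
  structure(list(spec = spec, layers = layers,
                 terminal_count = counts[1L]),
            class = "dendrimer_topology")
}

#' Assign the neutral-pH protonation pattern
#'
#' At neutral pH the two families protonate differently. PAMAM: only the
#' terminal primary amines (depth 0) are protonated; interior tertiary
#' amines stay neutral. PPI: terminal primaries plus alternating interior
#' layers are protonated -- specifically the layers at even depth from the
#' terminal surface (0, 2, 4, ...). The even-depth alternation is the one
#' that reproduces the formal charges +42 (PPI G3) and +84 (PPI G4) and
#' amounts to protonating two-thirds of all amines.
#'
#' Repeated application is idempotent; applying it to a topology that is
#' already protonated raises a warning and returns the same pattern.
#'
#' @param topology A \code{"dendrimer_topology"}.
#' @return The topology with \code{layers$protonated} set.
#' @examples
#' net_charge(assign_protonation(build_topology("PPI", 3)))  # 42
#' @export
assign_protonation <- function(topology) {
  stopifnot(inherits(topology, "dendrimer_topology"))
  if (any(topology$layers$protonated))
    warning("topology already carries protonation flags; reassigning")
  fam <- topology$spec$family
  d <- topology$layers$depth
  topology$layers$protonated <- if (fam == "PAMAM") d == 0L else d %% 2L == 0L
  topology
}

#' Formal net charge of a protonated dendrimer topology
#'
#' Each protonated amine carries one elementary charge; the net charge is
#' the sum of counts over protonated layers. Returns 0 for an
#' unprotonated topology.
#'
#' @param topology A \code{"dendrimer_topology"}.
#' @return Integer net charge in elementary charges.
#' @examples
#' net_charge(assign_protonation(build_topology("PAMAM", 4)))  # 64
#' @export
net_charge <- function(topology) {
  stopifnot(inherits(topology, "dendrimer_topology"))
  sum(topology$layers$count[topology$layers$protonated])
}

#' @export
print.dendrimer_topology <- function(x, ...) {
  cat(sprintf("%s G%d topology: %d terminal primary amines, %d layers\n",
              x$spec$family, x$spec$generation, x$terminal_count,
              nrow(x$layers)))
  print(x$layers, row.names = FALSE)
  cat(sprintf("net charge: %+d e\n", net_charge(x)))
  invisible(x)
}

#' Serialize a topology to JSON
#'
#' @param topology A \code{"dendrimer_topology"}.
#' @param file Optional path; if \code{NULL} the JSON string is returned.
#' @return JSON string (invisibly, when writing to file).
#' @export
topology_to_json <- function(topology, file = NULL) {
  stopifnot(inherits(topology, "dendrimer_topology"))
  obj <- list(family = topology$spec$family,
              generation = topology$spec$generation,
              terminal_count = topology$terminal_count,
              layers = topology$layers,
              net_charge = net_charge(topology))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}
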