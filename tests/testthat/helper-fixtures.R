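# shared fixtures and independent oracles

# random rigid rotation matrix from a seed
random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# apply a rigid rotation + translation to every frame
transform_ensemble <- function(ens, rot = diag(3), shift = c(0, 0, 0)) {
  for (f in seq_len(n_frames(ens)))
    ens$coords[, , f] <- frame_coords(ens, f) %*% t(rot) +
      matrix(shift, n_atoms(ens), 3L, byrow = TRUE)
  ens
}

# independent brute-force radial density: plain loops, same binning rule
# as graphics::hist (right-closed bins, lowest bin closed on both sides)
brute_radial_density <- function(ens, selection, reference, edges) {
  nb <- length(edges) - 1L
  acc <- numeric(nb)
  nf <- n_frames(ens)
  for (f in seq_len(nf)) {
    ref <- center_of_mass(ens, reference, f)
    for (i in selection) {
      d <- sqrt(sum((ens$coords[i, , f] - ref)^2))
      if (d > edges[nb + 1L]) next
      for (b in seq_len(nb)) {
        lo_ok <- if (b == 1L) d >= edges[1L] else d > edges[b]
        if (lo_ok && d <= edges[b + 1L]) { acc[b] <- acc[b] + 1; break }
      }
    }
  }
  acc / nf / (4 / 3 * pi * diff(edges^3))
}

# independent exhaustive hydrogen-bond search (triple loop)
brute_hbonds <- function(ens, donors, acceptors, criteria) {
  hits <- 0L
  key <- character()
  for (f in seq_len(n_frames(ens))) {
    xyz <- frame_coords(ens, f)
    for (j in seq_len(nrow(donors))) {
      d <- donors[j, 1L]; h <- donors[j, 2L]
      for (a in acceptors) {
        if (a == d) next
        dda <- sqrt(sum((xyz[a, ] - xyz[d, ])^2))
        if (dda > criteria$max_distance) next
        vdh <- xyz[h, ] - xyz[d, ]; vda <- xyz[a, ] - xyz[d, ]
        ang <- acos(min(1, max(-1, sum(vdh * vda) /
                                 sqrt(sum(vdh^2) * sum(vda^2))))) * 180 / pi
        if (ang <= criteria$max_angle) {
          hits <- hits + 1L
          key <- c(key, paste(f, d, a, sep = ":"))
        }
      }
    }
  }
  list(n = hits, key = sort(key))
}

# small labelled ensemble for selection / center-of-mass tests
make_simple_ensemble <- function() {
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0), c(0, 0, 3), c(1, 1, 1))
  conf_ensemble(xyz, masses = c(1, 1, 2, 3, 1),
                labels = c("core", "dendrimer", "dendrimer", "RB", "water"))
}
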