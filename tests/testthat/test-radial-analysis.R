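test_that("a single fixed particle lands in its shell at 1/V_shell density", {
  xyz <- rbind(c(0, 0, 0), c(1.0, 0, 0))
  ens <- conf_ensemble(xyz, labels = c("core", "RB"))
  prof <- radial_density(ens, select_atoms(ens, "RB"), bin_width = 0.1,
                         r_max = 2)
  b <- findInterval(1.0, prof$edges, left.open = TRUE)
  expect_equal(sum(prof$counts), 1)
  vshell <- 4 / 3 * pi * (prof$edges[b + 1]^3 - prof$edges[b]^3)
  expect_equal(prof$density[b], 1 / vshell)
  expect_true(all(prof$density[-b] == 0))
})

test_that("count conservation holds to 1e-6 relative on varied systems", {
  systems <- list(
    gen_complex_ensemble(gen_dendrimer_ensemble(build_topology("PPI", 3),
                                                n_frames = 4L, seed = 71),
                         seed = 72),
    gen_reference_solids("solid_ball", list(n = 2000L), n_frames = 3L,
                         seed = 73),
    gen_reference_solids("isotropic_cloud", list(n = 500L), n_frames = 2L,
                         seed = 74))
  for (ens in systems) {
    sel <- select_atoms(ens, setdiff(unique(ens$labels), "core"))
    prof <- radial_density(ens, sel, bin_width = 0.07)
    vshell <- 4 / 3 * pi * diff(prof$edges^3)
    expect_equal(sum(prof$density * vshell), prof$mean_n,
                 tolerance = 1e-6)
    expect_true(all(prof$density >= 0))
    expect_true(all(diff(prof$edges) > 0))
  }
})

test_that("uniform points in a spherical annulus give a flat density", {
  set.seed(81)
  n <- 100000L
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- (runif(n, 2^3, 3^3))^(1 / 3)   # uniform in volume over [2, 3]
  ens <- conf_ensemble(rbind(0, u * r),
                       labels = c("core", rep("water", n)))
  prof <- radial_density(ens, select_atoms(ens, "water"), bin_width = 0.1,
                         r_max = 3.2)
  inside <- prof$mid > 2.05 & prof$mid < 2.95
  expected <- n / (4 / 3 * pi * (27 - 8))
  expect_true(all(abs(prof$density[inside] / expected - 1) < 0.03))
})

test_that("binned density agrees with a brute-force loop to 1e-12", {
  ens <- gen_complex_ensemble(
    gen_dendrimer_ensemble(build_topology("PAMAM", 3), n_frames = 6L,
                           seed = 91), depth = "surface", seed = 92)
  sel <- select_atoms(ens, "RB")
  ref <- select_atoms(ens, "core")
  prof <- radial_density(ens, sel, bin_width = 0.15, r_max = 5)
  brute <- brute_radial_density(ens, sel, ref, prof$edges)
  expect_equal(prof$density, brute, tolerance = 1e-12)
})

test_that("g(r) is about 1 for a homogeneous cloud and rescales the density exactly", {
  set.seed(101)
  n <- 30000L
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- u * 3 * runif(n)^(1 / 3)
  ens <- conf_ensemble(rbind(0, pts), labels = c("core", rep("water", n)))
  bulk <- n / (4 / 3 * pi * 27)
  prof <- rdf(ens, select_atoms(ens, "water"), bin_width = 0.25, r_max = 3,
              bulk_density = bulk)
  mid_region <- prof$mid > 1 & prof$mid < 2.8
  expect_true(all(abs(prof$g[mid_region] - 1) < 0.1))
  expect_equal(prof$g * prof$reference_density, prof$density,
               tolerance = 1e-12)
  expect_equal(prof$reference_mode, "supplied_bulk")
  # default reference: mean density over the sampled sphere
  prof2 <- rdf(ens, select_atoms(ens, "water"), bin_width = 0.25, r_max = 3)
  expect_equal(prof2$reference_density, prof2$mean_n / (4 / 3 * pi * 27),
               tolerance = 1e-12)
})

test_that("internalization fraction counts mass inside a radius", {
  base <- gen_dendrimer_ensemble(build_topology("PPI", 3),
                                 target_rog = 1.284, stiffness = 40,
                                 n_frames = 10L, seed = 111)
  rog <- mean(radius_of_gyration(base))
  inside <- gen_complex_ensemble(base, depth = "internal", seed = 112)
  pin <- rdf(inside, select_atoms(inside, "RB"), r_max = 5)
  expect_equal(internalization_fraction(pin, 5), 1)
  outside <- gen_complex_ensemble(base, depth = 3.0, radial_sd = 0.05,
                                  seed = 113)
  pout <- rdf(outside, select_atoms(outside, "RB"), r_max = 8)
  expect_equal(internalization_fraction(pout, rog), 0)
  # half inside by construction: two fixed ligands at r = 0.5 and 2.0
  xyz <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(2, 0, 0))
  e2 <- conf_ensemble(xyz, labels = c("core", "RB", "RB"))
  p2 <- radial_density(e2, 2:3, bin_width = 0.1, r_max = 3)
  expect_equal(internalization_fraction(p2, 1.0), 0.5, tolerance = 0.1)
  expect_error(internalization_fraction(p2, 99), "support")
})
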