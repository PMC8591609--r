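test_that("generators are seed-deterministic and record their truth", {
  s1 <- gen_titration(26, noise_sd = 1, seed = 7)
  s2 <- gen_titration(26, noise_sd = 1, seed = 7)
  expect_identical(s1$y, s2$y)
  expect_equal(s1$meta$n_true, 26)
  s3 <- gen_titration(26, noise_sd = 1, seed = 8)
  expect_false(identical(s1$y, s3$y))

  e1 <- gen_dendrimer_ensemble(build_topology("PPI", 3), n_frames = 4L,
                               seed = 9)
  e2 <- gen_dendrimer_ensemble(build_topology("PPI", 3), n_frames = 4L,
                               seed = 9)
  expect_identical(e1$coords, e2$coords)
  expect_equal(e1$meta$seed, 9)
})

test_that("titration generator honours its contracts", {
  s <- gen_titration(26, noise_sd = 0, seed = 1)
  expect_equal(job_stoichiometry(s)$n, 26, tolerance = 1e-9)
  expect_error(gen_titration(60, ratios = 1:50, seed = 1), "span")
  expect_warning(flat <- gen_titration(25, initial = -30, plateau = -30,
                                       noise_sd = 0, seed = 1), "flat")
  expect_true(flat$meta$degenerate)
  expect_error(gen_titration(25, noise_sd = -1, seed = 1), ">= 0")
})

test_that("bead ensembles hit the target size and stiffness controls spread", {
  ens <- gen_dendrimer_ensemble(build_topology("PPI", 3),
                                target_rog = 1.284, stiffness = 40,
                                n_frames = 30L, seed = 10)
  rog <- radius_of_gyration(ens)
  expect_equal(mean(rog), 1.284, tolerance = 0.02)
  # one core bead + one bead per amine of the layer model
  expect_equal(n_atoms(ens), 1L + 62L)

  rigid <- gen_dendrimer_ensemble(build_topology("PPI", 3),
                                  target_rog = 1.284, stiffness = 60,
                                  n_frames = 30L, seed = 11)
  floppy <- gen_dendrimer_ensemble(build_topology("PAMAM", 3),
                                   target_rog = 1.46, stiffness = 5,
                                   n_frames = 30L, seed = 11)
  expect_lt(sd(radius_of_gyration(rigid)) / 1.284,
            sd(radius_of_gyration(floppy)) / 1.46)

  frozen <- gen_dendrimer_ensemble(build_topology("PPI", 3),
                                   stiffness = Inf, n_frames = 5L,
                                   seed = 12)
  expect_equal(sd(radius_of_gyration(frozen)), 0)
  expect_identical(frozen$coords[, , 1], frozen$coords[, , 5])
  expect_error(gen_dendrimer_ensemble(build_topology("PPI", 3),
                                      segment = -1), "positive")
})

test_that("ligand placement depth controls internalization", {
  base <- gen_dendrimer_ensemble(build_topology("PPI", 3),
                                 target_rog = 1.284, stiffness = 40,
                                 n_frames = 12L, seed = 13)
  rog <- mean(radius_of_gyration(base))
  internal <- gen_complex_ensemble(base, depth = "internal", seed = 14)
  fin <- internalization_fraction(
    rdf(internal, select_atoms(internal, "RB"), r_max = 6), rog)
  expect_gt(fin, 0.8)
  surface <- gen_complex_ensemble(base, depth = "surface", seed = 15)
  fsur <- internalization_fraction(
    rdf(surface, select_atoms(surface, "RB"), r_max = 6), rog)
  expect_lt(fsur, 0.2)
  expect_error(gen_complex_ensemble(base, n_ligands = 0L), "positive")
})

test_that("spectra generator spans the free and bound band limits", {
  specs <- gen_spectra_series(ratios = c(1, 100), n_sat = 10, seed = 16)
  expect_equal(peak_wavelength(specs[[1]]), 575, tolerance = 1)   # saturated
  expect_equal(peak_wavelength(specs[[2]]), 564, tolerance = 1)   # mostly free
  expect_error(gen_spectra_series(1:5, free_peak = 400), "within")
  expect_error(gen_spectra_series(1:5, quench_depth = 2), "quench")
})

test_that("reference solids match their analytic descriptors", {
  ball <- gen_reference_solids("solid_ball", list(n = 50000L, radius = 1.5),
                               seed = 17)
  expect_equal(mean(radius_of_gyration(ball, select_atoms(ball, "dendrimer"))),
               sqrt(3 / 5) * 1.5, tolerance = 0.01)
  rod <- gen_reference_solids("rod", list(n = 10000L), seed = 18)
  expect_equal(suppressWarnings(inertia_descriptors(rod))$delta, 0.25,
               tolerance = 1e-5)
  shell <- gen_reference_solids("hollow_shell", seed = 19)
  xyz <- frame_coords(shell, 1)[-1, ]
  expect_equal(unname(sqrt(rowSums(xyz^2))), rep(1.5, nrow(xyz)),
               tolerance = 1e-12)
  expect_equal(shell$meta$kind, "hollow_shell")
})

test_that("planted hydrogen-bond systems encode their truth", {
  sys <- gen_hbond_system(n_frames = 3L, k = 4L, seed = 20)
  expect_equal(sys$ensemble$meta$k_planted, 4L)
  expect_equal(nrow(sys$donors), 4L)
  # every planted geometry is inside the default criteria by construction
  rec <- find_hbonds(sys$ensemble, sys$donors, sys$acceptors)
  expect_equal(nrow(rec), 3L * 4L)
})
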