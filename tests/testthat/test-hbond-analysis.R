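test_that("a collinear contact inside both cutoffs is one bond; bent is none", {
  # N-H...O, d(N,O) = 0.29 nm, perfectly linear
  xyz <- rbind(c(0, 0, 0),            # core marker
               c(0, 0, 0.5),          # donor N
               c(0.10, 0, 0.5),       # H along +x
               c(0.29, 0, 0.5))       # acceptor O on the same axis
  ens <- conf_ensemble(xyz, labels = c("core", rep("dendrimer", 3)))
  donors <- cbind(2L, 3L)
  rec <- find_hbonds(ens, donors, acceptors = 4L)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$distance, 0.29)
  expect_equal(rec$angle, 0, tolerance = 1e-8)
  expect_equal(rec$class, "internal")

  # same distance, hydrogen bent 60 degrees off the donor-acceptor axis
  bent <- xyz
  bent[3, ] <- c(0.10 * cos(pi / 3), 0.10 * sin(pi / 3), 0.5)
  ens2 <- conf_ensemble(bent, labels = ens$labels)
  expect_equal(nrow(find_hbonds(ens2, donors, acceptors = 4L)), 0L)
})

test_that("criteria validation and donor-list consistency are enforced", {
  expect_error(hbond_criteria(max_distance = -1), "positive")
  expect_error(hbond_criteria(max_angle = 120), "90")
  xyz <- rbind(c(0, 0, 0), c(0, 0, 1), c(1, 1, 1), c(0.29, 0, 1))
  ens <- conf_ensemble(xyz, labels = c("core", rep("dendrimer", 3)))
  # "hydrogen" 1.7 nm from its donor: inconsistent list
  expect_error(find_hbonds(ens, cbind(2L, 3L), 4L), "not bonded")
})

test_that("vectorized detection matches the exhaustive triple loop", {
  set.seed(121)
  for (rep in 1:3) {
    n <- 60L
    nf <- 20L
    coords <- array(runif(n * 3 * nf, 0, 1.5), dim = c(n, 3L, nf))
    labels <- c("core", sample(c("dendrimer", "water", "RB"), n - 1L,
                               replace = TRUE))
    donor_heavy <- seq(2L, 20L, by = 2L)
    hyd <- donor_heavy + 1L
    # pin each hydrogen near its donor so the list is consistent
    for (f in seq_len(nf))
      coords[hyd, , f] <- coords[donor_heavy, , f] +
        matrix(rnorm(length(hyd) * 3, sd = 0.03), ncol = 3)
    ens <- conf_ensemble(coords, labels = labels)
    donors <- cbind(donor_heavy, hyd)
    acceptors <- seq(21L, n, by = 2L)
    crit <- hbond_criteria(0.35, 30)
    rec <- find_hbonds(ens, donors, acceptors, crit)
    brute <- brute_hbonds(ens, donors, acceptors, crit)
    expect_equal(nrow(rec), brute$n)
    expect_equal(sort(paste(rec$frame, rec$donor, rec$acceptor, sep = ":")),
                 brute$key)
  }
})

test_that("loosening either cutoff never decreases the count", {
  set.seed(131)
  n <- 40L
  coords <- array(runif(n * 3 * 10L, 0, 1.2), dim = c(n, 3L, 10L))
  dh <- seq(2L, 12L, by = 2L)
  for (f in 1:10)
    coords[dh + 1L, , f] <- coords[dh, , f] +
      matrix(rnorm(length(dh) * 3, sd = 0.03), ncol = 3)
  ens <- conf_ensemble(coords, labels = c("core",
                                          rep(c("dendrimer", "water"),
                                              length.out = n - 1L)))
  donors <- cbind(dh, dh + 1L)
  acceptors <- 14:40
  counts <- sapply(c(0.25, 0.30, 0.35, 0.45), function(d)
    nrow(find_hbonds(ens, donors, acceptors, hbond_criteria(d, 30))))
  expect_true(all(diff(counts) >= 0))
  counts_a <- sapply(c(10, 20, 30, 60, 90), function(a)
    nrow(find_hbonds(ens, donors, acceptors, hbond_criteria(0.35, a))))
  expect_true(all(diff(counts_a) >= 0))
})

test_that("class labels are disjoint and sum to the total", {
  sys <- gen_hbond_system(n_frames = 8L, k = 6L, seed = 141)
  rec <- find_hbonds(sys$ensemble, sys$donors, sys$acceptors)
  expect_true(all(rec$class %in% c("internal", "with_water", "with_RB")))
  summ <- hbond_count_summary(rec)
  expect_equal(sum(summ$mean), nrow(rec) / 8)
})

test_that("planted contacts are recovered exactly, frame by frame", {
  for (k in c(1L, 5L, 12L)) {
    sys <- gen_hbond_system(n_frames = 10L, k = k, seed = 150 + k)
    rec <- find_hbonds(sys$ensemble, sys$donors, sys$acceptors)
    summ <- hbond_count_summary(rec)
    expect_equal(summ$mean[summ$class == "internal"], k)
    expect_equal(summ$sd[summ$class == "internal"], 0)
  }
})

test_that("count summaries use the stated SD convention", {
  # two frames with 3 and 5 internal bonds
  sys3 <- gen_hbond_system(n_frames = 1L, k = 3L, seed = 161)
  sys5 <- gen_hbond_system(n_frames = 1L, k = 5L, seed = 161)
  rec3 <- find_hbonds(sys3$ensemble, sys3$donors, sys3$acceptors)
  rec5 <- find_hbonds(sys5$ensemble, sys5$donors, sys5$acceptors)
  rec5$frame <- 2L
  both <- rbind(as.data.frame(rec3), as.data.frame(rec5))
  attr(both, "frames") <- 1:2
  summ <- hbond_count_summary(both, n_frames = 2L)
  expect_equal(summ$mean[summ$class == "internal"], 4)
  expect_equal(summ$sd[summ$class == "internal"], sd(c(3, 5)))
  expect_equal(attr(summ, "sd_convention"), "sample")
  # empty records give 0 +/- 0
  empty <- find_hbonds(sys3$ensemble, sys3$donors, sys3$acceptors,
                       hbond_criteria(0.01, 1))
  s0 <- hbond_count_summary(empty)
  expect_true(all(s0$mean == 0) && all(s0$sd == 0))
  expect_error(hbond_count_summary(empty, n_frames = 0L), "positive")
})
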