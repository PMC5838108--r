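test_that("profile and z statistics agree with brute-force oracles on random datasets", {
  for (seed in 201:230) {
    ds <- random_dataset(seed, max_subjects = 6L, max_nodes = 5L)
    m <- ds$metric_names[1]
    tr <- ds$tract_names[1]
    mat <- value_matrix(ds, m, tr)
    ps <- group_profile(ds, tr, m, ds$subject_ids)
    o <- oracle_profile(mat)
    expect_equal(ps$mean, o$mean, tolerance = 1e-10)
    expect_equal(ps$sd, o$sd, tolerance = 1e-10)
    expect_equal(ps$se, o$se, tolerance = 1e-10)
    expect_identical(ps$n, o$n)

    subj <- ds$subject_ids[1]
    ref <- ds$subject_ids[-1]
    oz <- oracle_z(mat[1, ], mat[-1, , drop = FALSE])
    if (!all(is.na(oz))) {
      zp <- suppressWarnings(subject_zscores(ds, subj, tr, m, ref))
      expect_equal(zp$z, oz, tolerance = 1e-10)
      pk <- summarize_z(zp, how = "peak")
      opk <- oracle_peak(oz)
      expect_equal(pk$value, opk$value, tolerance = 1e-10)
      expect_identical(pk$node, opk$node)
      expect_equal(summarize_z(zp, how = "mean")$value, oracle_mean_z(oz),
                   tolerance = 1e-10)
    }
  }
})

test_that("leave-self-in z-profiles of reference members average to exactly zero", {
  ds <- random_dataset(301, na_frac = 0)
  m <- ds$metric_names[1]; tr <- ds$tract_names[1]
  zs <- sapply(ds$subject_ids, function(s) {
    subject_zscores(ds, s, tr, m, ds$subject_ids, exclude_self = FALSE)$z
  })
  expect_equal(rowMeans(zs), rep(0, ds$n_nodes), tolerance = 1e-12)
  # and leave-self-out z-profiles average approximately to zero
  zs_loo <- sapply(ds$subject_ids, function(s) {
    subject_zscores(ds, s, tr, m, ds$subject_ids)$z
  })
  expect_lt(max(abs(rowMeans(zs_loo))), 0.5)
})

test_that("z-profiles are invariant under affine rescaling of the metric", {
  for (seed in 401:420) {
    ds <- random_dataset(seed)
    m <- ds$metric_names[1]; tr <- ds$tract_names[1]
    set.seed(seed + 5000)
    a <- stats::runif(1, 0.1, 10); b <- stats::runif(1, -5, 5)
    ds2 <- tractometry:::set_value_matrix(
      ds, m, tr, a * value_matrix(ds, m, tr) + b)
    z1 <- suppressWarnings(
      subject_zscores(ds, ds$subject_ids[1], tr, m, ds$subject_ids))
    z2 <- suppressWarnings(
      subject_zscores(ds2, ds$subject_ids[1], tr, m, ds$subject_ids))
    expect_equal(z1$z, z2$z, tolerance = 1e-10)
  }
})

test_that("the deviant fraction is non-increasing in the threshold", {
  for (seed in 501:510) {
    set.seed(seed)
    n_ctrl <- 12; n_pat <- 5; n_nodes <- 12
    mat <- matrix(stats::rnorm((n_ctrl + n_pat) * n_nodes, 0.5, 0.05),
                  n_ctrl + n_pat, n_nodes)
    ids <- c(sprintf("c%02d", seq_len(n_ctrl)),
             sprintf("p%02d", seq_len(n_pat)))
    ds <- tractometry_dataset(ids, "t", "fa", n_nodes,
                              values = list(fa = list(t = mat)))
    fracs <- vapply(c(0, 0.5, 1, 1.5, 2, 3, 5), function(thr) {
      as.numeric(fraction_deviant(ds, ids[(n_ctrl + 1):(n_ctrl + n_pat)],
                                  ids[1:n_ctrl], "t", "fa", thr))
    }, numeric(1))
    expect_true(all(diff(fracs) <= 0))
    expect_true(all(fracs >= 0 & fracs <= 1))
  }
})
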