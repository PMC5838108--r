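test_that("group_profile matches hand-computed sample statistics", {
  ds <- tiny_profile_dataset()
  ps <- group_profile(ds, "tract1", "fa", c("s1", "s2", "s3"))
  expect_equal(ps$mean, c(0.5, 0.6, 0.7, 0.6))
  expect_equal(ps$sd, rep(0.1, 4))
  expect_equal(ps$se, rep(0.1 / sqrt(3), 4))
  expect_identical(ps$n, rep(3L, 4))
})

test_that("single-member groups have a mean but no dispersion", {
  ds <- tiny_profile_dataset()
  ps <- group_profile(ds, "tract1", "fa", "s2")
  expect_equal(ps$mean, c(0.5, 0.6, 0.7, 0.6))
  expect_true(all(is.na(ps$sd)))
  expect_true(all(is.na(ps$se)))
})

test_that("missing member cells reduce per-node n and are excluded from the stats", {
  ds <- tiny_profile_dataset()
  mat <- value_matrix(ds, "fa", "tract1")
  mat[1, 3] <- NA  # s1, node 2
  ds <- tractometry:::set_value_matrix(ds, "fa", "tract1", mat)
  ps <- group_profile(ds, "tract1", "fa", c("s1", "s2", "s3"))
  expect_identical(ps$n, c(3L, 3L, 2L, 3L))
  o <- oracle_profile(mat)
  expect_equal(ps$mean, o$mean)
  expect_equal(ps$sd, o$sd)
  expect_error(group_profile(ds, "tract1", "fa", character(0)), "empty")
  expect_error(group_profile(ds, "nope", "fa", "s1"), "unknown tract")
})

test_that("subject z-scores reproduce the (x - mean) / sd oracle", {
  ds <- tiny_profile_dataset()
  mat <- rbind(value_matrix(ds, "fa", "tract1"), c(0.5, 0.6, 1.0, 0.6))
  ds2 <- tractometry_dataset(
    c("s1", "s2", "s3", "patient"), "tract1", "fa", 4,
    values = list(fa = list(tract1 = mat)))
  zp <- subject_zscores(ds2, "patient", "tract1", "fa",
                        reference = c("s1", "s2", "s3"))
  expect_equal(zp$z, c(0, 0, 3, 0))
  expect_identical(zp$ref_n, rep(3L, 4))
  # identical to reference mean -> all-zero z
  mid <- tractometry_dataset(
    c("s1", "s2", "s3", "mid"), "tract1", "fa", 4,
    values = list(fa = list(
      tract1 = rbind(value_matrix(ds, "fa", "tract1"),
                     c(0.5, 0.6, 0.7, 0.6)))))
  expect_equal(subject_zscores(mid, "mid", "tract1", "fa",
                               c("s1", "s2", "s3"))$z, rep(0, 4))
})

test_that("self-exclusion is the default and degenerate reference SD warns", {
  ds <- tiny_profile_dataset()
  # with self-exclusion, s1 is scored against {s2, s3} only
  zp <- subject_zscores(ds, "s1", "tract1", "fa", ds$subject_ids)
  ref <- group_profile(ds, "tract1", "fa", c("s2", "s3"))
  expect_equal(zp$z, (value_matrix(ds, "fa", "tract1")[1, ] - ref$mean) /
                 ref$sd)
  expect_error(subject_zscores(ds, "s1", "tract1", "fa", "s1"),
               "empty")
  # zero reference SD -> missing z with warning
  flat <- tractometry_dataset(
    c("a", "b", "c"), "t", "fa", 2,
    values = list(fa = list(t = rbind(c(0.5, 0.4), c(0.5, 0.5),
                                      c(0.5, 0.6)))))
  expect_warning(zz <- subject_zscores(flat, "a", "t", "fa", c("b", "c")),
                 "SD is zero")
  expect_true(is.na(zz$z[1]))
  expect_false(is.na(zz$z[2]))
})

test_that("summarize_z peak takes the signed value at max |z|, lowest node on ties", {
  zp <- structure(list(subject = "p", tract = "t", metric = "fa",
                       label = "ref", ref_n = rep(3L, 4),
                       z = c(0, 0, 3, 0)), class = "z_profile")
  pk <- summarize_z(zp, how = "peak")
  expect_equal(pk$value, 3)
  expect_identical(pk$node, 2L)

  zp$z <- c(-4, 1, 2, NA)
  pk <- summarize_z(zp, how = "peak")
  expect_equal(pk$value, -4)
  expect_identical(pk$node, 0L)

  zp$z <- c(2, -2, 2, -2)  # tie on |z| -> node 0
  expect_identical(summarize_z(zp, how = "peak")$node, 0L)

  zp$z <- rep(1.25, 4)
  expect_equal(summarize_z(zp, how = "mean")$value, 1.25)
  expect_equal(summarize_z(zp, range = node_range(1, 2), how = "peak")$node,
               1L)
  zp$z <- c(1, NA, NA, 1)
  expect_error(summarize_z(zp, range = node_range(1, 2)), "non-missing")
})

test_that("fraction_deviant counts strict threshold exceedance within the range", {
  # 4 patients, exactly 3 with an in-range |z| > 1
  set.seed(55)
  n_nodes <- 10
  ctrl <- matrix(stats::rnorm(30 * n_nodes, 0.5, 0.05), 30, n_nodes)
  pat <- rbind(
    ctrl[1, ] + 0.3,   # clearly deviant everywhere (not a control row below)
    c(rep(0.5, 5), 0.8, rep(0.5, 4)),
    c(rep(0.5, 9), 0.9),
    rep(0.5, n_nodes))  # on the mean -> not deviant
  ids <- c(sprintf("c%02d", 1:30), sprintf("p%d", 1:4))
  ds <- tractometry_dataset(
    ids, "t", "fa", n_nodes,
    values = list(fa = list(t = rbind(ctrl, pat))))
  patients <- sprintf("p%d", 1:4)
  controls <- sprintf("c%02d", 1:30)
  frac <- fraction_deviant(ds, patients, controls, "t", "fa", threshold = 1)
  expect_equal(as.numeric(frac), 0.75)
  expect_equal(as.numeric(frac),
               oracle_fraction_deviant(ds, patients, controls, "t", "fa",
                                       1, 0, n_nodes - 1))
  # degenerate threshold 0: everyone with any nonzero z is deviant
  expect_equal(as.numeric(
    fraction_deviant(ds, patients, controls, "t", "fa", 0)), 1)
  # one-sided: all-negative deviations never trip direction = "positive"
  neg <- tractometry_dataset(
    c("c1", "c2", "c3", "p"), "t", "fa", 3,
    values = list(fa = list(t = rbind(c(0.4, 0.5, 0.6), c(0.5, 0.6, 0.7),
                                      c(0.6, 0.7, 0.8), c(0.1, 0.2, 0.3)))))
  expect_equal(as.numeric(
    fraction_deviant(neg, "p", c("c1", "c2", "c3"), "t", "fa", 1,
                     direction = "positive")), 0)
  expect_equal(as.numeric(
    fraction_deviant(neg, "p", c("c1", "c2", "c3"), "t", "fa", 1,
                     direction = "negative")), 1)
  expect_error(
    fraction_deviant(ds, patients, c(controls, "p1"), "t", "fa", 1),
    "overlap")
})

test_that("compare_groups returns one summary per group in index order", {
  ds <- generate_dataset(synthetic_spec(n_subjects = 10, seed = 9,
                                        n_nodes = 20,
                                        tract_names = "Left CST",
                                        metric_names = "fa"))
  ga <- bin_subjects(ds, "age", 2, method = "quantile")
  out <- compare_groups(ds, ga, "Left CST", "fa")
  expect_length(out, 2L)
  expect_identical(names(out), ga$labels)
  expect_true(all(out[[1]]$n <= 5L), all(out[[2]]$n <= 5L))
  # single bin == group_profile over all assigned
  g1 <- bin_subjects(ds, "age", 1, method = "quantile")
  all_members <- group_members(g1, 0L)
  expect_equal(compare_groups(ds, g1, "Left CST", "fa")[[1]]$mean,
               group_profile(ds, "Left CST", "fa", all_members)$mean)
})

test_that("an injected group shift is recovered by the group summaries", {
  spec <- synthetic_spec(
    n_subjects = 200, n_nodes = 100, seed = 77,
    tract_names = "Left CST", metric_names = "fa",
    metadata = list(group = list(dist = "categorical",
                                 levels = c("ctl", "pat"))),
    effects = list(list(metric = "fa", tract = "Left CST",
                        window = c(40, 60), delta = 0.3,
                        column = "group", level = "pat")))
  ds <- generate_dataset(spec)
  ga <- bin_subjects(ds, "group", method = "categorical")
  out <- compare_groups(ds, ga, "Left CST", "fa")
  diff_mean <- out[["pat"]]$mean - out[["ctl"]]$mean
  pooled_se <- sqrt(out[["pat"]]$se^2 + out[["ctl"]]$se^2)
  inside <- 41:61    # 1-based columns of window 40..60
  expect_true(all(abs(diff_mean[inside] - 0.3) < 3 * pooled_se[inside]))
  expect_true(all(abs(diff_mean[-inside]) < 4 * pooled_se[-inside]))
})

test_that("brush masks cover the inclusive union of ranges", {
  expect_identical(sum(brush_mask(100, list(node_range(50, 80)))), 31L)
  expect_identical(sum(brush_mask(100, list())), 0L)
  expect_identical(sum(brush_mask(10, list(node_range(0, 5),
                                           node_range(3, 9)))), 10L)
  m <- brush_mask(10, list(node_range(2, 4)))
  expect_identical(which(m) - 1L, 2:4)
  expect_error(brush_mask(10, list(node_range(5, 12))), "exceeds")
  expect_error(node_range(4, 2), "invalid")
})
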