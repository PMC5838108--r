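test_that("the noise-free limit reproduces the mean profile exactly", {
  spec <- synthetic_spec(n_subjects = 4, seed = 61, n_nodes = 50,
                         tract_names = "Left CST", metric_names = "fa",
                         tau = 0, sigma = 0)
  ds <- generate_dataset(spec)
  mu <- tractometry:::mean_profile(spec, "fa", "Left CST")
  mat <- value_matrix(ds, "fa", "Left CST")
  for (i in 1:4) expect_equal(mat[i, ], mu)
})

test_that("generation is deterministic in the seed", {
  spec <- synthetic_spec(n_subjects = 6, seed = 62, n_nodes = 30)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_dataset_equal(d1, d2)
  d3 <- generate_dataset(synthetic_spec(n_subjects = 6, seed = 63,
                                        n_nodes = 30))
  expect_false(isTRUE(all.equal(value_matrix(d1, "fa", d1$tract_names[1]),
                                value_matrix(d3, "fa", d3$tract_names[1]))))
})

test_that("a large-n group effect is recovered at the injected amplitude", {
  spec <- synthetic_spec(
    n_subjects = 400, seed = 64, n_nodes = 100,
    tract_names = "Left CST", metric_names = "fa",
    metadata = list(group = list(dist = "categorical",
                                 levels = c("ctl", "pat"))),
    effects = list(list(metric = "fa", tract = "Left CST",
                        window = c(40, 60), delta = 0.3,
                        column = "group", level = "pat")))
  ds <- generate_dataset(spec)
  ga <- bin_subjects(ds, "group", method = "categorical")
  out <- compare_groups(ds, ga, "Left CST", "fa")
  d <- out[["pat"]]$mean - out[["ctl"]]$mean
  se <- sqrt(out[["pat"]]$se^2 + out[["ctl"]]$se^2)
  expect_true(all(abs(d[41:61] - 0.3) < 3 * se[41:61]))
  expect_true(all(abs(d[-(41:61)]) < 4 * se[-(41:61)]))
})

test_that("node noise has the requested AR(1) lag-1 autocorrelation", {
  eps <- tractometry:::ar1_noise(1L, 10000L, sigma = 1, rho = 0.7)[1, ]
  r1 <- stats::cor(eps[-1], eps[-length(eps)])
  expect_lt(abs(r1 - 0.7), 0.05)
  expect_lt(abs(stats::sd(eps) - 1), 0.05)
  white <- tractometry:::ar1_noise(1L, 10000L, sigma = 1, rho = 0)[1, ]
  expect_lt(abs(stats::cor(white[-1], white[-length(white)])), 0.05)
})

test_that("lesion injection honours amplitude, width and sign", {
  spec <- synthetic_spec(n_subjects = 31, seed = 65, n_nodes = 100,
                         tract_names = "Left ILF",
                         metric_names = c("fa", "md"))
  ds <- generate_dataset(spec)
  patient <- ds$subject_ids[31]
  controls <- ds$subject_ids[1:30]

  # A = 0 leaves the dataset untouched
  les0 <- lesion_spec(patient, "Left ILF", "md", center = 50, width = 3,
                      amplitude = 0)
  expect_dataset_equal(inject_lesion(ds, les0, controls), ds)

  # near-zero width changes essentially only the center node; z there ~ A
  les <- lesion_spec(patient, "Left ILF", "md", center = 50, width = 0.1,
                     amplitude = 5)
  ds2 <- inject_lesion(ds, les, controls)
  delta <- value_matrix(ds2, "md", "Left ILF")[31, ] -
    value_matrix(ds, "md", "Left ILF")[31, ]
  sd_c <- group_profile(ds, "Left ILF", "md", controls)$sd
  expect_equal(delta[51], 5 * sd_c[51], tolerance = 1e-12)
  expect_true(all(abs(delta[-51]) < 1e-8))
  z <- subject_zscores(ds2, patient, "Left ILF", "md", controls)$z
  expect_gt(z[51], 3.5)

  # negative sign on FA drives the center z negative
  lesn <- lesion_spec(patient, "Left ILF", "fa", center = 40, width = 2,
                      amplitude = 3, sign = -1)
  ds3 <- inject_lesion(ds, lesn, controls)
  zf <- subject_zscores(ds3, patient, "Left ILF", "fa", controls)$z
  expect_lt(zf[41], 0)
})

test_that("invalid specs are rejected up front", {
  expect_error(synthetic_spec(rho = 1), "rho")
  expect_error(synthetic_spec(tau = -1), "tau")
  expect_error(synthetic_spec(metric_names = "qspace"), "baseline")
  expect_error(
    synthetic_spec(effects = list(list(metric = "fa", tract = "nope",
                                       window = c(0, 5), delta = 1,
                                       column = "g", level = "x"))),
    "unknown tract")
  expect_error(lesion_spec("s", "t", "fa", 10, width = 0, amplitude = 1),
               "width")
})
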