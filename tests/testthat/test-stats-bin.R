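ages_dataset <- function(ages, ids = sprintf("s%02d", seq_along(ages)),
                         extra = NULL) {
  n <- length(ages)
  meta <- data.frame(subjectID = ids, age = ages, stringsAsFactors = FALSE)
  if (!is.null(extra)) meta <- cbind(meta, extra)
  tractometry_dataset(
    ids, "t1", "fa", 4,
    values = list(fa = list(t1 = matrix(0.5, n, 4))), metadata = meta)
}

test_that("quantile binning splits sorted subjects into near-equal groups", {
  ages <- c(8, 9, 10, 11, 20, 21, 22, 30, 31)
  ds <- ages_dataset(ages)
  ga <- bin_subjects(ds, "age", 3, method = "quantile")
  expect_identical(ga$n_groups, 3L)
  oracle <- oracle_quantile_bins(ages, ds$subject_ids, 3)
  for (g in 1:3) {
    expect_setequal(group_members(ga, g - 1L), oracle[[g]])
  }
  # the paper-style 3-way split of 9 ordered ages
  expect_setequal(group_members(ga, 0L), c("s01", "s02", "s03"))
  expect_setequal(group_members(ga, 1L), c("s04", "s05", "s06"))
  expect_setequal(group_members(ga, 2L), c("s07", "s08", "s09"))
})

test_that("quantile tie-break is stable on (value, subjectID)", {
  ds <- ages_dataset(c(10, 10, 10, 10), ids = c("d", "c", "b", "a"))
  ga <- bin_subjects(ds, "age", 2, method = "quantile")
  expect_setequal(group_members(ga, 0L), c("a", "b"))
  expect_setequal(group_members(ga, 1L), c("c", "d"))
})

test_that("explicit edges reproduce half-open development bins with lo-hi labels", {
  ages <- c(8, 12, 15, 22, 29.9, 30, 45, 50)
  ds <- ages_dataset(ages)
  ga <- bin_subjects(ds, "age", method = "explicit_edges",
                     edges = c(8, 15, 30, 50))
  expect_identical(ga$labels, c("8–15", "15–30", "30–50"))
  # half-open [e_i, e_{i+1}), last interval closed
  expect_setequal(group_members(ga, 0L), c("s01", "s02"))       # 8, 12
  expect_setequal(group_members(ga, 1L), c("s03", "s04", "s05")) # 15..29.9
  expect_setequal(group_members(ga, 2L), c("s06", "s07", "s08")) # 30..50
})

test_that("equal-width bins span [min, max] and group index is monotone in value", {
  ages <- c(0, 1, 2, 5, 9, 10)
  ds <- ages_dataset(ages)
  ga <- bin_subjects(ds, "age", 2, method = "equal_width")
  expect_equal(ga$edges, c(0, 5, 10))
  idx <- ga$assignment[order(ds$metadata$age)]
  expect_true(all(diff(idx) >= 0))
  expect_setequal(group_members(ga, 0L), c("s01", "s02", "s03"))
  expect_setequal(group_members(ga, 1L), c("s04", "s05", "s06"))
})

test_that("categorical binning makes one group per sorted level; missing values stay unassigned", {
  ds <- ages_dataset(c(10, 20, NA, 40),
                     extra = data.frame(dx = c("pat", "ctl", "ctl", NA)))
  ga <- bin_subjects(ds, "dx", method = "categorical")
  expect_identical(ga$labels, c("ctl", "pat"))
  expect_setequal(group_members(ga, "ctl"), c("s02", "s03"))
  expect_setequal(group_members(ga, "pat"), "s01")
  expect_identical(ga$n_unassigned, 1L)

  gq <- bin_subjects(ds, "age", 1, method = "quantile")
  expect_setequal(group_members(gq, 0L), c("s01", "s02", "s04"))
})

test_that("binning errors: unknown key, non-numeric key, too many groups", {
  ds <- ages_dataset(c(10, 20), extra = data.frame(dx = c("a", "b")))
  expect_error(bin_subjects(ds, "height", 2), "unknown metadata column")
  expect_error(bin_subjects(ds, "dx", 2, method = "quantile"),
               "not numeric")
  expect_error(bin_subjects(ds, "age", 3, method = "quantile"), "exceeds")
  expect_error(bin_subjects(ds, "age", 2, method = "quantile",
                            edges = c(1, 2)), "edges")
})

test_that("every binning method partitions the assigned subjects", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:12, 1)
    ages <- round(stats::runif(n, 8, 50), 1)
    if (stats::runif(1) < 0.5) ages[sample(n, 1)] <- NA
    ds <- ages_dataset(ages, extra = data.frame(
      dx = sample(c("x", "y", "z"), n, replace = TRUE)))
    specs <- list(
      bin_subjects(ds, "age", sample(1:3, 1), method = "quantile"),
      bin_subjects(ds, "age", sample(1:3, 1), method = "equal_width"),
      bin_subjects(ds, "age", method = "explicit_edges",
                   edges = c(8, 20, 50)),
      bin_subjects(ds, "dx", method = "categorical"))
    for (ga in specs) {
      members <- unlist(lapply(seq_len(ga$n_groups) - 1L,
                               function(g) group_members(ga, g)))
      expect_identical(anyDuplicated(members), 0L)
      assigned <- names(ga$assignment)[!is.na(ga$assignment)]
      expect_setequal(members, assigned)
      if (ga$method == "quantile") {
        sizes <- tabulate(ga$assignment + 1L, nbins = ga$n_groups)
        expect_lte(diff(range(sizes)), 1L)
      }
      expect_length(ga$labels, ga$n_groups)
    }
  }
})
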