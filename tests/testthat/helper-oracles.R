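# Independent brute-force oracles and randomized fixture builders. The
# oracles are deliberately written as plain per-node loops so they share no
# code path with the package implementations they check.

# Per-node n/mean/sd/se of a subjects-by-nodes matrix, by explicit loops.
oracle_profile <- function(mat) {
  n_nodes <- ncol(mat)
  n <- integer(n_nodes); mu <- sdv <- se <- rep(NA_real_, n_nodes)
  for (v in seq_len(n_nodes)) {
    vals <- mat[, v]
    vals <- vals[!is.na(vals)]
    n[v] <- length(vals)
    if (n[v] >= 1L) mu[v] <- sum(vals) / n[v]
    if (n[v] >= 2L) {
      sdv[v] <- sqrt(sum((vals - mu[v])^2) / (n[v] - 1))
      se[v] <- sdv[v] / sqrt(n[v])
    }
  }
  list(n = n, mean = mu, sd = sdv, se = se)
}

# z-profile of vector x against a reference matrix, by loops.
oracle_z <- function(x, ref_mat) {
  p <- oracle_profile(ref_mat)
  z <- rep(NA_real_, length(x))
  for (v in seq_along(x)) {
    if (!is.na(x[v]) && !is.na(p$sd[v]) && p$sd[v] != 0) {
      z[v] <- (x[v] - p$mean[v]) / p$sd[v]
    }
  }
  z
}

# Signed peak z within a 0-based inclusive range, first node wins ties.
oracle_peak <- function(z, lo = 0L, hi = length(z) - 1L) {
  best <- NA_real_; best_node <- NA_integer_
  for (v in lo:hi) {
    zv <- z[v + 1L]
    if (is.na(zv)) next
    if (is.na(best) || abs(zv) > abs(best)) {
      best <- zv; best_node <- v
    }
  }
  list(value = best, node = best_node)
}

oracle_mean_z <- function(z, lo = 0L, hi = length(z) - 1L) {
  acc <- 0; k <- 0L
  for (v in lo:hi) {
    if (!is.na(z[v + 1L])) { acc <- acc + z[v + 1L]; k <- k + 1L }
  }
  if (k == 0L) NA_real_ else acc / k
}

# Fraction of group subjects whose z exceeds threshold somewhere in range.
oracle_fraction_deviant <- function(ds, group, reference, tract, metric,
                                    threshold, lo, hi,
                                    direction = "absolute") {
  mat <- value_matrix(ds, metric, tract)
  ref_mat <- mat[match(reference, ds$subject_ids), , drop = FALSE]
  hits <- 0L
  for (s in group) {
    z <- oracle_z(mat[match(s, ds$subject_ids), ], ref_mat)
    dev <- FALSE
    for (v in lo:hi) {
      zv <- z[v + 1L]
      if (is.na(zv)) next
      sc <- switch(direction, absolute = abs(zv), positive = zv,
                   negative = -zv)
      if (sc > threshold) dev <- TRUE
    }
    if (dev) hits <- hits + 1L
  }
  hits / length(group)
}

# Quantile binning oracle: stable sort by (value, subjectID), split into
# near-equal consecutive chunks (earlier chunks take the remainder).
oracle_quantile_bins <- function(values, ids, n_groups) {
  keep <- !is.na(values)
  ord <- order(values[keep], ids[keep])
  ids_sorted <- ids[keep][ord]
  n <- length(ids_sorted)
  sizes <- rep(n %/% n_groups, n_groups)
  if (n %% n_groups) sizes[seq_len(n %% n_groups)] <-
    sizes[seq_len(n %% n_groups)] + 1L
  split(ids_sorted, rep(seq_len(n_groups), times = sizes))
}

# Randomized small dataset with missing values and mixed metadata.
random_dataset <- function(seed, max_subjects = 6L, max_nodes = 8L,
                           na_frac = 0.1) {
  set.seed(seed)
  n_sub <- sample(2:max_subjects, 1L)
  n_nodes <- sample(3:max_nodes, 1L)
  tracts <- paste("Tract", seq_len(sample(1:3, 1L)))
  metrics <- sample(c("fa", "md", "rd"), sample(1:3, 1L))
  values <- list()
  for (m in metrics) {
    values[[m]] <- list()
    for (tr in tracts) {
      mat <- matrix(round(stats::runif(n_sub * n_nodes, 0.05, 0.95), 6),
                    n_sub, n_nodes)
      mat[stats::runif(n_sub * n_nodes) < na_frac] <- NA_real_
      values[[m]][[tr]] <- mat
    }
  }
  ids <- sprintf("sub_%02d", seq_len(n_sub))
  meta <- data.frame(subjectID = ids,
                     age = round(stats::runif(n_sub, 8, 50), 2),
                     dx = sample(c("ctl", "pat"), n_sub, replace = TRUE),
                     stringsAsFactors = FALSE)
  meta$age[sample(n_sub, 1L)] <- NA_real_
  tractometry_dataset(ids, tracts, metrics, n_nodes, values, meta,
                      params = list(seed = seed))
}

# Dataset-by-hand fixture: 3 subjects, 1 tract, 4 nodes, 1 metric -- the
# worked example behind several derived expectations.
tiny_profile_dataset <- function() {
  mat <- rbind(c(0.4, 0.5, 0.6, 0.5),
               c(0.5, 0.6, 0.7, 0.6),
               c(0.6, 0.7, 0.8, 0.7))
  tractometry_dataset(
    c("s1", "s2", "s3"), "tract1", "fa", 4L,
    values = list(fa = list(tract1 = mat)),
    metadata = data.frame(subjectID = c("s1", "s2", "s3"),
                          age = c(10, 20, 30)))
}

expect_dataset_equal <- function(a, b, tolerance = 0) {
  expect_identical(a$subject_ids, b$subject_ids)
  expect_identical(a$tract_names, b$tract_names)
  expect_identical(a$metric_names, b$metric_names)
  expect_identical(a$n_nodes, b$n_nodes)
  for (m in a$metric_names) {
    for (tr in a$tract_names) {
      expect_equal(value_matrix(a, m, tr), value_matrix(b, m, tr),
                   tolerance = tolerance,
                   label = sprintf("values[%s][%s]", m, tr))
    }
  }
  expect_identical(names(a$metadata), names(b$metadata))
  for (col in names(a$metadata)) {
    expect_equal(a$metadata[[col]], b$metadata[[col]], tolerance = tolerance,
                 label = sprintf("metadata$%s", col))
  }
}

# Randomized viewer state, unicode included.
random_state <- function(seed) {
  set.seed(seed)
  pool <- c("fa", "md", "Left CST", "tract/å", "sübject 1", "a&b=c",
            "100%", "comma,name", "plain")
  pick <- function(n) sample(pool, n, replace = FALSE)
  brushes <- list()
  if (stats::runif(1) < 0.6) {
    for (tr in pick(sample(1:2, 1L))) {
      lo <- sample(0:40, 1L)
      brushes[[tr]] <- node_range(lo, lo + sample(0:50, 1L))
    }
  }
  viewer_state(
    metric = if (stats::runif(1) < 0.7) sample(c("fa", "md"), 1L) else NULL,
    selected_tracts = if (stats::runif(1) < 0.5) pick(2) else character(),
    group_key = if (stats::runif(1) < 0.5) "age" else NULL,
    n_groups = sample(1:5, 1L),
    error_band = sample(c("se", "sd"), 1L),
    brushes = brushes,
    selected_subjects = if (stats::runif(1) < 0.5) pick(sample(1:3, 1L))
                        else character(),
    table_sort = if (stats::runif(1) < 0.4) {
      list(column = sample(pool, 1L), ascending = stats::runif(1) < 0.5)
    } else NULL)
}
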