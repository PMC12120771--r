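test_that("series_scores composes internal Z and trimmed means", {
  sim <- simulate_time_series(n_genes = 60, n_planted = c(AD = 8, NE = 8,
                                                   DORMANT = 8),
                              seed = 19, n_rep = 3)
  ts <- series_scores(sim$series)
  expect_identical(colnames(ts), names(sim$series))
  # composition oracle: per timepoint, compute_internal_z + trimmed mean
  genes <- rownames(ts)
  for (tp in names(sim$series)) {
    z <- compute_internal_z(sim$series[[tp]][genes, , drop = FALSE])
    ref <- apply(z, 1, trimmean_oracle, 0.2)
    expect_equal(ts[, tp], ref, tolerance = 1e-12)
  }
})

test_that("single-sample timepoints score as the internal Z itself", {
  sim <- simulate_time_series(n_genes = 50, n_planted = c(AD = 8, NE = 8,
                                                   DORMANT = 8),
                              seed = 23, n_rep = 1)
  ts <- series_scores(sim$series)
  z0 <- compute_internal_z(sim$series$T0[rownames(ts), , drop = FALSE])
  expect_equal(ts[, "T0"], z0[, 1], tolerance = 1e-12)
  expect_error(series_scores(sim$series[1:2]), "3 timepoints")
})

test_that("series_scores uses the shared gene universe and reports dropped genes", {
  sim <- simulate_time_series(n_genes = 50, n_planted = c(AD = 8, NE = 8,
                                                   DORMANT = 8), seed = 29)
  series <- sim$series
  series$T0 <- series$T0[-(1:5), , drop = FALSE]
  ts <- series_scores(series)
  expect_identical(nrow(ts), 45L)
  expect_length(attr(ts, "dropped"), 5L)
})

test_that("set_trajectory is the unweighted row mean over found members", {
  ts <- matrix(c(1, -1, 0.5, 2, 0, 1), 2, 3,
               dimnames = list(c("A", "B"), c("T0", "T1", "T2")))
  expect_equal(set_trajectory("A", ts), ts["A", ], ignore_attr = TRUE)
  traj <- set_trajectory(c("A", "B", "MISSING"), ts)
  expect_equal(traj, colMeans(ts), ignore_attr = TRUE)
  expect_identical(attr(traj, "coverage"), list(found = 2L, total = 3L))
  expect_error(set_trajectory("NOPE", ts), "disjoint")
})

test_that("assign_phases labels timepoints and rejects double-high states", {
  ad <- c(T0 = 1.0, T1 = -0.3, T2 = -0.5)
  ne <- c(T0 = -0.5, T1 = -0.4, T2 = 0.8)
  ph <- assign_phases(ad, ne, theta = 0.2)
  expect_equal(unname(ph), c("ADENO_LIKE", "DORMANT", "NE_LIKE"),
               ignore_attr = TRUE)
  expect_identical(attr(ph, "transitions"),
                   c("T0->T1: ADENO_LIKE->DORMANT",
                     "T1->T2: DORMANT->NE_LIKE"))
  expect_error(assign_phases(c(T0 = 1), c(T0 = 1)), "T0")
})

test_that("screen_dormant flags exactly the TFs satisfying the predicate", {
  ts <- rbind(UP2 = c(-0.5, -0.2, 1.0, -0.4),   # dormant-specific
              FLAT = c(1.0, 1.0, 1.0, 1.0),     # high but no margin
              LOWP = c(-1.0, -1.0, 0.1, -1.0))  # margin but below floor
  colnames(ts) <- paste0("T", 0:3)
  res <- screen_dormant(ts, "T2", c("T0", "T3"), delta = 0.2,
                        theta_floor = 0.2)
  expect_identical(res$tf, "UP2")
  expect_equal(res$Z_dormant, 1.0)
  expect_equal(res$margin_T0, 1.5)
  expect_error(screen_dormant(ts, "T0", c("T0", "T3")), "terminal")
})

test_that("screen_dormant matches an independent predicate oracle on random series", {
  set.seed(37)
  ts <- matrix(rnorm(200 * 4, 0, 1), 200, 4,
               dimnames = list(sprintf("G%03d", 1:200), paste0("T", 0:3)))
  res <- screen_dormant(ts, "T2", c("T0", "T3"), delta = 0.3,
                        theta_floor = 0.1)
  want <- rownames(ts)[ts[, "T2"] > 0.1 &
                       ts[, "T2"] - ts[, "T0"] > 0.3 &
                       ts[, "T2"] - ts[, "T3"] > 0.3]
  expect_setequal(res$tf, want)
  # ranked by descending dormant score
  expect_false(is.unsorted(rev(res$Z_dormant)))
  # monotonicity: raising the dormant score never unflags
  ts2 <- ts
  ts2[res$tf, "T2"] <- ts2[res$tf, "T2"] + 1
  expect_true(all(res$tf %in% screen_dormant(ts2, "T2", c("T0", "T3"),
                                             0.3, 0.1)$tf))
  # raising a terminal score never flags a new TF
  ts3 <- ts
  ts3[, "T0"] <- ts3[, "T0"] + 1
  expect_true(all(screen_dormant(ts3, "T2", c("T0", "T3"),
                                 0.3, 0.1)$tf %in% res$tf))
})

test_that("series scoring inherits per-sample scale invariance", {
  sim <- simulate_time_series(n_genes = 80, n_planted = c(AD = 8, NE = 8,
                                                   DORMANT = 8),
                              seed = 43, sigma_s = 0)
  ts1 <- series_scores(sim$series, log2_transform = FALSE)
  scaled <- lapply(sim$series, function(m)
    sweep(m, 2, runif(ncol(m), 0.5, 2), "*"))
  ts2 <- series_scores(scaled, log2_transform = FALSE)
  expect_equal(ts1, ts2, tolerance = 1e-9, ignore_attr = TRUE)
})
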