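test_that("length equalization trims to the minimum length, keeping the tail", {
  tr <- list(seq_len(100), seq_len(102), 3 + seq_len(101))
  out <- equalize_lengths(tr)
  expect_true(all(lengths(out) == 100L))
  expect_identical(out[[2L]], 3:102)   # extra points removed from the start
  expect_identical(out[[1L]], tr[[1L]])

  same <- list(1:50, 51:100)
  expect_identical(equalize_lengths(same), same)

  out2 <- equalize_lengths(list(1:5, 11:13), min_length = 3L)
  expect_identical(out2[[1L]], 3:5)

  expect_error(equalize_lengths(list(1:5, 1:20)), "minimum length")

  sym <- equalize_lengths(list(1:10, 1:14), trim = "symmetric",
                          min_length = 5L)
  expect_identical(sym[[2L]], 3:12)
})

test_that("baseline normalization divides (or subtracts) the stabilized tail", {
  baseline <- c(rnorm(20), rep(2, 10))
  expect_equal(normalize_to_baseline(c(2, 4, 6), baseline), c(1, 2, 3))
  expect_equal(normalize_to_baseline(rep(2, 5), baseline), rep(1, 5))
  expect_equal(normalize_to_baseline(rep(2, 5), baseline, mode = "difference"),
               rep(0, 5))
  expect_error(normalize_to_baseline(1:3, rep(0, 10)), "degenerate baseline")
  expect_error(normalize_to_baseline(1:3, 1:5), "fewer than b_tail")
})

test_that("ratio normalization is scale invariant", {
  set.seed(1)
  breath <- rnorm(30, 5); baseline <- rnorm(15, 5)
  ref <- normalize_to_baseline(breath, baseline)
  for (c in c(0.01, 3, -7)) {
    expect_equal(normalize_to_baseline(c * breath, c * baseline), ref)
  }
})

test_that("median filter smooths spikes with replicate padding", {
  expect_equal(median_filter(c(1, 100, 1, 1), 3), c(1, 1, 1, 1))
  mono <- c(1, 2, 4, 7, 11)
  expect_equal(median_filter(mono, 3), mono)
  expect_identical(median_filter(mono, 1L), mono)
  expect_error(median_filter(mono, 2), "odd")
  expect_error(median_filter(mono, 7), "out of range")
  # idempotent on piecewise-constant signals
  pc <- rep(c(0, 3, 1), times = c(6, 5, 7))
  once <- median_filter(pc, 3)
  expect_equal(median_filter(once, 3), once)
})

test_that("score and orthogonal distances behave on degenerate geometry", {
  set.seed(2)
  # rank-2 data: all rows lie in the retained subspace -> OD = 0
  Z <- matrix(rnorm(40), 20, 2)
  W <- matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE)
  X <- Z %*% W
  rep <- detect_outliers(X, alpha = 0.01)
  expect_true(all(rep$orthogonal_distance < 1e-8))

  # a row equal to the column mean has SD = 0
  X2 <- matrix(rnorm(19 * 4), 19, 4)
  X2 <- rbind(X2, colMeans(X2) * 20 - colSums(X2)) # make last row the mean
  expect_equal(colMeans(X2), X2[20, ], ignore_attr = TRUE)
  rep2 <- detect_outliers(X2, alpha = 0.01)
  expect_lt(rep2$score_distance[20], 1e-8)

  expect_error(detect_outliers(matrix(1, 12, 3)), "no variation")
  expect_error(detect_outliers(matrix(rnorm(12), 4, 3)), "at least 10 rows")
  expect_error(detect_outliers(matrix(rnorm(120), 12), alpha = 0.7), "alpha")
})

test_that("rows displaced along the residual direction are flagged exactly", {
  set.seed(7)
  n <- 100L
  Z <- matrix(rnorm(n * 3), n, 3)
  basis <- qr.Q(qr(matrix(rnorm(6 * 6), 6)))   # orthonormal 6x6
  X <- Z %*% t(basis[, 1:3]) + matrix(rnorm(n * 6, 0, 0.02), n, 6)
  resid_dir <- basis[, 5L]
  out_rows <- c(11L, 47L, 90L)
  X[out_rows, ] <- X[out_rows, ] + 10 * matrix(resid_dir, 3, 6, byrow = TRUE)

  rep <- detect_outliers(X, alpha = 0.001)
  expect_identical(which(rep$flagged), out_rows)

  # oracle: recompute SD/OD from an explicit eigendecomposition of the
  # clean-row covariance
  clean <- setdiff(seq_len(n), out_rows)
  ctr <- colMeans(X[clean, ])
  S <- cov(sweep(X[clean, ], 2, ctr))
  eig <- eigen(S, symmetric = TRUE)
  a <- which(cumsum(eig$values) / sum(eig$values) >= 0.95)[1L]
  V <- eig$vectors[, seq_len(a), drop = FALSE]
  sc <- sweep(X, 2, ctr) %*% V
  sd_o <- sqrt(rowSums(sweep(sc^2, 2, eig$values[seq_len(a)], "/")))
  od_o <- sqrt(rowSums((sweep(X, 2, ctr) - sc %*% t(V))^2))
  expect_equal(rep$score_distance, sd_o, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(rep$orthogonal_distance, od_o, tolerance = 1e-8,
               ignore_attr = TRUE)
  # report invariant: flagged iff a distance exceeds its cutoff
  expect_identical(rep$flagged,
                   rep$score_distance > rep$sd_cutoff |
                     rep$orthogonal_distance > rep$od_cutoff)
})

test_that("outlier flags are invariant to orthogonal rotation of columns", {
  set.seed(8)
  X <- matrix(rnorm(30 * 5), 30, 5)
  X[c(3, 17), ] <- X[c(3, 17), ] * 8
  R <- qr.Q(qr(matrix(rnorm(25), 5)))
  f1 <- detect_outliers(X)$flagged
  f2 <- detect_outliers(X %*% R)$flagged
  expect_identical(f1, f2)
})

test_that("cohort preprocessing yields row-aligned panels and drops outliers", {
  px <- tiny_panels(n_cancer = 10, n_control = 12, seed = 21)
  ids <- lapply(px$panels, function(p) p$measurement_ids)
  expect_true(all(vapply(ids, identical, logical(1), ids[[1L]])))
  expect_identical(px$prep$removed, character(0))

  # one measurement with a wild spike on every sensor
  co <- tiny_cohort(n_cancer = 10, n_control = 12, seed = 22)
  victim <- names(co$measurements)[5L]
  for (sid in names(co$measurements[[5L]]$sensors))
    co$measurements[[5L]]$sensors[[sid]]$breath <-
      co$measurements[[5L]]$sensors[[sid]]$breath * 10
  prep <- suppressMessages(preprocess_cohort(suppressMessages(screen_cohort(co))))
  expect_identical(prep$removed, victim)
  for (p in prep$panels) expect_false(victim %in% p$measurement_ids)

  expect_error(preprocess_config(stages = c("filter", "normalize", "equalize")),
               "invalid stage order")
})

test_that("noiseless simulated curves reproduce their prototypes exactly", {
  cfg <- sim_config(n_cancer = 5, n_control = 5, n_sensors = 2, T = 40,
                    noise_sd = 0, outlier_rate = 0, length_jitter = 0,
                    seed = 4)
  co <- simulate_cohort(cfg)
  protos <- attr(co, "prototypes")
  truth <- attr(co, "truth")
  m <- co$measurements[[1L]]
  tr <- m$sensors[[1L]]
  got <- normalize_to_baseline(tr$breath, tr$baseline)
  row <- truth[truth$measurement_id == m$measurement_id, ]
  want <- protos[[tr$sensor_id]][[row$class]][row$prototype_id, ]
  expect_equal(got, want, tolerance = 1e-12)
})
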