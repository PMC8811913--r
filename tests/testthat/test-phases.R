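test_that("standardization gives exact z-scores and is idempotent", {
  # two points at 0 and 2: centred to +/-1, sample sd sqrt(2), so z = +/-1/sqrt(2)
  m <- matrix(c(0, 2, 2, 0), 2, dimnames = list(NULL, c("a", "b")))
  z <- standardize_traits(m)
  expect_equal(abs(unclass(z)), matrix(1 / sqrt(2), 2, 2,
                                       dimnames = dimnames(z)),
               ignore_attr = TRUE)
  expect_equal(unname(apply(z, 2, var)), c(1, 1))
  expect_equal(standardize_traits(z), z, ignore_attr = TRUE)
  tt <- generate_trait_table(default_traj())
  zz <- standardize_traits(tt)
  expect_true(all(abs(colMeans(zz)) < 1e-12))
  expect_true(all(abs(apply(zz, 2, sd) - 1) < 1e-12))
})

test_that("constant traits are dropped with a warning", {
  df <- data.frame(day = 1:4, a = c(1, 2, 3, 4), b = 5)
  expect_warning(z <- standardize_traits(df), "b")
  expect_equal(colnames(z), "a")
  expect_error(suppressWarnings(standardize_traits(data.frame(day = 1:3, b = 1))),
               "non-constant")
})

test_that("PCA recovers exact variance splits on constructed matrices", {
  # rank one: a single direction carries all variance
  r1 <- outer(c(1, 2, 3, 4), c(2, -1, 0.5))
  p1 <- run_pca(r1)
  expect_equal(p1$explained_variance[1], 1)
  # two orthogonal equal-variance coordinates split 50/50
  m <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1))
  p2 <- run_pca(m)
  expect_equal(p2$explained_variance[1:2], c(0.5, 0.5))
  expect_error(run_pca(m[1, , drop = FALSE]), "at least 2")
})

test_that("PCA agrees with a direct eigen-decomposition oracle", {
  z <- standardize_traits(generate_trait_table(default_traj()))
  fit <- run_pca(z)
  expect_equal(fit$explained_variance,
               oracle_pca_variance(z)[seq_along(fit$explained_variance)])
  # loadings orthonormal
  expect_equal(crossprod(fit$loadings), diag(ncol(fit$loadings)),
               ignore_attr = TRUE)
  # deterministic orientation: dominant entry of each loading is positive
  for (j in seq_len(ncol(fit$loadings))) {
    expect_gt(fit$loadings[which.max(abs(fit$loadings[, j])), j], 0)
  }
})

test_that("reconstruction error decreases as components are added", {
  z <- standardize_traits(generate_trait_table(default_traj()))
  fit <- run_pca(z)
  zc <- scale(z, scale = FALSE)
  errs <- vapply(1:5, function(k) {
    hat <- fit$scores[, 1:k, drop = FALSE] %*% t(fit$loadings[, 1:k, drop = FALSE])
    sum((zc - hat)^2)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("well-separated blobs split perfectly with no transition calls", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(10, 0, 0.05), 5),
               matrix(rnorm(10, 8, 0.05), 5))
  fit <- list(scores = cbind(pts, 0))
  lab <- segment_phases(fit, time_axis = 1:10)
  expect_equal(as.character(lab), rep(c("NRep", "NS"), each = 5))
})

test_that("identical points degenerate to a single replete cluster", {
  fit <- list(scores = matrix(1, 6, 2))
  expect_warning(lab <- segment_phases(fit, 1:6), "identical")
  expect_true(all(lab == "NRep"))
})

test_that("tau at or below one is rejected", {
  fit <- list(scores = matrix(rnorm(12), 6, 2))
  expect_error(segment_phases(fit, 1:6, tau = 1), "tau")
})

test_that("default synthetic experiment segments into the published phases", {
  tt <- generate_trait_table(default_traj())
  lab <- segment_phases(run_pca(standardize_traits(tt)), tt$day)
  expect_equal(as.character(lab),
               ifelse(tt$day <= 4, "NRep",
                      ifelse(tt$day <= 6, "transition", "NS")))
  expect_equal(ari(lab, attr(tt, "phase")), 1.0)
})

test_that("segmentation stays accurate under doubled measurement noise", {
  traj <- default_traj()
  aris <- vapply(1:20, function(seed) {
    cfg <- traj$config
    cfg$seed <- seed
    cfg$noise_cv <- 0.10
    tt <- generate_trait_table(traj, cfg)
    lab <- segment_phases(run_pca(standardize_traits(tt)), tt$day)
    ari(lab, attr(tt, "phase"))
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})

test_that("five-phase convention detaches days 5, 6 and 15", {
  days <- -2:15
  lab <- ifelse(days <= 4, "NRep", ifelse(days <= 6, "transition", "NS"))
  five <- five_phase_labels(lab, days)
  expect_equal(levels(five), c("NRep", "D5", "D6", "NS", "D15"))
  expect_equal(sum(five == "D5"), 1L)
  expect_equal(sum(five == "D6"), 1L)
  expect_equal(sum(five == "D15"), 1L)
  expect_equal(as.character(five[days == 15]), "D15")  # precedence over NS
  expect_true(all(five[days <= 4] == "NRep"))
  # replete-only axis collapses to one phase, with a warning for the rest
  expect_warning(f2 <- five_phase_labels(rep("NRep", 7), -2:4), "absent")
  expect_true(all(f2 == "NRep"))
})
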