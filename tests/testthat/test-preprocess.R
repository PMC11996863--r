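# Preprocessing: log2, class-I filter, truncated-normal fitting, KNN-TN
# imputation, median normalization, surrogate variable, PCA.

test_that("log2 transform maps values, preserves missing, rejects non-positive", {
  m <- matrix(c(8, NA, 2, 1), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  out <- log2_transform(m)
  expect_equal(out["a", "s1"], 3)
  expect_true(is.na(out["b", "s1"]))
  m[1, 1] <- 0
  expect_error(log2_transform(m), "s1")
})

test_that("class-I filter keeps the 0.75 boundary (inclusive)", {
  pset <- tiny_pset()
  pset$sites$loc_prob <- c(0.74, 0.75, 0.97)
  kept <- filter_class1(pset, 0.75)
  expect_identical(kept$sites$site_id, pset$sites$site_id[2:3])
  expect_equal(nrow(filter_class1(pset, 0)$sites), 3)
  expect_equal(nrow(filter_class1(pset, 1)$sites), 0)
})

test_that("truncated-normal fit recovers moments in the untruncated limit", {
  set.seed(11)
  vals <- stats::rnorm(400, 25, 1.5)
  fit <- fit_truncated_normal(vals, truncation_point = 5)
  expect_identical(fit$method, "moments")
  expect_lt(abs(fit$mu - mean(vals)) / mean(vals), 0.01)
  expect_lt(abs(fit$sigma - stats::sd(vals)) / stats::sd(vals), 0.01)
})

test_that("truncated-normal MLE recovers (mu, sigma) under truncation", {
  set.seed(3)
  draws <- stats::rnorm(5000, 20, 1)
  vals <- draws[draws > 20][1:500]
  fit <- fit_truncated_normal(vals, truncation_point = 20)
  expect_identical(fit$method, "ml")
  expect_lt(abs(fit$mu - 20), 0.15)
  expect_lt(abs(fit$sigma - 1), 0.15)
})

test_that("truncated-normal fit applies the sigma floor and minimum-n rule", {
  fit <- fit_truncated_normal(c(5, 5, 5, 5), truncation_point = 0)
  expect_equal(fit$sigma, 0.05)
  expect_error(fit_truncated_normal(c(1, 2), truncation_point = 0), "at least 3")
})

test_that("imputation leaves observed entries untouched and handles exact cases", {
  # complete matrix -> identity
  set.seed(3)
  m <- matrix(stats::rnorm(60, 20), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("c", 1:10)))
  expect_identical(impute_knn_tn(m), m)

  # duplicate rows: the missing entry sits at the row mean, so the neighbor's
  # standardized value is zero and back-transforms exactly to the duplicate's
  # value; rows far below keep the truncation points away from the data
  base <- c(18, 19, 20, 21, 22, 20)
  m2 <- rbind(r1 = c(18, 19, 20, 21, 22, NA), r2 = base,
              r3 = base - 10, r4 = base - 11, r5 = base - 12)
  colnames(m2) <- paste0("c", 1:6)
  out <- suppressMessages(impute_knn_tn(m2, k = 1))
  expect_equal(out["r1", "c6"], 20)
  obs <- !is.na(m2)
  expect_identical(out[obs], m2[obs])
})

test_that("KNN-TN beats per-sample-minimum imputation on MNAR data", {
  cfg <- small_sim_config(seed = 1L)
  gen <- generate_intensities(cfg)
  m <- log2(gen$data$intensities)
  truth <- gen$truth$log2_true
  mask <- is.na(m)
  imp <- suppressMessages(impute_knn_tn(m))
  minimp <- m
  for (j in seq_len(ncol(m))) minimp[mask[, j], j] <- min(m[, j], na.rm = TRUE)
  rmse <- function(x) sqrt(mean((x[mask] - truth[mask])^2))
  expect_lt(rmse(imp), rmse(minimp))
})

test_that("median normalization equalizes medians and preserves differences", {
  m <- matrix(c(9, 10, 11, 11, 12, 13), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  out <- median_normalize(m)
  expect_equal(unname(attr(out, "shifts")), c(1, -1))
  expect_equal(apply(out, 2, stats::median), c(a = 11, b = 11))
  # within-sample pairwise differences unchanged
  expect_equal(diff(out[, 1]), diff(m[, 1]))
  # already-equal medians -> zero shifts
  expect_equal(unname(attr(median_normalize(out), "shifts")), c(0, 0))
  set.seed(4)
  big <- matrix(stats::rnorm(200, 20), 20, 10)
  med <- apply(median_normalize(big), 2, stats::median)
  expect_lt(diff(range(med)), 1e-9)
})

test_that("surrogate variable recovers a planted batch vector and stays orthogonal", {
  cfg <- small_sim_config(seed = 1L, mnar_center = -Inf)
  gen <- generate_intensities(cfg)
  m <- log2(gen$data$intensities)
  d <- gen$data$design
  X <- stats::model.matrix(~ phenotype + treatment + sex, d)
  sv <- estimate_surrogate_variable(m, X)
  expect_gt(abs(stats::cor(sv$scores, gen$truth$sv_scores[names(sv$scores)])), 0.9)
  expect_true(all(abs(crossprod(X, sv$scores)) < 1e-8))
  expect_equal(sum(sv$scores^2), 1)
})

test_that("surrogate-variable estimation flags a degenerate residual", {
  X <- cbind(1, rep(c(0, 1), each = 4))
  m <- matrix(rep(X[, 2], 5), 5, 8, byrow = TRUE)
  expect_error(estimate_surrogate_variable(m, X), "zero")
  expect_error(estimate_surrogate_variable(m, cbind(X, X[, 2])), "rank deficient")
})

test_that("SV adjustment removes the batch component without touching design effects", {
  cfg <- small_sim_config(seed = 2L, mnar_center = -Inf)
  gen <- generate_intensities(cfg)
  m <- log2(gen$data$intensities)
  d <- gen$data$design
  X <- stats::model.matrix(~ phenotype + treatment + sex, d)
  sv <- estimate_surrogate_variable(m, X)
  adj <- adjust_matrix_for_sv(m, X, sv)
  # re-estimating on the adjusted matrix explains less residual variance
  sv2 <- estimate_surrogate_variable(adj, X)
  expect_lt(sv2$variance_explained, sv$variance_explained)
  # design coefficients identical (SV orthogonal to design)
  bhat <- function(mm) mm %*% X %*% solve(crossprod(X))
  expect_lt(max(abs(bhat(adj) - bhat(m))), 1e-8)
  # all-zero scores -> identity
  sv0 <- structure(list(scores = stats::setNames(rep(0, ncol(m)), colnames(m)),
                        variance_explained = 0),
                   class = "surrogate_variable")
  expect_equal(adjust_matrix_for_sv(m, X, sv0), m)
})

test_that("PCA scores are deterministic and separate treatment groups", {
  m <- matrix(c(1, 5, 2, 6, 3, 7), 3, 2,
              dimnames = list(NULL, c("s1", "s2")))
  sc <- pca_qc(m)
  expect_false(isTRUE(all.equal(sc$PC1[1], sc$PC1[2])))
  # duplicated sample -> identical scores
  m2 <- cbind(m, s3 = m[, 2])
  sc2 <- pca_qc(m2)
  expect_equal(sc2$PC1[2], sc2$PC1[3])
  expect_equal(sc2$PC2[2], sc2$PC2[3])

  # on simulated data the batch vector dominates the raw PCs; on the
  # SV-adjusted matrix (the pipeline's QC input) treatment groups separate
  cfg <- sim_config(seed = 3L, mnar_center = -Inf)
  gen <- generate_intensities(cfg)
  m3 <- log2(gen$data$intensities)
  d3 <- gen$data$design
  X3 <- stats::model.matrix(~ phenotype + treatment + sex, d3)
  sv3 <- estimate_surrogate_variable(m3, X3)
  sc3 <- pca_qc(adjust_matrix_for_sv(m3, X3, sv3))
  sil <- mean_silhouette(as.matrix(sc3[, c("PC1", "PC2")]), d3$treatment)
  expect_gt(sil, 0)
})
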