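# Linear modeling, empirical-Bayes moderation, moderated t/F and BH FDR.

test_that("stimulation ratios are paired insulin-minus-basal differences", {
  pset <- tiny_pset()
  m <- matrix(c(10, 12, 11, 11,
                5, 5, 6, 8), 2, 4, byrow = TRUE,
              dimnames = list(c("s1", "s2"), pset$design$sample_id))
  pr <- paired_stimulation_ratios(m, pset$design)
  expect_equal(pr$ratios["s1", "L001"], 2)
  expect_equal(pr$ratios["s1", "L002"], 0)
  expect_equal(pr$ratios["s2", "L002"], 2)
  expect_equal(pr$lines$phenotype, c("CTL", "T2D"))

  # unpaired line excluded with a warning
  d2 <- rbind(pset$design,
              data.frame(sample_id = "CTL_F_L003_basal", cell_line = "L003",
                         phenotype = "CTL", sex = "F", treatment = "basal"))
  m2 <- cbind(m, CTL_F_L003_basal = c(1, 1))
  expect_warning(pr2 <- paired_stimulation_ratios(m2, d2), "L003")
  expect_false("L003" %in% colnames(pr2$ratios))
})

test_that("least squares matches closed forms and a normal-equations oracle", {
  set.seed(21)
  x <- matrix(stats::rnorm(50), 5, 10, dimnames = list(paste0("s", 1:5), NULL))
  fit <- fit_linear_model(x, matrix(1, 10, 1, dimnames = list(NULL, "int")))
  expect_equal(unname(fit$coefficients[, 1]), unname(rowMeans(x)))
  expect_equal(unname(fit$sigma2), unname(apply(x, 1, stats::var)))

  # paired two-sample design: treatment coefficient is the paired difference
  pset <- tiny_pset()
  m <- matrix(c(10, 12, 11, 15), 1, 4,
              dimnames = list("s1", pset$design$sample_id))
  X <- stats::model.matrix(~ cell_line + treatment,
                           transform(pset$design,
                                     treatment = factor(treatment,
                                                        c("basal", "insulin"))))
  fitp <- fit_linear_model(m, X)
  expect_equal(unname(fitp$coefficients[, "treatmentinsulin"]), 3) # mean(2, 4)

  # random 6x3 designs against an explicit normal-equations oracle
  for (i in 1:5) {
    set.seed(100 + i)
    X <- cbind(1, matrix(stats::rnorm(12), 6, 2))
    colnames(X) <- c("a", "b", "c")
    y <- matrix(stats::rnorm(18), 3, 6)
    rownames(y) <- paste0("g", 1:3)
    fit <- fit_linear_model(y, X)
    beta_oracle <- t(solve(t(X) %*% X, t(X) %*% t(y)))
    expect_lt(max(abs(fit$coefficients - beta_oracle)), 1e-10)
    res <- t(y) - X %*% t(beta_oracle)
    expect_lt(max(abs(fit$sigma2 - colSums(res^2) / 3)), 1e-10)
  }

  expect_error(fit_linear_model(x, cbind(a = rep(1, 10), b = rep(1, 10))),
               "collinear")
})

test_that("moderation prior matches the log-F moment equations", {
  # identical variances: infinite prior df, s0 from the mean equation
  s2 <- rep(0.7, 50)
  mp <- fit_moderation(s2, df = 6)
  expect_identical(mp$df_prior, Inf)
  expect_equal(mp$s2_prior, exp(mean(log(s2)) - digamma(3) + log(3)))

  # scaled chi-squared mixture with true d0 = 4: recovered within 25%
  set.seed(22)
  d0 <- 4; s0 <- 0.5; dg <- 10; n <- 5000
  true_var <- s0 * d0 / stats::rchisq(n, d0)
  s2_sim <- true_var * stats::rchisq(n, dg) / dg
  mp2 <- fit_moderation(s2_sim, dg)
  expect_lt(abs(mp2$df_prior - d0) / d0, 0.25)
  # inversion root-check: fitted d0 solves the trigamma equation
  target <- stats::var(log(s2_sim)) - trigamma(dg / 2)
  expect_lt(abs(trigamma(mp2$df_prior / 2) - target), 1e-8)

  expect_error(fit_moderation(rep(0, 20), 4), "zero")
})

test_that("moderated t interpolates between ordinary t and the s0-scaled z", {
  set.seed(23)
  X <- cbind(int = 1, grp = rep(c(0, 1), each = 5))
  y <- matrix(stats::rnorm(200), 20, 10)
  rownames(y) <- paste0("g", 1:20)
  fit <- fit_linear_model(y, X)

  # d0 = 0 (no shrinkage): ordinary t statistic, exactly
  mp0 <- structure(list(df_prior = 0, s2_prior = 1), class = "moderation_params")
  tt0 <- moderated_t(fit, mp0, "grp")
  t_ord <- apply(y, 1, function(r) stats::t.test(r[6:10], r[1:5],
                                                 var.equal = TRUE)$statistic)
  expect_lt(max(abs(tt0$t - t_ord)), 1e-6)

  # d0 = Inf (full shrinkage): beta / (u * s0), normal p-values
  mpI <- structure(list(df_prior = Inf, s2_prior = 0.8),
                   class = "moderation_params")
  ttI <- moderated_t(fit, mpI, "grp")
  expect_lt(max(abs(ttI$t - fit$coefficients[, "grp"] /
                      (fit$stdev_unscaled[["grp"]] * sqrt(0.8)))), 1e-12)
  expect_equal(ttI$p, 2 * stats::pnorm(-abs(ttI$t)))

  # monotone interpolation at intermediate d0 for fixed data
  mid <- moderated_t(fit, structure(list(df_prior = 4, s2_prior = 0.8),
                                    class = "moderation_params"), "grp")$t
  lo <- pmin(abs(tt0$t), abs(ttI$t))
  hi <- pmax(abs(tt0$t), abs(ttI$t))
  expect_true(all(abs(mid) >= lo - 1e-9 & abs(mid) <= hi + 1e-9))

  expect_error(moderated_t(fit, mp0, c(0, 0)), "zero")
})

test_that("moderated t/F agree with the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(24)
  X <- cbind(1, rep(c(0, 1), each = 7))
  colnames(X) <- c("int", "grp")
  y <- matrix(stats::rnorm(100 * 14, sd = rep(stats::rchisq(100, 4) / 4, 14)),
              100, 14)
  rownames(y) <- paste0("g", 1:100)
  fit <- fit_linear_model(y, X)
  mp <- fit_moderation(fit$sigma2, fit$df_residual)
  lf <- limma::lmFit(y, X)
  ref <- limma::eBayes(lf)
  expect_equal(mp$df_prior, ref$df.prior, tolerance = 1e-6)
  expect_equal(mp$s2_prior, ref$s2.prior, tolerance = 1e-6)
  tt <- moderated_t(fit, mp, "grp")
  expect_equal(tt$t, unname(ref$t[, "grp"]), tolerance = 1e-10)
  expect_equal(tt$p, unname(ref$p.value[, "grp"]), tolerance = 1e-10)
})

test_that("moderated F reduces to t-squared for one contrast and stays non-negative", {
  set.seed(25)
  X <- cbind(int = 1, a = rep(c(0, 1), 5), b = stats::rnorm(10))
  y <- matrix(stats::rnorm(150), 15, 10)
  rownames(y) <- paste0("g", 1:15)
  fit <- fit_linear_model(y, X)
  mp <- fit_moderation(fit$sigma2, fit$df_residual)
  tt <- moderated_t(fit, mp, "a")
  ff1 <- moderated_f(fit, mp, "a")
  expect_equal(ff1$F, tt$t^2, tolerance = 1e-12)
  expect_equal(ff1$p, tt$p, tolerance = 1e-12)
  ff2 <- moderated_f(fit, mp, c("a", "b"))
  expect_true(all(ff2$F >= 0))
})

test_that("BH adjustment matches the hand step-up and its invariances", {
  expect_equal(bh_fdr(c(0.005, 0.01, 0.03, 0.04)), c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(26)
  p <- stats::runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12)) # monotone in raw order
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), q[perm]) # permutation invariant
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("planted treatment effects are detected with high power", {
  # |log2FC| >= 1 on the study-sized paired design
  hits <- vapply(1:3, function(s) {
    cfg <- sim_config(seed = s, n_sites = 300L,
                      n_per_class = c("1A" = 50L),
                      insulin_effect_range = c(1, 2),
                      sv_loading_sd = 0, mnar_center = -Inf)
    gen <- generate_intensities(cfg)
    m <- log2(gen$data$intensities)
    diff <- run_differential(m, gen$data$design, NULL)
    ctl <- get_contrast(diff, "ctl_ins_vs_bas")
    planted <- gen$truth$sites$site_id[gen$truth$sites$class == "1A"]
    mean(ctl$p[match(planted, ctl$site_id)] < 0.05)
  }, numeric(1))
  expect_gt(mean(hits), 0.8)
})
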