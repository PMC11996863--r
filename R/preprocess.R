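# Preprocessing: raw site table -> analysis-ready log2 matrix.
#
# The imputation model treats each site's observed log2 intensities as draws
# from a left-truncated normal (the MNAR mechanism censors the low tail at a
# per-sample detection limit), estimates (mu, sigma) per site by maximum
# likelihood, standardizes sites by their fits, and borrows the standardized
# profile of the k nearest neighbor sites to fill gaps — the KNN-TN scheme.

#' Log2-transform intensities
#'
#' @param x a [phospho_set] with raw (linear-scale) intensities, or a matrix
#' @return same type with log2 intensities; missing values stay missing
#' @export
log2_transform <- function(x) {
  m <- if (inherits(x, "phospho_set")) x$intensities else x
  bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-positive intensity at site ",
         rownames(m)[bad[1, 1]], ", sample ", colnames(m)[bad[1, 2]],
         ": cannot log2-transform")
  }
  lm2 <- log2(m)
  if (inherits(x, "phospho_set")) {
    x$intensities <- lm2
    x
  } else {
    lm2
  }
}

#' Filter to class-I phosphosites
#'
#' Retains sites whose localization probability is at or above `min_prob`
#' (the cutoff is inclusive: a probability of exactly 0.75 is class I).
#'
#' @param pset a [phospho_set]
#' @param min_prob localization probability cutoff in \[0, 1\] (default 0.75)
#' @export
filter_class1 <- function(pset, min_prob = 0.75) {
  stopifnot(min_prob >= 0, min_prob <= 1)
  keep <- !is.na(pset$sites$loc_prob) & pset$sites$loc_prob >= min_prob
  pset[keep, ]
}

#' Fit a left-truncated normal to observed values
#'
#' Maximum-likelihood estimate of (mu, sigma) for values observed above a
#' known truncation point (scalar, or one per value when detection limits
#' differ across samples). When every value lies more than 4 sample standard
#' deviations above its truncation point the truncation is negligible and the
#' plain sample moments are returned.
#'
#' @param values numeric vector of observed (non-missing) values
#' @param truncation_point scalar or per-value truncation point(s)
#' @param sigma_floor lower bound applied to the sigma estimate (default 0.05)
#' @return list with `mu`, `sigma`, `truncation_point`, `n_observed`,
#'   `method` ("moments" or "ml"); class `truncated_normal_fit`
#' @export
fit_truncated_normal <- function(values, truncation_point, sigma_floor = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) {
    stop("fit_truncated_normal needs at least 3 observed values (got ", n, ")")
  }
  tp <- rep_len(truncation_point, n)
  m <- mean(values)
  s <- stats::sd(values)
  out <- function(mu, sigma, method) {
    structure(list(mu = mu, sigma = max(sigma, sigma_floor),
                   truncation_point = truncation_point, n_observed = n,
                   method = method),
              class = "truncated_normal_fit")
  }
  if (s == 0 || all(values > tp + 4 * s)) {
    return(out(m, s, "moments"))
  }
  nll <- function(theta) {
    mu <- theta[1]
    sigma <- exp(theta[2])
    z <- (values - mu) / sigma
    alpha <- (tp - mu) / sigma
    # truncated density: phi(z) / (sigma * (1 - Phi(alpha)))
    sum(0.5 * z^2 + log(sigma) +
          stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE))
  }
  # Bounded optimization: with few observations sitting right at the
  # truncation point the unbounded likelihood degenerates (mu -> -Inf with
  # the hazard at the boundary growing without limit), so mu is kept within
  # a generous window of the sample mean and falls back to moments at the
  # boundary.
  lower <- c(m - 4 * s, log(sigma_floor))
  upper <- c(m + 2 * s, log(4 * s))
  fit <- tryCatch(
    stats::optim(c(m, log(max(s, sigma_floor))), nll, method = "L-BFGS-B",
                 lower = lower, upper = upper, control = list(maxit = 200)),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$par[1] <= lower[1] + 1e-8) {
    return(out(m, s, "moments"))
  }
  out(fit$par[1], exp(fit$par[2]), "ml")
}

#' KNN-TN imputation of a log2 intensity matrix
#'
#' Per-sample truncation points are the minimum observed log2 intensity in
#' each sample. Every site is standardized by its truncated-normal fit;
#' missing entries are filled with the mean standardized value of the site's
#' k nearest neighbors (Euclidean distance over jointly observed standardized
#' entries, scaled by the number of shared entries; at least `min_shared`
#' shared entries required; ties broken by row order), back-transformed by the
#' target site's (mu, sigma). Observed entries are never altered. Sites with
#' fewer than 3 observations, and entries with no usable neighbor, fall back
#' to the site's fitted mean (a message reports how many).
#'
#' @param x numeric matrix (sites x samples, log2 scale) with `NA` for
#'   missing entries; rownames required
#' @param k number of neighbors (default 10)
#' @param min_shared minimum jointly observed entries for a neighbor
#'   (default 4)
#' @param sigma_floor see [fit_truncated_normal()]
#' @return complete numeric matrix of the same shape
#' @export
impute_knn_tn <- function(x, k = 10, min_shared = 4, sigma_floor = 0.05) {
  stopifnot(is.matrix(x), k >= 1)
  if (!anyNA(x)) return(x)
  obs <- !is.na(x)
  n_obs_site <- rowSums(obs)
  trunc_sample <- apply(x, 2, function(col) {
    if (all(is.na(col))) -Inf else min(col, na.rm = TRUE)
  })

  n_sites <- nrow(x)
  mu <- sigma <- numeric(n_sites)
  few_obs <- n_obs_site < 3
  global_mean <- mean(x, na.rm = TRUE)
  global_sd <- stats::sd(as.numeric(x), na.rm = TRUE)
  for (g in seq_len(n_sites)) {
    if (few_obs[g]) {
      mu[g] <- if (n_obs_site[g] > 0) mean(x[g, ], na.rm = TRUE) else global_mean
      sigma[g] <- max(global_sd, sigma_floor)
    } else {
      o <- obs[g, ]
      fit <- fit_truncated_normal(x[g, o], trunc_sample[o], sigma_floor)
      mu[g] <- fit$mu
      sigma[g] <- fit$sigma
    }
  }
  if (any(few_obs)) {
    message(sum(few_obs), " site(s) with <3 observed values imputed from the fitted mean")
  }

  z <- (x - mu) / sigma
  z0 <- z
  z0[!obs] <- 0

  out <- x
  n_fallback <- 0L
  targets <- which(rowSums(!obs) > 0 & !few_obs)
  for (g in targets) {
    og <- obs[g, ]
    # scaled Euclidean distance over entries observed in both site g and the
    # candidate: sqrt(mean squared standardized difference)
    diffs <- z0[, og, drop = FALSE] -
      matrix(z0[g, og], n_sites, sum(og), byrow = TRUE)
    shared_mask <- obs[, og, drop = FALSE]
    diffs[!shared_mask] <- 0
    n_shared <- rowSums(shared_mask)
    d <- sqrt(rowSums(diffs^2) / pmax(n_shared, 1))
    usable <- n_shared >= min_shared
    usable[g] <- FALSE
    for (j in which(!og)) {
      cand <- usable & obs[, j]
      if (!any(cand)) {
        out[g, j] <- mu[g]
        n_fallback <- n_fallback + 1L
        next
      }
      idx <- which(cand)
      nb <- idx[order(d[idx], idx)][seq_len(min(k, length(idx)))]
      out[g, j] <- mu[g] + sigma[g] * mean(z[nb, j])
    }
  }
  for (g in which(few_obs)) {
    out[g, !obs[g, ]] <- mu[g]
  }
  if (n_fallback > 0) {
    message(n_fallback, " entr(ies) had no neighbor with >= ", min_shared,
            " shared observations; imputed from the fitted mean")
  }
  out
}

#' Median-normalize samples
#'
#' Shifts each sample additively so all sample medians equal the median of
#' the per-sample medians. The applied shifts are attached as attribute
#' `shifts`.
#'
#' @param x complete numeric matrix (sites x samples, log2 scale)
#' @export
median_normalize <- function(x) {
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("median_normalize requires a complete matrix")
  med <- apply(x, 2, stats::median)
  target <- stats::median(med)
  shifts <- target - med
  out <- sweep(x, 2, shifts, `+`)
  attr(out, "shifts") <- shifts
  out
}

#' Estimate a surrogate variable from model residuals
#'
#' Projects the known design out of the matrix and takes the first right
#' singular vector of the residual as the surrogate variable: a unit-norm
#' per-sample score vector, orthogonal to every design column by
#' construction, capturing the dominant unmodeled systematic variation
#' (batch drift). Its sign is fixed so the largest-|score| element is
#' positive.
#'
#' @param x complete numeric matrix (sites x samples)
#' @param design_matrix numeric model matrix (samples x covariates), full rank
#' @param n_sv number of surrogate variables; only 1 is supported
#' @return list with `scores` (unit norm, named by sample) and
#'   `variance_explained` (fraction of residual variance); class
#'   `surrogate_variable`
#' @export
estimate_surrogate_variable <- function(x, design_matrix, n_sv = 1) {
  stopifnot(is.matrix(x), n_sv == 1)
  X <- as.matrix(design_matrix)
  if (qr(X)$rank < ncol(X)) stop("design_matrix is rank deficient")
  if (nrow(X) != ncol(x)) stop("design_matrix rows must match samples")
  H <- X %*% solve(crossprod(X), t(X))
  R <- x - x %*% H
  total <- sum(R^2)
  if (total < 1e-12 * max(sum(x^2), 1)) {
    stop("residual matrix is (numerically) zero: no surrogate variable to estimate")
  }
  sv <- svd(R, nu = 0, nv = 1)
  scores <- sv$v[, 1]
  if (scores[which.max(abs(scores))] < 0) scores <- -scores
  names(scores) <- colnames(x)
  structure(
    list(scores = scores, variance_explained = sv$d[1]^2 / sum(sv$d^2)),
    class = "surrogate_variable"
  )
}

#' Remove the fitted surrogate-variable component from a matrix
#'
#' Re-estimates per-site coefficients jointly for the design and the
#' surrogate variable, then subtracts only the surrogate-variable term. The
#' adjusted matrix is intended for visualization, clustering and PCA; the
#' statistical tests include the surrogate variable as a covariate instead.
#'
#' @param x complete numeric matrix (sites x samples)
#' @param design_matrix numeric model matrix (samples x covariates)
#' @param sv a `surrogate_variable` from [estimate_surrogate_variable()]
#' @export
adjust_matrix_for_sv <- function(x, design_matrix, sv) {
  stopifnot(inherits(sv, "surrogate_variable"))
  if (all(sv$scores == 0)) return(x)
  X <- cbind(as.matrix(design_matrix), `_sv` = sv$scores)
  beta <- x %*% X %*% solve(crossprod(X))
  x - outer(beta[, ncol(X)], sv$scores)
}

#' PCA of samples for quality control
#'
#' Row-centered principal component analysis; returns per-sample scores on
#' the first two components with a deterministic sign convention (the
#' largest-|loading| site of each component is positive).
#'
#' @param x complete numeric matrix (sites x samples)
#' @return data.frame with sample_id, PC1, PC2; attribute `var_explained`
#' @export
pca_qc <- function(x) {
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("pca_qc requires a complete matrix")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  n_comp <- min(2, ncol(pc$x))
  scores <- pc$x[, seq_len(n_comp), drop = FALSE]
  for (j in seq_len(n_comp)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) {
      scores[, j] <- -scores[, j]
    }
  }
  out <- data.frame(sample_id = colnames(x),
                    PC1 = scores[, 1],
                    PC2 = if (n_comp >= 2) scores[, 2] else 0)
  rownames(out) <- NULL
  attr(out, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_comp)]
  out
}
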