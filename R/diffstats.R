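# Linear modeling with empirical-Bayes moderated statistics.
#
# Per site, ordinary least squares gives coefficients, unscaled standard
# errors and a residual variance s2_g on d_g degrees of freedom. Across
# sites, the residual variances are modeled as scaled F draws around a prior
# (d0, s0^2) estimated by moment-matching log s2 to a log-F distribution;
# posterior variances s2_post = (d0*s0^2 + d_g*s2_g) / (d0 + d_g) then yield
# t and F statistics with d0 + d_g denominator degrees of freedom. This is
# the classical variance-shrinkage scheme for small-sample omics designs,
# implemented here from its moment equations.

#' Per-cell-line insulin stimulation ratios
#'
#' The stimulation ratio of a site in a cell line is its insulin log2
#' intensity minus its basal log2 intensity, i.e. log2(treated/basal).
#' Cell lines missing either treatment are excluded with a warning.
#'
#' @param x complete log2 matrix (sites x samples)
#' @param design sample design data.frame (see [phospho_set()])
#' @return list with `ratios` (sites x cell lines) and `lines` (data.frame
#'   cell_line, phenotype, sex)
#' @export
paired_stimulation_ratios <- function(x, design) {
  stopifnot(is.matrix(x))
  lines <- unique(design$cell_line)
  has_both <- vapply(lines, function(l) {
    trt <- design$treatment[design$cell_line == l]
    all(c("basal", "insulin") %in% trt)
  }, logical(1))
  if (any(!has_both)) {
    warning("cell line(s) without both treatments excluded: ",
            paste(lines[!has_both], collapse = ", "))
  }
  lines <- lines[has_both]
  ratios <- vapply(lines, function(l) {
    ins <- design$sample_id[design$cell_line == l & design$treatment == "insulin"]
    bas <- design$sample_id[design$cell_line == l & design$treatment == "basal"]
    x[, ins] - x[, bas]
  }, numeric(nrow(x)))
  if (is.null(dim(ratios))) ratios <- matrix(ratios, nrow = nrow(x))
  dimnames(ratios) <- list(rownames(x), lines)
  info <- unique(design[design$cell_line %in% lines,
                        c("cell_line", "phenotype", "sex")])
  info <- info[match(lines, info$cell_line), ]
  rownames(info) <- NULL
  list(ratios = ratios, lines = info)
}

#' Ordinary least squares fits for every site
#'
#' @param x numeric matrix (sites x samples)
#' @param design_matrix numeric model matrix (samples x coefficients),
#'   full rank with more samples than coefficients
#' @return list (class `linear_fit`): `coefficients` (sites x p),
#'   `stdev_unscaled` (per-coefficient unscaled SE, sqrt of the diagonal of
#'   (X'X)^-1), `sigma2` (residual variances), `df_residual`, `cov_unscaled`
#'   ((X'X)^-1), `design`
#' @export
fit_linear_model <- function(x, design_matrix) {
  stopifnot(is.matrix(x))
  X <- as.matrix(design_matrix)
  if (nrow(X) != ncol(x)) stop("design_matrix rows must match samples")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(colnames(X)[setdiff(seq_len(ncol(X)), keep)], collapse = ", "))
  }
  if (nrow(X) <= ncol(X)) stop("need more samples than coefficients")
  XtXi <- chol2inv(chol(crossprod(X)))
  dimnames(XtXi) <- list(colnames(X), colnames(X))
  beta <- x %*% X %*% XtXi
  colnames(beta) <- colnames(X)
  res <- x - beta %*% t(X)
  df <- nrow(X) - ncol(X)
  structure(
    list(coefficients = beta,
         stdev_unscaled = sqrt(diag(XtXi)),
         sigma2 = rowSums(res^2) / df,
         df_residual = df,
         cov_unscaled = XtXi,
         design = X),
    class = "linear_fit"
  )
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used to solve trigamma(d0/2) = target.
trigamma_inverse <- function(y) {
  stopifnot(y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment-matching of log residual variances to a log-F distribution: solve
#' `trigamma(d0/2) = var(log s2) - trigamma(d_g/2)` for the prior degrees of
#' freedom d0 (via monotone trigamma inversion), then get the prior variance
#' s0^2 from the mean equation. A non-positive variance deficit gives
#' `d0 = Inf` (all sites share one variance) with
#' `s0^2 = exp(mean(log s2) - digamma(d_g/2) + log(d_g/2))`.
#'
#' @param s2 per-site residual variances (at least 10 positive values)
#' @param df residual degrees of freedom (scalar)
#' @return list with `df_prior` (possibly `Inf`) and `s2_prior`; class
#'   `moderation_params`
#' @export
fit_moderation <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (all(s2[is.finite(s2)] == 0)) stop("all residual variances are zero")
  if (sum(ok) < 10) stop("need at least 10 sites with positive residual variance")
  e <- log(s2[ok])
  e_mean <- mean(e)
  e_var <- stats::var(e)
  deficit <- e_var - trigamma(df / 2)
  if (deficit <= 0) {
    d0 <- Inf
    s0 <- exp(e_mean - digamma(df / 2) + log(df / 2))
  } else {
    d0 <- 2 * trigamma_inverse(deficit)
    s0 <- exp(e_mean - digamma(df / 2) + log(df / 2) +
                digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(df_prior = d0, s2_prior = s0), class = "moderation_params")
}

# Posterior (shrunken) variances.
posterior_s2 <- function(s2, df, params) {
  d0 <- params$df_prior
  if (is.infinite(d0)) {
    rep(params$s2_prior, length(s2))
  } else {
    (d0 * params$s2_prior + df * s2) / (d0 + df)
  }
}

# Effect and unscaled SE for a coefficient (by name/index) or a numeric
# contrast vector.
contrast_effect <- function(fit, contrast) {
  if (is.numeric(contrast) && length(contrast) == ncol(fit$coefficients)) {
    beta <- as.numeric(fit$coefficients %*% contrast)
    u <- sqrt(as.numeric(t(contrast) %*% fit$cov_unscaled %*% contrast))
  } else {
    beta <- fit$coefficients[, contrast]
    u <- fit$stdev_unscaled[[contrast]]
  }
  list(beta = unname(beta), u = unname(u))
}

#' Moderated t-test for one coefficient or contrast
#'
#' t = beta / (u * s_post) with d0 + d_g degrees of freedom; two-sided p
#' (standard normal when d0 is infinite).
#'
#' @param fit a `linear_fit`
#' @param params a `moderation_params`
#' @param contrast coefficient name/index, or a numeric contrast vector over
#'   the fit's coefficients
#' @return data.frame: site_id, log2FC, t, df_total, p, fdr
#' @export
moderated_t <- function(fit, params, contrast) {
  eff <- contrast_effect(fit, contrast)
  if (any(eff$u == 0)) stop("contrast has zero unscaled standard error")
  s2_post <- posterior_s2(fit$sigma2, fit$df_residual, params)
  tstat <- eff$beta / (eff$u * sqrt(s2_post))
  df_total <- fit$df_residual + params$df_prior
  p <- if (is.infinite(df_total)) {
    2 * stats::pnorm(-abs(tstat))
  } else {
    2 * stats::pt(-abs(tstat), df_total)
  }
  data.frame(site_id = rownames(fit$coefficients),
             log2FC = eff$beta, t = tstat, df_total = df_total,
             p = p, fdr = bh_fdr(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Moderated F-test over a set of contrasts
#'
#' F = beta_c' U^-1 beta_c / (k * s2_post) where U is the unscaled covariance
#' of the contrast estimates (i.e. the mean of squared moderated t statistics
#' after orthogonalizing the contrasts); p from F(k, d0 + d_g)
#' (chi-squared_k / k when d0 is infinite).
#'
#' @param fit a `linear_fit`
#' @param params a `moderation_params`
#' @param contrasts a coefficient-by-contrast numeric matrix (or a vector /
#'   names for a single contrast)
#' @return data.frame: site_id, F, df1, df2, p, fdr
#' @export
moderated_f <- function(fit, params, contrasts) {
  p_coef <- ncol(fit$coefficients)
  if (is.character(contrasts)) {
    C <- matrix(0, p_coef, length(contrasts))
    for (i in seq_along(contrasts)) {
      C[match(contrasts[i], colnames(fit$coefficients)), i] <- 1
    }
  } else {
    C <- as.matrix(contrasts)
    if (nrow(C) != p_coef) stop("contrast matrix must have one row per coefficient")
  }
  k <- ncol(C)
  U <- t(C) %*% fit$cov_unscaled %*% C
  Rc <- chol(U)
  beta_c <- fit$coefficients %*% C
  q <- beta_c %*% solve(Rc) # q q' = beta' U^-1 beta
  s2_post <- posterior_s2(fit$sigma2, fit$df_residual, params)
  Fstat <- rowSums(q^2) / (k * s2_post)
  df2 <- fit$df_residual + params$df_prior
  p <- if (is.infinite(df2)) {
    stats::pchisq(k * Fstat, k, lower.tail = FALSE)
  } else {
    stats::pf(Fstat, k, df2, lower.tail = FALSE)
  }
  data.frame(site_id = rownames(fit$coefficients),
             F = unname(Fstat), df1 = k, df2 = df2, p = p, fdr = bh_fdr(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: sort p ascending, q_i = min over j >= i of
#' p_j * m / j clipped at 1, returned in input order.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
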