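# The standard contrast battery for the paired insulin-stimulation design.
#
# Fixed contrast names:
#   ctl_ins_vs_bas    paired insulin response in control lines
#   t2d_ins_vs_bas    paired insulin response in T2D lines
#   t2d_vs_ctl_basal  unpaired CTL-vs-T2D difference in the basal state
#   t2d_vs_ctl_ins    unpaired CTL-vs-T2D difference under insulin
#   stim_ratio_diff   unpaired test on per-line stimulation ratios
#                     (the impaired/emergent interaction test)
#   sex_F             female-minus-male difference across all samples
#
# Paired contrasts use cell-line fixed effects in the design matrix, so the
# treatment coefficient is the within-line insulin response; unpaired
# contrasts adjust for the surrogate variable only. Each contrast family is
# fitted, moderated and FDR-adjusted on its own.

subset_sv <- function(sv, ids) {
  if (is.null(sv)) return(NULL)
  sv$scores[ids]
}

fit_and_test <- function(x, X, coef) {
  fit <- fit_linear_model(x, X)
  params <- fit_moderation(fit$sigma2, fit$df_residual)
  res <- moderated_t(fit, params, coef)
  attr(res, "moderation") <- params
  res
}

#' Run the full differential-testing battery
#'
#' Computes all six standard contrasts (see the contrast table in the
#' package's methods vignette) plus the moderated group F-test over the four
#' phenotype-by-treatment group means used to select sites for clustering.
#'
#' @param x complete, normalized log2 matrix (sites x samples)
#' @param design sample design data.frame
#' @param sv optional `surrogate_variable`; included as a covariate in every
#'   sample-level model
#' @return long-format data.frame with columns site_id, contrast, log2FC, t,
#'   df_total, p, fdr; the group F-test is attached as attribute `group_f`
#'   (data.frame site_id, F, df1, df2, p, fdr)
#' @export
run_differential <- function(x, design, sv = NULL) {
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("run_differential requires a complete (imputed) matrix")
  design$treatment <- factor(design$treatment, levels = c("basal", "insulin"))
  design$phenotype <- factor(design$phenotype, levels = c("CTL", "T2D"))
  design$sex <- factor(design$sex, levels = c("M", "F"))

  paired_one <- function(phen, name) {
    idx <- design$phenotype == phen
    d <- droplevels(design[idx, ])
    X <- stats::model.matrix(~ cell_line + treatment, d)
    svv <- subset_sv(sv, d$sample_id)
    if (!is.null(svv)) X <- cbind(X, sv = svv)
    res <- fit_and_test(x[, idx, drop = FALSE], X, "treatmentinsulin")
    res$contrast <- name
    res
  }
  unpaired_one <- function(trt, name) {
    idx <- design$treatment == trt
    d <- droplevels(design[idx, ])
    X <- stats::model.matrix(~ phenotype, d)
    svv <- subset_sv(sv, d$sample_id)
    if (!is.null(svv)) X <- cbind(X, sv = svv)
    res <- fit_and_test(x[, idx, drop = FALSE], X, "phenotypeT2D")
    res$contrast <- name
    res
  }

  out <- list(
    paired_one("CTL", "ctl_ins_vs_bas"),
    paired_one("T2D", "t2d_ins_vs_bas"),
    unpaired_one("basal", "t2d_vs_ctl_basal"),
    unpaired_one("insulin", "t2d_vs_ctl_ins")
  )

  # interaction: CTL-vs-T2D difference of per-line stimulation ratios; the
  # SV enters as the within-line insulin-minus-basal difference of scores,
  # the component of the batch drift that survives the pairing
  pr <- paired_stimulation_ratios(x, design)
  Xr <- stats::model.matrix(~ phenotype,
                            data.frame(phenotype = factor(pr$lines$phenotype,
                                                          levels = c("CTL", "T2D"))))
  if (!is.null(sv)) {
    d_sv <- vapply(pr$lines$cell_line, function(l) {
      ids <- design$sample_id[design$cell_line == l]
      trt <- design$treatment[design$cell_line == l]
      sv$scores[ids[trt == "insulin"]] - sv$scores[ids[trt == "basal"]]
    }, numeric(1))
    Xr <- cbind(Xr, sv = d_sv)
  }
  ratio_res <- fit_and_test(pr$ratios, Xr, "phenotypeT2D")
  ratio_res$contrast <- "stim_ratio_diff"
  out <- c(out, list(ratio_res))

  # sex dimorphism across all samples
  Xs <- stats::model.matrix(~ sex + phenotype + treatment, design)
  svv <- subset_sv(sv, design$sample_id)
  if (!is.null(svv)) Xs <- cbind(Xs, sv = svv)
  sex_res <- fit_and_test(x, Xs, "sexF")
  sex_res$contrast <- "sex_F"
  out <- c(out, list(sex_res))

  long <- do.call(rbind, out)
  long <- long[, c("site_id", "contrast", "log2FC", "t", "df_total", "p", "fdr")]
  rownames(long) <- NULL

  # moderated F over the 4 phenotype-by-treatment group means
  group <- factor(paste(design$phenotype, design$treatment, sep = "."))
  Xg <- stats::model.matrix(~ 0 + group)
  colnames(Xg) <- levels(group)
  if (!is.null(svv)) Xg <- cbind(Xg, sv = svv)
  fitg <- fit_linear_model(x, Xg)
  paramsg <- fit_moderation(fitg$sigma2, fitg$df_residual)
  k <- length(levels(group))
  C <- matrix(0, ncol(Xg), k - 1)
  rownames(C) <- colnames(Xg)
  for (i in 2:k) {
    C[levels(group)[1], i - 1] <- -1
    C[levels(group)[i], i - 1] <- 1
  }
  attr(long, "group_f") <- moderated_f(fitg, paramsg, C)
  long
}

#' Extract one contrast from the long differential table
#'
#' @param diff long-format result of [run_differential()]
#' @param contrast one of the fixed contrast names
#' @export
get_contrast <- function(diff, contrast) {
  if (!contrast %in% diff$contrast) {
    stop("contrast '", contrast, "' not present; available: ",
         paste(unique(diff$contrast), collapse = ", "))
  }
  out <- diff[diff$contrast == contrast, , drop = FALSE]
  rownames(out) <- NULL
  out
}
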