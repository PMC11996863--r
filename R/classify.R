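# The six-way signaling-class taxonomy.
#
# Class 1 sites are insulin-upregulated (log2FC >= +log2(fold), p < stim_p) in
# at least one phenotype; class 2 sites are downregulated symmetrically.
# Within a class, the CTL-vs-T2D difference in stimulation response (the
# interaction test on per-line ratios) splits sites into:
#   A  no significant difference (interaction p >= threshold)
#   B  "impaired":  significant difference, T2D response smaller in magnitude
#   C  "emergent":  significant difference, T2D response larger in magnitude
# The strict emergent filter additionally requires the T2D response itself to
# clear the fold/p thresholds.

#' Classify phosphosites into signaling classes
#'
#' @param diff long-format result of [run_differential()]; must contain the
#'   `ctl_ins_vs_bas`, `t2d_ins_vs_bas` and `stim_ratio_diff` contrasts
#' @param config a [pipeline_config()] supplying `stim_p`, `stim_fold`,
#'   `interaction_p`
#' @return data.frame, one row per site: `class` ("1A".."2C" or "none"),
#'   `strict_emergent` (TRUE/FALSE for C sites, NA otherwise),
#'   `sign_discordant`, plus the supporting statistics (ctl_log2FC, ctl_p,
#'   t2d_log2FC, t2d_p, interaction_p)
#' @export
classify_sites <- function(diff, config = pipeline_config()) {
  need <- c("ctl_ins_vs_bas", "t2d_ins_vs_bas", "stim_ratio_diff")
  missing_c <- setdiff(need, unique(diff$contrast))
  if (length(missing_c) > 0) {
    stop("diff is missing contrast(s): ", paste(missing_c, collapse = ", "))
  }
  ctl <- get_contrast(diff, "ctl_ins_vs_bas")
  t2d <- get_contrast(diff, "t2d_ins_vs_bas")
  int <- get_contrast(diff, "stim_ratio_diff")
  stopifnot(identical(ctl$site_id, t2d$site_id),
            identical(ctl$site_id, int$site_id))

  lfc_cut <- log2(config$stim_fold)
  up_c <- ctl$log2FC >= lfc_cut & ctl$p < config$stim_p
  dn_c <- ctl$log2FC <= -lfc_cut & ctl$p < config$stim_p
  up_t <- t2d$log2FC >= lfc_cut & t2d$p < config$stim_p
  dn_t <- t2d$log2FC <= -lfc_cut & t2d$p < config$stim_p

  discordant <- (up_c & dn_t) | (dn_c & up_t)
  class1 <- up_c | up_t
  class2 <- dn_c | dn_t
  # a sign-flipped site (both phenotypes significant, opposite directions) is
  # labeled by its CTL direction and flagged
  main <- ifelse(discordant, ifelse(up_c, "1", "2"),
                 ifelse(class1, "1", ifelse(class2, "2", NA)))

  interacts <- int$p < config$interaction_p
  sub <- ifelse(!interacts, "A",
                ifelse(abs(t2d$log2FC) < abs(ctl$log2FC), "B", "C"))
  cls <- ifelse(is.na(main), "none", paste0(main, sub))

  out <- data.frame(
    site_id = ctl$site_id,
    class = cls,
    sign_discordant = discordant,
    ctl_log2FC = ctl$log2FC, ctl_p = ctl$p,
    t2d_log2FC = t2d$log2FC, t2d_p = t2d$p,
    interaction_p = int$p,
    stringsAsFactors = FALSE
  )
  out$strict_emergent <- strict_emergent_filter(out, config)
  out
}

#' Strict emergent filter
#'
#' For emergent (subclass C) sites, flags whether the T2D stimulation
#' response itself meets the fold-change and p thresholds in the
#' insulin-stimulated comparison (|log2FC| >= log2(fold) and p < stim_p).
#' Non-C sites get `NA`.
#'
#' @param classification output of [classify_sites()] (the flag column it
#'   carries is recomputed here, so a partial frame with `class`,
#'   `t2d_log2FC`, `t2d_p` suffices)
#' @param config a [pipeline_config()]
#' @return logical vector aligned with `classification`
#' @export
strict_emergent_filter <- function(classification, config = pipeline_config()) {
  is_c <- classification$class %in% c("1C", "2C")
  flag <- rep(NA, nrow(classification))
  flag[is_c] <- abs(classification$t2d_log2FC[is_c]) >= log2(config$stim_fold) &
    classification$t2d_p[is_c] < config$stim_p
  flag
}

#' Call sex-dimorphic phosphosites
#'
#' A site is female-dominant (`F`) when its sex contrast passes the FDR
#' threshold with a higher female mean, male-dominant (`M`) when the male
#' mean is higher, otherwise `none`.
#'
#' @param diff long-format result of [run_differential()] containing the
#'   `sex_F` contrast (log2FC = female minus male)
#' @param fdr_threshold FDR cutoff (default 0.1)
#' @return data.frame: site_id, sex_dominance, sex_log2FC, sex_fdr
#' @export
call_sex_dimorphism <- function(diff, fdr_threshold = 0.1) {
  sx <- get_contrast(diff, "sex_F")
  dom <- ifelse(sx$fdr < fdr_threshold & sx$log2FC > 0, "F",
                ifelse(sx$fdr < fdr_threshold & sx$log2FC < 0, "M", "none"))
  data.frame(site_id = sx$site_id, sex_dominance = dom,
             sex_log2FC = sx$log2FC, sex_fdr = sx$fdr,
             stringsAsFactors = FALSE)
}
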