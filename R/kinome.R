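# Kinase-substrate motif inference.
#
# Each S/T-centered sequence window is scored against every kinase's PSSM
# (sum of log2 position probabilities over the flanks), calibrated to a
# percentile against that kinase's background score distribution, and the
# top-15 kinases by percentile are the site's biochemically predicted
# kinases. Enrichment of a kinase among regulated versus unregulated sites is
# summarized by a Haldane-corrected frequency factor and a one-sided Fisher
# exact test, BH-adjusted per side, with the more significant side reported.

PSSM_PROB_FLOOR <- 1e-4

#' Score a sequence window against one kinase PSSM
#'
#' score = sum over flank positions carrying a standard residue of
#' log2(matrix\[pos, residue\]), with a probability floor of 1e-4 before the
#' log. Positions outside the window and non-standard residues contribute 0.
#' The window center must be S or T (tyrosine-centered sites are outside the
#' S/T kinome and are skipped upstream).
#'
#' @param pssm position x residue probability matrix (rownames are signed
#'   flank positions, no 0)
#' @param window amino-acid string centered on the phosphoresidue
#' @return numeric raw score
#' @export
score_site <- function(pssm, window) {
  positions <- as.integer(rownames(pssm))
  # the phosphoacceptor sits at the window's own center (flanks
  # -floor(L/2) .. ceiling(L/2) - 1), so short windows score correctly
  center <- floor(nchar(window) / 2) + 1L
  ctr_res <- substr(window, center, center)
  if (!ctr_res %in% c("S", "T")) {
    warning("window center '", ctr_res, "' is not S/T; site skipped")
    return(NA_real_)
  }
  chars <- strsplit(window, "")[[1]]
  score <- 0
  for (i in seq_along(positions)) {
    idx <- center + positions[i]
    if (idx < 1 || idx > length(chars)) next
    res <- chars[idx]
    if (!res %in% AA_ALPHABET) next
    score <- score + log2(max(pssm[i, res], PSSM_PROB_FLOOR))
  }
  score
}

# Vectorized scoring of many windows against every kinase in the atlas.
# Returns a windows x kinases matrix of raw scores. Non-S/T-centered windows
# get NA rows.
score_windows <- function(atlas, windows) {
  stopifnot(inherits(atlas, "kinase_atlas"))
  flank_min <- atlas$flank_range[1]
  center <- -flank_min + 1L
  len <- atlas$flank_range[2] - flank_min + 1L
  n <- length(windows)
  chars <- matrix("", n, len)
  for (j in seq_len(len)) chars[, j] <- substr(windows, j, j)
  valid <- chars[, center] %in% c("S", "T")
  res_idx <- matrix(match(chars, AA_ALPHABET), n, len)
  out <- matrix(NA_real_, n, length(atlas$kinases),
                dimnames = list(names(windows), names(atlas$kinases)))
  for (ki in seq_along(atlas$kinases)) {
    pssm <- atlas$kinases[[ki]]
    logp <- log2(pmax(pssm, PSSM_PROB_FLOOR))
    positions <- as.integer(rownames(pssm))
    s <- numeric(n)
    for (i in seq_along(positions)) {
      col <- center + positions[i]
      if (col < 1 || col > len) next
      ri <- res_idx[, col]
      contrib <- ifelse(is.na(ri), 0, logp[i, ][ifelse(is.na(ri), 1L, ri)])
      s <- s + contrib
    }
    out[, ki] <- ifelse(valid, s, NA_real_)
  }
  out
}

#' Percentile of a raw score in a background distribution
#'
#' 100 * (number of background scores <= raw) / background size.
#'
#' @param raw numeric raw score(s)
#' @param background sorted numeric background scores (non-empty)
#' @export
percentile_score <- function(raw, background) {
  if (length(background) == 0) stop("empty background distribution")
  background <- sort(background)
  100 * findInterval(raw, background, left.open = FALSE) / length(background)
}

#' Predict kinases for phosphosites
#'
#' Scores every S/T-centered window against every atlas kinase, converts raw
#' scores to background percentiles, and marks the `top_k` kinases per site
#' (ranked by percentile, ties broken by raw score, then kinase name) as
#' biochemically predicted. Tyrosine-centered windows are excluded with a
#' warning.
#'
#' @param windows named character vector of sequence windows (names =
#'   site_id), or a [phospho_set] (its windows are used)
#' @param atlas a `kinase_atlas` with background distributions
#' @param top_k number of predicted kinases per site (default 15; capped at
#'   the atlas size)
#' @return list of class `site_predictions`: `raw` and `percentile`
#'   (site x kinase matrices), `predicted` (logical site x kinase matrix),
#'   `top_k`
#' @export
predict_kinases <- function(windows, atlas, top_k = 15) {
  if (inherits(windows, "phospho_set")) {
    windows <- stats::setNames(windows$sites$window, windows$sites$site_id)
  }
  if (length(atlas$background) != length(atlas$kinases)) {
    stop("atlas has no background score distributions; cannot calibrate percentiles")
  }
  raw <- score_windows(atlas, windows)
  excluded <- rowSums(is.na(raw)) == ncol(raw)
  if (any(excluded)) {
    warning(sum(excluded), " non-S/T-centered site(s) excluded from kinome scoring")
    raw <- raw[!excluded, , drop = FALSE]
  }
  pct <- raw
  for (kn in colnames(raw)) {
    pct[, kn] <- percentile_score(raw[, kn], atlas$background[[kn]])
  }
  k <- min(top_k, ncol(raw))
  kin_order <- order(colnames(raw)) # name tie-break
  predicted <- matrix(FALSE, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  for (i in seq_len(nrow(raw))) {
    o <- order(-pct[i, ], -raw[i, ], kin_order)
    predicted[i, o[seq_len(k)]] <- TRUE
  }
  structure(list(raw = raw, percentile = pct, predicted = predicted,
                 top_k = k),
            class = "site_predictions")
}

#' Split sites into regulated and unregulated sets for kinome enrichment
#'
#' For the basal CTL-vs-T2D comparison the FDR cut is 0.5; for the
#' insulin-stimulated ("treated") comparison it is 0.25. Regulated-up sites
#' have FDR < cut and log2FC > 0, regulated-down FDR < cut and log2FC < 0;
#' unregulated sites have FDR > cut (inequalities strict on both sides, so a
#' site exactly at the cut belongs to neither).
#'
#' @param diff long-format result of [run_differential()]
#' @param comparison "basal" or "treated"
#' @param fdr_cut override of the comparison's default cut
#' @return list with character vectors `up`, `down`, `unregulated`
#' @export
define_regulated_sets <- function(diff, comparison = c("basal", "treated"),
                                  fdr_cut = NULL) {
  comparison <- match.arg(comparison)
  contrast <- switch(comparison, basal = "t2d_vs_ctl_basal",
                     treated = "t2d_vs_ctl_ins")
  if (is.null(fdr_cut)) fdr_cut <- switch(comparison, basal = 0.5, treated = 0.25)
  res <- get_contrast(diff, contrast)
  list(
    up = res$site_id[res$fdr < fdr_cut & res$log2FC > 0],
    down = res$site_id[res$fdr < fdr_cut & res$log2FC < 0],
    unregulated = res$site_id[res$fdr > fdr_cut]
  )
}

#' Haldane-corrected frequency factor of a 2x2 table
#'
#' Adds 0.5 to all four cells, then returns the log2 ratio of the corrected
#' predicted fractions: log2((a'/(a'+b')) / (c'/(c'+d'))). The correction
#' keeps the ratio finite for zero counts.
#'
#' @param table numeric vector c(a, b, c, d): a = regulated & predicted,
#'   b = regulated & not predicted, c = unregulated & predicted,
#'   d = unregulated & not predicted
#' @export
haldane_frequency_factor <- function(table) {
  stopifnot(length(table) == 4, all(table >= 0))
  ct <- table + 0.5
  log2((ct[1] / (ct[1] + ct[2])) / (ct[3] / (ct[3] + ct[4])))
}

#' One-sided Fisher exact test for enrichment
#'
#' p = P(A >= a) under the hypergeometric law with the table's margins fixed
#' (the enrichment direction). Counts must be non-negative integers; the
#' Haldane correction is applied only to the frequency factor, not here.
#'
#' @param table integer vector c(a, b, c, d) as in
#'   [haldane_frequency_factor()]
#' @export
fisher_one_sided <- function(table) {
  stopifnot(length(table) == 4)
  if (any(table < 0)) stop("contingency counts must be non-negative")
  if (any(table != round(table))) stop("contingency counts must be integers")
  a <- table[1]; b <- table[2]; c <- table[3]; d <- table[4]
  # A ~ hypergeometric: population a+b regulated / c+d unregulated,
  # a+c predicted draws
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Kinase enrichment among regulated phosphosites
#'
#' For each kinase and each regulated side (up, down), builds the 2x2 table
#' of predicted/not-predicted against side/unregulated, computes the
#' one-sided Fisher p and the Haldane-corrected frequency factor, adjusts p
#' across kinases within each side (Benjamini-Hochberg), and reports for
#' every kinase the side with the smaller adjusted p. Kinases with adjusted
#' p <= `display_adjp` are flagged display-significant. An empty regulated
#' side is skipped.
#'
#' @param predictions a `site_predictions` from [predict_kinases()]
#' @param reg_sets output of [define_regulated_sets()]
#' @param display_adjp display-significance cutoff on the adjusted p
#'   (default 0.1)
#' @return data.frame per kinase: kinase, side, a, b, c, d,
#'   frequency_factor, p, adj_p, significant; the per-side tables are kept in
#'   attribute `per_side`
#' @export
kinome_enrichment <- function(predictions, reg_sets, display_adjp = 0.1) {
  stopifnot(inherits(predictions, "site_predictions"))
  pred <- predictions$predicted
  unreg <- intersect(reg_sets$unregulated, rownames(pred))
  if (length(unreg) == 0) stop("empty unregulated set")
  kinases <- colnames(pred)
  c_cnt <- colSums(pred[unreg, , drop = FALSE])
  n_unreg <- length(unreg)

  side_table <- function(side_sites, side) {
    sites <- intersect(side_sites, rownames(pred))
    if (length(sites) == 0) return(NULL)
    a <- colSums(pred[sites, , drop = FALSE])
    b <- length(sites) - a
    d <- n_unreg - c_cnt
    p <- vapply(kinases, function(kn) {
      fisher_one_sided(c(a[kn], b[kn], c_cnt[kn], d[kn]))
    }, numeric(1))
    ff <- vapply(kinases, function(kn) {
      haldane_frequency_factor(c(a[kn], b[kn], c_cnt[kn], d[kn]))
    }, numeric(1))
    data.frame(kinase = kinases, side = side,
               a = unname(a), b = unname(b), c = unname(c_cnt), d = unname(d),
               frequency_factor = unname(ff), p = unname(p),
               adj_p = bh_fdr(unname(p)),
               stringsAsFactors = FALSE)
  }
  per_side <- list(up = side_table(reg_sets$up, "up"),
                   down = side_table(reg_sets$down, "down"))
  if (is.null(per_side$up) && is.null(per_side$down)) {
    stop("both regulated sides are empty")
  }
  both <- do.call(rbind, per_side)
  # keep, per kinase, the side with the smaller adjusted p (ties: smaller
  # raw p, then "up")
  both$side_rank <- match(both$side, c("up", "down"))
  o <- order(both$kinase, both$adj_p, both$p, both$side_rank)
  both <- both[o, ]
  best <- both[!duplicated(both$kinase), ]
  best$side_rank <- NULL
  best$significant <- best$adj_p <= display_adjp
  best <- best[order(best$adj_p, best$p, best$kinase), ]
  rownames(best) <- NULL
  attr(best, "per_side") <- per_side
  best
}

#' Bubble-plot coordinates for kinome enrichment
#'
#' Convenience extractor emitting (kinase, frequency factor, adjusted p,
#' side) for the display-significant kinases, the quantities a bubble map of
#' the kinome screen plots.
#'
#' @param enrichment output of [kinome_enrichment()]
#' @param only_significant keep only display-significant kinases
#'   (default TRUE)
#' @export
kinome_bubble_data <- function(enrichment, only_significant = TRUE) {
  out <- enrichment[, c("kinase", "frequency_factor", "adj_p", "side")]
  if (only_significant) out <- out[enrichment$significant, , drop = FALSE]
  rownames(out) <- NULL
  out
}
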