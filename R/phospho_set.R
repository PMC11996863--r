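#' phosflow: differential phosphoproteomics of paired insulin-stimulation designs
#'
#' The package analyses phosphosite intensity tables from experiments in which
#' hepatocyte (or other) cell lines derived from control and type 2 diabetes
#' (T2D) donors are each measured in a basal and an insulin-stimulated state.
#' It covers the full path from raw intensities to biology: preprocessing
#' (log2, class-I localization filtering, truncated-normal KNN imputation,
#' median normalization, surrogate-variable adjustment), empirical-Bayes
#' moderated t/F statistics on the paired design, a six-way signaling-class
#' taxonomy separating impaired from emergent insulin responses, hierarchical
#' clustering with variable-height cutting, over-representation analysis, and
#' kinase substrate-motif enrichment. A synthetic-data generator with planted
#' ground truth makes every stage testable.
#'
#' @keywords internal
"_PACKAGE"

# Standard 20-residue alphabet used for sequence windows and PSSMs.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a phosphosite data set
#'
#' Bundles per-site metadata, a sites-by-samples intensity matrix, and the
#' sample design into a single validated object, the central container of the
#' package (analogous to limma's `EList`).
#'
#' @param sites data.frame with columns `site_id`, `gene`, `residue`
#'   (one of S/T/Y), `position` (1-based protein coordinate), `window`
#'   (amino-acid string centered on the phosphoresidue; may be `NA` while
#'   windows are pending), `loc_prob` (localization probability in \[0, 1\]).
#' @param intensities numeric matrix, one row per site (rownames = `site_id`),
#'   one column per sample. Values must be non-negative; missing measurements
#'   are `NA`, never 0.
#' @param design data.frame with columns `sample_id`, `cell_line`,
#'   `phenotype` (`CTL`/`T2D`), `sex` (`M`/`F`), `treatment`
#'   (`basal`/`insulin`). `sample_id` must match the intensity columns.
#'
#' @return An object of class `phospho_set`.
#' @export
phospho_set <- function(sites, intensities, design) {
  stopifnot(is.data.frame(sites), is.matrix(intensities), is.data.frame(design))
  required_site_cols <- c("site_id", "gene", "residue", "position", "window", "loc_prob")
  missing_cols <- setdiff(required_site_cols, names(sites))
  if (length(missing_cols) > 0) {
    stop("sites is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  required_design_cols <- c("sample_id", "cell_line", "phenotype", "sex", "treatment")
  missing_cols <- setdiff(required_design_cols, names(design))
  if (length(missing_cols) > 0) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  dup <- sites$site_id[duplicated(sites$site_id)]
  if (length(dup) > 0) {
    stop("duplicate site_id: ", paste(unique(dup), collapse = ", "))
  }
  if (nrow(intensities) != nrow(sites)) {
    stop("intensities has ", nrow(intensities), " rows but sites has ", nrow(sites))
  }
  if (is.null(rownames(intensities))) rownames(intensities) <- sites$site_id
  if (nrow(sites) > 0 &&
      !identical(rownames(intensities), as.character(sites$site_id))) {
    stop("rownames(intensities) must equal sites$site_id in order")
  }
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  if (!identical(colnames(intensities), as.character(design$sample_id))) {
    stop("colnames(intensities) must equal design$sample_id in order")
  }
  if (!all(design$phenotype %in% c("CTL", "T2D"))) {
    stop("phenotype must be CTL or T2D")
  }
  if (!all(design$sex %in% c("M", "F"))) stop("sex must be M or F")
  if (!all(design$treatment %in% c("basal", "insulin"))) {
    stop("treatment must be basal or insulin")
  }
  per_line <- table(design$cell_line, design$treatment)
  if (any(per_line > 1)) {
    stop("a cell line has more than one sample for the same treatment")
  }
  if (!all(sites$residue %in% c("S", "T", "Y"))) stop("residue must be S, T or Y")
  bad_prob <- !is.na(sites$loc_prob) & (sites$loc_prob < 0 | sites$loc_prob > 1)
  if (any(bad_prob)) {
    stop("loc_prob outside [0, 1] for site(s): ",
         paste(utils::head(sites$site_id[bad_prob]), collapse = ", "))
  }
  has_window <- !is.na(sites$window)
  if (any(has_window)) {
    ctr <- window_center_residue(sites$window[has_window])
    mismatch <- ctr != sites$residue[has_window]
    if (any(mismatch)) {
      stop("window center does not equal residue for site(s): ",
           paste(utils::head(sites$site_id[has_window][mismatch]), collapse = ", "))
    }
  }
  neg <- which(!is.na(intensities) & intensities < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative intensity at site ", rownames(intensities)[neg[1, 1]],
         ", sample ", colnames(intensities)[neg[1, 2]])
  }
  structure(
    list(sites = sites, intensities = intensities, design = design),
    class = "phospho_set"
  )
}

# Center residue of a window string: windows span flank_min..flank_max around
# the phosphoresidue at position 0, so the center index is nchar-after-center
# agnostic; we store windows with attribute-free convention center = position
# -flank_min + 1 and recover it from the stored flank attribute when present,
# else assume the canonical -5..+4 layout used throughout the package.
window_center_residue <- function(windows, flank_min = NULL) {
  if (is.null(flank_min)) {
    # canonical layout: length L windows have flanks -(L/2)..(L/2 - 1)
    flank_min <- -floor(nchar(windows) / 2)
  }
  substr(windows, -flank_min + 1L, -flank_min + 1L)
}

#' @export
print.phospho_set <- function(x, ...) {
  cat("phospho_set: ", nrow(x$sites), " sites x ", nrow(x$design), " samples\n", sep = "")
  cat("  phenotypes: ", paste(names(table(x$design$phenotype)),
                              table(x$design$phenotype), collapse = ", "), "\n", sep = "")
  n_miss <- sum(is.na(x$intensities))
  cat(sprintf("  missing values: %d (%.1f%%)\n", n_miss,
              100 * n_miss / length(x$intensities)))
  invisible(x)
}

#' @export
dim.phospho_set <- function(x) dim(x$intensities)

#' Subset a phosphosite data set by sites and/or samples
#'
#' @param x a `phospho_set`
#' @param i site index (logical, integer or site_id character)
#' @param j sample index (logical, integer or sample_id character)
#' @param ... ignored
#' @export
`[.phospho_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$sites))
  if (missing(j)) j <- seq_len(nrow(x$design))
  if (is.character(i)) i <- match(i, x$sites$site_id)
  if (is.character(j)) j <- match(j, x$design$sample_id)
  phospho_set(
    sites = x$sites[i, , drop = FALSE],
    intensities = x$intensities[i, j, drop = FALSE],
    design = x$design[j, , drop = FALSE]
  )
}
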