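# Readers and writers for the plain-text interchange formats used by the
# pipeline: site-table TSV, design CSV, GMT gene sets, and the tabular PSSM
# dialect (kinase, position, 20 residue columns) with a companion background
# score table. All writers emit deterministic column order; all readers reject
# ambiguous input rather than guessing.

SITE_META_COLS <- c("site_id", "gene", "residue", "position", "window", "loc_prob")

#' Write a phosphosite table to TSV
#'
#' One row per site: the six metadata columns followed by one intensity column
#' per sample. Missing intensities are written as `NA`.
#'
#' @param pset a [phospho_set]
#' @param path output file
#' @export
write_site_table <- function(pset, path) {
  df <- cbind(pset$sites[, SITE_META_COLS],
              as.data.frame(pset$intensities, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phosphosite table from TSV
#'
#' Inverse of [write_site_table()]; requires a separate design table
#' ([read_design()]) to build a full [phospho_set]. Empty cells and `NA` are
#' treated as missing measurements (never as zero).
#'
#' @param path TSV written by [write_site_table()] (or following its contract)
#' @param design sample design data.frame whose `sample_id`s name the
#'   intensity columns
#' @return a [phospho_set]
#' @export
read_site_table <- function(path, design) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          na.strings = c("NA", ""), colClasses = NA,
                          stringsAsFactors = FALSE, quote = "")
  missing_cols <- setdiff(SITE_META_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("site table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  dup <- df$site_id[duplicated(df$site_id)]
  if (length(dup) > 0) {
    stop("duplicate site_id in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
  sample_cols <- setdiff(names(df), SITE_META_COLS)
  intens <- as.matrix(df[, sample_cols, drop = FALSE])
  if (!is.numeric(intens)) {
    bad <- which(!vapply(df[sample_cols], is.numeric, logical(1)))
    first_col <- sample_cols[bad[1]]
    vals <- df[[first_col]]
    first_row <- which(!is.na(vals) & is.na(suppressWarnings(as.numeric(vals))))[1]
    stop("non-numeric intensity in column '", first_col, "', row ",
         if (is.na(first_row)) "?" else first_row, " (site ",
         if (is.na(first_row)) "?" else df$site_id[first_row], ")")
  }
  rownames(intens) <- df$site_id
  design <- design[match(sample_cols, design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id)) {
    stop("design does not cover intensity column(s): ",
         paste(setdiff(sample_cols, design$sample_id), collapse = ", "))
  }
  phospho_set(df[, SITE_META_COLS], intens, design)
}

#' Write / read the sample design table (CSV)
#'
#' @param design data.frame with columns sample_id, cell_line, phenotype,
#'   sex, treatment
#' @param path file path
#' @export
write_design <- function(design, path) {
  cols <- c("sample_id", "cell_line", "phenotype", "sex", "treatment")
  utils::write.csv(design[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "cell_line", "phenotype", "sex", "treatment")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in ", path)
  df
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then one or more member gene symbols. Blank lines are skipped.
#'
#' @param path GMT file
#' @return a named list of character vectors with a `description` attribute
#'   (named character vector), class `gene_set_collection`
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    stop("GMT line ", line_no[which(n_fields < 3)[1]],
         " has fewer than 3 tab-separated fields")
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name: ", nm[duplicated(nm)][1])
  }
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  names(desc) <- nm
  structure(sets, description = desc, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param sets a `gene_set_collection` (or plain named list of character
#'   vectors) to serialize
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a kinase atlas from PSSM tables
#'
#' The PSSM file is long-format TSV with columns `kinase`, `position` and the
#' 20 standard residue columns holding position probabilities; position 0 (the
#' phosphoacceptor itself) is excluded. Rows whose probabilities do not sum to
#' 1 are renormalized (with a warning when off by more than 1e-6). A companion
#' background table (columns `kinase`, `score`) supplies the raw-score
#' distribution each kinase's percentiles are calibrated against.
#'
#' @param path PSSM TSV
#' @param background_path optional companion TSV of background scores
#' @return a `kinase_atlas`: list with elements `kinases` (named list of
#'   position x residue probability matrices), `background` (named list of
#'   sorted numeric vectors, possibly empty), `flank_range`.
#' @export
read_pssm_matrices <- function(path, background_path = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("kinase", "position", AA_ALPHABET), names(df))
  if (length(missing_cols) > 0) {
    stop("PSSM table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  probs <- as.matrix(df[, AA_ALPHABET])
  if (any(probs < 0)) {
    bad <- which(rowSums(probs < 0) > 0)[1]
    stop("negative PSSM entry for kinase ", df$kinase[bad],
         " position ", df$position[bad])
  }
  if (any(df$position == 0)) stop("PSSM contains position 0 (center excluded)")
  positions <- sort(unique(df$position))
  kin_names <- unique(df$kinase)
  kinases <- lapply(kin_names, function(kn) {
    sub <- df[df$kinase == kn, , drop = FALSE]
    if (!setequal(sub$position, positions)) {
      stop("kinase ", kn, " is missing position row(s): ",
           paste(setdiff(positions, sub$position), collapse = ", "))
    }
    sub <- sub[order(sub$position), , drop = FALSE]
    m <- as.matrix(sub[, AA_ALPHABET])
    rs <- rowSums(m)
    if (any(abs(rs - 1) > 1e-6)) {
      warning("PSSM rows for kinase ", kn, " renormalized (max |sum - 1| = ",
              format(max(abs(rs - 1))), ")")
    }
    m <- m / rs
    dimnames(m) <- list(as.character(sub$position), AA_ALPHABET)
    m
  })
  names(kinases) <- kin_names
  background <- list()
  if (!is.null(background_path)) {
    bg <- utils::read.table(background_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    stopifnot(all(c("kinase", "score") %in% names(bg)))
    background <- lapply(split(bg$score, bg$kinase), sort)
    background <- background[intersect(kin_names, names(background))]
  }
  structure(
    list(kinases = kinases, background = background,
         flank_range = range(positions)),
    class = "kinase_atlas"
  )
}

#' @rdname read_pssm_matrices
#' @param atlas a `kinase_atlas` to serialize
#' @export
write_pssm_matrices <- function(atlas, path, background_path = NULL) {
  rows <- lapply(names(atlas$kinases), function(kn) {
    m <- atlas$kinases[[kn]]
    data.frame(kinase = kn, position = as.integer(rownames(m)),
               as.data.frame(m, check.names = FALSE), check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(background_path) && length(atlas$background) > 0) {
    bg <- data.frame(
      kinase = rep(names(atlas$background), lengths(atlas$background)),
      score = unlist(atlas$background, use.names = FALSE)
    )
    utils::write.table(bg, background_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.kinase_atlas <- function(x, ...) {
  cat("kinase_atlas: ", length(x$kinases), " kinases, flank positions ",
      x$flank_range[1], "..", x$flank_range[2], "\n", sep = "")
  cat("  background distributions: ", length(x$background), "\n", sep = "")
  invisible(x)
}
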