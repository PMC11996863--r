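# End-to-end orchestration: raw site table -> preprocessed matrix ->
# differential statistics -> classes, clusters, ORA and kinome enrichment.

#' Preprocess a raw phosphosite table
#'
#' log2 transform, class-I filter, KNN-TN imputation, median normalization,
#' surrogate-variable estimation. The covariate model projected out before
#' the residual SVD contains intercept, phenotype, treatment and sex (not the
#' cell-line fixed effects: with one coefficient per line little residual
#' dimension would remain for a batch vector on a design this size).
#'
#' @param pset a [phospho_set] with raw intensities
#' @param config a [pipeline_config()]
#' @return list: `matrix` (complete normalized log2 matrix), `pset` (the
#'   filtered [phospho_set]), `sv` (a `surrogate_variable`), `adjusted`
#'   (SV-subtracted matrix for visualization/clustering), `pca`
#'   (per-sample scores on the adjusted matrix)
#' @export
preprocess_pipeline <- function(pset, config = pipeline_config()) {
  pset <- log2_transform(pset)
  pset <- filter_class1(pset, config$loc_prob_min)
  m <- impute_knn_tn(pset$intensities, k = config$impute_k,
                     min_shared = config$impute_min_shared,
                     sigma_floor = config$sigma_floor)
  m <- median_normalize(m)
  d <- pset$design
  mod <- stats::model.matrix(
    ~ phenotype + treatment + sex,
    data.frame(phenotype = factor(d$phenotype, c("CTL", "T2D")),
               treatment = factor(d$treatment, c("basal", "insulin")),
               sex = factor(d$sex, c("M", "F")))
  )
  sv <- estimate_surrogate_variable(m, mod)
  adjusted <- adjust_matrix_for_sv(m, mod, sv)
  list(matrix = m, pset = pset, sv = sv, adjusted = adjusted,
       pca = pca_qc(adjusted))
}

#' Run the full analysis pipeline
#'
#' Chains preprocessing, the differential-contrast battery, signaling-class
#' and sex-dimorphism calls, F-selected hierarchical clustering with
#' variable-height cutting, per-cluster and per-class ORA, and the basal and
#' insulin-stimulated kinome enrichment screens.
#'
#' @param pset a [phospho_set] with raw intensities
#' @param gene_sets optional `gene_set_collection` for ORA
#' @param atlas optional `kinase_atlas` (with backgrounds) for the kinome
#'   stages
#' @param config a [pipeline_config()]
#' @return named list with every stage result (see the methods vignette)
#' @export
run_pipeline <- function(pset, gene_sets = NULL, atlas = NULL,
                         config = pipeline_config()) {
  prep <- preprocess_pipeline(pset, config)
  diff <- run_differential(prep$matrix, prep$pset$design, prep$sv)
  classification <- classify_sites(diff, config)
  sex <- call_sex_dimorphism(diff, config$sex_fdr)

  group_f <- attr(diff, "group_f")
  sel <- group_f$site_id[group_f$fdr < config$cluster_fdr]
  clusters <- NULL
  if (length(sel) >= 2) {
    zm <- suppressWarnings(zscore_rows(prep$adjusted[sel, , drop = FALSE]))
    hc <- hcluster(zm, config$linkage)
    clusters <- data.frame(
      site_id = rownames(zm),
      cluster = unname(cut_variable_height(hc, config$min_cluster_size,
                                           config$split_fraction)[rownames(zm)]),
      stringsAsFactors = FALSE
    )
  }

  ora <- NULL
  if (!is.null(gene_sets)) {
    universe <- unique(prep$pset$sites$gene)
    queries <- list()
    if (!is.null(clusters)) {
      for (cl in sort(unique(clusters$cluster))) {
        queries[[paste0("cluster_", cl)]] <-
          map_sites_to_genes(clusters$site_id[clusters$cluster == cl])
      }
    }
    classified <- classification$site_id[classification$class != "none"]
    if (length(classified) > 0) {
      queries[["regulated"]] <- map_sites_to_genes(classified)
    }
    ora <- do.call(rbind, lapply(names(queries), function(qn) {
      res <- ora_test(queries[[qn]], gene_sets, universe)
      cbind(query = qn, res, stringsAsFactors = FALSE)
    }))
  }

  kinome <- NULL
  if (!is.null(atlas)) {
    predictions <- predict_kinases(prep$pset, atlas, config$top_k)
    kin_one <- function(comparison, cut) {
      sets <- define_regulated_sets(diff, comparison, cut)
      if (length(sets$up) + length(sets$down) == 0) return(NULL)
      kinome_enrichment(predictions, sets, config$kinome_display_adjp)
    }
    kinome <- list(
      predictions = predictions,
      basal = kin_one("basal", config$kinome_fdr_basal),
      treated = kin_one("treated", config$kinome_fdr_treated)
    )
  }

  list(prep = prep, diff = diff, group_f = group_f,
       classification = classification, sex = sex, clusters = clusters,
       ora = ora, kinome = kinome, config = config)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pipeline results as TSV tables
#'
#' Deterministic column order and formatting, so a rerun with the same seed
#' produces byte-identical files.
#'
#' @param results output of [run_pipeline()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_pipeline_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, name)
    write_tsv(df, p)
    paths <<- c(paths, p)
  }
  mat <- results$prep$matrix
  emit(data.frame(site_id = rownames(mat),
                  as.data.frame(mat, check.names = FALSE),
                  check.names = FALSE), "normalized_matrix.tsv")
  emit(data.frame(sample_id = names(results$prep$sv$scores),
                  sv_score = unname(results$prep$sv$scores)), "surrogate_variable.tsv")
  emit(results$prep$pca, "pca_scores.tsv")
  emit(results$diff, "differential.tsv")
  emit(results$group_f, "group_f.tsv")
  emit(results$classification, "classification.tsv")
  emit(results$sex, "sex_dimorphism.tsv")
  if (!is.null(results$clusters)) emit(results$clusters, "clusters.tsv")
  if (!is.null(results$ora)) emit(results$ora, "ora.tsv")
  if (!is.null(results$kinome)) {
    if (!is.null(results$kinome$basal)) {
      emit(results$kinome$basal, "kinome_basal.tsv")
    }
    if (!is.null(results$kinome$treated)) {
      emit(results$kinome$treated, "kinome_treated.tsv")
    }
    pred <- results$kinome$predictions
    long <- data.frame(
      site_id = rep(rownames(pred$percentile), ncol(pred$percentile)),
      kinase = rep(colnames(pred$percentile), each = nrow(pred$percentile)),
      raw_score = as.vector(pred$raw),
      percentile = as.vector(pred$percentile),
      predicted = as.vector(pred$predicted)
    )
    emit(long[long$predicted, , drop = FALSE], "kinase_predictions.tsv")
  }
  invisible(paths)
}
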