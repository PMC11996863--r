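# Configuration objects. Thresholds follow the analysis conventions of the
# study design the package targets; every value is overridable, either in code
# or through a YAML config file consumed by the command-line interface.

#' Pipeline configuration
#'
#' All thresholds and tuning parameters of the analysis stages, with the
#' defaults used throughout:
#' \describe{
#'   \item{loc_prob_min}{class-I localization probability cutoff (0.75,
#'     inclusive).}
#'   \item{stim_p, stim_fold}{per-phenotype insulin-response calls require
#'     p < 0.05 and a fold change of at least 1.5 (|log2FC| >= log2(1.5)).}
#'   \item{interaction_p}{p cutoff (0.05) on the CTL-vs-T2D difference in
#'     stimulation response that separates subclasses A from B/C.}
#'   \item{sex_fdr}{FDR cutoff (0.10) for sex-dimorphism calls.}
#'   \item{cluster_fdr}{moderated-F FDR cutoff (0.10) selecting sites for
#'     hierarchical clustering.}
#'   \item{kinome_fdr_basal, kinome_fdr_treated}{FDR cuts defining regulated
#'     sites for kinase enrichment: 0.5 for the basal CTL-vs-T2D comparison,
#'     0.25 for the insulin-stimulated comparison.}
#'   \item{kinome_display_adjp}{adjusted-p cutoff (0.1) for display-significant
#'     kinases.}
#'   \item{top_k}{number of top-ranked kinases treated as biochemically
#'     predicted per site (15).}
#'   \item{impute_k, impute_min_shared}{KNN-TN imputation neighbors (10) and
#'     minimum jointly observed entries for a usable neighbor (4).}
#'   \item{sigma_floor}{lower bound (0.05 log2 units) on truncated-normal
#'     sigma estimates.}
#'   \item{linkage, min_cluster_size, split_fraction}{hierarchical clustering
#'     linkage ("complete") and variable-cut-height parameters (20, 0.8).}
#'   \item{seed}{seed for any stochastic step (none in the deterministic
#'     pipeline itself; recorded for provenance).}
#' }
#'
#' @param ... named overrides of any default listed above
#' @return a classed list `pipeline_config`
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    loc_prob_min = 0.75,
    stim_p = 0.05,
    stim_fold = 1.5,
    interaction_p = 0.05,
    sex_fdr = 0.10,
    cluster_fdr = 0.10,
    kinome_fdr_basal = 0.5,
    kinome_fdr_treated = 0.25,
    kinome_display_adjp = 0.1,
    top_k = 15,
    impute_k = 10,
    impute_min_shared = 4,
    sigma_floor = 0.05,
    linkage = "complete",
    min_cluster_size = 20,
    split_fraction = 0.8,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown pipeline_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  probs <- c("loc_prob_min", "stim_p", "interaction_p", "sex_fdr", "cluster_fdr",
             "kinome_fdr_basal", "kinome_fdr_treated", "kinome_display_adjp",
             "split_fraction")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  if (cfg$stim_fold < 1) stop("stim_fold must be >= 1")
  if (cfg$impute_k < 1) stop("impute_k must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults of [pipeline_config()];
#' unknown fields are an error.
#'
#' @param path YAML file
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Simulation configuration
#'
#' Defines the synthetic experiment the generator emulates: 8 control and
#' 8 T2D donors with equal sexes, two of the T2D donors (one male, one female)
#' excluded, and each retained donor measured in a basal and an
#' insulin-stimulated state (28 samples). Intensities live on the log2 scale;
#' missingness is intensity-dependent (missing-not-at-random, MNAR).
#'
#' Planted site classes (counts in `n_per_class`):
#' \describe{
#'   \item{1A/2A}{insulin up-/downregulated equally in both phenotypes.}
#'   \item{1B/2B}{"impaired": full response delta in CTL, attenuated to
#'     delta * (1 - a) in T2D with a drawn from `attenuation_range`.}
#'   \item{1C/2C}{"emergent": no response in CTL, full response delta in T2D.}
#'   \item{sexF/sexM}{constant offset `sex_effect` in all samples of the
#'     dominant sex.}
#'   \item{basal_shift}{constant phenotype offset in all T2D samples (a pure
#'     basal-state difference; sign random).}
#' }
#' Remaining sites are nulls. Insulin-response magnitudes are drawn uniformly
#' from `insulin_effect_range` with sign fixed by the class (up for 1x, down
#' for 2x).
#'
#' `driver_kinases` assigns a motif-consistent driver kinase to the planted
#' regulated classes so kinase enrichment is testable end to end.
#'
#' @param ... named overrides of any default
#' @return a classed list `sim_config`
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_ctl_donors = 8L,
    n_t2d_donors = 8L,
    n_t2d_excluded = 2L,
    sex_balance = TRUE,
    n_sites = 2000L,
    baseline_mean = 23.0,
    baseline_sd = 2.0,
    donor_sd = 0.3,
    noise_sd = 0.5,
    sv_loading_sd = 0.5,
    insulin_effect_range = c(0.6, 2.0),
    attenuation_range = c(0.5, 1.0),
    sex_effect = 1.5,
    n_per_class = c("1A" = 100L, "1B" = 100L, "1C" = 100L,
                    "2A" = 100L, "2B" = 100L, "2C" = 100L,
                    "sexF" = 100L, "sexM" = 100L, "basal_shift" = 100L),
    mnar_center = 20.0,
    mnar_width = 0.7,
    loc_prob_low_frac = 0.10,
    n_kinases = 50L,
    flank_range = c(-5L, 4L),
    n_genes = 1000L,
    n_background = 5000L,
    n_gene_sets = 20L,
    gene_set_size = 50L,
    driver_kinases = c("1C" = "K01", "2C" = "K02"),
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  counts <- c("n_ctl_donors", "n_t2d_donors", "n_t2d_excluded", "n_sites",
              "n_kinases", "n_genes", "n_background", "n_gene_sets",
              "gene_set_size")
  for (f in counts) {
    if (cfg[[f]] < 0) stop(f, " must be >= 0")
  }
  if (any(cfg$n_per_class < 0)) stop("n_per_class entries must be >= 0")
  if (sum(cfg$n_per_class) > cfg$n_sites) {
    stop("sum of n_per_class (", sum(cfg$n_per_class),
         ") exceeds n_sites (", cfg$n_sites, ")")
  }
  for (f in c("insulin_effect_range", "attenuation_range")) {
    r <- cfg[[f]]
    if (length(r) != 2 || r[1] > r[2]) stop(f, " must be an ordered interval")
  }
  if (cfg$attenuation_range[1] < 0 || cfg$attenuation_range[2] > 1) {
    stop("attenuation_range must lie within [0, 1]")
  }
  if (cfg$loc_prob_low_frac < 0 || cfg$loc_prob_low_frac > 1) {
    stop("loc_prob_low_frac must lie in [0, 1]")
  }
  fr <- cfg$flank_range
  if (length(fr) != 2 || fr[1] >= fr[2]) stop("flank_range must be an ordered interval")
  if (fr[1] == 0 || fr[2] == 0) {
    stop("flank_range bounds must not be 0 (the phosphoacceptor is excluded)")
  }
  if (cfg$n_t2d_excluded > cfg$n_t2d_donors) {
    stop("cannot exclude more T2D donors than exist")
  }
  if (abs(cfg$seed) > 2^30) stop("seed must satisfy |seed| <= 2^30")
  structure(cfg, class = "sim_config")
}
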