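# Synthetic phosphoproteomics experiments with planted ground truth.
#
# The generator emulates the statistical structure of a paired
# basal/insulin-stimulation design on control and T2D donor cell lines:
# log2-normal baselines, shared per-cell-line (donor) offsets that create the
# pairing, planted insulin responses that are equal (A), attenuated (B,
# "impaired") or exclusive to T2D (C, "emergent"), sex-dimorphic offsets, a
# standardized batch vector loading on every site (the surrogate-variable
# target), Gaussian noise, and left-tail intensity-dependent (MNAR)
# missingness. Sequence windows of driver-kinase sites are sampled from that
# kinase's PSSM so motif enrichment is recoverable.
#
# Each generator reseeds its own RNG stream from config$seed (plus a fixed
# per-stage offset), so identical seed + config gives bit-identical output for
# every stage independently of call order.

# Background residue frequencies (approximate natural amino-acid abundances,
# renormalized over the 20-letter alphabet).
BG_RESIDUE_FREQ <- c(
  A = 0.078, C = 0.019, D = 0.053, E = 0.063, F = 0.039, G = 0.072,
  H = 0.023, I = 0.053, K = 0.059, L = 0.091, M = 0.022, N = 0.043,
  P = 0.052, Q = 0.042, R = 0.051, S = 0.068, T = 0.059, V = 0.066,
  W = 0.014, Y = 0.032
)
BG_RESIDUE_FREQ <- BG_RESIDUE_FREQ / sum(BG_RESIDUE_FREQ)

#' Generate the sample design of a synthetic experiment
#'
#' One basal and one insulin sample per retained donor cell line. With the
#' defaults this yields 28 samples: 8 control donors plus 8 T2D donors of whom
#' 2 (one male, one female) are excluded, i.e. (8 CTL + 6 T2D) x 2 treatments.
#'
#' @param config a [sim_config()]
#' @return data.frame with columns sample_id, cell_line, phenotype, sex,
#'   treatment
#' @export
generate_design <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  balanced_sexes <- function(n, what) {
    if (n == 0) return(character(0))
    if (config$sex_balance && n %% 2 != 0) {
      stop("sex_balance requires an even number of ", what, " donors (got ", n, ")")
    }
    if (config$sex_balance) rep(c("M", "F"), each = n / 2)
    else rep(c("M", "F"), length.out = n)
  }
  ctl_sex <- balanced_sexes(config$n_ctl_donors, "control")
  t2d_sex <- balanced_sexes(config$n_t2d_donors, "T2D")
  donors <- data.frame(
    cell_line = sprintf("L%03d", seq_len(config$n_ctl_donors + config$n_t2d_donors)),
    phenotype = rep(c("CTL", "T2D"), c(config$n_ctl_donors, config$n_t2d_donors)),
    sex = c(ctl_sex, t2d_sex),
    stringsAsFactors = FALSE
  )
  # Exclusion emulates dropping poorly differentiated T2D lines: remove the
  # last T2D donors alternating male/female so a default of 2 drops 1 M + 1 F.
  drop_idx <- integer(0)
  want_sex <- rep(c("M", "F"), length.out = config$n_t2d_excluded)
  t2d_rows <- which(donors$phenotype == "T2D")
  for (s in want_sex) {
    cand <- setdiff(t2d_rows[donors$sex[t2d_rows] == s], drop_idx)
    if (length(cand) == 0) cand <- setdiff(t2d_rows, drop_idx)
    drop_idx <- c(drop_idx, max(cand))
  }
  if (length(drop_idx) > 0) donors <- donors[-drop_idx, , drop = FALSE]
  design <- donors[rep(seq_len(nrow(donors)), each = 2), , drop = FALSE]
  design$treatment <- rep(c("basal", "insulin"), nrow(donors))
  design$sample_id <- paste(design$phenotype, design$sex, design$cell_line,
                            design$treatment, sep = "_")
  rownames(design) <- NULL
  design[, c("sample_id", "cell_line", "phenotype", "sex", "treatment")]
}

# Deterministic per-stage RNG streams derived from the config seed.
stage_seed <- function(config, offset) as.integer(config$seed + offset)

#' Generate synthetic intensities with planted effects and ground truth
#'
#' Builds the log2-scale signal for every site/sample cell as
#' baseline(site) + donor offset + planted effects + batch loading x batch
#' score + Gaussian noise, then masks values as missing with probability
#' `plogis((mnar_center - value) / mnar_width)` (set `mnar_center = -Inf` to
#' disable missingness). Localization probabilities are drawn so a
#' configurable fraction falls below the class-I cutoff. The returned table
#' stores raw (linear-scale) intensities, i.e. 2^value.
#'
#' @param config a [sim_config()]
#' @param design output of [generate_design()]
#' @return list with elements `data` (a [phospho_set], windows still `NA`)
#'   and `truth` (ground-truth list: per-site table, batch scores, donor
#'   offsets, pre-missingness log2 matrix)
#' @export
generate_intensities <- function(config = sim_config(), design = generate_design(config)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, 0L))
  n_sites <- config$n_sites
  n_samples <- nrow(design)

  classes <- rep("null", n_sites)
  planted <- rep(names(config$n_per_class), config$n_per_class)
  classes[seq_along(planted)] <- planted

  # site metadata -----------------------------------------------------------
  gene <- sample(sprintf("G%04d", seq_len(config$n_genes)), n_sites, replace = TRUE)
  residue <- sample(c("S", "T"), n_sites, replace = TRUE, prob = c(0.8, 0.2))
  position <- sample(9999L, n_sites, replace = TRUE)
  site_id <- paste0(gene, "_", residue, position)
  while (anyDuplicated(site_id)) {
    dup <- duplicated(site_id)
    position[dup] <- sample(9999L, sum(dup), replace = TRUE)
    site_id <- paste0(gene, "_", residue, position)
  }
  n_low <- round(config$loc_prob_low_frac * n_sites)
  loc_prob <- stats::runif(n_sites, 0.75, 1)
  if (n_low > 0) {
    low_idx <- sample(n_sites, n_low)
    loc_prob[low_idx] <- stats::runif(n_low, 0, 0.75)
  }

  # planted effect sizes ----------------------------------------------------
  delta_mag <- stats::runif(n_sites, config$insulin_effect_range[1],
                            config$insulin_effect_range[2])
  sign_class <- ifelse(substr(classes, 1, 1) == "2", -1, 1)
  atten <- stats::runif(n_sites, config$attenuation_range[1],
                        config$attenuation_range[2])
  ctl_effect <- t2d_effect <- numeric(n_sites)
  is_a <- classes %in% c("1A", "2A")
  is_b <- classes %in% c("1B", "2B")
  is_c <- classes %in% c("1C", "2C")
  ctl_effect[is_a] <- (sign_class * delta_mag)[is_a]
  t2d_effect[is_a] <- (sign_class * delta_mag)[is_a]
  ctl_effect[is_b] <- (sign_class * delta_mag)[is_b]
  t2d_effect[is_b] <- (sign_class * delta_mag * (1 - atten))[is_b]
  t2d_effect[is_c] <- (sign_class * delta_mag)[is_c]

  sex_offset <- numeric(n_sites)
  sex_offset[classes == "sexF"] <- config$sex_effect
  sex_offset[classes == "sexM"] <- -config$sex_effect
  basal_shift <- numeric(n_sites)
  is_shift <- classes == "basal_shift"
  basal_shift[is_shift] <- delta_mag[is_shift] *
    sample(c(-1, 1), sum(is_shift), replace = TRUE)

  driver <- rep(NA_character_, n_sites)
  for (cl in names(config$driver_kinases)) {
    driver[classes == cl] <- config$driver_kinases[[cl]]
  }

  # sample-level components -------------------------------------------------
  lines <- unique(design$cell_line)
  donor_effect <- stats::setNames(stats::rnorm(length(lines), 0, config$donor_sd), lines)
  # Batch drift: a random score per sample, orthogonalized against the
  # phenotype/treatment/sex covariate space and standardized. Any component
  # aligned with the design would be statistically indistinguishable from a
  # design effect (no adjustment method could separate them), so the planted
  # drift carries none.
  lambda <- stats::rnorm(n_samples)
  D <- stats::model.matrix(~ phenotype + treatment + sex,
                           data.frame(phenotype = design$phenotype,
                                      treatment = design$treatment,
                                      sex = design$sex))
  lambda <- lambda - D %*% solve(crossprod(D), crossprod(D, lambda))
  lambda <- as.numeric(scale(lambda)) # standardized batch score per sample
  names(lambda) <- design$sample_id
  loading <- stats::rnorm(n_sites, 0, config$sv_loading_sd)

  baseline <- stats::rnorm(n_sites, config$baseline_mean, config$baseline_sd)
  is_insulin <- design$treatment == "insulin"
  is_t2d <- design$phenotype == "T2D"
  is_female <- design$sex == "F"

  effect_mat <- matrix(0, n_sites, n_samples)
  phen_eff <- cbind(CTL = ctl_effect, T2D = t2d_effect)
  effect_mat[, is_insulin] <- phen_eff[, design$phenotype[is_insulin], drop = FALSE]
  # sex_offset is the F-minus-M difference: applied to female samples only,
  # so sexF sites sit sex_effect higher in females and sexM sites lower.
  effect_mat <- effect_mat + outer(sex_offset, as.numeric(is_female))
  effect_mat[, is_t2d] <- effect_mat[, is_t2d] + basal_shift

  value <- baseline +
    matrix(donor_effect[design$cell_line], n_sites, n_samples, byrow = TRUE) +
    effect_mat +
    outer(loading, lambda) +
    matrix(stats::rnorm(n_sites * n_samples, 0, config$noise_sd), n_sites, n_samples)
  dimnames(value) <- list(site_id, design$sample_id)

  p_missing <- stats::plogis((config$mnar_center - value) / config$mnar_width)
  mask <- matrix(stats::runif(length(value)) < p_missing, n_sites, n_samples)
  raw <- 2^value
  raw[mask] <- NA_real_

  sites <- data.frame(
    site_id = site_id, gene = gene, residue = residue, position = position,
    window = NA_character_, loc_prob = loc_prob, stringsAsFactors = FALSE
  )
  truth_sites <- data.frame(
    site_id = site_id, gene = gene, residue = residue, class = classes,
    ctl_effect = ctl_effect, t2d_effect = t2d_effect,
    sex_offset = sex_offset, basal_shift = basal_shift,
    driver = driver, stringsAsFactors = FALSE
  )
  list(
    data = phospho_set(sites, raw, design),
    truth = list(sites = truth_sites, sv_scores = lambda,
                 donor_effects = donor_effect, log2_true = value)
  )
}

# Draw one Dirichlet row (gamma normalization).
rdirichlet_row <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic kinase atlas
#'
#' For each kinase, a position x residue probability matrix over the flank
#' positions (position 0, the phosphoacceptor, is excluded): 2-4 randomly
#' chosen "sharp" positions strongly prefer one residue (Dirichlet with a
#' concentrated component); the remaining positions are near-background. The
#' background score distribution of each kinase is computed by scoring
#' `n_background` windows drawn from background residue frequencies.
#'
#' @param config a [sim_config()]
#' @return a `kinase_atlas` (see [read_pssm_matrices()])
#' @export
generate_kinase_atlas <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_kinases < 1) stop("n_kinases must be >= 1")
  set.seed(stage_seed(config, 1000L))
  positions <- setdiff(seq(config$flank_range[1], config$flank_range[2]), 0L)
  kin_names <- sprintf("K%02d", seq_len(config$n_kinases))
  kinases <- lapply(kin_names, function(kn) {
    n_sharp <- sample(2:4, 1)
    sharp <- sample(positions, n_sharp)
    m <- t(vapply(positions, function(p) {
      if (p %in% sharp) {
        alpha <- rep(0.5, 20)
        alpha[sample.int(20, 1)] <- 25
      } else {
        alpha <- rep(4, 20)
      }
      rdirichlet_row(alpha)
    }, numeric(20)))
    dimnames(m) <- list(as.character(positions), AA_ALPHABET)
    m
  })
  names(kinases) <- kin_names
  atlas <- structure(
    list(kinases = kinases, background = list(), flank_range = config$flank_range),
    class = "kinase_atlas"
  )
  bg_windows <- draw_background_windows(config$n_background, config$flank_range)
  scores <- score_windows(atlas, bg_windows)
  atlas$background <- lapply(seq_len(ncol(scores)), function(j) sort(scores[, j]))
  names(atlas$background) <- kin_names
  atlas
}

# Random windows with background-frequency flanks and an S/T center.
draw_background_windows <- function(n, flank_range) {
  len <- flank_range[2] - flank_range[1] + 1L
  center <- -flank_range[1] + 1L
  mat <- matrix(sample(AA_ALPHABET, n * len, replace = TRUE, prob = BG_RESIDUE_FREQ),
                n, len)
  mat[, center] <- sample(c("S", "T"), n, replace = TRUE, prob = c(0.8, 0.2))
  apply(mat, 1, paste, collapse = "")
}

#' Generate sequence windows consistent with planted driver kinases
#'
#' Sites with a ground-truth driver kinase get flank residues sampled from
#' that kinase's PSSM position probabilities; all other sites get
#' background-frequency flanks. The center residue is the site's
#' phosphoacceptor (S or T).
#'
#' @param truth ground-truth list from [generate_intensities()]
#' @param atlas a `kinase_atlas` from [generate_kinase_atlas()]
#' @param config a [sim_config()]
#' @return character vector of windows, named by site_id
#' @export
generate_windows <- function(truth, atlas, config = sim_config()) {
  stopifnot(inherits(atlas, "kinase_atlas"))
  set.seed(stage_seed(config, 2000L))
  ts <- truth$sites
  len <- config$flank_range[2] - config$flank_range[1] + 1L
  center <- -config$flank_range[1] + 1L
  positions <- setdiff(seq(config$flank_range[1], config$flank_range[2]), 0L)
  n <- nrow(ts)
  mat <- matrix("", n, len)
  no_driver <- is.na(ts$driver)
  mat[no_driver, ] <- sample(AA_ALPHABET, sum(no_driver) * len, replace = TRUE,
                             prob = BG_RESIDUE_FREQ)
  for (kn in unique(ts$driver[!no_driver])) {
    idx <- which(!no_driver & ts$driver == kn)
    pssm <- atlas$kinases[[kn]]
    if (is.null(pssm)) stop("driver kinase ", kn, " not present in atlas")
    for (p in positions) {
      col <- center + p
      mat[idx, col] <- sample(AA_ALPHABET, length(idx), replace = TRUE,
                              prob = pssm[as.character(p), ])
    }
  }
  mat[, center] <- ts$residue
  stats::setNames(apply(mat, 1, paste, collapse = ""), ts$site_id)
}

#' Generate synthetic gene-set collections
#'
#' One set is enriched for the parent genes of planted insulin-regulated
#' sites (classes 1A-2C); the remaining sets are random draws from the gene
#' universe of the simulated site table. The enriched set's name is recorded
#' in the `enriched` attribute.
#'
#' @param truth ground-truth list from [generate_intensities()]
#' @param config a [sim_config()]
#' @return a `gene_set_collection` (see [read_gmt()])
#' @export
generate_gene_sets <- function(truth, config = sim_config()) {
  set.seed(stage_seed(config, 3000L))
  ts <- truth$sites
  universe <- unique(ts$gene)
  regulated_genes <- unique(ts$gene[ts$class %in% c("1A", "1B", "1C", "2A", "2B", "2C")])
  size <- min(config$gene_set_size, length(universe))
  n_reg <- min(length(regulated_genes), round(0.8 * size))
  enriched <- c(sample(regulated_genes, n_reg),
                sample(setdiff(universe, regulated_genes), size - n_reg))
  sets <- list(SET001 = enriched)
  if (config$n_gene_sets > 1) {
    for (i in 2:config$n_gene_sets) {
      sets[[sprintf("SET%03d", i)]] <- sample(universe, size)
    }
  }
  desc <- stats::setNames(
    c("planted_regulated", rep("random", length(sets) - 1)), names(sets)
  )
  structure(sets, description = desc, enriched = "SET001",
            class = "gene_set_collection")
}

#' Simulate a complete synthetic experiment
#'
#' Chains [generate_design()], [generate_intensities()],
#' [generate_kinase_atlas()], [generate_windows()] and
#' [generate_gene_sets()], attaching the windows to the site table.
#'
#' @param config a [sim_config()]
#' @return list with `data` ([phospho_set]), `truth`, `atlas`, `gene_sets`,
#'   and the `config` used
#' @export
simulate_experiment <- function(config = sim_config()) {
  design <- generate_design(config)
  gen <- generate_intensities(config, design)
  atlas <- generate_kinase_atlas(config)
  windows <- generate_windows(gen$truth, atlas, config)
  gen$data$sites$window <- unname(windows[gen$data$sites$site_id])
  gen$data <- phospho_set(gen$data$sites, gen$data$intensities, gen$data$design)
  gene_sets <- generate_gene_sets(gen$truth, config)
  list(data = gen$data, truth = gen$truth, atlas = atlas,
       gene_sets = gene_sets, config = config)
}
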