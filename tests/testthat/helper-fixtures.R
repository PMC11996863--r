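# Shared fixtures and small oracles, all built in code.

# A tiny hand-written phospho_set: 3 sites x 4 samples (2 cell lines).
tiny_pset <- function() {
  sites <- data.frame(
    site_id = c("GAAA_S10", "GBBB_T20", "GCCC_S30"),
    gene = c("GAAA", "GBBB", "GCCC"),
    residue = c("S", "T", "S"),
    position = c(10L, 20L, 30L),
    window = c("AKRRASLLEP", "PLSRTTVDEA", "MMKQLSEEDF"),
    loc_prob = c(0.99, 0.80, 0.60),
    stringsAsFactors = FALSE
  )
  design <- data.frame(
    sample_id = c("CTL_M_L001_basal", "CTL_M_L001_insulin",
                  "T2D_F_L002_basal", "T2D_F_L002_insulin"),
    cell_line = c("L001", "L001", "L002", "L002"),
    phenotype = c("CTL", "CTL", "T2D", "T2D"),
    sex = c("M", "M", "F", "F"),
    treatment = c("basal", "insulin", "basal", "insulin"),
    stringsAsFactors = FALSE
  )
  intens <- matrix(c(1000, 2000, 1500, 1800,
                     500, NA, 700, 650,
                     8, 8, 8, 8),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(sites$site_id, design$sample_id))
  phospho_set(sites, intens, design)
}

# A small but realistic simulation for unit tests (fewer sites than the
# default study-scale config; planted structure kept).
small_sim_config <- function(seed = 1L, ...) {
  sim_config(
    n_sites = 400L,
    n_per_class = c("1A" = 20L, "1B" = 20L, "1C" = 20L,
                    "2A" = 20L, "2B" = 20L, "2C" = 20L,
                    "sexF" = 20L, "sexM" = 20L, "basal_shift" = 20L),
    n_kinases = 20L,
    n_background = 1000L,
    seed = seed,
    ...
  )
}

# Exhaustive one-sided Fisher oracle: enumerate every table with the observed
# margins and sum the probabilities of tables at least as enriched.
fisher_enumeration_oracle <- function(a, b, c, d) {
  m1 <- a + b   # regulated row
  m2 <- c + d   # unregulated row
  k <- a + c    # predicted column
  total <- m1 + m2
  xs <- max(0, k - m2):min(m1, k)
  probs <- vapply(xs, function(x) {
    exp(lchoose(m1, x) + lchoose(m2, k - x) - lchoose(total, k))
  }, numeric(1))
  sum(probs[xs >= a])
}

# Hypergeometric upper-tail oracle by enumerating subsets is infeasible, but
# for small universes the tail can be summed term by term from factorials.
ora_enumeration_oracle <- function(k, K, N, n) {
  xs <- max(0, n - (N - K)):min(K, n)
  probs <- vapply(xs, function(x) {
    exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
  }, numeric(1))
  sum(probs[xs >= k])
}

# Brute-force O(n^3) agglomerative clustering oracle (complete linkage).
# Returns merge heights in merge order.
hclust_bruteforce_heights <- function(x) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(j, i)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    clusters[[best[1]]] <- merged
    heights <- c(heights, best_h)
  }
  heights
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum(choose(tab, 2))
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  (sij - expected) / (maxi - expected)
}

# Mean silhouette width for a labeled point set (Euclidean), written out so
# the tests do not depend on a clustering package.
mean_silhouette <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  sil <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}
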