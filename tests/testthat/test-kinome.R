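# PSSM scoring, percentile calibration, top-k prediction, regulated-set
# definitions, Haldane frequency factors and one-sided Fisher tests.

uniform_pssm <- function(positions = c(-5:-1, 1:4)) {
  m <- matrix(1 / 20, length(positions), 20,
              dimnames = list(as.character(positions), phosflow:::AA_ALPHABET))
  m
}

test_that("window scoring sums log2 position probabilities with a floor", {
  pssm <- uniform_pssm(c(-3:-1, 1:3))
  # center S with 6 in-range flanks, uniform matrix: 6 * log2(0.05)
  expect_equal(score_site(pssm, "AKRSRLE"), 6 * log2(0.05))
  # probability-1 entry at the window's residue contributes 0
  pssm2 <- pssm
  pssm2["1", ] <- 0
  pssm2["1", "R"] <- 1
  expect_equal(score_site(pssm2, "AKRSRLE"), 5 * log2(0.05))
  # window shorter than the flank range: missing positions contribute 0
  expect_equal(score_site(pssm, "KSR"), 2 * log2(0.05))
  # zero probability hits the 1e-4 floor
  pssm3 <- pssm
  pssm3["-1", ] <- 0
  pssm3["-1", "A"] <- 1
  expect_equal(score_site(pssm3, "AKRSRLE"), 5 * log2(0.05) + log2(1e-4))
  # tyrosine-centered sites are skipped
  expect_warning(sc <- score_site(pssm, "AKRYRLE"), "not S/T")
  expect_true(is.na(sc))
})

test_that("percentiles follow the counting convention", {
  bg <- c(-3, -1, 2, 5)
  expect_equal(percentile_score(2, bg), 75)
  expect_equal(percentile_score(5, bg), 100)
  expect_equal(percentile_score(-10, bg), 0)
  expect_error(percentile_score(1, numeric(0)), "empty")
})

test_that("top-k prediction is capped, deterministic and order-invariant", {
  cfg <- small_sim_config(n_kinases = 10L, n_background = 200L)
  sim <- simulate_experiment(cfg)
  pred <- suppressWarnings(predict_kinases(sim$data, sim$atlas, top_k = 15))
  expect_true(all(rowSums(pred$predicted) == 10)) # all 10 predicted
  pred5 <- suppressWarnings(predict_kinases(sim$data, sim$atlas, top_k = 5))
  expect_true(all(rowSums(pred5$predicted) == 5))
  expect_true(all(pred$percentile >= 0 & pred$percentile <= 100))

  w <- stats::setNames(sim$data$sites$window, sim$data$sites$site_id)
  shuffled <- w[rev(seq_along(w))]
  pred_r <- suppressWarnings(predict_kinases(shuffled, sim$atlas, top_k = 5))
  expect_identical(pred_r$predicted[rownames(pred5$predicted), ],
                   pred5$predicted)
})

test_that("regulated-set definitions use strict inequalities at the cut", {
  ids <- sprintf("G%03d_S%d", 1:5, 1:5)
  diff <- data.frame(
    site_id = ids, contrast = "t2d_vs_ctl_ins",
    log2FC = c(1, -1, 2, -2, 1), t = 0, df_total = 10,
    p = c(0.01, 0.01, 0.5, 0.9, 0.2),
    fdr = c(0.1, 0.2, 0.25, 0.9, 0.3), stringsAsFactors = FALSE
  )
  sets <- define_regulated_sets(diff, "treated")
  expect_equal(sets$up, ids[1])
  expect_equal(sets$down, ids[2])
  # the site exactly at the 0.25 cut is in neither set
  expect_equal(sort(sets$unregulated), sort(ids[4:5]))
  expect_false(ids[3] %in% unlist(sets))
})

test_that("Haldane frequency factor matches forced arithmetic and symmetries", {
  expect_equal(haldane_frequency_factor(c(3, 7, 0, 10)),
               log2((3.5 / 11) / (0.5 / 11)))
  expect_equal(haldane_frequency_factor(c(3, 7, 0, 10)), log2(7))
  # equal proportions with equal margins: FF = 0
  expect_equal(haldane_frequency_factor(c(4, 6, 4, 6)), 0)
  # antisymmetric under swapping the regulated/unregulated rows
  expect_equal(haldane_frequency_factor(c(2, 8, 5, 5)),
               -haldane_frequency_factor(c(5, 5, 2, 8)))
})

test_that("one-sided Fisher p matches hand enumeration and the full oracle", {
  # 0 is the minimum feasible value -> p = 1
  expect_equal(fisher_one_sided(c(0, 5, 3, 7)), 1)
  # 6-table enumeration
  expect_equal(fisher_one_sided(c(2, 0, 0, 2)), 1 / 6, tolerance = 1e-12)
  expect_error(fisher_one_sided(c(-1, 1, 1, 1)), "non-negative")
  expect_error(fisher_one_sided(c(0.5, 1, 1, 1)), "integers")

  set.seed(61)
  for (i in 1:30) {
    tb <- as.integer(stats::rmultinom(1, sample(4:25, 1), rep(0.25, 4)))
    expect_equal(fisher_one_sided(tb),
                 fisher_enumeration_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
  }
})

test_that("Fisher p mirrors under column swap with direction flip", {
  # P_greater(a | a,b,c,d) equals P_less on the column-swapped table,
  # i.e. 1 - P(A >= a+1) of the swapped-direction count
  tb <- c(5, 3, 2, 7)
  p_greater <- fisher_one_sided(tb)
  swapped <- c(tb[2], tb[1], tb[4], tb[3])
  p_less_swapped <- 1 - fisher_one_sided(c(swapped[1] + 1, swapped[2] - 1,
                                           swapped[3] - 1, swapped[4] + 1))
  expect_equal(p_greater, p_less_swapped, tolerance = 1e-12)
})

test_that("enrichment rows behave under zero predictions and count doubling", {
  pred_mat <- matrix(FALSE, 40, 2, dimnames = list(sprintf("G%03d_S%d", 1:40, 1:40),
                                                   c("KA", "KB")))
  pred_mat[1:12, "KA"] <- TRUE # KA predicted only among first sites
  predictions <- structure(list(raw = NULL, percentile = NULL,
                                predicted = pred_mat, top_k = 1),
                           class = "site_predictions")
  ids <- rownames(pred_mat)
  sets <- list(up = ids[1:10], down = character(0), unregulated = ids[11:40])
  enr <- kinome_enrichment(predictions, sets)
  kb <- enr[enr$kinase == "KB", ]
  expect_equal(kb$p, 1) # never predicted -> p = 1
  expect_true(is.finite(kb$frequency_factor)) # Haldane keeps FF finite
  ka <- enr[enr$kinase == "KA", ]
  expect_equal(ka$side, "up")
  expect_lt(ka$p, 0.01)

  # doubling all counts of an enrichment-direction table strengthens the
  # evidence (p non-increasing) and moves the Haldane FF toward the
  # uncorrected ratio it stabilizes
  set.seed(62)
  n_checked <- 0
  while (n_checked < 20) {
    tb <- as.integer(stats::rmultinom(1, sample(8:30, 1), c(0.3, 0.2, 0.2, 0.3)))
    if (any(tb == 0)) next
    if (tb[1] / (tb[1] + tb[2]) <= tb[3] / (tb[3] + tb[4])) next
    n_checked <- n_checked + 1
    expect_lte(fisher_one_sided(2 * tb), fisher_one_sided(tb) + 1e-12)
    ff_raw <- log2((tb[1] / (tb[1] + tb[2])) / (tb[3] / (tb[3] + tb[4])))
    expect_lte(abs(haldane_frequency_factor(2 * tb) - ff_raw),
               abs(haldane_frequency_factor(tb) - ff_raw) + 1e-12)
  }
})

test_that("percentiles of background draws are uniform", {
  cfg <- small_sim_config(n_background = 2000L)
  atlas <- generate_kinase_atlas(cfg)
  set.seed(63)
  bgw <- phosflow:::draw_background_windows(2000, cfg$flank_range)
  sc <- phosflow:::score_windows(atlas, bgw)
  pct <- percentile_score(sc[, 1], atlas$background[[1]])
  D <- max(abs(sort(pct) / 100 - seq_along(pct) / length(pct)))
  expect_lt(D, 0.05)
})
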