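test_that("dominance profile applies strict cutoffs per group", {
  relab <- matrix(c(0.51, 0.49,
                    0.50, 0.50,
                    0.009, 0.991), 3, 2, byrow = TRUE,
                  dimnames = list(c("AV01", "AV02", "NL01"), c("X", "Y")))
  meta <- sample_metadata(data.frame(sample_id = rownames(relab),
                                     group = c("AV", "AV", "NL")))
  d <- dominance_profile(relab, meta)
  av_x <- d[d$taxon == "X" & d$group == "AV", ]
  expect_equal(av_x$n_dominant, 1)   # 0.51 yes, 0.50 no (strict)
  expect_equal(av_x$n_present, 2)
  nl_x <- d[d$taxon == "X" & d$group == "NL", ]
  expect_equal(nl_x$n_present, 0)    # 0.009 below the 1% cutoff
  expect_true(all(d$n_dominant <= d$n_present & d$n_present <= d$n_group))
  # counts invariant to per-sample rescaling of the underlying counts
  cc <- generate_cohort(cohort_config(n_per_group = c(AV = 4, NL = 4), seed = 2))
  counts <- unclass(aggregate_taxa(cc$counts, cc$taxonomy, "genus"))
  d1 <- dominance_profile(relative_abundance(asv_count_table(counts)),
                          cc$metadata)
  counts[3, ] <- counts[3, ] * 11L
  d2 <- dominance_profile(relative_abundance(asv_count_table(counts)),
                          cc$metadata)
  expect_identical(d1, d2)
})

test_that("top-genus table ranks, pools a residual and conserves mass", {
  fx <- make_fixture_tables()
  full <- top_genus_table(fx$counts, fx$taxonomy, n = 4)  # all 4 genera
  expect_equal(unname(full[, "residual"]), rep(0, 6))
  t1 <- top_genus_table(fx$counts, fx$taxonomy, n = 1)
  expect_identical(colnames(t1), c("Lactobacillus", "residual"))
  t2 <- top_genus_table(fx$counts, fx$taxonomy, n = 2)
  expect_equal(unname(rowSums(t2)), rep(1, 6), tolerance = 1e-12)
  expect_equal(unname(rowSums(top_genus_table(fx$counts, fx$taxonomy, n = 99))),
               rep(1, 6), tolerance = 1e-12)
})

test_that("bray_curtis matches its formula, vegan, and its bounds", {
  expect_equal(bray_curtis(c(2, 1, 0), c(1, 1, 1)), 1 / 3)
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(bray_curtis(c(-1, 2), c(1, 2)), "non-negative")
  skip_if_not_installed("vegan")
  set.seed(9)
  for (i in 1:200) {
    x <- stats::runif(5); y <- stats::runif(5)
    b <- bray_curtis(x, y)
    expect_equal(b, bc_oracle(x, y))
    expect_equal(b, as.numeric(vegan::vegdist(rbind(x, y), "bray")))
    expect_gte(b, 0); expect_lte(b, 1)
    expect_equal(b, bray_curtis(y, x))
  }
})

test_that("seriation is exhaustive-optimal for small n and deterministic", {
  set.seed(10)
  relab <- matrix(stats::runif(5 * 4), 5, 4,
                  dimnames = list(paste0("S", 1:5), paste0("T", 1:4)))
  relab <- relab / rowSums(relab)
  ord <- seriate_samples(relab)
  d <- sapply(seq_len(5), function(i) sapply(seq_len(5), function(j)
    bc_oracle(relab[i, ], relab[j, ])))
  dimnames(d) <- list(rownames(relab), rownames(relab))
  got <- sum(d[cbind(ord[-5], ord[-1])])
  expect_equal(got, seriation_oracle_length(relab), tolerance = 1e-12)
  expect_identical(seriate_samples(relab), ord)            # deterministic
  expect_identical(seriate_samples(relab[c(3, 1, 5, 2, 4), ]), ord)
  # two samples: identifier-sorted
  expect_identical(seriate_samples(relab[c("S2", "S1"), ]), c("S1", "S2"))
  # duplicated rows end up adjacent
  dup <- rbind(relab, S9 = relab["S3", ])
  o2 <- seriate_samples(dup)
  expect_equal(abs(diff(match(c("S3", "S9"), o2))), 1)
})

test_that("large-n seriation beats the identity ordering and stays deterministic", {
  set.seed(11)
  relab <- matrix(stats::rgamma(14 * 6, 0.5), 14, 6,
                  dimnames = list(sprintf("S%02d", 1:14), paste0("T", 1:6)))
  relab <- relab / rowSums(relab)
  ord <- seriate_samples(relab)
  expect_setequal(ord, rownames(relab))
  d <- sapply(1:14, function(i) sapply(1:14, function(j)
    bc_oracle(relab[i, ], relab[j, ])))
  dimnames(d) <- list(rownames(relab), rownames(relab))
  plen <- function(o) sum(d[cbind(o[-length(o)], o[-1])])
  expect_lte(plen(ord), plen(rownames(relab)))
  expect_identical(seriate_samples(relab[sample(14), ]), ord)
})

test_that("score correlation behaves at its anchors and on calibrated cohorts", {
  relab <- matrix(c(seq(0.1, 0.9, 0.2), 1 - seq(0.1, 0.9, 0.2)), 5, 2,
                  dimnames = list(paste0("S", 1:5), c("Prevotella", "Other")))
  r <- pearson_score_correlation(relab, "Prevotella", relab[, "Prevotella"])
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_error(pearson_score_correlation(relab, "Prevotella", rep(3, 5)),
               "zero variance")
  expect_error(pearson_score_correlation(relab, "Prevotella",
                                         c(1, 2, NA, NA, NA)), "3 samples")
  cc <- generate_cohort(cohort_config(seed = 21))
  relab <- relative_abundance(aggregate_taxa(cc$counts, cc$taxonomy, "genus"))
  sc <- cc$metadata$av_score[match(rownames(relab), cc$metadata$sample_id)]
  out <- pearson_score_correlation(relab, "Prevotella", sc)
  expect_equal(out$n, sum(cc$metadata$group == "AV"))
  expect_gt(out$r, 0)
})

test_that("pairwise Wilcoxon with Holm matches the hand computation", {
  # three clearly separated groups
  meta <- sample_metadata(data.frame(sample_id = paste0("S", 1:9),
                                     group = rep(c("AV", "BV", "NL"), each = 3)))
  v <- stats::setNames(c(1, 2, 3, 11, 12, 13, 24, 25, 26), meta$sample_id)
  out <- pairwise_wilcoxon_holm(v, meta)
  expect_equal(nrow(out), 3)
  expect_true(all(out$p_adjusted >= out$p_value))
  expect_equal(out$p_adjusted, holm_oracle(out$p_value))
  # identical groups: all adjusted p = 1
  v2 <- stats::setNames(rep(c(5, 6, 7), 3), meta$sample_id)
  expect_true(all(pairwise_wilcoxon_holm(v2, meta)$p_adjusted == 1))
  # hand-applied Holm on a fixed p-vector
  expect_equal(holm_oracle(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(stats::p.adjust(c(0.01, 0.04, 0.03), "holm"),
               c(0.03, 0.06, 0.06))
  meta$group[1:2] <- "BV"
  expect_error(pairwise_wilcoxon_holm(v, sample_metadata(meta)), "< 2 samples")
})

test_that("kruskal_wallis matches the hand rank computation", {
  meta <- sample_metadata(data.frame(sample_id = paste0("S", 1:6),
                                     group = rep(c("AV", "BV", "NL"), each = 2)))
  v <- stats::setNames(c(1, 2, 3, 4, 5, 6), meta$sample_id)
  out <- kruskal_wallis(v, meta)
  expect_equal(out$H, 32 / 7, tolerance = 1e-9)
  expect_equal(out$df, 2)
  expect_equal(out$H, kw_oracle(unname(v), meta$group), tolerance = 1e-9)
  expect_error(kruskal_wallis(stats::setNames(rep(1, 6), meta$sample_id), meta),
               "identical")
  # permutation sanity: under exchangeability p is roughly uniform
  set.seed(12)
  ps <- replicate(400, {
    kruskal_wallis(stats::setNames(stats::rnorm(6)[sample(6)], meta$sample_id),
                   meta)$p
  })
  expect_gt(mean(ps > 0.5), 0.3)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("assay comparison reports medians, blanks and Holm-adjusted tests", {
  meta <- sample_metadata(data.frame(sample_id = paste0("S", 1:12),
                                     group = rep(c("AV", "BV", "NL"), each = 4)))
  tab <- data.frame(sample_id = meta$sample_id,
                    response = rep(c(1.13, 1.50, 1.99), each = 4),
                    blank_mean = 0.155, assay = "TLR2/6")
  out <- assay_group_comparison(tab, meta)
  expect_equal(out$medians$median, c(1.13, 1.50, 1.99))
  expect_equal(out$blank_mean, 0.155)
  expect_true(all(out$tests$p_adjusted >= out$tests$p_value))
  # blank-only responses: medians equal the blank mean
  blank <- transform(tab, response = 0.155)
  expect_equal(assay_group_comparison(blank, meta)$medians$median,
               rep(0.155, 3))
  # synthetic responses recover the configured group medians
  cc_meta <- sample_metadata(data.frame(
    sample_id = sprintf("S%03d", 1:150), group = rep(c("AV", "BV", "NL"), 50)))
  sim <- simulate_assay_responses(cc_meta, seed = 8)
  rec <- assay_group_comparison(sim, cc_meta)$medians
  expect_equal(rec$median[rec$group == "NL"], 1.99, tolerance = 0.15)
  expect_equal(rec$median[rec$group == "BV"], 1.50, tolerance = 0.12)
  expect_equal(rec$median[rec$group == "AV"], 1.13, tolerance = 0.10)
})
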