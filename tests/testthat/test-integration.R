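prof <- function(v, pairs = paste0("p", seq_along(v)), analyte = "a",
                 kind = "metabolite", flag = NULL)
  fc_profile(analyte, kind, pairs, v, flag)

test_that("G-test matches hand values and handles degeneracy", {
  even <- g_test(matrix(c(2, 2, 2, 2), 2))
  expect_equal(even$G, 0)
  expect_equal(even$p, 1)
  diag <- g_test(matrix(c(3, 0, 0, 3), 2))
  expect_equal(diag$G, 12 * log(2), tolerance = 1e-12)
  expect_lt(diag$p, 0.05)
  # zero margin: degenerate, not an error
  degen <- g_test(matrix(c(0, 0, 2, 3), 2, byrow = TRUE))
  expect_equal(degen$G, 0)
  expect_equal(degen$p, 1)
  expect_error(g_test(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  expect_error(g_test(matrix(c(0.5, 1, 1, 1), 2)), "integer")
  expect_error(g_test(matrix(0L, 2, 2)), "grand total")
})

test_that("Benjamini-Hochberg agrees with the hand step-up on examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  p <- c(0.003, 0.04, 0.9, 0.02, 0.51)
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_true(all(bh_adjust(p) >= p))
})

test_that("scaled Pearson equals the textbook statistic and is symmetric", {
  a <- prof(c(1, 2, 3, 4, 5, 6))
  expect_equal(scaled_pearson(a, a)$r, 1)
  neg <- prof(-c(1, 2, 3, 4, 5, 6))
  expect_equal(scaled_pearson(a, neg)$r, -1)
  withr::with_seed(31, {
    for (i in 1:30) {
      x <- rnorm(6); y <- rnorm(6)
      res <- scaled_pearson(prof(x), prof(y), p_method = "pairs")
      expect_equal(res$r, cor(x, y), tolerance = 1e-12)
      expect_equal(res$p, cor.test(x, y)$p.value, tolerance = 1e-12)
      # scaling either input leaves r unchanged; symmetry holds
      expect_equal(scaled_pearson(prof(3 * x + 1), prof(y))$r, res$r,
                   tolerance = 1e-12)
      expect_equal(scaled_pearson(prof(y), prof(x))$r, res$r,
                   tolerance = 1e-12)
    }
  })
})

test_that("correlation is withheld below three shared pairs", {
  a <- prof(c(1, 2, NA, NA, 5, NA))
  b <- prof(c(1, NA, 3, 4, 2, NA))
  res <- scaled_pearson(a, b)
  expect_true(is.na(res$r))
  expect_match(res$reason, "fewer than 3")
  flatv <- prof(c(1, 1, 1, 1, 1, 1))
  expect_match(scaled_pearson(flatv, prof(rnorm(6)))$reason, "zero variance")
})

test_that("peptide profiles compute ratios, flags and sufficiency", {
  layout <- tiny_layout()
  obs <- rbind(obs_roi("P1", "CL1", "LM1", c(8, 8, 8)),
               obs_roi("P1", "CL1", "LM2", c(2, 2, 2)),
               obs_roi("P1", "CL1", "LM3", rep(2, 6)),
               obs_roi("P1", "CL1", "PMM", c(2, 2, 2)))
  pr <- peptide_fc_profile(obs, layout, "P1")
  expect_equal(pr$log2fc[pr$pairs == "LM1/LM2"], 2)
  expect_equal(pr$log2fc[pr$pairs == "LM2/PMM"], 0)

  # one fully missing ROI: the 2x2 detection G-test flags direction
  obs2 <- rbind(obs_roi("P2", "CL1", "LM1", c(5, 5, 5)),
                obs_roi("P2", "CL1", "LM2", c(5, 5, 5)),
                obs_roi("P2", "CL1", "LM3", rep(5, 6)),
                obs_roi("P2", "CL1", "PMM", c(NA, NA, NA)))
  pr2 <- peptide_fc_profile(obs2, layout, "P2")
  k <- which(pr2$pairs == "LM1/PMM")
  expect_equal(pr2$flag[k], 1L)          # toward LM1, the side with data
  expect_true(is.na(pr2$log2fc[k]))
  gt <- g_test(matrix(c(3, 0, 0, 3), 2, byrow = TRUE))
  expect_equal(gt$G, 12 * log(2))        # the table the flag came from

  # fewer than three usable ROIs: profile withheld
  obs3 <- rbind(obs_roi("P3", "CL1", "LM1", c(5, 5, 5)),
                obs_roi("P3", "CL1", "LM2", c(4, NA, NA)),
                obs_roi("P3", "CL1", "LM3", c(NA, 9, rep(NA, 4))),
                obs_roi("P3", "CL1", "PMM", c(NA, 8, NA)))
  expect_null(peptide_fc_profile(obs3, layout, "P3"))

  # a single observed intensity never makes a mean (insufficient data)
  obs4 <- rbind(obs_roi("P4", "CL1", "LM1", c(5, 5, 5)),
                obs_roi("P4", "CL1", "LM2", c(4, 4, 4)),
                obs_roi("P4", "CL1", "LM3", c(9, 9, 9, rep(NA, 3))),
                obs_roi("P4", "CL1", "PMM", c(8, NA, NA)))
  pr4 <- peptide_fc_profile(obs4, layout, "P4")
  expect_true(all(is.na(pr4$log2fc[grepl("PMM", pr4$pairs)])))
})

test_that("sentinels dominate observed fold changes and keep direction", {
  a <- prof(c(1.5, -2, NA), flag = c(0L, 0L, 1L))
  b <- prof(c(0.5, NA, NA), flag = c(0L, -1L, 0L))
  out <- resolve_sentinels(list(a = a, b = b))
  s <- attr(out, "sentinel")
  expect_equal(s, 3)               # max |log2fc| + 1
  expect_equal(out$a$log2fc[3], 3)
  expect_equal(out$b$log2fc[2], -3)
  expect_true(all(abs(out$a$log2fc[1:2]) < s))
})

test_that("planted noiseless triplets correlate perfectly end to end", {
  layout <- tiny_layout()
  images <- generate_ion_images(layout, noise_sd = 0, seed = 2)$images
  met <- lapply(images, metabolite_fc_profile, rois = layout)
  names(met) <- names(images)
  pep <- generate_peptide_table(layout, missing_rate = 0, noise_sd = 0,
                                seed = 2)$observations
  profs <- peptide_fc_profiles(pep, layout)
  for (i in seq_along(profs)) {
    cl <- profs[[i]]$cluster
    ko <- unique(pep$ko[pep$cluster == cl])
    profs[[i]]$ko <- ko
  }
  triplets <- find_triplets(generate_reaction_graph(seed = 2),
                            default_planted_triplets()$ko, names(met))
  res <- correlate_triplets(triplets, profs, met)
  expect_gt(nrow(res), 0)
  expect_equal(max(abs(1 - res$r)), 0, tolerance = 1e-12)
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(abs(res$r) <= 1))
})

test_that("pair-level df inflates the null rejection rate that ROI-level df controls", {
  pairs_mode <- simulate_null_pairs(150, seed = 2, p_method = "pairs")
  roi_mode <- simulate_null_pairs(150, seed = 2, p_method = "roi")
  expect_gt(mean(pairs_mode$p < 0.05), 0.12)   # several-fold inflation
  expect_lt(mean(roi_mode$p < 0.05), 0.12)
})

test_that("dropping one ROI pair shrinks n_pairs by one, sign intact", {
  x <- c(1, 2, 3, 4, 5, 6)
  full <- scaled_pearson(prof(x), prof(2 * x))
  drop1 <- scaled_pearson(prof(replace(x, 2, NA)), prof(2 * x))
  expect_equal(full$n_pairs - drop1$n_pairs, 1)
  expect_equal(sign(full$r), sign(drop1$r))
  expect_equal(drop1$r, 1)
})
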