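test_that("all generators regenerate bit-identically under one seed", {
  layout <- tiny_layout()
  a <- generate_ion_images(layout, noise_sd = 0.2, seed = 99)
  b <- generate_ion_images(layout, noise_sd = 0.2, seed = 99)
  expect_identical(a, b)
  p1 <- generate_peptide_table(layout, missing_rate = 0.2, seed = 99)
  p2 <- generate_peptide_table(layout, missing_rate = 0.2, seed = 99)
  expect_identical(p1, p2)
  s1 <- generate_psm_table(50, 50, 2, seed = 99)
  s2 <- generate_psm_table(50, 50, 2, seed = 99)
  expect_identical(s1, s2)
  g1 <- generate_reaction_graph(seed = 99)
  g2 <- generate_reaction_graph(seed = 99)
  expect_identical(g1, g2)
  expect_false(identical(
    generate_ion_images(layout, noise_sd = 0.2, seed = 100)$images,
    a$images))
})

test_that("noise-free images hit the planted ROI means exactly", {
  layout <- tiny_layout()
  out <- generate_ion_images(layout, noise_sd = 0, seed = 1)
  for (spec in default_metabolite_specs()) {
    img <- out$images[[spec$compound]]
    for (lab in layout$labels) {
      expect_equal(roi_mean_intensity(img, layout$masks[[lab]]),
                   unname(spec$roi_means[lab]))
    }
    bg <- !Reduce(`|`, layout$masks)
    expect_true(all(img$intensities[bg] == 0))
  }
})

test_that("image m/z sits at the adduct-specific theoretical mass", {
  layout <- tiny_layout()
  out <- generate_ion_images(layout, noise_sd = 0, seed = 1)
  expect_equal(out$images$C01720$mz, adduct_mz("C6H12O6", "[M-H]-"),
               tolerance = 1e-9)
  expect_equal(out$images$C00031$mz, adduct_mz("C6H12O6", "[M+Cl]-"),
               tolerance = 1e-9)
  expect_false(isTRUE(all.equal(out$images$C01720$mz, out$images$C00031$mz)))
  # a molecule whose anion falls below the acquisition window is rejected
  tiny <- list(list(compound = "C99990", name = "formate", formula = "CH2O2",
                    adduct = "[M-H]-", roi_means = c(LM1 = 1, LM2 = 1,
                                                     LM3 = 1, PMM = 1)))
  expect_error(generate_ion_images(layout, tiny, 0, 1),
               "outside acquisition range")
})

test_that("peptide tables respect missingness bounds and planted truth", {
  layout <- tiny_layout()
  full <- generate_peptide_table(layout, missing_rate = 0, seed = 5)
  expect_false(anyNA(full$observations$intensity))
  expect_true(all(full$observations$psm_count >= 1))
  empty <- generate_peptide_table(layout, missing_rate = 1, seed = 5)
  expect_true(all(is.na(empty$observations$intensity)))
  expect_named(empty$truth$planted_profiles)
  # planted enzyme cluster shares its triplet's image profile
  img_truth <- generate_ion_images(layout, seed = 5)$truth
  for (i in seq_len(nrow(default_planted_triplets()))) {
    tr <- default_planted_triplets()[i, ]
    cl <- Filter(function(s) s$ko == tr$ko, default_cluster_specs())[[1]]
    expect_equal(cl$roi_means,
                 img_truth$planted_profiles[[tr$substrate]])
  }
})

test_that("intensity-dependent missingness removes more low-abundance cells", {
  layout <- tiny_layout()
  specs <- list(
    list(cluster = "HI", ko = "K11111", lineage = "x", n_peptides = 6L,
         roi_means = c(LM1 = 1000, LM2 = 1000, LM3 = 1000, PMM = 1000)),
    list(cluster = "LO", ko = "K22222", lineage = "x", n_peptides = 6L,
         roi_means = c(LM1 = 2, LM2 = 2, LM3 = 2, PMM = 2)))
  obs <- generate_peptide_table(layout, specs, missing_rate = 0.25,
                                missing_mode = "intensity",
                                seed = 3)$observations
  miss <- tapply(is.na(obs$intensity), obs$cluster, mean)
  expect_gt(miss[["LO"]], miss[["HI"]])
})

test_that("PSM tables separate decoys by score_sep and are reproducible", {
  sep <- generate_psm_table(200, 200, score_sep = 12, seed = 2)
  acc <- filter_psms(sep, list(spec_prob_max = 1e-7, abs_delm_ppm_max = 20))
  expect_equal(sum(acc$is_decoy), 0)
  expect_gt(sum(!acc$is_decoy), 0)

  flat <- generate_psm_table(400, 400, score_sep = 0, seed = 2)
  keep <- flat[flat$ntt == 2 & flat$missed_cleavages <= 2, ]
  thr <- median(keep$spec_prob)
  acc2 <- keep[keep$spec_prob <= thr, ]
  fdr <- sum(acc2$is_decoy) / sum(!acc2$is_decoy)
  # with no separation the accepted-set FDR tracks the decoy/target ratio
  expect_gt(fdr, 0.6)
  expect_lt(fdr, 1.6)
})

test_that("reaction graphs contain planted triplets and isolate distractors", {
  g <- generate_reaction_graph(n_distractors = 4, seed = 1)
  tr <- find_triplets(g, default_planted_triplets()$ko,
                      c(default_planted_triplets()$substrate,
                        default_planted_triplets()$product))
  got <- tr[, c("substrate", "ko", "product")]
  expect_equal(got[order(got$ko), ],
               default_planted_triplets()[
                 order(default_planted_triplets()$ko), ],
               ignore_attr = TRUE)
  # distractor KOs never reach planted compounds
  dko <- setdiff(unique(g$ko2rxn$ko), default_planted_triplets()$ko)
  for (k in dko) {
    cpds <- ko_to_compounds(g, k)
    expect_length(intersect(unlist(cpds),
                            unlist(default_planted_triplets()[
                              , c("substrate", "product")])), 0)
  }
  g0 <- generate_reaction_graph(n_distractors = 0, seed = 1)
  expect_equal(sort(unique(g0$ko2rxn$ko)),
               sort(default_planted_triplets()$ko))
  expect_error(
    generate_reaction_graph(data.frame(substrate = "X1", ko = "K1",
                                       product = "C00002")),
    "malformed")
})
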