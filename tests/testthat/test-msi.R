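flat_dataset <- function(mz, per_pixel, nx = 3, ny = 3) {
  coords <- cbind(x = rep(seq_len(nx) - 1L, each = ny),
                  y = rep(seq_len(ny) - 1L, nx))
  msi_dataset(coords, mz, rep(list(per_pixel), nrow(coords)),
              mode = "continuous")
}

test_that("ion image extraction sums signal inside an inclusive ppm window", {
  target <- 200
  ds <- flat_dataset(c(199.9, 200, 200.4), c(1, 5, 2))
  img <- extract_ion_image(ds, target, tol_ppm = 5)
  expect_true(all(img$intensities == 5))

  # deviation of +2 ppm: included at 5 ppm, excluded at 1 ppm
  ds2 <- flat_dataset(target * (1 + 2e-6), 7)
  expect_true(all(extract_ion_image(ds2, target, 5)$intensities == 7))
  expect_true(all(extract_ion_image(ds2, target, 1)$intensities == 0))
  # symmetric in the sign of the deviation
  ds3 <- flat_dataset(target * (1 - 2e-6), 3)
  expect_true(all(extract_ion_image(ds3, target, 5)$intensities == 3))
  expect_true(all(extract_ion_image(ds3, target, 1)$intensities == 0))

  expect_error(extract_ion_image(ds, 90, 5), "outside acquisition range")
})

test_that("empty spectra yield zero pixels", {
  ds <- flat_dataset(c(150, 300), c(0, 0))
  expect_true(all(extract_ion_image(ds, 150, 5)$intensities == 0))
})

test_that("ROI means match a brute-force pixel loop and ignore order", {
  withr::with_seed(4, {
    for (rep in 1:20) {
      img <- ion_image(150, matrix(runif(60), 6, 10))
      mask <- matrix(runif(60) < 0.4, 6, 10)
      if (!any(mask)) mask[1, 1] <- TRUE
      acc <- 0; n <- 0
      for (i in 1:6) for (j in 1:10) if (mask[i, j]) {
        acc <- acc + img$intensities[i, j]; n <- n + 1
      }
      expect_equal(roi_mean_intensity(img, mask), acc / n)
    }
  })
  img <- ion_image(150, matrix(c(4, 8, 1, 1), 2, 2))
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(roi_mean_intensity(img, mask), 6)
  expect_error(roi_mean_intensity(img, matrix(FALSE, 2, 2)), "empty ROI")
})

test_that("metabolite fold-change profiles cover C(n,2) ordered pairs", {
  layout <- tiny_layout()
  img <- ion_image(150, matrix(0, 40, 40))
  img$intensities[layout$masks$LM1] <- 8
  img$intensities[layout$masks$LM2] <- 2
  img$intensities[layout$masks$LM3] <- 2
  img$intensities[layout$masks$PMM] <- 2
  prof <- metabolite_fc_profile(img, layout)
  expect_length(prof$log2fc, choose(4, 2))
  expect_equal(prof$log2fc[prof$pairs == "LM1/LM2"], 2)
  expect_equal(prof$log2fc[prof$pairs == "LM2/LM3"], 0)
  # zero mean flagged missing, not infinite
  img$intensities[layout$masks$PMM] <- 0
  prof0 <- metabolite_fc_profile(img, layout)
  expect_true(all(is.na(prof0$log2fc[grepl("PMM", prof0$pairs)])))
  expect_true(all(is.finite(stats::na.omit(prof0$log2fc))))
})

test_that("annotation separates isomers per adduct and applies decoy FDR", {
  layout <- tiny_layout()
  specs <- default_metabolite_specs()
  ds <- images_to_dataset(generate_ion_images(layout, specs, 0, 1)$images,
                          layout)
  db <- do.call(rbind, lapply(specs, function(s)
    data.frame(compound = s$compound, formula = s$formula)))
  ann <- annotate_images(ds, db, adduct_rules(), tol_ppm = 3, fdr_max = 0.2)
  keys <- vapply(ann, function(im)
    paste(im$annotation$compound, im$annotation$adduct), "")
  # the shared-formula channels annotate both isomers, one entry per adduct
  expect_true("C01720 [M-H]-" %in% keys)
  expect_true("C00031 [M+Cl]-" %in% keys)
  expect_true(all(!vapply(ann, function(im)
    is.null(im$annotation$fdr), TRUE)))

  # fdr_max = 1 returns every within-tolerance target match
  all_ann <- annotate_images(ds, db, adduct_rules(), 3, fdr_max = 1)
  expect_gte(length(all_ann), length(ann))
  expect_error(annotate_images(ds, db, adduct_rules(decoys = FALSE), 3, 0.2),
               "decoy adduct")
})

test_that("a pure decoy-mass dataset annotates nothing at 20% FDR", {
  db <- data.frame(compound = c("C00001", "C00002"),
                   formula = c("C6H12O6", "C8H6O4"))
  decoy_mz <- unlist(lapply(db$formula, function(f)
    vapply(c("[M+Br]-", "[M+Na-2H]-", "[M+K-2H]-"),
           function(a) adduct_mz(f, a), 0)))
  ds <- flat_dataset(sort(decoy_mz), rep(10, length(decoy_mz)))
  ann <- annotate_images(ds, db, adduct_rules(), 3, fdr_max = 0.2)
  expect_length(ann, 0)
})

test_that("annotation FDR never rises as the score cut tightens", {
  layout <- tiny_layout()
  ds <- images_to_dataset(generate_ion_images(layout, seed = 2)$images,
                          layout)
  db <- do.call(rbind, lapply(default_metabolite_specs(), function(s)
    data.frame(compound = s$compound, formula = s$formula)))
  m <- attr(annotate_images(ds, db, adduct_rules(), 10, 1), "matches")
  m <- m[order(abs(m$ppm_error)), ]
  expect_true(all(diff(m$fdr) >= -1e-12))
})
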