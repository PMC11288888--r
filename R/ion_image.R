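#' Single-channel ion image
#'
#' One m/z channel of an MSI dataset: a pixel grid of non-negative
#' intensities with its channel centre and optional annotation.
#'
#' @param mz channel centre m/z (Da).
#' @param intensities numeric matrix (rows = y, cols = x) of non-negative
#'   pixel intensities.
#' @param pitch_um pixel pitch in microns.
#' @param annotation optional list with elements such as `compound`,
#'   `formula`, `adduct`, `ppm_error`, `fdr`.
#' @return Object of class `ion_image`.
#' @export
ion_image <- function(mz, intensities, pitch_um = 50, annotation = NULL) {
  stopifnot(is.numeric(mz), length(mz) == 1L, is.matrix(intensities))
  if (any(intensities < 0, na.rm = TRUE))
    stop2("ion image intensities must be non-negative")
  structure(list(mz = mz, intensities = intensities, pitch_um = pitch_um,
                 annotation = annotation),
            class = "ion_image")
}

#' @export
print.ion_image <- function(x, ...) {
  ann <- if (is.null(x$annotation)) "" else
    sprintf(" [%s %s %s]", x$annotation$compound %||% "",
            x$annotation$formula %||% "", x$annotation$adduct %||% "")
  cat(sprintf("ion image m/z %.5f, %d x %d px%s\n", x$mz,
              ncol(x$intensities), nrow(x$intensities), ann))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
plot.ion_image <- function(x, rois = NULL, ...) {
  z <- t(x$intensities)[, rev(seq_len(nrow(x$intensities))), drop = FALSE]
  graphics::image(z, axes = FALSE, useRaster = TRUE,
                  main = sprintf("m/z %.4f", x$mz), ...)
  invisible(x)
}

#' Extract an ion image from an MSI dataset
#'
#' Per-pixel intensity is the sum of all signal within a symmetric,
#' boundary-inclusive ppm window around the target m/z; pixels with no signal
#' in the window are 0.
#'
#' @param dataset an [msi_dataset()].
#' @param target_mz target m/z (Da); must lie inside the acquisition range.
#' @param tol_ppm tolerance in ppm (> 0); default 3.
#' @return An [ion_image()].
#' @export
extract_ion_image <- function(dataset, target_mz, tol_ppm = 3) {
  stopifnot(inherits(dataset, "msi_dataset"), tol_ppm > 0)
  if (target_mz < dataset$mz_range[1] || target_mz > dataset$mz_range[2])
    stop2("target m/z ", target_mz, " outside acquisition range [",
          dataset$mz_range[1], ", ", dataset$mz_range[2], "]")
  dims <- msi_dims(dataset)
  img <- matrix(0, dims[2], dims[1])
  tol <- tol_ppm * 1e-6 * target_mz
  n <- nrow(dataset$coords)
  shared <- dataset$mode == "continuous"
  if (shared) hit <- abs(dataset$mz - target_mz) <= tol
  for (i in seq_len(n)) {
    h <- if (shared) hit else abs(dataset$mz[[i]] - target_mz) <= tol
    if (any(h)) {
      img[dataset$coords[i, 2L] + 1L, dataset$coords[i, 1L] + 1L] <-
        sum(dataset$intensities[[i]][h])
    }
  }
  ion_image(target_mz, img, pitch_um = dataset$pitch_um)
}

#' Mean intensity of an ion image over an ROI mask
#'
#' Arithmetic mean over the mask pixels; zeros count.
#'
#' @param image an [ion_image()].
#' @param roi logical mask matrix with the image's dimensions.
#' @return Non-negative scalar.
#' @export
roi_mean_intensity <- function(image, roi) {
  stopifnot(inherits(image, "ion_image"), is.logical(roi))
  if (!identical(dim(roi), dim(image$intensities)))
    stop2("mask dimensions do not match the image grid")
  if (!any(roi)) stop2("empty ROI mask")
  mean(image$intensities[roi])
}

#' Pairwise-ROI log2 fold-change profile of an ion image
#'
#' For each ordered ROI pair (i < j in label order) computes
#' log2(mean_i / mean_j) of the within-mask mean pixel intensities. A pair
#' with a zero mean on either side is marked missing rather than infinite.
#'
#' @param image an [ion_image()].
#' @param rois an [roi_set()] with at least 2 ROIs.
#' @return An `fc_profile` (see [fc_profile()]).
#' @export
metabolite_fc_profile <- function(image, rois) {
  stopifnot(inherits(rois, "roi_set"), length(rois$labels) >= 2L)
  means <- vapply(rois$labels,
                  function(l) roi_mean_intensity(image, rois$masks[[l]]), 0)
  cmb <- utils::combn(rois$labels, 2L)
  vals <- ifelse(means[cmb[1L, ]] > 0 & means[cmb[2L, ]] > 0,
                 log2(means[cmb[1L, ]] / means[cmb[2L, ]]), NA_real_)
  ann <- image$annotation
  fc_profile(analyte = ann$compound %||% sprintf("mz_%.5f", image$mz),
             kind = "metabolite", pairs = roi_pairs(rois),
             log2fc = unname(vals),
             flag = integer(length(vals)),
             roi_means = means, adduct = ann$adduct %||% NA_character_)
}

#' Annotate MSI channels by molecular formula and adduct
#'
#' MS1 annotation against a formula database under the negative-mode adduct
#' rules, with a simplified decoy-adduct false discovery rate: candidate
#' matches are scored by absolute ppm error, and the FDR at a score cut is
#' the decoy-adduct fraction of matches at or below the cut (made monotone in
#' the cut, q-value style). Only target-adduct annotations with FDR at or
#' below `fdr_max` are returned, each as an extracted [ion_image()]. Isomers
#' sharing a formula annotate separately per adduct. This decoy-adduct FDR is
#' a deliberately simple spatial-agnostic stand-in for image-aware annotation
#' engines.
#'
#' @param dataset an [msi_dataset()].
#' @param formula_db data.frame with columns `compound`, `formula` (optional
#'   `name`).
#' @param adducts adduct rule table from [adduct_rules()]; must contain at
#'   least one decoy rule whenever `fdr_max < 1`.
#' @param tol_ppm matching tolerance in ppm (default 3).
#' @param fdr_max maximum annotation FDR (default 0.2).
#' @return List of annotated `ion_image`s; the match table is attached as
#'   attribute `"matches"`.
#' @export
annotate_images <- function(dataset, formula_db, adducts = adduct_rules(),
                            tol_ppm = 3, fdr_max = 0.2) {
  stopifnot(inherits(dataset, "msi_dataset"), nrow(formula_db) >= 1L)
  if (fdr_max < 1 && !any(adducts$decoy))
    stop2("fdr_max < 1 requires at least one decoy adduct rule")
  channels <- detected_channels(dataset)
  cand <- list()
  for (k in seq_len(nrow(formula_db))) {
    for (a in seq_len(nrow(adducts))) {
      theo <- formula_mass(formula_db$formula[k]) + adducts$mass_shift[a]
      dppm <- ppm_error(channels, theo)
      hit <- which(abs(dppm) <= tol_ppm)
      for (h in hit) {
        cand[[length(cand) + 1L]] <- data.frame(
          mz = channels[h], compound = formula_db$compound[k],
          formula = formula_db$formula[k], adduct = adducts$name[a],
          decoy = adducts$decoy[a], ppm_error = dppm[h],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) return(structure(list(), matches = NULL))
  m <- do.call(rbind, cand)
  m <- m[order(abs(m$ppm_error)), , drop = FALSE]
  # FDR at each cut = decoys/targets among matches with |ppm| <= cut;
  # q-value = min FDR over all cuts at least as loose (monotone, so
  # tightening the cut never raises the FDR).
  nd <- cumsum(m$decoy)
  nt <- cumsum(!m$decoy)
  fdr <- ifelse(nt > 0, nd / nt, Inf)
  m$fdr <- rev(cummin(rev(fdr)))
  keep <- m[!m$decoy & m$fdr <= fdr_max, , drop = FALSE]
  imgs <- lapply(seq_len(nrow(keep)), function(i) {
    img <- extract_ion_image(dataset, keep$mz[i], tol_ppm)
    img$annotation <- list(compound = keep$compound[i],
                           formula = keep$formula[i],
                           adduct = keep$adduct[i],
                           ppm_error = keep$ppm_error[i],
                           fdr = keep$fdr[i])
    img
  })
  structure(imgs, matches = m)
}

# unique m/z channels carrying any signal
detected_channels <- function(dataset) {
  if (dataset$mode == "continuous") {
    tot <- Reduce(`+`, dataset$intensities)
    sort(unique(dataset$mz[tot > 0]))
  } else {
    sort(unique(unlist(Map(function(mz, it) mz[it > 0],
                           dataset$mz, dataset$intensities))))
  }
}

#' Export annotations as a TSV table
#'
#' @param images list returned by [annotate_images()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(images, path) {
  rows <- lapply(images, function(im) {
    a <- im$annotation
    data.frame(mz = im$mz, formula = a$formula, adduct = a$adduct,
               compound = a$compound, ppm_error = a$ppm_error, fdr = a$fdr,
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}
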