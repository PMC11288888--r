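#' Construct a set of labelled region-of-interest masks
#'
#' An `roi_set` ties pixel masks over the imaging grid to the proteomic
#' section replicates collected from each microhabitat. Masks must be pairwise
#' disjoint and every label must carry at least one replicate id.
#'
#' @param masks named list of logical matrices (rows = y, cols = x), one per
#'   ROI label, all with identical dimensions.
#' @param replicates named list (same names) of character replicate ids,
#'   e.g. `c("R1","R2","R3")`.
#' @param pitch_um pixel pitch in microns (default 50, the acquisition pitch
#'   the package's synthetic layouts emulate).
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(masks, replicates, pitch_um = 50) {
  stopifnot(is.list(masks), length(masks) >= 1L, !is.null(names(masks)))
  labels <- names(masks)
  if (anyDuplicated(labels)) stop2("ROI labels must be unique")
  dims <- dim(masks[[1]])
  for (m in masks) {
    if (!is.logical(m) || !identical(dim(m), dims))
      stop2("all masks must be logical matrices with identical dimensions")
  }
  # pairwise disjointness, offending pair named
  if (length(masks) > 1L) {
    for (i in seq_len(length(masks) - 1L)) {
      for (j in seq((i + 1L), length(masks))) {
        if (any(masks[[i]] & masks[[j]]))
          stop2("overlapping ROIs: ", labels[i], " and ", labels[j])
      }
    }
  }
  if (!is.list(replicates)) replicates <- as.list(replicates)
  if (!setequal(names(replicates), labels))
    stop2("replicates must be named by ROI label")
  replicates <- replicates[labels]
  if (any(vapply(replicates, length, 1L) < 1L))
    stop2("every ROI needs at least one replicate id")
  structure(
    list(labels = labels, masks = masks,
         replicates = lapply(replicates, as.character),
         dims = dims, pitch_um = pitch_um),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  cat("ROI set:", length(x$labels), "regions on a",
      paste(rev(x$dims), collapse = " x "), "grid at",
      x$pitch_um, "um pitch\n")
  for (lab in x$labels) {
    cat(sprintf("  %-6s %5d px, %d replicate sections (%s)\n", lab,
                sum(x$masks[[lab]]), length(x$replicates[[lab]]),
                paste(x$replicates[[lab]], collapse = ",")))
  }
  invisible(x)
}

#' Canonical ordered ROI pairs of a layout
#'
#' All pairs (i < j in label order); the first-listed ROI is the fold-change
#' numerator everywhere in the package.
#'
#' @param rois an `roi_set` or character vector of labels.
#' @return Character vector of `"A/B"` pair labels.
#' @export
roi_pairs <- function(rois) {
  labels <- if (inherits(rois, "roi_set")) rois$labels else rois
  if (length(labels) < 2L) stop2("need at least 2 ROIs")
  cmb <- utils::combn(labels, 2L)
  paste(cmb[1L, ], cmb[2L, ], sep = "/")
}

#' Write / read ROI masks as a TSV pixel list
#'
#' Serializes the masks as a three-column table (`roi`, `x`, `y`; 0-based
#' pixel coordinates) with replicate ids in a header comment, a plain-text
#' exchange format for the masks.
#'
#' @param rois an `roi_set`.
#' @param path output TSV path.
#' @return `path`, invisibly (`write_roi_tsv`); an `roi_set` (`read_roi_tsv`).
#' @export
write_roi_tsv <- function(rois, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dims\t%d\t%d", rois$dims[1], rois$dims[2]), con)
  writeLines(sprintf("# pitch_um\t%g", rois$pitch_um), con)
  for (lab in rois$labels)
    writeLines(sprintf("# replicates\t%s\t%s", lab,
                       paste(rois$replicates[[lab]], collapse = ",")), con)
  writeLines("roi\tx\ty", con)
  for (lab in rois$labels) {
    idx <- which(rois$masks[[lab]], arr.ind = TRUE)
    if (nrow(idx))
      writeLines(sprintf("%s\t%d\t%d", lab, idx[, 2L] - 1L, idx[, 1L] - 1L),
                 con)
  }
  invisible(path)
}

#' @rdname write_roi_tsv
#' @export
read_roi_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_hdr <- function(key) {
    h <- hdr[startsWith(hdr, paste0("# ", key))]
    lapply(strsplit(h, "\t", fixed = TRUE), function(x) x[-1L])
  }
  dims <- as.integer(get_hdr("dims")[[1]])
  pitch <- as.numeric(get_hdr("pitch_um")[[1]])
  reps <- get_hdr("replicates")
  replicates <- stats::setNames(
    lapply(reps, function(x) strsplit(x[2], ",", fixed = TRUE)[[1]]),
    vapply(reps, `[`, "", 1L))
  body <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                            stringsAsFactors = FALSE)
  masks <- lapply(names(replicates), function(lab) {
    m <- matrix(FALSE, dims[1], dims[2])
    rows <- body[body$roi == lab, , drop = FALSE]
    m[cbind(rows$y + 1L, rows$x + 1L)] <- TRUE
    m
  })
  names(masks) <- names(replicates)
  roi_set(masks, replicates, pitch_um = pitch)
}
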