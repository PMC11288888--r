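#' Filter peptide-spectrum matches by the qualification rules
#'
#' A PSM is kept iff it is fully tryptic (NTT = 2), has at most two missed
#' cleavages, spectral probability at or below `spec_prob_max` (lower is
#' better) and absolute adjusted mass error at or below `abs_delm_ppm_max`.
#'
#' @param psms data.frame with columns `peptide`, `is_decoy`, `spec_prob`,
#'   `delm_ppm`, `missed_cleavages`, `ntt` (plus any others, carried along).
#' @param thresholds list/vector with `spec_prob_max` and `abs_delm_ppm_max`,
#'   both positive.
#' @return The accepted subset of `psms`.
#' @export
filter_psms <- function(psms, thresholds) {
  sp <- thresholds[["spec_prob_max"]]
  dm <- thresholds[["abs_delm_ppm_max"]]
  stopifnot(is.numeric(sp), sp > 0, is.numeric(dm), dm > 0)
  keep <- psms$ntt == 2L & psms$missed_cleavages <= 2L &
    psms$spec_prob <= sp & abs(psms$delm_ppm) <= dm
  psms[keep, , drop = FALSE]
}

# decoy status of each peptide in an accepted set: a peptide is decoy iff
# all of its accepted PSMs are decoy
peptide_level <- function(accepted) {
  if (!nrow(accepted)) return(list(targets = character(), decoys = character()))
  any_target <- tapply(!accepted$is_decoy, accepted$peptide, any)
  list(targets = names(any_target)[any_target],
       decoys = names(any_target)[!any_target])
}

#' Audit target-decoy FDR of an accepted PSM set
#'
#' Simple decoys/targets ratio at both spectrum and peptide level (peptide
#' decoy iff all its accepted PSMs are decoy).
#'
#' @param accepted accepted PSM data.frame.
#' @return List `spectrum_fdr`, `peptide_fdr`, `n_target_psms`,
#'   `n_target_peptides`.
#' @export
audit_fdr <- function(accepted) {
  n_t <- sum(!accepted$is_decoy)
  n_d <- sum(accepted$is_decoy)
  pl <- peptide_level(accepted)
  list(spectrum_fdr = if (n_t > 0) n_d / n_t else if (n_d > 0) Inf else 0,
       peptide_fdr = if (length(pl$targets) > 0)
         length(pl$decoys) / length(pl$targets)
       else if (length(pl$decoys) > 0) Inf else 0,
       n_target_psms = n_t, n_target_peptides = length(pl$targets))
}

#' Optimize spectral-probability and mass-error thresholds under FDR control
#'
#' Grid search over the observed spectral probability values crossed with the
#' observed absolute mass errors (of structurally valid PSMs: NTT = 2, at
#' most 2 missed cleavages), returning the pair that maximizes the number of
#' distinct accepted target peptides subject to target-decoy FDR at or below
#' `fdr_max` at both the spectrum and the peptide level. Ties prefer the
#' smaller spectral-probability cap, then the smaller mass-error cap. For
#' large inputs each grid axis is thinned to at most `max_grid` observed
#' quantile values; below that the search is exhaustive.
#'
#' @param psms PSM data.frame (targets and decoys).
#' @param fdr_max maximum FDR (default 0.05).
#' @param max_grid per-axis candidate cap (default 60).
#' @return List `spec_prob_max`, `abs_delm_ppm_max` plus the audit of the
#'   winning acceptance set.
#' @export
optimize_thresholds <- function(psms, fdr_max = 0.05, max_grid = 60L) {
  stopifnot(any(psms$is_decoy), any(!psms$is_decoy))
  valid <- psms[psms$ntt == 2L & psms$missed_cleavages <= 2L, , drop = FALSE]
  if (!nrow(valid))
    stop2("no structurally valid PSMs (NTT = 2, missed cleavages <= 2)")
  sp_grid <- sort(unique(valid$spec_prob))
  dm_grid <- sort(unique(abs(valid$delm_ppm)))
  thin <- function(g) {
    if (length(g) <= max_grid) g
    else unique(g[unique(round(seq(1, length(g), length.out = max_grid)))])
  }
  sp_grid <- thin(sp_grid); dm_grid <- thin(dm_grid)

  best <- NULL
  absdm <- abs(valid$delm_ppm)
  for (sp in sp_grid) {
    ok_sp <- valid$spec_prob <= sp
    for (dm in dm_grid) {
      acc <- valid[ok_sp & absdm <= dm, , drop = FALSE]
      a <- audit_fdr(acc)
      if (a$spectrum_fdr <= fdr_max && a$peptide_fdr <= fdr_max) {
        cand <- list(spec_prob_max = sp, abs_delm_ppm_max = dm,
                     n_target_peptides = a$n_target_peptides,
                     n_target_psms = a$n_target_psms,
                     spectrum_fdr = a$spectrum_fdr,
                     peptide_fdr = a$peptide_fdr)
        if (is.null(best) ||
            cand$n_target_peptides > best$n_target_peptides ||
            (cand$n_target_peptides == best$n_target_peptides &&
             (cand$spec_prob_max < best$spec_prob_max ||
              (cand$spec_prob_max == best$spec_prob_max &&
               cand$abs_delm_ppm_max < best$abs_delm_ppm_max))))
          best <- cand
      }
    }
  }
  if (is.null(best))
    stop2("no threshold pair satisfies FDR <= ", fdr_max,
          " at both levels; consider relaxing fdr_max")
  best
}

#' Qualified peptides: at least two accepted PSMs
#'
#' @param accepted accepted PSM data.frame.
#' @param target_only drop peptides whose accepted PSMs are all decoy
#'   (default TRUE).
#' @return Character vector of qualified peptide sequences.
#' @export
qualify_peptides <- function(accepted, target_only = TRUE) {
  if (!nrow(accepted)) return(character())
  n <- table(accepted$peptide)
  qualified <- names(n)[n >= 2L]
  if (target_only) qualified <- intersect(qualified,
                                          peptide_level(accepted)$targets)
  sort(qualified)
}

#' Identified clusters: at least two qualified peptides
#'
#' @param qualified character vector of qualified peptides.
#' @param peptide_cluster data.frame with columns `peptide`, `cluster`
#'   covering every qualified peptide.
#' @return Character vector of identified cluster ids.
#' @export
rollup_clusters <- function(qualified, peptide_cluster) {
  i <- match(qualified, peptide_cluster$peptide)
  if (anyNA(i))
    stop2("unmapped peptide(s): ",
          paste(qualified[is.na(i)], collapse = ", "))
  n <- table(peptide_cluster$cluster[i])
  sort(names(n)[n >= 2L])
}

#' Normalize peptide intensities
#'
#' `"median"` (default): scale each replicate column (ROI x replicate) so
#' its median matches the global median; `"total"`: total-sum scaling;
#' `"none"`: passthrough.
#'
#' @param observations peptide observation data.frame with `roi`,
#'   `replicate`, `intensity`.
#' @param method normalization mode.
#' @return The table with `intensity` replaced by normalized values.
#' @export
normalize_intensities <- function(observations,
                                  method = c("median", "total", "none")) {
  method <- match.arg(method)
  if (method == "none") return(observations)
  key <- interaction(observations$roi, observations$replicate, drop = TRUE)
  x <- observations$intensity
  stat <- if (method == "median") function(v) stats::median(v, na.rm = TRUE)
          else function(v) sum(v, na.rm = TRUE)
  per <- tapply(x, key, stat)
  ref <- stats::median(per, na.rm = TRUE)
  observations$intensity <- x * ref / per[key]
  observations
}

#' Presence calls per ROI (Table-style O/X detection)
#'
#' A peptide is present in an ROI iff it is observed (non-missing intensity)
#' in at least two of that ROI's section replicates. A cluster is present iff
#' at least two of its peptides individually meet that rule within the same
#' ROI.
#'
#' @param observations data.frame with `peptide`, `cluster`, `roi`,
#'   `replicate`, `intensity`.
#' @param rois an [roi_set()].
#' @param level `"peptide"` or `"cluster"`.
#' @return Logical matrix (analyte x ROI), TRUE = detected.
#' @export
detect_presence <- function(observations, rois,
                            level = c("peptide", "cluster")) {
  level <- match.arg(level)
  stopifnot(inherits(rois, "roi_set"))
  labels <- rois$labels
  peps <- sort(unique(observations$peptide))
  pm <- matrix(FALSE, length(peps), length(labels),
               dimnames = list(peps, labels))
  for (l in labels) {
    sub <- observations[observations$roi == l &
                          observations$replicate %in% rois$replicates[[l]] &
                          !is.na(observations$intensity), , drop = FALSE]
    if (!nrow(sub)) next
    n <- tapply(sub$replicate, sub$peptide,
                function(r) length(unique(r)))
    pm[names(n)[n >= 2L], l] <- TRUE
  }
  if (level == "peptide") return(pm)
  map <- unique(observations[, c("peptide", "cluster")])
  cl <- sort(unique(map$cluster))
  cm <- matrix(FALSE, length(cl), length(labels),
               dimnames = list(cl, labels))
  for (l in labels) {
    present_peps <- rownames(pm)[pm[, l]]
    n <- table(map$cluster[map$peptide %in% present_peps])
    cm[names(n)[n >= 2L], l] <- TRUE
  }
  cm
}

#' Attribute peptides to unique owning proteins
#'
#' A peptide is taxon-attributable iff it occurs as a substring of exactly
#' one protein sequence in the database; such peptides inherit the owning
#' protein's annotation downstream. Isoleucine/leucine are collapsed before
#' matching by default (isobaric residues).
#'
#' @param peptides character vector of peptide sequences.
#' @param protein_fasta path to a protein FASTA, or a named character vector
#'   of sequences, or a `Biostrings::AAStringSet`.
#' @param collapse_il treat I and L as equivalent (default TRUE).
#' @return data.frame `peptide`, `n_proteins`, `unique`, `protein` (owner id
#'   when unique, NA otherwise; unmatched peptides have `n_proteins = 0`).
#' @export
unique_peptide_attribution <- function(peptides, protein_fasta,
                                       collapse_il = TRUE) {
  seqs <- if (is.character(protein_fasta) && length(protein_fasta) == 1L &&
              file.exists(protein_fasta)) {
    aa <- Biostrings::readAAStringSet(protein_fasta)
    stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  } else if (inherits(protein_fasta, "AAStringSet")) {
    stats::setNames(as.character(protein_fasta),
                    sub("\\s.*$", "", names(protein_fasta)))
  } else {
    protein_fasta
  }
  collapse <- function(x) if (collapse_il) chartr("I", "L", x) else x
  cs <- collapse(seqs)
  out <- lapply(peptides, function(p) {
    hits <- names(cs)[vapply(cs, function(s)
      grepl(collapse(p), s, fixed = TRUE), TRUE)]
    data.frame(peptide = p, n_proteins = length(hits),
               unique = length(hits) == 1L,
               protein = if (length(hits) == 1L) hits else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
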