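#' Fold-change profile over ordered ROI pairs
#'
#' The analyte-level unit of the colocalization statistic: for each ordered
#' ROI pair (first label = numerator) either a log2 fold change of mean
#' intensities, a G-test directional flag (+1 toward the numerator side, -1
#' toward the denominator side; resolved to a signed sentinel magnitude at
#' run level), or missing.
#'
#' @param analyte analyte id (peptide sequence or compound id).
#' @param kind `"peptide"` or `"metabolite"`.
#' @param pairs character vector of `"A/B"` pair labels (canonical order).
#' @param log2fc numeric per-pair values; `NA` = missing or flagged.
#' @param flag integer per-pair: 0 none, +1/-1 G-test directional flag.
#' @param roi_means named per-ROI means (diagnostic).
#' @param cluster,ko,adduct optional linkage metadata.
#' @return Object of class `fc_profile`.
#' @export
fc_profile <- function(analyte, kind, pairs, log2fc, flag = NULL,
                       roi_means = NULL, cluster = NA_character_,
                       ko = NA_character_, adduct = NA_character_) {
  if (is.null(flag)) flag <- integer(length(pairs))
  stopifnot(length(log2fc) == length(pairs), length(flag) == length(pairs))
  structure(list(analyte = analyte, kind = kind, pairs = pairs,
                 log2fc = log2fc, flag = as.integer(flag),
                 roi_means = roi_means, cluster = cluster, ko = ko,
                 adduct = adduct),
            class = "fc_profile")
}

#' @export
print.fc_profile <- function(x, ...) {
  cat(sprintf("fold-change profile [%s] %s\n", x$kind, x$analyte))
  v <- ifelse(x$flag != 0, sprintf("flag%+d", x$flag),
              ifelse(is.na(x$log2fc), "NA", sprintf("%.3f", x$log2fc)))
  cat(paste(sprintf("  %s: %s", x$pairs, v), collapse = "\n"), "\n")
  invisible(x)
}

#' Likelihood-ratio (G) test of independence on a 2x2 table
#'
#' G = 2 * sum over cells with O > 0 of O * ln(O/E), expected counts from the
#' row/column margins; p from the chi-square distribution with 1 df. A table
#' with a zero row or column margin is degenerate: G = 0, p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts, grand total > 0.
#' @return List with elements `G` and `p`.
#' @export
#' @examples
#' g_test(matrix(c(3, 0, 0, 3), 2))  # G = 12 * log(2)
g_test <- function(table) {
  O <- as.matrix(table)
  stopifnot(identical(dim(O), c(2L, 2L)))
  if (any(O < 0) || any(O != floor(O)))
    stop2("G-test requires non-negative integer counts")
  N <- sum(O)
  if (N == 0) stop2("G-test requires a positive grand total")
  r <- rowSums(O); cc <- colSums(O)
  if (any(r == 0) || any(cc == 0)) return(list(G = 0, p = 1))
  E <- outer(r, cc) / N
  pos <- O > 0
  G <- 2 * sum(O[pos] * log(O[pos] / E[pos]))
  list(G = G, p = stats::pchisq(G, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment returned in input order; thin validated wrapper
#' over `stats::p.adjust(method = "BH")`.
#'
#' @param pvals numeric vector of p-values in \\[0, 1\\].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(is.numeric(pvals))
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop2("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

shared_idx <- function(a, b) {
  if (!identical(a$pairs, b$pairs))
    stop2("profiles must share one canonical pair order")
  which(!is.na(a$log2fc) & !is.na(b$log2fc))
}

n_rois_of_pairs <- function(pairs) {
  length(unique(unlist(split_pair(pairs))))
}

#' Scaled Pearson correlation of two fold-change profiles
#'
#' Restricts both profiles to their shared non-missing pairs, centers and
#' scales each to unit variance, and computes the Pearson correlation as the
#' mean of elementwise products with the n/(n-1) normalization. Significance
#' is two-sided from t = r * sqrt(df / (1 - r^2)).
#'
#' The default degrees of freedom depend on `p_method`: `"roi"` (default)
#' uses df = (number of distinct ROIs spanned by the shared pairs) - 2 and
#' computes the test statistic from the uncentered cosine of the difference
#' profiles, which for complete profiles equals the Pearson correlation of
#' the underlying ROI log-means and gives a calibrated null; `"pairs"` uses
#' the literal df = n_pairs - 2 on the centered correlation (anticonservative
#' for profiles of pairwise differences; retained for comparison).
#'
#' @param a,b `fc_profile` objects (numeric vectors are accepted and treated
#'   as complete profiles) with identical pair order. Sentinel-resolved flag
#'   values participate as numbers.
#' @param p_method `"roi"` or `"pairs"`.
#' @return List `r`, `n_pairs`, `n_rois`, `df`, `p`, `shared`; or, with fewer
#'   than 3 shared pairs, a withheld result (`r = NA`) carrying `reason`.
#' @export
scaled_pearson <- function(a, b, p_method = c("roi", "pairs")) {
  p_method <- match.arg(p_method)
  if (is.numeric(a)) a <- fc_profile("a", "metabolite",
                                     paste0("p", seq_along(a)), a)
  if (is.numeric(b)) b <- fc_profile("b", "metabolite", a$pairs, b)
  idx <- shared_idx(a, b)
  n <- length(idx)
  if (n < 3L)
    return(list(r = NA_real_, n_pairs = n, n_rois = NA_integer_,
                df = NA_real_, p = NA_real_,
                reason = "fewer than 3 shared non-missing pairs"))
  x <- a$log2fc[idx]; y <- b$log2fc[idx]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, n_pairs = n, n_rois = NA_integer_,
                df = NA_real_, p = NA_real_,
                reason = "zero variance on shared pairs"))
  zx <- (x - mean(x)) / stats::sd(x)
  zy <- (y - mean(y)) / stats::sd(y)
  r <- sum(zx * zy) / (n - 1)
  n_rois <- n_rois_of_pairs(a$pairs[idx])
  if (p_method == "roi") {
    r0 <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    df <- n_rois - 2
  } else {
    r0 <- r
    df <- n - 2
  }
  p <- if (df < 1) NA_real_ else {
    r0c <- max(min(r0, 1), -1)
    if (abs(r0c) == 1) 0
    else 2 * stats::pt(abs(r0c) * sqrt(df / (1 - r0c^2)), df,
                       lower.tail = FALSE)
  }
  list(r = min(max(r, -1), 1), n_pairs = n, n_rois = n_rois, df = df, p = p)
}

#' Pairwise-ROI fold-change profile of one peptide
#'
#' An ROI mean is computable iff the peptide has at least two observed
#' intensities among that ROI's section replicates. Per pair: both means
#' computable gives log2(mean_i/mean_j); exactly one computable triggers a
#' G-test on the 2x2 detection table (observed/missing x the two ROIs) and,
#' if significant at `alpha_g`, a directional flag toward the side with data;
#' otherwise the pair is missing. The profile is withheld (NULL, with the
#' reason as an attribute) unless at least three ROIs are computable or
#' carry a significant flag.
#'
#' @param observations data.frame with columns `peptide`, `roi`, `replicate`,
#'   `intensity` (NA = not observed) and optionally `cluster`.
#' @param rois an [roi_set()].
#' @param peptide peptide to profile (default: the single peptide present).
#' @param alpha_g significance level for the directional G-test flag.
#' @return An `fc_profile`, or NULL when withheld.
#' @export
peptide_fc_profile <- function(observations, rois, peptide = NULL,
                               alpha_g = 0.05) {
  stopifnot(inherits(rois, "roi_set"))
  if (is.null(peptide)) {
    peptide <- unique(observations$peptide)
    if (length(peptide) != 1L)
      stop2("observations contain several peptides; name one")
  }
  obs <- observations[observations$peptide == peptide, , drop = FALSE]
  labels <- rois$labels
  n_rep <- vapply(rois$replicates, length, 1L)
  n_obs <- means <- stats::setNames(numeric(length(labels)), labels)
  for (l in labels) {
    v <- obs$intensity[obs$roi == l &
                         obs$replicate %in% rois$replicates[[l]]]
    v <- v[!is.na(v)]
    n_obs[l] <- length(v)
    means[l] <- if (length(v) >= 2L) mean(v) else NA_real_
  }
  computable <- !is.na(means)
  pairs <- roi_pairs(rois)
  cmb <- utils::combn(labels, 2L)
  vals <- rep(NA_real_, length(pairs))
  flags <- integer(length(pairs))
  flagged <- stats::setNames(logical(length(labels)), labels)
  for (k in seq_along(pairs)) {
    i <- cmb[1L, k]; j <- cmb[2L, k]
    if (computable[i] && computable[j]) {
      if (means[i] > 0 && means[j] > 0) vals[k] <- log2(means[i] / means[j])
    } else if (xor(computable[i], computable[j])) {
      tab <- matrix(c(n_obs[i], n_rep[i] - n_obs[i],
                      n_obs[j], n_rep[j] - n_obs[j]), 2L, byrow = TRUE)
      gt <- g_test(tab)
      if (!is.na(gt$p) && gt$p < alpha_g) {
        flags[k] <- if (computable[i]) 1L else -1L
        flagged[if (computable[i]) j else i] <- TRUE
      }
    }
  }
  usable <- sum(computable | flagged)
  if (usable < 3L) return(NULL)  # insufficient data: profile withheld
  fc_profile(analyte = peptide, kind = "peptide", pairs = pairs,
             log2fc = vals, flag = flags, roi_means = means,
             cluster = if ("cluster" %in% names(obs) && nrow(obs))
               obs$cluster[1] else NA_character_)
}

#' Fold-change profiles for every peptide in a table
#'
#' @inheritParams peptide_fc_profile
#' @return Named list of `fc_profile`s; withheld peptides are dropped and
#'   counted in attribute `"n_withheld"`.
#' @export
peptide_fc_profiles <- function(observations, rois, alpha_g = 0.05) {
  peps <- unique(observations$peptide)
  out <- list(); withheld <- 0L
  for (p in peps) {
    pr <- peptide_fc_profile(observations, rois, p, alpha_g)
    if (is.null(pr)) withheld <- withheld + 1L else out[[p]] <- pr
  }
  structure(out, n_withheld = withheld)
}

#' Resolve G-test flags into signed numeric sentinels
#'
#' The sentinel magnitude is (max |log2fc| observed across all profiles in
#' the run) + 1, so a flag dominates every real fold change in rank while
#' carrying its direction into the correlation.
#'
#' @param profiles list of `fc_profile`s (one run).
#' @return The profiles with flagged pairs replaced by signed sentinel values
#'   (flags kept); sentinel magnitude in attribute `"sentinel"`.
#' @export
resolve_sentinels <- function(profiles) {
  vals <- unlist(lapply(profiles, function(p) p$log2fc))
  m <- if (all(is.na(vals))) 1 else max(abs(vals), na.rm = TRUE) + 1
  out <- lapply(profiles, function(p) {
    f <- p$flag != 0L
    p$log2fc[f] <- p$flag[f] * m
    p
  })
  structure(out, sentinel = m, names = names(profiles))
}

#' Correlate enzyme peptides with their substrate and product images
#'
#' For each reaction triplet and each peptide profile whose KEGG Orthology id
#' matches the triplet's enzyme, correlates the peptide profile against the
#' substrate and the product metabolite profile, then Benjamini-Hochberg
#' adjusts across all tests emitted in the run and ranks by adjusted p.
#' G-test flags are resolved to sentinels across the whole run first.
#'
#' @param triplets data.frame of reaction triplets
#'   (see [find_triplets()]): columns `substrate`, `ko`, `product`,
#'   `reaction`, `pathways`.
#' @param peptide_profiles named list of peptide `fc_profile`s carrying `ko`.
#' @param metabolite_profiles named list of metabolite `fc_profile`s keyed by
#'   compound id.
#' @param alpha significance level applied to the adjusted p-values.
#' @param p_method passed to [scaled_pearson()].
#' @return data.frame of class `coloc_results`: one row per (triplet,
#'   peptide, role) test with `r`, `n_pairs`, `p`, `p_adj`, `significant`.
#' @export
correlate_triplets <- function(triplets, peptide_profiles,
                               metabolite_profiles, alpha = 0.05,
                               p_method = c("roi", "pairs")) {
  p_method <- match.arg(p_method)
  peptide_profiles <- resolve_sentinels(peptide_profiles)
  metabolite_profiles <- resolve_sentinels(metabolite_profiles)
  rows <- list()
  for (t in seq_len(nrow(triplets))) {
    kos <- vapply(peptide_profiles, function(p) p$ko %||% NA_character_, "")
    peps <- peptide_profiles[!is.na(kos) & kos == triplets$ko[t]]
    for (pep in peps) {
      for (role in c("substrate", "product")) {
        cid <- triplets[[role]][t]
        mp <- metabolite_profiles[[cid]]
        if (is.null(mp)) next
        res <- scaled_pearson(pep, mp, p_method = p_method)
        if (is.na(res$r)) next
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = pep$analyte, cluster = pep$cluster, ko = triplets$ko[t],
          compound = cid, adduct = mp$adduct %||% NA_character_,
          role = role, reaction = triplets$reaction[t],
          r = res$r, n_pairs = res$n_pairs, p = res$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(peptide = character(), cluster = character(),
                      ko = character(), compound = character(),
                      adduct = character(),
                      role = character(), reaction = character(),
                      r = numeric(), n_pairs = integer(), p = numeric(),
                      p_adj = numeric(), significant = logical())
    class(out) <- c("coloc_results", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj <= alpha
  out <- out[order(out$p_adj, out$p, -abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("coloc_results", "data.frame")
  out
}
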