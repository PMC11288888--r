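# Independent brute-force oracles. These deliberately re-derive each
# quantity by a different route than the package implementation.

# likelihood-ratio statistic by explicit cell loop
oracle_g <- function(O) {
  N <- sum(O)
  G <- 0
  for (i in 1:2) for (j in 1:2) {
    if (O[i, j] > 0) {
      e <- sum(O[i, ]) * sum(O[, j]) / N
      G <- G + 2 * O[i, j] * log(O[i, j] / e)
    }
  }
  list(G = G, p = pchisq(G, 1, lower.tail = FALSE))
}

# step-up BH by explicit loop (the implementation delegates to p.adjust)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  adj
}

# longest shared rank prefix by position-wise scan
oracle_lca <- function(lins) {
  lins <- lapply(lins, function(x)
    if (length(x) == 1L) strsplit(x, ";", fixed = TRUE)[[1]] else x)
  out <- character()
  d <- 1L
  repeat {
    ranks <- vapply(lins, function(l)
      if (length(l) >= d) l[d] else NA_character_, "")
    if (anyNA(ranks) || any(ranks != ranks[1])) break
    out <- c(out, ranks[1]); d <- d + 1L
  }
  out
}

# four-clause acceptance predicate, row by row
oracle_filter <- function(psms, sp, dm) {
  keep <- logical(nrow(psms))
  for (i in seq_len(nrow(psms))) {
    keep[i] <- psms$ntt[i] == 2 && psms$missed_cleavages[i] <= 2 &&
      psms$spec_prob[i] <= sp && abs(psms$delm_ppm[i]) <= dm
  }
  psms[keep, , drop = FALSE]
}

# exhaustive threshold grid search maximizing distinct target peptides
oracle_optimize <- function(psms, fdr_max) {
  valid <- psms[psms$ntt == 2 & psms$missed_cleavages <= 2, , drop = FALSE]
  best <- NULL
  for (sp in sort(unique(valid$spec_prob))) {
    for (dm in sort(unique(abs(valid$delm_ppm)))) {
      acc <- valid[valid$spec_prob <= sp & abs(valid$delm_ppm) <= dm, ,
                   drop = FALSE]
      nt <- sum(!acc$is_decoy); nd <- sum(acc$is_decoy)
      grp <- split(acc$is_decoy, acc$peptide)
      tpep <- sum(vapply(grp, function(z) any(!z), TRUE))
      dpep <- length(grp) - tpep
      ok_s <- if (nt > 0) nd / nt <= fdr_max else nd == 0
      ok_p <- if (tpep > 0) dpep / tpep <= fdr_max else dpep == 0
      if (ok_s && ok_p &&
          (is.null(best) || tpep > best$tpep ||
           (tpep == best$tpep &&
            (sp < best$sp || (sp == best$sp && dm < best$dm)))))
        best <- list(sp = sp, dm = dm, tpep = tpep)
    }
  }
  best
}

# independent monoisotopic masses (IUPAC/CIAAW values keyed in separately)
ORACLE_MASS <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                 O = 15.9949146221, P = 30.97376200, S = 31.9720711744,
                 Cl = 34.96885271)
ORACLE_E <- 0.00054857991

oracle_mz <- function(counts, adduct) {
  m <- sum(ORACLE_MASS[names(counts)] * counts)
  switch(adduct,
         "[M-H]-" = m - ORACLE_MASS[["H"]] + ORACLE_E,
         "[M+Cl]-" = m + ORACLE_MASS[["Cl"]] + ORACLE_E)
}

# random PSM table with coarse score grids (keeps exhaustive search small)
random_psms <- function(n, n_pep = 5) {
  data.frame(
    peptide = sample(paste0("PEP", seq_len(n_pep)), n, TRUE),
    is_decoy = runif(n) < 0.4,
    spec_prob = sample(10^-c(4, 6, 8, 10), n, TRUE),
    delm_ppm = sample(c(-6, -3, -0.5, 0.5, 3, 6), n, TRUE),
    missed_cleavages = sample(0:3, n, TRUE),
    ntt = sample(0:2, n, TRUE, prob = c(0.1, 0.1, 0.8)),
    stringsAsFactors = FALSE)
}

random_lineages <- function(k) {
  pool <- list(c("Eukaryota", "Fungi", "Basidiomycota", "Agaricales",
                 "Agaricaceae", "Leucoagaricus"),
               c("Eukaryota", "Fungi", "Basidiomycota", "Agaricales",
                 "Agaricaceae", "Agaricus"),
               c("Eukaryota", "Fungi", "Ascomycota", "Eurotiales"),
               c("Eukaryota", "Metazoa", "Arthropoda", "Insecta"),
               c("Bacteria", "Pseudomonadota", "Gammaproteobacteria"))
  lapply(sample(seq_along(pool), k, TRUE), function(i) {
    l <- pool[[i]]
    utils::head(l, sample(seq_along(l), 1))
  })
}
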