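psm <- function(peptide = "PEPK", decoy = FALSE, sp = 1e-12, dm = 1,
                mc = 0, ntt = 2) {
  data.frame(peptide = peptide, is_decoy = decoy, spec_prob = sp,
             delm_ppm = dm, missed_cleavages = mc, ntt = ntt,
             stringsAsFactors = FALSE)
}
thr <- list(spec_prob_max = 1e-10, abs_delm_ppm_max = 4.5)

test_that("each qualification clause independently rejects a PSM", {
  expect_equal(nrow(filter_psms(psm(), thr)), 1)
  expect_equal(nrow(filter_psms(psm(ntt = 1), thr)), 0)   # semi-tryptic
  expect_equal(nrow(filter_psms(psm(ntt = 1, sp = 1e-20), thr)), 0)
  expect_equal(nrow(filter_psms(psm(mc = 3), thr)), 0)
  expect_equal(nrow(filter_psms(psm(sp = 1e-9), thr)), 0)
  expect_equal(nrow(filter_psms(psm(dm = -5), thr)), 0)
  expect_equal(nrow(filter_psms(psm(sp = 1e-12, dm = 2.0), thr)), 1)
  expect_equal(nrow(filter_psms(psm(dm = -4.5), thr)), 1)  # boundary holds
})

test_that("the PSM filter equals the four-clause predicate on random sets", {
  withr::with_seed(8, {
    for (i in 1:25) {
      tab <- random_psms(40)
      sp <- sample(10^-c(5, 7, 9), 1); dm <- sample(c(1, 4, 7), 1)
      expect_equal(
        filter_psms(tab, list(spec_prob_max = sp, abs_delm_ppm_max = dm)),
        oracle_filter(tab, sp, dm))
    }
  })
})

test_that("threshold optimization is FDR-feasible and oracle-optimal", {
  sep <- generate_psm_table(120, 120, score_sep = 12, seed = 3)
  best <- optimize_thresholds(sep, 0.05)
  acc <- filter_psms(sep, best)
  expect_equal(sum(acc$is_decoy), 0)
  valid_targets <- sep[!sep$is_decoy & sep$ntt == 2 &
                         sep$missed_cleavages <= 2, ]
  expect_equal(best$n_target_peptides, length(unique(valid_targets$peptide)))

  # independent re-audit of the returned acceptance set
  a <- audit_fdr(acc)
  expect_lte(a$spectrum_fdr, 0.05)
  expect_lte(a$peptide_fdr, 0.05)

  # inseparable scores at fdr_max = 0: no candidate admits zero decoys
  flat <- random_psms(60)
  flat$is_decoy <- rep(c(TRUE, FALSE), 30)
  flat$spec_prob <- 1e-8
  flat$ntt <- 2L; flat$missed_cleavages <- 0L
  expect_error(optimize_thresholds(flat, 0), "no threshold pair")
})

test_that("qualification and rollup match counting oracles", {
  acc <- rbind(psm("A"), psm("A"), psm("B"),
               psm("C"), psm("C"), psm("C"),
               psm("D"), psm("D"))
  q <- qualify_peptides(acc)
  expect_equal(q, c("A", "C", "D"))      # B has a single PSM
  counts <- table(acc$peptide)
  expect_equal(q, sort(names(counts)[counts >= 2]))

  map <- data.frame(peptide = c("A", "C", "D"),
                    cluster = c("CL1", "CL1", "CL2"))
  expect_equal(rollup_clusters(q, map), "CL1")   # CL2 has one peptide
  expect_error(rollup_clusters(c(q, "E"), map), "unmapped peptide.*E")

  # decoy-only peptides never qualify
  dec <- rbind(psm("Z", decoy = TRUE), psm("Z", decoy = TRUE))
  expect_length(qualify_peptides(dec), 0)
  expect_equal(qualify_peptides(dec, target_only = FALSE), "Z")
})

test_that("filter-qualify-rollup is monotone in added PSMs", {
  withr::with_seed(21, {
    base <- random_psms(50, n_pep = 8)
    extra <- random_psms(25, n_pep = 8)
    t2 <- list(spec_prob_max = 1e-6, abs_delm_ppm_max = 6)
    map <- data.frame(peptide = paste0("PEP", 1:8),
                      cluster = rep(c("CL1", "CL2"), 4))
    q1 <- qualify_peptides(filter_psms(base, t2))
    q2 <- qualify_peptides(filter_psms(rbind(base, extra), t2))
    expect_true(all(q1 %in% q2))
    expect_true(all(rollup_clusters(q1, map) %in% rollup_clusters(q2, map)))
  })
})

test_that("presence needs two section replicates, two peptides per cluster", {
  layout <- tiny_layout()
  obs <- rbind(
    obs_roi("P1", "CL1", "LM1", c(10, NA, 12)),     # R1,R3 observed
    obs_roi("P1", "CL1", "LM2", c(NA, 9, NA)),
    obs_roi("P1", "CL1", "PMM", c(NA, NA, NA)),
    obs_roi("P2", "CL1", "LM1", c(7, 8, NA)),
    obs_roi("P3", "CL2", "LM1", c(5, 5, 5)))
  pm <- detect_presence(obs, layout, "peptide")
  expect_true(pm["P1", "LM1"])
  expect_false(pm["P1", "LM2"])   # single replicate
  expect_false(pm["P1", "PMM"])
  cm <- detect_presence(obs, layout, "cluster")
  expect_true(cm["CL1", "LM1"])   # P1 and P2 both present
  expect_false(cm["CL2", "LM1"])  # one peptide only

  # invariant to replicate row order
  pm2 <- detect_presence(obs[rev(seq_len(nrow(obs))), ], layout, "peptide")
  expect_identical(pm, pm2[rownames(pm), colnames(pm)])
})

test_that("unique-peptide attribution respects I/L equivalence", {
  fasta <- c(PROT1 = "MKAAPELIRGGK", PROT2 = "MKTTAPELIRWW",
             PROT3 = "MQQQGGGHHHKK")
  att <- unique_peptide_attribution(c("APELIR", "GGGHHH", "APELLR",
                                      "WWWWWW"), fasta)
  expect_equal(att$n_proteins[att$peptide == "APELIR"], 2)  # in PROT1+2
  expect_false(att$unique[att$peptide == "APELIR"])
  expect_true(att$unique[att$peptide == "GGGHHH"])
  expect_equal(att$protein[att$peptide == "GGGHHH"], "PROT3")
  expect_equal(att$n_proteins[att$peptide == "APELLR"], 2)  # I~L collapse
  expect_equal(
    unique_peptide_attribution("APELLR", fasta, collapse_il = FALSE)$n_proteins,
    0)
  expect_equal(att$n_proteins[att$peptide == "WWWWWW"], 0)  # unmatched
  expect_false(att$unique[att$peptide == "WWWWWW"])

  # FASTA file input goes through the same path
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">PROT1 desc", "MKAAPELIRGGK", ">PROT2", "MKTTAPELIRWW"), f)
  att2 <- unique_peptide_attribution("APELIR", f)
  expect_equal(att2$n_proteins, 2)
})

test_that("normalization modes rescale per replicate column", {
  layout <- tiny_layout()
  obs <- rbind(obs_roi("P1", "CL1", "LM1", c(10, 20, 30)),
               obs_roi("P2", "CL1", "LM1", c(30, 60, 90)))
  norm <- normalize_intensities(obs, "median")
  med <- tapply(norm$intensity, norm$replicate, median)
  expect_true(all(abs(med - med[1]) < 1e-9))
  expect_identical(normalize_intensities(obs, "none"), obs)
})
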