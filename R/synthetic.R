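# Synthetic-data generators. They emulate the structure of the study the
# package is built around: four microhabitat ROIs (LM1, LM2, LM3, PMM) with
# 3/3/6/3 section replicates, 50-um-pitch negative-mode ion images on an
# m/z 92-700 window, peptide intensity tables with missingness, scored
# decoy-containing PSM tables, and a local reaction graph -- with planted
# substrate-enzyme-product colocalization as recoverable ground truth.
# Intensities use multiplicative lognormal noise (positive, MS-like);
# missingness is completely at random per cell, with an optional
# intensity-dependent mode. One global seed fans out to per-generator
# subseeds by stable name hashing.

#' Planted ground truth of a synthetic run
#'
#' @param planted_triplets data.frame `substrate`, `ko`, `product`.
#' @param planted_profiles named list: analyte id -> named per-ROI mean.
#' @param noise_sd lognormal (log-scale) noise sd.
#' @param missing_rate per-cell missingness probability.
#' @param seed integer seed that generated the artifacts.
#' @return Object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(planted_triplets, planted_profiles,
                            noise_sd, missing_rate, seed) {
  stopifnot(noise_sd >= 0, missing_rate >= 0, missing_rate <= 1)
  structure(list(planted_triplets = planted_triplets,
                 planted_profiles = planted_profiles,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 seed = seed),
            class = "synthetic_truth")
}

#' Write planted truth as JSON
#'
#' @param truth a [synthetic_truth()].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a microhabitat ROI layout
#'
#' Places labelled, non-overlapping masks on a pixel grid and attaches the
#' section-replicate ids of each microhabitat (default 3/3/6/3 for
#' LM1/LM2/LM3/PMM). Each ROI must cover at least 25 pixels.
#'
#' @param width,height grid size in pixels.
#' @param roi_specs list of lists with `label`, `shape` (`"disc"` or
#'   `"rect"`), geometry (`cx`, `cy`, `r` or `x0`, `y0`, `x1`, `y1`) and
#'   optional `n_replicates`.
#' @param seed integer seed (reserved for randomized layouts; the default
#'   discs are deterministic).
#' @return An [roi_set()].
#' @export
generate_roi_layout <- function(width = 100, height = 100,
                                roi_specs = default_roi_specs(),
                                seed = 1L) {
  masks <- list(); reps <- list()
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), width), height, width)
  for (spec in roi_specs) {
    m <- switch(spec$shape %||% "disc",
      disc = (xs - spec$cx)^2 + (ys - spec$cy)^2 <= spec$r^2,
      rect = xs >= spec$x0 & xs <= spec$x1 & ys >= spec$y0 & ys <= spec$y1,
      stop2("unknown ROI shape: ", spec$shape))
    if (sum(m) < 25L)
      stop2("ROI ", spec$label, " covers ", sum(m), " px (< 25)")
    masks[[spec$label]] <- m
    n <- spec$n_replicates %||% 3L
    reps[[spec$label]] <- paste0("R", seq_len(n))
  }
  roi_set(masks, reps, pitch_um = 50)
}

#' @rdname generate_roi_layout
#' @export
default_roi_specs <- function() {
  list(list(label = "LM1", shape = "disc", cx = 25, cy = 25, r = 11,
            n_replicates = 3L),
       list(label = "LM2", shape = "disc", cx = 72, cy = 28, r = 11,
            n_replicates = 3L),
       list(label = "LM3", shape = "disc", cx = 30, cy = 72, r = 14,
            n_replicates = 6L),
       list(label = "PMM", shape = "disc", cx = 73, cy = 70, r = 10,
            n_replicates = 3L))
}

#' Default planted metabolite and enzyme-cluster specifications
#'
#' Three planted substrate-enzyme-product triplets spanning the two
#' microhabitat archetypes, including the isomer pair: fuconate ionizing as
#' `[M-H]-` in the lignin microhabitats and its mass isomer glucose as
#' `[M+Cl]-` in the primary-metabolite microhabitat. Well-established KEGG
#' ids are used where certain (C00031 glucose, C00092 glucose 6-phosphate,
#' K01576, K18334, K00844); C9xxxx ids are synthetic placeholders. Per-ROI
#' mean contrasts between on/off microhabitats are ~16-25 fold. Distractor
#' metabolites carry no planted relationship.
#'
#' @return `default_metabolite_specs()`: list of per-compound specs;
#'   `default_cluster_specs()`: list of per-cluster specs;
#'   `default_planted_triplets()`: data.frame of the planted triplets.
#' @export
default_metabolite_specs <- function() {
  list(
    list(compound = "C90001", name = "4-hydroxyphenylglyoxylate",
         formula = "C8H6O4", adduct = "[M-H]-",
         roi_means = c(LM1 = 500, LM2 = 350, LM3 = 450, PMM = 25)),
    list(compound = "C90002", name = "4-hydroxybenzaldehyde",
         formula = "C7H6O2", adduct = "[M-H]-",
         roi_means = c(LM1 = 500, LM2 = 350, LM3 = 450, PMM = 25)),
    list(compound = "C01720", name = "L-fuconate",
         formula = "C6H12O6", adduct = "[M-H]-",
         roi_means = c(LM1 = 300, LM2 = 450, LM3 = 380, PMM = 20)),
    list(compound = "C90003", name = "2-dehydro-3-deoxy-L-fuconate",
         formula = "C6H10O5", adduct = "[M-H]-",
         roi_means = c(LM1 = 300, LM2 = 450, LM3 = 380, PMM = 20)),
    list(compound = "C00031", name = "D-glucose",
         formula = "C6H12O6", adduct = "[M+Cl]-",
         roi_means = c(LM1 = 20, LM2 = 25, LM3 = 18, PMM = 520)),
    list(compound = "C00092", name = "D-glucose 6-phosphate",
         formula = "C6H13O9P", adduct = "[M-H]-",
         roi_means = c(LM1 = 20, LM2 = 25, LM3 = 18, PMM = 520)),
    list(compound = "C90010", name = "distractor-1",
         formula = "C10H8O3", adduct = "[M-H]-",
         roi_means = c(LM1 = 120, LM2 = 110, LM3 = 130, PMM = 115)),
    list(compound = "C90011", name = "distractor-2",
         formula = "C5H9NO4", adduct = "[M-H]-",
         roi_means = c(LM1 = 60, LM2 = 220, LM3 = 90, PMM = 150))
  )
}

#' @rdname default_metabolite_specs
#' @export
default_cluster_specs <- function() {
  fungi <- "Eukaryota;Fungi;Basidiomycota;Agaricomycetes;Agaricales;Agaricaceae;Leucoagaricus"
  ant <- "Eukaryota;Metazoa;Arthropoda;Insecta;Hymenoptera;Formicidae;Atta"
  list(
    list(cluster = "CL0001", ko = "K01576",
         name = "benzoylformate decarboxylase", lineage = fungi,
         n_peptides = 3L,
         roi_means = c(LM1 = 500, LM2 = 350, LM3 = 450, PMM = 25)),
    list(cluster = "CL0002", ko = "K18334",
         name = "L-fuconate dehydratase", lineage = fungi,
         n_peptides = 3L,
         roi_means = c(LM1 = 300, LM2 = 450, LM3 = 380, PMM = 20)),
    list(cluster = "CL0003", ko = "K00844", name = "hexokinase",
         lineage = ant, n_peptides = 3L,
         roi_means = c(LM1 = 20, LM2 = 25, LM3 = 18, PMM = 520)),
    list(cluster = "CL0101", ko = "K90001", name = "distractor enzyme 1",
         lineage = fungi, n_peptides = 3L,
         roi_means = c(LM1 = 140, LM2 = 100, LM3 = 120, PMM = 125)),
    list(cluster = "CL0102", ko = "K90002", name = "distractor enzyme 2",
         lineage = ant, n_peptides = 3L,
         roi_means = c(LM1 = 200, LM2 = 70, LM3 = 150, PMM = 95)),
    # uniformly expressed background proteins: the bulk of a real
    # metaproteomic table, and the stability anchor median normalization
    # assumes (most peptides unchanged across samples)
    background_cluster("BG0001", "K70001", fungi, 60),
    background_cluster("BG0002", "K70002", fungi, 80),
    background_cluster("BG0003", "K70003", fungi, 100),
    background_cluster("BG0004", "K70004", ant, 120),
    background_cluster("BG0005", "K70005", fungi, 150),
    background_cluster("BG0006", "K70006", ant, 90)
  )
}

background_cluster <- function(id, ko, lineage, level) {
  list(cluster = id, ko = ko, name = paste("background protein", id),
       lineage = lineage, n_peptides = 3L,
       roi_means = c(LM1 = level, LM2 = level, LM3 = level, PMM = level))
}

#' @rdname default_metabolite_specs
#' @export
default_planted_triplets <- function() {
  data.frame(
    substrate = c("C90001", "C01720", "C00031"),
    ko = c("K01576", "K18334", "K00844"),
    product = c("C90002", "C90003", "C00092"),
    stringsAsFactors = FALSE)
}

#' @rdname default_metabolite_specs
#' @export
default_distractor_triplets <- function() {
  # a detectable enzyme linked to imaged metabolites it has no spatial
  # relationship with: emits genuine null tests in the default run
  data.frame(substrate = "C90010", ko = "K90001", product = "C90011",
             stringsAsFactors = FALSE)
}

#' Generate ion images with planted ROI structure
#'
#' One image per (compound, adduct) at its theoretical m/z: within-ROI
#' pixels are lognormal around the planted ROI mean, background pixels are
#' zero, and isomer pairs separate only through their preferred adduct.
#' Images whose m/z falls outside the 92-700 acquisition window are
#' rejected.
#'
#' @param layout an [roi_set()].
#' @param metabolite_specs list of specs (`compound`, `formula`, `adduct`,
#'   `roi_means`), see [default_metabolite_specs()].
#' @param noise_sd log-scale lognormal noise sd (default 0.1).
#' @param seed integer seed.
#' @return List with `images` (annotated [ion_image()]s, named by compound)
#'   and `truth` (a [synthetic_truth()]).
#' @export
generate_ion_images <- function(layout, metabolite_specs =
                                  default_metabolite_specs(),
                                noise_sd = 0.1, seed = 1L) {
  stopifnot(inherits(layout, "roi_set"), noise_sd >= 0)
  profiles <- list()
  images <- with_seed(subseed(seed, "ion_images"), {
    lapply(metabolite_specs, function(spec) {
      if (any(spec$roi_means < 0)) stop2("per-ROI means must be nonnegative")
      mz <- adduct_mz(spec$formula, spec$adduct)
      if (mz < 92 || mz > 700)
        stop2("m/z ", round(mz, 4), " of ", spec$compound, " ", spec$adduct,
              " outside acquisition range [92, 700]")
      img <- matrix(0, layout$dims[1], layout$dims[2])
      for (lab in layout$labels) {
        m <- layout$masks[[lab]]
        mu <- spec$roi_means[[lab]]
        if (mu > 0)
          img[m] <- mu * exp(stats::rnorm(sum(m), 0, noise_sd))
      }
      profiles[[spec$compound]] <<- spec$roi_means
      ion_image(mz, img, pitch_um = layout$pitch_um,
                annotation = list(compound = spec$compound,
                                  formula = spec$formula,
                                  adduct = spec$adduct))
    })
  })
  names(images) <- vapply(metabolite_specs, `[[`, "", "compound")
  list(images = images,
       truth = synthetic_truth(default_planted_triplets()[0, ], profiles,
                               noise_sd, 0, seed))
}

#' Bundle ion images into a continuous-mode MSI dataset
#'
#' Builds the shared m/z axis from the image channels so the set can be
#' written as imzML and re-annotated from raw form.
#'
#' @param images list of [ion_image()]s.
#' @param layout the [roi_set()] giving the grid.
#' @return An [msi_dataset()].
#' @export
images_to_dataset <- function(images, layout) {
  mz <- vapply(images, `[[`, 0, "mz")
  o <- order(mz)
  images <- images[o]; mz <- mz[o]
  h <- layout$dims[1]; w <- layout$dims[2]
  coords <- cbind(x = rep(seq_len(w) - 1L, each = h),
                  y = rep(seq_len(h) - 1L, w))
  ints <- lapply(seq_len(nrow(coords)), function(i) {
    vapply(images, function(im)
      im$intensities[coords[i, 2L] + 1L, coords[i, 1L] + 1L], 0)
  })
  msi_dataset(coords, mz, ints, mode = "continuous",
              pitch_um = layout$pitch_um)
}

rand_peptide <- function(len) {
  aa <- strsplit("ACDEFGHKLMNPQRSTVWY", "")[[1]]  # no I: I/L collapsed later
  paste0(paste(sample(aa, len - 1L, TRUE), collapse = ""),
         sample(c("K", "R"), 1L))
}

#' Generate a peptide observation table with planted structure
#'
#' Peptide intensities are lognormal around each cluster's planted ROI mean;
#' every observed cell carries a PSM count of at least 1; missingness is
#' applied per cell, completely at random by default or with probability
#' rising as intensity falls (`missing_mode = "intensity"`).
#'
#' @param layout an [roi_set()].
#' @param cluster_specs list of specs (`cluster`, `ko`, `lineage`,
#'   `n_peptides`, `roi_means`), see [default_cluster_specs()].
#' @param missing_rate cell missingness probability (default 0.1).
#' @param noise_sd log-scale noise sd (default 0.1).
#' @param missing_mode `"mcar"` or `"intensity"` (dropout odds double per
#'   4-fold intensity decrease below the global median).
#' @param seed integer seed.
#' @return List with `observations` (data.frame `peptide`, `cluster`, `ko`,
#'   `roi`, `replicate`, `intensity`, `psm_count`) and `truth` (presence map
#'   in `planted_profiles`, `present` data.frame of truly present
#'   cluster-ROI pairs).
#' @export
generate_peptide_table <- function(layout,
                                   cluster_specs = default_cluster_specs(),
                                   missing_rate = 0.1, noise_sd = 0.1,
                                   missing_mode = c("mcar", "intensity"),
                                   seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  stopifnot(inherits(layout, "roi_set"),
            missing_rate >= 0, missing_rate <= 1, noise_sd >= 0)
  with_seed(subseed(seed, "peptide_table"), {
    rows <- list(); profiles <- list(); present <- list()
    for (spec in cluster_specs) {
      peptides <- vapply(seq_len(spec$n_peptides), function(i)
        rand_peptide(sample(9:14, 1L)), "")
      profiles[[spec$cluster]] <- spec$roi_means
      for (lab in layout$labels) {
        mu <- spec$roi_means[[lab]]
        if (mu > 0)
          present[[length(present) + 1L]] <- data.frame(
            cluster = spec$cluster, roi = lab, stringsAsFactors = FALSE)
        for (pep in peptides) {
          for (rep_id in layout$replicates[[lab]]) {
            if (mu <= 0) { intensity <- NA_real_ } else {
              intensity <- mu * exp(stats::rnorm(1, 0, noise_sd))
            }
            rows[[length(rows) + 1L]] <- data.frame(
              peptide = pep, cluster = spec$cluster, ko = spec$ko,
              roi = lab, replicate = rep_id, intensity = intensity,
              psm_count = 1L + stats::rpois(1, 1.5),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    obs <- do.call(rbind, rows)
    if (missing_rate > 0) {
      p <- rep(missing_rate, nrow(obs))
      if (missing_mode == "intensity") {
        med <- stats::median(obs$intensity, na.rm = TRUE)
        lo <- !is.na(obs$intensity) & obs$intensity < med
        odds <- missing_rate / (1 - missing_rate) *
          2^(log2(med / obs$intensity[lo]) / 2)
        p[lo] <- odds / (1 + odds)
      }
      drop <- stats::runif(nrow(obs)) < p
      obs$intensity[drop] <- NA_real_
    }
    obs$psm_count[is.na(obs$intensity)] <- 0L
    list(observations = obs,
         truth = synthetic_truth(default_planted_triplets()[0, ], profiles,
                                 noise_sd, missing_rate, seed),
         present = do.call(rbind, present))
  })
}

#' Generate a decoy-containing scored PSM table
#'
#' Target spectral probabilities are drawn log-uniformly well below decoy
#' scores separated by `score_sep` orders of magnitude; decoys also carry
#' wider mass errors. Includes structurally invalid rows (NTT < 2, 3 missed
#' cleavages) to exercise the qualification filter.
#'
#' @param n_targets,n_decoys row counts (> 0).
#' @param score_sep separation of decoy log10 spectral probability from the
#'   target distribution (default 4; 0 = indistinguishable).
#' @param seed integer seed.
#' @param peptides optional peptide sequences guaranteed in the target pool
#'   (e.g. the quantified table's peptides); they are sampled with
#'   `peptide_weight`-fold higher probability than the background pool, the
#'   way abundant quantified peptides accumulate many PSMs in a search.
#' @param peptide_weight sampling weight of `peptides` relative to the
#'   background pool (default 4).
#' @return data.frame `peptide`, `is_decoy`, `spec_prob`, `delm_ppm`,
#'   `missed_cleavages`, `ntt`.
#' @export
generate_psm_table <- function(n_targets, n_decoys, score_sep = 4,
                               seed = 1L, peptides = NULL,
                               peptide_weight = 6) {
  stopifnot(n_targets > 0, n_decoys > 0)
  with_seed(subseed(seed, "psm_table"), {
    pool_size <- max(2L, ceiling(n_targets / 2.5))
    background <- vapply(seq_len(pool_size),
                         function(i) rand_peptide(sample(9:14, 1L)), "")
    pool <- c(peptides, background)
    w <- c(rep(peptide_weight, length(peptides)),
           rep(1, length(background)))
    t_pep <- sample(pool, n_targets, TRUE, prob = w)
    d_pep <- paste0("DECOY_", vapply(seq_len(n_decoys), function(i)
      rand_peptide(sample(9:14, 1L)), ""))
    tab <- data.frame(
      peptide = c(t_pep, d_pep),
      is_decoy = rep(c(FALSE, TRUE), c(n_targets, n_decoys)),
      spec_prob = 10^c(stats::rnorm(n_targets, -11, 1.3),
                       stats::rnorm(n_decoys, -11 + score_sep, 1.3)),
      delm_ppm = c(stats::rnorm(n_targets, 0, 1.2),
                   stats::runif(n_decoys, -12, 12)),
      missed_cleavages = sample(0:3, n_targets + n_decoys, TRUE,
                                prob = c(0.6, 0.25, 0.1, 0.05)),
      ntt = sample(0:2, n_targets + n_decoys, TRUE,
                   prob = c(0.03, 0.07, 0.9)),
      stringsAsFactors = FALSE)
    tab$spec_prob <- pmin(tab$spec_prob, 1)
    tab[sample.int(nrow(tab)), , drop = FALSE]
  })
}

#' Generate a reaction graph containing planted triplets
#'
#' Each planted (substrate, KO, product) becomes a KO -> reaction ->
#' substrate/product unit on a shared pathway; distractor KOs get private
#' reactions over private compounds, with no path to any planted analyte.
#'
#' @param planted_triplets data.frame `substrate`, `ko`, `product`
#'   (`K\\d{5}` / `C\\d{5}` ids).
#' @param n_distractors number of distractor KOs (default 5).
#' @param seed integer seed.
#' @return A `reaction_graph`.
#' @export
generate_reaction_graph <- function(planted_triplets =
                                      default_planted_triplets(),
                                    n_distractors = 5L, seed = 1L) {
  ok_ids <- grepl("^K\\d{5}$", planted_triplets$ko) &
    grepl("^C\\d{5}$", planted_triplets$substrate) &
    grepl("^C\\d{5}$", planted_triplets$product)
  if (!all(ok_ids)) stop2("malformed KO/compound ids in planted triplets")
  n_p <- nrow(planted_triplets)
  ko2rxn <- data.frame(ko = planted_triplets$ko,
                       reaction = sprintf("R9%04d", seq_len(n_p)),
                       stringsAsFactors = FALSE)
  rxn2cpd <- rbind(
    data.frame(reaction = ko2rxn$reaction,
               compound = planted_triplets$substrate, side = "substrate",
               stringsAsFactors = FALSE),
    data.frame(reaction = ko2rxn$reaction,
               compound = planted_triplets$product, side = "product",
               stringsAsFactors = FALSE))
  cpds <- data.frame(compound = unique(c(planted_triplets$substrate,
                                         planted_triplets$product)),
                     stringsAsFactors = FALSE)
  cpds$name <- cpds$compound; cpds$formula <- NA_character_
  rxn2path <- data.frame(reaction = ko2rxn$reaction, pathway = "map90001",
                         stringsAsFactors = FALSE)
  if (n_distractors > 0) {
    d_ko <- sprintf("K8%04d", seq_len(n_distractors))
    d_rxn <- sprintf("R8%04d", seq_len(n_distractors))
    d_sub <- sprintf("C8%04d", 2 * seq_len(n_distractors) - 1)
    d_prod <- sprintf("C8%04d", 2 * seq_len(n_distractors))
    ko2rxn <- rbind(ko2rxn, data.frame(ko = d_ko, reaction = d_rxn))
    rxn2cpd <- rbind(rxn2cpd,
      data.frame(reaction = d_rxn, compound = d_sub, side = "substrate"),
      data.frame(reaction = d_rxn, compound = d_prod, side = "product"))
    cpds <- rbind(cpds, data.frame(compound = c(d_sub, d_prod),
                                   name = c(d_sub, d_prod),
                                   formula = NA_character_))
    rxn2path <- rbind(rxn2path,
                      data.frame(reaction = d_rxn, pathway = "map80001"))
  }
  reaction_graph(ko2rxn, rxn2cpd, cpds, rxn2path)
}

#' Generate homology hit tables consistent with planted annotations
#'
#' For each query, the two top-bit-score hits agree on the planted lineage
#' and KO; lower-ranked hits degrade in lineage depth and score, and a couple
#' of sub-threshold hits (bit score <= 50 or e-value >= 1e-5) are included
#' to exercise the filters.
#'
#' @param queries data.frame `query`, `lineage`, `ko`.
#' @param n_hits hits per query (default 6).
#' @param seed integer seed.
#' @return data.frame `query`, `lineage`, `bit_score`, `e_value`, `ko`.
#' @export
generate_hit_table <- function(queries, n_hits = 6L, seed = 1L) {
  with_seed(subseed(seed, "hit_table"), {
    rows <- lapply(seq_len(nrow(queries)), function(i) {
      lin <- parse_lineage(queries$lineage[i])
      top_bit <- round(stats::runif(1, 150, 400), 1)
      bits <- c(top_bit, top_bit,
                sort(stats::runif(max(0L, n_hits - 4L), 60, top_bit - 1),
                     decreasing = TRUE),
                45, 80)  # last two: below bit floor / above e ceiling
      ev <- 10^-stats::runif(n_hits, 10, 60)
      ev[n_hits] <- 1e-3
      lines <- c(format_lineage(lin), format_lineage(lin),
                 vapply(seq_len(n_hits - 2L), function(k)
                   format_lineage(utils::head(lin, max(2L, length(lin) - k))),
                   ""))
      data.frame(query = queries$query[i], lineage = lines[seq_len(n_hits)],
                 bit_score = bits[seq_len(n_hits)], e_value = ev,
                 ko = queries$ko[i], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Write a protein FASTA for the synthetic clusters
#'
#' One protein per cluster, containing that cluster's peptides as substrings
#' separated by random filler, so unique-peptide attribution can recover the
#' owner.
#'
#' @param observations peptide table from [generate_peptide_table()].
#' @param path FASTA output path.
#' @param seed integer seed.
#' @return `path`, invisibly.
#' @export
write_cluster_fasta <- function(observations, path, seed = 1L) {
  with_seed(subseed(seed, "fasta"), {
    map <- unique(observations[, c("peptide", "cluster")])
    lines <- character()
    for (cl in unique(map$cluster)) {
      peps <- map$peptide[map$cluster == cl]
      filler <- function() rand_peptide(sample(8:20, 1L))
      seqs <- paste0(filler(),
                     paste(vapply(peps, function(p) paste0(p, filler()), ""),
                           collapse = ""))
      lines <- c(lines, paste0(">", cl), seqs)
    }
    writeLines(lines, path)
  })
  invisible(path)
}
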