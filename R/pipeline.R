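#' Colocalization analysis of enzymes and metabolites
#'
#' The central analysis: correlates every detected enzyme's peptide
#' fold-change profiles against its substrate and product metabolite
#' profiles over the canonical ROI pairs, with run-level sentinel
#' resolution, Benjamini-Hochberg adjustment and ranking.
#'
#' @param peptide_profiles named list of peptide `fc_profile`s (carrying
#'   `cluster` and `ko`).
#' @param metabolite_profiles named list of metabolite `fc_profile`s keyed
#'   by compound id.
#' @param triplets data.frame from [find_triplets()].
#' @param alpha adjusted-significance level (default 0.05).
#' @param p_method `"roi"` (calibrated, default) or `"pairs"`; see
#'   [scaled_pearson()].
#' @return Object of class `coloc` with the test table (`$results`), the
#'   profiles and counts; supports `print`, `summary`, `plot`,
#'   `as.data.frame`.
#' @export
colocalize <- function(peptide_profiles, metabolite_profiles, triplets,
                       alpha = 0.05, p_method = c("roi", "pairs")) {
  p_method <- match.arg(p_method)
  results <- correlate_triplets(triplets, peptide_profiles,
                                metabolite_profiles, alpha = alpha,
                                p_method = p_method)
  structure(list(
    results = results,
    peptide_profiles = resolve_sentinels(peptide_profiles),
    metabolite_profiles = resolve_sentinels(metabolite_profiles),
    triplets = triplets, alpha = alpha, p_method = p_method,
    counts = list(n_triplets = nrow(triplets),
                  n_peptide_profiles = length(peptide_profiles),
                  n_metabolite_profiles = length(metabolite_profiles),
                  n_tests = nrow(results),
                  n_significant = sum(results$significant))),
    class = "coloc")
}

#' @export
print.coloc <- function(x, n = 6L, ...) {
  cat(sprintf(
    "Enzyme-metabolite colocalization: %d triplets, %d tests, %d significant (BH <= %g)\n",
    x$counts$n_triplets, x$counts$n_tests, x$counts$n_significant, x$alpha))
  if (nrow(x$results)) {
    cat("Top associations:\n")
    print(utils::head(as.data.frame(x$results)[,
      c("peptide", "ko", "compound", "role", "r", "n_pairs", "p", "p_adj")],
      n), digits = 4)
  }
  invisible(x)
}

#' @export
summary.coloc <- function(object, ...) {
  res <- object$results
  out <- list(counts = object$counts, alpha = object$alpha,
              p_method = object$p_method,
              by_role = if (nrow(res)) table(res$role, res$significant)
                        else NULL,
              r_range = if (nrow(res)) range(res$r) else NULL)
  class(out) <- "summary.coloc"
  out
}

#' @export
print.summary.coloc <- function(x, ...) {
  cat("Colocalization summary\n")
  cat(sprintf("  tests: %d (alpha = %g, p_method = %s)\n",
              x$counts$n_tests, x$alpha, x$p_method))
  cat(sprintf("  significant: %d\n", x$counts$n_significant))
  if (!is.null(x$r_range))
    cat(sprintf("  correlation range: [%.3f, %.3f]\n",
                x$r_range[1], x$r_range[2]))
  if (!is.null(x$by_role)) { cat("  by role:\n"); print(x$by_role) }
  invisible(x)
}

#' @export
as.data.frame.coloc <- function(x, ...) as.data.frame(x$results)

#' @export
plot.coloc <- function(x, which = 1L, ...) {
  if (!nrow(x$results)) stop2("nothing to plot: no tests emitted")
  row <- x$results[which, ]
  a <- x$peptide_profiles[[row$peptide]]
  b <- x$metabolite_profiles[[row$compound]]
  idx <- which(!is.na(a$log2fc) & !is.na(b$log2fc))
  graphics::plot(b$log2fc[idx], a$log2fc[idx],
                 xlab = sprintf("%s log2 FC", row$compound),
                 ylab = sprintf("%s log2 FC", row$peptide),
                 main = sprintf("%s vs %s (%s): r = %.3f, p_adj = %.2g",
                                row$peptide, row$compound, row$role,
                                row$r, row$p_adj), ...)
  graphics::text(b$log2fc[idx], a$log2fc[idx], a$pairs[idx], pos = 3,
                 cex = 0.7)
  graphics::abline(stats::lm(a$log2fc[idx] ~ b$log2fc[idx]), lty = 2)
  invisible(x)
}

#' Table-style O/X detection matrix
#'
#' One row per enzyme cluster detected in at least one ROI; cells are `"O"`
#' (detected: backed by the presence rule) or `"X"` (absent or below
#' detection limits); column headers carry the replicate counts.
#'
#' @param clusters data.frame `cluster`, `ko`, `name`, `taxonomy`.
#' @param presence logical matrix (cluster x ROI) from
#'   [detect_presence()] at cluster level.
#' @param rois an [roi_set()].
#' @return data.frame of class `detection_matrix`.
#' @export
build_detection_matrix <- function(clusters, presence, rois) {
  keep <- rownames(presence)[rowSums(presence) > 0]
  keep <- intersect(clusters$cluster, keep)
  cells <- ifelse(presence[keep, , drop = FALSE], "O", "X")
  colnames(cells) <- sprintf("%s (n = %d)", rois$labels,
                             vapply(rois$replicates, length, 1L))
  meta <- clusters[match(keep, clusters$cluster),
                   c("cluster", "ko", "name", "taxonomy"), drop = FALSE]
  out <- cbind(meta, as.data.frame(cells, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("detection_matrix", "data.frame")
  out
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat("Enzyme detection matrix (O = detected, X = absent or below detection limits)\n")
  print(as.data.frame(x), right = FALSE)
  invisible(x)
}

#' Write / read a detection matrix TSV (lossless round trip)
#'
#' @param dm a `detection_matrix`.
#' @param path TSV path.
#' @return `path` invisibly; `read_detection_tsv` returns the matrix.
#' @export
write_detection_tsv <- function(dm, path) {
  utils::write.table(as.data.frame(dm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_detection_tsv
#' @export
read_detection_tsv <- function(path) {
  out <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  class(out) <- c("detection_matrix", "data.frame")
  out
}

#' Default end-to-end configuration
#'
#' The default synthetic study conditions: 4 disc ROIs on a 100x100 grid at
#' 50-um pitch with section replicates 3/3/6/3, lognormal noise sd 0.1,
#' missingness 0.1, PSM FDR 5%, annotation FDR 20%, 3-ppm matching, alpha
#' 0.05.
#'
#' @param seed global seed.
#' @param out_dir output directory.
#' @return Named list of configuration values.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("coloc_run_")) {
  list(seed = seed, out_dir = out_dir,
       grid = c(width = 100L, height = 100L),
       noise_sd = 0.1, missing_rate = 0.1, missing_mode = "mcar",
       n_target_psms = 1500L, n_decoy_psms = 1500L, score_sep = 4,
       psm_fdr_max = 0.05, annotation_fdr_max = 0.2, tol_ppm = 3,
       alpha = 0.05, alpha_g = 0.05, p_method = "roi",
       triplet_mode = "either", n_distractor_kos = 5L,
       normalization = "median", write_imzml = TRUE)
}

#' Write a configuration as YAML
#'
#' @param config configuration list.
#' @param path YAML output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

require_keys <- function(config, keys) {
  for (k in keys)
    if (is.null(config[[k]])) stop2("config missing key: ", k)
}

#' Run the full synthetic-to-report pipeline
#'
#' Generates (or loads) the inputs, applies every stage -- PSM threshold
#' optimization and filtering, peptide/cluster qualification, presence
#' calls, consensus taxonomy and function, MS1 annotation with decoy-adduct
#' FDR, reaction-graph triplet enumeration, and the colocalization
#' statistic -- and writes matrices, correlation tables and a JSON manifest
#' with the counts at every filter stage. Deterministic given the config
#' seed.
#'
#' @param config a configuration list (see [default_config()]) or the path
#'   to a YAML file of the same shape.
#' @return Invisibly, a list with the `coloc` object, the detection matrix,
#'   stage products and the manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop2("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  require_keys(config, c("seed", "out_dir"))
  config <- utils::modifyList(default_config(config$seed), config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stage <- function(name) message("[coloc] stage: ", name)

  stage("simulate")
  layout <- generate_roi_layout(config$grid[["width"]],
                                config$grid[["height"]], seed = seed)
  met_specs <- config$metabolite_specs %||% default_metabolite_specs()
  clu_specs <- config$cluster_specs %||% default_cluster_specs()
  planted <- config$planted_triplets %||% default_planted_triplets()
  ion <- generate_ion_images(layout, met_specs, config$noise_sd, seed)
  dataset <- images_to_dataset(ion$images, layout)
  if (isTRUE(config$write_imzml)) {
    write_imzml(dataset, file.path(config$out_dir, "synthetic.imzML"))
    dataset <- read_imzml(file.path(config$out_dir, "synthetic.imzML"))
  }
  pep <- generate_peptide_table(layout, clu_specs, config$missing_rate,
                                config$noise_sd, config$missing_mode, seed)
  obs <- pep$observations
  psms <- generate_psm_table(config$n_target_psms, config$n_decoy_psms,
                             config$score_sep, seed,
                             peptides = unique(obs$peptide))
  distractors <- config$distractor_triplets %||% default_distractor_triplets()
  graph <- generate_reaction_graph(rbind(planted, distractors),
                                   config$n_distractor_kos, seed)
  write_roi_tsv(layout, file.path(config$out_dir, "rois.tsv"))

  stage("proteome")
  thresholds <- optimize_thresholds(psms, config$psm_fdr_max)
  accepted <- filter_psms(psms, thresholds)
  qualified <- qualify_peptides(accepted)
  pep_cluster <- unique(obs[, c("peptide", "cluster")])
  qualified <- intersect(qualified, pep_cluster$peptide)
  clusters_id <- rollup_clusters(qualified, pep_cluster)
  obs_q <- obs[obs$peptide %in% qualified &
                 obs$cluster %in% clusters_id, , drop = FALSE]
  obs_q <- normalize_intensities(obs_q, config$normalization)
  presence <- detect_presence(obs_q, layout, level = "cluster")

  stage("taxonomy")
  queries <- do.call(rbind, lapply(clu_specs, function(s)
    data.frame(query = s$cluster, lineage = s$lineage, ko = s$ko,
               name = s$name, stringsAsFactors = FALSE)))
  hits <- generate_hit_table(queries, seed = seed)
  tax <- list(); ko_map <- character()
  for (cl in clusters_id) {
    h <- hits[hits$query == cl, , drop = FALSE]
    prot <- protein_consensus(h)
    contig <- taxon_assignment(cl,
      parse_lineage(queries$lineage[queries$query == cl]), "contig",
      "classified")
    tax[[cl]] <- method_crosscheck(prot, contig)
    ko_map[cl] <- functional_consensus(h)
  }
  detected_kos <- unique(ko_map[!is.na(ko_map)])

  stage("annotate")
  formula_db <- do.call(rbind, lapply(met_specs, function(s)
    data.frame(compound = s$compound, formula = s$formula,
               preferred_adduct = s$adduct, stringsAsFactors = FALSE)))
  ann <- annotate_images(dataset, formula_db, adduct_rules(),
                         config$tol_ppm, config$annotation_fdr_max)
  # isomer disambiguation: keep each compound's image under its preferred
  # adduct (ionization-specificity knowledge, an input)
  pref <- stats::setNames(formula_db$preferred_adduct, formula_db$compound)
  ann_pref <- Filter(function(im)
    identical(im$annotation$adduct, pref[[im$annotation$compound]]), ann)
  write_annotations_tsv(ann, file.path(config$out_dir, "annotations.tsv"))
  annotated_cpds <- unique(vapply(ann_pref,
                                  function(im) im$annotation$compound, ""))

  stage("integrate")
  met_profiles <- lapply(ann_pref, metabolite_fc_profile, rois = layout)
  names(met_profiles) <- vapply(ann_pref,
                                function(im) im$annotation$compound, "")
  met_profiles <- met_profiles[!duplicated(names(met_profiles))]
  pep_profiles <- peptide_fc_profiles(obs_q, layout, config$alpha_g)
  for (i in seq_along(pep_profiles)) {
    cl <- pep_profiles[[i]]$cluster
    pep_profiles[[i]]$ko <- if (!is.na(cl) && cl %in% names(ko_map))
      ko_map[[cl]] else NA_character_
  }
  triplets <- find_triplets(graph, detected_kos, annotated_cpds,
                            mode = config$triplet_mode)
  fit <- colocalize(pep_profiles, met_profiles, triplets,
                    alpha = config$alpha, p_method = config$p_method)

  stage("report")
  cluster_meta <- data.frame(
    cluster = clusters_id, ko = unname(ko_map[clusters_id]),
    name = queries$name[match(clusters_id, queries$query)],
    taxonomy = vapply(tax[clusters_id], function(a)
      format_lineage(a$lineage), ""),
    stringsAsFactors = FALSE)
  dm <- build_detection_matrix(cluster_meta, presence, layout)
  write_detection_tsv(dm, file.path(config$out_dir, "detection_matrix.tsv"))
  write_tsv(as.data.frame(fit$results),
            file.path(config$out_dir, "correlations.tsv"))
  manifest <- list(
    seed = seed,
    config = config[setdiff(names(config),
                            c("metabolite_specs", "cluster_specs",
                              "planted_triplets"))],
    thresholds = thresholds,
    counts = list(
      psms_in = nrow(psms), psms_accepted = nrow(accepted),
      peptides_qualified = length(qualified),
      clusters_identified = length(clusters_id),
      kos_detected = length(detected_kos),
      channels_annotated = length(ann),
      compounds_annotated = length(annotated_cpds),
      triplets_tested = nrow(triplets),
      tests_emitted = fit$counts$n_tests,
      tests_significant = fit$counts$n_significant,
      peptide_profiles_withheld = attr(pep_profiles, "n_withheld")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fit = fit, detection_matrix = dm, manifest = manifest,
                 layout = layout, truth = list(images = ion$truth,
                                               peptides = pep$truth,
                                               planted = planted),
                 observations = obs_q, psms = psms, graph = graph,
                 taxonomy = tax, thresholds = thresholds))
}

#' Simulate independent (null) peptide-metabolite pairs
#'
#' Draws unrelated random per-ROI mean profiles for a metabolite image and a
#' peptide, pushes both through the package's own profile machinery and
#' correlation test, and returns the per-pair statistics. Used to check
#' type-I error calibration.
#'
#' @param n number of null pairs.
#' @param seed integer seed.
#' @param noise_sd lognormal noise sd (default 0.1).
#' @param p_method passed to [scaled_pearson()].
#' @return data.frame with columns `r`, `p`.
#' @export
simulate_null_pairs <- function(n = 300L, seed = 1L, noise_sd = 0.1,
                                p_method = "roi") {
  layout <- generate_roi_layout(48, 48, list(
    list(label = "LM1", cx = 12, cy = 12, r = 5, n_replicates = 3L),
    list(label = "LM2", cx = 35, cy = 13, r = 5, n_replicates = 3L),
    list(label = "LM3", cx = 14, cy = 35, r = 6, n_replicates = 6L),
    list(label = "PMM", cx = 36, cy = 34, r = 5, n_replicates = 3L)))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- subseed(seed, paste0("null_pair_", i))
    means <- with_seed(s, list(met = exp(stats::rnorm(4, log(100), 1)),
                               pep = exp(stats::rnorm(4, log(100), 1))))
    spec <- list(list(compound = "C99999", name = "null",
                      formula = "C9H10O4", adduct = "[M-H]-",
                      roi_means = stats::setNames(means$met,
                                                  layout$labels)))
    img <- generate_ion_images(layout, spec, noise_sd, s)$images[[1]]
    mp <- metabolite_fc_profile(img, layout)
    cl <- list(list(cluster = "CLNULL", ko = "K99999", lineage = "x",
                    n_peptides = 1L,
                    roi_means = stats::setNames(means$pep, layout$labels)))
    obs <- generate_peptide_table(layout, cl, missing_rate = 0,
                                  noise_sd = noise_sd, seed = s)$observations
    pp <- peptide_fc_profile(obs, layout, unique(obs$peptide))
    res <- scaled_pearson(pp, mp, p_method = p_method)
    out[[i]] <- data.frame(r = res$r, p = res$p)
  }
  do.call(rbind, out)
}
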