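# Small in-code fixtures shared across test files.

tiny_layout <- function() {
  generate_roi_layout(40, 40, list(
    list(label = "LM1", cx = 10, cy = 10, r = 4, n_replicates = 3L),
    list(label = "LM2", cx = 30, cy = 10, r = 4, n_replicates = 3L),
    list(label = "LM3", cx = 10, cy = 30, r = 5, n_replicates = 6L),
    list(label = "PMM", cx = 30, cy = 30, r = 4, n_replicates = 3L)))
}

# observation table with explicit per-(roi, replicate) presence
obs_row <- function(peptide, cluster, roi, rep, intensity) {
  data.frame(peptide = peptide, cluster = cluster, roi = roi,
             replicate = rep, intensity = intensity,
             psm_count = if (is.na(intensity)) 0L else 2L,
             stringsAsFactors = FALSE)
}

# peptide observed with given intensities across an ROI's replicates
obs_roi <- function(peptide, cluster, roi, intensities, reps = NULL) {
  if (is.null(reps)) reps <- paste0("R", seq_along(intensities))
  do.call(rbind, Map(function(r, v) obs_row(peptide, cluster, roi, r, v),
                     reps, intensities))
}

tiny_graph <- function() {
  reaction_graph(
    ko2rxn = data.frame(ko = c("K18334", "K18334", "K00844"),
                        reaction = c("R03688", "R99901", "R01786")),
    rxn2cpd = data.frame(
      reaction = c("R03688", "R03688", "R99901", "R99901",
                   "R01786", "R01786"),
      compound = c("C01720", "C99001", "C99002", "C99003",
                   "C00031", "C00092"),
      side = c("substrate", "product", "substrate", "product",
               "substrate", "product")),
    compounds = data.frame(
      compound = c("C01720", "C99001", "C99002", "C99003", "C00031",
                   "C00092"),
      name = c("L-fuconate", "2-dehydro-3-deoxy-L-fuconate", "x1", "x2",
               "D-glucose", "D-glucose 6-phosphate"),
      formula = c("C6H12O6", "C6H10O5", "C5H8O4", "C5H6O3", "C6H12O6",
                  "C6H13O9P")),
    rxn2path = data.frame(reaction = c("R03688", "R01786"),
                          pathway = c("map00051", "map00010")))
}
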