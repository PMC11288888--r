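# Lineages are ordered rank vectors root -> leaf ("superkingdom ... species"
# scaffold, higher ranks allowed). String form is semicolon-separated.
# Unknown intermediate ranks (empty or NA) act as wildcards matching nothing,
# which prevents false agreement between sparsely annotated hits.

#' Parse / format semicolon-separated lineages
#'
#' @param x lineage string, e.g. `"Eukaryota;Fungi;Agaricaceae;Leucoagaricus"`.
#' @return Character vector of ranks (`parse_lineage`); a string
#'   (`format_lineage`).
#' @export
parse_lineage <- function(x) {
  if (length(x) == 1L && (is.na(x) || !nzchar(x))) return(character())
  out <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  out[!nzchar(out)] <- NA_character_
  out
}

#' @rdname parse_lineage
#' @param ranks character vector of ranks.
#' @export
format_lineage <- function(ranks) paste(ranks, collapse = ";")

#' Lowest common ancestor of lineages
#'
#' Longest shared prefix of ranks; comparison stops at the first rank where
#' any two lineages differ or any lineage is exhausted or unknown.
#'
#' @param lineages list of rank vectors (strings accepted and parsed).
#' @return Rank vector (possibly empty = root).
#' @export
#' @examples
#' lca(list("Eukaryota;Fungi;Agaricaceae;Leucoagaricus",
#'          "Eukaryota;Fungi;Agaricaceae;Agaricus"))
lca <- function(lineages) {
  if (!length(lineages)) stop2("lca of an empty lineage set")
  lin <- lapply(lineages, function(x)
    if (is.character(x) && length(x) == 1L) parse_lineage(x) else x)
  depth <- min(vapply(lin, length, 1L))
  out <- character()
  for (d in seq_len(depth)) {
    ranks <- vapply(lin, `[`, "", d)
    if (anyNA(ranks) || length(unique(ranks)) != 1L) break
    out <- c(out, ranks[1])
  }
  out
}

filter_hits <- function(hits, max_hits = 10L, min_bit = 50, max_e = 1e-5) {
  hits <- hits[order(-hits$bit_score), , drop = FALSE]
  hits <- utils::head(hits, max_hits)
  hits[hits$bit_score > min_bit & hits$e_value < max_e, , drop = FALSE]
}

lineages_equal <- function(lin) {
  keys <- vapply(lin, format_lineage, "")
  length(unique(keys)) == 1L && !anyNA(lin[[1]])
}

#' Consensus taxonomic assignment from a protein hit table
#'
#' Keeps the top `max_hits` hits by bit score, drops hits with bit score at
#' or below 50 or e-value at or above 1e-5, and considers the set sharing the
#' maximum remaining bit score: if they agree exactly on a lineage that
#' lineage is assigned, otherwise their lowest common ancestor. No surviving
#' hits leaves the query unclassified.
#'
#' @param hits data.frame with columns `query`, `lineage` (semicolon string),
#'   `bit_score`, `e_value` (optionally `ko`).
#' @param max_hits,min_bit,max_e filter parameters.
#' @return List (`taxon_assignment`): `query`, `lineage` (rank vector),
#'   `method`, `status`.
#' @export
protein_consensus <- function(hits, max_hits = 10L, min_bit = 50,
                              max_e = 1e-5) {
  query <- if (nrow(hits)) hits$query[1] else NA_character_
  surv <- filter_hits(hits, max_hits, min_bit, max_e)
  if (!nrow(surv))
    return(taxon_assignment(query, character(), "protein-lca",
                            "unclassified"))
  top <- surv[surv$bit_score == max(surv$bit_score), , drop = FALSE]
  lin <- lapply(top$lineage, parse_lineage)
  assigned <- if (lineages_equal(lin)) lin[[1]] else lca(lin)
  taxon_assignment(query, assigned, "protein-lca",
                   if (length(assigned)) "classified" else "unclassified")
}

#' @rdname protein_consensus
#' @param lineage rank vector.
#' @param method provenance label.
#' @param status `"classified"` or `"unclassified"`.
#' @export
taxon_assignment <- function(query, lineage, method, status) {
  structure(list(query = query, lineage = lineage, method = method,
                 status = status), class = "taxon_assignment")
}

#' @export
print.taxon_assignment <- function(x, ...) {
  cat(sprintf("%s [%s]: %s\n", x$query, x$method,
              if (x$status == "classified") format_lineage(x$lineage)
              else "unclassified"))
  invisible(x)
}

#' Consensus functional (KEGG Orthology) assignment
#'
#' Same hit filtering as [protein_consensus()]; the KO that all maximum-bit
#' score hits agree on is assigned, otherwise the query remains unclassified.
#'
#' @inheritParams protein_consensus
#' @return KO id string, or `NA_character_` (unclassified).
#' @export
functional_consensus <- function(hits, max_hits = 10L, min_bit = 50,
                                 max_e = 1e-5) {
  surv <- filter_hits(hits, max_hits, min_bit, max_e)
  if (!nrow(surv)) return(NA_character_)
  top <- surv[surv$bit_score == max(surv$bit_score), , drop = FALSE]
  kos <- unique(top$ko)
  if (length(kos) == 1L && !is.na(kos)) kos else NA_character_
}

#' Cross-check taxonomic assignments from independent methods
#'
#' Conservative consensus of the workflow, protein-LCA and contig
#' assignments: the lowest common ancestor of all classified inputs, with
#' provenance recording the contributing methods.
#'
#' @param ... `taxon_assignment` objects (or a single list of them).
#' @return A `taxon_assignment` with method `"crosscheck"`; unclassified if
#'   every input is.
#' @export
method_crosscheck <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1L && !inherits(inputs[[1]], "taxon_assignment"))
    inputs <- inputs[[1]]
  classified <- Filter(function(a) a$status == "classified", inputs)
  query <- inputs[[1]]$query
  if (!length(classified))
    return(taxon_assignment(query, character(), "crosscheck", "unclassified"))
  consensus <- lca(lapply(classified, `[[`, "lineage"))
  out <- taxon_assignment(query, consensus, "crosscheck",
                          if (length(consensus)) "classified"
                          else "unclassified")
  out$provenance <- vapply(classified, `[[`, "", "method")
  out
}
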