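# Local KEGG-style reaction graph: KO -> reaction -> {substrates, products}
# edges with compound and pathway metadata. Kept hermetic (a file, never a
# live API) so analyses are reproducible.

#' Construct a validated reaction graph
#'
#' @param ko2rxn data.frame `ko`, `reaction`.
#' @param rxn2cpd data.frame `reaction`, `compound`, `side` (`"substrate"` or
#'   `"product"`).
#' @param compounds data.frame `compound`, `name`, `formula`.
#' @param rxn2path data.frame `reaction`, `pathway` (may be empty).
#' @return Object of class `reaction_graph`.
#' @export
reaction_graph <- function(ko2rxn, rxn2cpd, compounds,
                           rxn2path = data.frame(reaction = character(),
                                                 pathway = character())) {
  stopifnot(all(c("ko", "reaction") %in% names(ko2rxn)),
            all(c("reaction", "compound", "side") %in% names(rxn2cpd)),
            all(c("compound", "name", "formula") %in% names(compounds)))
  if (!all(rxn2cpd$side %in% c("substrate", "product")))
    stop2("rxn2cpd side must be 'substrate' or 'product'")
  dangling <- setdiff(rxn2cpd$compound, compounds$compound)
  if (length(dangling))
    stop2("dangling compound reference(s): ",
          paste(dangling, collapse = ", "))
  dangling_r <- setdiff(ko2rxn$reaction, rxn2cpd$reaction)
  if (length(dangling_r))
    stop2("reaction(s) without compound edges: ",
          paste(dangling_r, collapse = ", "))
  for (r in unique(rxn2cpd$reaction)) {
    sides <- rxn2cpd$side[rxn2cpd$reaction == r]
    if (!("substrate" %in% sides) || !("product" %in% sides))
      stop2("reaction ", r, " needs at least one substrate and one product")
  }
  structure(list(ko2rxn = ko2rxn, rxn2cpd = rxn2cpd, compounds = compounds,
                 rxn2path = rxn2path),
            class = "reaction_graph")
}

#' @export
print.reaction_graph <- function(x, ...) {
  cat("reaction graph:", length(unique(x$ko2rxn$ko)), "KOs,",
      length(unique(x$rxn2cpd$reaction)), "reactions,",
      nrow(x$compounds), "compounds,",
      length(unique(x$rxn2path$pathway)), "pathways\n")
  invisible(x)
}

#' Write / load a reaction graph as JSON
#'
#' @param graph a `reaction_graph`.
#' @param path JSON file path.
#' @return `path` invisibly; `load_graph` returns the validated graph.
#' @export
write_graph <- function(graph, path) {
  jsonlite::write_json(unclass(graph), path, dataframe = "rows",
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_graph
#' @export
load_graph <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (part in c("ko2rxn", "rxn2cpd", "compounds"))
    if (is.null(x[[part]]) || !nrow(as.data.frame(x[[part]])))
      stop2("graph file lacks ", part)
  rxn2path <- if (!is.null(x$rxn2path) && length(x$rxn2path))
    as.data.frame(x$rxn2path) else
    data.frame(reaction = character(), pathway = character())
  reaction_graph(as.data.frame(x$ko2rxn), as.data.frame(x$rxn2cpd),
                 as.data.frame(x$compounds), rxn2path)
}

#' Compounds reachable from a KEGG Orthology id
#'
#' Union over the KO's reactions, substrate and product sides preserved.
#'
#' @param graph a `reaction_graph`.
#' @param ko KO id present in the graph.
#' @return List `substrates`, `products` (character vectors).
#' @export
ko_to_compounds <- function(graph, ko) {
  rxns <- graph$ko2rxn$reaction[graph$ko2rxn$ko == ko]
  if (!length(rxns)) stop2("unknown KO: ", ko)
  edges <- graph$rxn2cpd[graph$rxn2cpd$reaction %in% rxns, , drop = FALSE]
  list(substrates = sort(unique(edges$compound[edges$side == "substrate"])),
       products = sort(unique(edges$compound[edges$side == "product"])))
}

#' Enumerate substrate-enzyme-product triplets to test
#'
#' All (substrate, KO, product) combinations of each detected KO's reactions
#' whose compounds pass the annotation filter: `"either"` (default) requires
#' the substrate or the product among the annotated compounds (a product may
#' be observable when its substrate was consumed below detection);
#' `"both"` requires both. With `reversible = TRUE` each triplet is also
#' emitted in the reverse orientation.
#'
#' @param graph a `reaction_graph`.
#' @param detected_kos character vector of detected KO ids.
#' @param annotated_compounds character vector of annotated compound ids.
#' @param mode `"either"` or `"both"`.
#' @param reversible also emit reversed orientations (default FALSE).
#' @return data.frame `substrate`, `ko`, `product`, `reaction`, `pathways`
#'   (semicolon-collapsed).
#' @export
find_triplets <- function(graph, detected_kos, annotated_compounds,
                          mode = c("either", "both"), reversible = FALSE) {
  mode <- match.arg(mode)
  rows <- list()
  emit <- function(s, ko, p, rxn) {
    if (s == p) return()
    s_in <- s %in% annotated_compounds
    p_in <- p %in% annotated_compounds
    ok <- if (mode == "both") s_in && p_in else s_in || p_in
    if (!ok) return()
    paths <- graph$rxn2path$pathway[graph$rxn2path$reaction == rxn]
    rows[[length(rows) + 1L]] <<- data.frame(
      substrate = s, ko = ko, product = p, reaction = rxn,
      pathways = paste(sort(unique(paths)), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  for (ko in intersect(detected_kos, unique(graph$ko2rxn$ko))) {
    for (rxn in graph$ko2rxn$reaction[graph$ko2rxn$ko == ko]) {
      edges <- graph$rxn2cpd[graph$rxn2cpd$reaction == rxn, , drop = FALSE]
      subs <- edges$compound[edges$side == "substrate"]
      prods <- edges$compound[edges$side == "product"]
      for (s in subs) for (p in prods) {
        emit(s, ko, p, rxn)
        if (reversible) emit(p, ko, s, rxn)
      }
    }
  }
  if (!length(rows))
    return(data.frame(substrate = character(), ko = character(),
                      product = character(), reaction = character(),
                      pathways = character()))
  unique(do.call(rbind, rows))
}
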