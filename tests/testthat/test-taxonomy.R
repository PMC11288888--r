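hit <- function(lineage, bit, e = 1e-30, ko = "K01576", query = "Q1") {
  data.frame(query = query, lineage = lineage, bit_score = bit, e_value = e,
             ko = ko, stringsAsFactors = FALSE)
}
fungi <- "Eukaryota;Fungi;Basidiomycota;Agaricales;Agaricaceae"

test_that("LCA is the longest shared rank prefix", {
  expect_equal(
    lca(list(paste0(fungi, ";Leucoagaricus"), paste0(fungi, ";Agaricus"))),
    strsplit(fungi, ";")[[1]])
  expect_equal(lca(list("A;B;C", "A;B;C")), c("A", "B", "C"))
  expect_equal(lca(list("A;B", "X;Y")), character())
  expect_error(lca(list()), "empty")
  # unknown intermediate ranks match nothing
  expect_equal(lca(list("A;;C", "A;;C")), "A")
})

test_that("LCA equals the position-wise scan oracle on random sets", {
  withr::with_seed(13, {
    for (i in 1:60) {
      lins <- random_lineages(sample(2:5, 1))
      expect_equal(lca(lins), oracle_lca(lins))
    }
  })
})

test_that("protein consensus assigns agreement, else the LCA, else nothing", {
  agree <- rbind(hit(paste0(fungi, ";Leucoagaricus"), 300),
                 hit(paste0(fungi, ";Leucoagaricus"), 300),
                 hit("Eukaryota;Fungi", 200))
  a <- protein_consensus(agree)
  expect_equal(a$status, "classified")
  expect_equal(utils::tail(a$lineage, 1), "Leucoagaricus")

  split <- rbind(hit(paste0(fungi, ";Leucoagaricus"), 300),
                 hit(paste0(fungi, ";Agaricus"), 300))
  b <- protein_consensus(split)
  expect_equal(utils::tail(b$lineage, 1), "Agaricaceae")

  weak <- rbind(hit(fungi, 40), hit(fungi, 35))
  expect_equal(protein_consensus(weak)$status, "unclassified")
  # e-value ceiling also empties the set
  late <- hit(fungi, 300, e = 1e-4)
  expect_equal(protein_consensus(late)$status, "unclassified")
})

test_that("consensus is invariant to hit order and capped at ten hits", {
  hits <- rbind(hit(paste0(fungi, ";Leucoagaricus"), 300),
                hit(paste0(fungi, ";Agaricus"), 280),
                hit("Eukaryota;Fungi", 100),
                hit("Bacteria;Pseudomonadota", 90))
  a <- protein_consensus(hits)
  b <- protein_consensus(hits[sample(nrow(hits)), ])
  expect_equal(a$lineage, b$lineage)
  # an 11th top-scoring conflicting hit outside the cap cannot influence
  many <- do.call(rbind, c(
    replicate(10, hit(paste0(fungi, ";Leucoagaricus"), 300,
                      e = 1e-40), simplify = FALSE),
    list(hit("Bacteria;Pseudomonadota", 299))))
  expect_equal(utils::tail(protein_consensus(many)$lineage, 1),
               "Leucoagaricus")
})

test_that("raising the bit-score floor only coarsens assignments", {
  withr::with_seed(17, {
    for (i in 1:20) {
      lins <- vapply(random_lineages(5), paste, "", collapse = ";")
      hits <- do.call(rbind, lapply(lins, function(l)
        hit(l, round(runif(1, 30, 300)))))
      lo <- protein_consensus(hits, min_bit = 50)
      hi <- protein_consensus(hits, min_bit = 150)
      if (hi$status == "classified") {
        expect_true(lo$status == "classified")
        expect_lte(length(hi$lineage), max(length(lo$lineage),
                                           length(hi$lineage)))
      }
    }
  })
})

test_that("functional consensus requires unanimity of the top hits", {
  expect_equal(functional_consensus(rbind(hit(fungi, 300, ko = "K01576"),
                                          hit(fungi, 300, ko = "K01576"))),
               "K01576")
  expect_true(is.na(functional_consensus(
    rbind(hit(fungi, 300, ko = "K01576"), hit(fungi, 300, ko = "K01061")))))
  expect_true(is.na(functional_consensus(hit(fungi, 40, ko = "K01576"))))
})

test_that("method cross-check takes the LCA of classified assignments", {
  w <- taxon_assignment("Q1", strsplit(paste0(fungi, ";Leucoagaricus"),
                                       ";")[[1]], "workflow", "classified")
  p <- taxon_assignment("Q1", c("Eukaryota", "Fungi"), "protein-lca",
                        "classified")
  u <- taxon_assignment("Q1", character(), "contig", "unclassified")
  x <- method_crosscheck(w, p, u)
  expect_equal(x$lineage, c("Eukaryota", "Fungi"))
  expect_setequal(x$provenance, c("workflow", "protein-lca"))
  expect_equal(method_crosscheck(u, u, u)$status, "unclassified")
  same <- method_crosscheck(w, w, w)
  expect_equal(same$lineage, w$lineage)
  # random triples agree with the lca oracle over the classified subset
  withr::with_seed(29, {
    for (i in 1:20) {
      lins <- random_lineages(3)
      asn <- lapply(lins, function(l)
        taxon_assignment("Q", l, "workflow", "classified"))
      expect_equal(method_crosscheck(asn)$lineage, oracle_lca(lins))
    }
  })
})
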