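#' Hypergeometric category enrichment with BH correction
#'
#' One-sided hypergeometric (over-representation) test per category, with
#' Benjamini-Hochberg adjustment across categories. Significance is flagged
#' at an adjusted p of 0.05, the q-equivalent of a `-log10(p) >= 1.3`
#' display cutoff.
#'
#' @param hit_genes Character vector of hit gene ids; must be a subset of
#'   `universe`.
#' @param category_map A `data.frame` with columns `gene` and `category`
#'   (one row per membership; genes may belong to several categories).
#' @param universe Character vector of all testable gene ids.
#' @return A `data.frame` per category: `category`, `n_category`
#'   (category size within the universe), `n_hit` (hits in the category),
#'   `p`, `padj`, `significant`; ordered by `p`.
#' @export
enrichment_test <- function(hit_genes, category_map, universe) {
  universe <- unique(universe)
  assert_that(length(universe) > 0, "empty universe")
  hit_genes <- unique(hit_genes)
  assert_that(all(hit_genes %in% universe),
              "hit genes must be a subset of the universe")
  assert_that(all(c("gene", "category") %in% names(category_map)),
              "category_map needs columns gene, category")
  cm <- category_map[category_map$gene %in% universe, , drop = FALSE]
  cats <- sort(unique(cm$category))
  n_u <- length(universe); n_h <- length(hit_genes)
  res <- do.call(rbind, lapply(cats, function(cc) {
    members <- unique(cm$gene[cm$category == cc])
    m <- length(members)
    q <- length(intersect(members, hit_genes))
    # P(X >= q) for X ~ Hypergeometric(m, n_u - m, n_h)
    p <- stats::phyper(q - 1, m, n_u - m, n_h, lower.tail = FALSE)
    data.frame(category = cc, n_category = m, n_hit = q, p = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res)) {
    return(data.frame(category = character(), n_category = integer(),
                      n_hit = integer(), p = numeric(), padj = numeric(),
                      significant = logical()))
  }
  res$padj <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$padj <= 0.05
  res[order(res$p, res$category), , drop = FALSE]
}
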