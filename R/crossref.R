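#' Intersect co-expression and interaction rankings
#'
#' Computes the genes ranked high in both evidence streams -- a top
#' co-expression table and a top interactor table -- and partitions them
#' into query and non-query members. Convergence of the two independent
#' streams on non-query genes is the screen's strongest nomination signal.
#'
#' @param coexpr Ranked co-expression table (data frame with a \code{gene}
#'   or \code{gene_symbol} column) or character vector.
#' @param ppi Ranked interactor table or character vector.
#' @param queries Query group ([gene_set] or character).
#' @return Object of class \code{cross_evidence}: list with
#'   \code{top_n_coexpr}, \code{top_n_ppi}, \code{common},
#'   \code{common_queries}, \code{common_nonqueries} (the latter three are
#'   [gene_set]s; \code{common} is the disjoint union of the other two).
#' @export
intersect_rankings <- function(coexpr, ppi, queries) {
  a <- ranking_genes(coexpr)
  b <- ranking_genes(ppi)
  if (anyDuplicated(a) || anyDuplicated(b)) {
    stop("ranked tables must carry unique gene symbols")
  }
  queries <- as_symbols(queries)
  common <- intersect(a, b)
  in_q <- common %in% queries
  message(length(common), " gene(s) ranked high in both lists (",
          sum(in_q), " queries, ", sum(!in_q), " non-queries)")
  structure(list(top_n_coexpr = length(a), top_n_ppi = length(b),
                 common = gene_set(common, "common"),
                 common_queries = gene_set(common[in_q], "common_queries"),
                 common_nonqueries = gene_set(common[!in_q],
                                              "common_nonqueries")),
            class = "cross_evidence")
}

#' @export
print.cross_evidence <- function(x, ...) {
  cat("<cross_evidence> ", length(x$common), " common gene(s) from top ",
      x$top_n_coexpr, " co-expression x top ", x$top_n_ppi, " interactors\n",
      "  queries:     ", paste(x$common_queries$genes, collapse = ", "), "\n",
      "  non-queries: ", paste(x$common_nonqueries$genes, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

ranking_genes <- function(x) {
  if (is.character(x)) return(normalize_symbol(x))
  if (inherits(x, "gene_set")) return(x$genes)
  gene_col <- intersect(c("gene", "gene_symbol"), names(x))[1L]
  if (is.na(gene_col)) stop("ranked table needs a 'gene' or 'gene_symbol' column")
  normalize_symbol(x[[gene_col]])
}

#' Shortlist cross-evidence candidates
#'
#' Orders the non-query genes supported by both evidence streams by the sum
#' of their two within-list rank positions (ascending; ties alphabetical),
#' giving the final candidate shortlist for experimental follow-up.
#'
#' @param report A \code{cross_evidence} report.
#' @param coexpr_ranking Ranked co-expression table with \code{rank} (or
#'   \code{ranking}) and gene columns covering the report's non-query genes.
#' @param ppi_ranking Ranked interactor table, same requirements.
#' @return Data frame with columns \code{gene}, \code{coexpr_rank},
#'   \code{ppi_rank}, \code{rank_sum}, sorted by \code{rank_sum}.
#' @export
candidate_shortlist <- function(report, coexpr_ranking, ppi_ranking) {
  stopifnot(inherits(report, "cross_evidence"))
  genes <- report$common_nonqueries$genes
  if (!length(genes)) {
    return(data.frame(gene = character(), coexpr_rank = integer(),
                      ppi_rank = integer(), rank_sum = integer(),
                      stringsAsFactors = FALSE))
  }
  r1 <- ranking_positions(coexpr_ranking, genes, "co-expression")
  r2 <- ranking_positions(ppi_ranking, genes, "interactor")
  out <- data.frame(gene = genes, coexpr_rank = r1, ppi_rank = r2,
                    rank_sum = r1 + r2, stringsAsFactors = FALSE)
  out <- out[order(out$rank_sum, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

ranking_positions <- function(ranking, genes, label) {
  syms <- ranking_genes(ranking)
  rank_col <- if (is.data.frame(ranking)) {
    intersect(c("rank", "ranking"), names(ranking))[1L]
  } else NA
  pos <- if (is.data.frame(ranking) && !is.na(rank_col)) {
    ranking[[rank_col]][match(genes, syms)]
  } else {
    match(genes, syms)
  }
  if (any(is.na(pos))) {
    stop("gene(s) missing a ", label, " score: ",
         paste(genes[is.na(pos)], collapse = ", "))
  }
  as.integer(pos)
}
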