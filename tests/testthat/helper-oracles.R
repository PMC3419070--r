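# Fixture builders and independent brute-force oracles used across tests.

make_ds <- function(mat, id = "d1", genes = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(mat)))
  rownames(mat) <- genes
  colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  expression_dataset(mat, id)
}

rand_ds <- function(n_genes, n_samples, id = "d1", seed = 1) {
  set.seed(seed)
  make_ds(matrix(rnorm(n_genes * n_samples), n_genes, n_samples), id)
}

# exhaustive pairwise-Pearson neighbour oracle: straight loop, no reuse of
# package internals
oracle_neighbors <- function(ds, query, k) {
  genes <- rownames(ds$values)
  pool <- setdiff(genes, query)
  sims <- vapply(pool, function(g)
    cor(ds$values[query, ], ds$values[g, ]), numeric(1))
  ord <- order(-sims, pool)
  data.frame(gene = pool[ord], similarity = unname(sims[ord]),
             stringsAsFactors = FALSE)[seq_len(min(k, length(pool))), ]
}

# edge-by-edge degree oracle
oracle_profile <- function(edges, queries, node) {
  inc <- edges[edges[, 1] == node | edges[, 2] == node, , drop = FALSE]
  other <- ifelse(inc[, 1] == node, inc[, 2], inc[, 1])
  list(k_global = length(other), k_query = sum(other %in% queries))
}

# neighbourhood-enumeration oracle for sub-network extraction
oracle_subnet_nodes <- function(edges, nodes, queries) {
  present <- intersect(queries, nodes)
  nbrs <- character()
  for (q in present) {
    inc <- edges[edges[, 1] == q | edges[, 2] == q, , drop = FALSE]
    nbrs <- c(nbrs, ifelse(inc[, 1] == q, inc[, 2], inc[, 1]))
  }
  sort(union(present, nbrs))
}

# assemble a neighbor_list object directly (for pooling tests)
fake_list <- function(genes, query = "Q", dataset_id = "d1") {
  out <- data.frame(gene = genes, similarity = seq(1, 0.5, length.out = length(genes)),
                    rank = seq_along(genes), stringsAsFactors = FALSE)
  attr(out, "dataset_id") <- dataset_id
  attr(out, "query") <- query
  class(out) <- c("neighbor_list", "data.frame")
  out
}

# small deterministic graph builders
graph_from_pairs <- function(...) {
  ppi_network(matrix(c(...), ncol = 2, byrow = TRUE))
}

edge_file <- function(lines) {
  p <- tempfile(fileext = ".tsv")
  writeLines(lines, p)
  p
}
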