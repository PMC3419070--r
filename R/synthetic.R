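#' Simulate a multi-dataset expression ensemble with a planted module
#'
#' Generates \code{n_datasets} independent genes-by-samples matrices in
#' which one gene module is transcriptionally co-regulated: module genes
#' follow a one-factor model, \code{value = beta * latent +
#' sqrt(1 - beta^2) * noise}, with an independent standard-normal latent
#' draw per sample and per dataset (independent chips measuring the same
#' biology), while background genes are pure noise. Expected pairwise
#' correlation between module genes is \code{beta^2}; between any other
#' pair it is 0. A subset of the module is designated as the query group,
#' so recovery of the remaining module genes can be scored against truth.
#'
#' @param n_genes Total genes (default 300).
#' @param n_samples Samples per dataset (default 30; must be >= 4).
#' @param n_datasets Number of datasets (default 3).
#' @param module_size Planted module size (default 64; must be < n_genes).
#' @param n_queries Query genes taken from the module (default 24).
#' @param beta Module co-regulation strength in [0, 1] (default 0.9).
#' @param noise_sd Standard deviation of latent and noise draws (default 1;
#'   rescales values without changing correlations).
#' @param seed Optional integer seed; identical seed and parameters give
#'   byte-identical output.
#' @return List with \code{datasets} (list of [expression_dataset]) and
#'   \code{truth} (a \code{synthetic_truth}).
#' @export
simulate_expression_ensemble <- function(n_genes = 300L, n_samples = 30L,
                                         n_datasets = 3L, module_size = 64L,
                                         n_queries = 24L, beta = 0.9,
                                         noise_sd = 1, seed = NULL) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  if (module_size >= n_genes) stop("module_size must be < n_genes")
  if (n_samples < 4L) stop("n_samples must be >= 4")
  if (n_queries > module_size) stop("n_queries must be <= module_size")
  if (!is.null(seed)) local_seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  module <- genes[seq_len(module_size)]
  queries <- module[seq_len(n_queries)]
  in_module <- genes %in% module
  datasets <- lapply(seq_len(n_datasets), function(d) {
    latent <- stats::rnorm(n_samples, sd = noise_sd)
    mat <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                  n_genes, n_samples, dimnames = list(genes, NULL))
    mat[in_module, ] <- beta * matrix(latent, sum(in_module), n_samples,
                                      byrow = TRUE) +
      sqrt(1 - beta^2) * mat[in_module, ]
    colnames(mat) <- sprintf("S%02d", seq_len(n_samples))
    expression_dataset(mat, sprintf("chip%d", d))
  })
  truth <- synthetic_truth(module, queries, genes,
                           params = list(n_genes = n_genes,
                                         n_samples = n_samples,
                                         n_datasets = n_datasets,
                                         module_size = module_size,
                                         n_queries = n_queries, beta = beta,
                                         noise_sd = noise_sd, seed = seed))
  list(datasets = datasets, truth = truth)
}

synthetic_truth <- function(module, queries, all_genes, params) {
  structure(list(module_genes = gene_set(module, "planted_module"),
                 query_genes = gene_set(queries, "planted_queries"),
                 all_genes = all_genes, params = params),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> module of ", length(x$module_genes$genes),
      " genes (", length(x$query_genes$genes), " queries) among ",
      length(x$all_genes), " genes\n", sep = "")
  invisible(x)
}

#' Simulate a PPI network with a planted query-enriched cluster
#'
#' Background edges come from an undirected preferential-attachment process,
#' giving the heavy-tailed degree distribution typical of interactomes;
#' cluster edges are then added independently with probability \code{p_in}
#' between every pair of planted cluster genes. With \code{attach_m = 0} and
#' \code{p_in = 0} the edge set is empty; with \code{p_in = 1} the cluster
#' induces a clique.
#'
#' @param n_nodes Total nodes (default 300).
#' @param cluster_size Planted cluster size when \code{cluster_genes} is not
#'   given (default 30).
#' @param p_in Within-cluster edge probability in [0, 1] (default 0.4).
#' @param attach_m Edges added per node by the attachment process
#'   (default 2; 0 disables background edges).
#' @param n_queries Query genes taken from the cluster (default
#'   \code{cluster_size \%/\% 2}).
#' @param cluster_genes Optional explicit cluster symbols (must be a subset
#'   of the node names).
#' @param seed Optional integer seed.
#' @return List with \code{network} (an \code{igraph}) and \code{truth}
#'   (a \code{synthetic_truth}).
#' @export
simulate_ppi <- function(n_nodes = 300L, cluster_size = 30L, p_in = 0.4,
                         attach_m = 2L, n_queries = max(1L, cluster_size %/% 2L),
                         cluster_genes = NULL, seed = NULL) {
  if (p_in < 0 || p_in > 1) stop("p_in must lie in [0, 1]")
  if (is.null(cluster_genes) && cluster_size >= n_nodes) {
    stop("cluster_size must be < n_nodes")
  }
  if (!is.null(seed)) local_seed(seed)
  genes <- sprintf("G%04d", seq_len(n_nodes))
  cluster <- if (is.null(cluster_genes)) genes[seq_len(cluster_size)]
             else normalize_symbol(cluster_genes)
  if (!all(cluster %in% genes)) stop("cluster_genes outside the node set")
  if (attach_m > 0L) {
    bg <- igraph::sample_pa(n_nodes, m = attach_m, directed = FALSE)
    ## assign symbols to attachment vertices in random order so that planted
    ## cluster membership is independent of background hub structure
    igraph::V(bg)$name <- sample(genes)
    el <- igraph::as_edgelist(bg)
  } else {
    el <- matrix(character(), 0L, 2L)
  }
  pairs <- if (length(cluster) >= 2L) t(utils::combn(cluster, 2L)) else
    matrix(character(), 0L, 2L)
  if (nrow(pairs)) {
    pairs <- pairs[stats::runif(nrow(pairs)) < p_in, , drop = FALSE]
  }
  net <- ppi_network(rbind(el, pairs), nodes = genes)
  queries <- cluster[seq_len(min(n_queries, length(cluster)))]
  truth <- synthetic_truth(cluster, queries, genes,
                           params = list(n_nodes = n_nodes,
                                         cluster_size = length(cluster),
                                         p_in = p_in, attach_m = attach_m,
                                         seed = seed))
  list(network = net, truth = truth)
}

#' Simulate a matched expression + PPI screen bundle
#'
#' Draws an expression ensemble and a PPI network over the same gene
#' symbols, with one planted 64-gene module that is both transcriptionally
#' co-regulated (strength \code{beta}) and densely interconnected
#' (within-module edge probability \code{p_in}), and a 24-gene query group
#' inside it -- the standard synthetic study conditions for end-to-end
#' validation of the screen.
#'
#' @inheritParams simulate_expression_ensemble
#' @param p_in Within-module PPI edge probability (default 0.4).
#' @param attach_m Background attachment parameter (default 2).
#' @param seed Optional integer seed for the whole bundle.
#' @return List with \code{datasets}, \code{network}, \code{truth}.
#' @export
simulate_screen_bundle <- function(n_genes = 300L, n_samples = 30L,
                                   n_datasets = 3L, module_size = 64L,
                                   n_queries = 24L, beta = 0.9,
                                   noise_sd = 1, p_in = 0.4, attach_m = 2L,
                                   seed = NULL) {
  if (!is.null(seed)) local_seed(seed)
  expr <- simulate_expression_ensemble(n_genes, n_samples, n_datasets,
                                       module_size, n_queries, beta, noise_sd)
  ppi <- simulate_ppi(n_nodes = n_genes, p_in = p_in, attach_m = attach_m,
                      cluster_genes = expr$truth$module_genes$genes)
  truth <- expr$truth
  truth$params <- c(truth$params[setdiff(names(truth$params), "seed")],
                    list(p_in = p_in, attach_m = attach_m, seed = seed))
  list(datasets = expr$datasets, network = ppi$network, truth = truth)
}

#' Write a synthetic bundle to disk
#'
#' Emits the standard on-disk forms consumed by the pipeline: one expression
#' TSV per dataset, an edge-list TSV, a one-symbol-per-line query file, and
#' a truth JSON recording the planted module and generator parameters.
#'
#' @param bundle Output of [simulate_screen_bundle].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (ds in bundle$datasets) {
    p <- file.path(dir, paste0(ds$dataset_id, ".tsv"))
    write_expression_tsv(ds, p)
    paths[ds$dataset_id] <- p
  }
  paths["edges"] <- file.path(dir, "ppi_edges.tsv")
  write_edge_list(bundle$network, paths[["edges"]])
  paths["queries"] <- file.path(dir, "queries.txt")
  write_gene_set(bundle$truth$query_genes, paths[["queries"]])
  paths["truth"] <- file.path(dir, "truth.json")
  truth <- bundle$truth
  jsonlite::write_json(list(module_genes = truth$module_genes$genes,
                            query_genes = truth$query_genes$genes,
                            params = truth$params),
                       paths[["truth"]], auto_unbox = TRUE, null = "null")
  invisible(paths)
}

#' Recovery metrics for a candidate ranking against planted truth
#'
#' Scores how well a ranked candidate table recovers the planted non-query
#' module genes: \code{precision_at_k} is the fraction of the top \code{k}
#' non-query entries that are planted, and \code{auc} is the rank-based
#' (Mann-Whitney) probability that a planted non-query gene is ranked above
#' a background gene. Genes absent from the ranking are treated as tied at
#' the bottom.
#'
#' @param ranking Ranked table (data frame with a gene column) or character
#'   vector, best first.
#' @param truth A \code{synthetic_truth}.
#' @param k Cutoff for precision (default 20). If larger than the ranking, a
#'   warning is issued and the full list is used.
#' @return List with \code{precision_at_k}, \code{auc}, \code{k}.
#' @export
recovery_metrics <- function(ranking, truth, k = 20L) {
  stopifnot(inherits(truth, "synthetic_truth"), k >= 1L)
  if (!length(truth$module_genes$genes)) stop("truth has no planted genes")
  ranked <- setdiff(ranking_genes(ranking), truth$query_genes$genes)
  if (!length(ranked)) stop("ranking is empty after removing query genes")
  positives <- setdiff(truth$module_genes$genes, truth$query_genes$genes)
  background <- setdiff(truth$all_genes,
                        union(truth$module_genes$genes,
                              truth$query_genes$genes))
  if (k > length(ranked)) {
    warning("k = ", k, " exceeds ranking length ", length(ranked),
            "; using the full list")
    k <- length(ranked)
  }
  precision <- mean(ranked[seq_len(k)] %in% positives)
  pos_p <- match(positives, ranked)
  pos_b <- match(background, ranked)
  pos_p[is.na(pos_p)] <- Inf
  pos_b[is.na(pos_b)] <- Inf
  cmp <- outer(pos_p, pos_b, function(p, b) (p < b) + 0.5 * (p == b))
  list(precision_at_k = precision, auc = mean(cmp), k = as.integer(k))
}
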