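#' Construct a PPI network
#'
#' Builds a simple undirected graph over normalized gene symbols from a
#' two-column edge table. Self-loops are dropped with a warning; duplicate
#' and reversed edges collapse to one.
#'
#' @param edges Two-column matrix or data frame of symbol pairs, or a
#'   character vector of length 2k.
#' @param nodes Optional extra node symbols to include as isolated vertices.
#' @return An \code{igraph} object with vertex \code{name} attributes.
#' @export
ppi_network <- function(edges = NULL, nodes = character()) {
  nodes <- if (length(nodes)) normalize_symbol(nodes) else character()
  if (is.null(edges) || NROW(edges) == 0L) {
    return(igraph::make_empty_graph(directed = FALSE) +
             igraph::vertices(unique(nodes)))
  }
  em <- as.matrix(edges)
  if (ncol(em) != 2L) stop("edge table must have exactly two columns")
  em[] <- normalize_symbol(as.character(em))
  loops <- em[, 1L] == em[, 2L]
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    em <- em[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- g + igraph::vertices(setdiff(unique(nodes), igraph::V(g)$name))
  igraph::simplify(g)
}

#' Read a PPI edge list from TSV
#'
#' Two tab-separated gene symbols per line; blank lines and \code{#} comments
#' are ignored. Lines without exactly two fields raise a parse error naming
#' the line.
#'
#' @param path Path to the edge-list file.
#' @return An \code{igraph} object (see [ppi_network]).
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) return(ppi_network())
  parts <- strsplit(lines[keep], "[\t ]+")
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    stop("edge list ", path, ": line ", keep[which(nf != 2L)[1L]],
         " does not have two fields")
  }
  ppi_network(do.call(rbind, parts))
}

#' Write a PPI network as an edge-list TSV
#'
#' @param net \code{igraph} network.
#' @param path Output path.
#' @param comment Optional \code{#}-prefixed header lines.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(net, path, comment = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  el <- igraph::as_edgelist(net)
  if (nrow(el)) writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), con)
  invisible(path)
}

#' Extract the query-group sub-network
#'
#' Returns the graph induced by the query genes present in the network plus
#' all of their first neighbours -- the "sub-network" whose interactions
#' define the specificity scoring. Queries absent from the network are
#' reported, and queries present but without any interactor are listed in a
#' warning (the published screen saw 58 of its 64 queries return
#' interactors).
#'
#' @param net \code{igraph} network.
#' @param queries Query group ([gene_set] or character).
#' @return An \code{igraph} induced sub-network.
#' @export
subnetwork_extract <- function(net, queries) {
  queries <- as_symbols(queries)
  present <- intersect(queries, igraph::V(net)$name)
  absent <- setdiff(queries, present)
  if (length(absent)) {
    message(length(absent), " query gene(s) absent from the network: ",
            paste(absent, collapse = ", "))
  }
  if (!length(present)) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  deg <- igraph::degree(net, v = present)
  if (any(deg == 0)) {
    warning("query gene(s) with no interactors: ",
            paste(present[deg == 0], collapse = ", "))
  }
  nbrs <- unique(unlist(lapply(igraph::adjacent_vertices(net, present),
                               function(v) v$name)))
  igraph::induced_subgraph(net, union(present, nbrs))
}

#' Degree profile of a node against a query group
#'
#' Counts a node's global degree (all interactions) and its sub-network
#' degree (interactions with query-group members), plus their ratio -- the
#' first ingredient of the sub-network specificity score. The ratio is
#' defined as 0 for isolated nodes.
#'
#' @param net \code{igraph} network.
#' @param queries Query group.
#' @param node Gene symbol present in the network.
#' @return List of class \code{degree_profile}: \code{node},
#'   \code{k_global}, \code{k_query}, \code{ratio}.
#' @export
degree_profile <- function(net, queries, node) {
  queries <- as_symbols(queries)
  node <- normalize_symbol(node)
  if (!node %in% igraph::V(net)$name) {
    stop("node '", node, "' absent from the network")
  }
  nbr <- igraph::neighbors(net, node)$name
  k_global <- length(nbr)
  k_query <- sum(nbr %in% queries)
  structure(list(node = node, k_global = k_global, k_query = k_query,
                 ratio = if (k_global > 0L) k_query / k_global else 0),
            class = "degree_profile")
}

## Minimum standard deviation used when standardizing against the null, so
## degenerate (zero-variance) nulls cannot produce infinite Z.
SD_FLOOR <- 1e-9

#' Random-group interaction null for one node
#'
#' Draws \code{n_groups} random gene groups of the query-group's size,
#' uniformly without replacement from the network's nodes (excluding the
#' focal node), and records how many interactions the node has with each --
#' the empirical null against which the observed query-group degree is
#' standardized.
#'
#' @param net \code{igraph} network.
#' @param node Focal gene symbol.
#' @param group_size Size of each random group (the query-group size).
#' @param n_groups Number of random groups (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @param observed Optional observed query-group degree; when given, the
#'   exceedance fraction \code{mean(samples >= observed)} is reported.
#' @return List of class \code{random_group_null}: \code{node},
#'   \code{group_size}, \code{n_groups}, \code{samples}, \code{mean},
#'   \code{sd}, \code{exceedance}, \code{seed}.
#' @export
random_group_null <- function(net, node, group_size, n_groups = 1000L,
                              seed = NULL, observed = NA_real_) {
  node <- normalize_symbol(node)
  vs <- igraph::V(net)$name
  if (!node %in% vs) stop("node '", node, "' absent from the network")
  universe <- sort(setdiff(vs, node))  # storage-order independent draws
  if (group_size >= length(universe) + 1L || group_size < 1L) {
    stop("infeasible group_size ", group_size, " for a universe of ",
         length(universe), " nodes")
  }
  if (!is.null(seed)) local_seed(seed)
  memb <- universe %in% igraph::neighbors(net, node)$name
  nu <- length(universe)
  samples <- vapply(seq_len(n_groups), function(i) {
    sum(memb[sample.int(nu, group_size)])
  }, numeric(1L))
  structure(list(node = node, group_size = as.integer(group_size),
                 n_groups = as.integer(n_groups), samples = samples,
                 mean = mean(samples), sd = stats::sd(samples),
                 exceedance = if (is.na(observed)) NA_real_
                              else mean(samples >= observed),
                 seed = seed),
            class = "random_group_null")
}

#' Sub-network specificity (S3) score
#'
#' Combines the two specificity ingredients for a node: the ratio of
#' sub-network to global degree, and the standardized excess of the observed
#' query-group degree over the random-group null
#' (\code{null_z = (k_query - null mean) / max(null sd, floor)}).
#' The combination used is \code{s3 = ratio * max(null_z, 0)}: zero whenever
#' either signal is absent, and strictly increasing in each ingredient at a
#' fixed value of the other.
#'
#' @param profile A [degree_profile].
#' @param null A [random_group_null] for the same node and group size.
#' @return List of class \code{s3_score}: \code{node}, \code{ratio},
#'   \code{null_z}, \code{s3}.
#' @export
s3_score <- function(profile, null) {
  stopifnot(inherits(profile, "degree_profile"),
            inherits(null, "random_group_null"))
  if (!identical(profile$node, null$node)) {
    stop("profile node '", profile$node, "' does not match null node '",
         null$node, "'")
  }
  z <- (profile$k_query - null$mean) / max(null$sd, SD_FLOOR)
  structure(list(node = profile$node, ratio = profile$ratio, null_z = z,
                 s3 = profile$ratio * max(z, 0)),
            class = "s3_score")
}

#' Rank non-query interactors by sub-network specificity
#'
#' Scores every non-query node with at least one interaction with the query
#' group and ranks by S3 score descending; ties are broken by smaller global
#' degree (more specific), then alphabetically. The output mirrors the
#' published interactor table's schema (total interactions and interactions
#' with the query group) with the score appended.
#'
#' @param net \code{igraph} network.
#' @param queries Query group.
#' @param n_groups Random groups per node for the null (default 1000).
#' @param seed Optional integer seed; the full ranking is bit-reproducible
#'   given the seed.
#' @return Data frame with columns \code{ranking}, \code{gene},
#'   \code{total_interactions}, \code{query_interactions}, \code{ratio},
#'   \code{null_z}, \code{s3}; attributes \code{n_groups}, \code{seed},
#'   \code{group_size}.
#' @export
rank_interactors <- function(net, queries, n_groups = 1000L, seed = NULL) {
  queries <- as_symbols(queries)
  if (!length(queries)) stop("queries must be non-empty")
  if (!is.null(seed)) local_seed(seed)
  vs <- sort(igraph::V(net)$name)
  group_size <- length(queries)
  rows <- list()
  for (v in setdiff(vs, queries)) {
    prof <- degree_profile(net, queries, v)
    if (prof$k_query < 1L) next
    null <- random_group_null(net, v, group_size, n_groups,
                              observed = prof$k_query)
    sc <- s3_score(prof, null)
    rows[[v]] <- data.frame(gene = v, total_interactions = prof$k_global,
                            query_interactions = prof$k_query,
                            ratio = prof$ratio, null_z = sc$null_z,
                            s3 = sc$s3, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), total_interactions = integer(),
               query_interactions = integer(), ratio = numeric(),
               null_z = numeric(), s3 = numeric(), stringsAsFactors = FALSE)
  out <- out[order(-out$s3, out$total_interactions, out$gene), , drop = FALSE]
  out <- data.frame(ranking = seq_len(nrow(out)), out,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_groups") <- as.integer(n_groups)
  attr(out, "seed") <- seed
  attr(out, "group_size") <- as.integer(group_size)
  out
}

## Seed the RNG for the calling function's scope, restoring the caller's RNG
## state on exit.
local_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(seed, .local_envir = env)
}
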