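#' Construct an expression dataset
#'
#' One genes-by-samples real matrix standing in for a single expression
#' platform; an ensemble (plain list) of these emulates multiple chips
#' profiling the same transcriptome. Gene symbols are taken from row names
#' and normalized; rows with zero variance are flagged as constant and are
#' excluded from similarity rankings (with a warning) rather than assigned a
#' correlation of zero.
#'
#' @param values Numeric matrix, genes in rows (row names are symbols),
#'   samples in columns. At least 3 samples.
#' @param dataset_id Identifier string for the dataset.
#' @return An object of class \code{expression_dataset}: list with
#'   \code{dataset_id}, \code{values}, and logical \code{constant} flags.
#' @export
expression_dataset <- function(values, dataset_id) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values))) stop("values must carry gene symbols as row names")
  if (ncol(values) < 3L) stop("expression dataset needs >= 3 samples")
  rownames(values) <- normalize_symbol(rownames(values))
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene symbols in dataset '", dataset_id, "'")
  }
  if (any(!is.finite(values))) stop("non-finite expression values")
  constant <- apply(values, 1L, function(r) stats::var(r) == 0)
  structure(list(dataset_id = as.character(dataset_id)[1L],
                 values = values,
                 constant = constant),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> '", x$dataset_id, "': ", nrow(x$values),
      " genes x ", ncol(x$values), " samples",
      if (any(x$constant)) paste0(" (", sum(x$constant), " constant rows)"),
      "\n", sep = "")
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers and gene symbols in the first
#' column (the on-disk layout used for all expression inputs).
#'
#' @param path Path to a tab-separated file.
#' @param dataset_id Identifier; defaults to the file base name.
#' @return An [expression_dataset].
#' @export
read_expression_tsv <- function(path, dataset_id = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df[[1L]]
  expression_dataset(mat, dataset_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write an expression dataset to TSV
#'
#' @param dataset An [expression_dataset].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(gene = rownames(dataset$values), dataset$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Pearson correlation matrix over the non-constant rows of a dataset.
dataset_cor <- function(dataset) {
  usable <- dataset$values[!dataset$constant, , drop = FALSE]
  stats::cor(t(usable))
}

## Directed similarity ranks: R[a, b] = position of b in a's ranking of all
## other genes by decreasing similarity, alphabetical tie-break. Diagonal NA.
directed_rank_matrix <- function(C) {
  g <- rownames(C)
  n <- length(g)
  R <- matrix(NA_real_, n, n, dimnames = list(g, g))
  for (i in seq_len(n)) {
    ord <- order(-C[i, -i], g[-i])
    pos <- integer(n - 1L)
    pos[ord] <- seq_len(n - 1L)
    R[i, -i] <- pos
  }
  R
}

#' Top-K co-expression neighbours of a query gene
#'
#' Ranks all other genes in one dataset by similarity of expression pattern
#' to the query (Pearson correlation across samples) and returns the top
#' \code{k}. Ties are broken alphabetically so outputs are bit-reproducible.
#' Constant rows are excluded from the candidate pool with a warning; a
#' constant query has no defined correlation and is an error.
#'
#' @param dataset An [expression_dataset].
#' @param query Gene symbol present in the dataset.
#' @param k Number of neighbours to keep (default 50, the list length pooled
#'   by the occurrence screen). If fewer eligible genes exist, all are
#'   returned.
#' @return A data frame of class \code{neighbor_list} with columns
#'   \code{gene}, \code{similarity}, \code{rank}, and attributes
#'   \code{dataset_id} and \code{query}.
#' @export
similarity_rank_neighbors <- function(dataset, query, k = 50L) {
  stopifnot(inherits(dataset, "expression_dataset"), k >= 1L)
  query <- normalize_symbol(query)
  genes <- rownames(dataset$values)
  if (!query %in% genes) {
    stop("query '", query, "' absent from dataset '", dataset$dataset_id, "'")
  }
  if (dataset$constant[[query]]) {
    stop("query '", query, "' has constant expression in dataset '",
         dataset$dataset_id, "': correlation undefined")
  }
  if (any(dataset$constant)) {
    warning(sum(dataset$constant), " constant row(s) excluded from ranking in '",
            dataset$dataset_id, "'")
  }
  pool <- genes[!dataset$constant & genes != query]
  if (!length(pool)) stop("no eligible neighbour genes in dataset")
  sims <- as.vector(stats::cor(dataset$values[query, ],
                               t(dataset$values[pool, , drop = FALSE])))
  ord <- order(-sims, pool)
  keep <- ord[seq_len(min(k, length(ord)))]
  out <- data.frame(gene = pool[keep], similarity = sims[keep],
                    rank = seq_along(keep), stringsAsFactors = FALSE)
  attr(out, "dataset_id") <- dataset$dataset_id
  attr(out, "query") <- query
  class(out) <- c("neighbor_list", "data.frame")
  out
}

## All top-K lists for a query group over an ensemble; queries missing from a
## dataset simply contribute no list there (mirrors partial chip coverage).
coexpression_neighbor_lists <- function(datasets, queries, k = 50L) {
  queries <- as_symbols(queries)
  lists <- list()
  for (ds in datasets) {
    present <- intersect(queries, rownames(ds$values)[!ds$constant])
    for (q in present) {
      lists[[length(lists) + 1L]] <-
        suppressWarnings(similarity_rank_neighbors(ds, q, k))
    }
  }
  lists
}

#' Pool top-K neighbour lists into an occurrence table
#'
#' Combines per-query, per-dataset neighbour lists and counts how many lists
#' each gene appears in. Under the default \code{exclusion = "self"} policy a
#' query's own symbol is removed only from its own lists (neighbour lists
#' already exclude their query), so other queries still accumulate counts --
#' the behaviour that lets query genes appear with large occurrence counts in
#' the screen's result tables. \code{exclusion = "all"} additionally drops
#' every query symbol from every list before counting.
#'
#' @param lists List of \code{neighbor_list} objects
#'   (see [similarity_rank_neighbors]).
#' @param queries Query group as a [gene_set] or character vector.
#' @param exclusion \code{"self"} (default) or \code{"all"}.
#' @return A data frame of class \code{occurrence_table} with columns
#'   \code{gene} and \code{occurrences} (sorted by count descending, then
#'   symbol), and attributes \code{n_lists} and \code{provenance}.
#' @export
pool_occurrences <- function(lists, queries, exclusion = c("self", "all")) {
  exclusion <- match.arg(exclusion)
  queries <- as_symbols(queries)
  if (!length(queries)) stop("queries must be non-empty")
  entries <- character()
  prov <- data.frame(dataset_id = character(), query = character(),
                     stringsAsFactors = FALSE)
  for (nl in lists) {
    stopifnot(inherits(nl, "neighbor_list"))
    q <- attr(nl, "query")
    g <- nl$gene
    g <- if (exclusion == "all") setdiff(g, queries) else g[g != q]
    entries <- c(entries, g)
    prov <- rbind(prov, data.frame(dataset_id = attr(nl, "dataset_id"),
                                   query = q, stringsAsFactors = FALSE))
  }
  counts <- table(entries)
  out <- data.frame(gene = names(counts),
                    occurrences = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$occurrences, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_lists") <- length(lists)
  attr(out, "provenance") <- prov
  class(out) <- c("occurrence_table", "data.frame")
  out
}

#' Build an occurrence table from a plain count table
#'
#' Wraps an existing (gene, occurrences) table -- e.g. a packaged fixture --
#' in the \code{occurrence_table} class so it can feed the enrichment stage.
#'
#' @param df Data frame with columns \code{gene_symbol} or \code{gene}, and
#'   \code{occurrences}.
#' @param n_lists Number of pooled lists behind the counts (\code{NA} if
#'   unknown).
#' @return An \code{occurrence_table}.
#' @export
as_occurrence_table <- function(df, n_lists = NA_integer_) {
  gene_col <- intersect(c("gene", "gene_symbol"), names(df))[1L]
  if (is.na(gene_col)) stop("need a 'gene' or 'gene_symbol' column")
  out <- data.frame(gene = normalize_symbol(df[[gene_col]]),
                    occurrences = as.integer(df$occurrences),
                    stringsAsFactors = FALSE)
  attr(out, "n_lists") <- n_lists
  attr(out, "provenance") <- NULL
  class(out) <- c("occurrence_table", "data.frame")
  out
}

#' Rank genes by pooled occurrence count
#'
#' Keeps genes whose occurrence count is at least \code{min_count} and ranks
#' them by count descending, ties broken alphabetically. The default
#' \code{min_count = 10} mirrors the published screen's "more than 9 times"
#' cutoff for its top co-expression table.
#'
#' @param table An \code{occurrence_table}.
#' @param min_count Minimum occurrence count to retain (>= 0).
#' @return Data frame with columns \code{rank}, \code{gene},
#'   \code{occurrences}.
#' @export
rank_by_occurrence <- function(table, min_count = 10L) {
  stopifnot(min_count >= 0L)
  keep <- table[table$occurrences >= min_count, , drop = FALSE]
  keep <- keep[order(-keep$occurrences, keep$gene), , drop = FALSE]
  data.frame(rank = seq_len(nrow(keep)), gene = keep$gene,
             occurrences = keep$occurrences,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mutual rank of a gene pair
#'
#' Within each dataset containing both genes, the mutual rank is the
#' geometric mean of the two directed similarity ranks: the rank of \code{b}
#' among \code{a}'s co-expression ranking of all other genes and vice versa.
#' Across datasets the per-dataset values are combined by geometric mean.
#' Smaller is stronger; the minimum of 1 is attained only by a
#' reciprocal-rank-1 pair.
#'
#' @param datasets List of [expression_dataset] objects.
#' @param gene_a,gene_b Gene symbols.
#' @return List of class \code{mr_score} with \code{gene_a}, \code{gene_b},
#'   \code{mr}, and the per-dataset values \code{per_dataset}.
#' @export
mutual_rank <- function(datasets, gene_a, gene_b) {
  gene_a <- normalize_symbol(gene_a)
  gene_b <- normalize_symbol(gene_b)
  if (gene_a == gene_b) stop("mutual rank requires two distinct genes")
  per <- c()
  for (ds in datasets) {
    genes <- rownames(ds$values)[!ds$constant]
    if (!(gene_a %in% genes && gene_b %in% genes)) next
    per[ds$dataset_id] <- sqrt(directed_rank_of(ds, gene_a, gene_b) *
                               directed_rank_of(ds, gene_b, gene_a))
  }
  if (!length(per)) {
    stop("genes '", gene_a, "' and '", gene_b,
         "' share no dataset with usable expression")
  }
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 mr = exp(mean(log(per))), per_dataset = per),
            class = "mr_score")
}

#' @export
print.mr_score <- function(x, ...) {
  cat("<mr_score> ", x$gene_a, " ~ ", x$gene_b, ": MR = ",
      format(x$mr, digits = 4L), " over ", length(x$per_dataset),
      " dataset(s)\n", sep = "")
  invisible(x)
}

## Position of `target` in `from`'s ranking of all other genes.
directed_rank_of <- function(dataset, from, target) {
  genes <- rownames(dataset$values)[!dataset$constant]
  pool <- genes[genes != from]
  sims <- as.vector(stats::cor(dataset$values[from, ],
                               t(dataset$values[pool, , drop = FALSE])))
  ord <- order(-sims, pool)
  match(target, pool[ord])
}

#' Group mutual-rank ranking of candidate genes
#'
#' Scores every non-query gene by the geometric mean of its mutual rank to
#' each query available in the data, then sorts ascending (smaller aggregate
#' MR = stronger shared co-expression with the group). This is the rank-based
#' group-query search: genes co-expressed with many group members float to
#' the top.
#'
#' @param datasets List of [expression_dataset] objects.
#' @param queries Query group ([gene_set] or character).
#' @param top_n Number of top genes to return (default 300, the list size the
#'   screen carries into cross-evidence comparisons).
#' @return Data frame with columns \code{rank}, \code{gene},
#'   \code{aggregate_mr}.
#' @export
group_mr_ranking <- function(datasets, queries, top_n = 300L) {
  queries <- as_symbols(queries)
  all_genes <- unique(unlist(lapply(datasets, function(d)
    rownames(d$values)[!d$constant])))
  present_q <- intersect(queries, all_genes)
  if (!length(present_q)) stop("no query gene present in the expression data")
  candidates <- setdiff(all_genes, queries)

  ## log-MR sums per (candidate, query) accumulated across datasets
  lsum <- matrix(0, length(candidates), length(present_q),
                 dimnames = list(candidates, present_q))
  nobs <- matrix(0L, length(candidates), length(present_q),
                 dimnames = list(candidates, present_q))
  for (ds in datasets) {
    C <- dataset_cor(ds)
    R <- directed_rank_matrix(C)
    g <- rownames(C)
    qs <- intersect(present_q, g)
    cs <- intersect(candidates, g)
    if (!length(qs) || !length(cs)) next
    mr_d <- sqrt(R[cs, qs, drop = FALSE] * t(R[qs, cs, drop = FALSE]))
    lsum[cs, qs] <- lsum[cs, qs] + log(mr_d)
    nobs[cs, qs] <- nobs[cs, qs] + 1L
  }
  have <- nobs > 0L
  if (!any(have)) stop("no candidate shares a dataset with any query")
  mr_agg <- exp(lsum / ifelse(have, nobs, NA))           # per-pair aggregate
  score <- exp(rowMeans(log(mr_agg), na.rm = TRUE))      # per-candidate
  score <- score[rowSums(have) > 0L]
  ord <- order(score, names(score))
  keep <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(rank = seq_along(keep), gene = names(score)[keep],
             aggregate_mr = unname(score[keep]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write an occurrence table to TSV
#'
#' @param table An \code{occurrence_table} or ranked table.
#' @param path Output path.
#' @param comment Optional header comment lines (written with a leading
#'   \code{#}).
#' @return \code{path}, invisibly.
#' @export
write_occurrence_tsv <- function(table, path, comment = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
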