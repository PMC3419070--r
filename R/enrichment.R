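#' Occurrence statistic of a target gene set
#'
#' Summarizes how strongly a target set is represented in a pooled
#' occurrence table, in one of two modes: \code{"total_occurrences"} sums
#' the counts of target genes present in the table;
#' \code{"n_represented"} counts how many target genes appear at all.
#'
#' @param table An \code{occurrence_table}.
#' @param target Target set ([gene_set] or character).
#' @param mode \code{"total_occurrences"} or \code{"n_represented"}.
#' @return A single number.
#' @export
occurrence_statistic <- function(table,
                                 target,
                                 mode = c("total_occurrences",
                                          "n_represented")) {
  mode <- match.arg(mode)
  target <- as_symbols(target)
  hit <- table$gene %in% target
  if (mode == "total_occurrences") sum(table$occurrences[hit])
  else sum(hit & table$occurrences >= 1L)
}

#' Random-set null for the occurrence statistic
#'
#' Draws \code{n_perm} random gene sets of the target's size, uniformly
#' without replacement from the universe, and recomputes the occurrence
#' statistic for each -- the resampling null used to standardize an observed
#' target statistic. A degenerate null (\code{target_size == |universe|}) is
#' flagged and its standard deviation floored.
#'
#' @param table An \code{occurrence_table}.
#' @param target_size Size of each random set.
#' @param universe Background genes to draw from; defaults to all genes in
#'   the table.
#' @param n_perm Number of random sets (default 1000).
#' @param seed Optional integer seed.
#' @param mode Statistic mode, see [occurrence_statistic].
#' @return List with \code{samples}, \code{mean}, \code{sd},
#'   \code{degenerate}, \code{n_perm}, \code{seed}, \code{mode}.
#' @export
random_set_null <- function(table, target_size, universe = NULL,
                            n_perm = 1000L, seed = NULL,
                            mode = c("total_occurrences", "n_represented")) {
  mode <- match.arg(mode)
  universe <- if (is.null(universe)) unique(table$gene)
              else unique(as_symbols(universe))
  target_size <- as.integer(target_size)
  if (target_size > length(universe) || target_size < 1L) {
    stop("infeasible target_size ", target_size, " for a universe of ",
         length(universe), " genes")
  }
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) local_seed(seed)
  counts <- table$occurrences[match(universe, table$gene)]
  counts[is.na(counts)] <- 0L
  nu <- length(universe)
  samples <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(nu, target_size)
    if (mode == "total_occurrences") sum(counts[idx]) else sum(counts[idx] >= 1L)
  }, numeric(1L))
  degenerate <- target_size == nu
  if (degenerate) warning("target_size equals universe size: null degenerate")
  list(samples = samples, mean = mean(samples), sd = stats::sd(samples),
       degenerate = degenerate, n_perm = as.integer(n_perm), seed = seed,
       mode = mode)
}

#' Permutation Z-score enrichment of a target set
#'
#' Tests whether a target gene set is over-represented in a pooled
#' occurrence table relative to random sets of the same size drawn from the
#' universe. Reports the Z score
#' \code{(observed - null mean) / max(null sd, floor)} and the add-one
#' empirical p-value \code{(1 + #\{null >= observed\}) / (n_perm + 1)},
#' which is never exactly zero.
#'
#' @inheritParams random_set_null
#' @param target Target set ([gene_set] or character).
#' @return Object of class \code{enrichment_result}: list with
#'   \code{target_name}, \code{mode}, \code{observed}, \code{null_mean},
#'   \code{null_sd}, \code{z}, \code{p_empirical}, \code{n_perm},
#'   \code{seed}.
#' @export
enrichment_z <- function(table, target, universe = NULL, n_perm = 1000L,
                         seed = NULL,
                         mode = c("total_occurrences", "n_represented")) {
  mode <- match.arg(mode)
  target_name <- if (inherits(target, "gene_set")) target$name else "target"
  target <- as_symbols(target)
  if (!nrow(table)) stop("occurrence table is empty")
  if (!any(table$gene %in% target)) {
    warning("target set '", target_name,
            "' is disjoint from the occurrence table")
  }
  observed <- occurrence_statistic(table, target, mode)
  null <- random_set_null(table, length(target), universe, n_perm, seed, mode)
  structure(list(target_name = target_name, mode = mode, observed = observed,
                 null_mean = null$mean, null_sd = null$sd,
                 z = (observed - null$mean) / max(null$sd, SD_FLOOR),
                 p_empirical = (1 + sum(null$samples >= observed)) /
                               (null$n_perm + 1),
                 n_perm = null$n_perm, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> '", x$target_name, "' (", x$mode, ")\n",
      "  observed ", format(x$observed), ", null ",
      format(x$null_mean, digits = 4L), " +/- ",
      format(x$null_sd, digits = 4L), "\n",
      "  Z = ", format(x$z, digits = 4L), ", empirical P = ",
      format(x$p_empirical, digits = 4L), " (", x$n_perm, " permutations)\n",
      sep = "")
  invisible(x)
}

#' Query-group resampling enrichment (synthetic-data mode)
#'
#' The expensive alternative null: instead of resampling the target set, it
#' redraws the *query group* from the expression data's genes, re-runs the
#' top-K pooling for each random group, and recomputes the target statistic
#' on each resulting table. Intended for synthetic data where ensembles are
#' small; the screen's standard null is [enrichment_z].
#'
#' @param datasets List of [expression_dataset] objects.
#' @param query_size Size of each random query group.
#' @param target Target set.
#' @param observed Observed statistic (from the real query group's table).
#' @param k Top-K list length (default 50).
#' @param n_perm Number of random query groups (kept small by design).
#' @param seed Optional integer seed.
#' @param mode Statistic mode, see [occurrence_statistic].
#' @return An \code{enrichment_result}.
#' @export
query_group_enrichment <- function(datasets, query_size, target, observed,
                                   k = 50L, n_perm = 50L, seed = NULL,
                                   mode = c("total_occurrences",
                                            "n_represented")) {
  mode <- match.arg(mode)
  target_name <- if (inherits(target, "gene_set")) target$name else "target"
  target <- as_symbols(target)
  if (!is.null(seed)) local_seed(seed)
  pool <- unique(unlist(lapply(datasets, function(d)
    rownames(d$values)[!d$constant])))
  if (query_size > length(pool)) stop("query_size exceeds available genes")
  samples <- vapply(seq_len(n_perm), function(i) {
    qs <- sample(pool, query_size)
    tab <- pool_occurrences(coexpression_neighbor_lists(datasets, qs, k), qs)
    occurrence_statistic(tab, target, mode)
  }, numeric(1L))
  structure(list(target_name = target_name, mode = mode, observed = observed,
                 null_mean = mean(samples), null_sd = stats::sd(samples),
                 z = (observed - mean(samples)) /
                     max(stats::sd(samples), SD_FLOOR),
                 p_empirical = (1 + sum(samples >= observed)) / (n_perm + 1),
                 n_perm = as.integer(n_perm), seed = seed),
            class = "enrichment_result")
}

#' Hypergeometric overlap test for two gene lists
#'
#' Intersects two gene lists and reports the hypergeometric tail probability
#' of observing an overlap at least as large when both lists are random
#' draws from the universe.
#'
#' @param list_a,list_b Gene lists ([gene_set] or character), both contained
#'   in the universe.
#' @param universe Background gene list.
#' @return List with \code{intersection} (a [gene_set]), \code{overlap},
#'   and \code{p}.
#' @export
overlap_test <- function(list_a, list_b, universe) {
  a <- unique(as_symbols(list_a))
  b <- unique(as_symbols(list_b))
  u <- unique(as_symbols(universe))
  if (!all(a %in% u)) stop("list_a contains genes outside the universe")
  if (!all(b %in% u)) stop("list_b contains genes outside the universe")
  ov <- intersect(a, b)
  p <- stats::phyper(length(ov) - 1L, length(a), length(u) - length(a),
                     length(b), lower.tail = FALSE)
  list(intersection = gene_set(ov, name = "overlap"),
       overlap = length(ov), p = p)
}

#' Write an enrichment report to TSV
#'
#' @param results List of \code{enrichment_result} objects (or a single one).
#' @param path Output path.
#' @param comment Optional \code{#}-prefixed header lines.
#' @return \code{path}, invisibly.
#' @export
write_enrichment_tsv <- function(results, path, comment = character()) {
  if (inherits(results, "enrichment_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(target = r$target_name, mode = r$mode, observed = r$observed,
               null_mean = r$null_mean, null_sd = r$null_sd, z = r$z,
               p = r$p_empirical, n_perm = r$n_perm,
               seed = r$seed %||% NA_integer_, stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
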