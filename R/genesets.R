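#' Normalize gene symbols
#'
#' Trims surrounding whitespace and uppercases each symbol so that user data,
#' fixture tables and synthetic genes are compared on a common footing
#' (published tables mix styles, e.g. \code{"C13orf3"} vs \code{"C13ORF3"}).
#' The transformation is idempotent.
#'
#' @param raw Character vector of raw gene symbols.
#' @return Character vector of normalized symbols.
#' @examples
#' normalize_symbol(c("zwint ", "TRIP13", "c13orf3"))
#' @export
normalize_symbol <- function(raw) {
  if (!is.character(raw)) {
    stop("gene symbols must be character, got ", class(raw)[1L])
  }
  out <- toupper(trimws(raw))
  if (any(!nzchar(out) | is.na(out))) {
    bad <- which(!nzchar(out) | is.na(out))
    stop("empty gene symbol at position ", paste(bad, collapse = ", "))
  }
  out
}

#' Construct a gene set
#'
#' A named, ordered collection of unique normalized gene symbols. Duplicates
#' (after normalization) are dropped, keeping the first occurrence; the number
#' dropped is reported via a message.
#'
#' @param genes Character vector of gene symbols.
#' @param name Short name for the set.
#' @return An object of class \code{gene_set}: a list with elements
#'   \code{name} and \code{genes}.
#' @export
gene_set <- function(genes, name = "gene_set") {
  genes <- if (length(genes)) normalize_symbol(genes) else character()
  dup <- duplicated(genes)
  if (any(dup)) {
    message(sum(dup), " duplicate symbol(s) dropped from '", name, "'")
    genes <- genes[!dup]
  }
  structure(list(name = as.character(name)[1L], genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  if (length(x$genes)) {
    shown <- utils::head(x$genes, 8L)
    cat("  ", paste(shown, collapse = ", "),
        if (length(x$genes) > 8L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' @export
as.character.gene_set <- function(x, ...) x$genes

## Accept either a gene_set or a plain character vector.
as_symbols <- function(x) {
  if (inherits(x, "gene_set")) x$genes else normalize_symbol(as.character(x))
}

#' Read a gene set from disk
#'
#' Supports two dialects: \code{"lines"} (one symbol per line, blank lines and
#' \code{#} comments ignored) and \code{"gmt"} (tab-separated
#' \code{name<TAB>description<TAB>gene...}; the set selected by \code{set} is
#' returned).
#'
#' @param path Path to the file.
#' @param format \code{"lines"} or \code{"gmt"}.
#' @param name Name for the resulting set (defaults to the file base name for
#'   \code{"lines"}, the GMT record name for \code{"gmt"}).
#' @param set For GMT files, the record to return: an index or a set name.
#' @return A [gene_set].
#' @export
read_gene_set <- function(path, format = c("lines", "gmt"), name = NULL,
                          set = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "lines") {
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) warning("empty gene set file: ", path)
    return(gene_set(lines, name = name %||% basename(path)))
  }
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) {
    warning("empty GMT file: ", path)
    return(gene_set(character(), name = name %||% basename(path)))
  }
  recs <- lapply(keep, function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, " in ", path,
           ": expected >= 3 tab-separated fields, got ", length(fields))
    }
    fields
  })
  rec_names <- vapply(recs, `[[`, character(1L), 1L)
  idx <- if (is.character(set)) match(set, rec_names) else as.integer(set)
  if (is.na(idx) || idx < 1L || idx > length(recs)) {
    stop("GMT set '", set, "' not found in ", path)
  }
  fields <- recs[[idx]]
  gene_set(fields[-c(1L, 2L)], name = name %||% fields[1L])
}

#' Write a gene set to disk
#'
#' @param gs A [gene_set].
#' @param path Output path.
#' @param format \code{"lines"} or \code{"gmt"}.
#' @param description Description field for the GMT dialect.
#' @return \code{path}, invisibly.
#' @export
write_gene_set <- function(gs, path, format = c("lines", "gmt"),
                           description = "") {
  format <- match.arg(format)
  stopifnot(inherits(gs, "gene_set"))
  if (format == "lines") {
    writeLines(gs$genes, path)
  } else {
    writeLines(paste(c(gs$name, description, gs$genes), collapse = "\t"), path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "mitoscreen")
  if (!nzchar(p)) stop("packaged fixture missing: ", file)
  p
}

read_fixture_tsv <- function(file) {
  utils::read.delim(fixture_path(file), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

#' Packaged query-group table (64 core centromere/kinetochore genes)
#'
#' Transcription of the published table of 64 "core" centromere/kinetochore
#' query genes with, per gene, the number of expression datasets in which it
#' was present (1-3) and its occurrence count in the pooled "top 50"
#' co-expression lists (0 where the printed cell is blank). The printed
#' alias column is retained as \code{notes} but never used for matching; the
#' printed symbol \code{"SKA"} (alias FAM33A, presumably SKA2) is kept as
#' printed rather than corrected.
#'
#' @return A data frame with columns \code{gene_symbol}, \code{n_datasets},
#'   \code{occurrences}, \code{notes}; 64 rows.
#' @export
load_table1_fixture <- function() {
  t1 <- read_fixture_tsv("table1_queries.tsv")
  t1$gene_symbol <- normalize_symbol(t1$gene_symbol)
  if (nrow(t1) != 64L) stop("table 1 fixture corrupt: expected 64 rows")
  if (anyDuplicated(t1$gene_symbol)) stop("table 1 fixture: duplicate symbols")
  if (!all(t1$n_datasets %in% 1:3)) {
    stop("table 1 fixture: n_datasets outside 1..3")
  }
  if (any(t1$occurrences < 0L)) stop("table 1 fixture: negative occurrences")
  t1
}

#' Packaged top-ranking co-expressed gene table
#'
#' Transcription of the published table of genes with the highest occurrence
#' counts in the pooled "top 50" co-expression lists, sorted by occurrences
#' descending. The printed table includes its tail of 9-count rows even
#' though its caption describes genes appearing more than 9 times; the
#' fixture reproduces the print.
#'
#' @return A data frame with columns \code{gene_symbol}, \code{occurrences}.
#' @export
load_table2_fixture <- function() {
  t2 <- read_fixture_tsv("table2_coexpression.tsv")
  t2$gene_symbol <- normalize_symbol(t2$gene_symbol)
  if (anyDuplicated(t2$gene_symbol)) stop("table 2 fixture: duplicate symbols")
  if (any(t2$occurrences < 9L)) stop("table 2 fixture: occurrences below 9")
  if (is.unsorted(rev(t2$occurrences))) {
    stop("table 2 fixture: not sorted by occurrences descending")
  }
  t2
}

#' Packaged top-ranking interactor table
#'
#' Transcription of the published table of top-ranking non-query genes whose
#' proteins interact with the query group, with each gene's total interaction
#' count and its count of interactions with the 64 queries.
#'
#' @return A data frame with columns \code{ranking}, \code{gene_id},
#'   \code{gene_symbol}, \code{total_interactions}, \code{query_interactions}.
#' @export
load_table3_fixture <- function() {
  t3 <- read_fixture_tsv("table3_ppi.tsv")
  t3$gene_symbol <- normalize_symbol(t3$gene_symbol)
  if (anyDuplicated(t3$gene_symbol)) stop("table 3 fixture: duplicate symbols")
  if (any(t3$query_interactions > t3$total_interactions)) {
    stop("table 3 fixture: query_interactions exceeds total_interactions")
  }
  if (any(t3$query_interactions < 1L) || any(t3$total_interactions < 1L)) {
    stop("table 3 fixture: non-positive interaction counts")
  }
  if (any(diff(t3$ranking) <= 0L)) {
    stop("table 3 fixture: ranking not strictly increasing")
  }
  t3
}

#' The 64-gene core query group
#'
#' Convenience accessor returning the packaged query table's symbols as a
#' [gene_set], the collective query used throughout the screen.
#'
#' @return A [gene_set] of 64 symbols.
#' @export
core_query_set <- function() {
  gene_set(load_table1_fixture()$gene_symbol, name = "core_queries")
}
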