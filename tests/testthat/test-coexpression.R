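test_that("an exact copy of the query ranks first with similarity 1", {
  set.seed(3)
  mat <- matrix(rnorm(30), 5, 6)
  mat[2, ] <- mat[1, ]                      # B copies A
  ds <- make_ds(mat, genes = c("A", "B", "C", "D", "E"))
  nl <- similarity_rank_neighbors(ds, "A", k = 3)
  expect_equal(nl$gene[1], "B")
  expect_equal(nl$similarity[1], 1.0)
  expect_equal(nl$rank, 1:3)
})

test_that("neighbour ranking equals the exhaustive pairwise-Pearson oracle", {
  for (seed in 1:20) {
    n_genes <- sample(5:20, 1)
    ds <- rand_ds(n_genes, 8, seed = seed)
    q <- rownames(ds$values)[1]
    k <- sample(seq_len(n_genes - 1), 1)
    got <- similarity_rank_neighbors(ds, q, k)
    exp <- oracle_neighbors(ds, q, k)
    expect_identical(got$gene, exp$gene, label = paste("seed", seed))
    expect_equal(got$similarity, exp$similarity, tolerance = 1e-12)
  }
})

test_that("k beyond the gene count returns all non-query genes ranked", {
  ds <- rand_ds(6, 8, seed = 11)
  nl <- similarity_rank_neighbors(ds, rownames(ds$values)[1], k = 50)
  expect_equal(nrow(nl), 5L)
  expect_equal(nl$rank, 1:5)
})

test_that("query lookups and constant rows are handled explicitly", {
  ds <- rand_ds(5, 6, seed = 2)
  expect_error(similarity_rank_neighbors(ds, "NOPE", 3), "absent")
  mat <- ds$values
  mat[2, ] <- 7
  ds2 <- make_ds(mat, genes = rownames(mat))
  expect_error(similarity_rank_neighbors(ds2, rownames(mat)[2], 3),
               "undefined")
  expect_warning(nl <- similarity_rank_neighbors(ds2, rownames(mat)[1], 10),
                 "constant")
  expect_false(rownames(mat)[2] %in% nl$gene)
})

test_that("permuting sample order leaves neighbour lists unchanged", {
  ds <- rand_ds(12, 10, seed = 5)
  set.seed(99)
  perm <- sample(ncol(ds$values))
  ds2 <- expression_dataset(ds$values[, perm], ds$dataset_id)
  for (q in rownames(ds$values)[1:3]) {
    a <- similarity_rank_neighbors(ds, q, 6)
    b <- similarity_rank_neighbors(ds2, q, 6)
    expect_identical(a$gene, b$gene)
    expect_equal(a$similarity, b$similarity, tolerance = 1e-12)
  }
})

test_that("pooled occurrence counts match hand enumeration", {
  one <- pool_occurrences(list(fake_list(c("A", "B", "C"))), "Q")
  expect_equal(sort(one$gene), c("A", "B", "C"))
  expect_true(all(one$occurrences == 1L))

  three <- pool_occurrences(list(fake_list(c("A", "B"), "Q1"),
                                 fake_list(c("A", "C"), "Q2"),
                                 fake_list(c("A", "B"), "Q3")),
                            c("Q1", "Q2", "Q3"))
  expect_equal(three$occurrences[three$gene == "A"], 3L)
  expect_equal(three$occurrences[three$gene == "B"], 2L)
  expect_equal(three$occurrences[three$gene == "C"], 1L)
  expect_equal(sum(three$occurrences), 6L)
  expect_equal(attr(three, "n_lists"), 3L)
})

test_that("self-only exclusion keeps other queries; strict drops them all", {
  lists <- list(fake_list(c("Q2", "X"), "Q1"), fake_list(c("Q1", "X"), "Q2"))
  soft <- pool_occurrences(lists, c("Q1", "Q2"), exclusion = "self")
  expect_equal(soft$occurrences[soft$gene == "Q1"], 1L)
  expect_equal(soft$occurrences[soft$gene == "Q2"], 1L)
  hard <- pool_occurrences(lists, c("Q1", "Q2"), exclusion = "all")
  expect_false(any(c("Q1", "Q2") %in% hard$gene))
  expect_equal(hard$occurrences[hard$gene == "X"], 2L)
})

test_that("pooled counts never exceed the number of lists", {
  ens <- simulate_expression_ensemble(n_genes = 40, n_samples = 10,
                                      n_datasets = 3, module_size = 10,
                                      n_queries = 5, beta = 0.8, seed = 21)
  lists <- mitoscreen:::coexpression_neighbor_lists(ens$datasets,
                                                    ens$truth$query_genes, 8)
  tab <- pool_occurrences(lists, ens$truth$query_genes)
  expect_equal(attr(tab, "n_lists"), 15L)
  expect_true(max(tab$occurrences) <= attr(tab, "n_lists"))
  expect_equal(sum(tab$occurrences),
               sum(vapply(lists, nrow, integer(1))))
})

test_that("occurrence ranking applies the cutoff and alphabetical tie-break", {
  tab <- as_occurrence_table(data.frame(gene = c("B", "A", "C"),
                                        occurrences = c(2L, 2L, 1L)))
  r <- rank_by_occurrence(tab, min_count = 2)
  expect_identical(r$gene, c("A", "B"))
  expect_equal(r$rank, 1:2)
  empty <- rank_by_occurrence(as_occurrence_table(
    data.frame(gene = character(), occurrences = integer())), 0)
  expect_equal(nrow(empty), 0L)
})

test_that("mutual rank is the geometric mean of brute-forced directed ranks", {
  ds <- rand_ds(10, 8, seed = 7)
  g <- rownames(ds$values)
  C <- cor(t(ds$values))
  dir_rank <- function(a, b) {
    pool <- setdiff(g, a)
    ord <- order(-C[a, pool], pool)
    match(b, pool[ord])
  }
  for (pair in list(c(1, 2), c(3, 9), c(5, 6))) {
    a <- g[pair[1]]; b <- g[pair[2]]
    mr <- mutual_rank(list(ds), a, b)
    expect_equal(mr$mr, sqrt(dir_rank(a, b) * dir_rank(b, a)),
                 tolerance = 1e-12)
    expect_equal(mutual_rank(list(ds), b, a)$mr, mr$mr)  # symmetry
    expect_gte(mr$mr, 1)
  }
})

test_that("a reciprocal best pair attains the mutual-rank lower bound of 1", {
  set.seed(13)
  mat <- matrix(rnorm(48), 6, 8)
  mat[2, ] <- mat[1, ] + rnorm(8, sd = 1e-4)  # A and B near-copies
  ds <- make_ds(mat)
  mr <- mutual_rank(list(ds), "G01", "G02")
  expect_equal(mr$mr, 1.0)
})

test_that("mutual rank across two datasets is the geometric mean of both", {
  ds1 <- rand_ds(8, 8, "d1", seed = 30)
  ds2 <- rand_ds(8, 8, "d2", seed = 31)
  mr12 <- mutual_rank(list(ds1, ds2), "G01", "G02")
  m1 <- mutual_rank(list(ds1), "G01", "G02")$mr
  m2 <- mutual_rank(list(ds2), "G01", "G02")$mr
  expect_equal(mr12$mr, sqrt(m1 * m2), tolerance = 1e-12)
  expect_error(mutual_rank(list(ds1), "G01", "NOPE"), "no dataset")
})

test_that("group mutual-rank ranking recovers a planted module outright", {
  ens <- simulate_expression_ensemble(n_genes = 60, n_samples = 25,
                                      n_datasets = 3, module_size = 15,
                                      n_queries = 6, beta = 0.9, seed = 7)
  r <- group_mr_ranking(ens$datasets, ens$truth$query_genes, top_n = 60)
  planted <- setdiff(ens$truth$module_genes$genes,
                     ens$truth$query_genes$genes)
  expect_identical(sort(r$gene[seq_along(planted)]), sort(planted))
})

test_that("a single-query group reduces to that query's own MR ordering", {
  ds <- rand_ds(10, 12, seed = 17)
  q <- rownames(ds$values)[4]
  r <- group_mr_ranking(list(ds), q, top_n = 9)
  mrs <- vapply(r$gene, function(g) mutual_rank(list(ds), q, g)$mr,
                numeric(1))
  expect_equal(unname(mrs), r$aggregate_mr, tolerance = 1e-12)
  expect_false(is.unsorted(r$aggregate_mr))
  expect_error(group_mr_ranking(list(ds), "NOPE"), "no query")
})

test_that("expression TSVs round-trip through the reader and writer", {
  ds <- rand_ds(8, 5, "chipA", seed = 41)
  p <- tempfile(fileext = ".tsv")
  write_expression_tsv(ds, p)
  back <- read_expression_tsv(p, "chipA")
  expect_equal(back$values, ds$values, tolerance = 1e-9)
  expect_identical(back$dataset_id, "chipA")
})
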