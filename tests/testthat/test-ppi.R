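test_that("edge lists collapse symmetric duplicates and drop self-loops", {
  p <- edge_file(c("A\tB", "B\tA", "A\tA"))
  expect_warning(net <- read_edge_list(p), "self-loop")
  expect_equal(igraph::vcount(net), 2L)
  expect_equal(igraph::ecount(net), 1L)

  empty <- read_edge_list(edge_file(character()))
  expect_equal(igraph::vcount(empty), 0L)

  expect_error(read_edge_list(edge_file(c("A\tB", "C"))), "line 2")
})

test_that("edge-list writing round-trips node and edge sets", {
  sim <- simulate_ppi(n_nodes = 30, cluster_size = 8, p_in = 0.5, seed = 3)
  p <- tempfile(fileext = ".tsv")
  write_edge_list(sim$network, p)
  back <- read_edge_list(p)
  expect_equal(igraph::ecount(back), igraph::ecount(sim$network))
  canon <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(canon(back), canon(sim$network))
})

test_that("a star's centre as sole query pulls in the whole star", {
  net <- graph_from_pairs("HUB", "A", "HUB", "B", "HUB", "C")
  sub <- subnetwork_extract(net, "HUB")
  expect_setequal(igraph::V(sub)$name, c("HUB", "A", "B", "C"))
  expect_equal(igraph::ecount(sub), 3L)
})

test_that("edgeless queries stay as isolated nodes and are named in a warning", {
  net <- ppi_network(rbind(c("A", "B")), nodes = c("Q1", "A", "B"))
  expect_warning(sub <- subnetwork_extract(net, c("Q1", "A")), "Q1")
  expect_true("Q1" %in% igraph::V(sub)$name)
  expect_message(subnetwork_extract(net, c("A", "MISSING")), "MISSING")
})

test_that("sub-network extraction matches neighbourhood enumeration on toys", {
  for (seed in 1:5) {
    set.seed(seed)
    nodes <- LETTERS[1:10]
    edges <- t(combn(nodes, 2))[sample(45, 12), ]
    net <- ppi_network(edges, nodes = nodes)
    queries <- sample(nodes, 3)
    got <- suppressWarnings(suppressMessages(
      subnetwork_extract(net, queries)))
    expect_setequal(igraph::V(got)$name,
                    oracle_subnet_nodes(edges, nodes, queries))
  }
})

test_that("degree profiles equal the edge-by-edge counting oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    nodes <- LETTERS[1:15]
    edges <- t(combn(nodes, 2))[sample(105, 25), ]
    net <- ppi_network(edges)
    queries <- sample(nodes, 4)
    for (v in setdiff(igraph::V(net)$name, queries)) {
      got <- degree_profile(net, queries, v)
      ora <- oracle_profile(edges, queries, v)
      expect_equal(got$k_global, ora$k_global)
      expect_equal(got$k_query, ora$k_query)
      expect_equal(got$ratio, ora$k_query / ora$k_global)
    }
  }
  expect_error(degree_profile(ppi_network(rbind(c("A", "B"))), "A", "Z"),
               "absent")
})

test_that("a node touching only queries has ratio 1; printed counts give 4/81", {
  net <- graph_from_pairs("X", "Q1", "X", "Q2", "X", "Q3")
  prof <- degree_profile(net, c("Q1", "Q2", "Q3"), "X")
  expect_equal(prof$k_global, 3L)
  expect_equal(prof$k_query, 3L)
  expect_equal(prof$ratio, 1.0)
  kiaa <- load_table3_fixture()
  kiaa <- kiaa[kiaa$gene_symbol == "KIAA1377", ]
  expect_equal(kiaa$query_interactions / kiaa$total_interactions, 4 / 81)
})

test_that("query-degree totals decompose into within- and cross-query edges", {
  sim <- simulate_ppi(n_nodes = 40, cluster_size = 10, p_in = 0.6, seed = 9)
  queries <- sim$truth$query_genes$genes
  net <- sim$network
  k_query_sum <- sum(vapply(igraph::V(net)$name, function(v)
    degree_profile(net, queries, v)$k_query, numeric(1)))
  el <- igraph::as_edgelist(net)
  within <- sum(el[, 1] %in% queries & el[, 2] %in% queries)
  crossing <- sum(xor(el[, 1] %in% queries, el[, 2] %in% queries))
  expect_equal(k_query_sum, 2 * within + crossing)
})

test_that("isolated nodes give an all-zero null with exceedance 1", {
  net <- ppi_network(rbind(c("A", "B")), nodes = c("A", "B", "LONER", "C"))
  null <- random_group_null(net, "LONER", 2, n_groups = 50, seed = 1,
                            observed = 0)
  expect_true(all(null$samples == 0))
  expect_equal(null$exceedance, 1.0)
})

test_that("a complete graph forces a degenerate null handled by the sd floor", {
  nodes <- LETTERS[1:6]
  net <- ppi_network(t(combn(nodes, 2)))
  null <- random_group_null(net, "A", 2, n_groups = 30, seed = 4)
  expect_true(all(null$samples == 2))
  expect_equal(null$mean, 2)
  expect_equal(null$sd, 0)
  prof <- degree_profile(net, c("B", "C"), "A")
  sc <- s3_score(prof, null)
  expect_true(is.finite(sc$null_z))
  expect_error(random_group_null(net, "A", 10, 10), "infeasible")
})

test_that("the Monte-Carlo null mean converges to exact group enumeration", {
  set.seed(12)
  nodes <- sprintf("N%02d", 1:12)
  edges <- t(combn(nodes, 2))[sample(66, 18), ]
  net <- ppi_network(edges)
  focal <- "N01"
  universe <- setdiff(nodes, focal)
  nbr <- igraph::neighbors(net, focal)$name
  groups <- combn(universe, 3)                       # all C(11,3) groups
  exact <- apply(groups, 2, function(g) sum(g %in% nbr))
  null <- random_group_null(net, focal, 3, n_groups = 2000, seed = 8)
  se <- sd(exact) / sqrt(null$n_groups)
  expect_lt(abs(null$mean - mean(exact)), 3 * se)
})

test_that("the S3 score is zero without ratio signal and monotone in both parts", {
  mk <- function(ratio, z) {
    prof <- structure(list(node = "X", k_global = 10L,
                           k_query = as.integer(ratio * 10), ratio = ratio),
                      class = "degree_profile")
    null <- structure(list(node = "X", group_size = 3L, n_groups = 10L,
                           samples = rep(0, 10),
                           mean = prof$k_query - z, sd = 1,
                           exceedance = NA_real_, seed = NULL),
                      class = "random_group_null")
    s3_score(prof, null)$s3
  }
  expect_equal(mk(0, 5), 0)
  expect_gt(mk(0.5, 2), mk(0.25, 2))
  expect_gt(mk(0.5, 3), mk(0.5, 2))
  expect_equal(mk(0.5, -2), 0)   # clipped below at zero excess
  prof <- structure(list(node = "X", k_global = 1L, k_query = 1L, ratio = 1),
                    class = "degree_profile")
  null <- structure(list(node = "Y", mean = 0, sd = 1),
                    class = "random_group_null")
  expect_error(s3_score(prof, null), "match")
})

test_that("interactor ranking puts an all-query hub first and is reproducible", {
  net <- graph_from_pairs("X", "Q1", "X", "Q2", "X", "Q3",
                          "Y", "Q1", "Y", "A", "Y", "B", "A", "B")
  r1 <- rank_interactors(net, c("Q1", "Q2", "Q3"), n_groups = 200, seed = 2)
  expect_equal(r1$gene[1], "X")
  expect_identical(names(r1), c("ranking", "gene", "total_interactions",
                                "query_interactions", "ratio", "null_z",
                                "s3"))
  r2 <- rank_interactors(net, c("Q1", "Q2", "Q3"), n_groups = 200, seed = 2)
  expect_identical(r1, r2)
  # only nodes touching the query group are scored
  expect_false(any(c("A", "B") %in% r1$gene))
  expect_true(all(r1$query_interactions >= 1L))
})

test_that("deterministic score components are invariant under relabeling", {
  sim <- simulate_ppi(n_nodes = 25, cluster_size = 8, p_in = 0.7, seed = 14)
  net <- sim$network
  queries <- sim$truth$query_genes$genes
  map <- setNames(sprintf("Z%02d", seq_len(igraph::vcount(net))),
                  igraph::V(net)$name)
  net2 <- net
  igraph::V(net2)$name <- unname(map[igraph::V(net)$name])
  r1 <- rank_interactors(net, queries, n_groups = 100, seed = 6)
  r2 <- rank_interactors(net2, unname(map[queries]), n_groups = 100, seed = 6)
  m1 <- r1[order(map[r1$gene]), c("total_interactions", "query_interactions",
                                  "ratio")]
  m2 <- r2[order(r2$gene), c("total_interactions", "query_interactions",
                             "ratio")]
  expect_equal(unname(as.matrix(m1)), unname(as.matrix(m2)))
})
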