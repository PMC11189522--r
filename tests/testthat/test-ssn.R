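# build an ssn object directly from an edge list (bypasses alignment so the
# graph-analysis logic can be tested on exact toy topologies)
toy_ssn <- function(nodes, from = character(), to = character(),
                    identity = rep(0.5, length(from))) {
  structure(
    list(nodes = nodes,
         edges = tibble::tibble(from = from, to = to, identity = identity),
         identity_threshold = 0.4,
         align = align_params(mode = "global")),
    class = "ssn"
  )
}

test_that("find_clusters enumerates components, ranks them and finds singletons", {
  g <- toy_ssn(as.character(1:7), from = c("1", "2", "4"),
               to = c("2", "3", "5"))
  p <- find_clusters(g)
  expect_equal(nrow(p$clusters), 2)
  expect_equal(p$clusters$members[[1]], c("1", "2", "3"))
  expect_equal(p$clusters$members[[2]], c("4", "5"))
  expect_equal(p$singletons, c("6", "7"))
  # partition property
  expect_setequal(c(unlist(p$clusters$members), p$singletons), g$nodes)
  expect_equal(tidy(p)$cluster_id[match(c("3", "6"), tidy(p)$id)],
               c(1L, NA_integer_))
})

test_that("convergence ratio is edges over possible edges", {
  k4 <- t(combn(paste0("n", 1:4), 2))
  p <- find_clusters(toy_ssn(paste0("n", 1:4), k4[, 1], k4[, 2],
                             rep(0.9, 6)))
  expect_equal(p$clusters$convergence_ratio, 1)

  path3 <- toy_ssn(c("a", "b", "c"), c("a", "b"), c("b", "c"))
  p <- find_clusters(path3)
  expect_equal(p$clusters$convergence_ratio, 2 / 3)
  expect_equal(convergence_ratio(p, 1), 2 / 3)
  expect_error(convergence_ratio(p, 99), "no cluster")
})

test_that("equal-size clusters are ranked by smallest member id", {
  g <- toy_ssn(c("z1", "z2", "a1", "a2"), from = c("z1", "a1"),
               to = c("z2", "a2"))
  p <- find_clusters(g)
  expect_equal(p$clusters$members[[1]], c("a1", "a2"))
  expect_equal(p$clusters$members[[2]], c("z1", "z2"))
})

test_that("cluster ids are stable under node-order permutation", {
  co <- generate_families(3, 4, length = 60, p_sub = 0.05, seed = 31)
  net1 <- build_ssn(co)
  set.seed(1)
  net2 <- build_ssn(co[sample(nrow(co)), ])
  p1 <- find_clusters(net1)
  p2 <- find_clusters(net2)
  expect_equal(p1$clusters$members, p2$clusters$members)
})

test_that("top_k_labels restricts labels to the k largest clusters", {
  g <- toy_ssn(as.character(1:12),
               from = c("1", "1", "1", "1", "6", "6", "9"),
               to = c("2", "3", "4", "5", "7", "8", "10"))
  p <- find_clusters(g)  # sizes 5, 3, 2 + singletons 11, 12
  lab <- top_k_labels(p, 2)
  expect_equal(nrow(lab), 8)
  expect_setequal(unique(lab$cluster_id), 1:2)
  # k beyond the number of clusters labels all cluster members, never
  # singletons
  lab_all <- top_k_labels(p, 99)
  expect_equal(nrow(lab_all), 10)
  expect_false(any(c("11", "12") %in% lab_all$id))
})

test_that("with at least 45 clusters the k = 45 label alphabet is exactly 1..45", {
  nodes <- paste0(rep(sprintf("c%02d", 1:60), each = 2), "_", 1:2)
  from <- nodes[seq(1, 120, 2)]
  to <- nodes[seq(2, 120, 2)]
  p <- find_clusters(toy_ssn(nodes, from, to, rep(0.5, 60)))
  lab <- top_k_labels(p, 45)
  expect_equal(sort(unique(lab$cluster_id)), 1:45)
  expect_equal(nrow(lab), 90)
})

test_that("build_ssn thresholds all-vs-all identities", {
  s <- seq_tbl(c("a", "b"), rep("ACDEFGHIKLMNPQRSTVWY", 2))
  expect_message(net <- build_ssn(s), "duplicate")
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$identity, 1)

  set.seed(17)
  a <- random_protein(50); b <- random_protein(50)
  net <- build_ssn(seq_tbl(c("a", "b"), c(a, b)), identity_threshold = 0.4)
  expect_equal(nrow(net$edges), 0)
  r <- align_identity(a, b, align_params(mode = "global"))
  expect_true(oracle_consistent(r, a, b, "global"))
  expect_lt(r$identity, 0.4)

  expect_error(build_ssn(s[0, ]), "at least one")
})

test_that("build_ssn recovers synthetic families as exactly the intra-family edges", {
  co <- generate_families(3, 5, length = 120, p_sub = 0.15, seed = 23)
  net <- build_ssn(co)
  fam <- co$family[match(net$edges$from, co$id)]
  fam2 <- co$family[match(net$edges$to, co$id)]
  expect_true(all(fam == fam2))  # no inter-family edge
  expect_equal(nrow(net$edges), 3 * choose(5, 2))  # every intra-family pair
})

test_that("graph export round-trips through GraphML and writes edge TSVs", {
  g <- toy_ssn(c("a", "b", "c", "d"), c("a", "b"), c("b", "c"),
               c(0.5, 0.8123456))
  p <- find_clusters(g)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, p, path, format = "graphml")
  back <- igraph::read_graph(path, format = "graphml")
  expect_setequal(igraph::V(back)$name, g$nodes)
  expect_equal(igraph::ecount(back), 2)
  expect_equal(sort(igraph::E(back)$identity), c(0.5, 0.8123456))
  memb <- igraph::V(back)$cluster
  expect_equal(memb[igraph::V(back)$name == "d"], "singleton")
  expect_equal(memb[igraph::V(back)$name == "a"], "1")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_graph(g, p, tsv, format = "edge-tsv")
  rows <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(rows), 2)
  expect_equal(rows$identity[2], 0.812346)  # 6 decimal places

  # empty-edge graph exports nodes only
  g0 <- toy_ssn(c("x", "y"))
  export_graph(g0, find_clusters(g0), path, format = "graphml")
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), 2)
  expect_equal(igraph::ecount(back), 0)
})
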