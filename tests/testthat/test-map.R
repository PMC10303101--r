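test_that("the 3-node tree picks the two shortest edges", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 0.1
  d["A", "C"] <- d["C", "A"] <- 0.5
  d["B", "C"] <- d["C", "B"] <- 0.2
  map <- semantic_map(d)
  expect_equal(nrow(map$edges), 2)
  expect_setequal(paste(map$edges$from, map$edges$to), c("A B", "B C"))
  # exhaustive enumeration of all three spanning trees agrees
  expect_equal(sum(map$edges$distance), mst_bruteforce_total(d))
})

test_that("the map is always a spanning tree", {
  set.seed(7)
  for (n in c(2, 3, 5, 10, 25, 60)) {
    d <- matrix(runif(n * n), n, n); d <- (d + t(d)) / 2; diag(d) <- 0
    map <- semantic_map(d, labels = sprintf("v%02d", seq_len(n)))
    expect_equal(nrow(map$edges), n - 1)
    g <- igraph::graph_from_data_frame(map$edges[, 1:2], directed = FALSE,
                                       vertices = map$nodes)
    expect_true(igraph::is_connected(g))
    expect_equal(igraph::gsize(g), n - 1) # acyclic given connected + n-1 edges
  }
})

test_that("tree total distance matches brute force and igraph on small instances", {
  set.seed(8)
  for (trial in 1:50) {
    n <- sample(3:6, 1)
    d <- random_distance_matrix(n)
    map <- semantic_map(d)
    total <- sum(map$edges$distance)
    expect_equal(total, mst_bruteforce_total(d), tolerance = 1e-12)
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(total, sum(igraph::E(igraph::mst(g))$weight),
                 tolerance = 1e-12)
  }
})

test_that("equal distances resolve to the lexicographically first tree", {
  d <- matrix(0.5, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  map <- semantic_map(d)
  expect_equal(paste(map$edges$from, map$edges$to), c("A B", "A C", "A D"))
  # deterministic: same result on repeat
  expect_identical(map$edges, semantic_map(d)$edges)
})

test_that("hub statistics identify the most connected node", {
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 0.1
  d["A", "C"] <- d["C", "A"] <- 0.2
  d["A", "D"] <- d["D", "A"] <- 0.3
  map <- semantic_map(d)
  expect_equal(map$central_node, "A")
  expect_equal(map$hub_scores$degree[map$hub_scores$node == "A"], 3L)
  expect_equal(map$hub_scores$summed_strength[map$hub_scores$node == "A"],
               (1 - 0.1) + (1 - 0.2) + (1 - 0.3))
})

test_that("map exports round-trip and are well-formed", {
  set.seed(9)
  d <- random_distance_matrix(6)
  map <- semantic_map(d)

  gml <- tempfile(fileext = ".graphml")
  export_map(map, gml, "graphml")
  back <- import_map_graphml(gml)
  expect_setequal(back$nodes, map$nodes)
  key <- function(m) m$edges[order(m$edges$from, m$edges$to), ]
  expect_equal(key(back)$strength, key(map)$strength, tolerance = 1e-9)
  expect_equal(back$central_node, map$central_node)

  dot <- tempfile(fileext = ".dot")
  export_map(map, dot, "dot")
  lines <- readLines(dot)
  expect_true(grepl("^graph", lines[1]))
  # strength labels are printed to 2 decimals
  expect_true(all(grepl('label="\\d\\.\\d{2}"', grep("--", lines, value = TRUE))))
  # DOT output parses with a standard graph tool
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 6)

  csv <- tempfile(fileext = ".csv")
  export_map(map, csv, "csv")
  back_csv <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(back_csv), nrow(map$edges))

  expect_error(export_map(map, tempfile(), "svg"),
               class = "autocmap_invalid_argument")
})

test_that("degenerate distance inputs are rejected", {
  expect_error(semantic_map(matrix(1, 2, 3)),
               class = "autocmap_invalid_argument")
  d <- matrix(c(0, 1, 2, 0), 2)
  expect_error(semantic_map(d), class = "autocmap_invalid_argument")
})

test_that("planted factor structure shapes the recovered tree", {
  ps <- planted_spec(per_factor = 5, loading = 0.7)
  co <- simulate_cohort(ps, n = 2000, seed = 17)
  enc <- encode_cohort(co, variables = names(ps$factor_of))
  map <- semantic_map(strengths_to_distances(link_strengths(train_autocm(enc))))
  fac <- ps$factor_of
  same_frac <- mean(fac[map$edges$from] == fac[map$edges$to])
  # permutation baseline: relabel nodes at random, keep the tree fixed
  set.seed(18)
  null_frac <- replicate(200, {
    pf <- setNames(sample(fac), names(fac))
    mean(pf[map$edges$from] == pf[map$edges$to])
  })
  expect_gt(same_frac, mean(null_frac))
})
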