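two_node_strengths <- function(s) {
  m <- matrix(c(1, s, s, 1), 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  as_strengths(m)
}

test_that("zero coupling leaves the system inert at rest", {
  s <- as_strengths(diag(3) * 1)
  dimnames(s) <- list(c("A", "B", "C"), c("A", "B", "C"))
  res <- run_acs(s, acs_params("A", max_iterations = 100))
  expect_true(res$converged)
  expect_equal(unname(res$steady_state[c("B", "C")]), c(0.5, 0.5))
  expect_equal(unname(res$steady_state["A"]), 1)
  # all non-responders
  expect_false(any(res$activation_order$responder))
})

test_that("the 2-node steady state matches the closed-form fixed point", {
  # fixed point of a' = a + g(s(1 - a) - lambda(a - r)):
  # a* = (s + lambda r) / (s + lambda)
  for (s in c(0.25, 0.6, 1.0)) {
    prm <- acs_params("X", steady_tolerance = 1e-9, max_iterations = 20000)
    res <- run_acs(two_node_strengths(s), prm)
    a_star <- (s + prm$competition * prm$rest_value) / (s + prm$competition)
    expect_true(res$converged)
    expect_equal(unname(res$steady_state["Y"]), a_star, tolerance = 1e-6)
    expect_gt(res$steady_state["Y"], prm$rest_value)
  }
})

test_that("stronger coupling never lowers the partner's steady state", {
  couplings <- seq(0.1, 1, by = 0.1)
  steady <- vapply(couplings, function(s) {
    res <- run_acs(two_node_strengths(s),
                   acs_params("X", steady_tolerance = 1e-9,
                              max_iterations = 20000))
    unname(res$steady_state["Y"])
  }, numeric(1))
  expect_true(all(diff(steady) >= -1e-9))
})

test_that("activations stay in [0,1] and the clamped node constant", {
  set.seed(12)
  for (trial in 1:10) {
    n <- sample(3:12, 1)
    s <- matrix(runif(n * n), n, n); s <- (s + t(s)) / 2; diag(s) <- 1
    dimnames(s) <- list(paste0("v", 1:n), paste0("v", 1:n))
    res <- run_acs(as_strengths(s), acs_params("v1", max_iterations = 2000))
    expect_true(all(res$trajectories >= 0 & res$trajectories <= 1))
    expect_true(all(res$trajectories[, "v1"] == 1))
    expect_true(res$converged)
  }
})

test_that("relabeling variables permutes trajectories identically", {
  set.seed(13)
  n <- 6
  s <- matrix(runif(n * n), n, n); s <- (s + t(s)) / 2; diag(s) <- 1
  labels <- paste0("v", 1:n)
  dimnames(s) <- list(labels, labels)
  res <- run_acs(as_strengths(s), acs_params("v3", max_iterations = 500))

  perm <- c(4, 2, 6, 1, 3, 5)
  s2 <- s[perm, perm]
  res2 <- run_acs(as_strengths(s2), acs_params("v3", max_iterations = 500))
  expect_equal(res2$trajectories[, labels[perm]],
               res$trajectories[, labels[perm]])
  expect_equal(res2$steady_state[labels], res$steady_state[labels])
})

test_that("the activation hierarchy orders by first passage then intensity", {
  # chain X - Y - Z: Y responds before Z
  s <- matrix(0, 3, 3, dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  diag(s) <- 1
  s["X", "Y"] <- s["Y", "X"] <- 0.9
  s["Y", "Z"] <- s["Z", "Y"] <- 0.9
  res <- run_acs(as_strengths(s), acs_params("X", steady_tolerance = 1e-8,
                                             max_iterations = 10000))
  h <- res$activation_order
  expect_equal(nrow(h), 2)
  expect_equal(h$variable[1], "Y")
  expect_true(h$first_passage[1] <= h$first_passage[2])

  # the coupled partner ranks first in the 2-node system
  res2 <- run_acs(two_node_strengths(0.8), acs_params("X"))
  expect_equal(res2$activation_order$variable[1], "Y")
  expect_equal(nrow(res2$activation_order), 1)
})

test_that("variable subsets prune the dynamics (mineral pruning)", {
  set.seed(14)
  n <- 5
  s <- matrix(runif(n * n), n, n); s <- (s + t(s)) / 2; diag(s) <- 1
  labels <- c("fli", "ti", "Pb", "Hg", "framingham")
  dimnames(s) <- list(labels, labels)
  res <- run_acs(as_strengths(s),
                 acs_params("framingham",
                            variable_subset = c("framingham", "fli", "ti")))
  expect_setequal(res$labels, c("framingham", "fli", "ti"))
  expect_error(
    run_acs(as_strengths(s), acs_params("nope")),
    class = "autocmap_schema_error")
  expect_error(
    acs_params("framingham", variable_subset = c("fli", "ti")),
    class = "autocmap_invalid_argument")
})

test_that("ACS exports round-trip trajectories and hierarchy", {
  res <- run_acs(two_node_strengths(0.7), acs_params("X"))

  csv <- tempfile(fileext = ".csv")
  export_acs(res, csv, "csv")
  tab <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(tab), nrow(res$trajectories))
  expect_equal(ncol(tab), 3) # iteration + 2 variables
  expect_true(all(tab$X == 1)) # clamped column constant

  js <- tempfile(fileext = ".json")
  export_acs(res, js, "json")
  back <- jsonlite::fromJSON(js)
  expect_equal(back$variable, res$activation_order$variable)
  expect_equal(back$first_passage, res$activation_order$first_passage)
  expect_equal(back$steady_intensity, res$activation_order$steady_intensity,
               tolerance = 1e-12)

  expect_error(export_acs(res, tempfile(), "xml"),
               class = "autocmap_invalid_argument")
})
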