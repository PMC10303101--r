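# Shared fixtures and independent oracles used across the suite.

# small planted two-factor spec: `per_factor` Gaussian variables per factor,
# built entirely from the package's public spec constructors
planted_spec <- function(per_factor = 5, loading = 0.7) {
  vars_a <- paste0("a", seq_len(per_factor))
  vars_b <- paste0("b", seq_len(per_factor))
  marginals <- marginal_spec(tibble::tibble(
    name = c(vars_a, vars_b), label = c(vars_a, vars_b), unit = "au",
    family = "truncated_gaussian", mean = 50, sd = 10, min = 0, max = 100,
    median = 50, role = "clinical"))
  structure_tbl <- tibble::tibble(
    variable = c(vars_a, vars_b),
    factor = rep(c("f1", "f2"), each = per_factor),
    loading = loading)
  list(marginals = marginals, structure = latent_structure(structure_tbl),
       n = 200,
       factor_of = setNames(rep(c("f1", "f2"), each = per_factor),
                            c(vars_a, vars_b)))
}

# a tiny deterministic encoded matrix with one duplicated pair and noise
tiny_encoded <- function(n = 40, seed = 42) {
  set.seed(seed)
  a <- rbinom(n, 1, 0.5)
  cbind(A = a, B = a, C = rbinom(n, 1, 0.5), D = rbinom(n, 1, 0.5))
}

# R-level reference implementation of the Auto-CM training loop, kept
# independent of the compiled path (used to cross-check it on tiny fixtures)
autocm_train_ref <- function(X, C, lr, max_epochs, tol, init) {
  N <- ncol(X)
  v <- rep(init, N)
  w <- matrix(init, N, N)
  trace <- numeric(0)
  converged <- FALSE
  for (epoch in seq_len(max_epochs)) {
    delta <- 0
    for (r in seq_len(nrow(X))) {
      ms <- X[r, ]
      ci <- 1 - v / C
      mh <- ms * ci
      dv <- lr * (ms - mh) * ci
      v <- v + dv
      net <- as.numeric((1 - w / C) %*% mh)
      mt <- mh * (1 - net / C)
      dw <- lr * (mh - mt) * t(t(1 - w / C) * mh) # dw_ij = lr (mh_i - mt_i)(1-w_ij/C) mh_j
      w <- w + dw
      delta <- delta + sum(abs(dv)) + sum(abs(dw))
    }
    trace <- c(trace, delta / (nrow(X) * (N + N^2)))
    if (trace[epoch] < tol) { converged <- TRUE; break }
  }
  list(v = v, w = w, trace = trace, converged = converged)
}

# exhaustive minimum-spanning-tree oracle: enumerate every edge subset of
# size N-1 and keep the connected acyclic ones. Returns the minimum total.
mst_bruteforce_total <- function(d) {
  n <- nrow(d)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  m <- nrow(idx)
  combos <- utils::combn(m, n - 1)
  best <- Inf
  for (k in seq_len(ncol(combos))) {
    sel <- combos[, k]
    # connectivity check by union-find
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    acyclic <- TRUE
    for (e in sel) {
      ri <- find(idx[e, 1]); rj <- find(idx[e, 2])
      if (ri == rj) { acyclic <- FALSE; break }
      parent[ri] <- rj
    }
    if (!acyclic) next
    best <- min(best, sum(d[idx[sel, , drop = FALSE]]))
  }
  best
}

# random symmetric distance matrix with labels
random_distance_matrix <- function(n) {
  d <- matrix(runif(n * n), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  d
}

# strength matrix wrapper for hand-built matrices
as_strengths <- function(s) {
  structure(s, class = c("link_strength_matrix", class(s)))
}
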