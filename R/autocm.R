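#' Auto-CM training parameters
#'
#' @param contraction Contraction parameter `C` (> 1). Default `NULL` sets
#'   `C = N`, the number of variables, which guarantees every contraction
#'   factor `(1 - net/C)` stays non-negative.
#' @param learning_rate Positive step size of the weight adaptation.
#' @param max_epochs Maximum passes over the dataset.
#' @param tolerance Convergence threshold on the mean absolute weight change
#'   per epoch (must be in `(0, 1)`).
#' @param init_weight Common small positive initial value of all weights
#'   (default 0.01). All units start identically; the trained structure comes
#'   entirely from the data, and training is fully deterministic.
#' @param seed Integer recorded with the model (training itself is
#'   deterministic: fixed record order, no random initialisation).
#' @return A list of class `autocm_params`.
#' @export
autocm_params <- function(contraction = NULL, learning_rate = 0.1,
                          max_epochs = 2000, tolerance = 1e-6,
                          init_weight = 0.01, seed = 1L) {
  if (!is.null(contraction) && (!is.finite(contraction) || contraction <= 1)) {
    abort_autocmap("`contraction` must be > 1.", "autocmap_invalid_argument")
  }
  if (learning_rate <= 0 || max_epochs < 1 || tolerance <= 0 || tolerance >= 1) {
    abort_autocmap("Invalid Auto-CM parameters: need learning_rate > 0, max_epochs >= 1, 0 < tolerance < 1.",
                   "autocmap_invalid_argument")
  }
  structure(list(contraction = contraction, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), tolerance = tolerance,
                 init_weight = init_weight, seed = as.integer(seed)),
            class = "autocm_params")
}

#' Train an Auto-Contractive Map
#'
#' Trains the three-layer contractive network on an encoded `[0, 1]` matrix
#' (subjects x variables). Each record is contracted into a hidden layer by
#' the weight vector `v` (factor `1 - v/C`) and into the output layer through
#' the weight matrix `w`; both weight sets adapt monotonically toward the
#' contraction parameter `C`. Training stops when the mean absolute weight
#' change per epoch falls below `tolerance` or after `max_epochs`. Records are
#' presented in fixed dataset order, so training is exactly reproducible.
#'
#' @param x Numeric matrix with values in `[0, 1]`, >= 2 rows and >= 2
#'   columns; typically an [encode_cohort()] result.
#' @param params An [autocm_params()] object.
#' @return An object of class `autocm_model`: `v` (input-hidden weights), `w`
#'   (hidden-output weight matrix), `contraction`, `epochs_run`, `converged`,
#'   `training_trace` (per-epoch mean absolute weight change), `labels`.
#' @examples
#' x <- cbind(a = c(0, 1, 0, 1), b = c(0, 1, 0, 1), c = c(1, 0, 0, 1))
#' m <- train_autocm(x, autocm_params(max_epochs = 200, tolerance = 1e-4))
#' glance(m)
#' @export
train_autocm <- function(x, params = autocm_params()) {
  x <- as.matrix(unclass(x))
  if (!is.numeric(x) || nrow(x) < 2 || ncol(x) < 2) {
    abort_autocmap("`x` must be a numeric matrix with >= 2 rows and >= 2 columns.",
                   "autocmap_invalid_argument")
  }
  if (any(!is.finite(x)) || any(x < 0 | x > 1)) {
    abort_autocmap("All values must lie in [0, 1].", "autocmap_invalid_argument")
  }
  n_vars <- ncol(x)
  C <- params$contraction %||% n_vars
  init <- params$init_weight %||% 0.01
  fit <- autocm_train_cpp(x, C, params$learning_rate, params$max_epochs,
                          params$tolerance, init)
  labels <- colnames(x) %||% paste0("V", seq_len(n_vars))
  dimnames(fit$w) <- list(labels, labels)
  structure(list(v = setNames(as.numeric(fit$v), labels), w = fit$w,
                 contraction = C, params = params,
                 epochs_run = fit$epochs_run, converged = fit$converged,
                 training_trace = fit$training_trace, labels = labels,
                 n_records = nrow(x)),
            class = "autocm_model")
}

#' @export
print.autocm_model <- function(x, ...) {
  cat("<autocm_model> ", length(x$labels), " variables, ", x$n_records,
      " records\n", "  C = ", signif(x$contraction, 4), ", epochs = ",
      x$epochs_run, ", converged = ", x$converged, "\n", sep = "")
  invisible(x)
}

#' @rdname train_autocm
#' @param x,object An `autocm_model`.
#' @param ... Unused.
#' @export
glance.autocm_model <- function(x, ...) {
  tibble::tibble(n_variables = length(x$labels), n_records = x$n_records,
                 contraction = x$contraction, epochs_run = x$epochs_run,
                 converged = x$converged,
                 final_delta = x$training_trace[length(x$training_trace)])
}

#' @rdname train_autocm
#' @export
tidy.autocm_model <- function(x, ...) {
  tidy(link_strengths(x))
}

#' Link strengths from a trained Auto-CM
#'
#' Converts the trained hidden-output weight matrix into the symmetric
#' link-strength matrix in `[0, 1]`: the (possibly asymmetric) trained `w` is
#' symmetrised by the arithmetic mean, divided by its global maximum, and the
#' diagonal set to 1. The normalisation is invariant to rescaling `w`.
#'
#' @param model A trained [train_autocm()] model, or a raw weight matrix.
#' @return A symmetric matrix of class `link_strength_matrix` with entries in
#'   `[0, 1]` and unit diagonal.
#' @export
link_strengths <- function(model) {
  w <- if (inherits(model, "autocm_model")) model$w else as.matrix(model)
  if (all(w == 0)) {
    abort_autocmap("Degenerate model: all weights are zero.",
                   "autocmap_degenerate")
  }
  s <- (w + t(w)) / 2
  s <- s / max(s)
  diag(s) <- 1
  structure(s, class = c("link_strength_matrix", class(s)))
}

#' @export
tidy.link_strength_matrix <- function(x, ...) {
  labels <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(from = labels[idx[, 1]], to = labels[idx[, 2]],
                 strength = x[idx]) |>
    dplyr::arrange(dplyr::desc(.data$strength))
}

#' Convert link strengths to distances
#'
#' `d = 1 - s`: the stronger the link, the closer the nodes. The diagonal is
#' zero.
#'
#' @param strengths A `link_strength_matrix` (entries in `[0, 1]`).
#' @return Distance matrix with zero diagonal.
#' @export
strengths_to_distances <- function(strengths) {
  s <- unclass(strengths)
  if (any(s < 0 | s > 1)) {
    abort_autocmap("Strengths must lie in [0, 1].", "autocmap_invalid_argument")
  }
  d <- 1 - s
  diag(d) <- 0
  d
}
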