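#' ACS parameters
#'
#' Controls the Activation and Competition System dynamics: one variable is
#' clamped at maximal activation, the others start at a resting level and
#' evolve under excitatory coupling through the link strengths with a
#' competitive leak back toward rest.
#'
#' @param clamp_variable Label of the variable to clamp.
#' @param clamp_value Activation at which the clamped variable is held (1).
#' @param rest_value Resting activation of all other variables (in `[0, 1]`).
#' @param step_gain Positive integration step size.
#' @param competition Positive leak rate toward rest; the competitive force a
#'   unit must overcome to stay activated.
#' @param max_iterations Iteration cap.
#' @param steady_tolerance Stop when the largest absolute activation change in
#'   an iteration falls below this (> 0).
#' @param variable_subset Optional label subset to run on (pruning); must
#'   contain `clamp_variable`.
#' @param threshold First-passage threshold used by
#'   [activation_hierarchy()]; default `rest_value + 0.1`.
#' @return A list of class `acs_params`.
#' @export
acs_params <- function(clamp_variable, clamp_value = 1.0, rest_value = 0.5,
                       step_gain = 0.1, competition = 0.5,
                       max_iterations = 5000, steady_tolerance = 1e-5,
                       variable_subset = NULL, threshold = rest_value + 0.1) {
  if (rest_value < 0 || rest_value > 1 || step_gain <= 0 ||
      steady_tolerance <= 0 || competition <= 0 || max_iterations < 1) {
    abort_autocmap("Invalid ACS parameters.", "autocmap_invalid_argument")
  }
  if (!is.null(variable_subset) && !clamp_variable %in% variable_subset) {
    abort_autocmap("`clamp_variable` must belong to `variable_subset`.",
                   "autocmap_invalid_argument")
  }
  structure(list(clamp_variable = clamp_variable, clamp_value = clamp_value,
                 rest_value = rest_value, step_gain = step_gain,
                 competition = competition,
                 max_iterations = as.integer(max_iterations),
                 steady_tolerance = steady_tolerance,
                 variable_subset = variable_subset, threshold = threshold),
            class = "acs_params")
}

#' Run the Activation and Competition System
#'
#' Clamps one variable at maximal activation and iterates the auto-associative
#' dynamics over the link-strength couplings until a steady state. Update rule
#' for each non-clamped unit `i`:
#' \deqn{a_i \leftarrow \mathrm{clip}_{[0,1]}\big(a_i + g\big[\textstyle\sum_{j \ne i}
#'   s_{ij}(a_j - a_i) - \lambda (a_i - r)\big]\big)}
#' with step gain `g`, link strengths `s`, competition rate `lambda` and rest
#' level `r`. The step gain is divided by the largest total coupling of any
#' unit, so the discrete dynamics remain contractive for dense strength
#' matrices without changing the fixed points. Excitation flows through
#' positive couplings; the `lambda` leak makes units compete: only those with
#' strong enough paths to the clamped source rise above rest. With zero
#' couplings the system is inert at rest.
#' For a 2-node system with coupling `s` the steady state of the free node is
#' `(s + lambda * r) / (s + lambda)`, strictly increasing in `s`.
#'
#' @param strengths A `link_strength_matrix` (from [link_strengths()]).
#' @param params An [acs_params()] object.
#' @return An object of class `acs_result`: `trajectories` (iterations x
#'   variables, one row per executed iteration), `steady_state`,
#'   `activation_order` (the [activation_hierarchy()] tibble), `converged`,
#'   `params`.
#' @export
run_acs <- function(strengths, params) {
  s <- as.matrix(unclass(strengths))
  labels <- rownames(s) %||% paste0("V", seq_len(ncol(s)))
  if (any(s < 0 | s > 1)) {
    abort_autocmap("Strengths must lie in [0, 1].", "autocmap_invalid_argument")
  }
  if (!is.null(params$variable_subset)) {
    missing_vs <- setdiff(params$variable_subset, labels)
    if (length(missing_vs) > 0) {
      abort_autocmap(paste0("Subset variables not found: ",
                            paste(missing_vs, collapse = ", ")),
                     "autocmap_schema_error")
    }
    keep <- labels %in% params$variable_subset
    s <- s[keep, keep, drop = FALSE]
    labels <- labels[keep]
  }
  if (!params$clamp_variable %in% labels) {
    abort_autocmap(paste0("Clamp variable not found: ", params$clamp_variable),
                   "autocmap_schema_error")
  }
  n <- length(labels)
  diag(s) <- 0
  clamp <- match(params$clamp_variable, labels)
  # competitive normalization: the step is scaled by the largest total
  # coupling so the discrete dynamics stay contractive however dense the
  # strength matrix is; fixed points are unchanged
  g <- params$step_gain / max(1, max(rowSums(s)))
  lam <- params$competition
  r <- params$rest_value

  a <- rep(r, n)
  a[clamp] <- params$clamp_value
  traj <- matrix(NA_real_, nrow = params$max_iterations, ncol = n,
                 dimnames = list(NULL, labels))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(params$max_iterations)) {
    net <- as.numeric(s %*% a) - rowSums(s) * a
    a_new <- a + g * (net - lam * (a - r))
    a_new <- pmin(pmax(a_new, 0), 1)
    a_new[clamp] <- params$clamp_value
    delta <- max(abs(a_new - a))
    a <- a_new
    traj[it, ] <- a
    if (delta < params$steady_tolerance) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("ACS did not reach steady state within ", params$max_iterations,
            " iterations.", call. = FALSE)
  }
  res <- structure(list(trajectories = traj[seq_len(it), , drop = FALSE],
                        steady_state = setNames(a, labels),
                        converged = converged, params = params,
                        labels = labels, clamp = params$clamp_variable),
                   class = "acs_result")
  res$activation_order <- activation_hierarchy(res)
  res
}

#' @export
print.acs_result <- function(x, ...) {
  cat("<acs_result> clamp: ", x$clamp, "; ", nrow(x$trajectories),
      " iterations; converged = ", x$converged, "\n", sep = "")
  print(utils::head(x$activation_order, 10))
  invisible(x)
}

#' Activation hierarchy of an ACS run
#'
#' Orders the non-clamped variables by how early they respond to the clamped
#' perturbation: ascending first-passage iteration above the threshold, ties
#' broken by descending steady-state intensity. Variables that never cross the
#' threshold are listed last as non-responders (`first_passage = NA`). The
#' ordering describes activation timing only; no causal claim is attached.
#'
#' @param result An [run_acs()] result.
#' @param threshold Activation threshold; defaults to the run's
#'   `params$threshold` (rest + 0.1).
#' @return Tibble with `variable`, `first_passage` (iteration or `NA`),
#'   `steady_intensity`, `responder`, `rank`.
#' @export
activation_hierarchy <- function(result, threshold = NULL) {
  threshold <- threshold %||% result$params$threshold
  traj <- result$trajectories
  free <- setdiff(result$labels, result$clamp)
  fp <- purrr::map_dbl(free, function(v) {
    hit <- which(traj[, v] >= threshold)
    if (length(hit) == 0) NA_real_ else hit[1]
  })
  tibble::tibble(variable = free, first_passage = fp,
                 steady_intensity = as.numeric(result$steady_state[free])) |>
    dplyr::mutate(responder = !is.na(.data$first_passage)) |>
    dplyr::arrange(!.data$responder, .data$first_passage,
                   dplyr::desc(.data$steady_intensity), .data$variable) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' @rdname run_acs
#' @param x An `acs_result`.
#' @param ... Unused.
#' @export
tidy.acs_result <- function(x, ...) {
  tibble::as_tibble(x$trajectories) |>
    dplyr::mutate(iteration = dplyr::row_number(), .before = 1) |>
    tidyr::pivot_longer(-"iteration", names_to = "variable",
                        values_to = "activation")
}

#' @rdname run_acs
#' @export
glance.acs_result <- function(x, ...) {
  tibble::tibble(clamp = x$clamp, n_variables = length(x$labels),
                 iterations = nrow(x$trajectories), converged = x$converged,
                 n_responders = sum(x$activation_order$responder))
}

#' Export an ACS result
#'
#' `"csv"` writes the trajectory table (one row per iteration, one column per
#' variable plus `iteration`); `"json"` writes the activation hierarchy.
#'
#' @param result An [run_acs()] result.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_acs <- function(result, path, format = c("csv", "json")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort_autocmap(
                       paste0("Unknown export format: ", format[1]),
                       "autocmap_invalid_argument"))
  if (format == "csv") {
    tab <- tibble::as_tibble(result$trajectories) |>
      dplyr::mutate(iteration = dplyr::row_number(), .before = 1)
    readr::write_csv(tab, path)
  } else {
    jsonlite::write_json(result$activation_order, path, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Plot ACS activation trajectories
#'
#' Activation curves against iteration, with the clamped variable highlighted
#' in red.
#'
#' @param object An [run_acs()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.acs_result <- function(object, ...) {
  dat <- tidy(object) |>
    dplyr::mutate(clamped = .data$variable == object$clamp)
  ggplot2::ggplot(dat, ggplot2::aes(.data$iteration, .data$activation,
                                    group = .data$variable,
                                    colour = .data$clamped)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"), guide = "none") +
    ggplot2::labs(x = "iteration", y = "activation") +
    ggplot2::theme_minimal()
}
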