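#' Dichotomize a variable
#'
#' Binarizes a numeric vector for the contractive-map preprocessing: 1 when a
#' value exceeds the split point, 0 otherwise. The default split is the
#' variable's median, the most balanced achievable cut (ties at the median go
#' to 0). Vectors that are already binary pass through unchanged.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @param split Numeric split point, or `"median"` (default).
#' @return Integer vector of 0/1.
#' @examples
#' dichotomize(c(1, 2, 3, 4)) # 0 0 1 1
#' @export
dichotomize <- function(values, split = "median") {
  v <- values[!is.na(values)]
  if (length(unique(v)) < 2) {
    abort_autocmap("Degenerate variable: fewer than 2 distinct values; drop it instead of encoding.",
                   "autocmap_degenerate")
  }
  if (all(v %in% c(0, 1))) return(as.integer(values))
  s <- if (identical(split, "median")) median(v) else split
  as.integer(values > s)
}

#' Min-max scale a variable to \[0, 1\]
#'
#' `(x - min) / (max - min)`; the observed minimum maps to 0 and the maximum
#' to 1, preserving ranks.
#'
#' @param values Numeric vector with `max > min`.
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_scale <- function(values) {
  v <- values[!is.na(values)]
  rng <- range(v)
  if (diff(rng) <= 0) {
    abort_autocmap("Degenerate variable: constant vector cannot be min-max scaled.",
                   "autocmap_degenerate")
  }
  (values - rng[1]) / diff(rng)
}

#' Encode a cohort for contractive-map training
#'
#' Applies per-variable encodings (dichotomic median split by default, min-max
#' optionally) and assembles the training matrix in declaration order. The
#' default variable set is the full study panel: the 25 clinical variables,
#' all 31 hair elements, the derived toxicity/MetS/obesity flags and age -- no
#' pruning, matching the hypothesis-free design of the mapping stage.
#'
#' Variables with more than `missing_tolerance` missing values are dropped
#' with a warning; remaining missing entries are imputed by the variable
#' median before encoding.
#'
#' @param cohort A `cohort_tbl`.
#' @param variables Character vector of variables to encode (default: full
#'   study panel present in `cohort`).
#' @param encodings Optional named character vector mapping variable ->
#'   `"dichotomic"` or `"minmax"`; unlisted variables use `default_mode`.
#' @param default_mode `"dichotomic"` (default) or `"minmax"`.
#' @param splits Optional named numeric vector of per-variable split overrides
#'   for dichotomization.
#' @param missing_tolerance Maximum tolerated fraction of missing values per
#'   variable (default 0.1).
#' @return A numeric matrix in `[0, 1]` (subjects x variables) of class
#'   `encoded_cohort`, with column names as variable labels and attributes
#'   `encodings` and `dropped`.
#' @export
encode_cohort <- function(cohort, variables = NULL, encodings = NULL,
                          default_mode = c("dichotomic", "minmax"),
                          splits = NULL, missing_tolerance = 0.1) {
  default_mode <- match.arg(default_mode)
  variables <- variables %||% default_map_variables(cohort)
  if (length(variables) == 0) {
    abort_autocmap("Empty variable selection.", "autocmap_invalid_argument")
  }
  absent <- setdiff(variables, names(cohort))
  if (length(absent) > 0) {
    abort_autocmap(paste0("Variables not in cohort: ",
                          paste(absent, collapse = ", ")),
                   "autocmap_schema_error")
  }
  dropped <- character(0)
  cols <- list()
  for (v in variables) {
    x <- cohort[[v]]
    frac_na <- mean(is.na(x))
    if (frac_na > missing_tolerance) {
      warning("Dropping `", v, "`: ", round(100 * frac_na), "% missing.",
              call. = FALSE)
      dropped <- c(dropped, v)
      next
    }
    if (frac_na > 0) x[is.na(x)] <- median(x, na.rm = TRUE)
    mode <- encodings[v]
    if (is.null(encodings) || is.na(mode)) mode <- default_mode
    enc <- tryCatch(
      if (mode == "minmax") minmax_scale(x)
      else dichotomize(x, split = if (!is.null(splits) && v %in% names(splits))
        splits[[v]] else "median"),
      autocmap_degenerate = function(e) {
        warning("Dropping degenerate variable `", v, "`.", call. = FALSE)
        NULL
      })
    if (is.null(enc)) { dropped <- c(dropped, v); next }
    cols[[v]] <- enc
  }
  if (length(cols) < 2) {
    abort_autocmap("Fewer than 2 encodable variables remain.",
                   "autocmap_degenerate")
  }
  m <- do.call(cbind, cols)
  rownames(m) <- cohort$subject_id
  structure(m, class = c("encoded_cohort", class(m)),
            encodings = purrr::map_chr(names(cols), function(v) {
              mo <- encodings[v]
              if (is.null(encodings) || is.na(mo)) default_mode else mo
            }),
            dropped = dropped)
}

# the full no-pruning default variable panel for the semantic map
default_map_variables <- function(cohort) {
  panel <- c(clinical_table()$name, element_schema()$symbol,
             "ti", "mets", "obesity", "age")
  intersect(panel, names(cohort))
}
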