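#' Closed-form lognormal parameters from a target mean and SD
#'
#' Inverts the analytic lognormal moment formulas: if `X ~ LN(mu, sigma)` then
#' `E[X] = exp(mu + sigma^2/2)` and `Var[X] = (exp(sigma^2) - 1) E[X]^2`.
#'
#' @param mean Target arithmetic mean (> 0).
#' @param sd Target arithmetic standard deviation (> 0).
#' @return Named list with `mu` and `sigma` (log-scale location and scale).
#' @examples
#' p <- lognormal_params_from_moments(1.29, 1.63)
#' exp(p$mu + p$sigma^2 / 2) # recovers 1.29
#' @export
lognormal_params_from_moments <- function(mean, sd) {
  if (!is.numeric(mean) || !is.numeric(sd) || length(mean) != 1L ||
      length(sd) != 1L || !is.finite(mean) || !is.finite(sd) ||
      mean <= 0 || sd <= 0) {
    abort_autocmap("`mean` and `sd` must be finite positive scalars.",
                   "autocmap_invalid_argument")
  }
  sigma2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

# ---- truncated-distribution moments (analytic) -------------------------------

# P(lo < Z < hi) for standard normal, computed in whichever tail avoids
# catastrophic cancellation of pnorm values near 1
pnorm_diff <- function(lo, hi) {
  if (lo > 0) pnorm(lo, lower.tail = FALSE) - pnorm(hi, lower.tail = FALSE)
  else pnorm(hi) - pnorm(lo)
}

# mean/sd of a normal(m, s) truncated to [a, b]
truncnorm_moments <- function(m, s, a, b) {
  alpha <- (a - m) / s
  beta <- (b - m) / s
  if (alpha > 36) return(list(mean = a, sd = 0))   # all mass below a
  if (beta < -36) return(list(mean = b, sd = 0))   # all mass above b
  Z <- pnorm_diff(alpha, beta)
  if (Z < 1e-300) return(list(mean = (a + b) / 2, sd = 0))
  dphi <- stats::dnorm(alpha) - stats::dnorm(beta)
  mu_t <- m + s * dphi / Z
  v <- s^2 * (1 + (alpha * stats::dnorm(alpha) - beta * stats::dnorm(beta)) / Z -
                (dphi / Z)^2)
  list(mean = mu_t, sd = sqrt(max(v, 0)))
}

# mean/sd of LN(mu, sigma) truncated to [a, b]; a may be 0
trunclnorm_moments <- function(mu, sigma, a, b) {
  la <- if (a > 0) (log(a) - mu) / sigma else -Inf
  lb <- (log(b) - mu) / sigma
  if (la > 36) return(list(mean = a, sd = 0))
  if (lb < -36) return(list(mean = b, sd = 0))
  Z <- pnorm_diff(la, lb)
  if (Z < 1e-300) return(list(mean = (max(a, 0) + b) / 2, sd = 0))
  m1 <- exp(mu + sigma^2 / 2) * pnorm_diff(la - sigma, lb - sigma) / Z
  m2 <- exp(2 * mu + 2 * sigma^2) * pnorm_diff(la - 2 * sigma, lb - 2 * sigma) / Z
  list(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# Calibrate (location, scale) so the TRUNCATED distribution on [lower, upper]
# has the requested mean and (as nearly as possible) the requested sd. The
# location is solved exactly for the mean by root finding at each candidate
# scale; the scale is then chosen to minimise the sd mismatch. Printed summary
# statistics that sit on (or outside) the attainable range are nudged just
# inside it.
calibrate_truncated <- function(family, mean, sd, lower, upper) {
  stopifnot(family %in% c("truncated_gaussian", "lognormal"))
  eps <- 1e-3 * (upper - lower)
  target <- min(max(mean, lower + eps), upper - eps)

  moments <- function(loc, scl) {
    if (family == "lognormal") trunclnorm_moments(loc, scl, max(lower, 0), upper)
    else truncnorm_moments(loc, scl, lower, upper)
  }
  solve_loc <- function(scl) {
    f <- function(loc) moments(loc, scl)$mean - target
    lo <- if (family == "lognormal") log(target) - 1 else target - scl
    hi <- if (family == "lognormal") log(target) + 1 else target + scl
    for (i in 1:60) { if (f(lo) < 0) break; lo <- lo - 1 }
    for (i in 1:60) { if (f(hi) > 0) break; hi <- hi + 1 }
    if (f(lo) > 0 || f(hi) < 0) return(NA_real_)
    uniroot(f, c(lo, hi), tol = 1e-10)$root
  }
  sd_gap <- function(log_scl) {
    scl <- exp(log_scl)
    loc <- solve_loc(scl)
    if (is.na(loc)) return(1e6)
    (moments(loc, scl)$sd - sd)^2 / sd^2
  }
  # search bracket for the scale parameter
  br <- if (family == "lognormal") log(c(1e-3, 6)) else log(c(sd / 50, sd * 50))
  opt <- optimize(sd_gap, br, tol = 1e-8)
  scl <- exp(opt$minimum)
  loc <- solve_loc(scl)
  if (is.na(loc)) { # degenerate: fall back to the untruncated fit
    if (family == "lognormal") {
      p <- lognormal_params_from_moments(mean, sd)
      loc <- p$mu; scl <- p$sigma
    } else {
      loc <- mean; scl <- sd
    }
  }
  list(location = loc, scale = scl)
}

#' Build a marginal specification table
#'
#' Validates and calibrates a table of per-variable marginal distributions.
#' Families: `truncated_gaussian` and `lognormal` are calibrated so that the
#' distribution truncated to `[min, max]` reproduces the stated mean (exactly,
#' by root finding on the location parameter) and SD (least-squares in the
#' scale parameter); `bernoulli` uses `mean` as the success probability;
#' `derived` rows carry documentation only and are computed, not sampled.
#'
#' @param specs Tibble with columns `name`, `label`, `unit`, `family`, `mean`,
#'   `sd`, `min`, `max`, `median`, `role`.
#' @return The input tibble with calibrated `location` and `scale` columns.
#' @export
marginal_spec <- function(specs) {
  req <- c("name", "label", "unit", "family", "mean", "sd", "min", "max", "role")
  missing_cols <- setdiff(req, names(specs))
  if (length(missing_cols) > 0) {
    abort_autocmap(paste0("Marginal spec missing columns: ",
                          paste(missing_cols, collapse = ", ")),
                   "autocmap_schema_error")
  }
  sampled <- specs$family %in% c("truncated_gaussian", "lognormal")
  bad_sd <- sampled & (!is.finite(specs$sd) | specs$sd <= 0)
  bad_bounds <- sampled & (specs$min >= specs$max)
  bad_ln <- specs$family == "lognormal" & specs$mean <= 0
  if (any(bad_sd) || any(bad_bounds) || any(bad_ln)) {
    abort_autocmap(
      paste0("Invalid marginal spec for: ",
             paste(specs$name[bad_sd | bad_bounds | bad_ln], collapse = ", "),
             " (need sd > 0, min < max, and mean > 0 for lognormal)."),
      "autocmap_invalid_argument")
  }
  cal <- purrr::pmap(specs, function(family, mean, sd, min, max, ...) {
    if (family %in% c("truncated_gaussian", "lognormal")) {
      calibrate_truncated(family, mean, sd, min, max)
    } else {
      list(location = NA_real_, scale = NA_real_)
    }
  })
  specs$location <- purrr::map_dbl(cal, "location")
  specs$scale <- purrr::map_dbl(cal, "scale")
  specs
}

#' Latent factor structure for the synthetic cohort
#'
#' Correlation is induced through shared standard-normal factors on the
#' (latent) z-scale of every variable: `z = sum(loading_k * f_k) + noise`,
#' standardised to unit variance so the calibrated marginals are preserved
#' exactly regardless of the loadings.
#'
#' @param loadings Tibble with columns `variable`, `factor`, `loading`
#'   (each loading in `[-1, 1]`; per-variable sum of squared loadings <= 1).
#' @param noise_sd Relative scale of the idiosyncratic noise (> 0; `1` keeps
#'   the loadings' share of variance exactly as declared).
#' @return An object of class `latent_structure`.
#' @export
latent_structure <- function(loadings, noise_sd = 1) {
  stopifnot(is.data.frame(loadings),
            all(c("variable", "factor", "loading") %in% names(loadings)))
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    abort_autocmap("`noise_sd` must be > 0.", "autocmap_invalid_argument")
  }
  if (any(abs(loadings$loading) > 1)) {
    abort_autocmap("Loadings must lie in [-1, 1].", "autocmap_invalid_argument")
  }
  tot <- loadings |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(v = sum(.data$loading^2), .groups = "drop")
  if (any(tot$v > 1 + 1e-12)) {
    abort_autocmap(
      paste0("Total loading variance exceeds 1 for: ",
             paste(tot$variable[tot$v > 1], collapse = ", ")),
      "autocmap_invalid_argument")
  }
  structure(list(factor_names = unique(loadings$factor),
                 loadings = tibble::as_tibble(loadings),
                 noise_sd = noise_sd),
            class = "latent_structure")
}

#' Default study specification
#'
#' Marginals for the emulated 95-subject overweight-obesity cohort: the 25
#' clinical variables (21 sampled primitives plus 4 derived indices), the 31
#' hair elements (lognormal, calibrated by moments to the published summary
#' statistics and truncated at the observed minima/maxima), and auxiliary
#' variables (age, sex, HDL, GGT, smoking, BP treatment) required by the index
#' formulas. The default latent structure ties the metabolic-syndrome cluster
#' (WC, BMI, TG, insulin, glycaemia, HbA1c, fibrinogen, uric acid) to one
#' factor and the 13 toxic elements to an exposure factor.
#'
#' @param n Default cohort size (95, the emulated study).
#' @param metabolic_loading,exposure_loading Factor loadings of the two default
#'   latent factors.
#' @return List with elements `marginals` (calibrated [marginal_spec()] table),
#'   `structure` ([latent_structure()]), `schema` ([element_schema()]) and `n`.
#' @examples
#' spec <- default_study_spec()
#' sum(spec$marginals$role == "element") # 31
#' @export
default_study_spec <- function(n = 95, metabolic_loading = 0.6,
                               exposure_loading = 0.6) {
  schema <- element_schema()
  elements <- schema |>
    dplyr::transmute(name = .data$symbol, label = .data$symbol,
                     unit = "ug/g", family = "lognormal",
                     mean = .data$mean, sd = .data$sd,
                     min = pmax(.data$min, 0), max = .data$max,
                     median = .data$median, role = "element")
  marginals <- marginal_spec(dplyr::bind_rows(clinical_table(),
                                              elements, auxiliary_table()))
  metabolic_vars <- c("wc", "bmi", "tg", "insulin", "glycaemia", "hba1c",
                      "fibrinogen", "uric_acid")
  structure_tbl <- dplyr::bind_rows(
    tibble::tibble(variable = metabolic_vars, factor = "metabolic",
                   loading = metabolic_loading),
    tibble::tibble(variable = toxic_elements(schema), factor = "exposure",
                   loading = exposure_loading)
  )
  list(marginals = marginals,
       structure = latent_structure(structure_tbl),
       schema = schema,
       n = n)
}

# exact inverse-CDF draw of a standard normal truncated to [lo, hi],
# computed in whichever tail keeps pnorm/qnorm away from 1
rtruncnorm_std <- function(n, lo, hi) {
  if (lo > 0) {
    u <- runif(n, pnorm(hi, lower.tail = FALSE), pnorm(lo, lower.tail = FALSE))
    qnorm(u, lower.tail = FALSE)
  } else {
    u <- runif(n, pnorm(lo), pnorm(hi))
    qnorm(u)
  }
}

# z-scale truncation bounds implied by a spec row's [min, max]
z_bounds <- function(spec_row) {
  if (spec_row$family == "lognormal") {
    lo <- if (spec_row$min > 0) (log(spec_row$min) - spec_row$location) / spec_row$scale else -Inf
    hi <- (log(spec_row$max) - spec_row$location) / spec_row$scale
  } else {
    lo <- (spec_row$min - spec_row$location) / spec_row$scale
    hi <- (spec_row$max - spec_row$location) / spec_row$scale
  }
  c(lo, hi)
}

# transform a standard-normal draw into the spec's marginal; values outside
# [min, max] redraw the idiosyncratic component (rejection sampling), keeping
# the factor contribution so planted correlation survives truncation
marginal_transform <- function(z, spec_row) {
  switch(spec_row$family,
         lognormal = exp(spec_row$location + spec_row$scale * z),
         truncated_gaussian = spec_row$location + spec_row$scale * z,
         abort_autocmap(paste0("Cannot transform family ", spec_row$family),
                        "autocmap_schema_error"))
}

#' Sample one marginal distribution
#'
#' Draws from the calibrated, truncated marginal of a single variable,
#' ignoring the latent structure. Used for calibration checks.
#'
#' @param spec A [default_study_spec()] result or calibrated marginal table.
#' @param variable Variable name (e.g. `"Ba"`).
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`, all inside the spec's `[min, max]`.
#' @examples
#' mean(sample_marginal(default_study_spec(), "Hg", 1000, seed = 1))
#' @export
sample_marginal <- function(spec, variable, n, seed = 1L) {
  marginals <- if (is.data.frame(spec)) spec else spec$marginals
  row <- marginals[marginals$name == variable, ]
  if (nrow(row) != 1L) {
    abort_autocmap(paste0("Unknown variable: ", variable), "autocmap_schema_error")
  }
  if (row$family == "bernoulli") {
    set.seed(seed)
    return(rbinom(n, 1L, row$mean))
  }
  set.seed(seed)
  z <- rnorm(n)
  x <- marginal_transform(z, row)
  for (i in 1:100) {
    bad <- x < row$min | x > row$max
    if (!any(bad)) break
    x[bad] <- marginal_transform(rnorm(sum(bad)), row)
  }
  # exact truncated draw for the values rejection could not place (extreme
  # skew: the acceptance region can be a far tail of the parent distribution)
  bad <- x < row$min | x > row$max
  if (any(bad)) {
    zb <- z_bounds(row)
    x[bad] <- marginal_transform(rtruncnorm_std(sum(bad), zb[1], zb[2]), row)
  }
  pmin(pmax(x, row$min), row$max)
}

#' Simulate a synthetic cohort
#'
#' Draws a subjects-by-variables cohort table: sampled primitives follow the
#' calibrated truncated marginals with correlation induced by the latent
#' factors; derived indices (FLI, VAI, Framingham points, CV risk, MetS,
#' obesity, toxicity index) are computed from the simulated primitives, never
#' sampled. The result is bit-identical for a fixed `(spec, structure, n,
#' seed)`.
#'
#' @param spec A [default_study_spec()]-style list (or calibrated marginal
#'   tibble, in which case `structure`/`schema` must be given).
#' @param structure Optional [latent_structure()] override.
#' @param n Cohort size; defaults to `spec$n` (95).
#' @param seed Integer seed driving all randomness.
#' @param toxicity_weights Optional named weight vector for the toxicity index
#'   (defaults to [default_toxicity_weights()]).
#' @return A `cohort_tbl` tibble: `subject_id` plus one column per variable,
#'   with a `units` attribute. Missing values are `NA` (none are generated).
#' @examples
#' cohort <- simulate_cohort(default_study_spec(), n = 20, seed = 7)
#' dim(cohort)
#' @export
simulate_cohort <- function(spec = default_study_spec(), structure = NULL,
                            n = NULL, seed = 1L, toxicity_weights = NULL) {
  if (is.data.frame(spec)) spec <- list(marginals = spec, n = 95)
  marginals <- spec$marginals
  structure <- structure %||% spec$structure
  schema <- spec$schema %||% element_schema()
  n <- n %||% spec$n %||% 95L
  if (n < 2) abort_autocmap("`n` must be >= 2.", "autocmap_invalid_argument")

  sampled <- marginals[marginals$family != "derived", ]
  unknown <- setdiff(structure$loadings$variable, sampled$name)
  if (length(unknown) > 0) {
    abort_autocmap(paste0("Latent structure loads unknown variables: ",
                          paste(unknown, collapse = ", ")),
                   "autocmap_schema_error")
  }

  set.seed(seed)
  factors <- matrix(rnorm(n * length(structure$factor_names)), nrow = n,
                    dimnames = list(NULL, structure$factor_names))

  values <- matrix(NA_real_, nrow = n, ncol = nrow(sampled),
                   dimnames = list(NULL, sampled$name))
  for (k in seq_len(nrow(sampled))) {
    row <- sampled[k, ]
    if (row$family == "bernoulli") {
      values[, k] <- rbinom(n, 1L, row$mean)
      next
    }
    lds <- structure$loadings[structure$loadings$variable == row$name, ]
    common <- if (nrow(lds) > 0) {
      as.numeric(factors[, lds$factor, drop = FALSE] %*% lds$loading)
    } else rep(0, n)
    lam2 <- sum(lds$loading^2)
    noise_scale <- sqrt(max(1 - lam2, 0)) * structure$noise_sd
    denom <- sqrt(lam2 + noise_scale^2)
    z <- (common + noise_scale * rnorm(n)) / denom
    x <- marginal_transform(z, row)
    # rejection: redraw the idiosyncratic part of out-of-bounds values
    for (i in 1:100) {
      bad <- x < row$min | x > row$max
      if (!any(bad)) break
      z[bad] <- (common[bad] + noise_scale * rnorm(sum(bad))) / denom
      x[bad] <- marginal_transform(z[bad], row)
    }
    # exact conditional truncated draw where rejection cannot place a value,
    # keeping the factor contribution fixed
    bad <- which(x < row$min | x > row$max)
    if (length(bad) > 0 && noise_scale > 0) {
      zb <- z_bounds(row)
      lo <- (zb[1] * denom - common[bad]) / noise_scale
      hi <- (zb[2] * denom - common[bad]) / noise_scale
      eps <- purrr::map2_dbl(lo, hi, function(l, h) rtruncnorm_std(1, l, h))
      z[bad] <- (common[bad] + noise_scale * eps) / denom
      x[bad] <- marginal_transform(z[bad], row)
    }
    values[, k] <- pmin(pmax(x, row$min), row$max)
  }

  tbl <- tibble::as_tibble(values)

  # derived indices, computed (not sampled) from the primitives; only when the
  # study primitives are present (generic planted specs skip this block)
  study_primitives <- c("glycaemia", "tg", "bmi", "ggt", "wc", "sex", "hdl",
                        "age", "total_chol", "sbp", "dbp", "bp_treated",
                        "smoker")
  if (all(study_primitives %in% names(tbl))) {
    tbl$diabetes <- as.integer(tbl$glycaemia >= 126)
    tbl$fli <- fatty_liver_index(tbl$tg, tbl$bmi, tbl$ggt, tbl$wc)
    tbl$vai <- visceral_adiposity_index(
      sex = ifelse(tbl$sex == 1, "female", "male"),
      wc = tbl$wc, bmi = tbl$bmi,
      tg = convert_tg_to_mmol(tbl$tg), hdl = convert_chol_to_mmol(tbl$hdl))
    fr <- framingham_risk(age = tbl$age,
                          sex = ifelse(tbl$sex == 1, "female", "male"),
                          total_chol = tbl$total_chol, hdl = tbl$hdl,
                          sbp = tbl$sbp, treated_bp = tbl$bp_treated == 1,
                          smoker = tbl$smoker == 1, diabetes = tbl$diabetes == 1)
    tbl$framingham <- fr$points
    tbl$cv_risk <- progetto_cuore_risk(risk_percent = fr$risk_percent)
    tbl$mets <- as.integer(mets_atpiii(
      wc = tbl$wc, sex = ifelse(tbl$sex == 1, "female", "male"), tg = tbl$tg,
      hdl = tbl$hdl, sbp = tbl$sbp, dbp = tbl$dbp,
      bp_treated = tbl$bp_treated == 1, glucose = tbl$glycaemia))
    tbl$obesity <- as.integer(obesity_flag(tbl$bmi))
  }
  tox <- toxic_elements(schema)
  if (all(tox %in% names(tbl))) {
    w <- toxicity_weights %||% default_toxicity_weights(schema)
    conc <- as.matrix(tbl[, names(w), drop = FALSE])
    tbl$ti <- as.numeric(conc %*% w) / sum(w)
  }

  tbl <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%03d", seq_len(n))), tbl)
  units <- study_units(names(tbl))
  extra <- setdiff(names(tbl), names(units))
  units <- c(units, setNames(marginals$unit[match(extra, marginals$name)], extra))
  as_cohort_tbl(tbl, units = units[names(tbl)])
}

as_cohort_tbl <- function(tbl, units = NULL) {
  attr(tbl, "units") <- units
  class(tbl) <- unique(c("cohort_tbl", class(tbl)))
  tbl
}

#' @export
print.cohort_tbl <- function(x, ...) {
  cat("<cohort_tbl> ", nrow(x), " subjects x ", ncol(x) - 1L, " variables\n",
      sep = "")
  NextMethod()
}
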