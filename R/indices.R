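#' Unit converters
#'
#' Conventional factors between mass and molar concentration units:
#' triglycerides mg/dL -> mmol/L (x 0.01129) and cholesterol mg/dL -> mmol/L
#' (x 0.02586).
#'
#' @param x Concentration in mg/dL.
#' @return Concentration in mmol/L.
#' @export
convert_tg_to_mmol <- function(x) x * 0.01129

#' @rdname convert_tg_to_mmol
#' @export
convert_chol_to_mmol <- function(x) x * 0.02586

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (any(!is.finite(v) | v <= 0)) {
      abort_autocmap(paste0("`", nm, "` must be positive and finite."),
                     "autocmap_invalid_argument")
    }
  }
}

#' Fatty liver index (FLI)
#'
#' Bedogni's logistic score from triglycerides, BMI, gamma-glutamyl-transferase
#' and waist circumference, on the 0-100 scale. FLI < 30 rules out fatty
#' liver; FLI >= 60 indicates it.
#'
#' @param tg Triglycerides, mg/dL.
#' @param bmi Body mass index, kg/m2.
#' @param ggt Gamma-glutamyl-transferase, U/L.
#' @param wc Waist circumference, cm.
#' @return Numeric vector in `[0, 100]`, strictly increasing in each argument.
#' @examples
#' fatty_liver_index(tg = 98, bmi = 32.1, ggt = 30, wc = 97)
#' @export
fatty_liver_index <- function(tg, bmi, ggt, wc) {
  check_positive(tg = tg, bmi = bmi, ggt = ggt, wc = wc)
  l <- 0.953 * log(tg) + 0.139 * bmi + 0.718 * log(ggt) + 0.053 * wc - 15.745
  100 * exp(l) / (1 + exp(l))
}

#' Classify a fatty liver index value
#'
#' @param fli FLI values from [fatty_liver_index()].
#' @return `"fatty liver excluded"` (< 30), `"indeterminate"` (30-60) or
#'   `"fatty liver indicated"` (>= 60).
#' @export
fli_class <- function(fli) {
  dplyr::case_when(fli < 30 ~ "fatty liver excluded",
                   fli >= 60 ~ "fatty liver indicated",
                   TRUE ~ "indeterminate")
}

#' Visceral adiposity index (VAI)
#'
#' Amato's sex-specific index of visceral adipose dysfunction.
#' Triglycerides and HDL must be in mmol/L (see [convert_tg_to_mmol()]).
#'
#' @param sex `"male"` or `"female"` (recycled).
#' @param wc Waist circumference, cm.
#' @param bmi Body mass index, kg/m2.
#' @param tg Triglycerides, mmol/L.
#' @param hdl HDL cholesterol, mmol/L.
#' @return Non-negative numeric vector; increasing in TG and WC, decreasing in
#'   HDL.
#' @examples
#' visceral_adiposity_index("female", wc = 99, bmi = 32.7, tg = 1.24, hdl = 1.35)
#' @export
visceral_adiposity_index <- function(sex, wc, bmi, tg, hdl) {
  check_positive(wc = wc, bmi = bmi, tg = tg, hdl = hdl)
  if (!all(sex %in% c("male", "female"))) {
    abort_autocmap('`sex` must be "male" or "female".', "autocmap_invalid_argument")
  }
  if (any(tg > 30)) {
    abort_autocmap(
      "Triglycerides > 30 mmol/L: values look like mg/dL; convert with convert_tg_to_mmol().",
      "autocmap_unit_error")
  }
  male <- (wc / (39.68 + 1.88 * bmi)) * (tg / 1.03) * (1.31 / hdl)
  female <- (wc / (36.58 + 1.89 * bmi)) * (tg / 0.81) * (1.52 / hdl)
  sex <- rep_len(sex, length(male))
  ifelse(sex == "male", male, female)
}

#' Age-specific VAI reference cutoff
#'
#' Piecewise-constant upper reference limits for the VAI: < 2.23 at ages
#' 30-41, < 1.92 at 42-51, < 1.93 at 52-65 and < 2 from age 66. No cutoff is
#' defined below age 30.
#'
#' @param age Age in years (>= 30).
#' @return The cutoff value for each age.
#' @export
vai_reference_cutoff <- function(age) {
  if (any(!is.finite(age) | age < 30)) {
    abort_autocmap("VAI reference cutoffs are not defined below age 30.",
                   "autocmap_not_defined")
  }
  dplyr::case_when(age < 42 ~ 2.23,
                   age < 52 ~ 1.92,
                   age < 66 ~ 1.93,
                   TRUE ~ 2.0)
}

# ---- Framingham ATP III office-based point tables ---------------------------

# age-group index for the cholesterol/smoking point columns (20-39, 40-49, ...)
fram_age_group <- function(age) findInterval(age, c(20, 40, 50, 60, 70))

fram_tables <- function(sex) {
  if (sex == "male") {
    list(
      age_pts = stats::stepfun(c(35, 40, 45, 50, 55, 60, 65, 70, 75),
                               c(-9, -4, 0, 3, 6, 8, 10, 11, 12, 13)),
      chol = rbind("160" = c(0, 0, 0, 0, 0),
                   "200" = c(4, 3, 2, 1, 0),
                   "240" = c(7, 5, 3, 1, 0),
                   "280" = c(9, 6, 4, 2, 1),
                   "999" = c(11, 8, 5, 3, 1)),
      smoke = c(8, 5, 3, 1, 1),
      sbp_untreated = c(0, 0, 1, 1, 2),
      sbp_treated = c(0, 1, 2, 2, 3),
      risk = function(p) {
        dplyr::case_when(p <= 0 ~ 0.5, p <= 4 ~ 1, p <= 6 ~ 2, p == 7 ~ 3,
                         p == 8 ~ 4, p == 9 ~ 5, p == 10 ~ 6, p == 11 ~ 8,
                         p == 12 ~ 10, p == 13 ~ 12, p == 14 ~ 16,
                         p == 15 ~ 20, p == 16 ~ 25, TRUE ~ 30)
      })
  } else {
    list(
      age_pts = stats::stepfun(c(35, 40, 45, 50, 55, 60, 65, 70, 75),
                               c(-7, -3, 0, 3, 6, 8, 10, 12, 14, 16)),
      chol = rbind("160" = c(0, 0, 0, 0, 0),
                   "200" = c(4, 3, 2, 1, 1),
                   "240" = c(8, 6, 4, 2, 1),
                   "280" = c(11, 8, 5, 3, 2),
                   "999" = c(13, 10, 7, 4, 2)),
      smoke = c(9, 7, 4, 2, 1),
      sbp_untreated = c(0, 1, 2, 3, 4),
      sbp_treated = c(0, 3, 4, 5, 6),
      risk = function(p) {
        dplyr::case_when(p <= 8 ~ 0.5, p <= 12 ~ 1, p <= 14 ~ 2, p == 15 ~ 3,
                         p == 16 ~ 4, p == 17 ~ 5, p == 18 ~ 6, p == 19 ~ 8,
                         p == 20 ~ 11, p == 21 ~ 14, p == 22 ~ 17,
                         p == 23 ~ 22, p == 24 ~ 27, TRUE ~ 30)
      })
  }
}

fram_one <- function(age, sex, total_chol, hdl, sbp, treated_bp, smoker) {
  tab <- fram_tables(sex)
  g <- fram_age_group(age)
  chol_row <- findInterval(total_chol, c(0, 160, 200, 240, 280))
  sbp_band <- findInterval(sbp, c(0, 120, 130, 140, 160))
  pts <- tab$age_pts(age) +
    tab$chol[chol_row, g] +
    (if (smoker) tab$smoke[g] else 0L) +
    dplyr::case_when(hdl >= 60 ~ -1, hdl >= 50 ~ 0, hdl >= 40 ~ 1, TRUE ~ 2) +
    (if (treated_bp) tab$sbp_treated[sbp_band] else tab$sbp_untreated[sbp_band])
  c(points = pts, risk = tab$risk(pts))
}

#' Framingham 10-year coronary risk (ATP III point score)
#'
#' The office-based sex-specific point tables of the ATP III Framingham score:
#' points from age band, total cholesterol by age group, smoking by age group,
#' HDL, and systolic blood pressure (treated/untreated), mapped to a 10-year
#' hard-CHD risk percentage via the published points-to-risk lookup. Risks
#' printed as "< 1%" are returned as 0.5 and ">= 30%" as 30. Diabetes is not
#' part of the point table (it is a CHD risk equivalent); with
#' `diabetes = TRUE` the returned risk percent is floored at 20.
#'
#' @param age Age in years (20-79).
#' @param sex `"male"` or `"female"`.
#' @param total_chol Total cholesterol, mg/dL.
#' @param hdl HDL cholesterol, mg/dL.
#' @param sbp Systolic blood pressure, mmHg.
#' @param treated_bp Logical, on antihypertensive treatment.
#' @param smoker Logical, current smoker.
#' @param diabetes Logical.
#' @return Tibble with integer `points` and `risk_percent`.
#' @examples
#' framingham_risk(55, "male", 220, 45, 135, FALSE, TRUE, FALSE)
#' @export
framingham_risk <- function(age, sex, total_chol, hdl, sbp,
                            treated_bp = FALSE, smoker = FALSE,
                            diabetes = FALSE) {
  if (any(!is.finite(age) | age < 20 | age > 79)) {
    abort_autocmap("`age` must be in [20, 79] for the Framingham point tables.",
                   "autocmap_invalid_argument")
  }
  if (!all(sex %in% c("male", "female"))) {
    abort_autocmap('`sex` must be "male" or "female".', "autocmap_invalid_argument")
  }
  check_positive(total_chol = total_chol, hdl = hdl, sbp = sbp)
  args <- vctrs_recycle(age = age, sex = sex, total_chol = total_chol,
                        hdl = hdl, sbp = sbp, treated_bp = treated_bp,
                        smoker = smoker, diabetes = diabetes)
  out <- purrr::pmap(args[c("age", "sex", "total_chol", "hdl", "sbp",
                            "treated_bp", "smoker")],
                     function(age, sex, total_chol, hdl, sbp, treated_bp,
                              smoker) {
                       fram_one(age, sex, total_chol, hdl, sbp, treated_bp,
                                smoker)
                     })
  pts <- as.integer(purrr::map_dbl(out, 1))
  risk <- purrr::map_dbl(out, 2)
  risk <- ifelse(args$diabetes, pmax(risk, 20), risk)
  tibble::tibble(points = pts, risk_percent = risk)
}

# recycle all arguments to a common length, base-R style
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, length.out = n)
}

#' Cardiovascular risk chart interface ("Progetto Cuore")
#'
#' Pluggable interface for the Italian CUORE project risk charts. The charts
#' themselves are not bundled; the default implementation is a documented stub
#' that passes through a Framingham-derived risk percentage so that pipelines
#' expecting a `cv_risk` column keep working. Supply your own function via the
#' `fn` argument to use a real chart.
#'
#' @param risk_percent A baseline 10-year risk percentage (e.g. Framingham).
#' @param fn Optional replacement function taking `risk_percent` and returning
#'   the chart value.
#' @return Numeric risk percentage.
#' @export
progetto_cuore_risk <- function(risk_percent, fn = NULL) {
  if (!is.null(fn)) return(fn(risk_percent))
  risk_percent
}

#' Metabolic syndrome by ATP III criteria
#'
#' Diagnosis by the 2005 revision of the NCEP ATP III definition: at least 3
#' of (1) WC > 102 cm (men) / > 88 cm (women); (2) TG >= 150 mg/dL; (3) HDL
#' < 40 (men) / < 50 (women) mg/dL; (4) BP >= 130/85 mmHg or treated;
#' (5) fasting glucose >= 100 mg/dL.
#'
#' @param wc Waist circumference, cm.
#' @param sex `"male"` or `"female"`.
#' @param tg Triglycerides, mg/dL.
#' @param hdl HDL cholesterol, mg/dL.
#' @param sbp,dbp Blood pressure, mmHg.
#' @param bp_treated Logical, antihypertensive treatment.
#' @param glucose Fasting glucose, mg/dL.
#' @return Logical vector, `TRUE` when >= 3 criteria are met.
#' @export
mets_atpiii <- function(wc, sex, tg, hdl, sbp, dbp, bp_treated, glucose) {
  args <- list(wc = wc, sex = sex, tg = tg, hdl = hdl, sbp = sbp, dbp = dbp,
               bp_treated = bp_treated, glucose = glucose)
  for (nm in names(args)) {
    if (any(is.na(args[[nm]]))) {
      abort_autocmap(paste0("Missing values in `", nm,
                            "`: all five MetS components are required."),
                     "autocmap_missing_component")
    }
  }
  if (!all(sex %in% c("male", "female"))) {
    abort_autocmap('`sex` must be "male" or "female".', "autocmap_invalid_argument")
  }
  wc_crit <- ifelse(sex == "male", wc > 102, wc > 88)
  tg_crit <- tg >= 150
  hdl_crit <- ifelse(sex == "male", hdl < 40, hdl < 50)
  bp_crit <- sbp >= 130 | dbp >= 85 | bp_treated
  glu_crit <- glucose >= 100
  (wc_crit + tg_crit + hdl_crit + bp_crit + glu_crit) >= 3
}

#' Obesity flag
#'
#' Obesity defined strictly as BMI > 30 kg/m2 (BMI of exactly 30 is not
#' flagged).
#'
#' @param bmi Body mass index, kg/m2 (> 0).
#' @return Logical vector.
#' @export
obesity_flag <- function(bmi) {
  check_positive(bmi = bmi)
  bmi > 30
}

#' Default toxicity weights
#'
#' The study's toxicity index uses proprietary per-gram relative-toxicity
#' weights. This package operationalises "relative toxicity per gram" as the
#' inverse of the tolerated hair concentration: `w_i = 1 / reference_upper_i`
#' from the element schema. This is a reimplementation choice, not the
#' original laboratory weighting, and can be overridden wherever weights are
#' accepted.
#'
#' @param schema An [element_schema()] tibble.
#' @return Named positive weights for the 13 toxic elements.
#' @export
default_toxicity_weights <- function(schema = element_schema()) {
  tox <- schema[schema$class == "toxic", ]
  setNames(1 / tox$reference_upper, tox$symbol)
}

#' Hair toxicity index (TI)
#'
#' Weighted average of the toxic-element hair concentrations,
#' `sum(w_i c_i) / sum(w_i)`; higher values mean a more toxic combined metal
#' burden. The index is homogeneous of degree 1 in the concentrations and
#' invariant to rescaling all weights.
#'
#' @param concentrations Named vector of the 13 toxic-element concentrations
#'   (ug/g), or a data frame with those columns (one row per subject).
#' @param weights Named positive weights covering all 13 toxic elements
#'   (default [default_toxicity_weights()]).
#' @return Non-negative toxicity index (one value per subject).
#' @examples
#' conc <- setNames(rep(0, 13), toxic_elements())
#' toxicity_index(conc) # 0
#' @export
toxicity_index <- function(concentrations, weights = default_toxicity_weights()) {
  if (any(!is.finite(weights) | weights <= 0)) {
    abort_autocmap("Toxicity weights must be positive.", "autocmap_invalid_argument")
  }
  tox <- toxic_elements()
  if (!all(tox %in% names(weights))) {
    abort_autocmap("Weights must cover all 13 toxic elements.",
                   "autocmap_invalid_argument")
  }
  weights <- weights[tox]
  if (is.data.frame(concentrations)) {
    missing_el <- setdiff(tox, names(concentrations))
    if (length(missing_el) > 0) {
      abort_autocmap(paste0("Missing toxic elements: ",
                            paste(missing_el, collapse = ", ")),
                     "autocmap_missing_component")
    }
    conc <- as.matrix(concentrations[, tox, drop = FALSE])
  } else {
    missing_el <- setdiff(tox, names(concentrations))
    if (length(missing_el) > 0) {
      abort_autocmap(paste0("Missing toxic elements: ",
                            paste(missing_el, collapse = ", ")),
                     "autocmap_missing_component")
    }
    conc <- matrix(concentrations[tox], nrow = 1)
  }
  if (any(!is.finite(conc) | conc < 0)) {
    abort_autocmap("Concentrations must be finite and non-negative.",
                   "autocmap_invalid_argument")
  }
  as.numeric(conc %*% weights) / sum(weights)
}

#' Flag element concentrations against reference intervals
#'
#' Compares each supplied element to its reference interval. Toxic elements
#' have upper-limit-only intervals and can therefore only be `"normal"` or
#' `"high"`.
#'
#' @param concentrations Named vector of element concentrations (ug/g).
#' @param schema An [element_schema()] tibble covering all supplied symbols.
#' @return Tibble with `symbol`, `value` and `status` in
#'   `c("low", "normal", "high")`.
#' @examples
#' flag_out_of_reference(c(Ba = 1.29, Zn = 176.6, Sr = 9.70))
#' @export
flag_out_of_reference <- function(concentrations, schema = element_schema()) {
  unknown <- setdiff(names(concentrations), schema$symbol)
  if (length(unknown) > 0 || is.null(names(concentrations))) {
    abort_autocmap(paste0("Unknown element symbols: ",
                          paste(unknown, collapse = ", ")),
                   "autocmap_schema_error")
  }
  tibble::tibble(symbol = names(concentrations),
                 value = as.numeric(concentrations)) |>
    dplyr::left_join(schema[, c("symbol", "reference_lower", "reference_upper")],
                     by = "symbol") |>
    dplyr::mutate(status = dplyr::case_when(
      .data$value > .data$reference_upper ~ "high",
      !is.na(.data$reference_lower) & .data$value < .data$reference_lower ~ "low",
      TRUE ~ "normal")) |>
    dplyr::select("symbol", "value", "status")
}

#' Per-subject composite indices for a cohort
#'
#' Computes all study indices (FLI with classification, VAI with its
#' age-specific cutoff, Framingham points and risk, MetS, obesity, TI) for
#' every row of a cohort table that carries the required primitives.
#'
#' @param cohort A `cohort_tbl` from [simulate_cohort()] or
#'   [read_cohort_csv()].
#' @param toxicity_weights Optional named toxicity weights.
#' @return A tibble with one row per subject.
#' @export
cohort_indices <- function(cohort, toxicity_weights = default_toxicity_weights()) {
  sex_chr <- ifelse(cohort$sex == 1, "female", "male")
  diabetes <- if ("diabetes" %in% names(cohort)) cohort$diabetes == 1
              else cohort$glycaemia >= 126
  fr <- framingham_risk(cohort$age, sex_chr, cohort$total_chol, cohort$hdl,
                        cohort$sbp, cohort$bp_treated == 1,
                        cohort$smoker == 1, diabetes)
  tibble::tibble(
    subject_id = cohort$subject_id,
    fli = fatty_liver_index(cohort$tg, cohort$bmi, cohort$ggt, cohort$wc),
    fli_class = fli_class(fli),
    vai = visceral_adiposity_index(sex_chr, cohort$wc, cohort$bmi,
                                   convert_tg_to_mmol(cohort$tg),
                                   convert_chol_to_mmol(cohort$hdl)),
    vai_cutoff = vai_reference_cutoff(cohort$age),
    vai_elevated = vai >= vai_cutoff,
    framingham_points = fr$points,
    framingham_risk = fr$risk_percent,
    mets = mets_atpiii(cohort$wc, sex_chr, cohort$tg, cohort$hdl, cohort$sbp,
                       cohort$dbp, cohort$bp_treated == 1, cohort$glycaemia),
    obesity = obesity_flag(cohort$bmi),
    ti = toxicity_index(cohort[, toxic_elements(), drop = FALSE],
                        toxicity_weights)
  )
}
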