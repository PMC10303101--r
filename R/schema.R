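#' Hair element panel schema
#'
#' The 31-element hair mineralogram panel measured by ICP-MS, split into 13
#' toxic metals (upper-limit-only reference intervals) and 18 essential or
#' other elements (two-sided reference intervals, except Gold which carries an
#' upper limit only). Concentrations are in micrograms of element per gram of
#' hair. The summary statistics (`mean`, `sd`, `min`, `max`, `median`) describe
#' the study population the synthetic generator emulates and are used to
#' calibrate its marginal distributions.
#'
#' @return A tibble with one row per element and columns `symbol`, `name`,
#'   `class` (`"toxic"` or `"essential"`), `reference_lower`, `reference_upper`
#'   (ug/g; `reference_lower` is `NA` for upper-limit-only intervals), and the
#'   population summary columns `mean`, `sd`, `min`, `max`, `median` (ug/g).
#' @examples
#' schema <- element_schema()
#' table(schema$class)
#' @export
element_schema <- function() {
  tox <- tibble::tribble(
    ~symbol, ~name,        ~reference_lower, ~reference_upper, ~mean, ~sd,   ~min, ~max,  ~median,
    "Al",    "Aluminium",  NA,               8.0,              7.64,  13.12, 0.70, 94.00, 4.10,
    "Sb",    "Antimony",   NA,               0.066,            0.05,  0.12,  0.01, 1.10,  0.02,
    "As",    "Arsenic",    NA,               0.080,            0.04,  0.04,  0.01, 0.27,  0.03,
    "Ba",    "Barium",     NA,               0.75,             1.29,  1.63,  0.04, 11.00, 0.95,
    "Bi",    "Bismuth",    NA,               2.0,              0.06,  0.18,  0.00, 1.60,  0.02,
    "Cd",    "Cadmium",    NA,               0.070,            0.74,  6.66,  0.00, 65.00, 0.03,
    "Pb",    "Lead",       NA,               1.0,              1.59,  3.49,  0.04, 29.00, 0.59,
    "Hg",    "Mercury",    NA,               0.40,             1.64,  1.49,  0.09, 7.80,  1.20,
    "U",     "Uranium",    NA,               0.060,            0.11,  0.12,  0.01, 0.63,  0.07,
    "Ni",    "Nickel",     NA,               0.20,             0.52,  0.82,  0.04, 6.20,  0.30,
    "Ag",    "Silver",     NA,               0.14,             1.68,  5.13,  0.01, 38.00, 0.21,
    "Sn",    "Tin",        NA,               0.30,             0.86,  1.48,  0.02, 7.80,  0.28,
    "Ti",    "Titanium",   NA,               0.70,             0.74,  0.44,  0.24, 2.40,  0.59
  )
  ess <- tibble::tribble(
    ~symbol, ~name,         ~reference_lower, ~reference_upper, ~mean,  ~sd,   ~min,  ~max,   ~median,
    "Cu",    "Copper",      11,               32,               17.01,  14.96, 6.70,  140.00, 14.00,
    "Zn",    "Zinc",        110,              190,              176.6,  63.7,  61.0,  440.0,  170.0,
    "Mn",    "Manganese",   0.08,             0.50,             0.27,   0.37,  0.03,  3.20,   0.18,
    "Cr",    "Chromium",    0.40,             0.70,             0.47,   0.10,  0.33,  0.94,   0.44,
    "V",     "Vanadium",    0.025,            0.10,             0.05,   0.04,  0.01,  0.33,   0.04,
    "Mo",    "Molybdenum",  0.040,            0.090,            0.03,   0.01,  0.01,  0.08,   0.03,
    "B",     "Boron",       0.50,             3.5,              0.97,   0.82,  0.07,  4.70,   0.68,
    "I",     "Iodine",      0.25,             1.3,              1.14,   3.06,  0.07,  26.00,  0.51,
    "Li",    "Lithium",     0.007,            0.020,            0.02,   0.08,  0.00,  0.75,   0.01,
    "Se",    "Selenium",    0.70,             1.1,              0.94,   2.54,  0.21,  25.00,  0.62,
    "Sr",    "Strontium",   0.21,             2.1,              9.70,   8.16,  0.16,  35.00,  9.20,
    "S",     "Sulphur",     44000,            51000,            47376,  1955,  43400, 51400,  47400,
    "Co",    "Cobalt",      0.004,            0.020,            0.05,   0.09,  0.00,  0.49,   0.02,
    "Fe",    "Iron",        7.0,              16,               15.07,  6.22,  3.90,  36.00,  15.00,
    "Ge",    "Germanium",   0.030,            0.040,            0.03,   0.01,  0.03,  0.05,   0.03,
    "Rb",    "Rubidium",    0.008,            0.080,            0.08,   0.17,  0.00,  1.10,   0.02,
    "Zr",    "Zirconium",   0.060,            0.70,             0.05,   0.06,  0.01,  0.40,   0.03,
    "Au",    "Gold",        NA,               0.50,             0.14,   0.34,  0.00,  3.00,   0.05
  )
  dplyr::bind_rows(
    dplyr::mutate(tox, class = "toxic", .after = "name"),
    dplyr::mutate(ess, class = "essential", .after = "name")
  )
}

#' Toxic element symbols
#'
#' @param schema An [element_schema()] tibble.
#' @return Character vector of the 13 toxic-metal symbols.
#' @export
toxic_elements <- function(schema = element_schema()) {
  schema$symbol[schema$class == "toxic"]
}

# Clinical variable summary statistics of the emulated study population
# (25 variables; the last four are indices derived from the primitives and are
# never sampled directly). `label` follows the abbreviation conventions of the
# connectivity-map figures.
clinical_table <- function() {
  tibble::tribble(
    ~name,          ~label,       ~unit,        ~family,              ~mean, ~sd,   ~min, ~max,  ~median, ~role,
    "bmi",          "BMI",        "kg/m2",      "truncated_gaussian", 32.7,  5.7,   27.5, 54.7,  32.1,    "clinical",
    "wc",           "WC",         "cm",         "truncated_gaussian", 99,    13,    75,   137,   97,      "clinical",
    "sbp",          "SBP",        "mmHg",       "truncated_gaussian", 124,   17,    85,   170,   120,     "clinical",
    "dbp",          "DBP",        "mmHg",       "truncated_gaussian", 79,    11,    55,   100,   80,      "clinical",
    "heart_rate",   "HR",         "bpm",        "truncated_gaussian", 72,    9,     52,   100,   70,      "clinical",
    "wbc",          "WBC",        "10^9/L",     "truncated_gaussian", 6.90,  1.79,  3.69, 14.39, 6.67,    "clinical",
    "rbc",          "RBC",        "10^12/L",    "truncated_gaussian", 4.85,  0.48,  3.71, 6.49,  4.77,    "clinical",
    "haemoglobin",  "HGB",        "g/dL",       "truncated_gaussian", 13.7,  1.3,   10.4, 17.4,  13.6,    "clinical",
    "haematocrit",  "HCT",        "%",          "truncated_gaussian", 41,    3,     32,   50,    41,      "clinical",
    "platelets",    "PLT",        "10^9/L",     "truncated_gaussian", 248,   59,    72,   414,   247,     "clinical",
    "fibrinogen",   "fibrinogen", "mg/dL",      "truncated_gaussian", 332,   61,    70,   491,   328,     "clinical",
    "crp",          "CRP",        "mg/dL",      "lognormal",          0.51,  0.77,  0.03, 4.48,  0.25,    "clinical",
    "uric_acid",    "UA",         "mg/dL",      "truncated_gaussian", 4.9,   1.2,   1.8,  8.2,   4.7,     "clinical",
    "creatinine",   "creat",      "mg/dL",      "truncated_gaussian", 0.74,  0.13,  0.51, 1.16,  0.72,    "clinical",
    "tg",           "Trigly",     "mg/dL",      "lognormal",          109,   47,    43,   279,   98,      "clinical",
    "total_chol",   "chol-T",     "mg/dL",      "truncated_gaussian", 216,   41,    126,  336,   213,     "clinical",
    "ldl",          "LDL-c",      "mg/dL",      "truncated_gaussian", 132,   36,    58,   226,   128,     "clinical",
    "homocysteine", "Hcy",        "umol/L",     "lognormal",          10.9,  3.8,   5.0,  27.8,  10.4,    "clinical",
    "glycaemia",    "gly",        "mg/dL",      "lognormal",          96,    27,    57,   297,   91,      "clinical",
    "insulin",      "INS",        "mIU/mL",     "truncated_gaussian", 12.50, 6.01,  0.40, 32.60, 11.90,   "clinical",
    "hba1c",        "glycHB",     "%",          "lognormal",          5.9,   0.7,   4.4,  9.5,   5.8,     "clinical",
    "fli",          "FLI",        "index",      "derived",            57.6,  28.5,  5.0,  99.7,  63.0,    "derived",
    "vai",          "VAI",        "index",      "derived",            3.8,   2.6,   0.9,  17.5,  2.7,     "derived",
    "framingham",   "Framingham", "points",     "derived",            3.8,   3.9,   0,    20,    2.0,     "derived",
    "cv_risk",      "CV",         "%",          "derived",            4.1,   5.5,   0.2,  29,    2.1,     "derived"
  )
}

# canonical units for every study variable, in the order of `vars`
study_units <- function(vars) {
  u <- setNames(
    c("id", clinical_table()$unit, rep("ug/g", nrow(element_schema())),
      auxiliary_table()$unit, "0/1", "0/1", "0/1", "index"),
    c("subject_id", clinical_table()$name, element_schema()$symbol,
      auxiliary_table()$name, "diabetes", "mets", "obesity", "ti"))
  u[intersect(vars, names(u))]
}

# Auxiliary variables required by the index formulas but not part of the
# printed 25-variable clinical panel. Their marginals are NOT calibrated to the
# emulated study (which does not report them) and are overridable.
auxiliary_table <- function() {
  tibble::tribble(
    ~name,        ~label,      ~unit,   ~family,              ~mean, ~sd, ~min, ~max, ~median, ~role,
    "age",        "age",       "years", "truncated_gaussian", 51,    12,  30,   79,   51,      "aux",
    "sex",        "sex",       "1=F",   "bernoulli",          0.5,   NA,  0,    1,    NA,      "aux",
    "hdl",        "HDL-c",     "mg/dL", "truncated_gaussian", 52,    13,  25,   100,  52,      "aux",
    "ggt",        "GGT",       "U/L",   "lognormal",          30,    20,  5,    300,  25,      "aux",
    "smoker",     "smoker",    "0/1",   "bernoulli",          0.25,  NA,  0,    1,    NA,      "aux",
    "bp_treated", "BPtreated", "0/1",   "bernoulli",          0.2,   NA,  0,    1,    NA,      "aux"
  )
}
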