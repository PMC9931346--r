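#' Clinical variable catalog
#'
#' Per-variable metadata for the 42 clinical variables of the cohort
#' (demographics, vitals, laboratory values, ventilation status and
#' comorbidity count) plus the three treatment series (fluid volume,
#' vasopressor dose, urine output). For each variable the catalog records
#' the measurement unit, the adult normal range, plausibility bounds used
#' for outlier filtering (e.g. weight above 300 kg or negative blood
#' pressures are implausible), the within-bin aggregation rule (vitals are
#' averaged, vasopressor doses take the maximum, fluid and urine volumes
#' accumulate), the maximum sample-and-hold time for imputation, the
#' direction in which departure from the normal range is abnormal, and the
#' cohort-level mean/SD used by the synthetic generator to map standardized
#' archetype space into clinical units.
#'
#' @param treatments logical; include the treatment series rows
#'   (`Fluids`, `Vasopressor`, `Urine`) in addition to the 42 clinical
#'   variables.
#' @return a `data.frame` with one row per variable and columns
#'   `name`, `group`, `unit`, `normal_low`, `normal_high`, `plausible_low`,
#'   `plausible_high`, `aggregation`, `max_hold_hours`, `direction`,
#'   `sim_mean`, `sim_sd`.
#' @examples
#' cat42 <- variable_catalog()
#' nrow(cat42)            # 42
#' subset(cat42, name == "HR")$aggregation
#' @export
variable_catalog <- function(treatments = FALSE) {
  row <- function(name, group, unit, nlo, nhi, plo, phi, agg, hold, dir,
                  mean, sd) {
    data.frame(name = name, group = group, unit = unit,
               normal_low = nlo, normal_high = nhi,
               plausible_low = plo, plausible_high = phi,
               aggregation = agg, max_hold_hours = hold, direction = dir,
               sim_mean = mean, sim_sd = sd, stringsAsFactors = FALSE)
  }
  cat <- rbind(
    row("Age",               "demographic", "years",     NA,   NA,    18,   120,  "last", Inf, "two_sided",        64.57, 16.67),
    row("Gender",            "demographic", "binary",    NA,   NA,    0,    1,    "last", Inf, "two_sided",        0.44,  0.50),
    row("HR",                "vital",       "bpm",       60,   100,   0,    300,  "mean", 8,   "two_sided",        87.21, 16.84),
    row("SysBP",             "vital",       "mmHg",      90,   120,   0,    300,  "mean", 8,   "two_sided",        119.92, 20.35),
    row("MeanBP",            "vital",       "mmHg",      70,   100,   0,    250,  "mean", 8,   "two_sided",        78.21, 13.48),
    row("DiaBP",             "vital",       "mmHg",      60,   80,    0,    200,  "mean", 8,   "two_sided",        57.12, 13.32),
    row("Temp",              "vital",       "Celsius",   36.5, 37.5,  25,   45,   "mean", 8,   "two_sided",        36.91, 2.01),
    row("RR",                "vital",       "bpm",       12,   20,    0,    80,   "mean", 8,   "two_sided",        20.21, 5.19),
    row("GCS",               "lab",         "score",     15,   15,    3,    15,   "mean", 24,  "low_is_abnormal",  12.57, 3.49),
    row("SpO2",              "lab",         "percent",   95,   100,   0,    100,  "mean", 8,   "low_is_abnormal",  96.91, 2.65),
    row("FiO2",              "lab",         "fraction",  0.21, 0.21,  0.21, 1,    "mean", 8,   "high_is_abnormal", 0.46,  0.18),
    row("Potassium",         "lab",         "mEq/L",     3.5,  5.0,   0.5,  12,   "mean", 24,  "two_sided",        4.08,  0.56),
    row("Sodium",            "lab",         "mEq/L",     135,  145,   90,   200,  "mean", 24,  "two_sided",        138.69, 4.89),
    row("Chloride",          "lab",         "mEq/L",     96,   106,   60,   160,  "mean", 24,  "two_sided",        104.72, 6.24),
    row("Glucose",           "lab",         "mg/dL",     80,   130,   10,   1500, "mean", 24,  "two_sided",        138.96, 51.18),
    row("BUN",               "lab",         "mg/dL",     7,    20,    0,    250,  "mean", 24,  "high_is_abnormal", 29.25, 22.56),
    row("Creatinine",        "lab",         "mg/dL",     0.6,  1.2,   0,    30,   "mean", 24,  "high_is_abnormal", 1.49,  2.16),
    row("Magnesium",         "lab",         "mg/dL",     1.5,  2.5,   0,    10,   "mean", 24,  "two_sided",        2.06,  0.35),
    row("Calcium",           "lab",         "mg/dL",     8.8,  10.7,  2,    20,   "mean", 24,  "two_sided",        8.31,  0.80),
    row("Ionised_Ca",        "lab",         "mmol/L",    1.16, 1.32,  0.2,  3,    "mean", 24,  "two_sided",        1.13,  0.12),
    row("CO2",               "lab",         "mEq/L",     23,   29,    0,    60,   "mean", 24,  "two_sided",        25.82, 5.66),
    row("SGOT",              "lab",         "u/L",       5,    40,    0,    30000,"mean", 24,  "high_is_abnormal", 155.69, 583.57),
    row("SGPT",              "lab",         "u/L",       7,    56,    0,    30000,"mean", 24,  "high_is_abnormal", 583.57, 466.35),
    row("Total_Bilirubin",   "lab",         "mg/dL",     0.1,  1.2,   0,    80,   "mean", 24,  "high_is_abnormal", 2.41,  5.15),
    row("Albumin",           "lab",         "g/dL",      3.4,  5.4,   0.5,  8,    "mean", 24,  "low_is_abnormal",  3.00,  0.68),
    row("Hb",                "lab",         "g/dL",      12.0, 17.5,  2,    25,   "mean", 24,  "low_is_abnormal",  10.30, 1.74),
    row("WBC",               "lab",         "1e9/L",     4.5,  11.0,  0,    300,  "mean", 24,  "two_sided",        12.27, 8.29),
    row("Platelets",         "lab",         "1e9/L",     150,  450,   0,    2000, "mean", 24,  "two_sided",        228.70, 139.19),
    row("aPTT",              "lab",         "s",         30,   40,    0,    250,  "mean", 24,  "high_is_abnormal", 37.81, 19.34),
    row("PT",                "lab",         "s",         11,   13.5,  0,    150,  "mean", 24,  "high_is_abnormal", 16.19, 6.75),
    row("INR",               "lab",         "ratio",     0.8,  1.1,   0.2,  20,   "mean", 24,  "high_is_abnormal", 1.51,  0.84),
    row("Arterial_pH",       "lab",         "pH",        7.35, 7.45,  6.5,  8,    "mean", 8,   "two_sided",        7.39,  0.07),
    row("PaO2",              "lab",         "mmHg",      80,   100,   0,    700,  "mean", 8,   "two_sided",        125.15, 72.45),
    row("PaCO2",             "lab",         "mmHg",      35,   45,    5,    150,  "mean", 8,   "two_sided",        41.95, 10.81),
    row("Arterial_BE",       "lab",         "mEq/L",     -2,   2,     -40,  40,   "mean", 8,   "two_sided",        0.35,  5.02),
    row("Arterial_Lactate",  "lab",         "mmol/L",    0.5,  1,     0,    40,   "mean", 8,   "high_is_abnormal", 2.05,  1.66),
    row("HCO3",              "lab",         "mEq/L",     22,   28,    0,    60,   "mean", 8,   "two_sided",        24.67, 5.09),
    row("Shock_Index",       "lab",         "bpm/mmHg",  0.5,  0.7,   0,    4,    "mean", 8,   "high_is_abnormal", 0.75,  0.20),
    row("PaO2_FiO2",         "lab",         "mmHg",      400,  NA,    0,    3000, "mean", 8,   "low_is_abnormal",  311.00, 223.71),
    row("Weight",            "other",       "kg",        NA,   NA,    1,    300,  "last", Inf, "two_sided",        83.23, 24.65),
    row("Mechvent",          "other",       "binary",    0,    0,     0,    1,    "max",  8,   "high_is_abnormal", 0.37,  0.48),
    row("Comorbidity_Count", "other",       "count",     NA,   NA,    0,    30,   "last", Inf, "high_is_abnormal", 4.01,  2.17)
  )
  if (treatments) {
    cat <- rbind(cat,
      row("Fluids",      "treatment", "mL",        NA, NA, 0, 10000, "sum", 0, "high_is_abnormal", 250, 200),
      row("Vasopressor", "treatment", "ug/kg/min", NA, NA, 0, 5,     "max", 0, "high_is_abnormal", 0.05, 0.1),
      row("Urine",       "treatment", "mL",        NA, NA, 0, 5000,  "sum", 0, "low_is_abnormal",  120, 80)
    )
  }
  rownames(cat) <- cat$name
  cat
}

#' Map standardized values to clinical units (and back)
#'
#' The synthetic generator defines archetypes on a standardized (z-score)
#' scale; these helpers apply the affine map `value = sim_mean + sim_sd * z`
#' per variable (and its inverse), using the catalog's cohort-level
#' mean/SD columns.
#'
#' @param z,x numeric matrix with columns named after catalog variables.
#' @param catalog a [variable_catalog()] data frame.
#' @param clamp logical; clamp mapped values into the plausibility bounds.
#' @return matrix of the same shape.
#' @export
std_to_unit <- function(z, catalog, clamp = TRUE) {
  vars <- colnames(z)
  spec <- catalog[match(vars, catalog$name), ]
  if (anyNA(spec$name)) stop_input("unknown variable(s): ",
    paste(setdiff(vars, catalog$name), collapse = ", "))
  x <- sweep(sweep(z, 2L, spec$sim_sd, "*"), 2L, spec$sim_mean, "+")
  if (clamp) {
    lo <- ifelse(is.na(spec$plausible_low), -Inf, spec$plausible_low)
    hi <- ifelse(is.na(spec$plausible_high), Inf, spec$plausible_high)
    x <- pmin(pmax(x, matrix(lo, nrow(x), ncol(x), byrow = TRUE)),
              matrix(hi, nrow(x), ncol(x), byrow = TRUE))
  }
  # binary variables are reported as flags in clinical units
  bin <- which(spec$unit == "binary")
  for (j in bin) x[, j] <- as.numeric(z[, j] > 0)
  x
}

#' @rdname std_to_unit
#' @export
unit_to_std <- function(x, catalog) {
  vars <- colnames(x)
  spec <- catalog[match(vars, catalog$name), ]
  if (anyNA(spec$name)) stop_input("unknown variable(s): ",
    paste(setdiff(vars, catalog$name), collapse = ", "))
  sweep(sweep(x, 2L, spec$sim_mean, "-"), 2L, spec$sim_sd, "/")
}
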