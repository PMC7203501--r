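#' Morphometric feature names and cohort defaults
#'
#' Canonical feature names used throughout the package, the CSV header
#' labels they map to (parameter label plus scaled unit), and the default
#' group-conditional moments of the reference cohort of 296 non-high-risk
#' acute pulmonary embolism patients (34 with an adverse event within 30
#' days, 262 without).
#'
#' @name features
NULL

# 15 continuous morphometric parameters, canonical order
.morpho_features <- c(
  "MPA inlet CSA", "MPA outlet CSA", "RPA inlet CSA", "LPA inlet CSA",
  "MPA inlet hydraulic diameter", "MPA outlet hydraulic diameter",
  "RPA inlet hydraulic diameter", "LPA inlet hydraulic diameter",
  "MPA inlet maximal diameter", "MPA outlet maximal diameter",
  "RPA inlet maximal diameter", "LPA inlet maximal diameter",
  "MPA bifurcation area", "MPA bifurcation angle", "MPA bifurcation volume"
)

.feature_units <- c(rep("100 mm^2", 4), rep("10 mm", 8),
                    "100 mm^2", "°", "1000 mm^3")

#' Canonical morphometric feature names
#' @return character vector of the 15 continuous morphometric features.
#' @export
morphometric_features <- function() .morpho_features

#' CSV column labels for cohort tables
#'
#' Parameter label with its scaled unit, as used in cohort CSV headers,
#' e.g. `"MPA inlet CSA (100 mm^2)"`, plus `Age (year)`, `Sex`,
#' `MPA dilation`, `event`, `set`.
#' @return named character vector mapping canonical names to CSV labels.
#' @export
cohort_csv_labels <- function() {
  lab <- paste0(.morpho_features, " (", .feature_units, ")")
  names(lab) <- .morpho_features
  c(lab,
    age = "Age (year)", sex = "Sex", dilation = "MPA dilation",
    event = "event", set = "set")
}

# group-conditional moments of the reference cohort (scaled units):
# mean_pos/sd_pos = adverse events (+), n = 34; mean_neg/sd_neg = (-), n = 262
.table1 <- data.frame(
  feature = .morpho_features,
  mean_pos = c(10.43, 11.98, 6.95, 6.71,
               3.28, 3.50, 2.60, 2.39,
               2.90, 3.24, 2.23, 2.15,
               1.32, 133.23, 19.78),
  sd_pos   = c(2.66, 3.00, 2.89, 3.28,
               0.42, 0.41, 0.38, 0.38,
               0.41, 0.53, 0.38, 0.43,
               0.95, 37.04, 8.43),
  mean_neg = c(7.67, 8.39, 4.98, 4.71,
               2.81, 2.92, 2.26, 2.19,
               2.78, 3.06, 2.15, 2.07,
               0.57, 152.12, 12.90),
  sd_neg   = c(2.15, 2.22, 1.56, 1.41,
               0.39, 0.42, 0.35, 0.32,
               0.37, 0.44, 0.37, 0.38,
               0.31, 22.15, 5.58),
  stringsAsFactors = FALSE
)

#' Reference cohort group-conditional moments
#'
#' Per-feature means and standard deviations of the adverse-event (+) and
#' (-) groups of the reference cohort, in scaled units, used as the
#' defaults of [cohort_spec()].
#' @return data.frame with columns `feature`, `mean_pos`, `sd_pos`,
#'   `mean_neg`, `sd_neg`.
#' @export
reference_cohort_moments <- function() .table1

# auxiliary reference rates: event prevalence 34/296, dilation 13/34 vs
# 31/262, male sex 14/34 vs 118/262, age 59.32 +/- 13.71 vs 60.71 +/- 14.57
.reference_rates <- list(
  n_total = 296L, n_events = 34L,
  dilation_pos = 13 / 34, dilation_neg = 31 / 262,
  male_pos = 14 / 34, male_neg = 118 / 262,
  age_mean_pos = 59.32, age_sd_pos = 13.71,
  age_mean_neg = 60.71, age_sd_neg = 14.57
)
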