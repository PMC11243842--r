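#' Crisp Low/Normal/High banding of a single physiological parameter
#'
#' A value is Low when strictly below the parameter's `low_cut`, High when
#' strictly above `high_cut`, and Normal otherwise — the cut points
#' themselves belong to the Normal band, matching the strict inequality
#' signs of the reference table (e.g. HR Low `<60`, Normal `60-90`,
#' High `>90`).
#'
#' @param parameter One of `"hr"`, `"prv"`, `"rr"`, `"spo2"`, `"gsr"`,
#'   `"bt"`, `"sbp"`, `"dbp"` (case-insensitive).
#' @param value Numeric vector of finite values.
#' @param ranges A [reference_ranges()] table.
#' @return Factor with levels `Low`, `Normal`, `High`.
#' @examples
#' classify_parameter("hr", c(55, 60, 75, 90, 95))
#' classify_parameter("spo2", 96)   # Low
#' classify_parameter("sbp", 130)   # High
#' @export
classify_parameter <- function(parameter, value, ranges = reference_ranges()) {
  stopifnot(length(parameter) == 1)
  r <- range_row(ranges, tolower(parameter))
  if (!all(is.finite(value))) stop("invalid input: non-finite value")
  band <- ifelse(value < r$low_cut, "Low",
                 ifelse(value > r$high_cut, "High", "Normal"))
  factor(band, levels = c("Low", "Normal", "High"))
}

#' Categorise a blood glucose reading
#'
#' Applies the state-specific cut points in mg/dL. Fasting: hypoglycemia
#' `<70`, normal `70-99`, pre-diabetes `100-125`, diabetes `>125`. After
#' meals: hypoglycemia `<70`, normal `70-139`, pre-diabetes `140-199`,
#' diabetes `>199`. The fasting table leaves the open interval (99, 100)
#' unassigned; such values are classified normal (the pre-diabetes band is
#' taken to start at 100).
#'
#' @param value Glucose in mg/dL, positive; vectorised.
#' @param state `"fasting"` or `"post_meal"`; recycled against `value`.
#' @return Factor with levels `hypoglycemia`, `normal`, `pre_diabetes`,
#'   `diabetes`.
#' @examples
#' classify_glucose(110, "fasting")     # pre_diabetes
#' classify_glucose(150, "post_meal")   # pre_diabetes
#' classify_glucose(65, "fasting")      # hypoglycemia
#' @export
classify_glucose <- function(value, state = c("fasting", "post_meal")) {
  if (!is.numeric(value) || !all(is.finite(value)) || any(value <= 0))
    stop("invalid input: glucose must be a positive finite value in mg/dL")
  if (identical(state, c("fasting", "post_meal"))) state <- "fasting"
  state <- rep_len(as.character(state), length(value))
  if (!all(state %in% c("fasting", "post_meal")))
    stop("state must be 'fasting' or 'post_meal'")
  pre_lo <- ifelse(state == "fasting", 100, 140)
  dia_lo <- ifelse(state == "fasting", 125, 199)
  cat <- ifelse(value < 70, "hypoglycemia",
                ifelse(value > dia_lo, "diabetes",
                       ifelse(value >= pre_lo, "pre_diabetes", "normal")))
  factor(cat, levels = c("hypoglycemia", "normal", "pre_diabetes", "diabetes"))
}

#' Band a blood pressure reading
#'
#' Classifies the systolic and diastolic components independently against
#' their reference ranges (systolic normal 90-120 mmHg, diastolic
#' 60-80 mmHg) and combines them into an overall band: High if either
#' component is High, otherwise Low if either is Low, otherwise Normal.
#'
#' @param sbp,dbp Systolic and diastolic pressure in mmHg; vectorised,
#'   `sbp > dbp > 0` required elementwise.
#' @param ranges A [reference_ranges()] table.
#' @return Data frame with factor columns `systolic_band`, `diastolic_band`,
#'   `overall`.
#' @examples
#' classify_bp(110, 70)   # all Normal
#' classify_bp(125, 70)   # overall High
#' @export
classify_bp <- function(sbp, dbp, ranges = reference_ranges()) {
  if (!all(is.finite(sbp)) || !all(is.finite(dbp)))
    stop("invalid input: non-finite blood pressure")
  if (any(dbp <= 0) || any(sbp <= dbp))
    stop("invalid input: require sbp > dbp > 0")
  s <- classify_parameter("sbp", sbp, ranges)
  d <- classify_parameter("dbp", dbp, ranges)
  overall <- ifelse(s == "High" | d == "High", "High",
                    ifelse(s == "Low" | d == "Low", "Low", "Normal"))
  data.frame(systolic_band = s, diastolic_band = d,
             overall = factor(overall, levels = c("Low", "Normal", "High")))
}
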