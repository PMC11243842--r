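#' Clinical reference ranges for the eight physiological parameters
#'
#' Returns the Low/Normal/High cut points used both for crisp banding and as
#' the anchor points of the fuzzy membership functions. The normal band for
#' each parameter is `[low_cut, high_cut]`; values strictly below `low_cut`
#' are Low and strictly above `high_cut` are High. Each range also carries a
#' transition half-width `delta` (in parameter units) giving the width of the
#' fuzzy transition around each cut point: `delta = transition_fraction *
#' (high_cut - low_cut)`. As `delta -> 0` the memberships degenerate to the
#' crisp bands.
#'
#' Defaults reflect resting adult reference values: HR 60-90 bpm, PRV (RMSSD)
#' 32-77 ms, RR 12-18 breaths/min, SpO2 97-99 %, GSR 30-50 kOhm, body
#' temperature 36.5-37.5 degC, systolic BP 90-120 mmHg, diastolic BP
#' 60-80 mmHg. GSR is expressed as skin *resistance*, so stress (sweating)
#' lowers the value.
#'
#' @param transition_fraction Fraction of the normal-band width used as the
#'   fuzzy transition half-width; must be in `[0, 0.5)`. Zero gives crisp
#'   step memberships.
#' @return A data frame with one row per parameter and columns `parameter`,
#'   `low_cut`, `high_cut`, `unit`, `delta`.
#' @examples
#' reference_ranges()
#' reference_ranges(transition_fraction = 0.05)
#' @export
reference_ranges <- function(transition_fraction = 0.10) {
  stopifnot(is.numeric(transition_fraction), length(transition_fraction) == 1,
            transition_fraction >= 0, transition_fraction < 0.5)
  r <- data.frame(
    parameter = c("hr", "prv", "rr", "spo2", "gsr", "bt", "sbp", "dbp"),
    low_cut   = c(60,   32,    12,   97,     30,    36.5, 90,    60),
    high_cut  = c(90,   77,    18,   99,     50,    37.5, 120,   80),
    unit      = c("beats/min", "ms", "breaths/min", "%", "kOhm", "degC",
                  "mmHg", "mmHg"),
    stringsAsFactors = FALSE
  )
  r$delta <- transition_fraction * (r$high_cut - r$low_cut)
  validate_ranges(r)
  r
}

#' Validate a reference-range table
#'
#' Checks the structural invariants of a range table: known parameter names,
#' `low_cut < high_cut`, and `delta < (high_cut - low_cut) / 2` so that at
#' most two memberships are ever simultaneously nonzero.
#'
#' @param ranges A data frame as returned by [reference_ranges()].
#' @return The validated table, invisibly.
#' @export
validate_ranges <- function(ranges) {
  need <- c("parameter", "low_cut", "high_cut", "delta")
  if (!is.data.frame(ranges) || !all(need %in% names(ranges)))
    stop("ranges must be a data frame with columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(ranges$parameter))
    stop("duplicated parameter in ranges")
  if (!all(is.finite(ranges$low_cut)) || !all(is.finite(ranges$high_cut)))
    stop("non-finite cut point in ranges")
  bad <- ranges$low_cut >= ranges$high_cut
  if (any(bad))
    stop("low_cut must be < high_cut (violated for: ",
         paste(ranges$parameter[bad], collapse = ", "), ")")
  bad <- !(ranges$delta >= 0 & ranges$delta < (ranges$high_cut - ranges$low_cut) / 2)
  if (any(bad))
    stop("delta must satisfy 0 <= delta < (high_cut - low_cut)/2 ",
         "(violated for: ", paste(ranges$parameter[bad], collapse = ", "), ")")
  invisible(ranges)
}

physio_params <- function() c("hr", "prv", "rr", "spo2", "gsr", "bt", "sbp", "dbp")

range_row <- function(ranges, parameter) {
  i <- match(parameter, ranges$parameter)
  if (is.na(i)) stop("unknown parameter: ", parameter)
  ranges[i, , drop = FALSE]
}
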