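#' Engine configuration for the fuzzy stress classifier
#'
#' Bundles the tunable parameters of the inference engine. The rule base and
#' membership shapes are fixed; everything a user might reasonably vary is
#' here.
#'
#' @param tnorm Aggregator for the eight antecedents of each rule: `"mean"`
#'   (arithmetic mean, the default), `"min"` (Goedel t-norm) or `"product"`.
#'   With eight-way `min` or `product`, a single parameter that disagrees
#'   with a rule's direction zeroes that rule, and realistic mixed samples
#'   frequently zero all three; `mean` keeps activations graded.
#' @param transition_fraction Fraction of each normal-band width used as the
#'   fuzzy transition half-width around the cut points (see
#'   [reference_ranges()]). In `[0, 0.5)`.
#' @param degenerate_policy What to do when all three rule activations are
#'   zero: `"fallback_normal"` returns score 2 (Normal) with
#'   `degenerate = TRUE`; `"error"` raises a degenerate-inference error.
#' @param t_low,t_high Score thresholds mapping the continuous 1-3 score to a
#'   class: Calm below `t_low`, Stressed above `t_high`, Normal otherwise
#'   (boundaries inclusive to Normal). Must satisfy `1 < t_low < t_high < 3`.
#' @return A list of class `"engine_config"`.
#' @examples
#' engine_config()
#' engine_config(tnorm = "min", transition_fraction = 0.05)
#' @export
engine_config <- function(tnorm = c("mean", "min", "product"),
                          transition_fraction = 0.10,
                          degenerate_policy = c("fallback_normal", "error"),
                          t_low = 1.5, t_high = 2.5) {
  tnorm <- match.arg(tnorm)
  degenerate_policy <- match.arg(degenerate_policy)
  stopifnot(is.numeric(transition_fraction), length(transition_fraction) == 1,
            transition_fraction >= 0, transition_fraction < 0.5,
            is.numeric(t_low), is.numeric(t_high),
            1 < t_low, t_low < t_high, t_high < 3)
  structure(list(tnorm = tnorm,
                 transition_fraction = transition_fraction,
                 degenerate_policy = degenerate_policy,
                 t_low = t_low, t_high = t_high),
            class = "engine_config")
}

#' @export
print.engine_config <- function(x, ...) {
  cat("Fuzzy engine configuration\n")
  cat("  t-norm:              ", x$tnorm, "\n")
  cat("  transition fraction: ", x$transition_fraction, "\n")
  cat("  degenerate policy:   ", x$degenerate_policy, "\n")
  cat("  class thresholds:    Calm < ", x$t_low, " <= Normal <= ", x$t_high,
      " < Stressed\n", sep = "")
  invisible(x)
}

stress_labels <- function() c("Calm", "Normal", "Stressed")

#' Fuzzify one parameter value into Low/Normal/High membership degrees
#'
#' Membership shapes follow the usual three-band scheme: a right-shoulder
#' trapezoid for Low (1 below `low_cut - delta`, falling linearly to 0 at
#' `low_cut + delta`), a left-shoulder trapezoid for High (mirrored around
#' `high_cut`), and a triangle for Normal rising from 0 at `low_cut - delta`
#' to 1 at the normal-band midpoint and falling back to 0 at
#' `high_cut + delta`. At `delta = 0` the shoulders become crisp steps and
#' the Normal triangle has vertices at the cut points.
#'
#' @param value Numeric vector of parameter values (finite).
#' @param range A single row of a [reference_ranges()] table (or any list
#'   with `low_cut`, `high_cut`, `delta`).
#' @return A data frame with columns `low`, `normal`, `high`, one row per
#'   value; each degree in `[0, 1]` and at most two nonzero.
#' @examples
#' hr <- reference_ranges()[1, ]
#' fuzzify(c(57, 60, 75, 90, 95), hr)
#' @export
fuzzify <- function(value, range) {
  if (!all(is.finite(value)))
    stop("invalid input: non-finite parameter value")
  L <- range$low_cut; H <- range$high_cut; d <- range$delta
  stopifnot(length(L) == 1, L < H, d >= 0, d < (H - L) / 2)
  m <- (L + H) / 2
  if (d > 0) {
    low  <- pmin(1, pmax(0, (L + d - value) / (2 * d)))
    high <- pmin(1, pmax(0, (value - (H - d)) / (2 * d)))
  } else {
    low  <- as.numeric(value < L)
    high <- as.numeric(value > H)
  }
  normal <- ifelse(value <= m,
                   (value - (L - d)) / (m - (L - d)),
                   ((H + d) - value) / ((H + d) - m))
  normal <- pmin(1, pmax(0, normal))
  data.frame(low = low, normal = normal, high = high)
}

# 8 x 3 membership matrix (rows = parameters, cols = low/normal/high) for one
# sample, or an n x 8 x 3 array for a matrix of samples.
membership_matrix <- function(values, ranges) {
  params <- physio_params()
  values <- as.matrix(values)
  if (!all(params %in% colnames(values)))
    stop("incomplete sample: missing parameter(s): ",
         paste(setdiff(params, colnames(values)), collapse = ", "))
  n <- nrow(values)
  out <- array(NA_real_, dim = c(n, length(params), 3),
               dimnames = list(NULL, params, c("low", "normal", "high")))
  for (p in params) {
    deg <- fuzzify(values[, p], range_row(ranges, p))
    out[, p, ] <- as.matrix(deg)
  }
  out
}

#' Fuzzify a complete eight-parameter sample
#'
#' @param sample A named list or one-row data frame with the eight parameters
#'   `hr`, `prv`, `rr`, `spo2`, `gsr`, `bt`, `sbp`, `dbp`.
#' @param ranges A [reference_ranges()] table.
#' @return An 8 x 3 numeric matrix of membership degrees (rows = parameters,
#'   columns = `low`, `normal`, `high`).
#' @export
fuzzify_sample <- function(sample, ranges = reference_ranges()) {
  v <- matrix(NA_real_, 1, 8, dimnames = list(NULL, physio_params()))
  for (p in physio_params()) {
    if (is.null(sample[[p]]))
      stop("incomplete sample: missing parameter(s): ", p)
    v[1, p] <- as.numeric(sample[[p]])
  }
  a <- membership_matrix(v, ranges)
  matrix(a[1, , ], nrow = 8, ncol = 3,
         dimnames = list(physio_params(), c("low", "normal", "high")))
}

# Rule directions: which linguistic band each parameter must occupy for each
# rule. R1 = Calm, R2 = Normal, R3 = Stressed. GSR is a resistance, so calm
# (dry skin) means High resistance and stress means Low.
rule_directions <- function() {
  list(
    r1 = c(hr = "low",  prv = "low",  rr = "low",  spo2 = "high",
           gsr = "high", bt = "high", sbp = "low",  dbp = "low"),
    r2 = c(hr = "normal", prv = "normal", rr = "normal", spo2 = "normal",
           gsr = "normal", bt = "normal", sbp = "normal", dbp = "normal"),
    r3 = c(hr = "high", prv = "high", rr = "high", spo2 = "low",
           gsr = "low",  bt = "low",  sbp = "high", dbp = "high")
  )
}

aggregate_degrees <- function(mat, tnorm) {
  # mat: n x 8 matrix of the eight antecedent degrees per sample
  switch(tnorm,
         mean    = rowMeans(mat),
         min     = do.call(pmin, as.data.frame(mat)),
         product = apply(mat, 1, prod),
         stop("unknown tnorm: ", tnorm))
}

#' Evaluate the three-rule base on fuzzified membership degrees
#'
#' Rule R1 (Calm) conjoins the eight calm-direction degrees (Low HR, Low PRV,
#' Low RR, High SpO2, High GSR, High BT, Low SBP, Low DBP), R2 (Normal) the
#' eight Normal degrees, and R3 (Stressed) the mirrored stressed-direction
#' degrees. The conjunction is the configured t-norm.
#'
#' @param degrees An 8 x 3 membership matrix from [fuzzify_sample()].
#' @param config An [engine_config()].
#' @return Named numeric vector `c(r1, r2, r3)`, each in `[0, 1]`.
#' @export
activate_rules <- function(degrees, config = engine_config()) {
  params <- physio_params()
  if (!is.matrix(degrees) || !all(params %in% rownames(degrees)) ||
      !all(c("low", "normal", "high") %in% colnames(degrees)))
    stop("incomplete sample: need an 8 x 3 membership matrix with rows ",
         paste(params, collapse = ", "))
  if (anyNA(degrees[params, ]))
    stop("incomplete sample: missing membership degree")
  dirs <- rule_directions()
  acts <- vapply(dirs, function(d) {
    v <- degrees[cbind(params, d[params])]
    aggregate_degrees(matrix(v, nrow = 1), config$tnorm)
  }, numeric(1))
  names(acts) <- c("r1", "r2", "r3")
  acts
}

#' Defuzzify rule activations into a stress score and class
#'
#' The crisp score is the weighted average of the rule consequents 1 (Calm),
#' 2 (Normal) and 3 (Stressed):
#' `score = (r1*1 + r2*2 + r3*3) / (r1 + r2 + r3)`.
#' The class is Calm when `score < t_low`, Stressed when `score > t_high`,
#' Normal otherwise. When all three activations are zero the score is
#' undefined; the configured `degenerate_policy` either falls back to Normal
#' (score 2, flagged) or errors.
#'
#' @param acts Numeric vector `c(r1, r2, r3)` with entries in `[0, 1]`.
#' @param config An [engine_config()].
#' @return A list of class `"stress_assessment"` with elements `score`
#'   (in `[1, 3]`), `label` (factor Calm/Normal/Stressed) and `degenerate`.
#' @examples
#' defuzzify(c(r1 = 0.1, r2 = 0.2, r3 = 0.3))  # score 7/3
#' @export
defuzzify <- function(acts, config = engine_config()) {
  acts <- as.numeric(acts)
  if (length(acts) != 3 || anyNA(acts) || any(acts < 0) || any(acts > 1))
    stop("activations must be three values in [0, 1]")
  tot <- sum(acts)
  if (tot > 0) {
    score <- sum(acts * 1:3) / tot
    degenerate <- FALSE
  } else if (config$degenerate_policy == "fallback_normal") {
    score <- 2
    degenerate <- TRUE
  } else {
    stop("degenerate inference: all rule activations are zero")
  }
  label <- score_to_label(score, config)
  structure(list(score = score, label = label, degenerate = degenerate),
            class = "stress_assessment")
}

score_to_label <- function(score, config) {
  lab <- ifelse(score < config$t_low, "Calm",
                ifelse(score > config$t_high, "Stressed", "Normal"))
  factor(lab, levels = stress_labels())
}

#' @export
print.stress_assessment <- function(x, ...) {
  cat(sprintf("Stress assessment: %s (score %.3f)%s\n", as.character(x$label),
              x$score, if (x$degenerate) " [degenerate: fallback]" else ""))
  invisible(x)
}

#' Construct a fuzzy stress inference system
#'
#' Creates the classifier object combining the clinical reference ranges and
#' the engine configuration. Use [predict.stress_fis()] to score data frames
#' of samples, or [assess()] for a single sample.
#'
#' @param ranges A [reference_ranges()] table; its `delta` column is
#'   recomputed from `config$transition_fraction` so the two stay consistent.
#' @param config An [engine_config()].
#' @return An object of class `"stress_fis"`.
#' @examples
#' fis <- stress_fis()
#' assess(list(hr = 75, prv = 54.5, rr = 15, spo2 = 98, gsr = 40, bt = 37,
#'             sbp = 105, dbp = 70), fis)
#' @export
stress_fis <- function(ranges = reference_ranges(), config = engine_config()) {
  ranges$delta <- config$transition_fraction * (ranges$high_cut - ranges$low_cut)
  validate_ranges(ranges)
  structure(list(ranges = ranges, config = config), class = "stress_fis")
}

#' @export
print.stress_fis <- function(x, ...) {
  cat("Fuzzy stress inference system (3 rules: Calm / Normal / Stressed)\n\n")
  print(x$config)
  cat("\nReference ranges:\n")
  print(x$ranges, row.names = FALSE)
  invisible(x)
}

#' Assess the stress level of one physiological sample
#'
#' Composes fuzzification of the eight parameters, evaluation of the three
#' rules, and defuzzification. Deterministic for fixed input and
#' configuration.
#'
#' @param sample Named list or one-row data frame with `hr`, `prv`, `rr`,
#'   `spo2`, `gsr`, `bt`, `sbp`, `dbp`.
#' @param fis A [stress_fis()] object.
#' @return A `"stress_assessment"` (see [defuzzify()]) with the rule
#'   activations attached as attribute `"activations"`.
#' @export
assess <- function(sample, fis = stress_fis()) {
  validate_sample(sample)
  deg <- fuzzify_sample(sample, fis$ranges)
  acts <- activate_rules(deg, fis$config)
  out <- defuzzify(acts, fis$config)
  attr(out, "activations") <- acts
  out
}

validate_sample <- function(sample) {
  for (p in physio_params()) {
    v <- sample[[p]]
    if (is.null(v) || !is.numeric(v) || !all(is.finite(v)))
      stop("invalid sample: parameter '", p, "' missing or non-finite")
  }
  if (any(sample[["spo2"]] > 100)) stop("invalid sample: spo2 > 100")
  if (any(sample[["gsr"]] < 0)) stop("invalid sample: gsr < 0")
  if (any(sample[["sbp"]] <= sample[["dbp"]]))
    stop("invalid sample: sbp must exceed dbp")
  invisible(sample)
}

#' Score a data frame of samples with the fuzzy stress system
#'
#' Vectorised assessment: fuzzifies every row, evaluates the rule base and
#' defuzzifies, returning one row of results per input row.
#'
#' @param object A [stress_fis()].
#' @param newdata Data frame with the eight parameter columns `hr`, `prv`,
#'   `rr`, `spo2`, `gsr`, `bt`, `sbp`, `dbp` (extra columns ignored).
#' @param ... Unused.
#' @return Data frame with columns `score`, `label`, `degenerate`, `r1`,
#'   `r2`, `r3`.
#' @export
predict.stress_fis <- function(object, newdata, ...) {
  params <- physio_params()
  miss <- setdiff(params, names(newdata))
  if (length(miss))
    stop("incomplete sample: missing parameter(s): ", paste(miss, collapse = ", "))
  v <- as.matrix(newdata[params])
  if (!all(is.finite(v))) stop("invalid input: non-finite parameter value")
  a <- membership_matrix(v, object$ranges)
  dirs <- rule_directions()
  cfg <- object$config
  acts <- sapply(dirs, function(d) {
    m <- sapply(params, function(p) a[, p, d[[p]]])
    if (nrow(v) == 1) m <- matrix(m, nrow = 1)
    aggregate_degrees(m, cfg$tnorm)
  })
  if (nrow(v) == 1) acts <- matrix(acts, nrow = 1, dimnames = list(NULL, names(dirs)))
  tot <- rowSums(acts)
  degenerate <- tot == 0
  score <- ifelse(degenerate, 2, (acts[, 1] + 2 * acts[, 2] + 3 * acts[, 3]) / tot)
  if (any(degenerate) && cfg$degenerate_policy == "error")
    stop("degenerate inference: all rule activations are zero for row(s) ",
         paste(utils::head(which(degenerate), 5), collapse = ", "))
  data.frame(score = score,
             label = score_to_label(score, cfg),
             degenerate = degenerate,
             r1 = acts[, 1], r2 = acts[, 2], r3 = acts[, 3])
}
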