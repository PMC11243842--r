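#' Specification of a synthetic diabetic cohort
#'
#' Parameters of the cohort generator. Defaults reproduce the study-like
#' demographics: 128 volunteers (68 male, 60 female), ages drawn from a
#' normal distribution with mean 42 and SD 17 truncated to 12-75 years.
#' Coupling strengths encode the observed co-movement of stress, glucose
#' and blood pressure: glucose shifts by `stress_glucose_coupling` mg/dL per
#' latent stress level (relative to Normal), blood pressure by
#' `stress_bp_coupling` mmHg per level plus `glucose_bp_coupling` mmHg per
#' mg/dL of glucose excursion from the subject's baseline.
#'
#' @param n_subjects,n_male Cohort size and number of males
#'   (`n_male <= n_subjects`).
#' @param age_mean,age_sd,age_range Truncated-normal age distribution
#'   (years); `age_range` within `[0, 120]`.
#' @param stress_glucose_coupling mg/dL per stress level, >= 0.
#' @param stress_bp_coupling mmHg per stress level, >= 0.
#' @param glucose_bp_coupling mmHg per mg/dL of glucose excursion, >= 0.
#' @param meal_rise Peak post-meal glucose rise, mg/dL (reached about 40
#'   minutes after eating).
#' @param med_drop Full medication-driven glucose fall, mg/dL (reached about
#'   60 minutes after the dose).
#' @param class_prevalence Probabilities of the latent Calm/Normal/Stressed
#'   classes per record; default uniform.
#' @param noise_sd Named numeric vector of additive noise SDs for the eight
#'   physiological parameters and glucose, in parameter units. Use
#'   `noise_scale` for a global multiplier.
#' @param noise_scale Global multiplier applied to `noise_sd` (0 = noiseless).
#' @param seed Integer seed making the whole cohort reproducible.
#' @return A list of class `"cohort_spec"`.
#' @examples
#' cohort_spec()
#' cohort_spec(n_subjects = 10, n_male = 5, noise_scale = 0, seed = 7)
#' @export
cohort_spec <- function(n_subjects = 128, n_male = 68,
                        age_mean = 42, age_sd = 17, age_range = c(12, 75),
                        stress_glucose_coupling = 12,
                        stress_bp_coupling = 2,
                        glucose_bp_coupling = 0.05,
                        meal_rise = 55, med_drop = 40,
                        class_prevalence = c(1, 1, 1) / 3,
                        noise_sd = c(hr = 2, prv = 3, rr = 0.8, spo2 = 0.3,
                                     gsr = 2, bt = 0.15, sbp = 3, dbp = 2,
                                     glucose = 6),
                        noise_scale = 1,
                        seed = 1L) {
  stopifnot(n_subjects >= 1, n_male >= 0, n_male <= n_subjects,
            age_range[1] >= 0, age_range[2] <= 120, age_range[1] < age_range[2],
            stress_glucose_coupling >= 0, stress_bp_coupling >= 0,
            glucose_bp_coupling >= 0, meal_rise >= 0, med_drop >= 0,
            noise_scale >= 0, length(class_prevalence) == 3,
            all(class_prevalence >= 0), sum(class_prevalence) > 0)
  need <- c(physio_params(), "glucose")
  if (!all(need %in% names(noise_sd)))
    stop("noise_sd must name: ", paste(need, collapse = ", "))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_male = as.integer(n_male),
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 stress_glucose_coupling = stress_glucose_coupling,
                 stress_bp_coupling = stress_bp_coupling,
                 glucose_bp_coupling = glucose_bp_coupling,
                 meal_rise = meal_rise, med_drop = med_drop,
                 class_prevalence = class_prevalence / sum(class_prevalence),
                 noise_sd = noise_sd[need] * noise_scale,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec: %d subjects (%d M / %d F), ages ~ N(%g, %g) on [%g, %g]\n",
              x$n_subjects, x$n_male, x$n_subjects - x$n_male,
              x$age_mean, x$age_sd, x$age_range[1], x$age_range[2]))
  cat(sprintf("  couplings: stress-glucose %g mg/dL, stress-BP %g mmHg, glucose-BP %g mmHg per mg/dL\n",
              x$stress_glucose_coupling, x$stress_bp_coupling,
              x$glucose_bp_coupling))
  cat(sprintf("  meal rise %g / medication drop %g mg/dL; seed %d\n",
              x$meal_rise, x$med_drop, x$seed))
  invisible(x)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate the subjects of a synthetic cohort
#'
#' Draws the requested number of subjects with the requested sex split,
#' truncated-normal ages, and per-subject baselines: fasting glucose spanning
#' the normal-to-diabetic range, and resting blood pressure mildly coupled to
#' the glucose baseline.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with one row per subject: `subject_id`, `tag_number`,
#'   `sex`, `age`, `glucose_baseline`, `sbp_baseline`, `dbp_baseline`.
#' @examples
#' subjects <- generate_cohort(cohort_spec(seed = 1))
#' nrow(subjects); mean(subjects$age)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  sex <- c(rep("M", spec$n_male), rep("F", n - spec$n_male))
  age <- rtruncnorm1(n, spec$age_mean, spec$age_sd,
                     spec$age_range[1], spec$age_range[2])
  glucose_baseline <- rtruncnorm1(n, 125, 30, 80, 190)
  sbp_baseline <- 105 + 0.15 * (glucose_baseline - 125) + stats::rnorm(n, 0, 8)
  dbp_baseline <- 70 + 0.5 * (sbp_baseline - 105) + stats::rnorm(n, 0, 4)
  dbp_baseline <- pmin(dbp_baseline, sbp_baseline - 15)
  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
             tag_number = sprintf("TAG-%05d", 10000 + seq_len(n)),
             sex = sex, age = age,
             glucose_baseline = glucose_baseline,
             sbp_baseline = sbp_baseline,
             dbp_baseline = dbp_baseline,
             stringsAsFactors = FALSE)
}

protocol_phases <- function() {
  # breakfast 08:00, medication 08:30, lunch 12:30; sampling clock times
  data.frame(
    phase = c("post_meal_1", "post_medication", "pre_meal", "post_meal_2"),
    clock = c("08:40", "10:00", "12:20", "13:10"),
    min_since_meal = c(40, 120, NA, 40),   # breakfast / breakfast / - / lunch
    min_since_dose = c(10, 90, 230, 280),  # medication 08:30
    stringsAsFactors = FALSE
  )
}

# piecewise-linear meal pulse: 0 -> peak at 40 min, linear decay to 0 at 160
meal_effect <- function(min_since_meal, rise) {
  ifelse(is.na(min_since_meal) | min_since_meal < 0, 0,
         ifelse(min_since_meal <= 40, rise * min_since_meal / 40,
                pmax(0, rise * (1 - (min_since_meal - 40) / 120))))
}

# medication: ramps to full effect at 60 min, holds through the day
med_effect <- function(min_since_dose, drop) {
  ifelse(is.na(min_since_dose) | min_since_dose < 0, 0,
         ifelse(min_since_dose <= 60, drop * min_since_dose / 60, drop))
}

# representative value inside the band a rule direction points at; offset
# 30% of the normal-band width beyond the cut, safely past the fuzzy
# transition (10% half-width) so zero-noise samples are crisply in band
band_target <- function(parameter, direction, ranges) {
  r <- range_row(ranges, parameter)
  w <- r$high_cut - r$low_cut
  v <- switch(direction,
              low    = r$low_cut - 0.3 * w,
              normal = (r$low_cut + r$high_cut) / 2,
              high   = r$high_cut + 0.3 * w)
  if (parameter == "spo2") v <- min(v, 99.8)
  if (parameter == "gsr") v <- max(v, 1)
  v
}

#' Generate the five-day, four-phase record series for one subject
#'
#' Emits 20 timestamped records (5 days x 4 daily phases: 40 min after
#' breakfast, after the morning medication has taken effect, before lunch,
#' and 40 min after lunch). Each record carries a latent stress class drawn
#' from `spec$class_prevalence`; the eight physiological parameters are
#' placed inside the reference band that the rule base associates with that
#' class (e.g. Stressed: HR above 90, GSR below 30 kOhm) plus noise.
#' Glucose follows baseline + meal pulse - medication effect + stress
#' coupling + noise; blood pressure adds stress and glucose-excursion
#' couplings. The pre-lunch reading is flagged fasting, the others
#' post-meal.
#'
#' @param subject One row of [generate_cohort()] output.
#' @param spec The [cohort_spec()] used to generate the cohort.
#' @param ranges A [reference_ranges()] table.
#' @return Data frame of 20 protocol records with the eight parameters,
#'   `glucose`, `glucose_state`, `latent_class` and ISO 8601 `timestamp`.
#' @export
generate_series <- function(subject, spec, ranges = reference_ranges()) {
  idx <- as.integer(sub("^S", "", subject$subject_id))
  set.seed((spec$seed * 1000L + idx) %% .Machine$integer.max)
  ph <- protocol_phases()
  grid <- expand.grid(day = 1:5, phase_i = seq_len(nrow(ph)))
  grid <- grid[order(grid$day, grid$phase_i), ]
  nrec <- nrow(grid)

  cls <- sample(1:3, nrec, replace = TRUE, prob = spec$class_prevalence)
  noise <- spec$noise_sd

  meal <- meal_effect(ph$min_since_meal[grid$phase_i], spec$meal_rise)
  med <- med_effect(ph$min_since_dose[grid$phase_i], spec$med_drop)
  glucose <- subject$glucose_baseline + meal - med +
    spec$stress_glucose_coupling * (cls - 2) +
    stats::rnorm(nrec, 0, noise[["glucose"]])
  glucose <- pmax(glucose, 40)

  dirs <- rule_directions()
  vals <- sapply(physio_params(), function(p) {
    tgt <- vapply(cls, function(k) {
      band_target(p, dirs[[k]][[p]], ranges)
    }, numeric(1))
    tgt + stats::rnorm(nrec, 0, noise[[p]])
  })
  vals <- as.data.frame(vals)

  excess <- glucose - subject$glucose_baseline
  vals$sbp <- vals$sbp + spec$stress_bp_coupling * (cls - 2) +
    spec$glucose_bp_coupling * excess
  vals$dbp <- vals$dbp + 0.5 * spec$stress_bp_coupling * (cls - 2) +
    0.5 * spec$glucose_bp_coupling * excess
  vals$dbp <- pmin(vals$dbp, vals$sbp - 5)
  vals$spo2 <- pmin(vals$spo2, 100)
  vals$gsr <- pmax(vals$gsr, 0.5)

  phase <- ph$phase[grid$phase_i]
  ts <- as.POSIXct(paste0("2024-01-", 7 + grid$day, " ",
                          ph$clock[grid$phase_i], ":00"), tz = "UTC")
  data.frame(subject_id = subject$subject_id,
             tag_number = subject$tag_number,
             day = grid$day,
             phase = phase,
             timestamp = format(ts, "%Y-%m-%dT%H:%M:%S+00:00"),
             vals,
             glucose = glucose,
             glucose_state = ifelse(phase == "pre_meal", "fasting", "post_meal"),
             latent_class = factor(stress_labels()[cls], levels = stress_labels()),
             stringsAsFactors = FALSE)
}

#' Generate the full protocol dataset for a cohort
#'
#' @param spec A [cohort_spec()].
#' @param ranges A [reference_ranges()] table.
#' @return Data frame of `n_subjects * 20` protocol records.
#' @examples
#' d <- generate_protocol_data(cohort_spec(n_subjects = 4, n_male = 2))
#' table(d$phase)
#' @export
generate_protocol_data <- function(spec = cohort_spec(),
                                   ranges = reference_ranges()) {
  subjects <- generate_cohort(spec)
  out <- lapply(seq_len(nrow(subjects)), function(i)
    generate_series(subjects[i, ], spec, ranges))
  do.call(rbind, out)
}

#' Latent-class recovery experiment
#'
#' Generates a full protocol dataset, scores every record with the fuzzy
#' stress system, and compares predicted against latent classes. This is the
#' package's internal validation surface: at zero noise the generator places
#' every parameter crisply inside its class-direction band, so the engine
#' should recover essentially all labels.
#'
#' @param spec A [cohort_spec()].
#' @param fis A [stress_fis()].
#' @return List of class `"recovery_result"`: `accuracy` (overall fraction
#'   correct), `per_class_accuracy` (recall per latent class), `confusion`
#'   (a [confusion()] matrix), `metrics` ([per_class_metrics()] table) and
#'   `n` (records scored).
#' @examples
#' res <- label_recovery_experiment(cohort_spec(n_subjects = 8, n_male = 4,
#'                                              noise_scale = 0))
#' res$accuracy
#' @export
label_recovery_experiment <- function(spec = cohort_spec(),
                                      fis = stress_fis()) {
  data <- generate_protocol_data(spec, fis$ranges)
  pred <- predict(fis, data)
  cm <- confusion(data$latent_class, pred$label)
  diag_ <- diag(unclass(cm))
  rs <- rowSums(unclass(cm))
  structure(list(accuracy = sum(diag_) / sum(cm),
                 per_class_accuracy = ifelse(rs > 0, diag_ / rs, NA_real_),
                 confusion = cm,
                 metrics = per_class_metrics(cm),
                 n = sum(cm)),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("Latent-class recovery: accuracy %.3f over %d records\n",
              x$accuracy, x$n))
  cat("Per-class recall:\n")
  print(round(x$per_class_accuracy, 3))
  print(x$confusion)
  invisible(x)
}
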