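hr_range <- reference_ranges()[1, ]   # 60-90, delta 3

test_that("fuzzification matches the piecewise membership shapes", {
  # apex of the Normal triangle at the band midpoint
  d <- fuzzify(75, hr_range)
  expect_equal(unlist(d), c(low = 0, normal = 1, high = 0))

  # midpoint of the linear transition exactly at the cut point
  d <- fuzzify(60, hr_range)
  expect_equal(d$low, 0.5)
  expect_equal(d$high, 0)

  # at low_cut - delta the Low shoulder saturates and the triangle starts
  d <- fuzzify(57, hr_range)
  expect_equal(unlist(d), c(low = 1, normal = 0, high = 0))

  # mirrored High shoulder
  expect_equal(fuzzify(90, hr_range)$high, 0.5)
  expect_equal(fuzzify(93, hr_range)$high, 1)

  expect_error(fuzzify(NaN, hr_range), "non-finite")
})

test_that("membership degrees are bounded and at most two are nonzero", {
  ranges <- reference_ranges()
  set.seed(42)
  for (i in seq_len(200)) {
    p <- sample(ranges$parameter, 1)
    r <- ranges[ranges$parameter == p, ]
    v <- runif(1, r$low_cut - (r$high_cut - r$low_cut),
               r$high_cut + (r$high_cut - r$low_cut))
    d <- unlist(fuzzify(v, r))
    expect_true(all(d >= 0 & d <= 1))
    expect_lte(sum(d > 0), 2)
  }
})

test_that("rule activation follows the Calm/Normal/Stressed directions", {
  fis <- stress_fis()
  all_normal <- matrix(rep(c(0, 1, 0), each = 8), 8, 3,
                       dimnames = list(c("hr", "prv", "rr", "spo2", "gsr",
                                         "bt", "sbp", "dbp"),
                                       c("low", "normal", "high")))
  for (tn in c("mean", "min", "product")) {
    acts <- activate_rules(all_normal, engine_config(tnorm = tn))
    expect_equal(unname(acts), c(0, 1, 0))
  }

  # saturated calm pattern: Low where R1 wants Low, High where it wants High
  calm <- all_normal * 0
  d1 <- c(hr = "low", prv = "low", rr = "low", spo2 = "high", gsr = "high",
          bt = "high", sbp = "low", dbp = "low")
  for (p in rownames(calm)) calm[p, d1[[p]]] <- 1
  acts <- activate_rules(calm, engine_config(tnorm = "min"))
  expect_equal(unname(acts[1]), 1)
  expect_equal(unname(acts[2]), 0)

  # mean aggregation is the arithmetic mean of the eight degrees per rule
  deg <- fuzzify_sample(mixed_sample(), stress_fis()$ranges)
  acts <- activate_rules(deg, engine_config(tnorm = "mean"))
  expect_equal(unname(acts["r1"]), mixed_sample_expected$r1, tolerance = 1e-9)
  expect_equal(unname(acts["r2"]), mixed_sample_expected$r2, tolerance = 1e-9)
  expect_equal(unname(acts["r3"]), mixed_sample_expected$r3, tolerance = 1e-9)

  expect_error(activate_rules(all_normal[1:4, ]), "incomplete")
})

test_that("defuzzification is the weighted average of rule consequents", {
  expect_equal(defuzzify(c(1, 0, 0))$score, 1)
  expect_identical(as.character(defuzzify(c(1, 0, 0))$label), "Calm")
  expect_equal(defuzzify(c(0.1, 0.2, 0.3))$score, 7 / 3)
  # symmetry: equal activations land exactly on Normal
  for (c_ in c(0.01, 0.3, 1)) {
    out <- defuzzify(c(c_, c_, c_))
    expect_identical(out$score, 2)
    expect_identical(as.character(out$label), "Normal")
  }
  expect_error(defuzzify(c(0.5, 1.2, 0)), "\\[0, 1\\]")
})

test_that("degenerate all-zero activations follow the configured policy", {
  out <- defuzzify(c(0, 0, 0), engine_config(degenerate_policy = "fallback_normal"))
  expect_true(out$degenerate)
  expect_equal(out$score, 2)
  expect_error(defuzzify(c(0, 0, 0), engine_config(degenerate_policy = "error")),
               "degenerate")
})

test_that("assess recovers the expected class on canonical samples", {
  fis <- stress_fis()
  out <- assess(midpoint_sample(), fis)
  expect_equal(out$score, 2)
  expect_identical(as.character(out$label), "Normal")

  stressed <- list(hr = 120, prv = 110, rr = 26, spo2 = 93, gsr = 8,
                   bt = 35.2, sbp = 150, dbp = 95)
  out <- assess(stressed, fis)
  expect_equal(out$score, 3)
  expect_identical(as.character(out$label), "Stressed")

  # frozen hand-computed fixture under tnorm = mean
  out <- assess(mixed_sample(), fis)
  expect_equal(out$score, mixed_sample_expected$score, tolerance = 1e-8)
  expect_equal(out$score, oracle_score_mean(mixed_sample()), tolerance = 1e-12)
})

test_that("assess validates its input", {
  fis <- stress_fis()
  s <- mixed_sample()
  s$spo2 <- 105
  expect_error(assess(s, fis), "spo2")
  s <- mixed_sample(); s$hr <- NULL
  expect_error(assess(s, fis), "hr")
  s <- mixed_sample(); s$sbp <- 60; s$dbp <- 70
  expect_error(assess(s, fis), "sbp")
})

test_that("scores stay in [1, 3] and assessment is deterministic", {
  fis <- stress_fis()
  set.seed(7)
  for (i in seq_len(100)) {
    s <- random_sample()
    a <- assess(s, fis)
    b <- assess(s, fis)
    expect_gte(a$score, 1)
    expect_lte(a$score, 3)
    expect_identical(a$score, b$score)
    expect_identical(a$label, b$label)
    # cross-check the vectorised path against the scalar one
    expect_equal(predict(fis, as.data.frame(s))$score, a$score,
                 tolerance = 1e-12)
  }
})

test_that("crisp limit reproduces the crisp band classification", {
  eng <- engine_config(transition_fraction = 1e-9)
  fis <- stress_fis(config = eng)
  expected <- c("Calm", "Normal", "Stressed")
  for (k in 1:3) {
    s <- directional_sample(k)
    out <- assess(s, fis)
    expect_identical(as.character(out$label), expected[k])
    # oracle: the crisp band of each parameter agrees with the direction
    if (k == 2) {
      for (p in names(oracle_cuts))
        expect_identical(as.character(classify_parameter(p, s[[p]])), "Normal")
    }
  }
})

test_that("score is monotone in HR toward the stressed direction (mean t-norm)", {
  fis <- stress_fis()
  s <- directional_sample(3)
  hrs <- seq(80, 100, by = 0.5)   # sweep through the transition band
  scores <- vapply(hrs, function(h) { s$hr <- h; assess(s, fis)$score },
                   numeric(1))
  expect_true(all(diff(scores) >= -1e-12))
})

test_that("t-norm choice changes graded activations as expected", {
  deg <- fuzzify_sample(mixed_sample(), stress_fis()$ranges)
  a_min <- activate_rules(deg, engine_config(tnorm = "min"))
  a_prod <- activate_rules(deg, engine_config(tnorm = "product"))
  a_mean <- activate_rules(deg, engine_config(tnorm = "mean"))
  # conjunctive t-norms are dominated by the mean for degrees in [0,1]
  expect_true(all(a_min <= a_mean + 1e-12))
  expect_true(all(a_prod <= a_min + 1e-12))
  # the mixed fixture zeroes every rule under min (conflicting directions)
  expect_equal(unname(a_min), c(0, 0, 0))
})
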