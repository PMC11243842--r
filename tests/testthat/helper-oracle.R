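# Independent oracles and fixtures, deliberately written from the membership
# definitions rather than via the package's own vectorised code paths.

oracle_low <- function(v, L, d) {
  if (d == 0) return(as.numeric(v < L))
  if (v <= L - d) 1 else if (v >= L + d) 0 else (L + d - v) / (2 * d)
}
oracle_high <- function(v, H, d) {
  if (d == 0) return(as.numeric(v > H))
  if (v >= H + d) 1 else if (v <= H - d) 0 else (v - (H - d)) / (2 * d)
}
oracle_normal <- function(v, L, H, d) {
  m <- (L + H) / 2
  if (v <= L - d || v >= H + d) return(0)
  if (v <= m) (v - (L - d)) / (m - (L - d)) else ((H + d) - v) / ((H + d) - m)
}

oracle_cuts <- list(hr = c(60, 90), prv = c(32, 77), rr = c(12, 18),
                    spo2 = c(97, 99), gsr = c(30, 50), bt = c(36.5, 37.5),
                    sbp = c(90, 120), dbp = c(60, 80))

oracle_degrees <- function(sample, fraction = 0.10) {
  sapply(names(oracle_cuts), function(p) {
    L <- oracle_cuts[[p]][1]; H <- oracle_cuts[[p]][2]; d <- fraction * (H - L)
    v <- sample[[p]]
    c(low = oracle_low(v, L, d), normal = oracle_normal(v, L, H, d),
      high = oracle_high(v, H, d))
  })
}

oracle_score_mean <- function(sample, fraction = 0.10) {
  deg <- oracle_degrees(sample, fraction)
  d1 <- c(hr = "low", prv = "low", rr = "low", spo2 = "high", gsr = "high",
          bt = "high", sbp = "low", dbp = "low")
  d3 <- c(hr = "high", prv = "high", rr = "high", spo2 = "low", gsr = "low",
          bt = "low", sbp = "high", dbp = "high")
  r1 <- mean(sapply(names(oracle_cuts), function(p) deg[d1[[p]], p]))
  r2 <- mean(deg["normal", ])
  r3 <- mean(sapply(names(oracle_cuts), function(p) deg[d3[[p]], p]))
  (r1 * 1 + r2 * 2 + r3 * 3) / (r1 + r2 + r3)
}

# a sample with every parameter at its normal-band midpoint
midpoint_sample <- function() {
  as.list(sapply(names(oracle_cuts), function(p) mean(oracle_cuts[[p]])))
}

# the frozen mixed-direction fixture used across tests; memberships and the
# Eq.-style score were hand-computed from the piecewise formulas above
mixed_sample <- function() {
  list(hr = 95, prv = 40, rr = 10, spo2 = 98, gsr = 55, bt = 36.6,
       sbp = 118, dbp = 62)
}
mixed_sample_expected <- list(r1 = 0.25, r2 = 2.4074074074 / 8,
                              r3 = 7 / 48, score = 1.8504983389)

# draw a random physiologically-valid sample (broad, direction-agnostic)
random_sample <- function() {
  s <- list(hr = runif(1, 40, 140), prv = runif(1, 5, 120),
            rr = runif(1, 6, 30), spo2 = runif(1, 90, 100),
            gsr = runif(1, 5, 80), bt = runif(1, 35, 39),
            sbp = runif(1, 80, 160), dbp = runif(1, 45, 75))
  s$dbp <- min(s$dbp, s$sbp - 10)
  s
}

# direction-consistent sample: every parameter deep inside the band the rule
# for `class_idx` (1 Calm, 2 Normal, 3 Stressed) points at
directional_sample <- function(class_idx) {
  d1 <- c(hr = "low", prv = "low", rr = "low", spo2 = "high", gsr = "high",
          bt = "high", sbp = "low", dbp = "low")
  d3 <- c(hr = "high", prv = "high", rr = "high", spo2 = "low", gsr = "low",
          bt = "low", sbp = "high", dbp = "high")
  dirs <- switch(class_idx, d1, setNames(rep("normal", 8), names(d1)), d3)
  s <- lapply(names(oracle_cuts), function(p) {
    L <- oracle_cuts[[p]][1]; H <- oracle_cuts[[p]][2]; w <- H - L
    v <- switch(dirs[[p]], low = L - 0.25 * w, normal = (L + H) / 2,
                high = H + 0.25 * w)
    if (p == "spo2") v <- min(v, 99.6)
    v
  })
  names(s) <- names(oracle_cuts)
  s
}

# brute-force confusion counts by double loop
brute_confusion <- function(truth, predicted, labels) {
  m <- matrix(0L, length(labels), length(labels),
              dimnames = list(true = labels, predicted = labels))
  for (i in seq_along(truth))
    for (a in labels) for (b in labels)
      if (truth[i] == a && predicted[i] == b) m[a, b] <- m[a, b] + 1L
  m
}

# brute-force one-vs-rest metrics by per-record counting
brute_metrics <- function(truth, predicted, label) {
  tp <- sum(truth == label & predicted == label)
  fn <- sum(truth == label & predicted != label)
  fp <- sum(truth != label & predicted == label)
  tn <- sum(truth != label & predicted != label)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  p <- div(tp, tp + fp); s <- div(tp, tp + fn)
  f1 <- if (is.na(p) || is.na(s) || p + s == 0) NA_real_ else 2 * p * s / (p + s)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       sensitivity = s, specificity = div(tn, tn + fp), precision = p,
       accuracy = (tp + tn) / length(truth), f1 = f1)
}
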