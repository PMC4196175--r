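# Independent brute-force oracles used for dual-route checks.
# Deliberately naive (loops, first-principles formulas) and kept free of any
# call into the package's own implementation paths.

# Benjamini-Hochberg step-up, straight from the definition
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  # enforce step-up monotonicity from the largest rank down
  if (m > 1)
    for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Kaplan-Meier product-limit by explicit product over event times
bf_km <- function(time, event) {
  ut <- sort(unique(time))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# two-group logrank chi-square by looping over risk sets
bf_logrank <- function(group, time, event) {
  group <- as.character(group)
  gs <- sort(unique(group))
  ut <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in ut) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == gs[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == gs[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# Harrell's c by exhaustive double loop
bf_cindex <- function(score, time, event) {
  n <- length(score)
  conc <- 0; usable <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    first <- NA  # which of i, j is known to fail first
    if (time[i] < time[j] && event[i] == 1) first <- i
    else if (time[j] < time[i] && event[j] == 1) first <- j
    else if (time[i] == time[j] && event[i] != event[j])
      first <- if (event[i] == 1) i else j
    if (is.na(first)) next
    second <- if (first == i) j else i
    usable <- usable + 1
    if (score[first] > score[second]) conc <- conc + 1
    else if (score[first] == score[second]) conc <- conc + 0.5
  }
  c(c = conc / usable, n_pairs = usable)
}

# confusion-matrix metrics at a horizon by explicit counting
bf_binary_metrics <- function(group, time, event, horizon) {
  high <- as.character(group) == "high"
  tp <- fn <- tn <- fp <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1 && time[i] <= horizon) {          # case
      if (high[i]) tp <- tp + 1 else fn <- fn + 1
    } else if (time[i] >= horizon) {                    # control
      if (high[i]) fp <- fp + 1 else tn <- tn + 1
    }                                                   # else excluded
  }
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  c(sensitivity = sens, specificity = spec, bcr = (sens + spec) / 2)
}

# reclassification fractions by explicit counting
bf_reclass_fractions <- function(npi, sig) {
  npi <- as.character(npi); sig <- as.character(sig)
  hi <- npi == "high"
  c(high_to_low = sum(hi & sig == "low") / sum(hi),
    low_to_high = sum(!hi & sig == "high") / sum(!hi))
}

# inverse-variance weighted mean
bf_pooled <- function(est, se) {
  w <- 1 / se^2
  c(estimate = sum(w * est) / sum(w), se = sqrt(1 / sum(w)))
}

# random censored survival dataset for oracle-equivalence loops
random_surv_data <- function(n, p_event = 0.6, tie_prob = 0.3) {
  time <- round(rexp(n, 0.2), digits = if (runif(1) < tie_prob) 0 else 3)
  time <- pmax(time, 0.25)
  data.frame(time = time,
             event = rbinom(n, 1, p_event),
             score = if (runif(1) < 0.3) sample(5, n, replace = TRUE)
                     else rnorm(n))
}

# small two-condition design + expression for derivation tests
tiny_experiment <- function(seed = 42, ...) {
  gen_cell_line_experiment(n_lines = 6, n_probes = 150, n_planted = 12,
                           overlap = 3, seed = seed, ...)
}
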