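# Independent brute-force oracles: explicit loops over the definitions,
# sharing no code with the implementation under test.

oracle_profile <- function(v, bin_count = 128L, report_scale = 1e-5) {
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  m3 <- sum((v - m)^3) / n
  m4 <- sum((v - m)^4) / n
  sdv <- sqrt(sum((v - m)^2) / (n - 1))
  pct <- function(p) { # linear interpolation between order statistics
    s <- sort(v)
    h <- (n - 1) * p
    lo <- floor(h)
    s[lo + 1] + (h - lo) * (s[min(lo + 2, n)] - s[lo + 1])
  }
  lo <- min(v); hi <- max(v)
  counts <- integer(bin_count)
  if (hi > lo) {
    for (x in v) {
      b <- floor((x - lo) / (hi - lo) * bin_count) + 1
      if (b > bin_count) b <- bin_count
      counts[b] <- counts[b] + 1L
    }
    width <- (hi - lo) / bin_count
    mode_bin <- which(counts == max(counts))[1]
    mode <- lo + (mode_bin - 0.5) * width
    ent <- 0
    for (cnt in counts[counts > 0]) {
      p <- cnt / n
      ent <- ent - p * log2(p)
    }
  } else {
    mode <- lo; ent <- 0
  }
  c(ADCmean = m / report_scale, ADCmin = lo / report_scale,
    ADCmax = hi / report_scale, ADCp10 = pct(0.10) / report_scale,
    ADCp25 = pct(0.25) / report_scale, ADCp75 = pct(0.75) / report_scale,
    ADCp90 = pct(0.90) / report_scale, ADCmedian = pct(0.5) / report_scale,
    ADCmode = mode / report_scale, ADCsd = sdv / report_scale,
    Kurtosis = if (m2 > 0) m4 / m2^2 else NA_real_,
    Skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_,
    Entropy = ent)
}

# AUC by O(n^2) pair counting, ties as 1/2
oracle_auc <- function(xpos, xneg) {
  s <- 0
  for (a in xpos) for (b in xneg) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(xpos) * length(xneg))
}

# exhaustive Youden search over every observed value (and +/-Inf) as
# threshold, rule "value >= t is positive"; ties -> higher specificity
oracle_youden <- function(xpos, xneg) {
  cand <- c(-Inf, sort(unique(c(xpos, xneg))), Inf)
  best <- list(j = -Inf, sens = NA, spec = NA)
  for (t in cand) {
    sens <- mean(xpos >= t)
    spec <- mean(xneg < t)
    j <- sens + spec - 1
    if (j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec)) {
      best <- list(j = j, sens = sens, spec = spec)
    }
  }
  best
}

# two-sided exact Mann-Whitney p by enumeration of all rank assignments
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(ix) {
    sum(rank(pooled)[ix]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
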