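# shared fixtures, all built in code

## noiseless exponential washout series
make_series <- function(A = 10, k = 0.05, B = -57, times = 120:240,
                        noise_sd = 0, seed = NULL, roi = "lesion") {
  simulate_tic(list(A = A, B = B, k = k, t0 = 0), times,
               noise_sd = noise_sd, seed = seed, roi = roi)
}

## degenerate, perfectly separable study conditions: zero AREA variance,
## zero TIC noise, no pattern misreads
separable_config <- function(n = 91, composition = default_composition(),
                             ...) {
  cohort_config(n = n, composition = composition,
                area_sd_malignant = 0, area_sd_benign = 0,
                parenchyma_area_sd = 0, noise_sd = 0,
                pattern_confusion_rate = 0, ...)
}

## all-pairs AUROC oracle, ties counted one half
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

## exact two-sided Mann-Whitney p by full enumeration of rank splits
wilcox_enum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(length(pooled), n1)
  u <- apply(splits, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  mean(abs(u - mu) >= abs(obs - mu) - 1e-12)
}
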