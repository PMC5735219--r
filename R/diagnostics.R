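# split-chain potential scale reduction: one chain split in half
split_rhat <- function(x) {
  n <- length(x)
  if (n < 4) return(NA_real_)
  half <- n %/% 2
  chains <- cbind(x[seq_len(half)], x[n - half + seq_len(half)])
  m <- ncol(chains)
  means <- colMeans(chains)
  vars <- apply(chains, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# effective sample size from the initial positive sequence of autocorrelations
ess_basic <- function(x) {
  n <- length(x)
  if (n < 4 || sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 2, 200), plot = FALSE,
                    demean = TRUE)$acf[-1]
  s <- 0
  for (k in seq_along(rho)) {
    if (rho[k] < 0.05) break
    s <- s + rho[k]
  }
  max(1, n / (1 + 2 * s))
}
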