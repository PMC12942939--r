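# Fixtures are built in code: small spectra with known structure, and
# finite-difference oracles for the network gradients.

# smooth toy dataset with known targets
toySpectra <- function(m = 24, n = 6, seed = 1) {
  set.seed(seed)
  w <- seq(800, 900, length.out = m)
  ints <- vapply(seq_len(n), function(j)
    5 + j * exp(-(w - 850)^2 / 200) + rnorm(m, sd = 0.05), numeric(m))
  RamanSpectra(w, ints, targets = seq_len(n) + 0.5, unit = "mmol/L")
}

# two noiseless Gaussian constituent profiles on a small grid
mixtureProfiles <- function(m = 60) {
  w <- seq(800, 1200, length.out = m)
  cbind(exp(-(w - 900)^2 / (2 * 20^2)),
        exp(-(w - 1100)^2 / (2 * 35^2)))
}

writeTempLines <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

# central finite differences of a scalar function at x (vectorized over
# the parameter array); independent oracle for the analytic gradients
finiteDiff <- function(f, x, eps = 1e-6) {
  g <- array(0, dim = dim(as.array(x)))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

relErr <- function(a, b) max(abs(a - b)) / max(max(abs(b)), 1e-8)

# brute-force double-loop cross-correlation with zero padding
bruteConv <- function(sig, ker) {
  n <- length(sig); k <- length(ker); h <- (k - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(k)) {
    idx <- i + j - 1 - h
    if (idx >= 1 && idx <= n) out[i] <- out[i] + ker[j] * sig[idx]
  }
  out
}
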