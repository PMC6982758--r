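# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_config(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_nonneg <- function(x, field) {
  if (length(x) != 1L || !is.finite(x) || x < 0)
    stop_config(field, "must be a single non-negative number")
  as.numeric(x)
}

check_pos <- function(x, field) {
  if (length(x) != 1L || !is.finite(x) || x <= 0)
    stop_config(field, "must be a single positive number")
  as.numeric(x)
}

# Derive a child seed from a parent seed and a stage/unit index; stays below
# 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Truncated-normal draws on [lo, hi] via inverse-CDF; deterministic given RNG state.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Population variance (divide by n); the convention used for SDNN/SD1/SD2 so
# the Poincare identity SD1^2 + SD2^2 = 2 SDNN^2 holds exactly.
var_pop <- function(x) mean((x - mean(x))^2)

# Rolling mean and sd over a centered window of w samples, via cumulative sums.
rolling_mean_sd <- function(x, w) {
  n <- length(x)
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cnt <- hi - lo + 1
  m <- (cs[hi + 1] - cs[lo]) / cnt
  v <- pmax((cs2[hi + 1] - cs2[lo]) / cnt - m^2, 0)
  list(mean = m, sd = sqrt(v))
}

# Welch power spectral density: Hann-windowed overlapping segments.
# Returns freq (Hz) and psd (power / Hz) with a scaling such that
# sum(psd) * df ~ variance of x (one-sided).
welch_psd <- function(x, fs, nperseg = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(n, 256L)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  u <- sum(win^2)
  nf <- nperseg %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(fft(seg)[seq_len(nf)])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * u * fs)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  if (nperseg %% 2 == 0) psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  else psd[2:nf] <- 2 * psd[2:nf]
  list(freq = (seq_len(nf) - 1) * fs / nperseg, psd = psd)
}

# Lomb-Scargle periodogram for unevenly sampled data, normalised so that
# sum(power) * df approximates the sample variance over the scanned range.
lomb_periodogram <- function(t, x, freq) {
  x <- x - mean(x)
  pw <- vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
  }, numeric(1))
  list(freq = freq, power = pw)
}
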