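## Shared fixtures and independent oracles for the test suite.

## A small noiseless membrane with known contents, continuous raster.
noiseless_membrane <- function(contents = c(S1 = 6, S2 = 18, S3 = 40),
                               signal = signal_model(), quantize = FALSE) {
  lay <- spot_layout_grid(length(contents),
                          sample_ids = names(contents))
  make_membrane(lay, contents, signal = signal,
                noise = noise_model(0, 0, 0, 0), quantize = quantize)
}

## Render one raw (unnormalized) Gaussian of amplitude A, sd sigma at the
## centre of a zero image; independent of render_spot.
raw_gaussian_image <- function(n = 60, A = 1000, sigma = 3) {
  ctr <- (n + 1) / 2
  d2 <- outer((1:n - ctr)^2, (1:n - ctr)^2, "+")
  A * exp(-d2 / (2 * sigma^2))
}

## Brute-force two-sided Mann-Whitney p by enumeration of all assignments
## of the pooled values to the two samples (no ties).  Independent of the
## package implementation: counts discordant pairs directly.
mw_enum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">"))
  }
  u_obs <- sum(outer(x, y, ">"))
  us <- apply(utils::combn(n + m, n), 2, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

## Direct-scan KS oracle: max |Fx - Fy| over pooled points, with sign.
ks_scan_D <- function(x, y) {
  pts <- sort(c(x, y))
  dif <- vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))
  dif[which.max(abs(dif))]
}

## Zooming grid-search oracle for the log-law least squares fit.
grid_fit_oracle <- function(contents, intensities, q_ref = 1,
                            rounds = 8, half = 20) {
  lx <- log(contents / q_ref)
  sse <- function(a, b) sum((intensities - a - b * lx)^2)
  a0 <- mean(intensities); b0 <- diff(range(intensities)) /
    max(diff(range(lx)), 1e-6)
  span_a <- max(abs(intensities)) + 1; span_b <- abs(b0) + 1
  for (r in seq_len(rounds)) {
    as <- seq(a0 - span_a, a0 + span_a, length.out = 2 * half + 1)
    bs <- seq(b0 - span_b, b0 + span_b, length.out = 2 * half + 1)
    g <- expand.grid(a = as, b = bs)
    v <- mapply(sse, g$a, g$b)
    i <- which.min(v)
    a0 <- g$a[i]; b0 <- g$b[i]
    span_a <- span_a / (half / 2); span_b <- span_b / (half / 2)
  }
  c(a = a0, b = b0)
}

## Bisection inversion oracle on t = ln(q/q_ref) for I = a + b*t.
bisect_invert_oracle <- function(curve, intensity) {
  f <- function(t) curve$a + curve$b * t - intensity
  lo <- -60; hi <- 60
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  curve$q_ref * exp((lo + hi) / 2)
}

## Brute force over ALL two-subset partitions (both nonempty): minimum
## total within-subset sum of squares and whether an optimum is contiguous
## in sorted order.
partition_brute_force <- function(values) {
  n <- length(values)
  wss <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  best <- Inf; best_mask <- NULL
  for (code in 1:(2^n - 2)) {
    mask <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    v <- wss(values[mask]) + wss(values[!mask])
    if (v < best - 1e-12) { best <- v; best_mask <- mask }
  }
  s <- sort(values)
  contiguous <- FALSE
  for (k in 1:(n - 1)) {
    v <- wss(s[1:k]) + wss(s[(k + 1):n])
    if (abs(v - best) < 1e-9) contiguous <- TRUE
  }
  list(min_wss = best, contiguous_optimum = contiguous)
}
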