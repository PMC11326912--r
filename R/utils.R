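# Shared numeric helpers: circular arithmetic, binomial intervals, seeded
# samplers. All angles are degrees; wrapped angles live in (-180, 180].

# reduce an angle in degrees to (-180, 180]
wrap_angle <- function(deg) {
  w <- deg %% 360
  big <- !is.na(w) & w > 180
  w[big] <- w[big] - 360
  w
}

# absolute circular distance between two directions, in [0, 180]
circ_dist <- function(a_deg, b_deg) {
  abs(wrap_angle(a_deg - b_deg))
}

# Wilson score interval for a binomial proportion (vectorised)
wilson_ci <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  lo <- pmax(0, ctr - hw)
  hi <- pmin(1, ctr + hw)
  lo[n == 0] <- NA_real_
  hi[n == 0] <- NA_real_
  list(low = lo, high = hi)
}

# Truncated-normal draws by inverse-CDF; a pure function of the RNG stream.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# Von Mises draws (Best & Fisher 1979 rejection sampler), returned in degrees
# centred on mu_deg. kappa = 0 falls back to the uniform circle.
rvonmises <- function(n, mu_deg = 0, kappa = 1) {
  if (kappa < 1e-8) {
    return(wrap_angle(runif(n, -180, 180) + mu_deg))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_angle(out * 180 / pi + mu_deg)
}

# Counts of sorted x falling in half-open windows [lo_i, hi_i).
count_in_windows <- function(x_sorted, lo, hi) {
  findInterval(hi, x_sorted, left.open = TRUE) -
    findInterval(lo, x_sorted, left.open = TRUE)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, min, max))
  }
  invisible(x)
}
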