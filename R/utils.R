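# Internal helpers: argument validation and small numerics shared by all modules.

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE, integer = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop_bad("'%s' must be a single finite number", name)
  ok_lower <- if (allow_equal_lower) x >= lower else x > lower
  if (!ok_lower || x > upper)
    stop_bad("'%s' = %g out of range %s%g, %g]", name, x,
             if (allow_equal_lower) "[" else "(", lower, upper)
  if (integer && x != round(x))
    stop_bad("'%s' must be an integer, got %g", name, x)
  invisible(x)
}

# lognormal (mu, sigma) from target arithmetic mean m > 0 and sd s >= 0
lognormal_from_moments <- function(m, s) {
  if (s == 0) return(list(mu = log(m), sigma = 0))
  sigma2 <- log(1 + (s / m)^2)
  list(mu = log(m) - sigma2 / 2, sigma = sqrt(sigma2))
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution,
# mean 0, concentration kappa >= 0. kappa >= 1e6 is treated as a point mass
# at 0 (degenerate limit used by the straight-walk construction).
rvonmises <- function(n, kappa) {
  if (kappa >= 1e6) return(rep(0, n))
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f)))
      i <- i + 1L
    }
  }
  out
}

# wrap angle to (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

# deterministic per-stage seed derived from a master seed; keeps values < 2^31
split_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}
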