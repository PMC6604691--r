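## Shared independent oracles and fixture builders. These deliberately avoid
## the package's own interpolation/integration code paths: quadrature is
## plain dense-grid trapezoid, interpolation closed-form.

## biexponential input function as a closed-form function of time
biexp_fun <- function(c0 = 20, f = 0.35, l1 = 0.08, l2 = 0.01) {
  force(c0); force(f); force(l1); force(l2)
  function(t) c0 * (f * exp(-l1 * t) + (1 - f) * exp(-l2 * t))
}

## dense-grid trapezoid quadrature of a function on [0, t]
quad_trapz <- function(fn, t, n = 20001) {
  g <- seq(0, t, length.out = n)
  v <- fn(g)
  sum((v[-1] + v[-length(v)]) / 2 * diff(g))
}

## a plasma_curve sampled from a closed-form function
sampled_curve <- function(fn, times, ...) {
  plasma_curve(times, fn(times), ...)
}

## clinical-style sampling schedule (blood draws + scans)
sched <- c(1, 3, 6, 12, 24, 48, 120)

## dense trapezoid AUC of a sampled curve interpolated the package's way is
## NOT used here; this integrates the *log-linear interpolant* independently
## for simulate_lesion_tac's quadrature oracle
quad_loglinear <- function(times, cp, t, n = 40001) {
  g <- seq(0, t, length.out = n)
  v <- vapply(g, function(ti) {
    if (ti <= times[1]) return(cp[1])
    i <- findInterval(ti, times, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(times) - 1L)
    w <- (ti - times[i]) / (times[i + 1] - times[i])
    exp((1 - w) * log(cp[i]) + w * log(cp[i + 1]))
  }, numeric(1))
  sum((v[-1] + v[-length(v)]) / 2 * diff(g))
}

## mean-1 lognormal multiplicative noise (mirrors the generator's model but
## reimplemented here so ratio-level Monte Carlo tests stay independent)
ln_noise <- function(n, cv) {
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}
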