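# Scaled conjugate gradient minimizer (Moller 1993), full batch.
#
# fn(w)  -> scalar objective
# gr(w)  -> gradient vector
# callback(k, w, fval, gnorm) -> TRUE to continue, FALSE to stop early;
#   invoked once per iteration ("cycle") after the weight update attempt.
#
# Returns list(par, value, iterations, stop_reason). stop_reason is one of
# "max_cycles", "min_gradient", "callback" (callback asked to stop) or
# "stalled" (step size underflow).
scg_minimize <- function(w, fn, gr, max_cycles = 1000, min_gradient = 1e-6,
                         callback = NULL,
                         sigma0 = 5e-5, lambda0 = 5e-7) {
  n <- length(w)
  lambda <- lambda0
  lambda_bar <- 0
  fval <- fn(w)
  r <- -gr(w)
  p <- r
  success <- TRUE
  delta <- 0
  stop_reason <- "max_cycles"
  k <- 0

  while (k < max_cycles) {
    k <- k + 1
    p2 <- sum(p * p)
    pnorm <- sqrt(p2)
    if (pnorm < .Machine$double.eps) { stop_reason <- "stalled"; break }

    if (success) {
      sigma <- sigma0 / pnorm
      g_fwd <- gr(w + sigma * p)
      s <- (g_fwd - (-r)) / sigma   # -r is the current gradient
      delta <- sum(p * s)
    }
    delta <- delta + (lambda - lambda_bar) * p2
    if (delta <= 0) {               # make the Hessian approximation PD
      lambda_bar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta

    f_new <- fn(w + alpha * p)
    Delta <- 2 * delta * (fval - f_new) / (mu * mu)

    if (is.finite(Delta) && Delta >= 0) {
      w <- w + alpha * p
      fval <- f_new
      r_new <- -gr(w)
      lambda_bar <- 0
      success <- TRUE
      if (k %% n == 0) {
        p <- r_new                  # restart in steepest-descent direction
      } else {
        beta <- (sum(r_new * r_new) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (is.finite(Delta) && Delta < 0.25) {
      lambda <- lambda + delta * (1 - Delta) / p2
    }
    if (!is.finite(lambda) || lambda > 1e100) { stop_reason <- "stalled"; break }

    gnorm <- sqrt(sum(r * r))
    if (!is.null(callback)) {
      if (!isTRUE(callback(k, w, fval, gnorm))) {
        stop_reason <- "callback"
        break
      }
    }
    if (gnorm < min_gradient) { stop_reason <- "min_gradient"; break }
  }
  list(par = w, value = fval, iterations = k, stop_reason = stop_reason)
}
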