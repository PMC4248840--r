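# Scaled conjugate gradient minimizer (Moller 1993).
#
# A conjugate-direction method that replaces the line search with a
# model-trust-region step scaled by a Levenberg-Marquardt damping term,
# using a finite-difference directional second derivative.  This is the
# standard optimizer for moderate-size neural-network training and the
# one used for the workload classifier.

# fn(w)   -> scalar objective
# gr(w)   -> gradient vector
# monitor(w, iter) -> optional scalar validation score evaluated after
#   every accepted step; optimization stops early when it fails to
#   improve for `patience` consecutive accepted steps, and the returned
#   weights are those with the best monitor value seen.
scg_minimize <- function(w0, fn, gr, max_iters = 200,
                         monitor = NULL, patience = 6,
                         sigma0 = 1e-4, tol_grad = 1e-8) {
  w <- w0
  n <- length(w)
  f_w <- fn(w)
  r <- -gr(w)
  p <- r
  success <- TRUE
  lambda <- 1e-6
  lambda_bar <- 0
  delta <- 0

  best_w <- w
  best_monitor <- if (is.null(monitor)) f_w else monitor(w, 0L)
  stall <- 0L
  iters_run <- 0L

  for (k in seq_len(max_iters)) {
    p2 <- sum(p * p)
    if (p2 < .Machine$double.eps) break
    if (success) {
      sigma <- sigma0 / sqrt(p2)
      s <- (gr(w + sigma * p) - gr(w)) / sigma
      delta <- sum(p * s)
    }
    delta_k <- delta + (lambda - lambda_bar) * p2
    if (delta_k <= 0) {
      lambda_bar <- 2 * (lambda - delta_k / p2)
      delta_k <- -delta_k + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta_k
    f_new <- fn(w + alpha * p)
    Delta <- 2 * delta_k * (f_w - f_new) / mu^2
    if (is.finite(Delta) && Delta >= 0) {
      w <- w + alpha * p
      f_w <- f_new
      r_new <- -gr(w)
      lambda_bar <- 0
      success <- TRUE
      iters_run <- k
      if (k %% n == 0) {
        p <- r_new
      } else {
        beta <- (sum(r_new * r_new) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
      if (!is.null(monitor)) {
        m <- monitor(w, k)
        if (m < best_monitor - 1e-10) {
          best_monitor <- m
          best_w <- w
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= patience) break
        }
      } else if (f_w < best_monitor - 1e-10) {
        best_monitor <- f_w
        best_w <- w
      }
      if (sqrt(sum(r * r)) < tol_grad) break
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta_k * (1 - Delta) / p2
    if (lambda > 1e100) break
  }
  if (is.null(monitor) && f_w < best_monitor) {
    best_w <- w
    best_monitor <- f_w
  }
  list(w = best_w, value = best_monitor, iters = iters_run)
}
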