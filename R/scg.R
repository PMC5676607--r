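# Scaled conjugate gradient minimiser (Moller 1993): a deterministic batch
# optimizer that sizes each step with a Hessian-vector estimate from a
# gradient difference, damped by a Levenberg-Marquardt scale, and accepts a
# step only if it decreases the objective. No line search, so the trace of
# accepted objective values is non-increasing by construction.

scg_minimize <- function(par, fn, gr, maxit = 100, f_tol = 1e-10,
                         grad_tol = 1e-6) {
  sigma0 <- 1e-4
  w <- par
  P <- length(w)
  fw <- fn(w)
  if (!is.finite(fw)) {
    stop("objective not finite at the starting point", call. = FALSE)
  }
  g <- gr(w)
  r <- -g
  p <- r
  success <- TRUE
  lambda <- 1e-6
  lambda_bar <- 0
  trace <- fw
  delta <- 0
  pnorm2 <- sum(p * p)
  converged <- FALSE
  iters <- 0L

  for (j in seq_len(maxit)) {
    iters <- j
    if (success) {
      pnorm2 <- sum(p * p)
      if (pnorm2 < .Machine$double.xmin) {
        converged <- TRUE
        break
      }
      sigma <- sigma0 / sqrt(pnorm2)
      g_shift <- gr(w + sigma * p)
      s <- (g_shift - g) / sigma # Hessian-vector product estimate
      delta <- sum(p * s)
    }
    # Levenberg-Marquardt damping; force positive curvature
    delta_d <- delta + (lambda - lambda_bar) * pnorm2
    if (delta_d <= 0) {
      lambda_bar <- 2 * (lambda - delta_d / pnorm2)
      delta_d <- -delta_d + lambda * pnorm2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta_d
    w_new <- w + alpha * p
    f_new <- fn(w_new)
    if (!is.finite(f_new)) {
      stop("objective became non-finite during optimization (step ", j,
           ", |step| = ", format(abs(alpha) * sqrt(pnorm2)), ")",
           call. = FALSE)
    }
    cmp <- 2 * delta_d * (fw - f_new) / mu^2 # comparison ratio
    if (cmp >= 0) {
      # accepted step
      f_prev <- fw
      w <- w_new
      fw <- f_new
      g <- gr(w)
      r_new <- -g
      trace <- c(trace, fw)
      lambda_bar <- 0
      success <- TRUE
      if (j %% P == 0) {
        p <- r_new # restart along steepest descent
      } else {
        beta <- (sum(r_new * r_new) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (cmp >= 0.75) lambda <- max(lambda * 0.25, 1e-15)
      if (sqrt(sum(g * g)) < grad_tol ||
          abs(f_prev - fw) < f_tol * (1 + abs(fw))) {
        converged <- TRUE
        break
      }
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (cmp < 0.25) lambda <- lambda + delta_d * (1 - cmp) / pnorm2
    if (lambda > 1e25) break # damping exhausted, no further progress
  }
  list(par = w, value = fw, trace = trace, iterations = iters,
       converged = converged)
}
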