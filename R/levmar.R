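# Minimal dense Levenberg-Marquardt least-squares driver with analytic
# Jacobians. The density models are nearly linear, so this converges in a
# handful of iterations from any sane start; failure to converge is an
# error, not a warning.

levmar <- function(par, resid_fn, jac_fn,
                   max_iter = 200L, rel_tol = 1e-12, lambda0 = 1e-3) {
  p <- length(par)
  r <- resid_fn(par)
  rss <- sum(r * r)
  lambda <- lambda0
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    J <- jac_fn(par)
    g <- crossprod(J, r)          # gradient/2
    H <- crossprod(J)
    step_ok <- FALSE
    for (k in 1:50) {
      A <- H + lambda * diag(diag(H) + 1e-300, p)
      delta <- tryCatch(solve(A, g), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- par - as.numeric(delta)
        rc <- resid_fn(cand)
        rssc <- sum(rc * rc)
        if (is.finite(rssc) && rssc <= rss) {
          rel <- max(abs(cand - par) / pmax(abs(par), 1e-8))
          par <- cand; r <- rc
          improved <- (rss - rssc) <= rel_tol * max(rss, 1e-300)
          rss <- rssc
          lambda <- max(lambda / 10, 1e-12)
          step_ok <- TRUE
          if (rel < rel_tol || improved) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!step_ok) { converged <- TRUE; break }  # cannot improve further
    if (converged) break
  }
  if (!converged)
    stop("levmar: failed to converge within ", max_iter, " iterations",
         call. = FALSE)
  J <- jac_fn(par)
  list(par = par, residuals = r, rss = rss, jtj = crossprod(J),
       iterations = iter)
}

# covariance = s^2 (J'J)^-1 with s^2 = rss/(n - p); names the offending
# parameter when J'J is numerically singular (identifiability failure).
levmar_covariance <- function(fit, n_obs, par_names = NULL) {
  p <- nrow(fit$jtj)
  s2 <- fit$rss / max(n_obs - p, 1)
  inv <- tryCatch(chol2inv(chol(fit$jtj)), error = function(e) NULL)
  if (is.null(inv)) {
    d <- svd(fit$jtj)
    bad <- which.max(abs(d$v[, which.min(d$d)]))
    nm <- if (!is.null(par_names)) par_names[bad] else paste0("par", bad)
    stop("parameter not identifiable from the design: ", nm, call. = FALSE)
  }
  cov <- inv * s2
  if (!is.null(par_names)) dimnames(cov) <- list(par_names, par_names)
  cov
}
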