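# Bias-reduced (Firth) logistic regression by penalised IRLS.
#
# Used only as the flagged fallback when an ordinary binomial GLM shows
# complete or quasi-complete separation, which is routine here: samples at
# prevalence extremes are often monomorphic. The score is corrected by the
# hat-value term h_i (0.5 - mu_i), which keeps the estimates finite.

firth_glm <- function(X, y, max_iter = 100L, tol = 1e-8) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    XtWX <- crossprod(X * sqrt(w))
    inv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(inv)) stopf("singular information matrix in Firth fit")
    h <- rowSums((X %*% inv) * X) * w
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    delta <- drop(inv %*% score)
    # step-halving guard against overshoot
    while (max(abs(delta)) > 5) delta <- delta / 2
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  loglik <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  names(beta) <- colnames(X)
  w <- pmax(mu * (1 - mu), 1e-12)
  vc <- solve(crossprod(X * sqrt(w)))
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(coefficients = beta, vcov = vc, fitted = mu, logLik = loglik,
       converged = converged, df = ncol(X))
}
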