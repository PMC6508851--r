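## Independent dense-matrix REML oracle: builds V explicitly and evaluates
## the restricted log-likelihood from its factorization; maximization is by
## general-purpose optimization over a Cholesky parameterization. Kept free
## of the package's solver internals on purpose.

dense_reml_loglik <- function(records, grm, spec, grid, Omega, P, Dvec) {
  des <- build_design(records, spec, grid, grm)
  y <- records$value
  N <- length(y)
  Z <- as.matrix(des$Z)
  X <- as.matrix(des$X)
  V <- Z %*% kronecker(grm$G, Omega) %*% t(Z)
  if (!is.null(des$Q)) {
    ne <- length(des$exp_ids)
    V <- V + as.matrix(des$Q) %*% kronecker(diag(ne), P) %*%
      t(as.matrix(des$Q))
  }
  grp <- if (spec$residual == "heterogeneous") des$day_idx else rep(1L, N)
  V <- V + diag(Dvec[grp])
  p <- ncol(X)
  cv <- chol(V)
  Vi <- chol2inv(cv)
  XtVX <- crossprod(X, Vi %*% X)
  Pm <- Vi - Vi %*% X %*% solve(XtVX, crossprod(X, Vi))
  ## the + log|X'X| term makes the value invariant to the fixed-effect
  ## parameterization (same convention as the package solver)
  as.numeric(-0.5 * (2 * sum(log(diag(cv))) +
                       determinant(XtVX)$modulus +
                       drop(t(y) %*% Pm %*% y) + (N - p) * log(2 * pi) -
                       determinant(crossprod(X))$modulus))
}

## brute-force maximization of the dense restricted likelihood
dense_reml_maximize <- function(records, grm, spec, grid, n_days_resid = 1L) {
  qg <- spec$genetic_order + 1L
  qs <- if (is.null(spec$experiment_order)) 0L else spec$experiment_order + 1L
  ltri_g <- which(lower.tri(diag(qg), diag = TRUE))
  ltri_s <- if (qs > 0) which(lower.tri(diag(qs), diag = TRUE)) else integer(0)
  nlg <- length(ltri_g); nls <- length(ltri_s)
  v0 <- stats::var(records$value)
  mk <- function(par) {
    Lg <- matrix(0, qg, qg); Lg[ltri_g] <- par[seq_len(nlg)]
    Om <- Lg %*% t(Lg)
    Pm <- if (qs > 0) {
      Ls <- matrix(0, qs, qs); Ls[ltri_s] <- par[nlg + seq_len(nls)]
      Ls %*% t(Ls)
    } else NULL
    Dv <- exp(par[nlg + nls + seq_len(n_days_resid)])
    list(Omega = Om, P = Pm, D = Dv)
  }
  nll <- function(par) {
    th <- mk(par)
    ll <- tryCatch(
      dense_reml_loglik(records, grm, spec, grid, th$Omega, th$P, th$D),
      error = function(e) -Inf)
    if (!is.finite(ll)) 1e12 else -ll
  }
  best <- NULL
  for (scale in c(0.3, 1, 3)) {
    par0 <- c(diag(sqrt(scale * v0 / 2), qg)[ltri_g],
              if (qs > 0) diag(sqrt(scale * v0 / 4), qs)[ltri_s] else NULL,
              rep(log(scale * v0 / 2), n_days_resid))
    opt <- stats::optim(par0, nll, method = "Nelder-Mead",
                        control = list(maxit = 8000, reltol = 1e-13))
    opt <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                        control = list(maxit = 8000, reltol = 1e-13))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  th <- mk(best$par)
  list(loglik = -best$value, Omega = th$Omega, P = th$P, D = th$D)
}
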