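#' Random-regression model specification
#'
#' Describes one candidate covariance structure: the fixed polynomial order
#' for the mean trend, the random polynomial orders for the additive-genetic
#' and experiment effects, and the residual structure (one variance, or one
#' free variance per imaging day).
#'
#' @param fixed_order Order of the fixed Legendre trend (default 2).
#' @param genetic_order Order of the random genetic regression (0, 1 or 2).
#' @param experiment_order Order of the random experiment regression (0, 1 or
#'   2), or `NULL` to omit the experiment term.
#' @param residual `"heterogeneous"` (one variance per day) or
#'   `"homogeneous"`.
#' @return An `rr_model_spec` list.
#' @export
rr_model_spec <- function(fixed_order = 2L, genetic_order = 2L,
                          experiment_order = 1L,
                          residual = c("heterogeneous", "homogeneous")) {
  residual <- match.arg(residual)
  stopifnot(fixed_order >= 0L, genetic_order >= 0L)
  if (!is.null(experiment_order)) stopifnot(experiment_order >= 0L)
  if (fixed_order < max(genetic_order,
                        if (is.null(experiment_order)) 0L else experiment_order)) {
    warning("fixed_order below a random order; the mean trend may be ",
            "under-parameterized")
  }
  structure(list(fixed_order = as.integer(fixed_order),
                 genetic_order = as.integer(genetic_order),
                 experiment_order = if (is.null(experiment_order)) NULL else
                   as.integer(experiment_order),
                 residual = residual),
            class = "rr_model_spec")
}

#' @export
print.rr_model_spec <- function(x, ...) {
  cat("rr_model_spec: fixed", x$fixed_order, "| genetic", x$genetic_order,
      "| experiment", if (is.null(x$experiment_order)) "none" else
        x$experiment_order,
      "| residual", x$residual, "\n")
  invisible(x)
}

spec_label <- function(spec) {
  paste0("g", spec$genetic_order, "_e",
         if (is.null(spec$experiment_order)) "x" else spec$experiment_order,
         "_", substr(spec$residual, 1, 3))
}

#' Default candidate model grid
#'
#' Genetic order \{1, 2\} x experiment order \{0, 1\} x residual
#' \{homogeneous, heterogeneous\}: eight candidate structures, all with the
#' fixed second-order trend.
#'
#' @return List of [rr_model_spec()] objects.
#' @export
default_model_grid <- function() {
  grid <- expand.grid(g = 1:2, e = 0:1, r = c("homogeneous", "heterogeneous"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    rr_model_spec(2L, grid$g[i], grid$e[i], grid$r[i])
  })
}

#' Build random-regression design matrices
#'
#' Constructs the fixed covariable matrix `X` and the sparse random
#' covariable matrices `Z` (genetic; one column block of Legendre covariables
#' per line of the relationship matrix, in its line order) and `Q`
#' (experiment). Row `r` of each matrix carries the basis row for record
#' `r`'s imaging day in the block of its line/experiment, zeros elsewhere.
#'
#' @param records A `phenotype_records` object.
#' @param spec An [rr_model_spec()].
#' @param grid A `time_grid` covering every record day.
#' @param grm A `genomic_relationship`; its `line_ids` fix the column-block
#'   order of `Z`.
#' @return List with `X`, `Z`, `Q` (or `NULL`), index vectors `day_idx`,
#'   `line_idx`, `exp_idx`, the basis matrices and id vectors.
#' @export
build_design <- function(records, spec, grid, grm) {
  day_idx <- match(records$day, grid$days)
  if (anyNA(day_idx)) {
    stop("record day(s) not in grid: ",
         paste(unique(records$day[is.na(day_idx)]), collapse = ", "))
  }
  line_ids <- grm$line_ids
  line_idx <- match(records$line_id, line_ids)
  if (anyNA(line_idx)) {
    stop("line(s) in phenotypes but absent from G: ",
         paste(unique(records$line_id[is.na(line_idx)]), collapse = ", "))
  }
  exp_ids <- sort(unique(records$experiment_id))
  exp_idx <- match(records$experiment_id, exp_ids)
  N <- nrow(records)
  n <- length(line_ids)
  ne <- length(exp_ids)

  Phi_f <- legendre_matrix(grid, spec$fixed_order)$phi
  Phi_g <- legendre_matrix(grid, spec$genetic_order)$phi
  qg <- spec$genetic_order + 1L
  X <- Phi_f[day_idx, , drop = FALSE]
  Z <- Matrix::sparseMatrix(
    i = rep(seq_len(N), each = qg),
    j = rep((line_idx - 1L) * qg, each = qg) + rep(1:qg, times = N),
    x = as.vector(t(Phi_g[day_idx, , drop = FALSE])),
    dims = c(N, n * qg))
  if (!is.null(spec$experiment_order)) {
    Phi_s <- legendre_matrix(grid, spec$experiment_order)$phi
    qs <- spec$experiment_order + 1L
    Q <- Matrix::sparseMatrix(
      i = rep(seq_len(N), each = qs),
      j = rep((exp_idx - 1L) * qs, each = qs) + rep(1:qs, times = N),
      x = as.vector(t(Phi_s[day_idx, , drop = FALSE])),
      dims = c(N, ne * qs))
  } else {
    Phi_s <- NULL
    Q <- NULL
  }
  list(X = X, Z = Z, Q = Q, day_idx = day_idx, line_idx = line_idx,
       exp_idx = exp_idx, line_ids = line_ids, exp_ids = exp_ids,
       Phi_f = Phi_f, Phi_g = Phi_g, Phi_s = Phi_s)
}

## ---------------------------------------------------------------------------
## Internal AI-REML core.
##
## Model: y = X beta + Z u + Q s + e with u ~ N(0, G (x) Omega),
## s ~ N(0, I (x) P), e ~ N(0, D) (day-grouped diagonal). Estimation is
## average-information REML with expectation-maximization fallback steps
## whenever an AI step fails to improve the restricted likelihood or leaves
## the parameter space.
##
## The mixed-model equations are solved in prior-whitened coordinates:
## writing Sigma = L L' (L from symmetric square roots of G, Omega, P via
## Kronecker structure), the working coefficient matrix is
##   C_hat = [X, W L]' R^-1 [X, W L] + diag(0, I),
## which never forms Sigma^-1, stays well conditioned when variance
## components approach the boundary (a singular Omega is handled exactly),
## and satisfies log|Sigma| + log|C_mme| = log|C_hat|, so the restricted
## likelihood is
##   -2 lR = log|R| + log|C_hat| + y'Py + (N-p) log 2pi - log|X'X|
## (the last term fixes the parameterization-dependence of the Harville
## form, making lR invariant to any full-rank recoding of X).
## All first-derivative trace terms reduce to strided diagonal-block sums of
## C_hat^-1, and the average-information matrix costs one extra multi-rhs
## triangular solve, so the per-iteration cost is a handful of dense
## factorizations/products of dimension p + n*qg + ne*qs.
## ---------------------------------------------------------------------------
#' REML solver settings
#'
#' @param max_iter Iteration cap (default 200).
#' @param tol_loglik Convergence tolerance on the change in restricted
#'   log-likelihood (default 1e-6).
#' @param tol_par Convergence tolerance on the relative parameter update
#'   (default 1e-6).
#' @param verbose Print per-iteration progress.
#' @param max_halving Step-halvings tried before falling back to an EM step.
#' @param polish After AI/EM convergence, refine by direct optimization over
#'   Cholesky factors — this moves smoothly along the PSD boundary, where
#'   projected AI/EM steps stall when an optimum has a singular `Omega` or
#'   `P`. `NULL` (default) enables it automatically for small parameter
#'   counts.
#' @return A list of settings for [fit_rr_reml()] and friends.
#' @export
reml_control <- function(max_iter = 200L, tol_loglik = 1e-6, tol_par = 1e-6,
                         verbose = FALSE, max_halving = 8L, polish = NULL) {
  list(max_iter = max_iter, tol_loglik = tol_loglik, tol_par = tol_par,
       verbose = verbose, max_halving = max_halving, polish = polish)
}

reml_core <- function(y, design, grm, residual_groups, control = reml_control(),
                      init = NULL, fix_vc = FALSE) {
  X <- design$X; Z <- design$Z; Q <- design$Q
  day_idx <- design$day_idx
  N <- length(y)
  p <- ncol(X)
  qg <- ncol(design$Phi_g)
  n <- length(design$line_ids)
  has_s <- !is.null(Q)
  qs <- if (has_s) ncol(design$Phi_s) else 0L
  ne <- if (has_s) length(design$exp_ids) else 0L
  M <- p + n * qg + ne * qs
  iu <- p + seq_len(n * qg)
  is_ <- if (has_s) p + n * qg + seq_len(ne * qs) else integer(0)
  irand <- c(iu, is_)

  grp_of_day <- residual_groups              # length t, values 1..ngrp
  ngrp <- max(grp_of_day, na.rm = TRUE)
  grp_rec <- grp_of_day[day_idx]

  G <- grm$G
  ## symmetric square root of (PSD-repaired) G, from the stored eigen pair
  Lg <- grm$eigen_vectors %*% (t(grm$eigen_vectors) *
                                 sqrt(pmax(grm$eigen_values, 0)))
  Lg <- (Lg + t(Lg)) / 2

  W <- if (has_s) cbind(X, Z, Q) else cbind(X, Z)
  W <- methods::as(W, "CsparseMatrix")

  ## per-residual-group sufficient statistics
  Mg <- vector("list", ngrp); rhsg <- matrix(0, M, ngrp)
  yyg <- numeric(ngrp); Ng <- integer(ngrp)
  Mg_trip <- vector("list", ngrp)
  rows_of_grp <- vector("list", ngrp)
  for (g in seq_len(ngrp)) {
    rows <- which(grp_rec == g)
    rows_of_grp[[g]] <- rows
    Wg <- W[rows, , drop = FALSE]
    Mgg <- methods::as(Matrix::crossprod(Wg), "generalMatrix")
    Mg[[g]] <- Mgg
    trip <- Matrix::summary(Mgg)
    Mg_trip[[g]] <- cbind(trip$i, trip$j)
    rhsg[, g] <- as.vector(Matrix::crossprod(Wg, y[rows]))
    yyg[g] <- sum(y[rows]^2)
    Ng[g] <- length(rows)
  }
  Mg_x <- lapply(seq_len(ngrp), function(g) Matrix::summary(Mg[[g]])$x)

  ## template for the weighted sum of per-group crossproducts: one sparse
  ## pattern, per-group value columns, only the @x slot updated per
  ## evaluation (avoids repeated sparse-matrix arithmetic dispatch)
  Csp_tpl <- abs(Mg[[1L]])              # abs: no cancellation in the union
  if (ngrp > 1L) for (g in 2:ngrp) Csp_tpl <- Csp_tpl + abs(Mg[[g]])
  Csp_tpl <- methods::as(Csp_tpl, "CsparseMatrix")
  tpl_sum <- Matrix::summary(Csp_tpl)
  tpl_key <- tpl_sum$i + (tpl_sum$j - 1) * M
  Vmat <- matrix(0, length(tpl_key), ngrp)
  for (g in seq_len(ngrp)) {
    key_g <- Mg_trip[[g]][, 1L] + (Mg_trip[[g]][, 2L] - 1) * M
    Vmat[match(key_g, tpl_key), g] <- Mg_x[[g]]
  }

  ## Region decomposition of each group's crossproduct pattern, so that
  ## tr(C^-1 M_g) can be assembled from small structured blocks of C^-1
  ## (fixed rows, within-line genetic diagonal blocks, the genetic-by-
  ## experiment strip) instead of forming the full dense inverse. The
  ## within-line property of the u-u entries holds because each record
  ## touches exactly one line block of Z.
  region_of <- function(k) {
    ifelse(k <= p, 1L, ifelse(k <= p + n * qg, 2L, 3L))
  }
  trace_idx <- lapply(seq_len(ngrp), function(g) {
    ii <- Mg_trip[[g]][, 1L]; jj <- Mg_trip[[g]][, 2L]; xv <- Mg_x[[g]]
    ri <- region_of(ii); rj <- region_of(jj)
    sw <- ri > rj
    tmp <- ii[sw]; ii[sw] <- jj[sw]; jj[sw] <- tmp
    r1 <- pmin(ri, rj); r2 <- pmax(ri, rj)
    out <- list()
    sel <- r1 == 1L & r2 == 1L
    out$xx <- cbind(ii[sel], jj[sel]); out$xx_x <- xv[sel]
    sel <- r1 == 1L & r2 == 2L
    out$xu <- cbind(ii[sel], jj[sel] - p); out$xu_x <- xv[sel]
    sel <- r1 == 1L & r2 == 3L
    out$xs <- cbind(ii[sel], jj[sel] - p - n * qg); out$xs_x <- xv[sel]
    sel <- r1 == 2L & r2 == 2L
    ui <- ii[sel] - p; uj <- jj[sel] - p
    li <- (ui - 1L) %/% qg + 1L; a <- (ui - 1L) %% qg + 1L
    lj <- (uj - 1L) %/% qg + 1L; b <- (uj - 1L) %% qg + 1L
    stopifnot(all(li == lj))
    out$uu <- li + (a - 1L) * n + (b - 1L) * n * qg
    out$uu_x <- xv[sel]
    sel <- r1 == 2L & r2 == 3L
    out$us <- cbind(ii[sel] - p, jj[sel] - p - n * qg); out$us_x <- xv[sel]
    sel <- r1 == 3L & r2 == 3L
    out$ss <- cbind(ii[sel] - p - n * qg, jj[sel] - p - n * qg)
    out$ss_x <- xv[sel]
    out
  })

  ## (Lg (x) Lo) v for a stack of columns, via vec(Lo Vm Lg')
  kron_u_mult <- function(Lo, V) {
    V <- as.matrix(V)
    out <- matrix(0, n * qg, ncol(V))
    for (k in seq_len(ncol(V))) {
      Vm <- matrix(V[, k], qg, n)
      out[, k] <- as.vector(Lo %*% Vm %*% Lg)   # Lg symmetric
    }
    out
  }

  ## starting values: project smooth per-day variance targets onto the
  ## coefficient bases (shape-aware moment start; cuts the climb-in phase)
  ols <- stats::lm.fit(as.matrix(X), y)
  v0 <- max(stats::var(ols$residuals), 1e-8)
  ## + 0.5 log|X'X| makes the restricted likelihood invariant to any
  ## full-rank reparameterization of the fixed effects
  logdetXtX <- determinant(crossprod(as.matrix(X)))$modulus
  days_rep <- sort(unique(day_idx))
  v_day <- vapply(days_rep, function(d) {
    r <- ols$residuals[day_idx == d]
    if (length(r) > 1L) stats::var(r) else v0
  }, numeric(1))
  v_day <- pmax(v_day, 1e-8)
  proj_start <- function(Phi, share) {
    Ph <- Phi[days_rep, , drop = FALSE]
    x_rep <- seq(-1, 1, length.out = length(days_rep))
    R <- exp(-outer(x_rep, x_rep, `-`)^2)      # smooth high correlation
    Cstar <- sqrt(share * v_day) * t(sqrt(share * v_day) * R)
    B <- tryCatch(solve(crossprod(Ph), t(Ph)), error = function(e) NULL)
    q <- ncol(Phi)
    if (is.null(B)) return(diag(share * v0 / mean(rowSums(Phi^2)), q))
    A <- B %*% Cstar %*% t(B)
    A <- (A + t(A)) / 2 + diag(0.01 * share * v0, q)
    A
  }
  if (is.null(init)) init <- list()
  Omega <- as.matrix(init$Omega %||% proj_start(design$Phi_g, 0.5))
  Pmat <- if (has_s) {
    as.matrix(init$P %||% proj_start(design$Phi_s, 0.1))
  } else NULL
  D <- if (!is.null(init$D)) rep(init$D, length.out = ngrp) else {
    vapply(seq_len(ngrp), function(g) {
      in_g <- days_rep %in% unique(day_idx[grp_rec == g])
      0.4 * mean(v_day[in_g])
    }, numeric(1))
  }
  D[!is.finite(D) | D <= 0] <- 0.4 * v0
  d_floor <- 1e-10 * v0
  n_projections <- 0L

  ## symmetric PSD square root; negative eigenvalues clamped to zero
  sym_sqrt <- function(A) {
    eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
    if (any(eg$values < -1e-12 * max(abs(eg$values), 1))) {
      n_projections <<- n_projections + 1L
    }
    lam <- pmax(eg$values, 0)
    L <- eg$vectors %*% (t(eg$vectors) * sqrt(lam))
    list(L = (L + t(L)) / 2, values = lam, vectors = eg$vectors)
  }
  ## inverse of the square root, flooring tiny eigenvalues (gradient use only)
  sym_sqrt_inv <- function(sq) {
    lam <- pmax(sq$values, max(sq$values, 0) * 1e-10 + 1e-12 * v0)
    Li <- sq$vectors %*% (t(sq$vectors) / sqrt(lam))
    (Li + t(Li)) / 2
  }

  project_psd <- function(A) {
    eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
    if (any(eg$values < 0)) {
      n_projections <<- n_projections + 1L
      eg$values <- pmax(eg$values, 0)
      A <- eg$vectors %*% (t(eg$vectors) * eg$values)
      A <- (A + t(A)) / 2
    }
    A
  }

  ## evaluate state at (Omega, P, D): whitened MME Cholesky, solutions, loglik
  eval_state <- function(Omega, Pmat, D) {
    if (any(!is.finite(D)) || any(D <= 0)) return(NULL)
    if (any(!is.finite(Omega))) return(NULL)
    sqO <- sym_sqrt(Omega)
    if (has_s) {
      if (any(!is.finite(Pmat))) return(NULL)
      sqP <- sym_sqrt(Pmat)
    }
    ## TL = blockdiag(I_p, Lg (x) Lo, I_ne (x) Lp), dense M x M
    TL <- matrix(0, M, M)
    if (p > 0) TL[seq_len(p), seq_len(p)] <- diag(1, p)
    TL[iu, iu] <- kronecker(Lg, sqO$L)
    if (has_s) TL[is_, is_] <- kronecker(diag(ne), sqP$L)
    Csp <- Csp_tpl
    Csp@x <- drop(Vmat %*% (1 / D))
    Y <- as.matrix(Csp %*% TL)
    Chat <- crossprod(TL, Y)
    diag(Chat)[irand] <- diag(Chat)[irand] + 1
    ch <- tryCatch(chol(Chat), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    rhs <- drop(rhsg %*% (1 / D))
    rhs_hat <- drop(crossprod(TL, rhs))
    sol_hat <- backsolve(ch, backsolve(ch, rhs_hat, transpose = TRUE))
    sol <- drop(TL %*% sol_hat)
    yRy <- sum(yyg / D)
    yPy <- yRy - sum(rhs_hat * sol_hat)
    logdetC <- 2 * sum(log(diag(ch)))
    logdetR <- sum(Ng * log(D))
    ll <- -0.5 * (logdetR + logdetC + yPy + (N - p) * log(2 * pi) -
                    logdetXtX)
    ehat <- y - as.vector(W %*% sol)
    Py <- ehat / D[grp_rec]
    list(Omega = Omega, P = if (has_s) Pmat else NULL, D = D,
         TL = TL, chol = ch, sol = sol, sol_hat = sol_hat,
         rhs_hat = rhs_hat, loglik = as.numeric(ll), Py = Py, ehat = ehat,
         sqO = sqO, sqP = if (has_s) sqP else NULL)
  }

  par_vec <- function(Omega, Pmat, D) {
    c(Omega[upper.tri(Omega, diag = TRUE)],
      if (has_s) Pmat[upper.tri(Pmat, diag = TRUE)] else NULL, D)
  }

  ## parameter bookkeeping: Omega pairs, P pairs, D groups
  pair_grid <- function(q) {
    idx <- which(upper.tri(diag(q), diag = TRUE), arr.ind = TRUE)
    idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
  }
  o_pairs <- pair_grid(qg)
  s_pairs <- if (has_s) pair_grid(qs) else NULL
  n_o <- nrow(o_pairs)
  n_s <- if (has_s) nrow(s_pairs) else 0L
  npar <- n_o + n_s + ngrp

  state <- eval_state(Omega, Pmat, D)
  if (is.null(state)) stop("invalid starting values for REML")

  ## strided diagonal-block sum: S[c,d] = sum_k T[off+(k-1)q+c, off+(k-1)q+d]
  block_diag_sum <- function(T_, off, q, nblock) {
    S <- matrix(0, q, q)
    for (cc in seq_len(q)) for (dd in seq_len(q)) {
      ii <- off + seq.int(cc, nblock * q, by = q)
      jj <- off + seq.int(dd, nblock * q, by = q)
      S[cc, dd] <- sum(T_[cbind(ii, jj)])
    }
    S
  }

  ## gradient, AI matrix and EM updates at the current state
  derivs <- function(state) {
    That <- chol2inv(state$chol)
    Lo <- state$sqO$L
    Svv <- matrix(0, qg, qg)
    ## per-line quadratic forms S_li[c,d] = Lg[li,]' B_cd Lg[li,] of the
    ## strided u-blocks B_cd of C_hat^-1; the within-line diagonal blocks
    ## of the raw-MME inverse are then Lo S_li Lo'
    Suu <- matrix(0, n, qg * qg)
    for (cc in seq_len(qg)) for (dd in cc:qg) {
      Bcd <- That[p + seq.int(cc, n * qg, qg), p + seq.int(dd, n * qg, qg),
                  drop = FALSE]
      Svv[cc, dd] <- Svv[dd, cc] <- sum(diag(Bcd))
      v <- rowSums((Lg %*% Bcd) * Lg)
      Suu[, cc + (dd - 1L) * qg] <- v
      if (dd > cc) Suu[, dd + (cc - 1L) * qg] <- v
    }
    Cuu_blocks <- Suu %*% t(kronecker(Lo, Lo))   # n x qg^2, vec(Lo S Lo')
    Cxx <- That[seq_len(p), seq_len(p), drop = FALSE]
    Cxu <- t(kron_u_mult(Lo, t(That[seq_len(p), iu, drop = FALSE])))
    if (has_s) {
      Sss <- block_diag_sum(That, p + n * qg, qs, ne)
      Lp <- state$sqP$L
      TLs_small <- kronecker(diag(ne), Lp)
      Cxs <- That[seq_len(p), is_, drop = FALSE] %*% t(TLs_small)
      Cus <- kron_u_mult(Lo, That[iu, is_, drop = FALSE]) %*% t(TLs_small)
      Css <- TLs_small %*% That[is_, is_, drop = FALSE] %*% t(TLs_small)
    }
    LoInv <- sym_sqrt_inv(state$sqO)
    if (has_s) LpInv <- sym_sqrt_inv(state$sqP)
    trCM <- vapply(seq_len(ngrp), function(g) {
      ti <- trace_idx[[g]]
      val <- sum(Cxx[ti$xx] * ti$xx_x) + sum(Cxu[ti$xu] * ti$xu_x) +
        sum(Cuu_blocks[ti$uu] * ti$uu_x)
      if (has_s) {
        val <- val + sum(Cxs[ti$xs] * ti$xs_x) +
          sum(Cus[ti$us] * ti$us_x) + sum(Css[ti$ss] * ti$ss_x)
      }
      val
    }, numeric(1))

    wPy <- as.vector(Matrix::crossprod(W, state$Py))
    Vm <- matrix(wPy[iu], qg, n)          # column j = line j coefficients
    VG <- Vm %*% G
    Qm <- VG %*% t(Vm)                    # qg x qg
    if (has_s) {
      Vs <- matrix(wPy[is_], qs, ne)
      Qs <- Vs %*% t(Vs)
    }

    grad <- numeric(npar)
    Fmat <- matrix(0, N, npar)            # f_i = V_i %*% Py, per parameter
    Pg_day <- design$Phi_g[day_idx, , drop = FALSE]
    for (k in seq_len(n_o)) {
      a <- o_pairs[k, "row"]; b <- o_pairs[k, "col"]
      E <- matrix(0, qg, qg); E[a, b] <- E[a, b] + 1; E[b, a] <- E[b, a] + 1
      if (a == b) E[a, a] <- 1
      Et <- LoInv %*% E %*% LoInv
      tr_term <- n * sum(diag(Et)) - sum(Et * t(Svv))
      quad <- if (a == b) Qm[a, a] else 2 * Qm[a, b]
      grad[k] <- -0.5 * (tr_term - quad)
      Fmat[, k] <- if (a == b) Pg_day[, a] * VG[a, design$line_idx] else
        Pg_day[, a] * VG[b, design$line_idx] +
        Pg_day[, b] * VG[a, design$line_idx]
    }
    if (has_s) {
      Ps_day <- design$Phi_s[day_idx, , drop = FALSE]
      for (k in seq_len(n_s)) {
        a <- s_pairs[k, "row"]; b <- s_pairs[k, "col"]
        E <- matrix(0, qs, qs); E[a, b] <- E[a, b] + 1; E[b, a] <- E[b, a] + 1
        if (a == b) E[a, a] <- 1
        Et <- LpInv %*% E %*% LpInv
        tr_term <- ne * sum(diag(Et)) - sum(Et * t(Sss))
        quad <- if (a == b) Qs[a, a] else 2 * Qs[a, b]
        grad[n_o + k] <- -0.5 * (tr_term - quad)
        Fmat[, n_o + k] <- if (a == b) Ps_day[, a] * Vs[a, design$exp_idx] else
          Ps_day[, a] * Vs[b, design$exp_idx] +
          Ps_day[, b] * Vs[a, design$exp_idx]
      }
    }
    for (g in seq_len(ngrp)) {
      k <- n_o + n_s + g
      tr_term <- Ng[g] / state$D[g] - trCM[g] / state$D[g]^2
      rows <- rows_of_grp[[g]]
      grad[k] <- -0.5 * (tr_term - sum(state$Py[rows]^2))
      Fmat[rows, k] <- state$Py[rows]
    }

    ## average-information matrix: AI_ij = 0.5 * f_i' P f_j
    Rinv_F <- Fmat / state$D[grp_rec]
    H <- as.matrix(Matrix::crossprod(W, Rinv_F))
    Hhat <- crossprod(state$TL, H)
    CH <- backsolve(state$chol,
                    backsolve(state$chol, Hhat, transpose = TRUE))
    PF <- Rinv_F - as.matrix(W %*% (state$TL %*% CH)) / state$D[grp_rec]
    AI <- 0.5 * crossprod(Fmat, PF)

    ## EM updates (used as fallback steps)
    Mv <- matrix(state$sol_hat[iu], qg, n)
    em_Omega <- state$sqO$L %*% (Mv %*% t(Mv) + Svv) %*% state$sqO$L / n
    em_Omega <- (em_Omega + t(em_Omega)) / 2
    if (has_s) {
      Ms <- matrix(state$sol_hat[is_], qs, ne)
      em_P <- state$sqP$L %*% (Ms %*% t(Ms) + Sss) %*% state$sqP$L / ne
      em_P <- (em_P + t(em_P)) / 2
    }
    em_D <- vapply(seq_len(ngrp), function(g) {
      (sum(state$ehat[rows_of_grp[[g]]]^2) + trCM[g]) / Ng[g]
    }, numeric(1))
    list(grad = grad, AI = AI,
         em = list(Omega = em_Omega, P = if (has_s) em_P else NULL,
                   D = em_D))
  }

  unpack <- function(theta) {
    Om <- matrix(0, qg, qg)
    Om[upper.tri(Om, diag = TRUE)] <- theta[seq_len(n_o)]
    Om <- Om + t(Om)
    diag(Om) <- diag(Om) / 2
    if (has_s) {
      Pm <- matrix(0, qs, qs)
      Pm[upper.tri(Pm, diag = TRUE)] <- theta[n_o + seq_len(n_s)]
      Pm <- Pm + t(Pm)
      diag(Pm) <- diag(Pm) / 2
    } else Pm <- NULL
    Dv <- theta[n_o + n_s + seq_len(ngrp)]
    list(Omega = Om, P = Pm, D = Dv)
  }

  converged <- FALSE
  n_iter <- 0L
  last_grad <- NULL
  n_flat <- 0L
  if (!fix_vc) {
    for (iter in seq_len(control$max_iter)) {
      n_iter <- iter
      dv <- derivs(state)
      last_grad <- dv$grad
      theta <- par_vec(state$Omega, state$P, state$D)
      AI <- dv$AI
      improved <- FALSE
      st2 <- NULL
      clean_ai <- FALSE
      ## Levenberg-Marquardt style damping: a rejected AI step is retried
      ## with a growing ridge, bending the direction toward the gradient
      ridge <- 1e-8
      mdiag <- mean(diag(AI)) + 1e-300
      for (h in seq_len(control$max_halving)) {
        step_dir <- tryCatch(
          solve(AI + ridge * mdiag * diag(npar), dv$grad),
          error = function(e) dv$grad / mdiag)
        cand <- unpack(theta + step_dir)
        cand$Omega <- project_psd(cand$Omega)
        if (has_s) cand$P <- project_psd(cand$P)
        cand$D <- pmax(cand$D, d_floor)
        st_try <- eval_state(cand$Omega, cand$P, cand$D)
        if (!is.null(st_try) && st_try$loglik >= state$loglik - 1e-10) {
          st2 <- st_try
          improved <- TRUE
          clean_ai <- h == 1L
          break
        }
        ridge <- ridge * 100
      }
      if (!improved) {
        ## EM fallback (monotone by construction, up to numerics), with
        ## over-relaxation: plain EM creeps along curved likelihood
        ## valleys, so extrapolated multiples of the EM step are tried
        ## first and the best improving candidate wins
        em <- dv$em
        em$Omega <- project_psd(em$Omega)
        if (has_s) em$P <- project_psd(em$P)
        em$D <- pmax(em$D, d_floor)
        th_em <- par_vec(em$Omega, em$P, em$D)
        st2 <- NULL
        for (kappa in c(16, 4, 1)) {
          cand <- unpack(theta + kappa * (th_em - theta))
          cand$Omega <- project_psd(cand$Omega)
          if (has_s) cand$P <- project_psd(cand$P)
          cand$D <- pmax(cand$D, d_floor)
          st_try <- eval_state(cand$Omega, cand$P, cand$D)
          if (!is.null(st_try) &&
              st_try$loglik >= state$loglik - 1e-10 &&
              (is.null(st2) || st_try$loglik > st2$loglik)) {
            st2 <- st_try
            if (kappa > 1) break      # extrapolation paid off; take it
          }
        }
        if (is.null(st2) || st2$loglik < state$loglik - 1e-8) {
          ## no direction improves: accept current point as the optimum
          converged <- TRUE
          break
        }
      }
      ## over-relaxation: damped or EM moves creep along curved likelihood
      ## valleys, so extrapolate the accepted move while it keeps paying
      if (!clean_ai) {
        repeat {
          th2 <- par_vec(st2$Omega, st2$P, st2$D)
          cand <- unpack(theta + 4 * (th2 - theta))
          cand$Omega <- project_psd(cand$Omega)
          if (has_s) cand$P <- project_psd(cand$P)
          cand$D <- pmax(cand$D, d_floor)
          st_try <- eval_state(cand$Omega, cand$P, cand$D)
          if (!is.null(st_try) && st_try$loglik > st2$loglik + 1e-10) {
            st2 <- st_try
          } else break
        }
      }
      d_ll <- st2$loglik - state$loglik
      ## relative parameter change, with a variance-scale slack so that
      ## parameters drifting within numerical noise of zero do not gate
      ## convergence
      d_par <- max(abs(par_vec(st2$Omega, st2$P, st2$D) - theta) /
                     (abs(theta) + 1e-4 * v0))
      if (control$verbose) {
        message(sprintf("iter %3d  loglik %.6f  dll %.2e  dpar %.2e",
                        iter, st2$loglik, d_ll, d_par))
      }
      state <- st2
      n_flat <- if (abs(d_ll) < control$tol_loglik) n_flat + 1L else 0L
      ## converged when the likelihood has stabilized and either parameters
      ## have too, or the likelihood has been flat for several iterations
      ## (parameters sliding along a flat ridge no longer matter)
      if (abs(d_ll) < control$tol_loglik &&
          (d_par < control$tol_par || n_flat >= 3L)) {
        converged <- TRUE
        break
      }
    }
    ## optional polish: direct maximization over Cholesky factors, which
    ## moves smoothly along the PSD boundary (rank-deficient Omega/P)
    ## worthwhile only where likelihood evaluations are near-free and
    ## boundary optima are likely (tiny instances)
    do_polish <- isTRUE(control$polish) ||
      (is.null(control$polish) && npar <= 10L && M <= 80L)
    if (do_polish) {
      low_tri <- function(q) which(lower.tri(diag(q), diag = TRUE))
      chol_from <- function(A) {
        q <- nrow(A)
        t(chol(A + diag(1e-12 * (mean(diag(A)) + v0), q)))
      }
      Lo0 <- chol_from(state$Omega)
      Lp0 <- if (has_s) chol_from(state$P) else NULL
      par0 <- c(Lo0[low_tri(qg)], if (has_s) Lp0[low_tri(qs)] else NULL,
                log(state$D))
      nlo <- length(low_tri(qg))
      nlp <- if (has_s) length(low_tri(qs)) else 0L
      fn <- function(par) {
        Lo <- matrix(0, qg, qg); Lo[low_tri(qg)] <- par[seq_len(nlo)]
        Om <- Lo %*% t(Lo)
        if (has_s) {
          Lp <- matrix(0, qs, qs)
          Lp[low_tri(qs)] <- par[nlo + seq_len(nlp)]
          Pm <- Lp %*% t(Lp)
        } else Pm <- NULL
        Dv <- exp(par[nlo + nlp + seq_len(ngrp)])
        st <- eval_state(Om, Pm, Dv)
        if (is.null(st)) return(1e12)
        -st$loglik
      }
      opt <- stats::optim(par0, fn, method = "Nelder-Mead",
                          control = list(maxit = 2000L, reltol = 1e-13))
      if (-opt$value > state$loglik + 1e-12) {
        Lo <- matrix(0, qg, qg); Lo[low_tri(qg)] <- opt$par[seq_len(nlo)]
        if (has_s) {
          Lp <- matrix(0, qs, qs)
          Lp[low_tri(qs)] <- opt$par[nlo + seq_len(nlp)]
        }
        st2 <- eval_state(Lo %*% t(Lo),
                          if (has_s) Lp %*% t(Lp) else NULL,
                          exp(opt$par[nlo + nlp + seq_len(ngrp)]))
        if (!is.null(st2) && st2$loglik > state$loglik) {
          if (control$verbose) {
            message(sprintf("polish: loglik %.6f -> %.6f",
                            state$loglik, st2$loglik))
          }
          state <- st2
        }
      }
    }
    ## final gradient at the accepted optimum
    last_grad <- derivs(state)$grad
  } else {
    converged <- TRUE
    last_grad <- derivs(state)$grad
  }

  mme_resid <- {
    Chat_sol <- crossprod(state$chol, state$chol %*% state$sol_hat)
    sqrt(sum((Chat_sol - state$rhs_hat)^2)) /
      max(sqrt(sum(state$rhs_hat^2)), 1e-300)
  }

  beta <- state$sol[seq_len(p)]
  u_hat <- matrix(state$sol[iu], n, qg, byrow = TRUE,
                  dimnames = list(design$line_ids,
                                  colnames(design$Phi_g)))
  s_hat <- if (has_s) {
    matrix(state$sol[is_], ne, qs, byrow = TRUE,
           dimnames = list(design$exp_ids, colnames(design$Phi_s)))
  } else NULL

  ## scale-free convergence diagnostic: gradient contracted with parameters
  theta_fin <- par_vec(state$Omega, state$P, state$D)
  grad_scaled <- if (all(is.na(last_grad))) NA_real_ else
    max(abs(last_grad * theta_fin))

  list(beta = beta, u_hat = u_hat, s_hat = s_hat,
       Omega = state$Omega, P = state$P, D = state$D,
       loglik = state$loglik, converged = converged, n_iter = n_iter,
       grad = last_grad, grad_scaled = grad_scaled,
       mme_residual = mme_resid, n_psd_projections = n_projections,
       Py = state$Py)
}

#' Fit the random-regression gBLUP model by REML
#'
#' Estimates the Kronecker-structured covariance components of
#' \deqn{y = X\beta + Zu + Qs + e,\quad u \sim N(0, G \otimes \Omega),\;
#'  s \sim N(0, I \otimes P),\; e \sim N(0, D)}
#' by average-information REML (with expectation-maximization fallback
#' steps), where the random genetic and experiment effects are Legendre
#' regression coefficient curves and `D` is diagonal with one variance per
#' imaging day (or a single variance, per the spec). Coefficient BLUPs
#' \eqn{\hat u} (every line of `grm`, including lines without records, whose
#' BLUPs are propagated through `G`) and \eqn{\hat s} are solved from the
#' mixed-model equations at the optimum.
#'
#' @param records A `phenotype_records` object.
#' @param grm A `genomic_relationship` covering every phenotyped line.
#' @param spec An [rr_model_spec()].
#' @param grid A `time_grid`; its domain controls the basis standardization
#'   (fit on a sub-window, evaluate later days inside the same domain).
#'   Defaults to the record days with their own range as domain.
#' @param control Solver settings from [reml_control()].
#' @param init Optional list with starting `Omega`, `P`, `D`.
#' @param fix_vc If `TRUE`, no REML iteration: solve BLUPs at `init`.
#' @return An `rr_fit` object: `beta`, `u_hat` (n x (genetic_order+1)),
#'   `s_hat`, `vc` (list `Omega`, `P`, `D` per day), `loglik`, `aic`,
#'   `n_params`, `converged`, `n_iter`, diagnostics, `spec`, `grid`.
#' @export
fit_rr_reml <- function(records, grm, spec = rr_model_spec(),
                        grid = standardize_time(day_set(records)),
                        control = reml_control(), init = NULL,
                        fix_vc = FALSE) {
  t_n <- length(grid$days)
  if (t_n < spec$genetic_order + 1L) {
    stop("need at least genetic_order+1 distinct days")
  }
  ## lines without records contribute nothing to the likelihood: fit on
  ## the phenotyped subset and propagate their coefficient BLUPs through
  ## G afterwards (exact, and much cheaper than carrying them in the MME)
  phen_lines <- unique(records$line_id)
  all_lines <- grm$line_ids
  miss <- setdiff(phen_lines, all_lines)
  if (length(miss)) {
    stop("line(s) in phenotypes but absent from G: ",
         paste(miss, collapse = ", "))
  }
  grm_full <- grm
  subset_fit <- length(phen_lines) < length(all_lines)
  if (subset_fit) {
    grm <- grm_subset(grm, all_lines[all_lines %in% phen_lines])
  }
  design <- build_design(records, spec, grid, grm)
  groups <- if (spec$residual == "heterogeneous") seq_len(t_n) else
    rep(1L, t_n)
  ## only days present in the records carry residual information
  present <- sort(unique(design$day_idx))
  if (spec$residual == "heterogeneous" && length(present) < t_n) {
    groups <- match(seq_len(t_n), present)       # NA for absent days
    groups_eval <- groups
    groups[is.na(groups)] <- 1L                   # unused slots
  } else groups_eval <- groups
  fit <- reml_core(records$value, design, grm, groups,
                   control = control, init = init, fix_vc = fix_vc)
  if (subset_fit) {
    fit$u_hat <- propagate_blups(fit$u_hat, grm_full, grm$line_ids)
  }
  ngrp <- max(groups[!is.na(groups_eval)], 1L)
  D_day <- fit$D[ifelse(is.na(groups_eval), NA, groups_eval)]
  names(D_day) <- as.character(grid$days)
  qg <- spec$genetic_order + 1L
  qs <- if (is.null(spec$experiment_order)) 0L else spec$experiment_order + 1L
  n_params <- qg * (qg + 1L) / 2L + qs * (qs + 1L) / 2L +
    if (spec$residual == "heterogeneous") length(present) else 1L
  structure(list(
    spec = spec, grid = grid, beta = fit$beta,
    u_hat = fit$u_hat, s_hat = fit$s_hat,
    vc = list(Omega = fit$Omega, P = fit$P, D = D_day),
    loglik = fit$loglik, n_params = n_params,
    aic = model_aic(fit$loglik, n_params),
    converged = fit$converged, n_iter = fit$n_iter,
    grad_scaled = fit$grad_scaled, mme_residual = fit$mme_residual,
    n_psd_projections = fit$n_psd_projections,
    line_ids = grm_full$line_ids, exp_ids = design$exp_ids),
    class = "rr_fit")
}

## gBLUP propagation to unphenotyped lines: u_all = G[all, s] G[s, s]^- u_s
## (conditional expectation under the joint normal; pseudo-inverse from the
## clamped eigen pair tolerates a singular G)
propagate_blups <- function(u_sub, grm_full, sub_ids) {
  idx <- match(sub_ids, grm_full$line_ids)
  Gsub <- grm_full$G[idx, idx, drop = FALSE]
  eg <- eigen(Gsub, symmetric = TRUE)
  keep <- eg$values > 1e-8 * max(eg$values, 1)
  Ginv_u <- eg$vectors[, keep, drop = FALSE] %*%
    ((t(eg$vectors[, keep, drop = FALSE]) %*% u_sub) / eg$values[keep])
  out <- grm_full$G[, idx, drop = FALSE] %*% Ginv_u
  ## the phenotyped lines keep their exact solutions
  out[idx, ] <- u_sub
  rownames(out) <- grm_full$line_ids
  colnames(out) <- colnames(u_sub)
  out
}

#' @export
print.rr_fit <- function(x, ...) {
  cat("rr_fit:", spec_label(x$spec), "\n")
  cat("  loglik", format(x$loglik, digits = 10), " AIC",
      format(x$aic, digits = 10), " params", x$n_params, "\n")
  cat("  converged:", x$converged, "in", x$n_iter, "iterations\n")
  invisible(x)
}

#' Akaike information criterion
#'
#' `-2 loglik + 2 n_params`, with `n_params` counting the free (co)variance
#' parameters only (REML-based AIC convention; fixed effects excluded).
#'
#' @param loglik Restricted log-likelihood at the optimum.
#' @param n_params Number of free covariance parameters (>= 1).
#' @return The AIC value.
#' @examples
#' model_aic(-100, 10)  # 220
#' @export
model_aic <- function(loglik, n_params) {
  stopifnot(n_params >= 1)
  -2 * loglik + 2 * n_params
}

#' Fit and rank candidate random-regression models by AIC
#'
#' @param records A `phenotype_records`.
#' @param grm A `genomic_relationship`.
#' @param grid A `time_grid`.
#' @param candidates List of [rr_model_spec()]s (default
#'   [default_model_grid()]).
#' @param control Solver settings.
#' @return A data frame (one row per candidate, ascending AIC; fits that did
#'   not converge are ranked last and flagged) with the fit objects attached
#'   as attribute `fits` (in ranked order).
#' @export
select_model <- function(records, grm,
                         grid = standardize_time(day_set(records)),
                         candidates = default_model_grid(),
                         control = reml_control()) {
  stopifnot(length(candidates) >= 1L)
  fits <- lapply(candidates, function(sp) {
    tryCatch(fit_rr_reml(records, grm, sp, grid, control = control),
             error = function(e) structure(list(spec = sp, error =
                                                  conditionMessage(e)),
                                           class = "rr_fit_failed"))
  })
  ok <- !vapply(fits, inherits, logical(1), "rr_fit_failed")
  if (!any(ok)) stop("all candidate fits failed")
  tab <- data.frame(
    model = vapply(fits, function(f) spec_label(f$spec), character(1)),
    genetic_order = vapply(candidates, `[[`, integer(1), "genetic_order"),
    experiment_order = vapply(candidates, function(s)
      s$experiment_order %||% NA_integer_, integer(1)),
    residual = vapply(candidates, `[[`, character(1), "residual"),
    n_params = NA_integer_, loglik = NA_real_, aic = NA_real_,
    converged = FALSE)
  for (i in which(ok)) {
    tab$n_params[i] <- fits[[i]]$n_params
    tab$loglik[i] <- fits[[i]]$loglik
    tab$aic[i] <- fits[[i]]$aic
    tab$converged[i] <- fits[[i]]$converged
  }
  ord <- order(!tab$converged, ifelse(is.na(tab$aic), Inf, tab$aic))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}

#' Single-time-point gBLUP fit
#'
#' Fits the conventional per-day mixed model \eqn{y = \mu + Zu + Qs + e}
#' with \eqn{u \sim N(0, G\sigma^2_g)}, \eqn{s \sim N(0, I\sigma^2_s)},
#' \eqn{e \sim N(0, I\sigma^2_e)} by REML, at one imaging day. gBLUPs are
#' returned for every line of `grm` (lines without records at that day get
#' `G`-propagated predictions).
#'
#' @param records A `phenotype_records`.
#' @param grm A `genomic_relationship`.
#' @param day The imaging day to fit.
#' @param control Solver settings.
#' @return List with `sigma_g2`, `sigma_s2`, `sigma_e2`, `h2`, `gblup`
#'   (named vector over all lines of `grm`), `loglik`, `aic`, `converged`.
#' @export
fit_tp_gblup <- function(records, grm, day, control = reml_control()) {
  sub <- records[records$day == day, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no records at day ", day)
  sub <- as_phenotype_records(sub)
  ne <- length(unique(sub$experiment_id))
  spec <- rr_model_spec(0L, 0L, if (ne >= 2L) 0L else NULL, "homogeneous")
  grid <- standardize_time(day, c(day, day))
  ## fit on the phenotyped subset; propagate gBLUPs through G afterwards
  phen_lines <- unique(sub$line_id)
  grm_full <- grm
  subset_fit <- length(phen_lines) < length(grm$line_ids)
  if (subset_fit) {
    grm <- grm_subset(grm, grm$line_ids[grm$line_ids %in% phen_lines])
  }
  design <- build_design(sub, spec, grid, grm)
  ## raw (unnormalized) order-0 basis: covariables are exactly 1, so the
  ## coefficient variances ARE the per-day variance components
  design$Phi_f <- matrix(1, 1, 1, dimnames = list(NULL, "deg0"))
  design$Phi_g <- matrix(1, 1, 1, dimnames = list(NULL, "deg0"))
  design$X <- design$Phi_f[design$day_idx, , drop = FALSE]
  design$Z@x <- rep(1, length(design$Z@x))
  if (!is.null(design$Q)) {
    design$Phi_s <- matrix(1, 1, 1, dimnames = list(NULL, "deg0"))
    design$Q@x <- rep(1, length(design$Q@x))
  }
  fit <- reml_core(sub$value, design, grm, residual_groups = 1L,
                   control = control)
  if (subset_fit) {
    fit$u_hat <- propagate_blups(fit$u_hat, grm_full, grm$line_ids)
  }
  sg2 <- fit$Omega[1, 1]
  ss2 <- if (!is.null(fit$P)) fit$P[1, 1] else 0
  se2 <- fit$D[1]
  n_params <- 2L + as.integer(!is.null(fit$P))
  list(day = day, sigma_g2 = sg2, sigma_s2 = ss2, sigma_e2 = se2,
       h2 = sg2 / (sg2 + ss2 + se2),
       gblup = stats::setNames(fit$u_hat[, 1], rownames(fit$u_hat)),
       loglik = fit$loglik, aic = model_aic(fit$loglik, n_params),
       converged = fit$converged, grad_scaled = fit$grad_scaled)
}

#' Per-day gBLUP fits across all imaging days
#'
#' @param records A `phenotype_records`.
#' @param grm A `genomic_relationship`.
#' @param days Days to fit (default all days present).
#' @param control Solver settings.
#' @return List of [fit_tp_gblup()] results, named by day.
#' @export
fit_tp_all <- function(records, grm, days = day_set(records),
                       control = reml_control()) {
  out <- lapply(days, function(d) fit_tp_gblup(records, grm, d, control))
  names(out) <- as.character(days)
  out
}
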