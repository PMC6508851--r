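test_that("design matrices carry basis rows in the right blocks", {
  grm <- suppressMessages(vanraden_grm(toy_dosages()))
  df <- data.frame(line_id = "A", experiment_id = "E1",
                   plant_id = "pA", day = 1:3, value = c(5, 6, 7))
  rec <- as_phenotype_records(df)
  grid <- standardize_time(1:3)
  spec <- rr_model_spec(2L, 1L, NULL, "homogeneous")
  des <- build_design(rec, spec, grid, grm)
  Z <- as.matrix(des$Z)
  expect_equal(dim(Z), c(3L, 6L))   # 3 lines x order-1 blocks
  expect_equal(Z[, 1:2], unname(des$Phi_g), ignore_attr = TRUE)
  expect_true(all(Z[, 3:6] == 0))
})

test_that("swapping line labels permutes Z blocks and leaves ZZ' unchanged", {
  grm <- suppressMessages(vanraden_grm(toy_dosages()))
  ## unbalanced day sets so the relabeling genuinely moves blocks
  df <- data.frame(line_id = c("A", "A", "A", "B", "B"),
                   experiment_id = "E1",
                   plant_id = c("p1", "p1", "p1", "p2", "p2"),
                   day = c(1, 2, 3, 2, 3), value = 11:15)
  rec <- as_phenotype_records(df)
  df2 <- df
  df2$line_id <- c("B", "B", "B", "A", "A")
  rec2 <- as_phenotype_records(df2)
  grid <- standardize_time(1:3)
  spec <- rr_model_spec(2L, 1L, NULL, "homogeneous")
  d1 <- build_design(rec, spec, grid, grm)
  d2 <- build_design(rec2, spec, grid, grm)
  Z1 <- as.matrix(d1$Z); Z2 <- as.matrix(d2$Z)
  expect_false(identical(Z1, Z2))
  ## match rows by (plant, day): the relatedness structure ZZ' is invariant
  k1 <- paste(rec$plant_id, rec$day)
  k2 <- paste(rec2$plant_id, rec2$day)
  perm <- match(k1, k2)
  expect_equal(tcrossprod(Z1), tcrossprod(Z2)[perm, perm],
               ignore_attr = TRUE)
})

test_that("design construction rejects unknown days and lines", {
  grm <- suppressMessages(vanraden_grm(toy_dosages()))
  df <- data.frame(line_id = "A", experiment_id = "E1", plant_id = "pA",
                   day = 5, value = 3)
  expect_error(build_design(as_phenotype_records(df), rr_model_spec(),
                            standardize_time(1:3), grm), "not in grid")
  df2 <- data.frame(line_id = "ZZZ", experiment_id = "E1", plant_id = "p",
                    day = 1, value = 3)
  expect_error(build_design(as_phenotype_records(df2), rr_model_spec(),
                            standardize_time(1:3), grm), "absent from G")
})

test_that("AIC follows the formula and penalizes parameters by 2", {
  expect_equal(model_aic(-100, 10), 220)
  expect_equal(model_aic(0, 1), 2)
  expect_equal(model_aic(-7.3, 6) - model_aic(-7.3, 5), 2)
  expect_error(model_aic(-1, 0))
})

test_that("internal restricted likelihood equals the dense formula at fixed parameters", {
  cfg <- sim_config(n_lines = 8, n_markers = 60, n_experiments = 2,
                    n_rep_lines = 2, days = c(1, 3, 5, 7), seed = 7)
  truth <- suppressMessages(simulate_trajectories(cfg))
  grid <- standardize_time(c(1, 3, 5, 7))
  for (spec in list(rr_model_spec(2L, 1L, 0L, "homogeneous"),
                    rr_model_spec(2L, 2L, 1L, "heterogeneous"))) {
    qg <- spec$genetic_order + 1L
    qs <- spec$experiment_order + 1L
    Om <- crossprod(matrix(seq_len(qg * qg) * 7, qg)) + 50 * diag(qg)
    Pm <- crossprod(matrix(seq_len(qs * qs) + 3, qs)) + 20 * diag(qs)
    Dv <- if (spec$residual == "heterogeneous") c(30, 40, 50, 60) else 45
    fit <- fit_rr_reml(truth$records, truth$grm, spec, grid,
                       fix_vc = TRUE, init = list(Omega = Om, P = Pm, D = Dv))
    ll_dense <- dense_reml_loglik(truth$records, truth$grm, spec, grid,
                                  Om, Pm, rep(Dv, length.out = 4))
    expect_equal(fit$loglik, ll_dense, tolerance = 1e-8)
  }
})

test_that("BLUPs at fixed variance components match the closed-form dense solution", {
  cfg <- sim_config(n_lines = 6, n_markers = 50, n_experiments = 2,
                    n_rep_lines = 2, days = c(1, 3, 5), seed = 7)
  truth <- suppressMessages(simulate_trajectories(cfg))
  grid <- standardize_time(c(1, 3, 5))
  spec <- rr_model_spec(2L, 1L, 0L, "homogeneous")
  Om <- matrix(c(900, 100, 100, 300), 2)
  Pm <- matrix(400, 1, 1)
  fit <- fit_rr_reml(truth$records, truth$grm, spec, grid, fix_vc = TRUE,
                     init = list(Omega = Om, P = Pm, D = 500))
  des <- build_design(truth$records, spec, grid, truth$grm)
  y <- truth$records$value
  Z <- as.matrix(des$Z); Q <- as.matrix(des$Q); X <- as.matrix(des$X)
  V <- Z %*% kronecker(truth$grm$G, Om) %*% t(Z) +
    Q %*% kronecker(diag(2), Pm) %*% t(Q) + diag(rep(500, length(y)))
  Vi <- chol2inv(chol(V))
  XtVX <- crossprod(X, Vi %*% X)
  Pmz <- Vi - Vi %*% X %*% solve(XtVX, crossprod(X, Vi))
  u_dense <- kronecker(truth$grm$G, Om) %*% crossprod(Z, Pmz %*% y)
  expect_equal(as.vector(t(fit$u_hat)), drop(u_dense), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lt(fit$mme_residual, 1e-8)
})

test_that("null-heritability data yields near-zero genetic variance estimates", {
  hits <- 0L
  reps <- 6L
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_lines = 100, n_markers = 300, seed = 500 + r,
                      h2_scale = 0)                  # sigma_g = 0
    ## zero genetic covariance makes the true correlation degenerate (NaN)
    truth <- suppressWarnings(suppressMessages(simulate_trajectories(cfg)))
    day <- 10
    tp <- fit_tp_gblup(truth$records, truth$grm, day)
    vy <- stats::var(truth$records$value[truth$records$day == day])
    if (tp$sigma_g2 < 0.05 * vy) hits <- hits + 1L
  }
  expect_gte(hits, reps - 1L)
})

test_that("single-day RR fit with order-0 terms agrees with the TP model", {
  cfg <- sim_config(n_lines = 40, n_markers = 150, days = 1:3, seed = 77)
  truth <- suppressMessages(simulate_trajectories(cfg))
  day <- 2
  tp <- fit_tp_gblup(truth$records, truth$grm, day)
  rec1 <- as_phenotype_records(
    truth$records[truth$records$day == day, , drop = FALSE])
  grid1 <- standardize_time(day, c(day, day))
  rr <- fit_rr_reml(rec1, truth$grm, rr_model_spec(0L, 0L, 0L, "homogeneous"),
                    grid1)
  ## normalized order-0 covariable is sqrt(1/2), so coefficient variances
  ## are 2x the per-day variance components
  expect_equal(rr$loglik, tp$loglik, tolerance = 1e-5)
  expect_equal(0.5 * rr$vc$Omega[1, 1], tp$sigma_g2,
               tolerance = 1e-4 * max(tp$sigma_g2, 1))
  expect_equal(0.5 * rr$vc$P[1, 1], tp$sigma_s2,
               tolerance = max(1e-4 * tp$sigma_s2, 1e-6))
  expect_equal(unname(rr$vc$D[as.character(day)]), tp$sigma_e2,
               tolerance = 1e-4 * tp$sigma_e2)
})

test_that("doubling phenotypes scales variance components by 4 and keeps correlations", {
  truth <- small_truth()
  grid <- standardize_time(1:20)
  rec2 <- truth$records
  rec2$value <- 2 * rec2$value
  f1 <- small_fit()
  f2 <- fit_rr_reml(rec2, truth$grm, rr_model_spec(), grid)
  expect_equal(f2$vc$Omega, 4 * f1$vc$Omega,
               tolerance = 1e-3)
  expect_equal(unname(f2$vc$D), unname(4 * f1$vc$D), tolerance = 1e-3)
  expect_equal(stats::cov2cor(f2$vc$Omega), stats::cov2cor(f1$vc$Omega),
               tolerance = 1e-4)
})

test_that("restricted likelihood is invariant to the fixed-effect parameterization", {
  cfg <- sim_config(n_lines = 12, n_markers = 60, days = c(2, 4, 6, 8),
                    seed = 13)
  truth <- suppressMessages(simulate_trajectories(cfg))
  grid <- standardize_time(c(2, 4, 6, 8))
  spec <- rr_model_spec(2L, 1L, 0L, "homogeneous")
  des <- build_design(truth$records, spec, grid, truth$grm)
  A <- matrix(c(1, 0.3, -0.2,
                0, 2.0, 0.7,
                0, 0, 0.5), 3, 3, byrow = TRUE)   # full-rank recombination
  des2 <- des
  des2$X <- des$X %*% A
  des2$Phi_f <- des$Phi_f %*% A
  f1 <- rrgrowth:::reml_core(truth$records$value, des, truth$grm, rep(1L, 4))
  f2 <- rrgrowth:::reml_core(truth$records$value, des2, truth$grm, rep(1L, 4))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-5)
})

test_that("the solver stops at a stationary point with tiny MME residuals", {
  truth <- small_truth()
  fit <- small_fit()
  expect_true(fit$converged)
  expect_lt(fit$mme_residual, 1e-8)
  ## stationarity: restarting at the reported optimum gains essentially
  ## nothing (the raw gradient need not vanish when the optimum lies on
  ## the PSD boundary, so restart gain is the honest check)
  refit <- fit_rr_reml(truth$records, truth$grm, rr_model_spec(),
                       standardize_time(1:20),
                       control = reml_control(max_iter = 50L),
                       init = list(Omega = fit$vc$Omega, P = fit$vc$P,
                                   D = unname(fit$vc$D)))
  expect_lt(refit$loglik - fit$loglik, 1e-4)
  ## interior optima do report vanishing scaled gradients: checked on the
  ## per-day TP fit, whose variance components sit away from boundaries
  tp <- fit_tp_gblup(truth$records, truth$grm, day = 10)
  expect_lt(tp$grad_scaled / abs(tp$loglik), 1e-4)
})

test_that("identity relationship matrix gives ridge-style shrinkage to the mean", {
  n <- 30
  G <- diag(n)
  dimnames(G) <- list(paste0("L", 1:n), paste0("L", 1:n))
  grm <- structure(list(line_ids = rownames(G), G = G,
                        eigen_values = rep(1, n), eigen_vectors = diag(n),
                        method = "identity", n_eigen_clamped = 0L),
                   class = "genomic_relationship")
  set.seed(2)
  df <- data.frame(line_id = rep(rownames(G), 2),
                   experiment_id = rep(c("E1", "E2"), each = n),
                   plant_id = paste0("p", 1:(2 * n)),
                   day = 1, value = 50 + stats::rnorm(2 * n, 0, 5))
  rec <- as_phenotype_records(df)
  strong_noise <- fit_rr_reml(
    rec, grm, rr_model_spec(0L, 0L, 0L, "homogeneous"),
    standardize_time(1, c(1, 1)), fix_vc = TRUE,
    init = list(Omega = matrix(0.02), P = matrix(0.01), D = 1000))
  weak_noise <- fit_rr_reml(
    rec, grm, rr_model_spec(0L, 0L, 0L, "homogeneous"),
    standardize_time(1, c(1, 1)), fix_vc = TRUE,
    init = list(Omega = matrix(2000), P = matrix(0.01), D = 0.5))
  expect_lt(max(abs(strong_noise$u_hat)), 0.05 * max(abs(weak_noise$u_hat)))
})

test_that("model ranking is by AIC with nesting consistency", {
  truth <- small_truth()
  grid <- standardize_time(1:20)
  small <- rr_model_spec(2L, 1L, 0L, "homogeneous")
  large <- rr_model_spec(2L, 2L, 1L, "homogeneous")
  tab <- select_model(truth$records, truth$grm, grid,
                      candidates = list(small, large))
  expect_equal(nrow(tab), 2L)
  ## ascending AIC among converged fits (non-converged rank last)
  expect_true(all(diff(tab$aic[tab$converged]) >= 0))
  fits <- attr(tab, "fits")
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  specs <- lapply(fits, `[[`, "spec")
  ll_small <- lls[vapply(specs, function(s) s$genetic_order == 1L, logical(1))]
  ll_large <- lls[vapply(specs, function(s) s$genetic_order == 2L, logical(1))]
  expect_gte(ll_large, ll_small - 1e-4)   # nested model cannot fit better
  ## single-candidate list is returned as-is
  tab1 <- select_model(truth$records, truth$grm, grid, candidates = list(small))
  expect_equal(nrow(tab1), 1L)
})
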