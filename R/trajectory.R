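#' Predict gBLUP trajectories from coefficient BLUPs
#'
#' For line `j` at day `t`, the genomic prediction is the dot product of the
#' Legendre basis row at that day with the line's coefficient BLUPs,
#' \eqn{\hat g_{jt} = \phi_t' \hat u_j}. The basis may be evaluated at any
#' days inside its declared domain, including days never seen in fitting —
#' this is how the forecasting scenarios predict ahead.
#'
#' @param u_hat n x q matrix of coefficient BLUPs (rows = lines), e.g.
#'   `fit$u_hat`.
#' @param basis A `legendre_basis` whose `order + 1` equals `q`.
#' @return n x t matrix of gBLUPs (rownames = lines, colnames = days if the
#'   basis carries a grid).
#' @export
predict_gblup_trajectory <- function(u_hat, basis) {
  u_hat <- as.matrix(u_hat)
  if (ncol(u_hat) != basis$order + 1L) {
    stop("u_hat has ", ncol(u_hat), " columns but basis order+1 is ",
         basis$order + 1L)
  }
  out <- u_hat %*% t(basis$phi)
  if (!is.null(basis$grid)) colnames(out) <- as.character(basis$grid$days)
  out
}

#' Variance trajectories implied by fitted covariance components
#'
#' Per-day variances from the coefficient covariances: genetic
#' \eqn{\sigma^2_g(t) = \phi_t' \Omega \phi_t}, experiment
#' \eqn{\sigma^2_s(t) = \psi_t' P \psi_t}, residual from the fitted
#' day-specific (or shared) variance.
#'
#' @param vc List with `Omega`, `P` (or `NULL`) and `D` (per-day vector or
#'   single value), e.g. `fit$vc`.
#' @param basis_g `legendre_basis` for the genetic term (order matching
#'   `Omega`).
#' @param basis_s `legendre_basis` for the experiment term, or `NULL`.
#' @return A `trajectory_surface` object: data frame columns `day`,
#'   `sigma_g2`, `sigma_s2`, `sigma_e2`, `h2` (filled by
#'   [heritability_trajectory()]), plus attribute `genetic_cor`.
#' @export
variance_trajectories <- function(vc, basis_g, basis_s = NULL) {
  Phi <- basis_g$phi
  if (ncol(Phi) != nrow(vc$Omega)) stop("basis order does not match Omega")
  days <- if (!is.null(basis_g$grid)) basis_g$grid$days else
    seq_len(nrow(Phi))
  sg2 <- rowSums((Phi %*% vc$Omega) * Phi)
  ss2 <- if (!is.null(vc$P) && !is.null(basis_s)) {
    Psi <- basis_s$phi
    if (ncol(Psi) != nrow(vc$P)) stop("basis order does not match P")
    rowSums((Psi %*% vc$P) * Psi)
  } else rep(0, length(days))
  se2 <- rep(vc$D, length.out = length(days))
  out <- data.frame(day = days, sigma_g2 = sg2, sigma_s2 = ss2,
                    sigma_e2 = se2, h2 = NA_real_)
  out$h2 <- heritability_trajectory(out)
  attr(out, "genetic_cor") <- genetic_correlation_matrix(vc$Omega, basis_g)
  class(out) <- c("trajectory_surface", "data.frame")
  out
}

#' Narrow-sense heritability trajectory
#'
#' \eqn{h^2(t) = \sigma^2_g(t) / (\sigma^2_g(t) + \sigma^2_s(t) +
#' \sigma^2_e(t))}. The experiment variance is part of the denominator: the
#' experiment term is treated as an environmental effect. Days where all
#' three variances are zero give `NA` with a warning.
#'
#' @param surface A `trajectory_surface` (or data frame with columns
#'   `sigma_g2`, `sigma_s2`, `sigma_e2`).
#' @return Numeric vector of per-day heritabilities.
#' @export
heritability_trajectory <- function(surface) {
  tot <- surface$sigma_g2 + surface$sigma_s2 + surface$sigma_e2
  if (any(tot == 0)) {
    warning("all variance components zero at day(s) ",
            paste(surface$day[tot == 0], collapse = ", "))
  }
  ifelse(tot == 0, NA_real_, surface$sigma_g2 / tot)
}

#' Genetic correlation matrix across days
#'
#' The day-by-day genetic correlation surface implied analytically by the
#' coefficient covariance: entry \eqn{(i, j)} is
#' \eqn{\phi_i' \Omega \phi_j / \sqrt{(\phi_i'\Omega\phi_i)
#' (\phi_j'\Omega\phi_j)}}. Days with zero genetic variance give `NA`
#' entries with a warning.
#'
#' @param Omega Coefficient covariance matrix (PSD).
#' @param basis A `legendre_basis` of matching order.
#' @return t x t correlation matrix with unit diagonal.
#' @export
genetic_correlation_matrix <- function(Omega, basis) {
  Phi <- basis$phi
  Cg <- Phi %*% Omega %*% t(Phi)
  v <- diag(Cg)
  if (any(v <= 0)) {
    warning("zero genetic variance at ", sum(v <= 0), " day(s)")
    v[v <= 0] <- NA_real_
  }
  R <- Cg / sqrt(outer(v, v))
  diag(R) <- ifelse(is.na(v), NA_real_, 1)
  if (!is.null(basis$grid)) {
    dimnames(R) <- list(as.character(basis$grid$days),
                        as.character(basis$grid$days))
  }
  R
}

#' Accuracy relative to the heritability ceiling
#'
#' Prediction accuracy divided by the square root of heritability,
#' \eqn{r / \sqrt{h^2}}: the accuracy of predicting the additive genetic
#' value itself rather than the phenotype. Near-equal relative accuracies
#' for two models indicate that an accuracy gap is driven by the
#' heritability gap.
#'
#' @param r Per-day prediction accuracy (correlation with phenotype).
#' @param h2 Per-day heritability (> 0; zero gives `NA` with a warning).
#' @return Per-day ratio.
#' @examples
#' relative_accuracy(0.5, 0.25)  # 1
#' @export
relative_accuracy <- function(r, h2) {
  if (any(h2 <= 0, na.rm = TRUE)) {
    warning("non-positive h2; returning NA there")
  }
  ifelse(is.na(h2) | h2 <= 0, NA_real_, r / sqrt(h2))
}

#' Trajectory surface from a fitted random-regression model
#'
#' Convenience wrapper: builds the genetic/experiment bases on the fit's own
#' grid and assembles [variance_trajectories()].
#'
#' @param fit An `rr_fit`.
#' @return A `trajectory_surface`.
#' @export
trajectory_surface <- function(fit) {
  basis_g <- legendre_matrix(fit$grid, fit$spec$genetic_order)
  basis_s <- if (!is.null(fit$spec$experiment_order)) {
    legendre_matrix(fit$grid, fit$spec$experiment_order)
  } else NULL
  variance_trajectories(fit$vc, basis_g, basis_s)
}
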