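#' Default simulation configuration
#'
#' Returns the configuration of the synthetic shoot-growth study the package
#' emulates: 357 lines genotyped at 2,000 markers (33,674 supported), three
#' experiments with 54 randomly replicated lines each, 20 consecutive daily
#' imaging time points, a convex increasing mean growth curve on a
#' kilopixel-like projected-shoot-area scale, high day-to-day genetic
#' correlations, per-day narrow-sense heritability around 0.7, and residual
#' standard deviation growing with the mean.
#'
#' The fixed trend `beta`, genetic coefficient covariance `Omega_true`,
#' experiment coefficient covariance `P_true` and the residual-sd rule
#' (`resid_coef`, `resid_floor`) are a calibrated fixture shipped with the
#' package (`inst/extdata/sim_defaults.json`); they were chosen once so that
#' the implied per-day h2 lies in [0.60, 0.80] and all genetic correlations in
#' [0.84, 1.0], and are never re-derived at run time.
#'
#' @param n_lines Number of lines (default 357).
#' @param n_markers Number of SNP markers (default 2000).
#' @param n_experiments Number of experiments (default 3).
#' @param n_rep_lines Lines with a second replicate plant per experiment
#'   (default 54).
#' @param days Imaging days (default `1:20`).
#' @param maf_range Uniform range for allele frequencies (default
#'   `c(0.05, 0.5)`).
#' @param seed Integer seed driving all randomness.
#' @param subpop_fst If positive, genotypes are drawn from two diverged
#'   subpopulations with this Wright's-F[ST]-like divergence (default 0,
#'   a single panmictic panel).
#' @param h2_scale Multiplier on the genetic covariance `Omega_true`; values
#'   below 1 lower the true heritability while leaving the other components
#'   untouched (default 1).
#' @return A `sim_config` list; fields as above plus `beta`, `Omega_true`,
#'   `P_true`, `resid_coef`, `resid_floor`, `domain`.
#' @export
sim_config <- function(n_lines = 357L, n_markers = 2000L,
                       n_experiments = 3L,
                       n_rep_lines = min(54L, n_lines),
                       days = 1:20, maf_range = c(0.05, 0.5),
                       seed = 1L, subpop_fst = 0, h2_scale = 1) {
  stopifnot(n_lines >= 2L, n_markers >= 1L, n_experiments >= 1L,
            n_rep_lines <= n_lines, length(days) >= 1L,
            maf_range[1] > 0, maf_range[2] < 1, h2_scale >= 0)
  defaults_path <- system.file("extdata", "sim_defaults.json",
                               package = "rrgrowth")
  if (defaults_path == "") {                      # pre-install fallback
    defaults_path <- file.path("inst", "extdata", "sim_defaults.json")
  }
  fx <- jsonlite::read_json(defaults_path, simplifyVector = TRUE)
  cfg <- list(n_lines = as.integer(n_lines), n_markers = as.integer(n_markers),
              n_experiments = as.integer(n_experiments),
              n_rep_lines = as.integer(n_rep_lines),
              days = as.numeric(days), domain = range(as.numeric(days)),
              maf_range = maf_range, seed = as.integer(seed),
              subpop_fst = subpop_fst,
              mean_poly = as.numeric(fx$mean_poly),
              beta = as.numeric(fx$beta),
              Omega_true = h2_scale * as.matrix(fx$Omega),
              P_true = as.matrix(fx$P),
              resid_coef = as.numeric(fx$resid_coef),
              resid_floor = as.numeric(fx$resid_floor))
  class(cfg) <- "sim_config"
  cfg
}

## Mean trend and per-day residual sd implied by a config, at arbitrary days.
sim_mean_curve <- function(cfg, days = cfg$days, domain = cfg$domain) {
  x <- standardize_time(days, domain)$standardized
  cfg$mean_poly[1] + cfg$mean_poly[2] * x + cfg$mean_poly[3] * x^2
}

sim_resid_sd <- function(cfg, days = cfg$days, domain = cfg$domain) {
  cfg$resid_coef * (sim_mean_curve(cfg, days, domain) + cfg$resid_floor)
}

## symmetric PSD square root (exact for the zero matrix, unlike chol)
psd_sqrt <- function(A) {
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  L <- eg$vectors %*% (t(eg$vectors) * sqrt(pmax(eg$values, 0)))
  (L + t(L)) / 2
}

#' Simulate SNP genotypes
#'
#' Draws per-marker allele frequencies uniformly in `maf_range` and dosages
#' as independent Binomial(2, p) per line and marker. With
#' `subpop_fst > 0`, lines are split into two equal subpopulations whose
#' allele frequencies are drawn around the common frequency with a
#' Balding-Nichols Beta model, mimicking the stratification of a diversity
#' panel.
#'
#' @param config A [sim_config()].
#' @return A `dosage_matrix`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_lines
  m <- config$n_markers
  set.seed(config$seed)
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  if (config$subpop_fst > 0) {
    f <- config$subpop_fst
    shape <- (1 - f) / f
    grp <- rep(1:2, length.out = n)
    M <- matrix(0, n, m)
    for (k in 1:2) {
      pk <- stats::rbeta(m, p * shape, (1 - p) * shape)
      pk <- pmin(pmax(pk, 1e-4), 1 - 1e-4)
      idx <- which(grp == k)
      M[idx, ] <- matrix(stats::rbinom(length(idx) * m, 2L, rep(pk, each = length(idx))),
                         length(idx), m)
    }
    attr_grp <- grp
  } else {
    M <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
    attr_grp <- NULL
  }
  dos <- as_dosage_matrix(M, line_ids = sprintf("L%03d", seq_len(n)),
                          marker_ids = sprintf("M%05d", seq_len(m)))
  ## monomorphic columns can arise by chance at small n; drop them
  pobs <- colMeans(dos$dosages) / 2
  keep <- pobs > 0 & pobs < 1
  if (any(!keep)) {
    dos$dosages <- dos$dosages[, keep, drop = FALSE]
    dos$marker_ids <- dos$marker_ids[keep]
    dos$n_monomorphic_dropped <- sum(!keep)
  }
  if (!is.null(attr_grp)) attr(dos, "subpop") <- attr_grp
  dos
}

#' Simulate longitudinal phenotype trajectories
#'
#' Given genotypes, draws genetic coefficient curves with covariance
#' \eqn{G \otimes \Omega} (via the marker-derived relationship matrix, i.e.
#' the gBLUP equivalence the analysis relies on, not explicit marker
#' effects), experiment coefficient curves with covariance `P_true`, and
#' per-record residuals with day-specific standard deviation
#' `resid_coef * (mean(t) + resid_floor)`. Replicated plants within a
#' line-by-experiment cell share the genetic and experiment curves and get
#' independent residual streams.
#'
#' @param config A [sim_config()].
#' @param dosages A `dosage_matrix`, typically from [simulate_genotypes()].
#' @return A `sim_truth` list: `records` (a `phenotype_records`), `dosages`,
#'   `grm`, `U_true` (n x 3 genetic coefficients), `S_true`
#'   (experiments x 2), `true_h2`, `true_gcor`, `true_sg2`, `true_ss2`,
#'   `true_se2`, and the `config`.
#' @export
simulate_trajectories <- function(config, dosages = simulate_genotypes(config)) {
  stopifnot(inherits(config, "sim_config"))
  grm <- vanraden_grm(dosages)
  n <- config$n_lines
  ne <- config$n_experiments
  days <- config$days
  t_n <- length(days)
  grid <- standardize_time(days, config$domain)
  Phi <- legendre_matrix(grid, 2L)$phi
  Psi <- Phi[, 1:2, drop = FALSE]
  set.seed(config$seed + 1L)

  ## genetic coefficients: rows U[i, ] per line, cov(U[i,a], U[j,b]) = G_ij Omega_ab
  Lg <- grm$eigen_vectors %*% diag(sqrt(grm$eigen_values))
  U <- Lg %*% matrix(stats::rnorm(n * 3L), n, 3L) %*%
    psd_sqrt(config$Omega_true)
  rownames(U) <- grm$line_ids
  S <- matrix(stats::rnorm(ne * 2L), ne, 2L) %*% psd_sqrt(config$P_true)
  rownames(S) <- sprintf("E%d", seq_len(ne))

  resid_sd <- sim_resid_sd(config)
  mean_curve <- drop(Phi %*% config$beta)
  g_curves <- U %*% t(Phi)          # n x t
  s_curves <- S %*% t(Psi)          # ne x t

  ## partially replicated design: n_rep_lines lines get 2 plants per experiment
  recs <- vector("list", ne)
  for (k in seq_len(ne)) {
    rep_lines <- if (config$n_rep_lines > 0) {
      sample(grm$line_ids, config$n_rep_lines)
    } else character(0)
    n_plants <- ifelse(grm$line_ids %in% rep_lines, 2L, 1L)
    line_of_plant <- rep(grm$line_ids, n_plants)
    plant_id <- paste0(line_of_plant, "_E", k, "_p",
                       unlist(lapply(n_plants, seq_len)))
    li <- match(line_of_plant, grm$line_ids)
    np <- length(plant_id)
    eps <- matrix(stats::rnorm(np * t_n, sd = rep(resid_sd, each = np)),
                  np, t_n)
    vals <- matrix(mean_curve, np, t_n, byrow = TRUE) +
      g_curves[li, , drop = FALSE] +
      matrix(s_curves[k, ], np, t_n, byrow = TRUE) + eps
    recs[[k]] <- data.frame(
      line_id = rep(line_of_plant, times = t_n),
      experiment_id = sprintf("E%d", k),
      plant_id = rep(plant_id, times = t_n),
      day = rep(days, each = np),
      value = as.vector(vals))
  }
  df <- do.call(rbind, recs)
  if (any(df$value <= 0)) {
    ## kilopixel scale keeps values positive in practice; guard regardless
    df$value <- pmax(df$value, 1e-3)
  }
  records <- as_phenotype_records(df)

  sg2 <- rowSums((Phi %*% config$Omega_true) * Phi)
  ss2 <- rowSums((Psi %*% config$P_true) * Psi)
  se2 <- resid_sd^2
  gcov <- Phi %*% config$Omega_true %*% t(Phi)
  structure(list(records = records, dosages = dosages, grm = grm,
                 U_true = U, S_true = S, config = config, grid = grid,
                 true_sg2 = sg2, true_ss2 = ss2, true_se2 = se2,
                 true_h2 = sg2 / (sg2 + ss2 + se2),
                 true_gcor = stats::cov2cor(gcov)),
            class = "sim_truth")
}

#' Simulate a paired later-window study for cross-study forecasting
#'
#' Generates a second phenotype table for the *same* lines (sharing their
#' genetic coefficient curves, evaluated on a domain spanning both studies)
#' over a later day window, with its own experiment effects and residual
#' streams. This emulates forecasting into an independent study conducted at
#' a later developmental window.
#'
#' @param config A [sim_config()] for the first study.
#' @param days2 Imaging days of the second study (default `8:28`, overlapping
#'   the tail of the default 1..20 window).
#' @param n_experiments2 Experiments in the second study (default 1).
#' @return List with `study1` (a `sim_truth`), `records2` (a
#'   `phenotype_records`), `days2` and `domain` (the shared spanning domain).
#' @export
simulate_two_studies <- function(config, days2 = 8:28, n_experiments2 = 1L) {
  domain <- range(c(config$days, days2))
  cfg1 <- config
  cfg1$domain <- domain
  truth <- simulate_trajectories(cfg1)
  t2 <- length(days2)
  Phi2 <- legendre_phi(days2, domain, 2L)
  Psi2 <- Phi2[, 1:2, drop = FALSE]
  set.seed(config$seed + 2L)
  S2 <- matrix(stats::rnorm(n_experiments2 * 2L), n_experiments2, 2L) %*%
    psd_sqrt(config$P_true)
  resid_sd2 <- sim_resid_sd(config, days2, domain)
  mean2 <- drop(Phi2 %*% config$beta)
  g2 <- truth$U_true %*% t(Phi2)
  recs <- vector("list", n_experiments2)
  ids <- rownames(truth$U_true)
  n <- length(ids)
  for (k in seq_len(n_experiments2)) {
    eps <- matrix(stats::rnorm(n * t2, sd = rep(resid_sd2, each = n)), n, t2)
    vals <- matrix(mean2, n, t2, byrow = TRUE) + g2 +
      matrix(drop(Psi2 %*% S2[k, ]), n, t2, byrow = TRUE) + eps
    recs[[k]] <- data.frame(
      line_id = rep(ids, times = t2),
      experiment_id = sprintf("S2E%d", k),
      plant_id = paste0(ids, "_S2E", k),
      day = rep(days2, each = n),
      value = pmax(as.vector(vals), 1e-3))
  }
  list(study1 = truth, records2 = as_phenotype_records(do.call(rbind, recs)),
       days2 = as.numeric(days2), domain = domain)
}

#' Write simulated data as the delimited formats the readers consume
#'
#' @param truth A `sim_truth` from [simulate_trajectories()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`phenotypes.tsv`, `dosages.tsv`).
#' @export
write_simulation <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ppath <- file.path(dir, "phenotypes.tsv")
  gpath <- file.path(dir, "dosages.tsv")
  data.table::fwrite(as.data.frame(unclass(truth$records))[
    c("line_id", "experiment_id", "plant_id", "day", "value")],
    ppath, sep = "\t")
  data.table::fwrite(data.frame(line_id = truth$dosages$line_ids,
                                truth$dosages$dosages, check.names = FALSE),
                     gpath, sep = "\t")
  invisible(c(phenotypes = ppath, dosages = gpath))
}
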