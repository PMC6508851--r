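## Shared fixtures, built once per test run and cached across test files.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

## small simulated study reused by several unit tests
small_truth <- function() {
  fixture("small_truth", function() {
    cfg <- sim_config(n_lines = 60, n_markers = 300, n_rep_lines = 10,
                      seed = 42)
    suppressMessages(simulate_trajectories(cfg))
  })
}

## full random-regression fit of the small study, shared across tests
small_fit <- function() {
  fixture("small_fit", function() {
    truth <- small_truth()
    fit_rr_reml(truth$records, truth$grm, rr_model_spec(),
                standardize_time(1:20))
  })
}

## hand-built phenotype table: 2 lines x 2 experiments x 3 days
toy_records <- function() {
  df <- expand.grid(line_id = c("L1", "L2"), experiment_id = c("E1", "E2"),
                    day = c(1, 2, 3), stringsAsFactors = FALSE)
  df$plant_id <- paste0(df$line_id, "_", df$experiment_id)
  df$value <- 10 + seq_len(nrow(df))
  as_phenotype_records(df)
}

## dosage matrix with known allele frequencies
toy_dosages <- function() {
  M <- matrix(c(0, 0,
                1, 1,
                2, 2), 3, 2, byrow = TRUE)
  as_dosage_matrix(M, line_ids = c("A", "B", "C"),
                   marker_ids = c("m1", "m2"))
}
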