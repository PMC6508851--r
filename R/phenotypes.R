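#' Read long-format longitudinal phenotypes
#'
#' Loads a delimited file with columns `line_id`, `experiment_id`,
#' `plant_id`, `day`, `value` (one row per plant per imaging day). Rows with
#' missing or non-positive trait values are dropped with a message; duplicate
#' `(plant_id, day)` rows are an error.
#'
#' @param path Path to the delimited file (separator auto-detected).
#' @return A `phenotype_records` object: a `data.frame` with the five columns
#'   above plus attribute `day_set` (sorted unique days).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  needed <- c("line_id", "experiment_id", "plant_id", "day", "value")
  missing_cols <- setdiff(needed, names(dt))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  dt <- dt[needed]
  dt$value <- suppressWarnings(as.numeric(dt$value))
  bad <- is.na(dt$value) | dt$value <= 0 | is.na(dt$day)
  if (any(bad)) {
    message(sum(bad), " row(s) with missing/non-positive values dropped")
    dt <- dt[!bad, , drop = FALSE]
  }
  as_phenotype_records(dt)
}

#' Assemble phenotype records from a data frame
#'
#' Validates the invariants of the long-format phenotype container:
#' unique `(plant_id, day)`, positive values, and a consistent day set.
#'
#' @param df Data frame with columns `line_id`, `experiment_id`, `plant_id`,
#'   `day`, `value`.
#' @return A `phenotype_records` object.
#' @export
as_phenotype_records <- function(df) {
  needed <- c("line_id", "experiment_id", "plant_id", "day", "value")
  stopifnot(all(needed %in% names(df)))
  df <- as.data.frame(df)[needed]
  df$line_id <- as.character(df$line_id)
  df$experiment_id <- as.character(df$experiment_id)
  df$plant_id <- as.character(df$plant_id)
  df$day <- as.numeric(df$day)
  if (nrow(df) == 0L) stop("no phenotype records")
  if (any(df$value <= 0)) stop("trait values must be positive")
  key <- paste(df$plant_id, df$day, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("plant_id", "day")]
    stop("duplicate (plant_id, day) record(s), e.g. plant ",
         dup$plant_id[1L], " day ", dup$day[1L])
  }
  df <- df[order(df$day, df$experiment_id, df$line_id, df$plant_id), ,
           drop = FALSE]
  rownames(df) <- NULL
  attr(df, "day_set") <- sort(unique(df$day))
  class(df) <- c("phenotype_records", "data.frame")
  df
}

#' @export
print.phenotype_records <- function(x, ...) {
  cat("phenotype_records:", nrow(x), "records,",
      length(unique(x$line_id)), "lines,",
      length(unique(x$experiment_id)), "experiments,",
      length(attr(x, "day_set")), "days\n")
  invisible(x)
}

#' Imaging days present in a phenotype table
#'
#' @param records A `phenotype_records` object.
#' @return Sorted numeric vector of unique imaging days.
#' @export
day_set <- function(records) attr(records, "day_set")

#' Flag outlier plants by the 1.5 IQR rule
#'
#' Per imaging day, computes the quartiles (linear-interpolation quantiles,
#' R type 7) and flags any plant whose value falls below
#' \eqn{Q_1 - 1.5\,\mathrm{IQR}} or above \eqn{Q_3 + 1.5\,\mathrm{IQR}} on at
#' least one day. Flagging is advisory: removal is the separate, explicit
#' [remove_plants()] step, mirroring a workflow where flagged plants are
#' reviewed before exclusion.
#'
#' @param records A `phenotype_records` object.
#' @return Character vector of flagged `plant_id`s (possibly empty).
#' @export
flag_outliers_iqr <- function(records) {
  flagged <- character(0)
  for (d in day_set(records)) {
    sub <- records[records$day == d, , drop = FALSE]
    if (nrow(sub) < 4L) {
      warning("day ", d, " skipped: fewer than 4 plants")
      next
    }
    q <- stats::quantile(sub$value, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2L] - q[1L]
    out <- sub$value < q[1L] - 1.5 * iqr | sub$value > q[2L] + 1.5 * iqr
    flagged <- c(flagged, sub$plant_id[out])
  }
  sort(unique(flagged))
}

#' Remove plants from a phenotype table
#'
#' @param records A `phenotype_records` object.
#' @param plant_ids Plant IDs to drop (e.g. the output of
#'   [flag_outliers_iqr()]).
#' @return A `phenotype_records` object without those plants.
#' @export
remove_plants <- function(records, plant_ids) {
  as_phenotype_records(records[!(records$plant_id %in% plant_ids), ,
                               drop = FALSE])
}

#' Phenotypic correlation matrix across days
#'
#' Pearson correlations between imaging days, computed over plants
#' (pairwise-complete, so plants missing at some days are tolerated). Days
#' with zero variance give `NA` entries with a warning.
#'
#' @param records A `phenotype_records` object.
#' @return A t x t symmetric correlation matrix with unit diagonal, dimnames
#'   the imaging days.
#' @export
phenotypic_correlation_matrix <- function(records) {
  days <- day_set(records)
  plants <- sort(unique(records$plant_id))
  wide <- matrix(NA_real_, length(plants), length(days),
                 dimnames = list(plants, as.character(days)))
  wide[cbind(match(records$plant_id, plants), match(records$day, days))] <-
    records$value
  sds <- apply(wide, 2L, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE)) {
    warning("zero variance at day(s) ",
            paste(days[which(sds == 0)], collapse = ", "),
            "; correlations involving them are NA")
  }
  R <- suppressWarnings(stats::cor(wide, use = "pairwise.complete.obs"))
  diag(R) <- ifelse(is.na(sds) | sds == 0, NA_real_, 1)
  R
}
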