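#' Read a SNP dosage matrix
#'
#' Loads a lines-by-markers matrix of alternate-allele dosages (0/1/2) from
#' either a delimited text file (header row of marker IDs, first column the
#' line ID; tab or comma auto-detected) or a VCF (biallelic SNPs only, via the
#' `vcfR` package).
#'
#' Monomorphic markers are dropped (with a message reporting the count), and
#' missing dosages are imputed to the marker mean \eqn{2\hat p} (count
#' reported). Non-biallelic VCF records are skipped with a warning.
#'
#' @param path Path to the file.
#' @param format `"delimited"` or `"vcf"`.
#' @return An object of class `dosage_matrix`: list with `line_ids`,
#'   `marker_ids`, `dosages` (n x m numeric matrix), `n_imputed` and
#'   `n_monomorphic_dropped`.
#' @export
read_dosage_matrix <- function(path, format = c("delimited", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "delimited") {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
    line_ids <- as.character(dt[[1L]])
    M <- as.matrix(dt[, -1L, drop = FALSE])
    storage.mode(M) <- "double"
    marker_ids <- colnames(M)
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF requires the 'vcfR' package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    biallelic <- vcfR::is.biallelic(v)
    if (any(!biallelic)) {
      warning(sum(!biallelic), " non-biallelic VCF record(s) skipped")
      v <- v[biallelic, ]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    conv <- function(g) {
      g <- sub(":.*", "", g)
      a <- strsplit(g, "[/|]")
      vapply(a, function(al) {
        if (length(al) != 2L || any(al == ".") || any(is.na(al))) {
          return(NA_real_)
        }
        sum(al != "0")
      }, numeric(1))
    }
    M <- t(apply(gt, 1L, conv))           # markers x lines
    M <- t(M)                              # lines x lines-major
    line_ids <- colnames(gt)
    marker_ids <- rownames(gt)
    colnames(M) <- marker_ids
  }
  if (anyDuplicated(line_ids)) {
    stop("duplicate line IDs: ",
         paste(unique(line_ids[duplicated(line_ids)]), collapse = ", "))
  }
  bad <- !is.na(M) & !(M %in% c(0, 1, 2))
  if (any(bad)) {
    stop(sum(bad), " dosage value(s) outside {0, 1, 2}")
  }
  ## mean imputation per marker
  n_imputed <- sum(is.na(M))
  if (n_imputed > 0L) {
    for (j in which(colSums(is.na(M)) > 0L)) {
      mj <- M[, j]
      mj[is.na(mj)] <- mean(mj, na.rm = TRUE)
      M[, j] <- mj
    }
    message(n_imputed, " missing dosage(s) imputed to marker mean")
  }
  ## drop monomorphic markers (zero variance columns)
  p_hat <- colMeans(M) / 2
  mono <- p_hat <= 0 | p_hat >= 1 | apply(M, 2L, function(z) all(z == z[1L]))
  if (any(mono)) {
    message(sum(mono), " monomorphic marker(s) dropped")
    M <- M[, !mono, drop = FALSE]
    marker_ids <- marker_ids[!mono]
  }
  if (ncol(M) < 1L) stop("no polymorphic markers left")
  if (nrow(M) < 2L) stop("need at least 2 lines")
  rownames(M) <- line_ids
  structure(list(line_ids = line_ids, marker_ids = marker_ids, dosages = M,
                 n_imputed = n_imputed, n_monomorphic_dropped = sum(mono)),
            class = "dosage_matrix")
}

#' Wrap an in-memory dosage matrix
#'
#' Puts a plain numeric matrix of 0/1/2 dosages into the same container
#' [read_dosage_matrix()] returns.
#'
#' @param M n x m numeric matrix (rows = lines).
#' @param line_ids,marker_ids Identifiers (default: dimnames, or generated).
#' @return A `dosage_matrix`.
#' @export
as_dosage_matrix <- function(M, line_ids = rownames(M),
                             marker_ids = colnames(M)) {
  if (is.null(line_ids)) line_ids <- paste0("L", seq_len(nrow(M)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(M)))
  rownames(M) <- line_ids
  colnames(M) <- marker_ids
  structure(list(line_ids = line_ids, marker_ids = marker_ids,
                 dosages = M, n_imputed = 0L, n_monomorphic_dropped = 0L),
            class = "dosage_matrix")
}

#' VanRaden genomic relationship matrix
#'
#' Computes \eqn{G = Z_{cs} Z_{cs}' / m} from a dosage matrix. With
#' `method = "per-marker"` (default) each marker column is centered by
#' \eqn{2\hat p_j} and scaled by \eqn{\sqrt{2 \hat p_j (1-\hat p_j)}}; with
#' `method = "vanraden1"` columns are centered only and the cross-product is
#' divided by \eqn{2 \sum_j \hat p_j (1-\hat p_j)} (VanRaden's method 1).
#' Allele frequencies \eqn{\hat p_j} are the observed column means / 2.
#'
#' After construction, eigenvalues below `psd_floor` are clamped up to the
#' floor (a message reports how many), so downstream factorizations always see
#' a positive-definite matrix.
#'
#' @param dosages A `dosage_matrix` (or plain n x m matrix with entries
#'   0/1/2).
#' @param method `"per-marker"` or `"vanraden1"`.
#' @param psd_floor Eigenvalue floor used for the positive-semidefinite
#'   repair (default `1e-8`).
#' @return Object of class `genomic_relationship`: list with `line_ids`, `G`
#'   (n x n, dimnames = line IDs) and the repaired eigendecomposition
#'   (`eigen_values`, `eigen_vectors`) reused by the REML solver.
#' @examples
#' M <- matrix(c(0, 0, 1, 1, 2, 2), 3, 2, byrow = TRUE)
#' vanraden_grm(as_dosage_matrix(M))$G
#' @export
vanraden_grm <- function(dosages, method = c("per-marker", "vanraden1"),
                         psd_floor = 1e-8) {
  method <- match.arg(method)
  M <- if (inherits(dosages, "dosage_matrix")) dosages$dosages else dosages
  line_ids <- if (inherits(dosages, "dosage_matrix")) dosages$line_ids else {
    rownames(M) %||% paste0("L", seq_len(nrow(M)))
  }
  m <- ncol(M)
  p_hat <- colMeans(M) / 2
  if (any(p_hat <= 0 | p_hat >= 1)) {
    stop("monomorphic marker(s) present; drop them before computing G")
  }
  Zc <- sweep(M, 2L, 2 * p_hat, `-`)
  if (method == "per-marker") {
    Zcs <- sweep(Zc, 2L, sqrt(2 * p_hat * (1 - p_hat)), `/`)
    G <- tcrossprod(Zcs) / m
  } else {
    G <- tcrossprod(Zc) / (2 * sum(p_hat * (1 - p_hat)))
  }
  G <- (G + t(G)) / 2
  eg <- eigen(G, symmetric = TRUE)
  n_clamped <- sum(eg$values < -psd_floor)
  if (n_clamped > 0L) {
    message(n_clamped, " negative eigenvalue(s) of G clamped to zero")
  }
  if (any(eg$values < 0)) {
    eg$values <- pmax(eg$values, 0)
    ## store the repaired matrix so every consumer sees the same G
    G <- eg$vectors %*% (t(eg$vectors) * eg$values)
    G <- (G + t(G)) / 2
  }
  dimnames(G) <- list(line_ids, line_ids)
  structure(list(line_ids = line_ids, G = G,
                 eigen_values = eg$values, eigen_vectors = eg$vectors,
                 method = method, n_eigen_clamped = n_clamped),
            class = "genomic_relationship")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genomic_relationship <- function(x, ...) {
  cat("genomic_relationship:", length(x$line_ids), "lines, method",
      x$method, "\n")
  invisible(x)
}

## Restrict a relationship matrix to a subset of lines (eigen recomputed).
grm_subset <- function(grm, ids) {
  idx <- match(ids, grm$line_ids)
  stopifnot(!anyNA(idx))
  G <- grm$G[idx, idx, drop = FALSE]
  eg <- eigen(G, symmetric = TRUE)
  eg$values <- pmax(eg$values, 0)
  structure(list(line_ids = grm$line_ids[idx], G = G,
                 eigen_values = eg$values, eigen_vectors = eg$vectors,
                 method = grm$method, n_eigen_clamped = grm$n_eigen_clamped),
            class = "genomic_relationship")
}

#' Export a relationship matrix as delimited text
#'
#' @param grm A `genomic_relationship`.
#' @param path Output path (tab-separated, line IDs as first column/header).
#' @export
write_grm <- function(grm, path) {
  df <- data.frame(line_id = grm$line_ids, grm$G, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
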