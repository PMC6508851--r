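test_that("delimited dosage reader round-trips and filters monomorphic markers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("line_id\tm1\tm2\tm3",
               "A\t0\t2\t1",
               "B\t1\t2\t0",
               "C\t2\t2\t2"), path)
  dos <- suppressMessages(read_dosage_matrix(path))
  expect_equal(dos$line_ids, c("A", "B", "C"))
  expect_equal(dos$marker_ids, c("m1", "m3"))   # m2 monomorphic, dropped
  expect_equal(dos$n_monomorphic_dropped, 1L)
  expect_equal(unname(dos$dosages[, "m1"]), c(0, 1, 2))
})

test_that("missing dosages are imputed to the marker mean", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("line_id,m1,m2", "A,0,1", "B,NA,1", "C,2,0"), path)
  dos <- suppressMessages(read_dosage_matrix(path))
  ## column mean of observed m1 values (0, 2) is 1
  expect_equal(unname(dos$dosages[, "m1"]), c(0, 1, 2))
  expect_equal(dos$n_imputed, 1L)
})

test_that("dosage reader rejects invalid input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("line_id\tm1", "A\t0", "A\t1"), path)
  expect_error(read_dosage_matrix(path), "duplicate line ID")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("line_id\tm1\tm2", "A\t3\t1", "B\t0\t0"), path2)
  expect_error(read_dosage_matrix(path2), "outside \\{0, 1, 2\\}")
  expect_error(read_dosage_matrix("no/such/file.tsv"), "not found")
})

test_that("VCF reader extracts alt-allele dosages and skips non-biallelic sites", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB\tC",
    "1\t100\ts1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\ts2\tC\tT,G\t.\tPASS\t.\tGT\t0/0\t0/1\t1/2",
    "1\t300\ts3\tG\tA\t.\tPASS\t.\tGT\t0|1\t1|1\t0|0"), path)
  dos <- suppressWarnings(suppressMessages(
    read_dosage_matrix(path, format = "vcf")))
  expect_equal(sort(dos$line_ids), c("A", "B", "C"))
  expect_equal(dos$marker_ids, c("s1", "s3"))   # multi-allelic s2 skipped
  expect_equal(unname(dos$dosages[c("A", "B", "C"), "s1"]), c(0, 1, 2))
  expect_equal(unname(dos$dosages[c("A", "B", "C"), "s3"]), c(1, 2, 0))
})

test_that("VanRaden G matches the hand-computed toy example", {
  G <- vanraden_grm(toy_dosages())$G
  expect_equal(unname(G),
               matrix(c(2, 0, -2,
                        0, 0, 0,
                        -2, 0, 2), 3, 3, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("centered/scaled marker matrix has zero column means and the trace identity", {
  truth <- small_truth()
  M <- truth$dosages$dosages
  p_hat <- colMeans(M) / 2
  Zcs <- sweep(sweep(M, 2, 2 * p_hat), 2, sqrt(2 * p_hat * (1 - p_hat)), "/")
  expect_lt(max(abs(colMeans(Zcs))), 1e-12)
  G <- vanraden_grm(truth$dosages)$G
  expect_equal(mean(diag(G)), mean(rowSums(Zcs^2) / ncol(M)),
               tolerance = 1e-6)
})

test_that("duplicated dosage rows give identical rows and columns of G", {
  M <- rbind(toy_dosages()$dosages,
             D = toy_dosages()$dosages["A", ])
  dos <- as_dosage_matrix(M, line_ids = c("A", "B", "C", "D"))
  G <- suppressMessages(vanraden_grm(dos))$G
  expect_equal(G["A", ], G["D", ], ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(G[, "A"], G[, "D"], ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("G is symmetric PSD after repair and eigen pair is stored", {
  grm <- small_truth()$grm
  expect_lt(max(abs(grm$G - t(grm$G))), 1e-10)
  expect_gte(min(grm$eigen_values), 0)
  rebuilt <- grm$eigen_vectors %*% (t(grm$eigen_vectors) * grm$eigen_values)
  expect_equal(unname(grm$G), rebuilt, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("monomorphic markers reaching the G computation are an error", {
  M <- matrix(c(2, 2, 2, 0, 1, 2), 3, 2)
  expect_error(vanraden_grm(M), "monomorphic")
})

test_that("VanRaden method-1 overall scaling is available", {
  M <- toy_dosages()
  G1 <- vanraden_grm(M, method = "vanraden1")$G
  p <- c(0.5, 0.5)
  Zc <- sweep(M$dosages, 2, 2 * p)
  expect_equal(unname(G1), unname(tcrossprod(Zc) / (2 * sum(p * (1 - p)))),
               tolerance = 1e-12)
})

test_that("G approaches the expected binomial kinship as markers grow", {
  d_for <- function(m, seed) {
    cfg <- sim_config(n_lines = 40, n_markers = m, seed = seed)
    G <- suppressMessages(vanraden_grm(simulate_genotypes(cfg)))$G
    norm(G - diag(40), "F") / norm(diag(40), "F")
  }
  expect_lt(d_for(3000, 9), d_for(150, 9))
})
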