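# Fixtures are written as plain text into tempdir() by the helpers below.

write_tsv_matrix <- function(m, path) {
  header <- paste(c("id", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], m[i, ]), collapse = "\t"), character(1))
  writeLines(c(header, rows), path)
  path
}

write_bed <- function(df, path) {
  # chrom, start, end, name; BED is 0-based half-open
  writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end, df$id),
             path)
  path
}

make_scan_fixture <- function(seed = 5, n = 30, n_genes = 4, n_snps = 12) {
  set.seed(seed)
  samples <- sprintf("s%02d", seq_len(n))
  X <- synthetic_genotypes(n, n_snps, block_size = 4, rho = 0.4)
  counts <- matrix(NA_real_, n_genes, n,
                   dimnames = list(paste0("g", seq_len(n_genes)), samples))
  for (g in seq_len(n_genes)) counts[g, ] <- rpois(n, 6)
  covs <- t(X)
  rownames(covs) <- paste0("snp", seq_len(n_snps))
  colnames(covs) <- samples
  positions <- data.frame(id = rownames(covs), chrom = "chr1",
                          start = seq(100, by = 500,
                                      length.out = n_snps),
                          stringsAsFactors = FALSE)
  positions$end <- positions$start + 1L
  annotations <- data.frame(
    id = rownames(counts), chrom = "chr1",
    start = c(0L, 1500L, 3000L, 4500L),
    end = c(1200L, 2600L, 4100L, 5600L),
    stringsAsFactors = FALSE
  )
  list(counts = counts, covs = covs, positions = positions,
       annotations = annotations, samples = samples)
}

test_that("count matrices round-trip through TSV and are validated", {
  m <- matrix(c(0, 3, 12, 7, 1, 0), 2, 3,
              dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
  path <- tempfile(fileext = ".tsv")
  write_tsv_matrix(m, path)
  expect_equal(read_count_matrix(path), m)

  bad <- m; bad[1, 1] <- -2
  write_tsv_matrix(bad, path)
  expect_error(read_count_matrix(path), class = "nbglobal_invalid_input")

  frac <- m; frac[2, 2] <- 1.5
  write_tsv_matrix(frac, path)
  expect_error(read_count_matrix(path), class = "nbglobal_invalid_input")
  # but fractional values are fine for covariates (e.g. methylation)
  expect_equal(read_covariate_matrix(path), frac)

  dup <- m; rownames(dup) <- c("gA", "gA")
  write_tsv_matrix(dup, path)
  expect_error(read_count_matrix(path), class = "nbglobal_invalid_input")

  dupcol <- m; colnames(dupcol) <- c("s1", "s1", "s3")
  write_tsv_matrix(dupcol, path)
  expect_error(read_count_matrix(path), class = "nbglobal_invalid_input")

  writeLines(c("id\ts1\ts2", "gA\t1\t2", "gB\t3"), path)
  expect_error(read_count_matrix(path))
})

test_that("BED positions come back 0-based with names intact", {
  df <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 250L),
                   end = c(100L, 251L), id = c("geneA", "snp1"),
                   stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".bed")
  write_bed(df, path)
  out <- read_bed(path)
  expect_equal(out$id, df$id)
  expect_equal(out$chrom, df$chrom)
  expect_equal(out$start, df$start)
  expect_equal(out$end, df$end)
})

test_that("window selection uses closed-left half-open intervals", {
  positions <- data.frame(id = paste0("c", 1:5), chrom = "chr1",
                          start = c(500L, 1000L, 2500L, 3999L, 4000L))
  gene <- list(id = "g", chrom = "chr1", start = 2000L, end = 3000L)

  # w = 0, gene_body: only positions inside [start, end)
  expect_equal(select_window_covariates(gene, positions, 0), 3L)
  # w = 1000 around the body: [1000, 4000)
  expect_equal(select_window_covariates(gene, positions, 1000), c(2L, 3L, 4L))
  # covariate exactly at start - w is included (closed left edge)
  expect_true(2L %in% select_window_covariates(gene, positions, 1000))
  # anchored at the start location: [1000, 3000)
  expect_equal(select_window_covariates(gene, positions, 1000,
                                        anchor = "gene_start"), 2:3)
  # other chromosome: nothing
  gene2 <- list(id = "g2", chrom = "chrX", start = 0L, end = 10000L)
  expect_length(select_window_covariates(gene2, positions, 1000), 0)

  # hand-enumerated oracle on a toy instance
  w <- 1000
  manual <- which(positions$chrom == gene$chrom &
                    positions$start >= gene$start - w &
                    positions$start < gene$end + w)
  expect_equal(select_window_covariates(gene, positions, w), manual)
})

test_that("strata files are two-column TSVs keyed by sample id", {
  path <- tempfile()
  writeLines(c("s1\tCEU", "s2\tYRI", "s3\tCEU"), path)
  st <- read_strata(path)
  expect_equal(st, c(s1 = "CEU", s2 = "YRI", s3 = "CEU"))
  writeLines(c("s1\tCEU", "s1\tYRI"), path)
  expect_error(read_strata(path), class = "nbglobal_invalid_input")
})

test_that("the scan reproduces a direct single-gene test", {
  fx <- make_scan_fixture()
  res <- suppressWarnings(
    genomewide_scan(fx$counts, fx$covs, fx$positions, fx$annotations,
                    window_bp = 1000, k = 100, seed = 3, offset = TRUE)
  )
  g <- "g2"
  row <- res[res$gene == g, ]
  sel <- select_window_covariates(fx$annotations[fx$annotations$id == g, ],
                                  fx$positions, 1000)
  Xg <- t(fx$covs[sel, , drop = FALSE])
  resp <- count_response(fx$counts[g, ], lib_sizes = colSums(fx$counts))
  direct <- run_test(resp, Xg, k = 100,
                     seed = nbglobal:::derive_seed(3, g))
  expect_equal(row$u, direct$u_obs)
  expect_equal(row$p, direct$p_value)
  expect_equal(row$n_cov, length(sel))
})

test_that("scan output is invariant to gene order and flags degenerate genes", {
  fx <- make_scan_fixture()
  fx$counts["g3", ] <- 0            # all-zero gene
  ann <- fx$annotations
  ann <- rbind(ann, data.frame(id = "g4b", chrom = "chr9", start = 0L,
                               end = 100L))
  fx$counts <- rbind(fx$counts, g4b = fx$counts["g4", ])

  res1 <- suppressWarnings(
    genomewide_scan(fx$counts, fx$covs, fx$positions, ann, k = 80, seed = 11))
  res2 <- suppressWarnings(
    genomewide_scan(fx$counts, fx$covs, fx$positions, ann[rev(seq_len(nrow(ann))), ],
                    k = 80, seed = 11))
  res2 <- res2[match(res1$gene, res2$gene), ]
  rownames(res2) <- NULL
  expect_equal(res1, res2)

  expect_equal(res1$flag[res1$gene == "g3"], "all_zero")
  expect_equal(res1$flag[res1$gene == "g4b"], "unknown_chrom")
  expect_true(all(is.na(res1$p[res1$flag != "ok"])))

  # BH adjustment: step-up oracle over the tested genes
  tested <- res1$flag == "ok"
  expect_true(all(res1$p_bh[tested] >= res1$p[tested]))
  expect_equal(res1$p_bh[tested], p.adjust(res1$p[tested], method = "BH"))
})

test_that("samples are aligned across inputs by id, not by position", {
  fx <- make_scan_fixture()
  shuffled <- fx$covs[, rev(fx$samples)]
  res1 <- genomewide_scan(fx$counts, fx$covs, fx$positions, fx$annotations,
                          k = 60, seed = 7)
  res2 <- genomewide_scan(fx$counts, shuffled, fx$positions, fx$annotations,
                          k = 60, seed = 7)
  expect_equal(res1, res2)
  # a missing sample is an error, not a silent drop
  expect_error(genomewide_scan(fx$counts, fx$covs[, -1], fx$positions,
                               fx$annotations, k = 60, seed = 7),
               class = "nbglobal_invalid_input")
})

test_that("scan tables round-trip through their TSV form", {
  fx <- make_scan_fixture()
  res <- genomewide_scan(fx$counts, fx$covs, fx$positions, fx$annotations,
                         k = 50, seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_scan_results(res, path)
  back <- read_scan_results(path)
  expect_equal(back, res)
})

test_that("the command-line front end runs and rejects bad usage", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "nbglobal.R", package = "nbglobal")
  expect_true(file.exists(cli))
  rscript <- file.path(R.home("bin"), "Rscript")

  fx <- make_scan_fixture()
  counts_path <- tempfile(fileext = ".tsv")
  covs_path <- tempfile(fileext = ".tsv")
  write_tsv_matrix(fx$counts, counts_path)
  write_tsv_matrix(fx$covs, covs_path)
  out_path <- tempfile(fileext = ".tsv")

  status <- system2(rscript, c(cli, "run",
                               "--counts", counts_path,
                               "--gene", "g1",
                               "--covariates", covs_path,
                               "--permutations", "50",
                               "--seed", "4",
                               "--out", out_path),
                    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out_path))
  tab <- read.delim(out_path)
  expect_equal(tab$gene, "g1")
  expect_true(tab$p >= 1 / 50 && tab$p <= 1)

  # missing required file -> usage error, exit status 2
  bad <- suppressWarnings(
    system2(rscript, c(cli, "scan", "--counts", counts_path),
            stdout = FALSE, stderr = FALSE))
  expect_equal(bad, 2L)
  unknown <- suppressWarnings(
    system2(rscript, c(cli, "frobnicate"), stdout = FALSE, stderr = FALSE))
  expect_equal(unknown, 2L)
})
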