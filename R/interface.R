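# File I/O, window-based covariate selection, and the genome-wide scan
# driver. All tabular inputs are TSV with a header of sample ids and a
# first column of feature ids; positions come as BED. Coordinates are
# interpreted as 0-based half-open throughout.

read_feature_matrix <- function(path, integer_only) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids))
    stop_invalid("duplicate sample ids in header of ", basename(path))
  tab <- utils::read.table(path, header = FALSE, sep = "\t", skip = 1L,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = c("character",
                                          rep("numeric", length(sample_ids))))
  if (ncol(tab) != length(sample_ids) + 1L)
    stop_invalid("ragged rows or header mismatch in ", basename(path))
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) stop_invalid("duplicate feature ids in ", basename(path))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  dimnames(m) <- list(ids, sample_ids)
  if (any(!is.finite(m))) stop_invalid("non-numeric or missing cells in ", basename(path))
  if (integer_only) {
    if (!is_whole(m) || any(m < 0))
      stop_invalid("counts must be non-negative integers in ", basename(path))
  }
  m
}

#' Read a gene-by-sample count matrix
#'
#' Tab-delimited text with a header row of sample ids and a first column
#' of gene ids. Cells must be non-negative integers; duplicate gene or
#' sample ids and ragged rows are errors.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_count_matrix <- function(path) read_feature_matrix(path, integer_only = TRUE)

#' Read a covariate-by-sample matrix
#'
#' Same layout as [read_count_matrix()] but cells may be any finite
#' numbers (e.g. minor-allele dosages 0/1/2, methylation levels, copy
#' numbers). Covariates are rows; the scan transposes per gene.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, covariates in rows, samples in columns.
#' @export
read_covariate_matrix <- function(path) read_feature_matrix(path, integer_only = FALSE)

#' Read positions or gene annotations from BED
#'
#' BED is 0-based half-open; the returned `start`/`end` keep that
#' convention (for point features such as SNPs, `start` is the
#' position). The `name` column is required, since covariates and genes
#' are joined to the matrices by id.
#'
#' @param path Path to a BED file (>= 4 columns).
#' @return A data.frame with columns `id`, `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  nm <- gr[["name"]]
  if (is.null(nm) || anyNA(nm))
    stop_invalid("BED file must carry a name for every feature: ", basename(path))
  if (anyDuplicated(nm)) stop_invalid("duplicate feature names in ", basename(path))
  data.frame(id = as.character(nm),
             chrom = as.character(gr$seqnames),
             start = gr$start - 1L,  # back to 0-based half-open
             end = gr$end,
             stringsAsFactors = FALSE)
}

#' Read sample strata from a two-column TSV
#'
#' Columns: sample id, stratum label; no header.
#'
#' @param path Path to the TSV file.
#' @return Named character vector of stratum labels.
#' @export
read_strata <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character"))
  if (ncol(tab) != 2L) stop_invalid("strata file must have two columns")
  if (anyDuplicated(tab[[1L]])) stop_invalid("duplicate sample ids in strata file")
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Select covariates in a window around a gene
#'
#' With `anchor = "gene_body"` a covariate at position `x` (0-based) is
#' selected when `start - w <= x < end + w`; with
#' `anchor = "gene_start"` when `start - w <= x < start + w`, the window
#' around the start location of the gene. The left edge is closed, the
#' right edge open. Strand is ignored: `start` is the smaller
#' coordinate.
#'
#' @param gene A single-row data.frame (or list) with `chrom`, `start`,
#'   `end` in 0-based half-open coordinates.
#' @param positions Data.frame with `id`, `chrom`, `start` (position of
#'   each covariate), as from [read_bed()].
#' @param window_bp Window half-width in base pairs.
#' @param anchor `"gene_body"` (default) or `"gene_start"`.
#' @return Integer vector of row indices into `positions` (possibly
#'   empty).
#' @export
select_window_covariates <- function(gene, positions, window_bp = 1000,
                                     anchor = c("gene_body", "gene_start")) {
  anchor <- match.arg(anchor)
  if (window_bp < 0) stop_invalid("'window_bp' must be non-negative")
  lo <- gene$start - window_bp
  hi <- if (anchor == "gene_body") gene$end + window_bp else gene$start + window_bp
  which(positions$chrom == gene$chrom &
          positions$start >= lo & positions$start < hi)
}

#' Genome-wide scan: one global test per gene
#'
#' For every annotated gene, selects the covariates in its window, runs
#' the global test of that gene's counts against them, and adjusts the
#' p-values across tested genes by Benjamini-Hochberg. Genes with no
#' covariates in the window, an unknown chromosome, all-zero counts or
#' counts without any variation within the sample are skipped and
#' flagged. The permutation stream of each gene is seeded from a hash of
#' the master seed and the gene id, so the output does not depend on
#' gene order.
#'
#' Samples are aligned across inputs by id (column names), not by
#' position.
#'
#' @param counts Gene-by-sample count matrix (see [read_count_matrix()]).
#' @param covariates Covariate-by-sample matrix.
#' @param positions Covariate positions (data.frame from [read_bed()]).
#' @param annotations Gene annotations (data.frame from [read_bed()]).
#' @param window_bp,anchor Window specification, see
#'   [select_window_covariates()].
#' @param family,k,strata Passed to [run_test()]; `strata` may be a
#'   named vector (matched to samples by id).
#' @param seed Master seed.
#' @param offset Use library-size offsets? Library sizes default to the
#'   column sums of `counts` unless `lib_sizes` is given.
#' @param lib_sizes Optional named vector of library sizes.
#' @return A data.frame of class `"scan_result"` with columns `gene`,
#'   `n_cov`, `u`, `p`, `p_bh`, `k`, `flag`.
#' @export
genomewide_scan <- function(counts, covariates, positions, annotations,
                            window_bp = 1000,
                            anchor = c("gene_body", "gene_start"),
                            family = c("negative_binomial", "poisson"),
                            k = 1000, strata = NULL, seed = 1L,
                            offset = TRUE, lib_sizes = NULL) {
  anchor <- match.arg(anchor)
  family <- match.arg(family)
  samples <- colnames(counts)
  if (is.null(samples)) stop_invalid("'counts' must carry sample ids as column names")
  if (is.null(colnames(covariates)))
    stop_invalid("'covariates' must carry sample ids as column names")
  missing_cov <- setdiff(samples, colnames(covariates))
  if (length(missing_cov))
    stop_invalid("samples missing from covariate matrix: ",
                 paste(utils::head(missing_cov), collapse = ", "))
  covariates <- covariates[, samples, drop = FALSE]
  if (!is.null(strata)) {
    if (is.null(names(strata))) {
      if (length(strata) != length(samples))
        stop_invalid("unnamed 'strata' must have one label per sample")
    } else {
      if (!all(samples %in% names(strata)))
        stop_invalid("strata labels missing for some samples")
      strata <- strata[samples]
    }
  }
  if (isTRUE(offset)) {
    if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
    if (!is.null(names(lib_sizes))) lib_sizes <- lib_sizes[samples]
  }
  pos_idx <- match(positions$id, rownames(covariates))
  if (anyNA(pos_idx))
    stop_invalid("positions refer to covariates absent from the matrix")

  genes <- annotations$id
  out <- data.frame(gene = genes, n_cov = 0L, u = NA_real_, p = NA_real_,
                    p_bh = NA_real_, k = as.integer(k), flag = "ok",
                    stringsAsFactors = FALSE)
  for (g in seq_along(genes)) {
    gene <- annotations[g, ]
    if (!gene$id %in% rownames(counts)) {
      out$flag[g] <- "no_counts"
      next
    }
    if (!gene$chrom %in% positions$chrom) {
      out$flag[g] <- "unknown_chrom"
      warning("gene ", gene$id, ": chromosome ", gene$chrom,
              " has no covariates; skipped", call. = FALSE)
      next
    }
    sel <- select_window_covariates(gene, positions, window_bp, anchor)
    if (length(sel) == 0L) {
      out$flag[g] <- "empty_window"
      warning("gene ", gene$id, ": no covariates in window; skipped",
              call. = FALSE)
      next
    }
    y <- counts[gene$id, ]
    if (max(y) == min(y)) {
      out$flag[g] <- if (all(y == 0)) "all_zero" else "constant_counts"
      warning("gene ", gene$id, ": no variation within the sample; skipped",
              call. = FALSE)
      next
    }
    out$n_cov[g] <- length(sel)
    Xg <- t(covariates[pos_idx[sel], , drop = FALSE])
    resp <- count_response(y, lib_sizes = lib_sizes, offset = isTRUE(offset))
    res <- run_test(resp, Xg, family = family, k = k, strata = strata,
                    seed = derive_seed(seed, gene$id))
    out$u[g] <- res$u_obs
    out$p[g] <- res$p_value
  }
  tested <- out$flag == "ok"
  out$p_bh[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Write / read a scan result table
#'
#' Plain TSV with the fixed column order
#' `gene, n_cov, u, p, p_bh, k, flag`; writing then reading is the
#' identity.
#'
#' @param x A `"scan_result"` data.frame.
#' @param path Output path.
#' @return `write_scan_results()` returns `path` invisibly;
#'   `read_scan_results()` returns the table.
#' @export
write_scan_results <- function(x, path) {
  utils::write.table(x[, c("gene", "n_cov", "u", "p", "p_bh", "k", "flag")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_results
#' @export
read_scan_results <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "numeric",
                                          "numeric", "numeric", "integer",
                                          "character"))
  class(out) <- c("scan_result", "data.frame")
  out
}
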