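#' Normalize an expression matrix to a housekeeping gene
#'
#' Divides each gene's value by the sample's housekeeping expression; the
#' result is scale-free per sample (a sample with all genes doubled,
#' housekeeping included, is unchanged).
#'
#' @param tpm genes x samples numeric matrix (TPM).
#' @param hk_gene housekeeping gene id (a row of `tpm`).
#' @return Normalized matrix of the same shape.
#' @examples
#' m <- matrix(c(10, 100, 20, 200), 2, dimnames = list(c("g", "hk"), NULL))
#' housekeeping_normalize(m, "hk")
#' @export
housekeeping_normalize <- function(tpm, hk_gene) {
  if (!hk_gene %in% rownames(tpm)) {
    stop("housekeeping gene ", hk_gene, " absent from the matrix")
  }
  hk <- tpm[hk_gene, ]
  bad <- which(!is.finite(hk) | hk <= 0)
  if (length(bad)) {
    stop("zero or missing housekeeping value in sample(s): ",
         paste(colnames(tpm)[bad] %||% bad, collapse = ", "))
  }
  sweep(tpm, 2, hk, "/")
}

#' Fold of the index sample above the cohort mean
#'
#' `FC = index value / mean over all non-index samples`; the index sample is
#' excluded from the mean to avoid self-contamination at small cohort sizes.
#'
#' @param norm normalized genes x samples matrix.
#' @param index_sample column name of the index sample.
#' @param gene gene id.
#' @return FC (positive scalar).
#' @export
fold_above_mean <- function(norm, index_sample, gene) {
  cohort <- norm[gene, setdiff(colnames(norm), index_sample)]
  if (length(cohort) < 3L) stop("need a cohort of >= 3 excluding the index")
  m <- mean(cohort)
  if (!is.finite(m) || m == 0) stop("cohort mean is zero; FC undefined")
  unname(norm[gene, index_sample] / m)
}

#' Cohort z-score of the index sample for one gene
#'
#' `Z = (index - cohort mean) / cohort sd`, computed on log2 values when
#' `log_transform = TRUE`. The cohort excludes the index sample. This is the
#' plain cohort z-score, not an autoencoder-controlled outlier statistic;
#' genes whose cohort mean TPM falls below `min_mean` are masked (ratio
#' instability) and return `NA`.
#'
#' @param norm normalized genes x samples matrix.
#' @param index_sample,gene index sample and gene ids.
#' @param log_transform compute on log2 values (default FALSE).
#' @param min_mean cohort mean (on the original scale) below which the gene
#'   is masked; default 0 (no masking; pass e.g. 1 for TPM input).
#' @return Z (scalar, `NA` if masked).
#' @export
expression_zscore <- function(norm, index_sample, gene,
                              log_transform = FALSE, min_mean = 0) {
  cohort <- norm[gene, setdiff(colnames(norm), index_sample)]
  if (mean(cohort) < min_mean) return(NA_real_)
  x <- norm[gene, index_sample]
  if (log_transform) {
    cohort <- log2(cohort)
    x <- log2(x)
  }
  s <- stats::sd(cohort)
  if (!is.finite(s) || s == 0) stop("cohort standard deviation is zero")
  unname((x - mean(cohort)) / s)
}

#' Expected fold-change under the naive proportional dosage model
#'
#' `FC = CN / 2`: expression scales with total copy number relative to the
#' diploid state, so a constitutional duplication (CN 3) gives 1.5 and a
#' triplication (CN 4) gives 2.0.
#'
#' @param total_cn total copy number (>= 0).
#' @return Expected FC.
#' @examples
#' expected_dosage_fc(4)  # 2
#' @export
expected_dosage_fc <- function(total_cn) {
  if (any(total_cn < 0)) stop("total CN must be >= 0")
  total_cn / 2
}

#' Score every gene of a cohort for dosage outliers in one sample
#'
#' Convenience wrapper: housekeeping-normalizes, then reports per gene the
#' index sample's normalized value, fold above the cohort mean, and cohort
#' z-score.
#'
#' @inheritParams housekeeping_normalize
#' @inheritParams fold_above_mean
#' @param log_transform,min_mean passed to [expression_zscore()].
#' @return data.frame with `gene`, `normalized_value`, `FC`, `Z`.
#' @export
expression_outliers <- function(tpm, hk_gene, index_sample,
                                log_transform = FALSE, min_mean = 0) {
  norm <- housekeeping_normalize(tpm, hk_gene)
  genes <- setdiff(rownames(norm), hk_gene)
  out <- lapply(genes, function(g) {
    data.frame(gene = g,
               normalized_value = unname(norm[g, index_sample]),
               FC = fold_above_mean(norm, index_sample, g),
               Z = expression_zscore(norm, index_sample, g,
                                     log_transform, min_mean),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
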