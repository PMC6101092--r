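#' Learn per-peptide standardization statistics
#'
#' Peptide log-ratios are standardized (mean 0, sd 1, sample-sd convention)
#' before entering the component model. Statistics are learned on training
#' samples only and reused unchanged on validation/test samples.
#'
#' @param quant A quant tibble (see [read_quant_matrix()]).
#' @return A `hiscom_standardizer`: a tibble with columns
#'   `peptide_id`, `mean`, `sd`.
#' @export
standardize_fit <- function(quant) {
  validate_quant_matrix(quant)
  peps <- names(quant)[-1]
  mu <- vapply(quant[peps], mean, numeric(1))
  sg <- vapply(quant[peps], stats::sd, numeric(1))
  if (any(sg == 0 | !is.finite(sg))) {
    bad <- peps[which(sg == 0 | !is.finite(sg))[1]]
    abort(paste0("constant peptide column cannot be standardized: `", bad, "`"))
  }
  std <- tibble::tibble(peptide_id = peps, mean = unname(mu), sd = unname(sg))
  class(std) <- c("hiscom_standardizer", class(std))
  std
}

#' Apply stored standardization statistics
#'
#' @param std A `hiscom_standardizer` from [standardize_fit()].
#' @param quant A quant tibble; must contain every peptide the standardizer
#'   was fitted on (extra columns are ignored).
#' @return A samples-by-peptides numeric matrix in the standardizer's
#'   peptide order, with sample ids as row names.
#' @export
standardize_apply <- function(std, quant) {
  validate_quant_matrix(quant)
  missing_p <- setdiff(std$peptide_id, names(quant))
  if (length(missing_p)) {
    abort(paste0("quant matrix lacks peptide(s): ",
                 paste(head(missing_p, 5), collapse = ", ")))
  }
  X <- as.matrix(quant[std$peptide_id])
  X <- sweep(X, 2, std$mean, "-")
  X <- sweep(X, 2, std$sd, "/")
  rownames(X) <- quant$sample_id
  X
}
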