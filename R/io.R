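#' Read a peptide quantification matrix
#'
#' Reads MRM-MS peptide quantities as log2(light/heavy) ratios. The wide
#' dialect is a delimited table whose first column is `sample_id` and whose
#' remaining columns are peptides holding already log2-transformed ratios.
#' The long dialect is a Skyline-style export with one row per
#' (peptide, sample) measurement and columns
#' `peptide_id, protein_id, sample_id, light_area, heavy_area`; the ratio
#' log2(light/heavy) is computed per record and the table pivoted to wide.
#'
#' Light intensity is the endogenous peptide signal; heavy intensity is the
#' spiked stable-isotope-labelled standard of identical sequence. Zero or
#' negative intensities have no defined ratio and are rejected.
#'
#' @param path Path to a delimited text file.
#' @param dialect `"wide"` or `"long"` (see Details).
#' @param delim Field delimiter, tab by default.
#' @param col_map Optional named character vector remapping the canonical
#'   long-dialect column names to the names actually present in the file,
#'   e.g. `c(light_area = "Area", heavy_area = "Area.1")`.
#' @param drop_incomplete_samples If `TRUE`, samples (rows) with any missing
#'   peptide value are dropped with a warning instead of raising an error.
#' @return A tibble with a `sample_id` character column followed by one
#'   numeric column per peptide.
#' @export
read_quant_matrix <- function(path, dialect = c("wide", "long"), delim = "\t",
                              col_map = NULL, drop_incomplete_samples = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  if (dialect == "wide") {
    if (names(raw)[1] != "sample_id") {
      abort("wide quant matrix must have `sample_id` as its first column")
    }
    quant <- parse_wide_quant(raw, drop_incomplete_samples)
  } else {
    quant <- parse_long_quant(raw, col_map)
  }
  validate_quant_matrix(quant)
}

parse_wide_quant <- function(raw, drop_incomplete_samples) {
  peps <- names(raw)[-1]
  vals <- lapply(peps, function(p) {
    x <- suppressWarnings(as.numeric(raw[[p]]))
    bad <- which(!is.na(raw[[p]]) & is.na(x))
    if (length(bad)) {
      abort(paste0("non-numeric cell at row ", bad[1], ", column `", p, "`"))
    }
    x
  })
  quant <- tibble::tibble(sample_id = raw$sample_id)
  quant[peps] <- vals
  if (drop_incomplete_samples) {
    keep <- stats::complete.cases(quant[peps])
    if (!all(keep)) {
      warn(paste0("dropping ", sum(!keep), " sample(s) with missing peptide values"))
      quant <- quant[keep, , drop = FALSE]
    }
  }
  quant
}

parse_long_quant <- function(raw, col_map = NULL) {
  canonical <- c("peptide_id", "protein_id", "sample_id", "light_area", "heavy_area")
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(raw)) {
        abort(paste0("col_map names absent column `", col_map[[nm]], "`"))
      }
      names(raw)[names(raw) == col_map[[nm]]] <- nm
    }
  }
  missing_cols <- setdiff(canonical, names(raw))
  if (length(missing_cols)) {
    abort(paste0("long quant table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in c("light_area", "heavy_area")) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x))
    if (length(bad)) {
      abort(paste0("non-numeric cell at row ", bad[1], ", column `", col, "`"))
    }
    raw[[col]] <- x
  }
  dup <- duplicated(raw[c("sample_id", "peptide_id")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(paste0("duplicate record for sample `", raw$sample_id[i],
                 "`, peptide `", raw$peptide_id[i], "`"))
  }
  if (any(raw$heavy_area <= 0)) {
    i <- which(raw$heavy_area <= 0)[1]
    abort(paste0("nonpositive heavy intensity at row ", i,
                 " (peptide `", raw$peptide_id[i], "`)"))
  }
  if (any(raw$light_area <= 0)) {
    i <- which(raw$light_area <= 0)[1]
    abort(paste0("nonpositive light intensity at row ", i,
                 " (peptide `", raw$peptide_id[i], "`)"))
  }
  raw$ratio <- log2(raw$light_area / raw$heavy_area)
  wide <- tidyr::pivot_wider(raw[c("sample_id", "peptide_id", "ratio")],
                             names_from = "peptide_id", values_from = "ratio")
  if (anyNA(wide)) {
    abort("long table is not complete: some (sample, peptide) pairs are unmeasured")
  }
  wide
}

#' Write a peptide quantification matrix
#'
#' Writes the wide dialect read back by [read_quant_matrix()]: `sample_id`
#' first, one column per peptide, cells holding log2(light/heavy) ratios.
#'
#' @param quant A quant tibble as returned by [read_quant_matrix()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_quant_matrix <- function(quant, path, delim = "\t") {
  validate_quant_matrix(quant)
  readr::write_delim(quant, path, delim = delim)
  invisible(path)
}

#' Validate a peptide quantification tibble
#'
#' Checks the invariants assumed downstream: a `sample_id` first column,
#' unique sample and peptide identifiers, and finite numeric values
#' throughout.
#'
#' @param quant A tibble with `sample_id` plus numeric peptide columns.
#' @return `quant`, invisibly validated (returned unchanged).
#' @export
validate_quant_matrix <- function(quant) {
  if (!is.data.frame(quant) || names(quant)[1] != "sample_id") {
    abort("quant matrix must be a data frame with `sample_id` as first column")
  }
  if (anyDuplicated(quant$sample_id)) {
    abort(paste0("duplicate sample_id: ",
                 quant$sample_id[anyDuplicated(quant$sample_id)]))
  }
  peps <- names(quant)[-1]
  if (anyDuplicated(peps)) abort("duplicate peptide identifiers")
  if (length(peps) == 0) abort("quant matrix has no peptide columns")
  for (p in peps) {
    if (!is.numeric(quant[[p]])) abort(paste0("peptide column `", p, "` is not numeric"))
    if (!all(is.finite(quant[[p]]))) {
      abort(paste0("peptide column `", p, "` contains missing or non-finite values"))
    }
  }
  invisible(quant)
}

#' Read a peptide-to-protein hierarchy
#'
#' The hierarchy defines the component structure: each peptide belongs to
#' exactly one protein, and each protein contributes one latent component.
#' Protein order is first-appearance order in the file.
#'
#' @param path Path to a delimited file with header columns
#'   `peptide_id`, `protein_id`.
#' @param delim Field delimiter.
#' @return A tibble with columns `peptide_id`, `protein_id`.
#' @export
read_hierarchy <- function(path, delim = "\t") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  h <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  validate_hierarchy(h)
}

#' Validate a peptide-to-protein hierarchy tibble
#'
#' @param hierarchy A tibble with columns `peptide_id`, `protein_id`.
#' @return The hierarchy, restricted to those two columns.
#' @export
validate_hierarchy <- function(hierarchy) {
  if (!is.data.frame(hierarchy) ||
      !all(c("peptide_id", "protein_id") %in% names(hierarchy))) {
    abort("hierarchy must have columns `peptide_id` and `protein_id`")
  }
  h <- dplyr::distinct(tibble::as_tibble(hierarchy[c("peptide_id", "protein_id")]))
  if (nrow(h) == 0) abort("hierarchy is empty")
  dup <- duplicated(h$peptide_id)
  if (any(dup)) {
    abort(paste0("peptide maps to multiple proteins: ", h$peptide_id[which(dup)[1]]))
  }
  h
}

#' Summarize a hierarchy
#'
#' @param hierarchy A validated hierarchy tibble.
#' @return A tibble with one row per protein in first-appearance order and
#'   columns `protein_id`, `n_peptides`.
#' @export
hierarchy_summary <- function(hierarchy) {
  h <- validate_hierarchy(hierarchy)
  h |>
    dplyr::mutate(protein_id = factor(.data$protein_id,
                                      levels = unique(.data$protein_id))) |>
    dplyr::count(.data$protein_id, name = "n_peptides") |>
    dplyr::mutate(protein_id = as.character(.data$protein_id))
}

#' Read a phenotype table
#'
#' @param path Path to a delimited file with header columns
#'   `sample_id, response, age, sex`. `response` is 1 for a positive drug
#'   response (complete/partial response or stable disease) and 0 for a
#'   negative response (progressive disease); `sex` is coded 0/1 (the
#'   code-to-label mapping is the caller's convention and is recorded, not
#'   interpreted, here).
#' @param delim Field delimiter.
#' @return A validated tibble with columns `sample_id`, `response`,
#'   `age`, `sex`.
#' @export
read_phenotype <- function(path, delim = "\t") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ph <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          col_types = readr::cols(
                            sample_id = readr::col_character(),
                            response = readr::col_double(),
                            age = readr::col_double(),
                            sex = readr::col_double()))
  validate_phenotype(ph)
}

#' Validate a phenotype tibble
#'
#' @param pheno A tibble with columns `sample_id, response, age, sex`.
#' @return The validated phenotype tibble.
#' @export
validate_phenotype <- function(pheno) {
  need <- c("sample_id", "response", "age", "sex")
  if (!is.data.frame(pheno) || !all(need %in% names(pheno))) {
    abort("phenotype must have columns sample_id, response, age, sex")
  }
  ph <- tibble::as_tibble(pheno[need])
  if (anyDuplicated(ph$sample_id)) {
    abort(paste0("duplicated sample_id: ",
                 ph$sample_id[anyDuplicated(ph$sample_id)]))
  }
  if (!all(ph$response %in% c(0, 1))) {
    abort("response must be 0 (negative) or 1 (positive)")
  }
  if (!all(is.finite(ph$age)) || any(ph$age <= 0)) abort("age must be positive")
  if (!all(ph$sex %in% c(0, 1))) abort("sex must be coded 0/1")
  ph$response <- as.integer(ph$response)
  ph$sex <- as.integer(ph$sex)
  ph
}

fit_artifact_fields <- c("w", "beta", "gamma", "lambda_pep", "lambda_prot",
                         "standardizer", "hierarchy", "objective_trace",
                         "converged", "n_iter")

#' Persist a fitted model to a text artifact
#'
#' Writes a self-describing JSON file holding the peptide weights, path
#' coefficients, covariate coefficients, ridge parameters, standardization
#' statistics, hierarchy and convergence trace, so that [read_fit()] can
#' reconstruct a fit usable for prediction.
#'
#' @param fit A `hiscom_fit` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "hiscom_fit"))
  payload <- list(
    format = "hiscom_fit",
    package_version = as.character(utils::packageVersion("hiscom")),
    w = as.list(fit$w),
    beta = as.list(fit$beta),
    gamma = as.list(fit$gamma),
    lambda_pep = fit$config$lambda_pep,
    lambda_prot = fit$config$lambda_prot,
    penalize_intercept = fit$config$penalize_intercept,
    penalize_covariates = fit$config$penalize_covariates,
    tol = fit$config$tol,
    max_outer = fit$config$max_outer,
    max_inner = fit$config$max_inner,
    standardizer = list(peptide_id = fit$standardizer$peptide_id,
                        mean = fit$standardizer$mean,
                        sd = fit$standardizer$sd),
    hierarchy = list(peptide_id = fit$hierarchy$peptide_id,
                     protein_id = fit$hierarchy$protein_id),
    objective_trace = fit$objective_trace,
    converged = fit$converged,
    n_iter = fit$n_iter
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a fitted model from a text artifact
#'
#' @param path Path written by [write_fit()].
#' @return A `hiscom_fit` object (without training component scores; all
#'   coefficients, standardization statistics and the trace are restored
#'   losslessly).
#' @export
read_fit <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) abort(paste0("unreadable model file: ",
                                                       conditionMessage(e))))
  if (!identical(payload$format, "hiscom_fit")) abort("unreadable model file: bad format tag")
  missing_f <- fit_artifact_fields[!fit_artifact_fields %in% names(payload)]
  if (length(missing_f)) {
    abort(paste0("incomplete model file: missing ",
                 paste(missing_f, collapse = ", ")))
  }
  std <- tibble::tibble(peptide_id = payload$standardizer$peptide_id,
                        mean = payload$standardizer$mean,
                        sd = payload$standardizer$sd)
  hier <- tibble::tibble(peptide_id = payload$hierarchy$peptide_id,
                         protein_id = payload$hierarchy$protein_id)
  fit <- list(
    w = unlist(payload$w),
    beta = unlist(payload$beta),
    gamma = unlist(payload$gamma),
    F = NULL,
    standardizer = std,
    hierarchy = hier,
    config = list(lambda_pep = payload$lambda_pep,
                  lambda_prot = payload$lambda_prot,
                  penalize_intercept = payload$penalize_intercept,
                  penalize_covariates = payload$penalize_covariates,
                  tol = payload$tol,
                  max_outer = payload$max_outer,
                  max_inner = payload$max_inner),
    objective_trace = payload$objective_trace,
    converged = payload$converged,
    n_iter = payload$n_iter
  )
  class(fit) <- "hiscom_fit"
  fit
}

#' Write a phenotype / hierarchy / generic result tibble
#'
#' Convenience TSV writer used by the command-line wrapper.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, delim = "\t") {
  readr::write_delim(x, path, delim = delim)
  invisible(path)
}
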