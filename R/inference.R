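# Permutation significance of protein path coefficients and the replicated
# biomarker-selection screen.

#' Permutation test of protein path coefficients
#'
#' Builds each protein's null path-coefficient distribution by refitting the
#' full model `B` times with response labels shuffled uniformly across
#' subjects (a permutation automatically preserves the positive:negative
#' ratio), then computes per-protein p-values with the add-one correction
#' `p_k = (1 + #\{b : |beta_k^(b)| >= |beta_k^obs|\}) / (B + 1)`, so no
#' p-value can be zero. The default comparison is two-sided on magnitude
#' because a path coefficient's sign trades off against the weight signs;
#' one-sided alternatives are exposed.
#'
#' Permuted refits that fail to converge are excluded with a warning and `B`
#' adjusted; more than 10% failures is an error.
#'
#' @param quant,pheno,hierarchy The cohort tables.
#' @param B Number of permutations (default 1000).
#' @param lambda_pep,lambda_prot Ridge parameters (the permuted refits reuse
#'   the primary fit's values).
#' @param alternative `"two.sided"` (on magnitude), `"greater"` or
#'   `"less"`.
#' @param covariates Covariate columns.
#' @param seed Integer seed; identical seeds give identical p-values.
#' @param ... Passed to [hiscom()] (tolerances, iteration caps, penalty
#'   flags).
#' @return A `hiscom_perm` object: observed fit, `beta_obs`, the
#'   `B_effective` x K `beta_null` matrix, `p_values`, counts and seed.
#' @export
hiscom_permute <- function(quant, pheno, hierarchy, B = 1000,
                           lambda_pep = 10, lambda_prot = 10,
                           alternative = c("two.sided", "greater", "less"),
                           covariates = c("age", "sex"), seed = NULL, ...) {
  alternative <- match.arg(alternative)
  if (B < 1) abort("B must be at least 1")
  fit <- hiscom(quant, pheno, hierarchy, lambda_pep = lambda_pep,
                lambda_prot = lambda_prot, covariates = covariates, ...)
  proteins <- names(fit$beta)[-1]
  K <- length(proteins)
  beta_obs <- fit$beta[-1]

  # permuted refits share the standardized design; only labels change
  X <- standardize_apply(fit$standardizer,
                         quant[c("sample_id", fit$standardizer$peptide_id)])
  hi <- hierarchy_index(fit$hierarchy, colnames(X))
  ph <- pheno[match(quant$sample_id, pheno$sample_id), , drop = FALSE]
  y <- as.integer(ph$response)
  A <- if (length(covariates)) as.matrix(ph[covariates]) else NULL
  cfg <- fit$config

  run <- function() {
    null_mat <- matrix(NA_real_, B, K, dimnames = list(NULL, proteins))
    ok <- logical(B)
    for (b in seq_len(B)) {
      y_perm <- sample(y)
      eng <- tryCatch(
        hiscom_engine(X, y_perm, A, hi$pidx, hi$K,
                      cfg$lambda_pep, cfg$lambda_prot,
                      cfg$penalize_intercept, cfg$penalize_covariates,
                      cfg$tol, cfg$max_outer, cfg$max_inner,
                      warn_nonconverged = FALSE),
        error = function(e) NULL)
      if (!is.null(eng) && eng$converged) {
        null_mat[b, ] <- eng$betaK
        ok[b] <- TRUE
      }
    }
    list(null_mat = null_mat[ok, , drop = FALSE], n_failed = sum(!ok))
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (res$n_failed > 0.1 * B) {
    abort(paste0(res$n_failed, " of ", B, " permuted refits failed (> 10%)"))
  }
  if (res$n_failed > 0) {
    warn(paste0(res$n_failed, " permuted refit(s) failed to converge and were excluded"))
  }
  B_eff <- nrow(res$null_mat)
  p_values <- vapply(seq_len(K), function(k) {
    nullk <- res$null_mat[, k]
    exceed <- switch(alternative,
                     two.sided = sum(abs(nullk) >= abs(beta_obs[k])),
                     greater = sum(nullk >= beta_obs[k]),
                     less = sum(nullk <= beta_obs[k]))
    (1 + exceed) / (B_eff + 1)
  }, numeric(1))
  structure(list(fit = fit,
                 beta_obs = beta_obs,
                 beta_null = res$null_mat,
                 p_values = stats::setNames(p_values, proteins),
                 B = B, B_effective = B_eff, n_failed = res$n_failed,
                 alternative = alternative, seed = seed),
            class = "hiscom_perm")
}

#' @export
print.hiscom_perm <- function(x, ...) {
  cat(sprintf("Permutation test of %d protein path coefficients (B = %d",
              length(x$beta_obs), x$B))
  if (x$n_failed > 0) cat(sprintf(", %d excluded", x$n_failed))
  cat(sprintf(", %s)\n", x$alternative))
  print(tidy(x), n = 10)
  invisible(x)
}

#' Significant proteins from a permutation result
#'
#' @param result A `hiscom_perm` object.
#' @param alpha Significance level (proteins with `p < alpha` are selected;
#'   the study convention is raw `p < 0.05` per protein, with no
#'   multiple-testing correction across proteins).
#' @return A tibble (`protein_id`, `beta_obs`, `p_value`) in ascending
#'   p-value order.
#' @export
select_significant <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "hiscom_perm"))
  tidy(result) |>
    dplyr::filter(.data$p_value < alpha) |>
    dplyr::arrange(.data$p_value)
}

#' Replicated biomarker-selection screen
#'
#' Repeats, `n_replicates` times: halve the samples into ratio-preserving
#' training and validation sets, run the permutation test on the training
#' half, and record which proteins reach `p < alpha`. Proteins selected in
#' at least `frequency_threshold` of replicates form the consistent
#' biomarker panel.
#'
#' @param quant,pheno,hierarchy The cohort tables.
#' @param n_replicates Number of split-and-test replicates (default 100).
#' @param B Permutations per replicate.
#' @param alpha Per-replicate significance level.
#' @param frequency_threshold Minimum selection frequency for the final
#'   panel (default 0.5; the underlying study reports a top panel without
#'   quantifying "repeatedly", so this is a configurable convention).
#' @param lambda_pep,lambda_prot Ridge parameters.
#' @param covariates Covariate columns.
#' @param seed Integer seed.
#' @param ... Passed to [hiscom_permute()].
#' @return A `selection_report`: per-protein selection frequencies, the
#'   selected panel, and the screening parameters.
#' @export
replicate_selection <- function(quant, pheno, hierarchy, n_replicates = 100,
                                B = 1000, alpha = 0.05,
                                frequency_threshold = 0.5,
                                lambda_pep = 10, lambda_prot = 10,
                                covariates = c("age", "sex"),
                                seed = NULL, ...) {
  if (n_replicates < 1) abort("n_replicates must be at least 1")
  run <- function() {
    rep_seeds <- sample.int(.Machine$integer.max - 1, 2 * n_replicates)
    hits <- NULL
    for (r in seq_len(n_replicates)) {
      sp <- train_validation_split(pheno, seed = rep_seeds[2 * r - 1])
      train_ids <- sp$sample_id[sp$partition == "train"]
      q_train <- quant[match(train_ids, quant$sample_id), , drop = FALSE]
      ph_train <- pheno[match(train_ids, pheno$sample_id), , drop = FALSE]
      perm <- hiscom_permute(q_train, ph_train, hierarchy, B = B,
                             lambda_pep = lambda_pep,
                             lambda_prot = lambda_prot,
                             covariates = covariates,
                             seed = rep_seeds[2 * r], ...)
      sig <- perm$p_values < alpha
      if (is.null(hits)) {
        hits <- stats::setNames(integer(length(sig)), names(sig))
      }
      hits[names(sig)] <- hits[names(sig)] + as.integer(sig)
    }
    hits
  }
  hits <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  freq <- hits / n_replicates
  frequencies <- tibble::tibble(protein_id = names(freq),
                                frequency = unname(freq),
                                selected = unname(freq) >= frequency_threshold) |>
    dplyr::arrange(dplyr::desc(.data$frequency))
  structure(list(frequencies = frequencies,
                 selected = frequencies$protein_id[frequencies$selected],
                 alpha = alpha, n_replicates = n_replicates, B = B,
                 frequency_threshold = frequency_threshold, seed = seed),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Selection screen: %d replicates, B = %d, alpha = %g, threshold = %g\n",
              x$n_replicates, x$B, x$alpha, x$frequency_threshold))
  cat(sprintf("  selected: %s\n",
              if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)"))
  print(x$frequencies, n = 10)
  invisible(x)
}
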