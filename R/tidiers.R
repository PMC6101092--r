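# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' Tidy a fitted component model
#'
#' @param x A `hiscom_fit`.
#' @param level `"protein"` for the intercept and path coefficients,
#'   `"peptide"` for the weights, `"covariate"` for age/sex-style terms.
#' @param ... Unused.
#' @return A tibble; columns depend on `level`.
#' @method tidy hiscom_fit
#' @export
tidy.hiscom_fit <- function(x, level = c("protein", "peptide", "covariate"),
                            ...) {
  level <- match.arg(level)
  switch(level,
    protein = tibble::tibble(term = names(x$beta),
                             estimate = unname(x$beta)),
    peptide = tibble::tibble(protein_id = x$hierarchy$protein_id,
                             peptide_id = x$hierarchy$peptide_id,
                             weight = unname(x$w[x$hierarchy$peptide_id])),
    covariate = tibble::tibble(term = names(x$gamma),
                               estimate = unname(x$gamma))
  )
}

#' One-row summary of a fitted component model
#'
#' @param x A `hiscom_fit`.
#' @param ... Unused.
#' @return A one-row tibble: sizes, ridge parameters, final penalized
#'   log-likelihood, iterations and convergence.
#' @method glance hiscom_fit
#' @export
glance.hiscom_fit <- function(x, ...) {
  tibble::tibble(
    n = length(x$sample_ids),
    n_peptides = length(x$w),
    n_proteins = length(x$beta) - 1L,
    lambda_pep = x$config$lambda_pep,
    lambda_prot = x$config$lambda_prot,
    objective = x$objective_trace[length(x$objective_trace)],
    n_iter = x$n_iter,
    converged = x$converged
  )
}

#' @rdname tidy.hiscom_fit
#' @method tidy hiscom_perm
#' @export
tidy.hiscom_perm <- function(x, ...) {
  tibble::tibble(protein_id = names(x$beta_obs),
                 beta_obs = unname(x$beta_obs),
                 p_value = unname(x$p_values))
}

#' @rdname glance.hiscom_fit
#' @method glance hiscom_perm
#' @export
glance.hiscom_perm <- function(x, ...) {
  tibble::tibble(B = x$B, B_effective = x$B_effective,
                 n_failed = x$n_failed, alternative = x$alternative,
                 min_p = min(x$p_values))
}

#' @rdname tidy.hiscom_fit
#' @method tidy selection_report
#' @export
tidy.selection_report <- function(x, ...) x$frequencies

#' @rdname glance.hiscom_fit
#' @method glance selection_report
#' @export
glance.selection_report <- function(x, ...) {
  tibble::tibble(n_replicates = x$n_replicates, B = x$B, alpha = x$alpha,
                 frequency_threshold = x$frequency_threshold,
                 n_selected = length(x$selected))
}

#' @rdname tidy.hiscom_fit
#' @method tidy sim_result
#' @export
tidy.sim_result <- function(x, ...) x$auc

#' @rdname glance.hiscom_fit
#' @method glance sim_result
#' @export
glance.sim_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$means, names_from = "method",
                             values_from = "mean_auc",
                             names_prefix = "mean_auc_")
  dplyr::bind_cols(wide,
                   tibble::tibble(B = x$B, n_failed = x$n_failed,
                                  eval_scheme = x$eval_scheme))
}

#' Plot the convergence trace of a fit
#'
#' @param object A `hiscom_fit`.
#' @param ... Unused.
#' @return A ggplot: penalized log-likelihood per IRLS iteration.
#' @method autoplot hiscom_fit
#' @export
autoplot.hiscom_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective_trace) - 1,
                       objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "IRLS iteration", y = "Penalized log-likelihood",
                  title = "Convergence trace") +
    ggplot2::theme_minimal()
}

#' Plot permutation null distributions of path coefficients
#'
#' Histograms of the permuted path coefficients per protein with the
#' observed value marked.
#'
#' @param object A `hiscom_perm`.
#' @param proteins Proteins to show (default: up to 6 smallest p-values).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hiscom_perm
#' @export
autoplot.hiscom_perm <- function(object, proteins = NULL, ...) {
  if (is.null(proteins)) {
    proteins <- names(sort(object$p_values))[seq_len(min(6, length(object$p_values)))]
  }
  null_df <- tibble::as_tibble(object$beta_null[, proteins, drop = FALSE]) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "protein_id",
                        values_to = "beta")
  obs_df <- tibble::tibble(protein_id = proteins,
                           beta = unname(object$beta_obs[proteins]))
  ggplot2::ggplot(null_df, ggplot2::aes(x = .data$beta)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(data = obs_df,
                        ggplot2::aes(xintercept = .data$beta),
                        colour = "red") +
    ggplot2::facet_wrap(~protein_id, scales = "free") +
    ggplot2::labs(x = "Path coefficient under permuted labels", y = "Count",
                  title = "Permutation null distributions") +
    ggplot2::theme_minimal()
}

#' Plot selection frequencies from the replicated screen
#'
#' @param object A `selection_report`.
#' @param top Show at most this many proteins (by frequency).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot selection_report
#' @export
autoplot.selection_report <- function(object, top = 20, ...) {
  df <- head(object$frequencies, top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$protein_id, .data$frequency),
    y = .data$frequency, fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$frequency_threshold,
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Selection frequency across replicates",
                  title = "Replicated biomarker screen") +
    ggplot2::theme_minimal()
}

#' Boxplots of simulation AUC scores by method
#'
#' @param object A `sim_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sim_result
#' @export
autoplot.sim_result <- function(object, ...) {
  ggplot2::ggplot(object$auc, ggplot2::aes(x = .data$method, y = .data$auc)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "AUC per replicate",
                  title = sprintf("Simulation study (%d replicates)", object$B)) +
    ggplot2::theme_minimal()
}
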