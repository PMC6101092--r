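# Core estimator: alternating least squares for (w, beta) nested inside
# iteratively reweighted least squares for the Bernoulli likelihood.

MU_EPS <- 1e-10

# Bernoulli log-likelihood under the logit link, overflow-safe.
bernoulli_loglik <- function(y, eta) {
  sum(y * eta) - sum(pmax(eta, 0) + log1p(exp(-abs(eta))))
}

# Penalized weighted least-squares solve:
# minimize (z - M b)' V (z - M b) + lambda * sum(maskvec * b^2).
wls_ridge_solve <- function(M, z, v, lambda, maskvec) {
  MtVM <- crossprod(M, M * v)
  diag(MtVM) <- diag(MtVM) + lambda * maskvec
  b <- tryCatch(solve(MtVM, crossprod(M, v * z)),
                error = function(e) NULL)
  if (is.null(b)) abort("unidentifiable; increase lambda_prot")
  unname(drop(b))
}

# Restrict and order a hierarchy to the peptides of a standardized matrix,
# returning grouping indexes. Peptide order is hierarchy order (peptides
# grouped by protein, proteins in first-appearance order).
hierarchy_index <- function(hierarchy, peptide_ids) {
  h <- validate_hierarchy(hierarchy)
  missing_p <- setdiff(peptide_ids, h$peptide_id)
  if (length(missing_p)) {
    abort(paste0("peptide(s) absent from hierarchy: ",
                 paste(head(missing_p, 5), collapse = ", ")))
  }
  h <- h[h$peptide_id %in% peptide_ids, , drop = FALSE]
  proteins <- unique(h$protein_id)
  ord <- order(match(h$protein_id, proteins))
  h <- h[ord, , drop = FALSE]
  pidx <- match(h$protein_id, proteins)
  list(hierarchy = h, proteins = proteins, K = length(proteins),
       pidx = pidx, Tk = tabulate(pidx, length(proteins)))
}

#' Protein component scores from peptide values and weights
#'
#' The component score of protein k for sample j is the weighted sum of that
#' protein's (standardized) peptide values, `f_jk = sum_i x_jki w_ki` — the
#' latent protein-level variable of the model.
#'
#' @param x_std Samples-by-peptides numeric matrix with peptide ids as
#'   column names (typically from [standardize_apply()]).
#' @param hierarchy Peptide-to-protein mapping tibble.
#' @param weights Peptide weight vector, in the hierarchy's peptide order
#'   (peptides grouped by protein, proteins in first-appearance order), or
#'   named by peptide id.
#' @return Samples-by-proteins numeric matrix with protein ids as column
#'   names.
#' @export
compute_component_scores <- function(x_std, hierarchy, weights) {
  hi <- hierarchy_index(hierarchy, colnames(x_std))
  if (length(weights) != nrow(hi$hierarchy)) {
    abort("length(weights) must equal the number of mapped peptides")
  }
  if (!is.null(names(weights))) weights <- weights[hi$hierarchy$peptide_id]
  X <- x_std[, hi$hierarchy$peptide_id, drop = FALSE]
  G <- matrix(0, ncol(X), hi$K)
  G[cbind(seq_len(ncol(X)), hi$pidx)] <- 1
  F_mat <- X %*% (G * as.numeric(weights))
  colnames(F_mat) <- hi$proteins
  F_mat
}

#' One ridge-penalized weighted least-squares update of the path coefficients
#'
#' With the peptide weights held fixed, the path coefficients (and intercept
#' and covariate coefficients) minimizing the working objective
#' `(z - F b)' V (z - F b) + lambda_prot * sum(masked b^2)` have a closed
#' form; this computes it.
#'
#' @param F_full Design matrix: leading column of 1s, then component scores,
#'   then covariate columns.
#' @param z Adjusted (working) response vector.
#' @param v Working weight vector (diagonal of V).
#' @param lambda_prot Ridge parameter on the masked coefficients.
#' @param penalty_mask Logical vector, one per column of `F_full`; `TRUE`
#'   columns carry the ridge penalty.
#' @return The coefficient vector.
#' @export
beta_update <- function(F_full, z, v, lambda_prot, penalty_mask) {
  stopifnot(nrow(F_full) == length(z), length(z) == length(v),
            ncol(F_full) == length(penalty_mask))
  wls_ridge_solve(F_full, z, v, lambda_prot, as.numeric(penalty_mask))
}

#' One ridge-penalized weighted least-squares update of the peptide weights
#'
#' With the path coefficients held fixed, each peptide column enters the
#' linear predictor scaled by its protein's path coefficient; the weights
#' minimizing the working objective are the joint ridge regression of
#' `z - covariate_offset` on those scaled columns.
#'
#' @param x_std Standardized samples-by-peptides matrix (column names =
#'   peptide ids).
#' @param hierarchy Peptide-to-protein mapping tibble.
#' @param z,v Working response and weights.
#' @param beta Path coefficient vector, one per protein in hierarchy order
#'   (or named by protein id). Excludes the intercept.
#' @param covariate_offset Per-sample offset `beta_0 + AGE*beta_age +
#'   SEX*beta_sex` (a scalar is recycled).
#' @param lambda_pep Ridge parameter on the weights.
#' @return Peptide weight vector in hierarchy peptide order, named.
#' @export
weight_update <- function(x_std, hierarchy, z, v, beta, covariate_offset,
                          lambda_pep) {
  hi <- hierarchy_index(hierarchy, colnames(x_std))
  if (length(beta) != hi$K) abort("length(beta) must equal the number of proteins")
  if (!is.null(names(beta))) beta <- beta[hi$proteins]
  beta <- as.numeric(beta)
  if (lambda_pep == 0 && any(beta == 0)) {
    k <- hi$proteins[which(beta == 0)[1]]
    abort(paste0("weights of protein ", k,
                 " unidentifiable: path coefficient 0 with lambda_pep = 0"))
  }
  X <- x_std[, hi$hierarchy$peptide_id, drop = FALSE]
  C <- X * rep(beta[hi$pidx], each = nrow(X))
  r <- z - covariate_offset
  w <- wls_ridge_solve(C, r, v, lambda_pep, rep(1, ncol(C)))
  stats::setNames(w, hi$hierarchy$peptide_id)
}

#' Penalized Bernoulli log-likelihood of a coefficient set
#'
#' The canonical objective of the model: the Bernoulli log-likelihood of the
#' responses under the logit link, minus `lambda_pep/2 * sum(w^2)` and
#' `lambda_prot/2` times the sum of squared masked path coefficients
#' (intercept included by default, covariates excluded by default). Larger
#' is better.
#'
#' @param x_std Standardized samples-by-peptides matrix.
#' @param y Binary response vector.
#' @param hierarchy Peptide-to-protein mapping tibble.
#' @param w Peptide weights (hierarchy peptide order or named).
#' @param beta Numeric vector `c(intercept, path coefficients)` of length
#'   K + 1.
#' @param gamma Covariate coefficient vector (may be `NULL`).
#' @param A Covariate matrix matching `gamma` (may be `NULL`).
#' @param lambda_pep,lambda_prot Ridge parameters.
#' @param penalize_intercept,penalize_covariates Which coefficients beyond
#'   the path coefficients carry the `lambda_prot` penalty.
#' @return The penalized log-likelihood (scalar).
#' @export
penalized_objective <- function(x_std, y, hierarchy, w, beta, gamma = NULL,
                                A = NULL, lambda_pep, lambda_prot,
                                penalize_intercept = TRUE,
                                penalize_covariates = FALSE) {
  hi <- hierarchy_index(hierarchy, colnames(x_std))
  if (length(beta) != hi$K + 1) abort("beta must have length K + 1 (intercept first)")
  F_mat <- compute_component_scores(x_std, hierarchy, w)
  eta <- drop(beta[1] + F_mat %*% beta[-1])
  if (!is.null(A) && length(gamma)) eta <- eta + drop(A %*% gamma)
  pen <- 0.5 * lambda_pep * sum(w^2) +
    0.5 * lambda_prot * (sum(beta[-1]^2) +
                           (if (penalize_intercept) beta[1]^2 else 0) +
                           (if (penalize_covariates && length(gamma)) sum(gamma^2) else 0))
  bernoulli_loglik(y, eta) - pen
}

# Working objective minimized by the inner ALS sweeps at fixed (v, z).
working_objective <- function(z, v, eta_lin, w, coefs, lambda_pep, lambda_prot,
                              maskvec) {
  sum(v * (z - eta_lin)^2) + lambda_pep * sum(w^2) +
    lambda_prot * sum(maskvec * coefs^2)
}

# The estimator proper, on plain matrices. X: standardized N x p (hierarchy
# peptide order); A: N x q covariates or NULL; pidx: protein index per
# peptide.
hiscom_engine <- function(X, y, A, pidx, K, lambda_pep, lambda_prot,
                          penalize_intercept = TRUE,
                          penalize_covariates = FALSE,
                          tol = 1e-6, max_outer = 100L, max_inner = 50L,
                          track_inner = FALSE, warn_nonconverged = TRUE) {
  N <- nrow(X); p <- ncol(X)
  q <- if (is.null(A)) 0L else ncol(A)
  G <- matrix(0, p, K)
  G[cbind(seq_len(p), pidx)] <- 1
  Tk <- tabulate(pidx, K)
  maskvec <- c(as.numeric(penalize_intercept), rep(1, K),
               rep(as.numeric(penalize_covariates), q))

  # deterministic, scale-balanced start
  w <- (1 / sqrt(Tk))[pidx]
  beta0 <- qlogis(mean(y))
  betaK <- rep(0, K)
  gam <- rep(0, q)

  eta_of <- function(w, beta0, betaK, gam) {
    F_mat <- X %*% (G * w)
    eta <- drop(beta0 + F_mat %*% betaK)
    if (q) eta <- eta + drop(A %*% gam)
    list(eta = eta, F_mat = F_mat)
  }
  phi1_of <- function(eta, w, beta0, betaK, gam) {
    bernoulli_loglik(y, eta) -
      0.5 * lambda_pep * sum(w^2) -
      0.5 * lambda_prot * (sum(betaK^2) +
                             (if (penalize_intercept) beta0^2 else 0) +
                             (if (penalize_covariates && q) sum(gam^2) else 0))
  }

  cur <- eta_of(w, beta0, betaK, gam)
  obj <- phi1_of(cur$eta, w, beta0, betaK, gam)
  trace <- obj
  inner_trace <- if (track_inner) list() else NULL
  converged <- FALSE
  it <- 0L

  for (it in seq_len(max_outer)) {
    mu <- pmin(pmax(plogis(cur$eta), MU_EPS), 1 - MU_EPS)
    v <- mu * (1 - mu)
    z <- cur$eta + (y - mu) / v

    F_mat <- cur$F_mat
    phi2_vals <- numeric(0)
    phi2_prev <- Inf
    for (sweep_i in seq_len(max_inner)) {
      # path/intercept/covariate block at fixed weights
      M <- cbind(1, F_mat, A)
      b <- wls_ridge_solve(M, z, v, lambda_prot, maskvec)
      beta0 <- b[1]; betaK <- b[2:(K + 1)]
      if (q) gam <- b[(K + 2):(K + 1 + q)]
      if (track_inner) {
        phi2_vals <- c(phi2_vals,
                       working_objective(z, v, drop(M %*% b), w, b,
                                         lambda_pep, lambda_prot, maskvec))
      }
      # weight block at fixed path coefficients
      offset <- beta0 + (if (q) drop(A %*% gam) else 0)
      if (lambda_pep == 0 && any(betaK == 0)) {
        abort(paste0("weights of protein ", which(betaK == 0)[1],
                     " unidentifiable: path coefficient 0 with lambda_pep = 0"))
      }
      C <- X * rep(betaK[pidx], each = N)
      w <- wls_ridge_solve(C, z - offset, v, lambda_pep, rep(1, p))
      F_mat <- X %*% (G * w)
      eta_lin <- offset + drop(F_mat %*% betaK)
      phi2 <- working_objective(z, v, eta_lin, w, c(beta0, betaK, gam),
                                lambda_pep, lambda_prot, maskvec)
      if (track_inner) phi2_vals <- c(phi2_vals, phi2)
      if (is.finite(phi2_prev) &&
          abs(phi2_prev - phi2) <= tol * (abs(phi2_prev) + 1e-10)) {
        phi2_prev <- phi2
        break
      }
      phi2_prev <- phi2
    }
    if (track_inner) inner_trace[[it]] <- phi2_vals

    cur <- list(eta = (beta0 + (if (q) drop(A %*% gam) else 0) +
                         drop(F_mat %*% betaK)),
                F_mat = F_mat)
    new_obj <- phi1_of(cur$eta, w, beta0, betaK, gam)
    trace <- c(trace, new_obj)
    if (!is.finite(new_obj)) abort("non-finite objective during fitting")
    if (abs(new_obj - obj) <= tol * (abs(obj) + 1e-10)) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  if (!converged && warn_nonconverged) {
    warn(paste0("IRLS did not converge in ", max_outer, " outer iterations"))
  }

  # reporting-only sign convention: per protein, sum of weights >= 0
  # (first weight decides a zero-sum tie), path coefficient flipped in
  # compensation; the linear predictor is unchanged.
  for (k in seq_len(K)) {
    idx <- which(pidx == k)
    s <- sum(w[idx])
    if (s < 0 || (s == 0 && w[idx[1]] < 0)) {
      w[idx] <- -w[idx]
      betaK[k] <- -betaK[k]
      cur$F_mat[, k] <- -cur$F_mat[, k]
    }
  }

  list(w = w, beta0 = beta0, betaK = betaK, gamma = gam,
       F_mat = cur$F_mat, eta = cur$eta,
       objective = obj, objective_trace = trace,
       inner_trace = inner_trace, converged = converged, n_iter = it)
}

#' Fit a hierarchical structural component model
#'
#' Collapses peptides into protein-level latent components (one weighted sum
#' per protein) and fits a logistic outcome model on the component scores
#' plus covariates, with a ridge penalty `lambda_pep` on the peptide weights
#' and `lambda_prot` on the path coefficients. Estimation maximizes the
#' penalized Bernoulli log-likelihood by iteratively reweighted least
#' squares; at each IRLS step the working penalized least-squares problem is
#' solved by alternating closed-form ridge updates of the path coefficients
#' and the peptide weights.
#'
#' Peptides are standardized (training mean/sd) before fitting; covariates
#' enter on their original scale with unpenalized coefficients by default.
#' After convergence a sign convention is applied per protein (weight sum
#' nonnegative, path coefficient flipped in compensation) so reported signs
#' are reproducible; fitted probabilities are unaffected.
#'
#' @param quant Quant tibble: `sample_id` plus numeric peptide columns of
#'   log2(light/heavy) ratios.
#' @param pheno Phenotype tibble with `sample_id`, binary `response`, and
#'   any covariate columns named in `covariates`.
#' @param hierarchy Peptide-to-protein mapping tibble.
#' @param lambda_pep,lambda_prot Nonnegative ridge parameters (default 10
#'   and 10).
#' @param penalize_intercept Include the intercept in the `lambda_prot`
#'   penalty (default `TRUE`).
#' @param penalize_covariates Include covariate coefficients in the
#'   `lambda_prot` penalty (default `FALSE`).
#' @param covariates Character vector of `pheno` columns entering the model
#'   linearly (default `c("age", "sex")`); may be `character(0)`.
#' @param tol Relative-change convergence tolerance for both loops.
#' @param max_outer,max_inner Iteration caps for the IRLS and ALS loops.
#' @param track_inner Record the working-objective value after every ALS
#'   half-update (for diagnostics); off by default.
#' @return A `hiscom_fit` object with elements `w` (named peptide weights),
#'   `beta` (named: `(Intercept)` then one path coefficient per protein),
#'   `gamma` (named covariate coefficients), `F` (samples-by-(K+1) component
#'   score matrix with leading 1s column), `standardizer`, `hierarchy`,
#'   `config`, `objective_trace`, `converged`, `n_iter`.
#' @examples
#' sim <- simulate_cohort(n_samples = 60, n_positive = 20,
#'                        protein_sizes = c(A = 3, B = 2, C = 1), seed = 1)
#' fit <- hiscom(sim$quant, sim$pheno, sim$hierarchy)
#' glance(fit)
#' @export
hiscom <- function(quant, pheno, hierarchy, lambda_pep = 10, lambda_prot = 10,
                   penalize_intercept = TRUE, penalize_covariates = FALSE,
                   covariates = c("age", "sex"), tol = 1e-6,
                   max_outer = 100L, max_inner = 50L, track_inner = FALSE) {
  if (lambda_pep < 0 || lambda_prot < 0) abort("ridge parameters must be nonnegative")
  if (tol <= 0) abort("tol must be positive")
  validate_quant_matrix(quant)
  pheno <- validate_phenotype_loose(pheno, covariates)
  aligned <- align_samples(quant, pheno)
  y <- aligned$pheno$response
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    abort("need at least 2 samples in each response class")
  }

  std <- standardize_fit(aligned$quant)
  X_all <- standardize_apply(std, aligned$quant)
  hi <- hierarchy_index(hierarchy, colnames(X_all))
  X <- X_all[, hi$hierarchy$peptide_id, drop = FALSE]
  std <- std[match(hi$hierarchy$peptide_id, std$peptide_id), , drop = FALSE]
  A <- if (length(covariates)) as.matrix(aligned$pheno[covariates]) else NULL

  eng <- hiscom_engine(X, y, A, hi$pidx, hi$K, lambda_pep, lambda_prot,
                       penalize_intercept, penalize_covariates,
                       tol, max_outer, max_inner, track_inner)

  F_full <- cbind(1, eng$F_mat)
  colnames(F_full) <- c("(Intercept)", hi$proteins)
  rownames(F_full) <- aligned$quant$sample_id
  fit <- list(
    w = stats::setNames(eng$w, hi$hierarchy$peptide_id),
    beta = stats::setNames(c(eng$beta0, eng$betaK), c("(Intercept)", hi$proteins)),
    gamma = stats::setNames(eng$gamma, covariates),
    F = F_full,
    standardizer = std,
    hierarchy = hi$hierarchy,
    config = list(lambda_pep = lambda_pep, lambda_prot = lambda_prot,
                  penalize_intercept = penalize_intercept,
                  penalize_covariates = penalize_covariates,
                  covariates = covariates, tol = tol,
                  max_outer = max_outer, max_inner = max_inner),
    objective = eng$objective,
    objective_trace = eng$objective_trace,
    inner_trace = eng$inner_trace,
    converged = eng$converged,
    n_iter = eng$n_iter,
    sample_ids = aligned$quant$sample_id,
    response = y
  )
  class(fit) <- "hiscom_fit"
  fit
}

# phenotype validation that tolerates absent covariate columns not in use
validate_phenotype_loose <- function(pheno, covariates) {
  need <- c("sample_id", "response", covariates)
  if (!is.data.frame(pheno) || !all(need %in% names(pheno))) {
    abort(paste0("phenotype must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(pheno$sample_id)) abort("duplicated sample_id in phenotype")
  if (!all(pheno$response %in% c(0, 1))) abort("response must be 0 or 1")
  tibble::as_tibble(pheno)
}

align_samples <- function(quant, pheno) {
  missing_s <- setdiff(quant$sample_id, pheno$sample_id)
  if (length(missing_s)) {
    abort(paste0("sample(s) absent from phenotype: ",
                 paste(head(missing_s, 5), collapse = ", ")))
  }
  list(quant = quant,
       pheno = pheno[match(quant$sample_id, pheno$sample_id), , drop = FALSE])
}

#' Predicted response probabilities from a fitted model
#'
#' Applies the training standardizer to new peptide data, forms component
#' scores with the fitted weights, and evaluates
#' `logit(pi) = beta_0 + sum_k f_k beta_k + covariates`.
#'
#' @param object A `hiscom_fit`.
#' @param quant New quant tibble; must contain every training peptide.
#' @param pheno Phenotype tibble carrying the model's covariate columns
#'   (required when the fit uses covariates; `response` is not needed).
#' @param type `"response"` for probabilities, `"link"` for the linear
#'   predictor.
#' @param ... Unused.
#' @return A tibble with columns `sample_id` and `.pred` (probability) or
#'   `.link`.
#' @export
predict.hiscom_fit <- function(object, quant, pheno = NULL,
                               type = c("response", "link"), ...) {
  type <- match.arg(type)
  validate_quant_matrix(quant)
  X <- standardize_apply(object$standardizer, quant)
  F_mat <- compute_component_scores(X, object$hierarchy, object$w)
  eta <- drop(object$beta[1] + F_mat %*% object$beta[-1])
  covs <- names(object$gamma)
  if (length(covs)) {
    if (is.null(pheno) || !all(covs %in% names(pheno))) {
      abort(paste0("missing covariates: prediction needs pheno columns ",
                   paste(covs, collapse = ", ")))
    }
    ph <- pheno[match(quant$sample_id, pheno$sample_id), , drop = FALSE]
    if (anyNA(ph$sample_id)) abort("pheno lacks rows for some samples")
    eta <- eta + drop(as.matrix(ph[covs]) %*% object$gamma)
  }
  eta <- unname(eta)
  if (type == "link") {
    tibble::tibble(sample_id = quant$sample_id, .link = eta)
  } else {
    tibble::tibble(sample_id = quant$sample_id, .pred = plogis(eta))
  }
}

#' @export
print.hiscom_fit <- function(x, ...) {
  K <- length(x$beta) - 1
  cat("Hierarchical structural component model fit\n")
  cat(sprintf("  %d peptides in %d proteins, %d samples\n",
              length(x$w), K, length(x$sample_ids)))
  cat(sprintf("  lambda_pep = %g, lambda_prot = %g\n",
              x$config$lambda_pep, x$config$lambda_prot))
  cat(sprintf("  penalized log-likelihood %.4f after %d IRLS iterations (%s)\n",
              x$objective_trace[length(x$objective_trace)], x$n_iter,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}
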