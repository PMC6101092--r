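# Data splits, AUC, logistic baselines and the model-comparison harness.

round_half_away <- function(x) floor(x + 0.5) # positive arguments only

#' Stratified test split
#'
#' Removes `test_n` samples as a held-out test set while preserving the
#' positive:negative response ratio: positives receive
#' `round(test_n * n_pos / n)` slots (half rounded away from zero),
#' negatives the remainder; members are drawn uniformly without replacement
#' within class. With 115 samples (40 positive / 75 negative) and
#' `test_n = 39` the test set always holds 14 positives and 25 negatives.
#'
#' @param pheno Phenotype tibble with `sample_id` and binary `response`.
#' @param test_n Number of test samples.
#' @param seed Integer seed controlling membership (class counts do not
#'   depend on it).
#' @return A tibble with columns `sample_id`, `response`, `partition`
#'   (`"test"` or `"rest"`).
#' @export
stratified_test_split <- function(pheno, test_n, seed = NULL) {
  stopifnot(is.data.frame(pheno), all(c("sample_id", "response") %in% names(pheno)))
  n <- nrow(pheno)
  if (test_n >= n) abort("test_n must leave at least one non-test sample")
  n_pos <- sum(pheno$response == 1)
  n_neg <- n - n_pos
  if (n_pos == 0 || n_neg == 0) abort("both response classes must be present")
  pos_test <- round_half_away(test_n * n_pos / n)
  neg_test <- test_n - pos_test
  if (pos_test < 1 || neg_test < 1) {
    abort("a class would receive 0 test samples; adjust test_n")
  }
  if (pos_test > n_pos || neg_test > n_neg) {
    abort("test allocation exceeds a class size")
  }
  draw <- function() {
    pos_ids <- pheno$sample_id[pheno$response == 1]
    neg_ids <- pheno$sample_id[pheno$response == 0]
    test_ids <- c(sample(pos_ids, pos_test), sample(neg_ids, neg_test))
    tibble::tibble(sample_id = pheno$sample_id,
                   response = as.integer(pheno$response),
                   partition = ifelse(pheno$sample_id %in% test_ids,
                                      "test", "rest"))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Ratio-preserving train/validation halving
#'
#' Splits a sample set into training and validation halves of equal size per
#' response class (an odd class count sends the extra sample to one half at
#' random). With 76 samples (26 positive / 50 negative) each half holds 13
#' positives and 25 negatives.
#'
#' @param pheno Phenotype tibble (typically the `"rest"` partition of
#'   [stratified_test_split()]).
#' @param seed Integer seed.
#' @return A tibble with columns `sample_id`, `response`, `partition`
#'   (`"train"` or `"validation"`).
#' @export
train_validation_split <- function(pheno, seed = NULL) {
  stopifnot(is.data.frame(pheno), all(c("sample_id", "response") %in% names(pheno)))
  counts <- table(factor(pheno$response, levels = c(0, 1)))
  if (any(counts < 2)) abort("each response class needs at least 2 samples to halve")
  draw <- function() {
    train_ids <- unlist(lapply(c(0, 1), function(cl) {
      ids <- pheno$sample_id[pheno$response == cl]
      n_cl <- length(ids)
      n_train <- floor(n_cl / 2) + (n_cl %% 2) * stats::rbinom(1, 1, 0.5)
      sample(ids, n_train)
    }))
    tibble::tibble(sample_id = pheno$sample_id,
                   response = as.integer(pheno$response),
                   partition = ifelse(pheno$sample_id %in% train_ids,
                                      "train", "validation"))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Full train/validation/test split plan
#'
#' Convenience wrapper: a stratified test split followed by a
#' ratio-preserving halving of the remainder.
#'
#' @param pheno Phenotype tibble.
#' @param test_n Test-set size.
#' @param seed Integer seed (both stages derive from it).
#' @return A tibble with columns `sample_id`, `response`, `partition`
#'   (`"test"`, `"train"` or `"validation"`).
#' @export
split_plan <- function(pheno, test_n, seed = NULL) {
  run <- function() {
    s1 <- stratified_test_split(pheno, test_n)
    rest <- pheno[pheno$sample_id %in% s1$sample_id[s1$partition == "rest"], ,
                  drop = FALSE]
    s2 <- train_validation_split(rest)
    dplyr::bind_rows(
      s1[s1$partition == "test", c("sample_id", "response", "partition")],
      s2
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Area under the ROC curve
#'
#' The Mann-Whitney form: the proportion of (positive, negative) score pairs
#' where the positive outscores the negative, ties counting one half.
#' Computed via midranks, which is algebraically identical to pair
#' enumeration.
#'
#' @param scores Numeric score vector (higher means more positive-like).
#' @param labels Binary labels (0/1), same length.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- as.numeric(sum(labels == 1))
  n0 <- as.numeric(sum(labels == 0))
  if (n1 == 0 || n0 == 0) abort("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

glm_design <- function(quant, pheno, covariates) {
  validate_quant_matrix(quant)
  ph <- pheno[match(quant$sample_id, pheno$sample_id), , drop = FALSE]
  if (anyNA(ph$sample_id)) abort("pheno lacks rows for some samples")
  X <- as.matrix(quant[-1])
  A <- if (length(covariates)) as.matrix(ph[covariates]) else NULL
  M <- cbind(`(Intercept)` = 1, X, A)
  list(M = M, pheno = ph, peptides = colnames(X))
}

#' Unpenalized logistic baseline on raw peptide columns
#'
#' Ordinary logistic regression (IRLS via `stats::glm.fit`) of the response
#' on all peptide columns plus covariates — no hierarchy, no penalty. With
#' highly correlated peptides this model can fail to converge or be
#' singular; that state is reported, not fatal, and aliased coefficients are
#' set to zero for prediction.
#'
#' @param quant Quant tibble (peptide columns used as-is).
#' @param pheno Phenotype tibble with `response` and the covariate columns.
#' @param covariates Covariate columns to include (default age and sex).
#' @return A `glm_baseline` object with named `coefficients`, a `converged`
#'   flag, and a `singular` flag.
#' @export
fit_glm <- function(quant, pheno, covariates = c("age", "sex")) {
  d <- glm_design(quant, pheno, covariates)
  y <- d$pheno$response
  fit <- suppressWarnings(stats::glm.fit(d$M, y, family = stats::binomial()))
  cf <- fit$coefficients
  singular <- anyNA(cf)
  cf[is.na(cf)] <- 0
  converged <- isTRUE(fit$converged) && !singular && max(abs(cf)) < 1e6
  structure(list(coefficients = stats::setNames(cf, colnames(d$M)),
                 converged = converged, singular = singular,
                 lambda = 0, method = "GLM",
                 peptides = d$peptides, covariates = covariates),
            class = "glm_baseline")
}

#' Ridge-penalized logistic baseline on raw peptide columns
#'
#' Maximizes the Bernoulli log-likelihood minus `lambda/2` times the sum of
#' squared peptide coefficients (intercept and covariates unpenalized) by
#' Newton/IRLS with a ridge-augmented working system.
#'
#' @inheritParams fit_glm
#' @param lambda Nonnegative ridge parameter.
#' @param tol Convergence tolerance on the coefficient max-change.
#' @param max_iter Iteration cap.
#' @return A `glm_baseline` object.
#' @export
fit_glm_ridge <- function(quant, pheno, lambda, covariates = c("age", "sex"),
                          tol = 1e-10, max_iter = 200L) {
  if (lambda < 0) abort("lambda must be nonnegative")
  d <- glm_design(quant, pheno, covariates)
  y <- d$pheno$response
  M <- d$M
  maskvec <- c(0, rep(1, length(d$peptides)), rep(0, length(covariates)))
  b <- rep(0, ncol(M))
  b[1] <- qlogis(mean(pmin(pmax(y, 0.05), 0.95)))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(M %*% b)
    mu <- pmin(pmax(plogis(eta), MU_EPS), 1 - MU_EPS)
    v <- mu * (1 - mu)
    z <- eta + (y - mu) / v
    b_new <- tryCatch(wls_ridge_solve(M, z, v, lambda, maskvec),
                      error = function(e) NULL)
    if (is.null(b_new)) break
    if (max(abs(b_new - b)) < tol * (1 + max(abs(b)))) {
      b <- b_new
      converged <- TRUE
      break
    }
    b <- b_new
  }
  structure(list(coefficients = stats::setNames(b, colnames(M)),
                 converged = converged && max(abs(b)) < 1e6,
                 singular = FALSE,
                 lambda = lambda, method = "GLMwR",
                 peptides = d$peptides, covariates = covariates),
            class = "glm_baseline")
}

#' @export
predict.glm_baseline <- function(object, quant, pheno = NULL,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  validate_quant_matrix(quant)
  missing_p <- setdiff(object$peptides, names(quant))
  if (length(missing_p)) {
    abort(paste0("quant matrix lacks peptide(s): ",
                 paste(head(missing_p, 5), collapse = ", ")))
  }
  X <- as.matrix(quant[object$peptides])
  eta <- object$coefficients[1] + drop(X %*% object$coefficients[object$peptides])
  if (length(object$covariates)) {
    if (is.null(pheno)) abort("missing covariates: supply pheno")
    ph <- pheno[match(quant$sample_id, pheno$sample_id), , drop = FALSE]
    eta <- eta + drop(as.matrix(ph[object$covariates]) %*%
                        object$coefficients[object$covariates])
  }
  eta <- unname(eta)
  if (type == "link") {
    tibble::tibble(sample_id = quant$sample_id, .link = eta)
  } else {
    tibble::tibble(sample_id = quant$sample_id, .pred = plogis(eta))
  }
}

#' @export
print.glm_baseline <- function(x, ...) {
  cat(sprintf("%s logistic baseline: %d peptides%s, %s\n",
              x$method, length(x$peptides),
              if (x$lambda > 0) sprintf(", lambda = %g", x$lambda) else "",
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

standardized_quant <- function(std, quant) {
  X <- standardize_apply(std, quant)
  out <- tibble::tibble(sample_id = quant$sample_id)
  out[colnames(X)] <- as.data.frame(X)
  out
}

#' Compare the component model against logistic baselines on one split
#'
#' Restricts the data to the peptides of a protein subset, fits the
#' hierarchical component model, unpenalized logistic regression (GLM) and
#' ridge logistic regression (GLMwR) on the training partition, and reports
#' each method's AUC on the requested partition. Peptides are standardized
#' with training statistics for every method. The GLMwR ridge parameter is
#' chosen by validation-partition AUC over `glmwr_grid` unless a fixed value
#' is given.
#'
#' @param quant,pheno,hierarchy The cohort tables.
#' @param split A split tibble (`sample_id`, `partition`) from
#'   [split_plan()] or the two split functions.
#' @param protein_subset Character vector of proteins to use (all mapped
#'   proteins if `NULL`).
#' @param lambda_pep,lambda_prot Component-model ridge parameters.
#' @param glmwr_lambda Fixed ridge value for GLMwR, or `"auto"` to grid
#'   search by validation AUC.
#' @param glmwr_grid Candidate ridge values for the grid search.
#' @param partition Partition to score: `"validation"` or `"test"`.
#' @param covariates Covariate columns used by every method.
#' @return A tibble with columns `method`, `partition`, `protein_set`,
#'   `auc`, `converged`.
#' @export
compare_models <- function(quant, pheno, hierarchy, split,
                           protein_subset = NULL,
                           lambda_pep = 10, lambda_prot = 10,
                           glmwr_lambda = "auto",
                           glmwr_grid = c(0.01, 0.1, 1, 10, 100),
                           partition = c("validation", "test"),
                           covariates = c("age", "sex")) {
  partition <- match.arg(partition)
  h <- validate_hierarchy(hierarchy)
  if (is.null(protein_subset)) protein_subset <- unique(h$protein_id)
  if (length(protein_subset) == 0) abort("protein_subset must not be empty")
  unknown <- setdiff(protein_subset, h$protein_id)
  if (length(unknown)) {
    abort(paste0("unknown protein(s): ", paste(unknown, collapse = ", ")))
  }
  h_sub <- h[h$protein_id %in% protein_subset, , drop = FALSE]
  peps <- intersect(names(quant)[-1], h_sub$peptide_id)
  if (length(peps) == 0) abort("no quant peptides map to the requested proteins")
  q_sub <- quant[c("sample_id", peps)]

  part_of <- function(name) split$sample_id[split$partition == name]
  take <- function(tbl, ids) tbl[match(ids, tbl$sample_id), , drop = FALSE]
  train_ids <- part_of("train")
  eval_ids <- part_of(partition)
  if (length(train_ids) == 0 || length(eval_ids) == 0) {
    abort("split lacks train or requested evaluation partition")
  }
  q_train <- take(q_sub, train_ids); ph_train <- take(pheno, train_ids)
  q_eval <- take(q_sub, eval_ids); ph_eval <- take(pheno, eval_ids)

  std <- standardize_fit(q_train)
  sq_train <- standardized_quant(std, q_train)
  sq_eval <- standardized_quant(std, q_eval)

  score_auc <- function(pred_tbl, ph) auc(pred_tbl$.pred, ph$response)

  fit_h <- hiscom(q_train, ph_train, h_sub, lambda_pep = lambda_pep,
                  lambda_prot = lambda_prot, covariates = covariates)
  auc_h <- score_auc(predict(fit_h, q_eval, ph_eval), ph_eval)

  fit_g <- fit_glm(sq_train, ph_train, covariates = covariates)
  auc_g <- score_auc(predict(fit_g, sq_eval, ph_eval), ph_eval)

  if (identical(glmwr_lambda, "auto")) {
    val_ids <- part_of("validation")
    q_val <- take(q_sub, val_ids); ph_val <- take(pheno, val_ids)
    sq_val <- standardized_quant(std, q_val)
    val_auc <- vapply(glmwr_grid, function(lam) {
      f <- fit_glm_ridge(sq_train, ph_train, lam, covariates = covariates)
      score_auc(predict(f, sq_val, ph_val), ph_val)
    }, numeric(1))
    glmwr_lambda <- glmwr_grid[which.max(val_auc)]
  }
  fit_r <- fit_glm_ridge(sq_train, ph_train, glmwr_lambda,
                         covariates = covariates)
  auc_r <- score_auc(predict(fit_r, sq_eval, ph_eval), ph_eval)

  tibble::tibble(
    method = c("HisCoM", "GLM", "GLMwR"),
    partition = partition,
    protein_set = paste(sort(protein_subset), collapse = "+"),
    auc = c(auc_h, auc_g, auc_r),
    converged = c(fit_h$converged, fit_g$converged, fit_r$converged)
  )
}
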