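# Independent oracles used across the suite. These re-derive the model
# objective and reference quantities from scratch (dbinom, pair enumeration,
# exhaustive permutation) so they share no code with the implementation
# paths they check.

# Penalized Bernoulli log-likelihood evaluated from a flat parameter vector
# par = (w_1..w_p, beta0, beta_1..beta_K, gamma_1..gamma_q).
oracle_objective <- function(par, X, y, A, pidx, K, lambda_pep, lambda_prot,
                             penalize_intercept = TRUE,
                             penalize_covariates = FALSE) {
  p <- ncol(X)
  q <- if (is.null(A)) 0L else ncol(A)
  w <- par[seq_len(p)]
  beta0 <- par[p + 1]
  betaK <- par[p + 1 + seq_len(K)]
  gam <- if (q) par[p + 1 + K + seq_len(q)] else numeric(0)
  eta <- rep(beta0, nrow(X))
  for (k in seq_len(K)) {
    idx <- which(pidx == k)
    eta <- eta + drop(X[, idx, drop = FALSE] %*% w[idx]) * betaK[k]
  }
  if (q) eta <- eta + drop(A %*% gam)
  # clamp away from 0/1 so wild random starts stay finite; exact wherever
  # |eta| is moderate, in particular at the optimum
  pr <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  ll <- sum(stats::dbinom(y, 1, pr, log = TRUE))
  ll - 0.5 * lambda_pep * sum(w^2) -
    0.5 * lambda_prot * (sum(betaK^2) +
                           (if (penalize_intercept) beta0^2 else 0) +
                           (if (penalize_covariates) sum(gam^2) else 0))
}

oracle_gradient <- function(par, X, y, A, pidx, K, lambda_pep, lambda_prot,
                            penalize_intercept = TRUE,
                            penalize_covariates = FALSE) {
  p <- ncol(X)
  q <- if (is.null(A)) 0L else ncol(A)
  w <- par[seq_len(p)]
  beta0 <- par[p + 1]
  betaK <- par[p + 1 + seq_len(K)]
  gam <- if (q) par[p + 1 + K + seq_len(q)] else numeric(0)
  F_mat <- sapply(seq_len(K), function(k) {
    idx <- which(pidx == k)
    drop(X[, idx, drop = FALSE] %*% w[idx])
  })
  eta <- beta0 + drop(F_mat %*% betaK)
  if (q) eta <- eta + drop(A %*% gam)
  e <- y - stats::plogis(eta)
  gw <- vapply(seq_len(p), function(i) {
    betaK[pidx[i]] * sum(X[, i] * e) - lambda_pep * w[i]
  }, numeric(1))
  g0 <- sum(e) - (if (penalize_intercept) lambda_prot * beta0 else 0)
  gb <- drop(crossprod(F_mat, e)) - lambda_prot * betaK
  gg <- if (q) drop(crossprod(A, e)) -
    (if (penalize_covariates) lambda_prot * gam else 0) else numeric(0)
  c(gw, g0, gb, gg)
}

# Multi-start BFGS maximizer of the oracle objective; returns the best value
# and the maximizing parameters.
oracle_maximize <- function(X, y, A, pidx, K, lambda_pep, lambda_prot,
                            penalize_intercept = TRUE,
                            penalize_covariates = FALSE,
                            n_starts = 5, seed = 1) {
  p <- ncol(X)
  q <- if (is.null(A)) 0L else ncol(A)
  npar <- p + 1 + K + q
  best <- NULL
  withr::with_seed(seed, {
    for (s in seq_len(n_starts)) {
      par0 <- if (s == 1) rep(0, npar) else stats::rnorm(npar, sd = 0.3)
      fit <- stats::optim(par0, fn = oracle_objective, gr = oracle_gradient,
                          X = X, y = y, A = A, pidx = pidx, K = K,
                          lambda_pep = lambda_pep, lambda_prot = lambda_prot,
                          penalize_intercept = penalize_intercept,
                          penalize_covariates = penalize_covariates,
                          method = "BFGS",
                          control = list(fnscale = -1, maxit = 2000,
                                         reltol = 1e-14))
      if (is.null(best) || fit$value > best$value) best <- fit
    }
  })
  best
}

# Random small test instance with hierarchy c(2, 3)-style block sizes,
# correlated within-protein peptides, and a signal-bearing response.
# Returns both matrix-level pieces (for oracles) and tibbles (for the API).
random_instance <- function(N, sizes = c(2, 3), rho = 0.5, seed = 1,
                            with_covariates = TRUE, signal = 1) {
  withr::with_seed(seed, {
    K <- length(sizes)
    p <- sum(sizes)
    pidx <- rep(seq_len(K), sizes)
    Sigma <- outer(pidx, pidx, function(a, b) ifelse(a == b, rho, 0))
    diag(Sigma) <- 1
    X <- MASS::mvrnorm(N, rep(0, p), Sigma)
    colnames(X) <- paste0("pep", seq_len(p))
    A <- if (with_covariates) {
      cbind(age = stats::runif(N, 34, 84), sex = stats::rbinom(N, 1, 0.85))
    } else NULL
    eta <- signal * rowSums(X[, pidx == 1, drop = FALSE]) / sqrt(sizes[1])
    y <- stats::rbinom(N, 1, stats::plogis(eta))
    # ensure both classes have at least two members
    if (sum(y) < 2) y[sample(which(y == 0), 2)] <- 1
    if (sum(1 - y) < 2) y[sample(which(y == 1), 2)] <- 0
    hierarchy <- tibble::tibble(peptide_id = colnames(X),
                                protein_id = paste0("prot", pidx))
    quant <- tibble::tibble(sample_id = sprintf("S%03d", seq_len(N)))
    quant[colnames(X)] <- as.data.frame(X)
    pheno <- tibble::tibble(sample_id = quant$sample_id,
                            response = as.integer(y),
                            age = if (with_covariates) A[, "age"] else stats::runif(N, 34, 84),
                            sex = if (with_covariates) as.integer(A[, "sex"]) else 0L)
    list(X = X, y = y, A = A, pidx = pidx, K = K, sizes = sizes,
         quant = quant, pheno = pheno, hierarchy = hierarchy)
  })
}

# Standardize a matrix the way the package is documented to (sample sd),
# recomputed independently here for oracle use.
std_matrix <- function(X) {
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sweep(sweep(X, 2, mu, "-"), 2, sg, "/")
}

# AUC by explicit enumeration of all (positive, negative) pairs.
auc_pair_enumeration <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Monte-Carlo AUC oracle for large samples: the probability that a random
# positive outscores a random negative, estimated from one million sampled
# pairs (never via the implementation's rank formula).
auc_pair_oracle_large <- function(scores, labels, n_pairs = 1e6, seed = 99) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  withr::with_seed(seed, {
    a <- sample(pos, n_pairs, replace = TRUE)
    b <- sample(neg, n_pairs, replace = TRUE)
  })
  mean((a > b) + 0.5 * (a == b))
}
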