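# The component estimator: standardization, scores, the two closed-form
# updates, the penalized objective, the full IRLS/ALS fit and prediction.

test_that("standardization uses the sample-sd convention and is idempotent", {
  q <- tibble::tibble(sample_id = c("a", "b", "c"), pep1 = c(1, 2, 3),
                      pep2 = c(-1, 0, 4))
  std <- standardize_fit(q)
  X <- standardize_apply(std, q)
  expect_equal(X[, "pep1"], c(a = -1, b = 0, c = 1))
  q2 <- tibble::tibble(sample_id = q$sample_id, pep1 = X[, "pep1"],
                       pep2 = X[, "pep2"])
  X2 <- standardize_apply(standardize_fit(q2), q2)
  expect_equal(unname(X2), unname(X), tolerance = 1e-12)
})

test_that("constant peptide columns are rejected by name", {
  q <- tibble::tibble(sample_id = c("a", "b", "c"), flat = c(5, 5, 5))
  expect_error(standardize_fit(q), "flat")
})

test_that("standardizer applies training statistics to unseen samples", {
  inst <- random_instance(20, sizes = c(2, 2), seed = 1)
  std <- standardize_fit(inst$quant[1:10, ])
  X <- standardize_apply(std, inst$quant[11:20, ])
  # not mean zero on new data, but exactly the affine map of the raw values
  raw <- as.matrix(inst$quant[11:20, std$peptide_id])
  expect_equal(unname(X), unname(sweep(sweep(raw, 2, std$mean), 2, std$sd, "/")))
})

test_that("component scores respect the hierarchy blocks", {
  inst <- random_instance(15, sizes = c(1, 3), seed = 2)
  Xs <- std_matrix(inst$X)
  w0 <- rep(0, 4)
  expect_equal(unname(compute_component_scores(Xs, inst$hierarchy, w0)),
               matrix(0, 15, 2))
  w1 <- c(1, 0.3, -0.2, 0.5)
  F_mat <- compute_component_scores(Xs, inst$hierarchy, w1)
  # single-peptide protein with unit weight reproduces its peptide column
  expect_equal(unname(F_mat[, "prot1"]), unname(Xs[, 1]))
  expect_equal(unname(F_mat[, "prot2"]),
               unname(drop(Xs[, 2:4] %*% w1[2:4])))
})

test_that("a 231-peptide/124-protein layout yields 124 score columns", {
  coh <- simulate_cohort(n_samples = 12, n_positive = 5, seed = 3)
  Xs <- std_matrix(as.matrix(coh$quant[-1]))
  colnames(Xs) <- names(coh$quant)[-1]
  w <- rep(1, 231)
  expect_equal(dim(compute_component_scores(Xs, coh$hierarchy, w)),
               c(12L, 124L))
})

test_that("beta update solves the penalized weighted normal equations", {
  withr::with_seed(4, {
    # orthonormal design, V = I, lambda 0: plain projection
    M <- qr.Q(qr(matrix(rnorm(30), 10, 3)))
    z <- rnorm(10)
    b <- beta_update(M, z, rep(1, 10), 0, rep(TRUE, 3))
    expect_equal(b, drop(crossprod(M, z)), tolerance = 1e-10)
    # enormous penalty annihilates masked coefficients only
    F_full <- cbind(1, matrix(rnorm(20), 10, 2))
    b2 <- beta_update(F_full, z, runif(10, 0.5, 2), 1e12,
                      c(FALSE, TRUE, TRUE))
    expect_lt(max(abs(b2[2:3])), 1e-6)
    expect_gt(abs(b2[1]), 0)
  })
})

test_that("beta update matches a generic numerical quadratic minimizer", {
  F_full <- cbind(1, c(0.5, -1.2, 2.0), c(1.0, 0.3, -0.7))
  z <- c(0.8, -0.4, 1.5)
  v <- c(0.2, 1.0, 0.6)
  lambda <- 3
  mask <- c(TRUE, TRUE, FALSE)
  b <- beta_update(F_full, z, v, lambda, mask)
  obj <- function(bb) {
    sum(v * (z - drop(F_full %*% bb))^2) + lambda * sum(mask * bb^2)
  }
  num <- optim(c(0, 0, 0), obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(unname(b), num$par, tolerance = 1e-6)
  expect_lte(obj(b), num$value + 1e-10)
})

test_that("weight update handles degenerate and symmetric cases", {
  inst <- random_instance(25, sizes = c(2, 2), seed = 5)
  Xs <- std_matrix(inst$X)
  z <- rnorm(25)
  v <- runif(25, 0.1, 0.25)
  # all path coefficients zero with a positive penalty: weights vanish
  w <- weight_update(Xs, inst$hierarchy, z, v, beta = c(0, 0),
                     covariate_offset = 0, lambda_pep = 10)
  expect_equal(unname(w), rep(0, 4))
  # zero path coefficient with no penalty is unidentifiable
  expect_error(weight_update(Xs, inst$hierarchy, z, v, beta = c(0, 1),
                             covariate_offset = 0, lambda_pep = 0),
               "unidentifiable")
  # duplicated peptide columns in one protein get equal weights
  X2 <- Xs
  X2[, 2] <- X2[, 1]
  w2 <- weight_update(X2, inst$hierarchy, z, v, beta = c(0.7, -0.4),
                      covariate_offset = 0.2, lambda_pep = 5)
  expect_equal(unname(w2[1]), unname(w2[2]), tolerance = 1e-10)
})

test_that("weight update matches numerical minimization of the working objective", {
  inst <- random_instance(12, sizes = c(2, 3), seed = 6)
  Xs <- std_matrix(inst$X)
  z <- rnorm(12)
  v <- runif(12, 0.05, 0.25)
  beta <- c(0.8, -0.5)
  offset <- 0.3
  lambda_pep <- 4
  w <- weight_update(Xs, inst$hierarchy, z, v, beta, offset, lambda_pep)
  obj <- function(ww) {
    eta <- offset +
      drop(Xs[, 1:2] %*% ww[1:2]) * beta[1] +
      drop(Xs[, 3:5] %*% ww[3:5]) * beta[2]
    sum(v * (z - eta)^2) + lambda_pep * sum(ww^2)
  }
  num <- optim(rep(0, 5), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(unname(w), num$par, tolerance = 1e-6)
  expect_lte(obj(unname(w)), num$value + 1e-10)
})

test_that("penalized objective reduces to the Bernoulli log-likelihood and is additive in penalties", {
  inst <- random_instance(20, sizes = c(2, 2), seed = 7)
  Xs <- std_matrix(inst$X)
  withr::with_seed(8, {
    w <- rnorm(4)
    beta <- rnorm(3)
    gam <- rnorm(2, sd = 0.01) # moderate: keeps eta well inside (-30, 30)
  })
  val0 <- penalized_objective(Xs, inst$y, inst$hierarchy, w, beta,
                              gamma = gam, A = inst$A,
                              lambda_pep = 0, lambda_prot = 0)
  eta <- beta[1] +
    drop(Xs[, 1:2] %*% w[1:2]) * beta[2] +
    drop(Xs[, 3:4] %*% w[3:4]) * beta[3] +
    drop(inst$A %*% gam)
  expect_equal(val0, sum(dbinom(inst$y, 1, plogis(eta), log = TRUE)),
               tolerance = 1e-10)
  val <- penalized_objective(Xs, inst$y, inst$hierarchy, w, beta,
                             gamma = gam, A = inst$A,
                             lambda_pep = 3, lambda_prot = 7)
  expect_equal(val, val0 - 0.5 * 3 * sum(w^2) -
                 0.5 * 7 * (sum(beta[-1]^2) + beta[1]^2),
               tolerance = 1e-10)
  # matches the independent oracle evaluation term by term
  expect_equal(val, oracle_objective(c(w, beta, gam), Xs, inst$y, inst$A,
                                     inst$pidx, 2, 3, 7),
               tolerance = 1e-10)
})

test_that("the fit attains the oracle optimum on a small instance", {
  inst <- random_instance(40, sizes = c(2, 3), seed = 9)
  fit <- hiscom(inst$quant, inst$pheno, inst$hierarchy,
                lambda_pep = 10, lambda_prot = 10, tol = 1e-10)
  Xs <- std_matrix(inst$X)
  par_fit <- c(unname(fit$w), unname(fit$beta), unname(fit$gamma))
  val_fit <- oracle_objective(par_fit, Xs, inst$y, inst$A, inst$pidx, 2, 10, 10)
  orc <- oracle_maximize(Xs, inst$y, inst$A, inst$pidx, 2, 10, 10, seed = 10)
  expect_lt(abs(val_fit - orc$value) / abs(orc$value), 1e-5)
})

test_that("huge penalties with a free intercept recover the base rate", {
  inst <- random_instance(60, sizes = c(2, 3), seed = 11)
  fit <- hiscom(inst$quant, inst$pheno, inst$hierarchy,
                lambda_pep = 1e8, lambda_prot = 1e8,
                penalize_intercept = FALSE, penalize_covariates = TRUE)
  pred <- predict(fit, inst$quant, inst$pheno)$.pred
  expect_true(all(abs(pred - mean(inst$y)) < 1e-3))
})

test_that("predictions are invariant to peptide and protein ordering", {
  inst <- random_instance(45, sizes = c(3, 2), seed = 12)
  fit <- hiscom(inst$quant, inst$pheno, inst$hierarchy)
  perm_cols <- c(1, sample(2:6))
  withr::with_seed(13, perm_cols <- c(1, 1 + sample(5)))
  quant_perm <- inst$quant[, perm_cols]
  hier_perm <- inst$hierarchy[rev(seq_len(nrow(inst$hierarchy))), ]
  fit2 <- hiscom(quant_perm, inst$pheno, hier_perm)
  p1 <- predict(fit, inst$quant, inst$pheno)$.pred
  p2 <- predict(fit2, quant_perm, inst$pheno)$.pred
  expect_equal(p2, p1, tolerance = 1e-10)
})

test_that("inner ALS sweeps never increase the working objective", {
  for (s in 1:8) {
    inst <- random_instance(30, sizes = c(2, 2), seed = 100 + s)
    fit <- hiscom(inst$quant, inst$pheno, inst$hierarchy, track_inner = TRUE)
    for (phi2 in fit$inner_trace) {
      expect_true(all(diff(phi2) <= 1e-8 * (abs(phi2[-length(phi2)]) + 1)))
    }
  }
})

test_that("the objective trace improves monotonically up to tolerance", {
  inst <- random_instance(50, sizes = c(3, 2), seed = 14)
  fit <- hiscom(inst$quant, inst$pheno, inst$hierarchy)
  tr <- fit$objective_trace
  expect_true(all(diff(tr) >= -1e-6 * (abs(tr[-length(tr)]) + 1)))
  expect_true(fit$converged)
})

test_that("per-protein sign convention leaves probabilities intact and weight sums nonnegative", {
  inst <- random_instance(40, sizes = c(2, 3), seed = 15)
  fit <- hiscom(inst$quant, inst$pheno, inst$hierarchy)
  td <- tidy(fit, "peptide")
  sums <- tapply(td$weight, td$protein_id, sum)
  expect_true(all(sums >= 0))
})

test_that("one-peptide-per-protein products match the product-parameterized maximizer", {
  inst <- random_instance(60, sizes = c(1, 1), seed = 16,
                          with_covariates = FALSE, signal = 1.5)
  lam <- 10
  fit <- hiscom(inst$quant, inst$pheno, inst$hierarchy,
                lambda_pep = lam, lambda_prot = lam,
                covariates = character(0), tol = 1e-10)
  prod_fit <- unname(fit$w * fit$beta[-1])
  Xs <- std_matrix(inst$X)
  # at a fixed product c = w * beta, minimizing the two ridges over the
  # split gives sqrt(lambda_pep * lambda_prot) * |c|
  obj <- function(par) {
    b0 <- par[1]; cc <- par[2:3]
    eta <- b0 + drop(Xs %*% cc)
    -(sum(dbinom(inst$y, 1, plogis(eta), log = TRUE)) -
        lam * sum(abs(cc)) - 0.5 * lam * b0^2)
  }
  num <- optim(c(0, 0.1, 0.1), obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(prod_fit, num$par[2:3], tolerance = 1e-3)
})

test_that("prediction follows the logistic formula and its monotonicity", {
  # hand-built fit: one protein, two peptides, known coefficients
  fit <- structure(list(
    w = c(pep1 = 1, pep2 = -1),
    beta = c(`(Intercept)` = 0, prot1 = 0.5),
    gamma = setNames(numeric(0), character(0)),
    standardizer = tibble::tibble(peptide_id = c("pep1", "pep2"),
                                  mean = c(0, 0), sd = c(1, 1)),
    hierarchy = tibble::tibble(peptide_id = c("pep1", "pep2"),
                               protein_id = "prot1"),
    config = list(), objective_trace = 0, converged = TRUE, n_iter = 1L
  ), class = "hiscom_fit")
  q <- tibble::tibble(sample_id = "s1", pep1 = 1, pep2 = 0)
  expect_equal(predict(fit, q)$.pred, plogis(0.5), tolerance = 1e-12)
  # all-zero coefficients give 0.5
  fit0 <- fit
  fit0$w[] <- 0
  fit0$beta[] <- 0
  expect_equal(predict(fit0, q)$.pred, 0.5)
  # raising a peptide with positive w * beta raises the probability
  q_hi <- q
  q_hi$pep1 <- 2
  expect_gt(predict(fit, q_hi)$.pred, predict(fit, q)$.pred)
})

test_that("prediction demands the training peptides and covariates", {
  inst <- random_instance(30, sizes = c(2, 2), seed = 17)
  fit <- hiscom(inst$quant, inst$pheno, inst$hierarchy)
  expect_error(predict(fit, inst$quant[, 1:3], inst$pheno), "lacks peptide")
  expect_error(predict(fit, inst$quant), "missing covariates")
})
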