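# Splits, AUC, logistic baselines and the comparison harness.

make_pheno <- function(n_pos, n_neg) {
  tibble::tibble(sample_id = sprintf("S%03d", seq_len(n_pos + n_neg)),
                 response = c(rep(1L, n_pos), rep(0L, n_neg)),
                 age = seq(34, 84, length.out = n_pos + n_neg),
                 sex = rep(c(1L, 0L), length.out = n_pos + n_neg))
}

test_that("39-of-115 stratified test split allocates 14 positives and 25 negatives", {
  ph <- make_pheno(40, 75)
  sp <- stratified_test_split(ph, 39, seed = 1)
  test <- sp[sp$partition == "test", ]
  expect_equal(nrow(test), 39L)
  expect_equal(sum(test$response == 1), 14L)
  expect_equal(sum(test$response == 0), 25L)
})

test_that("test split class counts are seed-invariant but memberships are not", {
  ph <- make_pheno(40, 75)
  s1 <- stratified_test_split(ph, 39, seed = 1)
  s2 <- stratified_test_split(ph, 39, seed = 2)
  count_pos <- function(s) sum(s$response[s$partition == "test"])
  expect_equal(count_pos(s1), count_pos(s2))
  expect_false(identical(s1$partition, s2$partition))
  # same seed reproduces memberships exactly
  expect_identical(s1, stratified_test_split(ph, 39, seed = 1))
})

test_that("degenerate test splits are rejected", {
  ph <- make_pheno(4, 4)
  expect_error(stratified_test_split(ph, 8, seed = 1), "non-test sample")
  expect_error(stratified_test_split(make_pheno(1, 40), 5, seed = 1),
               "0 test samples")
})

test_that("halving 76 samples (26/50) yields 13 positives and 25 negatives per half", {
  ph <- make_pheno(26, 50)
  sp <- train_validation_split(ph, seed = 3)
  for (part in c("train", "validation")) {
    half <- sp[sp$partition == part, ]
    expect_equal(sum(half$response == 1), 13L)
    expect_equal(sum(half$response == 0), 25L)
  }
})

test_that("odd class counts send the extra sample to a seed-determined half", {
  ph <- make_pheno(3, 4)
  sp <- train_validation_split(ph, seed = 4)
  pos_train <- sum(sp$response == 1 & sp$partition == "train")
  expect_true(pos_train %in% c(1L, 2L))
  expect_error(train_validation_split(make_pheno(1, 6), seed = 1),
               "at least 2 samples")
  tiny <- train_validation_split(make_pheno(2, 2), seed = 5)
  expect_equal(sum(tiny$partition == "train"), 2L)
})

test_that("the full split plan partitions every sample exactly once", {
  ph <- make_pheno(40, 75)
  plan <- split_plan(ph, 39, seed = 6)
  expect_setequal(plan$sample_id, ph$sample_id)
  expect_equal(sort(as.integer(table(plan$partition))), c(38L, 38L, 39L))
})

test_that("AUC agrees with explicit pair enumeration, including ties", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc(c(3, 2, 1), c(1, 1, 0)), 1.0)
  expect_equal(auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
  withr::with_seed(7, {
    for (i in 1:50) {
      n <- sample(4:12, 1)
      labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
      scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)
      expect_equal(auc(scores, labels), auc_pair_enumeration(scores, labels))
    }
  })
})

test_that("AUC is invariant under strictly increasing transforms and label swap", {
  withr::with_seed(8, {
    scores <- rnorm(30)
    labels <- rbinom(30, 1, 0.4)
    labels[1:2] <- c(0, 1)
    a <- auc(scores, labels)
    expect_equal(auc(exp(scores), labels), a)
    expect_equal(auc(qlogis(plogis(scores)), labels), a, tolerance = 1e-12)
    expect_equal(a + auc(scores, 1 - labels), 1)
  })
})

test_that("unpenalized logistic baseline matches a numerical maximizer", {
  inst <- random_instance(60, sizes = c(2, 1), seed = 9)
  fit <- fit_glm(inst$quant, inst$pheno)
  expect_true(fit$converged)
  M <- cbind(1, inst$X, inst$A)
  negll <- function(b) -sum(dbinom(inst$y, 1, plogis(drop(M %*% b)), log = TRUE))
  negll_gr <- function(b) -drop(crossprod(M, inst$y - plogis(drop(M %*% b))))
  num <- optim(rep(0, ncol(M)), negll, negll_gr, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  expect_equal(unname(fit$coefficients), num$par, tolerance = 1e-6)
})

test_that("collinear peptides flag singularity and a noise column stays near zero", {
  inst <- random_instance(50, sizes = c(2, 1), seed = 10)
  q <- inst$quant
  q$pep3 <- q$pep1 # exact duplicate column
  fit <- fit_glm(q, inst$pheno)
  expect_true(fit$singular)
  expect_false(fit$converged)
  # an independent noise column gets a small coefficient
  withr::with_seed(11, {
    inst2 <- random_instance(400, sizes = c(1, 1), seed = 12, signal = 1)
  })
  fit2 <- fit_glm(inst2$quant, inst2$pheno)
  expect_lt(abs(fit2$coefficients["pep2"]), 0.3)
})

test_that("ridge logistic baseline matches its penalized-likelihood optimum", {
  inst <- random_instance(40, sizes = c(2, 1), seed = 13)
  lam <- 5
  fit <- fit_glm_ridge(inst$quant, inst$pheno, lam)
  expect_true(fit$converged)
  M <- cbind(1, inst$X, inst$A)
  mask <- c(0, 1, 1, 1, 0, 0)
  negobj <- function(b) {
    -(sum(dbinom(inst$y, 1, plogis(drop(M %*% b)), log = TRUE)) -
        0.5 * lam * sum(mask * b^2))
  }
  negobj_gr <- function(b) {
    -(drop(crossprod(M, inst$y - plogis(drop(M %*% b)))) - lam * mask * b)
  }
  num <- optim(rep(0, ncol(M)), negobj, negobj_gr, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  expect_equal(unname(fit$coefficients), num$par, tolerance = 1e-6)
})

test_that("ridge baseline limits: lambda 0 equals the GLM, huge lambda kills peptides", {
  inst <- random_instance(60, sizes = c(2, 1), seed = 14)
  f0 <- fit_glm_ridge(inst$quant, inst$pheno, 0)
  fg <- fit_glm(inst$quant, inst$pheno)
  expect_equal(unname(f0$coefficients), unname(fg$coefficients),
               tolerance = 1e-6)
  fh <- fit_glm_ridge(inst$quant, inst$pheno, 1e10)
  expect_lt(max(abs(fh$coefficients[fh$peptides])), 1e-5)
  expect_gt(abs(fh$coefficients["age"]) + abs(fh$coefficients["sex"]), 0)
})

test_that("ridge baseline agrees with glmnet on its shared objective", {
  skip_if_not_installed("glmnet")
  inst <- random_instance(80, sizes = c(3, 2), seed = 15)
  lam <- 2
  fit <- fit_glm_ridge(inst$quant, inst$pheno, lam, covariates = character(0))
  n <- nrow(inst$X)
  gn <- glmnet::glmnet(inst$X, inst$y, family = "binomial", alpha = 0,
                       lambda = lam / n, standardize = FALSE,
                       thresh = 1e-14)
  expect_equal(unname(fit$coefficients[-1]),
               unname(as.numeric(gn$beta)), tolerance = 1e-3)
})

test_that("compare_models scores all three methods on the requested partition", {
  inst <- random_instance(90, sizes = c(3, 2), seed = 16, signal = 1.5)
  plan <- split_plan(inst$pheno, 30, seed = 17)
  res <- compare_models(inst$quant, inst$pheno, inst$hierarchy, plan,
                        protein_subset = c("prot1", "prot2"))
  expect_equal(res$method, c("HisCoM", "GLM", "GLMwR"))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  expect_true(all(res$partition == "validation"))
  # a single-protein subset runs on that protein's peptides only
  res1 <- compare_models(inst$quant, inst$pheno, inst$hierarchy, plan,
                         protein_subset = "prot1", glmwr_lambda = 10)
  expect_equal(nrow(res1), 3L)
  expect_error(compare_models(inst$quant, inst$pheno, inst$hierarchy, plan,
                              protein_subset = character(0)),
               "must not be empty")
  expect_error(compare_models(inst$quant, inst$pheno, inst$hierarchy, plan,
                              protein_subset = "nope"), "unknown protein")
})
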