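test_that("pseudobulk binning respects animals and bin size", {
  norm <- matrix(rep(1:5, 60), nrow = 5,
                 dimnames = list(paste0("g", 1:5), paste0("c", 1:60)))
  animals <- rep(c("a1", "a2"), each = 30)
  meta <- data.frame(animal = c("a1", "a2"), age_months = c(3, 21))
  pb <- make_pseudobulk(norm, rep("T", 60), animals, meta, k = 15, seed = 1)
  # 30 cells at k = 15 -> 2 bins per animal
  expect_equal(as.integer(table(pb$meta$animal)), c(2L, 2L))
  # identical cells -> pseudobulk equals the single-cell profile
  expect_equal(unname(pb$profiles[, 1]), 1:5)
  expect_equal(pb$meta$ln_age, log(pb$meta$age_months))
  # deterministic binning
  pb2 <- make_pseudobulk(norm, rep("T", 60), animals, meta, k = 15, seed = 1)
  expect_identical(pb$profiles, pb2$profiles)
  # groups below k/2 cells are dropped with a warning
  expect_warning(
    make_pseudobulk(norm[, 1:35], rep("T", 35), c(rep("a1", 30), rep("a2", 5)),
                    meta, k = 15, seed = 1),
    "dropped"
  )
})

test_that("the ridge fit matches the closed-form normal-equations oracle", {
  set.seed(12)
  n <- 25; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  for (lambda in c(0.01, 1, 100)) {
    fit <- sciduet:::.ridge_fit(X, y, lambda)
    # oracle: standardized design, beta = (Xs'Xs + lambda I)^-1 Xs'(y - ybar)
    Xs <- scale(X)
    beta_oracle <- solve(crossprod(Xs) + lambda * diag(p),
                         crossprod(Xs, y - mean(y)))
    expect_equal(fit$beta, drop(beta_oracle), tolerance = 1e-8)
    expect_equal(sciduet:::.ridge_predict(fit, X),
                 drop(Xs %*% beta_oracle) + mean(y), tolerance = 1e-8)
  }
})

test_that("the ridge path agrees with an independent solver", {
  skip_if_not_installed("glmnet")
  set.seed(13)
  n <- 60; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, 1] - 2 * X[, 2] + rnorm(n, 0, 0.1)
  lambda <- 1
  fit <- sciduet:::.ridge_fit(X, y, lambda)
  gn <- glmnet::glmnet(X, y, alpha = 0, lambda = lambda / n,
                       standardize = TRUE, thresh = 1e-14)
  pred_gn <- drop(predict(gn, X))
  expect_gt(cor(sciduet:::.ridge_predict(fit, X), pred_gn), 0.999)
})

test_that("a noiseless ln(age)-linear clock predicts held-out ages exactly", {
  ap <- simulate_age_profiles(noise_sd = 0, cells_per_animal = 20, seed = 1)
  pb <- make_pseudobulk(ap$norm, ap$cell_types, ap$animals, ap$animal_meta,
                        k = 15, seed = 1)
  ck <- fit_clock(pb, seed = 1)
  m <- ck$models[["typeA"]]
  expect_lt(max(abs(m$predictions$predicted - m$predictions$ln_age)), 1e-6)
  # stratification: no animal in both train and test
  meta <- pb$meta
  tr_animals <- meta$animal[match(m$train, meta$pseudobulk)]
  te_animals <- meta$animal[match(m$test, meta$pseudobulk)]
  expect_length(intersect(tr_animals, te_animals), 0)
})

test_that("age-independent expression yields near-zero predictive power", {
  set.seed(14)
  ap <- simulate_age_profiles(n_slope_genes = 0, noise_sd = 0.3,
                              cells_per_animal = 30, seed = 2)
  pb <- make_pseudobulk(ap$norm, ap$cell_types, ap$animals, ap$animal_meta,
                        k = 15, seed = 1)
  ck <- fit_clock(pb, seed = 1)
  m <- ck$models[["typeA"]]
  # predictions hug the training mean; R^2 around zero
  expect_lt(m$r2, 0.3)
  expect_lt(sd(m$predictions$predicted), 0.35)
})

test_that("accelerated samples show positive mean age acceleration", {
  ap <- simulate_age_profiles(noise_sd = 0.2, n_accel = 3,
                              acceleration_factor = 2, seed = 3)
  pb <- make_pseudobulk(ap$norm, ap$cell_types, ap$animals, ap$animal_meta,
                        k = 15, seed = 1)
  ck <- fit_clock(pb, seed = 1, train_conditions = "WT")
  m <- ck$models[["typeA"]]
  acc <- pb$meta$pseudobulk[pb$meta$condition == "AD"]
  expect_length(intersect(m$train, acc), 0)     # never trained on queries
  aa <- age_acceleration(m, pb$profiles[, acc, drop = FALSE],
                         pb$meta$ln_age[match(acc, pb$meta$pseudobulk)])
  expect_gt(mean(aa$delta), 0)
  # accelerated samples read older than held-out wild-type ones
  wt <- age_acceleration(m, pb$profiles[, m$test, drop = FALSE],
                         pb$meta$ln_age[match(m$test, pb$meta$pseudobulk)])
  expect_gt(mean(aa$delta), mean(wt$delta))
  # invariant to gene-order permutation
  set.seed(4)
  perm <- sample(nrow(pb$profiles))
  aa2 <- age_acceleration(m, pb$profiles[perm, acc, drop = FALSE],
                          pb$meta$ln_age[match(acc, pb$meta$pseudobulk)])
  expect_equal(aa2$delta, aa$delta, tolerance = 1e-10)
})

test_that("clock models survive the JSON round trip", {
  ap <- simulate_age_profiles(noise_sd = 0.1, cells_per_animal = 20, seed = 5)
  pb <- make_pseudobulk(ap$norm, ap$cell_types, ap$animals, ap$animal_meta,
                        k = 15, seed = 1)
  m <- fit_clock(pb, seed = 1)$models[["typeA"]]
  path <- withr::local_tempfile(fileext = ".json")
  write_clock_model(m, path)
  back <- read_clock_model(path)
  expect_equal(back$fit$beta, unname(m$fit$beta), tolerance = 1e-12)
  pred_a <- sciduet:::.ridge_predict(m$fit, t(pb$profiles[, 1:3]))
  pred_b <- sciduet:::.ridge_predict(back$fit, t(pb$profiles[, 1:3]))
  expect_equal(unname(pred_a), unname(pred_b), tolerance = 1e-10)
})
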