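#' Build pseudobulk profiles for the aging clock
#'
#' Within each (animal, cell type), cells are shuffled and split into
#' random bins of about \code{k} cells (protocol: ~15); each bin is
#' averaged on the normalized expression scale and labelled with the
#' animal's ln(age). Bins never span animals, so no pseudobulk mixes
#' ages. Groups with fewer than k/2 cells are dropped with a warning.
#'
#' @param norm features x cells normalized matrix.
#' @param cell_types cell-type label per cell.
#' @param animals animal identifier per cell.
#' @param animal_meta data.frame with columns \code{animal},
#'   \code{age_months} (and optionally \code{condition}).
#' @param k target bin size.
#' @param seed RNG seed for the binning.
#' @return list: \code{profiles} (features x pseudobulks),
#'   \code{meta} (data.frame: pseudobulk, cell_type, animal, age_months,
#'   ln_age, n_cells, condition if supplied).
#' @export
make_pseudobulk <- function(norm, cell_types, animals, animal_meta,
                            k = 15L, seed = 1L) {
  stopifnot(ncol(norm) == length(cell_types), ncol(norm) == length(animals))
  am <- match(animals, animal_meta$animal)
  if (anyNA(am)) stop("animal(s) without metadata: ",
                      paste(unique(animals[is.na(am)]), collapse = ", "))
  set.seed(seed)
  groups <- split(seq_len(ncol(norm)), list(animal = animals, ct = cell_types),
                  drop = TRUE)
  profiles <- list()
  meta <- list()
  dropped <- 0L
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    if (length(idx) < k / 2) {
      dropped <- dropped + 1L
      next
    }
    idx <- sample(idx)
    n_bins <- max(1L, round(length(idx) / k))
    bins <- split(idx, rep(seq_len(n_bins), length.out = length(idx)))
    animal <- animals[idx[1L]]
    ct <- cell_types[idx[1L]]
    age <- animal_meta$age_months[match(animal, animal_meta$animal)]
    for (b in seq_along(bins)) {
      prof <- rowMeans(as.matrix(norm[, bins[[b]], drop = FALSE]))
      pid <- paste(ct, animal, b, sep = "|")
      profiles[[pid]] <- prof
      meta[[pid]] <- data.frame(
        pseudobulk = pid, cell_type = ct, animal = animal,
        age_months = age, ln_age = log(age), n_cells = length(bins[[b]]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (dropped) warning(dropped, " (animal, cell type) group(s) below k/2 cells dropped")
  if (!length(profiles)) stop("no pseudobulk profiles could be formed")
  meta <- do.call(rbind, meta)
  if ("condition" %in% names(animal_meta)) {
    meta$condition <- animal_meta$condition[match(meta$animal, animal_meta$animal)]
  }
  rownames(meta) <- NULL
  list(profiles = do.call(cbind, profiles), meta = meta)
}

# exact ridge fit via SVD on standardized features; returns a predictor
.ridge_fit <- function(X, y, lambda) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, `/`)
  ybar <- mean(y)
  sv <- svd(Xs)
  d <- sv$d
  # beta = V diag(d/(d^2+lambda)) U' (y - ybar)
  beta <- sv$v %*% ((d / (d^2 + lambda)) * crossprod(sv$u, y - ybar))
  list(beta = drop(beta), intercept = ybar, mu = mu, sd = sdv, lambda = lambda)
}

.ridge_predict <- function(fit, X) {
  Xs <- sweep(sweep(X, 2L, fit$mu), 2L, fit$sd, `/`)
  drop(Xs %*% fit$beta) + fit$intercept
}

#' Fit per-cell-type transcriptomic aging clocks
#'
#' For each cell type, ridge regression of ln(age) on standardized
#' pseudobulk expression. Pseudobulks are split 80/20 with the split
#' stratified by animal — no animal contributes to both train and test,
#' which prevents within-animal leakage. The ridge penalty is chosen by
#' 5-fold cross-validation on the training set over a logarithmic grid.
#' Cell types observed at fewer than three distinct ages are skipped.
#'
#' @param pb result of \code{\link{make_pseudobulk}}.
#' @param train_frac fraction of pseudobulks targeted for training
#'   (default 0.8).
#' @param lambda_grid penalty grid for cross-validation.
#' @param seed RNG seed (split and CV folds).
#' @param train_conditions optional: restrict training to animals whose
#'   \code{condition} is in this set (e.g. wild-type only); others are
#'   predicted but never trained on.
#' @return list of class \code{clock_model_set}: per cell type a list with
#'   \code{fit} (coefficients, intercept, penalty), \code{train}
#'   (pseudobulk ids), \code{test}, \code{predictions} (held-out
#'   data.frame: pseudobulk, ln_age, predicted), \code{r2} (held-out);
#'   plus \code{skipped}.
#' @export
fit_clock <- function(pb, train_frac = 0.8,
                      lambda_grid = 10^seq(-8, 4, length.out = 25),
                      seed = 1L, train_conditions = NULL) {
  meta <- pb$meta
  X_all <- t(pb$profiles)                  # pseudobulks x features
  out <- list()
  skipped <- character()
  for (ct in unique(meta$cell_type)) {
    rows <- which(meta$cell_type == ct)
    m <- meta[rows, , drop = FALSE]
    eligible <- if (!is.null(train_conditions) && "condition" %in% names(m)) {
      m$condition %in% train_conditions
    } else rep(TRUE, nrow(m))
    if (length(unique(m$age_months[eligible])) < 3L) {
      skipped <- c(skipped, ct)
      next
    }
    set.seed(seed)
    train_animals <- .split_animals(m[eligible, , drop = FALSE], train_frac)
    is_train <- eligible & m$animal %in% train_animals
    X <- X_all[rows, , drop = FALSE]
    Xtr <- X[is_train, , drop = FALSE]
    ytr <- m$ln_age[is_train]
    lambda <- .cv_lambda(Xtr, ytr, lambda_grid, seed = seed)
    fit <- .ridge_fit(Xtr, ytr, lambda)
    is_test <- !is_train
    pred <- .ridge_predict(fit, X[is_test, , drop = FALSE])
    truth <- m$ln_age[is_test]
    r2 <- 1 - sum((truth - pred)^2) / sum((truth - mean(ytr))^2)
    out[[ct]] <- list(
      cell_type = ct, fit = fit,
      features = rownames(pb$profiles),
      train = m$pseudobulk[is_train], test = m$pseudobulk[is_test],
      predictions = data.frame(pseudobulk = m$pseudobulk[is_test],
                               animal = m$animal[is_test],
                               ln_age = truth, predicted = pred,
                               stringsAsFactors = FALSE),
      r2 = r2
    )
  }
  structure(list(models = out, skipped = skipped), class = "clock_model_set")
}

# pick animals for training so roughly train_frac of pseudobulks per age
# are covered; every age keeps at least one test animal when it has >= 2
.split_animals <- function(m, train_frac) {
  train <- character()
  for (age in unique(m$age_months)) {
    ma <- m[m$age_months == age, , drop = FALSE]
    per_animal <- table(ma$animal)
    animals <- sample(names(per_animal))
    target <- train_frac * nrow(ma)
    got <- 0
    take <- character()
    for (a in animals) {
      take <- c(take, a)
      got <- got + per_animal[[a]]
      if (got >= target) break
    }
    # leave at least one animal of this age for the test set when possible
    if (length(take) == length(animals) && length(animals) > 1L) {
      take <- take[-length(take)]
    }
    train <- c(train, take)
  }
  train
}

.cv_lambda <- function(X, y, grid, nfold = 5L, seed = 1L) {
  set.seed(seed)
  n <- nrow(X)
  folds <- sample(rep(seq_len(min(nfold, n)), length.out = n))
  err <- vapply(grid, function(l) {
    se <- 0
    for (f in unique(folds)) {
      tr <- folds != f
      fit <- .ridge_fit(X[tr, , drop = FALSE], y[tr], l)
      pred <- .ridge_predict(fit, X[!tr, , drop = FALSE])
      se <- se + sum((y[!tr] - pred)^2)
    }
    se
  }, 0)
  grid[which.min(err)]
}

#' @export
print.clock_model_set <- function(x, ...) {
  cat("<clock_model_set>", length(x$models), "cell-type clock(s)\n")
  for (m in x$models) {
    cat(sprintf("  %s: lambda %.2g, held-out R^2 %.3f (%d train / %d test)\n",
                m$cell_type, m$fit$lambda, m$r2, length(m$train),
                length(m$test)))
  }
  invisible(x)
}

#' Transcriptomic age acceleration
#'
#' Predicted minus chronological ln(age) for query pseudobulks scored by a
#' trained clock; positive values mean an older-than-expected profile.
#' Query samples must not have been used in training.
#'
#' @param model one element of \code{fit_clock()$models}.
#' @param profiles features x pseudobulks matrix on the training feature
#'   set.
#' @param ln_age chronological ln(age) per pseudobulk.
#' @return data.frame: pseudobulk, ln_age, predicted, delta.
#' @export
age_acceleration <- function(model, profiles, ln_age) {
  if (!identical(rownames(profiles), model$features)) {
    m <- match(model$features, rownames(profiles))
    if (anyNA(m)) stop("query profiles lack trained feature(s): ",
                       paste(utils::head(model$features[is.na(m)], 3L),
                             collapse = ", "))
    profiles <- profiles[m, , drop = FALSE]
  }
  pred <- .ridge_predict(model$fit, t(as.matrix(profiles)))
  data.frame(pseudobulk = colnames(profiles), ln_age = ln_age,
             predicted = pred, delta = pred - ln_age,
             stringsAsFactors = FALSE)
}

#' Export / import a clock model as JSON
#' @param model one element of \code{fit_clock()$models}.
#' @param path JSON path.
#' @export
write_clock_model <- function(model, path) {
  obj <- list(cell_type = model$cell_type, features = model$features,
              beta = model$fit$beta, intercept = model$fit$intercept,
              mu = model$fit$mu, sd = model$fit$sd,
              lambda = model$fit$lambda)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_clock_model
#' @export
read_clock_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(cell_type = obj$cell_type, features = obj$features,
       fit = list(beta = obj$beta, intercept = obj$intercept,
                  mu = obj$mu, sd = obj$sd, lambda = obj$lambda))
}
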