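#' @include utils.R
NULL

FEATURE_NAMES <- c("ERP_global", "ERP_local", "HER_global", "HER_local")

# stratified k-fold assignment with seeded shuffling within class
stratifiedFolds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# linear discriminant with pooled within-class covariance and equal priors;
# ridge fallback (trace-scaled) when the pooled covariance is singular
ldaFitPredict <- function(Xtr, ytr, Xte, ridge = 1e-6) {
  classes <- sort(unique(ytr))
  fit <- tryCatch(MASS::lda(Xtr, grouping = ytr, prior = c(0.5, 0.5)),
                  error = function(e) NULL,
                  warning = function(w) NULL)   # "variables are collinear"
  if (!is.null(fit)) {
    pred <- tryCatch(as.character(stats::predict(fit, Xte)$class),
                     error = function(e) NULL)
    if (!is.null(pred)) return(list(pred = pred, ridge_used = FALSE))
  }
  # manual LDA with ridge regularisation of the pooled covariance
  mus <- lapply(classes, function(cl) colMeans(Xtr[ytr == cl, , drop = FALSE]))
  S <- Reduce(`+`, lapply(classes, function(cl) {
    Xc <- scale(Xtr[ytr == cl, , drop = FALSE], scale = FALSE)
    crossprod(Xc)
  })) / (nrow(Xtr) - length(classes))
  S <- S + diag(ridge * mean(diag(S)) + 1e-12, ncol(S))
  Sinv <- solve(S)
  scores <- vapply(seq_along(classes), function(j) {
    mu <- mus[[j]]
    as.numeric(Xte %*% Sinv %*% mu - 0.5 * sum(mu * (Sinv %*% mu)))
  }, numeric(nrow(Xte)))
  scores <- matrix(scores, nrow = nrow(Xte))
  list(pred = classes[max.col(scores)], ridge_used = TRUE)
}

#' Fivefold cross-validated linear discriminant classification
#'
#' Stratified k-fold split with seeded shuffling; per fold a linear
#' discriminant (pooled within-class covariance, equal priors) is fit on the
#' training folds and evaluated on the held-out fold. Accuracy and the
#' confusion matrix are pooled over all folds.
#'
#' @param features data.frame with a \code{label} column (two classes) and
#'   the feature columns.
#' @param subset character vector of feature columns to use.
#' @param k number of folds (default 5; must not exceed the minority class).
#' @param seed fold-shuffling seed.
#' @param folds optional precomputed fold assignment (overrides seed).
#' @param ridge ridge fallback scale for singular covariances.
#' @return list (class "herclust_classification") with feature_subset,
#'   fold_assignments, accuracy, confusion (rows true, columns predicted),
#'   seed.
#' @export
ldaCrossval <- function(features, subset = FEATURE_NAMES, k = 5, seed = 1,
                        folds = NULL, ridge = 1e-6) {
  if (!length(subset)) stop("ldaCrossval: empty feature subset")
  if (!all(subset %in% names(features)))
    stop("ldaCrossval: missing feature columns: ",
         paste(setdiff(subset, names(features)), collapse = ", "))
  y <- as.character(features$label)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("ldaCrossval: need exactly two classes")
  if (k > min(table(y))) stop("ldaCrossval: k exceeds the minority class size")
  X <- as.matrix(features[, subset, drop = FALSE])
  if (!all(is.finite(X))) stop("ldaCrossval: features must be finite")
  if (is.null(folds)) folds <- stratifiedFolds(y, k, seed)
  pred <- character(length(y))
  ridgeUsed <- FALSE
  for (f in seq_len(k)) {
    te <- folds == f
    res <- ldaFitPredict(X[!te, , drop = FALSE], y[!te], X[te, , drop = FALSE],
                         ridge = ridge)
    pred[te] <- res$pred
    ridgeUsed <- ridgeUsed || res$ridge_used
  }
  confusion <- table(factor(y, classes), factor(pred, classes))
  out <- list(feature_subset = subset, fold_assignments = folds,
              accuracy = mean(pred == y), confusion = confusion,
              seed = seed, ridge_used = ridgeUsed)
  class(out) <- "herclust_classification"
  out
}

#' Classification over all feature triads and the full quad
#'
#' Runs [ldaCrossval()] for the four possible feature triads and for all four
#' features, with identical fold assignments across subsets so the accuracies
#' are directly comparable.
#'
#' @param features data.frame with \code{label} and the four feature columns.
#' @param seed fold-shuffling seed.
#' @param k number of folds (default 5).
#' @return named list of 5 classification reports (triads keyed by the
#'   left-out feature, plus "quad").
#' @export
runAllSubsets <- function(features, seed = 1, k = 5) {
  if (!all(FEATURE_NAMES %in% names(features)))
    stop("runAllSubsets: need all four features: ", paste(FEATURE_NAMES, collapse = ", "))
  folds <- stratifiedFolds(as.character(features$label), k, seed)
  subsets <- c(lapply(FEATURE_NAMES, function(drop) setdiff(FEATURE_NAMES, drop)),
               list(FEATURE_NAMES))
  names(subsets) <- c(paste0("minus_", FEATURE_NAMES), "quad")
  lapply(subsets, function(ss) ldaCrossval(features, ss, k = k, seed = seed, folds = folds))
}

#' @export
print.herclust_classification <- function(x, ...) {
  cat(sprintf("LDA %d-fold CV [%s]: accuracy %.1f%%\n",
              max(x$fold_assignments), paste(x$feature_subset, collapse = ", "),
              100 * x$accuracy))
  print(x$confusion)
  invisible(x)
}
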