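#' Fit a sparse discriminant model (rest vs intention)
#'
#' Two-class sparse discriminant analysis by sparse optimal scoring:
#' linear discriminant analysis with a sparseness criterion, so feature
#' selection and classification happen simultaneously. The class
#' indicator scores are regressed on the features with an elastic-net
#' penalty (fixed ridge `gamma`, lasso path stopped at the feature
#' budget), and the score/coefficient iteration is repeated until the
#' coefficients stabilize. For two classes the optimal scores are unique
#' up to sign, so the iteration converges almost immediately; the loop is
#' retained for robustness. The elastic-net path is solved with glmnet on
#' ridge-augmented data; ties at the budget-th entering feature resolve
#' by path order (earlier-entering feature kept), deterministically.
#'
#' The intercept is set so that the decision threshold 0 lies midway
#' between the mean training scores of the two classes, with higher
#' scores meaning intention.
#'
#' @param X normalized windows x features matrix.
#' @param y labels, values `"rest"` / `"intention"` (factor or
#'   character).
#' @param budget feature budget K: maximum number of nonzero
#'   coefficients. Must be >= 1 and < `nrow(X)`; the cross-validation
#'   driver keeps it below the number of training trials.
#' @param gamma ridge penalty on the (normalized) features
#'   (default 1e-2).
#' @param maxit,tol score-iteration budget and tolerance on the
#'   coefficient change.
#' @return An \linkS4class{SdaModel}.
#' @export
fitSda <- function(X, y, budget, gamma = 1e-2, maxit = 30, tol = 1e-6) {
  y <- as.character(y)
  stopifnot(is.matrix(X), length(y) == nrow(X))
  classes <- c("rest", "intention")
  if (!all(y %in% classes)) stop("labels must be 'rest' or 'intention'")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (budget < 1) stop("budget must be >= 1")
  if (budget >= nrow(X))
    stop("budget must be smaller than the number of training windows")
  n <- nrow(X); p <- ncol(X)
  n1 <- sum(y == "rest"); n2 <- sum(y == "intention")

  ## optimal non-trivial class scores (theta' D theta = 1, 1' D theta = 0)
  theta <- c(rest = sqrt(n2 / n1), intention = -sqrt(n1 / n2))
  r <- theta[y]

  ## ridge-augmented lasso = elastic net with fixed ridge gamma
  Xa <- rbind(X, sqrt(n * gamma) * diag(p))
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    betaPrev <- beta
    ## the path is deliberately truncated at the budget; glmnet warns
    ## about the truncation it was asked for, so muffle exactly that
    fit <- withCallingHandlers(
      glmnet::glmnet(Xa, c(r, rep(0, p)), alpha = 1,
                     standardize = FALSE, intercept = FALSE,
                     dfmax = budget),
      warning = function(w) {
        if (grepl("pmax|dfmax|nonzero coefficients", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    ok <- which(fit$df <= budget)
    j <- ok[length(ok)]
    beta <- as.numeric(fit$beta[, j])
    if (all(beta == 0)) break
    d <- min(sqrt(sum((beta - betaPrev)^2)),
             sqrt(sum((beta + betaPrev)^2)))
    if (d < tol * max(1, sqrt(sum(betaPrev^2)))) break
    ## score update: projection of the fit back onto class scores,
    ## orthogonalized against the trivial score and renormalized
    s <- drop(X %*% beta)
    thRaw <- c(rest = mean(s[y == "rest"]),
               intention = mean(s[y == "intention"]))
    D <- c(rest = n1 / n, intention = n2 / n)
    thRaw <- thRaw - sum(D * thRaw)
    nrm <- sqrt(sum(D * thRaw^2))
    if (nrm < .Machine$double.eps) break
    theta <- thRaw / nrm
    r <- theta[y]
  }

  if (all(beta == 0)) {
    warning("SDA selected no features; scores will be constant")
    intercept <- 0
  } else {
    s <- drop(X %*% beta)
    m1 <- mean(s[y == "intention"]); m0 <- mean(s[y == "rest"])
    if (m1 < m0) { beta <- -beta; s <- -s; m1 <- -m1; m0 <- -m0 }
    intercept <- -(m1 + m0) / 2
  }
  new("SdaModel", beta = beta, intercept = intercept,
      budget = as.numeric(budget), gamma = gamma,
      selected = which(beta != 0))
}

#' Score feature vectors with a sparse discriminant model
#'
#' Deterministic linear score `beta . x + intercept`; positive means
#' intention-side of the symmetric decision threshold at 0. Inputs must
#' be normalized with the statistics the model was fitted with.
#'
#' @param model An \linkS4class{SdaModel}.
#' @param x numeric feature vector or windows x features matrix.
#' @return Scalar or vector of scores.
#' @export
sdaScore <- function(model, x) {
  if (is.matrix(x)) {
    if (ncol(x) != length(model@beta)) stop("feature length mismatch")
    drop(x %*% model@beta) + model@intercept
  } else {
    if (length(x) != length(model@beta)) stop("feature length mismatch")
    sum(x * model@beta) + model@intercept
  }
}

#' Feature selection frequency across models
#'
#' Fraction of models (e.g. leave-one-out folds) in which each feature
#' has a nonzero coefficient, joined with the feature index map so the
#' selection pattern can be projected to channel x frequency (ERD) and
#' channel x time (MRCP) grids.
#'
#' @param models list of \linkS4class{SdaModel} objects sharing one
#'   feature space.
#' @param map feature index map (default [featureIndexMap()]); must have
#'   one row per feature.
#' @return The map data.frame with an added `frequency` column in
#'   [0, 1].
#' @export
selectionMap <- function(models, map = featureIndexMap()) {
  stopifnot(length(models) >= 1)
  p <- length(models[[1]]@beta)
  if (nrow(map) != p) stop("feature map does not match model dimension")
  if (any(vapply(models, function(m) length(m@beta), 0L) != p))
    stop("models have inconsistent feature dimensions")
  counts <- Reduce(`+`, lapply(models, function(m)
    as.numeric(m@beta != 0)))
  map$frequency <- counts / length(models)
  map
}
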