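# Pair/site labeling, ROC/AUC/partial AUC, vertical averaging, normalized
# rank fractions, permutation baseline, logistic combination,
# cross-validation.

#' Label contact pairs by functional-site membership
#'
#' A contact is positive when at least one endpoint is a functional site and
#' negative when neither is; residue pairs not in contact are ignored (they
#' never appear in the output).
#'
#' @param graph an \code{smrf_graph}.
#' @param functional_sites integer vector of 1-based residue indices.
#' @return data.frame: i, j, label (1 positive / 0 negative), one row per
#'   graph edge.
#' @export
label_pairs <- function(graph, functional_sites) {
  sites <- as.integer(functional_sites)
  if (length(sites) && any(sites < 1L | sites > graph$n_nodes))
    stop("functional-site index out of range 1..", graph$n_nodes)
  e <- graph$edges
  lab <- as.integer(e[, 1] %in% sites | e[, 2] %in% sites)
  data.frame(i = e[, 1], j = e[, 2], label = lab)
}

#' ROC curve, AUC and partial AUCs
#'
#' Sweeps all score thresholds with tied scores grouped at a single
#' threshold, so the trapezoid AUC equals the normalized Mann-Whitney U
#' statistic. Partial AUCs are the unnormalized areas over FPR in [0, b] for
#' b in \code{partial_bounds} (each at most b).
#'
#' @param scores numeric vector (larger = more positive).
#' @param labels binary vector (1 positive, 0 negative), same length.
#' @param partial_bounds FPR upper bounds for partial AUCs.
#' @return An object of class \code{smrf_roc}: \code{roc} (data.frame fpr,
#'   tpr), \code{auc}, \code{partial_auc} (named vector), \code{n_positive},
#'   \code{n_negative}.
#' @export
roc_and_auc <- function(scores, labels, partial_bounds = c(0.1, 0.2, 0.5)) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  nP <- sum(labels == 1L); nN <- sum(labels == 0L)
  if (nP == 0L || nN == 0L)
    stop("degenerate labels: need at least one positive and one negative")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tpr <- c(0, tp[last] / nP)
  fpr <- c(0, fp[last] / nN)
  auc <- trapezoid_area(fpr, tpr)
  pauc <- vapply(partial_bounds, function(b) {
    partial_trapezoid(fpr, tpr, b)
  }, numeric(1))
  names(pauc) <- partial_bounds
  structure(list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc,
                 partial_auc = pauc, n_positive = nP, n_negative = nN),
            class = "smrf_roc")
}

#' @export
print.smrf_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_positive, x$n_negative))
  invisible(x)
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# area under the piecewise-linear ROC over fpr in [0, b]
partial_trapezoid <- function(fpr, tpr, b) {
  if (b >= max(fpr)) return(trapezoid_area(fpr, tpr))
  keep <- fpr <= b
  x <- fpr[keep]; y <- tpr[keep]
  if (max(x) < b) {  # interpolate the crossing point
    i <- which(fpr > b)[1]
    yb <- tpr[i - 1] + (tpr[i] - tpr[i - 1]) *
      (b - fpr[i - 1]) / (fpr[i] - fpr[i - 1])
    x <- c(x, b); y <- c(y, yb)
  }
  trapezoid_area(x, y)
}

#' Vertically average ROC curves
#'
#' Interpolates each curve's TPR on a common FPR grid (taking the maximum
#' TPR at duplicated FPR values, then linear interpolation) and averages
#' pointwise.
#'
#' @param reports list of \code{smrf_roc} objects.
#' @param grid FPR grid (default 0 to 1 by 0.01).
#' @return data.frame: fpr, tpr (the averaged curve).
#' @export
vertical_average_roc <- function(reports, grid = seq(0, 1, by = 0.01)) {
  if (length(reports) == 0L) stop("no ROC reports to average")
  curves <- vapply(reports, function(r) {
    fpr <- r$roc$fpr; tpr <- r$roc$tpr
    mx <- tapply(tpr, fpr, max)
    stats::approx(as.numeric(names(mx)), as.numeric(mx), xout = grid,
                  rule = 2)$y
  }, numeric(length(grid)))
  data.frame(fpr = grid, tpr = rowMeans(as.matrix(curves)))
}

#' Positive fraction among top-ranked items (normalized rank)
#'
#' For each normalized rank rho, takes the top round(rho * L) items by score
#' (ties broken by ascending index) and returns the fraction labeled
#' positive. Rounding is half away from zero; a cutoff that rounds to zero
#' items yields NA.
#'
#' @param scores numeric vector.
#' @param labels binary vector, same length.
#' @param normalized_ranks numeric vector of rho values.
#' @param L sequence length used to scale the ranks.
#' @return Named numeric vector, one fraction per rho.
#' @export
rank_fraction <- function(scores, labels, normalized_ranks, L) {
  stopifnot(L > 0, length(scores) == length(labels))
  o <- order(-scores, seq_along(scores))
  y <- as.integer(labels)[o]
  out <- vapply(normalized_ranks, function(rho) {
    k <- floor(rho * L + 0.5)  # round half away from zero (rho >= 0)
    if (k < 1L) return(NA_real_)
    k <- min(k, length(y))
    mean(y[seq_len(k)])
  }, numeric(1))
  names(out) <- normalized_ranks
  out
}

#' Permutation baseline scores
#'
#' Average of \code{n_permutations} random permutations of the score vector;
#' the random-predictor reference used alongside the coevolution scores.
#'
#' @param scores numeric vector.
#' @param n_permutations number of permutations (default 100).
#' @param seed RNG seed.
#' @return Numeric vector, same length as \code{scores}.
#' @export
random_baseline <- function(scores, n_permutations = 100L, seed = 1L) {
  stopifnot(n_permutations >= 1L)
  set.seed(seed)
  acc <- numeric(length(scores))
  for (b in seq_len(n_permutations)) acc <- acc + sample(scores)
  acc / n_permutations
}

#' Combine scores by logistic regression
#'
#' Maximum-likelihood logistic fit of the labels on the feature columns
#' (IRLS via \code{glm}). Under perfect separation the ML coefficients
#' diverge; a ridge-penalized fit (\code{glmnet}, alpha = 0, small lambda)
#' is substituted with a warning.
#'
#' @param features numeric matrix or data.frame, one row per residue.
#' @param labels binary vector.
#' @return List: \code{coefficients} (named, per feature),
#'   \code{intercept}, \code{probabilities} (fitted, in (0,1)).
#' @export
combine_scores_logistic <- function(features, labels) {
  x <- as.matrix(features)
  y <- as.integer(labels)
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L)
    stop("need at least one positive and one negative label")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  df <- data.frame(.y = y, x, check.names = FALSE)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf_raw <- stats::coef(fit)
  cf_raw[is.na(cf_raw)] <- 0  # aliased/zero-variance columns drop to 0
  if (separated) {
    warning("(quasi-)separation detected; using ridge-penalized fit")
    # glmnet needs >= 2 columns; duplicate a column if necessary
    xr <- if (ncol(x) == 1L) cbind(x, 0) else x
    rf <- glmnet::glmnet(xr, y, family = "binomial", alpha = 0,
                         lambda = 1e-3, standardize = FALSE)
    beta <- as.numeric(rf$beta)[seq_len(ncol(x))]
    names(beta) <- colnames(x)
    eta <- as.numeric(rf$a0) + x %*% beta
    return(list(coefficients = beta, intercept = as.numeric(rf$a0),
                probabilities = as.numeric(1 / (1 + exp(-eta)))))
  }
  list(coefficients = cf_raw[-1], intercept = unname(cf_raw[1]),
       probabilities = as.numeric(stats::fitted(fit)))
}

#' Repeated k-fold cross-validated AUC of the logistic combination
#'
#' Random fold assignment per repeat; the logistic model is fitted on k-1
#' folds and its held-out predictions scored by AUC. Folds containing a
#' single class are skipped with a warning.
#'
#' @param features numeric matrix or data.frame.
#' @param labels binary vector.
#' @param k folds (default 20).
#' @param repeats repetitions (default 30).
#' @param seed RNG seed.
#' @return List: \code{auc_per_repeat} (length \code{repeats}),
#'   \code{mean_auc}.
#' @export
crossvalidate <- function(features, labels, k = 20L, repeats = 30L,
                          seed = 1L) {
  x <- as.matrix(features)
  y <- as.integer(labels)
  n <- length(y)
  if (n < 2L * k) stop("too few items for ", k, "-fold cross-validation")
  set.seed(seed)
  aucs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold <- sample(rep(seq_len(k), length.out = n))
    pred <- rep(NA_real_, n)
    for (f in seq_len(k)) {
      test <- fold == f
      ytr <- y[!test]
      if (length(unique(ytr)) < 2L) {
        warning("training fold with a single class skipped")
        next
      }
      m <- suppressWarnings(
        combine_scores_logistic(x[!test, , drop = FALSE], ytr))
      eta <- m$intercept + x[test, , drop = FALSE] %*% m$coefficients
      pred[test] <- 1 / (1 + exp(-eta))
    }
    ok <- !is.na(pred)
    aucs[r] <- roc_and_auc(pred[ok], y[ok])$auc
  }
  list(auc_per_repeat = aucs, mean_auc = mean(aucs))
}

#' Read functional sites from a TSV/plain list
#'
#' One 1-based residue index per line; an optional second column (label) is
#' ignored. Lines starting with '#' are comments.
#'
#' @param path file path.
#' @return Integer vector of residue indices.
#' @export
read_sites <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  as.integer(vapply(strsplit(lines, "[\t ]+"), `[[`, character(1), 1L))
}
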