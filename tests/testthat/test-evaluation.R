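test_that("pair labeling follows the at-least-one-site rule", {
  g <- new_contact_graph(9, cbind(c(3L, 2L), c(7L, 5L)))
  lab <- label_pairs(g, c(3L))
  expect_equal(lab$label, c(1L, 0L))
  expect_equal(label_pairs(g, integer(0))$label, c(0L, 0L))
  expect_equal(nrow(lab), 2L)  # non-contact pairs never appear
  expect_error(label_pairs(g, 10L), "out of range")
})

test_that("ROC/AUC: perfect, random-tie, worked Mann-Whitney case", {
  r <- roc_and_auc(c(5, 4, 3, 2), c(1, 1, 0, 0))
  expect_equal(r$auc, 1.0)
  r2 <- roc_and_auc(rep(1, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(r2$auc, 0.5)
  # scores [.9,.8,.3,.1], labels [1,0,1,0]: 3 of 4 pairs ordered -> 0.75
  r3 <- roc_and_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))
  expect_equal(r3$auc, 0.75)
  expect_error(roc_and_auc(1:3, c(1, 1, 1)), "degenerate")
})

test_that("ROC curve is monotone from (0,0) to (1,1); pAUC bounded", {
  set.seed(100)
  for (rep in 1:5) {
    n <- 40
    s <- rnorm(n); y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    r <- roc_and_auc(s, y)
    expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
    expect_equal(utils::tail(r$roc$fpr, 1), 1)
    expect_equal(utils::tail(r$roc$tpr, 1), 1)
    expect_true(all(diff(r$roc$fpr) >= 0))
    expect_true(all(diff(r$roc$tpr) >= 0))
    for (b in c(0.1, 0.2, 0.5)) {
      expect_lte(r$partial_auc[[as.character(b)]], min(r$auc, b) + 1e-12)
    }
  }
})

test_that("AUC equals the all-pairs Mann-Whitney oracle", {
  mw_oracle <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    s <- round(rnorm(n), sample(0:2, 1))  # induce ties
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    expect_equal(roc_and_auc(s, y)$auc, mw_oracle(s, y), tolerance = 1e-12)
  }
})

test_that("vertical averaging: self-average identity, mixed-curve oracle", {
  r <- roc_and_auc(c(5, 4, 3, 2, 1, 0), c(1, 0, 1, 0, 1, 0))
  avg <- vertical_average_roc(list(r, r))
  single <- vertical_average_roc(list(r))
  expect_equal(avg$tpr, single$tpr)
  expect_true(all(diff(avg$tpr) >= 0))

  # perfect curve (AUC 1) averaged with the diagonal (AUC 0.5):
  # pointwise mean is (1 + f)/2 for f > 0 -> area 0.75
  perfect <- roc_and_auc(c(2, 1), c(1, 0))
  diag <- structure(list(roc = data.frame(fpr = c(0, 1), tpr = c(0, 1))),
                    class = "smrf_roc")
  avg2 <- vertical_average_roc(list(perfect, diag))
  auc2 <- sum(diff(avg2$fpr) * (utils::head(avg2$tpr, -1) +
                                  utils::tail(avg2$tpr, -1)) / 2)
  expect_equal(auc2, 0.75, tolerance = 0.005)
})

test_that("rank_fraction counts positives among top-round(rho*L)", {
  s <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  y <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1)
  rf <- rank_fraction(s, y, c(0.1, 0.3, 1.0), L = 10)
  expect_equal(unname(rf), c(1, 1, 0.4))
  # full coverage equals the base positive rate exactly
  expect_equal(unname(rf[3]), mean(y))
  # cutoff rounding to zero items -> NA
  expect_true(is.na(rank_fraction(s, y, 0.04, L = 10)))
  # half-away-from-zero rounding: rho*L = 0.5 -> k = 1
  expect_equal(unname(rank_fraction(s, y, 0.05, L = 10)), 1)
})

test_that("random baseline is reproducible and converges to the mean", {
  s <- c(1, 2, 3, 10)
  b1 <- random_baseline(s, 100, seed = 7)
  b2 <- random_baseline(s, 100, seed = 7)
  expect_identical(b1, b2)
  expect_identical(random_baseline(rep(2, 5), 10, seed = 1), rep(2, 5))
  b3 <- random_baseline(s, 5000, seed = 8)
  expect_equal(b3, rep(mean(s), 4), tolerance = 0.05)
  # permutation baseline's expected rank_fraction equals the base rate
  set.seed(9)
  y <- rbinom(100, 1, 0.3)
  bl <- random_baseline(rnorm(100), 1000, seed = 10)
  rf <- rank_fraction(bl, y, 0.5, L = 100)
  # binomial noise on a 50-item draw: sd ~ 0.065, allow 2 sd
  expect_lt(abs(unname(rf) - mean(y)), 0.13)
})

test_that("logistic combination: null model, recovery, separation", {
  # intercept-only behavior on balanced labels
  set.seed(110)
  x <- matrix(rnorm(200), 100, 2)
  y <- rep(c(0L, 1L), 50)
  m <- combine_scores_logistic(x * 0, y)
  expect_equal(m$probabilities, rep(0.5, 100), tolerance = 1e-6)

  # planted-coefficient simulation (n = 2000): recovery within 2 SE
  set.seed(111)
  n <- 2000
  X <- cbind(rnorm(n), rnorm(n))
  beta <- c(1.2, -0.7); eta <- -0.3 + X %*% beta
  yy <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  fit <- combine_scores_logistic(X, yy)
  se <- sqrt(diag(vcov(glm(yy ~ X, family = binomial()))))[2:3]
  expect_lt(abs(fit$coefficients[[1]] - 1.2), 2 * se[1])
  expect_lt(abs(fit$coefficients[[2]] + 0.7), 2 * se[2])
  expect_gt(fit$coefficients[[1]], 0)  # sign consistency
  expect_true(all(fit$probabilities > 0 & fit$probabilities < 1))

  # perfect separation falls back to ridge with a warning
  xs <- matrix(c(1:20), 20, 1)
  ys <- c(rep(0L, 10), rep(1L, 10))
  expect_warning(ms <- combine_scores_logistic(xs, ys), "separation")
  expect_true(all(is.finite(ms$coefficients)))
  expect_gt(ms$coefficients[[1]], 0)
})

test_that("cross-validation: null AUC near 0.5, predictive near 1, seeded", {
  set.seed(112)
  x <- matrix(rnorm(1000), 1000, 1)
  y <- rbinom(1000, 1, 0.5)
  cv <- crossvalidate(x, y, k = 20, repeats = 3, seed = 5)
  expect_lt(abs(cv$mean_auc - 0.5), 0.05)

  y2 <- as.integer(x[, 1] + rnorm(1000, sd = 0.1) > 0)
  cv2 <- crossvalidate(x, y2, k = 20, repeats = 3, seed = 5)
  expect_gt(cv2$mean_auc, 0.95)

  cv3 <- crossvalidate(x, y, k = 20, repeats = 3, seed = 5)
  expect_identical(cv$auc_per_repeat, cv3$auc_per_repeat)
})

test_that("site files read as 1-based indices", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# sites", "3", "7\tcatalytic", "12"), f)
  expect_equal(read_sites(f), c(3L, 7L, 12L))
})
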