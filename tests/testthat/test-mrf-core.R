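test_that("conditional distribution: uniform at zero, normalized, worked case", {
  g <- new_contact_graph(2, cbind(1L, 2L))
  m <- empty_mrf_model(g)
  p <- conditional_distribution(m, c(1L, 1L), 1L)
  expect_equal(p, rep(1 / 21, 21))

  # L=2 single edge, w(A,A)=5 else 0, neighbor in state A:
  # P(A | .) = e^5 / (e^5 + 20)
  m$w[[1]][1, 1] <- 5
  p <- conditional_distribution(m, c(1L, 1L), 1L)
  expect_equal(p[1], exp(5) / (exp(5) + 20), tolerance = 1e-12)
  # seen from the second endpoint the coupling is transposed
  p2 <- conditional_distribution(m, c(1L, 1L), 2L)
  expect_equal(p2[1], exp(5) / (exp(5) + 20), tolerance = 1e-12)

  set.seed(31)
  for (rep in 1:20) {
    mod <- random_model(6, 7, seed = rep)
    s <- sample.int(21L, 6, replace = TRUE)
    i <- sample.int(6L, 1)
    expect_equal(sum(conditional_distribution(mod, s, i)), 1,
                 tolerance = 1e-12)
  }
})

test_that("pseudo-likelihood closed forms", {
  # zero parameters, no edges: pll = -M * L * log 21
  msa <- random_msa(9, 4, seed = 2)
  g0 <- new_contact_graph(4, matrix(integer(0), 0, 2))
  expect_equal(pseudo_loglikelihood(empty_mrf_model(g0), msa)$value,
               -9 * 4 * log(21), tolerance = 1e-12)

  # L=1, M=2, both rows 'A', v(A)=1: pll = 2 * (1 - log(e + 20))
  msa1 <- new_msa(matrix(1L, 2, 1))
  g1 <- new_contact_graph(1, matrix(integer(0), 0, 2))
  m1 <- empty_mrf_model(g1)
  m1$v[1, 1] <- 1
  expect_equal(pseudo_loglikelihood(m1, msa1)$value,
               2 * (1 - log(exp(1) + 20)), tolerance = 1e-12)

  expect_error(pseudo_loglikelihood(empty_mrf_model(g1), msa),
               "does not match")
})

test_that("analytic gradient matches central finite differences", {
  # numerical-differentiation oracle, h = 1e-5, with and without edges
  cfg <- training_config()
  for (n_edges in c(0L, 12L)) {
    model <- random_model(8, n_edges, seed = 40 + n_edges)
    msa <- random_msa(20, 8, seed = 41 + n_edges)
    par <- pack_model(model)
    pll <- pseudo_loglikelihood(model, msa)
    pen <- regularization_penalty(model, cfg)
    analytic <- c(pen$grad_v, as.numeric(pen$grad_w)) -
      c(pll$grad_v, as.numeric(pll$grad_w))
    set.seed(50 + n_edges)
    idx <- sample(length(par), 40)
    h <- 1e-5
    numeric_grad <- vapply(idx, function(k) {
      up <- par; up[k] <- up[k] + h
      dn <- par; dn[k] <- dn[k] - h
      (objective_at(up, model$graph, msa, cfg) -
         objective_at(dn, model$graph, msa, cfg)) / (2 * h)
    }, numeric(1))
    rel <- abs(numeric_grad - analytic[idx]) /
      pmax(abs(numeric_grad), 1e-8)
    expect_lt(max(rel), 1e-5)
  }
})

test_that("regularization penalty values and gradient", {
  g <- new_contact_graph(2, cbind(1L, 2L))
  m <- empty_mrf_model(g)
  cfg <- training_config()
  expect_equal(regularization_penalty(m, cfg)$value, 0)
  m$v[1, 3] <- 3
  expect_equal(regularization_penalty(m, cfg)$value, 0.01 * 9)
  expect_equal(regularization_penalty(m, cfg)$grad_v[1, 3], 2 * 0.01 * 3)
  m$v[1, 3] <- 0
  m$w[[1]][4, 5] <- 2
  expect_equal(regularization_penalty(m, cfg)$value, 0.2 * 4)
})

test_that("edge-visit count is exactly 2*M*E and linear in E", {
  msa <- random_msa(11, 10, seed = 7)
  for (E in c(3L, 6L, 12L)) {
    model <- random_model(10, E, seed = E)
    visits <- pseudo_loglikelihood(model, msa)$edge_visits
    expect_equal(visits, 2 * 11 * E)
  }
})

test_that("fit: single conserved column overcomes regularization", {
  # edgeless graph, one column 100% 'A', M=50: fitted p(A) > 0.95.
  # 1-D numeric oracle: minimize 0.01 v^2 - 50 (v - log(e^v + 20)) over v.
  g <- new_contact_graph(1, matrix(integer(0), 0, 2))
  msa <- new_msa(matrix(1L, 50, 1))
  fit <- fit_mrf(msa, g)
  p <- conditional_distribution(fit, 1L, 1L)
  expect_gt(p[1], 0.95)
  # 2-D oracle by symmetry: v(A) = a, v(other 20 states) = b
  oracle <- stats::optim(c(0, 0), function(th) {
    0.01 * (th[1]^2 + 20 * th[2]^2) -
      50 * (th[1] - log(exp(th[1]) + 20 * exp(th[2])))
  })$par
  p_oracle <- exp(oracle[1]) / (exp(oracle[1]) + 20 * exp(oracle[2]))
  expect_equal(p[1], p_oracle, tolerance = 1e-3)
})

test_that("fit is deterministic, row-order invariant, convex", {
  model0 <- random_model(5, 4, seed = 60)
  set.seed(61)
  msa <- gibbs_sample_msa(model0, 30, seed = 61)
  g <- model0$graph
  f1 <- fit_mrf(msa, g)
  f2 <- fit_mrf(msa, g)
  expect_identical(f1$v, f2$v)
  expect_identical(f1$w, f2$w)

  set.seed(62)
  perm <- sample(nrow(msa$seq))
  msa_p <- new_msa(msa$seq[perm, ], query_index = which(perm == 1L))
  f3 <- fit_mrf(msa_p, g)
  expect_equal(f3$v, f1$v, tolerance = 1e-5)

  # convexity: a random start reaches the same objective
  npar <- 5 * 21 + 4 * 441
  set.seed(63)
  cfg <- training_config(init = rnorm(npar, sd = 0.3))
  f4 <- fit_mrf(msa, g, cfg)
  expect_equal(attr(f4, "objective"), attr(f1, "objective"),
               tolerance = 1e-4)

  expect_error(fit_mrf(new_msa(matrix(integer(0), 0, 5)), g))
  # M = 1 is accepted
  f5 <- fit_mrf(new_msa(msa$seq[1, , drop = FALSE]), g)
  expect_s3_class(f5, "smrf_model")
})

test_that("edge norms shrink monotonically in lambda_w", {
  model0 <- random_model(5, 4, seed = 70, sd_w = 0.8)
  msa <- gibbs_sample_msa(model0, 60, seed = 71)
  norms <- vapply(c(0.2, 2, 20, 200), function(lw) {
    f <- fit_mrf(msa, model0$graph, training_config(lambda_w = lw))
    sum(vapply(f$w, function(w) sum(w^2), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[4], 1e-2)  # degenerates toward independent columns
})

test_that("model serialization round-trips through JSON", {
  model <- random_model(4, 3, seed = 80)
  path <- withr::local_tempfile(fileext = ".json")
  write_mrf(model, path, config = training_config())
  back <- read_mrf(path)
  expect_equal(back$v, model$v)
  expect_equal(back$w, model$w)
  expect_equal(back$graph$edges, model$graph$edges)
})
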