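# Sparse Potts/MRF model: representation, pseudo-likelihood, L2 penalty,
# L-BFGS fitting.

#' Construct an MRF model
#'
#' Node weights v (L x 21) and one 21 x 21 coupling matrix per contact-graph
#' edge, rows indexed by the state of the lower-numbered endpoint; the higher
#' endpoint sees the transpose. Couplings exist only for graph edges.
#'
#' @param v L x 21 numeric matrix of node weights.
#' @param w list of 21 x 21 matrices, one per row of \code{graph$edges}.
#' @param graph an \code{smrf_graph} with \code{n_nodes == nrow(v)}.
#' @return An object of class \code{smrf_model}.
#' @export
new_mrf_model <- function(v, w, graph) {
  if (!is.matrix(v) || ncol(v) != 21L) stop("v must be L x 21")
  if (nrow(v) != graph$n_nodes) stop("v rows must equal graph node count")
  if (length(w) != nrow(graph$edges))
    stop("w must have one matrix per graph edge")
  for (m in w) if (!is.matrix(m) || any(dim(m) != 21L))
    stop("each coupling must be 21 x 21")
  structure(list(v = v, w = w, graph = graph), class = "smrf_model")
}

#' @export
print.smrf_model <- function(x, ...) {
  cat(sprintf("smrf_model: L = %d, %d coupled edges\n",
              nrow(x$v), nrow(x$graph$edges)))
  invisible(x)
}

#' Zero-initialized model on a graph
#' @param graph an \code{smrf_graph}.
#' @return An \code{smrf_model} with all parameters zero.
#' @export
empty_mrf_model <- function(graph) {
  L <- graph$n_nodes
  new_mrf_model(matrix(0, L, 21L),
                replicate(nrow(graph$edges), matrix(0, 21L, 21L),
                          simplify = FALSE),
                graph)
}

#' Training configuration
#'
#' L2 regularization weights follow the published constants: lambda_v = 0.01
#' on node weights and lambda_w = 0.2 per edge coupling, applied flat (no
#' scaling by neighbor count or length). Convergence is a projected-gradient
#' max-norm of 1e-5 or 500 L-BFGS iterations, whichever first.
#'
#' @param lambda_v L2 weight on node parameters.
#' @param lambda_w L2 weight on edge parameters (each edge counted once).
#' @param max_iterations L-BFGS iteration cap.
#' @param gradient_tolerance projected-gradient max-norm threshold.
#' @param init \code{"zeros"} or a numeric vector of packed parameters.
#' @return A list of class \code{smrf_config}.
#' @export
training_config <- function(lambda_v = 0.01, lambda_w = 0.2,
                            max_iterations = 500L,
                            gradient_tolerance = 1e-5, init = "zeros") {
  stopifnot(lambda_v >= 0, lambda_w >= 0)
  structure(list(lambda_v = lambda_v, lambda_w = lambda_w,
                 max_iterations = as.integer(max_iterations),
                 gradient_tolerance = gradient_tolerance, init = init),
            class = "smrf_config")
}

# pack / unpack parameters <-> flat vector (v first, then couplings by edge)
pack_params <- function(v, w) c(v, unlist(w, use.names = FALSE))

unpack_params <- function(par, L, E) {
  v <- matrix(par[seq_len(L * 21L)], L, 21L)
  if (E == 0L) return(list(v = v, W = array(0, c(21L, 21L, 0L))))
  W <- par[-seq_len(L * 21L)]
  dim(W) <- c(21L, 21L, E)
  list(v = v, W = W)
}

w_list_to_array <- function(w) {
  E <- length(w)
  W <- array(0, c(21L, 21L, E))
  for (e in seq_len(E)) W[, , e] <- w[[e]]
  W
}

w_array_to_list <- function(W) {
  E <- dim(W)[3]
  lapply(seq_len(E), function(e) W[, , e])
}

#' Conditional distribution of one column given the rest
#'
#' P(x_i = k | x_-i) is proportional to exp(v_i(k) + sum over graph neighbors
#' j of w_ij(k, x_j)); the sum runs only over contact-graph edges incident to
#' i. All 21 states, including the gap, participate.
#'
#' @param model an \code{smrf_model}.
#' @param sequence length-L integer state vector (1..21).
#' @param i column index.
#' @return Numeric probability vector of length 21 summing to 1.
#' @export
conditional_distribution <- function(model, sequence, i) {
  L <- nrow(model$v)
  stopifnot(length(sequence) == L, i >= 1L, i <= L,
            all(sequence >= 1L & sequence <= 21L))
  logits <- model$v[i, ]
  for (e in incident_edges(model$graph, i)) {
    a <- model$graph$edges[e, 1]; b <- model$graph$edges[e, 2]
    logits <- logits + if (a == i) model$w[[e]][, sequence[b]]
                       else        model$w[[e]][sequence[a], ]
  }
  p <- exp(logits - max(logits))
  p / sum(p)
}

#' Pseudo-log-likelihood and its gradient
#'
#' pll(v, w | D) = sum over rows m and columns i of log P(x_i[m] | x_-i[m]).
#' Each edge contributes to the conditionals of both of its endpoints (the
#' usual pseudo-likelihood double counting). The returned
#' \code{edge_visits} counts coupling-term accesses (2 M E), which grows
#' linearly in the edge count at fixed M.
#'
#' @param model an \code{smrf_model}.
#' @param msa an \code{smrf_msa} with \code{ncol == L}.
#' @return List: \code{value}, \code{grad_v} (L x 21), \code{grad_w}
#'   (21 x 21 x E array), \code{edge_visits}.
#' @export
pseudo_loglikelihood <- function(model, msa) {
  if (ncol(msa$seq) != nrow(model$v))
    stop("MSA width does not match model size")
  r <- smrf_pll_grad(model$v, w_list_to_array(model$w), model$graph$edges,
                     msa$seq)
  list(value = r$pll, grad_v = r$grad_v, grad_w = r$grad_w,
       edge_visits = r$edge_visits)
}

#' L2 regularization penalty and its gradient
#'
#' R(v, w) = lambda_v * sum_i ||v_i||^2 + lambda_w * sum_edges ||w_ij||^2,
#' each edge counted once; the gap state is regularized like any other.
#'
#' @param model an \code{smrf_model}.
#' @param config an \code{smrf_config}.
#' @return List: \code{value}, \code{grad_v}, \code{grad_w}.
#' @export
regularization_penalty <- function(model, config = training_config()) {
  W <- w_list_to_array(model$w)
  list(value = config$lambda_v * sum(model$v^2) + config$lambda_w * sum(W^2),
       grad_v = 2 * config$lambda_v * model$v,
       grad_w = 2 * config$lambda_w * W)
}

#' Fit a sparse MRF by regularized pseudo-likelihood
#'
#' Minimizes R(v, w) - pll(v, w | D) with L-BFGS-B from zero initialization.
#' The objective is convex, so initialization affects only the iteration
#' count; identical inputs give identical fitted models. Non-convergence
#' within \code{max_iterations} warns and returns the best model found.
#'
#' @param msa an \code{smrf_msa}.
#' @param graph an \code{smrf_graph} with \code{n_nodes == ncol(msa$seq)}.
#' @param config an \code{smrf_config}.
#' @return An \code{smrf_model} with attributes \code{"objective"} (final
#'   value of R - pll) and \code{"convergence"} (optim code).
#' @export
fit_mrf <- function(msa, graph, config = training_config()) {
  X <- msa$seq
  L <- ncol(X); E <- nrow(graph$edges)
  if (graph$n_nodes != L) stop("graph node count must equal MSA width")
  if (nrow(X) < 1L) stop("empty MSA")
  npar <- L * 21L + E * 441L
  par0 <- if (identical(config$init, "zeros")) numeric(npar)
          else {
            if (length(config$init) != npar) stop("init length mismatch")
            as.numeric(config$init)
          }
  lv <- config$lambda_v; lw <- config$lambda_w
  # fn and gr share one evaluation: optim calls them at the same point
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return()
    up <- unpack_params(par, L, E)
    r <- smrf_pll_grad(up$v, as.numeric(up$W), graph$edges, X)
    cache$par <- par
    cache$value <- lv * sum(up$v^2) + lw * sum(up$W^2) - r$pll
    cache$grad <- 2 * c(lv * up$v, lw * as.numeric(up$W)) -
      c(r$grad_v, as.numeric(r$grad_w))
  }
  fn <- function(par) { evaluate(par); cache$value }
  gr <- function(par) { evaluate(par); cache$grad }
  res <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = config$max_iterations,
                                     factr = 10,
                                     pgtol = config$gradient_tolerance))
  if (res$convergence == 1L)
    warning("L-BFGS did not converge within ", config$max_iterations,
            " iterations; returning best model found")
  up <- unpack_params(res$par, L, E)
  model <- new_mrf_model(up$v, w_array_to_list(up$W), graph)
  attr(model, "objective") <- res$value
  attr(model, "convergence") <- res$convergence
  model
}

#' Serialize a fitted model to JSON
#'
#' Plain-text container: node weights, edge list with coupling matrices,
#' alphabet and regularization constants, at full double precision.
#'
#' @param model an \code{smrf_model}.
#' @param path output path.
#' @param config optional \code{smrf_config} recorded as provenance.
#' @return \code{path}, invisibly.
#' @export
write_mrf <- function(model, path, config = NULL) {
  obj <- list(alphabet = smrf_alphabet(),
              n_nodes = model$graph$n_nodes,
              edges = model$graph$edges,
              distances = model$graph$distances,
              v = model$v,
              w = w_list_to_array(model$w))
  if (!is.null(config))
    obj$config <- list(lambda_v = config$lambda_v, lambda_w = config$lambda_w)
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' Read a serialized model
#' @param path path to a JSON file written by \code{\link{write_mrf}}.
#' @return An \code{smrf_model}.
#' @export
read_mrf <- function(path) {
  obj <- jsonlite::fromJSON(path)
  edges <- if (length(obj$edges) == 0L) matrix(integer(0), 0, 2)
           else matrix(as.integer(obj$edges), ncol = 2)
  graph <- new_contact_graph(obj$n_nodes, edges, as.numeric(obj$distances))
  W <- array(as.numeric(obj$w), c(21L, 21L, nrow(edges)))
  new_mrf_model(matrix(as.numeric(obj$v), obj$n_nodes, 21L),
                w_array_to_list(W), graph)
}
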