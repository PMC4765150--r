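# Ground-truth generators: toy structures, planted sparse Potts models,
# Gibbs-sampled alignments, functional-site labels. All randomness flows
# through an explicit seed per operation.

#' Generate a toy 3D chain structure
#'
#' Self-avoiding random walk with 3.8-Angstrom steps (the C-alpha virtual
#' bond length) and an excluded volume of \code{min_dist} between
#' non-consecutive residues. Consecutive residues are always within the
#' 8-Angstrom contact cutoff, so the resulting contact graph is sparse and
#' connected.
#'
#' @param L residue count (>= 2).
#' @param seed RNG seed.
#' @param step step length in Angstrom (default 3.8).
#' @param min_dist excluded-volume distance for non-neighbors (default 4).
#' @return A data.frame in the layout of
#'   \code{\link{extract_representative_atoms}} (all residues ALA/CA).
#' @export
make_toy_structure <- function(L, seed = 1L, step = 3.8, min_dist = 4.0) {
  stopifnot(L >= 2L)
  set.seed(seed)
  for (attempt in seq_len(50L)) {
    xyz <- matrix(NA_real_, L, 3)
    xyz[1, ] <- 0
    ok <- TRUE
    for (i in 2:L) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        u <- stats::rnorm(3)
        cand <- xyz[i - 1, ] + step * u / sqrt(sum(u^2))
        if (i > 2L) {
          d2 <- rowSums((xyz[seq_len(i - 2L), , drop = FALSE] -
                           matrix(cand, i - 2L, 3, byrow = TRUE))^2)
          if (min(d2) < min_dist^2) next
        }
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      return(data.frame(seq_position = seq_len(L), residue_name = "ALA",
                        aa = "A", rep_atom = "CA",
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        stringsAsFactors = FALSE))
    }
  }
  stop("self-avoiding walk placement failed after 50 restarts; ",
       "try a different seed")
}

#' Plant a sparse Potts model on a contact graph
#'
#' Node weights are Gaussian (sd \code{v_sd}; the default 1.5 yields
#' realistically conserved columns); all couplings are zero except
#' \code{n_strong} randomly chosen edges, which each receive a symmetric
#' favorable two-letter block of the given strength; the favored letters get
#' neutral (zero) fields at the two coupled positions, so the planted
#' co-occurrence signal is carried by the coupling alone and is analytically
#' transparent. Nodes incident to a strong edge are the planted constrained
#' nodes.
#'
#' @param graph an \code{smrf_graph}.
#' @param n_strong number of strong edges (<= edge count).
#' @param coupling coupling strength placed on each strong edge (default 9):
#'   the favored letter pair (a, b) gets w(a, b) = w(b, a) = coupling.
#' @param seed RNG seed.
#' @param v_sd standard deviation of the node weights (default 1.5).
#' @return A list of class \code{smrf_planted}: \code{model}
#'   (\code{smrf_model}), \code{strong_edges} (row indices into
#'   \code{graph$edges}), \code{constrained_nodes}, \code{seed}.
#' @export
make_planted_mrf <- function(graph, n_strong, coupling = 9.0, seed = 1L,
                             v_sd = 1.5) {
  E <- nrow(graph$edges)
  stopifnot(n_strong <= E, n_strong >= 0)
  set.seed(seed)
  L <- graph$n_nodes
  v <- matrix(stats::rnorm(L * 21L, sd = v_sd), L, 21L)
  w <- replicate(E, matrix(0, 21L, 21L), simplify = FALSE)
  strong <- sort(sample.int(E, n_strong))
  for (e in strong) {
    ab <- sample.int(20L, 2L)  # two distinct favored letters
    w[[e]][ab[1], ab[2]] <- coupling
    w[[e]][ab[2], ab[1]] <- coupling
    # neutral fields for the favored letters at both positions: the planted
    # contrast is then carried by the coupling alone, independent of the
    # field draw
    v[graph$edges[e, ], ab] <- 0
  }
  nodes <- sort(unique(as.integer(graph$edges[strong, ])))
  structure(list(model = new_mrf_model(v, w, graph),
                 strong_edges = strong, constrained_nodes = nodes,
                 seed = seed),
            class = "smrf_planted")
}

#' Sample an MSA from an MRF by Gibbs sampling
#'
#' Single-site Gibbs updates using the model conditionals: one chain with
#' \code{burn_in} full sweeps, then one sequence collected every \code{thin}
#' sweeps until M rows are drawn. Exact sampling is intractable beyond tiny
#' L because of the global partition function; for L <= 3 the exact
#' distribution is available from \code{\link{exact_msa_distribution}} as an
#' oracle. The default thinning of 5 sweeps keeps consecutive rows close to
#' independent even under strong couplings, where single-site updates mix
#' slowly.
#'
#' @param model an \code{smrf_model}.
#' @param M number of sequences.
#' @param burn_in burn-in sweeps (default 100).
#' @param thin sweeps between collected rows (default 5).
#' @param seed RNG seed.
#' @return An \code{smrf_msa} (query = row 1).
#' @export
gibbs_sample_msa <- function(model, M, burn_in = 100L, thin = 5L,
                             seed = 1L) {
  stopifnot(M >= 1L, burn_in >= 1L, thin >= 1L)
  set.seed(seed)
  X <- smrf_gibbs(model$v, w_list_to_array(model$w), model$graph$edges,
                  as.integer(M), as.integer(burn_in), as.integer(thin))
  new_msa(X, ids = paste0("sample_", seq_len(M)), query_index = 1L)
}

#' Exact joint distribution of a tiny MRF
#'
#' Brute-force enumeration of P(x) = (1/Z) prod_i phi_i prod_edges psi_ij
#' over all 21^L outcomes; tractable only for L <= 3. Serves as the
#' independent oracle for the Gibbs sampler.
#'
#' @param model an \code{smrf_model} with L <= 3.
#' @return Array of dimension rep(21, L) of outcome probabilities.
#' @export
exact_msa_distribution <- function(model) {
  L <- nrow(model$v)
  if (L > 3L) stop("exact enumeration supported only for L <= 3")
  states <- as.matrix(expand.grid(rep(list(1:21), L)))
  loge <- numeric(nrow(states))
  for (i in seq_len(L)) loge <- loge + model$v[i, states[, i]]
  for (e in seq_len(nrow(model$graph$edges))) {
    a <- model$graph$edges[e, 1]; b <- model$graph$edges[e, 2]
    loge <- loge + model$w[[e]][cbind(states[, a], states[, b])]
  }
  p <- exp(loge - max(loge))
  p <- p / sum(p)
  array(p, dim = rep(21L, L))
}

#' Plant functional-site labels
#'
#' Labels the constrained nodes (those incident to strong planted edges) as
#' functional sites, plus \code{n_decoys} randomly chosen unconstrained
#' nodes to control evaluation difficulty.
#'
#' @param planted an \code{smrf_planted}.
#' @param n_decoys number of decoy sites (default 0).
#' @param seed RNG seed.
#' @return Sorted integer vector of site indices. Labeling every node is
#'   degenerate and flagged with a warning.
#' @export
plant_functional_sites <- function(planted, n_decoys = 0L, seed = 1L) {
  set.seed(seed)
  L <- planted$model$graph$n_nodes
  other <- setdiff(seq_len(L), planted$constrained_nodes)
  n_decoys <- min(n_decoys, length(other))
  decoys <- if (n_decoys > 0L) sample(other, n_decoys) else integer(0)
  sites <- sort(c(planted$constrained_nodes, decoys))
  if (length(sites) == L)
    warning("all nodes labeled as sites; evaluation is degenerate")
  sites
}

#' One-call synthetic benchmark instance
#'
#' Toy structure, contact graph, planted model, Gibbs-sampled MSA and site
#' labels in one step, with sub-seeds derived from \code{seed}.
#'
#' @param L residue count (default 50).
#' @param n_strong strong edges (default 5).
#' @param M sampled sequences (default 2000).
#' @param coupling coupling strength (default 9).
#' @param seed master seed.
#' @param n_decoys decoy sites (default 0).
#' @return List: \code{coords}, \code{graph}, \code{planted}, \code{msa},
#'   \code{sites}.
#' @export
simulate_benchmark <- function(L = 50L, n_strong = 5L, M = 2000L,
                               coupling = 9.0, seed = 1L, n_decoys = 0L) {
  coords <- make_toy_structure(L, seed = seed)
  graph <- build_contact_graph(coords)
  planted <- make_planted_mrf(graph, n_strong, coupling, seed = seed + 1L)
  msa <- gibbs_sample_msa(planted$model, M, seed = seed + 2L)
  sites <- plant_functional_sites(planted, n_decoys, seed = seed + 3L)
  list(coords = coords, graph = graph, planted = planted, msa = msa,
       sites = sites)
}
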