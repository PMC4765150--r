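# Pairwise (edge-weight, APC) and positional (NW/EW/FC) coevolution scores,
# KLD/JSD conservation, Z-normalization.

#' Pairwise coevolution score from edge weights
#'
#' Squared Frobenius norm of the 20 x 20 amino-acid block of each coupling:
#' sum over amino-acid pairs of w_ij(a, b)^2. The gap row and column are
#' excluded. Set \code{sqrt = TRUE} for the square-root (GREMLIN-style)
#' variant.
#'
#' @param model a fitted \code{smrf_model}.
#' @param sqrt take the square root of the summed squares.
#' @return Numeric vector, one score per row of \code{model$graph$edges}.
#' @export
pairwise_score <- function(model, sqrt = FALSE) {
  s <- vapply(model$w, function(m) sum(m[1:20, 1:20]^2), numeric(1))
  if (sqrt) base::sqrt(s) else s
}

#' Average-product correction on a sparse edge set
#'
#' corrected(i,j) = s(i,j) - mean_i * mean_j / mean_all, where mean_i is the
#' mean score over edges incident to i and mean_all the mean over all edges.
#' Means run over existing edges only: the sparse graph carries no scores for
#' non-contact pairs.
#'
#' @param scores numeric vector of raw scores, one per graph edge.
#' @param graph the \code{smrf_graph} the scores are defined on.
#' @return Numeric vector of corrected scores (empty if the graph has no
#'   edges).
#' @export
apc_correct <- function(scores, graph) {
  E <- nrow(graph$edges)
  if (length(scores) != E) stop("one score per graph edge required")
  if (E == 0L) return(numeric(0))
  node_sum <- numeric(graph$n_nodes)
  node_deg <- integer(graph$n_nodes)
  for (e in seq_len(E)) {
    for (u in graph$edges[e, ]) {
      node_sum[u] <- node_sum[u] + scores[e]
      node_deg[u] <- node_deg[u] + 1L
    }
  }
  node_mean <- ifelse(node_deg > 0L, node_sum / pmax(node_deg, 1L), 0)
  overall <- mean(scores)
  if (overall == 0) return(scores)  # all-zero scores: nothing to correct
  scores - node_mean[graph$edges[, 1]] * node_mean[graph$edges[, 2]] / overall
}

#' Amino-acid distribution implied by a node weight
#'
#' Softmax of the node weight over the 20 amino-acid entries only; the gap
#' entry is ignored. Strictly positive, so KL divergences against it are
#' finite.
#'
#' @param v_i length-21 node-weight vector.
#' @return Length-20 probability vector.
#' @export
node_distribution <- function(v_i) {
  z <- v_i[1:20]
  p <- exp(z - max(z))
  p / sum(p)
}

#' Positional coevolution from the node weight (NW)
#'
#' KL divergence between the observed column frequencies f_i and the
#' distribution p_i implied by the fitted node weight. In a fitted MRF the
#' node weight absorbs only the part of the column's preference not explained
#' by couplings, so a large divergence marks a column shaped by its
#' neighbors.
#'
#' @param f_i length-20 column frequency vector.
#' @param p_i length-20 node distribution (see
#'   \code{\link{node_distribution}}).
#' @return Non-negative scalar (nats); 0 * log 0 is taken as 0.
#' @export
positional_nw <- function(f_i, p_i) kl_divergence(f_i, p_i)

kl_divergence <- function(p, q) {
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Proximity-averaged coevolution (EW)
#'
#' Mean of the APC-corrected pair scores over the contact-graph edges
#' incident to each residue; isolated nodes score 0 and are flagged.
#'
#' @param pair_apc APC-corrected scores, one per graph edge.
#' @param graph an \code{smrf_graph}.
#' @param i optional single node; default computes all L values.
#' @return Numeric vector (length L, or scalar when \code{i} is given) with
#'   attribute \code{"isolated"} marking flagged nodes.
#' @export
positional_ew <- function(pair_apc, graph, i = NULL) {
  nodes <- if (is.null(i)) seq_len(graph$n_nodes) else i
  out <- numeric(length(nodes))
  iso <- logical(length(nodes))
  for (t in seq_along(nodes)) {
    e <- incident_edges(graph, nodes[t])
    if (length(e) == 0L) iso[t] <- TRUE else out[t] <- mean(pair_apc[e])
  }
  attr(out, "isolated") <- iso
  out
}

#' Fraction of coevolving contacts (FC)
#'
#' Fraction of a residue's incident contacts whose pair Z-score exceeds the
#' threshold (default 3, i.e. a pair is called coevolving when its Z-score of
#' the coevolution score exceeds 3). Z-scores are computed over the
#' protein's full edge set. Isolated nodes score 0 and are flagged.
#'
#' @param pair_z Z-scores of the APC-corrected pair scores, one per edge.
#' @param graph an \code{smrf_graph}.
#' @param i optional single node; default computes all L values.
#' @param threshold Z-score cutoff (default 3).
#' @return Numeric vector in [0, 1] with attribute \code{"isolated"}.
#' @export
positional_fc <- function(pair_z, graph, i = NULL, threshold = 3.0) {
  nodes <- if (is.null(i)) seq_len(graph$n_nodes) else i
  out <- numeric(length(nodes))
  iso <- logical(length(nodes))
  for (t in seq_along(nodes)) {
    e <- incident_edges(graph, nodes[t])
    if (length(e) == 0L) iso[t] <- TRUE
    else out[t] <- sum(pair_z[e] > threshold) / length(e)
  }
  attr(out, "isolated") <- iso
  out
}

#' KL-divergence conservation score
#'
#' Divergence of the column frequencies from the background amino-acid
#' frequencies of the alignment.
#'
#' @param f_i length-20 column frequency vector.
#' @param q length-20 background frequency vector, strictly positive.
#' @return Non-negative scalar (nats).
#' @export
conservation_kld <- function(f_i, q) kl_divergence(f_i, q)

#' JS-divergence conservation score
#'
#' JSD(f, q) = lambda KLD(f, r) + (1 - lambda) KLD(q, r) with the mixture
#' r = lambda f + (1 - lambda) q. At lambda = 0.5 it is symmetric and bounded
#' by log 2 (nats).
#'
#' @param f_i length-20 column frequency vector.
#' @param q length-20 background frequency vector.
#' @param lambda mixture weight (default 0.5).
#' @return Scalar in [0, log 2] when lambda = 0.5.
#' @export
conservation_jsd <- function(f_i, q, lambda = 0.5) {
  r <- lambda * f_i + (1 - lambda) * q
  lambda * kl_divergence(f_i, r) + (1 - lambda) * kl_divergence(q, r)
}

#' Z-score normalization
#'
#' (x - mean) / SD with the population SD (divisor n). A constant vector maps
#' to all zeros and is flagged via attribute \code{"constant"}.
#'
#' @param values numeric vector, length >= 1.
#' @return Z-scored vector: mean 0, population SD 1 unless constant.
#' @export
zscore <- function(values) {
  stopifnot(length(values) >= 1L)
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) {
    out <- rep(0, length(values))
    attr(out, "constant") <- TRUE
    return(out)
  }
  (values - m) / s
}

#' Per-pair score table
#'
#' @param model a fitted \code{smrf_model}.
#' @return data.frame: i, j, distance, raw, apc, z (one row per edge).
#' @export
score_pairs <- function(model) {
  raw <- pairwise_score(model)
  apc <- apc_correct(raw, model$graph)
  z <- if (length(apc)) as.numeric(zscore(apc)) else numeric(0)
  data.frame(i = model$graph$edges[, 1], j = model$graph$edges[, 2],
             distance = model$graph$distances, raw = raw, apc = apc, z = z)
}

#' Per-residue score table
#'
#' Computes the positional coevolution scores (NW from node weights, EW
#' proximity average, FC coevolving fraction) and the KLD/JSD conservation
#' scores, each with its Z-normalized companion. Flags mark isolated nodes
#' (no contacts) and all-gap columns.
#'
#' @param model a fitted \code{smrf_model}.
#' @param msa the \code{smrf_msa} the model was fitted to.
#' @return data.frame with columns position, residue, nw, ew, fc, kld, jsd,
#'   nw_z, ew_z, fc_z, kld_z, jsd_z, isolated, all_gap.
#' @export
score_residues <- function(model, msa) {
  L <- nrow(model$v)
  if (ncol(msa$seq) != L) stop("MSA width does not match model size")
  ft <- frequency_table(msa)
  pr <- score_pairs(model)
  ew <- positional_ew(pr$apc, model$graph)
  fc <- positional_fc(pr$z, model$graph)
  nw <- kld <- jsd <- numeric(L)
  for (i in seq_len(L)) {
    p_i <- node_distribution(model$v[i, ])
    nw[i] <- positional_nw(ft$f[i, ], p_i)
    kld[i] <- conservation_kld(ft$f[i, ], ft$q)
    jsd[i] <- conservation_jsd(ft$f[i, ], ft$q)
  }
  qrow <- msa$seq[msa$query_index, ]
  data.frame(position = seq_len(L), residue = decode_states(qrow),
             nw = nw, ew = as.numeric(ew), fc = as.numeric(fc),
             kld = kld, jsd = jsd,
             nw_z = as.numeric(zscore(nw)), ew_z = as.numeric(zscore(ew)),
             fc_z = as.numeric(zscore(fc)), kld_z = as.numeric(zscore(kld)),
             jsd_z = as.numeric(zscore(jsd)),
             isolated = attr(ew, "isolated"), all_gap = ft$all_gap)
}

#' Write score tables as TSV
#' @param model a fitted \code{smrf_model}.
#' @param msa the fitted-to \code{smrf_msa}.
#' @param prefix output path prefix; writes \code{<prefix>_residues.tsv} and
#'   \code{<prefix>_pairs.tsv}.
#' @return The two paths, invisibly.
#' @export
write_scores <- function(model, msa, prefix) {
  pr <- file.path(paste0(prefix, "_residues.tsv"))
  pp <- file.path(paste0(prefix, "_pairs.tsv"))
  utils::write.table(score_residues(model, msa), pr, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(score_pairs(model), pp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pr, pp))
}
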