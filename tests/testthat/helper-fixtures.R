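# Shared fixture builders. Everything is generated in code; nothing binary.

# small MSA from explicit strings
msa_from_strings <- function(strings, query_index = 1L) {
  mat <- matrix(encode_states(unlist(strsplit(strings, ""))),
                nrow = length(strings), byrow = TRUE)
  new_msa(mat, query_index = query_index)
}

# random MSA with states in 1..21
random_msa <- function(M, L, seed = 1L) {
  set.seed(seed)
  new_msa(matrix(sample.int(21L, M * L, replace = TRUE), M, L))
}

# random small model on a random graph, for gradient/normalization checks
random_model <- function(L, n_edges, seed = 1L, sd_v = 0.3, sd_w = 0.2) {
  set.seed(seed)
  pairs <- t(utils::combn(L, 2))
  pick <- sample.int(nrow(pairs), min(n_edges, nrow(pairs)))
  edges <- pairs[pick, , drop = FALSE]
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  graph <- new_contact_graph(L, edges)
  v <- matrix(stats::rnorm(L * 21L, sd = sd_v), L, 21L)
  w <- replicate(nrow(edges), matrix(stats::rnorm(441L, sd = sd_w), 21L, 21L),
                 simplify = FALSE)
  new_mrf_model(v, w, graph)
}

# full objective R - pll evaluated from packed parameters (oracle plumbing)
objective_at <- function(par, graph, msa, config = training_config()) {
  L <- graph$n_nodes; E <- nrow(graph$edges)
  v <- matrix(par[seq_len(L * 21L)], L, 21L)
  rest <- par[-seq_len(L * 21L)]
  w <- lapply(seq_len(E), function(e)
    matrix(rest[((e - 1L) * 441L + 1L):(e * 441L)], 21L, 21L))
  m <- new_mrf_model(v, w, graph)
  regularization_penalty(m, config)$value - pseudo_loglikelihood(m, msa)$value
}

pack_model <- function(model) c(model$v, unlist(model$w))

# minimal PDB writer for fixtures (fixed-column ATOM records)
write_toy_pdb <- function(path, residues) {
  # residues: data.frame(resname, chain, resseq, atoms = list of
  #   list(name, x, y, z, altloc))
  lines <- character(0)
  serial <- 0L
  for (r in seq_len(nrow(residues))) {
    for (a in residues$atoms[[r]]) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial, paste0(" ", a$name), if (is.null(a$altloc)) " " else a$altloc,
        residues$resname[r], residues$chain[r], residues$resseq[r],
        a$x, a$y, a$z))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

toy_residue <- function(resname, chain, resseq, atoms) {
  data.frame(resname = resname, chain = chain, resseq = resseq,
             atoms = I(list(atoms)))
}

atom <- function(name, x, y, z, altloc = NULL) {
  list(name = name, x = x, y = y, z = z, altloc = altloc)
}
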