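# PDB parsing, representative atoms, contact graph, structure-to-MSA mapping.

AA3TO1 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
            GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
            MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
            SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")

#' Extract representative atoms from a PDB chain
#'
#' One representative atom per resolved standard residue, in chain order:
#' C-beta, except glycine (no C-beta) and residues with a missing C-beta,
#' which fall back to C-alpha (the latter with a warning). HETATM records,
#' waters and non-standard residues are skipped; only the first altloc and
#' the first model of multi-model (NMR) files are used.
#'
#' @param pdb path to a PDB file.
#' @param chain chain identifier; default is the first chain with ATOM
#'   records.
#' @return A data.frame with one row per residue: \code{seq_position}
#'   (1-based along resolved residues), \code{residue_name} (3-letter),
#'   \code{aa} (1-letter), \code{rep_atom} (\code{"CB"} or \code{"CA"}),
#'   \code{x}, \code{y}, \code{z} (Angstrom).
#' @export
extract_representative_atoms <- function(pdb, chain = NULL) {
  lines <- readLines(pdb, warn = FALSE)
  end_model <- grep("^ENDMDL", lines)
  if (length(end_model) > 0L) lines <- lines[seq_len(end_model[1L] - 1L)]
  atom <- lines[startsWith(lines, "ATOM  ")]
  if (length(atom) == 0L) stop("no ATOM records in ", pdb)
  parse_fw <- function(x, a, b) substr(x, a, b)
  name   <- trimws(parse_fw(atom, 13, 16))
  altloc <- parse_fw(atom, 17, 17)
  resn   <- trimws(parse_fw(atom, 18, 20))
  ch     <- parse_fw(atom, 22, 22)
  resid  <- paste0(parse_fw(atom, 23, 26), parse_fw(atom, 27, 27))
  if (is.null(chain)) chain <- ch[1L]
  keep <- ch == chain & name %in% c("CA", "CB") & resn %in% names(AA3TO1)
  if (!any(ch == chain)) stop("chain '", chain, "' not found in ", pdb)
  atom <- atom[keep]; name <- name[keep]; altloc <- altloc[keep]
  resn <- resn[keep]; resid <- resid[keep]
  if (length(atom) == 0L) stop("no resolved standard residues in chain ", chain)
  # first altloc only: drop duplicate (residue, atom-name) entries
  dup <- duplicated(paste(resid, name))
  atom <- atom[!dup]; name <- name[!dup]; resn <- resn[!dup]
  resid <- resid[!dup]
  xyz <- cbind(as.numeric(substr(atom, 31, 38)),
               as.numeric(substr(atom, 39, 46)),
               as.numeric(substr(atom, 47, 54)))
  order_res <- unique(resid)
  out <- vector("list", length(order_res))
  n_fallback <- 0L
  for (r in seq_along(order_res)) {
    sel <- which(resid == order_res[r])
    rn <- resn[sel[1L]]
    cb <- sel[name[sel] == "CB"]
    ca <- sel[name[sel] == "CA"]
    if (rn != "GLY" && length(cb) > 0L) {
      pick <- cb[1L]; rep_atom <- "CB"
    } else if (length(ca) > 0L) {
      pick <- ca[1L]; rep_atom <- "CA"
      if (rn != "GLY") n_fallback <- n_fallback + 1L
    } else {
      next  # residue with neither CA nor CB: unresolved, skip
    }
    out[[r]] <- data.frame(seq_position = NA_integer_, residue_name = rn,
                           aa = unname(AA3TO1[rn]), rep_atom = rep_atom,
                           x = xyz[pick, 1], y = xyz[pick, 2],
                           z = xyz[pick, 3], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L)
    stop("no resolved standard residues in chain ", chain)
  res$seq_position <- seq_len(nrow(res))
  if (n_fallback > 0L)
    warning(n_fallback, " non-GLY residue(s) missing CB; CA used instead")
  rownames(res) <- NULL
  res
}

#' Build the intramolecular contact graph
#'
#' An edge joins residues i and j when their representative atoms are closer
#' than \code{cutoff} (strict) and the pair is separated by at least
#' \code{min_separation} along the chain. The default 8-Angstrom C-beta
#' cutoff follows the CASP contact definition; no sequence-separation filter
#' is imposed by default.
#'
#' @param coords data.frame from \code{\link{extract_representative_atoms}},
#'   or an n x 3 numeric coordinate matrix.
#' @param cutoff contact distance in Angstrom (default 8).
#' @param min_separation minimum |i - j| for an eligible pair (default 1).
#' @return An object of class \code{smrf_graph}: \code{n_nodes}, \code{edges}
#'   (E x 2 integer matrix with i < j), \code{distances} (length E, Angstrom).
#' @export
build_contact_graph <- function(coords, cutoff = 8.0, min_separation = 1L) {
  xyz <- if (is.data.frame(coords)) as.matrix(coords[, c("x", "y", "z")])
         else as.matrix(coords)
  if (nrow(xyz) == 0L) stop("no coordinates")
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d) & d < cutoff &
                 abs(row(d) - col(d)) >= min_separation, arr.ind = TRUE)
  edges <- cbind(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
  o <- order(edges[, 1], edges[, 2])
  new_contact_graph(n, edges[o, , drop = FALSE], d[idx][o])
}

#' @rdname build_contact_graph
#' @param n_nodes node count.
#' @param edges E x 2 integer matrix, 1-based, i < j.
#' @param distances numeric length E.
#' @export
new_contact_graph <- function(n_nodes, edges, distances = rep(NA_real_,
                                                              nrow(edges))) {
  edges <- matrix(as.integer(edges), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  if (nrow(edges) > 0L) {
    if (any(edges[, 1] >= edges[, 2])) stop("edges must satisfy i < j")
    if (any(edges < 1L | edges > n_nodes)) stop("edge endpoint out of range")
    if (anyDuplicated(paste(edges[, 1], edges[, 2]))) stop("duplicate edges")
  }
  structure(list(n_nodes = as.integer(n_nodes), edges = edges,
                 distances = as.numeric(distances)), class = "smrf_graph")
}

#' @export
print.smrf_graph <- function(x, ...) {
  cat(sprintf("smrf_graph: %d nodes, %d edges\n", x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' Neighbors of a node in a contact graph
#' @param graph an \code{smrf_graph}.
#' @param i node index.
#' @return Integer vector of neighboring nodes.
#' @export
graph_neighbors <- function(graph, i) {
  e <- graph$edges
  sort(c(e[e[, 1] == i, 2], e[e[, 2] == i, 1]))
}

# rows of graph$edges incident to node i
incident_edges <- function(graph, i) {
  which(graph$edges[, 1] == i | graph$edges[, 2] == i)
}

#' Map structure residues to MSA columns
#'
#' If the structure sequence equals the query's ungapped sequence the mapping
#' is the identity; otherwise a global alignment (BLOSUM62) is computed and
#' positions aligned to identical residues are mapped. Structure positions are
#' then carried to alignment columns through the query row. A mapped identity
#' below 90 percent raises an error (likely a wrong chain or MSA pairing).
#'
#' @param structure_seq one-letter amino-acid string of the resolved chain.
#' @param msa an \code{smrf_msa}.
#' @return A data.frame with columns \code{struct_pos} and \code{column}.
#' @export
map_structure_to_msa <- function(structure_seq, msa) {
  qseq <- query_sequence(msa)
  if (nchar(structure_seq) == 0L || nchar(qseq) == 0L)
    stop("empty sequence")
  qcol <- query_columns(msa)
  if (structure_seq == qseq) {
    return(data.frame(struct_pos = seq_len(nchar(qseq)), column = qcol))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(structure_seq), Biostrings::AAString(qseq),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  pi <- cumsum(p != "-")
  si <- cumsum(s != "-")
  hit <- p != "-" & s != "-" & p == s
  ident <- sum(hit) / min(nchar(structure_seq), nchar(qseq))
  if (ident < 0.9)
    stop(sprintf(
      "structure/MSA mismatch: mapped identity %.1f%% (< 90%%)", 100 * ident))
  data.frame(struct_pos = pi[hit], column = qcol[si[hit]])
}

#' Transfer a structure contact graph onto MSA columns
#'
#' Relabels graph nodes from structure positions to alignment columns using a
#' mapping from \code{\link{map_structure_to_msa}}. Columns without a mapped
#' resolved residue become isolated nodes (no incident edges), since the
#' structure carries no contact information for them.
#'
#' @param graph contact graph over structure positions.
#' @param mapping data.frame(struct_pos, column).
#' @param L number of alignment columns.
#' @return An \code{smrf_graph} over \code{1..L}.
#' @export
transfer_graph <- function(graph, mapping, L) {
  col_of <- rep(NA_integer_, graph$n_nodes)
  col_of[mapping$struct_pos] <- mapping$column
  a <- col_of[graph$edges[, 1]]
  b <- col_of[graph$edges[, 2]]
  keep <- !is.na(a) & !is.na(b)
  edges <- cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
  o <- order(edges[, 1], edges[, 2])
  new_contact_graph(L, edges[o, , drop = FALSE], graph$distances[keep][o])
}

#' Contact graph on MSA columns, straight from a PDB file
#'
#' Convenience pipeline: representative atoms, structure contact graph,
#' structure-to-MSA mapping, graph transfer.
#'
#' @inheritParams extract_representative_atoms
#' @inheritParams build_contact_graph
#' @param msa an \code{smrf_msa}.
#' @return An \code{smrf_graph} over the MSA columns.
#' @export
contact_graph_for_msa <- function(pdb, msa, chain = NULL, cutoff = 8.0,
                                  min_separation = 1L) {
  coords <- extract_representative_atoms(pdb, chain)
  g <- build_contact_graph(coords, cutoff, min_separation)
  mp <- map_structure_to_msa(paste(coords$aa, collapse = ""), msa)
  transfer_graph(g, mp, ncol(msa$seq))
}

#' Write a contact graph as TSV
#' @param graph an \code{smrf_graph}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_contact_graph <- function(graph, path) {
  df <- data.frame(i = graph$edges[, 1], j = graph$edges[, 2],
                   distance = graph$distances)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
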