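# Alignment input/output and column/background frequencies.

#' Construct an MSA object
#'
#' An \code{smrf_msa} holds an integer-encoded alignment (M rows, L columns,
#' states in 1..21) plus a designated query row, whose ungapped sequence
#' defines the column-to-residue correspondence.
#'
#' @param seq integer matrix (M x L) of states in \code{1..21}.
#' @param ids character vector of M record identifiers.
#' @param query_index row index of the query sequence (default 1).
#' @return An object of class \code{smrf_msa}.
#' @export
new_msa <- function(seq, ids = NULL, query_index = 1L) {
  if (!is.matrix(seq) || !is.numeric(seq))
    stop("`seq` must be an integer matrix")
  if (nrow(seq) < 1L) stop("empty MSA: at least one row is required")
  storage.mode(seq) <- "integer"
  if (any(seq < 1L | seq > 21L)) stop("states must lie in 1..21")
  if (is.null(ids)) ids <- paste0("seq_", seq_len(nrow(seq)))
  if (length(ids) != nrow(seq)) stop("ids length must equal row count")
  query_index <- as.integer(query_index)
  if (query_index < 1L || query_index > nrow(seq)) stop("invalid query index")
  structure(list(seq = seq, ids = ids, query_index = query_index),
            class = "smrf_msa")
}

#' @export
print.smrf_msa <- function(x, ...) {
  cat(sprintf("smrf_msa: %d sequences x %d columns (query: %s)\n",
              nrow(x$seq), ncol(x$seq), x$ids[x$query_index]))
  invisible(x)
}

#' @export
dim.smrf_msa <- function(x) dim(x$seq)

#' Ungapped query sequence of an MSA
#' @param msa an \code{smrf_msa}.
#' @return Single string of amino-acid letters (gaps removed).
#' @export
query_sequence <- function(msa) {
  row <- msa$seq[msa$query_index, ]
  paste(decode_states(row[row != gap_state()]), collapse = "")
}

#' Columns occupied by the query
#'
#' Maps residue positions of the ungapped query to alignment columns.
#'
#' @param msa an \code{smrf_msa}.
#' @return Integer vector: element r is the column of query residue r.
#' @export
query_columns <- function(msa) {
  which(msa$seq[msa$query_index, ] != gap_state())
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA (all records equal length) and A3M, where lowercase
#' letters are insertions relative to the query and are deleted before
#' encoding. Any non-canonical letter encodes as the gap state.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"fasta"} or \code{"a3m"}.
#' @param query id of the query record; default is the first record.
#' @return An \code{smrf_msa}.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "a3m"), query = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.a3m$", path, ignore.case = TRUE)) "a3m" else "fasta"
  }
  recs <- read_fasta_records(path)
  if (length(recs$seq) == 0L) stop("empty alignment file: ", path)
  seqs <- recs$seq
  if (format == "a3m") seqs <- gsub("[a-z.]", "", seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: record lengths differ (", min(lens), "..",
         max(lens), ")")
  mat <- matrix(encode_states(unlist(strsplit(seqs, ""), use.names = FALSE)),
                nrow = length(seqs), byrow = TRUE)
  qi <- 1L
  if (!is.null(query)) {
    qi <- match(query, recs$id)
    if (is.na(qi)) stop("query id not found: ", query)
  }
  new_msa(mat, ids = recs$id, query_index = qi)
}

# Raw FASTA/A3M record reader (BStringSet: tolerates lowercase A3M insert
# states and ragged records, which are checked after insert stripping).
read_fasta_records <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  list(id = ids, seq = as.character(unname(set)))
}

#' Write an MSA as aligned FASTA
#' @param msa an \code{smrf_msa}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_msa <- function(msa, path) {
  letters <- matrix(decode_states(msa$seq), nrow = nrow(msa$seq))
  txt <- character(2L * nrow(msa$seq))
  txt[c(TRUE, FALSE)] <- paste0(">", msa$ids)
  txt[c(FALSE, TRUE)] <- apply(letters, 1, paste, collapse = "")
  writeLines(txt, path)
  invisible(path)
}

#' Per-column amino-acid frequencies
#'
#' Column frequencies f_i over the 20 amino acids with gap-excluded
#' normalization: the denominator of column i is its non-gap count. An
#' all-gap column receives the uniform distribution 1/20 and is flagged.
#'
#' @param msa an \code{smrf_msa}.
#' @return L x 20 matrix; rows sum to 1. Attribute \code{"all_gap"} is a
#'   logical length-L vector marking flagged columns.
#' @export
column_frequencies <- function(msa) {
  L <- ncol(msa$seq)
  f <- matrix(0, L, 20L, dimnames = list(NULL, smrf_alphabet()[1:20]))
  all_gap <- logical(L)
  for (i in seq_len(L)) {
    cnt <- tabulate(msa$seq[, i], nbins = 21L)[1:20]
    tot <- sum(cnt)
    if (tot == 0L) {
      f[i, ] <- 1 / 20
      all_gap[i] <- TRUE
    } else {
      f[i, ] <- cnt / tot
    }
  }
  if (any(all_gap))
    warning(sum(all_gap), " all-gap column(s); uniform frequencies assigned")
  attr(f, "all_gap") <- all_gap
  f
}

#' Background amino-acid frequencies
#'
#' Overall amino-acid frequency q across the whole alignment (gap-excluded).
#' Amino acids never observed receive a pseudocount fraction of 1e-6 before
#' renormalization so that KL divergences against q stay finite.
#'
#' @param msa an \code{smrf_msa}.
#' @return Numeric vector of length 20 summing to 1, strictly positive.
#' @export
background_frequencies <- function(msa) {
  cnt <- tabulate(msa$seq, nbins = 21L)[1:20]
  tot <- sum(cnt)
  if (tot == 0L) stop("degenerate MSA: all states are gaps")
  q <- cnt / tot
  q[q == 0] <- 1e-6
  q <- q / sum(q)
  names(q) <- smrf_alphabet()[1:20]
  q
}

#' Column and background frequencies together
#' @param msa an \code{smrf_msa}.
#' @return List with \code{f} (L x 20), \code{q} (length 20) and
#'   \code{all_gap} flags.
#' @export
frequency_table <- function(msa) {
  f <- column_frequencies(msa)
  list(f = f, q = background_frequencies(msa),
       all_gap = attr(f, "all_gap"))
}

#' Export column frequencies as TSV
#' @param msa an \code{smrf_msa}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_frequencies <- function(msa, path) {
  f <- column_frequencies(msa)
  df <- data.frame(position = seq_len(nrow(f)), f, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
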