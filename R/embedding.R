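#' Column means of a per-residue embedding matrix
#'
#' The protein-wise average embedding: element j is the arithmetic mean of
#' column j over all residues of the protein.
#'
#' @param matrix numeric L x D matrix (row i = residue i).
#' @return numeric vector of length D.
#' @export
proteinAverage <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) < 1L)
    stop("embedding matrix must have at least one row")
  colMeans(matrix)
}

#' Compute per-residue embeddings for a set of proteins
#'
#' Two backends sit behind one contract: an `L x D` finite matrix per
#' protein, row i corresponding to residue i (1-based).
#'
#' * `"synthetic"` — a pure deterministic function of
#'   (protein id, position, residue letter, `seed`): each residue row is a
#'   standard-Gaussian draw seeded from a hash of that key, so identical
#'   inputs give bit-identical matrices and changing one residue changes
#'   (at least) that row.  Intended for testing and fixtures.
#' * `"precomputed"` — reads matrices produced by a real protein language
#'   model from a container file written by [writeEmbeddings()]; matrix row
#'   counts are validated against the sequences.  If `file` is missing the
#'   function fails with a `backend_missing` error rather than silently
#'   falling back.
#'
#' @param proteins [Biostrings::AAStringSet].
#' @param backend `"synthetic"` or `"precomputed"`.
#' @param dim embedding dimension D (default 1024, matching common protein
#'   language models; tests use small D).
#' @param seed integer seed for the synthetic backend.
#' @param file container path for the precomputed backend.
#' @return [EmbeddingSet-class].
#' @export
embedProteins <- function(proteins, backend = c("synthetic", "precomputed"),
                          dim = 1024L, seed = 1L, file = NULL) {
  backend <- match.arg(backend)
  dim <- as.integer(dim)
  stopifnot(dim >= 1L)
  if (backend == "precomputed") {
    if (is.null(file) || !file.exists(file))
      stop("backend_missing: no precomputed embedding container at '",
           file, "'")
    return(readEmbeddings(file, proteins))
  }
  seqs <- as.character(proteins)
  mats <- lapply(names(seqs), function(pid) {
    chars <- strsplit(seqs[[pid]], "")[[1]]
    m <- matrix(0, nrow = length(chars), ncol = dim)
    for (i in seq_along(chars)) {
      h <- string_hash31(paste(pid, i, chars[i], seed, sep = "\r"))
      m[i, ] <- with_seed(h, stats::rnorm(dim))
    }
    m
  })
  names(mats) <- names(seqs)
  new("EmbeddingSet", matrices = mats, dim = dim)
}

#' Assemble per-site feature vectors
#'
#' One feature vector per site, in site order: the first D entries are the
#' embedding row at the site's position, the last D the protein-wise average
#' embedding (identical for all sites of one protein).  Embeddings are used
#' as-is; no scaling is applied.
#'
#' @param table [PhosphoSiteTable-class].
#' @param embeddings [EmbeddingSet-class] covering every protein with sites,
#'   with matrix row counts equal to sequence lengths.
#' @return numeric matrix (n_sites x 2D) with rownames `protein|position`.
#' @export
assembleFeatures <- function(table, embeddings) {
  stopifnot(is(table, "PhosphoSiteTable"), is(embeddings, "EmbeddingSet"))
  s <- siteRecords(table)
  D <- embeddingDim(embeddings)
  widths <- Biostrings::width(proteinSeqs(table))
  names(widths) <- names(proteinSeqs(table))
  pids <- unique(s$protein_id)
  avg <- matrix(NA_real_, length(pids), D, dimnames = list(pids, NULL))
  for (pid in pids) {
    m <- embeddingMatrix(embeddings, pid)
    if (nrow(m) != widths[[pid]])
      stop("embedding rows (", nrow(m), ") do not match sequence length (",
           widths[[pid]], ") for protein '", pid, "'")
    avg[pid, ] <- proteinAverage(m)
  }
  out <- matrix(NA_real_, nrow(s), 2L * D)
  for (i in seq_len(nrow(s))) {
    m <- embeddings@matrices[[s$protein_id[i]]]
    out[i, ] <- c(m[s$position[i], ], avg[s$protein_id[i], ])
  }
  rownames(out) <- site_key(s$protein_id, s$position)
  out
}

#' Write / read an embedding container
#'
#' Plain-text container: a TSV with columns `protein_id`, `position`, then
#' `V1..VD`.  One row per residue; the dimension is recovered from the
#' header.  `readEmbeddings()` validates the per-protein row counts against
#' the given sequences.
#'
#' @param embeddings [EmbeddingSet-class].
#' @param path container file path.
#' @param proteins optional [Biostrings::AAStringSet] used to validate
#'   lengths on read.
#' @return `writeEmbeddings`: the path, invisibly. `readEmbeddings`: an
#'   [EmbeddingSet-class].
#' @export
writeEmbeddings <- function(embeddings, path) {
  stopifnot(is(embeddings, "EmbeddingSet"))
  rows <- lapply(names(embeddings@matrices), function(pid) {
    m <- embeddings@matrices[[pid]]
    data.frame(protein_id = pid, position = seq_len(nrow(m)), m,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  names(df) <- c("protein_id", "position",
                 paste0("V", seq_len(embeddings@dim)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEmbeddings
#' @export
readEmbeddings <- function(path, proteins = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  vcols <- grep("^V\\d+$", names(df))
  D <- length(vcols)
  if (D < 1L) stop("no embedding columns (V1..VD) found in '", path, "'")
  mats <- lapply(split(df, df$protein_id), function(sub) {
    sub <- sub[order(sub$position), , drop = FALSE]
    if (!identical(as.integer(sub$position), seq_len(nrow(sub))))
      stop("embedding container has non-contiguous positions for '",
           sub$protein_id[1], "'")
    as.matrix(sub[, vcols, drop = FALSE])
  })
  mats <- lapply(mats, function(m) { dimnames(m) <- NULL; m })
  es <- new("EmbeddingSet", matrices = mats, dim = as.integer(D))
  if (!is.null(proteins)) {
    w <- Biostrings::width(proteins)
    names(w) <- names(proteins)
    for (pid in names(mats)) {
      if (pid %in% names(w) && nrow(mats[[pid]]) != w[[pid]])
        stop("embedding rows do not match sequence length for protein '",
             pid, "'")
    }
  }
  es
}
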