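#' Configuration for the synthetic fixture generator
#'
#' The generators emulate the structure of a plant phosphoproteomics
#' dataset at desk scale: random canonical protein sequences, a minority
#' positive class among S/T/Y residues (about 10%, mirroring the strong
#' label imbalance of experimental phosphosite tables), Gaussian per-residue
#' embeddings whose positive-site rows are shifted by a controlled offset,
#' point-mutated homolog proteomes that preserve phosphosite letters, and
#' multi-exon gene models.  All generators are pure functions of
#' (config, seed).
#'
#' @param nProteins number of proteins (default 100).
#' @param lengthRange inclusive range of protein lengths (default 50..80).
#' @param positiveFraction fraction of S/T/Y residues labeled positive, per
#'   residue type (default 0.1).
#' @param embeddingDim embedding dimension D for [makeEmbeddings()]
#'   (default 16).
#' @param delta class-separation offset: the Euclidean norm of the fixed
#'   vector added to positive-site embedding rows (default 2; 0 means no
#'   signal).
#' @param mutationRate per-residue substitution probability for
#'   [makeHomologs()] (default 0.1).
#' @param seed integer seed (default 1).
#' @return list of class `"FixtureConfig"`.
#' @export
fixtureConfig <- function(nProteins = 100L, lengthRange = c(50L, 80L),
                          positiveFraction = 0.1, embeddingDim = 16L,
                          delta = 2, mutationRate = 0.1, seed = 1L) {
  stopifnot(positiveFraction > 0, positiveFraction < 1, delta >= 0,
            mutationRate >= 0, mutationRate < 1, nProteins >= 1)
  structure(list(nProteins = as.integer(nProteins),
                 lengthRange = as.integer(lengthRange),
                 positiveFraction = positiveFraction,
                 embeddingDim = as.integer(embeddingDim),
                 delta = delta, mutationRate = mutationRate,
                 seed = as.integer(seed)),
            class = "FixtureConfig")
}

#' Generate a toy proteome with planted phosphosites
#'
#' Sequences are uniform over the 20 canonical amino acids; within each
#' residue type (S, T, Y) a `positiveFraction` of residues is sampled as
#' experimentally positive.  All remaining S/T/Y residues are labeled
#' negative.
#'
#' @param cfg a [fixtureConfig()].
#' @return [PhosphoSiteTable-class] containing positives and negatives for
#'   the generated proteome.
#' @export
makeProteome <- function(cfg = fixtureConfig()) {
  stopifnot(inherits(cfg, "FixtureConfig"))
  with_seed(cfg$seed, {
    lens <- sample(seq(cfg$lengthRange[1], cfg$lengthRange[2]),
                   cfg$nProteins, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(CANONICAL_AA, L, replace = TRUE), collapse = ""),
      character(1))
    names(seqs) <- sprintf("prot%04d", seq_len(cfg$nProteins))
    proteins <- Biostrings::AAStringSet(seqs)
    pos_rows <- lapply(names(seqs), function(pid) {
      chars <- strsplit(seqs[[pid]], "")[[1]]
      sel <- unlist(lapply(PHOSPHO_RESIDUES, function(res) {
        at <- which(chars == res)
        at[stats::runif(length(at)) < cfg$positiveFraction]
      }))
      if (!length(sel)) return(NULL)
      sel <- sort(sel)
      data.frame(protein_id = pid, position = sel, residue = chars[sel],
                 source = "fixture", stringsAsFactors = FALSE)
    })
    raw <- do.call(rbind, pos_rows)
    deriveNegatives(crossReference(raw, proteins))
  })
}

#' Generate class-separable synthetic embeddings
#'
#' Rows are the deterministic synthetic backend draws of
#' [embedProteins()]; rows at positive (or inferred-positive) sites are
#' additionally shifted by `delta` times the first standard basis vector,
#' so downstream classifier performance is a controlled function of `delta`
#' and `delta = 0` carries no signal.  The offset is axis-aligned — the
#' planted effect lives on one embedding coordinate — mirroring how tree
#' ensembles partition feature space, so the Bayes separation
#' (AUROC = pnorm(delta / sqrt(2))) is attainable by the intended learner.
#' Negative-site rows are identical across `delta` values.
#'
#' @param proteome [PhosphoSiteTable-class] from [makeProteome()].
#' @param cfg a [fixtureConfig()].
#' @return [EmbeddingSet-class].
#' @export
makeEmbeddings <- function(proteome, cfg = fixtureConfig()) {
  stopifnot(is(proteome, "PhosphoSiteTable"), inherits(cfg, "FixtureConfig"))
  es <- embedProteins(proteinSeqs(proteome), "synthetic",
                      dim = cfg$embeddingDim, seed = cfg$seed)
  if (cfg$delta > 0) {
    shift <- c(cfg$delta, rep(0, cfg$embeddingDim - 1L))
    s <- siteRecords(proteome)
    pos <- s[s$label %in% c("positive", "inferred_positive"), , drop = FALSE]
    for (i in seq_len(nrow(pos))) {
      pid <- pos$protein_id[i]
      es@matrices[[pid]][pos$position[i], ] <-
        es@matrices[[pid]][pos$position[i], ] + shift
    }
  }
  es
}

#' Generate a point-mutated homolog proteome
#'
#' Each protein is copied (id suffixed `_h`) with every residue substituted
#' independently with probability `mutationRate` — except planted positive
#' site positions, whose letters are preserved so transfer ground truth
#' stays intact.  Only site letters are guaranteed; elsewhere substitutions
#' may freely create or destroy S/T/Y residues.
#'
#' @param proteome [PhosphoSiteTable-class] from [makeProteome()].
#' @param cfg a [fixtureConfig()].
#' @return [PhosphoSiteTable-class]: homolog proteins with the mapped
#'   positive sites (same positions, `_h` ids) and derived negatives.
#' @export
makeHomologs <- function(proteome, cfg = fixtureConfig()) {
  stopifnot(is(proteome, "PhosphoSiteTable"), inherits(cfg, "FixtureConfig"))
  s <- siteRecords(proteome)
  pos <- s[s$label == "positive", , drop = FALSE]
  seqs <- as.character(proteinSeqs(proteome))
  with_seed(cfg$seed + 104729L, {
    hseqs <- vapply(names(seqs), function(pid) {
      chars <- strsplit(seqs[[pid]], "")[[1]]
      keep <- pos$position[pos$protein_id == pid]
      mut <- which(stats::runif(length(chars)) < cfg$mutationRate)
      mut <- setdiff(mut, keep)
      for (i in mut)
        chars[i] <- sample(setdiff(CANONICAL_AA, chars[i]), 1)
      paste(chars, collapse = "")
    }, character(1))
  })
  names(hseqs) <- paste0(names(seqs), "_h")
  hproteins <- Biostrings::AAStringSet(hseqs)
  raw <- data.frame(protein_id = paste0(pos$protein_id, "_h"),
                    position = pos$position, residue = pos$residue,
                    source = "homolog_map", stringsAsFactors = FALSE)
  deriveNegatives(crossReference(raw, hproteins))
}

#' Generate random gene models for a proteome
#'
#' Every protein gets a gene model with 1-3 CDS segments whose total length
#' is exactly `3 * L` bases, on a random strand, with intron gaps of
#' 30-300 bases; models are laid out head-to-tail along one chromosome.
#'
#' @param proteome [PhosphoSiteTable-class].
#' @param cfg a [fixtureConfig()].
#' @return named list of gene models (see [readGeneModels()] for the
#'   layout), named by protein id.
#' @export
makeGeneModels <- function(proteome, cfg = fixtureConfig()) {
  stopifnot(is(proteome, "PhosphoSiteTable"))
  widths <- Biostrings::width(proteinSeqs(proteome))
  pids <- names(proteinSeqs(proteome))
  offset <- 1000L
  with_seed(cfg$seed + 7919L, {
    models <- lapply(seq_along(pids), function(i) {
      total <- 3L * widths[i]
      nseg <- sample(1:3, 1)
      nseg <- min(nseg, total)
      cuts <- sort(sample(seq_len(total - 1L), nseg - 1L))
      seg_len <- diff(c(0L, cuts, total))
      strand <- sample(c("+", "-"), 1)
      starts <- integer(nseg); ends <- integer(nseg)
      at <- offset
      for (k in seq_len(nseg)) {
        starts[k] <- at
        ends[k] <- at + seg_len[k] - 1L
        at <- ends[k] + sample(30:300, 1)
      }
      offset <<- at + 500L
      segs <- data.frame(start = starts, end = ends)
      if (strand == "-") segs <- segs[rev(seq_len(nseg)), , drop = FALSE]
      rownames(segs) <- NULL
      list(gene_id = paste0(pids[i], "_g"),
           mrna_id = paste0(pids[i], "_m"),
           protein_id = pids[i], chrom = "chr1", strand = strand,
           cds = segs)
    })
  })
  names(models) <- pids
  models
}

#' Write fixture gene models as GFF3
#'
#' Emits a gene/mRNA/CDS hierarchy readable by [readGeneModels()].
#'
#' @param models gene-model list from [makeGeneModels()].
#' @param path output GFF3 path.
#' @return the path, invisibly.
#' @export
writeGeneModelsGFF3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- range(c(m$cds$start, m$cds$end))
    lines <- c(lines,
      paste(m$chrom, "fixture", "gene", span[1], span[2], ".", m$strand, ".",
            paste0("ID=", m$gene_id), sep = "\t"),
      paste(m$chrom, "fixture", "mRNA", span[1], span[2], ".", m$strand, ".",
            paste0("ID=", m$mrna_id, ";Parent=", m$gene_id,
                   ";protein_id=", m$protein_id), sep = "\t"))
    segs <- m$cds[order(m$cds$start), , drop = FALSE]
    phase <- 0L
    # phase in translation order; reorder back to genomic order for output
    tr <- m$cds
    phases <- integer(nrow(tr))
    for (k in seq_len(nrow(tr))) {
      phases[k] <- phase
      phase <- (3L - ((tr$end[k] - tr$start[k] + 1L - phase) %% 3L)) %% 3L
    }
    ord <- order(tr$start)
    for (j in seq_along(ord)) {
      k <- ord[j]
      lines <- c(lines,
        paste(m$chrom, "fixture", "CDS", tr$start[k], tr$end[k], ".",
              m$strand, phases[k],
              paste0("ID=", m$mrna_id, ".cds;Parent=", m$mrna_id), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
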