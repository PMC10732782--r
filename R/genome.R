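#' Read gene models (CDS structure) from a GFF3 file
#'
#' Parses a gene/mRNA/CDS hierarchy and returns one gene model per mRNA:
#' chromosome, strand, and the CDS segments in translation order (genomic
#' order on `+`, reverse genomic order on `-`).  The protein id defaults to
#' the mRNA's `protein_id` attribute when present, else the mRNA ID.
#' Models whose total CDS length is not divisible by 3 are dropped with a
#' warning.
#'
#' @param path GFF3 file with CDS features carrying `Parent` attributes.
#' @return named list of gene models; each a list with `gene_id`,
#'   `mrna_id`, `protein_id`, `chrom`, `strand`, and `cds` (data.frame
#'   `start`, `end` in translation order).
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (!length(cds)) stop("no CDS features in '", path, "'")
  parents <- vapply(cds$Parent, function(p) p[1], character(1))
  mrna <- gr[gr$type == "mRNA"]
  gene_of <- stats::setNames(vapply(mrna$Parent, function(p)
    if (length(p)) p[1] else NA_character_, character(1)), mrna$ID)
  prot_of <- if (!is.null(mrna$protein_id))
    stats::setNames(mrna$protein_id, mrna$ID) else character(0)
  models <- lapply(split(seq_along(cds), parents), function(idx) {
    sub <- cds[idx]
    strand <- as.character(GenomicRanges::strand(sub))[1]
    ord <- order(GenomicRanges::start(sub),
                 decreasing = identical(strand, "-"))
    sub <- sub[ord]
    mid <- parents[idx][1]
    pid <- if (mid %in% names(prot_of) && !is.na(prot_of[[mid]]))
      prot_of[[mid]] else mid
    list(gene_id = if (mid %in% names(gene_of)) gene_of[[mid]] else NA_character_,
         mrna_id = mid, protein_id = pid,
         chrom = as.character(GenomicRanges::seqnames(sub))[1],
         strand = strand,
         cds = data.frame(start = GenomicRanges::start(sub),
                          end = GenomicRanges::end(sub)))
  })
  lens <- vapply(models, function(m) sum(m$cds$end - m$cds$start + 1L),
                 numeric(1))
  bad <- lens %% 3 != 0
  if (any(bad)) {
    warning(sum(bad), " gene model(s) with CDS length not divisible by 3 ",
            "were dropped")
    models <- models[!bad]
  }
  names(models) <- vapply(models, `[[`, character(1), "protein_id")
  models
}

# Genomic coordinates of all CDS bases in translation order (5' to 3' of
# the coding strand).
#' @keywords internal
cds_base_walk <- function(model) {
  segs <- model$cds
  if (model$strand == "+") {
    unlist(lapply(seq_len(nrow(segs)), function(i)
      seq.int(segs$start[i], segs$end[i])))
  } else {
    unlist(lapply(seq_len(nrow(segs)), function(i)
      seq.int(segs$end[i], segs$start[i])))
  }
}

#' Genomic codon coordinates of a protein residue
#'
#' Returns the genomic positions of the three CDS bases encoding residue
#' `residueIndex`, merged into maximal contiguous blocks: a single
#' 3-base block for codons inside one exon, two blocks when the codon spans
#' an intron.  On the minus strand, translation order runs from the 3'
#' end of the genomic interval.
#'
#' @param model a gene model from [readGeneModels()] or
#'   [makeGeneModels()].
#' @param residueIndex 1-based residue position; must not exceed
#'   CDS length / 3.
#' @return `data.frame` with columns `start`, `end` (1-based inclusive,
#'   ascending genomic coordinates); block lengths always sum to 3.
#' @export
codonCoords <- function(model, residueIndex) {
  bases <- cds_base_walk(model)
  if (residueIndex < 1L || residueIndex > length(bases) %/% 3L)
    stop("residue index ", residueIndex, " outside protein of length ",
         length(bases) %/% 3L)
  codon <- bases[(3L * residueIndex - 2L):(3L * residueIndex)]
  codon <- sort(codon)
  brk <- c(0L, which(diff(codon) != 1L), length(codon))
  blocks <- data.frame(
    start = codon[utils::head(brk, -1) + 1L],
    end = codon[utils::tail(brk, -1)])
  blocks
}

#' Invert codon coordinates back to a residue index
#'
#' Given genomic blocks covering one codon of a model, recovers the 1-based
#' residue index; the inverse of [codonCoords()].
#'
#' @param model a gene model.
#' @param blocks `data.frame` with `start`, `end` genomic blocks.
#' @return integer residue index, or `NA` if the blocks do not match a
#'   codon of this model.
#' @export
residueFromCoords <- function(model, blocks) {
  bases <- sort(unlist(Map(seq.int, blocks$start, blocks$end)))
  if (length(bases) != 3L) return(NA_integer_)
  walk <- cds_base_walk(model)
  for (i in seq_len(length(walk) %/% 3L)) {
    if (identical(sort(walk[(3L * i - 2L):(3L * i)]), bases))
      return(i)
  }
  NA_integer_
}

# Display rules for exported sites: blue = alignment-inferred only,
# red = predicted (p > .5) only, pink = both; bold when p > .9.
#' @keywords internal
site_color <- function(probability, inferred) {
  predicted <- probability > 0.5
  if (predicted && inferred) "pink"
  else if (inferred) "blue"
  else if (predicted) "red"
  else NA_character_
}

#' Export predicted and inferred phosphosites as a GFF3 track
#'
#' Maps each site to its 3-bp genomic codon coordinates through the gene
#' models and writes a genome-browser-ready GFF3 track.  Attribute rules:
#' `color=blue` for sites supported only by alignment inference, `red` for
#' predicted sites (probability strictly above 0.5), `pink` when both
#' apply; `bold=true` when probability exceeds 0.9.  Each feature carries
#' `ID` (`protein|position|residue`), `probability`, `status` and the
#' `;`-safe encoded `matches` list.  Intron-spanning codons are written as
#' two feature lines sharing one `ID` (the GFF3 discontinuous-feature
#' convention).  Sites with probability at or below 0.5 and no alignment
#' support are omitted unless `includeAll`; sites without a gene model are
#' skipped and reported in the `"skipped"` attribute.
#'
#' @param sites `data.frame` with columns `protein_id`, `position`,
#'   `residue`, `probability`, and logical `inferred` (plus optional
#'   `matches`).
#' @param models gene-model list from [readGeneModels()] /
#'   [makeGeneModels()], named by protein id.
#' @param path output GFF3 path.
#' @param includeAll keep sites that are neither predicted nor inferred
#'   (default `FALSE`).
#' @return the path, invisibly, with attribute `"skipped"` listing
#'   unmappable protein ids.
#' @export
writeSiteGFF3 <- function(sites, models, path, includeAll = FALSE) {
  need <- c("protein_id", "position", "residue", "probability", "inferred")
  stopifnot(all(need %in% names(sites)))
  if (is.null(sites$matches)) sites$matches <- ""
  # GFF3 attribute escaping: percent-encode the reserved characters
  enc <- function(x) {
    x <- gsub("%", "%25", x, fixed = TRUE)
    x <- gsub(";", "%3B", x, fixed = TRUE)
    x <- gsub("=", "%3D", x, fixed = TRUE)
    x <- gsub(",", "%2C", x, fixed = TRUE)
    x <- gsub("&", "%26", x, fixed = TRUE)
    gsub("\t", "%09", x, fixed = TRUE)
  }
  lines <- c("##gff-version 3")
  skipped <- character(0)
  for (i in seq_len(nrow(sites))) {
    p <- sites$probability[i]
    inferred <- isTRUE(sites$inferred[i])
    col <- site_color(p, inferred)
    if (is.na(col) && !includeAll) next
    pid <- sites$protein_id[i]
    model <- models[[pid]]
    if (is.null(model)) { skipped <- c(skipped, pid); next }
    blocks <- codonCoords(model, sites$position[i])
    id <- paste(pid, sites$position[i], sites$residue[i], sep = "|")
    attrs <- paste0(
      "ID=", enc(id),
      ";probability=", format(p, digits = 6),
      ";status=", if (is.na(col)) "negative" else col,
      ";bold=", if (!is.na(p) && p > 0.9) "true" else "false",
      ";site_residue=", sites$residue[i],
      ";site_position=", sites$position[i],
      ";protein_id=", enc(pid),
      if (nzchar(sites$matches[i]))
        paste0(";matches=", enc(sites$matches[i])) else "")
    for (b in seq_len(nrow(blocks))) {
      lines <- c(lines, paste(model$chrom, "PhosphoStack",
                              "modified_amino_acid_feature",
                              blocks$start[b], blocks$end[b], ".",
                              model$strand, ".", attrs, sep = "\t"))
    }
  }
  writeLines(lines, path)
  out <- invisible(path)
  attr(out, "skipped") <- unique(skipped)
  invisible(out)
}

#' Read a phosphosite GFF3 track back into a site table
#'
#' Parses a track written by [writeSiteGFF3()], re-merging
#' discontinuous-feature lines that share an `ID`.
#'
#' @param path GFF3 path.
#' @return `data.frame` with `ID`, `protein_id`, `position`, `residue`,
#'   `probability`, `status`, `bold`, `chrom`, `strand` and a list-column
#'   `blocks` of per-site genomic blocks.
#' @export
readSiteGFF3 <- function(path) {
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#")]
  if (!length(raw))
    return(data.frame(ID = character(0)))
  f <- do.call(rbind, strsplit(raw, "\t", fixed = TRUE))
  attr_field <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]*)"), a))
    vapply(m, function(x) if (length(x) == 2) utils::URLdecode(x[2])
           else NA_character_, character(1))
  }
  ids <- attr_field(f[, 9], "ID")
  rows <- lapply(split(seq_len(nrow(f)), ids), function(idx) {
    a <- f[idx[1], 9]
    data.frame(ID = attr_field(a, "ID"),
               protein_id = attr_field(a, "protein_id"),
               position = as.integer(attr_field(a, "site_position")),
               residue = attr_field(a, "site_residue"),
               probability = as.numeric(attr_field(a, "probability")),
               status = attr_field(a, "status"),
               bold = attr_field(a, "bold") == "true",
               chrom = f[idx[1], 1], strand = f[idx[1], 7],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$blocks <- lapply(split(seq_len(nrow(f)), ids), function(idx) {
    b <- data.frame(start = as.integer(f[idx, 4]),
                    end = as.integer(f[idx, 5]))
    b[order(b$start), , drop = FALSE]
  })
  rownames(out) <- NULL
  out
}
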