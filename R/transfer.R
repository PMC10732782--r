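#' Configuration for homology-based annotation transfer
#'
#' @param windowLength odd peptide window length (default 31, the site at
#'   the center for interior residues).
#' @param maxTargets maximum alignment targets kept per query (default 100).
#' @param excludeSelf drop self-matches — same protein id AND same position
#'   (default `TRUE`).
#' @param requireResidueMatch require the aligned subject residue letter to
#'   equal the query residue letter (default `TRUE`, the strict reading;
#'   set `FALSE` to let e.g. an S site match a reference T site).
#' @param aligner `"builtin_sw"` (Smith-Waterman, BLOSUM62, gap open 11 /
#'   extend 1) or `"external_diamond"` (shell out to the diamond binary).
#' @param minScore minimum raw alignment score for a built-in hit to be
#'   reported (default 50); stands in for the external aligner's default
#'   e-value report cutoff, since a local aligner always returns some hit.
#' @return list of class `"TransferConfig"`.
#' @export
transferConfig <- function(windowLength = 31L, maxTargets = 100L,
                           excludeSelf = TRUE, requireResidueMatch = TRUE,
                           aligner = c("builtin_sw", "external_diamond"),
                           minScore = 50) {
  windowLength <- as.integer(windowLength)
  stopifnot(windowLength >= 1L, windowLength %% 2L == 1L, maxTargets >= 1L)
  structure(list(windowLength = windowLength,
                 maxTargets = as.integer(maxTargets),
                 excludeSelf = isTRUE(excludeSelf),
                 requireResidueMatch = isTRUE(requireResidueMatch),
                 aligner = match.arg(aligner), minScore = minScore),
            class = "TransferConfig")
}

#' Extract the peptide window around a candidate site
#'
#' Interior sites get a symmetric window of `windowLength` residues with the
#' site at the center; sites within half a window of an edge get the first
#' (or last) `windowLength` residues, the site's offset determined by its
#' distance from that edge; proteins shorter than the window contribute
#' their whole sequence.
#'
#' @param sequence protein sequence (character scalar).
#' @param position 1-based residue index of the site.
#' @param windowLength odd window length (default 31).
#' @return list with `peptide`, `centerOffset` (0-based index of the site
#'   within the peptide) and `start` (1-based protein coordinate of the
#'   first peptide residue).
#' @export
extractWindow <- function(sequence, position, windowLength = 31L) {
  L <- nchar(sequence)
  if (position < 1L || position > L) stop("position out of range")
  if (L <= windowLength) {
    return(list(peptide = sequence, centerOffset = position - 1L, start = 1L))
  }
  half <- (windowLength - 1L) %/% 2L
  start <- position - half
  if (start < 1L) start <- 1L
  if (start + windowLength - 1L > L) start <- L - windowLength + 1L
  list(peptide = substr(sequence, start, start + windowLength - 1L),
       centerOffset = position - start, start = as.integer(start))
}

# --- btop traceback handling -------------------------------------------------

# Tokenize a btop string into match runs (integers) and 2-character edit
# codes ("XY" substitution, "X-" query-only, "-Y" subject-only).
#' @keywords internal
parse_btop <- function(btop) {
  if (is.na(btop) || btop == "") return(character(0))
  toks <- regmatches(btop, gregexpr("\\d+|[A-Z*][A-Z*]|[A-Z*]-|-[A-Z*]",
                                    btop))[[1]]
  if (sum(nchar(toks)) != nchar(btop)) stop("malformed btop string: ", btop)
  toks
}

#' Map the window center through an alignment traceback
#'
#' Walks the btop traceback from (`qstart`, `sstart`) and returns the
#' 1-based subject position aligned to the query position
#' `centerOffset + 1`.  Returns `NA` ("unaligned") when the center lies
#' outside the locally aligned query range or sits opposite a gap.
#'
#' @param hit one-row `data.frame` (or list) with `qstart`, `qend`,
#'   `sstart`, `send` and `btop`.
#' @param centerOffset 0-based offset of the site within the query peptide.
#' @return subject position (integer) or `NA_integer_`.
#' @export
mapCenter <- function(hit, centerOffset) {
  target <- centerOffset + 1L # 1-based query coordinate of the site
  if (target < hit$qstart || target > hit$qend) return(NA_integer_)
  q <- hit$qstart; s <- hit$sstart
  for (tok in parse_btop(hit$btop)) {
    if (grepl("^\\d+$", tok)) {
      n <- as.integer(tok)
      if (target < q + n) return(as.integer(s + (target - q)))
      q <- q + n; s <- s + n
    } else {
      qc <- substr(tok, 1, 1); sc <- substr(tok, 2, 2)
      if (qc != "-" && sc != "-") {       # substitution: consumes both
        if (q == target) return(as.integer(s))
        q <- q + 1L; s <- s + 1L
      } else if (sc == "-") {             # query residue opposite a gap
        if (q == target) return(NA_integer_)
        q <- q + 1L
      } else {                            # subject-only column
        s <- s + 1L
      }
    }
  }
  NA_integer_
}

# Build a btop string from two equal-length gapped alignment strings.
#' @keywords internal
btop_from_gapped <- function(qaln, saln) {
  qc <- strsplit(qaln, "")[[1]]; sc <- strsplit(saln, "")[[1]]
  stopifnot(length(qc) == length(sc))
  out <- character(0); run <- 0L
  for (i in seq_along(qc)) {
    if (qc[i] == sc[i] && qc[i] != "-") {
      run <- run + 1L
    } else {
      if (run > 0L) { out <- c(out, as.character(run)); run <- 0L }
      out <- c(out, paste0(qc[i], sc[i]))
    }
  }
  if (run > 0L) out <- c(out, as.character(run))
  paste(out, collapse = "")
}

# Align one peptide against reference proteins with the built-in local
# aligner.  Returns a hit table in the external aligner's tabular layout.
# pairwiseAlignment vectorizes over patterns against one subject, so the
# references are the patterns and the peptide the subject; roles are swapped
# back when building the hit rows.
#' @keywords internal
align_builtin <- function(peptide, query_id, references, cfg) {
  BLOSUM62 <- NULL
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  # score-only sweep first; full traceback alignment only for reported hits
  sc <- Biostrings::pairwiseAlignment(
    pattern = references, subject = peptide, type = "local",
    substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1,
    scoreOnly = TRUE)
  keep <- which(sc >= cfg$minScore)
  if (!length(keep)) return(NULL)
  keep <- keep[order(sc[keep], decreasing = TRUE)]
  keep <- utils::head(keep, cfg$maxTargets)
  aln <- Biostrings::pairwiseAlignment(
    pattern = references[keep], subject = peptide, type = "local",
    substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1)
  # peptide-side (query) gapped strings come from the alignment's subject
  qa <- as.character(Biostrings::alignedSubject(aln))
  sa <- as.character(Biostrings::alignedPattern(aln))
  data.frame(
    qseqid = query_id,
    sseqid = names(references)[keep],
    qstart = Biostrings::start(Biostrings::subject(aln)),
    qend = Biostrings::end(Biostrings::subject(aln)),
    sstart = Biostrings::start(Biostrings::pattern(aln)),
    send = Biostrings::end(Biostrings::pattern(aln)),
    btop = mapply(btop_from_gapped, qa, sa, USE.NAMES = FALSE),
    bitscore = sc[keep],
    stringsAsFactors = FALSE)
}

#' Read external aligner tabular output
#'
#' Parses diamond/blastp tabular output produced with the field list
#' `qseqid sseqid pident length evalue bitscore qstart qend sstart send
#' btop`.
#'
#' @param path tabular output file (no header).
#' @return `data.frame` with those columns, coordinates integer.
#' @export
readDiamondTab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "evalue", "bitscore",
            "qstart", "qend", "sstart", "send", "btop")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != length(cols))
    stop("expected ", length(cols), " tabular columns, found ", ncol(df))
  names(df) <- cols
  for (cc in c("qstart", "qend", "sstart", "send"))
    df[[cc]] <- as.integer(df[[cc]])
  df
}

#' Write peptide windows as a query FASTA
#'
#' Query ids encode the site as `protein_id|position` so alignment results
#' can be traced back to candidate sites.
#'
#' @param candidates [PhosphoSiteTable-class] of candidate sites.
#' @param path output FASTA path.
#' @param cfg a [transferConfig()].
#' @return the path, invisibly.
#' @export
writePeptideFasta <- function(candidates, path, cfg = transferConfig()) {
  s <- siteRecords(candidates)
  seqs <- as.character(proteinSeqs(candidates))
  pep <- vapply(seq_len(nrow(s)), function(i)
    extractWindow(seqs[[s$protein_id[i]]], s$position[i],
                  cfg$windowLength)$peptide, character(1))
  aa <- Biostrings::AAStringSet(pep)
  names(aa) <- site_key(s$protein_id, s$position)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Run the external diamond aligner on peptide windows
#'
#' Shells out to the `diamond` binary with
#' `--masking none --ultra-sensitive --max-target-seqs <maxTargets>` and the
#' tabular field list consumed by [readDiamondTab()].  Errors with captured
#' diagnostics when the binary is unavailable or exits nonzero.
#'
#' @param queryFasta peptide FASTA (from [writePeptideFasta()]).
#' @param referenceFasta reference protein FASTA.
#' @param outPath tabular output path.
#' @param cfg a [transferConfig()].
#' @return `data.frame` of hits (via [readDiamondTab()]).
#' @export
runDiamond <- function(queryFasta, referenceFasta, outPath,
                       cfg = transferConfig(aligner = "external_diamond")) {
  bin <- Sys.which("diamond")
  if (bin == "")
    stop("aligner backend failure: 'diamond' binary not found on PATH")
  db <- tempfile(fileext = ".dmnd")
  st <- system2(bin, c("makedb", "--in", referenceFasta, "-d", db),
                stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(st, "status")))
    stop("aligner backend failure (makedb): ", paste(st, collapse = "\n"))
  out <- system2(bin, c("blastp", "-q", queryFasta, "-d", db, "-o", outPath,
                        "--masking", "none", "--ultra-sensitive",
                        "--max-target-seqs", cfg$maxTargets,
                        "--outfmt", "6", "qseqid", "sseqid", "pident",
                        "length", "evalue", "bitscore", "qstart", "qend",
                        "sstart", "send", "btop"),
                 stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(out, "status")))
    stop("aligner backend failure (blastp): ", paste(out, collapse = "\n"))
  readDiamondTab(outPath)
}

#' Infer positive labels for candidate sites by homology
#'
#' For each candidate site, extracts its peptide window, aligns it against
#' the reference proteins, maps the window center through each alignment
#' traceback, and marks the candidate `inferred_positive` when the center
#' lands on an experimentally supported positive position of a reference
#' protein.  Self-matches (same protein id and same position) are excluded
#' when configured; when `requireResidueMatch` is set, the subject residue
#' letter must equal the query residue letter.  All supporting
#' (subject, position) pairs are recorded, deduplicated and sorted, so the
#' result does not depend on hit ordering.
#'
#' @param candidates [PhosphoSiteTable-class] subset of candidate sites.
#' @param reference [PhosphoSiteTable-class] whose positive-labeled sites
#'   are the experimentally supported set (its proteins are the alignment
#'   targets).
#' @param cfg a [transferConfig()].
#' @param hits optional precomputed hit table (e.g. from [readDiamondTab()]
#'   on an external run) with `qseqid` encoding `protein_id|position`;
#'   when supplied no alignment is performed.
#' @return `data.frame` with one row per candidate: `protein_id`,
#'   `position`, `residue`, `status` (`inferred_positive` / `no_match`) and
#'   `matches` (`;`-joined `subject|position` pairs).
#' @export
inferPositives <- function(candidates, reference, cfg = transferConfig(),
                           hits = NULL) {
  stopifnot(is(candidates, "PhosphoSiteTable"),
            is(reference, "PhosphoSiteTable"))
  cand <- siteRecords(candidates)
  refs <- siteRecords(reference)
  refs <- refs[refs$label %in% c("positive", "inferred_positive"), ,
               drop = FALSE]
  ref_seqs <- proteinSeqs(reference)
  ref_chr <- as.character(ref_seqs)
  ref_keys <- site_key(refs$protein_id, refs$position)
  cand_seqs <- as.character(proteinSeqs(candidates))

  if (is.null(hits) && cfg$aligner == "external_diamond")
    stop("external aligner mode requires a precomputed 'hits' table ",
         "(see runDiamond())")

  status <- character(nrow(cand))
  matches <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    pid <- cand$protein_id[i]; pos <- cand$position[i]
    qid <- site_key(pid, pos)
    win <- extractWindow(cand_seqs[[pid]], pos, cfg$windowLength)
    h <- if (is.null(hits)) {
      align_builtin(win$peptide, qid, ref_seqs, cfg)
    } else {
      hits[hits$qseqid == qid, , drop = FALSE]
    }
    found <- character(0)
    if (!is.null(h) && nrow(h)) {
      for (j in seq_len(nrow(h))) {
        spos <- mapCenter(h[j, ], win$centerOffset)
        if (is.na(spos)) next
        sid <- h$sseqid[j]
        if (cfg$excludeSelf && sid == pid && spos == pos) next
        if (!site_key(sid, spos) %in% ref_keys) next
        if (cfg$requireResidueMatch &&
            substr(ref_chr[[sid]], spos, spos) != cand$residue[i]) next
        found <- c(found, site_key(sid, spos))
      }
    }
    found <- sort(unique(found))
    status[i] <- if (length(found)) "inferred_positive" else "no_match"
    matches[i] <- paste(found, collapse = ";")
  }
  data.frame(protein_id = cand$protein_id, position = cand$position,
             residue = cand$residue, status = status, matches = matches,
             stringsAsFactors = FALSE)
}

#' Alignment-only phosphosite classifier
#'
#' Predicts a candidate positive iff [inferPositives()] finds an alignment
#' match onto an experimentally supported reference site; a baseline
#' prediction method on its own, and the standard of comparison for the
#' learned classifier.
#'
#' @inheritParams inferPositives
#' @return integer 0/1 vector of hard calls, aligned with the candidate
#'   rows.
#' @export
alignmentOnlyClassifier <- function(candidates, reference,
                                    cfg = transferConfig(), hits = NULL) {
  ann <- inferPositives(candidates, reference, cfg, hits)
  as.integer(ann$status == "inferred_positive")
}

#' Merge inferred positives into confusion counts
#'
#' Promotes `nInferred` false-positive calls to inferred positives (IP) and
#' reports the merged counts: merged positives `TP + IP`, remaining false
#' positives `FP - IP`, post-merge precision `(TP + IP) / (TP + FP)` and
#' post-merge recall `(TP + IP) / (P + IP)` where `P = TP + FN` is the
#' original positive count.  Both post-merge metrics are never below their
#' pre-merge values for any `IP >= 0`.
#'
#' @param cm a `"ConfusionMatrix"` of the pre-merge hard calls.
#' @param nInferred number of false positives promoted (0 <= IP <= FP).
#' @return list with `TP`, `FP`, `IP`, `mergedPositives`, `remainingFP`,
#'   `precision`, `recall`.
#' @export
mergeInferred <- function(cm, nInferred) {
  stopifnot(nInferred >= 0, nInferred <= cm$FP)
  P <- cm$TP + cm$FN
  merged <- cm$TP + nInferred
  list(TP = cm$TP, FP = cm$FP, IP = nInferred,
       mergedPositives = merged, remainingFP = cm$FP - nInferred,
       precision = merged / (cm$TP + cm$FP),
       recall = merged / (P + nInferred))
}

#' Relabel predicted false positives using transfer annotations
#'
#' Convenience wrapper tying predictions, truth and [inferPositives()]
#' annotations together: counts how many false-positive calls carry an
#' `inferred_positive` annotation and returns the merged confusion summary.
#'
#' @param predictions integer 0/1 hard calls for the candidate sites.
#' @param annotations `data.frame` from [inferPositives()] (same order).
#' @param truth integer 0/1 experimental labels (same order).
#' @param threshold cutoff recorded in the underlying confusion matrix.
#' @return list as [mergeInferred()], plus `annotations` restricted to the
#'   promoted sites.
#' @export
mergeLabels <- function(predictions, annotations, truth, threshold = 0.5) {
  stopifnot(length(predictions) == nrow(annotations),
            length(predictions) == length(truth))
  cm <- confusionFromCounts(TP = sum(predictions == 1 & truth == 1),
                            FP = sum(predictions == 1 & truth == 0),
                            FN = sum(predictions == 0 & truth == 1),
                            TN = sum(predictions == 0 & truth == 0),
                            threshold = threshold)
  fp_idx <- which(predictions == 1 & truth == 0)
  promoted <- fp_idx[annotations$status[fp_idx] == "inferred_positive"]
  out <- mergeInferred(cm, length(promoted))
  out$annotations <- annotations[promoted, , drop = FALSE]
  out
}

#' Write transfer annotations to TSV
#'
#' @param annotations `data.frame` from [inferPositives()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeAnnotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
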