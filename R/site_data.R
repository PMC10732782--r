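#' Read a phosphosite evidence table
#'
#' Reads a tab-separated evidence table with required header columns
#' `protein_id`, `position` (1-based) and `residue`, plus optional
#' `species` and `source` columns (the layout used by plant PTM evidence
#' databases).
#'
#' @param path path to a TSV file with a header row.
#' @return `data.frame` of raw records ready for [crossReference()].
#' @export
readSiteTable <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("protein_id", "position", "residue")
  if (!all(need %in% names(raw)))
    stop("site table must have header columns: ", paste(need, collapse = ", "))
  raw$position <- suppressWarnings(as.integer(raw$position))
  if (is.null(raw$source)) raw$source <- "evidence"
  raw
}

#' Read a protein FASTA file
#'
#' @param path path to a (multi-record) protein FASTA file.
#' @return [Biostrings::AAStringSet] named by the first whitespace-delimited
#'   token of each header.
#' @export
readProteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  aa
}

#' Cross-reference raw phosphosite records against protein sequences
#'
#' Validates each evidence record against the provided sequences: the
#' protein must be present, consist only of the 20 canonical amino acids,
#' the position must lie inside the sequence, and the residue letter must
#' match the sequence at that 1-based position.  Records failing any check
#' are moved to a rejection log with a reason
#' (`no_sequence`, `noncanonical_sequence`, `out_of_range`,
#' `residue_mismatch`, `not_sty`); nothing is silently repaired.  Duplicate
#' evidence rows for one (protein, position) collapse to a single positive
#' site with their source tags concatenated (`;`-joined, unique).
#'
#' The operation is idempotent: applying it to the sites of its own output
#' changes nothing.
#'
#' @param table `data.frame` of raw records with columns `protein_id`,
#'   `position`, `residue` and optionally `source`.
#' @param proteins [Biostrings::AAStringSet] of candidate protein sequences.
#' @param label label assigned to retained sites (default `"positive"`).
#'   A valid `label` column in `table` (as written by [writeSiteTable()])
#'   takes precedence, so prepared tables survive a disk round trip.
#' @return [PhosphoSiteTable-class]; only proteins passing the canonical
#'   alphabet filter are kept in the object.
#' @export
crossReference <- function(table, proteins, label = "positive") {
  stopifnot(is.data.frame(table))
  if (is.null(table$source)) table$source <- "evidence"
  lab <- rep(label, nrow(table))
  if (!is.null(table$label)) {
    keep_lab <- table$label %in% c("positive", "negative",
                                   "inferred_positive")
    lab[keep_lab] <- table$label[keep_lab]
  }
  table$.label <- lab
  seq_chr <- as.character(proteins)
  canonical <- vapply(seq_chr, is_canonical_sequence, logical(1))
  keep_prot <- proteins[canonical]
  seq_chr <- seq_chr[canonical]

  n <- nrow(table)
  reason <- character(n)
  for (i in seq_len(n)) {
    pid <- table$protein_id[i]
    pos <- table$position[i]
    res <- toupper(table$residue[i])
    if (!pid %in% names(proteins)) {
      reason[i] <- "no_sequence"
    } else if (!pid %in% names(keep_prot)) {
      reason[i] <- "noncanonical_sequence"
    } else if (is.na(pos) || pos < 1L || pos > nchar(seq_chr[[pid]])) {
      reason[i] <- "out_of_range"
    } else if (!res %in% PHOSPHO_RESIDUES) {
      reason[i] <- "not_sty"
    } else if (substr(seq_chr[[pid]], pos, pos) != res) {
      reason[i] <- "residue_mismatch"
    }
  }

  ok <- table[reason == "", , drop = FALSE]
  rej <- data.frame(protein_id = table$protein_id[reason != ""],
                    position = table$position[reason != ""],
                    reason = reason[reason != ""],
                    stringsAsFactors = FALSE)

  if (nrow(ok)) {
    key <- site_key(ok$protein_id, ok$position)
    src <- vapply(split(ok$source, key), function(s)
      paste(unique(s), collapse = ";"), character(1))
    first <- !duplicated(key)
    sites <- data.frame(protein_id = ok$protein_id[first],
                        position = as.integer(ok$position[first]),
                        residue = toupper(ok$residue[first]),
                        label = ok$.label[first],
                        source = unname(src[key[first]]),
                        stringsAsFactors = FALSE)
    sites <- sites[order(sites$protein_id, sites$position), , drop = FALSE]
    rownames(sites) <- NULL
  } else {
    sites <- empty_sites()
  }

  new("PhosphoSiteTable", sites = sites, proteins = keep_prot, rejected = rej)
}

#' Derive the negative-site universe
#'
#' Every S, T or Y residue of every protein in the table that is not already
#' labeled positive (or inferred positive) is added exactly once as a
#' negative site.  Existing sites are unchanged.
#'
#' @param table [PhosphoSiteTable-class] with cross-referenced positives.
#' @return [PhosphoSiteTable-class] with negatives appended.
#' @export
deriveNegatives <- function(table) {
  stopifnot(is(table, "PhosphoSiteTable"))
  s <- table@sites
  taken <- site_key(s$protein_id, s$position)
  seq_chr <- as.character(table@proteins)
  neg <- lapply(names(seq_chr), function(pid) {
    chars <- strsplit(seq_chr[[pid]], "")[[1]]
    pos <- which(chars %in% PHOSPHO_RESIDUES)
    if (!length(pos)) return(NULL)
    pos <- pos[!site_key(pid, pos) %in% taken]
    if (!length(pos)) return(NULL)
    data.frame(protein_id = pid, position = as.integer(pos),
               residue = chars[pos], label = "negative", source = "",
               stringsAsFactors = FALSE)
  })
  neg <- do.call(rbind, neg)
  out <- rbind(s, neg)
  out <- out[order(out$protein_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  new("PhosphoSiteTable", sites = out, proteins = table@proteins,
      rejected = table@rejected)
}

#' Split configuration for stratified train/validation/test partitioning
#'
#' @param fractions numeric length-3 (train, validation, test) proportions
#'   summing to 1; default `c(0.6, 0.2, 0.2)`.
#' @param seed integer RNG seed; identical seeds give identical splits.
#' @param byProtein if `TRUE`, whole proteins are assigned to one split so no
#'   protein is shared between splits (site-level stratification is then only
#'   approximate).  Default `FALSE`: the stratification unit is the site.
#' @return list of class `"SplitConfig"`.
#' @export
splitConfig <- function(fractions = c(0.6, 0.2, 0.2), seed = 1L,
                        byProtein = FALSE) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8)
  structure(list(fractions = fractions, seed = as.integer(seed),
                 byProtein = isTRUE(byProtein)), class = "SplitConfig")
}

#' Stratified train/validation/test split of a site table
#'
#' Sites are partitioned into train/validation/test sets with stratification
#' on (residue letter, label), so each residue type and each class keeps the
#' configured proportions (within one site per stratum, by largest-remainder
#' allocation after a seeded shuffle).  Strata with fewer than 3 sites go
#' wholly to the training set with a warning.  The three outputs partition
#' the input exactly for any seed.
#'
#' @param table [PhosphoSiteTable-class] containing at least two labels.
#' @param cfg a [splitConfig()].
#' @return named list of three `PhosphoSiteTable`s: `train`, `validation`,
#'   `test` (all sharing the full protein set).
#' @export
stratifiedSplit <- function(table, cfg = splitConfig()) {
  stopifnot(is(table, "PhosphoSiteTable"), inherits(cfg, "SplitConfig"))
  s <- table@sites
  if (!nrow(s)) stop("cannot split an empty site table")
  assign_vec <- rep(NA_character_, nrow(s))
  strata <- split(seq_len(nrow(s)), paste(s$residue, s$label))
  n_small <- 0L
  with_seed(cfg$seed, {
    for (idx in strata) {
      n <- length(idx)
      if (n < 3L && any(cfg$fractions[-1] > 0)) {
        n_small <- n_small + 1L
        assign_vec[idx] <- "train"
        next
      }
      idx <- sample(idx)
      if (cfg$byProtein) {
        # group-aware variant: assign proteins (within this stratum) greedily
        prot <- s$protein_id[idx]
        sizes <- table(prot)
        target <- cfg$fractions * n
        got <- c(train = 0, validation = 0, test = 0)
        for (p in names(sort(sizes, decreasing = TRUE))) {
          deficit <- target - got
          g <- names(which.max(deficit))
          assign_vec[idx[prot == p]] <- g
          got[g] <- got[g] + sizes[[p]]
        }
      } else {
        # largest-remainder apportionment of n among the three splits
        quota <- cfg$fractions * n
        base <- floor(quota)
        rem <- n - sum(base)
        if (rem > 0) {
          extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
          base[extra] <- base[extra] + 1L
        }
        grp <- rep(c("train", "validation", "test"), times = base)
        assign_vec[idx] <- grp
      }
    }
  })
  if (n_small > 0L)
    warning(n_small, " stratum/strata with fewer than 3 sites assigned ",
            "wholly to train")
  out <- lapply(c(train = "train", validation = "validation", test = "test"),
                function(g) {
    sub <- s[which(assign_vec == g), , drop = FALSE]
    rownames(sub) <- NULL
    new("PhosphoSiteTable", sites = sub, proteins = table@proteins,
        rejected = empty_rejections())
  })
  out
}

#' Write the rejection log of a site table
#'
#' @param table [PhosphoSiteTable-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeRejectionLog <- function(table, path) {
  utils::write.table(rejectedRecords(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a site table to TSV
#'
#' @param table [PhosphoSiteTable-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeSiteTable <- function(table, path) {
  utils::write.table(siteRecords(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset a PhosphoSiteTable by row indices or a predicate on its sites
#'
#' @param table [PhosphoSiteTable-class].
#' @param i integer or logical index into the site rows.
#' @return [PhosphoSiteTable-class] with the selected sites (all proteins
#'   retained).
#' @export
subsetSites <- function(table, i) {
  s <- table@sites[i, , drop = FALSE]
  rownames(s) <- NULL
  new("PhosphoSiteTable", sites = s, proteins = table@proteins,
      rejected = empty_rejections())
}
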