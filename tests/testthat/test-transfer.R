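test_that("extractWindow applies the center, edge, and short-protein rules", {
  long <- paste(rep("ACDEF", 20), collapse = "")  # length 100
  w <- extractWindow(long, 50, 31)
  expect_equal(w$peptide, substr(long, 35, 65))
  expect_equal(w$centerOffset, 15)
  w2 <- extractWindow(long, 3, 31)                # near the start
  expect_equal(w2$peptide, substr(long, 1, 31))
  expect_equal(w2$centerOffset, 2)
  w3 <- extractWindow(long, 99, 31)               # near the end
  expect_equal(w3$peptide, substr(long, 70, 100))
  expect_equal(w3$centerOffset, 29)
  short <- substr(long, 1, 20)
  w4 <- extractWindow(short, 11, 31)              # shorter than the window
  expect_equal(w4$peptide, short)
  expect_equal(w4$centerOffset, 10)
  expect_error(extractWindow(short, 21, 31), "out of range")
  # the site letter sits at the reported offset
  expect_equal(substr(w$peptide, w$centerOffset + 1, w$centerOffset + 1),
               substr(long, 50, 50))
})

test_that("mapCenter walks match runs, substitutions and gaps correctly", {
  # ungapped identity hit: subject position is a pure offset
  hit <- list(qstart = 1L, qend = 31L, sstart = 11L, send = 41L, btop = "31")
  expect_equal(mapCenter(hit, 15), 26)
  # substitutions consume both sequences
  hit2 <- list(qstart = 1L, qend = 31L, sstart = 11L, send = 41L,
               btop = "10ST20")
  expect_equal(mapCenter(hit2, 15), 26)
  # center trimmed away by the local alignment
  hit3 <- list(qstart = 20L, qend = 31L, sstart = 1L, send = 12L,
               btop = "12")
  expect_true(is.na(mapCenter(hit3, 15)))
  # center opposite a query-side gap partner: subject insertion shifts it
  hit4 <- list(qstart = 1L, qend = 31L, sstart = 1L, send = 32L,
               btop = "10-A21")
  expect_equal(mapCenter(hit4, 15), 17)
  # center deleted from the subject
  hit5 <- list(qstart = 1L, qend = 31L, sstart = 1L, send = 30L,
               btop = "15S-15")
  expect_true(is.na(mapCenter(hit5, 15)))
  expect_error(mapCenter(list(qstart = 1L, qend = 5L, sstart = 1L,
                              send = 5L, btop = "2x3"), 2),
               "malformed btop")
})

test_that("mapCenter agrees with the gapped-string oracle on exhaustive small alignments", {
  set.seed(17)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ops <- c("M", "S", "QG", "SG")  # match, substitution, query gap, subject gap
  for (rep in 1:200) {
    # random short traceback over peptides of length <= 15
    n_ops <- sample(3:8, 1)
    script <- sample(ops, n_ops, replace = TRUE, prob = c(.5, .2, .15, .15))
    qseq <- paste(sample(aa, 15, TRUE), collapse = "")
    sseq <- paste(sample(aa, 15, TRUE), collapse = "")
    qstart <- sample(1:3, 1); sstart <- sample(1:3, 1)
    q <- qstart; s <- sstart; btop <- ""
    for (op in script) {
      if (q > 12 || s > 12) break
      if (op == "M") {
        run <- sample(1:3, 1)
        btop <- paste0(btop, run)
        q <- q + run; s <- s + run
      } else if (op == "S") {
        btop <- paste0(btop, substr(qseq, q, q), substr(sseq, s, s))
        q <- q + 1; s <- s + 1
      } else if (op == "QG") {
        btop <- paste0(btop, substr(qseq, q, q), "-")
        q <- q + 1
      } else {
        btop <- paste0(btop, "-", substr(sseq, s, s))
        s <- s + 1
      }
    }
    if (btop == "") next
    hit <- list(qstart = qstart, qend = q - 1L, sstart = sstart,
                send = s - 1L, btop = btop)
    for (off in 0:14) {
      expect_identical(mapCenter(hit, off),
                       oracle_map_center(hit, off, qseq, sseq),
                       info = paste("btop:", btop, "offset:", off))
    }
  }
})

test_that("inferPositives finds cross-protein matches and excludes self-matches", {
  # two identical proteins under different ids; positives at position 16
  seq1 <- paste(c(rep("A", 15), "S", rep("G", 15)), collapse = "")
  prot <- aa_set(u = seq1, v = seq1)
  ref_raw <- data.frame(protein_id = c("u", "v"), position = 16L,
                        residue = "S", source = "exp")
  ref <- deriveNegatives(crossReference(ref_raw, prot))
  cand <- subsetSites(ref, with(siteRecords(ref),
                                which(protein_id == "u" & position == 16)))
  # duplicated proteome: the v copy supports u's site
  ann <- inferPositives(cand, ref, transferConfig())
  expect_equal(ann$status, "inferred_positive")
  expect_match(ann$matches, "v\\|16")
  expect_false(grepl("u\\|16", ann$matches))  # self-match excluded
  # with only the self protein in the reference: no match
  ref_self <- deriveNegatives(crossReference(
    ref_raw[ref_raw$protein_id == "u", ], prot[ "u"]))
  ann2 <- inferPositives(cand, ref_self, transferConfig())
  expect_equal(ann2$status, "no_match")
  # with exclude_self off the self-hit counts
  ann3 <- inferPositives(cand, ref_self, transferConfig(excludeSelf = FALSE))
  expect_equal(ann3$status, "inferred_positive")
})

test_that("requireResidueMatch gates S/T cross-matching", {
  base <- c(rep("A", 15), "S", rep("G", 15))
  tvar <- base; tvar[16] <- "T"
  prot <- aa_set(s_prot = paste(base, collapse = ""),
                 t_prot = paste(tvar, collapse = ""))
  ref_raw <- data.frame(protein_id = "t_prot", position = 16L,
                        residue = "T", source = "exp")
  ref <- deriveNegatives(crossReference(ref_raw, prot))
  cand_raw <- data.frame(protein_id = "s_prot", position = 16L,
                         residue = "S", source = "pred")
  cand <- crossReference(cand_raw, prot)
  strict <- inferPositives(cand, ref, transferConfig())
  expect_equal(strict$status, "no_match")
  loose <- inferPositives(cand, ref,
                          transferConfig(requireResidueMatch = FALSE))
  expect_equal(loose$status, "inferred_positive")
})

test_that("alignment-only classification recovers planted homolog positives", {
  cfg <- fixtureConfig(nProteins = 30, seed = 11, mutationRate = 0.1)
  pt <- makeProteome(cfg)
  ho <- makeHomologs(pt, cfg)
  cand <- subsetSites(pt, siteRecords(pt)$label == "positive")
  pred <- alignmentOnlyClassifier(cand, ho, transferConfig())
  expect_gte(mean(pred), 0.8)  # >= 80% of planted positives recovered
  # empty reference -> all negative
  empty_ref <- new("PhosphoSiteTable",
                   proteins = proteinSeqs(ho))
  expect_equal(sum(alignmentOnlyClassifier(cand, empty_ref,
                                           transferConfig())), 0)
  # mutation rate 0 duplicates the proteome exactly: recall 1 with self off
  cfg0 <- fixtureConfig(nProteins = 15, seed = 12, mutationRate = 0)
  pt0 <- makeProteome(cfg0)
  ho0 <- makeHomologs(pt0, cfg0)
  cand0 <- subsetSites(pt0, siteRecords(pt0)$label == "positive")
  expect_equal(mean(alignmentOnlyClassifier(cand0, ho0, transferConfig())), 1)
})

test_that("annotations are independent of hit ordering and deduplicate matches", {
  hits <- data.frame(
    qseqid = "q|16", sseqid = c("r2", "r1", "r2"),
    qstart = 1L, qend = 31L, sstart = 1L, send = 31L, btop = "31",
    stringsAsFactors = FALSE)
  seqq <- paste(c(rep("A", 15), "S", rep("G", 15)), collapse = "")
  prot <- aa_set(q = seqq, r1 = seqq, r2 = seqq)
  ref <- deriveNegatives(crossReference(
    data.frame(protein_id = c("r1", "r2"), position = 16L, residue = "S",
               source = "e"), prot))
  cand <- crossReference(data.frame(protein_id = "q", position = 16L,
                                    residue = "S", source = "p"), prot)
  a1 <- inferPositives(cand, ref, transferConfig(), hits = hits)
  a2 <- inferPositives(cand, ref, transferConfig(),
                       hits = hits[c(3, 1, 2), ])
  expect_identical(a1, a2)
  expect_equal(a1$matches, "r1|16;r2|16")
})

test_that("mergeInferred implements the relabeling algebra and never lowers either metric", {
  cm <- confusionFromCounts(TP = 40, FP = 60, FN = 10)
  pre <- suppressWarnings(prf(cm))
  for (ip in c(0, 7, 60)) {
    m <- mergeInferred(cm, ip)
    expect_equal(m$mergedPositives, 40 + ip)
    expect_equal(m$remainingFP, 60 - ip)
    expect_equal(m$precision, (40 + ip) / 100)
    expect_equal(m$recall, (40 + ip) / (50 + ip))
    expect_gte(m$precision, pre["P"])
    expect_gte(m$recall, pre["R"])
  }
  expect_error(mergeInferred(cm, 61))
  m0 <- mergeInferred(cm, 0)
  expect_equal(m0$precision, unname(pre["P"]))
  expect_equal(m0$recall, unname(pre["R"]))
})

test_that("mergeLabels promotes only annotated false positives", {
  truth <- c(1, 0, 0, 0, 1)
  pred  <- c(1, 1, 1, 0, 0)
  ann <- data.frame(protein_id = letters[1:5], position = 1:5,
                    residue = "S",
                    status = c("no_match", "inferred_positive", "no_match",
                               "inferred_positive", "no_match"),
                    matches = "")
  m <- mergeLabels(pred, ann, truth)
  expect_equal(m$IP, 1)         # only index 2 is an annotated FP
  expect_equal(m$TP, 1)
  expect_equal(m$mergedPositives, 2)
  expect_equal(m$annotations$protein_id, "b")
})

test_that("external tabular parsing round-trips through the documented column set", {
  f <- tempfile()
  writeLines(c("q1|5\tsubj\t96.8\t31\t1e-12\t60.1\t1\t31\t10\t40\t31",
               "q1|5\tsubj2\t80.6\t31\t1e-5\t40.2\t2\t30\t11\t39\t5AS23"),
             f)
  hits <- readDiamondTab(f)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$sstart, c(10L, 11L))
  expect_equal(hits$btop[2], "5AS23")
  expect_error(readDiamondTab({
    g <- tempfile(); writeLines("a\tb\tc", g); g
  }), "tabular columns")
})

test_that("peptide FASTA writer encodes sites in the query ids", {
  st <- crossReference(tiny_raw_sites(), tiny_proteins())
  f <- tempfile(fileext = ".fa")
  writePeptideFasta(st, f, transferConfig())
  aa <- readProteome(f)
  expect_setequal(names(aa), c("p1|2", "p1|4", "p2|1"))
  expect_equal(as.character(aa[["p1|2"]]),
               as.character(proteinSeqs(st)[["p1"]]))  # short protein: whole sequence
})
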