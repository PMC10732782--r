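test_that("crossReference keeps matching sites and logs each rejection with its reason", {
  prot <- tiny_proteins()
  raw <- rbind(tiny_raw_sites(),
               data.frame(protein_id = c("p1", "p1", "missing", "p1"),
                          position = c(3L, 0L, 2L, 100L),
                          residue = c("Y", "S", "S", "S"),
                          source = "expC"))
  st <- crossReference(raw, prot)
  s <- siteRecords(st)
  expect_setequal(site_key <- paste(s$protein_id, s$position),
                  c("p1 2", "p1 4", "p2 1"))
  rej <- rejectedRecords(st)
  expect_equal(rej$reason[rej$protein_id == "p1" & rej$position == 3],
               "residue_mismatch")  # position 3 of MSTYK is T, not Y
  expect_equal(rej$reason[rej$protein_id == "missing"], "no_sequence")
  expect_setequal(rej$reason[rej$position %in% c(0L, 100L)], "out_of_range")
})

test_that("proteins with non-canonical letters are rejected wholesale", {
  prot <- aa_set(ok = "MSTYK", bad = "MSXTY")
  raw <- data.frame(protein_id = c("ok", "bad"), position = c(2L, 2L),
                    residue = "S", source = "e")
  st <- crossReference(raw, prot)
  expect_equal(siteRecords(st)$protein_id, "ok")
  expect_false("bad" %in% names(proteinSeqs(st)))
  expect_equal(rejectedRecords(st)$reason, "noncanonical_sequence")
})

test_that("duplicate evidence rows collapse to one site with concatenated sources", {
  prot <- tiny_proteins()
  raw <- data.frame(protein_id = "p1", position = 2L, residue = "S",
                    source = c("expA", "expB", "expA"))
  st <- crossReference(raw, prot)
  expect_equal(nrow(siteRecords(st)), 1L)
  expect_equal(siteRecords(st)$source, "expA;expB")
})

test_that("crossReference is idempotent", {
  st <- crossReference(tiny_raw_sites(), tiny_proteins())
  again <- crossReference(siteRecords(st), proteinSeqs(st))
  expect_equal(siteRecords(again)[names(siteRecords(st))], siteRecords(st))
  expect_equal(nrow(rejectedRecords(again)), 0L)
})

test_that("deriveNegatives enumerates every unlabeled S/T/Y exactly once", {
  prot <- aa_set(p2 = "SSTA", p3 = "MKLA")
  raw <- data.frame(protein_id = "p2", position = 1L, residue = "S",
                    source = "e")
  st <- deriveNegatives(crossReference(raw, prot))
  s <- siteRecords(st)
  neg <- s[s$label == "negative", ]
  expect_equal(neg$position, c(2L, 3L))          # remaining S and T of SSTA
  expect_equal(neg$residue, c("S", "T"))
  expect_false("p3" %in% s$protein_id)           # no S/T/Y -> no sites
  # count check against a direct scan on a generated proteome
  big <- makeProteome(fixtureConfig(nProteins = 10, seed = 4))
  sb <- siteRecords(big)
  total_sty <- sum(vapply(as.character(proteinSeqs(big)), function(x)
    sum(strsplit(x, "")[[1]] %in% c("S", "T", "Y")), numeric(1)))
  expect_equal(nrow(sb), total_sty)
  expect_equal(sum(sb$label == "negative"),
               total_sty - sum(sb$label == "positive"))
})

test_that("stratifiedSplit partitions exactly, reproducibly, and stratum-accurately", {
  fx <- fixture_dataset(nProteins = 100, seed = 7)
  s <- siteRecords(fx$table)
  sp <- stratifiedSplit(fx$table, splitConfig(seed = 7))
  sizes <- vapply(sp, function(x) nrow(siteRecords(x)), numeric(1))
  expect_equal(sum(sizes), nrow(s))
  keys <- lapply(sp, function(x)
    with(siteRecords(x), paste(protein_id, position)))
  expect_equal(length(unique(unlist(keys))), nrow(s))  # pairwise disjoint
  # per-stratum proportions within one site of target
  for (res in c("S", "T", "Y")) for (lab in c("positive", "negative")) {
    n <- sum(s$residue == res & s$label == lab)
    if (n < 10) next
    got <- vapply(sp, function(x) {
      xs <- siteRecords(x); sum(xs$residue == res & xs$label == lab)
    }, numeric(1))
    expect_lte(max(abs(got - c(0.6, 0.2, 0.2) * n)), 1)
  }
  # same seed identical, different seed different
  sp2 <- stratifiedSplit(fx$table, splitConfig(seed = 7))
  expect_identical(siteRecords(sp$train), siteRecords(sp2$train))
  sp3 <- stratifiedSplit(fx$table, splitConfig(seed = 8))
  expect_false(identical(siteRecords(sp$train), siteRecords(sp3$train)))
  expect_equal(nrow(siteRecords(sp3$train)), nrow(siteRecords(sp$train)))
})

test_that("degenerate split fractions and tiny strata are handled", {
  st <- deriveNegatives(crossReference(tiny_raw_sites(), tiny_proteins()))
  expect_warning(sp <- stratifiedSplit(st, splitConfig(seed = 1)),
                 "fewer than 3")
  expect_equal(nrow(siteRecords(sp$train)), nrow(siteRecords(st)))
  all_train <- stratifiedSplit(st, splitConfig(fractions = c(1, 0, 0),
                                               seed = 1))
  expect_equal(nrow(siteRecords(all_train$train)), nrow(siteRecords(st)))
  expect_equal(nrow(siteRecords(all_train$test)), 0L)
})

test_that("site tables round-trip through TSV and FASTA files", {
  st <- deriveNegatives(crossReference(tiny_raw_sites(), tiny_proteins()))
  tsv <- tempfile(fileext = ".tsv"); fa <- tempfile(fileext = ".fasta")
  writeSiteTable(st, tsv)
  Biostrings::writeXStringSet(proteinSeqs(st), fa)
  back <- crossReference(readSiteTable(tsv), readProteome(fa))
  expect_equal(nrow(siteRecords(back)), nrow(siteRecords(st)))
  expect_equal(siteRecords(back)$position, siteRecords(st)$position)
})
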