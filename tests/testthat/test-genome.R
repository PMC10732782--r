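# Independent oracle: read the codon by walking a literal base-by-base
# vector of the coding sequence laid out on the genome.
oracle_codon <- function(model, idx) {
  bases <- c()
  segs <- model$cds
  if (model$strand == "+") {
    for (k in seq_len(nrow(segs))) bases <- c(bases, segs$start[k]:segs$end[k])
  } else {
    for (k in seq_len(nrow(segs))) bases <- c(bases, segs$end[k]:segs$start[k])
  }
  sort(bases[(3 * idx - 2):(3 * idx)])
}

test_that("codonCoords maps plus, minus and intron-spanning codons", {
  plus <- list(protein_id = "p", chrom = "c", strand = "+",
               cds = data.frame(start = 1001, end = 1099))
  expect_equal(codonCoords(plus, 1), data.frame(start = 1001, end = 1003))
  minus <- list(protein_id = "p", chrom = "c", strand = "-",
                cds = data.frame(start = 1001, end = 1099))
  expect_equal(codonCoords(minus, 1), data.frame(start = 1097, end = 1099))
  split2 <- list(protein_id = "p", chrom = "c", strand = "+",
                 cds = data.frame(start = c(1001, 2001),
                                  end = c(1004, 2050)))
  b <- codonCoords(split2, 2)
  expect_equal(b, data.frame(start = c(1004, 2001), end = c(1004, 2002)))
  expect_equal(sum(b$end - b$start + 1), 3)
  expect_error(codonCoords(plus, 34), "outside protein")
})

test_that("codonCoords agrees with the base-walk oracle on random models", {
  cfg <- fixtureConfig(nProteins = 25, seed = 6)
  pt <- makeProteome(cfg)
  models <- makeGeneModels(pt, cfg)
  for (m in models[1:15]) {
    L <- sum(m$cds$end - m$cds$start + 1) / 3
    for (idx in unique(c(1, 2, sample(seq_len(L), 4), L))) {
      blocks <- codonCoords(m, idx)
      got <- sort(unlist(Map(seq.int, blocks$start, blocks$end)))
      expect_equal(got, oracle_codon(m, idx),
                   info = paste(m$protein_id, m$strand, idx))
      expect_equal(sum(blocks$end - blocks$start + 1), 3)
      # inverse walk recovers the residue index
      expect_equal(residueFromCoords(m, blocks), idx)
    }
  }
})

test_that("fixture gene models are valid and balanced across strands", {
  cfg <- fixtureConfig(nProteins = 60, seed = 8)
  pt <- makeProteome(cfg)
  models <- makeGeneModels(pt, cfg)
  lens <- vapply(models, function(m) sum(m$cds$end - m$cds$start + 1),
                 numeric(1))
  expect_true(all(lens %% 3 == 0))
  expect_equal(unname(lens / 3),
               unname(Biostrings::width(proteinSeqs(pt))))
  strands <- vapply(models, `[[`, character(1), "strand")
  expect_gt(mean(strands == "+"), 0.3)
  expect_lt(mean(strands == "+"), 0.7)
})

test_that("gene models survive a GFF3 round trip", {
  cfg <- fixtureConfig(nProteins = 12, seed = 9)
  pt <- makeProteome(cfg)
  models <- makeGeneModels(pt, cfg)
  f <- tempfile(fileext = ".gff3")
  writeGeneModelsGFF3(models, f)
  back <- readGeneModels(f)
  expect_setequal(names(back), names(models))
  for (pid in names(models)) {
    expect_equal(back[[pid]]$cds, models[[pid]]$cds,
                 ignore_attr = TRUE)
    expect_equal(back[[pid]]$strand, models[[pid]]$strand)
  }
})

test_that("site GFF3 export applies the color and bold display rules", {
  model <- list(protein_id = "p", chrom = "chr1", strand = "+",
                cds = data.frame(start = 1, end = 300))
  sites <- data.frame(protein_id = "p", position = c(1, 2, 3, 4),
                      residue = "S",
                      probability = c(0.95, 0.3, 0.6, 0.2),
                      inferred = c(FALSE, TRUE, TRUE, FALSE))
  f <- tempfile(fileext = ".gff3")
  writeSiteGFF3(sites, list(p = model), f)
  back <- readSiteGFF3(f)
  expect_equal(nrow(back), 3)  # p=.2 non-inferred site omitted
  expect_equal(back$status[back$position == 1], "red")
  expect_equal(back$bold[back$position == 1], TRUE)   # p > .9
  expect_equal(back$status[back$position == 2], "blue")
  expect_equal(back$bold[back$position == 2], FALSE)
  expect_equal(back$status[back$position == 3], "pink")
})

test_that("exported sites round-trip to their protein coordinates, including split codons", {
  cfg <- fixtureConfig(nProteins = 20, seed = 10)
  pt <- makeProteome(cfg)
  models <- makeGeneModels(pt, cfg)
  s <- siteRecords(pt)
  pos <- s  # export every S/T/Y site so intron-spanning codons are exercised
  sites <- data.frame(protein_id = pos$protein_id, position = pos$position,
                      residue = pos$residue, probability = 0.8,
                      inferred = FALSE,
                      matches = "r1|10;r2|20")
  f <- tempfile(fileext = ".gff3")
  writeSiteGFF3(sites, models, f)
  back <- readSiteGFF3(f)
  expect_equal(nrow(back), nrow(sites))
  expect_true(any(vapply(back$blocks, nrow, integer(1)) == 2))  # intron-split codons occur
  for (i in seq_len(nrow(back))) {
    m <- models[[back$protein_id[i]]]
    expect_equal(residueFromCoords(m, back$blocks[[i]]), back$position[i])
  }
  # skipped log for unmappable proteins
  out <- writeSiteGFF3(data.frame(protein_id = "nope", position = 1,
                                  residue = "S", probability = 0.9,
                                  inferred = FALSE),
                       models, tempfile(fileext = ".gff3"))
  expect_equal(attr(out, "skipped"), "nope")
})
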