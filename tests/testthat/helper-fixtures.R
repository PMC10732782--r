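# Shared in-code fixtures; everything is generated, nothing read from disk.

aa_set <- function(...) {
  x <- c(...)
  Biostrings::AAStringSet(x)
}

# A tiny hand-written proteome with known S/T/Y layout.
tiny_proteins <- function() {
  aa_set(p1 = "MSTYKASA",  # S at 2,6; T at 3; Y at 4
         p2 = "SSTA",      # S at 1,2; T at 3
         p3 = "MKLA")      # no S/T/Y
}

tiny_raw_sites <- function() {
  data.frame(protein_id = c("p1", "p1", "p2"),
             position = c(2L, 4L, 1L),
             residue = c("S", "Y", "S"),
             source = c("expA", "expB", "expA"),
             stringsAsFactors = FALSE)
}

# Moderate generated dataset with features, for classifier tests.
fixture_dataset <- function(nProteins = 80, delta = 2, seed = 1, D = 8) {
  cfg <- fixtureConfig(nProteins = nProteins, embeddingDim = D,
                       delta = delta, seed = seed)
  pt <- makeProteome(cfg)
  es <- makeEmbeddings(pt, cfg)
  list(cfg = cfg, table = pt, embeddings = es,
       X = assembleFeatures(pt, es),
       y = as.integer(siteRecords(pt)$label == "positive"))
}

# Reconstruct the two gapped strings a btop traceback encodes, given the
# ungapped aligned substrings; the independent oracle for mapCenter.
gapped_from_btop <- function(btop, qseq, sseq, qstart, sstart) {
  toks <- regmatches(btop, gregexpr("\\d+|[A-Z*][A-Z*]|[A-Z*]-|-[A-Z*]",
                                    btop))[[1]]
  q <- qstart; s <- sstart
  qa <- character(0); sa <- character(0)
  for (tok in toks) {
    if (grepl("^\\d+$", tok)) {
      n <- as.integer(tok)
      qa <- c(qa, strsplit(substr(qseq, q, q + n - 1L), "")[[1]])
      sa <- c(sa, strsplit(substr(sseq, s, s + n - 1L), "")[[1]])
      q <- q + n; s <- s + n
    } else {
      qc <- substr(tok, 1, 1); sc <- substr(tok, 2, 2)
      qa <- c(qa, qc); sa <- c(sa, sc)
      if (qc != "-") q <- q + 1L
      if (sc != "-") s <- s + 1L
    }
  }
  list(q = qa, s = sa)
}

# Oracle center mapping: read the alignment column-by-column.
oracle_map_center <- function(hit, centerOffset, qseq, sseq) {
  target <- centerOffset + 1L
  if (target < hit$qstart || target > hit$qend) return(NA_integer_)
  g <- gapped_from_btop(hit$btop, qseq, sseq, hit$qstart, hit$sstart)
  qpos <- hit$qstart - 1L
  spos <- hit$sstart - 1L
  for (i in seq_along(g$q)) {
    if (g$q[i] != "-") qpos <- qpos + 1L
    if (g$s[i] != "-") spos <- spos + 1L
    if (g$q[i] != "-" && qpos == target) {
      if (g$s[i] == "-") return(NA_integer_)
      return(spos)
    }
  }
  NA_integer_
}
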