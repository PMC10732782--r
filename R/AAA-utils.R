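## Internal helpers shared across modules.

# Canonical 20-letter amino-acid alphabet; anything else disqualifies a protein.
CANONICAL_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

PHOSPHO_RESIDUES <- c("S", "T", "Y")

#' @keywords internal
is_canonical_sequence <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  length(chars) > 0L && all(chars %in% CANONICAL_AA)
}

# Deterministic 31-bit string hash (polynomial rolling hash).  Used to seed
# per-residue draws in the synthetic embedding backend so that the backend is
# a pure function of (protein_id, position, residue, seed).
#' @keywords internal
string_hash31 <- function(key) {
  codes <- utf8ToInt(key)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' @keywords internal
site_key <- function(protein_id, position) paste(protein_id, position, sep = "|")

# Empty rejection log with the documented columns.
#' @keywords internal
empty_rejections <- function() {
  data.frame(protein_id = character(), position = integer(),
             reason = character(), stringsAsFactors = FALSE)
}

# Empty site data.frame with the canonical column set.
#' @keywords internal
empty_sites <- function() {
  data.frame(protein_id = character(), position = integer(),
             residue = character(), label = character(),
             source = character(), stringsAsFactors = FALSE)
}
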