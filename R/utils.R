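# Internal helpers shared across modules.

# Deterministic per-stage substream seed: mixes the user seed with a stage
# name so that re-running one stage reproduces its in-pipeline behaviour.
# Kept below 2^31 (R integers are 32-bit); arithmetic stays exact in doubles.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 1000003 + h) %% 2147483647)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_rng <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Canonical (lexicographic) ordering of unordered gene pairs.
canonical_pairs <- function(a, b) {
  swap <- b < a
  ga <- ifelse(swap, b, a)
  gb <- ifelse(swap, a, b)
  list(gene_a = ga, gene_b = gb)
}

pair_key <- function(a, b) {
  p <- canonical_pairs(a, b)
  paste(p$gene_a, p$gene_b, sep = "\r")
}

# Fixed-format numeric rendering so emitted text files are byte-identical
# across runs for a given seed.
fmt_num <- function(x) sprintf("%.10g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
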