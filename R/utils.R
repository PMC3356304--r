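# Deterministic 32-bit string hash (polynomial rolling, FNV-ish) used to
# derive per-sample RNG sub-streams from (seed, sample_id): adding or
# removing a sample never perturbs another sample's draws.
hash_string <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- (h * 16777619 + b) %% 2147483647
  }
  as.integer(h)
}

derive_seed <- function(seed, sample_id) {
  as.integer((as.numeric(seed) * 48271 + hash_string(sample_id)) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
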