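# Seeding contract: one master seed per run; every randomised operation
# draws from its own child stream derived from (master seed, fixed label),
# so adding or reordering operations never perturbs the draws of another.

#' Derive a deterministic child seed from a master seed and a label
#'
#' Hashes `label` and mixes it with `seed` so that distinct operations get
#' independent, reproducible RNG streams from one master seed.
#'
#' @param seed Integer master seed.
#' @param label Character label naming the operation (e.g. `"class_map"`).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(7, "class_map")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(label), length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, keeps all arithmetic exact in doubles
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  as.integer(((abs(seed) %% m) * 48271 + h) %% m)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  expr
}

# FNV-1a hash of a string, returned as 8 hex digits; used for config
# fingerprints in run manifests (stable across sessions, no dependency).
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  # 32-bit modular multiply kept exact in doubles by splitting into halves
  mulmod32 <- function(a, b) {
    ((a %% 65536) * b %% 4294967296 +
       ((a %/% 65536 * b) %% 65536) * 65536) %% 4294967296
  }
  xor_byte <- function(a, byte) {
    low <- a %% 256
    a - low + bitwXor(as.integer(low), as.integer(byte))
  }
  h <- 2166136261
  for (ch in as.integer(charToRaw(enc2utf8(x)))) {
    h <- mulmod32(xor_byte(h, ch), 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
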