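# Internal helpers: deterministic child seeds and small validators.

# FNV-1a style 32-bit string hash, kept in double arithmetic so it is exact
# (all intermediates < 2^53) and portable across platforms.
string_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h)
}

# Child seed derived from a master seed and a name; independent of the order
# in which formations are processed. Always in [0, 2^31).
child_seed <- function(master_seed, key) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  as.integer((as.double(master_seed) + as.double(string_hash(key))) %% .Machine$integer.max)
}

# Run code with a local RNG state; the caller's .Random.seed is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}
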