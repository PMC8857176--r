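# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a reproducible per-stage seed from a master seed and a stage name.
# Keeps results < 2^31 so they are valid R integer seeds.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

DNA_BASES <- c("A", "C", "G", "T")

# Random DNA strings, vectorised.
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  if (length(len) == 1L) len <- rep(len, n)
  chars <- sample(DNA_BASES, sum(len), replace = TRUE)
  ends <- cumsum(len)
  starts <- ends - len + 1L
  vapply(seq_len(n), function(i) paste(chars[starts[i]:ends[i]], collapse = ""),
         character(1))
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# Encode integers in [0, 4^len) as DNA strings (for collision-free UMIs).
int_to_dna <- function(x, len) {
  out <- matrix("", nrow = length(x), ncol = len)
  for (j in seq_len(len)) {
    out[, j] <- DNA_BASES[(x %% 4) + 1]
    x <- x %/% 4
  }
  apply(out, 1, paste, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
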