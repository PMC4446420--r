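# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Complement for plain character vectors of single bases (N passes through).
comp_base <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  unname(map[x])
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Character-level reverse complement, vectorized; avoids DNAStringSet
# construction cost in per-read hot paths.
revcomp_fast <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), ""), function(b) {
    paste(rev(b), collapse = "")
  }, character(1))
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# sample() without its scalar-x surprise: sample_int(5:5, 1) returns 5.
sample_from <- function(x, n = 1L) {
  if (length(x) == 1L) rep(x, n) else sample(x, n, replace = TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x <= 1)
}
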