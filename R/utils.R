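#' Round half away from zero
#'
#' Report-style rounding used for all printed percentages: ties are rounded
#' away from zero (13/40 = 32.5 becomes 33), unlike [base::round()]'s
#' round-half-even. Full precision is kept everywhere internally; this is
#' applied once at report emission.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(32.5)   # 33
#' round_half_up(1.25, 1) # 1.3
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive a labelled child seed from a root seed
#'
#' Each stochastic component draws from its own stream, derived
#' deterministically from the root seed and a fixed text label, so adding
#' samples or stages never perturbs the draws of earlier ones.
#'
#' @param seed integer root seed.
#' @param label character label naming the component/stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(label) == 1L, is.character(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 48271) %% 2147483647)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
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
  })
  set.seed(seed)
  force(code)
}

# Phred+33 encoding helpers (vectorised over one quality string).
phred_scores <- function(qual) utf8ToInt(qual) - 33L

phred_string <- function(scores) intToUtf8(scores + 33L)

#' Reverse complement of nucleotide strings
#'
#' Plain-character reverse complement over the ACGTN alphabet.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(
    x,
    function(s) intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", s)))),
    character(1),
    USE.NAMES = FALSE
  )
}

reverse_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
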