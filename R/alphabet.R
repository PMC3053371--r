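# Residue alphabet, encodings, substitution matrices and shared helpers.

#' Standard amino-acid alphabet
#'
#' The 20 standard residues in the fixed column order used by per-position
#' profile score matrices. `X` is the mask/unknown token and is handled
#' separately throughout.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# letters accepted on read but normalized to X
.nonstandard_aa <- c("B", "Z", "U", "O", "J", "*", "-", ".")

#' Uniform background residue frequencies
#'
#' Default background model for profile construction and E-value
#' calibration: uniform over the 20 standard residues. An empirical
#' frequency vector (named by residue) may be supplied wherever a
#' background is accepted.
#'
#' @return Named numeric vector summing to 1.
#' @export
aa_background <- function() {
  setNames(rep(1 / 20, 20), aa_alphabet())
}

# Encode a residue string to 0-based integer codes; X (and anything not in
# the standard alphabet) becomes 20.
encode_seq <- function(x) {
  idx <- match(strsplit(x, "", fixed = TRUE)[[1]], aa_alphabet())
  idx[is.na(idx)] <- 21L
  idx - 1L
}

decode_seq <- function(codes) {
  paste(c(aa_alphabet(), "X")[codes + 1L], collapse = "")
}

# BLOSUM62 over the 20 standard residues plus X, loaded once from
# Biostrings' bundled copy.
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      m <- env$BLOSUM62
      keep <- c(aa_alphabet(), "X")
      cache <<- m[keep, keep]
    }
    cache
  }
})

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Random residue string(s) under a background frequency model.
random_seq <- function(len, background = aa_background()) {
  paste(sample(names(background), len, replace = TRUE, prob = background),
        collapse = "")
}

# round half-up to integer percent (presentation parity with printed tables)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
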