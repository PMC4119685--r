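`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a nucleotide sequence to the DNA alphabet
#'
#' Uppercases and replaces U with T, so RNA-alphabet references (e.g. mature
#' miRNA FASTA files) and DNA reads live in one alphabet.
#'
#' @param x character vector of sequences.
#' @return character vector over \{A,C,G,T,N\}.
#' @export
normalize_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

#' Reverse-complement DNA sequences
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. Keeps simulator determinism from leaking
# into (or depending on) the session RNG.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# display form of a 3' modification suffix: lowercase, T shown as u
mod_display <- function(x) {
  chartr("t", "u", tolower(x))
}

# inverse of mod_display: DNA bases of a displayed suffix
mod_to_dna <- function(x) {
  chartr("U", "T", toupper(x))
}

stop_io <- function(...) stop(..., call. = FALSE)

fmt_count <- function(x) {
  ifelse(abs(x - round(x)) < 1e-9, format(round(x), scientific = FALSE, trim = TRUE),
         format(round(x, 3), scientific = FALSE, trim = TRUE))
}
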