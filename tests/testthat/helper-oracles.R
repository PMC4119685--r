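# Independent brute-force oracles and small fixture builders.
# These deliberately share no code with the package implementations they
# are used to check.

r_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

r_dna_vec <- function(n, lens) {
  vapply(seq_len(n), function(i) r_dna(if (length(lens) > 1) sample(lens, 1) else lens),
         character(1))
}

# position-by-position adaptor scan (0-based), mirroring the stated rule:
# full adaptor within max_mismatch anywhere, or an adaptor prefix of
# length >= min_overlap matching the read suffix
naive_find_adaptor <- function(seq, adaptor, min_overlap = 8, max_mismatch = 0) {
  L <- nchar(seq); alen <- nchar(adaptor)
  for (p0 in 0:(L - 1)) {
    k <- min(alen, L - p0)
    if (k < alen && k < min_overlap) next
    a <- strsplit(substr(seq, p0 + 1, p0 + k), "")[[1]]
    b <- strsplit(substr(adaptor, 1, k), "")[[1]]
    if (sum(a != b) <= max_mismatch) return(p0)
  }
  NA_integer_
}

rc_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# O(n*m) window scan over every reference; returns data.frame(name, offset,
# strand) like query_index()
naive_index_scan <- function(seqs, names, query, both_strands = FALSE) {
  out <- data.frame(name = character(0), offset = integer(0),
                    strand = character(0), stringsAsFactors = FALSE)
  scan1 <- function(q, strand) {
    m <- nchar(q)
    for (i in seq_along(seqs)) {
      n <- nchar(seqs[i])
      if (m > n || m == 0) next
      win <- substring(seqs[i], 1:(n - m + 1), m:n)
      hit <- which(win == q)
      if (length(hit))
        out <<- rbind(out, data.frame(name = names[i], offset = hit - 1L,
                                      strand = strand, stringsAsFactors = FALSE))
    }
  }
  scan1(query, "+")
  if (both_strands) scan1(rc_chr(query), "-")
  out[order(match(out$name, names), out$offset, out$strand), , drop = FALSE]
}

write_fastq <- function(seqs, path) {
  if (length(seqs))
    writeLines(paste0("@q", seq_along(seqs), "\n", seqs, "\n+\n",
                      strrep("I", nchar(seqs))), path)
  else file.create(path)
  path
}

write_fa <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  path
}

ADAPTOR1 <- "TGGAATTCTCGGGTGCCAAGG"
ADAPTOR2 <- "TCGTATGCCGTCTTCTGCTTG"

# independent collapse (table-based) producing the package's tag layout
collapse_seqs_for_test <- function(reads) {
  t <- table(reads)
  d <- data.frame(seq = names(t), count = as.vector(t), stringsAsFactors = FALSE)
  d <- d[order(-d$count, d$seq), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# sort an isomiR-style table into a canonical row order for comparison
canon_rows <- function(df, cols = names(df)) {
  df <- df[do.call(order, df[cols]), cols, drop = FALSE]
  rownames(df) <- NULL
  df
}
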