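#' 3' adaptor matching parameters
#'
#' @param adaptor 3' adaptor sequence (DNA alphabet). Widely used adaptors
#'   include `TGGAATTCTCGGGTGCCAAGG`, `TCGTATGCCGTCTTCTGCTTG`,
#'   `ATCTCGTATGCCGTCTTCTGCTTG` and `CTGTAGGCACCATCAATCGT`.
#' @param min_overlap minimum adaptor-prefix length required when the
#'   adaptor runs off the 3' end of the read (default 8 nt).
#' @param max_mismatch mismatches tolerated inside the adaptor match
#'   (default 0: exact matching, fully reproducible).
#' @return an object of class `trim_params`.
#' @export
trim_params <- function(adaptor, min_overlap = 8L, max_mismatch = 0L) {
  adaptor <- normalize_seq(adaptor)
  min_overlap <- as.integer(min_overlap)
  max_mismatch <- as.integer(max_mismatch)
  if (min_overlap < 1L) stop_io("min_overlap must be >= 1")
  if (max_mismatch < 0L) stop_io("max_mismatch must be >= 0")
  if (!nzchar(adaptor) || !grepl("^[ACGTN]+$", adaptor))
    stop_io("adaptor must be a nonempty DNA sequence")
  if (nchar(adaptor) < min_overlap)
    stop_io("adaptor (", nchar(adaptor), " nt) is shorter than min_overlap (",
            min_overlap, ")")
  structure(list(adaptor = adaptor, min_overlap = min_overlap,
                 max_mismatch = max_mismatch), class = "trim_params")
}

hamming_le <- function(a, b, k) {
  # is hamming(a, b) <= k for equal-length strings
  if (a == b) return(TRUE)
  if (k == 0L) return(FALSE)
  sum(utf8ToInt(a) != utf8ToInt(b)) <= k
}

#' Find the 3' adaptor in a read
#'
#' Returns the leftmost 0-based position `p` at which either (a) the full
#' adaptor matches `seq[p..]` within `max_mismatch`, or (b) the adaptor runs
#' off the read end and a prefix of length >= `min_overlap` matches the read
#' suffix starting at `p` within `max_mismatch`. `p` equals the insert
#' length; `p = 0` is an adaptor self-ligation product. `NA` when no match.
#'
#' @param seq single uppercased read sequence.
#' @param params a [trim_params()] object.
#' @return integer position (0-based) or `NA_integer_`.
#' @export
find_adaptor <- function(seq, params) {
  find_adaptor_vec(seq, params)
}

#' Vectorized adaptor search
#'
#' Same contract as [find_adaptor()] over a character vector of reads.
#'
#' @param seqs character vector of reads.
#' @inheritParams find_adaptor
#' @return integer vector of 0-based positions (`NA` where absent).
#' @export
find_adaptor_vec <- function(seqs, params) {
  stopifnot(inherits(params, "trim_params"))
  ad <- params$adaptor; alen <- nchar(ad)
  n <- nchar(seqs)
  if (params$max_mismatch == 0L) {
    p <- regexpr(ad, seqs, fixed = TRUE)   # leftmost full match, 1-based
    res <- ifelse(p > 0L, as.integer(p) - 1L, NA_integer_)
    # adaptor running off the read end: longest qualifying prefix = leftmost p
    todo <- is.na(res)
    if (any(todo)) {
      for (k in seq(alen - 1L, params$min_overlap)) {
        if (k < params$min_overlap || !any(todo)) break
        hit <- todo & n >= k & endsWith(seqs, substr(ad, 1L, k))
        res[hit] <- n[hit] - k
        todo <- todo & !hit
      }
    }
    return(res)
  }
  vapply(seqs, function(s) {
    L <- nchar(s)
    for (p0 in 0:(L - 1L)) {
      k <- min(alen, L - p0)
      if (k < alen && k < params$min_overlap) break
      if (hamming_le(substr(s, p0 + 1L, p0 + k), substr(ad, 1L, k),
                     params$max_mismatch))
        return(p0)
    }
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

#' Classify a unique tag by its 3' adaptor
#'
#' Adaptor at position 0 means the 5' adaptor ligated directly to the 3'
#' adaptor with no RNA insert (`self_ligation`); an adaptor at position
#' >= 1 yields a `clean` tag with the insert preceding it; a tag without a
#' detectable adaptor is `nonclean` and is discarded downstream.
#'
#' @param seq tag sequence.
#' @param params a [trim_params()] object.
#' @return list with `status` (`self_ligation`/`clean`/`nonclean`),
#'   `insert` (clean only) and `adaptor_pos` (0-based; `NA` for nonclean).
#' @export
classify_tag <- function(seq, params) {
  p <- find_adaptor_vec(seq, params)
  if (is.na(p)) return(list(status = "nonclean", insert = NULL, adaptor_pos = NA_integer_))
  if (p == 0L) return(list(status = "self_ligation", insert = NULL, adaptor_pos = 0L))
  list(status = "clean", insert = substr(seq, 1L, p), adaptor_pos = p)
}

collapse_seqs <- function(seqs, counts = NULL) {
  if (!length(seqs))
    return(data.frame(seq = character(0), count = numeric(0), stringsAsFactors = FALSE))
  if (is.null(counts)) counts <- rep(1, length(seqs))
  cnt <- rowsum(counts, group = seqs)
  out <- data.frame(seq = rownames(cnt), count = as.vector(cnt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse a FASTQ file into unique sequence tags
#'
#' Reads a (optionally gzipped) single-end FASTQ file and tabulates one tag
#' per distinct read sequence. Ordering is deterministic: descending count,
#' then lexicographic.
#'
#' @param fastq path to a FASTQ or FASTQ.gz file.
#' @return data.frame with columns `seq` and `count`; the counts sum to the
#'   number of FASTQ records.
#' @export
collapse_fastq <- function(fastq) {
  if (!file.exists(fastq)) stop_io("cannot read FASTQ file: ", fastq)
  if (file.size(fastq) == 0L)
    return(collapse_seqs(character(0)))
  reads <- tryCatch(
    as.character(Biostrings::readDNAStringSet(fastq, format = "fastq",
                                              use.names = FALSE)),
    error = function(e) stop_io("FASTQ parse error in ", fastq, ": ",
                                conditionMessage(e)))
  collapse_seqs(toupper(reads))
}

#' Count-weighted read length distribution
#'
#' @param tags data.frame with `seq` and `count` (typically clean inserts).
#' @return data.frame with `length`, `count`, `pct` (percentages sum to 100).
#' @export
length_histogram <- function(tags) {
  if (!nrow(tags))
    return(data.frame(length = integer(0), count = numeric(0), pct = numeric(0)))
  cnt <- rowsum(tags$count, group = nchar(tags$seq))
  out <- data.frame(length = as.integer(rownames(cnt)), count = as.vector(cnt))
  out <- out[order(out$length), , drop = FALSE]
  out$pct <- 100 * out$count / sum(out$count)
  rownames(out) <- NULL
  out
}

#' Run the read-processing stage
#'
#' Collapses the raw reads into unique tags, searches each tag for the 3'
#' adaptor, partitions the library into self-ligation / clean / nonclean,
#' re-collapses the clean inserts (reads with different adaptor positions
#' but identical inserts merge), computes the clean-read length
#' distribution, and keeps as *qualified* the clean inserts within the
#' length window whose collapsed count reaches `min_count` and that contain
#' no N. Percentages are count-weighted shares of all raw reads.
#'
#' @param fastq path to the raw FASTQ file; alternatively supply `tags`.
#' @param params a [trim_params()] object.
#' @param min_len,max_len insert length window in nt (defaults 15-30).
#' @param min_count minimum collapsed insert count (default 2).
#' @param tags pre-collapsed tags (data.frame `seq`, `count`) instead of
#'   `fastq`.
#' @return list of class `readpro_result` with `summary` (counts and
#'   percentages), `length_dist`, `qualified` (data.frame `rank`, `seq`,
#'   `count`) and `clean` (all collapsed clean inserts).
#' @export
run_readpro <- function(fastq = NULL, params, min_len = 15L, max_len = 30L,
                        min_count = 2L, tags = NULL) {
  stopifnot(inherits(params, "trim_params"))
  if (min_len > max_len) stop_io("min_len must be <= max_len")
  if (is.null(tags)) tags <- collapse_fastq(fastq)
  total <- sum(tags$count)
  pos <- find_adaptor_vec(tags$seq, params)
  status <- ifelse(is.na(pos), "nonclean",
                   ifelse(pos == 0L, "self_ligation", "clean"))
  n_self <- sum(tags$count[status == "self_ligation"])
  n_non <- sum(tags$count[status == "nonclean"])
  cl <- status == "clean"
  clean <- collapse_seqs(substr(tags$seq[cl], 1L, pos[cl]), tags$count[cl])
  n_clean <- sum(clean$count)
  stopifnot(n_self + n_non + n_clean == total)
  len <- nchar(clean$seq)
  ok <- len >= min_len & len <= max_len & clean$count >= min_count &
    !grepl("N", clean$seq, fixed = TRUE)
  qualified <- clean[ok, , drop = FALSE]
  rownames(qualified) <- NULL
  if (nrow(qualified)) qualified <- cbind(rank = seq_len(nrow(qualified)), qualified)
  else qualified <- data.frame(rank = integer(0), seq = character(0),
                               count = numeric(0))
  n_qual <- sum(qualified$count)
  pct <- function(x) if (total > 0) 100 * x / total else 0
  summary <- list(total_reads = total,
                  n_self_ligation = n_self, n_nonclean = n_non,
                  n_clean = n_clean, n_qualified = n_qual,
                  pct_self_ligation = pct(n_self), pct_nonclean = pct(n_non),
                  pct_clean = pct(n_clean), pct_qualified = pct(n_qual),
                  adaptor = params$adaptor,
                  min_len = min_len, max_len = max_len, min_count = min_count)
  structure(list(summary = summary, length_dist = length_histogram(clean),
                 qualified = qualified, clean = clean),
            class = "readpro_result")
}

#' @export
print.readpro_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<readpro_result> %s reads: self-ligation %.2f%%, ",
                     "nonclean %.2f%%, clean %.2f%%, qualified %.2f%% ",
                     "(%d unique qualified tags)\n"),
              format(s$total_reads, big.mark = ","), s$pct_self_ligation,
              s$pct_nonclean, s$pct_clean, s$pct_qualified, nrow(x$qualified)))
  invisible(x)
}

#' Write qualified tags as collapsed FASTA
#'
#' Headers follow the `>t<rank>_x<count>` dialect; the rank comes from the
#' deterministic ordering (descending count, then lexicographic).
#'
#' @param tags data.frame with `rank` (optional), `seq`, `count`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(tags, path) {
  rank <- if ("rank" %in% names(tags)) tags$rank else seq_len(nrow(tags))
  x <- Biostrings::BStringSet(tags$seq)
  names(x) <- sprintf("t%d_x%s", rank, fmt_count(tags$count))
  tryCatch(Biostrings::writeXStringSet(x, path, width = 100000L),
           error = function(e) stop_io("cannot write ", path, ": ",
                                       conditionMessage(e)))
  invisible(path)
}

#' Read a collapsed FASTA written by [write_collapsed_fasta()]
#'
#' @param path collapsed FASTA path.
#' @return data.frame with `rank`, `seq`, `count`.
#' @export
read_collapsed_fasta <- function(path) {
  if (!file.exists(path)) stop_io("cannot read collapsed FASTA: ", path)
  if (file.size(path) == 0L)
    return(data.frame(rank = integer(0), seq = character(0), count = numeric(0)))
  x <- Biostrings::readBStringSet(path)
  hd <- names(x)
  m <- regmatches(hd, regexec("^t([0-9]+)_x([0-9.]+)$", hd))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop_io("malformed collapsed-FASTA header: ", hd[which(bad)[1]])
  data.frame(rank = as.integer(vapply(m, `[[`, character(1), 2)),
             seq = normalize_seq(as.character(x)),
             count = as.numeric(vapply(m, `[[`, character(1), 3)),
             stringsAsFactors = FALSE)
}
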