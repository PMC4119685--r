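#' Exact-substring index over a set of reference sequences
#'
#' Builds a queryable index answering "at which (reference, offset, strand)
#' does a query occur as an exact substring?". Hairpin and transcript
#' references are searched on the sense strand only; a genome index built
#' with `both_strands = TRUE` is additionally searched on the reverse
#' complement. Internally the references are concatenated with a separator
#' that cannot occur in the DNA alphabet, so a single fixed-pattern scan per
#' query covers the whole collection; results are identical to a naive scan
#' over every reference.
#'
#' @param seqs character vector of reference sequences (DNA alphabet; U is
#'   normalized to T).
#' @param names reference identifiers; defaults to `names(seqs)` or
#'   `ref1..refN`.
#' @param both_strands search the reverse complement as well (genome mode).
#' @return an object of class `substring_index`.
#' @export
build_substring_index <- function(seqs, names = NULL, both_strands = FALSE) {
  seqs <- normalize_seq(as.character(seqs))
  if (is.null(names)) {
    names <- base::names(seqs) %||% if (length(seqs)) paste0("ref", seq_along(seqs)) else character(0)
  }
  stopifnot(length(names) == length(seqs))
  widths <- nchar(seqs)
  # 1-based start of each reference within the concatenated text
  starts <- if (length(seqs)) cumsum(c(1L, widths + 1L))[seq_along(seqs)] else integer(0)
  structure(
    list(seqs = unname(seqs), names = unname(names), widths = widths,
         starts = starts, concat = paste(seqs, collapse = "#"),
         both_strands = both_strands),
    class = "substring_index")
}

#' @export
print.substring_index <- function(x, ...) {
  cat(sprintf("<substring_index> %d reference(s), %s nt total%s\n",
              length(x$seqs), format(sum(x$widths), big.mark = ","),
              if (x$both_strands) ", both strands" else ""))
  invisible(x)
}

# positions (1-based, in concat) of fixed pattern occurrences
concat_hits <- function(index, query) {
  if (!nzchar(index$concat) || !nzchar(query)) return(integer(0))
  m <- gregexpr(query, index$concat, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m)
}

#' Query an exact-substring index
#'
#' @param index a `substring_index`.
#' @param query a single sequence (DNA alphabet).
#' @return data.frame with columns `name` (reference id), `offset` (0-based
#'   offset of the match on the reference's sense strand) and `strand`
#'   (`"+"`/`"-"`; minus-strand rows only arise for `both_strands` indexes
#'   and give the offset of the site whose reverse complement equals the
#'   query). Zero rows when the query occurs nowhere.
#' @export
query_index <- function(index, query) {
  stopifnot(inherits(index, "substring_index"), length(query) == 1L)
  query <- normalize_seq(query)
  empty <- data.frame(name = character(0), offset = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (!nzchar(query)) return(empty)
  one_strand <- function(q, strand) {
    pos <- concat_hits(index, q)
    if (!length(pos)) return(empty)
    ref <- findInterval(pos, index$starts)
    data.frame(name = index$names[ref], offset = pos - index$starts[ref],
               strand = strand, stringsAsFactors = FALSE)
  }
  out <- one_strand(query, "+")
  if (index$both_strands) {
    rcq <- revcomp(query)
    out <- rbind(out, one_strand(rcq, "-"))
  }
  out[order(match(out$name, index$names), out$offset, out$strand), , drop = FALSE]
}

#' Does a query occur anywhere in an index?
#'
#' Cheaper than [query_index()] when only presence matters (hierarchical
#' read classification).
#'
#' @inheritParams query_index
#' @return logical scalar.
#' @export
index_has <- function(index, query) {
  query <- normalize_seq(query)
  if (!nzchar(query) || !nzchar(index$concat)) return(FALSE)
  if (grepl(query, index$concat, fixed = TRUE)) return(TRUE)
  index$both_strands && grepl(revcomp(query), index$concat, fixed = TRUE)
}
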