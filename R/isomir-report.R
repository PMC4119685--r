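#' Render an isomiR alignment block for one hairpin
#'
#' The first line is the hairpin sequence in lowercase with annotated
#' mature regions in uppercase. Each isomiR record is printed on its own
#' line, indented so that its first matched base sits under the hairpin
#' position it maps to, with the matched body uppercase and the 3'
#' modification suffix lowercase, followed by the read count and the
#' "shift5,shift3" pair.
#'
#' @param hairpin_name hairpin identifier (block header `>name`).
#' @param hairpin_seq hairpin sequence.
#' @param matures data.frame of annotations on this hairpin (`name`,
#'   `start`, `end`).
#' @param records isomiR records for this hairpin: data.frame `mature`,
#'   `shift5`, `shift3`, `mod_suffix`, `count` (as from
#'   [enumerate_isomirs()], restricted to matures of this hairpin).
#' @return character scalar, lines separated by newlines.
#' @export
render_isomir_alignment <- function(hairpin_name, hairpin_seq, matures,
                                    records) {
  hairpin_seq <- normalize_seq(hairpin_seq)
  L <- nchar(hairpin_seq)
  top <- tolower(hairpin_seq)
  for (i in seq_len(nrow(matures))) {
    s <- matures$start[i]; e <- matures$end[i]
    substr(top, s, e) <- toupper(substr(top, s, e))
  }
  lines <- c(paste0(">", hairpin_name), top)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    ann <- matures[matures$name == r$mature, , drop = FALSE]
    if (!nrow(ann))
      stop_io("record for '", r$mature, "' does not belong to ", hairpin_name)
    s <- ann$start[1] + r$shift5
    e <- ann$end[1] + r$shift3
    if (s < 1L || e > L || s > e)
      stop_io("isomiR span ", s, "-", e, " outside hairpin ", hairpin_name)
    lines <- c(lines, paste0(strrep(" ", s - 1L),
                             toupper(substr(hairpin_seq, s, e)),
                             r$mod_suffix, "  ", fmt_count(r$count), " ",
                             r$shift5, ",", r$shift3))
  }
  paste(lines, collapse = "\n")
}

#' Parse an isomiR alignment block back into records
#'
#' Inverse of [render_isomir_alignment()] (used for round-trip checks and
#' downstream tooling).
#'
#' @param text block produced by [render_isomir_alignment()].
#' @return list with `hairpin` (name), `seq`, `matures` (data.frame
#'   `start`, `end` of uppercase runs on the top line) and `records`
#'   (data.frame `start`, `end`, `mod_suffix`, `count`, `shift5`,
#'   `shift3`).
#' @export
parse_isomir_alignment <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  stopifnot(length(lines) >= 2L, startsWith(lines[1], ">"))
  name <- substring(lines[1], 2L)
  top <- lines[2]
  m <- gregexpr("[A-Z]+", top)[[1]]
  matures <- if (m[1] == -1L)
    data.frame(start = integer(0), end = integer(0))
  else
    data.frame(start = as.integer(m),
               end = as.integer(m) + attr(m, "match.length") - 1L)
  rec <- data.frame(start = integer(0), end = integer(0),
                    mod_suffix = character(0), count = numeric(0),
                    shift5 = integer(0), shift3 = integer(0),
                    stringsAsFactors = FALSE)
  for (ln in lines[-(1:2)]) {
    if (!nzchar(trimws(ln))) next
    g <- regexec("^( *)([A-Z]+)([a-z]*)  ([0-9.]+) (-?[0-9]+),(-?[0-9]+)$", ln)
    p <- regmatches(ln, g)[[1]]
    if (!length(p)) stop_io("malformed isomiR line: ", ln)
    start <- nchar(p[2]) + 1L
    rec <- rbind(rec, data.frame(
      start = start, end = start + nchar(p[3]) - 1L, mod_suffix = p[4],
      count = as.numeric(p[5]), shift5 = as.integer(p[6]),
      shift3 = as.integer(p[7]), stringsAsFactors = FALSE))
  }
  list(hairpin = name, seq = toupper(top), matures = matures, records = rec)
}

#' Render all isomiR blocks of a mapping result
#'
#' @param isomirs isomiR table from [enumerate_isomirs()].
#' @param refs a `ref_set`.
#' @return character vector, one rendered block per hairpin with records.
#' @export
render_isomir_report <- function(isomirs, refs) {
  if (!nrow(isomirs)) return(character(0))
  hp_of <- refs$matures$hairpin[match(isomirs$mature, refs$matures$name)]
  blocks <- character(0)
  for (hp in unique(hp_of)) {
    seq <- refs$hairpins$seq[refs$hairpins$name == hp]
    ann <- refs$matures[refs$matures$hairpin == hp, , drop = FALSE]
    rec <- isomirs[hp_of == hp & isomirs$mature %in% ann$name, , drop = FALSE]
    blocks <- c(blocks, render_isomir_alignment(hp, seq, ann, rec))
  }
  blocks
}
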