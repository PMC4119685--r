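CATEGORY_ORDER <- c("rRNA", "tRNA", "mRNA", "ncRNA", "genome")

read_fasta_named <- function(path) {
  if (!file.exists(path)) stop_io("cannot read FASTA file: ", path)
  x <- Biostrings::readBStringSet(path)
  seqs <- normalize_seq(as.character(x))
  # miRBase headers are ">ID description"; keep the ID token only
  names(seqs) <- vapply(strsplit(names(x), "[ \t]"), `[[`, character(1), 1)
  seqs
}

#' Locate mature miRNAs on a hairpin precursor
#'
#' Each mature sequence is placed at its first exact occurrence in the
#' hairpin (1-based inclusive coordinates). The arm is called from the
#' midpoint rule: a mature whose midpoint lies at or before the hairpin
#' midpoint is `5p`, otherwise `3p`. A mature occurring more than once is
#' placed at its first occurrence with a warning; a mature absent from the
#' hairpin is skipped.
#'
#' @param hairpin_seq hairpin sequence (DNA alphabet; U normalized to T).
#' @param mature_seqs named character vector of mature sequences.
#' @param hairpin_name identifier used in the result and in warnings.
#' @return data.frame with columns `name`, `start`, `end`, `arm`, `seq`.
#' @export
locate_matures <- function(hairpin_seq, mature_seqs, hairpin_name = "hairpin") {
  hairpin_seq <- normalize_seq(hairpin_seq)
  mature_seqs <- normalize_seq(mature_seqs)
  L <- nchar(hairpin_seq)
  nm <- names(mature_seqs) %||% paste0("mature", seq_along(mature_seqs))
  out <- data.frame(name = character(0), start = integer(0), end = integer(0),
                    arm = character(0), seq = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(mature_seqs)) {
    m <- mature_seqs[[i]]
    if (!nzchar(m)) next
    hits <- gregexpr(m, hairpin_seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    if (length(hits) > 1L)
      warning(sprintf("mature '%s' occurs %d times on %s; using first occurrence",
                      nm[i], length(hits), hairpin_name), call. = FALSE)
    start <- as.integer(hits[1]); end <- start + nchar(m) - 1L
    arm <- if ((start + end) / 2 <= (1 + L) / 2) "5p" else "3p"
    out <- rbind(out, data.frame(name = nm[i], start = start, end = end,
                                 arm = arm, seq = m, stringsAsFactors = FALSE))
  }
  # at most one mature per arm: keep the first listed, drop the rest
  if (nrow(out) > 1L && anyDuplicated(out$arm)) {
    dup <- duplicated(out$arm)
    warning(sprintf("%s: %d additional mature(s) on an already-annotated arm dropped",
                    hairpin_name, sum(dup)), call. = FALSE)
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# name stem shared between a mature and its hairpin(s):
# hsa-miR-21-5p -> hsa-mir-21; hairpin hsa-mir-92a-1 -> hsa-mir-92a
mature_stem <- function(x) sub("-(5p|3p)$", "", tolower(x))
hairpin_stem <- function(x) sub("-[0-9]+$", "", tolower(x))

#' Load a miRBase-style reference set
#'
#' Reads hairpin and mature FASTA files, keeps only the records whose
#' identifier carries the species prefix (e.g. `hsa-`), normalizes U to T,
#' and locates every mature on its hairpin(s) by exact substring search.
#' Candidate hairpins for a mature are those sharing its name stem
#' (`hsa-miR-21-5p` matches `hsa-mir-21`, and also `hsa-mir-92a-1` /
#' `hsa-mir-92a-2` for duplicated loci); when no hairpin shares the stem
#' (non-miRBase naming), all hairpins are searched. Matures absent from
#' every candidate hairpin are skipped with a warning. Optional non-miRNA
#' reference FASTAs are attached in the fixed hierarchy order rRNA, tRNA,
#' mRNA, ncRNA, genome; absent categories are skipped. Substring indexes
#' are built for the hairpins and every category (genome: both strands).
#'
#' @param hairpin_fasta,mature_fasta paths to hairpin and mature FASTA files.
#' @param species species prefix (e.g. `"hsa"`, `"rno"`, `"cel"`, `"dme"`);
#'   `NULL` keeps all records.
#' @param category_fastas named list of FASTA paths; recognised names are
#'   `rRNA`, `tRNA`, `mRNA`, `ncRNA`, `genome` (case-insensitive).
#' @param quiet suppress the loaded-record message.
#' @return an object of class `ref_set` with elements `hairpins`
#'   (data.frame `name`, `seq`), `matures` (data.frame `name`, `hairpin`,
#'   `start`, `end`, `arm`, `seq`), `categories` (named list of sequence
#'   vectors), `species` and `indexes`.
#' @export
load_reference_set <- function(hairpin_fasta, mature_fasta, species = NULL,
                               category_fastas = list(), quiet = FALSE) {
  hp <- read_fasta_named(hairpin_fasta)
  mat <- read_fasta_named(mature_fasta)
  if (!is.null(species) && nzchar(species)) {
    pref <- paste0(species, "-")
    hp <- hp[startsWith(names(hp), pref)]
    mat <- mat[startsWith(names(mat), pref)]
  }
  if (!length(hp) || !length(mat))
    stop_io("empty reference: no hairpin/mature records for species '",
            species %||% "*", "'")
  cats <- list()
  if (length(category_fastas)) {
    cn <- names(category_fastas)
    canon <- CATEGORY_ORDER[match(tolower(cn), tolower(CATEGORY_ORDER))]
    if (anyNA(canon))
      stop_io("unknown reference category: ",
              paste(cn[is.na(canon)], collapse = ", "))
    for (k in CATEGORY_ORDER) {
      i <- which(canon == k)
      if (length(i)) cats[[k]] <- read_fasta_named(category_fastas[[i[1]]])
    }
  }
  refs <- new_ref_set(hairpins = data.frame(name = names(hp), seq = unname(hp),
                                            stringsAsFactors = FALSE),
                      mature_seqs = mat, categories = cats,
                      species = species %||% "")
  if (!quiet)
    message(sprintf("loaded %d hairpins, %d matures located (%d mature names annotated)",
                    nrow(refs$hairpins), nrow(refs$matures),
                    length(unique(refs$matures$name))))
  refs
}

# assemble a ref_set from in-memory pieces (shared by loader and simulator)
new_ref_set <- function(hairpins, mature_seqs, categories = list(), species = "") {
  hairpins$seq <- normalize_seq(hairpins$seq)
  stopifnot(!anyDuplicated(hairpins$name), all(nzchar(hairpins$seq)))
  mats <- list()
  hp_stems <- hairpin_stem(hairpins$name)
  hp_lc <- tolower(hairpins$name)
  for (i in seq_along(mature_seqs)) {
    mname <- names(mature_seqs)[i]
    stem <- mature_stem(mname)
    cand <- which(hp_lc == stem | hp_stems == stem)
    if (!length(cand)) cand <- seq_len(nrow(hairpins))
    placed <- FALSE
    for (j in cand) {
      ann <- locate_matures(hairpins$seq[j], stats::setNames(mature_seqs[i], mname),
                            hairpins$name[j])
      if (nrow(ann)) {
        ann$hairpin <- hairpins$name[j]
        mats[[length(mats) + 1L]] <- ann
        placed <- TRUE
      }
    }
    if (!placed)
      warning(sprintf("mature '%s' not found on any candidate hairpin; annotation skipped",
                      mname), call. = FALSE)
  }
  matures <- if (length(mats)) do.call(rbind, mats) else
    data.frame(name = character(0), start = integer(0), end = integer(0),
               arm = character(0), seq = character(0), hairpin = character(0),
               stringsAsFactors = FALSE)
  matures <- matures[, c("name", "hairpin", "start", "end", "arm", "seq")]
  # one mature per arm per hairpin
  key <- paste(matures$hairpin, matures$arm)
  if (anyDuplicated(key)) {
    warning("dropping extra matures on already-annotated arms", call. = FALSE)
    matures <- matures[!duplicated(key), , drop = FALSE]
  }
  rownames(matures) <- NULL
  categories <- categories[intersect(CATEGORY_ORDER, names(categories))]
  idx <- list(hairpin = build_substring_index(hairpins$seq, hairpins$name))
  for (k in names(categories))
    idx[[k]] <- build_substring_index(categories[[k]], names(categories[[k]]),
                                      both_strands = identical(k, "genome"))
  structure(list(hairpins = hairpins, matures = matures, categories = categories,
                 species = species, indexes = idx),
            class = "ref_set")
}

#' @export
print.ref_set <- function(x, ...) {
  cat(sprintf("<ref_set> species '%s': %d hairpins, %d mature annotations (%d names)\n",
              x$species, nrow(x$hairpins), nrow(x$matures),
              length(unique(x$matures$name))))
  for (k in names(x$categories))
    cat(sprintf("  %-6s %d sequence(s)\n", k, length(x$categories[[k]])))
  invisible(x)
}

#' Annotated totals of a reference set
#'
#' @param refs a `ref_set`.
#' @return list with `n_matures` (distinct mature names) and `n_hairpins`.
#' @export
annotated_totals <- function(refs) {
  list(n_matures = length(unique(refs$matures$name)),
       n_hairpins = nrow(refs$hairpins))
}

#' Write a reference set to a reloadable index directory
#'
#' Writes `hairpins.fa`, `matures.fa`, one FASTA per attached category and a
#' `meta.json`; [read_reference_set()] reloads it.
#'
#' @param refs a `ref_set`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_reference_set <- function(refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fa <- function(seqs, path) {
    x <- Biostrings::BStringSet(seqs)
    Biostrings::writeXStringSet(x, path, width = 70L)
  }
  write_fa(stats::setNames(refs$hairpins$seq, refs$hairpins$name),
           file.path(dir, "hairpins.fa"))
  m <- refs$matures[!duplicated(refs$matures$name), ]
  write_fa(stats::setNames(m$seq, m$name), file.path(dir, "matures.fa"))
  for (k in names(refs$categories))
    write_fa(refs$categories[[k]], file.path(dir, paste0(k, ".fa")))
  jsonlite::write_json(list(species = refs$species,
                            categories = as.list(names(refs$categories))),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Reload a reference set written by [write_reference_set()]
#'
#' @param dir index directory.
#' @return a `ref_set`.
#' @export
read_reference_set <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop_io("not an index directory: ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  cats <- as.list(stats::setNames(file.path(dir, paste0(meta$categories, ".fa")),
                                  meta$categories))
  load_reference_set(file.path(dir, "hairpins.fa"), file.path(dir, "matures.fa"),
                     species = if (nzchar(meta$species)) meta$species else NULL,
                     category_fastas = cats, quiet = TRUE)
}
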