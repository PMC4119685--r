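#' Place a tag on the hairpin set with 3' soft-clipping
#'
#' Sequence variation in small-RNA reads concentrates at the 3' end
#' (3' end modifications), so mapping clips the tag from its 3' end only:
#' for c = 0, 1, ..., `max_mod` in order, all exact hits of the tag with
#' its last c bases removed are collected, stopping at the smallest c with
#' at least one hit (the unmodified placement is always preferred). The
#' clipped bases become the modification suffix, reported lowercase with
#' T written as u.
#'
#' @param seq tag sequence.
#' @param index `substring_index` over the hairpin set.
#' @param max_mod maximum clipped 3' bases (default 3).
#' @param min_match minimum matched length (default 15; clip levels that
#'   would shorten the match below this are not tried).
#' @return data.frame with columns `hairpin`, `start`, `end` (1-based
#'   inclusive matched span) and `mod_suffix`; zero rows when unplaceable.
#' @export
align_tag <- function(seq, index, max_mod = 3L, min_match = 15L) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  empty <- data.frame(hairpin = character(0), start = integer(0),
                      end = integer(0), mod_suffix = character(0),
                      stringsAsFactors = FALSE)
  for (clip in 0:max_mod) {
    if (n - clip < min_match) break
    core <- substr(seq, 1L, n - clip)
    hits <- query_index(index, core)
    if (nrow(hits)) {
      return(data.frame(hairpin = hits$name, start = hits$offset + 1L,
                        end = hits$offset + nchar(core),
                        mod_suffix = mod_display(substr(seq, n - clip + 1L, n)),
                        stringsAsFactors = FALSE))
    }
  }
  empty
}

#' Assign a hairpin hit to a mature miRNA, the opposite arm, or elsewhere
#'
#' The annotated mature with maximal overlap with the matched span is
#' chosen; if that overlap covers at least half of the matched length the
#' hit is a mature assignment with 5'/3' shifts (`shift5 = start -
#' mature start`, `shift3 = matched end - mature end`). Otherwise, if the
#' span midpoint falls on an arm without an annotated mature the hit is an
#' opposite-arm (`opp_arm`) candidate; anything else (loop/flank) is
#' `hairpin_other`. Overlap ties go to the 5p mature; the arm of a
#' position is 5p when it lies at or before the hairpin midpoint.
#'
#' @param hit one-row data.frame from [align_tag()].
#' @param hairpin_seq the hairpin sequence.
#' @param matures data.frame of this hairpin's annotations (`name`,
#'   `start`, `end`, `arm`).
#' @param overlap_frac minimum overlap as a fraction of matched length
#'   (default 0.5).
#' @return list with `target` (mature name, `"opp_arm"` or
#'   `"hairpin_other"`), `type` (`mature`/`opp_arm`/`hairpin_other`),
#'   `shift5`, `shift3` (mature assignments only).
#' @export
assign_hit_to_mature <- function(hit, hairpin_seq, matures,
                                 overlap_frac = 0.5) {
  L <- nchar(hairpin_seq)
  span_len <- hit$end - hit$start + 1L
  if (nrow(matures)) {
    ov <- pmax(0L, pmin(hit$end, matures$end) - pmax(hit$start, matures$start) + 1L)
    best <- order(-ov, matures$arm)[1]   # ties -> 5p (sorts before 3p)
    if (ov[best] >= overlap_frac * span_len) {
      return(list(target = matures$name[best], type = "mature",
                  shift5 = hit$start - matures$start[best],
                  shift3 = hit$end - matures$end[best]))
    }
  }
  mid_arm <- if ((hit$start + hit$end) / 2 <= (1 + L) / 2) "5p" else "3p"
  if (!(mid_arm %in% matures$arm))
    return(list(target = "opp_arm", type = "opp_arm",
                shift5 = NA_integer_, shift3 = NA_integer_))
  list(target = "hairpin_other", type = "hairpin_other",
       shift5 = NA_integer_, shift3 = NA_integer_)
}

#' Classify qualified tags into read categories
#'
#' Each tag is assigned to the first category in the fixed hierarchy where
#' it matches: miRNA (hairpin hit with 3' soft-clipping), then rRNA, tRNA,
#' mRNA, ncRNA (full-length exact, sense strand), then genome (full-length
#' exact, both strands), else unknown. Shares are count-weighted.
#'
#' @param tags data.frame of qualified tags (`seq`, `count`).
#' @param refs a `ref_set`.
#' @param max_mod,min_match soft-clip parameters passed to [align_tag()].
#' @return list with `shares` (named percentages over all seven
#'   categories), `counts` (read counts per category) and `category`
#'   (per-tag category, aligned with `tags` rows).
#' @export
classify_tags <- function(tags, refs, max_mod = 3L, min_match = 15L) {
  cats <- c("miRNA", CATEGORY_ORDER, "unknown")
  category <- character(nrow(tags))
  for (i in seq_len(nrow(tags))) {
    s <- tags$seq[i]
    if (nrow(align_tag(s, refs$indexes$hairpin, max_mod, min_match))) {
      category[i] <- "miRNA"
      next
    }
    hit <- "unknown"
    for (k in names(refs$categories)) {
      if (index_has(refs$indexes[[k]], s)) { hit <- k; break }
    }
    category[i] <- hit
  }
  counts <- vapply(cats, function(k) sum(tags$count[category == k]), numeric(1))
  total <- sum(counts)
  shares <- if (total > 0) 100 * counts / total else counts
  list(shares = shares, counts = counts, category = category)
}

# one row per (tag, target) with fractional weight; the unit every
# downstream table is built from
build_assignments <- function(tags, refs, max_mod = 3L, min_match = 15L,
                              overlap_frac = 0.5) {
  rows <- vector("list", nrow(tags))
  for (i in seq_len(nrow(tags))) {
    hits <- align_tag(tags$seq[i], refs$indexes$hairpin, max_mod, min_match)
    if (!nrow(hits)) next
    asn <- vector("list", nrow(hits))
    for (j in seq_len(nrow(hits))) {
      hp <- hits$hairpin[j]
      a <- assign_hit_to_mature(
        hits[j, ], refs$hairpins$seq[refs$hairpins$name == hp],
        refs$matures[refs$matures$hairpin == hp, , drop = FALSE],
        overlap_frac)
      asn[[j]] <- data.frame(
        tag = tags$seq[i], count = tags$count[i], hairpin = hp,
        start = hits$start[j], end = hits$end[j],
        mod_suffix = hits$mod_suffix[j], type = a$type,
        target = if (a$type == "mature") a$target else paste0(hp, ":", a$type),
        mature = if (a$type == "mature") a$target else NA_character_,
        shift5 = a$shift5, shift3 = a$shift3, stringsAsFactors = FALSE)
    }
    asn <- do.call(rbind, asn)
    # duplicated loci yielding the same mature name are merged before the
    # fractional split; each distinct target receives count / k once
    asn <- asn[!duplicated(asn$target), , drop = FALSE]
    asn$weight <- asn$count / nrow(asn)
    rows[[i]] <- asn
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(tag = character(0), count = numeric(0),
                      hairpin = character(0), start = integer(0),
                      end = integer(0), mod_suffix = character(0),
                      type = character(0), target = character(0),
                      mature = character(0), shift5 = integer(0),
                      shift3 = integer(0), weight = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' miRNA expression profile in transcripts per million
#'
#' A tag hitting k distinct targets contributes count/k to each (fractional
#' split, so total read mass is conserved). TPM scales each mature's raw
#' count to a per-million share of all mature-assigned reads, making
#' profiles comparable between libraries with unequal miRNA yield.
#'
#' @param assignments assignment table from [build_assignments()].
#' @return data.frame (`mature`, `raw_count`, `tpm`) sorted by descending
#'   TPM then name; zero rows when no miRNA reads. Sum of `tpm` is 1e6.
#' @export
build_profile <- function(assignments) {
  m <- assignments[assignments$type == "mature", , drop = FALSE]
  if (!nrow(m))
    return(data.frame(mature = character(0), raw_count = numeric(0),
                      tpm = numeric(0), stringsAsFactors = FALSE))
  raw <- rowsum(m$weight, group = m$mature)
  out <- data.frame(mature = rownames(raw), raw_count = as.vector(raw),
                    stringsAsFactors = FALSE)
  out$tpm <- 1e6 * out$raw_count / sum(out$raw_count)
  out <- out[order(-out$tpm, out$mature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Share of the top-n miRNAs in a profile
#'
#' @param profile result of [build_profile()].
#' @param n number of top miRNAs (default 5).
#' @return percentage of miRNA reads carried by the n most abundant matures.
#' @export
top_share <- function(profile, n = 5L) {
  if (!nrow(profile)) return(0)
  sum(utils::head(profile$tpm, n)) / 1e4
}

#' 3' end modification pattern frequencies
#'
#' Count-weighted frequency of each modification suffix (the empty suffix
#' is the unmodified class) over all mature-assigned reads. The AU-rich
#' share is the percentage, among modified reads, of suffixes composed
#' only of a and u.
#'
#' @param assignments assignment table from [build_assignments()].
#' @param min_pct report view threshold: patterns at or below this
#'   percentage are dropped from `view` (default 1; `full` always keeps
#'   everything).
#' @return list with `full` (data.frame `pattern`, `count`, `pct`), `view`
#'   (patterns above `min_pct`) and `au_rich_pct`.
#' @export
mod_pattern_frequencies <- function(assignments, min_pct = 1) {
  m <- assignments[assignments$type == "mature", , drop = FALSE]
  if (!nrow(m)) {
    empty <- data.frame(pattern = character(0), count = numeric(0),
                        pct = numeric(0), stringsAsFactors = FALSE)
    return(list(full = empty, view = empty, au_rich_pct = NA_real_))
  }
  cnt <- rowsum(m$weight, group = m$mod_suffix)
  full <- data.frame(pattern = rownames(cnt), count = as.vector(cnt),
                     stringsAsFactors = FALSE)
  full$pct <- 100 * full$count / sum(full$count)
  full <- full[order(-full$count, full$pattern), , drop = FALSE]
  rownames(full) <- NULL
  modded <- full[full$pattern != "", , drop = FALSE]
  au <- sum(modded$count[grepl("^[au]+$", modded$pattern)])
  au_rich <- if (nrow(modded) && sum(modded$count) > 0)
    100 * au / sum(modded$count) else NA_real_
  list(full = full, view = full[full$pct > min_pct, , drop = FALSE],
       au_rich_pct = au_rich)
}

#' Enumerate isomiRs per mature miRNA
#'
#' Reads assigned to the same mature are merged by their isomiR key
#' (5' shift, 3' shift, modification suffix) with counts summed, so each
#' mature's isomiR counts add up exactly to its profile raw count.
#'
#' @param assignments assignment table from [build_assignments()].
#' @return data.frame (`mature`, `shift5`, `shift3`, `mod_suffix`,
#'   `count`) sorted per mature by descending count.
#' @export
enumerate_isomirs <- function(assignments) {
  m <- assignments[assignments$type == "mature", , drop = FALSE]
  if (!nrow(m))
    return(data.frame(mature = character(0), shift5 = integer(0),
                      shift3 = integer(0), mod_suffix = character(0),
                      count = numeric(0), stringsAsFactors = FALSE))
  key <- paste(m$mature, m$shift5, m$shift3, m$mod_suffix, sep = "\r")
  cnt <- rowsum(m$weight, group = key)
  parts <- strsplit(rownames(cnt), "\r", fixed = TRUE)
  out <- data.frame(
    mature = vapply(parts, `[`, character(1), 1),
    shift5 = as.integer(vapply(parts, `[`, character(1), 2)),
    shift3 = as.integer(vapply(parts, `[`, character(1), 3)),
    mod_suffix = vapply(parts, function(p) if (length(p) >= 4) p[4] else "",
                        character(1)),
    count = as.vector(cnt), stringsAsFactors = FALSE)
  out <- out[order(out$mature, -out$count, out$shift5, out$shift3,
                   out$mod_suffix), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect opposite-arm miRNA candidates
#'
#' Reads clustering on a hairpin arm that carries no annotated mature
#' define a putative opposite-arm product. Per hairpin, the defining span
#' is the most abundant distinct matched span (ties: smaller start, then
#' smaller end); the candidate is reported when the summed read count
#' reaches `opp_min_count`. Its isomiRs are expressed relative to the
#' defining span.
#'
#' @param assignments assignment table from [build_assignments()].
#' @param opp_min_count minimum total read count (default 2).
#' @return list with `table` (data.frame `hairpin`, `start`, `end`,
#'   `total_count`) and `isomirs` (data.frame `hairpin`, `shift5`,
#'   `shift3`, `mod_suffix`, `count` relative to the defining span).
#' @export
detect_opp_mirnas <- function(assignments, opp_min_count = 2) {
  o <- assignments[assignments$type == "opp_arm", , drop = FALSE]
  tab <- data.frame(hairpin = character(0), start = integer(0),
                    end = integer(0), total_count = numeric(0),
                    stringsAsFactors = FALSE)
  iso <- data.frame(hairpin = character(0), shift5 = integer(0),
                    shift3 = integer(0), mod_suffix = character(0),
                    count = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(o)) return(list(table = tab, isomirs = iso))
  for (hp in sort(unique(o$hairpin))) {
    g <- o[o$hairpin == hp, , drop = FALSE]
    total <- sum(g$weight)
    if (total < opp_min_count) next
    span <- rowsum(g$weight, group = paste(g$start, g$end))
    sp <- do.call(rbind, lapply(strsplit(rownames(span), " "), as.integer))
    ord <- order(-as.vector(span), sp[, 1], sp[, 2])
    def <- sp[ord[1], ]
    tab <- rbind(tab, data.frame(hairpin = hp, start = def[1], end = def[2],
                                 total_count = total, stringsAsFactors = FALSE))
    key <- paste(g$start - def[1], g$end - def[2], g$mod_suffix, sep = "\r")
    cnt <- rowsum(g$weight, group = key)
    parts <- strsplit(rownames(cnt), "\r", fixed = TRUE)
    gi <- data.frame(
      hairpin = hp,
      shift5 = as.integer(vapply(parts, `[`, character(1), 1)),
      shift3 = as.integer(vapply(parts, `[`, character(1), 2)),
      mod_suffix = vapply(parts, function(p) if (length(p) >= 3) p[3] else "",
                          character(1)),
      count = as.vector(cnt), stringsAsFactors = FALSE)
    iso <- rbind(iso, gi[order(-gi$count, gi$shift5, gi$shift3, gi$mod_suffix), ])
  }
  rownames(tab) <- rownames(iso) <- NULL
  list(table = tab, isomirs = iso)
}

#' Detection counts against the annotated reference
#'
#' A mature is detected when its raw count (after the fractional
#' multi-mapping split) exceeds `detect_min`; a hairpin is detected when
#' any read (mature, opposite-arm or other) was assigned to it.
#'
#' @param profile result of [build_profile()].
#' @param refs a `ref_set` supplying the annotated totals.
#' @param opp result of [detect_opp_mirnas()].
#' @param assignments assignment table (for hairpin-level detection).
#' @param detect_min raw-count threshold (default 0: any positive count).
#' @return list with detected and annotated counts.
#' @export
detection_summary <- function(profile, refs, opp, assignments,
                              detect_min = 0) {
  tot <- annotated_totals(refs)
  list(detected_matures = sum(profile$raw_count > detect_min),
       detected_hairpins = length(unique(assignments$hairpin[assignments$weight > 0])),
       detected_opp = nrow(opp$table),
       annotated_matures = tot$n_matures,
       annotated_hairpins = tot$n_hairpins)
}

#' Run the mapping stage on qualified tags
#'
#' Classifies tags into read categories, assigns hairpin hits to matures,
#' and derives the expression profile, 3' modification table, isomiR
#' table, opposite-arm candidates and detection counts.
#'
#' @param tags qualified tags (data.frame `seq`, `count`), e.g. from
#'   [run_readpro()] or [read_collapsed_fasta()].
#' @param refs a `ref_set`.
#' @param max_mod,min_match soft-clip parameters (defaults 3 and 15).
#' @param opp_min_count opposite-arm reporting threshold (default 2).
#' @param detect_min detection threshold on raw counts (default 0).
#' @param overlap_frac mature-assignment overlap threshold (default 0.5).
#' @return list of class `readmap_result` with `categories`, `profile`,
#'   `mods`, `isomirs`, `opp`, `detection` and `assignments`.
#' @export
run_readmap <- function(tags, refs, max_mod = 3L, min_match = 15L,
                        opp_min_count = 2, detect_min = 0,
                        overlap_frac = 0.5) {
  stopifnot(inherits(refs, "ref_set"))
  cls <- classify_tags(tags, refs, max_mod, min_match)
  asn <- build_assignments(tags, refs, max_mod, min_match, overlap_frac)
  profile <- build_profile(asn)
  opp <- detect_opp_mirnas(asn, opp_min_count)
  structure(list(categories = cls, profile = profile,
                 mods = mod_pattern_frequencies(asn),
                 isomirs = enumerate_isomirs(asn), opp = opp,
                 detection = detection_summary(profile, refs, opp, asn, detect_min),
                 assignments = asn),
            class = "readmap_result")
}

#' @export
print.readmap_result <- function(x, ...) {
  sh <- x$categories$shares
  cat("<readmap_result>\n  categories:",
      paste(sprintf("%s %.1f%%", names(sh), sh), collapse = ", "), "\n")
  cat(sprintf("  %d matures detected (top-5 share %.2f%%), %d opp-miRNA candidate(s)\n",
              x$detection$detected_matures, top_share(x$profile),
              nrow(x$opp$table)))
  invisible(x)
}
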