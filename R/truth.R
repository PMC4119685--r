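#' Roll ground-truth read records up into truth tables
#'
#' Aggregates the per-read truth of [simulate_library()] into tables
#' mirroring every pipeline output: read-processing summary, clean-read
#' length distribution, qualified-tag category shares, expression counts,
#' isomiR table, 3' modification frequencies, opposite-arm candidates and
#' detection counts. The aggregation is plain tabulation over the truth
#' records and shares no code with the pipeline stages it is used to
#' check; qualification applies the same definitional filters (length
#' window, collapsed insert count, adaptor status).
#'
#' @param truth per-read truth data.frame from [simulate_library()].
#' @param min_len,max_len,min_count qualification filters (defaults 15,
#'   30, 2).
#' @param opp_min_count opposite-arm reporting threshold (default 2).
#' @return list with `readpro`, `length_dist`, `category_shares`,
#'   `expression`, `isomirs`, `mods`, `au_rich_pct`, `opp`, `detection`.
#' @export
truth_summaries <- function(truth, min_len = 15L, max_len = 30L,
                            min_count = 2L, opp_min_count = 2) {
  total <- nrow(truth)
  n_self <- sum(truth$status == "self_ligation")
  n_non <- sum(truth$status == "nonclean")
  clean <- truth[truth$status == "clean", , drop = FALSE]
  pct <- function(x) if (total > 0) 100 * x / total else 0

  ins_cnt <- table(clean$insert)
  len_ok <- nchar(names(ins_cnt)) >= min_len & nchar(names(ins_cnt)) <= max_len
  qual_set <- names(ins_cnt)[len_ok & as.vector(ins_cnt) >= min_count]
  qual <- clean[clean$insert %in% qual_set, , drop = FALSE]

  len_tab <- table(nchar(clean$insert))
  length_dist <- data.frame(length = as.integer(names(len_tab)),
                            count = as.vector(len_tab))
  length_dist$pct <- if (nrow(clean)) 100 * length_dist$count / nrow(clean) else numeric(0)

  cats <- c("miRNA", CATEGORY_ORDER, "unknown")
  cat_counts <- vapply(cats, function(k) sum(qual$category == k), numeric(1))
  category_shares <- if (nrow(qual)) 100 * cat_counts / nrow(qual) else cat_counts

  is_opp <- qual$category == "miRNA" & grepl(":opp$", qual$source)
  ann <- qual[qual$category == "miRNA" & !is_opp, , drop = FALSE]
  expr_tab <- table(ann$source)
  expression <- data.frame(mature = names(expr_tab),
                           count = as.vector(expr_tab),
                           stringsAsFactors = FALSE)
  expression <- expression[order(-expression$count, expression$mature), , drop = FALSE]
  rownames(expression) <- NULL

  iso_key <- paste(ann$source, ann$shift5, ann$shift3, ann$mod_suffix, sep = "\r")
  iso_tab <- table(iso_key)
  parts <- strsplit(names(iso_tab), "\r", fixed = TRUE)
  isomirs <- data.frame(
    mature = vapply(parts, `[`, character(1), 1),
    shift5 = as.integer(vapply(parts, `[`, character(1), 2)),
    shift3 = as.integer(vapply(parts, `[`, character(1), 3)),
    mod_suffix = vapply(parts, function(p) if (length(p) >= 4) p[4] else "",
                        character(1)),
    count = as.vector(iso_tab), stringsAsFactors = FALSE)
  isomirs <- isomirs[order(isomirs$mature, -isomirs$count, isomirs$shift5,
                           isomirs$shift3, isomirs$mod_suffix), , drop = FALSE]
  rownames(isomirs) <- NULL

  mir_all <- qual[qual$category == "miRNA", , drop = FALSE]
  mod_src <- ann   # modification table is defined over mature-assigned reads
  mod_tab <- table(mod_src$mod_suffix)
  mods <- data.frame(pattern = names(mod_tab), count = as.vector(mod_tab),
                     stringsAsFactors = FALSE)
  mods$pct <- if (nrow(mod_src)) 100 * mods$count / nrow(mod_src) else numeric(0)
  mods <- mods[order(-mods$count, mods$pattern), , drop = FALSE]
  rownames(mods) <- NULL
  modded <- mods[mods$pattern != "", , drop = FALSE]
  au_rich_pct <- if (nrow(modded) && sum(modded$count) > 0)
    100 * sum(modded$count[grepl("^[au]+$", modded$pattern)]) / sum(modded$count)
  else NA_real_

  oppq <- qual[is_opp, , drop = FALSE]
  opp_table <- data.frame(hairpin = character(0), start = integer(0),
                          end = integer(0), total_count = numeric(0),
                          stringsAsFactors = FALSE)
  opp_isomirs <- data.frame(hairpin = character(0), shift5 = integer(0),
                            shift3 = integer(0), mod_suffix = character(0),
                            count = numeric(0), stringsAsFactors = FALSE)
  for (hp in sort(unique(oppq$hairpin))) {
    g <- oppq[oppq$hairpin == hp, , drop = FALSE]
    if (nrow(g) < opp_min_count) next
    span_tab <- table(paste(g$start, g$end))
    sp <- do.call(rbind, lapply(strsplit(names(span_tab), " "), as.integer))
    ord <- order(-as.vector(span_tab), sp[, 1], sp[, 2])
    def <- sp[ord[1], ]
    opp_table <- rbind(opp_table,
                       data.frame(hairpin = hp, start = def[1], end = def[2],
                                  total_count = nrow(g), stringsAsFactors = FALSE))
    k <- paste(g$start - def[1], g$end - def[2], g$mod_suffix, sep = "\r")
    kt <- table(k)
    pp <- strsplit(names(kt), "\r", fixed = TRUE)
    gi <- data.frame(
      hairpin = hp,
      shift5 = as.integer(vapply(pp, `[`, character(1), 1)),
      shift3 = as.integer(vapply(pp, `[`, character(1), 2)),
      mod_suffix = vapply(pp, function(p) if (length(p) >= 3) p[3] else "",
                          character(1)),
      count = as.vector(kt), stringsAsFactors = FALSE)
    opp_isomirs <- rbind(opp_isomirs,
                         gi[order(-gi$count, gi$shift5, gi$shift3, gi$mod_suffix), ])
  }
  rownames(opp_table) <- rownames(opp_isomirs) <- NULL

  list(
    readpro = list(total_reads = total,
                   n_self_ligation = n_self, n_nonclean = n_non,
                   n_clean = nrow(clean), n_qualified = nrow(qual),
                   pct_self_ligation = pct(n_self), pct_nonclean = pct(n_non),
                   pct_clean = pct(nrow(clean)), pct_qualified = pct(nrow(qual))),
    length_dist = length_dist,
    category_shares = category_shares,
    expression = expression,
    isomirs = isomirs,
    mods = mods,
    au_rich_pct = au_rich_pct,
    opp = list(table = opp_table, isomirs = opp_isomirs),
    detection = list(detected_matures = nrow(expression),
                     detected_hairpins = length(unique(mir_all$hairpin[
                       mir_all$insert %in% qual_set])),
                     detected_opp = nrow(opp_table)))
}
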