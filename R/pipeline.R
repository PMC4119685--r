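write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pct2 <- function(x) sprintf("%.2f", x)

#' Write the read-processing reports
#'
#' Writes `readpro_summary.tsv` (raw counts plus 2-decimal percentages for
#' the self-ligation / nonclean / clean / qualified partition and the
#' adaptor used), `length_distribution.tsv` and `qualified.fa` (collapsed
#' FASTA, `>t<rank>_x<count>` headers).
#'
#' @param res a `readpro_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_readpro_reports <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- res$summary
  write_tsv(data.frame(
    all = s$total_reads,
    self_ligation = s$n_self_ligation, nonclean = s$n_nonclean,
    clean = s$n_clean, qualified = s$n_qualified,
    self_ligation_pct = pct2(s$pct_self_ligation),
    nonclean_pct = pct2(s$pct_nonclean), clean_pct = pct2(s$pct_clean),
    qualified_pct = pct2(s$pct_qualified), adaptor = s$adaptor),
    file.path(dir, "readpro_summary.tsv"))
  ld <- res$length_dist
  ld$pct <- pct2(ld$pct)
  write_tsv(ld, file.path(dir, "length_distribution.tsv"))
  write_collapsed_fasta(res$qualified, file.path(dir, "qualified.fa"))
  invisible(dir)
}

#' Write the mapping-stage reports
#'
#' Writes `categories.tsv`, `mirna_profile.tsv`, `mod_patterns.tsv` (full
#' table; the empty pattern is written as `.`), `isomirs.txt` (aligned
#' blocks), `opp_mirna.tsv` and `detection_summary.tsv`.
#'
#' @param res a `readmap_result`.
#' @param refs the `ref_set` used for mapping.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_readmap_reports <- function(res, refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- res$categories
  write_tsv(data.frame(category = names(cl$shares),
                       count = fmt_count(unname(cl$counts)),
                       pct = pct2(unname(cl$shares))),
            file.path(dir, "categories.tsv"))
  pr <- res$profile
  write_tsv(data.frame(mature = pr$mature, raw_count = fmt_count(pr$raw_count),
                       tpm = sprintf("%.3f", pr$tpm)),
            file.path(dir, "mirna_profile.tsv"))
  mp <- res$mods$full
  write_tsv(data.frame(pattern = ifelse(mp$pattern == "", ".", mp$pattern),
                       count = fmt_count(mp$count), pct = pct2(mp$pct)),
            file.path(dir, "mod_patterns.tsv"))
  writeLines(render_isomir_report(res$isomirs, refs),
             file.path(dir, "isomirs.txt"), sep = "\n\n")
  ot <- res$opp$table
  write_tsv(data.frame(hairpin = ot$hairpin, start = ot$start, end = ot$end,
                       total_count = fmt_count(ot$total_count)),
            file.path(dir, "opp_mirna.tsv"))
  d <- res$detection
  write_tsv(data.frame(detected_mirna = d$detected_matures,
                       annotated_mirna = d$annotated_matures,
                       detected_pre_mirna = d$detected_hairpins,
                       annotated_pre_mirna = d$annotated_hairpins,
                       detected_opp_mirna = d$detected_opp),
            file.path(dir, "detection_summary.tsv"))
  invisible(dir)
}

#' Run the full pipeline on a FASTQ file
#'
#' Executes the read-processing stage then the mapping stage and writes
#' every report plus a `run_manifest.json` recording the tool version,
#' parameters, input checksum and timestamp. Both stages are also
#' invocable standalone ([run_readpro()] on a FASTQ; [run_readmap()] on a
#' collapsed FASTA) and give identical results.
#'
#' @param fastq input FASTQ path.
#' @param adaptor 3' adaptor sequence.
#' @param refs a `ref_set`, or `index_dir` pointing at a directory written
#'   by [write_reference_set()].
#' @param out_dir output directory.
#' @param index_dir index directory (alternative to `refs`).
#' @param min_len,max_len,min_count,min_overlap,max_mismatch
#'   read-processing parameters (see [run_readpro()], [trim_params()]).
#' @param max_mod,min_match,opp_min_count,detect_min mapping parameters
#'   (see [run_readmap()]).
#' @return invisibly, list with `readpro` and `readmap` results.
#' @export
run_pipeline <- function(fastq, adaptor, refs = NULL, out_dir,
                         index_dir = NULL, min_len = 15L, max_len = 30L,
                         min_count = 2L, min_overlap = 8L, max_mismatch = 0L,
                         max_mod = 3L, min_match = 15L, opp_min_count = 2,
                         detect_min = 0) {
  if (is.null(refs)) {
    if (is.null(index_dir)) stop_io("supply refs or index_dir")
    refs <- read_reference_set(index_dir)
  }
  if (!file.exists(fastq)) stop_io("cannot read FASTQ file: ", fastq)
  params <- trim_params(adaptor, min_overlap, max_mismatch)
  rp <- run_readpro(fastq, params, min_len, max_len, min_count)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_readpro_reports(rp, out_dir)
  rm_res <- run_readmap(rp$qualified, refs, max_mod, min_match,
                        opp_min_count, detect_min)
  write_readmap_reports(rm_res, refs, out_dir)
  manifest <- list(
    tool = "srnaprof",
    version = as.character(utils::packageVersion("srnaprof")),
    inputs = list(fastq = fastq, fastq_md5 = unname(tools::md5sum(fastq))),
    params = list(adaptor = params$adaptor, min_overlap = min_overlap,
                  max_mismatch = max_mismatch, min_len = min_len,
                  max_len = max_len, min_count = min_count, max_mod = max_mod,
                  min_match = min_match, opp_min_count = opp_min_count,
                  detect_min = detect_min),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(readpro = rp, readmap = rm_res))
}
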