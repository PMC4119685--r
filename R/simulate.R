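DEFAULT_ADAPTOR <- "TGGAATTCTCGGGTGCCAAGG"

default_fractions <- function() {
  c(self_ligation = 0.005, nonclean = 0.04, miRNA = 0.75, rRNA = 0.05,
    tRNA = 0.03, mRNA = 0.03, ncRNA = 0.03, unknown = 0.065)
}

default_isomir_model <- function() {
  c("0,0" = 0.70, "1,0" = 0.06, "-1,0" = 0.06, "0,1" = 0.09, "0,-1" = 0.09)
}

default_mod_model <- function() {
  stats::setNames(c(0.55, 0.25, 0.10, 0.04, 0.03, 0.03),
                  c("", "u", "a", "uu", "au", "ua"))
}

adaptor_min_period <- function(ad) {
  n <- nchar(ad)
  for (p in 1:(n - 1L))
    if (substr(ad, 1L + p, n) == substr(ad, 1L, n - p)) return(p)
  n
}

#' Simulation configuration
#'
#' Describes a synthetic single-end small-RNA library: total depth, the 3'
#' adaptor, the read-category mixture, per-mature expression weights, the
#' isomiR (5'/3' shift) model, the 3' tail model, and the seed. Defaults
#' emulate a well-prepared library: miRNA-dominated category mixture with
#' a low self-ligation rate, strongly skewed (Zipf) expression, shifts
#' concentrated on the annotated ends, and u- then a-dominated AU-rich
#' tails.
#'
#' @param n_reads total number of reads.
#' @param adaptor 3' adaptor sequence; must have no period shorter than 8
#'   so that adaptor detection is unambiguous.
#' @param fractions named fractions over \{self_ligation, nonclean, miRNA,
#'   rRNA, tRNA, mRNA, ncRNA, unknown\} summing to 1 (missing names = 0).
#'   Category counts are allocated by largest remainder, so planted
#'   fractions are reproduced exactly at integer resolution.
#' @param expression per-mature weights (named, matching the reference
#'   set), or `NULL` for Zipf (1/rank) weights over the annotated matures.
#' @param isomir_model named probabilities over `"shift5,shift3"` keys;
#'   shifts must lie in -2..2 (the generator guarantees templated
#'   placements in that window).
#' @param mod_model named probabilities over 3' tails written in display
#'   form (`""`, `"u"`, `"a"`, `"uu"`, ...); tails must match `[au]{0,3}`
#'   so that, with the reference generator's C/G flank rule, every planted
#'   tail is non-templated by construction.
#' @param opp_fraction fraction of miRNA-category reads drawn from the
#'   latent opposite-arm products of the reference set (default 0.03).
#' @param read_length pad (with A) / truncate reads to this length;
#'   `NULL` (default) emits insert + adaptor unchanged. Must be at least
#'   the maximal insert length + 8 so the adaptor stays detectable.
#' @param seed RNG seed; (config, seed) determines the library
#'   byte-for-byte.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_reads = 1e5, adaptor = DEFAULT_ADAPTOR,
                       fractions = default_fractions(), expression = NULL,
                       isomir_model = default_isomir_model(),
                       mod_model = default_mod_model(),
                       opp_fraction = 0.03, read_length = NULL, seed = 1L) {
  adaptor <- normalize_seq(adaptor)
  if (adaptor_min_period(adaptor) < 8L)
    stop_io("adaptor has period < 8; self-ligation detection would be ambiguous")
  all_frac <- default_fractions() * 0
  if (is.null(names(fractions)) || !all(names(fractions) %in% names(all_frac)))
    stop_io("fractions must be named with a subset of: ",
            paste(names(all_frac), collapse = ", "))
  all_frac[names(fractions)] <- fractions
  if (abs(sum(all_frac) - 1) > 1e-9) stop_io("fractions must sum to 1")
  if (any(all_frac < 0)) stop_io("fractions must be >= 0")
  shifts <- strsplit(names(isomir_model), ",", fixed = TRUE)
  if (any(vapply(shifts, length, integer(1)) != 2L) ||
      any(abs(as.integer(unlist(shifts))) > 2L))
    stop_io("isomir_model keys must be 'shift5,shift3' with shifts in -2..2")
  if (abs(sum(isomir_model) - 1) > 1e-9) stop_io("isomir_model must sum to 1")
  if (!all(grepl("^[au]{0,3}$", names(mod_model))))
    stop_io("mod_model tails must match [au]{0,3}")
  if (abs(sum(mod_model) - 1) > 1e-9) stop_io("mod_model must sum to 1")
  if (any(isomir_model < 0) || any(mod_model < 0))
    stop_io("probabilities must be >= 0")
  if (!is.null(read_length)) read_length <- as.integer(read_length)
  structure(list(n_reads = as.integer(n_reads), adaptor = adaptor,
                 fractions = all_frac, expression = expression,
                 isomir_model = isomir_model, mod_model = mod_model,
                 opp_fraction = opp_fraction, read_length = read_length,
                 seed = as.integer(seed)),
            class = "sim_config")
}

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

all_kmers <- function(seqs, k = 15L) {
  seqs <- seqs[nchar(seqs) >= k]
  unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
}

# largest-remainder allocation of n into integer counts proportional to p
allocate_counts <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(-(raw - base), seq_along(p))[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

#' Generate a toy reference set with planted ground truth
#'
#' Builds random hairpin precursors with planted 20-23 nt mature regions
#' (every hairpin carries a 5p mature starting at position 8; a fraction
#' additionally carries a 3p mature ending 4 nt from the 3' end) plus small
#' random rRNA/tRNA/mRNA/ncRNA decoys. Hairpins without a 3p mature carry a
#' latent opposite-arm product span (returned in `$opp_truth`, not
#' annotated) from which the simulator can draw opposite-arm reads. Two
#' construction rules make downstream recovery exact rather than merely
#' likely: every 15-mer across the whole reference set is unique (so any
#' templated core of >= 15 nt places uniquely), and the two bases ending
#' each planted product plus its three 3'-flank bases are C/G (so a/u
#' tails are non-templated at every shifted 3' end in -2..2). No reference
#' contains the first 8 bases of the adaptor. Generation retries until the
#' constraints hold.
#'
#' @param seed RNG seed; the result is byte-identical across runs.
#' @param n_hairpins number of hairpins (>= 1).
#' @param hairpin_len hairpin length in nt (>= 70).
#' @param n_decoys decoy sequences per category.
#' @param decoy_len decoy length in nt.
#' @param adaptor adaptor whose 8 nt prefix is excluded from references.
#' @param species species code used in the toy identifiers.
#' @param both_arm_frac fraction of hairpins with an annotated 3p mature.
#' @param categories decoy categories to generate.
#' @param max_tries generation attempts before giving up.
#' @return a `ref_set` with an extra `opp_truth` element.
#' @export
make_toy_references <- function(seed = 1L, n_hairpins = 30L, hairpin_len = 80L,
                                n_decoys = 5L, decoy_len = 200L,
                                adaptor = DEFAULT_ADAPTOR, species = "toy",
                                both_arm_frac = 0.4,
                                categories = c("rRNA", "tRNA", "mRNA", "ncRNA"),
                                max_tries = 50L) {
  stopifnot(n_hairpins >= 1L, hairpin_len >= 70L)
  adaptor <- normalize_seq(adaptor)
  ad8 <- substr(adaptor, 1L, 8L)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      hp <- rand_dna(n_hairpins, hairpin_len)
      n_both <- round(both_arm_frac * n_hairpins)
      ann <- list(); opp <- list()
      force_cg <- function(s, pos) {
        pos <- pos[pos >= 1 & pos <= nchar(s)]
        for (p in pos) substr(s, p, p) <- sample(c("C", "G"), 1)
        s
      }
      plant <- function(s, start, end) force_cg(s, (end - 1L):(end + 3L))
      m5_len <- sample(20:23, n_hairpins, replace = TRUE)
      m3_len <- sample(20:23, n_hairpins, replace = TRUE)
      for (i in seq_len(n_hairpins)) {
        e5 <- 8L + m5_len[i] - 1L
        hp[i] <- plant(hp[i], 8L, e5)
        ann[[i]] <- data.frame(hairpin = i, arm = "5p", start = 8L, end = e5)
        e3 <- hairpin_len - 4L
        s3 <- e3 - m3_len[i] + 1L
        hp[i] <- plant(hp[i], s3, e3)
        if (i <= n_both) {
          ann[[i]] <- rbind(ann[[i]],
                            data.frame(hairpin = i, arm = "3p", start = s3, end = e3))
        } else {
          opp[[length(opp) + 1L]] <- data.frame(hairpin = i, start = s3, end = e3)
        }
      }
      decoys <- stats::setNames(
        lapply(categories, function(k) {
          d <- rand_dna(n_decoys, decoy_len)
          stats::setNames(d, sprintf("%s_%s_%d", species, k, seq_len(n_decoys)))
        }), categories)
      refseqs <- c(hp, unlist(unname(decoys)))
      if (anyDuplicated(all_kmers(refseqs, 15L))) next
      if (any(grepl(ad8, refseqs, fixed = TRUE))) next
      ann <- do.call(rbind, ann)
      hp_names <- sprintf("%s-mir-%d", species, seq_len(n_hairpins))
      mat_names <- sprintf("%s-miR-%d-%s", species, ann$hairpin, ann$arm)
      mat_seqs <- stats::setNames(
        substr(hp[ann$hairpin], ann$start, ann$end), mat_names)
      refs <- new_ref_set(
        hairpins = data.frame(name = hp_names, seq = hp, stringsAsFactors = FALSE),
        mature_seqs = mat_seqs,
        categories = decoys, species = species)
      opp <- if (length(opp)) do.call(rbind, opp) else
        data.frame(hairpin = integer(0), start = integer(0), end = integer(0))
      if (nrow(opp)) opp$hairpin <- hp_names[opp$hairpin]
      refs$opp_truth <- opp
      return(refs)
    }
    stop_io("could not satisfy reference uniqueness constraints after ",
            max_tries, " attempts")
  })
}

# distinct random pool avoiding adaptor prefix and (optionally) any 15-mer
# present in the reference set
sample_pool <- function(n_pool, len_range, ad8, kmer_set = NULL,
                        max_tries = 10000L) {
  pool <- character(0)
  tries <- 0L
  while (length(pool) < n_pool && tries < max_tries) {
    tries <- tries + 1L
    s <- rand_dna(1L, sample(len_range, 1L))
    if (grepl(ad8, s, fixed = TRUE)) next
    if (!is.null(kmer_set) && nchar(s) >= 15L &&
        any(all_kmers(s, 15L) %in% kmer_set)) next
    if (s %in% pool) next
    pool <- c(pool, s)
  }
  if (length(pool) < n_pool) stop_io("rejection sampling exhausted")
  pool
}

#' Simulate a small-RNA library with full per-read ground truth
#'
#' Every read is insert + adaptor (self-ligation reads are the bare
#' adaptor at position 0; nonclean reads carry no adaptor), optionally
#' padded/truncated to `read_length`. miRNA-category inserts are templated
#' hairpin substrings spanning a planted product shifted by the isomiR
#' model, plus a non-templated a/u tail from the tail model; contaminant
#' inserts are drawn from a per-category pool of decoy substrings; unknown
#' inserts are rejection-sampled against every reference so their label is
#' correct by construction. Category counts follow the configured
#' fractions exactly (largest-remainder allocation); read order is a
#' seeded permutation. The returned ground truth records, per read, the
#' category, source, placement, shifts and tail, and is the basis for the
#' bookkept truth tables of [truth_summaries()].
#'
#' @param config a [sim_config()].
#' @param refs a `ref_set` from [make_toy_references()] (any `ref_set`
#'   works when `opp_fraction = 0` and expression names match).
#' @param fastq output FASTQ path.
#' @param contam_pool,unknown_pool,nonclean_pool distinct-sequence pool
#'   sizes for contaminant / unknown / nonclean reads (pools are what make
#'   collapsed counts >= 2 attainable at realistic depths).
#' @return list with `fastq`, `truth` (one row per read) and `config`.
#' @export
simulate_library <- function(config, refs, fastq,
                             contam_pool = 60L, unknown_pool = 40L,
                             nonclean_pool = 20L) {
  stopifnot(inherits(config, "sim_config"), inherits(refs, "ref_set"))
  ad <- config$adaptor
  ad8 <- substr(ad, 1L, min(8L, nchar(ad)))
  with_seed(config$seed, {
    counts <- allocate_counts(config$n_reads, config$fractions)
    mat <- refs$matures[!duplicated(refs$matures$name), , drop = FALSE]
    if (counts[["miRNA"]] > 0L && !nrow(mat))
      stop_io("miRNA fraction > 0 requires a reference set with matures")
    expr <- config$expression
    if (is.null(expr) && nrow(mat))
      expr <- stats::setNames(1 / seq_len(nrow(mat)), mat$name)
    rows <- list()
    add <- function(df) rows[[length(rows) + 1L]] <<- df
    blank <- function(n, category, status, insert, source = NA_character_,
                      hairpin = NA_character_, start = NA_integer_,
                      end = NA_integer_, shift5 = NA_integer_,
                      shift3 = NA_integer_, mod_suffix = NA_character_) {
      if (n == 0L) return(invisible(NULL))
      add(data.frame(category = category, status = status, insert = insert,
                     source = source, hairpin = hairpin, start = start,
                     end = end, shift5 = shift5, shift3 = shift3,
                     mod_suffix = mod_suffix, stringsAsFactors = FALSE))
    }
    ## self-ligation and nonclean
    blank(counts[["self_ligation"]], "self_ligation", "self_ligation",
          rep("", counts[["self_ligation"]]))
    if (counts[["nonclean"]] > 0L) {
      pool <- sample_pool(min(nonclean_pool, counts[["nonclean"]]), 20:40, ad8)
      blank(counts[["nonclean"]], "nonclean", "nonclean",
            sample(pool, counts[["nonclean"]], replace = TRUE))
    }
    ## miRNA-category reads: annotated matures + latent opposite-arm products
    n_mir <- counts[["miRNA"]]
    if (n_mir > 0L) {
      has_opp <- !is.null(refs$opp_truth) && nrow(refs$opp_truth) > 0L
      n_opp <- if (has_opp) round(config$opp_fraction * n_mir) else 0L
      n_ann <- n_mir - n_opp
      hp_seq <- stats::setNames(refs$hairpins$seq, refs$hairpins$name)
      draw_products <- function(n, src_name, src_hairpin, src_start, src_end,
                                weights) {
        if (n == 0L) return(invisible(NULL))
        pick <- sample(length(src_name), n, replace = TRUE, prob = weights)
        sk <- sample(names(config$isomir_model), n, replace = TRUE,
                     prob = config$isomir_model)
        sp <- do.call(rbind, strsplit(sk, ",", fixed = TRUE))
        s5 <- as.integer(sp[, 1]); s3 <- as.integer(sp[, 2])
        tail <- sample(names(config$mod_model), n, replace = TRUE,
                       prob = config$mod_model)
        start <- src_start[pick] + s5
        end <- src_end[pick] + s3
        core <- substr(hp_seq[src_hairpin[pick]], start, end)
        add(data.frame(category = "miRNA", status = "clean",
                       insert = paste0(core, mod_to_dna(tail)),
                       source = src_name[pick], hairpin = src_hairpin[pick],
                       start = start, end = end, shift5 = s5, shift3 = s3,
                       mod_suffix = tail, stringsAsFactors = FALSE))
      }
      draw_products(n_ann, mat$name, mat$hairpin, mat$start, mat$end,
                    unname(expr[mat$name]))
      if (n_opp > 0L) {
        ot <- refs$opp_truth
        draw_products(n_opp, paste0(ot$hairpin, ":opp"), ot$hairpin,
                      ot$start, ot$end, rep(1, nrow(ot)))
      }
    }
    ## contaminant categories from decoy substrings
    cat_seqs <- unlist(lapply(refs$categories, unname), use.names = FALSE)
    genome_rc <- if ("genome" %in% names(refs$categories))
      revcomp(unname(refs$categories$genome)) else character(0)
    ref_kmers <- all_kmers(c(refs$hairpins$seq, cat_seqs, genome_rc), 15L)
    for (k in names(refs$categories)) {
      n_k <- counts[[k]]
      if (n_k == 0L) next
      dec <- refs$categories[[k]]
      pool_n <- min(contam_pool, n_k)
      src <- sample(length(dec), pool_n, replace = TRUE)
      len <- sample(15:30, pool_n, replace = TRUE)
      maxs <- nchar(dec[src]) - len + 1L
      st <- vapply(maxs, function(m) sample.int(m, 1L), integer(1))
      pool <- substr(dec[src], st, st + len - 1L)
      keep <- !duplicated(pool) & !grepl(ad8, pool, fixed = TRUE)
      pool <- pool[keep]; psrc <- names(dec)[src][keep]
      if (!length(pool)) stop_io("contaminant pool construction failed for ", k)
      pick <- sample(length(pool), n_k, replace = TRUE)
      blank(n_k, k, "clean", pool[pick], source = psrc[pick])
    }
    ## unknown reads: rejection-sampled against all references
    if (counts[["unknown"]] > 0L) {
      pool <- sample_pool(min(unknown_pool, counts[["unknown"]]), 15:30, ad8,
                          kmer_set = unique(ref_kmers))
      blank(counts[["unknown"]], "unknown", "clean",
            sample(pool, counts[["unknown"]], replace = TRUE))
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(category = character(0), status = character(0),
                 insert = character(0), source = character(0),
                 hairpin = character(0), start = integer(0), end = integer(0),
                 shift5 = integer(0), shift3 = integer(0),
                 mod_suffix = character(0), stringsAsFactors = FALSE)
    if (nrow(truth)) {
      truth <- truth[sample.int(nrow(truth)), , drop = FALSE]
      rownames(truth) <- NULL
    }
    reads <- ifelse(truth$status == "nonclean", truth$insert,
                    paste0(truth$insert, ad))
    if (!is.null(config$read_length)) {
      rl <- config$read_length
      if (nrow(truth) && rl < max(nchar(truth$insert)) + 8L)
        stop_io("read_length must be >= max insert length + 8")
      reads <- substr(paste0(reads, strrep("A", rl)), 1L, rl)
    }
    truth$read_id <- if (nrow(truth)) sprintf("r%d", seq_len(nrow(truth))) else character(0)
    con <- file(fastq, "w")
    on.exit(close(con))
    if (length(reads))
      writeLines(paste0("@", truth$read_id, "\n", reads, "\n+\n",
                        strrep("I", nchar(reads))), con)
    list(fastq = fastq, truth = truth, config = config)
  })
}
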