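# a minimal hand-built hairpin world: one hairpin with a 5p mature at 8..29
# (optionally a 3p mature at 45..66); positions 30..32 are forced to C so
# that a/u tails are non-templated; all 15-mers unique by construction
make_tiny_world <- function(seed = 31, three_p = FALSE) {
  set.seed(seed)
  repeat {
    hp <- r_dna(70)
    substr(hp, 30, 32) <- "CCC"
    if (!anyDuplicated(substring(hp, 1:56, 15:70))) break
  }
  mature <- substr(hp, 8, 29)
  anns <- c("toy-miR-9-5p" = mature)
  if (three_p) anns <- c(anns, "toy-miR-9-3p" = substr(hp, 45, 66))
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_fa(c("toy-mir-9" = hp), file.path(dir, "h.fa"))
  write_fa(anns, file.path(dir, "m.fa"))
  load_reference_set(file.path(dir, "h.fa"), file.path(dir, "m.fa"),
                     species = "toy", quiet = TRUE)
}
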