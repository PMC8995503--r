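unscreened <- function(L, at = 1L) {
  design_constraints(stem_length_max = L, at_pairs_required = at,
                     forbidden_motifs = character(0),
                     self_comp_window = NULL)
}

test_that("enumeration matches forced cases and the analytic count", {
  expect_identical(enumerate_stems(unscreened(1))$bases, c("A", "T"))
  expect_identical(nrow(enumerate_stems(unscreened(2))), 8L)
  expect_identical(nrow(enumerate_stems(unscreened(3))), 24L)
  for (L in 1:6) {
    expect_identical(nrow(enumerate_stems(unscreened(L))),
                     as.integer(L * 2 * 2^(L - 1)))
  }
  expect_error(design_constraints(stem_length_max = 2,
                                  at_pairs_required = 3),
               "at_pairs_required")
})

test_that("enumeration with screening equals a brute-force enumerator", {
  motifs <- c("ACCGGT", "GAATTC")
  for (L in 4:6) {
    cons <- design_constraints(stem_length_max = L, at_pairs_required = 1,
                               forbidden_motifs = motifs,
                               self_comp_window = 4)
    expect_identical(enumerate_stems(cons)$bases,
                     brute_enumerate_stems(L, 1L, motifs, window = 4L))
  }
  # motif screening applies on both strands
  consA <- design_constraints(stem_length_max = 6, at_pairs_required = 1,
                              forbidden_motifs = "GGGGGA",
                              self_comp_window = NULL)
  got <- enumerate_stems(consA)$bases
  expect_false(any(grepl("GGGGGA", got)))
  expect_false(any(grepl("TCCCCC", got)))
})

test_that("self-complementarity agrees with brute force on random 11-mers", {
  expect_false(is_self_complementary("GGGG", 4))
  expect_true(is_self_complementary("GGGGAAACCCC", 4))
  expect_error(is_self_complementary("GGGG", 1), "window")
  set.seed(13)
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), 11, replace = TRUE),
               collapse = "")
    expect_identical(is_self_complementary(s, 4), brute_self_comp(s, 4L),
                     info = s)
  }
})

test_that("trimming deletes the loop-adjacent base down to the floor", {
  v <- derive_trimmed_variants("GCGCGCGCGCT", floor = 10)
  expect_identical(v$bases, "GCGCGCGCGC")
  expect_identical(v$parent_id, "GCGCGCGCGCT")
  expect_identical(v$trim_depth, 1L)
  v10 <- derive_trimmed_variants("GCGCGCGCGCT", floor = 1)
  expect_identical(nrow(v10), 10L)
  expect_identical(v10$length, 10:1)
  # re-extending any variant by its deleted suffix reproduces the parent
  parent <- "GATCCGCGGCG"
  for (r in seq_len(nrow(vv <- derive_trimmed_variants(parent, 1)))) {
    expect_identical(paste0(vv$bases[r],
                            substr(parent, vv$length[r] + 1L, 11L)),
                     parent)
  }
})

test_that("dedup removes duplicates and all-G/C stems, keeping first
          provenance", {
  out <- dedup_and_filter(kdrdesign:::.stem_frame(c("GC", "GC", "GT")))
  expect_identical(out$bases, "GT")
  out2 <- dedup_and_filter(kdrdesign:::.stem_frame(c("AG", "AG")))
  expect_identical(out2$bases, "AG")
  # two parents sharing a trimmed descendant keep it once, with the
  # lexicographically first parent
  a <- derive_trimmed_variants("GGAC", 2)
  b <- derive_trimmed_variants("GGAG", 2)
  pool <- dedup_and_filter(rbind(a, b))
  shared <- pool[pool$bases == "GGA", ]
  expect_identical(nrow(shared), 1L)
  expect_identical(shared$parent_id, "GGAC")
})

test_that("assembly satisfies the structural invariants and length classes", {
  # 5-9 bp variable stems give the 30/32/34/36/38 nt length classes
  for (L in 5:9) {
    stem <- paste0(strrep("G", L - 1), "T")
    hp <- assemble_hairpin(stem)
    expect_identical(hp$total_length, 2L * (7L + L) + 6L)
    expect_identical(hp$insert_sequence,
                     paste0("GCGGCCG", stem, "TATACT", revcomp(stem),
                            "CGGCCGC"))
    # intended pairing covers arm+stem, loop unpaired
    expect_identical(nrow(hp$pairing$pairs), 7L + L)
    expect_identical(hp$pairing$loop_span,
                     c(7L + L, hp$total_length - 7L - L - 1L))
  }
  empty <- assemble_hairpin("")
  expect_identical(empty$total_length, 20L)
  expect_identical(empty$insert_sequence, "GCGGCCGTATACTCGGCCGC")
  expect_error(assemble_hairpin("GCXG"), "ACGT")
})

test_that("build_library runs the whole pipeline deterministically at tiny
          scale", {
  cons <- unscreened(2)
  lib <- build_library(cons)
  # brute-force expectation: 8 full stems + their 1-nt trims, dedup,
  # all-G/C removed
  full <- brute_enumerate_stems(2, 1L)
  pool <- unique(c(full, substr(full, 1, 1)))
  pool <- pool[nchar(gsub("[GC]", "", pool)) > 0]
  expect_identical(sort(lib$stem), sort(pool))
  expect_true(all(diff(lib$delta_g_kcal_mol) >= 0))
  expect_identical(lib$id, paste0("HP", formatC(seq_len(nrow(lib)),
                                                width = 2, flag = "0")))
  # scored values agree with the scalar evaluator
  for (r in seq_len(nrow(lib))) {
    expect_equal(lib$delta_g_kcal_mol[r],
                 hairpin_dG(assemble_hairpin(lib$stem[r])))
  }
  # free-energy window filter
  empty <- build_library(design_constraints(stem_length_max = 2,
                                            forbidden_motifs = character(0),
                                            self_comp_window = NULL,
                                            dg_window = c(-1, 0)))
  expect_identical(nrow(empty), 0L)
})

test_that("every emitted stem passes the independent constraint validator
          and parent chains resolve", {
  cons <- design_constraints(stem_length_max = 6)
  full <- enumerate_stems(cons)
  expect_true(all(check_stem_constraints(full, cons)$ok))
  lib <- build_library(cons)
  chk <- check_stem_constraints(
    data.frame(bases = lib$stem, stringsAsFactors = FALSE), cons,
    full_length = FALSE)
  expect_true(all(chk$ok))
  trimmed <- lib[lib$trim_depth > 0L, ]
  expect_true(all(trimmed$parent_id %in% full$bases))
  expect_true(all(nchar(trimmed$parent_id) - nchar(trimmed$stem) ==
                    trimmed$trim_depth))
})

test_that("library and constraints round-trip through their file formats", {
  lib <- build_library(unscreened(2))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_library(lib, tsv, fasta = fa)
  back <- read_library(tsv)
  expect_equal(as.data.frame(back), as.data.frame(lib))
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_identical(names(seqs), lib$id)
  expect_identical(as.character(seqs[[1]]), lib$insert_sequence[1])

  cfg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("stem_length_max\t5", "at_pairs_required\t1",
               "self_comp_window\t4", "forbidden_motifs\tACCGGT,GAATTC",
               "trim_floor\t2", "dg_window\t-40,-16"), cfg)
  cons <- read_design_constraints(cfg)
  expect_identical(cons$stem_length_max, 5L)
  expect_identical(cons$forbidden_motifs, c("ACCGGT", "GAATTC"))
  expect_identical(cons$trim_floor, 2L)
  expect_equal(cons$dg_window, c(-40, -16))
})
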