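#' Constant parts of every attenuator insert
#'
#' The outer stem foundation is 7 of the 8 NotI recognition bases
#' (`GCGGCCG`), a highly stable G/C-rich arm that also facilitates cloning;
#' the unpaired loop is the fixed non-complementary hexamer `TATACT`.
#'
#' @name hairpin-constants
#' @export
KDR_BASE_ARM <- "GCGGCCG"

#' @rdname hairpin-constants
#' @export
KDR_LOOP <- "TATACT"

#' Assemble a full attenuator hairpin insert from a variable stem
#'
#' The insert is `base_arm + stem + loop + revcomp(stem) + revcomp(base_arm)`
#' and its intended pairing joins every base-arm and stem position with its
#' mirror partner, leaving the loop unpaired.  Total length is
#' `2 * (7 + stem length) + 6`.
#'
#' @param stem variable stem (5' arm only) as a DNA string, possibly empty,
#'   or a one-row stem data.frame.
#' @param id optional stable identifier.
#' @return a `hairpin_structure` with fields `insert_sequence`, `base_arm`,
#'   `loop`, `stem` (bases/length/at_count/parent_id/trim_depth), `pairing`,
#'   `total_length`, `delta_g` (NA until scored), `id`.
#' @examples
#' assemble_hairpin("GCGCGT")$total_length  # 32
#' @export
assemble_hairpin <- function(stem, id = NA_character_) {
  meta <- NULL
  if (is.data.frame(stem)) {
    stopifnot(nrow(stem) == 1L)
    meta <- stem
    stem <- stem$bases
  }
  if (nchar(stem) > 0L) assert_dna(stem, "stem")
  insert <- paste0(KDR_BASE_ARM, stem, KDR_LOOP,
                   revcomp(stem), revcomp(KDR_BASE_ARM))
  n <- nchar(insert)
  n_pairs <- 7L + nchar(stem)
  hp <- stemloop(insert, n_pairs)
  hp$base_arm <- KDR_BASE_ARM
  hp$loop <- KDR_LOOP
  hp$stem <- if (is.null(meta)) .stem_frame(stem) else meta
  hp$id <- id
  stopifnot(hp$total_length == 2L * (7L + nchar(stem)) + 6L)
  hp
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat("<hairpin_structure>", if (!is.na(x$id)) x$id else "",
      "\n  insert: ", x$insert_sequence,
      "\n  length: ", x$total_length, " nt, ",
      nrow(x$pairing$pairs), " stem pairs",
      if (!is.na(x$delta_g)) paste0(", dG = ", round(x$delta_g, 2),
                                    " kcal/mol"), "\n", sep = "")
  invisible(x)
}

# vectorised hairpin free energy for design-pipeline stems (fixed base arm
# and loop); agrees exactly with hairpin_dG(assemble_hairpin(stem), model)
.hairpin_dg_stems <- function(stems, model) {
  kind <- model$nucleic_acid_kind
  helix <- .to_alphabet(paste0(KDR_BASE_ARM, stems), kind)
  loop5 <- .to_alphabet(substr(KDR_LOOP, 1, 1), kind)
  loop3 <- .to_alphabet(substr(KDR_LOOP, nchar(KDR_LOOP), nchar(KDR_LOOP)),
                        kind)
  vapply(helix, function(h) {
    b5 <- .chars(h)
    b3 <- .comp_chars(b5, kind)
    m <- length(b5)
    codes <- paste0(b5[-m], b5[-1], b3[-1], b3[-m])
    dg <- sum(model$stack_table[codes]) +
      model$hairpin_loop_init[[as.character(nchar(KDR_LOOP))]]
    if (model$use_terminal_mismatch) {
      key <- paste0(b5[m], b3[m], loop5, loop3)
      dg <- dg + model$terminal_mismatch_table[[key]]
    }
    dg
  }, numeric(1), USE.NAMES = FALSE)
}

#' Build the scored attenuator library
#'
#' Runs the full design pipeline: enumerate full-length stems under the
#' constraints, derive trimmed variants down to the trim floor, remove
#' duplicates and all-G/C stems, assemble each survivor into a hairpin
#' insert and score it with [hairpin_dG()]; optionally filter to a
#' free-energy window; sort by free energy ascending (most stable first)
#' and assign identifiers `HP<rank>`.
#'
#' @param constraints a `design_constraints`.
#' @param model an `energy_model` (default: packaged RNA set).
#' @return a `kdr_library` data.frame with columns `id`, `stem`,
#'   `insert_sequence`, `stem_len`, `total_len`, `at_count`,
#'   `delta_g_kcal_mol`, `parent_id`, `trim_depth`.
#' @export
build_library <- function(constraints = design_constraints(),
                          model = load_energy_model("RNA")) {
  full <- enumerate_stems(constraints)
  trims <- list(full)
  if (nrow(full) && constraints$trim_floor < constraints$stem_length_max) {
    L <- constraints$stem_length_max
    for (len in (L - 1L):constraints$trim_floor) {
      trims[[length(trims) + 1L]] <-
        .stem_frame(substr(full$bases, 1L, len),
                    parent_id = full$bases, trim_depth = L - len)
    }
  }
  pool <- do.call(rbind, trims)
  pool <- dedup_and_filter(pool, constraints)
  empty_library <- function() {
    structure(data.frame(id = character(0), stem = character(0),
                         insert_sequence = character(0),
                         stem_len = integer(0), total_len = integer(0),
                         at_count = integer(0),
                         delta_g_kcal_mol = numeric(0),
                         parent_id = character(0),
                         trim_depth = integer(0)),
              class = c("kdr_library", "data.frame"))
  }
  if (!nrow(pool)) return(empty_library())
  dg <- .hairpin_dg_stems(pool$bases, model)
  if (!is.null(constraints$dg_window)) {
    keep <- dg >= constraints$dg_window[1] & dg <= constraints$dg_window[2]
    pool <- pool[keep, , drop = FALSE]
    dg <- dg[keep]
  }
  if (!nrow(pool)) return(empty_library())
  o <- order(dg, pool$bases)
  pool <- pool[o, , drop = FALSE]
  dg <- dg[o]
  n <- nrow(pool)
  lib <- data.frame(
    id = paste0("HP", formatC(seq_len(n), width = max(2L, nchar(n)),
                              flag = "0")),
    stem = pool$bases,
    insert_sequence = paste0(KDR_BASE_ARM, pool$bases, KDR_LOOP,
                             revcomp(pool$bases), revcomp(KDR_BASE_ARM)),
    stem_len = pool$length,
    total_len = 2L * (7L + pool$length) + 6L,
    at_count = pool$at_count,
    delta_g_kcal_mol = dg,
    parent_id = pool$parent_id,
    trim_depth = pool$trim_depth,
    stringsAsFactors = FALSE)
  rownames(lib) <- NULL
  structure(lib, class = c("kdr_library", "data.frame"))
}

#' @export
print.kdr_library <- function(x, ...) {
  cat("<kdr_library> ", nrow(x), " scored hairpin inserts, dG ",
      if (nrow(x)) paste0("[", round(min(x$delta_g_kcal_mol), 1), ", ",
                          round(max(x$delta_g_kcal_mol), 1), "] kcal/mol")
      else "(empty)", "\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Materialise one library member as a hairpin_structure
#'
#' @param library a `kdr_library`.
#' @param id member identifier.
#' @return a scored `hairpin_structure`.
#' @export
as_hairpin <- function(library, id) {
  row <- library[library$id == id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown library id: ", id)
  hp <- assemble_hairpin(row$stem, id = id)
  hp$stem$parent_id <- row$parent_id
  hp$stem$trim_depth <- row$trim_depth
  hp$delta_g <- row$delta_g_kcal_mol
  hp
}

#' Write / read a scored library
#'
#' TSV of the library table, and optionally a FASTA of the insert sequences
#' (identifiers as headers).
#'
#' @param library a `kdr_library`.
#' @param tsv output TSV path.
#' @param fasta optional FASTA path.
#' @return `tsv`, invisibly.
#' @export
write_library <- function(library, tsv, fasta = NULL) {
  utils::write.table(as.data.frame(library), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fasta)) {
    seqs <- Biostrings::DNAStringSet(library$insert_sequence)
    names(seqs) <- library$id
    Biostrings::writeXStringSet(seqs, fasta)
  }
  invisible(tsv)
}

#' @rdname write_library
#' @export
read_library <- function(tsv) {
  lib <- utils::read.delim(tsv, stringsAsFactors = FALSE,
                           colClasses = c(id = "character",
                                          parent_id = "character"))
  structure(lib, class = c("kdr_library", "data.frame"))
}

#' Non-binding diagnostics against the original pKDR library construction
#'
#' The original attenuator library reported 1,360 full-length stems, 5,729
#' structures after trimming/filtering, and a free-energy span of -15.7 to
#' -48.2 kcal/mol; the exact generator settings behind those counts are not
#' reproducible from their description alone, so this function only reports
#' the distance of this pipeline's numbers from them.  Nothing is asserted.
#'
#' @param library a `kdr_library` built with trimming enabled.
#' @param n_full_length number of full-length (trim_depth 0) stems that
#'   entered the pipeline; taken from the library if omitted.
#' @return a data.frame of quantity / this_pipeline / reference / difference.
#' @export
library_diagnostics <- function(library, n_full_length = NULL) {
  if (is.null(n_full_length)) {
    n_full_length <- sum(library$trim_depth == 0L)
  }
  ref <- c(full_length_stems = 1360, post_trim_structures = 5729,
           dg_min_kcal_mol = -48.2, dg_max_kcal_mol = -15.7)
  ours <- c(n_full_length, nrow(library),
            if (nrow(library)) min(library$delta_g_kcal_mol) else NA,
            if (nrow(library)) max(library$delta_g_kcal_mol) else NA)
  data.frame(quantity = names(ref), this_pipeline = unname(ours),
             reference = unname(ref), difference = unname(ours - ref),
             stringsAsFactors = FALSE)
}
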