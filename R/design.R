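#' Default forbidden motifs: the cloning sites the constructs rely on
#'
#' The KDR cloning geometry uses AgeI/NotI (attenuator insertion), NotI/SbfI
#' (rescue gene) and EcoRI/XhoI (shRNA into the miRE cassette); stems must
#' not recreate any of these sites.
#'
#' @return named character vector of recognition sequences.
#' @export
kdr_default_forbidden_motifs <- function() {
  c(AgeI = "ACCGGT", NotI = "GCGGCCGC", SbfI = "CCTGCAGG",
    EcoRI = "GAATTC", XhoI = "CTCGAG")
}

#' Stem design constraints
#'
#' Bundles the constraints under which variable stem sequences are
#' enumerated: maximum stem length, required number of A/T bases (one by
#' default, to keep G/C content maximal and uniform), the
#' self-complementarity screening window, forbidden motifs (checked on both
#' strands), the trimming floor, and an optional free-energy window applied
#' after scoring.
#'
#' @param stem_length_max full stem length enumerated, nt (default 11).
#' @param at_pairs_required exact number of A/T bases per stem (default 1).
#' @param self_comp_window minimum self-complementary stretch flagged, nt
#'   (default 4); `NULL` disables the screen.
#' @param forbidden_motifs character vector of motifs that must not occur on
#'   either strand; empty vector disables the screen.
#' @param trim_floor shortest trimmed stem retained (default 1).
#' @param dg_window optional numeric `c(lo, hi)` free-energy filter,
#'   kcal/mol.
#' @return an object of class `design_constraints`.
#' @export
design_constraints <- function(stem_length_max = 11L,
                               at_pairs_required = 1L,
                               self_comp_window = 4L,
                               forbidden_motifs = kdr_default_forbidden_motifs(),
                               trim_floor = 1L,
                               dg_window = NULL) {
  stem_length_max <- as.integer(stem_length_max)
  at_pairs_required <- as.integer(at_pairs_required)
  trim_floor <- as.integer(trim_floor)
  if (trim_floor < 1L || stem_length_max < trim_floor) {
    stop("need stem_length_max >= trim_floor >= 1")
  }
  if (at_pairs_required > stem_length_max || at_pairs_required < 0L) {
    stop("at_pairs_required must lie in [0, stem_length_max]")
  }
  if (!is.null(self_comp_window) && self_comp_window < 2L) {
    stop("self_comp_window must be >= 2")
  }
  if (length(forbidden_motifs)) assert_dna(forbidden_motifs, "forbidden motif")
  if (!is.null(dg_window) && (length(dg_window) != 2L ||
                              dg_window[1] > dg_window[2])) {
    stop("dg_window must be c(lo, hi) with lo <= hi")
  }
  structure(list(stem_length_max = stem_length_max,
                 at_pairs_required = at_pairs_required,
                 self_comp_window = if (is.null(self_comp_window)) NULL else
                   as.integer(self_comp_window),
                 forbidden_motifs = as.character(forbidden_motifs),
                 trim_floor = trim_floor,
                 dg_window = dg_window),
            class = "design_constraints")
}

#' Read design constraints from a flat key-value config file
#'
#' Lines are `key<TAB>value`; `forbidden_motifs` is a comma-separated list,
#' `dg_window` is `lo,hi`.  Missing keys take the defaults of
#' [design_constraints()].
#'
#' @param path config file path.
#' @return a `design_constraints` object.
#' @export
read_design_constraints <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  kv <- strsplit(ln, "\t")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "\t"), character(1))
  get <- function(k, default) if (k %in% keys) vals[match(k, keys)] else default
  motifs <- get("forbidden_motifs", NULL)
  motifs <- if (is.null(motifs)) kdr_default_forbidden_motifs() else
    if (nzchar(motifs)) trimws(strsplit(motifs, ",")[[1]]) else character(0)
  dgw <- get("dg_window", NULL)
  dgw <- if (is.null(dgw) || !nzchar(dgw)) NULL else
    as.numeric(trimws(strsplit(dgw, ",")[[1]]))
  scw <- get("self_comp_window", "4")
  design_constraints(
    stem_length_max = as.integer(get("stem_length_max", "11")),
    at_pairs_required = as.integer(get("at_pairs_required", "1")),
    self_comp_window = if (toupper(scw) %in% c("NONE", "NA", "")) NULL else
      as.integer(scw),
    forbidden_motifs = motifs,
    trim_floor = as.integer(get("trim_floor", "1")),
    dg_window = dgw)
}

# stems live in a plain data.frame: bases, length, at_count, parent_id,
# trim_depth
.stem_frame <- function(bases, parent_id = NA_character_, trim_depth = 0L) {
  data.frame(bases = bases,
             length = nchar(bases),
             at_count = nchar(bases) - nchar(gsub("[AT]", "", bases)),
             parent_id = rep_len(parent_id, length(bases)),
             trim_depth = rep_len(as.integer(trim_depth), length(bases)),
             stringsAsFactors = FALSE)
}

#' Enumerate all constrained full-length stem sequences
#'
#' Generates every stem of length `stem_length_max` with exactly
#' `at_pairs_required` A/T bases, then drops stems containing a forbidden
#' motif (on either strand) or an internal self-complementary stretch.
#' Output is in deterministic lexicographic order with no duplicates.
#'
#' @param constraints a `design_constraints` object.
#' @return data.frame of stems (columns `bases`, `length`, `at_count`,
#'   `parent_id`, `trim_depth`).
#' @examples
#' nrow(enumerate_stems(design_constraints(stem_length_max = 4)))
#' @export
enumerate_stems <- function(constraints) {
  stopifnot(inherits(constraints, "design_constraints"))
  L <- constraints$stem_length_max
  m <- constraints$at_pairs_required
  pos_sets <- if (m == 0L) list(integer(0)) else
    asplit(utils::combn(L, m), 2)
  out <- character(0)
  gc_fill <- if (L == m) matrix("", nrow = 1, ncol = 0) else
    as.matrix(expand.grid(rep(list(c("C", "G")), L - m),
                          stringsAsFactors = FALSE))
  at_fill <- if (m > 0L)
    as.matrix(expand.grid(rep(list(c("A", "T")), m),
                          stringsAsFactors = FALSE)) else
    matrix("", nrow = 1, ncol = 0)
  for (ps in pos_sets) {
    ps <- as.integer(ps)
    gc_pos <- setdiff(seq_len(L), ps)
    for (r in seq_len(nrow(at_fill))) {
      template <- character(L)
      template[ps] <- at_fill[r, ]
      block <- matrix(template, nrow = nrow(gc_fill), ncol = L, byrow = TRUE)
      block[, gc_pos] <- gc_fill
      out <- c(out, apply(block, 1, paste, collapse = ""))
    }
  }
  out <- sort(unique(out))
  out <- .screen_stems(out, constraints)
  .stem_frame(out)
}

# motif + self-complementarity screens, vectorised over stem strings
.screen_stems <- function(bases, constraints) {
  if (length(constraints$forbidden_motifs)) {
    for (motif in constraints$forbidden_motifs) {
      hit <- grepl(motif, bases, fixed = TRUE) |
        grepl(revcomp(motif), bases, fixed = TRUE)
      bases <- bases[!hit]
    }
  }
  w <- constraints$self_comp_window
  if (!is.null(w) && length(bases)) {
    bases <- bases[!.self_comp_vec(bases, w)]
  }
  bases
}

.self_comp_vec <- function(bases, window) {
  n <- nchar(bases)
  res <- logical(length(bases))
  for (L in unique(n)) {
    sel <- which(n == L)
    if (L < 2L * window + 3L) next
    hit <- logical(length(sel))
    for (i in seq_len(L - window + 1L)) {
      js <- seq_len(L - window + 1L)
      js <- js[js >= i + window + 3L]  # >= 3 unpaired bases between arms
      if (!length(js)) next
      a <- substr(bases[sel], i, i + window - 1L)
      arc <- revcomp(a)
      for (j in js) {
        b <- substr(bases[sel], j, j + window - 1L)
        hit <- hit | (b == arc)
      }
    }
    res[sel] <- hit
  }
  res
}

#' Is a stem self-complementary?
#'
#' TRUE when some substring of at least `window` nt has its reverse
#' complement present downstream in the same stem with at least 3 unpaired
#' bases between the two stretches (the minimum hairpin loop), i.e. the stem
#' could fold back on itself.
#'
#' @param stem a DNA string (or a stem data.frame row).
#' @param window minimum complementary stretch, nt (>= 2).
#' @return logical.
#' @examples
#' is_self_complementary("GGGG", 4)          # FALSE
#' is_self_complementary("GGGGAAACCCC", 4)   # TRUE
#' @export
is_self_complementary <- function(stem, window = 4L) {
  if (is.data.frame(stem)) stem <- stem$bases
  assert_dna(stem, "stem")
  if (window < 2L) stop("window must be >= 2")
  .self_comp_vec(stem, as.integer(window))
}

#' Derive trimmed lower-stability variants of a stem
#'
#' Deletes the 3'-most base of the stem arm (the base pair adjacent to the
#' loop in the assembled hairpin, the innermost pair) one at a time, down to
#' `floor` nt inclusive.  The original stem is not included in the result.
#'
#' @param stem a DNA string or a one-row stem data.frame.
#' @param floor shortest variant retained.
#' @return data.frame of variants with `parent_id` set to the ancestor stem
#'   and `trim_depth` = ancestor length - variant length.
#' @export
derive_trimmed_variants <- function(stem, floor = 1L) {
  if (is.data.frame(stem)) stem <- stem$bases
  assert_dna(stem, "stem")
  stopifnot(length(stem) == 1L)
  L <- nchar(stem)
  floor <- as.integer(floor)
  if (L < floor) stop("stem shorter than floor")
  lens <- rev(seq(floor, L - 1L))
  if (!length(lens)) return(.stem_frame(character(0)))
  .stem_frame(substr(rep(stem, length(lens)), 1L, lens),
              parent_id = stem, trim_depth = L - lens)
}

#' Remove duplicate and all-G/C stems
#'
#' Collapses exact duplicate base-strings (keeping, among duplicates, the
#' entry with the lexicographically first provenance: smallest `parent_id`,
#' then smallest `trim_depth`) and removes stems with no A/T base (100% G/C
#' stems).  Order of first occurrence is preserved.
#'
#' @param stems stem data.frame.
#' @param constraints a `design_constraints` (reserved for future
#'   constraint-dependent filters; only the all-G/C rule is applied).
#' @return filtered stem data.frame.
#' @export
dedup_and_filter <- function(stems, constraints = design_constraints()) {
  stopifnot(is.data.frame(stems))
  stems <- stems[stems$at_count > 0L, , drop = FALSE]
  if (!nrow(stems)) return(stems)
  prov <- paste(ifelse(is.na(stems$parent_id), stems$bases, stems$parent_id),
                formatC(stems$trim_depth, width = 3, flag = "0"))
  ord <- order(stems$bases, prov)
  keep_idx <- ord[!duplicated(stems$bases[ord])]
  out <- stems[sort(keep_idx), , drop = FALSE]
  out <- out[order(match(out$bases, stems$bases)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Independently re-check every active constraint
#'
#' Walks the constraint list with simple, direct checks (no shared code with
#' the enumerator) and reports per-stem violations; used as a post-hoc
#' validator of the design pipeline.
#'
#' @param stems stem data.frame.
#' @param constraints a `design_constraints`.
#' @param full_length if TRUE, stems are required to be exactly
#'   `stem_length_max` nt with exactly `at_pairs_required` A/T; if FALSE
#'   (trimmed pools), length and A/T count are only bounded.
#' @return data.frame with a logical column per check plus `ok`.
#' @export
check_stem_constraints <- function(stems, constraints, full_length = TRUE) {
  b <- stems$bases
  n <- nchar(b)
  at <- vapply(b, function(s) sum(.chars(s) %in% c("A", "T")), integer(1))
  len_ok <- if (full_length) n == constraints$stem_length_max else
    n >= constraints$trim_floor & n <= constraints$stem_length_max
  at_ok <- if (full_length) at == constraints$at_pairs_required else
    at <= constraints$at_pairs_required
  motif_ok <- rep(TRUE, length(b))
  for (motif in constraints$forbidden_motifs) {
    motif_ok <- motif_ok & !grepl(motif, b, fixed = TRUE) &
      !grepl(revcomp(motif), b, fixed = TRUE)
  }
  sc_ok <- if (is.null(constraints$self_comp_window)) rep(TRUE, length(b)) else
    !vapply(b, function(s) {
      w <- constraints$self_comp_window
      L <- nchar(s)
      found <- FALSE
      for (i in seq_len(max(0L, L - w + 1L))) {
        for (j in seq_len(max(0L, L - w + 1L))) {
          if (j < i + w + 3L) next
          if (substr(s, j, j + w - 1L) == revcomp(substr(s, i, i + w - 1L))) {
            found <- TRUE
          }
        }
      }
      found
    }, logical(1))
  data.frame(bases = b, len_ok = len_ok, at_ok = at_ok,
             motif_ok = motif_ok, self_comp_ok = unname(sc_ok),
             ok = len_ok & at_ok & motif_ok & unname(sc_ok),
             stringsAsFactors = FALSE)
}
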