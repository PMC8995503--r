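#' Pairing maps
#'
#' A `pairing_map` records a non-crossing set of base pairs over a sequence,
#' as 0-based index pairs (i, j) with i < j, plus the index interval of the
#' unpaired loop when the map is a single contiguous stem-loop.
#'
#' @param pairs integer matrix with two columns (0-based indices, i < j);
#'   may have zero rows.
#' @param loop_span optional integer vector `c(first, last)` (0-based,
#'   inclusive) of the unpaired loop, or `NULL`.
#' @return an object of class `pairing_map`.
#' @export
pairing_map <- function(pairs, loop_span = NULL) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs)) {
    if (any(pairs[, 1] >= pairs[, 2])) stop("pairs must satisfy i < j")
    idx <- c(pairs[, 1], pairs[, 2])
    if (anyDuplicated(idx)) stop("an index appears in more than one pair")
    # crossing check: for sorted-by-i pairs, each later pair must nest or
    # be disjoint
    o <- order(pairs[, 1])
    pairs <- pairs[o, , drop = FALSE]
    for (a in seq_len(nrow(pairs) - 1L)) {
      for (b in seq(a + 1L, nrow(pairs))) {
        i <- pairs[a, 1]; j <- pairs[a, 2]
        k <- pairs[b, 1]; l <- pairs[b, 2]
        if (i < k && k < j && j < l) stop("crossing pairs are forbidden")
      }
    }
  }
  structure(list(pairs = pairs, loop_span = loop_span), class = "pairing_map")
}

#' @rdname pairing_map
#' @param map a `pairing_map`.
#' @param sequence the sequence the map indexes (DNA or RNA string); every
#'   pair must be Watson-Crick complementary in it.
#' @export
validate_pairing <- function(map, sequence) {
  stopifnot(inherits(map, "pairing_map"))
  kind <- if (grepl("U", sequence)) "RNA" else "DNA"
  x <- .chars(sequence)
  p <- map$pairs
  if (nrow(p)) {
    if (max(p) >= length(x)) stop("pair index beyond sequence end")
    codes <- paste0(x[p[, 1] + 1L], x[p[, 2] + 1L])
    bad <- !.is_wc(codes, kind)
    if (any(bad)) {
      stop("non-Watson-Crick pair(s): ", paste(codes[bad], collapse = ", "))
    }
  }
  invisible(map)
}

#' @export
print.pairing_map <- function(x, ...) {
  cat("<pairing_map> ", nrow(x$pairs), " pairs\n", sep = "")
  invisible(x)
}

#' Construct a stem-loop structure from a sequence
#'
#' Builds a `hairpin_structure` whose intended pairing joins position i with
#' its mirror position (0-based i with n-1-i) for the outermost `n_pairs`
#' positions, leaving the centre unpaired as the loop.  Used for ad-hoc
#' structures; designed attenuator inserts come from [assemble_hairpin()].
#'
#' @param sequence DNA string.
#' @param n_pairs number of stem pairs (from the outside in).
#' @return a `hairpin_structure`.
#' @export
stemloop <- function(sequence, n_pairs) {
  assert_dna(sequence)
  n <- nchar(sequence)
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 1L || 2L * n_pairs >= n) stop("invalid stem pair count")
  idx <- seq_len(n_pairs) - 1L
  pairs <- cbind(idx, n - 1L - idx)
  map <- pairing_map(pairs, loop_span = c(n_pairs, n - n_pairs - 1L))
  validate_pairing(map, sequence)
  structure(list(insert_sequence = sequence, pairing = map,
                 total_length = n, delta_g = NA_real_, id = NA_character_),
            class = "hairpin_structure")
}

#' Folding free energy of a hairpin stem-loop
#'
#' Evaluates the intended stem-loop structure under the nearest-neighbor
#' model: the sum of stack free energies over consecutive stem pairs, plus
#' the hairpin-loop initiation penalty for the loop length, plus (when the
#' model enables it and the loop has >= 4 nt) the terminal mismatch of the
#' loop-closing pair, plus the terminal AU/AT penalty where the outermost or
#' (for 3-nt loops) closing pair is A-U/A-T.  The insert is treated as an
#' isolated stem-loop: no dangling ends, no coaxial stacking, no bulges.
#'
#' @param structure a `hairpin_structure` (from [assemble_hairpin()] or
#'   [stemloop()]) with a contiguous intended stem.
#' @param model an `energy_model`; default the packaged RNA set.
#' @return free energy in kcal/mol (negative = stable).
#' @examples
#' hp <- assemble_hairpin("GCGCGCGCGCT")
#' hairpin_dG(hp)
#' @export
hairpin_dG <- function(structure, model = load_energy_model("RNA")) {
  stopifnot(inherits(structure, "hairpin_structure"))
  validate_energy_model(model)
  p <- structure$pairing$pairs
  m <- nrow(p)
  if (m < 2L) stop("invalid structure: need at least 2 consecutive stem pairs")
  p <- p[order(p[, 1]), , drop = FALSE]
  if (any(diff(p[, 1]) != 1L) || any(diff(p[, 2]) != -1L)) {
    stop("invalid structure: stem pairs must be consecutive (no bulges)")
  }
  loop_len <- p[m, 2] - p[m, 1] - 1L
  if (loop_len < 3L) stop("invalid structure: loop length < 3")
  kind <- model$nucleic_acid_kind
  x <- .chars(.to_alphabet(structure$insert_sequence, kind))
  b5 <- x[p[, 1] + 1L]
  b3 <- x[p[, 2] + 1L]
  codes <- paste0(b5[-m], b5[-1], b3[-1], b3[-m])
  stack_vals <- model$stack_table[codes]
  if (anyNA(stack_vals)) {
    stop("missing nearest-neighbor parameter for stack ",
         codes[which(is.na(stack_vals))[1]])
  }
  init <- model$hairpin_loop_init[as.character(loop_len)]
  if (is.na(init)) stop("no hairpin-loop initiation for loop length ", loop_len)
  dg <- sum(stack_vals) + init
  closing <- paste0(b5[m], b3[m])
  au_pairs <- if (kind == "RNA") c("AU", "UA") else c("AT", "TA")
  if (loop_len >= 4L && model$use_terminal_mismatch) {
    key <- paste0(closing, x[p[m, 1] + 2L], x[p[m, 2]])
    mm <- model$terminal_mismatch_table[key]
    if (is.na(mm)) stop("missing terminal mismatch parameter ", key)
    dg <- dg + mm
  } else if (loop_len == 3L && closing %in% au_pairs) {
    dg <- dg + model$terminal_au
  }
  if (paste0(b5[1], b3[1]) %in% au_pairs) dg <- dg + model$terminal_au
  unname(dg)
}

# lexicographic comparison of (pairs, stacked-adjacency) score tuples
.score_gt <- function(a, b) a[1] > b[1] || (a[1] == b[1] && a[2] > b[2])

#' Maximum Watson-Crick pairing of a sequence (Nussinov dynamic program)
#'
#' Computes a maximum-cardinality non-crossing Watson-Crick pairing with a
#' minimum loop size.  Ties in pair count are broken deterministically:
#' first toward the structure with the most stacked pair adjacencies (which
#' favors long contiguous helices), then toward the lexicographically
#' smallest pair list.
#'
#' @param sequence DNA or RNA string (one of the two alphabets, upper case).
#' @param min_loop minimum number of unpaired bases enclosed by any pair.
#' @return a `pairing_map`.
#' @examples
#' max_pairing_fold("GGGAAACCC")
#' @export
max_pairing_fold <- function(sequence, min_loop = 3L) {
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop("sequence must be a single string")
  }
  sequence <- toupper(sequence)
  kind <- if (grepl("U", sequence)) "RNA" else "DNA"
  if (grepl(if (kind == "RNA") "[^ACGU]" else "[^ACGT]", sequence)) {
    stop("invalid alphabet in sequence")
  }
  min_loop <- as.integer(min_loop)
  n <- nchar(sequence)
  if (n < min_loop + 2L) stop("sequence shorter than min_loop + 2")
  x <- .chars(sequence)
  can_pair <- outer(x, x, function(a, b) .is_wc(paste0(a, b), kind))

  # F[i,j]: best (pairs, stacks) over the interval; C[i,j]: best with (i,j)
  # paired.  Intervals with j - i <= min_loop hold (0, 0).
  Fp <- matrix(0L, n, n); Fs <- matrix(0L, n, n)
  Cp <- matrix(NA_integer_, n, n); Cs <- matrix(NA_integer_, n, n)
  if (n >= min_loop + 2L) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in 1:(n - span)) {
        j <- i + span
        # C(i,j)
        if (can_pair[i, j]) {
          best <- c(Fp[i + 1L, j - 1L], Fs[i + 1L, j - 1L])
          if (j - i >= min_loop + 3L && can_pair[i + 1L, j - 1L]) {
            alt <- c(Cp[i + 1L, j - 1L], Cs[i + 1L, j - 1L] + 1L)
            if (.score_gt(alt, best)) best <- alt
          }
          Cp[i, j] <- best[1] + 1L
          Cs[i, j] <- best[2]
        }
        # F(i,j)
        best <- c(Fp[i + 1L, j], Fs[i + 1L, j])
        for (k in (i + min_loop + 1L):j) {
          if (!can_pair[i, k]) next
          rest <- if (k < j) c(Fp[k + 1L, j], Fs[k + 1L, j]) else c(0L, 0L)
          cand <- c(Cp[i, k] + rest[1], Cs[i, k] + rest[2])
          if (.score_gt(cand, best)) best <- cand
        }
        Fp[i, j] <- best[1]; Fs[i, j] <- best[2]
      }
    }
  }

  # deterministic traceback: prefer pairing i (smallest partner k first)
  pairs <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n, 0L))  # i, j, closed flag
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- fr[1]; j <- fr[2]; closed <- fr[3]
    if (j - i <= min_loop) next
    if (closed) {
      # (i,j) already recorded; decompose the inside
      ii <- i + 1L; jj <- j - 1L
      target <- c(Cp[i, j] - 1L, Cs[i, j])
      if (jj - ii >= min_loop + 1L && can_pair[ii, jj] &&
          !is.na(Cp[ii, jj]) &&
          identical(target, c(Cp[ii, jj], Cs[ii, jj] + 1L))) {
        pairs <- rbind(pairs, c(ii, jj))
        stack[[length(stack) + 1L]] <- c(ii, jj, 1L)
      } else {
        stack[[length(stack) + 1L]] <- c(ii, jj, 0L)
      }
      next
    }
    target <- c(Fp[i, j], Fs[i, j])
    if (target[1] == 0L) next
    done <- FALSE
    for (k in (i + min_loop + 1L):j) {
      if (!can_pair[i, k] || is.na(Cp[i, k])) next
      rest <- if (k < j) c(Fp[k + 1L, j], Fs[k + 1L, j]) else c(0L, 0L)
      if (identical(target, c(Cp[i, k] + rest[1], Cs[i, k] + rest[2]))) {
        pairs <- rbind(pairs, c(i, k))
        stack[[length(stack) + 1L]] <- c(i, k, 1L)
        if (k < j) stack[[length(stack) + 1L]] <- c(k + 1L, j, 0L)
        done <- TRUE
        break
      }
    }
    if (!done) stack[[length(stack) + 1L]] <- c(i + 1L, j, 0L)
  }
  if (nrow(pairs)) pairs <- pairs[order(pairs[, 1]), , drop = FALSE] - 1L
  pairing_map(pairs)
}

# longest run of stacked pairs (contiguous helix) restricted to pairs
# passing `keep`
.helix_runs <- function(pairs, keep = rep(TRUE, nrow(pairs))) {
  if (!nrow(pairs)) return(integer(0))
  o <- order(pairs[, 1])
  p <- pairs[o, , drop = FALSE]; k <- keep[o]
  runs <- integer(0); cur <- 0L
  for (a in seq_len(nrow(p))) {
    if (!k[a]) { if (cur) runs <- c(runs, cur); cur <- 0L; next }
    if (cur > 0L) {
      prev <- p[a - 1L, ]
      if (k[a - 1L] && p[a, 1] == prev[1] + 1L && p[a, 2] == prev[2] - 1L) {
        cur <- cur + 1L
      } else {
        runs <- c(runs, cur); cur <- 1L
      }
    } else cur <- 1L
  }
  if (cur) runs <- c(runs, cur)
  runs
}

#' Check that the designed stem is the dominant fold
#'
#' Refolds the assembled insert with [max_pairing_fold()] and reports
#' whether the intended stem pairing achieves the maximal attainable pair
#' count.  Isolated (lone) pairs in the refold are ignored for this
#' comparison: a pair with no stacked neighbor contributes no
#' nearest-neighbor stacking energy, so it cannot make an alternative fold
#' competitive.  Separately, the insert is scanned for self-complementary
#' stretches of at least `window` nt whose implied pairing is not part of
#' the intended stem -- the signature of a competing alternative helix.
#'
#' @param structure a `hairpin_structure`.
#' @param window minimum alternative helix length flagged (defaults to the
#'   self-complementarity screening window, 4).
#' @param min_loop minimum loop size for the refold and the helix scan.
#' @return a `fold_report` list with fields `intended_pair_count`,
#'   `alternative_pair_count` (raw maximum-cardinality refold),
#'   `alternative_stacked_pair_count` (excluding lone pairs),
#'   `intended_is_maximal`, `has_disjoint_alternative_helix`,
#'   `longest_disjoint_helix`.
#' @export
verify_intended_fold <- function(structure, window = 4L, min_loop = 3L) {
  stopifnot(inherits(structure, "hairpin_structure"))
  intended <- structure$pairing$pairs
  alt <- max_pairing_fold(structure$insert_sequence, min_loop = min_loop)
  ap <- alt$pairs
  runs <- .helix_runs(ap)
  stacked <- sum(runs[runs >= 2L])
  longest <- .longest_unintended_helix(structure$insert_sequence, intended,
                                       window, min_loop)
  structure(list(
    intended_pair_count = nrow(intended),
    alternative_pair_count = nrow(ap),
    alternative_stacked_pair_count = stacked,
    intended_is_maximal = nrow(intended) >= stacked,
    has_disjoint_alternative_helix = longest >= window,
    longest_disjoint_helix = longest
  ), class = "fold_report")
}

# longest self-complementary stretch whose implied intramolecular pairing
# (with >= min_loop enclosed bases) is not already the intended pairing
.longest_unintended_helix <- function(sequence, intended, window, min_loop) {
  x <- .chars(sequence)
  n <- length(x)
  key <- if (nrow(intended)) paste(intended[, 1], intended[, 2]) else
    character(0)
  best <- 0L
  k <- max(2L, as.integer(window))
  repeat {
    if (k > (n - min_loop) %/% 2L) break
    found <- FALSE
    for (i in seq_len(n - k + 1L)) {
      a <- substr(sequence, i, i + k - 1L)
      arc <- revcomp(a)
      j <- i + k + min_loop
      while (j <= n - k + 1L) {
        if (substr(sequence, j, j + k - 1L) == arc) {
          # implied pairs: (i+t-1, j+k-t) in 0-based coordinates
          t <- seq_len(k)
          pk <- paste(i + t - 2L, j + k - t - 1L)
          if (!all(pk %in% key)) { found <- TRUE; break }
        }
        j <- j + 1L
      }
      if (found) break
    }
    if (!found) break
    best <- k
    k <- k + 1L
  }
  best
}

#' @export
print.fold_report <- function(x, ...) {
  for (k in names(x)) cat(k, ": ", format(x[[k]]), "\n", sep = "")
  invisible(x)
}

#' Write a fold report as key-value text records
#'
#' @param report a `fold_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fold_report <- function(report, path) {
  stopifnot(inherits(report, "fold_report"))
  writeLines(paste0(names(report), "\t", vapply(report, format, character(1))),
             path)
  invisible(path)
}
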