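# Independent oracles used across the suite.

# Fixed-structure evaluation by ViennaRNA's RNAeval (reference folding
# implementation; -d0 disables dangling-end terms so the isolated stem-loop
# decomposition applies).  Sequences are DNA or RNA strings; structures in
# dot-bracket.
rnaeval <- function(seqs, structs) {
  inp <- paste(rbind(chartr("T", "U", seqs), structs), collapse = "\n")
  out <- system2("RNAeval", "-d0", input = inp, stdout = TRUE)
  en <- out[seq(2, length(out), by = 2)]
  as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)$", "\\1", en))
}

# dot-bracket for a contiguous stem-loop
dot_bracket <- function(n_pairs, total) {
  paste0(strrep("(", n_pairs), strrep(".", total - 2 * n_pairs),
         strrep(")", n_pairs))
}

# random Watson-Crick stem (5' arm) of given length
random_stem <- function(len, gc_bias = 0.7) {
  p <- c((1 - gc_bias) / 2, gc_bias / 2, gc_bias / 2, (1 - gc_bias) / 2)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
        collapse = "")
}

# exhaustive maximum non-crossing Watson-Crick pairing by structure
# recursion (no memoisation, no tie logic: explores every structure)
brute_max_pairs <- function(s, min_loop = 3L) {
  x <- strsplit(s, "")[[1]]
  wc <- c("AT", "TA", "GC", "CG", "AU", "UA")
  f <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- f(i, j - 1L)           # j unpaired
    for (k in i:(j - min_loop - 1L)) {
      if (paste0(x[k], x[j]) %in% wc) {
        v <- 1L + (if (k > i) f(i, k - 1L) else 0L) + f(k + 1L, j - 1L)
        if (v > best) best <- v
      }
    }
    best
  }
  f(1L, length(x))
}

# exhaustive enumeration of constrained stems by filtering all 4^L strings
brute_enumerate_stems <- function(L, at_required = 1L,
                                  motifs = character(0), window = NULL) {
  all_seqs <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), L),
                                          stringsAsFactors = FALSE))
  at <- nchar(all_seqs) - nchar(gsub("[AT]", "", all_seqs))
  keep <- at == at_required
  for (m in motifs) {
    keep <- keep & !grepl(m, all_seqs, fixed = TRUE) &
      !grepl(revcomp(m), all_seqs, fixed = TRUE)
  }
  if (!is.null(window)) {
    keep <- keep & !vapply(all_seqs, brute_self_comp, logical(1),
                           window = window)
  }
  sort(all_seqs[keep])
}

# direct double loop over all substring pairs
brute_self_comp <- function(s, window) {
  L <- nchar(s)
  for (i in seq_len(max(0L, L - window + 1L))) {
    for (j in seq_len(max(0L, L - window + 1L))) {
      if (j < i + window + 3L) next
      if (substr(s, j, j + window - 1L) ==
          revcomp(substr(s, i, i + window - 1L))) return(TRUE)
    }
  }
  FALSE
}

# exhaustive panel selection over all k-subsets (order-preserving matching
# of a sorted subset to the sorted grid is optimal for 1-D assignment)
brute_panel_cost <- function(dg, k, lo, hi) {
  grid <- seq(lo, hi, length.out = k)
  idx <- which(dg >= lo & dg <= hi)
  best <- Inf
  for (ss in utils::combn(idx, k, simplify = FALSE)) {
    v <- sum(abs(sort(dg[ss]) - grid))
    if (v < best) best <- v
  }
  best
}

# naive double-loop pixelwise ratio
brute_mean_ratio <- function(green, red, mask) {
  tot <- 0; n <- 0L
  for (i in seq_len(nrow(green))) {
    for (j in seq_len(ncol(green))) {
      if (mask[i, j]) {
        tot <- tot + green[i, j] / red[i, j]
        n <- n + 1L
      }
    }
  }
  if (n == 0L) NA_real_ else tot / n
}

# naive both-strand site scan
brute_site_scan <- function(sequence, site) {
  hits <- integer(0)
  n <- nchar(sequence); m <- nchar(site)
  rc <- revcomp(site)
  for (i in seq_len(n - m + 1L)) {
    sub <- substr(sequence, i, i + m - 1L)
    if (sub == site || sub == rc) hits <- c(hits, i - 1L)
  }
  unique(hits)
}

# fixture paths
extdata <- function(f) system.file("extdata", f, package = "kdrdesign",
                                   mustWork = TRUE)
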