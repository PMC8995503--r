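#' Construct parts
#'
#' @param name part name.
#' @param role one of `promoter`, `attenuator`, `kozak`, `rescue`, `ires`,
#'   `reporter`, `mirE_cassette`, `shrna`, `aux`.
#' @param sequence non-empty ACGT string.
#' @return a `kdr_part`.
#' @export
part <- function(name, role, sequence) {
  roles <- c("promoter", "attenuator", "kozak", "rescue", "ires",
             "reporter", "mirE_cassette", "shrna", "aux")
  if (!role %in% roles) stop("unknown part role: ", role)
  if (!nzchar(sequence)) stop("part sequence must be non-empty")
  assert_dna(sequence, paste0("part '", name, "' sequence"))
  structure(list(name = name, role = role, sequence = toupper(sequence)),
            class = "kdr_part")
}

#' Standard restriction enzymes of the KDR cloning geometry
#'
#' @return named character vector of recognition sequences.
#' @export
kdr_enzymes <- function() {
  c(AgeI = "ACCGGT", NotI = "GCGGCCGC", SbfI = "CCTGCAGG",
    EcoRI = "GAATTC", XhoI = "CTCGAG")
}

#' Construct plans
#'
#' The minimal constitutive construct orders promoter, attenuator, Kozak,
#' rescue, miRE cassette; the inducible reporter variant inserts an IRES and
#' a fluorescent reporter between rescue and miRE so expression can be
#' read ratiometrically.
#'
#' @param variant `"minimal_constitutive"` or `"inducible_reporter"`.
#' @param site_rules data.frame of rules (see [default_site_rules()]).
#' @return a `construct_plan` with `roles` in assembly order.
#' @export
construct_plan <- function(variant = c("minimal_constitutive",
                                       "inducible_reporter"),
                           site_rules = default_site_rules()) {
  variant <- match.arg(variant)
  roles <- if (variant == "minimal_constitutive") {
    c("promoter", "attenuator", "kozak", "rescue", "mirE_cassette")
  } else {
    c("promoter", "attenuator", "kozak", "rescue", "ires", "reporter",
      "mirE_cassette")
  }
  structure(list(variant = variant, roles = roles, site_rules = site_rules),
            class = "construct_plan")
}

#' Default cloning-site rules
#'
#' Internal recreations of the sites used for cloning would break the
#' geometry: the rescue gene is inserted via NotI/SbfI so must not contain
#' either site internally, and shRNAs enter the miRE cassette via
#' EcoRI/XhoI so the final cassette must be free of both.
#'
#' @return data.frame with columns `enzyme`, `role`, `rule`.
#' @export
default_site_rules <- function() {
  data.frame(
    enzyme = c("NotI", "SbfI", "EcoRI", "XhoI"),
    role = c("rescue", "rescue", "mirE_cassette", "mirE_cassette"),
    rule = "must_be_absent_internal",
    stringsAsFactors = FALSE)
}

#' Assemble a construct from parts
#'
#' Concatenates one part per role in plan order and annotates each part as
#' a feature with 0-based, half-open top-strand coordinates.
#'
#' @param plan a `construct_plan`.
#' @param parts list of `kdr_part`s covering each required role exactly
#'   once (extra `aux` parts are not permitted in the plan order).
#' @return a `construct_record`: `sequence`, `features` (data.frame of
#'   name/role/start/end/strand), `variant`.
#' @export
assemble_construct <- function(plan, parts) {
  stopifnot(inherits(plan, "construct_plan"))
  roles <- vapply(parts, `[[`, character(1), "role")
  feats <- list()
  seqs <- character(0)
  pos <- 0L
  for (role in plan$roles) {
    hit <- which(roles == role)
    if (length(hit) == 0L) stop("missing part for role: ", role)
    if (length(hit) > 1L) stop("duplicate parts for role: ", role)
    p <- parts[[hit]]
    len <- nchar(p$sequence)
    feats[[length(feats) + 1L]] <-
      data.frame(name = p$name, role = role, start = pos, end = pos + len,
                 strand = "+", stringsAsFactors = FALSE)
    seqs <- c(seqs, p$sequence)
    pos <- pos + len
  }
  structure(list(sequence = paste(seqs, collapse = ""),
                 features = do.call(rbind, feats),
                 variant = plan$variant),
            class = "construct_record")
}

#' @export
print.construct_record <- function(x, ...) {
  cat("<construct_record> ", x$variant, ", ", nchar(x$sequence), " bp, ",
      nrow(x$features), " features\n", sep = "")
  print.data.frame(x$features)
  invisible(x)
}

# all occurrence start positions (0-based) of a site on both strands;
# palindromic sites are reported once per genomic position
.site_occurrences <- function(sequence, site) {
  find <- function(pat) {
    hits <- gregexpr(pat, sequence, fixed = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
  }
  fwd <- find(site)
  rc <- revcomp(site)
  if (rc == site) return(sort(fwd))
  sort(unique(c(fwd, find(rc))))
}

#' Validate restriction-site geometry of an assembled construct
#'
#' For every rule, reports all occurrence coordinates of the enzyme's
#' recognition site on both strands of the construct and whether the rule
#' holds: `must_be_absent_internal` fails when a site occurrence lies fully
#' inside the named part, `required_flank` requires an occurrence
#' overlapping a window of one site-length around the part's 5' or 3'
#' boundary.
#'
#' @param record a `construct_record`.
#' @param rules data.frame with `enzyme`, `role`, `rule`; defaults to
#'   [default_site_rules()].
#' @param enzymes named recognition sequences (defaults to [kdr_enzymes()]);
#'   rules naming enzymes absent from this table are an error.
#' @return data.frame: one row per rule with `enzyme`, `role`, `rule`,
#'   `occurrences` (comma-separated 0-based starts within the part or
#'   flank window), `pass`.
#' @export
validate_cloning_sites <- function(record, rules = default_site_rules(),
                                   enzymes = kdr_enzymes()) {
  stopifnot(inherits(record, "construct_record"), is.data.frame(rules))
  out <- lapply(seq_len(nrow(rules)), function(r) {
    enz <- rules$enzyme[r]
    if (!enz %in% names(enzymes)) stop("unknown enzyme: ", enz)
    site <- enzymes[[enz]]
    slen <- nchar(site)
    feat <- record$features[record$features$role == rules$role[r], ,
                            drop = FALSE]
    if (nrow(feat) != 1L) stop("rule names role absent from construct: ",
                               rules$role[r])
    occ <- .site_occurrences(record$sequence, site)
    occ_end <- occ + slen
    if (rules$rule[r] == "must_be_absent_internal") {
      inside <- occ[occ >= feat$start & occ_end <= feat$end]
      pass <- length(inside) == 0L
      shown <- inside
    } else if (rules$rule[r] == "required_flank") {
      near5 <- occ[occ_end > feat$start - slen & occ < feat$start + slen]
      near3 <- occ[occ_end > feat$end - slen & occ < feat$end + slen]
      shown <- sort(unique(c(near5, near3)))
      pass <- length(shown) > 0L
    } else {
      stop("unknown rule: ", rules$rule[r])
    }
    data.frame(enzyme = enz, role = rules$role[r], rule = rules$rule[r],
               occurrences = paste(shown, collapse = ","),
               pass = pass, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write / read an annotated record as a minimal GenBank-style flat file
#'
#' Writes LOCUS, FEATURES (misc_feature with 1-based closed coordinates and
#' `/label`, `/role` qualifiers) and ORIGIN blocks.  The matching reader
#' restores the record exactly, converting coordinates back to 0-based
#' half-open.  This is a deliberately small subset of the format, intended
#' for round-tripping this package's own records.
#'
#' @param record a `construct_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  stopifnot(inherits(record, "construct_record"))
  n <- nchar(record$sequence)
  ln <- c(sprintf("LOCUS       %s %d bp    DNA     linear", record$variant, n),
          "FEATURES             Location/Qualifiers")
  for (r in seq_len(nrow(record$features))) {
    f <- record$features[r, ]
    loc <- sprintf("%d..%d", f$start + 1L, f$end)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    ln <- c(ln,
            sprintf("     misc_feature    %s", loc),
            sprintf("                     /label=\"%s\"", f$name),
            sprintf("                     /role=\"%s\"", f$role))
  }
  ln <- c(ln, "ORIGIN")
  for (i in seq(1L, n, by = 60L)) {
    chunk <- substr(record$sequence, i, min(i + 59L, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    ln <- c(ln, sprintf("%9d %s", i, paste(tolower(groups), collapse = " ")))
  }
  ln <- c(ln, "//")
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_genbank
#' @export
read_genbank <- function(path) {
  ln <- readLines(path)
  variant <- strsplit(trimws(sub("^LOCUS\\s+", "", ln[1])), "\\s+")[[1]][1]
  fstart <- grep("^FEATURES", ln)
  ostart <- grep("^ORIGIN", ln)
  feats <- list()
  i <- fstart + 1L
  while (i < ostart) {
    m <- regmatches(ln[i],
                    regexec("misc_feature\\s+(complement\\()?(\\d+)\\.\\.(\\d+)",
                            ln[i]))[[1]]
    if (length(m)) {
      lab <- sub(".*label=\"([^\"]*)\".*", "\\1", ln[i + 1L])
      role <- sub(".*role=\"([^\"]*)\".*", "\\1", ln[i + 2L])
      feats[[length(feats) + 1L]] <-
        data.frame(name = lab, role = role,
                   start = as.integer(m[3]) - 1L, end = as.integer(m[4]),
                   strand = if (nzchar(m[2])) "-" else "+",
                   stringsAsFactors = FALSE)
      i <- i + 3L
    } else i <- i + 1L
  }
  seq_lines <- ln[(ostart + 1L):(length(ln))]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^acgtACGT]", "", paste(seq_lines, collapse = "")))
  structure(list(sequence = sequence, features = do.call(rbind, feats),
                 variant = variant),
            class = "construct_record")
}

#' Read parts from a FASTA file
#'
#' Headers carry `name|role`; sequences must be ACGT.
#'
#' @param path FASTA path.
#' @return list of `kdr_part`s.
#' @export
read_parts_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(seqs), function(i) {
    hdr <- strsplit(names(seqs)[i], "|", fixed = TRUE)[[1]]
    if (length(hdr) != 2L) stop("FASTA header must be 'name|role': ",
                                names(seqs)[i])
    part(hdr[1], hdr[2], as.character(seqs[[i]]))
  })
}
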