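#' Nearest-neighbor free-energy parameter sets
#'
#' An `energy_model` holds the additive nearest-neighbor parameters used to
#' score hairpin stem-loops: Watson-Crick stack free energies, hairpin-loop
#' initiation penalties by loop length, terminal-mismatch free energies for
#' the loop-closing pair, and the terminal AU/AT helix-end penalty.  All
#' values are Gibbs free energies at 37 degrees C in kcal/mol.
#'
#' Two parameter sets ship with the package as plain tab-separated tables:
#' the Turner 2004 RNA set (default; the attenuator acts in mRNA, so T is
#' read as U) and the SantaLucia/Mathews 2004 DNA set.  Each file carries a
#' provenance header and a version string which tests pin.
#'
#' @param kind `"RNA"` or `"DNA"`; selects the packaged parameter file.
#' @param path optional path to a parameter table in the packaged format;
#'   overrides `kind`-based lookup of the shipped files.
#' @param terminal_mismatch logical; include the terminal mismatch of the
#'   loop-closing pair in hairpin energies (standard hairpin rule, default
#'   `TRUE`).  Exposed because the "initial dG" convention of folding
#'   servers is not universal.
#' @param temperature temperature in degrees C carried as metadata; the
#'   shipped tables are 37 C free energies and no rescaling is attempted.
#' @return an object of class `energy_model`.
#' @examples
#' mod <- load_energy_model("RNA")
#' stack_energy("GC", "GC", mod)
#' @export
load_energy_model <- function(kind = c("RNA", "DNA"), path = NULL,
                              terminal_mismatch = TRUE, temperature = 37) {
  kind <- match.arg(kind)
  if (is.null(path)) {
    file <- if (kind == "RNA") "energy_rna_turner2004.tsv" else
      "energy_dna_mathews2004.tsv"
    path <- system.file("extdata", file, package = "kdrdesign", mustWork = TRUE)
  }
  hdr <- readLines(path, n = 20L)
  hdr <- hdr[startsWith(hdr, "#")]
  version <- sub("^# version:\\s*", "", grep("^# version:", hdr, value = TRUE))
  provenance <- paste(sub("^#\\s*", "", hdr[!grepl("^# version:", hdr)]),
                      collapse = " ")
  tab <- utils::read.delim(path, comment.char = "#", header = TRUE,
                           colClasses = c("character", "character",
                                          "character", "numeric"))
  pick <- function(rec) tab[tab$record == rec, , drop = FALSE]
  st <- pick("stack")
  stack_table <- stats::setNames(st$dg_kcal_mol, st$key1)
  hp <- pick("hairpin_init")
  hairpin_loop_init <- stats::setNames(hp$dg_kcal_mol, hp$key1)
  mm <- pick("mismatch_hairpin")
  mismatch <- if (nrow(mm)) stats::setNames(mm$dg_kcal_mol,
                                            paste0(mm$key1, mm$key2)) else NULL
  ta <- pick("terminal_au")
  model <- structure(list(
    stack_table = stack_table,
    hairpin_loop_init = hairpin_loop_init,
    terminal_mismatch_table = mismatch,
    terminal_au = if (nrow(ta)) ta$dg_kcal_mol[[1]] else 0,
    nucleic_acid_kind = kind,
    temperature = temperature,
    use_terminal_mismatch = isTRUE(terminal_mismatch) && !is.null(mismatch),
    provenance = provenance,
    version = if (length(version)) version else NA_character_
  ), class = "energy_model")
  validate_energy_model(model)
}

#' @rdname load_energy_model
#' @param model an `energy_model`.
#' @export
validate_energy_model <- function(model) {
  stopifnot(inherits(model, "energy_model"))
  codes <- names(model$stack_table)
  if (any(nchar(codes) != 4L)) stop("stack codes must be 4 characters")
  # every shipped stack is WC over WC; such stacks are stabilising
  if (any(model$stack_table >= 0)) {
    stop("Watson-Crick stack free energies must be negative")
  }
  sizes <- as.integer(names(model$hairpin_loop_init))
  if (any(sizes < 3L)) stop("hairpin loops shorter than 3 nt are disallowed")
  if (any(model$hairpin_loop_init <= 0)) {
    stop("hairpin loop initiation penalties must be positive")
  }
  invisible(model)
}

#' Write an energy model back to the packaged table format
#'
#' Round-trips through [load_energy_model()] exactly (values are carried at
#' two decimals, the native precision of the tables).
#'
#' @param model an `energy_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_energy_model <- function(model, path) {
  validate_energy_model(model)
  rows <- c(
    sprintf("stack\t%s\t\t%.2f", names(model$stack_table), model$stack_table),
    if (!is.null(model$terminal_mismatch_table)) {
      keys <- names(model$terminal_mismatch_table)
      sprintf("mismatch_hairpin\t%s\t%s\t%.2f", substr(keys, 1, 2),
              substr(keys, 3, 4), model$terminal_mismatch_table)
    },
    sprintf("hairpin_init\t%s\t\t%.2f", names(model$hairpin_loop_init),
            model$hairpin_loop_init),
    sprintf("terminal_au\t\t\t%.2f", model$terminal_au)
  )
  hdr <- c(paste0("# ", model$provenance),
           paste0("# version: ", model$version),
           "record\tkey1\tkey2\tdg_kcal_mol")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Stack free energy of two adjacent base pairs
#'
#' Looks up the nearest-neighbor free energy of `downstream_pair` stacked
#' directly inside (3' of, on the top strand) `upstream_pair`.  Pairs are
#' given as two-character codes, 5' base then 3' base of the pair
#' (e.g. `"GC"` is G paired with C); T and U are interchangeable and are
#' normalised to the model alphabet.
#'
#' @param upstream_pair,downstream_pair two-character pair codes.
#' @param model an `energy_model`.
#' @return stack free energy, kcal/mol.
#' @export
stack_energy <- function(upstream_pair, downstream_pair, model) {
  validate_energy_model(model)
  kind <- model$nucleic_acid_kind
  up <- .to_alphabet(toupper(upstream_pair), kind)
  dn <- .to_alphabet(toupper(downstream_pair), kind)
  if (!.is_wc(up, kind) || !.is_wc(dn, kind)) {
    stop("stack_energy requires Watson-Crick pairs under ", kind,
         " rules; got ", up, " over ", dn)
  }
  code <- paste0(substr(up, 1, 1), substr(dn, 1, 1),
                 substr(dn, 2, 2), substr(up, 2, 2))
  val <- model$stack_table[code]
  if (is.na(val)) stop("missing nearest-neighbor parameter for stack ", code)
  unname(val)
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> ", x$nucleic_acid_kind, " parameters at ",
      x$temperature, " C (version ", x$version, ")\n", sep = "")
  cat("  ", length(x$stack_table), " stacks, loop sizes ",
      min(as.integer(names(x$hairpin_loop_init))), "-",
      max(as.integer(names(x$hairpin_loop_init))),
      if (x$use_terminal_mismatch) ", terminal mismatches on" else
        ", terminal mismatches off", "\n", sep = "")
  invisible(x)
}
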