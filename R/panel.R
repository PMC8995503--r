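#' Select a uniformly spaced attenuator panel
#'
#' Places `k` ideal grid points uniformly across the free-energy range and
#' assigns `k` distinct library members to them, minimising the total
#' absolute deviation between member free energies and grid points.  The
#' assignment is solved exactly by dynamic programming over the
#' free-energy-sorted pool (both sequences are monotone, so an optimal
#' assignment is order-preserving); ties are broken toward the more stable
#' (more negative) member.
#'
#' @param library a `kdr_library` (or any data.frame with `id` and
#'   `delta_g_kcal_mol`).
#' @param k panel size.
#' @param dg_range numeric `c(a, b)` free-energy bounds in kcal/mol (order
#'   irrelevant); members outside are excluded from the pool.
#' @return an `attenuator_panel`: `members` (id, delta_g, grid point,
#'   deviation, sorted by delta_g), `dg_range`, `mean_increment`
#'   (span of selected free energies / (k - 1)), `max_grid_deviation`,
#'   `total_deviation`.
#' @export
select_panel <- function(library, k, dg_range) {
  stopifnot(is.data.frame(library), k >= 2L, length(dg_range) == 2L)
  lo <- min(dg_range); hi <- max(dg_range)
  pool <- library[library$delta_g_kcal_mol >= lo &
                    library$delta_g_kcal_mol <= hi, , drop = FALSE]
  n <- nrow(pool)
  if (n < k) {
    stop("infeasible selection: need ", k, " members in [", lo, ", ", hi,
         "] kcal/mol but only ", n, " available (deficit ", k - n, ")")
  }
  o <- order(pool$delta_g_kcal_mol,
             if (!is.null(pool$id)) pool$id else seq_len(n))
  pool <- pool[o, , drop = FALSE]
  dg <- pool$delta_g_kcal_mol
  grid <- seq(lo, hi, length.out = k)
  # D[i+1, t+1] = min cost assigning grid points 1..t within pool 1..i
  INF <- Inf
  D <- matrix(INF, n + 1L, k + 1L)
  D[, 1L] <- 0
  for (i in seq_len(n)) {
    for (t in seq_len(min(i, k))) {
      skip <- D[i, t + 1L]
      take <- D[i, t] + abs(dg[i] - grid[t])
      # tie toward taking the earlier (more stable) member: <=
      D[i + 1L, t + 1L] <- if (take <= skip) take else skip
    }
  }
  # traceback; on ties prefer skipping the later member, which resolves the
  # assignment toward earlier (more stable) pool members
  sel <- integer(k)
  i <- n; t <- k
  while (t > 0L) {
    take <- D[i, t] + abs(dg[i] - grid[t])
    if (i == t || take < D[i, t + 1L]) {
      sel[t] <- i
      i <- i - 1L; t <- t - 1L
    } else {
      i <- i - 1L
    }
  }
  members <- data.frame(id = pool$id[sel], delta_g = dg[sel],
                        grid_point = grid, deviation = dg[sel] - grid,
                        stringsAsFactors = FALSE)
  structure(list(
    members = members,
    dg_range = c(lo, hi),
    mean_increment = (max(members$delta_g) - min(members$delta_g)) / (k - 1L),
    max_grid_deviation = max(abs(members$deviation)),
    total_deviation = sum(abs(members$deviation))
  ), class = "attenuator_panel")
}

#' @export
print.attenuator_panel <- function(x, ...) {
  cat("<attenuator_panel> ", nrow(x$members), " members over [",
      x$dg_range[1], ", ", x$dg_range[2], "] kcal/mol\n",
      "  mean increment ", round(x$mean_increment, 3),
      " kcal/mol, max grid deviation ", round(x$max_grid_deviation, 3),
      "\n", sep = "")
  invisible(x)
}

#' Implied free-energy step between ranked probe attenuators
#'
#' Given probe attenuators known by (rank, free energy), reports the implied
#' per-rank free-energy increment for every probe pair, for comparison
#' against a panel's mean increment.  With fewer than two probes the report
#' is empty.
#'
#' @param panel optional `attenuator_panel` whose `mean_increment` is
#'   attached for reference.
#' @param probes data.frame with columns `rank` and `delta_g` (any order;
#'   sorted by rank before differencing).
#' @return data.frame with one row per probe pair: ranks, free energies and
#'   `implied_step` (kcal/mol per rank step, absolute).
#' @export
panel_consistency_check <- function(panel = NULL, probes) {
  stopifnot(is.data.frame(probes), all(c("rank", "delta_g") %in% names(probes)))
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "attenuator_panel"))
    if (any(probes$rank > nrow(panel$members) | probes$rank < 1L)) {
      stop("probe rank outside panel size")
    }
  }
  probes <- probes[order(probes$rank), , drop = FALSE]
  n <- nrow(probes)
  if (n < 2L) {
    out <- data.frame(rank_a = integer(0), rank_b = integer(0),
                      dg_a = numeric(0), dg_b = numeric(0),
                      implied_step = numeric(0))
  } else {
    cmb <- utils::combn(n, 2)
    out <- data.frame(
      rank_a = probes$rank[cmb[1, ]], rank_b = probes$rank[cmb[2, ]],
      dg_a = probes$delta_g[cmb[1, ]], dg_b = probes$delta_g[cmb[2, ]])
    out$implied_step <- abs(out$dg_b - out$dg_a) / (out$rank_b - out$rank_a)
  }
  attr(out, "panel_mean_increment") <-
    if (!is.null(panel)) panel$mean_increment else NA_real_
  out
}

#' Mean, SEM and normal-theory confidence half-width of replicates
#'
#' Standard error of the mean is the sample standard deviation over the
#' square root of n; the confidence half-width is `z * sem` (z = 1.96 for a
#' 95% normal interval).  Values are returned unrounded; round only for
#' presentation.
#'
#' @param values numeric replicate values (percent of control, or any unit).
#' @param z confidence multiplier (> 0).
#' @return list with `mean`, `sem`, `ci95_halfwidth`, `n`.
#' @examples
#' summarize_replicates(c(34.2, 35.1, 35.4))
#' @export
summarize_replicates <- function(values, z = 1.96) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("insufficient replicates: need at least 2")
  if (!is.numeric(z) || z <= 0) stop("z must be positive")
  sem <- stats::sd(values) / sqrt(length(values))
  list(mean = mean(values), sem = sem, ci95_halfwidth = z * sem,
       n = length(values))
}

#' Calibration tables of measured attenuation
#'
#' A calibration table maps attenuators to their measured expression as a
#' percent of the un-attenuated control construct (100% by definition) under
#' a given promoter, with replicate statistics.
#'
#' @param entries data.frame with columns `hairpin_id`, `delta_g_kcal_mol`,
#'   `promoter`, `mean_percent`, `sem`, `n`.
#' @param control_id identifier of the un-attenuated control entry, whose
#'   `mean_percent` must be exactly 100.
#' @param z confidence multiplier used to derive `ci95_halfwidth`.
#' @return a `calibration_table`.
#' @export
calibration_table <- function(entries, control_id = "control", z = 1.96) {
  need <- c("hairpin_id", "delta_g_kcal_mol", "promoter", "mean_percent",
            "sem", "n")
  stopifnot(is.data.frame(entries), all(need %in% names(entries)))
  if (any(entries$mean_percent < 0) || any(entries$sem < 0)) {
    stop("mean_percent and sem must be non-negative")
  }
  ctrl <- entries[entries$hairpin_id == control_id, , drop = FALSE]
  if (nrow(ctrl) != 1L) stop("control entry '", control_id, "' not found")
  if (ctrl$mean_percent != 100) stop("control entry must be exactly 100%")
  entries$ci95_halfwidth <- z * entries$sem
  structure(list(entries = entries, control_id = control_id, z = z),
            class = "calibration_table")
}

#' @rdname calibration_table
#' @param path TSV path with the entry columns above.
#' @export
read_calibration <- function(path, control_id = "control", z = 1.96) {
  entries <- utils::read.delim(path, stringsAsFactors = FALSE,
                               comment.char = "#")
  calibration_table(entries, control_id = control_id, z = z)
}

#' @rdname calibration_table
#' @param table a `calibration_table`.
#' @export
write_calibration <- function(table, path) {
  cols <- c("hairpin_id", "delta_g_kcal_mol", "promoter", "mean_percent",
            "sem", "n")
  utils::write.table(table$entries[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.calibration_table <- function(x, ...) {
  cat("<calibration_table> ", nrow(x$entries), " entries (control: ",
      x$control_id, ")\n", sep = "")
  print.data.frame(x$entries)
  invisible(x)
}

#' Rank calibration entries by measured performance
#'
#' Orders entries by measured expression (percent of control) descending
#' within each promoter -- the practical ordering for choosing attenuators,
#' since measured attenuation, not modeled stability, is what matters.
#' Ties break toward the less stable (less negative free energy) entry; the
#' control is excluded.
#'
#' @param table a `calibration_table`.
#' @return the entry data.frame, ranked, with a `rank` column per promoter.
#' @export
rank_by_performance <- function(table) {
  stopifnot(inherits(table, "calibration_table"))
  e <- table$entries[table$entries$hairpin_id != table$control_id, ,
                     drop = FALSE]
  if (!nrow(e)) stop("calibration table has no non-control entries")
  e <- e[order(e$promoter, -e$mean_percent, -e$delta_g_kcal_mol), ,
         drop = FALSE]
  e$rank <- stats::ave(seq_len(nrow(e)), e$promoter, FUN = seq_along)
  rownames(e) <- NULL
  e
}

#' Choose the attenuator matching a target expression level
#'
#' Returns the calibration entry whose measured percent-of-control is
#' nearest the target; at 100% the un-attenuated control is returned by
#' definition.  Equidistant targets resolve to the less-attenuated (higher
#' expression) entry.  A monotone piecewise-linear interpolation of
#' mean_percent against performance rank, evaluated at the target, is
#' returned for diagnostics.
#'
#' @param target_percent desired expression, percent of control.
#' @param table a `calibration_table`.
#' @param promoter restrict to one promoter (default: all entries).
#' @return list with `entry` (one-row data.frame), `predicted_percent`, and
#'   `interpolated_rank`.
#' @export
choose_attenuator <- function(target_percent, table, promoter = NULL) {
  stopifnot(inherits(table, "calibration_table"))
  e <- table$entries
  if (!is.null(promoter)) e <- e[e$promoter == promoter, , drop = FALSE]
  if (!nrow(e)) stop("calibration table is empty for the requested promoter")
  if (target_percent >= 100) {
    ctrl <- e[e$hairpin_id == table$control_id, , drop = FALSE]
    return(list(entry = ctrl, predicted_percent = 100,
                interpolated_rank = 0))
  }
  e <- e[e$hairpin_id != table$control_id, , drop = FALSE]
  d <- abs(e$mean_percent - target_percent)
  # tie toward the less-attenuated entry (higher mean_percent)
  best <- e[order(d, -e$mean_percent), , drop = FALSE][1, , drop = FALSE]
  ranked <- e[order(-e$mean_percent), , drop = FALSE]
  interp <- if (nrow(ranked) >= 2L) {
    stats::approx(x = ranked$mean_percent, y = seq_len(nrow(ranked)),
                  xout = min(max(target_percent, min(ranked$mean_percent)),
                             max(ranked$mean_percent)),
                  ties = "ordered")$y
  } else 1
  list(entry = best, predicted_percent = best$mean_percent,
       interpolated_rank = unname(interp))
}

#' Compare plasmid-predicted to integrated-construct expression
#'
#' For every attenuator shared between a plasmid-based calibration table
#' and a table of measurements from genomically integrated constructs,
#' reports whether the integrated mean lies within the plasmid mean plus or
#' minus its 95% confidence half-width, together with the absolute
#' deviation.
#'
#' @param plasmid_table,integrated_table `calibration_table`s sharing
#'   hairpin ids.
#' @param include_control include the control entry in the comparison.
#' @return data.frame: `hairpin_id`, `plasmid_mean`, `ci95_halfwidth`,
#'   `integrated_mean`, `abs_deviation`, `within_ci`.
#' @export
predicted_vs_observed <- function(plasmid_table, integrated_table,
                                  include_control = FALSE) {
  stopifnot(inherits(plasmid_table, "calibration_table"),
            inherits(integrated_table, "calibration_table"))
  p <- plasmid_table$entries
  i <- integrated_table$entries
  if (!include_control) {
    p <- p[p$hairpin_id != plasmid_table$control_id, , drop = FALSE]
    i <- i[i$hairpin_id != integrated_table$control_id, , drop = FALSE]
  }
  shared <- intersect(p$hairpin_id, i$hairpin_id)
  if (!length(shared)) stop("no shared hairpin ids between the tables")
  p <- p[match(shared, p$hairpin_id), ]
  i <- i[match(shared, i$hairpin_id), ]
  out <- data.frame(
    hairpin_id = shared,
    plasmid_mean = p$mean_percent,
    ci95_halfwidth = p$ci95_halfwidth,
    integrated_mean = i$mean_percent,
    abs_deviation = abs(i$mean_percent - p$mean_percent),
    stringsAsFactors = FALSE)
  out$within_ci <- out$abs_deviation <= out$ci95_halfwidth
  out
}
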