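#' Conductance sweep specification
#'
#' Defines a 2-D sweep over inter-population conductance (E-I and I-E,
#' varied jointly) and intra-population conductance (I-I on the axis; E-E
#' follows at a quarter of the I-I value), crossed with cell-type
#' combinations, with several independent repetitions per condition.
#'
#' Default axis values are anchored at the three published raster
#' configurations (inter 0.00025, 0.00175, 0.002; I-I 0.00025, 0.0005,
#' 0.015 mS/cm^2).
#'
#' @param inter inter-connectivity conductance values, mS/cm^2 (ascending).
#' @param intra I-I conductance values, mS/cm^2 (ascending); E-E is
#'   `intra / 4`.
#' @param combos list of `c(exc_type, inh_type)` pairs from
#'   `{"I", "II"}`; default all four combinations.
#' @param repetitions independent simulations per grid cell.
#' @param base_seed integer; per-run seeds are derived from it, the cell
#'   index and the repetition so any cell can be re-run in isolation.
#' @param preset `"scaled"` (200E/50I, conductances compensated x4) or
#'   `"full"` (800E/200I).
#' @param ablate_IE if `TRUE`, zero the I-E conductance after wiring.
#' @param duration per-simulation duration, ms.
#' @return Object of class `sweep_grid`.
#' @export
sweep_grid <- function(inter = c(0.00025, 0.00175, 0.002),
                       intra = c(0.00025, 0.0005, 0.015),
                       combos = list(c("I", "I"), c("I", "II"),
                                     c("II", "I"), c("II", "II")),
                       repetitions = 3, base_seed = 1L,
                       preset = c("scaled", "full"),
                       ablate_IE = FALSE, duration = 1500) {
  stopifnot(length(inter) >= 1, !is.unsorted(inter),
            length(intra) >= 1, !is.unsorted(intra), repetitions >= 1)
  preset <- match.arg(preset)
  structure(list(inter = inter, intra = intra, combos = combos,
                 repetitions = as.integer(repetitions),
                 base_seed = as.integer(base_seed), preset = preset,
                 ablate_IE = isTRUE(ablate_IE), duration = duration),
            class = "sweep_grid")
}

# deterministic, collision-free enough seed for (cell, repetition)
.sweep_seed <- function(base_seed, cell_index, rep) {
  as.integer((as.numeric(base_seed) + 7919 * cell_index + 104729 * rep) %%
               2147483647)
}

.preset_sizes <- function(preset) {
  if (preset == "scaled") c(n_exc = 200L, n_inh = 50L)
  else c(n_exc = 800L, n_inh = 200L)
}

#' Run a single sweep condition
#'
#' Builds the network for one grid cell and repetition, simulates it and
#' returns the measure report over the final second.  Exposed so that any
#' sweep cell can be reproduced in isolation from its recorded seed.
#'
#' @param grid a [sweep_grid()].
#' @param combo `c(exc_type, inh_type)`.
#' @param inter,intra conductances for this cell, mS/cm^2.
#' @param cell_index linear index of the grid cell (drives the seed).
#' @param rep repetition number.
#' @param return_raster if `TRUE`, attach the raster as attribute.
#' @return One-row `data.frame` (a [measure_report()] plus bookkeeping
#'   columns).
#' @export
run_sweep_cell <- function(grid, combo, inter, intra, cell_index, rep,
                           return_raster = FALSE) {
  sz <- .preset_sizes(grid$preset)
  seed <- .sweep_seed(grid$base_seed, cell_index, rep)
  cfg <- network_config(n_exc = sz[["n_exc"]], n_inh = sz[["n_inh"]],
                        exc_type = combo[1], inh_type = combo[2],
                        g_inter = inter, g_II = intra, g_EE = intra / 4,
                        seed = seed)
  net <- build_network(cfg)
  if (grid$ablate_IE) net <- ablate_IE(net)
  ras <- run_simulation(net, simulation_settings(duration = grid$duration,
                                                 seed = seed + 1L))
  rep_row <- measure_report(ras)
  out <- cbind(data.frame(exc_type = combo[1], inh_type = combo[2],
                          inter = inter, intra = intra,
                          cell_index = cell_index, rep = rep, seed = seed),
               rep_row)
  if (return_raster) attr(out, "raster") <- ras
  out
}

#' Aggregate repetitions of one sweep cell
#'
#' Synchrony and active-cell counts are averaged over all repetitions;
#' burst frequency and width are averaged only over the repetitions in
#' which repetitive bursting was detected, and reported only when
#' detections form a majority.  Detection counts are flagged: `"all"`
#' (every repetition), `"majority-partial"` (more than half but not all),
#' `"minority"` (at least one but no majority), `"none"`.
#'
#' @param reports `data.frame` of per-repetition rows for one cell (as
#'   produced by [run_sweep_cell()] or [measure_report()]).
#' @return One-row `data.frame` with means, detection counts `k_exc` /
#'   `k_inh` and flags `flag_exc` / `flag_inh`.
#' @export
aggregate_repetitions <- function(reports) {
  stopifnot(nrow(reports) >= 1)
  reps <- nrow(reports)
  agg_pop <- function(suffix) {
    k <- sum(reports[[paste0("bursting_", suffix)]])
    majority <- k > reps / 2
    fmean <- function(col, rows = TRUE) {
      v <- reports[[col]][rows]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    det <- reports[[paste0("bursting_", suffix)]]
    list(S = fmean(paste0("S_", suffix)),
         active = fmean(paste0("active_", suffix)),
         k = k,
         flag = if (k == reps) "all" else if (majority) "majority-partial"
                else if (k > 0) "minority" else "none",
         freq = if (majority) fmean(paste0("burst_freq_", suffix), det)
                else NA_real_,
         width = if (majority) fmean(paste0("burst_width_", suffix), det)
                 else NA_real_)
  }
  e <- agg_pop("exc"); i <- agg_pop("inh")
  data.frame(repetitions = reps,
             S_exc = e$S, S_inh = i$S,
             active_exc = e$active, active_inh = i$active,
             k_exc = e$k, k_inh = i$k,
             flag_exc = e$flag, flag_inh = i$flag,
             burst_freq_exc = e$freq, burst_freq_inh = i$freq,
             burst_width_exc = e$width, burst_width_inh = i$width)
}

#' Run a conductance sweep
#'
#' Simulates every grid cell x cell-type combination x repetition,
#' measures each raster over its final second, and aggregates repetitions
#' with the majority rule.  A failed simulation (numerical blow-up) is
#' recorded for its cell and does not abort the sweep.
#'
#' @param grid a [sweep_grid()].
#' @param progress if `TRUE`, print one line per condition.
#' @return Object of class `sweep_result`: list with `grid`, `per_rep`
#'   (one row per simulation) and `cells` (one aggregated row per grid
#'   cell and combination, including `n_failed`).
#' @export
run_sweep <- function(grid, progress = FALSE) {
  stopifnot(inherits(grid, "sweep_grid"))
  conditions <- expand.grid(ci = seq_along(grid$combos),
                            inter = grid$inter, intra = grid$intra)
  per_rep <- list(); cells <- list()
  for (row in seq_len(nrow(conditions))) {
    combo <- grid$combos[[conditions$ci[row]]]
    inter <- conditions$inter[row]; intra <- conditions$intra[row]
    if (progress)
      message(sprintf("[%d/%d] E:%s I:%s inter=%g intra=%g",
                      row, nrow(conditions), combo[1], combo[2],
                      inter, intra))
    reps <- list(); failed <- 0L
    for (r in seq_len(grid$repetitions)) {
      res <- tryCatch(
        run_sweep_cell(grid, combo, inter, intra, row, r),
        error = function(e) e)
      if (inherits(res, "error")) failed <- failed + 1L
      else reps[[length(reps) + 1L]] <- res
    }
    if (length(reps)) {
      rep_df <- do.call(rbind, reps)
      per_rep[[length(per_rep) + 1L]] <- rep_df
      agg <- aggregate_repetitions(rep_df)
    } else {
      agg <- aggregate_repetitions(
        measure_report(spike_raster(list(numeric(0)), "E", grid$duration)))
      agg[] <- lapply(agg, function(x) x[NA])
    }
    cells[[length(cells) + 1L]] <- cbind(
      data.frame(exc_type = combo[1], inh_type = combo[2],
                 inter = inter, intra = intra, cell_index = row,
                 n_failed = failed), agg)
  }
  structure(list(grid = grid,
                 per_rep = do.call(rbind, per_rep),
                 cells = do.call(rbind, cells)),
            class = "sweep_result")
}

#' Run the I-E ablation experiment
#'
#' Identical to [run_sweep()] except that every network has its I-to-E
#' conductance forced to zero after wiring; seeds are shared with the
#' intact sweep, so for matching grids the ablation is the only
#' difference.
#'
#' @inheritParams run_sweep
#' @return A `sweep_result`.
#' @export
run_ablation <- function(grid, progress = FALSE) {
  grid$ablate_IE <- TRUE
  run_sweep(grid, progress = progress)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", nrow(x$cells), " conditions x ",
      x$grid$repetitions, " repetitions (", x$grid$preset, " preset",
      if (x$grid$ablate_IE) ", I-E ablated", ")\n", sep = "")
  invisible(x)
}

#' Export sweep heatmaps
#'
#' Writes, for each measure x population x cell-type combination, a CSV
#' matrix (rows = inter values, columns = intra values; unreported burst
#' statistics are empty cells) and, when ggplot2 is available, a PNG
#' heatmap with the detection flags overlaid.
#'
#' @param result a [run_sweep()] result.
#' @param dir output directory (created if needed).
#' @param png if `TRUE` and ggplot2 is installed, also write PNG heatmaps.
#' @return Invisibly, the paths written.
#' @export
export_heatmaps <- function(result, dir, png = TRUE) {
  stopifnot(inherits(result, "sweep_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- result$cells
  measures <- c("S", "active", "burst_freq", "burst_width")
  paths <- character(0)
  for (ci in unique(paste(cells$exc_type, cells$inh_type, sep = "-"))) {
    sub <- cells[paste(cells$exc_type, cells$inh_type, sep = "-") == ci, ]
    for (m in measures) for (pop in c("exc", "inh")) {
      col <- paste0(m, "_", pop)
      mat <- matrix(NA_real_, length(result$grid$inter),
                    length(result$grid$intra),
                    dimnames = list(inter = result$grid$inter,
                                    intra = result$grid$intra))
      for (r in seq_len(nrow(sub)))
        mat[as.character(sub$inter[r]), as.character(sub$intra[r])] <-
          sub[[col]][r]
      f <- file.path(dir, sprintf("%s_%s_%s.csv", ci, m, pop))
      utils::write.csv(mat, f, na = "")
      paths <- c(paths, f)
      if (png && requireNamespace("ggplot2", quietly = TRUE)) {
        df <- sub
        df$value <- df[[col]]
        df$flag <- df[[paste0("flag_", pop)]]
        df$intra_f <- factor(df$intra); df$inter_f <- factor(df$inter)
        gg <- ggplot2::ggplot(df, ggplot2::aes(x = intra_f, y = inter_f,
                                               fill = value)) +
          ggplot2::geom_tile() +
          ggplot2::geom_text(ggplot2::aes(label = flag), size = 2.5) +
          ggplot2::labs(x = "I-I (and E-E/4) conductance [mS/cm^2]",
                        y = "E-I and I-E conductance [mS/cm^2]",
                        title = sprintf("%s (%s cells), types %s", m, pop, ci)) +
          ggplot2::scale_fill_viridis_c(na.value = "white")
        pf <- sub("\\.csv$", ".png", f)
        ggplot2::ggsave(pf, gg, width = 5, height = 4, dpi = 120)
        paths <- c(paths, pf)
      }
    }
  }
  invisible(paths)
}
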