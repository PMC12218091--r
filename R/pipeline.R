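# Pipeline: per-recording orchestration, population breakdowns, and
# per-animal group statistics.

#' Analysis configuration for [run_recording()]
#'
#' @param trace a [trace_config()].
#' @param boundaries a [section_boundaries()].
#' @param material a [material_params()].
#' @param shape_modes number of shape modes to fit.
#' @return object of class `flagkin_config`.
#' @export
flagkin_config <- function(trace = trace_config(),
                           boundaries = section_boundaries(),
                           material = material_params(),
                           shape_modes = 2) {
  structure(list(trace = trace, boundaries = boundaries, material = material,
                 shape_modes = shape_modes), class = "flagkin_config")
}

#' Run the full analysis chain on one recording
#'
#' Traces the stack (unless a pre-traced `centerline_series` is supplied),
#' builds the tangent-angle waveform, and computes the kinematic summary,
#' shape-cycle circularity and energetics cycle averages. Stage errors are
#' recorded as QC flags rather than aborting the record; only unreadable
#' input is a hard failure.
#'
#' @param input a `synthetic_scene`, a `centerline_series`, or a path to a
#'   multi-page TIFF.
#' @param config a [flagkin_config()].
#' @param cell_id,animal_id,genotype identifiers carried into the record.
#' @param energetics compute the energetics block (slowest stage).
#' @return object of class `cell_record`.
#' @export
run_recording <- function(input, config = flagkin_config(), cell_id = "cell1",
                          animal_id = NA_character_,
                          genotype = NA_character_, energetics = TRUE) {
  qc <- character(0)
  if (is.character(input)) {
    if (!file.exists(input))
      stop_flagkin(paste("unreadable input:", input), "flagkin_io_error")
    stop_flagkin("raw TIFF paths need pixel_size/origin/fps; wrap with trace_stack()",
                 "flagkin_io_error")
  }
  series <- if (inherits(input, "centerline_series")) input
            else trace_stack(input, config$trace)
  if (!is.null(series$qc) && length(series$qc$failed_frames) > 0)
    qc <- c(qc, sprintf("%d frames failed tracing and were interpolated",
                        length(series$qc$failed_frames)))
  ks <- kinematic_summary(series, config$boundaries)
  if (!is.null(ks$qc)) qc <- c(qc, paste("frequency:", ks$qc))
  circ <- tryCatch({
    w <- to_waveform(series)
    sc <- fit_shape_modes(w, config$shape_modes)
    shape_cycle_circularity(sc)
  }, flagkin_error = function(e) {
    qc <<- c(qc, paste("shape cycle:", conditionMessage(e)))
    NA_real_
  })
  en <- NULL
  if (energetics) {
    en <- tryCatch(
      energetics_profile(series, m = config$material, b = config$boundaries,
                         f = ks$beat_frequency)$averages,
      flagkin_error = function(e) {
        qc <<- c(qc, paste("energetics:", conditionMessage(e)))
        NULL
      })
  }
  structure(list(cell_id = cell_id, animal_id = animal_id,
                 genotype = genotype, kinematics = ks, circularity = circ,
                 energetics = en, qc = qc, series = series),
            class = "cell_record")
}

#' @export
print.cell_record <- function(x, ...) {
  cat(sprintf("Cell record %s (animal %s, genotype %s)\n", x$cell_id,
              x$animal_id, x$genotype))
  print(x$kinematics)
  if (!is.na(x$circularity))
    cat(sprintf("  shape-cycle circularity: %.3f\n", x$circularity))
  if (!is.null(x$energetics))
    cat(sprintf("  P_in %.3g fW, D_m %.3g fW, D_i %.3g fW, D_h %.3g fW\n",
                x$energetics[["P_in"]], x$energetics[["D_m"]],
                x$energetics[["D_i"]], x$energetics[["D_h"]]))
  if (length(x$qc)) cat("  QC:", paste(x$qc, collapse = "; "), "\n")
  invisible(x)
}

#' Population breakdown over flexibility classes
#'
#' @param classes a factor of flexibility classes (from
#'   [classify_flexibility()]), or a list of `cell_record`s.
#' @return named numeric vector of percentages per class plus `stiff`
#'   (moderately + highly stiff combined).
#' @export
population_breakdown <- function(classes) {
  if (is.list(classes) && all(vapply(classes, inherits, TRUE, "cell_record")))
    classes <- vapply(classes, function(r)
      as.character(r$kinematics$flexibility_class), "")
  classes <- factor(classes, levels = FLEX_LEVELS)
  if (length(classes) == 0L || all(is.na(classes)))
    stop_flagkin("empty set: no classified records", "flagkin_empty_error")
  pct <- 100 * as.numeric(table(classes)) / sum(!is.na(classes))
  names(pct) <- FLEX_LEVELS
  c(pct, stiff = pct[["moderately_stiff"]] + pct[["highly_stiff"]])
}

#' Compare a per-cell quantity between two groups by per-animal means
#'
#' Cells are averaged within animal first; the group comparison is an
#' unpaired two-sample Student t-test (equal variance by default) across the
#' animal means, never across pooled cells.
#'
#' @param data data.frame with one row per cell.
#' @param quantity name of the numeric column to compare.
#' @param group name of the two-level grouping column (e.g. genotype).
#' @param animal name of the animal-identifier column.
#' @param welch use the Welch (unequal-variance) test instead of Student's.
#' @return object of class `group_comparison`.
#' @export
compare_groups <- function(data, quantity, group = "genotype",
                           animal = "animal_id", welch = FALSE) {
  stopifnot(is.data.frame(data),
            all(c(quantity, group, animal) %in% names(data)))
  ok <- is.finite(data[[quantity]])
  dropped <- unique(data[[animal]][!ok])
  data <- data[ok, , drop = FALSE]
  agg <- stats::aggregate(data[[quantity]],
                          by = list(group = data[[group]],
                                    animal = data[[animal]]),
                          FUN = mean)
  lev <- unique(agg$group)
  if (length(lev) != 2)
    stop_flagkin("compare_groups needs exactly 2 groups",
                 "flagkin_insufficient_groups")
  m1 <- agg$x[agg$group == lev[1]]
  m2 <- agg$x[agg$group == lev[2]]
  if (length(dropped))
    warning(sprintf("animals excluded (no valid cells): %s",
                    paste(dropped, collapse = ", ")))
  if (length(m1) < 2 || length(m2) < 2)
    stop_flagkin("insufficient groups: need >= 2 animals per group",
                 "flagkin_insufficient_groups")
  tt <- t.test(m1, m2, var.equal = !welch)
  structure(list(groups = as.character(lev),
                 animal_means = list(m1, m2),
                 group_means = c(mean(m1), mean(m2)),
                 group_sd = c(sd(m1), sd(m2)),
                 n_animals = c(length(m1), length(m2)),
                 t = unname(tt$statistic), p = tt$p.value,
                 df = unname(tt$parameter), welch = welch,
                 quantity = quantity),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of %s (%s t-test on animal means)\n",
              x$quantity, ifelse(x$welch, "Welch", "Student")))
  for (i in 1:2)
    cat(sprintf("  %s: %.4g +/- %.4g (n = %d animals)\n", x$groups[i],
                x$group_means[i], x$group_sd[i], x$n_animals[i]))
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Run a sampled population through the render -> trace -> classify chain
#'
#' For each cell of [sample_population()], simulates the ground-truth beat,
#' renders a noisy image stack at the requested SNR, traces it back, measures
#' the midpiece amplitude and classifies flexibility.
#'
#' @param cells list from [sample_population()].
#' @param snr rendering signal-to-noise ratio.
#' @param config a [flagkin_config()].
#' @param seed integer seed for rendering noise.
#' @param progress print a progress line every 100 cells.
#' @return data.frame with one row per cell: true label, target and measured
#'   midpiece amplitude, assigned class, frames traced.
#' @export
classify_population <- function(cells, snr = 10, config = flagkin_config(),
                                seed = 1, progress = FALSE) {
  set.seed(seed)
  rows <- lapply(seq_along(cells), function(i) {
    cell <- cells[[i]]
    if (progress && i %% 100 == 0) message("  cell ", i, "/", length(cells))
    res <- tryCatch({
      series <- simulate_beat(cell$params)
      scene <- render_frames(series, snr = snr, margin_px = 5)
      traced <- trace_stack(scene, config$trace)
      amps <- section_amplitude(traced, config$boundaries)
      cls <- classify_flexibility(amps[["mid"]])
      data.frame(label = as.character(cell$label),
                 target = cell$target_mid_amplitude,
                 measured = amps[["mid"]],
                 class = as.character(cls),
                 frames_ok = if (is.null(traced$qc)) nrow(traced$x)
                             else traced$qc$frames_ok,
                 error = NA_character_)
    }, flagkin_error = function(e)
      data.frame(label = as.character(cell$label),
                 target = cell$target_mid_amplitude, measured = NA_real_,
                 class = NA_character_, frames_ok = 0L,
                 error = conditionMessage(e)))
    res
  })
  do.call(rbind, rows)
}
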