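# Population generator: mixtures over the four midpiece-flexibility
# categories, with per-cell envelope scales solved so the ground-truth
# midpiece amplitude hits a target drawn from the category's interval.

FLEX_LEVELS <- c("highly_flexible", "relatively_flexible",
                 "moderately_stiff", "highly_stiff")

# printed category amplitude ranges (um) used for target sampling
FLEX_RANGES <- list(highly_flexible = c(27, 39),
                    relatively_flexible = c(16, 27),
                    moderately_stiff = c(6, 15),
                    highly_stiff = c(0.6, 6))

#' Population specification over flexibility categories
#'
#' Mixture weights over (highly_flexible, relatively_flexible,
#' moderately_stiff, highly_stiff) and the per-category midpiece-amplitude
#' sampling intervals (uniform over the printed category ranges: 27-39,
#' 16-27, 6-15 and 0.6-6 um).
#'
#' @param weights numeric(4) of category probabilities (will be checked to
#'   sum to 1).
#' @param n_cells number of cells to sample.
#' @param seed integer seed.
#' @param beat_frequency_range Hz range from which each cell's beat frequency
#'   is drawn uniformly.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(weights, n_cells, seed = 1,
                            beat_frequency_range = c(3, 7)) {
  if (length(weights) != 4 || any(weights < 0))
    stop_flagkin("weights must be 4 non-negative probabilities",
                 "flagkin_invalid_parameter")
  if (abs(sum(weights) - 1) > 1e-8)
    stop_flagkin("weights must sum to 1", "flagkin_invalid_parameter")
  names(weights) <- FLEX_LEVELS
  structure(list(weights = weights, ranges = FLEX_RANGES, n_cells = n_cells,
                 seed = seed, beat_frequency_range = beat_frequency_range),
            class = "population_spec")
}

#' Wildtype-like and knockout-like mixture weights
#'
#' Flexibility breakdowns of motile sperm populations: the wildtype-like
#' mixture is 17% highly flexible, 60% relatively flexible, 19% moderately
#' stiff and 4% highly stiff; the knockout-like (rigid-midpiece phenotype)
#' mixture is 0%, 12%, 28% and 60%.
#'
#' @param genotype `"wildtype"` or `"knockout"`.
#' @return numeric(4) of weights in the order of `levels(classify_flexibility(0))`.
#' @export
mixture_weights <- function(genotype = c("wildtype", "knockout")) {
  genotype <- match.arg(genotype)
  w <- if (genotype == "wildtype") c(0.17, 0.60, 0.19, 0.04)
       else c(0.00, 0.12, 0.28, 0.60)
  names(w) <- FLEX_LEVELS
  w
}

# category labels for n cells: iid multinomial draw from the weights, or
# largest-remainder allocation of n*w (order shuffled) for "stratified"
allocate_categories <- function(weights, n, method) {
  if (method == "multinomial") {
    sample(FLEX_LEVELS, n, replace = TRUE, prob = weights)
  } else {
    exact <- weights * n
    counts <- floor(exact)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    sample(rep(FLEX_LEVELS, counts))
  }
}

# ground-truth midpiece amplitude of a beat_params wave, measured with the
# same metric as the analysis chain (full peak-to-peak transverse excursion
# at the midpiece set point)
ground_truth_mid_amplitude <- function(params, b = section_boundaries()) {
  series <- simulate_beat(params)
  amps <- section_amplitude(series, b, smooth_window = 0)
  amps[["mid"]]
}

# solve the envelope scale (bisection) so the midpiece amplitude hits target
solve_envelope_scale <- function(target, envelope_kind, beat_frequency,
                                 duration, fps, phase0 = 0, tol = 0.02,
                                 scale_range = c(0.01, 2.5)) {
  f_of <- function(scale) {
    p <- beat_params(beat_frequency = beat_frequency,
                     envelope_kind = envelope_kind, envelope_scale = scale,
                     phase0 = phase0, duration = duration, fps = fps)
    ground_truth_mid_amplitude(p)
  }
  lo <- scale_range[1]; hi <- scale_range[2]
  a_lo <- f_of(lo); a_hi <- f_of(hi)
  if (target < a_lo || target > a_hi)
    stop_flagkin(sprintf(
      "solver error: midpiece amplitude %.1f um unreachable for '%s' envelope (range %.2f-%.2f um)",
      target, envelope_kind, a_lo, a_hi), "flagkin_solver_error")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    a <- f_of(mid)
    if (abs(a - target) / target < tol) return(mid)
    if (a < target) lo <- mid else hi <- mid
  }
  mid
}

#' Sample a category-labelled population of beat parameters
#'
#' For each cell a flexibility category is drawn from the mixture weights
#' (`method = "multinomial"`), or category counts are allocated by largest
#' remainder (`method = "stratified"`, which removes category-sampling noise
#' and is used for validating the analysis chain against known mixtures). A
#' target midpiece amplitude is then drawn uniformly from the category's
#' interval and the envelope scale is solved by bisection so the ground-truth
#' midpiece amplitude hits the target within `tol`. The two flexible
#' categories use the `"flexible"` envelope family, the two stiff categories
#' the `"stiff-midpiece"` family.
#'
#' @param spec a [population_spec()].
#' @param duration,fps per-cell record length (s) and frame rate; the default
#'   NULL picks two beat cycles sampled at 12 frames per cycle, matched
#'   between the solver and downstream rendering (the peak-to-peak metric is
#'   then consistent between the solve and the traced measurement).
#' @param method `"multinomial"` or `"stratified"` category allocation.
#' @param tol relative amplitude tolerance of the bisection solve.
#' @return list of cells, each a list with `params` (a [beat_params()]),
#'   `label` (category factor), `target_mid_amplitude` (um).
#' @export
sample_population <- function(spec, duration = NULL, fps = NULL,
                              method = c("multinomial", "stratified"),
                              tol = 0.02) {
  stopifnot(inherits(spec, "population_spec"))
  method <- match.arg(method)
  set.seed(spec$seed)
  cats <- allocate_categories(spec$weights, spec$n_cells, method)
  n <- spec$n_cells
  lapply(seq_len(n), function(i) {
    cat_i <- cats[i]
    rng <- spec$ranges[[cat_i]]
    target <- runif(1, rng[1], rng[2])
    f <- runif(1, spec$beat_frequency_range[1], spec$beat_frequency_range[2])
    phase0 <- runif(1, 0, 2 * pi)
    dur <- if (is.null(duration)) 2 / f else duration
    fr <- if (is.null(fps)) 12 * f else fps
    kind <- if (cat_i %in% FLEX_LEVELS[1:2]) "flexible" else "stiff-midpiece"
    scale <- solve_envelope_scale(target, kind, f, dur, fr, phase0, tol = tol)
    params <- beat_params(beat_frequency = f, envelope_kind = kind,
                          envelope_scale = scale, phase0 = phase0,
                          duration = dur, fps = fr)
    list(params = params, label = factor(cat_i, levels = FLEX_LEVELS),
         target_mid_amplitude = target)
  })
}
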