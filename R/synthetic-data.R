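# Synthetic-data generator: microscopy fields, flow-cytometry samples and
# population kinetics with known ground truth. The generator is
# phenomenological: it reproduces the statistical structure the downstream
# analyses assume (a unimodal, right-skewed single-cell intensity
# distribution whose upper tail grows with the induced fraction), not any
# gene-regulatory mechanism.

#' Two-component lognormal intensity mixture
#'
#' Statistical model of a single-cell fluorescence distribution: most cells
#' sit in a baseline lognormal component and a fraction `induced_fraction`
#' in a brighter induced component. With the default parameters the overall
#' distribution stays unimodal and right-skewed, matching the gradual
#' tail enrichment seen in competence reporter strains rather than a
#' bistable two-peak profile.
#'
#' @param baseline_log_mean,baseline_log_sd log10-intensity mean and sd of
#'   the baseline component (`sd > 0`).
#' @param induced_log_mean,induced_log_sd log10-intensity mean and sd of the
#'   induced component; `induced_log_mean > baseline_log_mean`.
#' @param induced_fraction probability in \[0, 1\] that a cell is induced.
#' @return object of class `mixture_model`.
#' @export
mixture_model <- function(baseline_log_mean = 2.0, baseline_log_sd = 0.15,
                          induced_log_mean = 3.0, induced_log_sd = 0.25,
                          induced_fraction = 0) {
  if (!(induced_fraction >= 0 && induced_fraction <= 1)) {
    abort_comphet("mixture_model: induced_fraction must lie in [0, 1]")
  }
  if (!(induced_log_mean > baseline_log_mean)) {
    abort_comphet("mixture_model: induced_log_mean must exceed baseline_log_mean")
  }
  if (!(baseline_log_sd > 0 && induced_log_sd > 0)) {
    abort_comphet("mixture_model: component sds must be positive")
  }
  structure(list(baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 induced_log_mean = induced_log_mean,
                 induced_log_sd = induced_log_sd,
                 induced_fraction = induced_fraction),
            class = "mixture_model")
}

#' Draw single-cell intensities from a mixture model
#'
#' @param model a [mixture_model()].
#' @param n number of cells/events (`n >= 0`).
#' @param seed integer seed; the draw is reproducible.
#' @return data.frame with columns `intensity` (linear fluorescence units,
#'   positive) and `class` (`"baseline"` or `"induced"`).
#' @export
draw_intensities <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "mixture_model"), n >= 0)
  if (n == 0) {
    return(data.frame(intensity = numeric(0), class = character(0)))
  }
  withr::with_seed(seed, {
    induced <- rbinom(n, 1L, model$induced_fraction) == 1L
    logv <- ifelse(induced,
                   rnorm(n, model$induced_log_mean, model$induced_log_sd),
                   rnorm(n, model$baseline_log_mean, model$baseline_log_sd))
    data.frame(intensity = 10^logv,
               class = ifelse(induced, "induced", "baseline"))
  })
}

#' Microscopy field geometry
#'
#' @param width,height field size in pixels.
#' @param cell_radius_mean,cell_radius_sd cell radius distribution (pixels);
#'   cells are circular (the organism is a coccus).
#' @param n_cells number of cells to place.
#' @param background_level camera background (counts).
#' @param background_gradient linear background ramp along x (counts/pixel),
#'   included to exercise per-image normalization.
#' @param bit_depth image bit depth (8 or 16).
#' @return object of class `field_geometry`.
#' @export
field_geometry <- function(width = 512, height = 512,
                           cell_radius_mean = 6, cell_radius_sd = 1,
                           n_cells = 50, background_level = 100,
                           background_gradient = 0, bit_depth = 16) {
  if (width <= 0 || height <= 0) abort_comphet("field_geometry: width and height must be positive")
  if (n_cells < 0) abort_comphet("field_geometry: n_cells must be >= 0")
  if (cell_radius_mean <= 0) abort_comphet("field_geometry: cell radii must be positive")
  if (!bit_depth %in% c(8, 16)) abort_comphet("field_geometry: bit_depth must be 8 or 16")
  structure(list(width = width, height = height,
                 cell_radius_mean = cell_radius_mean,
                 cell_radius_sd = cell_radius_sd, n_cells = n_cells,
                 background_level = background_level,
                 background_gradient = background_gradient,
                 bit_depth = bit_depth),
            class = "field_geometry")
}

#' Camera noise model
#'
#' @param shot_noise if `TRUE`, pixel counts are Poisson draws around the
#'   expected counts.
#' @param read_noise_sd additive Gaussian read noise sd (counts, `>= 0`).
#' @return object of class `noise_model`.
#' @export
noise_model <- function(shot_noise = TRUE, read_noise_sd = 2) {
  if (read_noise_sd < 0) abort_comphet("noise_model: read_noise_sd must be >= 0")
  structure(list(shot_noise = shot_noise, read_noise_sd = read_noise_sd),
            class = "noise_model")
}

#' Render a synthetic microscopy field
#'
#' Places non-overlapping circular cells in the field by rejection sampling
#' (cells are kept at least 3 px apart; imaged cultures are sonicated to
#' disperse aggregates, so overlap is disallowed by default), paints each
#' cell's expected intensity over the background, applies the noise model,
#' and quantizes to the geometry's bit depth.
#'
#' @param geometry a [field_geometry()]; `geometry$n_cells` must equal
#'   `nrow(intensities)`.
#' @param intensities data.frame from [draw_intensities()] (columns
#'   `intensity`, `class`).
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param max_attempts rejection-sampling retry cap per cell.
#' @return list with `image` (integer matrix, rows = y, cols = x), `mask`
#'   (integer label matrix, labels `1..n_cells`, 0 = background) and
#'   `ground_truth` (data.frame: label, class, true_intensity, centroid_x,
#'   centroid_y, radius, area_px; centroids 0-based pixel coordinates).
#' @export
render_field <- function(geometry, intensities, noise = noise_model(),
                         seed = 1L, max_attempts = 5000L) {
  stopifnot(inherits(geometry, "field_geometry"),
            inherits(noise, "noise_model"))
  n <- nrow(intensities)
  if (n != geometry$n_cells) {
    abort_comphet("render_field: length of intensities must equal geometry$n_cells")
  }
  w <- geometry$width; h <- geometry$height
  maxval <- 2^geometry$bit_depth - 1

  withr::with_seed(seed, {
    radii <- if (n > 0) {
      pmax(2, rnorm(n, geometry$cell_radius_mean, geometry$cell_radius_sd))
    } else numeric(0)
    cx <- numeric(n); cy <- numeric(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        x <- runif(1, radii[i] + 2, w - radii[i] - 1)
        y <- runif(1, radii[i] + 2, h - radii[i] - 1)
        if (i == 1 || all(sqrt((cx[seq_len(i - 1)] - x)^2 +
                               (cy[seq_len(i - 1)] - y)^2) >=
                          radii[seq_len(i - 1)] + radii[i] + 3)) {
          cx[i] <- x; cy[i] <- y; placed <- TRUE; break
        }
      }
      if (!placed) {
        abort_comphet(sprintf(
          "render_field: could not place cell %d of %d after %d attempts; cell density too high for a %dx%d field",
          i, n, max_attempts, w, h))
      }
    }

    # expected counts: background (+ optional x-gradient) plus cell signal
    xs <- matrix(rep(seq_len(w) - 1, each = h), nrow = h)
    expected <- matrix(geometry$background_level, nrow = h, ncol = w) +
      geometry$background_gradient * xs
    mask <- matrix(0L, nrow = h, ncol = w)
    for (i in seq_len(n)) {
      x0 <- max(1L, floor(cx[i] - radii[i])); x1 <- min(w, ceiling(cx[i] + radii[i]))
      y0 <- max(1L, floor(cy[i] - radii[i])); y1 <- min(h, ceiling(cy[i] + radii[i]))
      sub_x <- x0:x1; sub_y <- y0:y1
      dx2 <- outer(rep(1, length(sub_y)), (sub_x - 1 - cx[i])^2)
      dy2 <- outer((sub_y - 1 - cy[i])^2, rep(1, length(sub_x)))
      inside <- dx2 + dy2 <= radii[i]^2
      expected[sub_y, sub_x][inside] <-
        expected[sub_y, sub_x][inside] + intensities$intensity[i]
      mask[sub_y, sub_x][inside] <- i
    }
    if (max(expected) > maxval) {
      abort_comphet(sprintf(
        "render_field: expected counts (max %.0f) exceed the %d-bit range; lower intensities or background",
        max(expected), geometry$bit_depth))
    }

    img <- expected
    if (noise$shot_noise) img[] <- rpois(length(img), lambda = expected)
    if (noise$read_noise_sd > 0) {
      img <- img + rnorm(length(img), 0, noise$read_noise_sd)
    }
    img <- matrix(as.integer(pmin(pmax(round(img), 0), maxval)),
                  nrow = h, ncol = w)

    gt <- data.frame(label = seq_len(n),
                     class = if (n > 0) intensities$class else character(0),
                     true_intensity = if (n > 0) intensities$intensity else numeric(0),
                     centroid_x = cx, centroid_y = cy, radius = radii,
                     area_px = vapply(seq_len(n),
                                      function(i) sum(mask == i), numeric(1)))
    list(image = img, mask = mask, ground_truth = gt)
  })
}

#' Simulate a flow-cytometry sample
#'
#' Draws `n_events` single-cell fluorescence values (linear scale, one
#' channel) from the mixture model. The default event count follows the
#' acquisition convention of collecting at least 100,000 events per sample.
#'
#' @param model a [mixture_model()].
#' @param n_events number of events (`> 0`); default 100000.
#' @param seed integer seed.
#' @param strain,timepoint_h metadata tags recorded on the table.
#' @param channel channel name recorded on the table.
#' @return data.frame (one row per event) with column `value`; attributes
#'   `strain`, `timepoint_h`, `channel`, `seed`, `true_induced_fraction`.
#' @export
simulate_fc_sample <- function(model, n_events = 100000L, seed = 1L,
                               strain = "reporter", timepoint_h = 0,
                               channel = "PE-A") {
  if (n_events <= 0) abort_comphet("simulate_fc_sample: n_events must be > 0")
  draws <- draw_intensities(model, n_events, seed = seed)
  tab <- data.frame(value = draws$intensity)
  attr(tab, "strain") <- strain
  attr(tab, "timepoint_h") <- timepoint_h
  attr(tab, "channel") <- channel
  attr(tab, "seed") <- seed
  attr(tab, "true_induced_fraction") <- model$induced_fraction
  attr(tab, "true_class") <- draws$class
  tab
}

#' Logistic growth parameters
#'
#' @param initial_od starting OD600 (`> 0`).
#' @param doubling_time early-exponential doubling time (hours, `> 0`);
#'   about 8 h for slow growth in glutamate minimal medium.
#' @param carrying_capacity saturating OD600 (`>= initial_od`).
#' @return object of class `growth_params`.
#' @export
growth_params <- function(initial_od = 0.2, doubling_time = 8,
                          carrying_capacity = 4) {
  if (initial_od <= 0) abort_comphet("growth_params: initial_od must be > 0")
  if (doubling_time <= 0) abort_comphet("growth_params: doubling_time must be > 0")
  if (carrying_capacity < initial_od) {
    abort_comphet("growth_params: carrying_capacity must be >= initial_od")
  }
  structure(list(initial_od = initial_od, doubling_time = doubling_time,
                 carrying_capacity = carrying_capacity),
            class = "growth_params")
}

#' Simulate logistic culture growth
#'
#' Deterministic logistic solution; in early exponential phase
#' `log2(OD(t)/OD(0)) ~ t / doubling_time`.
#'
#' @param params a [growth_params()].
#' @param times nondecreasing vector of times (hours).
#' @return data.frame with columns `time_h`, `od`.
#' @export
simulate_growth <- function(params, times) {
  stopifnot(inherits(params, "growth_params"))
  if (is.unsorted(times)) abort_comphet("simulate_growth: times must be nondecreasing")
  K <- params$carrying_capacity; n0 <- params$initial_od
  r <- log(2) / params$doubling_time
  od <- if (K == n0) rep(n0, length(times)) else {
    K / (1 + ((K - n0) / n0) * exp(-r * times))
  }
  data.frame(time_h = times, od = od)
}

#' Sigmoidal transformation-frequency trajectory parameters
#'
#' The true TF trajectory is logistic on the log10 scale: it starts at the
#' censoring floor, rises around `onset_time` with maximum log10 slope
#' `max_log_slope`, and saturates at `peak_tf`.
#'
#' @param floor_tf baseline frequency (the censoring floor), `<= peak_tf`.
#' @param peak_tf plateau frequency, `<= 1`.
#' @param onset_time time of steepest rise (hours).
#' @param max_log_slope maximum slope of log10(TF) per hour (`>= 0`).
#' @return object of class `tf_trajectory_params`.
#' @export
tf_trajectory_params <- function(floor_tf = 1e-9, peak_tf = 1e-2,
                                 onset_time = 10, max_log_slope = 0.5) {
  if (!(floor_tf <= peak_tf && peak_tf <= 1)) {
    abort_comphet("tf_trajectory_params: need floor_tf <= peak_tf <= 1")
  }
  if (max_log_slope < 0) abort_comphet("tf_trajectory_params: max_log_slope must be >= 0")
  structure(list(floor_tf = floor_tf, peak_tf = peak_tf,
                 onset_time = onset_time, max_log_slope = max_log_slope),
            class = "tf_trajectory_params")
}

#' True transformation frequencies along a sigmoidal trajectory
#'
#' @param params a [tf_trajectory_params()].
#' @param times vector of times (hours).
#' @return numeric vector of true frequencies.
#' @export
simulate_tf_trajectory <- function(params, times) {
  stopifnot(inherits(params, "tf_trajectory_params"))
  L <- log10(params$peak_tf / params$floor_tf)
  if (L == 0 || params$max_log_slope == 0) {
    return(rep(params$floor_tf, length(times)))
  }
  k <- 4 * params$max_log_slope / L   # logistic max slope = L*k/4
  log_tf <- log10(params$floor_tf) +
    L / (1 + exp(-k * (times - params$onset_time)))
  10^log_tf
}

#' Simulate a plating experiment
#'
#' Selective-plate transformant counts are Poisson with mean
#' `total_cfu * (tf_true + reversion_rate)`; the no-DNA control plate counts
#' are Poisson with mean `total_cfu * reversion_rate`, providing the
#' spontaneous-reversion background that defines the assay detection limit.
#'
#' @param tf_true vector of true transformation frequencies in \[0, 1\].
#' @param times vector of sampling times (hours), same length.
#' @param total_cfu viable cells plated per sample (scalar or vector).
#' @param reversion_rate spontaneous reversion frequency.
#' @param seed integer seed.
#' @param condition condition label recorded per row.
#' @return data.frame of plate counts with columns `condition`, `time_h`,
#'   `selective_cfu`, `total_cfu`, `selective_dilution`, `total_dilution`,
#'   `control_selective_cfu`, `control_total_cfu`.
#' @export
simulate_plating <- function(tf_true, times = seq_along(tf_true),
                             total_cfu = 1e6, reversion_rate = 1e-9,
                             seed = 1L, condition = "default") {
  if (any(tf_true < 0 | tf_true > 1)) {
    abort_comphet("simulate_plating: tf_true must lie in [0, 1]")
  }
  n <- length(tf_true)
  total_cfu <- rep_len(total_cfu, n)
  withr::with_seed(seed, {
    sel <- rpois(n, total_cfu * (tf_true + reversion_rate))
    ctrl <- rpois(n, total_cfu * reversion_rate)
    obs_total <- rpois(n, total_cfu)
    data.frame(condition = condition, time_h = times,
               selective_cfu = sel, total_cfu = obs_total,
               selective_dilution = 1, total_dilution = 1,
               control_selective_cfu = ctrl, control_total_cfu = obs_total)
  })
}

#' Reporter-kinetics parameters
#'
#' @param fourpl list with elements `a`, `d`, `c`, `b`: the true 4PL of
#'   normalized promoter activity (see [fourpl()]).
#' @param substrate_capacity plateau cap on the normalized signal
#'   (fluorogenic substrate is finite, `> 0`).
#' @param decay_rate post-depletion exponential decline (per hour, `>= 0`).
#' @param meas_noise_sd multiplicative measurement noise sd (relative units).
#' @return object of class `reporter_params`.
#' @export
reporter_params <- function(fourpl = list(a = 0.05, d = 1, c = 12, b = 4),
                            substrate_capacity = 0.9, decay_rate = 0,
                            meas_noise_sd = 0.02) {
  if (substrate_capacity <= 0) abort_comphet("reporter_params: substrate_capacity must be > 0")
  if (decay_rate < 0) abort_comphet("reporter_params: decay_rate must be >= 0")
  structure(list(fourpl = fourpl, substrate_capacity = substrate_capacity,
                 decay_rate = decay_rate, meas_noise_sd = meas_noise_sd),
            class = "reporter_params")
}

#' Simulate MUG / Nile Red reporter time series
#'
#' Nile Red fluorescence is proportional to biomass (logistic growth); the
#' true normalized promoter activity follows the 4PL, capped at
#' `substrate_capacity` and declining exponentially afterwards (substrate
#' depletion). Raw MUG is the normalized curve times the Nile Red signal;
#' both channels get multiplicative Gaussian noise.
#'
#' @param params a [reporter_params()].
#' @param times nondecreasing vector of times (hours).
#' @param seed integer seed.
#' @param growth a [growth_params()] for the biomass channel.
#' @param nilered_scale fluorescence counts per OD unit.
#' @return data.frame with columns `time_h`, `mug`, `nilered`,
#'   `true_normalized` (noise-free normalized curve).
#' @export
simulate_reporter <- function(params, times, seed = 1L,
                              growth = growth_params(),
                              nilered_scale = 1000) {
  stopifnot(inherits(params, "reporter_params"))
  if (is.unsorted(times)) abort_comphet("simulate_reporter: times must be nondecreasing")
  p <- params$fourpl
  curve <- fourpl(times, p$a, p$d, p$c, p$b)
  capped <- pmin(curve, params$substrate_capacity)
  if (params$decay_rate > 0 && any(curve >= params$substrate_capacity)) {
    t_cap <- times[min(which(curve >= params$substrate_capacity))]
    post <- times > t_cap
    capped[post] <- params$substrate_capacity *
      exp(-params$decay_rate * (times[post] - t_cap))
  }
  biomass <- simulate_growth(growth, times)$od * nilered_scale
  withr::with_seed(seed, {
    noise1 <- if (params$meas_noise_sd > 0) {
      rnorm(length(times), 1, params$meas_noise_sd)
    } else rep(1, length(times))
    noise2 <- if (params$meas_noise_sd > 0) {
      rnorm(length(times), 1, params$meas_noise_sd)
    } else rep(1, length(times))
    data.frame(time_h = times,
               mug = capped * biomass * noise1,
               nilered = biomass * noise2,
               true_normalized = capped)
  })
}
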