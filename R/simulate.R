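#' Instrument channel-axis profiles
#'
#' Three portable-instrument profiles: `"micronir"` (125 channels,
#' 900-1700 nm), `"mems"` (3108 channels, 1100-2100 nm) and `"raman"`
#' (3122 channels, 175-3200 cm^-1).
#'
#' @param profile profile name.
#' @return List with `axis` (channel positions), `p` and `units`.
#' @export
instrument_profile <- function(profile = c("micronir", "mems", "raman")) {
  profile <- match.arg(profile)
  switch(profile,
    micronir = list(axis = seq(900, 1700, length.out = 125), p = 125L,
                    units = "nm"),
    mems = list(axis = seq(1100, 2100, length.out = 3108), p = 3108L,
                units = "nm"),
    raman = list(axis = seq(175, 3200, length.out = 3122), p = 3122L,
                 units = "cm-1"))
}

#' Define an oil component for the simulator
#'
#' A pure mixture component: its iodine value and the Gaussian bands of
#' its pure spectrum.
#'
#' @param name component name.
#' @param iodine_value iodine value of the pure component
#'   (g I2 / 100 g oil).
#' @param bands data frame with columns `center`, `width`, `amplitude`
#'   (widths and amplitudes positive).
#' @return Object of class `oil_component`.
#' @export
oil_component <- function(name, iodine_value, bands) {
  bands <- as.data.frame(bands)
  stopifnot(all(c("center", "width", "amplitude") %in% names(bands)))
  if (any(bands$width <= 0) || any(bands$amplitude <= 0))
    stop_ss("band widths and amplitudes must be positive")
  structure(list(name = name, iodine_value = as.numeric(iodine_value),
                 bands = bands),
            class = "oil_component")
}

# Band positions by spectral region. NIR: C-H second overtones (1168,
# 1210 nm), C-H combination bands (1392, 1414 nm), C-H first overtones
# (1660 nm / 1726, 1761 nm where the axis reaches them). Raman: the ten
# common oil bands (C=O and C=C stretches, CH2 scissor/twist, =C-H cis
# rocks/bends, C-C stretches).
band_positions <- function(units, axis) {
  pos <- if (units == "nm") c(1168, 1210, 1392, 1414, 1660, 1726, 1761)
         else c(1745, 1655, 1438, 1301, 1266, 1125, 1080, 1068, 970, 868)
  pos[pos >= min(axis) & pos <= max(axis)]
}

#' Default oil components for an instrument profile
#'
#' Four components (soybean, olive, peanut, blend) with iodine values
#' 130, 84, 96 and 108 — spanning the realistic 84-130 range so blend
#' responses fall in roughly 86-126. Each shares the band positions of
#' the profile's spectral region but with distinct per-band amplitudes,
#' making the mixture fractions spectrally identifiable; bands sensitive
#' to C=C unsaturation scale with the component's iodine value.
#'
#' @param profile an [instrument_profile()] name or object.
#' @return List of four [oil_component()] objects.
#' @export
default_components <- function(profile = "micronir") {
  if (is.character(profile)) profile <- instrument_profile(profile)
  pos <- band_positions(profile$units, profile$axis)
  width <- if (profile$units == "nm") 18 else 14
  ivs <- c(soybean = 130, olive = 84, peanut = 96, blend = 108)
  # Fixed per-component amplitude multipliers, cycled over bands.
  mult <- list(soybean = c(1.0, 0.3, 0.8, 0.5, 0.6),
               olive   = c(0.4, 1.0, 0.3, 0.9, 0.5),
               peanut  = c(0.7, 0.5, 1.0, 0.3, 0.9),
               blend   = c(0.5, 0.8, 0.5, 1.0, 0.4))
  lapply(names(ivs), function(nm) {
    amp <- rep_len(mult[[nm]], length(pos)) * (0.4 + 0.6 * ivs[[nm]] / 130)
    oil_component(nm, ivs[[nm]],
                  data.frame(center = pos, width = width, amplitude = amp))
  })
}

#' Simulation configuration for synthetic oil-blend spectra
#'
#' @param n_samples number of blend samples (default 59).
#' @param instrument_profile one of `"micronir"`, `"mems"`, `"raman"`.
#' @param components list of [oil_component()]s (default:
#'   [default_components()] for the profile).
#' @param fraction_ranges matrix with one `(min, max)` row per component,
#'   in `[0, 1]`; the defaults are the mixing-design bounds 0-0.8546,
#'   0-0.6934, 0-0.8835, 0-0.8546.
#' @param noise_sd_spectral SD of the per-channel Gaussian noise
#'   (absorbance units; default 0.005).
#' @param noise_sd_response SD of the response noise (g I2 / 100 g;
#'   default 0.5, a typical titration repeatability).
#' @param baseline_amplitude scale of the smooth polynomial baseline
#'   (default 0.05).
#' @param seed RNG seed for the generator.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 59,
                              instrument_profile = "micronir",
                              components = NULL,
                              fraction_ranges = NULL,
                              noise_sd_spectral = 0.005,
                              noise_sd_response = 0.5,
                              baseline_amplitude = 0.05,
                              seed = 1) {
  prof <- specsel::instrument_profile(instrument_profile)
  if (is.null(components)) components <- default_components(prof)
  if (is.null(fraction_ranges))
    fraction_ranges <- cbind(min = c(0, 0, 0, 0),
                             max = c(0.8546, 0.6934, 0.8835, 0.8546))
  fraction_ranges <- as.matrix(fraction_ranges)
  if (nrow(fraction_ranges) != length(components))
    stop_ss("one (min, max) range per component required")
  if (any(fraction_ranges < 0) || any(fraction_ranges > 1) ||
      any(fraction_ranges[, 1] > fraction_ranges[, 2]))
    stop_ss("fraction ranges must be nested in [0, 1]")
  if (sum(fraction_ranges[, 1]) > 1 || sum(fraction_ranges[, 2]) < 1)
    stop_ss("infeasible fraction ranges: no simplex point satisfies them")
  for (cmp in components)
    if (any(cmp$bands$center < min(prof$axis)) ||
        any(cmp$bands$center > max(prof$axis)))
      stop_ss("component '", cmp$name, "' has bands outside the axis")
  structure(
    list(n_samples = as.integer(n_samples), profile = prof,
         profile_name = if (is.character(instrument_profile))
           instrument_profile else "custom",
         components = components, fraction_ranges = fraction_ranges,
         noise_sd_spectral = noise_sd_spectral,
         noise_sd_response = noise_sd_response,
         baseline_amplitude = baseline_amplitude, seed = seed),
    class = "simulation_config")
}

#' Draw mixture fractions on the simplex
#'
#' Rejection sampling of Dirichlet draws: each accepted row sums to one
#' and lies within every component's `(min, max)` range. The Dirichlet
#' concentration is 0.5, pushing draws toward the simplex boundary the
#' way a deliberately wide mixing design does (single components ranging
#' from 0 up to ~85%).
#'
#' @param config a [simulation_config()] (its `fraction_ranges` and
#'   `n_samples` are used).
#' @param seed RNG seed; defaults to the config seed.
#' @param max_tries rejection budget in batches of `n_samples`.
#' @return `n_samples x n_components` matrix of fractions.
#' @export
sample_fractions <- function(config, seed = config$seed, max_tries = 1000) {
  rng <- config$fraction_ranges
  nc <- nrow(rng)
  n <- config$n_samples
  with_seed(seed, {
    out <- matrix(NA_real_, 0, nc)
    for (try in seq_len(max_tries)) {
      g <- matrix(stats::rgamma(n * nc, shape = 0.5), n, nc)
      f <- g / rowSums(g)
      ok <- apply(f, 1, function(r)
        all(r >= rng[, 1]) && all(r <= rng[, 2]))
      out <- rbind(out, f[ok, , drop = FALSE])
      if (nrow(out) >= n) return(out[seq_len(n), , drop = FALSE])
    }
    stop_ss("rejection budget exceeded; fraction ranges are too tight")
  })
}

pure_spectra <- function(components, axis) {
  t(vapply(components, function(cmp) {
    s <- numeric(length(axis))
    for (b in seq_len(nrow(cmp$bands)))
      s <- s + cmp$bands$amplitude[b] *
        exp(-0.5 * ((axis - cmp$bands$center[b]) / cmp$bands$width[b])^2)
    s
  }, numeric(length(axis))))
}

#' Generate a synthetic oil-blend spectral dataset
#'
#' Each spectrum is the fraction-weighted sum of the pure component
#' spectra (Gaussian bands), plus a smooth fixed baseline (a low-order
#' polynomial with small seeded coefficients, shared by all samples like
#' an instrument background) and i.i.d. Gaussian channel noise. The
#' response is the same fraction-weighted mixture of the component
#' iodine values plus Gaussian noise — exactly the bilinear model PLS
#' assumes, so with both noise SDs at zero PLS recovers the response to
#' numerical precision.
#'
#' @param config a [simulation_config()].
#' @param fractions optional explicit fraction matrix overriding
#'   [sample_fractions()] (rows need not satisfy the ranges; they must
#'   sum to 1).
#' @return List with `dataset` (a [spectral_dataset()]), `truth` (the
#'   truth mask: indices of channels where some pure-component band
#'   contributes more than 1% of the maximum pure intensity),
#'   `fractions` and the additive `baseline` curve.
#' @export
generate_dataset <- function(config, fractions = NULL) {
  prof <- config$profile
  S <- pure_spectra(config$components, prof$axis)
  if (is.null(fractions)) fractions <- sample_fractions(config)
  fractions <- as.matrix(fractions)
  if (any(abs(rowSums(fractions) - 1) > 1e-8))
    stop_ss("fraction rows must sum to 1")
  ivs <- vapply(config$components, `[[`, numeric(1), "iodine_value")
  with_seed(config$seed + 1L, {
    u <- seq(-1, 1, length.out = prof$p)
    cf <- stats::runif(3, -1, 1)
    baseline <- config$baseline_amplitude * (cf[1] + cf[2] * u + cf[3] * u^2)
    n <- nrow(fractions)
    X <- fractions %*% S +
      matrix(baseline, n, prof$p, byrow = TRUE) +
      matrix(stats::rnorm(n * prof$p, 0, config$noise_sd_spectral), n, prof$p)
    y <- as.numeric(fractions %*% ivs) +
      stats::rnorm(n, 0, config$noise_sd_response)
    truth <- which(apply(S, 2, max) > 0.01 * max(S))
    list(dataset = spectral_dataset(X, prof$axis, y,
                                    instrument_label = config$profile_name),
         truth = truth, fractions = fractions, baseline = baseline)
  })
}

#' Overwrite a spectral region with pure noise
#'
#' Emulates a detector region carrying no chemical signal (such as the
#' noisy low-shift end of a portable Raman spectrometer): the channels in
#' `region` are replaced by seeded Gaussian noise and removed from the
#' truth mask.
#'
#' @param ds a [spectral_dataset()].
#' @param truth current truth-mask channel indices.
#' @param region `c(lo, hi)` interval on the channel axis.
#' @param noise_sd SD of the replacement noise.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return List with the modified `dataset` and updated `truth`.
#' @export
plant_uninformative_region <- function(ds, truth, region, noise_sd = 0.01,
                                       seed = NULL) {
  validate_dataset(ds)
  idx <- which(ds$axis >= min(region) & ds$axis <= max(region))
  if (length(idx) == 0) stop_ss("region contains no channels")
  new_truth <- setdiff(truth, idx)
  if (length(new_truth) == 0)
    stop_ss("region would cover every informative channel")
  X <- ds$X
  X[, idx] <- with_seed(seed,
    matrix(stats::rnorm(nrow(X) * length(idx), 0, noise_sd), nrow(X)))
  list(dataset = spectral_dataset(X, ds$axis, ds$y, ds$instrument_label,
                                  ds$sample_ids),
       truth = new_truth)
}

#' Planted sparse-signal benchmark fixture
#'
#' A dataset in which exactly `n_informative` channels carry the
#' response signal and every other channel is pure noise — the fixture
#' used to score the recall of the wavelength-selection methods against
#' a known truth mask. Each planted channel tracks its own independent
#' latent concentration (think of isolated marker bands of independent
#' constituents), and the response is a weighted sum of those
#' concentrations mapped into the iodine-value range; because the
#' latent factors are independent, every planted channel carries
#' information no other channel can substitute, so a perfect selector
#' must retain all of them.
#'
#' Uninformative channels carry structureless baseline variation on a
#' scale clearly smaller than, but not negligible against, the signal
#' channels (default one third of the signal SD) — the regime of real
#' no-absorption regions, and one in which coefficient-magnitude-based
#' selectors remain meaningful, since spectra are centered but not
#' variance-scaled before modelling.
#'
#' @param n samples (default 59).
#' @param p channels (default 125).
#' @param n_informative planted signal channels (default 5, evenly
#'   spread over the axis).
#' @param noise_sd_spectral measurement noise SD added on the signal
#'   channels (default 0.02; the latent concentrations are
#'   Uniform(0, 1), signal SD about 0.29).
#' @param noise_sd_uninformative SD of the structureless variation on
#'   the uninformative channels (default 0.1).
#' @param noise_sd_response response noise SD (default 0.5 g I2/100 g).
#' @param seed RNG seed.
#' @return List with `dataset`, `truth` (the planted channel indices)
#'   and `concentrations` (the n x n_informative latent factors).
#' @export
planted_dataset <- function(n = 59, p = 125, n_informative = 5,
                            noise_sd_spectral = 0.02,
                            noise_sd_uninformative = 0.1,
                            noise_sd_response = 0.5, seed = 1) {
  if (n_informative < 1 || n_informative >= p)
    stop_ss("need 1 <= n_informative < p")
  informative <- as.integer(round(seq(0.1 * p, 0.9 * p,
                                      length.out = n_informative)))
  # Fixed response weights, all of the same order so every planted
  # channel matters; scaled so the realised response sits in the
  # iodine-value range of edible-oil blends.
  w <- rep_len(c(1.0, 0.8, 1.2, 0.9, 1.1), n_informative)
  with_seed(seed + 2L, {
    Z <- matrix(stats::runif(n * n_informative), n, n_informative)
    X <- matrix(stats::rnorm(n * p, 0, noise_sd_uninformative), n, p)
    X[, informative] <- Z +
      matrix(stats::rnorm(n * n_informative, 0, noise_sd_spectral), n)
    y <- 76 + (50 / sum(w)) * as.numeric(Z %*% w) +
      stats::rnorm(n, 0, noise_sd_response)
    axis <- seq(900, 1700, length.out = p)
    list(dataset = spectral_dataset(X, axis, y,
                                    instrument_label = "planted"),
         truth = informative, concentrations = Z)
  })
}
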