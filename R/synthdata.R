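# Seeded generators for EC mass voltammograms, hydrolysis time series and
# single spectra, with ground-truth manifests for pipeline validation.
#
# All stochastic draws derive from one master seed; the caller's RNG state
# is saved and restored around each generator, the seed is recorded in the
# manifest and identical calls are reproducible to the byte.

# scoped seeding: set the seed now, restore the caller's RNG state when the
# calling function exits
scoped_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, envir = envir)
  set.seed(seed)
}

#' Species specification for the generators
#'
#' @param formula Neutral formula of the species.
#' @param base_intensity Intensity (counts) of the monoisotopic sodium
#'   adduct peak at response 1.
#' @param adduct_ratio NH4:Na intensity ratio (> 0). Ammonium adducts of
#'   polyethers measured with ammonium-based modifiers are typically the
#'   more intense; default 3.
#' @param curve Response along the scan axis: `"constant"`, `"rise"`
#'   (sigmoid up, products) or `"fall"` (sigmoid down, precursors).
#' @param midpoint,steepness Sigmoid location and scale in axis units.
#' @param rt Optional retention time (s), carried onto generated peaks so
#'   formula-neutral isomers stay separable.
#' @param label Species name for the manifest.
#' @return A `species_spec` list.
#' @export
species_spec <- function(formula, base_intensity = 1e6, adduct_ratio = 3,
                         curve = c("constant", "rise", "fall"),
                         midpoint = NA_real_, steepness = NA_real_,
                         rt = NA_real_, label = NULL) {
  curve <- match.arg(curve)
  if (adduct_ratio <= 0) stop("adduct_ratio must be positive")
  if (curve != "constant" && (is.na(midpoint) || is.na(steepness)))
    stop("sigmoid curves need midpoint and steepness")
  structure(list(formula = format_formula(formula),
                 base_intensity = base_intensity,
                 adduct_ratio = adduct_ratio, curve = curve,
                 midpoint = midpoint, steepness = steepness, rt = rt,
                 label = if (is.null(label)) format_formula(formula) else label),
            class = "species_spec")
}

response_curve <- function(spec, axis) {
  switch(spec$curve,
         constant = rep(1, length(axis)),
         rise = stats::plogis((axis - spec$midpoint) / spec$steepness),
         fall = 1 - stats::plogis((axis - spec$midpoint) / spec$steepness))
}

#' Measurement noise model
#'
#' @param mz_sigma_ppm Gaussian m/z error in ppm (default 0.7, consistent
#'   with sub-2-ppm TOF mass accuracy).
#' @param intensity_sigma Multiplicative log-normal intensity noise (sd of
#'   log intensity, default 0.05).
#' @param baseline_rate Expected number of random baseline peaks per scan
#'   (Poisson, default 5), uniform in `baseline_mz_range`.
#' @param baseline_mz_range m/z range of baseline peaks.
#' @param baseline_meanlog,baseline_sdlog Log-normal intensity parameters
#'   of baseline peaks.
#' @return A `noise_model` list.
#' @export
noise_model <- function(mz_sigma_ppm = 0.7, intensity_sigma = 0.05,
                        baseline_rate = 5, baseline_mz_range = c(200, 1000),
                        baseline_meanlog = log(300), baseline_sdlog = 1) {
  if (mz_sigma_ppm < 0 || intensity_sigma < 0 || baseline_rate < 0)
    stop("noise parameters must be non-negative")
  structure(list(mz_sigma_ppm = mz_sigma_ppm,
                 intensity_sigma = intensity_sigma,
                 baseline_rate = baseline_rate,
                 baseline_mz_range = baseline_mz_range,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog),
            class = "noise_model")
}

# noisy peaks of one species over the scan axis, both adducts
species_peaks <- function(spec, axis, response, noise, rt_jitter_sd = 0) {
  rows <- list()
  for (a in c("+Na", "+NH4")) {
    true_mz <- adduct_mz(spec$formula, a)
    fac <- if (a == "+NH4") spec$adduct_ratio else 1
    true_int <- spec$base_intensity * fac * response
    n <- length(axis)
    mz <- true_mz * (1 + stats::rnorm(n, 0, noise$mz_sigma_ppm) * 1e-6)
    int <- true_int * exp(stats::rnorm(n, 0, noise$intensity_sigma))
    rt <- if (is.na(spec$rt)) rep(NA_real_, n) else
      spec$rt + stats::rnorm(n, 0, rt_jitter_sd)
    rows[[a]] <- data.frame(axis_value = axis, mz = mz, intensity = int,
                            rt = rt, species = spec$label, adduct = a,
                            true_mz = true_mz, true_intensity = true_int,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

baseline_peaks <- function(axis, noise, with_rt = FALSE) {
  rows <- lapply(axis, function(v) {
    n <- stats::rpois(1, noise$baseline_rate)
    if (!n) return(NULL)
    data.frame(axis_value = v,
               mz = stats::runif(n, noise$baseline_mz_range[1],
                                 noise$baseline_mz_range[2]),
               intensity = stats::rlnorm(n, noise$baseline_meanlog,
                                         noise$baseline_sdlog),
               rt = if (with_rt) stats::runif(n, 40, 200) else NA_real_,
               species = "baseline", adduct = NA_character_,
               true_mz = NA_real_, true_intensity = NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

assemble_series <- function(peakdf, axis_kind, ph = NA_real_,
                            ramp_rate = NA_real_, keep_rt = TRUE) {
  cols <- c("axis_value", "mz", "intensity", if (keep_rt) "rt")
  scan_series(peakdf[, cols, drop = FALSE], axis_kind = axis_kind,
              ph = ph, ramp_rate = ramp_rate)
}

#' Default EC species scenario
#'
#' Monensin A and B as decaying precursors plus the five oxidative TPs seen
#' on a glassy-carbon electrode as rising products, with base intensities
#' graded after their reported intensity classes.
#'
#' @return List of [species_spec()] objects.
#' @export
ec_default_species <- function() {
  list(
    species_spec("C36H62O11", 1e6,  curve = "fall", midpoint = 1.2,
                 steepness = 0.25, label = "MON A"),
    species_spec("C35H60O11", 2e5,  curve = "fall", midpoint = 1.2,
                 steepness = 0.25, label = "MON B"),
    species_spec("C33H56O9",  2e5,  curve = "rise", midpoint = 1.3,
                 steepness = 0.20, label = "TP 1"),
    species_spec("C35H62O10", 1.5e5, curve = "rise", midpoint = 1.4,
                 steepness = 0.25, label = "TP 2"),
    species_spec("C34H58O9",  7e5,  curve = "rise", midpoint = 1.1,
                 steepness = 0.20, label = "TP 3"),
    species_spec("C35H60O9",  4.5e5, curve = "rise", midpoint = 1.2,
                 steepness = 0.20, label = "TP 4"),
    species_spec("C36H64O10", 6.5e5, curve = "rise", midpoint = 1.5,
                 steepness = 0.25, label = "TP 5")
  )
}

#' Generate a synthetic EC mass voltammogram
#'
#' Each species emits its sodium and ammonium adduct peaks at the exact
#' m/z plus Gaussian ppm error, with intensities following its response
#' curve times multiplicative log-normal noise, over a 0-2.5 V potential
#' ramp; Poisson baseline peaks are sprinkled per scan. At least one
#' falling (precursor) species is required.
#'
#' @param species List of [species_spec()]; default [ec_default_species()].
#' @param v_range Potential range (V); must stay within [0, 3.5], the
#'   ceiling of boron-doped diamond electrodes.
#' @param v_step Potential sampling step between MS scans (V).
#' @param scan_rate Ramp rate (V/s), metadata only.
#' @param noise A [noise_model()].
#' @param seed Master seed; every stochastic draw derives from it.
#' @return List with `series` (a `scan_series`) and `manifest` (seed, axis,
#'   per-species truth table and true intensity matrix).
#' @export
generate_voltammogram <- function(species = ec_default_species(),
                                  v_range = c(0, 2.5), v_step = 0.05,
                                  scan_rate = 0.02, noise = noise_model(),
                                  seed = 1L) {
  if (v_range[1] < 0 || v_range[2] > 3.5 || v_range[1] >= v_range[2])
    stop("potential range must lie within [0, 3.5] V")
  if (!any(vapply(species, function(s) s$curve == "fall", logical(1))))
    stop("at least one falling (precursor) species is required")
  axis <- seq(v_range[1], v_range[2], by = v_step)
  scoped_seed(seed)
  truth <- lapply(species, function(sp)
    species_peaks(sp, axis, response_curve(sp, axis), noise))
  peakdf <- rbind(do.call(rbind, truth), baseline_peaks(axis, noise))
  manifest <- list(
    seed = seed, axis = axis, kind = "voltammogram",
    species = do.call(rbind, lapply(species, function(sp) data.frame(
      label = sp$label, formula = sp$formula, curve = sp$curve,
      midpoint = sp$midpoint, steepness = sp$steepness,
      base_intensity = sp$base_intensity, adduct_ratio = sp$adduct_ratio,
      mz_na = adduct_mz(sp$formula, "+Na"),
      mz_nh4 = adduct_mz(sp$formula, "+NH4"),
      stringsAsFactors = FALSE))),
    truth = do.call(rbind, truth))
  list(series = assemble_series(peakdf, "potential", ramp_rate = scan_rate,
                                keep_rt = FALSE),
       manifest = manifest)
}

#' Hydrolysis reaction-network specification
#'
#' Sequential acid-catalyzed hydrolysis of a polyether drug: parent
#' reversibly isomerizes to a spiroketal diastereomer, which opens to the
#' ring-opened isomer, which dehydrates irreversibly. Every rate constant
#' scales with acidity as `([H+]/[H+]_ref)^alpha` relative to the reference
#' pH. Rates are per day at `ref_ph`; defaults are calibrated so that the
#' dehydrated product appears by day 2 at pH 3 but not within 30 days at
#' pH 5, with the ring-opened isomer appearing in between at every pH.
#'
#' @param k_isomerization Parent -> diastereomer (1/day).
#' @param k_reverse Diastereomer -> parent (1/day).
#' @param k_ring_opening Diastereomer -> ring-opened (1/day).
#' @param k_dehydration Ring-opened -> dehydrated (1/day).
#' @param alpha Effective reaction order in [H+] (default 0.7; buffered
#'   general-acid catalysis is typically sub-first-order).
#' @param ref_ph pH at which the rate constants are stated.
#' @return A `kinetic_spec` list.
#' @export
kinetic_spec <- function(k_isomerization = 0.2, k_reverse = 0.3,
                         k_ring_opening = 0.4, k_dehydration = 0.15,
                         alpha = 0.7, ref_ph = 3) {
  ks <- c(k_isomerization, k_reverse, k_ring_opening, k_dehydration)
  if (any(ks < 0)) stop("rate constants must be non-negative")
  structure(list(k_isomerization = k_isomerization, k_reverse = k_reverse,
                 k_ring_opening = k_ring_opening,
                 k_dehydration = k_dehydration, alpha = alpha,
                 ref_ph = ref_ph),
            class = "kinetic_spec")
}

#' Integrate the hydrolysis network
#'
#' First-order concentrations of (parent, diastereomer, ring-opened,
#' dehydrated) at the requested times, starting from unit parent, with all
#' rate constants scaled by `([H+]/[H+]_ref)^alpha` for the given pH.
#'
#' @param kin A [kinetic_spec()].
#' @param ph Solution pH.
#' @param times Times in days (day 0 is prepended internally).
#' @return A matrix with one row per requested time and columns `parent`,
#'   `diastereomer`, `ring_opened`, `dehydrated`; concentrations are
#'   non-negative and conserve total mass to the integrator tolerance.
#' @export
hydrolysis_concentrations <- function(kin, ph, times) {
  scale <- (10^(-ph) / 10^(-kin$ref_ph))^kin$alpha
  k1 <- kin$k_isomerization * scale
  kr <- kin$k_reverse * scale
  k2 <- kin$k_ring_opening * scale
  k3 <- kin$k_dehydration * scale
  deriv <- function(t, y, p) {
    list(c(-k1 * y[1] + kr * y[2],
           k1 * y[1] - (kr + k2) * y[2],
           k2 * y[2] - k3 * y[3],
           k3 * y[3]))
  }
  y0 <- c(parent = 1, diastereomer = 0, ring_opened = 0, dehydrated = 0)
  tt <- sort(unique(c(0, times)))
  sol <- deSolve::lsoda(y0, tt, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  out <- sol[match(times, sol[, "time"]), -1, drop = FALSE]
  if (any(out < -1e-8)) stop("integration produced negative concentrations")
  out[out < 0] <- 0
  rownames(out) <- as.character(times)
  out
}

#' Generate synthetic hydrolysis time series
#'
#' One LC/HRMS-style scan series per pH over the sampling days, with peak
#' intensities proportional to the integrated concentrations. The three
#' formula-neutral isomers (parent, diastereomer, ring-opened) are
#' separated by retention time, as they would be on a reversed-phase
#' column; the dehydrated product has its own formula.
#'
#' @param kin A [kinetic_spec()].
#' @param ph pH values, one series each.
#' @param days Sampling days.
#' @param base_intensity Counts corresponding to unit concentration
#'   (sodium adduct).
#' @param adduct_ratio NH4:Na intensity ratio.
#' @param noise A [noise_model()].
#' @param seed Master seed.
#' @param rt_map Retention times (s) of parent, diastereomer, ring-opened
#'   and dehydrated species.
#' @return List with `series` (named list of `scan_series`, one per pH) and
#'   `manifest` (seed, kinetics, per-pH concentration curves, species
#'   table).
#' @export
generate_hydrolysis_series <- function(kin = kinetic_spec(),
                                       ph = c(3, 4, 5),
                                       days = c(1, 2, 3, 4, 5, 8, 15, 30),
                                       base_intensity = 1e6,
                                       adduct_ratio = 3,
                                       noise = noise_model(),
                                       seed = 1L,
                                       rt_map = c(parent = 162,
                                                  diastereomer = 75,
                                                  ring_opened = 99,
                                                  dehydrated = 86)) {
  scoped_seed(seed)
  specs <- list(
    parent = species_spec("C36H62O11", base_intensity, adduct_ratio,
                          rt = rt_map[["parent"]], label = "MON A"),
    diastereomer = species_spec("C36H62O11", base_intensity, adduct_ratio,
                                rt = rt_map[["diastereomer"]],
                                label = "TP 10"),
    ring_opened = species_spec("C36H62O11", base_intensity, adduct_ratio,
                               rt = rt_map[["ring_opened"]],
                               label = "TP 11"),
    dehydrated = species_spec("C36H60O10", base_intensity, adduct_ratio,
                              rt = rt_map[["dehydrated"]], label = "TP 12"))
  series <- list()
  conc_by_ph <- list()
  for (p in ph) {
    conc <- hydrolysis_concentrations(kin, p, days)
    conc_by_ph[[as.character(p)]] <- conc
    peaks <- do.call(rbind, lapply(names(specs), function(nm)
      species_peaks(specs[[nm]], days, conc[, nm], noise,
                    rt_jitter_sd = 0.5)))
    bl <- baseline_peaks(days, noise, with_rt = TRUE)
    peaks <- rbind(peaks, bl)
    series[[as.character(p)]] <- assemble_series(peaks, "time", ph = p)
  }
  manifest <- list(
    seed = seed, kind = "hydrolysis", days = days, kinetics = unclass(kin),
    species = data.frame(
      role = names(specs),
      label = vapply(specs, `[[`, character(1), "label"),
      formula = vapply(specs, `[[`, character(1), "formula"),
      rt = vapply(specs, `[[`, numeric(1), "rt"),
      mz_na = vapply(specs, function(s) adduct_mz(s$formula, "+Na"),
                     numeric(1)),
      mz_nh4 = vapply(specs, function(s) adduct_mz(s$formula, "+NH4"),
                      numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE),
    concentrations = conc_by_ph)
  list(series = series, manifest = manifest)
}

#' Generate a single synthetic spectrum
#'
#' One scan in which every species contributes full isotope envelopes
#' (from [theoretical_pattern()]) for both adducts, scaled by its base
#' intensity and the NH4:Na ratio, plus random baseline peaks.
#'
#' @param species List of [species_spec()] (curves are ignored; constant
#'   response).
#' @param noise A [noise_model()].
#' @param seed Master seed.
#' @param prune,max_peaks Isotope pattern settings.
#' @return List with `peaks` (data.frame `mz`, `intensity`) and `manifest`
#'   (true envelope table).
#' @export
generate_spectrum <- function(species, noise = noise_model(), seed = 1L,
                              prune = 1e-4, max_peaks = 6L) {
  scoped_seed(seed)
  rows <- lapply(species, function(sp) {
    do.call(rbind, lapply(c("+Na", "+NH4"), function(a) {
      pat <- theoretical_pattern(sp$formula, a, prune = prune,
                                 max_peaks = max_peaks)
      fac <- if (a == "+NH4") sp$adduct_ratio else 1
      data.frame(species = sp$label, adduct = a, true_mz = pat$mass,
                 true_intensity = sp$base_intensity * fac * pat$abundance,
                 stringsAsFactors = FALSE)
    }))
  })
  truth <- do.call(rbind, rows)
  n <- nrow(truth)
  mz <- truth$true_mz * (1 + stats::rnorm(n, 0, noise$mz_sigma_ppm) * 1e-6)
  int <- truth$true_intensity * exp(stats::rnorm(n, 0, noise$intensity_sigma))
  nb <- stats::rpois(1, noise$baseline_rate)
  peaks <- data.frame(
    mz = c(mz, stats::runif(nb, noise$baseline_mz_range[1],
                            noise$baseline_mz_range[2])),
    intensity = c(int, stats::rlnorm(nb, noise$baseline_meanlog,
                                     noise$baseline_sdlog)))
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  list(peaks = peaks, manifest = list(seed = seed, kind = "spectrum",
                                      truth = truth))
}
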