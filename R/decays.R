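# NMR decay curves: pulsed-field-gradient (diffusion) and CPMG (T2)
# generators plus the shared Stejskal-Tanner attenuation kernel.

#' Decay curve container
#'
#' Holds an NMR intensity decay: signal versus gradient strength for
#' pulsed-field-gradient (PFG/DOSY) experiments, or signal versus echo delay
#' for CPMG transverse-relaxation experiments.
#'
#' @param abscissa strictly increasing numeric vector: gradient strength
#'   (T/m, or any consistent unit) for `kind = "pfg"`, echo delay in seconds
#'   for `kind = "cpmg"`. At least 4 points.
#' @param intensity numeric vector of the same length, arbitrary units.
#' @param kind `"pfg"` or `"cpmg"`.
#' @param delta gradient-pulse duration in seconds (PFG only).
#' @param big_delta diffusion time in seconds (PFG only).
#' @return object of class `decay_curve`.
#' @export
decay_curve <- function(abscissa, intensity, kind = c("pfg", "cpmg"),
                        delta = NULL, big_delta = NULL) {
  kind <- match.arg(kind)
  if (length(abscissa) < 4L)
    stop_param("a decay curve needs at least 4 points")
  if (length(intensity) != length(abscissa))
    stop_param("'abscissa' and 'intensity' must have equal length")
  if (any(diff(abscissa) <= 0))
    stop_param("'abscissa' must be strictly increasing")
  if (!all(is.finite(intensity)))
    stop_param("'intensity' contains non-finite values")
  if (kind == "pfg") {
    check_pos(delta %||% stop_param("'delta' is required for PFG curves"),
              "delta")
    check_pos(big_delta %||% stop_param("'big_delta' is required for PFG curves"),
              "big_delta")
  }
  structure(list(abscissa = as.numeric(abscissa),
                 intensity = as.numeric(intensity),
                 kind = kind, delta = delta, big_delta = big_delta),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("<decay_curve:%s> %d points, abscissa %.4g..%.4g\n",
              x$kind, length(x$abscissa), min(x$abscissa), max(x$abscissa)))
  invisible(x)
}

#' Stejskal-Tanner attenuation kernel
#'
#' The exponent multiplying `-D` in the PFG attenuation law
#' `I(g) = I0 exp(-D k(g))`, with
#' `k(g) = sigma gamma^2 g^2 delta^2 (Delta - delta/3)`.
#'
#' @param g gradient strength (T/m or consistent unit).
#' @param delta gradient-pulse duration, s.
#' @param big_delta diffusion time, s.
#' @param sigma gradient shape factor; default `(2/pi)^2` for half-sine
#'   bipolar pulses. Irrelevant to radius ratios: internal referencing
#'   cancels it.
#' @param gamma gyromagnetic ratio, rad/(s T); default 1H.
#' @return numeric vector, s/m^2 when `g` is in T/m.
#' @export
st_kernel <- function(g, delta, big_delta, sigma = (2 / pi)^2,
                      gamma = 2.6752218744e8) {
  sigma * gamma^2 * g^2 * delta^2 * (big_delta - delta / 3)
}

#' Default DOSY gradient ramp
#'
#' Logarithmic ramp from 3 to 86 percent of the maximum gradient in 60 steps,
#' the acquisition scheme the package's PFG generator emulates.
#'
#' @param g_max maximum gradient strength, T/m.
#' @param n number of steps.
#' @return increasing numeric vector of gradient strengths.
#' @export
dosy_gradients <- function(g_max = 0.5, n = 60) {
  exp(seq(log(0.03 * g_max), log(0.86 * g_max), length.out = n))
}

#' Generate a synthetic PFG (DOSY) decay
#'
#' `I(g) = I0 exp(-D k(g))` with the [st_kernel()] attenuation factor and
#' multiplicative Gaussian noise (relative standard deviation `noise_sd`).
#' Ground truth is recorded in `attr(x, "ground_truth")`.
#'
#' @param D diffusion coefficient, m^2/s (must be > 0).
#' @param gradients increasing gradient strengths; default [dosy_gradients()].
#' @param delta gradient-pulse duration, s (default 5 ms).
#' @param big_delta diffusion time, s (default 100 ms).
#' @param noise_sd relative (multiplicative) noise level; 0 for noiseless.
#' @param I0 zero-gradient intensity.
#' @param seed integer seed.
#' @param sigma,gamma see [st_kernel()].
#' @return a [decay_curve()] of kind `"pfg"`.
#' @export
gen_pfg_decay <- function(D, gradients = dosy_gradients(), delta = 0.005,
                          big_delta = 0.1, noise_sd = 0, I0 = 1, seed = 1,
                          sigma = (2 / pi)^2, gamma = 2.6752218744e8) {
  check_pos(D, "D")
  check_pos(I0, "I0")
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  k <- st_kernel(gradients, delta, big_delta, sigma, gamma)
  signal <- I0 * exp(-D * k)
  if (noise_sd > 0)
    signal <- with_seed(seed,
      signal * (1 + stats::rnorm(length(signal), sd = noise_sd)))
  out <- decay_curve(gradients, signal, "pfg", delta = delta,
                     big_delta = big_delta)
  attr(out, "ground_truth") <- list(D = D, I0 = I0, noise_sd = noise_sd,
                                    sigma = sigma, gamma = gamma, seed = seed)
  out
}

#' Default CPMG delay schedule
#'
#' Fifteen echo delays spaced logarithmically up to a maximum interval, the
#' schedule used for transverse-relaxation series (e.g. a 1.2 s maximum for a
#' slowly relaxing peptide-lipid complex).
#'
#' @param t_max maximum delay, s.
#' @param n number of delays.
#' @param t_min minimum delay, s.
#' @return increasing numeric vector of delays in seconds.
#' @export
cpmg_delays <- function(t_max = 1.2, n = 15, t_min = t_max / 100) {
  exp(seq(log(t_min), log(t_max), length.out = n))
}

#' Generate a synthetic CPMG relaxation decay
#'
#' `I(t) = I0 exp(-t/T2)` with multiplicative Gaussian noise; ground truth in
#' `attr(x, "ground_truth")`.
#'
#' @param T2 transverse relaxation time, s (> 0).
#' @param delays increasing echo delays, s; default [cpmg_delays()].
#' @param I0 zero-delay intensity.
#' @param noise_sd relative noise level.
#' @param seed integer seed.
#' @return a [decay_curve()] of kind `"cpmg"`.
#' @export
gen_cpmg_decay <- function(T2, delays = cpmg_delays(), I0 = 1, noise_sd = 0,
                           seed = 1) {
  check_pos(T2, "T2")
  check_pos(I0, "I0")
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  signal <- I0 * exp(-delays / T2)
  if (noise_sd > 0)
    signal <- with_seed(seed,
      signal * (1 + stats::rnorm(length(signal), sd = noise_sd)))
  out <- decay_curve(delays, signal, "cpmg")
  attr(out, "ground_truth") <- list(T2 = T2, I0 = I0, noise_sd = noise_sd,
                                    seed = seed)
  out
}

#' Generate a synthetic NMR peak-area table
#'
#' Emulates the 1D peak-area measurement behind a ligand:peptide binding
#' stoichiometry: integrated areas of well-resolved regions satisfy
#' `area_ligand / protons_ligand = stoich * area_peptide / protons_peptide`
#' up to optional multiplicative noise.
#'
#' @param stoich ligand molecules per peptide molecule (> 0).
#' @param protons_peptide protons contributing to each peptide region.
#' @param protons_ligand protons contributing to each ligand region.
#' @param n_regions number of (peptide, ligand) region pairs.
#' @param peptide_area base integrated area of the peptide regions.
#' @param noise_sd relative noise on areas; 0 for exact.
#' @param seed integer seed.
#' @return data frame of class `peak_table` with columns `species`, `region`,
#'   `area`, `protons_per_molecule`.
#' @seealso [stoichiometry_from_peaks()]
#' @export
gen_peak_table <- function(stoich, protons_peptide = 3, protons_ligand = 2,
                           n_regions = 2, peptide_area = 100,
                           noise_sd = 0, seed = 1) {
  check_pos(stoich, "stoich")
  check_count(protons_peptide, "protons_peptide")
  check_count(protons_ligand, "protons_ligand")
  check_count(n_regions, "n_regions")
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  area_pep <- rep(peptide_area, n_regions)
  area_lig <- stoich * area_pep / protons_peptide * protons_ligand
  tab <- data.frame(
    species = rep(c("peptide", "ligand"), each = n_regions),
    region = c(paste0("pep_", seq_len(n_regions)),
               paste0("lig_", seq_len(n_regions))),
    area = c(area_pep, area_lig),
    protons_per_molecule = rep(c(protons_peptide, protons_ligand),
                               each = n_regions),
    stringsAsFactors = FALSE)
  if (noise_sd > 0)
    tab$area <- with_seed(seed,
      tab$area * (1 + stats::rnorm(nrow(tab), sd = noise_sd)))
  class(tab) <- c("peak_table", "data.frame")
  attr(tab, "ground_truth") <- list(stoich = stoich, noise_sd = noise_sd,
                                    seed = seed)
  tab
}
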