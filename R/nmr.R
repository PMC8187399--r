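# Diffusion / relaxation fitting, hydrodynamic radii, stoichiometry,
# SE-HPLC calibration and mean residue ellipticity.

#' Fit the Stejskal-Tanner attenuation law to a PFG decay
#'
#' Nonlinear least squares of
#' `I(g) = I0 * sum_j f_j exp(-D_j k(g))` with `k(g)` the [st_kernel()]
#' attenuation factor. The one-component fit is seeded from the log-linear
#' regression of `log I` on `k`; the two-component fit is started from the
#' one-component solution split by three log-spaced D ratios and the best
#' residual is kept. Components are reported in decreasing D with fractions
#' summing to 1.
#'
#' @param decay a `decay_curve` of kind `"pfg"` (with `delta`, `big_delta`).
#' @param n_components 1 or 2 discrete diffusing components.
#' @param sigma,gamma attenuation-kernel constants; must match those used at
#'   acquisition/generation. See [st_kernel()].
#' @return object of class `diffusion_fit`: `D` (length `n_components`,
#'   decreasing), `fractions`, `I0`, `residual` (RSS), `n_components`,
#'   `converged`.
#' @export
fit_stejskal_tanner <- function(decay, n_components = 1,
                                sigma = (2 / pi)^2,
                                gamma = 2.6752218744e8) {
  stopifnot(inherits(decay, "decay_curve"))
  if (decay$kind != "pfg")
    stop_param("'decay' must be a PFG curve (kind 'pfg')")
  n_components <- check_count(n_components, "n_components")
  if (n_components > 2L)
    stop_param("only 1 or 2 diffusing components are supported")
  k <- st_kernel(decay$abscissa, decay$delta, decay$big_delta, sigma, gamma)
  I <- decay$intensity
  if (any(I <= 0))
    stop_param("non-positive intensities cannot be fit on this decay")
  lin <- stats::lm(log(I) ~ k)
  D0 <- max(-stats::coef(lin)[[2]], 1e-16)
  I00 <- exp(stats::coef(lin)[[1]])
  df <- data.frame(I = I, k = k)
  if (n_components == 1L) {
    fit <- minpack.lm::nlsLM(
      I ~ I0 * exp(-D * k), data = df,
      start = list(I0 = I00, D = D0),
      lower = c(0, 0), control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    return(structure(list(D = unname(cf["D"]), fractions = 1,
                          I0 = unname(cf["I0"]),
                          residual = sum(stats::resid(fit)^2),
                          n_components = 1L, converged = TRUE),
                     class = "diffusion_fit"))
  }
  best <- NULL
  for (ratio in c(3, 10, 30)) {  # log-spaced starts around the 1-comp D
    st <- list(I0 = I00, f = 0.5,
               D1 = D0 * sqrt(ratio), D2 = D0 / sqrt(ratio))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        I ~ I0 * (f * exp(-D1 * k) + (1 - f) * exp(-D2 * k)), data = df,
        start = st, lower = c(0, 0, 0, 0), upper = c(Inf, 1, Inf, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop_param("two-component Stejskal-Tanner fit did not converge")
  cf <- stats::coef(best$fit)
  D <- c(cf[["D1"]], cf[["D2"]])
  fr <- c(cf[["f"]], 1 - cf[["f"]])
  ord <- order(-D)
  structure(list(D = D[ord], fractions = fr[ord], I0 = cf[["I0"]],
                 residual = best$rss, n_components = 2L, converged = TRUE),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> %d component(s)\n", x$n_components))
  for (j in seq_along(x$D))
    cat(sprintf("  D%d = %.4g (fraction %.3f)\n", j, x$D[j], x$fractions[j]))
  cat(sprintf("  I0 = %.4g, RSS = %.3g\n", x$I0, x$residual))
  invisible(x)
}

#' Hydrodynamic radius by internal referencing
#'
#' Stokes-Einstein ratio against an internal reference measured in the same
#' run (so temperature, viscosity and the gradient calibration cancel):
#' `R_H = rh_reference * D_reference / D_solute`. The conventional internal
#' reference is 1,4-dioxane with `R_H = 2.12` Angstrom.
#'
#' @param d_solute solute diffusion coefficient (any unit, same as
#'   `d_reference`).
#' @param d_reference reference diffusion coefficient.
#' @param rh_reference reference hydrodynamic radius, Angstrom (default
#'   2.12).
#' @return hydrodynamic radius in Angstrom (full precision; see
#'   [round_rh()] for the reporting convention).
#' @examples
#' hydrodynamic_radius(2.162, 14.10)  # ~13.83 Angstrom
#' @export
hydrodynamic_radius <- function(d_solute, d_reference, rh_reference = 2.12) {
  check_pos(d_solute, "d_solute")
  check_pos(d_reference, "d_reference")
  check_pos(rh_reference, "rh_reference")
  rh_reference * d_reference / d_solute
}

#' Reporting convention for hydrodynamic radii
#'
#' Two decimals up to 20 Angstrom, one decimal above (the convention of the
#' package's reference tables). Full precision should be kept internally.
#'
#' @param rh radius in Angstrom.
#' @return rounded radius.
#' @export
round_rh <- function(rh) {
  ifelse(rh <= 20, round(rh, 2), round(rh, 1))
}

#' Fit a monoexponential CPMG relaxation decay
#'
#' Least-squares fit of `I(t) = I0 exp(-t / T2)`, seeded from the log-linear
#' regression. Degenerate decays (no attenuation across the sampled delays,
#' i.e. effectively infinite T2) are an error, not a number.
#'
#' @param decay a `decay_curve` of kind `"cpmg"`.
#' @return object of class `relaxation_fit`: `T2` (s), `R2` (`1/T2`, 1/s),
#'   `I0`, `residual`, `well_conditioned` (TRUE when the sampled delays
#'   extend to at least the fitted T2).
#' @export
fit_t2 <- function(decay) {
  stopifnot(inherits(decay, "decay_curve"))
  if (decay$kind != "cpmg")
    stop_param("'decay' must be a CPMG curve (kind 'cpmg')")
  t <- decay$abscissa; I <- decay$intensity
  if (any(I <= 0))
    stop_param("non-positive intensities cannot be fit on this decay")
  lin <- stats::lm(log(I) ~ t)
  slope <- stats::coef(lin)[[2]]
  if (slope >= -1e-12)
    stop_param("decay shows no attenuation over the sampled delays (T2 not identifiable)")
  df <- data.frame(I = I, t = t)
  fit <- minpack.lm::nlsLM(
    I ~ I0 * exp(-t / T2), data = df,
    start = list(I0 = exp(stats::coef(lin)[[1]]), T2 = -1 / slope),
    lower = c(0, 1e-12), control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  T2 <- unname(cf["T2"])
  structure(list(T2 = T2, R2 = 1 / T2, I0 = unname(cf["I0"]),
                 residual = sum(stats::resid(fit)^2),
                 well_conditioned = max(t) >= T2),
            class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf("<relaxation_fit> T2 = %.4g s (R2 = %.4g 1/s), I0 = %.4g%s\n",
              x$T2, x$R2, x$I0,
              if (x$well_conditioned) "" else " [delays < T2: poorly conditioned]"))
  invisible(x)
}

#' Binding stoichiometry from NMR peak areas
#'
#' Each peak area is normalised by the proton count behind it; the
#' stoichiometry is the ratio of normalised ligand to normalised peptide
#' areas, averaged over all (ligand region, peptide region) pairs.
#'
#' @param peaks a `peak_table` (see [gen_peak_table()]) or data frame with
#'   columns `species` (`"peptide"`/`"ligand"`), `area`,
#'   `protons_per_molecule`.
#' @return scalar ligand:peptide stoichiometry.
#' @export
stoichiometry_from_peaks <- function(peaks) {
  need <- c("species", "area", "protons_per_molecule")
  if (!is.data.frame(peaks) || !all(need %in% names(peaks)))
    stop_param("'peaks' must have columns %s", paste(need, collapse = ", "))
  if (any(peaks$area < 0)) stop_param("peak areas must be >= 0")
  if (any(peaks$protons_per_molecule < 1))
    stop_param("protons_per_molecule must be >= 1")
  pep <- peaks[peaks$species == "peptide", ]
  lig <- peaks[peaks$species == "ligand", ]
  if (nrow(pep) == 0L || nrow(lig) == 0L)
    stop_param("need at least one peptide and one ligand row")
  norm_pep <- pep$area / pep$protons_per_molecule
  if (any(norm_pep == 0)) stop_param("zero peptide peak area")
  norm_lig <- lig$area / lig$protons_per_molecule
  mean(outer(norm_lig, norm_pep, "/"))
}

#' Calibrate a size-exclusion HPLC column
#'
#' Linear fit of `log10(R_H)` on elution volume over a set of standards. The
#' linearity of such calibrations is lost beyond about 3.8 mL of elution
#' volume, so the model's validity range is capped there and predictions
#' outside it are flagged as extrapolations.
#'
#' @param standards data frame with columns `rh` (Angstrom) and `volume`
#'   (mL); at least 3 standards inside the validity range.
#' @param max_volume linearity bound, mL (default 3.8).
#' @return object of class `sehplc_calibration`: `slope`, `intercept` (of
#'   `log10(rh) ~ volume`), `validity` (mL range).
#' @export
calibrate_sehplc <- function(standards, max_volume = 3.8) {
  need <- c("rh", "volume")
  if (!is.data.frame(standards) || !all(need %in% names(standards)))
    stop_param("'standards' must have columns rh, volume")
  if (nrow(standards) < 3L)
    stop_param("at least 3 calibration standards are required")
  if (any(standards$volume > max_volume))
    stop_param("calibration standards beyond the %.1f mL linearity bound",
               max_volume)
  if (any(standards$rh <= 0)) stop_param("standard radii must be positive")
  fit <- stats::lm(log10(rh) ~ volume, data = standards)
  structure(list(slope = stats::coef(fit)[[2]],
                 intercept = stats::coef(fit)[[1]],
                 validity = c(min(standards$volume),
                              min(max_volume, max(standards$volume)))),
            class = "sehplc_calibration")
}

#' Predict a hydrodynamic radius from an SE-HPLC calibration
#'
#' @param model a [calibrate_sehplc()] fit.
#' @param volume elution volume, mL.
#' @return radius in Angstrom, with attribute `extrapolated` set `TRUE` (and
#'   a warning raised) when `volume` lies outside the calibration's validity
#'   range.
#' @export
sehplc_rh <- function(model, volume) {
  stopifnot(inherits(model, "sehplc_calibration"))
  extrap <- volume < model$validity[1] | volume > model$validity[2]
  if (any(extrap))
    warning(sprintf(
      "elution volume outside the calibrated range [%.2f, %.2f] mL: extrapolated",
      model$validity[1], model$validity[2]), call. = FALSE)
  out <- 10^(model$intercept + model$slope * volume)
  attr(out, "extrapolated") <- extrap
  out
}

#' Mean residue ellipticity from an observed CD spectrum
#'
#' `[theta] = theta_obs(mdeg) * MRW / (10 * path(cm) * conc(mg/mL))` in
#' deg cm^2/dmol, with MRW the mean residue weight (molecular weight per
#' peptide bond).
#'
#' @param theta_obs observed ellipticity in millidegrees: numeric vector, or
#'   data frame with columns `wavelength` and `theta`.
#' @param conc concentration, mg/mL (> 0).
#' @param path cuvette path length, cm (> 0).
#' @param mrw mean residue weight, g/mol per residue.
#' @return same shape as the input with ellipticities replaced by MRE; data
#'   frame input gains an `mre` column (class `ellipticity_spectrum`).
#' @export
mean_residue_ellipticity <- function(theta_obs, conc, path, mrw) {
  check_pos(conc, "conc")
  check_pos(path, "path")
  check_pos(mrw, "mrw")
  scale <- mrw / (10 * path * conc)
  if (is.data.frame(theta_obs)) {
    if (!all(c("wavelength", "theta") %in% names(theta_obs)))
      stop_param("spectrum data frame needs columns wavelength, theta")
    out <- theta_obs
    out$mre <- out$theta * scale
    class(out) <- c("ellipticity_spectrum", "data.frame")
    return(out)
  }
  theta_obs * scale
}
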