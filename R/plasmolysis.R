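## Tip-localized plasmolytic retraction: forward model, synthetic-curve
## generator, and least-squares recovery of the osmotic permeability and
## osmotic-zone length from retraction time courses.

#' Forward model of plasmolytic retraction
#'
#' When a growing tube is stepped into hypertonic medium, water leaves only
#' through the permeable apical zone and the cytoplasm retracts from the
#' tip. Because wall that the membrane has already left contributes no
#' further efflux (the unstirred layer behind the retracting membrane has
#' effectively zero osmotic permeability), the permeable contact area
#' shrinks as the retraction front passes down the zone:
#' \deqn{P_{os} \Delta\Pi \cdot 2\pi r (l - x) = \pi r^2 \, dx/dt,}
#' whose solution is the saturating curve
#' \deqn{x(t) = l\,(1 - e^{-kt}), \qquad k = 2 P_{os} \Delta\Pi / r.}
#' The plateau `l` is the length of the permeable zone (`L_perm`); the rate
#' constant carries the permeability.
#'
#' @param P_os_bar Osmotic permeability, um MPa^-1 s^-1.
#' @param dPi Osmotic step driving efflux, MPa (e.g. 0.5 Osm sucrose at
#'   298.15 K gives 1.239 MPa).
#' @param r Tube radius, um.
#' @param l Osmotic-zone (retraction) length, um.
#' @param t Time(s), s.
#' @return Retraction x(t), um.
#' @examples
#' retraction_forward(0.0936, vant_hoff_pressure(0.5), 8, 20, c(0, 50, 100))
#' @export
retraction_forward <- function(P_os_bar, dPi, r, l, t) {
  stopifnot(P_os_bar > 0, dPi > 0, r > 0, l > 0, all(t >= 0))
  k <- 2 * P_os_bar * dPi / r
  l * (1 - exp(-k * t))
}

#' Generate a synthetic retraction curve
#'
#' Forward model plus seeded additive Gaussian measurement noise; a
#' synthetic stand-in for digitized plasmolysis video tracks.
#'
#' @param P_os Generating permeability: either concentration form (cm/s,
#'   the default interpretation when `P_os < 0.01`) or pressure form
#'   (um MPa^-1 s^-1) via `P_os_bar`.
#' @param P_os_bar Pressure-form permeability; overrides `P_os`.
#' @param l Generating zone length, um.
#' @param r Tube radius, um.
#' @param dPi Osmotic step, MPa.
#' @param times Sampling times, s.
#' @param noise_sd Measurement noise SD, um.
#' @param seed RNG seed (curves are reproducible per seed).
#' @param temperature K, for the permeability conversion.
#' @return A `retraction_curve`: data frame (`t`, `x`) with the known inputs
#'   and generating truth attached as attributes.
#' @export
synth_retraction <- function(P_os = 1.32e-3, P_os_bar = NULL, l = 20,
                             r = 8, dPi = vant_hoff_pressure(0.5),
                             times = seq(0, 300, by = 10),
                             noise_sd = 0.5, seed = 1,
                             temperature = 298.15) {
  stopifnot(noise_sd >= 0)
  if (is.null(P_os_bar)) P_os_bar <- pos_cm_to_bar(P_os, temperature)
  x <- retraction_forward(P_os_bar, dPi, r, l, times)
  if (noise_sd > 0) {
    x <- withr::with_seed(seed, x + stats::rnorm(length(times), 0, noise_sd))
  }
  curve <- data.frame(t = times, x = x)
  structure(curve,
            class = c("retraction_curve", "data.frame"),
            r = r, dPi = dPi, seed = seed, noise_sd = noise_sd,
            truth = list(P_os_bar = P_os_bar,
                         P_os_cm = pos_bar_to_cm(P_os_bar, temperature),
                         l = l),
            temperature = temperature)
}

#' Construct a retraction curve from measured data
#'
#' @param t Times, s.
#' @param x Retraction, um.
#' @param r Tube radius, um.
#' @param dPi Osmotic step, MPa.
#' @param temperature K.
#' @return A `retraction_curve`.
#' @export
retraction_curve <- function(t, x, r, dPi, temperature = 298.15) {
  stopifnot(length(t) == length(x), all(diff(t) > 0), t[1] >= 0)
  structure(data.frame(t = t, x = x),
            class = c("retraction_curve", "data.frame"),
            r = r, dPi = dPi, seed = NA, noise_sd = NA, truth = NULL,
            temperature = temperature)
}

#' Fit the retraction model to a curve
#'
#' Nonlinear least squares of `x ~ l * (1 - exp(-k*t))` over `(l, k)`
#' (Levenberg-Marquardt), reporting the osmotic permeability in both unit
#' forms (from `k = 2 P_os dPi / r`) and the zone length, with the residual
#' norm and a convergence flag. Initial values: `l0` is 1.1x the largest
#' observed retraction; `k0` comes from the mean slope of the first fifth
#' of the curve. When the curve is much shorter than `1/k` the plateau is
#' weakly identified; the fit is flagged via the relative standard error of
#' `l` (`l_rse`).
#'
#' @param curve A `retraction_curve` (needs at least 5 points and known
#'   radius and osmotic step).
#' @return A list: `P_os_bar`, `P_os_cm`, `l`, `k`, `residual_norm`,
#'   `converged`, `l_rse`, and the `fit` object.
#' @export
fit_retraction <- function(curve) {
  stopifnot(inherits(curve, "retraction_curve"))
  if (nrow(curve) < 5)
    stop("need at least 5 time points to fit", call. = FALSE)
  r <- attr(curve, "r")
  dPi <- attr(curve, "dPi")
  temperature <- attr(curve, "temperature")
  d <- as.data.frame(curve)

  l0 <- max(d$x) * 1.1
  early <- d[d$t <= stats::quantile(d$t, 0.2) | seq_len(nrow(d)) <= 3, ]
  slope0 <- stats::coef(stats::lm(x ~ t, data = early))[["t"]]
  k0 <- max(slope0 / l0, 1e-4)

  fit <- try(minpack.lm::nlsLM(x ~ l * (1 - exp(-k * t)), data = d,
                               start = list(l = l0, k = k0),
                               lower = c(l = 1e-6, k = 1e-8),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(P_os_bar = NA_real_, P_os_cm = NA_real_, l = NA_real_,
                k = NA_real_, residual_norm = NA_real_, converged = FALSE,
                l_rse = NA_real_, fit = NULL))
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(l = NA_real_, k = NA_real_))
  P_os_bar <- co[["k"]] * r / (2 * dPi)
  list(P_os_bar = P_os_bar,
       P_os_cm = pos_bar_to_cm(P_os_bar, temperature),
       l = co[["l"]], k = co[["k"]],
       residual_norm = sqrt(sum(stats::residuals(fit)^2)),
       converged = fit$convInfo$isConv,
       l_rse = unname(se[["l"]] / co[["l"]]),
       fit = fit)
}

#' Read/write retraction curves as CSV with a JSON sidecar
#'
#' The CSV holds two columns (`time_s`, `retraction_um`); the sidecar
#' (`<path>.json`) records the radius, osmotic step, seed and, for
#' synthetic curves, the generating truth.
#'
#' @param curve A `retraction_curve`.
#' @param path CSV path.
#' @export
write_retraction <- function(curve, path) {
  stopifnot(inherits(curve, "retraction_curve"))
  d <- data.frame(time_s = curve$t, retraction_um = curve$x)
  utils::write.csv(d, path, row.names = FALSE)
  meta <- list(r_um = attr(curve, "r"), dPi_MPa = attr(curve, "dPi"),
               temperature_K = attr(curve, "temperature"),
               seed = attr(curve, "seed"),
               noise_sd_um = attr(curve, "noise_sd"),
               truth = attr(curve, "truth"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_retraction
#' @export
read_retraction <- function(path) {
  d <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("missing JSON sidecar ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  out <- retraction_curve(d$time_s, d$retraction_um, meta$r_um,
                          meta$dPi_MPa,
                          temperature = meta$temperature_K %||% 298.15)
  attr(out, "seed") <- meta$seed
  attr(out, "noise_sd") <- meta$noise_sd_um
  if (!is.null(meta$truth)) attr(out, "truth") <- meta$truth
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
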