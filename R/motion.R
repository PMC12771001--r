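#' @include surface.R
NULL

#' Construct peristaltic motion parameters
#'
#' Unless phase times are given explicitly, the phases span exactly one wave
#' period: \code{t_k = k * (wavelength / speed) / (nPhases - 1)}, so the
#' first and last phase carry identical deformations when the wave is
#' non-dispersive.
#'
#' @param amplitude A, mm (>= 0).
#' @param wavelength lambda, mm (> 0).
#' @param speed c, mm/s (> 0).
#' @param attenuation alpha (>= 0); units 1/mm for spatial dispersion,
#'   1/s for temporal.
#' @param nPhases number of motion phases (default 21, matching the
#'   temporal sampling of one stomach contraction cycle).
#' @param phaseTimes optional explicit phase times, seconds (first must
#'   be 0).
#' @param dispersionDomain "none", "spatial" or "temporal".
#' @return a \linkS4class{MotionParams}.
#' @seealso [stomachMotionParams()], [largeBowelMotionParams()]
#' @export
motionParams <- function(amplitude, wavelength, speed, attenuation = 0,
                         nPhases = 21L, phaseTimes = NULL,
                         dispersionDomain = c("none", "spatial",
                                              "temporal")) {
    dispersionDomain <- match.arg(dispersionDomain)
    nPhases <- as.integer(nPhases)
    if (is.null(phaseTimes)) {
        phaseTimes <- if (nPhases == 1L) 0 else
            (seq_len(nPhases) - 1L) * (wavelength / speed) / (nPhases - 1L)
    }
    new("MotionParams", amplitude = amplitude, wavelength = wavelength,
        speed = speed, attenuation = attenuation, nPhases = nPhases,
        phaseTimes = as.numeric(phaseTimes),
        dispersionDomain = dispersionDomain)
}

#' Stomach peristalsis preset
#'
#' A = 16 mm, lambda = 55 mm, c = 5 mm/s, alpha = 0 (high-magnitude,
#' non-dispersive gastric contraction wave), 21 phases.
#'
#' @param ... overrides passed to [motionParams()].
#' @return a \linkS4class{MotionParams}.
#' @export
stomachMotionParams <- function(...) {
    args <- list(amplitude = 16, wavelength = 55, speed = 5,
                 attenuation = 0, nPhases = 21L)
    extra <- list(...)
    args[names(extra)] <- extra
    do.call(motionParams, args)
}

#' Large-bowel peristalsis preset
#'
#' A = 16 mm, lambda = 40 mm, c = 8 mm/s, alpha = 0, 21 phases.
#'
#' @inheritParams stomachMotionParams
#' @return a \linkS4class{MotionParams}.
#' @export
largeBowelMotionParams <- function(...) {
    args <- list(amplitude = 16, wavelength = 40, speed = 8,
                 attenuation = 0, nPhases = 21L)
    extra <- list(...)
    args[names(extra)] <- extra
    do.call(motionParams, args)
}

#' Peristaltic traveling-wave displacement
#'
#' \code{F(L, t) = (A / sqrt(3)) * sin(2 * pi * (L - c * t) / lambda)}:
#' the signed radial displacement (mm) of the sectional curve at arc-length
#' station L and time t. Positive values expand the section, negative
#' values contract it.
#'
#' @param L arc-length station(s), mm.
#' @param t time, seconds.
#' @param params a \linkS4class{MotionParams}.
#' @return signed displacement(s), mm.
#' @examples
#' p <- stomachMotionParams()
#' peristalticWave(55 / 4, 0, p)   # quarter wavelength: A / sqrt(3)
#' @export
peristalticWave <- function(L, t, params) {
    (params@amplitude / sqrt(3)) *
        sin(2 * pi * (L - params@speed * t) / params@wavelength)
}

#' Exponential wave dispersion
#'
#' \code{D(u) = exp(-alpha * u)}; attenuates the wave in the spatial
#' (u = arc length, mm) or temporal (u = seconds) domain. alpha = 0 gives
#' no attenuation.
#'
#' @param u non-negative coordinate (mm or s).
#' @param alpha attenuation rate (>= 0).
#' @return attenuation factor(s) in (0, 1].
#' @export
dispersion <- function(u, alpha) {
    if (any(u < 0)) stop("dispersion coordinate u must be >= 0")
    if (alpha < 0) stop("attenuation alpha must be >= 0")
    exp(-alpha * u)
}

# Combined wave * dispersion factor per section at time t.
.waveFactor <- function(L, t, params) {
    f <- peristalticWave(L, t, params)
    if (params@dispersionDomain == "spatial")
        f <- f * dispersion(L, params@attenuation)
    else if (params@dispersionDomain == "temporal")
        f <- f * dispersion(t, params@attenuation)
    f
}

#' Deform the control net of a surface at one time point
#'
#' Each control point moves along its radial unit direction d (from the
#' section centre to the point) by the wave factor:
#' \code{P' = P + F(L_i, t) * D_s * D_t * d}. Contractions are clamped so
#' that no point crosses its section centre (post-deformation radius is
#' kept at least \code{clampMm}); the number of clamped points is recorded
#' in an attribute.
#'
#' @param surface a \linkS4class{NurbsSurface}.
#' @param params \linkS4class{MotionParams}.
#' @param t time, seconds.
#' @param clampMm minimum post-deformation radius, mm.
#' @return a deformed \linkS4class{NurbsSurface} with attribute
#'   \code{"clamped"} (count of clamped control points).
#' @export
deformControls <- function(surface, params, t, clampMm = 0.25) {
    net <- surface@controlNet
    I <- dim(net)[1]
    f <- .waveFactor(surface@arcLength, t, params)
    radial <- net
    for (comp in 1:3)
        radial[, , comp] <- net[, , comp] - surface@centers[, comp]
    radii <- sqrt(radial[, , 1]^2 + radial[, , 2]^2 + radial[, , 3]^2)
    newRadii <- pmax(radii + f, clampMm)     # f recycles over rays
    nClamped <- sum(radii + f < clampMm)
    scale <- ifelse(radii > 0, newRadii / radii, 0)
    out <- net
    for (comp in 1:3)
        out[, , comp] <- surface@centers[, comp] + radial[, , comp] * scale
    res <- initialize(surface, controlNet = out)
    attr(res, "clamped") <- nClamped
    res
}

#' Synthesize the deformed-surface sequence over all phases
#'
#' One deformed control net per phase time; deterministic.
#'
#' @inheritParams deformControls
#' @return a \linkS4class{SurfaceSequence}.
#' @export
synthesizeSequence <- function(surface, params, clampMm = 0.25) {
    validObject(params)
    surfs <- lapply(params@phaseTimes, function(t)
        deformControls(surface, params, t, clampMm))
    new("SurfaceSequence", surfaces = surfs, times = params@phaseTimes,
        params = params)
}
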