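#' @include evaluate.R
NULL

#' Build the geometric model of one organ
#'
#' Mask to centerline (thinning, cycle pruning, endpoint-to-endpoint path,
#' equidistant resampling) to sectional curves to NURBS surface to radial
#' shell stack.
#'
#' @param mask organ \linkS4class{LabelMask}.
#' @param startMm,endMm centerline endpoints, world mm (snapped to the
#'   skeleton).
#' @param stepMm centerline resampling step; defaults to the largest
#'   in-plane spacing, fine enough that the control polygon does not
#'   attenuate a traveling wave of typical gastrointestinal wavelength.
#' @param raysPerSection rays per sectional curve.
#' @param shellLevels radial factors of the shell stack.
#' @return list with \code{centerline}, \code{surface}, \code{stack},
#'   \code{mask}.
#' @export
buildOrganModel <- function(mask, startMm, endMm,
                            stepMm = max(gridSpacing(mask)[1:2]),
                            raysPerSection = 36L,
                            shellLevels = c(0, 0.25, 0.5, 0.75, 1)) {
    line <- extractCenterline(mask, startMm, endMm, stepMm)
    sections <- castSections(mask, line, raysPerSection)
    surface <- fitNurbs(sections)
    stack <- makeShellStack(surface, shellLevels)
    list(centerline = line, surface = surface, stack = stack, mask = mask)
}

# Sampling densities: aim for at least one surface sample per voxel length
# along and around the organ.
.samplingDensity <- function(model, spacing) {
    L <- max(arcLength(model$surface))
    rmax <- max(vapply(seq_len(dim(model$surface@controlNet)[1]),
        function(i) max(sqrt(rowSums((model$surface@controlNet[i, , ] -
            matrix(model$surface@centers[i, ],
                   dim(model$surface@controlNet)[2], 3L,
                   byrow = TRUE))^2))), 0))
    nu <- max(50L, ceiling(L / min(spacing)) + 1L)
    nv <- max(72L, ceiling(2 * pi * rmax / min(spacing)))
    list(nu = nu, nv = nv)
}

#' Ground-truth displacement field for one motion phase
#'
#' Deforms every organ's control net at time t, interpolates shells,
#' samples original/deformed shell points, voxelizes the vectors (averaging
#' collisions) and fills the gaps by iterative neighbor averaging inside
#' the support region.
#'
#' @param models list of organ models from [buildOrganModel()].
#' @param paramsList list of \linkS4class{MotionParams}, one per organ.
#' @param t phase time, seconds.
#' @param grid grid-backed object defining the field geometry.
#' @param phaseIndex phase label.
#' @param supportDilationMm dilation of the organ union used as smoothing
#'   support; default covers the largest outward surface excursion
#'   (max A / sqrt(3)) plus two voxels.
#' @param tolMm smoothing tolerance, mm.
#' @param clampMm contraction clamp, mm.
#' @param withInverse also build the exact backward map by scattering the
#'   negated correspondence vectors at the deformed sample positions
#'   (stored as \code{info$inverse}); [warpVolume()] uses it for hole-free,
#'   fold-free resampling.
#' @return a \linkS4class{DisplacementField}.
#' @export
phaseField <- function(models, paramsList, t, grid, phaseIndex = 0L,
                       supportDilationMm = NULL, tolMm = 0.001,
                       clampMm = 0.25, withInverse = TRUE) {
    stopifnot(length(models) == length(paramsList), length(models) >= 1L)
    sp <- gridSpacing(grid)
    if (is.null(supportDilationMm)) {
        amax <- max(vapply(paramsList, function(p) p@amplitude, 0))
        supportDilationMm <- amax / sqrt(3) + 2 * max(sp)
    }
    allOrig <- NULL
    allDef <- NULL
    for (k in seq_along(models)) {
        m <- models[[k]]
        dens <- .samplingDensity(m, sp)
        defOuter <- deformControls(m$surface, paramsList[[k]], t, clampMm)
        defStack <- makeShellStack(defOuter, m$stack@p)
        s <- sampleShells(m$stack, defStack, dens$nu, dens$nv)
        allOrig <- rbind(allOrig, s@original)
        allDef <- rbind(allDef, s@deformed)
    }
    zv <- numeric(nrow(allOrig))
    samples <- new("ShellSampleSet", original = allOrig, deformed = allDef,
                   u = zv, v = zv, p = zv)
    raw <- voxelize(samples, grid, phaseIndex)
    union <- array(0, gridDim(grid))
    for (m in models) union <- pmax(union, voxelData(m$mask))
    support <- dilateMask(LabelMask(union, sp, gridOrigin(grid)),
                          supportDilationMm)
    field <- smoothFill(raw, support, tolMm)
    if (withInverse) {
        swapped <- new("ShellSampleSet", original = allDef,
                       deformed = allOrig, u = zv, v = zv, p = zv)
        rawInv <- voxelize(swapped, grid, phaseIndex)
        field@info$inverse <- smoothFill(rawInv, support, tolMm)
    }
    field
}

#' Generate the full digital twin: one displacement field per phase
#'
#' Phase times are taken from the first organ's motion parameters (one
#' shared clock for the 4D sequence); every organ's wave is evaluated at
#' those times with its own parameters.
#'
#' @inheritParams phaseField
#' @param verbose print per-phase progress.
#' @return list with \code{fields} (per-phase
#'   \linkS4class{DisplacementField}s), \code{times}, and per-phase
#'   bookkeeping (\code{iterations}, \code{coverage}, \code{clamped}).
#' @export
generateTwin <- function(models, paramsList, grid,
                         supportDilationMm = NULL, tolMm = 0.001,
                         clampMm = 0.25, verbose = FALSE) {
    times <- paramsList[[1]]@phaseTimes
    fields <- vector("list", length(times))
    for (k in seq_along(times)) {
        t0 <- proc.time()[["elapsed"]]
        fields[[k]] <- phaseField(models, paramsList, times[k], grid,
                                  phaseIndex = k - 1L,
                                  supportDilationMm = supportDilationMm,
                                  tolMm = tolMm, clampMm = clampMm)
        if (verbose)
            message(sprintf(
                "phase %2d/%d: t = %6.2f s, %d seed voxels, %d smoothing iterations (%.1f s)",
                k, length(times), times[k],
                fields[[k]]@info$coverage, fields[[k]]@info$iterations,
                proc.time()[["elapsed"]] - t0))
    }
    list(fields = fields, times = times,
         iterations = vapply(fields, function(f) f@info$iterations, 0L),
         coverage = vapply(fields, function(f) f@info$coverage, 0L))
}

#' Phase with the largest mean displacement
#'
#' Identifies the phase exhibiting the maximum deformation (mean |u| over
#' the union of the animated organs), the phase a registration method is
#' evaluated against.
#'
#' @param fields list of \linkS4class{DisplacementField}s.
#' @param mask \linkS4class{LabelMask} (organ union).
#' @return integer index into \code{fields}.
#' @export
maxDeformationPhase <- function(fields, mask) {
    sel <- as.vector(voxelData(mask) > 0)
    means <- vapply(fields, function(f) {
        m <- matrix(f@data, ncol = 3L)[sel, , drop = FALSE]
        mean(sqrt(rowSums(m^2)))
    }, 0)
    which.max(means)
}

# ---- YAML run configuration ----------------------------------------------

#' Validated pipeline run configuration
#'
#' @slot cfg named list with the validated, default-filled settings.
#' @export
setClass("RunConfig", representation(cfg = "list"))

setMethod("show", "RunConfig", function(object) {
    cat("RunConfig: ", length(object@cfg$organs), " organ(s), output '",
        object@cfg$output, "'\n", sep = "")
})

.organDefaults <- list(
    stomach = list(A_mm = 16, lambda_mm = 55, c_mm_per_s = 5),
    large_bowel = list(A_mm = 16, lambda_mm = 40, c_mm_per_s = 8))

.checkKeys <- function(x, allowed, where, errs) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown))
        errs <- c(errs, paste0(where, ": unknown key(s) ",
                               paste(unknown, collapse = ", ")))
    errs
}

#' Validate a YAML pipeline configuration
#'
#' Parses and schema-checks a run configuration, filling defaults (stomach:
#' A = 16 mm, lambda = 55 mm, c = 5 mm/s; large bowel: lambda = 40 mm,
#' c = 8 mm/s; alpha = 0; 21 phases). Unknown keys and schema violations
#' are collected and reported exhaustively.
#'
#' @param x path to a YAML file, a YAML string, or an already-parsed list.
#' @return a \linkS4class{RunConfig}.
#' @export
validateConfig <- function(x) {
    cfg <- if (is.list(x)) x
        else if (file.exists(x)) yaml::read_yaml(x)
        else yaml::yaml.load(x)
    if (!is.list(cfg)) stop("configuration must be a YAML mapping")
    errs <- character()
    errs <- .checkKeys(cfg, c("image", "dose", "phantom", "output",
                              "seed", "sampling", "smoothing", "organs"),
                       "top level", errs)
    if (is.null(cfg$output)) errs <- c(errs, "output directory is required")
    if (is.null(cfg$organs) || !length(cfg$organs))
        errs <- c(errs, "at least one organ must be configured")
    if (!is.null(cfg$phantom)) {
        errs <- .checkKeys(cfg$phantom, c("preset", "seed", "noise_sd"),
                           "phantom", errs)
        if (!is.null(cfg$phantom$preset) &&
            !cfg$phantom$preset %in% c("stomach", "bowel"))
            errs <- c(errs, "phantom$preset must be 'stomach' or 'bowel'")
    } else {
        if (is.null(cfg$image))
            errs <- c(errs, "an input image (or a phantom block) is required")
        else if (!file.exists(cfg$image))
            errs <- c(errs, paste0("image not found: ", cfg$image))
    }
    cfg$seed <- if (is.null(cfg$seed)) 7L else as.integer(cfg$seed)
    smoothing <- cfg$smoothing
    if (!is.null(smoothing))
        errs <- .checkKeys(smoothing, c("tol_mm", "support_dilation_mm"),
                           "smoothing", errs)
    cfg$smoothing <- list(
        tol_mm = if (is.null(smoothing$tol_mm)) 0.001
                 else as.numeric(smoothing$tol_mm),
        support_dilation_mm = if (is.null(smoothing$support_dilation_mm))
            NULL else as.numeric(smoothing$support_dilation_mm))
    if (cfg$smoothing$tol_mm <= 0)
        errs <- c(errs, "smoothing$tol_mm must be > 0")
    sampling <- cfg$sampling
    if (!is.null(sampling))
        errs <- .checkKeys(sampling,
                           c("rays_per_section", "shell_levels", "step_mm"),
                           "sampling", errs)
    cfg$sampling <- list(
        rays_per_section = if (is.null(sampling$rays_per_section)) 36L
                           else as.integer(sampling$rays_per_section),
        shell_levels = if (is.null(sampling$shell_levels))
            c(0, 0.25, 0.5, 0.75, 1) else as.numeric(sampling$shell_levels),
        step_mm = if (is.null(sampling$step_mm)) NULL
                  else as.numeric(sampling$step_mm))
    if (cfg$sampling$rays_per_section < 8L)
        errs <- c(errs, "sampling$rays_per_section must be >= 8")
    organs <- cfg$organs
    for (i in seq_along(organs)) {
        o <- organs[[i]]
        where <- paste0("organs[", i, "]")
        errs <- .checkKeys(o, c("name", "mask", "start", "end", "motion"),
                           where, errs)
        if (is.null(o$name)) {
            errs <- c(errs, paste0(where, ": name is required"))
            o$name <- "organ"
        }
        if (is.null(cfg$phantom)) {
            if (is.null(o$mask))
                errs <- c(errs, paste0(where, ": mask path is required"))
            else if (!file.exists(o$mask))
                errs <- c(errs, paste0(where, ": mask not found: ", o$mask))
            if (is.null(o$start) || is.null(o$end))
                errs <- c(errs, paste0(where,
                    ": start and end centerline points are required"))
        }
        for (pt in c("start", "end"))
            if (!is.null(o[[pt]]) && length(o[[pt]]) != 3L)
                errs <- c(errs, paste0(where, ": ", pt,
                                       " must be 3 coordinates (mm)"))
        m <- if (is.null(o$motion)) list() else o$motion
        errs <- .checkKeys(m, c("A_mm", "lambda_mm", "c_mm_per_s", "alpha",
                                "n_phases", "dispersion_domain"),
                           paste0(where, "$motion"), errs)
        dflt <- .organDefaults[[o$name]]
        if (is.null(dflt)) dflt <- .organDefaults$stomach
        m$A_mm <- if (is.null(m$A_mm)) dflt$A_mm else as.numeric(m$A_mm)
        m$lambda_mm <- if (is.null(m$lambda_mm)) dflt$lambda_mm
                       else as.numeric(m$lambda_mm)
        m$c_mm_per_s <- if (is.null(m$c_mm_per_s)) dflt$c_mm_per_s
                        else as.numeric(m$c_mm_per_s)
        m$alpha <- if (is.null(m$alpha)) 0 else as.numeric(m$alpha)
        m$n_phases <- if (is.null(m$n_phases)) 21L
                      else as.integer(m$n_phases)
        m$dispersion_domain <- if (is.null(m$dispersion_domain)) "none"
                               else m$dispersion_domain
        if (m$A_mm < 0) errs <- c(errs, paste0(where, ": A_mm must be >= 0"))
        if (m$lambda_mm <= 0)
            errs <- c(errs, paste0(where, ": lambda_mm must be > 0"))
        if (m$c_mm_per_s <= 0)
            errs <- c(errs, paste0(where, ": c_mm_per_s must be > 0"))
        if (m$alpha < 0) errs <- c(errs, paste0(where, ": alpha must be >= 0"))
        if (m$n_phases < 1L)
            errs <- c(errs, paste0(where, ": n_phases must be >= 1"))
        if (!m$dispersion_domain %in% c("none", "spatial", "temporal"))
            errs <- c(errs, paste0(where,
                ": dispersion_domain must be none, spatial or temporal"))
        o$motion <- m
        organs[[i]] <- o
    }
    cfg$organs <- organs
    if (length(errs))
        stop("invalid configuration:\n  - ",
             paste(errs, collapse = "\n  - "))
    new("RunConfig", cfg = cfg)
}

.motionFromConfig <- function(m) {
    motionParams(m$A_mm, m$lambda_mm, m$c_mm_per_s, m$alpha,
                 nPhases = m$n_phases,
                 dispersionDomain = m$dispersion_domain)
}

#' Run the full digital-twin pipeline from a configuration
#'
#' Executes phantom generation (or input reading), centerline extraction,
#' surface modeling, motion synthesis, displacement-field voxelization and
#' warping, and writes every artifact plus a checksummed manifest. Re-runs
#' with the same configuration and seed reproduce identical outputs.
#'
#' @param config a \linkS4class{RunConfig} (or anything accepted by
#'   [validateConfig()]).
#' @param verbose print stage progress.
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config, verbose = TRUE) {
    if (!is(config, "RunConfig")) config <- validateConfig(config)
    cfg <- config@cfg
    dir.create(cfg$output, recursive = TRUE, showWarnings = FALSE)
    say <- function(...) if (verbose) message(...)

    # --- stage 1: inputs -------------------------------------------------
    organMasks <- list()
    endpoints <- list()
    if (!is.null(cfg$phantom)) {
        say("stage 1: generating '", cfg$phantom$preset, "' phantom")
        spec <- phantomPreset(
            if (is.null(cfg$phantom$preset)) "stomach"
            else cfg$phantom$preset,
            noiseSd = if (is.null(cfg$phantom$noise_sd)) 10
                      else cfg$phantom$noise_sd,
            seed = if (is.null(cfg$phantom$seed)) cfg$seed
                   else cfg$phantom$seed)
        mask <- makeTubeMask(spec)
        image <- makePhantomImage(mask, spec)
        path <- tubePath(spec)
        for (i in seq_along(cfg$organs)) {
            o <- cfg$organs[[i]]
            organMasks[[o$name]] <- mask
            endpoints[[o$name]] <- list(
                start = if (is.null(o$start)) path@points[1, ]
                        else as.numeric(o$start),
                end = if (is.null(o$end))
                        path@points[nrow(path@points), ]
                      else as.numeric(o$end))
        }
        writeVolume(image, file.path(cfg$output, "image.nii.gz"))
        writeVolume(mask, file.path(cfg$output, "mask.nii.gz"))
        jsonlite::write_json(
            list(points = path@points, arc_length_mm = path@arcLength),
            file.path(cfg$output, "tube_path.json"), digits = NA)
    } else {
        say("stage 1: reading inputs")
        image <- readVolume(cfg$image)
        for (o in cfg$organs) {
            m <- readMask(o$mask)
            .stopIfGridMismatch(image, m, "image and mask")
            organMasks[[o$name]] <- m
            endpoints[[o$name]] <- list(start = as.numeric(o$start),
                                        end = as.numeric(o$end))
        }
    }
    dose <- if (!is.null(cfg$dose)) readVolume(cfg$dose) else NULL

    # --- stage 2: organ models -------------------------------------------
    models <- list()
    paramsList <- list()
    for (o in cfg$organs) {
        say("stage 2: modeling organ '", o$name, "'")
        m <- organMasks[[o$name]]
        step <- if (is.null(cfg$sampling$step_mm))
            max(gridSpacing(m)[1:2]) else cfg$sampling$step_mm
        models[[o$name]] <- buildOrganModel(
            m, endpoints[[o$name]]$start, endpoints[[o$name]]$end,
            stepMm = step,
            raysPerSection = cfg$sampling$rays_per_section,
            shellLevels = cfg$sampling$shell_levels)
        paramsList[[o$name]] <- .motionFromConfig(o$motion)
        line <- models[[o$name]]$centerline
        jsonlite::write_json(
            list(points = line@points, arc_length_mm = line@arcLength),
            file.path(cfg$output,
                      paste0("centerline_", o$name, ".json")), digits = NA)
    }

    # --- stage 3 + 4: motion synthesis, DVFs, 4D sequence ----------------
    say("stage 3/4: synthesizing ", paramsList[[1]]@nPhases,
        " motion phases")
    twin <- generateTwin(models, paramsList, image,
                         supportDilationMm =
                             cfg$smoothing$support_dilation_mm,
                         tolMm = cfg$smoothing$tol_mm, verbose = verbose)
    files <- c("image.nii.gz", "mask.nii.gz", "tube_path.json")
    files <- files[file.exists(file.path(cfg$output, files))]
    files <- c(files, paste0("centerline_", names(models), ".json"))
    for (k in seq_along(twin$fields)) {
        tag <- sprintf("%02d", k - 1L)
        f <- twin$fields[[k]]
        writeDVF(f, file.path(cfg$output, paste0("dvf_", tag, ".nii.gz")))
        warped <- warpVolume(image, f, kind = "image",
                             inverse = f@info$inverse)
        writeVolume(warped,
                    file.path(cfg$output, paste0("phase_", tag, ".nii.gz")))
        jac <- logJacobian(f)
        jd <- voxelData(jac)
        jd[!is.finite(jd)] <- 0
        writeVolume(VolumeGrid(jd, gridSpacing(jac), gridOrigin(jac)),
                    file.path(cfg$output, paste0("logjac_", tag,
                                                 ".nii.gz")))
        for (nm in names(models)) {
            wm <- warpVolume(models[[nm]]$mask, f, kind = "mask",
                             inverse = f@info$inverse)
            writeVolume(wm, file.path(cfg$output,
                paste0("mask_", nm, "_", tag, ".nii.gz")))
        }
        files <- c(files, paste0("dvf_", tag, ".nii.gz"),
                   paste0("phase_", tag, ".nii.gz"),
                   paste0("logjac_", tag, ".nii.gz"),
                   paste0("mask_", names(models), "_", tag, ".nii.gz"))
    }
    jsonlite::write_json(list(times_s = twin$times),
                         file.path(cfg$output, "phases.json"), digits = NA)
    files <- c(files, "phases.json")

    manifest <- list(
        seed = cfg$seed,
        n_phases = length(twin$fields),
        phase_times_s = twin$times,
        smoothing_iterations = twin$iterations,
        seeded_voxels = twin$coverage,
        artifacts = lapply(files, function(f) list(
            file = f,
            md5 = unname(tools::md5sum(file.path(cfg$output, f))))))
    jsonlite::write_json(manifest,
                         file.path(cfg$output, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("wrote ", length(files) + 1L, " artifacts to ", cfg$output)
    invisible(manifest)
}
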