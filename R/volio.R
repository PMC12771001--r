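#' @include utils.R
NULL

# Pull spacing/origin out of a NIfTI header and reject oblique orientations:
# the package works in one axis-aligned convention, so direction cosines
# other than the identity are a hard error.
.niftiGeometry <- function(img, path) {
    sp <- RNifti::pixdim(img)[1:3]
    x <- RNifti::xform(img)
    code <- attr(x, "code")
    if (is.null(code) || code == 0L) {
        origin <- c(0, 0, 0)
    } else {
        rot <- x[1:3, 1:3]
        cosines <- sweep(rot, 2L, sp, "/")
        if (max(abs(cosines - diag(3))) > 1e-4)
            stop("'", path, "': non-identity direction cosines; only ",
                 "axis-aligned volumes are supported")
        origin <- x[1:3, 4]
    }
    list(spacing = as.numeric(sp), origin = as.numeric(origin))
}

.asNiftiImage <- function(data, spacing, origin) {
    img <- RNifti::asNifti(data)
    nd <- length(dim(data))
    img <- RNifti::`pixdim<-`(img, c(spacing, rep(1, nd - 3L)))
    m <- diag(c(spacing, 1))
    m[1:3, 4] <- origin
    img <- RNifti::`qform<-`(img, structure(m, code = 2L))
    img
}

#' Read a 3D volume from a NIfTI file
#'
#' Spacing and origin are taken from the header; data are unchanged. Only
#' strictly 3D, axis-aligned, finite-valued images are accepted.
#'
#' @param path path to a .nii or .nii.gz file.
#' @return a \linkS4class{VolumeGrid}.
#' @seealso [readMask()], [readDVF()], [writeVolume()]
#' @export
readVolume <- function(path) {
    if (!file.exists(path)) stop("file not found: '", path, "'")
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3L)
        stop("'", path, "': expected 3D volume, got ", length(dim(img)),
             " dimensions")
    if (any(!is.finite(img)))
        stop("'", path, "': volume contains non-finite voxels")
    g <- .niftiGeometry(img, path)
    VolumeGrid(array(as.numeric(img), dim(img)), g$spacing, g$origin)
}

#' Read a binary organ mask from a NIfTI file
#'
#' @param path path to the mask file; voxels must be 0/1.
#' @param requireForeground error when the mask is empty (the default for
#'   organ inputs).
#' @return a \linkS4class{LabelMask}.
#' @export
readMask <- function(path, requireForeground = TRUE) {
    v <- readVolume(path)
    if (!all(unique(as.vector(v@data)) %in% c(0, 1)))
        stop("'", path, "': mask voxels must all be 0 or 1")
    if (requireForeground && sum(v@data) == 0)
        stop("'", path, "': mask has no foreground voxels")
    LabelMask(v@data, v@spacing, v@origin)
}

#' Write a volume or mask to NIfTI
#'
#' @param vol a \linkS4class{VolumeGrid} or \linkS4class{LabelMask}.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeVolume <- function(vol, path) {
    validObject(vol)
    img <- .asNiftiImage(vol@data, vol@spacing, vol@origin)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Write a displacement field as a vector NIfTI
#'
#' Stored as a 4D image whose last dimension holds the x, y, z displacement
#' components in mm along the world axes. Round-trips to float32 precision.
#'
#' @param field a \linkS4class{DisplacementField}; must be finite.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDVF <- function(field, path) {
    if (any(!is.finite(field@data)))
        stop("displacement field contains non-finite components")
    img <- .asNiftiImage(field@data, field@spacing, field@origin)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read a displacement field from a vector NIfTI
#'
#' @param path path to a 4D NIfTI with 3 components in the last dimension.
#' @param phaseIndex phase label to attach.
#' @param convention \code{"forward"} (vectors at undeformed positions, the
#'   package convention) or \code{"backward"}; backward fields are negated
#'   on load so external tools with the opposite convention can be scored.
#' @return a \linkS4class{DisplacementField}.
#' @export
readDVF <- function(path, phaseIndex = 0L,
                    convention = c("forward", "backward")) {
    convention <- match.arg(convention)
    if (!file.exists(path)) stop("file not found: '", path, "'")
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) == 5L && d[4] == 1L) {
        # NIfTI vector-intent files park components in the 5th dimension
        img <- array(img, d[c(1:3, 5)])
        d <- dim(img)
    }
    if (length(d) != 4L || d[4] != 3L)
        stop("'", path, "': expected a 4D vector field with 3 components")
    if (any(!is.finite(img)))
        stop("'", path, "': field contains non-finite components")
    g <- .niftiGeometry(img, path)
    dat <- array(as.numeric(img), d)
    if (convention == "backward") dat <- -dat
    DisplacementField(dat, g$spacing, g$origin, phaseIndex)
}
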