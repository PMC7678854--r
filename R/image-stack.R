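#' Construct a 3D image stack
#'
#' @param voxels 3D numeric array (x, y, z), non-negative.
#' @param pitch voxel pitch in um: either one number (isotropic) or three
#'   (x, y, z). Default `c(0.1, 0.1, 0.2)`.
#' @return an [ImageStack3D-class].
#' @export
imageStack3D <- function(voxels, pitch = c(0.1, 0.1, 0.2)) {
  if (length(pitch) == 1L) pitch <- rep(pitch, 3L)
  new("ImageStack3D", voxels = voxels, pitch = as.numeric(pitch))
}

#' @rdname ImageStack3D-class
#' @export
setMethod("voxels", "ImageStack3D", function(x) x@voxels)

#' @rdname ImageStack3D-class
#' @export
setMethod("voxelPitch", "ImageStack3D", function(x) x@pitch)

#' @rdname ImageStack3D-class
#' @export
setMethod("dim", "ImageStack3D", function(x) dim(x@voxels))

setMethod("show", "ImageStack3D", function(object) {
  d <- dim(object@voxels)
  cat("ImageStack3D:", paste(d, collapse = " x "), "voxels at (",
      paste(format(object@pitch, digits = 3), collapse = ", "),
      ") um pitch\n")
  cat("  intensity range:", format(min(object@voxels), digits = 4), "..",
      format(max(object@voxels), digits = 4),
      " total:", format(sum(object@voxels), digits = 6), "\n")
})

# Physical voxel-centre coordinates along one axis, centred on the array.
stackAxisCoords <- function(stack, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  i <- match(axis, c("x", "y", "z"))
  centeredCoords(dim(stack@voxels)[i], stack@pitch[i])
}

#' Construct a bead phantom
#'
#' @param beads data.frame with columns `x`, `y`, `z` (um), `diameter` (um),
#'   `brightness` (expected photons per bead).
#' @param background expected photons per voxel (default 0).
#' @return a [BeadPhantom-class].
#' @export
beadPhantom <- function(beads = data.frame(x = numeric(), y = numeric(),
                                           z = numeric(),
                                           diameter = numeric(),
                                           brightness = numeric()),
                        background = 0) {
  new("BeadPhantom", beads = beads, background = background)
}

setMethod("show", "BeadPhantom", function(object) {
  cat("BeadPhantom:", nrow(object@beads), "bead(s), background",
      object@background, "photons/voxel\n")
})
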