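#' Construct a phase image
#'
#' @param phase numeric matrix of optical phase, radians.
#' @param pixelPitch pixel pitch, um (default 0.1).
#' @return a [PhaseImage-class].
#' @export
phaseImage <- function(phase, pixelPitch = 0.1) {
  new("PhaseImage", phase = phase, pixelPitch = pixelPitch)
}

#' @rdname PhaseImage-class
#' @export
setMethod("phaseValues", "PhaseImage", function(x) x@phase)

#' @rdname PhaseImage-class
#' @export
setMethod("pixelPitch", "PhaseImage", function(x) x@pixelPitch)

#' @rdname PhaseImage-class
#' @export
setMethod("dim", "PhaseImage", function(x) dim(x@phase))

setMethod("show", "PhaseImage", function(object) {
  cat("PhaseImage:", nrow(object@phase), "x", ncol(object@phase),
      "pixels at", object@pixelPitch, "um;  phase range:",
      format(min(object@phase), digits = 4), "..",
      format(max(object@phase), digits = 4), "rad\n")
})

# 8-connected component labelling of a logical matrix. EBImage::bwlabel is
# 4-connected, so the 8-neighbour pixel graph is labelled through igraph
# components instead. Returns an integer matrix (0 = background).
labelConnected8 <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (!length(idx)) return(lab)
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rows + off[1]; c2 <- cols + off[2]
    okn <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nidx <- (c2[okn] - 1L) * nr + r2[okn]
    hit <- mask[nidx]
    if (any(hit))
      edges <- c(edges, rbind(vid[idx[okn][hit]], vid[nidx[hit]]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

#' Segment a phase image by thresholding
#'
#' Connected components (8-connectivity) of `phase > threshold` with holes
#' filled, discarding regions smaller than `minArea`, ordered by descending
#' area. Cells and their lipid droplets are segmented with the same routine
#' at different threshold levels.
#'
#' @param img a [PhaseImage-class].
#' @param threshold phase threshold, radians.
#' @param minArea minimum region area, um^2 (default 0).
#' @return list of logical masks (matrices matching `img`), each with
#'   attributes `area_um2` and `centroid_um` (physical coordinates with the
#'   image centred on 0); empty list if nothing exceeds the threshold.
#' @examples
#' img <- phaseImage(matrix(0, 32, 32), 0.1)
#' segmentByPhase(img, 0.5)   # empty list
#' @export
segmentByPhase <- function(img, threshold, minArea = 0) {
  stopifnot(is(img, "PhaseImage"))
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  if (minArea < 0) stop("minArea must be >= 0", call. = FALSE)
  mask <- img@phase > threshold
  lab <- labelConnected8(mask)
  if (!any(lab > 0L)) return(list())
  lab <- EBImage::fillHull(lab)
  pitch <- img@pixelPitch
  pxArea <- pitch^2
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes * pxArea >= minArea)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  xs <- centeredCoords(nrow(mask), pitch)
  ys <- centeredCoords(ncol(mask), pitch)
  lapply(keep, function(k) {
    m <- lab == k
    w <- which(m, arr.ind = TRUE)
    structure(m,
              area_um2 = sizes[k] * pxArea,
              centroid_um = c(mean(xs[w[, 1]]), mean(ys[w[, 2]])))
  })
}

# TRUE if a mask touches the image border.
touchesBorder <- function(mask) {
  any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
}
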