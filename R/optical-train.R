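#' Build an optical train from lens/gap elements
#'
#' @param elements list of elements, each `list(type = "lens", f_cm = ...)`
#'   or `list(type = "gap", d_cm = ...)`.
#' @param finalScanRange axial sampling window around the last focus, mm
#'   (default 4).
#' @return an [OpticalTrain-class].
#' @seealso [airyTrain()] for the default seven-lens illumination train.
#' @export
opticalTrain <- function(elements = list(), finalScanRange = 4) {
  new("OpticalTrain", elements = elements, finalScanRange = finalScanRange)
}

#' The default Airy illumination lens train
#'
#' Seven thin lenses: the SLM-relay 4f pair (75.6 cm, 40 cm), the scanner 4f
#' pair (3.5 cm, 1.2 cm), scan lens (7.5 cm), tube lens (30 cm) and the
#' illumination objective modelled as a 2 cm thin lens. Gap lengths follow
#' the cascaded-4f layout: the source sits one focal length before the first
#' lens and consecutive lenses are separated by the sum of their focal
#' lengths, so each relay images the mask plane onto the next and the last
#' lens Fourier-transforms the relayed mask into its focal region.
#'
#' @param focalLengths focal lengths in cm, in order (default the seven
#'   values above).
#' @param finalScanRange axial sampling window around the last focus, mm.
#' @return an [OpticalTrain-class] ending at the last lens.
#' @examples
#' airyTrain()
#' @export
airyTrain <- function(focalLengths = c(75.6, 40, 3.5, 1.2, 7.5, 30, 2),
                      finalScanRange = 4) {
  stopifnot(length(focalLengths) >= 1, all(focalLengths > 0))
  f <- focalLengths
  gaps <- c(f[1], if (length(f) > 1) f[-length(f)] + f[-1])
  elements <- vector("list", 2 * length(f))
  for (i in seq_along(f)) {
    elements[[2 * i - 1]] <- list(type = "gap", d_cm = gaps[i])
    elements[[2 * i]] <- list(type = "lens", f_cm = f[i])
  }
  opticalTrain(elements, finalScanRange)
}

#' Focal lengths / positions of a train
#'
#' `trainFocalLengths` returns the lens focal lengths (cm) in order;
#' `lastFocalLength` the focal length (um) of the final lens, i.e. the
#' nominal distance from the train's exit plane to its focus.
#'
#' @param train an [OpticalTrain-class].
#' @return numeric vector (cm) or a single length (um).
#' @export
trainFocalLengths <- function(train) {
  stopifnot(is(train, "OpticalTrain"))
  vapply(Filter(function(e) e$type == "lens", train@elements),
         function(e) e$f_cm, numeric(1))
}

#' @rdname trainFocalLengths
#' @export
lastFocalLength <- function(train) {
  f <- trainFocalLengths(train)
  if (!length(f)) return(0)
  f[length(f)] * 1e4
}

setMethod("show", "OpticalTrain", function(object) {
  lenses <- sum(vapply(object@elements, function(e) e$type == "lens",
                       logical(1)))
  gaps <- length(object@elements) - lenses
  cat("OpticalTrain:", lenses, "lens(es),", gaps, "gap(s)\n")
  if (length(object@elements)) {
    desc <- vapply(object@elements, function(e)
      if (e$type == "lens") paste0("lens f=", e$f_cm, "cm")
      else paste0("gap ", e$d_cm, "cm"), character(1))
    cat(" ", paste(desc, collapse = " -> "), "\n")
  }
  cat("  final scan range:", object@finalScanRange, "mm\n")
})

#' @describeIn propagateTrain execute the train's exact interleaving of
#'   free-space segments ([angularSpectrumPropagate()]) and thin lenses
#'   ([applyThinLens()]). An empty train returns the input unchanged.
#' @export
setMethod("propagateTrain", signature("SampledField", "OpticalTrain"),
  function(field, train) {
    for (el in train@elements) {
      field <- switch(el$type,
        gap = angularSpectrumPropagate(field, el$d_cm * 1e4),
        lens = applyThinLens(field, el$f_cm),
        stop("unknown train element type: ", el$type))
    }
    field
  })

#' Read an optical-train configuration file
#'
#' Parses a YAML (or JSON) document with an `elements` list
#' (`{type: lens, f_cm: ...}` / `{type: gap, d_cm: ...}`), an optional
#' `source` block (`w0_mm`, `alpha_mm3`, `lambda_um`, `amplitude`) and an
#' optional `sampling` block (`grid_pow2`, `pitch_um`, `zwindow_um`,
#' `zpitch_um`, `xwindow_um`).
#'
#' @param path path to the config file.
#' @return a list with components `train` ([OpticalTrain-class]), `source`
#'   ([GaussianCubicSource-class] or NULL), `wavelength` and `sampling`.
#' @export
readTrainConfig <- function(path) {
  cfg <- readConfigFile(path)
  if (is.null(cfg$elements))
    stop("train config must contain an 'elements' list", call. = FALSE)
  elements <- lapply(cfg$elements, function(e) {
    e <- as.list(e)
    if (is.null(e$type)) stop("train element without a type", call. = FALSE)
    e
  })
  train <- opticalTrain(elements,
                        finalScanRange = cfg$final_scan_range_mm %||% 4)
  src <- NULL
  if (!is.null(cfg$source))
    src <- gaussianCubicSource(
      waist = cfg$source$w0_mm,
      amplitudeScale = cfg$source$amplitude %||% 1,
      cubicScaling = cfg$source$alpha_mm3 %||% 0)
  sampling <- cfg$sampling %||% list()
  list(train = train, source = src,
       wavelength = cfg$source$lambda_um %||% 0.488,
       sampling = sampling)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
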