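#' Accessors for tinnscreen classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object a tinnscreen S4 object.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("animalId", function(object) standardGeneric("animalId"))

#' @rdname accessors
#' @export
setGeneric("schedule", function(object) standardGeneric("schedule"))

#' @rdname accessors
#' @export
setGeneric("pressTimes", function(object) standardGeneric("pressTimes"))

#' @rdname accessors
#' @export
setGeneric("qcPassed", function(object) standardGeneric("qcPassed"))

#' @rdname accessors
#' @export
setGeneric("aoi", function(object) standardGeneric("aoi"))

#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("pixelArea", function(object) standardGeneric("pixelArea"))

#' @rdname accessors
#' @export
setGeneric("percentArea", function(object) standardGeneric("percentArea"))

#' @rdname accessors
#' @export
setMethod("animalId", "AnimalState", function(object) object@animalId)

#' @rdname accessors
#' @export
setMethod("animalId", "SessionLog", function(object) object@animalId)

#' @rdname accessors
#' @export
setMethod("animalId", "Micrograph", function(object) object@animalId)

#' @rdname accessors
#' @export
setMethod("schedule", "Protocol", function(object) object@schedule)

#' @rdname accessors
#' @export
setMethod("schedule", "SessionLog", function(object) object@schedule)

#' @rdname accessors
#' @export
setMethod("pressTimes", "SessionLog", function(object) object@pressTimes)

#' @rdname accessors
#' @export
setMethod("qcPassed", "QCReport", function(object) object@passed)

#' @rdname accessors
#' @export
setMethod("aoi", "Micrograph", function(object) object@aoi)

#' @rdname accessors
#' @export
setMethod("intensity", "Micrograph", function(object) object@image)

#' @rdname accessors
#' @export
setMethod("pixelArea", "Micrograph", function(object) object@pixelArea)

#' @rdname accessors
#' @export
setMethod("percentArea", "ParticleStats", function(object) object@percentArea)

setMethod("show", "Protocol", function(object) {
  cat("Protocol:", object@sessionMinutes, "min session,",
      object@nProbes, "probe periods (", object@nSpeakerOff, "speaker-off ),",
      "background", object@backgroundLevel, "dB SPL\n")
  kinds <- table(object@schedule$kind)
  cat("  schedule periods:",
      paste(names(kinds), as.integer(kinds), collapse = ", "), "\n")
})

setMethod("show", "AnimalState", function(object) {
  cat(sprintf("AnimalState %s: %s, tau = %.3f, pitch = %g kHz, lambdaBg = %.2f/min, cOff = %.2f\n",
              object@animalId,
              if (object@exposed) "exposed" else "unexposed",
              object@tau, object@tinnitusPitch, object@lambdaBg, object@cOff))
})

setMethod("show", "SessionLog", function(object) {
  cat(sprintf("SessionLog %s session %d: %d presses over %g min\n",
              object@animalId, object@session, length(object@pressTimes),
              max(object@schedule$end_sec) / 60))
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: %s (total presses = %d, mean background R = %s)\n",
              if (object@passed) "PASS" else "FAIL",
              object@totalPresses,
              formatC(object@meanBackgroundR, digits = 3, format = "f")))
  if (length(object@failureReasons))
    cat("  reasons:", paste(object@failureReasons, collapse = "; "), "\n")
})

setMethod("show", "Micrograph", function(object) {
  d <- dim(object@image)
  cat(sprintf("Micrograph %s [%s %s %s]: %d x %d px, AOI %d px, pixelArea %g\n",
              object@id, object@animalId, object@region, object@side,
              d[1], d[2], sum(object@aoi), object@pixelArea))
})

setMethod("show", "ParticleStats", function(object) {
  cat(sprintf("ParticleStats: %d particles, %.4g stained / %.4g AOI area (%.2f%%), threshold %.4g\n",
              object@nParticles, object@stainedArea, object@aoiArea,
              object@percentArea, object@thresholdUsed))
})
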