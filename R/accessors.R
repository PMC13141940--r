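#' @include AllClasses.R
NULL

#' Accessors for mvatkit classes
#'
#' Small, stable accessor functions; user code should prefer these over slot
#' access.
#'
#' @param x an mvatkit object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setMethod("atoms", "StructureModel", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("identifier", function(x) standardGeneric("identifier"))

#' @rdname accessors
#' @export
setMethod("identifier", "StructureModel", function(x) x@identifier)

#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname accessors
#' @export
setMethod("chainIds", "StructureModel", function(x) unique(x@atoms$chain))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setMethod("nAtoms", "StructureModel", function(x) nrow(x@atoms))

#' Coordinate matrix of a structure
#'
#' @param x a [StructureModel-class].
#' @return numeric matrix with one row per atom and columns x, y, z (Angstrom).
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "StructureModel", function(x)
  cbind(x = x@atoms$x, y = x@atoms$y, z = x@atoms$z))

#' @rdname accessors
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))

#' @rdname accessors
#' @export
setMethod("rotation", "RigidTransform", function(x) x@rotation)

#' @rdname accessors
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))

#' @rdname accessors
#' @export
setMethod("translation", "RigidTransform", function(x) x@translation)

#' @rdname accessors
#' @export
setGeneric("fitTransform", function(x) standardGeneric("fitTransform"))

#' @rdname accessors
#' @export
setMethod("fitTransform", "SuperpositionResult", function(x) x@transform)

#' @rdname accessors
#' @export
setGeneric("rmsd", function(x) standardGeneric("rmsd"))

#' @rdname accessors
#' @export
setMethod("rmsd", "SuperpositionResult", function(x) x@rmsd)

#' @rdname accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname accessors
#' @export
setMethod("nPairs", "SuperpositionResult", function(x) x@nPairs)

#' @rdname accessors
#' @export
setGeneric("profileQ", function(x) standardGeneric("profileQ"))

#' @rdname accessors
#' @export
setMethod("profileQ", "ScatteringProfile", function(x) x@q)

#' @rdname accessors
#' @export
setMethod("profileQ", "FrameSeries", function(x) x@q)

#' @rdname accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setMethod("intensity", "ScatteringProfile", function(x) x@intensity)

#' @rdname accessors
#' @export
setMethod("intensity", "FrameSeries", function(x) x@intensities)

#' @rdname accessors
#' @export
setGeneric("uncertainty", function(x) standardGeneric("uncertainty"))

#' @rdname accessors
#' @export
setMethod("uncertainty", "ScatteringProfile", function(x) x@sigma)

#' @rdname accessors
#' @export
setGeneric("radiusOfGyration", function(x, ...) standardGeneric("radiusOfGyration"))

#' @rdname accessors
#' @export
setMethod("radiusOfGyration", "GuinierResult", function(x, ...) x@rg)

#' @rdname accessors
#' @export
setGeneric("forwardIntensity", function(x) standardGeneric("forwardIntensity"))

#' @rdname accessors
#' @export
setMethod("forwardIntensity", "GuinierResult", function(x) x@i0)

#' @rdname accessors
#' @export
setGeneric("fitRange", function(x) standardGeneric("fitRange"))

#' @rdname accessors
#' @export
setMethod("fitRange", "GuinierResult", function(x) x@fitRange)

#' @rdname accessors
#' @export
setGeneric("junctionReport", function(x) standardGeneric("junctionReport"))

#' @rdname accessors
#' @export
setMethod("junctionReport", "FilamentModel", function(x) x@junctionReport)

#' @rdname accessors
#' @export
setGeneric("nDimers", function(x) standardGeneric("nDimers"))

#' @rdname accessors
#' @export
setMethod("nDimers", "FilamentModel", function(x) x@nDimers)

#' @rdname accessors
#' @export
setGeneric("assembledStructure", function(x) standardGeneric("assembledStructure"))

#' @rdname accessors
#' @export
setMethod("assembledStructure", "FilamentModel", function(x) x@structure)
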