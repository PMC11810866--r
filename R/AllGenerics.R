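#' @include AllClasses.R
NULL

#' Accessors for VolumetricImage
#'
#' @param x a [VolumetricImage-class].
#' @return `volData` the intensity array, `volSpacing`/`volOrigin` mm
#'   3-vectors, `volAxes` the 3x3 direction matrix, `sliceAxis` the
#'   stacking axis index.
#' @name volume-accessors
#' @aliases volData volSpacing volOrigin volAxes sliceAxis
NULL

#' @rdname volume-accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname volume-accessors
#' @export
setGeneric("volSpacing", function(x) standardGeneric("volSpacing"))
#' @rdname volume-accessors
#' @export
setGeneric("volOrigin", function(x) standardGeneric("volOrigin"))
#' @rdname volume-accessors
#' @export
setGeneric("volAxes", function(x) standardGeneric("volAxes"))
#' @rdname volume-accessors
#' @export
setGeneric("sliceAxis", function(x) standardGeneric("sliceAxis"))

#' @rdname volume-accessors
setMethod("volData", "VolumetricImage", function(x) x@data)
#' @rdname volume-accessors
setMethod("volSpacing", "VolumetricImage", function(x) x@spacing)
#' @rdname volume-accessors
setMethod("volOrigin", "VolumetricImage", function(x) x@origin)
#' @rdname volume-accessors
setMethod("volAxes", "VolumetricImage", function(x) x@axes)
#' @rdname volume-accessors
setMethod("sliceAxis", "VolumetricImage", function(x) x@sliceAxis)

#' @describeIn volume-accessors voxel grid dimensions.
#' @export
setMethod("dim", "VolumetricImage", function(x) dim(x@data))

#' Accessors for MockupGrid
#'
#' @param x a [MockupGrid-class].
#' @return `gridLabels` the 0/1/2 label array, `isoValue` the threshold
#'   used, `gridVolume` the volume the labels refer to.
#' @name mockup-accessors
#' @aliases gridLabels isoValue gridVolume
NULL

#' @rdname mockup-accessors
#' @export
setGeneric("gridLabels", function(x) standardGeneric("gridLabels"))
#' @rdname mockup-accessors
#' @export
setGeneric("isoValue", function(x) standardGeneric("isoValue"))
#' @rdname mockup-accessors
#' @export
setGeneric("gridVolume", function(x) standardGeneric("gridVolume"))

#' @rdname mockup-accessors
setMethod("gridLabels", "MockupGrid", function(x) x@labels)
#' @rdname mockup-accessors
setMethod("isoValue", "MockupGrid", function(x) x@isoValue)
#' @rdname mockup-accessors
setMethod("gridVolume", "MockupGrid", function(x) x@volume)

#' Accessors for TriangleMesh
#'
#' @param x a [TriangleMesh-class].
#' @return `vertices` N x 3 mm matrix, `triangles` M x 3 index matrix,
#'   `normals` N x 3 unit-normal matrix (0 rows when unset), `scalarField`
#'   the per-vertex scalar values, `vertexColors` the RGB matrix,
#'   `nVertices`/`nTriangles` counts.
#' @name mesh-accessors
#' @aliases vertices triangles normals scalarField vertexColors nVertices
#'   nTriangles
NULL

#' @rdname mesh-accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname mesh-accessors
#' @export
setGeneric("triangles", function(x) standardGeneric("triangles"))
#' @rdname mesh-accessors
#' @export
setGeneric("normals", function(x) standardGeneric("normals"))
#' @rdname mesh-accessors
#' @export
setGeneric("scalarField", function(x) standardGeneric("scalarField"))
#' @rdname mesh-accessors
#' @export
setGeneric("vertexColors", function(x) standardGeneric("vertexColors"))
#' @rdname mesh-accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname mesh-accessors
#' @export
setGeneric("nTriangles", function(x) standardGeneric("nTriangles"))

#' @rdname mesh-accessors
setMethod("vertices", "TriangleMesh", function(x) x@vertices)
#' @rdname mesh-accessors
setMethod("triangles", "TriangleMesh", function(x) x@triangles)
#' @rdname mesh-accessors
setMethod("normals", "TriangleMesh", function(x) x@normals)
#' @rdname mesh-accessors
setMethod("scalarField", "TriangleMesh", function(x) x@scalar)
#' @rdname mesh-accessors
setMethod("vertexColors", "TriangleMesh", function(x) x@colors)
#' @rdname mesh-accessors
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))
#' @rdname mesh-accessors
setMethod("nTriangles", "TriangleMesh", function(x) nrow(x@triangles))

#' Accessors for RigidTransform
#'
#' @param x a [RigidTransform-class].
#' @return `rotation` the 3x3 rotation matrix, `translation` the mm
#'   3-vector.
#' @name transform-accessors
#' @aliases rotation translation
NULL

#' @rdname transform-accessors
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))
#' @rdname transform-accessors
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))

#' @rdname transform-accessors
setMethod("rotation", "RigidTransform", function(x) x@rotation)
#' @rdname transform-accessors
setMethod("translation", "RigidTransform", function(x) x@translation)

#' Accessors for RegistrationResult
#'
#' @param x a [RegistrationResult-class].
#' @return `transform` the final [RigidTransform-class], `perStageRMS`
#'   named RMS distances (mm) per stage, `hausdorffValue` the symmetric
#'   Hausdorff distance (mm), `iterationsUsed` ICP iteration counts.
#' @name result-accessors
#' @aliases transform perStageRMS hausdorffValue iterationsUsed
NULL

#' @rdname result-accessors
#' @export
setGeneric("transform", function(x) standardGeneric("transform"))
#' @rdname result-accessors
#' @export
setGeneric("perStageRMS", function(x) standardGeneric("perStageRMS"))
#' @rdname result-accessors
#' @export
setGeneric("hausdorffValue", function(x) standardGeneric("hausdorffValue"))
#' @rdname result-accessors
#' @export
setGeneric("iterationsUsed", function(x) standardGeneric("iterationsUsed"))

#' @rdname result-accessors
setMethod("transform", "RegistrationResult", function(x) x@transform)
#' @rdname result-accessors
setMethod("perStageRMS", "RegistrationResult", function(x) x@perStageRMS)
#' @rdname result-accessors
setMethod("hausdorffValue", "RegistrationResult", function(x) x@hausdorff)
#' @rdname result-accessors
setMethod("iterationsUsed", "RegistrationResult", function(x) x@iterations)

#' @describeIn volume-accessors compact display.
#' @param object object to display.
setMethod("show", "VolumetricImage", function(object) {
    d <- dim(object@data)
    cat(sprintf("VolumetricImage %d x %d x %d voxels\n", d[1], d[2], d[3]))
    cat(sprintf("  spacing : %s mm\n",
                paste(format(object@spacing), collapse = " x ")))
    cat(sprintf("  origin  : (%s) mm\n",
                paste(format(object@origin), collapse = ", ")))
    cat(sprintf("  intensity range: [%g, %g]\n",
                min(object@data), max(object@data)))
})

#' @describeIn mockup-accessors compact display.
#' @param object object to display.
setMethod("show", "MockupGrid", function(object) {
    n <- tabulate(as.integer(object@labels) + 1L, 3L)
    cat(sprintf("MockupGrid (iso-value %g)\n", object@isoValue))
    cat(sprintf("  background (0): %d  body edge (1): %d  interior (2): %d\n",
                n[1], n[2], n[3]))
})

#' @describeIn mesh-accessors compact display.
#' @param object object to display.
setMethod("show", "TriangleMesh", function(object) {
    cat(sprintf("TriangleMesh: %d vertices, %d triangles\n",
                nrow(object@vertices), nrow(object@triangles)))
    if (nrow(object@normals) > 0L) cat("  with vertex normals\n")
    if (length(object@scalar) > 0L)
        cat(sprintf("  scalar field range [%.3g, %.3g]\n",
                    min(object@scalar), max(object@scalar)))
    if (nrow(object@colors) > 0L) cat("  with vertex colours\n")
})

#' @describeIn transform-accessors compact display.
#' @param object object to display.
setMethod("show", "RigidTransform", function(object) {
    cat("RigidTransform\n")
    cat(sprintf("  rotation angle: %.4f deg\n", rotationAngle(object)))
    cat(sprintf("  translation   : (%s) mm\n",
                paste(format(object@translation, digits = 4),
                      collapse = ", ")))
})

#' @describeIn result-accessors compact display.
#' @param object object to display.
setMethod("show", "RegistrationResult", function(object) {
    cat("RegistrationResult\n")
    cat(sprintf("  Hausdorff: %.3f mm\n", object@hausdorff))
    cat(sprintf("  stage RMS (mm): %s\n",
                paste(sprintf("%s=%.3f", names(object@perStageRMS),
                              object@perStageRMS), collapse = "  ")))
    cat(sprintf("  ICP iterations: %s\n",
                paste(sprintf("%s=%d", names(object@iterations),
                              object@iterations), collapse = "  ")))
    show(object@transform)
})
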