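#' Pixel size accessor
#' @param x an object with a physical pixel calibration.
#' @return pixel pitch in nm.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Channel label accessor
#' @param x an object carrying a channel label.
#' @return the channel label.
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))

#' Pixel matrix accessor
#' @param x an \linkS4class{ImageChannel} or \linkS4class{SynapseMask}.
#' @return the underlying matrix (rows = y, columns = x).
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' Mask area in square micrometers
#' @param x a \linkS4class{SynapseMask}.
#' @return true-pixel count times \code{(pixel_size_nm / 1000)^2}.
#' @export
setGeneric("maskArea", function(x) standardGeneric("maskArea"))

#' Per-punctum record table accessor
#' @param x a \linkS4class{PunctaSet} or \linkS4class{SceneSpec}.
#' @return a \code{data.frame} with one row per punctum.
#' @export
setGeneric("punctaTable", function(x) standardGeneric("punctaTable"))

#' Label image accessor
#' @param x a \linkS4class{PunctaSet}.
#' @return integer matrix mapping pixels to punctum labels (0 = background).
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))

#' @rdname pixelSize
setMethod("pixelSize", "ImageChannel", function(x) x@pixel_size_nm)
#' @rdname pixelSize
setMethod("pixelSize", "SynapseMask", function(x) x@pixel_size_nm)
#' @rdname pixelSize
setMethod("pixelSize", "PunctaSet", function(x) x@pixel_size_nm)
#' @rdname pixelSize
setMethod("pixelSize", "SceneSpec", function(x) x@pixel_size_nm)

#' @rdname channelName
setMethod("channelName", "ImageChannel", function(x) x@channel)
#' @rdname channelName
setMethod("channelName", "PunctaSet", function(x) x@channel)

#' @rdname imageData
setMethod("imageData", "ImageChannel", function(x) x@pixels)
#' @rdname imageData
setMethod("imageData", "SynapseMask", function(x) x@pixels)

#' @rdname maskArea
setMethod("maskArea", "SynapseMask", function(x)
    sum(x@pixels) * (x@pixel_size_nm / 1000)^2)

#' @rdname punctaTable
setMethod("punctaTable", "PunctaSet", function(x) x@puncta)
#' @rdname punctaTable
setMethod("punctaTable", "SceneSpec", function(x) x@puncta)

#' @rdname labelImage
setMethod("labelImage", "PunctaSet", function(x) x@label_image)

setMethod("show", "SceneSpec", function(object) {
    cat(sprintf("SceneSpec: %d x %d px at %g nm/px (%.2f x %.2f um)\n",
                object@width_px, object@height_px, object@pixel_size_nm,
                object@width_px * object@pixel_size_nm / 1000,
                object@height_px * object@pixel_size_nm / 1000))
    cat(sprintf("  channels: %s\n", paste(object@channels, collapse = ", ")))
    tb <- table(object@puncta$channel)
    cat(sprintf("  puncta: %d (%s)\n", nrow(object@puncta),
                paste(sprintf("%s: %d", names(tb), tb), collapse = ", ")))
    cat(sprintf("  background %g, read noise SD %g, seed %d\n",
                object@background_level, object@read_noise_sd,
                object@rng_seed))
})

setMethod("show", "ImageChannel", function(object) {
    cat(sprintf("ImageChannel '%s': %d x %d px at %g nm/px, range [%g, %g]\n",
                object@channel, nrow(object@pixels), ncol(object@pixels),
                object@pixel_size_nm, min(object@pixels), max(object@pixels)))
})

setMethod("show", "SynapseMask", function(object) {
    cat(sprintf("SynapseMask: %d x %d px, %d true pixels, %.3f um^2\n",
                nrow(object@pixels), ncol(object@pixels), sum(object@pixels),
                maskArea(object)))
})

setMethod("show", "ThresholdResult", function(object) {
    cat(sprintf(paste0("ThresholdResult: threshold %.4g (background peak bin",
                       " %d, trough bin %d, object peak bin %d of %d)\n"),
                object@threshold, object@background_peak_bin,
                object@trough_bin, object@object_peak_bin,
                length(object@histogram)))
})

setMethod("show", "PunctaSet", function(object) {
    cat(sprintf("PunctaSet '%s': %d puncta at %g nm/px%s\n", object@channel,
                nrow(object@puncta), object@pixel_size_nm,
                if (length(object@label_image)) "" else " (no label image)"))
})

setMethod("show", "AssociationGraph", function(object) {
    cat(sprintf(
        "AssociationGraph %s <-> %s: %d + %d puncta, %d edges (radius %g nm)\n",
        object@channel_a, object@channel_b, length(object@nodes_a),
        length(object@nodes_b), nrow(object@edges), object@radius_nm))
})

setMethod("show", "ColocCategoryTable", function(object) {
    cat(sprintf("ColocCategoryTable (%s):\n", object@scheme))
    print(data.frame(category = names(object@counts),
                     count = as.integer(object@counts),
                     normalized = round(object@normalized, 4),
                     row.names = NULL))
})

setMethod("show", "GroupStats", function(object) {
    cat(sprintf("GroupStats: n = %d, mean = %.4g, sd = %.4g, sem = %.4g\n",
                object@n, object@mean, object@sd, object@sem))
})

setMethod("show", "TTestResult", function(object) {
    cat(sprintf("Two-tailed unpaired t-test (%s): t = %.4f, df = %g, p = %.4g\n",
                object@method, object@t_statistic,
                object@degrees_of_freedom, object@p_value))
})
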