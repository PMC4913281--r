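#' @import methods
NULL

# Coordinate convention used throughout: continuous nm coordinates with the
# origin at the top-left image corner; the center of pixel (r, c) (1-based R
# matrix indices, r = row = y, c = column = x) lies at
# x = (c - 0.5) * pixel_size_nm, y = (r - 0.5) * pixel_size_nm.

#' SceneSpec: a fully specified synthetic dual-channel scene
#'
#' Holds the ground truth for a simulated STED-like acquisition: image
#' geometry, channel labels, one row per ground-truth punctum, the synapse
#' mask specification, background and read-noise levels, and the seed that
#' generated it.  The \code{puncta} slot is a \code{data.frame} with columns
#' \code{punctum_id}, \code{channel}, \code{x_nm}, \code{y_nm},
#' \code{amplitude}, \code{fwhm_true_nm}, \code{motif_id}, \code{motif_role}.
#'
#' @slot width_px,height_px image size in pixels.
#' @slot pixel_size_nm physical pixel pitch in nm (default 20).
#' @slot channels character vector of unique channel labels.
#' @slot puncta ground-truth punctum table (see Description).
#' @slot mask_spec a \linkS4class{MaskSpec}.
#' @slot background_level uniform background in counts.
#' @slot read_noise_sd Gaussian read-noise standard deviation in counts.
#' @slot rng_seed integer seed the scene was built from.
#' @export
setClass("SceneSpec", representation(
    width_px = "integer", height_px = "integer", pixel_size_nm = "numeric",
    channels = "character", puncta = "data.frame", mask_spec = "ANY",
    background_level = "numeric", read_noise_sd = "numeric",
    rng_seed = "integer"))

setValidity("SceneSpec", function(object) {
    msg <- character(0)
    if (object@width_px < 1L || object@height_px < 1L)
        msg <- c(msg, "image dimensions must be positive")
    if (object@pixel_size_nm <= 0)
        msg <- c(msg, "pixel_size_nm must be > 0")
    if (anyDuplicated(object@channels))
        msg <- c(msg, "channel labels must be unique")
    if (object@background_level < 0 || object@read_noise_sd < 0)
        msg <- c(msg, "background_level and read_noise_sd must be >= 0")
    p <- object@puncta
    if (nrow(p)) {
        need <- c("punctum_id", "channel", "x_nm", "y_nm", "amplitude",
                  "fwhm_true_nm", "motif_id", "motif_role")
        miss <- setdiff(need, names(p))
        if (length(miss))
            msg <- c(msg, paste("puncta table missing column(s):",
                                paste(miss, collapse = ", ")))
        else {
            wnm <- object@width_px * object@pixel_size_nm
            hnm <- object@height_px * object@pixel_size_nm
            if (any(p$x_nm < 0 | p$x_nm >= wnm | p$y_nm < 0 | p$y_nm >= hnm))
                msg <- c(msg, "punctum coordinates must lie within the image")
            if (any(p$fwhm_true_nm <= 0)) msg <- c(msg, "fwhm_true_nm must be > 0")
            if (any(p$amplitude <= 0)) msg <- c(msg, "amplitude must be > 0")
            if (!all(p$channel %in% object@channels))
                msg <- c(msg, "punctum channel not among scene channels")
            ctr <- p$motif_role == "center"
            if (any(ctr & is.na(p$motif_id)))
                msg <- c(msg, "motif_role 'center' requires motif_id")
        }
    }
    if (length(msg)) msg else TRUE
})

#' MaskSpec: parametric description of the synapse analysis mask
#'
#' @slot shape one of \code{"ellipse_band"}, \code{"rectangle"},
#'   \code{"custom"}.
#' @slot params named list of geometry parameters in nm (see
#'   \code{\link{maskSpec}}).
#' @slot fold_line_spacing_nm spacing of junctional-fold guide lines, or
#'   \code{NA} (informational only; not rendered).
#' @export
setClass("MaskSpec", representation(
    shape = "character", params = "list", fold_line_spacing_nm = "numeric"))

setValidity("MaskSpec", function(object) {
    if (!object@shape %in% c("ellipse_band", "rectangle", "custom"))
        return("shape must be 'ellipse_band', 'rectangle' or 'custom'")
    TRUE
})

#' ImageChannel: a single-channel intensity image with physical calibration
#'
#' @slot pixels numeric matrix (rows = y, columns = x), finite and >= 0.
#' @slot pixel_size_nm physical pixel pitch in nm.
#' @slot channel channel label.
#' @export
setClass("ImageChannel", representation(
    pixels = "matrix", pixel_size_nm = "numeric", channel = "character"))

setValidity("ImageChannel", function(object) {
    msg <- character(0)
    if (!length(object@pixels)) msg <- c(msg, "pixel grid must be non-empty")
    if (any(!is.finite(object@pixels)))
        msg <- c(msg, "all pixels must be finite")
    else if (any(object@pixels < 0)) msg <- c(msg, "all pixels must be >= 0")
    if (object@pixel_size_nm <= 0) msg <- c(msg, "pixel_size_nm must be > 0")
    if (length(msg)) msg else TRUE
})

#' SynapseMask: binary analysis region (AChR-cluster analogue)
#'
#' @slot pixels logical matrix, same shape as the images it restricts.
#' @slot pixel_size_nm physical pixel pitch in nm.
#' @export
setClass("SynapseMask", representation(
    pixels = "matrix", pixel_size_nm = "numeric"))

setValidity("SynapseMask", function(object) {
    if (!is.logical(object@pixels)) return("mask pixels must be logical")
    if (!any(object@pixels)) return("mask must cover at least one pixel")
    if (object@pixel_size_nm <= 0) return("pixel_size_nm must be > 0")
    TRUE
})

#' ThresholdResult: outcome of histogram-trough auto-thresholding
#'
#' Bin indices are 1-based into \code{histogram}; \code{breaks} has one more
#' element than \code{histogram}.  The threshold is the upper gray edge of the
#' trough bin; pixels strictly above it are objects.
#'
#' @slot threshold gray value separating background from objects.
#' @slot histogram integer bin counts over the masked pixels.
#' @slot breaks bin edges (length \code{length(histogram) + 1}).
#' @slot background_peak_bin modal (background) bin.
#' @slot object_peak_bin brightest-side object peak bin.
#' @slot trough_bin minimal-count bin strictly between the two peaks.
#' @export
setClass("ThresholdResult", representation(
    threshold = "numeric", histogram = "integer", breaks = "numeric",
    background_peak_bin = "integer", object_peak_bin = "integer",
    trough_bin = "integer"))

setValidity("ThresholdResult", function(object) {
    if (!(object@background_peak_bin < object@trough_bin &&
          object@trough_bin <= object@object_peak_bin))
        return("bin order must satisfy background < trough <= object peak")
    TRUE
})

#' PunctaSet: labeled puncta of one channel
#'
#' The \code{puncta} slot is a \code{data.frame} with one row per punctum and
#' columns \code{label}, \code{centroid_x_nm}, \code{centroid_y_nm},
#' \code{area_px}, \code{area_um2}, \code{peak_intensity},
#' \code{mean_intensity}, \code{integrated_intensity}, \code{fwhm_nm} (NA
#' until measured), \code{border_flag}.  \code{label_image} maps pixels to
#' punctum labels (0 = background); it may be a 0x0 matrix for puncta sets
#' built from coordinate tables rather than segmentation (see
#' \code{\link{punctaSetFromTable}}).
#'
#' @slot puncta per-punctum record table (see Description).
#' @slot label_image integer label matrix, or a 0x0 matrix.
#' @slot channel channel label.
#' @slot pixel_size_nm physical pixel pitch in nm.
#' @export
setClass("PunctaSet", representation(
    puncta = "data.frame", label_image = "matrix", channel = "character",
    pixel_size_nm = "numeric"))

setValidity("PunctaSet", function(object) {
    msg <- character(0)
    p <- object@puncta
    if (nrow(p) && anyDuplicated(p$label))
        msg <- c(msg, "punctum labels must be unique")
    if (length(object@label_image)) {
        labs <- sort(unique(object@label_image[object@label_image > 0]))
        if (!setequal(labs, p$label))
            msg <- c(msg, "labels in table and label_image must match")
    }
    if (object@pixel_size_nm <= 0) msg <- c(msg, "pixel_size_nm must be > 0")
    if (length(msg)) msg else TRUE
})

#' LineProfile: intensity samples along a line through a punctum
#'
#' @slot positions_nm strictly increasing sample positions along the line.
#' @slot intensities sampled intensities (bilinear interpolation).
#' @slot background_estimate mean of the outer 20\% of samples at each end.
#' @slot step_nm sampling step in nm.
#' @export
setClass("LineProfile", representation(
    positions_nm = "numeric", intensities = "numeric",
    background_estimate = "numeric", step_nm = "numeric"))

setValidity("LineProfile", function(object) {
    if (length(object@positions_nm) != length(object@intensities))
        return("positions and intensities must have equal length")
    if (any(diff(object@positions_nm) <= 0))
        return("positions must be strictly increasing")
    TRUE
})

#' AssociationGraph: cross-channel punctum pairings
#'
#' Bipartite graph between the puncta of two channels.  \code{edges} is a
#' \code{data.frame} with columns \code{id_a}, \code{id_b},
#' \code{centroid_distance_nm}, \code{overlap_px}.
#'
#' @slot edges edge table (see Description).
#' @slot nodes_a,nodes_b punctum labels of the two channels.
#' @slot channel_a,channel_b channel labels (used for scheme validation).
#' @slot radius_nm association radius the graph was built with.
#' @export
setClass("AssociationGraph", representation(
    edges = "data.frame", nodes_a = "integer", nodes_b = "integer",
    channel_a = "character", channel_b = "character", radius_nm = "numeric"))

setValidity("AssociationGraph", function(object) {
    e <- object@edges
    if (nrow(e)) {
        if (!all(e$id_a %in% object@nodes_a) ||
            !all(e$id_b %in% object@nodes_b))
            return("every edge must reference existing nodes")
        if (any(e$centroid_distance_nm < 0))
            return("centroid distances must be >= 0")
    }
    TRUE
})

#' ColocCategoryTable: categorical colocalization counts and ratios
#'
#' @slot scheme \code{"bassoon_vgcc"} (5 categories) or
#'   \code{"piccolo_bassoon"} (6 categories).
#' @slot counts named nonnegative integer vector over the scheme's categories.
#' @slot normalized counts divided by their total (all zero if total is 0).
#' @export
setClass("ColocCategoryTable", representation(
    scheme = "character", counts = "integer", normalized = "numeric"))

.coloc_categories <- list(
    bassoon_vgcc = c("1V:1B", "2V:1B", ">=3V:1B", "B_only", "V_only"),
    piccolo_bassoon = c("1P:1B", "2P:1B", ">=3P:1B", "1P:2B", "B_only",
                        "P_only"))

setValidity("ColocCategoryTable", function(object) {
    if (!object@scheme %in% names(.coloc_categories))
        return("unknown scheme")
    want <- .coloc_categories[[object@scheme]]
    if (!identical(names(object@counts), want))
        return(paste("counts must have exactly the categories:",
                     paste(want, collapse = ", ")))
    if (any(object@counts < 0)) return("counts must be nonnegative")
    tot <- sum(object@counts)
    if (tot > 0 && abs(sum(object@normalized) - 1) > 1e-9)
        return("normalized values must sum to 1")
    TRUE
})

#' GroupStats: per-group summary (n, mean, SD, SEM)
#'
#' @slot n number of observations.
#' @slot mean sample mean.
#' @slot sd sample standard deviation (n - 1 denominator).
#' @slot sem standard error of the mean, \code{sd / sqrt(n)}.
#' @export
setClass("GroupStats", representation(
    n = "integer", mean = "numeric", sd = "numeric", sem = "numeric"))

setValidity("GroupStats", function(object) {
    if (object@n < 1L) return("n must be >= 1")
    if (is.finite(object@sd) && object@sd < 0) return("sd must be >= 0")
    if (abs(object@sem - object@sd / sqrt(object@n)) > 1e-12 * max(1, object@sd))
        return("sem must equal sd / sqrt(n)")
    TRUE
})

#' TTestResult: two-tailed unpaired t-test outcome
#'
#' @slot t_statistic the t statistic.
#' @slot degrees_of_freedom residual degrees of freedom
#'   (\code{n1 + n2 - 2} for the pooled test).
#' @slot p_value two-tailed p value.
#' @slot method \code{"pooled"} or \code{"welch"}.
#' @export
setClass("TTestResult", representation(
    t_statistic = "numeric", degrees_of_freedom = "numeric",
    p_value = "numeric", method = "character"))

setValidity("TTestResult", function(object) {
    if (object@p_value < 0 || object@p_value > 1)
        return("p_value must lie in [0, 1]")
    if (object@degrees_of_freedom <= 0) return("df must be positive")
    TRUE
})

#' FrequencyDistribution: histogram of punctum sizes
#'
#' @slot bin_edges_nm increasing bin edges, anchored at 0.
#' @slot counts nonnegative integer counts per bin.
#' @export
setClass("FrequencyDistribution", representation(
    bin_edges_nm = "numeric", counts = "integer"))

setValidity("FrequencyDistribution", function(object) {
    if (length(object@counts) != length(object@bin_edges_nm) - 1L)
        return("counts must have one element fewer than bin_edges_nm")
    if (any(diff(object@bin_edges_nm) <= 0))
        return("bin edges must be strictly increasing")
    if (any(object@counts < 0)) return("counts must be nonnegative")
    TRUE
})
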