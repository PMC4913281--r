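# Synthetic dual-channel STED-like scene generation with known ground truth.
#
# The generator emulates the acquisition geometry of dual-color STED imaging
# of neuromuscular-junction active zones: 20 nm pixels, diffraction-shaped
# puncta modeled as isotropic 2D Gaussians (sigma = FWHM / 2.3548), motif
# layouts (Piccolo-Bassoon-Piccolo sandwiches with ~100 nm flank separation,
# colocalized cross-channel pairs, solitary puncta), a parametric synapse
# mask, uniform background, and Poisson shot noise plus Gaussian read noise.

.FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))  # 1/2.3548

#' Construct a synapse-mask specification
#'
#' @param shape \code{"rectangle"}, \code{"ellipse_band"} or \code{"custom"}.
#' @param ... geometry parameters in nm.  For \code{"rectangle"}:
#'   \code{x0_nm}, \code{y0_nm} (top-left corner), \code{width_nm},
#'   \code{height_nm}.  For \code{"ellipse_band"}: \code{center_x_nm},
#'   \code{center_y_nm}, outer semi-axes \code{a_nm}, \code{b_nm}, and
#'   \code{band_width_nm} (band thickness; a value >= min(a, b) gives a solid
#'   ellipse).  For \code{"custom"}: \code{pixels}, a logical matrix.
#' @param fold_line_spacing_nm optional junctional-fold spacing (metadata
#'   only).
#' @return a \linkS4class{MaskSpec}.
#' @export
maskSpec <- function(shape = c("rectangle", "ellipse_band", "custom"), ...,
                     fold_line_spacing_nm = NA_real_) {
    shape <- match.arg(shape)
    new("MaskSpec", shape = shape, params = list(...),
        fold_line_spacing_nm = as.numeric(fold_line_spacing_nm))
}

#' Describe one motif population for scene building
#'
#' @param type \code{"sandwich"} (two flank puncta in \code{flank_channel}
#'   separated by \code{flank_separation_nm} with one \code{center_channel}
#'   punctum at their midpoint), \code{"tandem_sandwich"} (the sandwich
#'   repeated in tandem, sharing the middle flank punctum),
#'   \code{"coloc_pair"} (one punctum per channel at a common position), or
#'   \code{"solitary"} (a single punctum).
#' @param n how many motifs of this type to place.
#' @param n_range optional integer range \code{c(lo, hi)}; when given, the
#'   motif count is drawn uniformly from it at scene-building time
#'   (synapse-to-synapse variability), overriding \code{n}.
#' @param flank_channel,center_channel channel labels for sandwich flanks and
#'   center (also used as the two channels of a \code{coloc_pair}).
#' @param channel channel of a \code{solitary} punctum.
#' @param flank_separation_nm flank-to-flank distance (default 100 nm).
#' @param jitter_sd_nm isotropic Gaussian positional jitter per punctum.
#' @param at_nm optional fixed motif center \code{c(x, y)} in nm (only
#'   sensible with \code{n = 1}); default random placement inside the mask.
#' @param orientation_deg optional fixed motif axis; default random.
#' @return a list describing the motif population.
#' @export
motifSpec <- function(type = c("sandwich", "tandem_sandwich", "coloc_pair",
                               "solitary"),
                      n = 1L, n_range = NULL, flank_channel = "piccolo",
                      center_channel = "bassoon", channel = flank_channel,
                      flank_separation_nm = 100, jitter_sd_nm = 0,
                      at_nm = NULL, orientation_deg = NULL) {
    type <- match.arg(type)
    stopifnot(n >= 0, flank_separation_nm > 0, jitter_sd_nm >= 0)
    if (!is.null(n_range))
        stopifnot(length(n_range) == 2, n_range[1] >= 0,
                  n_range[2] >= n_range[1])
    list(type = type, n = as.integer(n),
         n_range = if (is.null(n_range)) NULL else as.integer(n_range),
         flank_channel = flank_channel,
         center_channel = center_channel, channel = channel,
         flank_separation_nm = flank_separation_nm,
         jitter_sd_nm = jitter_sd_nm, at_nm = at_nm,
         orientation_deg = orientation_deg)
}

.mask_inclusion <- function(spec, width_px, height_px, pixel_size_nm) {
    xc <- (seq_len(width_px) - 0.5) * pixel_size_nm
    yc <- (seq_len(height_px) - 0.5) * pixel_size_nm
    p <- spec@params
    if (spec@shape == "rectangle") {
        need <- c("x0_nm", "y0_nm", "width_nm", "height_nm")
        if (!all(need %in% names(p)))
            stop("rectangle mask needs parameters: ",
                 paste(setdiff(need, names(p)), collapse = ", "))
        inx <- xc >= p$x0_nm & xc < p$x0_nm + p$width_nm
        iny <- yc >= p$y0_nm & yc < p$y0_nm + p$height_nm
        outer(iny, inx, "&")
    } else if (spec@shape == "ellipse_band") {
        need <- c("center_x_nm", "center_y_nm", "a_nm", "b_nm",
                  "band_width_nm")
        if (!all(need %in% names(p)))
            stop("ellipse_band mask needs parameters: ",
                 paste(setdiff(need, names(p)), collapse = ", "))
        dx <- xc - p$center_x_nm
        dy <- yc - p$center_y_nm
        uo <- outer((dy / p$b_nm)^2, (dx / p$a_nm)^2, "+")
        inside <- uo <= 1
        ai <- p$a_nm - p$band_width_nm
        bi <- p$b_nm - p$band_width_nm
        if (ai > 0 && bi > 0) {
            ui <- outer((dy / bi)^2, (dx / ai)^2, "+")
            inside <- inside & ui >= 1
        }
        inside
    } else {
        if (is.null(p$pixels) || !is.logical(p$pixels))
            stop("custom mask needs a logical 'pixels' matrix")
        if (nrow(p$pixels) != height_px || ncol(p$pixels) != width_px)
            stop("custom mask pixels do not match the image dimensions")
        p$pixels
    }
}

#' Realize a mask specification as a binary pixel grid
#'
#' @param spec a \linkS4class{MaskSpec}.
#' @param width_px,height_px image size in pixels.
#' @param pixel_size_nm pixel pitch in nm.
#' @return a \linkS4class{SynapseMask}; its area in um^2 is the true-pixel
#'   count times \code{(pixel_size_nm / 1000)^2} (see \code{\link{maskArea}}).
#' @export
realizeMask <- function(spec, width_px, height_px, pixel_size_nm = 20) {
    px <- .mask_inclusion(spec, as.integer(width_px), as.integer(height_px),
                          pixel_size_nm)
    if (!any(px))
        stop("mask is empty: no pixel center falls inside the '",
             spec@shape, "' geometry")
    new("SynapseMask", pixels = px, pixel_size_nm = pixel_size_nm)
}

#' Mask centroid in nm coordinates
#'
#' @param mask a \linkS4class{SynapseMask}.
#' @return \code{c(x_nm, y_nm)} of the true-pixel centroid.
#' @export
maskCentroid <- function(mask) {
    idx <- which(mask@pixels, arr.ind = TRUE)
    c(x_nm = mean((idx[, 2] - 0.5) * mask@pixel_size_nm),
      y_nm = mean((idx[, 1] - 0.5) * mask@pixel_size_nm))
}

# Binary erosion by a disc of radius r pixels (r = 0 returns the input).
.erode_mask <- function(px, r) {
    if (r <= 0L) return(px)
    h <- nrow(px); w <- ncol(px)
    out <- px
    for (dr in -r:r) for (dc in -r:r) {
        if (dr * dr + dc * dc > r * r) next
        sh <- matrix(FALSE, h, w)
        rs <- max(1L, 1L + dr):min(h, h + dr)
        cs <- max(1L, 1L + dc):min(w, w + dc)
        sh[rs, cs] <- px[rs - dr, cs - dc]
        out <- out & sh
    }
    out
}

.motif_layout <- function(m, center, theta) {
    sep <- m$flank_separation_nm
    u <- c(cos(theta), sin(theta))
    off <- function(d) center + d * u
    if (m$type == "sandwich") {
        list(pos = rbind(off(-sep / 2), off(sep / 2), off(0)),
             channel = c(m$flank_channel, m$flank_channel, m$center_channel),
             role = c("flank", "flank", "center"))
    } else if (m$type == "tandem_sandwich") {
        list(pos = rbind(off(-sep), off(0), off(sep), off(-sep / 2),
                         off(sep / 2)),
             channel = c(rep(m$flank_channel, 3), rep(m$center_channel, 2)),
             role = c(rep("flank", 3), rep("center", 2)))
    } else if (m$type == "coloc_pair") {
        list(pos = rbind(off(0), off(0)),
             channel = c(m$flank_channel, m$center_channel),
             role = c("pair_member", "pair_member"))
    } else {
        list(pos = rbind(off(0)), channel = m$channel, role = "solo")
    }
}

#' Build a synthetic scene realizing the requested motifs
#'
#' Motif centers are placed by rejection sampling uniformly over the mask,
#' honoring a minimum inter-motif spacing and a border margin; punctum
#' amplitudes and true FWHMs are drawn uniformly from the given ranges.  All
#' randomness is governed by \code{seed}: identical arguments yield an
#' identical scene.
#'
#' @param motifs list of motif populations from \code{\link{motifSpec}}.
#' @param width_px,height_px image size in pixels (default the 970 x 970 px
#'   field of a 19.4 um x 19.4 um acquisition at 20 nm pixels).
#' @param pixel_size_nm pixel pitch in nm (default 20).
#' @param channels channel labels of the scene.
#' @param mask a \linkS4class{MaskSpec} (default: centered solid ellipse
#'   covering ~60\% of the field).
#' @param background_level uniform background in counts (default 10).
#' @param read_noise_sd Gaussian read-noise SD in counts (default 1).
#' @param seed integer seed.
#' @param amplitude_range peak amplitude range above background, in counts
#'   (default 110--200: peak SNR >= 10 over the default background).
#' @param amplitude_scale_range range of a scene-wide amplitude scale
#'   factor drawn once per scene (default \code{c(1, 1)}, i.e. none);
#'   models synapse-to-synapse differences in overall protein level.
#' @param fwhm_range_nm true punctum FWHM range (default 100--125 nm, the
#'   size range of STED-resolved active-zone puncta).
#' @param min_motif_spacing_nm minimum center-to-center distance between
#'   motifs (default 400 nm).
#' @param border_margin_nm keep motif centers this far from the image edge
#'   (default 400 nm).
#' @param mask_margin_nm keep motif centers this far inside the mask
#'   boundary (default 100 nm), so that "inside the mask" is unambiguous
#'   for every ground-truth punctum.
#' @param max_tries rejection-sampling attempts per motif before giving up.
#' @return a \linkS4class{SceneSpec}.
#' @export
buildScene <- function(motifs, width_px = 970L, height_px = 970L,
                       pixel_size_nm = 20,
                       channels = c("bassoon", "piccolo"),
                       mask = NULL, background_level = 10,
                       read_noise_sd = 1, seed = 1L,
                       amplitude_range = c(110, 200),
                       amplitude_scale_range = c(1, 1),
                       fwhm_range_nm = c(100, 125),
                       min_motif_spacing_nm = 400,
                       border_margin_nm = 400, mask_margin_nm = 100,
                       max_tries = 2000L) {
    width_px <- as.integer(width_px); height_px <- as.integer(height_px)
    if (is.null(mask)) {
        w <- width_px * pixel_size_nm; h <- height_px * pixel_size_nm
        mask <- maskSpec("ellipse_band", center_x_nm = w / 2,
                         center_y_nm = h / 2, a_nm = 0.45 * w,
                         b_nm = 0.45 * h,
                         band_width_nm = 0.45 * min(w, h))
    }
    msk <- realizeMask(mask, width_px, height_px, pixel_size_nm)
    placeable <- .erode_mask(msk@pixels,
                             ceiling(mask_margin_nm / pixel_size_nm))
    if (!any(placeable))
        stop("mask interior is empty after applying the ", mask_margin_nm,
             " nm mask margin; use a thicker mask or a smaller margin")
    in_idx <- which(placeable, arr.ind = TRUE)
    wnm <- width_px * pixel_size_nm; hnm <- height_px * pixel_size_nm
    set.seed(as.integer(seed))
    centers <- matrix(numeric(0), ncol = 2)
    placed <- list()
    for (m in motifs) {
        n_this <- if (!is.null(m$n_range))
            m$n_range[1] + sample.int(m$n_range[2] - m$n_range[1] + 1L,
                                      1L) - 1L else m$n
        for (k in seq_len(n_this)) {
            if (!is.null(m$at_nm)) {
                ctr <- as.numeric(m$at_nm)
            } else {
                ok <- FALSE
                for (try in seq_len(max_tries)) {
                    i <- sample.int(nrow(in_idx), 1L)
                    ctr <- c((in_idx[i, 2] - 0.5) * pixel_size_nm,
                             (in_idx[i, 1] - 0.5) * pixel_size_nm) +
                        stats::runif(2, -pixel_size_nm / 2, pixel_size_nm / 2)
                    if (ctr[1] < border_margin_nm ||
                        ctr[1] > wnm - border_margin_nm ||
                        ctr[2] < border_margin_nm ||
                        ctr[2] > hnm - border_margin_nm) next
                    if (nrow(centers) == 0 ||
                        all(sqrt((centers[, 1] - ctr[1])^2 +
                                 (centers[, 2] - ctr[2])^2) >=
                            min_motif_spacing_nm)) { ok <- TRUE; break }
                }
                if (!ok)
                    stop("could not place ", m$n, " '", m$type, "' motif(s) ",
                         "inside the mask at the minimum inter-motif ",
                         "spacing of ", min_motif_spacing_nm, " nm")
            }
            centers <- rbind(centers, ctr)
            theta <- if (is.null(m$orientation_deg))
                stats::runif(1, 0, pi) else m$orientation_deg * pi / 180
            lay <- .motif_layout(m, ctr, theta)
            if (m$jitter_sd_nm > 0)
                lay$pos <- lay$pos + matrix(
                    stats::rnorm(length(lay$pos), 0, m$jitter_sd_nm),
                    ncol = 2)
            placed[[length(placed) + 1L]] <- lay
        }
    }
    np <- sum(vapply(placed, function(l) nrow(l$pos), integer(1)))
    if (np == 0) {
        puncta <- data.frame(punctum_id = integer(0), channel = character(0),
                             x_nm = numeric(0), y_nm = numeric(0),
                             amplitude = numeric(0),
                             fwhm_true_nm = numeric(0),
                             motif_id = integer(0), motif_role = character(0),
                             stringsAsFactors = FALSE)
    } else {
        puncta <- do.call(rbind, lapply(seq_along(placed), function(i) {
            l <- placed[[i]]
            data.frame(punctum_id = NA_integer_, channel = l$channel,
                       x_nm = l$pos[, 1], y_nm = l$pos[, 2],
                       amplitude = NA_real_, fwhm_true_nm = NA_real_,
                       motif_id = i, motif_role = l$role,
                       stringsAsFactors = FALSE)
        }))
        puncta$punctum_id <- seq_len(nrow(puncta))
        scene_scale <- stats::runif(1, amplitude_scale_range[1],
                                    amplitude_scale_range[2])
        puncta$amplitude <- scene_scale *
            stats::runif(np, amplitude_range[1], amplitude_range[2])
        puncta$fwhm_true_nm <- stats::runif(np, fwhm_range_nm[1],
                                            fwhm_range_nm[2])
        # jitter may nudge a punctum outside the field; clamp to the image
        puncta$x_nm <- pmin(pmax(puncta$x_nm, 0), wnm - 1e-9)
        puncta$y_nm <- pmin(pmax(puncta$y_nm, 0), hnm - 1e-9)
        rownames(puncta) <- NULL
    }
    new("SceneSpec", width_px = width_px, height_px = height_px,
        pixel_size_nm = pixel_size_nm, channels = channels, puncta = puncta,
        mask_spec = mask, background_level = background_level,
        read_noise_sd = read_noise_sd, rng_seed = as.integer(seed))
}

#' Render the noiseless image of one channel
#'
#' Each punctum contributes an isotropic 2D Gaussian
#' \code{amplitude * exp(-((x - x0)^2 + (y - y0)^2) / (2 sigma^2))} with
#' \code{sigma = fwhm_true_nm / 2.3548}, evaluated at pixel centers, on top
#' of the uniform background.
#'
#' @param scene a \linkS4class{SceneSpec}.
#' @param channel channel label to render.
#' @return an \linkS4class{ImageChannel}.
#' @export
renderChannel <- function(scene, channel) {
    if (!channel %in% scene@channels)
        stop("unknown channel '", channel, "'; scene has: ",
             paste(scene@channels, collapse = ", "))
    w <- scene@width_px; h <- scene@height_px; px <- scene@pixel_size_nm
    xc <- (seq_len(w) - 0.5) * px
    yc <- (seq_len(h) - 0.5) * px
    img <- matrix(scene@background_level, nrow = h, ncol = w)
    p <- scene@puncta[scene@puncta$channel == channel, , drop = FALSE]
    for (i in seq_len(nrow(p))) {
        s <- p$fwhm_true_nm[i] * .FWHM_TO_SIGMA
        r <- 5 * s  # beyond 5 sigma the Gaussian is < 4e-6 of the amplitude
        cs <- which(xc >= p$x_nm[i] - r & xc <= p$x_nm[i] + r)
        rs <- which(yc >= p$y_nm[i] - r & yc <= p$y_nm[i] + r)
        if (!length(cs) || !length(rs)) next
        gx <- exp(-(xc[cs] - p$x_nm[i])^2 / (2 * s^2))
        gy <- exp(-(yc[rs] - p$y_nm[i])^2 / (2 * s^2))
        img[rs, cs] <- img[rs, cs] + p$amplitude[i] * outer(gy, gx)
    }
    new("ImageChannel", pixels = img, pixel_size_nm = px, channel = channel)
}

#' Apply the photon-counting noise model
#'
#' Each pixel becomes \code{Poisson(value) + Normal(0, read_noise_sd)},
#' clipped at 0.  Deterministic given \code{seed}.
#'
#' @param image an \linkS4class{ImageChannel} with nonnegative pixels.
#' @param read_noise_sd Gaussian read-noise SD in counts.
#' @param seed integer seed.
#' @return a noisy \linkS4class{ImageChannel}.
#' @export
applyNoise <- function(image, read_noise_sd, seed) {
    v <- image@pixels
    if (any(v < 0)) stop("input pixels must be >= 0")
    set.seed(as.integer(seed))
    n <- length(v)
    noisy <- stats::rpois(n, as.vector(v))
    if (read_noise_sd > 0)
        noisy <- noisy + stats::rnorm(n, 0, read_noise_sd)
    new("ImageChannel",
        pixels = matrix(pmax(0, noisy), nrow = nrow(v), ncol = ncol(v)),
        pixel_size_nm = image@pixel_size_nm, channel = image@channel)
}

.gt_columns <- c("punctum_id", "channel", "x_nm", "y_nm", "amplitude",
                 "fwhm_true_nm", "motif_id", "motif_role")

.scene_sidecar <- function(path)
    file.path(dirname(path),
              paste0(sub("\\.[^.]*$", "", basename(path)), "_scene.json"))

#' Write / read scene ground truth
#'
#' \code{writeGroundTruth} writes the punctum table as CSV (columns
#' \code{punctum_id, channel, x_nm, y_nm, amplitude, fwhm_true_nm, motif_id,
#' motif_role}) plus a JSON sidecar (\code{<stem>_scene.json}) holding the
#' scene geometry, mask specification, noise model and seed.
#' \code{readGroundTruth} reverses this; the round trip reproduces the scene
#' (coordinates to 1e-3 nm).
#'
#' @param scene a \linkS4class{SceneSpec}.
#' @param path CSV file path.
#' @return \code{writeGroundTruth}: \code{path}, invisibly;
#'   \code{readGroundTruth}: a \linkS4class{SceneSpec}.
#' @export
writeGroundTruth <- function(scene, path) {
    utils::write.csv(scene@puncta, path, row.names = FALSE, quote = FALSE)
    ms <- scene@mask_spec
    meta <- list(width_px = scene@width_px, height_px = scene@height_px,
                 pixel_size_nm = scene@pixel_size_nm,
                 channels = scene@channels,
                 background_level = scene@background_level,
                 read_noise_sd = scene@read_noise_sd,
                 rng_seed = scene@rng_seed,
                 mask = list(shape = ms@shape, params = ms@params,
                             fold_line_spacing_nm = ms@fold_line_spacing_nm))
    jsonlite::write_json(meta, .scene_sidecar(path), auto_unbox = TRUE,
                         digits = NA, na = "null")
    invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
    p <- utils::read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(.gt_columns, names(p))
    if (length(miss))
        stop("ground-truth CSV is missing column(s): ",
             paste(miss, collapse = ", "))
    p <- p[, .gt_columns]
    p$motif_id <- as.integer(p$motif_id)
    p$punctum_id <- as.integer(p$punctum_id)
    meta <- jsonlite::read_json(.scene_sidecar(path), simplifyVector = TRUE)
    mp <- as.list(meta$mask$params)
    if (!is.null(mp$pixels)) mp$pixels <- as.matrix(mp$pixels)
    fl <- meta$mask$fold_line_spacing_nm
    mask <- new("MaskSpec", shape = meta$mask$shape, params = mp,
                fold_line_spacing_nm =
                    if (is.null(fl)) NA_real_ else as.numeric(fl))
    new("SceneSpec", width_px = as.integer(meta$width_px),
        height_px = as.integer(meta$height_px),
        pixel_size_nm = meta$pixel_size_nm,
        channels = as.character(meta$channels), puncta = p,
        mask_spec = mask, background_level = meta$background_level,
        read_noise_sd = meta$read_noise_sd,
        rng_seed = as.integer(meta$rng_seed))
}

#' Write / read a channel image as 16-bit grayscale TIFF
#'
#' Pixel values are rounded and clamped to [0, 65535].  The pixel size and
#' channel label are recorded in a JSON sidecar (\code{<stem>.json}).
#'
#' @param image an \linkS4class{ImageChannel}.
#' @param path TIFF file path.
#' @return \code{writeChannelTiff}: \code{path}, invisibly;
#'   \code{readChannelTiff}: an \linkS4class{ImageChannel}.
#' @export
writeChannelTiff <- function(image, path) {
    v <- pmin(pmax(round(image@pixels), 0), 65535)
    tiff::writeTIFF(v / 65535, path, bits.per.sample = 16,
                    compression = "none")
    jsonlite::write_json(list(pixel_size_nm = image@pixel_size_nm,
                              channel = image@channel),
                         paste0(sub("\\.[^.]*$", "", path), ".json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeChannelTiff
#' @export
readChannelTiff <- function(path) {
    v <- tiff::readTIFF(path, as.is = TRUE)
    meta <- jsonlite::read_json(paste0(sub("\\.[^.]*$", "", path), ".json"),
                                simplifyVector = TRUE)
    new("ImageChannel", pixels = matrix(as.numeric(v), nrow = nrow(v)),
        pixel_size_nm = meta$pixel_size_nm, channel = meta$channel)
}

#' Write / read a synapse mask as 8-bit TIFF
#'
#' @param mask a \linkS4class{SynapseMask}.
#' @param path TIFF file path.
#' @param pixel_size_nm pixel pitch for \code{readMaskTiff}.
#' @return \code{writeMaskTiff}: \code{path}, invisibly;
#'   \code{readMaskTiff}: a \linkS4class{SynapseMask}.
#' @export
writeMaskTiff <- function(mask, path) {
    tiff::writeTIFF(mask@pixels * 1, path, bits.per.sample = 8,
                    compression = "none")
    invisible(path)
}

#' @rdname writeMaskTiff
#' @export
readMaskTiff <- function(path, pixel_size_nm = 20) {
    v <- tiff::readTIFF(path, as.is = TRUE)
    new("SynapseMask", pixels = matrix(v > 0, nrow = nrow(v)),
        pixel_size_nm = pixel_size_nm)
}
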