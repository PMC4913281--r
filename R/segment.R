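# Thresholding, punctum segmentation and deconvolution.

# Strict-local-maximum peak finding on a histogram.  A peak is a run of equal
# counts whose outer neighbors are both strictly smaller (a missing neighbor
# at the array boundary counts as smaller); a plateau contributes its dimmest
# bin.  Returns 1-based bin indices.
.histogram_peaks <- function(counts) {
    nb <- length(counts)
    peaks <- integer(0)
    i <- 1L
    while (i <= nb) {
        j <- i
        while (j < nb && counts[j + 1L] == counts[i]) j <- j + 1L
        left <- if (i == 1L) -Inf else counts[i - 1L]
        right <- if (j == nb) -Inf else counts[j + 1L]
        if (counts[i] > left && counts[i] > right && counts[i] > 0)
            peaks <- c(peaks, i)
        i <- j + 1L
    }
    peaks
}

#' Histogram-trough auto-threshold for bright objects
#'
#' Builds a gray-value histogram of the masked pixels, takes the modal bin as
#' the background peak, the highest-count strict local maximum at a strictly
#' brighter bin as the object peak, and the minimal-count bin strictly
#' between the two (ties broken toward the dimmest bin) as the trough.  The
#' threshold is the upper gray edge of the trough bin; pixels strictly above
#' it are objects.
#'
#' Binning: integer-valued images whose masked range spans at most 256 gray
#' levels are binned one bin per gray level; otherwise \code{n_bins}
#' equal-width bins over the masked [min, max] range.
#'
#' The object-peak search starts beyond the background clump: candidate
#' bins must lie at or past the first bin brighter than the background peak
#' whose count has decayed to \code{bg_decay_frac} of the modal count.
#' Without this guard, count fluctuations on the flank of a heavily
#' populated background mode (Poisson shot noise across tens of thousands
#' of background pixels) masquerade as the brightest local maximum and pull
#' the threshold into the background.  On a well-separated bimodal
#' histogram the guard changes nothing.
#'
#' @param image an \linkS4class{ImageChannel}.
#' @param mask a \linkS4class{SynapseMask} covering at least 100 pixels, or
#'   \code{NULL} to use the whole image.
#' @param n_bins number of equal-width bins for non-integer data
#'   (default 256).
#' @param bg_decay_frac background-decay fraction defining where the object
#'   search may start (default 0.01).
#' @return a \linkS4class{ThresholdResult}.
#' @export
autoThresholdLight <- function(image, mask = NULL, n_bins = 256L,
                               bg_decay_frac = 0.01) {
    v <- if (is.null(mask)) as.vector(image@pixels) else {
        if (!identical(dim(image@pixels), dim(mask@pixels)))
            stop("image and mask dimensions differ")
        image@pixels[mask@pixels]
    }
    if (length(v) < 100L)
        stop("mask too small: auto-thresholding needs >= 100 pixels")
    if (length(unique(v)) < 2L)
        stop("NoObjectPeak: image is constant inside the mask")
    rng <- range(v)
    integerish <- all(abs(v - round(v)) < 1e-9) && diff(rng) <= 256
    if (integerish) {
        lv <- as.integer(round(v))
        lo <- min(lv); hi <- max(lv)
        breaks <- seq(lo - 0.5, hi + 0.5, by = 1)
        counts <- tabulate(lv - lo + 1L, nbins = hi - lo + 1L)
    } else {
        breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
        idx <- findInterval(v, breaks, rightmost.closed = TRUE)
        counts <- tabulate(pmin(pmax(idx, 1L), n_bins), nbins = n_bins)
    }
    bg <- which.max(counts)  # modal bin; ties resolve to the dimmest
    peaks <- .histogram_peaks(counts)
    # object candidates start where the background clump has decayed
    floor_ct <- bg_decay_frac * counts[bg]
    past <- which(counts <= floor_ct)
    past <- past[past > bg]
    start <- if (length(past)) min(past) else bg + 1L
    op <- peaks[peaks >= start]
    if (!length(op))
        stop("NoObjectPeak: no local maximum brighter than the background ",
             "peak")
    obj <- op[which.max(counts[op])]  # ties resolve to the dimmest
    if (obj - bg < 2L)
        stop("NoObjectPeak: object peak is adjacent to the background peak; ",
             "no trough bin exists between them")
    between <- (bg + 1L):(obj - 1L)
    trough <- between[which.min(counts[between])]
    new("ThresholdResult", threshold = breaks[trough + 1L],
        histogram = as.integer(counts), breaks = as.numeric(breaks),
        background_peak_bin = as.integer(bg),
        object_peak_bin = as.integer(obj), trough_bin = as.integer(trough))
}

# 8-connected labeling of a logical matrix by iterative minimum-label
# propagation (vectorized over the eight neighbor shifts).  Returns an
# integer matrix with labels renumbered 1..k in raster order.
.label_components8 <- function(b) {
    h <- nrow(b); w <- ncol(b)
    lab <- matrix(0L, h, w)
    lab[b] <- seq_len(sum(b))
    repeat {
        changed <- FALSE
        for (dr in -1:1) for (dc in -1:1) {
            if (dr == 0L && dc == 0L) next
            sh <- matrix(0L, h, w)
            rs <- max(1L, 1L + dr):min(h, h + dr)
            cs <- max(1L, 1L + dc):min(w, w + dc)
            sh[rs, cs] <- lab[rs - dr, cs - dc]
            upd <- b & sh > 0L & (lab == 0L | sh < lab)
            if (any(upd)) { lab[upd] <- sh[upd]; changed <- TRUE }
        }
        if (!changed) break
    }
    u <- sort(unique(lab[lab > 0L]))
    if (length(u)) lab[lab > 0L] <- match(lab[lab > 0L], u)
    lab
}

#' Segment puncta above a threshold inside the synapse mask
#'
#' Objects are 8-connected components of \code{pixels > threshold}.  A
#' component is kept when its size is at least \code{min_size_px} and its
#' intensity-weighted centroid falls on a mask pixel.  Components touching
#' the image edge are flagged (\code{border_flag}); they count toward
#' density, but FWHM and per-punctum intensity analyses should skip them.
#'
#' @param image an \linkS4class{ImageChannel}.
#' @param threshold finite gray-value threshold (usually from
#'   \code{\link{autoThresholdLight}}).
#' @param mask a \linkS4class{SynapseMask} (same shape as the image), or
#'   \code{NULL} for no restriction.
#' @param min_size_px minimum component size in pixels (default 4).
#' @return a \linkS4class{PunctaSet}.
#' @export
segmentPuncta <- function(image, threshold, mask = NULL, min_size_px = 4L) {
    stopifnot(is.finite(threshold), min_size_px >= 1L)
    img <- image@pixels
    px <- image@pixel_size_nm
    if (!is.null(mask) && !identical(dim(img), dim(mask@pixels)))
        stop("image and mask dimensions differ")
    lab <- .label_components8(img > threshold)
    nlab <- max(lab)
    h <- nrow(img); w <- ncol(img)
    fg <- which(lab > 0L)
    groups <- split(fg, lab[fg])
    keep_rows <- list()
    relabel <- integer(nlab)
    nxt <- 0L
    for (l in seq_along(groups)) {
        lin <- groups[[l]]
        if (length(lin) < min_size_px) next
        rows <- ((lin - 1L) %% h) + 1L
        cols <- ((lin - 1L) %/% h) + 1L
        ints <- img[lin]
        cx <- sum((cols - 0.5) * px * ints) / sum(ints)
        cy <- sum((rows - 0.5) * px * ints) / sum(ints)
        if (!is.null(mask)) {
            r <- min(max(floor(cy / px) + 1L, 1L), h)
            c <- min(max(floor(cx / px) + 1L, 1L), w)
            if (!mask@pixels[r, c]) next
        }
        nxt <- nxt + 1L
        relabel[as.integer(names(groups)[l])] <- nxt
        keep_rows[[nxt]] <- data.frame(
            label = nxt, centroid_x_nm = cx, centroid_y_nm = cy,
            area_px = length(lin), area_um2 = length(lin) * (px / 1000)^2,
            peak_intensity = max(ints), mean_intensity = mean(ints),
            integrated_intensity = sum(ints), fwhm_nm = NA_real_,
            border_flag = any(rows == 1L | rows == h |
                              cols == 1L | cols == w))
    }
    lab[fg] <- relabel[lab[fg]]
    puncta <- if (length(keep_rows)) do.call(rbind, keep_rows) else
        data.frame(label = integer(0), centroid_x_nm = numeric(0),
                   centroid_y_nm = numeric(0), area_px = integer(0),
                   area_um2 = numeric(0), peak_intensity = numeric(0),
                   mean_intensity = numeric(0),
                   integrated_intensity = numeric(0), fwhm_nm = numeric(0),
                   border_flag = logical(0))
    new("PunctaSet", puncta = puncta, label_image = lab,
        channel = image@channel, pixel_size_nm = px)
}

# Gaussian PSF kernel, normalized to unit sum, truncated at ~4 sigma.
.gaussian_psf <- function(fwhm_nm, pixel_size_nm) {
    s <- fwhm_nm * .FWHM_TO_SIGMA / pixel_size_nm
    r <- max(2L, ceiling(4 * s))
    x <- (-r):r
    k <- exp(-outer(x^2, x^2, "+") / (2 * s^2))
    k / sum(k)
}

# 2D convolution with reflective boundary handling via FFT on a
# reflect-padded copy.  Kernel must be odd-sized and centered.
.convolve_reflect <- function(img, kern) {
    r <- (nrow(kern) - 1L) / 2L
    n1 <- nrow(img); n2 <- ncol(img)
    pr <- c(r:1, 1:n1, n1:(n1 - r + 1L))
    pc <- c(r:1, 1:n2, n2:(n2 - r + 1L))
    pimg <- img[pr, pc]
    N1 <- nrow(pimg); N2 <- ncol(pimg)
    K <- matrix(0, N1, N2)
    K[seq_len(nrow(kern)), seq_len(ncol(kern))] <- kern
    K <- K[c((r + 1L):N1, seq_len(r)), c((r + 1L):N2, seq_len(r))]
    out <- Re(stats::fft(stats::fft(pimg) * stats::fft(K), inverse = TRUE)) /
        (N1 * N2)
    out[(r + 1L):(r + n1), (r + 1L):(r + n2)]
}

#' Richardson-Lucy deconvolution with a Gaussian PSF
#'
#' Multiplicative maximum-likelihood iterations with reflective boundary
#' handling.  Zero iterations return the input unchanged; the output is
#' nonnegative and conserves total flux (within the reflective-boundary
#' approximation).  More iterations monotonically sharpen an isolated
#' blurred punctum.
#'
#' @param image an \linkS4class{ImageChannel}.
#' @param psf_fwhm_nm FWHM of the Gaussian point-spread-function model
#'   (default 100 nm, a typical effective STED PSF width).
#' @param iterations number of iterations (>= 0).
#' @return the deconvolved \linkS4class{ImageChannel}.
#' @export
deconvolve <- function(image, psf_fwhm_nm = 100, iterations = 10L) {
    if (psf_fwhm_nm <= 0) stop("psf_fwhm_nm must be > 0")
    iterations <- as.integer(iterations)
    stopifnot(iterations >= 0L)
    if (iterations == 0L) return(image)
    img <- image@pixels
    kern <- .gaussian_psf(psf_fwhm_nm, image@pixel_size_nm)
    eps <- 1e-12
    est <- pmax(img, eps)
    for (i in seq_len(iterations)) {
        pred <- pmax(.convolve_reflect(est, kern), eps)
        est <- est * .convolve_reflect(img / pred, kern)
        est[est < 0] <- 0
    }
    new("ImageChannel", pixels = est, pixel_size_nm = image@pixel_size_nm,
        channel = image@channel)
}
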