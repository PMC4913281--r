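# Per-punctum and per-synapse measurements: line-profile FWHM, intensity per
# area, intensity per punctum, puncta density, and hierarchical sampling of
# representative puncta.

# Bilinear interpolation of img at continuous nm coordinates (vectorized).
# Pixel (r, c) center is at ((c - 0.5) px, (r - 0.5) px).
.bilinear <- function(img, x_nm, y_nm, pixel_size_nm) {
    c0 <- x_nm / pixel_size_nm + 0.5
    r0 <- y_nm / pixel_size_nm + 0.5
    c1 <- pmin(pmax(floor(c0), 1), ncol(img) - 1L)
    r1 <- pmin(pmax(floor(r0), 1), nrow(img) - 1L)
    fc <- pmin(pmax(c0 - c1, 0), 1)
    fr <- pmin(pmax(r0 - r1, 0), 1)
    img[cbind(r1, c1)] * (1 - fr) * (1 - fc) +
        img[cbind(r1 + 1L, c1)] * fr * (1 - fc) +
        img[cbind(r1, c1 + 1L)] * (1 - fr) * fc +
        img[cbind(r1 + 1L, c1 + 1L)] * fr * fc
}

# Intensity-weighted principal-axis orientation (radians) from the second
# moments of background-subtracted intensities in a window around (x0, y0).
.principal_axis <- function(img, x0, y0, radius_nm, pixel_size_nm) {
    h <- nrow(img); w <- ncol(img)
    rs <- max(1L, floor((y0 - radius_nm) / pixel_size_nm) + 1L):
        min(h, ceiling((y0 + radius_nm) / pixel_size_nm))
    cs <- max(1L, floor((x0 - radius_nm) / pixel_size_nm) + 1L):
        min(w, ceiling((x0 + radius_nm) / pixel_size_nm))
    sub <- img[rs, cs, drop = FALSE]
    wts <- sub - min(sub)
    if (sum(wts) <= 0) return(0)
    xs <- (cs - 0.5) * pixel_size_nm
    ys <- (rs - 0.5) * pixel_size_nm
    W <- sum(wts)
    mx <- sum(t(wts) * xs) / W
    my <- sum(wts * ys) / W
    dx <- matrix(xs, nrow = length(rs), ncol = length(cs), byrow = TRUE) - mx
    dy <- matrix(ys, nrow = length(rs), ncol = length(cs)) - my
    sxx <- sum(wts * dx * dx); syy <- sum(wts * dy * dy)
    sxy <- sum(wts * dx * dy)
    # Near-isotropic puncta have no defined major axis.  The canonical
    # direction is 22.5 degrees off the pixel lattice: lattice-aligned (or
    # diagonal) lines sample the bilinear surface at a fixed knot phase and
    # maximize interpolation aliasing, while an off-lattice direction
    # spreads the sample phases uniformly.
    aniso <- sqrt((sxx - syy)^2 + 4 * sxy^2) / (sxx + syy)
    if (!is.finite(aniso) || aniso < 0.05) return(pi / 8)
    0.5 * atan2(2 * sxy, sxx - syy)
}

#' Extract an intensity line profile through a punctum
#'
#' Samples the image by bilinear interpolation at \code{pixel_size_nm / 2}
#' steps along a line through the punctum's peak pixel, oriented along the
#' punctum's intensity-weighted major axis, long enough to include the
#' background level on both sides.  The background estimate is the mean of
#' the outer 20\% of samples at each end.
#'
#' @param image an \linkS4class{ImageChannel}.
#' @param punctum one row of a \linkS4class{PunctaSet} table (needs
#'   \code{centroid_x_nm}, \code{centroid_y_nm}; \code{border_flag} must be
#'   \code{FALSE}).
#' @param length_nm profile length; default
#'   \code{max(600, 3 * expected_fwhm_nm)}.
#' @param expected_fwhm_nm expected punctum FWHM, used for the default
#'   length and the orientation window (default 120 nm).
#' @param label_image optional label image; when given, the peak pixel is
#'   the brightest pixel of the punctum's component, otherwise the brightest
#'   pixel within \code{expected_fwhm_nm} of the centroid.
#' @return a \linkS4class{LineProfile}.
#' @export
extractProfile <- function(image, punctum, length_nm = NULL,
                           expected_fwhm_nm = 120, label_image = NULL) {
    if (isTRUE(punctum$border_flag))
        stop("punctum touches the image border; profile would be truncated")
    if (is.null(length_nm)) length_nm <- max(600, 3 * expected_fwhm_nm)
    img <- image@pixels
    px <- image@pixel_size_nm
    h <- nrow(img); w <- ncol(img)
    # peak pixel
    if (!is.null(label_image) && length(label_image) &&
        !is.null(punctum$label)) {
        lin <- which(label_image == punctum$label)
        if (!length(lin)) stop("label not present in label_image")
        pk <- lin[which.max(img[lin])]
        pr <- ((pk - 1L) %% h) + 1L
        pc <- ((pk - 1L) %/% h) + 1L
    } else {
        rs <- max(1L, floor((punctum$centroid_y_nm - expected_fwhm_nm) / px) +
                      1L):
            min(h, ceiling((punctum$centroid_y_nm + expected_fwhm_nm) / px))
        cs <- max(1L, floor((punctum$centroid_x_nm - expected_fwhm_nm) / px) +
                      1L):
            min(w, ceiling((punctum$centroid_x_nm + expected_fwhm_nm) / px))
        sub <- img[rs, cs, drop = FALSE]
        pk <- which.max(sub)
        pr <- rs[((pk - 1L) %% nrow(sub)) + 1L]
        pc <- cs[((pk - 1L) %/% nrow(sub)) + 1L]
    }
    x0 <- (pc - 0.5) * px
    y0 <- (pr - 0.5) * px
    theta <- .principal_axis(img, x0, y0, 1.5 * expected_fwhm_nm, px)
    step <- px / 2
    t <- seq(-length_nm / 2, length_nm / 2, by = step)
    xs <- x0 + t * cos(theta)
    ys <- y0 + t * sin(theta)
    if (any(xs < 0 | xs > w * px | ys < 0 | ys > h * px))
        stop("profile line exits the image bounds; skip this punctum")
    ints <- .bilinear(img, xs, ys, px)
    n <- length(ints)
    k <- max(1L, round(0.2 * n))
    bg <- mean(c(ints[seq_len(k)], ints[(n - k + 1L):n]))
    new("LineProfile", positions_nm = t, intensities = ints,
        background_estimate = bg, step_nm = step)
}

# FWHM from the two half-height crossings nearest the maximum, each located
# by linear interpolation between bracketing samples.  `peak_height` is the
# height used for the half level.
.fwhm_crossings <- function(pos, ints, bg, peak_height) {
    im <- which.max(ints)
    half <- bg + (peak_height - bg) / 2
    left <- NA_real_
    if (im > 1L) for (i in (im - 1L):1L) {
        if (ints[i] <= half && ints[i + 1L] > half) {
            left <- pos[i] + (half - ints[i]) / (ints[i + 1L] - ints[i]) *
                (pos[i + 1L] - pos[i])
            break
        }
    }
    right <- NA_real_
    if (im < length(ints)) for (i in im:(length(ints) - 1L)) {
        if (ints[i] > half && ints[i + 1L] <= half) {
            right <- pos[i] + (half - ints[i]) / (ints[i + 1L] - ints[i]) *
                (pos[i + 1L] - pos[i])
            break
        }
    }
    if (is.na(left) || is.na(right))
        stop("NoCrossing: profile does not return to half maximum on ",
             if (is.na(left) && is.na(right)) "either side"
             else if (is.na(left)) "the left side" else "the right side")
    right - left
}

#' Measure the full width at half maximum of a line profile
#'
#' The half-maximum level is \code{background + (peak - background) / 2};
#' the FWHM is the distance between the two half-level crossings nearest the
#' maximum, each located by linear interpolation between bracketing samples.
#'
#' Two readings of the peak height are available.  \code{"quadratic"} (the
#' default) refines the peak by a local quadratic fit to the logarithm of
#' the background-subtracted samples around the argmax -- exact for a
#' Gaussian punctum and robust to shot noise at the sample maximum, the
#' computational analogue of reading the peak off the smooth intensity plot.
#' \code{"max"} uses the raw sample maximum.
#'
#' @param profile a \linkS4class{LineProfile}.
#' @param peak \code{"quadratic"} or \code{"max"}.
#' @return the FWHM in nm.
#' @export
measureFwhm <- function(profile, peak = c("quadratic", "max")) {
    peak <- match.arg(peak)
    pos <- profile@positions_nm
    ints <- profile@intensities
    bg <- profile@background_estimate
    mx <- max(ints)
    if (mx <= bg)
        stop("profile maximum does not exceed the background estimate")
    w0 <- .fwhm_crossings(pos, ints, bg, mx)
    if (peak == "max") return(w0)
    # refine the peak height: quadratic in log space around the argmax,
    # window scaled to ~0.3 x the first-pass width
    im <- which.max(ints)
    qwin <- max(2L, round(0.3 * w0 / profile@step_nm))
    lo <- max(1L, im - qwin)
    hi <- min(length(ints), im + qwin)
    t <- (lo:hi) - im
    y <- ints[lo:hi] - bg
    if (all(y > 0)) {
        co <- tryCatch(stats::coef(stats::lm(log(y) ~ t + I(t^2))),
                       error = function(e) NULL)
        if (!is.null(co) && all(is.finite(co)) && co[3] < 0) {
            fit_mx <- bg + exp(co[1] - co[2]^2 / (4 * co[3]))
            mx <- min(fit_mx, mx)
        }
    }
    .fwhm_crossings(pos, ints, bg, mx)
}

#' Integrated punctum intensity per unit synapse area
#'
#' Sum of pixel intensities over all labeled punctum pixels lying inside the
#' mask, divided by the mask area in um^2.
#'
#' @param image an \linkS4class{ImageChannel}.
#' @param puncta a \linkS4class{PunctaSet} with a label image.
#' @param mask a \linkS4class{SynapseMask}.
#' @return intensity per um^2 (counts/um^2).
#' @export
intensityPerArea <- function(image, puncta, mask) {
    area <- maskArea(mask)
    if (area <= 0) stop("mask area must be > 0")
    lab <- puncta@label_image
    if (!length(lab)) stop("puncta set has no label image")
    sel <- lab > 0L & mask@pixels
    sum(image@pixels[sel]) / area
}

#' Mean signal intensity within one punctum
#'
#' @param image an \linkS4class{ImageChannel}.
#' @param label punctum label.
#' @param label_image integer label image.
#' @return arithmetic mean of the punctum's pixel intensities.
#' @export
intensityPerPunctum <- function(image, label, label_image) {
    lin <- which(label_image == label)
    if (!length(lin)) stop("label ", label, " not present in label_image")
    mean(image@pixels[lin])
}

#' Puncta density over the synapse mask
#'
#' @param puncta a \linkS4class{PunctaSet}.
#' @param mask a \linkS4class{SynapseMask}.
#' @return puncta count divided by mask area (puncta/um^2).
#' @export
punctaDensity <- function(puncta, mask) {
    area <- maskArea(mask)
    if (area <= 0) stop("mask area must be > 0")
    nrow(puncta@puncta) / area
}

#' Sample representative puncta from an animal/synapse hierarchy
#'
#' Seeded uniform sampling without replacement of \code{per_synapse} puncta
#' from each synapse of each animal; with 5 animals x 5 synapses x 10 puncta
#' this yields the conventional 250 representative puncta.  A synapse with
#' fewer eligible puncta contributes all of them, with a warning.
#'
#' @param puncta_by_unit nested list: animals, each a list of synapses, each
#'   a \code{data.frame} of eligible (non-border, measurable) punctum
#'   records.
#' @param per_synapse puncta to draw per synapse (default 10).
#' @param seed integer seed.
#' @return a \code{data.frame} of sampled records with added \code{animal}
#'   and \code{synapse} columns.
#' @export
sampleRepresentativePuncta <- function(puncta_by_unit, per_synapse = 10L,
                                       seed = 1L) {
    if (!length(puncta_by_unit)) stop("empty hierarchy")
    set.seed(as.integer(seed))
    out <- list()
    for (a in seq_along(puncta_by_unit)) {
        syns <- puncta_by_unit[[a]]
        if (!length(syns)) stop("animal ", a, " has no synapses")
        for (s in seq_along(syns)) {
            df <- syns[[s]]
            n <- nrow(df)
            if (n < per_synapse) {
                warning("synapse ", s, " of animal ", a, " has only ", n,
                        " eligible puncta (requested ", per_synapse,
                        "); taking all")
                take <- seq_len(n)
            } else {
                take <- sample.int(n, per_synapse)
            }
            sel <- df[take, , drop = FALSE]
            sel$animal <- a
            sel$synapse <- s
            out[[length(out) + 1L]] <- sel
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Measure FWHM for the puncta of a set
#'
#' Convenience wrapper: extracts a profile and measures the FWHM for each
#' non-border punctum, filling the \code{fwhm_nm} column.  Puncta whose
#' profile fails (truncated, no crossing) keep \code{NA}.
#'
#' @param image an \linkS4class{ImageChannel}.
#' @param puncta a \linkS4class{PunctaSet}.
#' @param expected_fwhm_nm expected punctum FWHM in nm.
#' @param peak peak reading passed to \code{\link{measureFwhm}}.
#' @return the \linkS4class{PunctaSet} with \code{fwhm_nm} filled in.
#' @export
measurePunctaFwhm <- function(image, puncta, expected_fwhm_nm = 120,
                              peak = "quadratic") {
    tab <- puncta@puncta
    for (i in seq_len(nrow(tab))) {
        if (tab$border_flag[i]) next
        tab$fwhm_nm[i] <- tryCatch(
            measureFwhm(extractProfile(image, tab[i, , drop = FALSE],
                                       expected_fwhm_nm = expected_fwhm_nm,
                                       label_image = puncta@label_image),
                        peak = peak),
            error = function(e) NA_real_)
    }
    initialize(puncta, puncta = tab)
}
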