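# Shared fixtures and independent oracles, built in code.

# Brute-force trough search over a histogram: scan every (background, object,
# trough) triple admissible under the documented rules and return the winner.
# Written independently of the package's peak/trough scan.
brute_force_trough <- function(counts, bg_decay_frac = 0.01) {
    nb <- length(counts)
    bg <- which(counts == max(counts))[1]  # dimmest modal bin
    # object search starts once the background clump has decayed
    start <- nb + 1L
    for (i in seq_len(nb))
        if (i > bg && counts[i] <= bg_decay_frac * counts[bg]) {
            start <- i; break
        }
    if (start > nb) start <- bg + 1L
    # object peak: highest-count strict local max at or past `start`,
    # plateaus collapse to their dimmest bin, ties to the dimmest
    best <- NA_integer_
    for (i in seq_len(nb)) {
        if (i < start || counts[i] == 0) next
        j <- i
        while (j < nb && counts[j + 1] == counts[i]) j <- j + 1
        if (i > 1 && counts[i - 1] == counts[i]) next  # not plateau start
        left <- if (i == 1) -Inf else counts[i - 1]
        right <- if (j == nb) -Inf else counts[j + 1]
        if (!(counts[i] > left && counts[i] > right)) next
        if (is.na(best) || counts[i] > counts[best]) best <- i
    }
    if (is.na(best) || best - bg < 2) return(NULL)
    mid <- (bg + 1):(best - 1)
    trough <- mid[which(counts[mid] == min(counts[mid]))[1]]
    list(bg = bg, obj = best, trough = trough)
}

# Build an ImageChannel whose histogram reproduces `counts` exactly: value k
# (0-based gray level) occurs counts[k+1] times.  A 1 x n grid avoids any
# padding that would distort the histogram.
image_from_histogram <- function(counts) {
    vals <- rep(seq_along(counts) - 1L, counts)
    new("ImageChannel", pixels = matrix(as.numeric(vals), nrow = 1),
        pixel_size_nm = 20, channel = "synthetic")
}

# Random bimodal integer histogram with a guaranteed gap between the
# background clump and the object clump.
random_bimodal_counts <- function(seed) {
    set.seed(seed)
    nb <- sample(40:120, 1)
    counts <- integer(nb)
    bg_center <- sample(3:10, 1)
    bg_span <- sample(2:4, 1)
    for (k in (bg_center - bg_span):(bg_center + bg_span))
        if (k >= 1 && k <= nb)
            counts[k] <- sample(200:400, 1) - 30 * abs(k - bg_center)
    obj_center <- sample((bg_center + 12):(nb - 3), 1)
    obj_span <- sample(1:3, 1)
    for (k in (obj_center - obj_span):(obj_center + obj_span))
        if (k >= 1 && k <= nb)
            counts[k] <- sample(20:60, 1) - 5 * abs(k - obj_center)
    # sprinkle low counts into the gap without creating a new mode
    gap <- (bg_center + bg_span + 2):(obj_center - obj_span - 2)
    if (length(gap) > 2)
        counts[sample(gap, min(3, length(gap)))] <- sample(0:5, 3,
                                                           replace = TRUE)
    counts <- pmax(counts, 0L)
    # trim empty edge bins so the realized image reproduces these counts
    # bin-for-bin under data-range-anchored binning
    nz <- which(counts > 0)
    counts[min(nz):max(nz)]
}

# A single isolated Gaussian punctum rendered at a random subpixel position;
# returns the scene plus the rendered (optionally noisy) image.
single_punctum_scene <- function(fwhm_nm, amplitude = 100, background = 0,
                                 width_px = 64L, seed = 1L, noisy = FALSE,
                                 read_noise_sd = 1) {
    set.seed(seed)
    ctr <- width_px * 20 / 2 + stats::runif(2, -10, 10)
    sc <- buildScene(list(motifSpec("solitary", n = 1, channel = "ch",
                                    at_nm = ctr)),
                     width_px = width_px, height_px = width_px,
                     channels = "ch", background_level = background,
                     read_noise_sd = read_noise_sd, seed = seed,
                     amplitude_range = c(amplitude, amplitude),
                     fwhm_range_nm = c(fwhm_nm, fwhm_nm))
    img <- renderChannel(sc, "ch")
    if (noisy) img <- applyNoise(img, read_noise_sd, seed + 1L)
    list(scene = sc, image = img,
         x = sc@puncta$x_nm[1], y = sc@puncta$y_nm[1])
}

# FWHM of a continuous 1D Gaussian profile read off a 0.1 nm dense grid by
# the same half-maximum crossing definition -- the dense-sampling oracle.
dense_fwhm_oracle <- function(fwhm_true, length_nm = 1000) {
    s <- fwhm_true / (2 * sqrt(2 * log(2)))
    t <- seq(-length_nm / 2, length_nm / 2, by = 0.1)
    y <- exp(-t^2 / (2 * s^2))
    half <- max(y) / 2
    above <- which(y > half)
    lo <- min(above); hi <- max(above)
    xl <- t[lo - 1] + (half - y[lo - 1]) / (y[lo] - y[lo - 1]) * 0.1
    xr <- t[hi] + (half - y[hi]) / (y[hi + 1] - y[hi]) * 0.1
    xr - xl
}

# Ground-truth-derived puncta sets for one channel of a scene.
gt_puncta_set <- function(scene, channel) {
    tab <- scene@puncta[scene@puncta$channel == channel, , drop = FALSE]
    punctaSetFromTable(tab, channel, scene@pixel_size_nm)
}

# Mixed-motif scene at the study geometry: sandwiches (flank separation
# 100 nm, jitter SD 10 nm), colocalized pairs, and solitary puncta of both
# channels, FWHM 100-125 nm at 20 nm pixels.
mixed_motif_scene <- function(seed, n_sandwich = 4, n_pair = 4,
                              n_solo_p = 3, n_solo_b = 2,
                              width_px = 256L) {
    buildScene(list(
        motifSpec("sandwich", n = n_sandwich, flank_channel = "piccolo",
                  center_channel = "bassoon", flank_separation_nm = 100,
                  jitter_sd_nm = 10),
        motifSpec("coloc_pair", n = n_pair, flank_channel = "piccolo",
                  center_channel = "bassoon", jitter_sd_nm = 10),
        motifSpec("solitary", n = n_solo_p, channel = "piccolo",
                  jitter_sd_nm = 10),
        motifSpec("solitary", n = n_solo_b, channel = "bassoon",
                  jitter_sd_nm = 10)),
        width_px = width_px, height_px = width_px,
        channels = c("bassoon", "piccolo"), seed = seed,
        fwhm_range_nm = c(100, 125), min_motif_spacing_nm = 400)
}

# Expected piccolo_bassoon category of every punctum from motif labels.
expected_categories <- function(scene) {
    p <- scene@puncta
    bass <- p[p$channel == "bassoon", , drop = FALSE]
    picc <- p[p$channel == "piccolo", , drop = FALSE]
    bcat <- vapply(seq_len(nrow(bass)), function(i) {
        switch(bass$motif_role[i],
               center = "2P:1B", pair_member = "1P:1B", solo = "B_only",
               stop("unexpected role"))
    }, "")
    names(bcat) <- bass$punctum_id
    pcat <- ifelse(picc$motif_role == "solo", "P_only", "associated")
    names(pcat) <- picc$punctum_id
    list(bassoon = bcat, piccolo = pcat)
}
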