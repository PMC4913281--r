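# Line profiles, FWHM estimation, intensities, density, and representative
# sampling.

make_profile <- function(pos, ints, step = diff(pos[1:2])) {
    n <- length(ints)
    k <- max(1, round(0.2 * n))
    bg <- mean(c(ints[1:k], ints[(n - k + 1):n]))
    new("LineProfile", positions_nm = pos, intensities = ints,
        background_estimate = bg, step_nm = step)
}

test_that("profiles through isotropic puncta are symmetric and flat fields
           give flat profiles", {
    # punctum exactly on a pixel center: reflection through that center maps
    # the pixel lattice onto itself, so the sampled profile is symmetric
    sc <- buildScene(list(motifSpec("solitary", n = 1, channel = "ch",
                                    at_nm = c(630, 630))),
                     width_px = 64, height_px = 64, channels = "ch",
                     background_level = 0, seed = 4,
                     amplitude_range = c(150, 150),
                     fwhm_range_nm = c(120, 120))
    img <- renderChannel(sc, "ch")
    thr <- autoThresholdLight(img)
    ps <- segmentPuncta(img, thr@threshold, NULL)
    pf <- extractProfile(img, punctaTable(ps)[1, , drop = FALSE],
                         label_image = labelImage(ps))
    ints <- pf@intensities
    im <- which.max(ints)
    k <- min(im - 1, length(ints) - im, 15)
    expect_equal(ints[im - seq_len(k)], ints[im + seq_len(k)],
                 tolerance = 1e-9)

    flat <- new("ImageChannel", pixels = matrix(12, 64, 64),
                pixel_size_nm = 20, channel = "ch")
    rec <- data.frame(label = 1L, centroid_x_nm = 640, centroid_y_nm = 640,
                      border_flag = FALSE)
    pf2 <- extractProfile(flat, rec)
    expect_true(all(pf2@intensities == 12))
    expect_equal(pf2@background_estimate, 12)
    expect_error(measureFwhm(pf2), "background")
})

test_that("profile orientation follows the intensity-weighted major axis", {
    # anisotropic Gaussian, sigma_x = 80 nm > sigma_y = 40 nm
    px <- 20
    xc <- (seq_len(64) - 0.5) * px
    img <- 100 * outer(exp(-(xc - 640)^2 / (2 * 40^2)),
                       exp(-(xc - 640)^2 / (2 * 80^2)))
    theta <- stedpuncta:::.principal_axis(img, 640, 640, 200, px)
    expect_lt(abs(theta) * 180 / pi, 5)
    # second-moment eigenvector oracle on the same window
    rs <- which(abs(xc - 640) <= 200)
    sub <- img[rs, rs]
    w <- sub - min(sub)
    xg <- matrix(xc[rs], length(rs), length(rs), byrow = TRUE)
    yg <- matrix(xc[rs], length(rs), length(rs))
    mx <- sum(w * xg) / sum(w); my <- sum(w * yg) / sum(w)
    cov <- matrix(c(sum(w * (xg - mx)^2), sum(w * (xg - mx) * (yg - my)),
                    sum(w * (xg - mx) * (yg - my)), sum(w * (yg - my)^2)),
                  2, 2) / sum(w)
    ev <- eigen(cov)$vectors[, 1]
    oracle_deg <- atan2(ev[2], ev[1]) * 180 / pi
    expect_lt(abs((theta * 180 / pi - oracle_deg + 90) %% 180 - 90), 5)
})

test_that("FWHM is read off ideal and triangular profiles correctly", {
    pos <- seq(-300, 300, by = 10)
    s <- 100 / (2 * sqrt(2 * log(2)))
    gauss <- make_profile(pos, exp(-pos^2 / (2 * s^2)))
    expect_equal(measureFwhm(gauss), 100, tolerance = 0.01)
    expect_equal(measureFwhm(gauss, peak = "max"), 100, tolerance = 0.01)

    # triangle: baseline 10, peak 50, linear rise/fall over 100 nm each side
    tri <- make_profile(pos, pmax(10, 50 - 0.4 * abs(pos)))
    expect_equal(measureFwhm(tri, peak = "max"), 100, tolerance = 1e-9)

    # truncated profile: no crossing on one side
    half <- make_profile(seq(0, 300, 10),
                         exp(-seq(0, 300, 10)^2 / (2 * s^2)))
    expect_error(measureFwhm(half), "NoCrossing")
})

test_that("FWHM is scale-equivariant and affine-invariant", {
    g1 <- single_punctum_scene(100, amplitude = 150, width_px = 64,
                               seed = 6)
    thr1 <- autoThresholdLight(g1$image)
    ps1 <- segmentPuncta(g1$image, thr1@threshold, NULL)
    f1 <- measureFwhm(extractProfile(g1$image,
                                     punctaTable(ps1)[1, , drop = FALSE],
                                     length_nm = 600,
                                     label_image = labelImage(ps1)))

    # doubled pixel size and doubled sigma: estimate doubles
    img2 <- new("ImageChannel", pixels = imageData(g1$image),
                pixel_size_nm = 40, channel = "ch")
    ps2tab <- punctaTable(ps1)
    ps2tab$centroid_x_nm <- ps2tab$centroid_x_nm * 2
    ps2tab$centroid_y_nm <- ps2tab$centroid_y_nm * 2
    f2 <- measureFwhm(extractProfile(img2, ps2tab[1, , drop = FALSE],
                                     length_nm = 1200,
                                     expected_fwhm_nm = 240,
                                     label_image = labelImage(ps1)))
    expect_equal(f2, 2 * f1, tolerance = 1e-6)

    # gain and offset leave the estimate unchanged
    img3 <- new("ImageChannel", pixels = 3.7 * imageData(g1$image) + 55,
                pixel_size_nm = 20, channel = "ch")
    f3 <- measureFwhm(extractProfile(img3,
                                     punctaTable(ps1)[1, , drop = FALSE],
                                     label_image = labelImage(ps1)))
    expect_equal(f3, f1, tolerance = 1e-6)
})

test_that("noiseless FWHM recovery is within 3% across punctum widths", {
    for (fwhm in c(60, 100, 160, 240)) {
        est <- vapply(1:8, function(seed) {
            g <- single_punctum_scene(fwhm, amplitude = 150,
                                      width_px = 80, seed = seed)
            thr <- autoThresholdLight(g$image)
            ps <- segmentPuncta(g$image, thr@threshold, NULL)
            measureFwhm(extractProfile(g$image,
                                       punctaTable(ps)[1, , drop = FALSE],
                                       expected_fwhm_nm = fwhm,
                                       label_image = labelImage(ps)))
        }, numeric(1))
        oracle <- dense_fwhm_oracle(fwhm)
        expect_equal(oracle, fwhm, tolerance = 1e-4)
        expect_lt(abs(mean(est) / oracle - 1), 0.03, label = fwhm)
    }
})

test_that("intensity per area, per punctum, and density follow their
           definitions", {
    # 10-pixel punctum of uniform intensity 50 in a 2 um^2 mask
    img <- matrix(0, 100, 100)
    img[40, 41:50] <- 50
    lab <- matrix(0L, 100, 100)
    lab[40, 41:50] <- 1L
    ic <- new("ImageChannel", pixels = img, pixel_size_nm = 20,
              channel = "ch")
    mask <- realizeMask(maskSpec("rectangle", x0_nm = 0, y0_nm = 0,
                                 width_nm = 2000, height_nm = 1000),
                        100, 100, 20)
    tab <- data.frame(label = 1L, centroid_x_nm = 910, centroid_y_nm = 790,
                      area_px = 10L, area_um2 = 10 * 4e-4,
                      peak_intensity = 50, mean_intensity = 50,
                      integrated_intensity = 500, fwhm_nm = NA_real_,
                      border_flag = FALSE)
    ps <- new("PunctaSet", puncta = tab, label_image = lab, channel = "ch",
              pixel_size_nm = 20)
    expect_equal(maskArea(mask), 2.0)
    expect_equal(intensityPerArea(ic, ps, mask), 250)

    # linearity
    ic2 <- new("ImageChannel", pixels = 2 * img, pixel_size_nm = 20,
               channel = "ch")
    expect_equal(intensityPerArea(ic2, ps, mask), 500)

    # zero puncta
    ps0 <- new("PunctaSet", puncta = tab[0, ],
               label_image = matrix(0L, 100, 100), channel = "ch",
               pixel_size_nm = 20)
    expect_equal(intensityPerArea(ic, ps0, mask), 0)
    expect_equal(punctaDensity(ps0, mask), 0)

    # intensity per punctum
    img[40, 41:42] <- c(40, 60)
    ic3 <- new("ImageChannel", pixels = img, pixel_size_nm = 20,
               channel = "ch")
    lab2 <- matrix(0L, 100, 100); lab2[40, 41:42] <- 1L
    expect_equal(intensityPerPunctum(ic3, 1L, lab2), 50)
    expect_error(intensityPerPunctum(ic3, 9L, lab2), "label 9")
    # locality: other labels' intensities are irrelevant
    img_b <- img; img_b[70, 70] <- 9999
    lab2b <- lab2; lab2b[70, 70] <- 2L
    ic4 <- new("ImageChannel", pixels = img_b, pixel_size_nm = 20,
               channel = "ch")
    expect_equal(intensityPerPunctum(ic4, 1L, lab2b), 50)

    # density: 12 puncta in 2 um^2
    tab12 <- do.call(rbind, lapply(1:12, function(i) {
        r <- tab; r$label <- i; r
    }))
    lab12 <- matrix(0L, 100, 100); lab12[1, 1:12] <- 1:12
    ps12 <- new("PunctaSet", puncta = tab12, label_image = lab12,
                channel = "ch", pixel_size_nm = 20)
    expect_equal(punctaDensity(ps12, mask), 6.0)
})

test_that("representative sampling honors the animal/synapse hierarchy", {
    mk <- function(n) data.frame(label = seq_len(n),
                                 fwhm_nm = runif(n, 90, 130))
    set.seed(1)
    hier <- lapply(1:5, function(a) lapply(1:5, function(s) mk(14)))
    s1 <- sampleRepresentativePuncta(hier, per_synapse = 10, seed = 99)
    expect_equal(nrow(s1), 250)
    expect_equal(unname(table(s1$animal)), rep(50L, 5), ignore_attr = TRUE)
    s2 <- sampleRepresentativePuncta(hier, per_synapse = 10, seed = 99)
    expect_identical(s1, s2)

    hier2 <- list(list(mk(6)))
    expect_warning(s3 <- sampleRepresentativePuncta(hier2, 10, 1),
                   "only 6")
    expect_equal(nrow(s3), 6)

    expect_error(sampleRepresentativePuncta(list(), 10, 1), "empty")
})

test_that("frequency distributions bin FWHM values from zero", {
    fd <- fwhmFrequencyDistribution(c(95, 105, 105), 10)
    expect_equal(fd@counts[10], 1L)   # [90, 100)
    expect_equal(fd@counts[11], 2L)   # [100, 110)
    expect_equal(sum(fd@counts), 3L)
    expect_equal(fd@bin_edges_nm[1], 0)
    fd2 <- fwhmFrequencyDistribution(c(101, 103, 108), 20)
    expect_equal(sum(fd2@counts > 0), 1L)
    expect_error(fwhmFrequencyDistribution(numeric(0), 10), "no values")
})
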