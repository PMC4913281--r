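# Cross-channel association, categorical colocalization, and sandwich-motif
# detection.

pset <- function(xy, channel, labels = seq_len(nrow(xy)))
    punctaSetFromTable(data.frame(label = labels, centroid_x_nm = xy[, 1],
                                  centroid_y_nm = xy[, 2]), channel)

test_that("association uses centroid distance with an overlap OR-condition", {
    a <- pset(rbind(c(1000, 1000)), "bassoon")
    b <- pset(rbind(c(1080, 1000), c(1000, 1300)), "piccolo")
    g <- associatePuncta(a, b, 150)
    expect_equal(nrow(g@edges), 1)
    expect_equal(g@edges$id_b, 1L)
    expect_equal(g@edges$centroid_distance_nm, 80)

    # overlapping labeled regions connect even beyond the radius
    la <- matrix(0L, 40, 40); la[10:25, 10:13] <- 1L
    lb <- matrix(0L, 40, 40); lb[25:28, 10:30] <- 1L
    ta <- data.frame(label = 1L, centroid_x_nm = 230, centroid_y_nm = 350)
    tb <- data.frame(label = 1L, centroid_x_nm = 410, centroid_y_nm = 530)
    sa <- new("PunctaSet", puncta = punctaTable(pset(
        cbind(230, 350), "bassoon")), label_image = la,
        channel = "bassoon", pixel_size_nm = 20)
    sb <- new("PunctaSet", puncta = punctaTable(pset(
        cbind(410, 530), "piccolo")), label_image = lb,
        channel = "piccolo", pixel_size_nm = 20)
    g2 <- associatePuncta(sa, sb, 150)
    expect_equal(nrow(g2@edges), 1)
    expect_gt(g2@edges$overlap_px, 0)
    expect_gt(g2@edges$centroid_distance_nm, 150)

    expect_error(associatePuncta(a, punctaSetFromTable(
        data.frame(label = 1, centroid_x_nm = 1, centroid_y_nm = 1),
        "piccolo", pixel_size_nm = 40), 150), "pixel size")
})

test_that("association matches a brute-force all-pairs oracle", {
    set.seed(42)
    na <- 25; nb <- 25
    xa <- cbind(runif(na, 0, 4000), runif(na, 0, 4000))
    xb <- cbind(runif(nb, 0, 4000), runif(nb, 0, 4000))
    g <- associatePuncta(pset(xa, "bassoon"), pset(xb, "piccolo"), 150)
    oracle <- list()
    for (i in seq_len(na)) for (j in seq_len(nb)) {
        d <- sqrt(sum((xa[i, ] - xb[j, ])^2))
        if (d <= 150) oracle[[length(oracle) + 1L]] <- c(i, j)
    }
    om <- if (length(oracle)) do.call(rbind, oracle) else
        matrix(0L, 0, 2)
    expect_equal(nrow(g@edges), nrow(om))
    expect_equal(g@edges$id_a, om[, 1])
    expect_equal(g@edges$id_b, om[, 2])
})

test_that("Bassoon-VGCC categories follow the five-way scheme", {
    # one Bassoon linked to one VGCC
    g <- associatePuncta(pset(rbind(c(500, 500)), "bassoon"),
                         pset(rbind(c(550, 500)), "vgcc"), 150)
    ct <- categorizeBassoonVgcc(g)
    expect_equal(unname(ct@counts["1V:1B"]), 1L)
    expect_equal(sum(ct@counts), 1L)

    # Bassoon alone
    g2 <- associatePuncta(pset(rbind(c(500, 500)), "bassoon"),
                          pset(matrix(numeric(0), 0, 2), "vgcc"), 150)
    expect_equal(unname(categorizeBassoonVgcc(g2)@counts["B_only"]), 1L)

    # two Bassoon sharing one VGCC plus an isolated VGCC (hand enumeration:
    # both Bassoon have degree 1, the far VGCC degree 0)
    g3 <- associatePuncta(
        pset(rbind(c(500, 500), c(700, 500)), "bassoon"),
        pset(rbind(c(600, 500), c(2000, 2000)), "vgcc"), 150)
    ct3 <- categorizeBassoonVgcc(g3)
    expect_equal(unname(ct3@counts[c("1V:1B", "V_only")]), c(2L, 1L))
    expect_equal(sum(ct3@counts[c("1V:1B", "2V:1B", ">=3V:1B", "B_only")]),
                 2L)

    expect_error(categorizeBassoonVgcc(associatePuncta(
        pset(rbind(c(1, 1)), "piccolo"), pset(rbind(c(1, 1)), "bassoon"),
        150)), "scheme")
})

test_that("Piccolo-Bassoon categories implement the six-way scheme with
           1P:2B precedence", {
    # sandwich: two Piccolo flanking one Bassoon
    g <- associatePuncta(
        pset(rbind(c(1000, 1000)), "bassoon"),
        pset(rbind(c(950, 1000), c(1050, 1000)), "piccolo"), 150)
    ct <- categorizePiccoloBassoon(g)
    expect_equal(unname(ct@counts["2P:1B"]), 1L)
    expect_equal(sum(ct@counts), 1L)

    # solitary Piccolo
    g2 <- associatePuncta(pset(matrix(numeric(0), 0, 2), "bassoon"),
                          pset(rbind(c(1, 1)), "piccolo"), 150)
    expect_equal(unname(categorizePiccoloBassoon(g2)@counts["P_only"]), 1L)

    # tandem P-B-P-B-P at 50 nm spacing: middle Piccolo bridges two Bassoon
    # (hand enumeration: one 1P:2B, each Bassoon then keeps one flank)
    xs <- cbind(c(1000, 1050, 1100, 1150, 1200), 1000)
    g3 <- associatePuncta(pset(xs[c(2, 4), , drop = FALSE], "bassoon"),
                          pset(xs[c(1, 3, 5), , drop = FALSE], "piccolo"),
                          70)
    det <- categorizePiccoloBassoon(g3, detail = TRUE)
    expect_equal(unname(det$table@counts[c("1P:2B", "1P:1B")]), c(1L, 2L))
    expect_equal(unname(det$partner_category["2"]), "1P:2B")
    expect_equal(unname(det$bassoon_category), c("1P:1B", "1P:1B"))
})

test_that("category counts conserve totals and normalize to one", {
    set.seed(7)
    for (rep in 1:20) {
        na <- sample(3:12, 1); nb <- sample(3:12, 1)
        xa <- cbind(runif(na, 0, 2500), runif(na, 0, 2500))
        xb <- cbind(runif(nb, 0, 2500), runif(nb, 0, 2500))
        g <- associatePuncta(pset(xa, "bassoon"), pset(xb, "piccolo"), 200)
        ct <- categorizePiccoloBassoon(g)
        # every Bassoon lands in exactly one Bassoon-side category
        expect_equal(sum(ct@counts[c("1P:1B", "2P:1B", ">=3P:1B",
                                     "B_only")]), na)
        if (sum(ct@counts) > 0) {
            norm <- normalizeCategoryCounts(ct)
            expect_equal(sum(norm@normalized), 1, tolerance = 1e-9)
        }
        gv <- associatePuncta(pset(xa, "bassoon"), pset(xb, "vgcc"), 200)
        cv <- categorizeBassoonVgcc(gv)
        expect_equal(sum(cv@counts[c("1V:1B", "2V:1B", ">=3V:1B",
                                     "B_only")]), na)
    }
})

test_that("categorization is a pure function of the graph: relabeling puncta
           permutes the assignments", {
    set.seed(11)
    xa <- cbind(runif(6, 0, 2000), runif(6, 0, 2000))
    xb <- cbind(runif(8, 0, 2000), runif(8, 0, 2000))
    g1 <- associatePuncta(pset(xa, "bassoon"), pset(xb, "piccolo"), 250)
    d1 <- categorizePiccoloBassoon(g1, detail = TRUE)
    perm <- sample(8)
    g2 <- associatePuncta(pset(xa, "bassoon"),
                          pset(xb[order(perm), , drop = FALSE], "piccolo",
                               labels = sort(perm)), 250)
    d2 <- categorizePiccoloBassoon(g2, detail = TRUE)
    expect_identical(d1$table@counts, d2$table@counts)
    expect_identical(unname(d1$bassoon_category),
                     unname(d2$bassoon_category))
})

test_that("sandwich detection applies separation and angle gates", {
    b <- pset(rbind(c(1050, 1000)), "bassoon")
    p <- pset(rbind(c(1000, 1000), c(1100, 1000)), "piccolo")
    g <- associatePuncta(b, p, 150)
    hits <- detectSandwich(p, b, g)
    expect_equal(nrow(hits), 1)
    expect_equal(hits$flank_separation_nm, 100)
    expect_equal(hits$flank_angle_deg, 180, tolerance = 1e-9)

    # both flanks on the same side: angle too small
    p2 <- pset(rbind(c(1100, 1000), c(1120, 1030)), "piccolo")
    g2 <- associatePuncta(b, p2, 150)
    expect_equal(nrow(detectSandwich(p2, b, g2, min_angle_deg = 120)), 0)

    # separation out of range
    p3 <- pset(rbind(c(1030, 1000), c(1070, 1000)), "piccolo")
    g3 <- associatePuncta(b, p3, 150)
    expect_equal(nrow(detectSandwich(p3, b, g3, min_sep_nm = 60)), 0)
})

test_that("sandwich detection on simulated motifs reaches high recall with
           no decoy hits", {
    sc <- buildScene(list(motifSpec("sandwich", n = 20,
                                    flank_separation_nm = 100,
                                    jitter_sd_nm = 10),
                          motifSpec("solitary", n = 10,
                                    channel = "piccolo"),
                          motifSpec("solitary", n = 10,
                                    channel = "bassoon")),
                     width_px = 512, height_px = 512, seed = 31,
                     min_motif_spacing_nm = 400)
    p <- gt_puncta_set(sc, "piccolo")
    b <- gt_puncta_set(sc, "bassoon")
    g <- associatePuncta(b, p, 150)
    hits <- detectSandwich(p, b, g)
    truth <- punctaTable(sc)
    centers <- truth$punctum_id[truth$motif_role == "center"]
    tp <- sum(hits$bassoon_id %in% centers)
    expect_gte(tp, 18)
    expect_equal(nrow(hits) - tp, 0)
})

test_that("normalization divides by the total and rejects empty tables", {
    ct <- stedpuncta:::.category_table(
        "bassoon_vgcc", c("1V:1B" = 3L, "B_only" = 1L))
    norm <- normalizeCategoryCounts(ct)
    expect_equal(unname(norm@normalized[c("1V:1B", "B_only")]),
                 c(0.75, 0.25))
    expect_equal(sum(norm@normalized), 1)

    empty <- stedpuncta:::.category_table("bassoon_vgcc", integer(0))
    expect_error(normalizeCategoryCounts(empty), "zero")
})
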