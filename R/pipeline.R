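# End-to-end orchestration: simulate (or load) -> deconvolve -> threshold ->
# segment -> measure -> sample -> colocalize -> group statistics -> report.

# Deterministic seed splitting: every stage draws its seed from the single
# run seed through a Lehmer step, so one integer reproduces the whole run.
.child_seed <- function(seed, k) {
    m <- 2147483647
    as.integer((as.numeric(seed) %% m * 48271 + k) %% m)
}

#' Assemble and validate a pipeline configuration
#'
#' A configuration either simulates its inputs (\code{simulate}) or loads
#' them from disk (\code{inputs}); exactly one must be given.  Validation
#' happens here, before any computation.
#'
#' @param groups list of group descriptions; each a list with \code{name},
#'   \code{n_synapses}, and (simulation mode) \code{motifs} (see
#'   \code{\link{motifSpec}}) plus optional overrides of the scene
#'   arguments.
#' @param scene simulation-mode defaults passed to \code{\link{buildScene}}
#'   (e.g. \code{width_px}, \code{channels}, \code{background_level},
#'   \code{fwhm_range_nm}).
#' @param inputs file mode: list of groups, each a list of synapses, each a
#'   list with \code{images} (named character vector of TIFF paths, one per
#'   channel) and \code{mask} (TIFF path).
#' @param segmentation list: \code{use_deconvolved} (default TRUE),
#'   \code{psf_fwhm_nm} (100), \code{iterations} (10), \code{min_size_px}
#'   (4), \code{n_bins} (256).
#' @param coloc list: \code{scheme} (\code{"piccolo_bassoon"} or
#'   \code{"bassoon_vgcc"} or NULL to skip), \code{radius_nm} (150),
#'   \code{min_sep_nm} (60), \code{max_sep_nm} (200), \code{min_angle_deg}
#'   (120).
#' @param sampling list: \code{per_synapse} (default 10) representative
#'   puncta per synapse for FWHM measurement.
#' @param seed single integer governing all randomness.
#' @return a validated configuration list of class \code{pipeline_config}.
#' @export
pipelineConfig <- function(groups, scene = list(), inputs = NULL,
                           segmentation = list(), coloc = list(),
                           sampling = list(), seed = 1L) {
    if (is.null(inputs)) {
        if (!length(groups)) stop("config field 'groups' is empty")
        for (g in groups) {
            if (is.null(g$name)) stop("config group is missing field 'name'")
            if (is.null(g$n_synapses))
                stop("config group '", g$name,
                     "' is missing field 'n_synapses'")
            if (is.null(g$motifs) && is.null(scene$motifs))
                stop("config group '", g$name, "' is missing field 'motifs'")
        }
    } else {
        if (length(groups) != length(inputs))
            stop("config fields 'groups' and 'inputs' must align")
        for (g in groups)
            if (is.null(g$name)) stop("config group is missing field 'name'")
        for (gi in seq_along(inputs)) for (si in seq_along(inputs[[gi]])) {
            syn <- inputs[[gi]][[si]]
            if (is.null(syn$images))
                stop("config inputs[[", gi, "]][[", si,
                     "]] is missing field 'images'")
            if (is.null(syn$mask))
                stop("config inputs[[", gi, "]][[", si,
                     "]] is missing field 'mask'")
        }
    }
    seg <- utils::modifyList(list(use_deconvolved = TRUE, psf_fwhm_nm = 100,
                                  iterations = 10L, min_size_px = 4L,
                                  n_bins = 256L), segmentation)
    col <- utils::modifyList(list(scheme = "piccolo_bassoon",
                                  radius_nm = 150, min_sep_nm = 60,
                                  max_sep_nm = 200, min_angle_deg = 120),
                             coloc)
    if (!is.null(col$scheme) &&
        !col$scheme %in% c("piccolo_bassoon", "bassoon_vgcc"))
        stop("unknown coloc scheme '", col$scheme, "'")
    smp <- utils::modifyList(list(per_synapse = 10L), sampling)
    structure(list(groups = groups, scene = scene, inputs = inputs,
                   segmentation = seg, coloc = col, sampling = smp,
                   seed = as.integer(seed)),
              class = "pipeline_config")
}

.scene_for_synapse <- function(config, group, syn_seed) {
    sc <- config$scene
    args <- list(
        motifs = if (!is.null(group$motifs)) group$motifs else sc$motifs,
        seed = syn_seed)
    for (f in c("width_px", "height_px", "pixel_size_nm", "channels",
                "mask", "background_level", "read_noise_sd",
                "amplitude_range", "amplitude_scale_range",
                "fwhm_range_nm", "min_motif_spacing_nm",
                "border_margin_nm", "mask_margin_nm")) {
        v <- if (!is.null(group[[f]])) group[[f]] else sc[[f]]
        if (!is.null(v)) args[[f]] <- v
    }
    do.call(buildScene, args)
}

# Segment one channel image: optional deconvolution, auto-threshold,
# labeling, per-punctum records.  Returns list(puncta_set, threshold).
.segment_channel <- function(img, mask, seg) {
    work <- if (isTRUE(seg$use_deconvolved) && seg$iterations > 0L)
        deconvolve(img, seg$psf_fwhm_nm, seg$iterations) else img
    thr <- autoThresholdLight(work, mask, n_bins = seg$n_bins)
    ps <- segmentPuncta(work, thr@threshold, mask,
                        min_size_px = seg$min_size_px)
    list(puncta = ps, threshold = thr@threshold, image = work)
}

#' Run the full quantification pipeline
#'
#' Simulates (or loads) dual-channel synapse images per group, segments
#' puncta, measures intensities, densities and sampled FWHMs, associates
#' puncta across channels, scores colocalization categories and sandwich
#' motifs, and compares groups.  Identical configuration and seed yield
#' byte-identical outputs.
#'
#' @param config a \code{pipeline_config} from \code{\link{pipelineConfig}}.
#' @param out_dir output directory; created if missing.  Writes
#'   \code{puncta.csv}, \code{synapse_summary.csv},
#'   \code{coloc_categories.csv}, \code{sandwich_hits.csv},
#'   \code{group_stats.csv} and \code{manifest.json}.
#' @param quiet suppress per-stage progress on stderr.
#' @return invisibly, a list with the per-punctum table, per-synapse
#'   summary, category tables, sandwich hits and group statistics.
#' @export
runPipeline <- function(config, out_dir, quiet = FALSE) {
    stopifnot(inherits(config, "pipeline_config"))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    say <- function(...) if (!quiet) message(sprintf(...))
    t_run <- proc.time()[["elapsed"]]
    seg <- config$segmentation
    colc <- config$coloc
    puncta_rows <- list()
    synapse_rows <- list()
    sandwich_rows <- list()
    cat_counts <- list()
    sampled_fwhm <- list()
    sidx <- 0L
    simulate_mode <- is.null(config$inputs)
    for (gi in seq_along(config$groups)) {
        grp <- config$groups[[gi]]
        t_grp <- proc.time()[["elapsed"]]
        n_syn <- if (simulate_mode) grp$n_synapses else
            length(config$inputs[[gi]])
        for (si in seq_len(n_syn)) {
            sidx <- sidx + 1L
            syn_seed <- .child_seed(config$seed, sidx)
            if (simulate_mode) {
                scene <- .scene_for_synapse(config, grp, syn_seed)
                mask <- realizeMask(scene@mask_spec, scene@width_px,
                                    scene@height_px, scene@pixel_size_nm)
                chans <- scene@channels
                imgs <- NULL
            } else {
                syn <- config$inputs[[gi]][[si]]
                imgs <- lapply(syn$images, readChannelTiff)
                chans <- vapply(imgs, channelName, "")
                mask <- readMaskTiff(syn$mask,
                                     pixel_size_nm = pixelSize(imgs[[1]]))
            }
            sets <- list()
            for (ci in seq_along(chans)) {
                ch <- chans[ci]
                img <- if (simulate_mode)
                    applyNoise(renderChannel(scene, ch),
                               scene@read_noise_sd,
                               .child_seed(syn_seed, ci))
                else imgs[[ci]]
                res <- .segment_channel(img, mask, seg)
                ps <- res$puncta
                sets[[ch]] <- ps
                tab <- ps@puncta
                # representative puncta for FWHM
                eligible <- tab[!tab$border_flag, , drop = FALSE]
                if (nrow(eligible)) {
                    set.seed(.child_seed(syn_seed, 100L + ci))
                    take <- if (nrow(eligible) > config$sampling$per_synapse)
                        sample.int(nrow(eligible),
                                   config$sampling$per_synapse)
                    else seq_len(nrow(eligible))
                    for (j in take) {
                        fw <- tryCatch(measureFwhm(extractProfile(
                            res$image, eligible[j, , drop = FALSE],
                            label_image = ps@label_image)),
                            error = function(e) NA_real_)
                        tab$fwhm_nm[tab$label == eligible$label[j]] <- fw
                    }
                    sampled_fwhm[[length(sampled_fwhm) + 1L]] <- data.frame(
                        group = grp$name, synapse = sidx, channel = ch,
                        fwhm_nm = tab$fwhm_nm[!is.na(tab$fwhm_nm)])
                }
                if (nrow(tab))
                    puncta_rows[[length(puncta_rows) + 1L]] <- cbind(
                        data.frame(group = grp$name, synapse = sidx,
                                   channel = ch), tab)
                synapse_rows[[length(synapse_rows) + 1L]] <- data.frame(
                    group = grp$name, synapse = sidx, channel = ch,
                    threshold = res$threshold, n_puncta = nrow(tab),
                    mask_area_um2 = maskArea(mask),
                    density_per_um2 = punctaDensity(ps, mask),
                    intensity_per_area = if (nrow(tab))
                        intensityPerArea(res$image, ps, mask) else 0,
                    mean_intensity_per_punctum = if (nrow(tab))
                        mean(tab$mean_intensity) else NA_real_)
            }
            if (!is.null(colc$scheme) && length(chans) >= 2L) {
                bass <- grep("bassoon", chans, ignore.case = TRUE,
                             value = TRUE)[1]
                other <- setdiff(chans, bass)[1]
                if (!is.na(bass)) {
                    gr <- associatePuncta(sets[[bass]], sets[[other]],
                                          radius_nm = colc$radius_nm)
                    ct <- if (colc$scheme == "piccolo_bassoon")
                        categorizePiccoloBassoon(gr)
                    else categorizeBassoonVgcc(gr)
                    cat_counts[[length(cat_counts) + 1L]] <- data.frame(
                        group = grp$name, synapse = sidx,
                        scheme = ct@scheme, category = names(ct@counts),
                        count = as.integer(ct@counts))
                    if (colc$scheme == "piccolo_bassoon") {
                        hits <- detectSandwich(
                            sets[[other]], sets[[bass]], gr,
                            min_sep_nm = colc$min_sep_nm,
                            max_sep_nm = colc$max_sep_nm,
                            min_angle_deg = colc$min_angle_deg)
                        if (nrow(hits))
                            sandwich_rows[[length(sandwich_rows) + 1L]] <-
                                cbind(data.frame(group = grp$name,
                                                 synapse = sidx), hits)
                    }
                }
            }
        }
        say("group '%s': %d synapses in %.1f s", grp$name, n_syn,
            proc.time()[["elapsed"]] - t_grp)
    }
    bindr <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
    puncta_df <- bindr(puncta_rows, data.frame())
    synapse_df <- bindr(synapse_rows, data.frame())
    cat_df <- bindr(cat_counts, data.frame())
    sandwich_df <- bindr(sandwich_rows, data.frame(
        group = character(0), synapse = integer(0), bassoon_id = integer(0),
        piccolo_id_1 = integer(0), piccolo_id_2 = integer(0),
        flank_separation_nm = numeric(0), flank_angle_deg = numeric(0)))
    fwhm_df <- bindr(sampled_fwhm, data.frame())

    # group statistics: per-synapse metrics (density, intensity per area) as
    # mean +/- SEM; sampled FWHM as mean +/- SD; two-group pooled t-tests
    gnames <- vapply(config$groups, `[[`, "", "name")
    stat_rows <- list()
    add_stat <- function(metric, channel, values_by_group) {
        for (g in names(values_by_group)) {
            v <- values_by_group[[g]]
            if (length(v) >= 2L) {
                gs <- summarizeGroup(v)
                stat_rows[[length(stat_rows) + 1L]] <<- data.frame(
                    metric = metric, channel = channel, group = g,
                    n = gs@n, mean = gs@mean, sd = gs@sd, sem = gs@sem,
                    t = NA_real_, df = NA_real_, p_value = NA_real_)
            }
        }
        if (length(gnames) >= 2L) {
            va <- values_by_group[[gnames[1]]]
            vb <- values_by_group[[gnames[2]]]
            if (length(va) >= 2L && length(vb) >= 2L &&
                (stats::var(va) > 0 || stats::var(vb) > 0)) {
                tt <- unpairedTTest(va, vb)
                stat_rows[[length(stat_rows) + 1L]] <<- data.frame(
                    metric = metric, channel = channel,
                    group = paste(gnames[1], "vs", gnames[2]),
                    n = length(va) + length(vb), mean = NA_real_,
                    sd = NA_real_, sem = NA_real_, t = tt@t_statistic,
                    df = tt@degrees_of_freedom, p_value = tt@p_value)
            }
        }
    }
    if (nrow(synapse_df)) {
        for (ch in unique(synapse_df$channel)) {
            sub <- synapse_df[synapse_df$channel == ch, , drop = FALSE]
            for (metric in c("density_per_um2", "intensity_per_area",
                             "mean_intensity_per_punctum")) {
                vbg <- lapply(stats::setNames(gnames, gnames), function(g)
                    sub[[metric]][sub$group == g &
                                  is.finite(sub[[metric]])])
                add_stat(metric, ch, vbg)
            }
        }
    }
    if (nrow(fwhm_df)) {
        for (ch in unique(fwhm_df$channel)) {
            sub <- fwhm_df[fwhm_df$channel == ch, , drop = FALSE]
            vbg <- lapply(stats::setNames(gnames, gnames), function(g)
                sub$fwhm_nm[sub$group == g & is.finite(sub$fwhm_nm)])
            add_stat("fwhm_nm", ch, vbg)
        }
    }
    stats_df <- bindr(stat_rows, data.frame())

    wcsv <- function(df, name)
        utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    wcsv(puncta_df, "puncta.csv")
    wcsv(synapse_df, "synapse_summary.csv")
    wcsv(cat_df, "coloc_categories.csv")
    wcsv(sandwich_df, "sandwich_hits.csv")
    wcsv(stats_df, "group_stats.csv")
    manifest <- list(
        seed = config$seed,
        groups = lapply(config$groups, function(g)
            g[setdiff(names(g), "motifs")]),
        scene = config$scene[setdiff(names(config$scene),
                                     c("motifs", "mask"))],
        segmentation = config$segmentation,
        coloc = config$coloc, sampling = config$sampling)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("pipeline finished in %.1f s",
        proc.time()[["elapsed"]] - t_run)
    invisible(list(puncta = puncta_df, synapse_summary = synapse_df,
                   coloc_categories = cat_df, sandwich_hits = sandwich_df,
                   group_stats = stats_df))
}
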