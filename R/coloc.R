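# Cross-channel punctum association and categorical colocalization,
# including Piccolo-Bassoon-Piccolo sandwich-motif detection.
#
# Pixel-intensity correlation coefficients are deliberately not offered:
# side-by-side puncta ~100 nm apart do not overlap in pixels, and differing
# punctum sizes across proteins make coefficient-based colocalization
# uninformative for this kind of data.  The object-based categorical scheme
# below is the automated analogue of scoring each punctum on an overlaid
# two-channel image.

#' Build a PunctaSet from a coordinate table
#'
#' Constructs a \linkS4class{PunctaSet} without a label image from punctum
#' coordinates, e.g. a simulator ground-truth table or a manually logged
#' punctum list.  Only centroid-based operations (association,
#' categorization, sandwich detection) are meaningful on such a set.
#'
#' @param tab \code{data.frame} with columns \code{label} (or
#'   \code{punctum_id}), \code{centroid_x_nm} (or \code{x_nm}),
#'   \code{centroid_y_nm} (or \code{y_nm}).
#' @param channel channel label.
#' @param pixel_size_nm pixel pitch in nm.
#' @return a \linkS4class{PunctaSet}.
#' @export
punctaSetFromTable <- function(tab, channel, pixel_size_nm = 20) {
    lab <- if ("label" %in% names(tab)) tab$label else tab$punctum_id
    x <- if ("centroid_x_nm" %in% names(tab)) tab$centroid_x_nm else tab$x_nm
    y <- if ("centroid_y_nm" %in% names(tab)) tab$centroid_y_nm else tab$y_nm
    if (is.null(lab) || is.null(x) || is.null(y))
        stop("table needs label/punctum_id and x/y coordinate columns")
    n <- length(lab)
    puncta <- data.frame(label = as.integer(lab), centroid_x_nm = x,
                         centroid_y_nm = y, area_px = rep(NA_integer_, n),
                         area_um2 = rep(NA_real_, n),
                         peak_intensity = rep(NA_real_, n),
                         mean_intensity = rep(NA_real_, n),
                         integrated_intensity = rep(NA_real_, n),
                         fwhm_nm = rep(NA_real_, n),
                         border_flag = rep(FALSE, n))
    new("PunctaSet", puncta = puncta,
        label_image = matrix(integer(0), 0, 0), channel = channel,
        pixel_size_nm = pixel_size_nm)
}

#' Associate puncta across two channels
#'
#' An edge joins punctum a (set A) and punctum b (set B) when their
#' centroids lie within \code{radius_nm} of each other OR their labeled
#' regions overlap in at least one pixel.  The distance criterion captures
#' side-by-side pairs that never overlap in pixels; the overlap criterion
#' captures large colocalized objects whose centroids may be farther apart.
#'
#' @param set_a,set_b \linkS4class{PunctaSet}s on the same pixel grid.
#' @param radius_nm association radius (default 150 nm, roughly one punctum
#'   FWHM plus localization slack; must be configurable because the
#'   underlying scoring has no canonical distance).
#' @return an \linkS4class{AssociationGraph}.
#' @export
associatePuncta <- function(set_a, set_b, radius_nm = 150) {
    stopifnot(radius_nm > 0)
    if (set_a@pixel_size_nm != set_b@pixel_size_nm)
        stop("puncta sets have different pixel sizes")
    ta <- set_a@puncta; tb <- set_b@puncta
    edges <- data.frame(id_a = integer(0), id_b = integer(0),
                        centroid_distance_nm = numeric(0),
                        overlap_px = integer(0))
    if (nrow(ta) && nrow(tb)) {
        d <- sqrt(outer(ta$centroid_x_nm, tb$centroid_x_nm, "-")^2 +
                  outer(ta$centroid_y_nm, tb$centroid_y_nm, "-")^2)
        ov <- matrix(0L, nrow(ta), nrow(tb))
        la <- set_a@label_image; lb <- set_b@label_image
        if (length(la) && length(lb)) {
            both <- la > 0L & lb > 0L
            if (any(both)) {
                tt <- table(la[both], lb[both])
                ra <- match(as.integer(rownames(tt)), ta$label)
                cb <- match(as.integer(colnames(tt)), tb$label)
                ok <- !is.na(ra) & !is.na(cb)
                ov[cbind(rep(ra, ncol(tt))[ok],
                         rep(cb, each = nrow(tt))[ok])] <-
                    as.integer(tt)[ok]
            }
        }
        hit <- which(d <= radius_nm | ov > 0L, arr.ind = TRUE)
        if (nrow(hit)) {
            hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
            edges <- data.frame(
                id_a = ta$label[hit[, 1]], id_b = tb$label[hit[, 2]],
                centroid_distance_nm = d[hit], overlap_px = ov[hit])
        }
    }
    new("AssociationGraph", edges = edges,
        nodes_a = as.integer(ta$label), nodes_b = as.integer(tb$label),
        channel_a = set_a@channel, channel_b = set_b@channel,
        radius_nm = radius_nm)
}

.category_table <- function(scheme, counts) {
    cats <- .coloc_categories[[scheme]]
    cnt <- stats::setNames(integer(length(cats)), cats)
    cnt[names(counts)] <- cnt[names(counts)] + as.integer(counts)
    tot <- sum(cnt)
    norm <- if (tot > 0) as.numeric(cnt) / tot else numeric(length(cats))
    names(norm) <- cats
    new("ColocCategoryTable", scheme = scheme, counts = cnt,
        normalized = norm)
}

.degree_tab <- function(ids, edges_col) {
    deg <- stats::setNames(integer(length(ids)), ids)
    if (length(edges_col)) {
        t <- table(edges_col)
        deg[names(t)] <- as.integer(t)
    }
    deg
}

#' Score Bassoon puncta by associated VGCC count (5 categories)
#'
#' Each Bassoon punctum is scored by its VGCC degree in the association
#' graph: 1 -> \code{1V:1B}, 2 -> \code{2V:1B}, >= 3 -> \code{>=3V:1B},
#' 0 -> \code{B_only}; each VGCC punctum with no Bassoon partner contributes
#' one \code{V_only}.
#'
#' @param graph an \linkS4class{AssociationGraph} with A = Bassoon,
#'   B = VGCC.
#' @param detail also return the per-punctum assignments.
#' @return a \linkS4class{ColocCategoryTable} (scheme
#'   \code{"bassoon_vgcc"}); with \code{detail = TRUE}, a list with elements
#'   \code{table}, \code{bassoon_category} (named by Bassoon label) and
#'   \code{partner_category} (named by VGCC label; \code{"V_only"} or
#'   \code{"associated"}).
#' @export
categorizeBassoonVgcc <- function(graph, detail = FALSE) {
    if (!grepl("bassoon", graph@channel_a, ignore.case = TRUE) ||
        grepl("bassoon", graph@channel_b, ignore.case = TRUE))
        stop("bassoon_vgcc scheme expects channel A = bassoon, B = VGCC; ",
             "graph has A = '", graph@channel_a, "', B = '",
             graph@channel_b, "'")
    degB <- .degree_tab(graph@nodes_a, graph@edges$id_a)
    degV <- .degree_tab(graph@nodes_b, graph@edges$id_b)
    cnt <- c("1V:1B" = sum(degB == 1L), "2V:1B" = sum(degB == 2L),
             ">=3V:1B" = sum(degB >= 3L), "B_only" = sum(degB == 0L),
             "V_only" = sum(degV == 0L))
    tab <- .category_table("bassoon_vgcc", cnt)
    if (!detail) return(tab)
    bcat <- ifelse(degB == 0L, "B_only",
                   ifelse(degB == 1L, "1V:1B",
                          ifelse(degB == 2L, "2V:1B", ">=3V:1B")))
    names(bcat) <- names(degB)
    vcat <- ifelse(degV == 0L, "V_only", "associated")
    names(vcat) <- names(degV)
    list(table = tab, bassoon_category = bcat, partner_category = vcat)
}

#' Score Bassoon puncta by associated Piccolo count (6 categories)
#'
#' Bassoon puncta are scored by their Piccolo degree (1 -> \code{1P:1B},
#' 2 -> \code{2P:1B}, >= 3 -> \code{>=3P:1B}, 0 -> \code{B_only}).  A
#' Piccolo punctum associated with exactly two Bassoon puncta is scored as
#' one \code{1P:2B} and removed from those Bassoons' degree counts before
#' their binning, so no pairing is counted twice.  Piccolo puncta with no
#' Bassoon partner score \code{P_only}.
#'
#' @param graph an \linkS4class{AssociationGraph} with A = Bassoon,
#'   B = Piccolo.
#' @param detail also return the per-punctum assignments.
#' @return a \linkS4class{ColocCategoryTable} (scheme
#'   \code{"piccolo_bassoon"}); with \code{detail = TRUE}, a list with
#'   elements \code{table}, \code{bassoon_category} (named by Bassoon label)
#'   and \code{partner_category} (named by Piccolo label; \code{"P_only"},
#'   \code{"1P:2B"} or \code{"associated"}).
#' @export
categorizePiccoloBassoon <- function(graph, detail = FALSE) {
    if (!grepl("bassoon", graph@channel_a, ignore.case = TRUE) ||
        !grepl("piccolo", graph@channel_b, ignore.case = TRUE))
        stop("piccolo_bassoon scheme expects channel A = bassoon, ",
             "B = piccolo; graph has A = '", graph@channel_a, "', B = '",
             graph@channel_b, "'")
    e <- graph@edges
    degP <- .degree_tab(graph@nodes_b, e$id_b)
    shared <- as.integer(names(degP)[degP == 2L])  # Piccolo bridging 2 Bassoon
    keep <- !(e$id_b %in% shared)
    degB <- .degree_tab(graph@nodes_a, e$id_a[keep])
    cnt <- c("1P:1B" = sum(degB == 1L), "2P:1B" = sum(degB == 2L),
             ">=3P:1B" = sum(degB >= 3L), "1P:2B" = length(shared),
             "B_only" = sum(degB == 0L), "P_only" = sum(degP == 0L))
    tab <- .category_table("piccolo_bassoon", cnt)
    if (!detail) return(tab)
    bcat <- ifelse(degB == 0L, "B_only",
                   ifelse(degB == 1L, "1P:1B",
                          ifelse(degB == 2L, "2P:1B", ">=3P:1B")))
    names(bcat) <- names(degB)
    pcat <- ifelse(degP == 0L, "P_only",
                   ifelse(degP == 2L, "1P:2B", "associated"))
    names(pcat) <- names(degP)
    list(table = tab, bassoon_category = bcat, partner_category = pcat)
}

#' Re-normalize a category table
#'
#' @param table a \linkS4class{ColocCategoryTable} with a positive total.
#' @return the table with \code{normalized = counts / sum(counts)}.
#' @export
normalizeCategoryCounts <- function(table) {
    tot <- sum(table@counts)
    if (tot <= 0) stop("cannot normalize: category counts total zero")
    norm <- as.numeric(table@counts) / tot
    names(norm) <- names(table@counts)
    initialize(table, normalized = norm)
}

#' Detect Piccolo-Bassoon-Piccolo sandwich motifs
#'
#' For every Bassoon punctum with at least two associated Piccolo puncta,
#' all Piccolo pairs are considered; a pair is a candidate hit when the
#' flank-to-flank separation lies within \code{[min_sep_nm, max_sep_nm]} and
#' the Piccolo-Bassoon-Piccolo angle is at least \code{min_angle_deg}.  For
#' each Bassoon the pair maximizing the angle is reported; each Piccolo
#' joins at most one hit, conflicts resolved greedily by descending angle.
#'
#' @param piccolo,bassoon the two \linkS4class{PunctaSet}s.
#' @param graph association graph between them (either orientation).
#' @param min_sep_nm,max_sep_nm admissible flank separation (defaults 60 and
#'   200 nm, bracketing the ~100 nm spacing of flank pairs with jitter
#'   tolerance).
#' @param min_angle_deg minimum flank angle at the Bassoon punctum (default
#'   120 degrees; collinear = 180).
#' @return \code{data.frame} with columns \code{bassoon_id},
#'   \code{piccolo_id_1}, \code{piccolo_id_2}, \code{flank_separation_nm},
#'   \code{flank_angle_deg}.
#' @export
detectSandwich <- function(piccolo, bassoon, graph, min_sep_nm = 60,
                           max_sep_nm = 200, min_angle_deg = 120) {
    tp <- piccolo@puncta; tb <- bassoon@puncta
    e <- graph@edges
    # orient edges as (bassoon, piccolo)
    if (grepl("bassoon", graph@channel_a, ignore.case = TRUE)) {
        bid <- e$id_a; pid <- e$id_b
    } else {
        bid <- e$id_b; pid <- e$id_a
    }
    empty <- data.frame(bassoon_id = integer(0), piccolo_id_1 = integer(0),
                        piccolo_id_2 = integer(0),
                        flank_separation_nm = numeric(0),
                        flank_angle_deg = numeric(0))
    if (!length(bid)) return(empty)
    cand <- list()
    for (b in unique(bid)) {
        ps <- pid[bid == b]
        if (length(ps) < 2L) next
        bx <- tb$centroid_x_nm[match(b, tb$label)]
        by <- tb$centroid_y_nm[match(b, tb$label)]
        prs <- utils::combn(sort(ps), 2L)
        for (k in seq_len(ncol(prs))) {
            i1 <- match(prs[1L, k], tp$label)
            i2 <- match(prs[2L, k], tp$label)
            v1 <- c(tp$centroid_x_nm[i1] - bx, tp$centroid_y_nm[i1] - by)
            v2 <- c(tp$centroid_x_nm[i2] - bx, tp$centroid_y_nm[i2] - by)
            sep <- sqrt(sum((v1 - v2)^2))
            if (sep < min_sep_nm || sep > max_sep_nm) next
            cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
            ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
            if (ang < min_angle_deg) next
            cand[[length(cand) + 1L]] <- data.frame(
                bassoon_id = b, piccolo_id_1 = prs[1L, k],
                piccolo_id_2 = prs[2L, k], flank_separation_nm = sep,
                flank_angle_deg = ang)
        }
    }
    if (!length(cand)) return(empty)
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$flank_angle_deg, cand$bassoon_id,
                       cand$piccolo_id_1, cand$piccolo_id_2), ,
                 drop = FALSE]
    used_b <- integer(0); used_p <- integer(0)
    hits <- list()
    for (k in seq_len(nrow(cand))) {
        row <- cand[k, ]
        if (row$bassoon_id %in% used_b) next
        if (row$piccolo_id_1 %in% used_p || row$piccolo_id_2 %in% used_p)
            next
        used_b <- c(used_b, row$bassoon_id)
        used_p <- c(used_p, row$piccolo_id_1, row$piccolo_id_2)
        hits[[length(hits) + 1L]] <- row
    }
    out <- do.call(rbind, hits)
    out <- out[order(out$bassoon_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}
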