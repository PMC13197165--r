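#' Per-cell gene-expression quantification
#'
#' Normalized marker channels are binned at the nucleus level (mean over each
#' label's voxels), cells are called positive or negative per marker by Otsu
#' thresholding of the per-cell intensity distribution, and positive cells
#' are mapped back to space as coarse-grained positive-fraction fields,
#' radial profiles versus distance to the sample border, and pairwise
#' co-expression quadrants.
#'
#' @name expression_analysis
NULL

#' Mean per-nucleus intensity of one or more channels
#'
#' @param labels `label_image` of nuclei.
#' @param channels named list of `voxel_image`s on the same grid (typically
#'   normalized intensities).
#' @return data.frame: `label`, centroid `cz/cy/cx` (um), `volume` (um^3),
#'   one `mean_<name>` column per channel.
#' @export
nuclei_mean_intensities <- function(labels, channels) {
  if (!all(vapply(channels, function(ch) all(dim(ch) == dim(labels)),
                  logical(1))))
    stop("channel grids do not match the label image")
  st <- label_stats(labels)
  if (!length(st$ids)) stop("label image contains no objects")
  out <- object_table(labels)
  arrl <- unclass_arr_int(labels)
  pos <- which(arrl > 0L)
  labv <- arrl[pos]
  nm <- names(channels)
  if (is.null(nm)) nm <- paste0("ch", seq_along(channels))
  for (k in seq_along(channels)) {
    v <- unclass_arr(channels[[k]])[pos]
    sums <- rowsum(v, labv, na.rm = TRUE)[, 1]
    cnts <- rowsum((!is.na(v)) * 1, labv)[, 1]
    out[[paste0("mean_", nm[k])]] <- sums / pmax(cnts, 1)
  }
  out
}

#' Otsu threshold of a value distribution
#'
#' Maximizes the between-class variance over a 256-bin histogram of the
#' values; the returned threshold is the upper edge of the best cut bin, and
#' values strictly above it are classed positive. When several cuts tie (the
#' argmax plateau spanned by an empty gap between modes), the middle cut is
#' taken, placing the threshold centrally in the gap. A warning flags poorly
#' separable (near-unimodal) distributions.
#'
#' @param values numeric vector (>= 2 distinct values).
#' @param n_bins histogram bins.
#' @return threshold; attribute `separability` is the ratio of between-class
#'   to total variance at the optimum.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2) stop("need at least 2 distinct values")
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins),
                n_bins)
  p <- h / sum(h)
  centres <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centres)
  mu_t <- mu[n_bins]
  # between-class variance for a cut after bin t
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  cuts <- bcv[-n_bins]
  ties <- which(cuts >= max(cuts) * (1 - 1e-12))
  t_best <- ties[ceiling(length(ties) / 2)]   # middle of the argmax plateau
  thr <- edges[t_best + 1]
  sep <- bcv[t_best] / stats::var(v) * length(v) / (length(v) - 1)
  if (is.finite(sep) && sep < 0.3)
    warning("low-separability distribution: Otsu threshold may be unstable")
  attr(thr, "separability") <- sep
  thr
}

#' Positive / negative marker calls
#'
#' @param cells data.frame from [nuclei_mean_intensities()].
#' @param marker column name (e.g. `"mean_foxa2"`).
#' @param threshold optional fixed threshold; default Otsu on the column.
#' @return logical vector (strictly above threshold = positive); attribute
#'   `threshold`.
#' @export
classify_positive <- function(cells, marker, threshold = NULL) {
  x <- cells[[marker]]
  if (is.null(x)) stop(sprintf("no column '%s'", marker))
  if (is.null(threshold)) threshold <- otsu_threshold(x)
  out <- x > as.numeric(threshold)
  attr(out, "threshold") <- as.numeric(threshold)
  out
}

#' Coarse-grained fraction of marker-positive cells
#'
#' Density of positive-cell centroids divided by the density of all cells at
#' the same scale: the local fraction of positive cells, in [0, 1].
#'
#' @param cells data.frame from [nuclei_mean_intensities()].
#' @param positive logical vector, e.g. from [classify_positive()].
#' @param sigma coarse-graining scale, um.
#' @param template grid-defining image.
#' @param sample_mask binary inside-sample mask.
#' @param cell_density optional precomputed total-cell density field at the
#'   same sigma.
#' @return `voxel_image` in [0, 1] (NA where cell density is zero/invalid).
#' @export
positive_fraction_field <- function(cells, positive, sigma, template,
                                    sample_mask = NULL, cell_density = NULL) {
  if (is.null(cell_density))
    cell_density <- density_field(cells, sigma, sample_mask,
                                  template = template)
  pos_cells <- cells[positive, , drop = FALSE]
  if (nrow(pos_cells) == 0) {
    out <- unclass_arr(cell_density) * 0
    return(vox_like(out, cell_density))
  }
  pd <- density_field(pos_cells, sigma, sample_mask, template = template)
  out <- unclass_arr(pd) / unclass_arr(cell_density)
  out[!is.na(out)] <- pmin(pmax(out[!is.na(out)], 0), 1)
  vox_like(out, cell_density)
}

#' Radial profile of a field versus distance to the sample border
#'
#' Bins the field's valid voxels by Euclidean distance to the border of the
#' sample mask (anisotropic-spacing-aware) and reports per-bin mean, SD and
#' voxel count. Empty shells are omitted with a note.
#'
#' @param field `voxel_image`.
#' @param sample_mask binary inside-sample mask.
#' @param bin_width shell width in um.
#' @return data.frame: `bin_lo`, `bin_hi`, `bin_mid` (um), `mean`, `sd`, `n`.
#' @export
radial_profile <- function(field, sample_mask, bin_width = 10) {
  dist <- distance_to_border(sample_mask, vox_spacing(field))
  m <- unclass_arr(sample_mask) != 0
  v <- unclass_arr(field)
  ok <- m & is.finite(v)
  dmax <- max(dist[ok])
  edges <- seq(0, dmax + bin_width, by = bin_width)
  bin <- findInterval(dist[ok], edges, rightmost.closed = TRUE)
  vals <- v[ok]
  rows <- lapply(seq_len(length(edges) - 1), function(b) {
    sel <- bin == b
    if (!any(sel)) return(NULL)
    data.frame(bin_lo = edges[b], bin_hi = edges[b + 1],
               bin_mid = (edges[b] + edges[b + 1]) / 2,
               mean = mean(vals[sel]),
               sd = stats::sd(vals[sel]), n = sum(sel))
  })
  empty <- sum(vapply(rows, is.null, logical(1)))
  if (empty) message(sprintf("%d empty distance shell(s) omitted", empty))
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Pairwise co-expression quadrants
#'
#' Partitions cells into the 2x2 quadrants defined by per-marker Otsu
#' thresholds (background vs actual expression for each marker), reporting
#' counts, fractions, the cell ids of each quadrant for spatial back-mapping,
#' and Pearson / Spearman correlations overall and within the double-positive
#' quadrant.
#'
#' @param cells data.frame from [nuclei_mean_intensities()].
#' @param marker_a,marker_b column names.
#' @param thresholds optional length-2 numeric overriding the Otsu
#'   thresholds.
#' @return list with `thresholds`, `counts` (2x2 matrix, rows = marker A
#'   -/+), `fractions`, `ids` (list pp/pn/np/nn of label ids),
#'   `correlation` (overall Pearson/Spearman) and `correlation_pp` (within
#'   double-positives).
#' @export
coexpression_quadrants <- function(cells, marker_a, marker_b,
                                   thresholds = NULL) {
  xa <- cells[[marker_a]]; xb <- cells[[marker_b]]
  if (is.null(xa) || is.null(xb))
    stop("marker column missing from the cell table")
  for (nm in c(marker_a, marker_b)) {
    x <- cells[[nm]]
    if (length(unique(x[is.finite(x)])) < 2)
      stop(sprintf("marker '%s' is degenerate (constant values)", nm))
  }
  if (is.null(thresholds))
    thresholds <- c(as.numeric(otsu_threshold(xa)),
                    as.numeric(otsu_threshold(xb)))
  pa <- xa > thresholds[1]; pb <- xb > thresholds[2]
  counts <- matrix(c(sum(!pa & !pb), sum(!pa & pb),
                     sum(pa & !pb), sum(pa & pb)),
                   2, 2, byrow = TRUE,
                   dimnames = list(c("A-", "A+"), c("B-", "B+")))
  ids <- list(pp = cells$label[pa & pb], pn = cells$label[pa & !pb],
              np = cells$label[!pa & pb], nn = cells$label[!pa & !pb])
  corr <- c(pearson = stats::cor(xa, xb),
            spearman = stats::cor(xa, xb, method = "spearman"))
  corr_pp <- if (sum(pa & pb) >= 3)
    c(pearson = stats::cor(xa[pa & pb], xb[pa & pb]),
      spearman = stats::cor(xa[pa & pb], xb[pa & pb], method = "spearman"))
  else c(pearson = NA_real_, spearman = NA_real_)
  list(thresholds = stats::setNames(thresholds, c(marker_a, marker_b)),
       counts = counts, fractions = counts / length(xa), ids = ids,
       correlation = corr, correlation_pp = corr_pp)
}

#' Quick quadrant scatter plot
#'
#' Base-graphics scatter of two per-cell markers with the Otsu thresholds as
#' quadrant lines.
#'
#' @param cells cell table.
#' @param marker_a,marker_b column names.
#' @param quad optional result of [coexpression_quadrants()].
#' @param ... passed to [graphics::plot()].
#' @return the quadrant result, invisibly.
#' @export
plot_quadrants <- function(cells, marker_a, marker_b, quad = NULL, ...) {
  if (is.null(quad)) quad <- coexpression_quadrants(cells, marker_a, marker_b)
  graphics::plot(cells[[marker_a]], cells[[marker_b]],
                 xlab = marker_a, ylab = marker_b,
                 pch = 16, cex = 0.5,
                 col = grDevices::adjustcolor("steelblue", 0.6), ...)
  graphics::abline(v = quad$thresholds[1], h = quad$thresholds[2],
                   lty = 2, col = "grey40")
  invisible(quad)
}

#' Plot a radial profile with an SD ribbon
#'
#' @param profile data.frame from [radial_profile()].
#' @param ... passed to [graphics::plot()].
#' @return `profile`, invisibly.
#' @export
plot_radial_profile <- function(profile, ...) {
  graphics::plot(profile$bin_mid, profile$mean, type = "l",
                 xlab = "distance to border (um)", ylab = "mean", ...)
  sd0 <- ifelse(is.na(profile$sd), 0, profile$sd)
  graphics::polygon(c(profile$bin_mid, rev(profile$bin_mid)),
                    c(profile$mean - sd0, rev(profile$mean + sd0)),
                    border = NA,
                    col = grDevices::adjustcolor("steelblue", 0.25))
  graphics::lines(profile$bin_mid, profile$mean)
  invisible(profile)
}
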