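# In-silico insertion simulation: artificial insertions covering the whole
# normalized input space, consolidated predictions over a 100 x 100 grid per
# family x orientation combination, and the triangle "prediction plots".

#' Grid coordinates for the in-silico simulation
#'
#' Divides the normalized `[0, 1]` range of each continuous factor into
#' `nUnits` equal units and places a point at every unit midpoint
#' `u_i = (i - 0.5) / nUnits`, crossed with the four family x orientation
#' combinations: `4 * nUnits^2` artificial insertions in total (40,000 at the
#' default 100 units).
#'
#' @param nUnits number of units per axis (>= 2; default 100).
#' @return data.frame with columns `family`, `orientation`, `u_intron`,
#'   `u_distance`.
#' @export
makeGrid <- function(nUnits = 100L) {
  nUnits <- as.integer(nUnits)
  stopifnot(nUnits >= 2)
  u <- (seq_len(nUnits) - 0.5) / nUnits
  combos <- expand.grid(family = ERV_FAMILIES,
                        orientation = ERV_ORIENTATIONS,
                        stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    grid <- expand.grid(u_intron = u, u_distance = u)
    data.frame(family = combos$family[i],
               orientation = combos$orientation[i],
               grid, stringsAsFactors = FALSE)
  }))
}

#' Consolidated predictions over the in-silico grid
#'
#' Presents every grid point to the trained ensemble and records the
#' consolidated (averaged over all members) output.
#'
#' @param ensemble a trained [ErvEnsemble-class].
#' @param nUnits units per axis (default 100).
#' @return a named list of four [GridPrediction-class] objects
#'   (`"IAP.sense"`, `"IAP.antisense"`, `"ETnMusD.sense"`,
#'   `"ETnMusD.antisense"`).
#' @export
predictGrid <- function(ensemble, nUnits = 100L) {
  stopifnot(is(ensemble, "ErvEnsemble"))
  if (length(ensemble@members) == 0) stop("ensemble has no trained members")
  nUnits <- as.integer(nUnits)
  u <- (seq_len(nUnits) - 0.5) / nUnits
  grid <- expand.grid(u_intron = u, u_distance = u)
  out <- list()
  for (fam in ERV_FAMILIES) {
    for (ori in ERV_ORIENTATIONS) {
      X <- cbind(x_orientation = as.numeric(ori == "sense"),
                 x_family = as.numeric(fam == "ETnMusD"),
                 x_intron = grid$u_intron, x_distance = grid$u_distance)
      y <- consolidate(ensemble@members, X)
      out[[paste(fam, ori, sep = ".")]] <-
        new("GridPrediction", family = fam, orientation = ori,
            uIntron = u, uDistance = u,
            outputs = matrix(y, nrow = nUnits, ncol = nUnits))
    }
  }
  out
}

#' Geometric feasibility mask for the prediction plot
#'
#' A grid cell is infeasible when its denormalized ERV-exon distance exceeds
#' half the denormalized intron size (an insertion cannot be farther from the
#' nearer exon than the intron's midpoint); masking these cells produces the
#' triangle shape of the prediction plots.
#'
#' @param uIntron,uDistance normalized axis coordinates.
#' @return logical matrix (`length(uIntron)` x `length(uDistance)`), `TRUE`
#'   where infeasible.
#' @export
feasibilityMask <- function(uIntron, uDistance) {
  intronBp <- denormalizeLength(uIntron, INTRON_CAP_BP)
  distBp <- denormalizeLength(uDistance, DISTANCE_CAP_BP)
  outer(intronBp, distBp, function(L, d) d > L / 2)
}

#' Render a prediction plot
#'
#' Heatmap of the consolidated output over the normalized (exon distance x
#' intron size) plane for one family x orientation combination, in the style
#' of a stack of ERV-containing introns aligned by their centers: x is the
#' normalized distance from the insertion to the nearest exon, y the
#' normalized intron size with large introns at the bottom (inverted axis).
#' Outputs are discretized into ordered rainbow color bins; geometrically
#' infeasible cells (distance beyond the intron midpoint) are masked out,
#' and the labeled training cases can be superimposed (positives as filled
#' circles, negatives as filled squares).
#'
#' @param gp a [GridPrediction-class].
#' @param overlays optional [ErvSet-class] (or data.frame) of labeled
#'   training cases; every record must match `gp`'s family and orientation.
#' @param colorBins ordered likelihood bin edges (default
#'   `seq(0, 1, 0.1)`).
#' @param maskInfeasible mask cells beyond the intron midpoint (default
#'   `TRUE`); the underlying predictions are computed for the full square
#'   either way.
#' @param mirror duplicate the plot symmetrically around the intron center.
#' @param file optional output path (PNG/SVG/PDF via [ggplot2::ggsave()]).
#' @return the ggplot object, invisibly if `file` is given.
#' @export
renderPredictionPlot <- function(gp, overlays = NULL,
                                 colorBins = seq(0, 1, 0.1),
                                 maskInfeasible = TRUE, mirror = FALSE,
                                 file = NULL) {
  stopifnot(is(gp, "GridPrediction"))
  if (is.unsorted(colorBins, strictly = TRUE) || colorBins[1] != 0 ||
      colorBins[length(colorBins)] != 1)
    stop("colorBins must increase strictly from 0 to 1")
  df <- expand.grid(u_intron = gp@uIntron, u_distance = gp@uDistance)
  df$output <- as.vector(gp@outputs)
  if (maskInfeasible)
    df <- df[!as.vector(feasibilityMask(gp@uIntron, gp@uDistance)), ]
  nb <- length(colorBins) - 1
  df$bin <- cut(df$output, colorBins, include.lowest = TRUE,
                labels = sprintf("%.1f-%.1f", colorBins[-(nb + 1)],
                                 colorBins[-1]))
  if (mirror) {
    flipped <- df
    flipped$u_distance <- -flipped$u_distance
    df <- rbind(df, flipped)
  }
  distTicks <- c(10, 100, 1000, 10000, 50000)
  intronTicks <- c(10, 100, 1000, 10000, 100000)
  pal <- grDevices::rainbow(nb, end = 0.7, rev = TRUE)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = u_distance,
                                        y = u_intron,
                                        fill = bin)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE,
                               name = "predicted\nlikelihood") +
    ggplot2::scale_x_continuous(
      breaks = normalizeLength(distTicks, DISTANCE_CAP_BP),
      labels = distTicks) +
    ggplot2::scale_y_reverse(  # large introns at the bottom
      breaks = normalizeLength(intronTicks, INTRON_CAP_BP),
      labels = intronTicks) +
    ggplot2::labs(x = "distance to nearest exon (bp)",
                  y = "intron size (bp)",
                  title = sprintf("%s, %s", gp@family, gp@orientation)) +
    ggplot2::theme_minimal()
  if (!is.null(overlays)) {
    ov <- if (is(overlays, "ErvSet")) as.data.frame(overlays) else overlays
    if (any(ov$family != gp@family) || any(ov$orientation != gp@orientation))
      stop("overlay records must match the plot's family and orientation")
    ov$u_distance <- normalizeLength(ov$exon_distance_bp, DISTANCE_CAP_BP)
    ov$u_intron <- normalizeLength(ov$intron_size_bp, INTRON_CAP_BP)
    p <- p + ggplot2::geom_point(
      data = ov,
      ggplot2::aes(x = u_distance, y = u_intron,
                   shape = label),
      fill = ifelse(ov$label == "positive", "cyan", "white"),
      size = 2, inherit.aes = FALSE) +
      ggplot2::scale_shape_manual(values = c(positive = 21, negative = 22))
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 5, dpi = 150)
    return(invisible(p))
  }
  p
}
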