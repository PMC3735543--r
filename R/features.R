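# Feature normalization: the four raw factors -> the [0,1] inputs of the
# perceptron.  Orientation and family are Boolean; the two length factors are
# log10-scaled against a saturation cap (100 kb for introns, 50 kb for
# ERV-exon distances, half the maximum intron size).

#' Normalize a genomic length to the unit interval
#'
#' Computes `log10(clamp(length_bp, 1, cap_bp)) / log10(cap_bp)`.  Lengths at
#' or above the cap saturate at 1; lengths of 0 or 1 bp map to 0 (0 bp is
#' clamped to 1 bp before the log, the "as close as possible" extreme).
#'
#' @param length_bp non-negative length(s) in bp.
#' @param cap_bp saturation cap in bp (> 1).
#' @return value(s) in `[0, 1]`.
#' @examples
#' normalizeLength(100000, 100000)  # 1
#' normalizeLength(10000, 100000)   # 0.8
#' @export
normalizeLength <- function(length_bp, cap_bp) {
  if (length(cap_bp) != 1L || !is.finite(cap_bp) || cap_bp <= 1)
    stop("cap_bp must be a single value > 1")
  if (any(!is.finite(length_bp)) || any(length_bp < 0))
    stop("length_bp must be non-negative and finite")
  log10(pmin(pmax(length_bp, 1), cap_bp)) / log10(cap_bp)
}

#' Invert the length normalization
#'
#' Maps a unit value back to bp: `10^(u * log10(cap_bp))`.  Inverse of
#' [normalizeLength()] on `(1, cap_bp]`; used to label the axes of the
#' prediction plots.
#'
#' @param u value(s) in `[0, 1]`.
#' @param cap_bp saturation cap in bp (> 1).
#' @return length(s) in bp.
#' @export
denormalizeLength <- function(u, cap_bp) {
  if (length(cap_bp) != 1L || !is.finite(cap_bp) || cap_bp <= 1)
    stop("cap_bp must be a single value > 1")
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1))
    stop("u must lie in [0, 1]")
  10^(u * log10(cap_bp))
}

#' Encode insertions as network inputs
#'
#' Builds the normalized 4-column input matrix consumed by the perceptron:
#' `x_orientation` (1 = sense), `x_family` (1 = ETn/MusD), `x_intron`
#' (log10-normalized intron size, 100 kb cap) and `x_distance`
#' (log10-normalized ERV-exon distance, 50 kb cap), plus the Boolean training
#' target (positive = 1, negative = 0, `NA` for unlabeled records).
#'
#' @param x an [ErvSet-class] (or a data.frame with its columns).
#' @return list with `x` (numeric matrix, n x 4) and `target` (numeric
#'   vector with `NA` for unknown labels).
#' @examples
#' es <- ErvSet(id = "a", family = "IAP", orientation = "sense",
#'              intron_size_bp = 10000, exon_distance_bp = 500)
#' encodeInsertions(es)$x
#' @export
encodeInsertions <- function(x) {
  if (is(x, "ErvSet")) x <- as.data.frame(x)
  for (col in c("family", "orientation", "intron_size_bp",
                "exon_distance_bp")) {
    if (!col %in% names(x)) stop("missing factor column: ", col)
    if (anyNA(x[[col]])) stop("missing value in factor column: ", col)
  }
  X <- cbind(
    x_orientation = as.numeric(x$orientation == "sense"),
    x_family = as.numeric(x$family == "ETnMusD"),
    x_intron = normalizeLength(x$intron_size_bp, INTRON_CAP_BP),
    x_distance = normalizeLength(x$exon_distance_bp, DISTANCE_CAP_BP))
  target <- rep(NA_real_, nrow(X))
  if ("label" %in% names(x)) {
    target[x$label == "positive"] <- 1
    target[x$label == "negative"] <- 0
  }
  list(x = X, target = target)
}
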