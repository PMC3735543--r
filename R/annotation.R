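# Factor derivation from genomic coordinates: locate the enclosing intron,
# measure the insertion-to-exon distance and the relative orientation.

#' Find the intron(s) fully enclosing an insertion
#'
#' Returns every intron (across genes) that contains the insertion entirely.
#' An insertion that overlaps any exon, or lies outside all introns, yields
#' an empty result; an insertion inside introns of several overlapping genes
#' yields one row per candidate, and disambiguation is left to the caller.
#'
#' @param insertion a length-1 [GenomicRanges::GRanges] interval.
#' @param geneModels a [GeneModels-class] from [readGeneModels()].
#' @return a [GenomicRanges::GRanges] of enclosing introns (possibly empty)
#'   with metadata `gene_id`, `intron_index`, `upstream_boundary_type`,
#'   `downstream_boundary_type`.
#' @export
findEnclosingIntron <- function(insertion, geneModels) {
  stopifnot(is(insertion, "GRanges"), length(insertion) == 1,
            is(geneModels, "GeneModels"))
  allExons <- unlist(geneExons(geneModels))
  if (length(allExons) &&
      length(GenomicRanges::findOverlaps(insertion, allExons,
                                         ignore.strand = TRUE)) > 0)
    return(geneIntrons(geneModels)[0])
  hits <- GenomicRanges::findOverlaps(insertion, geneIntrons(geneModels),
                                      type = "within",
                                      ignore.strand = TRUE)
  geneIntrons(geneModels)[S4Vectors::subjectHits(hits)]
}

#' Distance from an insertion to the nearest exon
#'
#' Measures, from the nearer edge of the insertion, the number of bases to
#' the nearer intron/exon boundary of the enclosing intron, and reports the
#' splice-site type (donor/acceptor) found at that boundary.  Ties are broken
#' toward the intron's upstream boundary in transcription order (the donor
#' side).
#'
#' @param insertion a length-1 [GenomicRanges::GRanges] inside `ctx`.
#' @param ctx a length-1 enclosing intron from [findEnclosingIntron()].
#' @return list with `distance_bp` (non-negative integer) and `nearest_site`
#'   (`"donor"` or `"acceptor"`).
#' @export
computeExonDistance <- function(insertion, ctx) {
  stopifnot(is(insertion, "GRanges"), length(insertion) == 1,
            is(ctx, "GRanges"), length(ctx) == 1)
  dLeft <- GenomicRanges::start(insertion) - GenomicRanges::start(ctx)
  dRight <- GenomicRanges::end(ctx) - GenomicRanges::end(insertion)
  if (dLeft < 0 || dRight < 0)
    stop("insertion is not contained in the intron")
  leftSite <- ctx$upstream_boundary_type      # genomic-left boundary type
  rightSite <- ctx$downstream_boundary_type
  if (dLeft < dRight) {
    list(distance_bp = dLeft, nearest_site = leftSite)
  } else if (dRight < dLeft) {
    list(distance_bp = dRight, nearest_site = rightSite)
  } else {
    # tie: prefer the upstream boundary in transcription order, i.e. the
    # donor side of the intron
    site <- if (leftSite == "donor") leftSite else rightSite
    list(distance_bp = dLeft, nearest_site = site)
  }
}

#' Orientation of an ERV relative to its host gene
#'
#' @param ervStrand,geneStrand strand characters, each `"+"` or `"-"`
#'   (vectorized).
#' @return `"sense"` where the strands agree, `"antisense"` otherwise.
#' @examples
#' relativeOrientation(c("+", "-"), c("+", "+"))
#' @export
relativeOrientation <- function(ervStrand, geneStrand) {
  ok <- function(s) all(s %in% c("+", "-"))
  if (!ok(ervStrand) || !ok(geneStrand))
    stop("strands must be '+' or '-'")
  ifelse(ervStrand == geneStrand, "sense", "antisense")
}

#' Derive the factor table for BED insertions
#'
#' Convenience wrapper: for each insertion interval, locates its enclosing
#' intron (skipping, with a message, insertions that are exonic, intergenic
#' or ambiguous across overlapping genes) and assembles the four raw factors
#' into an [ErvSet-class].
#'
#' @param insertions a [GenomicRanges::GRanges] of ERV insertions (stranded),
#'   e.g. from [readInsertionBed()]; families are taken from the `name`
#'   metadata column when it matches `"IAP"`/`"ETnMusD"`, otherwise from
#'   `family`.
#' @param geneModels a [GeneModels-class].
#' @param family optional family override (recycled).
#' @return an [ErvSet-class] of the resolvable insertions.
#' @export
annotateInsertions <- function(insertions, geneModels, family = NULL) {
  stopifnot(is(insertions, "GRanges"))
  if (is.null(family)) {
    family <- if (!is.null(insertions$family)) insertions$family else
      insertions$name
  }
  family <- rep_len(family, length(insertions))
  rows <- list()
  for (i in seq_along(insertions)) {
    ins <- insertions[i]
    ctx <- findEnclosingIntron(ins, geneModels)
    if (length(ctx) != 1) {
      message("insertion ", i, ": ",
              if (length(ctx) == 0) "no enclosing intron" else
                "ambiguous across overlapping genes", "; skipped")
      next
    }
    d <- computeExonDistance(ins, ctx)
    rows[[length(rows) + 1L]] <- data.frame(
      id = if (!is.null(ins$name)) ins$name else paste0("ins", i),
      family = family[i],
      orientation = relativeOrientation(
        as.character(GenomicRanges::strand(ins)),
        as.character(GenomicRanges::strand(ctx))),
      intron_size_bp = GenomicRanges::width(ctx),
      exon_distance_bp = d$distance_bp,
      label = "unknown",
      gene_id = ctx$gene_id,
      nearest_site = d$nearest_site,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(ErvSet())
  ErvSet(table = do.call(rbind, rows))
}
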