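# Synthetic fixture generation: labeled insertion tables whose
# class-conditional structure mirrors the curated training sets (positives
# sense-enriched, in smaller introns, closer to exons), an unlabeled
# polymorphic-like table, and toy GTF/BED loci for annotation tests.

#' Configuration for the synthetic generators
#'
#' Class-conditional sampling parameters.  Lengths are log-normal (normal in
#' log10 bp) — consistent with the log10 feature transform used to correct
#' the non-normal genomic distribution of intron sizes.  The defaults make
#' positives sense-enriched, hosted in smaller introns and closer to exons
#' than negatives, at the class sizes of the curated sets (33 positives, 117
#' negatives, 134 polymorphic).
#'
#' @param nPos,nNeg,nPolymorphic table sizes.
#' @param pSensePos,pSenseNeg probability of sense orientation per class.
#' @param pEtnPos,pEtnNeg probability of the ETn/MusD family per class.
#' @param intronLog10Mean,intronLog10Sd per-class (positive, negative) mean
#'   and sd of log10 intron size (bp).
#' @param distanceLog10Mean,distanceLog10Sd per-class mean and sd of log10
#'   ERV-exon distance (bp).
#' @param posLikeFraction fraction of positive-like records in the
#'   polymorphic-like table.
#' @param pEtnPolymorphic ETn/MusD share of the polymorphic-like table
#'   (default 8/134).
#' @param seed master seed.
#' @return a named list of generator parameters.
#' @export
synthConfig <- function(nPos = 33L, nNeg = 117L, nPolymorphic = 134L,
                        pSensePos = 0.8, pSenseNeg = 0.2,
                        pEtnPos = 0.45, pEtnNeg = 0.15,
                        intronLog10Mean = c(pos = 3.6, neg = 4.5),
                        intronLog10Sd = c(pos = 0.5, neg = 0.5),
                        distanceLog10Mean = c(pos = 2.8, neg = 3.8),
                        distanceLog10Sd = c(pos = 0.5, neg = 0.5),
                        posLikeFraction = 0.07,
                        pEtnPolymorphic = 8 / 134,
                        seed = 1L) {
  probs <- c(pSensePos, pSenseNeg, pEtnPos, pEtnNeg, posLikeFraction,
             pEtnPolymorphic)
  stopifnot(all(probs >= 0 & probs <= 1), all(intronLog10Sd > 0),
            all(distanceLog10Sd > 0))
  list(nPos = as.integer(nPos), nNeg = as.integer(nNeg),
       nPolymorphic = as.integer(nPolymorphic),
       pSensePos = pSensePos, pSenseNeg = pSenseNeg,
       pEtnPos = pEtnPos, pEtnNeg = pEtnNeg,
       intronLog10Mean = intronLog10Mean, intronLog10Sd = intronLog10Sd,
       distanceLog10Mean = distanceLog10Mean,
       distanceLog10Sd = distanceLog10Sd,
       posLikeFraction = posLikeFraction,
       pEtnPolymorphic = pEtnPolymorphic, seed = as.integer(seed))
}

# Draw n records of one class ("pos"/"neg"); family probability may be
# overridden (polymorphic tables share one family mix across classes).
# The exon distance follows the class log-normal conditioned on being at
# most half the intron size (geometric feasibility), drawn exactly by
# inverse-CDF truncation — equivalent in law to resampling until feasible,
# but it cannot stall on far-tail introns.  A record whose constraint is
# genuinely unsatisfiable (intron < 2 bp, so no distance >= 1 bp fits)
# raises an error.
sampleClass <- function(n, class, cfg, pEtn = NULL) {
  if (n == 0) return(NULL)
  pSense <- if (class == "pos") cfg$pSensePos else cfg$pSenseNeg
  if (is.null(pEtn)) pEtn <- if (class == "pos") cfg$pEtnPos else cfg$pEtnNeg
  orientation <- ifelse(rbinom(n, 1, pSense) == 1, "sense", "antisense")
  family <- ifelse(rbinom(n, 1, pEtn) == 1, "ETnMusD", "IAP")
  intron <- pmax(1, round(10^rnorm(n, cfg$intronLog10Mean[[class]],
                                   cfg$intronLog10Sd[[class]])))
  dMax <- floor(intron / 2)
  if (any(dMax < 1))
    stop("unsatisfiable feasibility constraint: intron of ",
         min(intron), " bp leaves no room for a 1 bp exon distance")
  m <- cfg$distanceLog10Mean[[class]]
  s <- cfg$distanceLog10Sd[[class]]
  pUpper <- stats::pnorm(log10(intron / 2), m, s)
  q <- stats::qnorm(runif(n) * pUpper, m, s)
  distance <- pmin(pmax(1, round(10^q)), dMax)
  data.frame(family = family, orientation = orientation,
             intron_size_bp = intron, exon_distance_bp = distance,
             stringsAsFactors = FALSE)
}

#' Generate a labeled training-like insertion table
#'
#' Draws `nPos` positive and `nNeg` negative insertions from the configured
#' class-conditional distributions (positives first), fully reproducible from
#' the seed.  Exon distances are drawn from the class log-normal truncated to
#' at most half the intron size (geometric feasibility), so all emitted
#' records satisfy the [ErvSet-class] invariants.
#'
#' @param cfg a [synthConfig()] list.
#' @return a labeled [ErvSet-class] with `nPos + nNeg` rows.
#' @examples
#' es <- generateTrainingLike(synthConfig(seed = 1))
#' table(ervLabel(es))
#' @export
generateTrainingLike <- function(cfg = synthConfig()) {
  stopifnot(cfg$nPos >= 3, cfg$nNeg >= 3)
  withSeed(cfg$seed, {
    pos <- sampleClass(cfg$nPos, "pos", cfg)
    neg <- sampleClass(cfg$nNeg, "neg", cfg)
    tab <- rbind(pos, neg)
    tab <- cbind(id = sprintf("synth_%03d", seq_len(nrow(tab))), tab,
                 label = rep(c("positive", "negative"),
                             c(cfg$nPos, cfg$nNeg)),
                 stringsAsFactors = FALSE)
    ErvSet(table = tab)
  })
}

#' Generate an unlabeled polymorphic-like insertion table
#'
#' A mixture of mostly negative-like records with a small positive-like
#' fraction (`posLikeFraction`, default 7%), all emitted with label
#' `"unknown"`.  The family mix follows `pEtnPolymorphic` (default 8/134
#' ETn/MusD) for both mixture components.
#'
#' @param cfg a [synthConfig()] list.
#' @return an unlabeled [ErvSet-class] with `nPolymorphic` rows.
#' @export
generatePolymorphicLike <- function(cfg = synthConfig()) {
  withSeed(cfg$seed + 1L, {
    isPos <- rbinom(cfg$nPolymorphic, 1, cfg$posLikeFraction) == 1
    pos <- sampleClass(sum(isPos), "pos", cfg, pEtn = cfg$pEtnPolymorphic)
    neg <- sampleClass(sum(!isPos), "neg", cfg, pEtn = cfg$pEtnPolymorphic)
    tab <- data.frame(family = character(cfg$nPolymorphic),
                      orientation = character(cfg$nPolymorphic),
                      intron_size_bp = numeric(cfg$nPolymorphic),
                      exon_distance_bp = numeric(cfg$nPolymorphic),
                      stringsAsFactors = FALSE)
    if (any(isPos)) tab[isPos, ] <- pos
    if (any(!isPos)) tab[!isPos, ] <- neg
    tab <- cbind(id = sprintf("poly_%03d", seq_len(nrow(tab))), tab,
                 label = "unknown", stringsAsFactors = FALSE)
    ErvSet(table = tab)
  })
}

#' Write a toy locus as GTF + BED fixture files
#'
#' Builds a syntactically valid single-gene GTF and a BED6 file of insertion
#' intervals at specified coordinates, for exercising the annotation layer.
#' The layout uses 0-based half-open coordinates (the BED convention); the
#' GTF is written 1-based closed.
#'
#' @param geneId gene identifier.
#' @param strand gene strand, `"+"` or `"-"`.
#' @param exons list of `c(start, end)` 0-based half-open exon intervals,
#'   in increasing order and non-overlapping; at least 2.
#' @param insertions data.frame with `start`, `end` (0-based half-open),
#'   `strand` and optional `name` columns.
#' @param chrom chromosome name (default `"chrT"`).
#' @param gtfPath,bedPath output paths (default: temporary files).
#' @return list with elements `gtf` and `bed` (the file paths).
#' @examples
#' locus <- generateToyLocus(exons = list(c(0, 200), c(1200, 1400)),
#'                           insertions = data.frame(start = 500, end = 700,
#'                                                   strand = "+"))
#' readGeneModels(locus$gtf)
#' @export
generateToyLocus <- function(geneId = "toyGene", strand = "+", exons,
                             insertions = NULL, chrom = "chrT",
                             gtfPath = tempfile(fileext = ".gtf"),
                             bedPath = tempfile(fileext = ".bed")) {
  stopifnot(strand %in% c("+", "-"), length(exons) >= 2)
  starts <- vapply(exons, `[`, 0, 1)
  ends <- vapply(exons, `[`, 0, 2)
  if (any(ends <= starts)) stop("each exon needs end > start")
  if (any(starts[-1] < ends[-length(ends)]))
    stop("exons must be non-overlapping and in increasing order")
  gtf <- sprintf(
    "%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
    chrom, starts + 1, ends, strand, geneId, geneId)
  writeLines(gtf, gtfPath)
  if (!is.null(insertions)) {
    if (is.null(insertions$name))
      insertions$name <- sprintf("ins%d", seq_len(nrow(insertions)))
    bed <- sprintf("%s\t%d\t%d\t%s\t0\t%s", chrom, insertions$start,
                   insertions$end, insertions$name, insertions$strand)
    writeLines(bed, bedPath)
  } else {
    writeLines(character(), bedPath)
  }
  list(gtf = gtfPath, bed = bedPath)
}
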