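# Tabular and genomic I/O: insertion factor tables (TSV), gene models (GTF),
# insertion intervals (BED6) and the JSON model archive.

ARCHIVE_FORMAT_VERSION <- 1L

#' Read an insertion factor table
#'
#' Reads a tab-separated table with a mandatory header naming at least the
#' columns `id`, `family`, `orientation`, `intron_size_bp`,
#' `exon_distance_bp` (and `label` when `require_labels = TRUE`; a missing
#' label column otherwise defaults to `"unknown"`).  Every row is validated:
#' illegal categories, unparseable integers and distances exceeding the
#' intron size are rejected with the offending row number.
#'
#' @param path path to the TSV file.
#' @param require_labels require a `label` column with a known class
#'   (`positive`/`negative`) on every row.
#' @return an [ErvSet-class] with records in file order.
#' @seealso [writeInsertionTable()]
#' @export
readInsertionTable <- function(path, require_labels = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  required <- c("id", "family", "orientation", "intron_size_bp",
                "exon_distance_bp", if (require_labels) "label")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("intron_size_bp", "exon_distance_bp")) {
    val <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(val) | val != floor(val))
    if (length(bad))
      stop(sprintf("row %d: column '%s' is not an integer ('%s')",
                   bad[1], col, tab[[col]][bad[1]]))
    tab[[col]] <- val
  }
  if (!"label" %in% names(tab)) tab$label <- "unknown"
  if (require_labels) {
    bad <- which(!tab$label %in% c("positive", "negative"))
    if (length(bad))
      stop(sprintf("row %d: training tables need label positive/negative ('%s')",
                   bad[1], tab$label[bad[1]]))
  }
  ErvSet(table = tab)
}

#' Write an insertion factor table
#'
#' Serializes an [ErvSet-class] as the tab-separated schema read back by
#' [readInsertionTable()]; writing then reading reproduces the records.
#'
#' @param x an [ErvSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeInsertionTable <- function(x, path) {
  stopifnot(is(x, "ErvSet"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Imports exon features, flattens each gene to its union of exons (so
#' overlapping exons merge, with a warning) and derives introns as the gaps
#' between consecutive flattened exons.  Single-exon genes contribute no
#' introns.  Intron metadata carries the gene, the intron ordinal in
#' transcription order, and the splice-site type (donor/acceptor) of the two
#' genomic boundaries: on the `+` strand the left boundary is a donor and the
#' right an acceptor, reversed on `-`.
#'
#' @param path path to a GTF file whose exon features carry `gene_id`.
#' @return a [GeneModels-class].
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("no exon features in ", path)
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("exon features must carry gene_id")
  byGene <- GenomicRanges::split(gr, gr$gene_id)
  flat <- GenomicRanges::reduce(byGene)
  if (any(S4Vectors::elementNROWS(flat) < S4Vectors::elementNROWS(byGene)))
    warning("overlapping exons within a gene were merged")
  intronList <- lapply(names(flat), function(g) {
    ex <- flat[[g]]
    strand <- as.character(GenomicRanges::strand(gr[gr$gene_id == g]))[1]
    if (length(ex) < 2) return(NULL)
    gaps <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(ex)[-1],
      IRanges::IRanges(start = GenomicRanges::end(ex)[-length(ex)] + 1,
                       end = GenomicRanges::start(ex)[-1] - 1),
      strand = strand)
    idx <- seq_along(gaps)                       # genomic left-to-right
    txIdx <- if (strand == "-") rev(idx) else idx  # transcription order
    S4Vectors::mcols(gaps) <- S4Vectors::DataFrame(
      gene_id = g, intron_index = txIdx,
      upstream_boundary_type = if (strand == "-") "acceptor" else "donor",
      downstream_boundary_type = if (strand == "-") "donor" else "acceptor")
    gaps
  })
  introns <- do.call(c, c(intronList[!vapply(intronList, is.null, TRUE)],
                          list(GenomicRanges::GRanges())))
  introns <- GenomicRanges::sort(introns, ignore.strand = TRUE)
  new("GeneModels", exons = flat, introns = introns)
}

#' Read ERV insertions from a BED6 file
#'
#' @param path path to a BED6 file (0-based half-open intervals with name,
#'   score, strand).
#' @return a [GenomicRanges::GRanges] of insertion intervals.
#' @export
readInsertionBed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  rtracklayer::import(path, format = "bed")
}

#' Save a trained ensemble as a JSON archive
#'
#' Writes a self-describing text archive with the format version, the
#' training configuration, all seeds, the cross-validation plan and every
#' member's 19 parameters at full precision; [loadModelArchive()] restores
#' the ensemble with bit-identical weights.
#'
#' @param ensemble an [ErvEnsemble-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
saveModelArchive <- function(ensemble, path) {
  stopifnot(is(ensemble, "ErvEnsemble"))
  plan <- ensemble@plan
  obj <- list(
    format_version = ARCHIVE_FORMAT_VERSION,
    training_config = ensemble@config,
    seeds = ensemble@seeds,
    cv_plan = list(nPos = plan@nPos, nNeg = plan@nNeg, folds = plan@folds,
                   permutations = plan@permutations, seed = plan@seed,
                   splits = plan@splits),
    split_id = ensemble@splitId,
    reinit_id = ensemble@reinitId,
    members = lapply(ensemble@members, mlpToPar))
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Load an ensemble archive
#'
#' @param path path to a JSON archive written by [saveModelArchive()].
#' @return the restored [ErvEnsemble-class].
#' @export
loadModelArchive <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- tryCatch(jsonlite::fromJSON(readLines(path, warn = FALSE),
                                     simplifyVector = FALSE),
                  error = function(e)
                    stop("truncated or malformed archive: ",
                         conditionMessage(e)))
  if (is.null(obj$format_version) ||
      obj$format_version != ARCHIVE_FORMAT_VERSION)
    stop("unsupported archive format_version: ",
         if (is.null(obj$format_version)) "missing" else obj$format_version)
  cp <- obj$cv_plan
  plan <- new("CvPlan", nPos = as.integer(cp$nPos),
              nNeg = as.integer(cp$nNeg), folds = as.integer(cp$folds),
              permutations = as.integer(cp$permutations),
              seed = as.integer(cp$seed),
              splits = lapply(cp$splits, function(s)
                list(train = as.integer(unlist(s$train)),
                     test = as.integer(unlist(s$test)),
                     permutation = as.integer(s$permutation),
                     fold = as.integer(s$fold))))
  cfg <- lapply(obj$training_config, function(v) unlist(v))
  cfg$maxEpochs <- as.integer(cfg$maxEpochs)
  new("ErvEnsemble",
      members = lapply(obj$members,
                       function(p) parToMlp(as.numeric(unlist(p)))),
      splitId = as.integer(unlist(obj$split_id)),
      reinitId = as.integer(unlist(obj$reinit_id)),
      plan = plan, config = cfg,
      seeds = list(master = as.integer(obj$seeds$master),
                   member = as.integer(unlist(obj$seeds$member))))
}
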