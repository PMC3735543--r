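#' ErvSet: a table of intronic ERV insertions
#'
#' Container for the per-insertion factor table: one row per intronic ERV
#' insertion with its four raw factors (family, orientation relative to the
#' host gene, host intron size in bp, distance from the insertion to the
#' nearest exon in bp) and an optional class label.  Validity enforces the
#' factor domains and the geometric constraint that an insertion cannot be
#' farther from the nearest exon than its intron is long.
#'
#' @slot table a `data.frame` with columns `id`, `family` (`"IAP"` or
#'   `"ETnMusD"`), `orientation` (`"sense"` or `"antisense"`),
#'   `intron_size_bp` (positive integer), `exon_distance_bp` (non-negative
#'   integer) and `label` (`"positive"`, `"negative"` or `"unknown"`).
#'   Optional columns (`gene_id`, coordinates) are carried through untouched.
#'
#' @seealso [ErvSet()], [readInsertionTable()], [encodeInsertions()]
#' @export
setClass("ErvSet", representation(table = "data.frame"))

ERV_REQUIRED_COLUMNS <- c("id", "family", "orientation", "intron_size_bp",
                          "exon_distance_bp", "label")

validErvSet <- function(object) {
  tab <- object@table
  msgs <- character()
  missing <- setdiff(ERV_REQUIRED_COLUMNS, names(tab))
  if (length(missing)) {
    return(paste("missing column(s):", paste(missing, collapse = ", ")))
  }
  bad <- which(!tab$family %in% ERV_FAMILIES)
  if (length(bad)) {
    msgs <- c(msgs, sprintf("row %d: illegal family '%s' (expected %s)",
                            bad[1], tab$family[bad[1]],
                            paste(ERV_FAMILIES, collapse = "/")))
  }
  bad <- which(!tab$orientation %in% ERV_ORIENTATIONS)
  if (length(bad)) {
    msgs <- c(msgs, sprintf("row %d: illegal orientation '%s'",
                            bad[1], tab$orientation[bad[1]]))
  }
  bad <- which(!tab$label %in% ERV_LABELS)
  if (length(bad)) {
    msgs <- c(msgs, sprintf("row %d: illegal label '%s'",
                            bad[1], tab$label[bad[1]]))
  }
  bad <- which(!is.finite(tab$intron_size_bp) | tab$intron_size_bp < 1)
  if (length(bad)) {
    msgs <- c(msgs, sprintf("row %d: intron_size_bp must be a positive integer",
                            bad[1]))
  }
  bad <- which(!is.finite(tab$exon_distance_bp) | tab$exon_distance_bp < 0)
  if (length(bad)) {
    msgs <- c(msgs, sprintf("row %d: exon_distance_bp must be non-negative",
                            bad[1]))
  }
  bad <- which(is.finite(tab$exon_distance_bp) & is.finite(tab$intron_size_bp) &
               tab$exon_distance_bp > tab$intron_size_bp)
  if (length(bad)) {
    msgs <- c(msgs, sprintf("row %d: exon_distance_bp exceeds intron_size_bp",
                            bad[1]))
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("ErvSet", validErvSet)

#' Construct an ErvSet from vectors or a data.frame
#'
#' @param table a data.frame with the `ErvSet` columns, or `NULL` to build
#'   one from the remaining arguments.
#' @param id,family,orientation,intron_size_bp,exon_distance_bp,label
#'   per-insertion vectors (recycled `label` defaults to `"unknown"`).
#' @return an [ErvSet-class] object.
#' @examples
#' es <- ErvSet(id = "ins1", family = "IAP", orientation = "sense",
#'              intron_size_bp = 10000, exon_distance_bp = 500,
#'              label = "positive")
#' ervFamily(es)
#' @export
ErvSet <- function(table = NULL, id = character(), family = character(),
                   orientation = character(), intron_size_bp = integer(),
                   exon_distance_bp = integer(), label = "unknown") {
  if (is.null(table)) {
    n <- length(id)
    table <- data.frame(id = as.character(id),
                        family = as.character(family),
                        orientation = as.character(orientation),
                        intron_size_bp = as.numeric(intron_size_bp),
                        exon_distance_bp = as.numeric(exon_distance_bp),
                        label = rep_len(as.character(label), n),
                        stringsAsFactors = FALSE)
  } else {
    table <- as.data.frame(table, stringsAsFactors = FALSE)
    if (!"label" %in% names(table)) table$label <- "unknown"
    table$label[is.na(table$label)] <- "unknown"
  }
  rownames(table) <- NULL
  new("ErvSet", table = table)
}

#' @describeIn ErvSet number of insertions
#' @param x an `ErvSet`
#' @export
setMethod("length", "ErvSet", function(x) nrow(x@table))

#' @export
setMethod("show", "ErvSet", function(object) {
  tab <- object@table
  cat("ErvSet with", nrow(tab), "insertion(s)\n")
  lab <- table(factor(tab$label, levels = ERV_LABELS))
  cat(sprintf("  labels: %d positive, %d negative, %d unknown\n",
              lab[["positive"]], lab[["negative"]], lab[["unknown"]]))
  fam <- table(factor(tab$family, levels = ERV_FAMILIES))
  cat(sprintf("  families: %d IAP, %d ETn/MusD\n",
              fam[["IAP"]], fam[["ETnMusD"]]))
  print(utils::head(tab, 4))
  if (nrow(tab) > 4) cat("  ...\n")
})

#' @export
setMethod("[", "ErvSet", function(x, i, j, ..., drop = FALSE) {
  ErvSet(table = x@table[i, , drop = FALSE])
})

#' @export
setMethod("as.data.frame", "ErvSet", function(x, ...) x@table)

#' Accessors for ErvSet columns
#'
#' @param x an [ErvSet-class]
#' @return the corresponding per-insertion vector.
#' @name ErvSet-accessors
NULL

#' @rdname ErvSet-accessors
#' @export
ervId <- function(x) x@table$id
#' @rdname ErvSet-accessors
#' @export
ervFamily <- function(x) x@table$family
#' @rdname ErvSet-accessors
#' @export
ervOrientation <- function(x) x@table$orientation
#' @rdname ErvSet-accessors
#' @export
intronSize <- function(x) x@table$intron_size_bp
#' @rdname ErvSet-accessors
#' @export
exonDistance <- function(x) x@table$exon_distance_bp
#' @rdname ErvSet-accessors
#' @export
ervLabel <- function(x) x@table$label

#' MlpModel: a 4-3-1 multilayer perceptron
#'
#' Weights and biases of the three-layer perceptron: four input nodes, one
#' hidden layer of three neurons, a single output neuron, with logistic
#' activation on the hidden and output layers.  The parameter count is fixed
#' at 3*4 + 3 + 3 + 1 = 19.
#'
#' @slot W1 3 x 4 hidden-layer weight matrix (rows: hidden units).
#' @slot b1 hidden biases (length 3).
#' @slot w2 hidden-to-output weights (length 3).
#' @slot b2 output bias (length 1).
#' @seealso [initMlp()], [mlpForward()], [trainMlp()]
#' @export
setClass("MlpModel", representation(W1 = "matrix", b1 = "numeric",
                                    w2 = "numeric", b2 = "numeric"))

setValidity("MlpModel", function(object) {
  if (!identical(dim(object@W1), c(3L, 4L))) return("W1 must be 3 x 4")
  if (length(object@b1) != 3L) return("b1 must have length 3")
  if (length(object@w2) != 3L) return("w2 must have length 3")
  if (length(object@b2) != 1L) return("b2 must have length 1")
  pars <- c(object@W1, object@b1, object@w2, object@b2)
  if (!all(is.finite(pars))) return("all 19 parameters must be finite")
  TRUE
})

#' @export
setMethod("show", "MlpModel", function(object) {
  cat("MlpModel: 4-3-1 perceptron, logistic activations (19 parameters)\n")
  cat("  |w| range:", sprintf("%.4g .. %.4g",
      min(abs(mlpToPar(object))), max(abs(mlpToPar(object)))), "\n")
})

# 19-vector packing shared with the C++ kernels: c(W1 column-major, b1, w2, b2)
mlpToPar <- function(model) {
  c(as.numeric(model@W1), model@b1, model@w2, model@b2)
}

parToMlp <- function(par) {
  stopifnot(length(par) == 19L)
  new("MlpModel", W1 = matrix(par[1:12], nrow = 3, ncol = 4),
      b1 = par[13:15], w2 = par[16:18], b2 = par[19])
}

#' CvPlan: a stratified repeated 3-fold cross-validation plan
#'
#' Each permutation shuffles the positive and the negative cases separately,
#' cuts each class into `folds` subgroups of (near-)equal size, and pairs the
#' k-th positive subgroup with the k-th negative subgroup as the held-out test
#' set of split k; the remaining cases form the training set.  By convention
#' indices `1..nPos` are the positive cases and `nPos+1..nPos+nNeg` the
#' negative ones.
#'
#' @slot nPos,nNeg class sizes.
#' @slot folds number of folds per permutation (3 by default).
#' @slot permutations number of independent permutations (10 by default).
#' @slot seed master seed for the permutation draws.
#' @slot splits list of splits; each has `train`, `test`, `permutation`,
#'   `fold` entries.
#' @seealso [buildCvPlan()], [trainEnsemble()]
#' @export
setClass("CvPlan", representation(nPos = "integer", nNeg = "integer",
                                  folds = "integer", permutations = "integer",
                                  seed = "integer", splits = "list"))

setValidity("CvPlan", function(object) {
  n <- object@nPos + object@nNeg
  for (s in object@splits) {
    if (length(intersect(s$train, s$test)) > 0)
      return("a split's train and test indices overlap")
    if (!setequal(union(s$train, s$test), seq_len(n)))
      return("a split does not cover all indices")
  }
  if (length(object@splits) != object@folds * object@permutations)
    return("split count must equal folds * permutations")
  TRUE
})

#' @export
setMethod("show", "CvPlan", function(object) {
  cat(sprintf(paste0("CvPlan: %d permutation(s) x %d-fold, stratified ",
                     "(%d positive / %d negative cases)\n"),
              object@permutations, object@folds, object@nPos, object@nNeg))
  cat(sprintf("  %d splits; test sets of %s cases\n", length(object@splits),
              paste(unique(vapply(object@splits,
                                  function(s) length(s$test), 0L)),
                    collapse = "/")))
})

#' ErvEnsemble: the trained ensemble of perceptrons
#'
#' Holds every trained member together with the cross-validation plan it was
#' trained under.  At the default scale (10 permutations x 3 folds x 100
#' reinitializations) the ensemble has 3000 members.  Prediction on unseen
#' data consolidates (averages) the outputs of all members; per-split
#' evaluation averages only the members of that split.
#'
#' @slot members list of [MlpModel-class] objects.
#' @slot splitId,reinitId integer vectors tagging each member with its
#'   cross-validation split and reinitialization number.
#' @slot plan the [CvPlan-class] used for training.
#' @slot config training hyperparameters (see [trainConfig()]).
#' @slot seeds list with the master seed and the per-member init seeds.
#' @seealso [trainEnsemble()], [consolidate()], [predict,ErvEnsemble-method]
#' @export
setClass("ErvEnsemble", representation(members = "list", splitId = "integer",
                                       reinitId = "integer", plan = "CvPlan",
                                       config = "list", seeds = "list"))

setValidity("ErvEnsemble", function(object) {
  m <- length(object@members)
  if (length(object@splitId) != m || length(object@reinitId) != m)
    return("splitId/reinitId must tag every member")
  if (m > 0 && max(object@splitId) > length(object@plan@splits))
    return("splitId refers to a split outside the plan")
  TRUE
})

#' @export
setMethod("show", "ErvEnsemble", function(object) {
  cat(sprintf("ErvEnsemble: %d member(s) (%d split(s) x %d reinit(s))\n",
              length(object@members), length(object@plan@splits),
              if (length(object@members))
                max(object@reinitId) else 0L))
  show(object@plan)
})

#' GridPrediction: consolidated outputs over the in-silico insertion grid
#'
#' One family-by-orientation combination of the in-silico simulation: the
#' normalized intron-size and exon-distance axes and the matrix of
#' consolidated ensemble outputs over their Cartesian grid.
#'
#' @slot family,orientation the fixed Boolean factors of this combination.
#' @slot uIntron,uDistance normalized grid coordinates in (0,1) (bin
#'   midpoints).
#' @slot outputs matrix of consolidated likelihoods; `outputs[i, j]` is the
#'   prediction at `uIntron[i]`, `uDistance[j]`.
#' @seealso [predictGrid()], [renderPredictionPlot()]
#' @export
setClass("GridPrediction", representation(family = "character",
                                          orientation = "character",
                                          uIntron = "numeric",
                                          uDistance = "numeric",
                                          outputs = "matrix"))

setValidity("GridPrediction", function(object) {
  if (!object@family %in% ERV_FAMILIES) return("illegal family")
  if (!object@orientation %in% ERV_ORIENTATIONS) return("illegal orientation")
  if (!identical(dim(object@outputs),
                 c(length(object@uIntron), length(object@uDistance))))
    return("outputs dimensions must match the grid axes")
  if (any(object@outputs <= 0 | object@outputs >= 1))
    return("outputs must lie strictly in (0,1)")
  TRUE
})

#' @export
setMethod("show", "GridPrediction", function(object) {
  cat(sprintf("GridPrediction: %s / %s, %d x %d grid, outputs %.3g .. %.3g\n",
              object@family, object@orientation, length(object@uIntron),
              length(object@uDistance), min(object@outputs),
              max(object@outputs)))
})

#' GeneModels: flattened exon/intron structure per gene
#'
#' Per-gene union-of-exons ("flattened") models: one strand and one ordered
#' exon set per gene, with introns as the gaps between consecutive flattened
#' exons.  Intron metadata records the ordinal of each intron in
#' transcription order and the splice-site type (donor/acceptor) of its two
#' genomic boundaries.
#'
#' @slot exons a [GenomicRanges::GRangesList] of flattened exons, one element
#'   per gene.
#' @slot introns a [GenomicRanges::GRanges] with metadata columns `gene_id`,
#'   `intron_index`, `upstream_boundary_type`, `downstream_boundary_type`
#'   (upstream/downstream in genomic left/right order).
#' @seealso [readGeneModels()], [findEnclosingIntron()]
#' @export
setClass("GeneModels", representation(exons = "GRangesList",
                                      introns = "GRanges"))

#' @export
setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels: %d gene(s), %d intron(s)\n",
              length(object@exons), length(object@introns)))
})

#' @rdname GeneModels-class
#' @param x a `GeneModels` object
#' @export
geneExons <- function(x) x@exons
#' @rdname GeneModels-class
#' @export
geneIntrons <- function(x) x@introns
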