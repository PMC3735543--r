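# Ensemble construction: stratified repeated 3-fold cross-validation,
# per-split reinitialized training, and consolidated (averaged) prediction.

# Cut a permuted index vector into `folds` subgroups whose sizes differ by at
# most one (remainders handed out one per subgroup, first subgroups first).
cutSubgroups <- function(idx, folds) {
  sizes <- rep(length(idx) %/% folds, folds)
  extra <- length(idx) %% folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(idx, rep(seq_len(folds), sizes))
}

#' Build a stratified cross-validation plan
#'
#' For each of `permutations` independent shuffles, the positive and the
#' negative cases are permuted separately and each class is cut into `folds`
#' subgroups of (near-)equal size; split k holds out the k-th positive plus
#' the k-th negative subgroup as its test set and trains on the rest.  With
#' the curated class sizes (33 positives, 117 negatives) each test set has
#' 50 cases and each training set 100.  Indices `1..nPos` denote the positive
#' cases, `nPos+1..nPos+nNeg` the negative ones.
#'
#' @param nPos,nNeg class sizes (each at least `folds`).
#' @param permutations number of independent shuffles (default 10).
#' @param seed master seed for the shuffles.
#' @param folds folds per permutation (default 3).
#' @return a [CvPlan-class] with `folds * permutations` splits.
#' @examples
#' plan <- buildCvPlan(33, 117, permutations = 1, seed = 1)
#' lengths(plan@splits[[1]][c("train", "test")])
#' @export
buildCvPlan <- function(nPos, nNeg, permutations = 10L, seed = 1L,
                        folds = 3L) {
  nPos <- as.integer(nPos); nNeg <- as.integer(nNeg)
  folds <- as.integer(folds); permutations <- as.integer(permutations)
  if (nPos < folds || nNeg < folds)
    stop("each class needs at least `folds` members")
  permSeeds <- deriveSeeds(seed, permutations)
  splits <- list()
  for (p in seq_len(permutations)) {
    posPerm <- withSeed(permSeeds[p], sample(nPos))
    negPerm <- withSeed(permSeeds[p] + 1L, sample(nNeg)) + nPos
    posGroups <- cutSubgroups(posPerm, folds)
    negGroups <- cutSubgroups(negPerm, folds)
    for (k in seq_len(folds)) {
      test <- sort(c(posGroups[[k]], negGroups[[k]]))
      splits[[length(splits) + 1L]] <-
        list(train = sort(setdiff(seq_len(nPos + nNeg), test)),
             test = test, permutation = p, fold = k)
    }
  }
  new("CvPlan", nPos = nPos, nNeg = nNeg, folds = folds,
      permutations = permutations, seed = as.integer(seed), splits = splits)
}

#' Train the full ensemble
#'
#' For every split of the plan, `nReinits` members are trained from
#' independent random initializations on that split's training cases only
#' (the held-out test cases are never shown to its members).  Member count is
#' `length(plan@splits) * nReinits` — 3000 at the default scale of 10
#' permutations x 3 folds x 100 reinitializations.  A member whose training
#' diverges (non-finite loss) is re-seeded once before failing.
#'
#' @param plan a [CvPlan-class].
#' @param x n x 4 encoded input matrix (rows in plan index order: positives
#'   first).
#' @param target length-n 0/1 targets matching the plan's classes.
#' @param nReinits reinitializations per split (default 100).
#' @param config hyperparameters from [trainConfig()].
#' @param seed master seed for the member initializations.
#' @return an [ErvEnsemble-class].
#' @export
trainEnsemble <- function(plan, x, target, nReinits = 100L,
                          config = trainConfig(), seed = plan@seed) {
  x <- asInputMatrix(x)
  n <- plan@nPos + plan@nNeg
  if (nrow(x) != n) stop("data rows must match the plan's case count")
  stopifnot(length(target) == n, all(target %in% c(0, 1)))
  if (any(target[seq_len(plan@nPos)] != 1) ||
      any(target[plan@nPos + seq_len(plan@nNeg)] != 0))
    stop("targets do not follow the plan convention (positives first)")
  nReinits <- as.integer(nReinits)
  nSplits <- length(plan@splits)
  memberSeeds <- deriveSeeds(seed + 1L, nSplits * nReinits)
  members <- vector("list", nSplits * nReinits)
  splitId <- integer(nSplits * nReinits)
  reinitId <- integer(nSplits * nReinits)
  m <- 0L
  for (s in seq_len(nSplits)) {
    tr <- plan@splits[[s]]$train
    for (r in seq_len(nReinits)) {
      m <- m + 1L
      fit <- tryCatch(
        trainMlp(initMlp(memberSeeds[m], config$initRange),
                 x[tr, , drop = FALSE], target[tr], config),
        error = function(e) NULL)
      if (is.null(fit)) {  # diverged: one fresh re-seed, then fail loudly
        retrySeed <- memberSeeds[m] %% (.Machine$integer.max - 1L) + 1L
        memberSeeds[m] <- retrySeed
        fit <- trainMlp(initMlp(retrySeed, config$initRange),
                        x[tr, , drop = FALSE], target[tr], config)
      }
      members[[m]] <- fit$model
      splitId[m] <- s
      reinitId[m] <- r
    }
  }
  new("ErvEnsemble", members = members, splitId = splitId,
      reinitId = reinitId, plan = plan, config = config,
      seeds = list(master = as.integer(seed), member = memberSeeds))
}

# Stack member parameter vectors into the 19 x M matrix the C++ kernel wants.
memberParMatrix <- function(members) {
  vapply(members, mlpToPar, numeric(19))
}

#' Consolidate member outputs
#'
#' The consolidated prediction is the arithmetic mean of the member forward
#' outputs, itself strictly inside (0, 1).
#'
#' @param members a list of [MlpModel-class] objects or an
#'   [ErvEnsemble-class] (all of whose members are used).
#' @param x a length-4 input vector or an n x 4 matrix.
#' @return numeric vector of consolidated likelihoods.
#' @export
consolidate <- function(members, x) {
  if (is(members, "ErvEnsemble")) members <- members@members
  if (length(members) == 0) stop("cannot consolidate an empty member set")
  cpp_ensemble_consolidate(memberParMatrix(members), asInputMatrix(x))
}

# Members belonging to one cross-validation split.
splitMembers <- function(ensemble, split) {
  ensemble@members[ensemble@splitId == split]
}

#' Predict disruption likelihoods for insertions
#'
#' Encodes the records, consolidates over all ensemble members and calls an
#' insertion positive when its likelihood reaches the threshold (ties count
#' as positive).
#'
#' @param object a trained [ErvEnsemble-class].
#' @param newdata an [ErvSet-class], a compatible data.frame, or an already
#'   encoded n x 4 matrix.
#' @param threshold classification cutoff in `[0, 1]` (default 0.5).
#' @param ... ignored.
#' @return data.frame with columns `id`, `likelihood` and `call`
#'   (`"positive"`/`"negative"`).
#' @examples
#' \donttest{
#' cfg <- synthConfig(nPos = 6, nNeg = 12, seed = 1)
#' es <- generateTrainingLike(cfg)
#' enc <- encodeInsertions(es)
#' plan <- buildCvPlan(6, 12, permutations = 1, seed = 1)
#' ens <- trainEnsemble(plan, enc$x, enc$target, nReinits = 2)
#' predict(ens, es)
#' }
#' @export
setMethod("predict", "ErvEnsemble",
          function(object, newdata, threshold = 0.5, ...) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (is(newdata, "ErvSet") || is.data.frame(newdata)) {
    tab <- if (is(newdata, "ErvSet")) as.data.frame(newdata) else newdata
    ids <- as.character(tab$id)
    # a record that cannot be encoded yields an NA entry, not a global abort
    ok <- !is.na(tab$family) & tab$family %in% ERV_FAMILIES &
      !is.na(tab$orientation) & tab$orientation %in% ERV_ORIENTATIONS &
      is.finite(tab$intron_size_bp) & tab$intron_size_bp >= 1 &
      is.finite(tab$exon_distance_bp) & tab$exon_distance_bp >= 0
    likelihood <- rep(NA_real_, nrow(tab))
    if (any(!ok))
      warning(sum(!ok), " record(s) could not be encoded; returned NA")
    if (any(ok)) {
      X <- encodeInsertions(tab[ok, , drop = FALSE])$x
      likelihood[ok] <- consolidate(object@members, X)
    }
  } else {
    X <- asInputMatrix(newdata)
    ids <- as.character(seq_len(nrow(X)))
    likelihood <- consolidate(object@members, X)
  }
  data.frame(id = ids, likelihood = likelihood,
             call = ifelse(likelihood >= threshold, "positive", "negative"),
             stringsAsFactors = FALSE)
})
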