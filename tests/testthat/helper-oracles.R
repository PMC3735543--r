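# Independent oracles and shared fixtures.

# Mann-Whitney pair-counting AUC: fraction of (positive, negative) score
# pairs ranked correctly, ties counted 1/2.
bruteAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Plain-R forward pass written independently of the package kernel
# (spreadsheet-style: explicit matrix arithmetic on one input at a time).
refForward <- function(par, x) {
  W1 <- matrix(par[1:12], 3, 4)
  b1 <- par[13:15]; w2 <- par[16:18]; b2 <- par[19]
  h <- 1 / (1 + exp(-(as.vector(W1 %*% x) + b1)))
  1 / (1 + exp(-(sum(w2 * h) + b2)))
}

# Exact conditional (margin-fixed) two-sided test of equal proportions,
# ordered by |p1 - p2|: the permutation-distribution oracle for the
# chi-square approximation.
exactPropP <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  ks <- max(0, K - n2):min(n1, K)
  stat <- function(a) abs(a / n1 - (K - a) / n2)
  pr <- stats::dhyper(ks, n1, n2, K)
  sum(pr[stat(ks) >= stat(k1) - 1e-12])
}

# A small fully valid insertion table.
tinyTable <- function() {
  data.frame(
    id = paste0("e", 1:5),
    family = c("IAP", "ETnMusD", "IAP", "IAP", "ETnMusD"),
    orientation = c("sense", "antisense", "sense", "antisense", "sense"),
    intron_size_bp = c(10000, 816, 2469, 100000, 50),
    exon_distance_bp = c(500, 279, 215, 50000, 10),
    label = c("positive", "positive", "negative", "negative", "unknown"),
    stringsAsFactors = FALSE)
}

# A quick small ensemble on the default synthetic table (1 permutation,
# few reinitializations) for tests that need a trained predictor.
.small <- new.env()
smallEnsembleFixture <- function() {
  if (is.null(.small$state)) {
    cfg <- synthConfig(seed = 1)
    es <- generateTrainingLike(cfg)
    enc <- encodeInsertions(es)
    plan <- buildCvPlan(cfg$nPos, cfg$nNeg, permutations = 1, seed = 1)
    ens <- trainEnsemble(plan, enc$x, enc$target, nReinits = 5)
    .small$state <- list(cfg = cfg, es = es, enc = enc, plan = plan,
                         ens = ens)
  }
  .small$state
}

# The full study-scale run (33 + 117 cases, 10 permutations x 3 folds x 100
# reinitializations = 3000 members), trained once and reused across the
# acceptance checks.
.acc <- new.env()
fullScaleFixture <- function() {
  if (is.null(.acc$state)) {
    cfg <- synthConfig(seed = 1)
    es <- generateTrainingLike(cfg)
    enc <- encodeInsertions(es)
    plan <- buildCvPlan(cfg$nPos, cfg$nNeg, permutations = 10, seed = 1)
    t0 <- Sys.time()
    ens <- trainEnsemble(plan, enc$x, enc$target, nReinits = 100)
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    .acc$state <- list(cfg = cfg, es = es, enc = enc, plan = plan,
                       ens = ens, elapsed = elapsed)
  }
  .acc$state
}
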