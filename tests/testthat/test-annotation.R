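# Factor derivation from coordinates: enclosing introns, exon distances,
# relative orientation.

toyLocus <- function(strand = "+") {
  generateToyLocus(strand = strand,
                   exons = list(c(0, 200), c(1200, 1400), c(3000, 3200)))
}

grT <- function(start, end, strand = "+") {
  GenomicRanges::GRanges("chrT", IRanges::IRanges(start + 1, end),
                         strand = strand)
}

test_that("enclosing introns are found and exonic insertions excluded", {
  gm <- readGeneModels(toyLocus()$gtf)
  ctx <- findEnclosingIntron(grT(500, 700), gm)
  expect_length(ctx, 1)
  expect_equal(ctx$intron_index, 1)
  expect_equal(GenomicRanges::width(ctx), 1000)
  # overlapping an exon boundary -> none
  expect_length(findEnclosingIntron(grT(150, 350), gm), 0)
  # fully exonic -> none
  expect_length(findEnclosingIntron(grT(10, 50), gm), 0)
  # outside the gene -> none
  expect_length(findEnclosingIntron(grT(5000, 5100), gm), 0)
})

test_that("insertions inside introns of two overlapping genes report both", {
  gtf <- tempfile(fileext = ".gtf")
  lines <- c(
    sprintf(paste0("chrT\ttoy\texon\t%d\t%d\t.\t+\t.\t",
                   "gene_id \"gA\"; transcript_id \"gA.t1\";"),
            c(1, 2001), c(100, 2100)),
    sprintf(paste0("chrT\ttoy\texon\t%d\t%d\t.\t-\t.\t",
                   "gene_id \"gB\"; transcript_id \"gB.t1\";"),
            c(201, 1901), c(300, 2000)))
  writeLines(lines, gtf)
  gm <- readGeneModels(gtf)
  ctx <- findEnclosingIntron(grT(800, 900), gm)
  expect_length(ctx, 2)
  expect_setequal(ctx$gene_id, c("gA", "gB"))
})

test_that("exon distance is measured from the nearer edge, ties to the donor", {
  gm <- readGeneModels(toyLocus()$gtf)
  # measured against our toy intron 1, which spans [200, 1200) 0-based:
  ctx <- findEnclosingIntron(grT(300, 400), gm)
  d <- computeExonDistance(grT(300, 400), ctx)
  expect_equal(d$distance_bp, 100)
  expect_equal(d$nearest_site, "donor")  # upstream boundary on + strand
  # abutting the upstream boundary -> 0
  d0 <- computeExonDistance(grT(200, 300), ctx)
  expect_equal(d0$distance_bp, 0)
  # exactly centered -> (intron - insertion)/2, tie to the donor side
  dc <- computeExonDistance(grT(600, 800), ctx)
  expect_equal(dc$distance_bp, (1000 - 200) / 2)
  expect_equal(dc$nearest_site, "donor")
  # nearer the downstream boundary -> acceptor
  da <- computeExonDistance(grT(1000, 1100), ctx)
  expect_equal(da$distance_bp, 100)
  expect_equal(da$nearest_site, "acceptor")
  expect_error(computeExonDistance(grT(100, 250), ctx), "not contained")
})

test_that("any intronic insertion satisfies the distance bounds", {
  gm <- readGeneModels(toyLocus()$gtf)
  set.seed(71)
  for (i in 1:50) {
    len <- sample(1:500, 1)
    start <- sample(200:(1200 - len), 1)
    ins <- grT(start, start + len)
    ctx <- findEnclosingIntron(ins, gm)
    d <- computeExonDistance(ins, ctx)$distance_bp
    expect_gte(d, 0)
    expect_lte(d, (1000 - len) / 2)
    expect_lte(d, 1000)
  }
})

test_that("mirroring the locus preserves distances and swaps splice sites", {
  gmPlus <- readGeneModels(toyLocus("+")$gtf)
  gmMinus <- readGeneModels(toyLocus("-")$gtf)
  ins <- grT(300, 400)
  dPlus <- computeExonDistance(ins, findEnclosingIntron(ins, gmPlus))
  dMinus <- computeExonDistance(ins, findEnclosingIntron(ins, gmMinus))
  expect_equal(dPlus$distance_bp, dMinus$distance_bp)
  expect_equal(dPlus$nearest_site, "donor")
  expect_equal(dMinus$nearest_site, "acceptor")
  expect_equal(GenomicRanges::width(geneIntrons(gmPlus)),
               GenomicRanges::width(geneIntrons(gmMinus)))
})

test_that("relative orientation is sense iff strands agree", {
  expect_equal(relativeOrientation("+", "+"), "sense")
  expect_equal(relativeOrientation("-", "+"), "antisense")
  strands <- expand.grid(erv = c("+", "-"), gene = c("+", "-"),
                         stringsAsFactors = FALSE)
  expect_equal(relativeOrientation(strands$erv, strands$gene),
               ifelse(strands$erv == strands$gene, "sense", "antisense"))
  expect_error(relativeOrientation("*", "+"), "strand")
})

test_that("annotateInsertions assembles the factor table end to end", {
  loc <- generateToyLocus(
    exons = list(c(0, 200), c(1200, 1400), c(3000, 3200)),
    insertions = data.frame(start = c(500, 100, 1500), end = c(700, 150, 1600),
                            strand = c("-", "+", "+")))
  gm <- readGeneModels(loc$gtf)
  ins <- readInsertionBed(loc$bed)
  expect_message(es <- annotateInsertions(ins, gm, family = "IAP"),
                 "skipped")  # the exonic insertion
  expect_length(es, 2)
  expect_equal(intronSize(es), c(1000, 1600))
  expect_equal(exonDistance(es), c(300, 100))
  expect_equal(ervOrientation(es), c("antisense", "sense"))
})
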