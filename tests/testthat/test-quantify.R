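# Hand-built BAM with known read placements for boundary cases
write_boundary_bam <- function() {
  dir <- tempfile("boundary"); dir.create(dir)
  reads <- c(
    # five reads fully inside [101, 200]
    sprintf("in%d\t0\tchrQ\t%d\t60\t10M\t*\t0\t0\t%s\t*", 1:5,
            c(101, 120, 150, 180, 191), strrep("A", 10)),
    # abutting read ending at 100 (overlap 0 with [101, 200])
    paste0("ab1\t0\tchrQ\t91\t60\t10M\t*\t0\t0\t", strrep("A", 10), "\t*"),
    # read with 3 bp overlap (198..207)
    paste0("edge\t0\tchrQ\t198\t60\t10M\t*\t0\t0\t", strrep("A", 10), "\t*"),
    # low mapq read inside
    paste0("lowq\t0\tchrQ\t130\t5\t10M\t*\t0\t0\t", strrep("A", 10), "\t*"),
    # duplicate-flagged read inside (flag 1024)
    paste0("dup\t1024\tchrQ\t140\t60\t10M\t*\t0\t0\t", strrep("A", 10), "\t*"))
  sam <- c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chrQ\tLN:10000", reads)
  sam_path <- file.path(dir, "b.sam")
  writeLines(sam, sam_path)
  suppressMessages(Rsamtools::asBam(sam_path, file.path(dir, "b"),
                                    overwrite = TRUE,
                                    indexDestination = TRUE))
}

test_that("region counting respects boundaries, MAPQ, duplicates and min_overlap", {
  bam <- write_boundary_bam()
  region <- GRanges("chrQ", IRanges(101, 200))
  # default: 5 inside + 1 edge; abutting, low-mapq and duplicate excluded
  expect_equal(unname(count_reads(bam, region)), 6L)
  # raising min_overlap above the edge read's 3 bp drops it
  expect_equal(unname(count_reads(bam, region,
                                  counting_params(min_overlap_bp = 4L))), 5L)
  # admitting low MAPQ adds one
  expect_equal(unname(count_reads(bam, region,
                                  counting_params(min_mapq = 0L))), 7L)
  # admitting duplicates adds one more
  expect_equal(unname(count_reads(
    bam, region, counting_params(min_mapq = 0L,
                                 include_duplicates = TRUE))), 8L)
  # empty region list
  expect_length(count_reads(bam, GRanges()), 0L)
  # unknown contig: zero with warning
  expect_warning(z <- count_reads(bam, GRanges("chrZ", IRanges(1, 100))),
                 "chrZ")
  expect_equal(unname(z), 0L)
})

test_that("unindexed BAMs are rejected with an instruction to index", {
  bam <- write_boundary_bam()
  noidx <- tempfile(fileext = ".bam")
  file.copy(bam, noidx)
  expect_error(count_reads(noidx, GRanges("chrQ", IRanges(1, 10))), "index")
})

test_that("a multi-interval feature counts a read once, a shared exon counts for both genes", {
  bam <- write_boundary_bam()
  # one feature with two intervals both hit by read in3 (150..159)
  feat <- GRangesList(f1 = GRanges("chrQ", IRanges(c(145, 155), c(152, 165))))
  expect_equal(unname(count_reads(bam, feat)), 1L)
  # two genes sharing the exon containing read in1 (101..110)
  g1 <- gene_model("gA", GRanges("chrQ", IRanges(95, 300), strand = "+"),
                   GRanges("chrQ", IRanges(95, 115), strand = "+"))
  g2 <- gene_model("gB", GRanges("chrQ", IRanges(95, 400), strand = "+"),
                   GRanges("chrQ", IRanges(95, 115), strand = "+"))
  res <- gene_counts(bam, list(g1, g2),
                     counting_params(min_overlap_bp = 10L))
  expect_equal(unname(res$counts["gA"]), unname(res$counts["gB"]))
  expect_gte(unname(res$counts["gA"]), 1L)
})

test_that("gene counts on the toy BAMs reproduce the generator truth exactly", {
  toy <- get_toy()
  q <- get_toy_counted()
  got <- q$counts$counts[rownames(toy$truth$counts),
                         colnames(toy$truth$counts)]
  expect_identical(unname(got), unname(toy$truth$counts))
  # intronic/intergenic noise reads exist but are not counted
  total_noise <- sum(vapply(toy$truth$reads, function(df)
    sum(df$placement != "exonic"), 0))
  expect_gt(total_noise, 0)
})

test_that("counting equals a naive all-reads overlap scan on random regions", {
  toy <- get_toy()
  smp_id <- names(toy$truth$reads)[1]
  reads_df <- toy$truth$reads[[smp_id]]
  bam <- file.path(toy$dir, paste0(smp_id, ".bam"))
  set.seed(99)
  chroms <- sprintf("chrS%d", seq_len(toy$config$n_contigs))
  n_regions <- 100
  starts <- sample.int(toy$config$contig_length - 2000L, n_regions)
  widths <- sample(50:2000, n_regions, replace = TRUE)
  chrom <- sample(chroms, n_regions, replace = TRUE)
  regions <- GRanges(chrom, IRanges(starts, width = widths))
  got <- count_reads(bam, regions)
  expected <- vapply(seq_len(n_regions), function(i)
    naive_region_count(reads_df, chrom[i], starts[i],
                       starts[i] + widths[i] - 1L), 0)
  expect_identical(unname(got), as.integer(expected))
})

test_that("size factors match the median-of-ratios worked examples", {
  # identical samples -> unit factors
  m1 <- matrix(c(5, 9, 5, 9), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(size_factors(m1)), c(1, 1))

  # two genes, sample2 doubles sample1: geomean (2*4)^.5 = 2.828 per gene
  m2 <- matrix(c(2, 2, 4, 4), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-9)

  # zero-geomean gene excluded
  m3 <- matrix(c(0, 2, 4, 2), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(size_factors(m3)), c(1, 1), tolerance = 1e-12)

  # all-zero-containing features only -> error
  m4 <- matrix(c(0, 2, 4, 0), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(m4), "positive")
})

test_that("size factors scale exactly with a c-fold sample on positive matrices", {
  set.seed(3)
  base <- matrix(rpois(50, 40) + 1, 10, 5,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  for (c_fold in c(0.5, 2, 3.7)) {
    m <- base
    m[, 2] <- base[, 1] * c_fold
    sf <- size_factors(m)
    expect_equal(unname(sf[2] / sf[1]), c_fold, tolerance = 1e-9)
  }
})

test_that("size factors agree with the reference median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  toy <- get_toy()
  m <- toy$truth$counts
  keep <- rowSums(m == 0) == 0
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
})

test_that("scale transforms match their closed forms", {
  cm <- count_matrix(
    matrix(c(10, 0, 8, 20, 0, 8), 3,
           dimnames = list(c("f1", "f2", "f3"), c("s1", "s2"))),
    lengths = c(f1 = 1000, f2 = 500, f3 = 100))
  # RPKM: 10 reads, 1 kb, 1e6 library -> 10
  rpkm <- transform_counts(cm, "rpkm", library_sizes = c(s1 = 1e6, s2 = 2e6))
  expect_equal(rpkm$values["f1", "s1"], 10)
  expect_equal(rpkm$values["f1", "s2"], 10)   # 20 reads in 2e6 library
  # normalized: count / factor
  norm <- transform_counts(cm, "normalized", factors = c(s1 = 2, s2 = 1))
  expect_equal(norm$values["f3", "s1"], 4)
  # log2 of zero with pseudocount 1 is 0
  lg <- transform_counts(cm, "log2raw")
  expect_equal(lg$values["f2", "s1"], 0)
  # raw is the identity
  raw <- transform_counts(cm, "raw")
  expect_equal(raw$values, cm$counts * 1.0)
  # missing requirements error
  expect_error(transform_counts(cm, "normalized"), "factors")
  expect_error(transform_counts(cm, "rpkm"), "library")
})

test_that("flags mark low-count, short and silent features without removing them", {
  cm <- count_matrix(
    matrix(c(0, 50, 5, 0, 30, 12), 3,
           dimnames = list(c("silent", "short", "low"), c("s1", "s2"))),
    lengths = c(silent = 500, short = 150, low = 900))
  cm <- assign_flags(cm)
  expect_setequal(cm$flags$silent, c("LOW_COUNT", "ZERO_IN_ALL"))
  expect_equal(cm$flags$short, "SHORT")
  expect_length(cm$flags$low, 0)       # max(5, 12) >= 10 -> no LOW_COUNT
  expect_equal(nrow(cm$counts), 3L)
})

test_that("quantify_regions appends custom regions normalized by gene-derived factors", {
  toy <- get_toy()
  inst <- get_toy_instance()
  store <- get_toy_store()
  # an unannotated (intergenic) region that the generator seeded with reads
  reads1 <- toy$truth$reads[[1]]
  inter <- reads1[reads1$placement == "intergenic", ][1, ]
  lnc <- GRanges(inter$chrom, IRanges(inter$start - 25, inter$end + 25))
  mcols(lnc)$name <- "novel_linc"

  q_raw <- quantify_regions(inst, store, regions = lnc, scale = "raw")
  smp1 <- colnames(q_raw$expr$values)[1]
  expected <- naive_region_count(toy$truth$reads[[smp1]], inter$chrom,
                                 start(lnc), end(lnc))
  expect_equal(q_raw$expr$values["novel_linc", smp1], expected)

  # gene-derived factors are unaffected by appending the region
  q_genes_only <- get_toy_counted()
  sf_with <- size_factors(q_raw$counts$counts[
    seq_len(nrow(store$genes)), , drop = FALSE])
  sf_without <- size_factors(q_genes_only$counts$counts)
  expect_equal(sf_with, sf_without, tolerance = 1e-12)

  # RPKM path matches the formula on the known library size
  q_rpkm <- quantify_regions(inst, store, regions = lnc, scale = "rpkm")
  libsize <- get_toy_library_sizes()[[smp1]]
  expect_equal(q_rpkm$expr$values["novel_linc", smp1],
               expected / (width(lnc) / 1e3) / (libsize / 1e6),
               tolerance = 1e-9)

  # raw scale equals the plain count matrix cast to numeric
  expect_equal(q_raw$expr$values, q_raw$counts$counts * 1.0)
})

test_that("quantification without BAMs fails with an actionable message", {
  toy <- get_toy()
  m <- load_manifest(toy$manifest_path)
  m$samples$bam_path <- NA_character_
  inst <- create_instance(m)
  expect_error(
    quantify_regions(inst, get_toy_store(),
                     regions = GRanges("chrS1", IRanges(1, 100))),
    "BAM")
})

test_that("duplicating every read doubles counts and preserves RPKM", {
  toy <- get_toy()
  smp_id <- names(toy$truth$reads)[1]
  bam <- file.path(toy$dir, paste0(smp_id, ".bam"))
  store <- get_toy_store()
  genes <- lapply(store$genes$gene_id[1:5], get_gene, store = store)

  dup_dir <- tempfile("dup"); dir.create(dup_dir)
  merged <- file.path(dup_dir, "doubled.bam")
  Rsamtools::mergeBam(c(bam, bam), merged, indexDestination = TRUE)

  params <- counting_params(include_duplicates = TRUE)
  single <- gene_counts(bam, genes, params)
  doubled <- gene_counts(merged, genes, params)
  expect_equal(unname(doubled$counts), unname(2L * single$counts))

  lib1 <- bam_library_size(bam)
  cm1 <- count_matrix(matrix(single$counts, ncol = 1,
                             dimnames = list(names(single$counts), "s")),
                      single$lengths)
  cm2 <- count_matrix(matrix(doubled$counts, ncol = 1,
                             dimnames = list(names(doubled$counts), "s")),
                      doubled$lengths)
  r1 <- transform_counts(cm1, "rpkm", library_sizes = c(s = lib1))
  r2 <- transform_counts(cm2, "rpkm", library_sizes = c(s = 2 * lib1))
  expect_equal(r1$values, r2$values, tolerance = 1e-12)
})

test_that("expression tables round-trip through TSV with flags and lengths", {
  q <- get_toy_counted()
  path <- tempfile(fileext = ".tsv")
  write_expression_tsv(q$expr, path)
  back <- read.delim(path, check.names = FALSE)
  expect_equal(back$feature_id, rownames(q$expr$values))
  expect_equal(as.matrix(back[, colnames(q$expr$values)]),
               q$expr$values, ignore_attr = TRUE)
})
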