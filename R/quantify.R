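## Read counting over exon unions and custom regions, size factors,
## scale transforms and QC flags.
##
## Counting contract: a read (or fragment, for paired-end data) counts for a
## feature iff its aligned bases overlap the feature's intervals by at least
## `min_overlap_bp` in total, after MAPQ / duplicate / strand filters; it is
## counted at most once per feature however many of the feature's intervals
## it touches, and a read overlapping several features counts for each (no
## ambiguity resolution).

#' Counting parameters
#'
#' @param min_mapq Minimum mapping quality (default 10).
#' @param count_fragments Count read pairs once (paired-end data)?
#' @param include_duplicates Keep PCR/optical duplicates?
#' @param min_overlap_bp Minimum aligned-base overlap with a feature.
#' @param stranded `"none"` (ignore strand), `"forward"` (read strand must
#'   equal feature strand) or `"reverse"` (must be opposite).
#' @return A `CountingParams` list.
#' @export
counting_params <- function(min_mapq = 10L, count_fragments = FALSE,
                            include_duplicates = FALSE, min_overlap_bp = 1L,
                            stranded = c("none", "forward", "reverse")) {
  stranded <- match.arg(stranded)
  stopifnot(min_mapq >= 0L, min_overlap_bp >= 1L)
  structure(list(min_mapq = as.integer(min_mapq),
                 count_fragments = isTRUE(count_fragments),
                 include_duplicates = isTRUE(include_duplicates),
                 min_overlap_bp = as.integer(min_overlap_bp),
                 stranded = stranded),
            class = "CountingParams")
}

.read_alignments <- function(bam, params) {
  bf <- BamFile(bam)
  if (is.na(index(bf)) || !file.exists(index(bf)))
    stop("BAM '", bam, "' is not indexed; run samtools index (or ",
         "Rsamtools::indexBam) first")
  sbp <- ScanBamParam(flag = .bam_flag_default(params$include_duplicates),
                      mapqFilter = params$min_mapq)
  if (params$count_fragments)
    readGAlignmentPairs(bf, param = sbp)
  else
    readGAlignments(bf, param = sbp)
}

## Features as GRangesList (one element per feature, possibly multi-interval)
.as_feature_list <- function(regions) {
  if (is(regions, "GRangesList")) return(regions)
  if (is(regions, "GRanges")) {
    grl <- GRangesList(lapply(seq_along(regions), function(i)
      granges(regions[i])))
    names(grl) <- if (!is.null(mcols(regions)$name))
      mcols(regions)$name else as.character(seq_along(regions))
    return(grl)
  }
  if (is.list(regions) && all(vapply(regions, is, TRUE, "GeneModel")))
    return(GRangesList(setNames(
      lapply(regions, function(g) exon_union(g)$exons),
      vapply(regions, `[[`, "", "gene_id"))))
  stop("regions must be a GRanges, GRangesList, or list of GeneModel")
}

## Core overlap counter: reads (GAlignments / GAlignmentPairs) vs features.
## Aligned blocks only (CIGAR N/I/S excluded); per (read, feature) pair the
## intersection widths are summed across blocks and intervals before the
## min_overlap test, so a read straddling an intron counts its two exonic
## chunks jointly.
.count_overlaps <- function(reads, features, params) {
  blocks <- grglist(reads)
  ub <- unlist(blocks, use.names = FALSE)
  read_of <- rep.int(seq_along(blocks), lengths(blocks))
  uf <- unlist(features, use.names = FALSE)
  feat_of <- rep.int(seq_along(features), lengths(features))
  hits <- suppressWarnings(findOverlaps(ub, uf, ignore.strand = TRUE))
  if (length(hits) == 0L)
    return(integer(length(features)))
  qi <- queryHits(hits); si <- subjectHits(hits)
  ov <- pmin(end(ub)[qi], end(uf)[si]) - pmax(start(ub)[qi], start(uf)[si]) + 1L
  pair_key <- paste(read_of[qi], feat_of[si])
  tot <- rowsum(ov, pair_key)
  keep <- tot[, 1] >= params$min_overlap_bp
  if (!any(keep)) return(integer(length(features)))
  kept <- strsplit(rownames(tot)[keep], " ", fixed = TRUE)
  r_idx <- as.integer(vapply(kept, `[`, "", 1L))
  f_idx <- as.integer(vapply(kept, `[`, "", 2L))
  if (params$stranded != "none") {
    rs <- as.character(strand(reads))[r_idx]
    feat_strand <- vapply(runValue(strand(features)),
                          function(x) as.character(x)[1], "")
    fs <- feat_strand[f_idx]
    ok <- if (params$stranded == "forward") rs == fs else
      (rs == "+" & fs == "-") | (rs == "-" & fs == "+")
    r_idx <- r_idx[ok]; f_idx <- f_idx[ok]
  }
  tabulate(f_idx, nbins = length(features))
}

#' Count reads over genomic regions
#'
#' On-the-fly abundance counting for arbitrary — typically non-annotated —
#' regions, straight from an indexed BAM file.
#'
#' @param bam Path to an indexed BAM file.
#' @param regions `GRanges` (one feature per row), `GRangesList`
#'   (multi-interval features) or list of `GeneModel`.
#' @param params A [counting_params()] object.
#' @return Named integer vector of per-feature counts.
#' @export
count_reads <- function(bam, regions, params = counting_params()) {
  features <- .as_feature_list(regions)
  if (length(features) == 0L)
    return(setNames(integer(0), character(0)))
  reads <- .read_alignments(bam, params)
  hdr_contigs <- names(scanBamHeader(BamFile(bam))$targets)
  feat_contigs <- unique(as.character(unlist(seqnames(features),
                                             use.names = FALSE)))
  unknown <- setdiff(feat_contigs, hdr_contigs)
  if (length(unknown) > 0L)
    warning("contig(s) absent from BAM header (counted as 0): ",
            paste(unknown, collapse = ", "))
  setNames(.count_overlaps(reads, features, params), names(features))
}

#' Gene-level counts over exon unions
#'
#' Counts reads over each gene's merged exon intervals; the associated
#' feature length is the exon-union length (the RPKM denominator). Reads
#' overlapping several genes count for each.
#'
#' @param bam Path to an indexed BAM file.
#' @param genes List of `GeneModel`, or an `AnnotationStore` (all genes).
#' @param params A [counting_params()] object.
#' @return List with `counts` (named integer vector) and `lengths`
#'   (named exon-union lengths in bp).
#' @export
gene_counts <- function(bam, genes, params = counting_params()) {
  if (is(genes, "AnnotationStore"))
    genes <- lapply(genes$genes$gene_id, get_gene, store = genes)
  features <- .as_feature_list(genes)
  lens <- vapply(features, function(g) sum(width(reduce(g))), 0)
  counts <- count_reads(bam, features, params)
  list(counts = counts, lengths = setNames(as.numeric(lens),
                                           names(features)))
}

#' Assemble a count matrix
#'
#' @param counts Integer matrix, features x samples.
#' @param lengths Per-feature lengths in bp (exon-union for genes, span for
#'   plain regions).
#' @param flags Optional named list of per-feature flag character vectors.
#' @return A `CountMatrix`.
#' @export
count_matrix <- function(counts, lengths, flags = NULL) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            length(lengths) == nrow(counts), all(lengths > 0),
            all(counts >= 0))
  if (is.null(names(lengths))) names(lengths) <- rownames(counts)
  if (is.null(flags))
    flags <- setNames(rep(list(character(0)), nrow(counts)),
                      rownames(counts))
  structure(list(counts = counts, lengths = lengths, flags = flags),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d feature(s) x %d sample(s)\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' Per sample, the median over features of the ratio of the sample's count
#' to the feature's geometric mean across samples; features whose geometric
#' mean is zero (any zero count) are excluded from the median. This is the
#' classical median-of-ratios normalization for sequencing depth and RNA
#' composition.
#'
#' @param counts A `CountMatrix` or a features x samples matrix.
#' @return Named positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  m <- if (is(counts, "CountMatrix")) counts$counts else as.matrix(counts)
  log_geomean <- rowMeans(log(m))
  use <- is.finite(log_geomean)
  if (!any(use))
    stop("no feature with all-positive counts; size factors need at least ",
         "one feature expressed in every sample")
  apply(m, 2, function(col)
    exp(median(log(col[use]) - log_geomean[use])))
}

#' Transform counts across expression scales
#'
#' * `raw` — counts unchanged (cast to numeric);
#' * `normalized` — count / size factor;
#' * `rpkm` — count / (length/1e3 * library_size/1e6);
#' * `log2*` — log2(x + pseudocount) of the corresponding scale.
#'
#' @param counts A `CountMatrix`.
#' @param scale One of `raw`, `normalized`, `rpkm`, `log2raw`,
#'   `log2normalized`, `log2rpkm`.
#' @param factors Per-sample size factors (required for normalized scales).
#' @param library_sizes Per-sample mapped-read totals (required for RPKM).
#' @param pseudocount Added before log2 (default 1).
#' @return An `ExpressionTable` (same shape, real-valued, with `scale`).
#' @export
transform_counts <- function(counts,
                             scale = c("raw", "normalized", "rpkm",
                                       "log2raw", "log2normalized",
                                       "log2rpkm"),
                             factors = NULL, library_sizes = NULL,
                             pseudocount = 1) {
  scale <- match.arg(scale)
  stopifnot(is(counts, "CountMatrix"))
  m <- counts$counts * 1.0
  base <- sub("^log2", "", scale)
  if (base == "" ) base <- "raw"
  if (base %in% c("normalized")) {
    if (is.null(factors))
      stop("scale '", scale, "' requires size factors")
    m <- sweep(m, 2, factors, "/")
  } else if (base == "rpkm") {
    if (is.null(library_sizes))
      stop("scale 'rpkm' requires per-sample library sizes")
    m <- m / (counts$lengths / 1e3)
    m <- sweep(m, 2, library_sizes / 1e6, "/")
  }
  if (grepl("^log2", scale)) m <- log2(m + pseudocount)
  structure(list(values = m, scale = scale, lengths = counts$lengths,
                 flags = counts$flags),
            class = "ExpressionTable")
}

#' @export
print.ExpressionTable <- function(x, ...) {
  cat(sprintf("ExpressionTable (%s): %d feature(s) x %d sample(s)\n",
              x$scale, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Attach QC flags to features
#'
#' Flags mark — but never remove — features a user may want to exclude
#' downstream:
#' * `LOW_COUNT` — maximum count across samples below `low_count`;
#' * `SHORT` — feature length below `short_bp`;
#' * `ZERO_IN_ALL` — zero in every sample.
#'
#' @param counts A `CountMatrix`.
#' @param low_count LOW_COUNT threshold (default 10).
#' @param short_bp SHORT threshold in bp (default 200).
#' @return The `CountMatrix` with its `flags` field filled.
#' @export
assign_flags <- function(counts, low_count = 10, short_bp = 200) {
  stopifnot(is(counts, "CountMatrix"))
  mx <- apply(counts$counts, 1, max)
  counts$flags <- setNames(lapply(seq_len(nrow(counts$counts)), function(i) {
    fl <- character(0)
    if (mx[i] < low_count) fl <- c(fl, "LOW_COUNT")
    if (counts$lengths[i] < short_bp) fl <- c(fl, "SHORT")
    if (mx[i] == 0) fl <- c(fl, "ZERO_IN_ALL")
    fl
  }), rownames(counts$counts))
  counts
}

#' Quantify genes and custom regions across an instance
#'
#' Orchestrates counting over every selected sample: gene-level counts over
#' exon unions, optional custom regions appended below them, size factors
#' computed from the gene-level matrix only (a handful of custom regions
#' cannot support median-of-ratios, so they are normalized with the
#' gene-derived factors without influencing them), then the requested scale
#' transform. Columns follow the instance's condition-grouped sample order.
#'
#' @param instance A `DatasetInstance` whose samples have BAM files.
#' @param store An `AnnotationStore` (gene models), or `NULL` to quantify
#'   `regions` only (no normalization support in that case).
#' @param regions Optional `GRanges` of custom regions (a `name` metadata
#'   column labels the rows).
#' @param scale Expression scale, as [transform_counts()].
#' @param params A [counting_params()] object.
#' @param pseudocount For log scales.
#' @return A list: `expr` (`ExpressionTable`), `counts` (`CountMatrix`,
#'   genes + regions), `size_factors`, `library_sizes`.
#' @export
quantify_regions <- function(instance, store, regions = NULL,
                             scale = "raw", params = counting_params(),
                             pseudocount = 1) {
  stopifnot(is(instance, "DatasetInstance"))
  report <- validate_instance(instance, require = "bam")
  if (!report$pass)
    stop("on-the-fly quantification requires BAM files for every selected ",
         "sample:\n", paste(report$messages, collapse = "\n"))
  smp <- report$samples
  smp$bam_path <- instance_samples(instance)$bam_path
  genes <- if (is.null(store)) list()
  else lapply(store$genes$gene_id, get_gene, store = store)
  gene_feats <- if (length(genes) > 0L) .as_feature_list(genes) else NULL
  region_feats <- if (!is.null(regions)) .as_feature_list(regions) else NULL
  cols <- lapply(seq_len(nrow(smp)), function(i) {
    bam <- smp$bam_path[i]
    g <- if (!is.null(gene_feats))
      count_reads(bam, gene_feats, params) else integer(0)
    r <- if (!is.null(region_feats))
      count_reads(bam, region_feats, params) else integer(0)
    c(g, r)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- smp$sample_id
  lens <- c(
    if (!is.null(gene_feats))
      vapply(gene_feats, function(g) sum(width(reduce(g))), 0) else NULL,
    if (!is.null(region_feats))
      vapply(region_feats, function(g) sum(width(g)), 0) else NULL)
  cm <- assign_flags(count_matrix(m, lens))
  n_genes <- if (is.null(gene_feats)) 0L else length(gene_feats)
  factors <- NULL
  if (grepl("normalized", scale)) {
    if (n_genes < 1L)
      stop("normalized scales need gene-level counts to derive size factors")
    factors <- size_factors(cm$counts[seq_len(n_genes), , drop = FALSE])
  }
  library_sizes <- NULL
  if (grepl("rpkm", scale))
    library_sizes <- setNames(smp$library_size, smp$sample_id)
  expr <- transform_counts(cm, scale, factors = factors,
                           library_sizes = library_sizes,
                           pseudocount = pseudocount)
  list(expr = expr, counts = cm, size_factors = factors,
       library_sizes = library_sizes, conditions = smp$condition)
}

#' Write an expression or count table as TSV
#'
#' Features in rows, samples in columns (instance order), with feature id,
#' length and flags in leading columns.
#'
#' @param x An `ExpressionTable` or `CountMatrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  m <- if (is(x, "CountMatrix")) x$counts else x$values
  flags <- vapply(x$flags[rownames(m)], paste, "", collapse = ",")
  df <- data.frame(feature_id = rownames(m),
                   length_bp = x$lengths[rownames(m)],
                   flags = flags, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read regions from a BED file or a coordinate-list file
#'
#' BED files go through the standard importer; any other text file is read
#' as one `chrom:start-end[:strand]` string per line.
#'
#' @param path Input path.
#' @return A `GRanges` with a `name` column.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("region file not found: ", path)
  if (tolower(file_ext(path)) == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    if (is.null(mcols(gr)$name) || anyNA(mcols(gr)$name))
      mcols(gr)$name <- sprintf("region_%04d", seq_along(gr))
    return(gr)
  }
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  grs <- lapply(lines, parse_region)
  out <- do.call(c, grs)
  mcols(out)$name <- lines
  out
}
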