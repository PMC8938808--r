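## Coverage extraction, binning and condition-averaged profiles.
##
## Coverage from BigWig tracks is taken as-is (tracks are assumed
## depth-normalized to a per-million scale when they were produced);
## coverage from BAM is raw read depth of primary, QC-pass, non-duplicate
## alignments, with CIGAR-aware placement: aligned (M/=/X) and deleted (D)
## bases contribute depth, skipped introns (N), insertions and clips do not.

.bam_flag_default <- function(include_duplicates = FALSE) {
  scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
              isSupplementaryAlignment = FALSE,
              isDuplicate = if (include_duplicates) NA else FALSE,
              isNotPassingQualityControls = FALSE)
}

#' Extract per-base coverage over a region
#'
#' @param sample One row of a manifest sample table (see
#'   [instance_samples()]), or a list with `sample_id` and `bam_path` /
#'   `bigwig_path` entries.
#' @param region Length-1 `GRanges`.
#' @param source `"bigwig"` or `"bam"`.
#' @return A `CoverageVector`: `region`, per-base `values` (length equal to
#'   the region width), and `scale` (`"per_million"` for BigWig,
#'   `"raw"` for BAM).
#' @export
extract_coverage <- function(sample, region, source = c("bigwig", "bam")) {
  source <- match.arg(source)
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  chrom <- as.character(seqnames(region))
  if (source == "bigwig") {
    path <- sample$bigwig_path
    if (is.null(path) || is.na(path) || !file.exists(path))
      stop("sample '", sample$sample_id, "': BigWig file not available")
    bwf <- BigWigFile(path)
    if (!(chrom %in% seqlevels(seqinfo(bwf))))
      stop("contig '", chrom, "' absent from BigWig header of '", path, "'")
    q <- GRanges(chrom, ranges(region))   # unstranded query
    vals <- tryCatch(
      as.numeric(import.bw(bwf, which = q, as = "NumericList")[[1]]),
      error = function(e) stop("failed to read BigWig '", path, "': ",
                               conditionMessage(e)))
    vals[is.na(vals)] <- 0            # absent intervals count as zero signal
    scale <- "per_million"
  } else {
    path <- sample$bam_path
    if (is.null(path) || is.na(path) || !file.exists(path))
      stop("sample '", sample$sample_id, "': BAM file not available")
    bf <- BamFile(path)
    hdr <- scanBamHeader(bf)$targets
    if (!(chrom %in% names(hdr)))
      stop("contig '", chrom, "' absent from BAM header of '", path, "'")
    q <- GRanges(chrom, ranges(region))
    ga <- readGAlignments(bf, param = ScanBamParam(
      flag = .bam_flag_default(), which = q))
    cov <- coverage(ga)[[chrom]]
    vals <- .rle_window(cov, start(region), end(region), hdr[[chrom]])
    scale <- "raw"
  }
  structure(list(region = region, values = vals, scale = scale,
                 sample_id = sample$sample_id),
            class = "CoverageVector")
}

## window [from, to] out of a coverage Rle, zero-padded past the Rle end
.rle_window <- function(rle, from, to, contig_length) {
  if (to > contig_length)
    stop("region extends past contig end (", contig_length, " bp)")
  n <- length(rle)
  upto <- min(to, n)
  vals <- if (from > n) numeric(0) else as.numeric(rle[from:upto])
  c(vals, numeric(to - max(from - 1, upto)))
}

#' Bin a coverage vector into a fixed-length profile
#'
#' The region is split into `n_bins` contiguous, near-equal base spans
#' (when the width is not divisible, the leftover bases widen the leftmost
#' bins by one) and each bin takes the mean of its member bases. For a
#' minus-strand region with `oriented = TRUE`, the bin vector is reversed so
#' index 1 is the 5' end — profiles of genes on either strand line up.
#'
#' @param cov A `CoverageVector`.
#' @param n_bins Number of bins (at most the region width).
#' @param oriented Reverse minus-strand profiles to 5'->3' order?
#' @return A `BinnedProfile`.
#' @export
bin_profile <- function(cov, n_bins, oriented = TRUE) {
  stopifnot(is(cov, "CoverageVector"), n_bins >= 1L)
  L <- length(cov$values)
  if (n_bins > L)
    stop("n_bins (", n_bins, ") exceeds region width (", L, ")")
  base_w <- L %/% n_bins
  extra <- L %% n_bins
  widths <- rep(base_w, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bin_of <- rep.int(seq_len(n_bins), widths)
  values <- as.numeric(tapply(cov$values, bin_of, mean))
  is_minus <- as.character(strand(cov$region)) == "-"
  if (oriented && is_minus) values <- rev(values)
  structure(list(sample_id = cov$sample_id, region = cov$region,
                 n_bins = as.integer(n_bins), values = values,
                 oriented = oriented && is_minus, scale = cov$scale),
            class = "BinnedProfile")
}

## fixed-width binning for browser-style windows; last bin may be short
.bin_fixed_width <- function(values, bin_width) {
  L <- length(values)
  n_bins <- ceiling(L / bin_width)
  bin_of <- rep.int(seq_len(n_bins),
                    c(rep(bin_width, n_bins - 1L),
                      L - bin_width * (n_bins - 1L)))
  as.numeric(tapply(values, bin_of, mean))
}

#' Condition-averaged coverage profiles
#'
#' Extracts coverage for every selected sample, bins it, and averages the
#' binned profiles within each biological condition, in the condition order
#' of the instance. With `source = "bam"` each sample's raw depth is scaled
#' to per-million using its library size before averaging, so conditions
#' sequenced at different depths remain comparable; BigWig tracks are taken
#' as already normalized. The dispersion band is the per-bin across-sample
#' SD (default) or SE; it is all-zero for single-sample conditions.
#'
#' @param instance A `DatasetInstance`.
#' @param region Length-1 `GRanges`.
#' @param n_bins Number of bins (default 200, capped at the region width).
#' @param source `"bigwig"` or `"bam"`.
#' @param band `"sd"` or `"se"`.
#' @param oriented Orient profiles 5'->3' on the minus strand?
#' @return A list of `ConditionProfile` objects, one per condition.
#' @export
average_by_condition <- function(instance, region, n_bins = 200L,
                                 source = c("bigwig", "bam"),
                                 band = c("sd", "se"), oriented = TRUE) {
  source <- match.arg(source)
  band <- match.arg(band)
  stopifnot(is(instance, "DatasetInstance"))
  n_bins <- min(n_bins, width(region))
  smp <- instance_samples(instance)
  lapply(names(instance$selection), function(cond) {
    rows <- which(smp$condition == cond)
    profs <- lapply(rows, function(i) {
      s <- as.list(smp[i, ])
      cov <- tryCatch(extract_coverage(s, region, source),
                      error = function(e) stop("sample '", s$sample_id,
                                               "': ", conditionMessage(e)))
      if (source == "bam") {
        libsize <- s$library_size
        if (is.na(libsize)) libsize <- bam_library_size(s$bam_path)
        cov$values <- cov$values * 1e6 / libsize
        cov$scale <- "per_million"
      }
      bin_profile(cov, n_bins, oriented = oriented)
    })
    mat <- do.call(rbind, lapply(profs, `[[`, "values"))
    n <- nrow(mat)
    mu <- colMeans(mat)
    disp <- if (n == 1L) numeric(ncol(mat)) else apply(mat, 2, sd)
    if (band == "se" && n > 1L) disp <- disp / sqrt(n)
    structure(list(condition = cond, n = n, mean = mu, band = disp,
                   band_type = band, region = region, n_bins = n_bins,
                   per_sample = profs),
              class = "ConditionProfile")
  })
}

#' @export
print.ConditionProfile <- function(x, ...) {
  cat(sprintf(
    "ConditionProfile '%s' (%d sample(s), %d bins over %s); mean %.3g\n",
    x$condition, x$n, x$n_bins, region_string(x$region), mean(x$mean)))
  invisible(x)
}

#' Browser-style neighborhood profile with gene glyphs
#'
#' Computes unoriented condition-averaged profiles over a genomic window at
#' a fixed bin width (the last bin may be short), plus a glyph table of the
#' genes overlapping the window with their exon sub-intervals — the data
#' behind a track-style plot of a genomic neighborhood.
#'
#' @param instance A `DatasetInstance`.
#' @param window Length-1 `GRanges` (width at least `bin_width`).
#' @param bin_width Bin width in bp.
#' @param store An `AnnotationStore` supplying the gene glyphs.
#' @param source `"bigwig"` or `"bam"`.
#' @return A list with `profiles` (as [average_by_condition()]) and
#'   `glyphs` (data.frame: gene_id, symbol, strand, gene/exon coordinates).
#' @export
neighborhood_profile <- function(instance, window, bin_width, store,
                                 source = c("bigwig", "bam")) {
  source <- match.arg(source)
  stopifnot(is(store, "AnnotationStore"), width(window) >= bin_width)
  smp <- instance_samples(instance)
  profiles <- lapply(names(instance$selection), function(cond) {
    rows <- which(smp$condition == cond)
    mat <- do.call(rbind, lapply(rows, function(i) {
      s <- as.list(smp[i, ])
      cov <- extract_coverage(s, window, source)
      if (source == "bam") {
        libsize <- s$library_size
        if (is.na(libsize)) libsize <- bam_library_size(s$bam_path)
        cov$values <- cov$values * 1e6 / libsize
      }
      .bin_fixed_width(cov$values, bin_width)
    }))
    n <- nrow(mat)
    disp <- if (n == 1L) numeric(ncol(mat)) else apply(mat, 2, sd)
    structure(list(condition = cond, n = n, mean = colMeans(mat),
                   band = disp, band_type = "sd", region = window,
                   n_bins = ncol(mat), per_sample = NULL),
              class = "ConditionProfile")
  })
  g <- store$genes
  spans <- GRanges(g$chrom, IRanges(g$start, g$end))
  hits <- queryHits(findOverlaps(spans, window, ignore.strand = TRUE))
  glyphs <- do.call(rbind, lapply(hits, function(i) {
    ex <- store$exons[[g$gene_id[i]]]
    data.frame(gene_id = g$gene_id[i], symbol = g$symbol[i],
               strand = g$strand[i], gene_start = g$start[i],
               gene_end = g$end[i], exon_start = start(ex),
               exon_end = end(ex), stringsAsFactors = FALSE)
  }))
  if (is.null(glyphs))
    glyphs <- data.frame(gene_id = character(0), symbol = character(0),
                         strand = character(0), gene_start = integer(0),
                         gene_end = integer(0), exon_start = integer(0),
                         exon_end = integer(0))
  list(profiles = profiles, glyphs = glyphs)
}

#' Export condition profiles as TSV
#'
#' One row per bin: bin index, then per condition its mean and dispersion
#' band half-width.
#'
#' @param profiles List of `ConditionProfile` (one region).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profiles, path) {
  stopifnot(length(profiles) >= 1L)
  out <- data.frame(bin = seq_along(profiles[[1]]$mean))
  for (p in profiles) {
    out[[paste0(p$condition, "_mean")]] <- p$mean
    out[[paste0(p$condition, "_band")]] <- p$band
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an averaged unbinned track as bedGraph
#'
#' Writes the across-sample mean per-base coverage of one condition over a
#' region in bedGraph format (0-based half-open intervals, as the format
#' requires), suitable for loading into any genome browser.
#'
#' @param instance A `DatasetInstance`.
#' @param condition Condition name within the instance.
#' @param region Length-1 `GRanges`.
#' @param path Output bedGraph path.
#' @param source `"bigwig"` or `"bam"`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(instance, condition, region, path,
                           source = c("bigwig", "bam")) {
  source <- match.arg(source)
  smp <- instance_samples(instance)
  rows <- which(smp$condition == condition)
  if (length(rows) == 0L) stop("unknown condition: '", condition, "'")
  mat <- do.call(rbind, lapply(rows, function(i) {
    s <- as.list(smp[i, ])
    cov <- extract_coverage(s, region, source)
    if (source == "bam") {
      libsize <- s$library_size
      if (is.na(libsize)) libsize <- bam_library_size(s$bam_path)
      cov$values <- cov$values * 1e6 / libsize
    }
    cov$values
  }))
  mu <- colMeans(mat)
  r <- Rle(mu)
  ends <- cumsum(runLength(r))
  starts <- c(0L, head(ends, -1L))
  df <- data.frame(chrom = as.character(seqnames(region)),
                   start = start(region) - 1L + starts,
                   end = start(region) - 1L + ends,
                   value = runValue(r))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s mean\"", condition), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
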