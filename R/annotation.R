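## Gene annotation import, query resolution and interval arithmetic.
## All regions are GRanges (1-based, closed intervals, the Bioconductor
## convention); user-facing coordinate strings ("chr1:100-200") are 1-based
## inclusive, the genome-browser convention, so they map onto GRanges
## verbatim. Lengths are therefore end - start + 1 everywhere.

#' Parse a genomic coordinate string into a region
#'
#' Accepts `"chrom:start-end"` or `"chrom:start-end:strand"` with 1-based
#' inclusive coordinates (browser convention). Commas in numbers are
#' tolerated.
#'
#' @param text A single coordinate string.
#' @return A length-1 [GenomicRanges::GRanges].
#' @examples
#' parse_region("chr1:100-200")
#' parse_region("chr2:5,000-6,000:-")
#' @export
parse_region <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec(
    "^([^:[:space:]]+):([0-9,]+)-([0-9,]+)(?::([+.-]))?$", text))[[1]]
  if (length(m) == 0L)
    stop("malformed coordinate string: '", text,
         "' (expected chrom:start-end[:strand])")
  start <- as.numeric(gsub(",", "", m[3]))
  end <- as.numeric(gsub(",", "", m[4]))
  if (start < 1 || start > end)
    stop("malformed coordinate string: '", text,
         "' (need 1 <= start <= end)")
  strand <- if (m[5] == "") "." else m[5]
  GRanges(m[2], IRanges(start, end), strand = if (strand == ".") "*" else strand)
}

#' Format a region as a coordinate string
#'
#' Inverse of [parse_region()]: 1-based inclusive, strand appended only when
#' the region is stranded.
#'
#' @param region A length-1 `GRanges`.
#' @return A character scalar such as `"chr1:100-200"`.
#' @export
region_string <- function(region) {
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  s <- as.character(strand(region))
  base <- sprintf("%s:%d-%d", as.character(seqnames(region)),
                  start(region), end(region))
  if (s %in% c("+", "-")) paste0(base, ":", s) else base
}

#' Construct a gene model
#'
#' A gene model is the unit of gene-level quantification: a genomic span plus
#' the (possibly overlapping) exons of all its transcripts, on one strand of
#' one chromosome.
#'
#' @param gene_id,symbol Identifiers; `symbol` defaults to `gene_id`.
#' @param region Length-1 `GRanges`, the gene span.
#' @param exons `GRanges` of exons, same chromosome and strand as `region`.
#' @param biotype Optional biotype string.
#' @return An object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, region, exons, symbol = gene_id,
                       biotype = NA_character_) {
  stopifnot(is(region, "GRanges"), length(region) == 1L,
            is(exons, "GRanges"), length(exons) >= 1L)
  if (!all(as.character(seqnames(exons)) == as.character(seqnames(region))))
    stop("gene ", gene_id, ": exons on a different chromosome than the gene")
  out_of_bounds <- start(exons) < start(region) | end(exons) > end(region)
  if (any(out_of_bounds)) {
    warning("gene ", gene_id, ": ", sum(out_of_bounds),
            " exon(s) outside gene bounds were clamped")
    start(exons) <- pmax(start(exons), start(region))
    end(exons) <- pmin(end(exons), end(region))
  }
  structure(list(gene_id = gene_id, symbol = symbol, region = region,
                 exons = exons, biotype = biotype),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s) %s, %d exon(s), union length %d bp\n",
              x$gene_id, x$symbol, region_string(x$region),
              length(x$exons), exon_union(x)$union_length))
  invisible(x)
}

#' Import gene annotation from GTF or BED
#'
#' GTF files (Ensembl dialect) contribute `gene` and `exon` features; a gene's
#' exon set is the pool of all its transcripts' exons. BED12 rows become
#' single genes with block-defined exons; BED6 (or fewer columns) rows become
#' single-exon genes. Exons falling outside their gene's recorded bounds are
#' clamped with a warning.
#'
#' @param path Path to a `.gtf` / `.gff` or `.bed` file.
#' @param format Override format detection (`"gtf"` or `"bed"`).
#' @return An `AnnotationStore`: gene lookup by id and symbol plus per-gene
#'   exon structure.
#' @export
import_annotation <- function(path, format = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(file_ext(path))
    format <- if (ext %in% c("bed", "bed6", "bed12")) "bed" else "gtf"
  }
  if (format == "gtf") .store_from_gtf(path) else .store_from_bed(path)
}

.store_from_gtf <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("failed to parse GTF '", path, "': ",
                             conditionMessage(e)))
  if (!("type" %in% names(mcols(gr))) || !("gene_id" %in% names(mcols(gr))))
    stop("GTF '", path, "' lacks type/gene_id attributes")
  exons <- gr[gr$type == "exon"]
  if (length(exons) == 0L) stop("GTF '", path, "' contains no exon features")
  genes <- gr[gr$type == "gene"]
  exons_by_gene <- split(granges(exons), exons$gene_id)
  gene_ids <- names(exons_by_gene)
  if (length(genes) > 0L) {
    gene_rows <- genes[match(gene_ids, genes$gene_id)]
    spans <- granges(gene_rows)
    symbols <- .first_non_na(gene_rows$gene_name, gene_ids)
    biotypes <- if ("gene_biotype" %in% names(mcols(gene_rows)))
      gene_rows$gene_biotype else rep(NA_character_, length(gene_ids))
  } else {
    spans <- unlist(range(exons_by_gene))
    sym_by_gene <- if ("gene_name" %in% names(mcols(exons)))
      vapply(split(exons$gene_name, exons$gene_id), function(x) x[1], "")
    else setNames(gene_ids, gene_ids)
    symbols <- .first_non_na(sym_by_gene[gene_ids], gene_ids)
    biotypes <- rep(NA_character_, length(gene_ids))
  }
  .build_store(gene_ids, symbols, spans, exons_by_gene, biotypes,
               seqlengths(gr))
}

.store_from_bed <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop("failed to parse BED '", path, "': ",
                             conditionMessage(e)))
  if (length(gr) == 0L) stop("BED '", path, "' is empty")
  ids <- if (!is.null(gr$name) && !anyNA(gr$name)) gr$name
  else sprintf("region_%04d", seq_along(gr))
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "_")
  exons_by_gene <- if ("blocks" %in% names(mcols(gr))) {
    bl <- rtracklayer::blocks(gr)          # BED12: block-defined exons
    names(bl) <- ids
    bl
  } else {
    g <- granges(gr)
    setNames(split(g, seq_along(g)), ids)  # BED6: single-exon genes
  }
  .build_store(ids, ids, granges(gr), exons_by_gene[ids],
               rep(NA_character_, length(ids)), seqlengths(gr))
}

.first_non_na <- function(x, fallback) {
  x <- as.character(x)
  ifelse(is.na(x) | x == "", fallback, x)
}

.build_store <- function(gene_ids, symbols, spans, exons_by_gene, biotypes,
                         contig_lengths) {
  names(spans) <- NULL
  clamped <- 0L
  for (i in seq_along(gene_ids)) {
    ex <- exons_by_gene[[gene_ids[i]]]
    bad <- start(ex) < start(spans[i]) | end(ex) > end(spans[i])
    if (any(bad)) {
      clamped <- clamped + sum(bad)
      start(ex) <- pmax(start(ex), start(spans[i]))
      end(ex) <- pmin(end(ex), end(spans[i]))
      exons_by_gene[[gene_ids[i]]] <- ex
    }
  }
  if (clamped > 0L)
    warning(clamped, " exon(s) outside gene bounds were clamped")
  genes <- data.frame(
    gene_id = gene_ids,
    symbol = as.character(symbols),
    chrom = as.character(seqnames(spans)),
    start = start(spans),
    end = end(spans),
    strand = as.character(strand(spans)),
    biotype = biotypes,
    stringsAsFactors = FALSE)
  structure(list(genes = genes,
                 exons = GRangesList(exons_by_gene),
                 contig_lengths = contig_lengths),
            class = "AnnotationStore")
}

#' @export
print.AnnotationStore <- function(x, ...) {
  cat(sprintf("AnnotationStore: %d gene(s) on %d contig(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Fetch one gene model from an annotation store
#'
#' @param store An `AnnotationStore`.
#' @param gene_id Gene identifier present in the store.
#' @return A [gene_model()].
#' @export
get_gene <- function(store, gene_id) {
  stopifnot(is(store, "AnnotationStore"))
  i <- match(gene_id, store$genes$gene_id)
  if (is.na(i)) stop("gene not found in annotation: '", gene_id, "'")
  g <- store$genes[i, ]
  region <- GRanges(g$chrom, IRanges(g$start, g$end), strand = g$strand)
  ex <- store$exons[[gene_id]]
  strand(ex) <- g$strand
  gene_model(g$gene_id, region, ex, symbol = g$symbol, biotype = g$biotype)
}

#' Resolve a free-text query to genomic regions
#'
#' A query is either a coordinate string (`"chrom:start-end[:strand]"`,
#' 1-based inclusive), a gene id, or a gene symbol. Symbols shared by several
#' genes return one region per gene; results are position-sorted so lookup is
#' deterministic.
#'
#' @param store An `AnnotationStore`.
#' @param query Query string.
#' @return A `GRanges` (one row per match) with `name` metadata.
#' @export
resolve_query <- function(store, query) {
  stopifnot(is(store, "AnnotationStore"), is.character(query),
            length(query) == 1L)
  if (grepl("^[^:[:space:]]+:[0-9,]+-[0-9,]+(:[+.-])?$", query)) {
    r <- parse_region(query)
    mcols(r)$name <- query
    return(r)
  }
  g <- store$genes
  hits <- which(g$gene_id == query)
  if (length(hits) == 0L) hits <- which(g$symbol == query)
  if (length(hits) == 0L)
    stop("query '", query, "' matches no gene id, symbol or coordinate")
  hits <- hits[order(g$chrom[hits], g$start[hits], g$end[hits])]
  out <- GRanges(g$chrom[hits], IRanges(g$start[hits], g$end[hits]),
                 strand = g$strand[hits])
  mcols(out)$name <- g$gene_id[hits]
  out
}

#' Exon union of a gene model
#'
#' Merges a gene's exons (pooled across transcripts) into disjoint, sorted
#' intervals. Their total length is the gene length used for RPKM.
#'
#' @param gene A `GeneModel`, or a `GRanges` of exon intervals.
#' @return A list with `exons` (disjoint, sorted `GRanges`) and
#'   `union_length` (total bp).
#' @export
exon_union <- function(gene) {
  ex <- if (is(gene, "GeneModel")) gene$exons else gene
  stopifnot(is(ex, "GRanges"), length(ex) >= 1L)
  merged <- reduce(sort(granges(ex)), ignore.strand = FALSE)
  list(exons = merged, union_length = sum(width(merged)))
}

#' Strand-aware flanking / anchoring of a region
#'
#' With `anchor = "body"` the region is extended `upstream` bp beyond its
#' 5' end and `downstream` bp beyond its 3' end (strand-aware: for a minus
#' strand gene the 5' end is the right edge). With `anchor = "tss"` the
#' result is a window of length `upstream + downstream` around the
#' strand-aware transcription start site, covering `upstream` bp before and
#' `downstream` bp after it. Windows are clamped at contig edges (when
#' contig lengths are known) with a warning.
#'
#' @param region Length-1 `GRanges`; must be stranded for `anchor = "tss"`.
#' @param upstream,downstream Non-negative extensions in bp.
#' @param anchor `"body"` or `"tss"`.
#' @param contig_lengths Optional named vector of contig lengths for clamping.
#' @return A length-1 `GRanges`.
#' @export
flank_region <- function(region, upstream, downstream,
                         anchor = c("body", "tss"), contig_lengths = NULL) {
  anchor <- match.arg(anchor)
  stopifnot(is(region, "GRanges"), length(region) == 1L,
            upstream >= 0, downstream >= 0)
  s <- as.character(strand(region))
  if (anchor == "tss") {
    if (!(s %in% c("+", "-")))
      stop("anchor = 'tss' requires a stranded region")
    if (upstream + downstream < 1)
      stop("tss window requires upstream + downstream >= 1")
    if (s == "+") {
      tss <- start(region)
      new_start <- tss - upstream
      new_end <- tss + downstream - 1
    } else {
      tss <- end(region)
      new_start <- tss - downstream + 1
      new_end <- tss + upstream
    }
  } else {
    if (s == "-") {
      new_start <- start(region) - downstream
      new_end <- end(region) + upstream
    } else {
      new_start <- start(region) - upstream
      new_end <- end(region) + downstream
    }
  }
  chrom <- as.character(seqnames(region))
  limit <- if (!is.null(contig_lengths) && chrom %in% names(contig_lengths))
    contig_lengths[[chrom]] else NA_integer_
  if (new_start < 1 || (!is.na(limit) && new_end > limit)) {
    warning("flank of ", region_string(region), " clamped at contig edge")
    new_start <- max(new_start, 1)
    if (!is.na(limit)) new_end <- min(new_end, limit)
  }
  GRanges(chrom, IRanges(new_start, new_end), strand = s)
}
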