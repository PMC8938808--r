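## Deterministic synthetic-dataset generator.
##
## Produces a complete miniature RNA-Seq dataset — genome sizes, GTF gene
## models on both strands of several contigs, per-sample coordinate-sorted
## and indexed BAM files, per-million-scaled BigWig tracks, a manifest, and
## truth tables — entirely from a seeded configuration, so that per-region
## counts and coverage are exactly recoverable and every other module can
## be tested offline. Reads are single-end, fully exonic and unspliced
## (CIGAR <read_length>M); placement is uniform over each gene's exons.
## Intronic and intergenic noise reads are added so that exon-union
## counting is genuinely exercised, without touching the per-gene truth.

#' Simulation configuration
#'
#' Defaults describe a small but non-trivial study: two conditions with
#' three replicates each, 10% of genes differentially expressed at
#' |log2FC| = 2 over a negative-binomial baseline (mean 100, dispersion
#' 0.1) — the design used throughout the package's own calibration and
#' recovery checks.
#'
#' @param n_contigs,contig_length Genome shape.
#' @param n_genes Number of genes (laid out without overlap).
#' @param exons_per_gene Inclusive range of exon counts per gene.
#' @param conditions Named integer vector: condition -> replicate count.
#' @param baseline_mean Baseline NB mean expression per gene.
#' @param nb_dispersion NB dispersion phi (> 0); var = mu + phi mu^2.
#' @param de_fraction Fraction of genes differentially expressed.
#' @param de_log2fc Absolute log2 fold change of DE genes (sign random).
#' @param read_length Read length in bp.
#' @param noise_reads Per-sample intronic/intergenic noise reads.
#' @param seed Integer seed; every derived artifact is a pure function of
#'   the configuration.
#' @return A validated `SimConfig`.
#' @export
sim_config <- function(n_contigs = 2L, contig_length = 100000L,
                       n_genes = 40L, exons_per_gene = c(1L, 4L),
                       conditions = c(control = 3L, treated = 3L),
                       baseline_mean = 100, nb_dispersion = 0.1,
                       de_fraction = 0.1, de_log2fc = 2,
                       read_length = 50L, noise_reads = 60L, seed = 42L) {
  stopifnot(n_contigs >= 1L, contig_length > 0L, n_genes >= 1L,
            length(exons_per_gene) == 2L, exons_per_gene[1L] >= 1L,
            exons_per_gene[2L] >= exons_per_gene[1L],
            baseline_mean > 0, nb_dispersion > 0,
            de_fraction >= 0, de_fraction <= 1, de_log2fc >= 0,
            read_length >= 1L, noise_reads >= 0L)
  if (length(conditions) < 1L || is.null(names(conditions)) ||
      any(!nzchar(names(conditions))))
    stop("conditions must be a named vector (condition -> replicates)")
  if (any(conditions < 1L))
    stop("every condition needs at least one replicate; got ",
         paste0(names(conditions), "=", conditions, collapse = ", "))
  structure(list(n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 conditions = conditions,
                 baseline_mean = baseline_mean,
                 nb_dispersion = nb_dispersion,
                 de_fraction = de_fraction,
                 de_log2fc = de_log2fc,
                 read_length = as.integer(read_length),
                 noise_reads = as.integer(noise_reads),
                 seed = as.integer(seed)),
            class = "SimConfig")
}

.sim_sample_ids <- function(config) {
  unlist(lapply(names(config$conditions), function(cond)
    paste0(cond, "_", seq_len(config$conditions[[cond]]))),
    use.names = FALSE)
}

.sim_conditions_of_samples <- function(config) {
  rep(names(config$conditions), config$conditions)
}

## counts + DE truth; assumes the RNG is already seeded
.sim_counts_impl <- function(config) {
  gene_ids <- sprintf("g%03d", seq_len(config$n_genes))
  n_de <- round(config$de_fraction * config$n_genes)
  de_idx <- if (n_de > 0) sort(sample.int(config$n_genes, n_de)) else integer(0)
  lfc <- numeric(config$n_genes)
  if (n_de > 0)
    lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) * config$de_log2fc
  sample_ids <- .sim_sample_ids(config)
  cond_of <- .sim_conditions_of_samples(config)
  reference <- names(config$conditions)[1L]
  counts <- sapply(seq_along(sample_ids), function(j) {
    shifted <- cond_of[j] != reference
    mu <- config$baseline_mean * 2^(lfc * as.numeric(shifted))
    rnbinom(config$n_genes, mu = mu, size = 1 / config$nb_dispersion)
  })
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_ids, sample_ids)
  truth <- data.frame(gene_id = gene_ids,
                      is_de = seq_len(config$n_genes) %in% de_idx,
                      true_log2fc = lfc, stringsAsFactors = FALSE)
  list(counts = counts, de = truth)
}

#' Simulate a negative-binomial count matrix with known DE genes
#'
#' Per gene and condition the mean is `baseline * 2^(lfc * treated)` where
#' `lfc` is zero for non-DE genes and `±de_log2fc` (random sign) for the DE
#' subset, and `treated` marks every non-reference condition (the first
#' named condition is the reference). Counts are drawn NB(mean, dispersion
#' phi). Bit-for-bit reproducible per seed.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (genes x samples integer matrix) and `de`
#'   (truth data.frame: gene_id, is_de, true_log2fc).
#' @export
simulate_counts <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config$seed)
  .sim_counts_impl(config)
}

## non-overlapping gene models laid out round-robin over the contigs;
## every exon and intron is wider than the read length so reads fit
.sim_layout_impl <- function(config) {
  contigs <- sprintf("chrS%d", seq_len(config$n_contigs))
  cursor <- setNames(rep(1000L, config$n_contigs), contigs)
  rl <- config$read_length
  genes <- vector("list", config$n_genes)
  exons <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    chrom <- contigs[((i - 1L) %% config$n_contigs) + 1L]
    n_ex <- sample(seq(config$exons_per_gene[1L],
                       config$exons_per_gene[2L]), 1L)
    ex_w <- sample(seq(rl + 50L, rl + 350L), n_ex, replace = TRUE)
    in_w <- if (n_ex > 1L)
      sample(seq(rl + 20L, rl + 250L), n_ex - 1L, replace = TRUE)
    else integer(0)
    span <- sum(ex_w) + sum(in_w)
    if (cursor[chrom] + span + 1000L > config$contig_length)
      stop("genome too small for the requested gene layout; increase ",
           "contig_length or reduce n_genes")
    starts <- cursor[chrom] + cumsum(c(0L, head(ex_w, -1L) + in_w))
    strand <- if (i %% 2L == 0L) "-" else "+"
    exons[[i]] <- GRanges(chrom, IRanges(starts, width = ex_w),
                          strand = strand)
    genes[[i]] <- data.frame(
      gene_id = sprintf("g%03d", i),
      symbol = sprintf("GENE%d", i),
      chrom = chrom, start = as.integer(cursor[chrom]),
      end = as.integer(cursor[chrom] + span - 1L), strand = strand,
      stringsAsFactors = FALSE)
    cursor[chrom] <- cursor[chrom] + span + sample(500:1500, 1L)
  }
  genes <- do.call(rbind, genes)
  names(exons) <- genes$gene_id
  list(genes = genes, exons = exons, contigs = contigs)
}

.write_gtf <- function(layout, path) {
  lines <- character(0)
  for (i in seq_len(nrow(layout$genes))) {
    g <- layout$genes[i, ]
    attr_g <- sprintf(
      'gene_id "%s"; gene_name "%s"; gene_biotype "protein_coding";',
      g$gene_id, g$symbol)
    lines <- c(lines, paste(g$chrom, "toysim", "gene", g$start, g$end, ".",
                            g$strand, ".", attr_g, sep = "\t"))
    ex <- layout$exons[[g$gene_id]]
    for (j in seq_along(ex)) {
      attr_e <- sprintf(
        'gene_id "%s"; transcript_id "%s.t1"; gene_name "%s"; exon_number "%d";',
        g$gene_id, g$gene_id, g$symbol, j)
      lines <- c(lines, paste(g$chrom, "toysim", "exon", start(ex)[j],
                              end(ex)[j], ".", g$strand, ".", attr_e,
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
}

## uniform fully-exonic read starts for one gene; returns GRanges of reads
.place_gene_reads <- function(exons, k, read_length, strand) {
  if (k == 0L) return(GRanges())
  valid <- width(exons) - read_length + 1L
  stopifnot(all(valid >= 1L))
  ex_idx <- sample.int(length(exons), k, replace = TRUE,
                       prob = valid / sum(valid))
  offs <- vapply(ex_idx, function(e) sample.int(valid[e], 1L), 1L)
  GRanges(as.character(seqnames(exons))[1L],
          IRanges(start(exons)[ex_idx] + offs - 1L, width = read_length),
          strand = strand)
}

.write_sam_bam <- function(reads_gr, qnames, contig_lengths, dest_prefix) {
  sam_path <- paste0(dest_prefix, ".sam")
  con <- file(sam_path, "w")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                       contig_lengths)), con)
  if (length(reads_gr) > 0L) {
    rl <- width(reads_gr)[1L]
    flag <- ifelse(as.character(strand(reads_gr)) == "-", 16L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                       qnames, flag, as.character(seqnames(reads_gr)),
                       start(reads_gr), rl, strrep("A", rl)), con)
  }
  close(con)
  bam <- suppressMessages(
    asBam(sam_path, dest_prefix, overwrite = TRUE, indexDestination = TRUE))
  unlink(sam_path)
  bam
}

#' Write a complete toy dataset to disk
#'
#' Emits `chrom.sizes`, a GTF of the simulated gene models, one
#' coordinate-sorted indexed BAM and one per-million-scaled BigWig per
#' sample, a YAML manifest, and truth tables. By construction,
#' [gene_counts()] on the emitted BAM files reproduces the truth count
#' matrix exactly, and BigWig coverage equals the per-million scaling of
#' BAM depth at every base.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return List: `manifest_path`, `annotation_path`, `dir`, `config`, and
#'   `truth` (`counts` matrix, `de` table, `library_sizes`, per-sample
#'   `reads` placement tables).
#' @export
make_toy_dataset <- function(config, out_dir) {
  stopifnot(is(config, "SimConfig"))
  if (any(config$conditions < 1L))     # re-checked so no file is written
    stop("every condition needs at least one replicate")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  sim <- .sim_counts_impl(config)
  layout <- .sim_layout_impl(config)
  contig_lengths <- setNames(rep(config$contig_length, config$n_contigs),
                             layout$contigs)
  writeLines(sprintf("%s\t%d", names(contig_lengths), contig_lengths),
             file.path(out_dir, "chrom.sizes"))
  gtf_path <- file.path(out_dir, "genes.gtf")
  .write_gtf(layout, gtf_path)

  sample_ids <- colnames(sim$counts)
  cond_of <- .sim_conditions_of_samples(config)
  rl <- config$read_length
  multi_exon <- which(vapply(layout$exons, length, 1L) > 1L)
  gene_spans <- GRanges(layout$genes$chrom,
                        IRanges(layout$genes$start, layout$genes$end))
  intergenic <- GenomicRanges::gaps(gene_spans,
                                    end = contig_lengths[
                                      seqlevels(gene_spans)])
  intergenic <- intergenic[strand(intergenic) == "*" &
                             width(intergenic) >= rl + 2L]
  library_sizes <- integer(0)
  reads_truth <- list()
  for (j in seq_along(sample_ids)) {
    smp <- sample_ids[j]
    per_gene <- lapply(seq_len(config$n_genes), function(i) {
      g <- layout$genes[i, ]
      .place_gene_reads(layout$exons[[g$gene_id]], sim$counts[i, j], rl,
                        g$strand)
    })
    gene_of <- rep(layout$genes$gene_id,
                   vapply(per_gene, length, 1L))
    reads <- suppressWarnings(do.call(c, per_gene))
    placement <- rep("exonic", length(reads))
    if (config$noise_reads > 0L) {
      n_intr <- config$noise_reads %/% 2L
      n_inter <- config$noise_reads - n_intr
      if (length(multi_exon) > 0L && n_intr > 0L) {
        intr <- suppressWarnings(do.call(c, lapply(seq_len(n_intr), function(x) {
          gi <- multi_exon[sample.int(length(multi_exon), 1L)]
          ex <- sort(layout$exons[[gi]])
          introns <- GRanges(as.character(seqnames(ex))[1L],
                             IRanges(end(ex)[-length(ex)] + 1L,
                                     start(ex)[-1L] - 1L))
          introns <- introns[width(introns) >= rl]
          pick <- introns[sample.int(length(introns), 1L)]
          GRanges(seqnames(pick),
                  IRanges(start(pick) +
                            sample.int(width(pick) - rl + 1L, 1L) - 1L,
                          width = rl), strand = "+")
        })))
        reads <- suppressWarnings(c(reads, intr))
        gene_of <- c(gene_of, rep(NA_character_, length(intr)))
        placement <- c(placement, rep("intronic", length(intr)))
      }
      if (length(intergenic) > 0L && n_inter > 0L) {
        inter <- suppressWarnings(do.call(c, lapply(seq_len(n_inter), function(x) {
          pick <- intergenic[sample.int(length(intergenic), 1L)]
          GRanges(seqnames(pick),
                  IRanges(start(pick) +
                            sample.int(width(pick) - rl + 1L, 1L) - 1L,
                          width = rl), strand = "+")
        })))
        reads <- suppressWarnings(c(reads, inter))
        gene_of <- c(gene_of, rep(NA_character_, length(inter)))
        placement <- c(placement, rep("intergenic", length(inter)))
      }
    }
    qnames <- sprintf("%s_r%06d", smp, seq_along(reads))
    seqlevels(reads) <- layout$contigs
    seqlengths(reads) <- contig_lengths
    .write_sam_bam(reads, qnames, contig_lengths,
                   file.path(out_dir, smp))
    libsize <- length(reads)
    library_sizes[smp] <- libsize
    cov <- coverage(reads) * (1e6 / libsize)
    export.bw(cov, file.path(out_dir, paste0(smp, ".bw")))
    reads_truth[[smp]] <- data.frame(
      read_id = qnames, chrom = as.character(seqnames(reads)),
      start = start(reads), end = end(reads),
      strand = as.character(strand(reads)),
      gene_id = gene_of, placement = placement, stringsAsFactors = FALSE)
    write.table(reads_truth[[smp]],
                file.path(out_dir, paste0("truth_reads_", smp, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    dataset_id = "toy_dataset", genome_id = "toySim1",
    annotation_path = "genes.gtf",
    samples = lapply(seq_along(sample_ids), function(j)
      list(sample_id = sample_ids[j], condition = cond_of[j],
           bam_path = paste0(sample_ids[j], ".bam"),
           bigwig_path = paste0(sample_ids[j], ".bw"))))
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  write.table(data.frame(gene_id = rownames(sim$counts), sim$counts,
                         check.names = FALSE),
              file.path(out_dir, "truth_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$de, file.path(out_dir, "truth_de.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  list(manifest_path = manifest_path, annotation_path = gtf_path,
       dir = out_dir, config = config,
       truth = list(counts = sim$counts, de = sim$de,
                    library_sizes = library_sizes, reads = reads_truth,
                    layout = layout))
}

#' Write a small spliced/indel BAM fixture
#'
#' A hand-crafted alignment file exercising CIGAR-aware depth: a plain
#' match, a spliced read (N), a deletion (D, covered), an insertion (I,
#' not covered) and a soft-clipped read (S, clip not covered). Used to
#' verify the coverage rules; the expected per-base depths are derived by
#' hand where the fixture is consumed.
#'
#' @param out_dir Output directory.
#' @return Path of the indexed BAM (contig `chrT`, 1000 bp).
#' @export
write_spliced_fixture <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sam <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chrT\tLN:1000",
    ## covers 101-120
    paste0("m1\t0\tchrT\t101\t60\t20M\t*\t0\t0\t", strrep("A", 20), "\t*"),
    ## covers 201-210 and 241-250; 211-240 is a skipped intron
    paste0("sp1\t0\tchrT\t201\t60\t10M30N10M\t*\t0\t0\t",
           strrep("A", 20), "\t*"),
    ## covers 301-312 (5M 2D 5M: deletion bases are covered)
    paste0("d1\t0\tchrT\t301\t60\t5M2D5M\t*\t0\t0\t", strrep("A", 10), "\t*"),
    ## covers 401-410 only (insertion adds no reference bases)
    paste0("i1\t0\tchrT\t401\t60\t5M3I5M\t*\t0\t0\t", strrep("A", 13), "\t*"),
    ## covers 501-510 (5S soft clip consumes no reference)
    paste0("s1\t0\tchrT\t501\t60\t5S10M\t*\t0\t0\t", strrep("A", 15), "\t*"))
  sam_path <- file.path(out_dir, "spliced.sam")
  writeLines(sam, sam_path)
  bam <- suppressMessages(asBam(sam_path, file.path(out_dir, "spliced"),
                                overwrite = TRUE, indexDestination = TRUE))
  unlink(sam_path)
  bam
}
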