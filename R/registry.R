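## Dataset manifests and analysis instances.
##
## A manifest is a flat YAML (or JSON) file describing one dataset: its
## genome, its annotation, and its samples grouped by biological condition,
## each pointing at a BAM and/or BigWig file. An instance is a validated
## selection of manifest samples — the unit every analysis operation takes.
## Relative paths in a manifest are resolved against the manifest directory.

MANIFEST_FIELDS <- c("dataset_id", "genome_id", "annotation_path", "samples")
SAMPLE_FIELDS <- c("sample_id", "condition", "bam_path", "bigwig_path",
                   "library_size")

#' Load a dataset manifest
#'
#' Reads and validates a manifest file (YAML or JSON). Structural invariants
#' (unique sample ids, at least one sample per condition, at least one of
#' bam/bigwig per sample) are enforced here; the existence of the referenced
#' files is deliberately deferred to [validate_instance()].
#'
#' @param path Path to the manifest file.
#' @return A `DatasetManifest`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  raw <- tryCatch(
    if (tolower(file_ext(path)) == "json") jsonlite::read_json(path)
    else yaml::read_yaml(path),
    error = function(e) stop("manifest parse error in '", path, "': ",
                             conditionMessage(e)))
  .as_manifest(raw, base_dir = dirname(normalizePath(path)))
}

.as_manifest <- function(raw, base_dir = ".") {
  for (f in c("dataset_id", "genome_id", "annotation_path"))
    if (is.null(raw[[f]]))
      stop("manifest schema violation: missing field '", f, "'")
  unknown <- setdiff(names(raw), MANIFEST_FIELDS)
  if (length(unknown) > 0L)
    stop("manifest schema violation: unknown field(s) ",
         paste0("'", unknown, "'", collapse = ", "))
  if (is.null(raw$samples) || length(raw$samples) == 0L)
    stop("manifest schema violation: field 'samples' is empty")
  samples <- do.call(rbind, lapply(seq_along(raw$samples), function(i) {
    s <- raw$samples[[i]]
    if (is.null(s$sample_id) || is.null(s$condition))
      stop("manifest schema violation: samples[", i,
           "] lacks sample_id/condition")
    bad <- setdiff(names(s), SAMPLE_FIELDS)
    if (length(bad) > 0L)
      stop("manifest schema violation: samples[", i, "] unknown field(s) ",
           paste0("'", bad, "'", collapse = ", "))
    if (is.null(s$bam_path) && is.null(s$bigwig_path))
      stop("sample '", s$sample_id, "' has neither bam_path nor bigwig_path")
    ls <- s$library_size
    if (!is.null(ls) && (!is.numeric(ls) || ls <= 0))
      stop("sample '", s$sample_id, "' has non-positive library_size")
    data.frame(sample_id = as.character(s$sample_id),
               condition = as.character(s$condition),
               bam_path = if (is.null(s$bam_path)) NA_character_
                          else as.character(s$bam_path),
               bigwig_path = if (is.null(s$bigwig_path)) NA_character_
                             else as.character(s$bigwig_path),
               library_size = if (is.null(ls)) NA_real_ else as.numeric(ls),
               stringsAsFactors = FALSE)
  }))
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup) > 0L)
    stop("manifest validation error: duplicated sample_id ",
         paste0("'", unique(dup), "'", collapse = ", "))
  resolve <- function(p) ifelse(is.na(p) | grepl("^/", p), p,
                                file.path(base_dir, p))
  samples$bam_path <- resolve(samples$bam_path)
  samples$bigwig_path <- resolve(samples$bigwig_path)
  structure(list(dataset_id = raw$dataset_id,
                 genome_id = raw$genome_id,
                 annotation_path = resolve(raw$annotation_path),
                 samples = samples),
            class = "DatasetManifest")
}

#' @export
print.DatasetManifest <- function(x, ...) {
  tab <- table(x$samples$condition)
  cat(sprintf("DatasetManifest '%s' (%s): %d sample(s) in %d condition(s)\n",
              x$dataset_id, x$genome_id, nrow(x$samples), length(tab)))
  for (cond in names(tab))
    cat(sprintf("  %s: %s\n", cond,
                paste(x$samples$sample_id[x$samples$condition == cond],
                      collapse = ", ")))
  invisible(x)
}

#' Create an analysis instance from a manifest
#'
#' Selects samples, grouped by biological condition, for downstream
#' analysis. Conditions omitted from `selection` are excluded, which is how
#' a dataset is subsetted (dropping poor-quality replicates, restricting to
#' two conditions for a contrast, and so on).
#'
#' @param manifest A `DatasetManifest`.
#' @param selection Named list: condition -> character vector of sample ids.
#'   `NULL` (default) selects every sample of every condition.
#' @return A `DatasetInstance`.
#' @export
create_instance <- function(manifest, selection = NULL) {
  stopifnot(is(manifest, "DatasetManifest"))
  if (is.null(selection))
    selection <- split(manifest$samples$sample_id, manifest$samples$condition)
  if (length(selection) == 0L || is.null(names(selection)))
    stop("selection must be a non-empty named list (condition -> sample ids)")
  known_conditions <- unique(manifest$samples$condition)
  for (cond in names(selection)) {
    if (!(cond %in% known_conditions))
      stop("unknown condition in selection: '", cond, "'")
    ids <- as.character(selection[[cond]])
    if (length(ids) == 0L)
      stop("empty selection for condition '", cond, "'")
    pool <- manifest$samples$sample_id[manifest$samples$condition == cond]
    missing <- setdiff(ids, pool)
    if (length(missing) > 0L)
      stop("unknown sample(s) for condition '", cond, "': ",
           paste0("'", missing, "'", collapse = ", "))
  }
  selection <- lapply(selection, as.character)
  structure(list(manifest = manifest,
                 selection = selection,
                 created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "DatasetInstance")
}

#' @export
print.DatasetInstance <- function(x, ...) {
  cat(sprintf("DatasetInstance of '%s' (created %s)\n",
              x$manifest$dataset_id, x$created_at))
  for (cond in names(x$selection))
    cat(sprintf("  %s: %s\n", cond, paste(x$selection[[cond]],
                                          collapse = ", ")))
  invisible(x)
}

#' Samples of an instance, in condition-grouped order
#'
#' @param instance A `DatasetInstance`.
#' @return The manifest sample table restricted and ordered to the
#'   instance's selection (conditions in selection order).
#' @export
instance_samples <- function(instance) {
  stopifnot(is(instance, "DatasetInstance"))
  ids <- unlist(instance$selection, use.names = FALSE)
  out <- instance$manifest$samples[
    match(ids, instance$manifest$samples$sample_id), , drop = FALSE]
  out$condition <- rep(names(instance$selection),
                       lengths(instance$selection))
  rownames(out) <- NULL
  out
}

#' Validate an instance against required on-disk resources
#'
#' Checks, per selected sample, that each required resource (`"bam"`,
#' `"bigwig"`, `"counts"`) exists and opens. Problems are reported, never
#' raised, so a report can drive an actionable error message upstream. For
#' BAM-backed samples with no recorded library size, the size is computed
#' (primary, mapped, QC-pass, non-duplicate records) and returned in the
#' report. The function never mutates files and is idempotent.
#'
#' @param instance A `DatasetInstance`.
#' @param require Character subset of `c("bam", "bigwig", "counts")`.
#' @param counts_path Optional path of a precomputed count table, checked
#'   when `"counts"` is required.
#' @return A `ValidationReport`: `pass` flag, per-sample table, messages.
#' @export
validate_instance <- function(instance, require = c("bam"),
                              counts_path = NULL) {
  stopifnot(is(instance, "DatasetInstance"))
  require <- match.arg(require, c("bam", "bigwig", "counts"),
                       several.ok = TRUE)
  smp <- instance_samples(instance)
  msgs <- character(0)
  check_file <- function(path, opener) {
    if (is.na(path) || !file.exists(path)) return(FALSE)
    tryCatch({ opener(path); TRUE }, error = function(e) FALSE)
  }
  bam_ok <- bigwig_ok <- rep(NA, nrow(smp))
  library_size <- smp$library_size
  if ("bam" %in% require) {
    for (i in seq_len(nrow(smp))) {
      bam_ok[i] <- check_file(smp$bam_path[i], function(p)
        scanBamHeader(BamFile(p)))
      if (!bam_ok[i])
        msgs <- c(msgs, sprintf("sample '%s': BAM missing or unreadable (%s)",
                                smp$sample_id[i], smp$bam_path[i]))
      else if (is.na(library_size[i]))
        library_size[i] <- bam_library_size(smp$bam_path[i])
    }
  }
  if ("bigwig" %in% require) {
    for (i in seq_len(nrow(smp))) {
      bigwig_ok[i] <- check_file(smp$bigwig_path[i], function(p)
        seqinfo(BigWigFile(p)))
      if (!bigwig_ok[i])
        msgs <- c(msgs, sprintf(
          "sample '%s': BigWig missing or unreadable (%s)",
          smp$sample_id[i], smp$bigwig_path[i]))
    }
  }
  counts_ok <- NA
  if ("counts" %in% require) {
    counts_ok <- !is.null(counts_path) && file.exists(counts_path)
    if (!counts_ok)
      msgs <- c(msgs, paste0(
        "no precomputed count table available",
        if (!is.null(counts_path)) paste0(" at '", counts_path, "'"),
        "; supply counts_path or quantify from BAM files"))
  }
  per_sample <- data.frame(sample_id = smp$sample_id,
                           condition = smp$condition,
                           bam_ok = bam_ok, bigwig_ok = bigwig_ok,
                           library_size = library_size,
                           stringsAsFactors = FALSE)
  pass <- all(c(bam_ok[!is.na(bam_ok)], bigwig_ok[!is.na(bigwig_ok)],
                counts_ok[!is.na(counts_ok)]))
  structure(list(pass = pass, require = require, samples = per_sample,
                 messages = msgs),
            class = "ValidationReport")
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat(sprintf("ValidationReport (require: %s): %s\n",
              paste(x$require, collapse = ","),
              if (x$pass) "PASS" else "FAIL"))
  if (length(x$messages) > 0L)
    cat(paste0("  - ", x$messages, collapse = "\n"), "\n")
  invisible(x)
}

#' Library size of a BAM file
#'
#' Counts primary, mapped, QC-pass, non-duplicate alignment records — the
#' denominator used for per-million coverage scaling and RPKM.
#'
#' @param bam_path Path to an indexed BAM file.
#' @return Integer count of records.
#' @export
bam_library_size <- function(bam_path) {
  flag <- scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                      isSupplementaryAlignment = FALSE, isDuplicate = FALSE,
                      isNotPassingQualityControls = FALSE)
  countBam(BamFile(bam_path), param = ScanBamParam(flag = flag))$records
}

#' Serialize / restore analysis instances
#'
#' Instances are plain JSON files embedding their manifest, so an analysis
#' selection can be versioned, diffed and shared.
#'
#' @param instance A `DatasetInstance`.
#' @param path Output (input) JSON path.
#' @return `write_instance` returns `path` invisibly; `read_instance` a
#'   `DatasetInstance`.
#' @export
write_instance <- function(instance, path) {
  stopifnot(is(instance, "DatasetInstance"))
  m <- instance$manifest
  payload <- list(
    manifest = list(dataset_id = m$dataset_id, genome_id = m$genome_id,
                    annotation_path = m$annotation_path,
                    samples = lapply(seq_len(nrow(m$samples)), function(i) {
                      s <- as.list(m$samples[i, ])
                      s[!vapply(s, function(v) is.na(v), TRUE)]
                    })),
    selection = instance$selection,
    created_at = instance$created_at)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_instance
#' @export
read_instance <- function(path) {
  if (!file.exists(path)) stop("instance file not found: ", path)
  payload <- jsonlite::read_json(path)
  manifest <- .as_manifest(payload$manifest, base_dir = dirname(
    normalizePath(path)))
  inst <- create_instance(manifest, lapply(payload$selection,
                                           function(x) unlist(x)))
  inst$created_at <- payload$created_at
  inst
}
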