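# Shared fixtures, generated once per test run and memoized.

.toy_cache <- new.env(parent = emptyenv())

# Default toy dataset (2 conditions x 3 replicates, 40 genes, seed 42)
get_toy <- function() {
  if (is.null(.toy_cache$toy)) {
    dir <- file.path(tempdir(), "seqscout-toy")
    .toy_cache$toy <- suppressWarnings(
      make_toy_dataset(sim_config(seed = 42L), dir))
  }
  .toy_cache$toy
}

get_toy_instance <- function() {
  if (is.null(.toy_cache$instance)) {
    manifest <- load_manifest(get_toy()$manifest_path)
    .toy_cache$instance <- create_instance(manifest)
  }
  .toy_cache$instance
}

get_toy_store <- function() {
  if (is.null(.toy_cache$store))
    .toy_cache$store <- import_annotation(get_toy()$annotation_path)
  .toy_cache$store
}

# Library sizes as written by the generator, in manifest sample order
get_toy_library_sizes <- function() {
  get_toy()$truth$library_sizes
}

# Gene-level count matrix recomputed from the toy BAMs, memoized because
# several test files compare against it
get_toy_counted <- function() {
  if (is.null(.toy_cache$counted)) {
    inst <- get_toy_instance()
    store <- get_toy_store()
    .toy_cache$counted <- quantify_regions(inst, store, scale = "raw")
  }
  .toy_cache$counted
}

# Independent oracle: count reads overlapping a feature set by a naive scan
# over the generator's truth read table (start/end arithmetic only, no
# package counting code).
naive_region_count <- function(reads_df, chrom, start, end, min_overlap = 1L) {
  ov <- pmin(reads_df$end, end) - pmax(reads_df$start, start) + 1L
  sum(reads_df$chrom == chrom & ov >= min_overlap)
}

# Tiny two-sample manifest written by hand (no generator) for registry tests
write_mini_manifest <- function(dir = tempfile("mini")) {
  dir.create(dir, showWarnings = FALSE)
  toy <- get_toy()
  smp <- function(id, cond) list(
    sample_id = id, condition = cond,
    bam_path = file.path(toy$dir, paste0(id, ".bam")),
    bigwig_path = file.path(toy$dir, paste0(id, ".bw")))
  manifest <- list(
    dataset_id = "mini", genome_id = "toySim1",
    annotation_path = toy$annotation_path,
    samples = list(smp("control_1", "control"), smp("control_2", "control"),
                   smp("control_3", "control"), smp("treated_1", "treated"),
                   smp("treated_2", "treated"), smp("treated_3", "treated")))
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  path
}
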