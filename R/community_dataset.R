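#' Construct a community dataset
#'
#' The central container of the pipeline: an ASV count table together with
#' per-ASV taxonomy, a rooted phylogeny, per-sample design metadata and
#' optional soil-property and fruit-quality tables. All downstream stages
#' (diversity, assembly, traits, quality, drivers) operate on this object.
#'
#' @param counts non-negative integer matrix, samples in rows and ASVs in
#'   columns, with unique row and column names.
#' @param taxonomy data.frame with columns `asv_id` and `lineage`; lineages
#'   are PR2-style semicolon-separated `rank:name` strings, most inclusive
#'   rank first (e.g. `"kingdom:Eukaryota;supergroup:Alveolata;..."`).
#' @param tree rooted `phylo` object with non-negative branch lengths, or
#'   `NULL`. Tip coverage of the ASVs is checked lazily by the phylogenetic
#'   operations that need it, not here, so a dataset without a tree can still
#'   run the non-phylogenetic stages.
#' @param metadata data.frame with columns `sample_id`, `cultivation_mode`
#'   (one of `greenhouse`, `hilly`, `paddy`) and `growth_stage` (one of
#'   `flowering`, `fruiting`).
#' @param soil optional data.frame, `sample_id` plus numeric soil variables.
#' @param quality optional data.frame, `sample_id` plus numeric fruit-quality
#'   parameters.
#'
#' @return An object of class `community_dataset`.
#' @export
community_dataset <- function(counts, taxonomy, tree = NULL, metadata,
                              soil = NULL, quality = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  ds <- structure(
    list(counts = counts, taxonomy = taxonomy, tree = tree,
         metadata = metadata, soil = soil, quality = quality),
    class = "community_dataset")
  validate_community_dataset(ds)
}

#' Validate a community dataset
#'
#' Checks the container invariants: unique sample and ASV identifiers,
#' identical sample sets across all per-sample tables, non-negative integer
#' counts, non-negative branch lengths, and admissible metadata levels.
#'
#' @param ds a `community_dataset`.
#' @return `ds`, invisibly usable, after passing all checks.
#' @export
validate_community_dataset <- function(ds) {
  counts <- ds$counts
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and ASV column names", call. = FALSE)
  samples <- rownames(counts)
  asvs <- colnames(counts)
  if (anyDuplicated(samples))
    stop("duplicate sample IDs: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(asvs))
    stop("duplicate ASV IDs: ",
         paste(unique(asvs[duplicated(asvs)]), collapse = ", "), call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  if (any(counts != round(counts)))
    stop("counts must be integers (non-integer values found)", call. = FALSE)

  md <- ds$metadata
  if (!is.data.frame(md) || !all(c("sample_id", "cultivation_mode",
                                   "growth_stage") %in% names(md)))
    stop("metadata needs columns sample_id, cultivation_mode, growth_stage",
         call. = FALSE)
  missing_md <- setdiff(samples, md$sample_id)
  if (length(missing_md))
    stop("samples absent from metadata: ",
         paste(missing_md, collapse = ", "), call. = FALSE)
  bad_mode <- setdiff(unique(md$cultivation_mode),
                      c("greenhouse", "hilly", "paddy"))
  if (length(bad_mode))
    stop("unknown cultivation_mode: ", paste(bad_mode, collapse = ", "),
         call. = FALSE)
  bad_stage <- setdiff(unique(md$growth_stage), c("flowering", "fruiting"))
  if (length(bad_stage))
    stop("unknown growth_stage: ", paste(bad_stage, collapse = ", "),
         call. = FALSE)

  tx <- ds$taxonomy
  if (!is.data.frame(tx) || !all(c("asv_id", "lineage") %in% names(tx)))
    stop("taxonomy needs columns asv_id and lineage", call. = FALSE)
  missing_tx <- setdiff(asvs, tx$asv_id)
  if (length(missing_tx))
    stop("ASVs absent from taxonomy: ",
         paste(missing_tx, collapse = ", "), call. = FALSE)

  for (nm in c("soil", "quality")) {
    tab <- ds[[nm]]
    if (is.null(tab)) next
    if (!is.data.frame(tab) || !"sample_id" %in% names(tab))
      stop(nm, " table needs a sample_id column", call. = FALSE)
    miss <- setdiff(samples, tab$sample_id)
    if (length(miss))
      stop("samples absent from ", nm, " table: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }

  if (!is.null(ds$tree)) {
    tree <- ds$tree
    if (!inherits(tree, "phylo")) stop("tree must be a phylo object", call. = FALSE)
    if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
      stop("tree has negative branch lengths", call. = FALSE)
    if (anyDuplicated(tree$tip.label))
      stop("tree has duplicate tip labels", call. = FALSE)
  }
  ds
}

#' @export
print.community_dataset <- function(x, ...) {
  cat("community_dataset:", nrow(x$counts), "samples x", ncol(x$counts),
      "ASVs\n")
  cat("  total reads:", sum(x$counts), "\n")
  cat("  tree:", if (is.null(x$tree)) "absent"
      else paste(length(x$tree$tip.label), "tips"), "\n")
  cat("  soil:", if (is.null(x$soil)) "absent"
      else paste(ncol(x$soil) - 1, "variables"), "\n")
  cat("  quality:", if (is.null(x$quality)) "absent"
      else paste(ncol(x$quality) - 1, "parameters"), "\n")
  tab <- table(x$metadata$cultivation_mode, x$metadata$growth_stage)
  print(tab)
  invisible(x)
}

# Subset samples and/or ASVs consistently across all tables. The tree is kept
# as-is; phylogenetic operations prune lazily.
subset_dataset <- function(ds, samples = NULL, asvs = NULL) {
  counts <- ds$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(asvs)) counts <- counts[, asvs, drop = FALSE]
  keep_s <- rownames(counts)
  keep_a <- colnames(counts)
  md <- ds$metadata[ds$metadata$sample_id %in% keep_s, , drop = FALSE]
  tx <- ds$taxonomy[ds$taxonomy$asv_id %in% keep_a, , drop = FALSE]
  soil <- if (!is.null(ds$soil))
    ds$soil[ds$soil$sample_id %in% keep_s, , drop = FALSE]
  quality <- if (!is.null(ds$quality))
    ds$quality[ds$quality$sample_id %in% keep_s, , drop = FALSE]
  structure(list(counts = counts, taxonomy = tx, tree = ds$tree,
                 metadata = md, soil = soil, quality = quality),
            class = "community_dataset")
}

# metadata rows aligned to the counts row order
aligned_metadata <- function(ds) {
  md <- ds$metadata
  md[match(rownames(ds$counts), md$sample_id), , drop = FALSE]
}

#' Per-sample group labels from the design metadata
#'
#' @param ds a `community_dataset`.
#' @param by `"mode_stage"` (the six design cells), `"mode"` or `"stage"`.
#' @return Named character vector aligned to the counts rows.
#' @export
sample_groups <- function(ds, by = c("mode_stage", "mode", "stage")) {
  by <- match.arg(by)
  md <- aligned_metadata(ds)
  g <- switch(by,
              mode = md$cultivation_mode,
              stage = md$growth_stage,
              mode_stage = paste(md$cultivation_mode, md$growth_stage,
                                 sep = "."))
  stats::setNames(g, rownames(ds$counts))
}
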