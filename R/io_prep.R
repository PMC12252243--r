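#' Read a community dataset from disk
#'
#' Reads the tab-delimited tables and newick tree that make up a dataset and
#' returns a validated [community_dataset()]. All tables are UTF-8 TSV with a
#' header row and the identifier in the first column.
#'
#' @param counts_path TSV count table. By default samples are rows and ASVs
#'   columns; set `samples_as_rows = FALSE` if the file is transposed. The
#'   orientation is declared, never guessed.
#' @param taxonomy_path TSV with columns `asv_id`, `lineage`.
#' @param tree_path newick file with a rooted, branch-length-bearing tree,
#'   or `NULL`.
#' @param metadata_path TSV with `sample_id`, `cultivation_mode`,
#'   `growth_stage`.
#' @param soil_path,quality_path optional TSVs, `sample_id` plus numeric
#'   columns.
#' @param samples_as_rows logical flag declaring the counts orientation.
#' @return A validated `community_dataset`.
#' @export
read_community_data <- function(counts_path, taxonomy_path, tree_path = NULL,
                                metadata_path, soil_path = NULL,
                                quality_path = NULL, samples_as_rows = TRUE) {
  for (p in c(counts_path, taxonomy_path, tree_path, metadata_path,
              soil_path, quality_path)) {
    if (!is.null(p) && !file.exists(p))
      stop("file not found: ", p, call. = FALSE)
  }
  counts_df <- utils::read.delim(counts_path, check.names = FALSE,
                                 stringsAsFactors = FALSE)
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- as.character(counts_df[[1]])
  if (!samples_as_rows) counts <- t(counts)
  if (!is.numeric(counts))
    stop("counts table contains non-numeric entries", call. = FALSE)

  taxonomy <- utils::read.delim(taxonomy_path, check.names = FALSE,
                                stringsAsFactors = FALSE)
  names(taxonomy)[1] <- "asv_id"
  metadata <- utils::read.delim(metadata_path, check.names = FALSE,
                                stringsAsFactors = FALSE)
  names(metadata)[1] <- "sample_id"

  tree <- if (!is.null(tree_path)) read_newick_checked(tree_path)
  soil <- if (!is.null(soil_path)) {
    s <- utils::read.delim(soil_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    names(s)[1] <- "sample_id"
    s
  }
  quality <- if (!is.null(quality_path)) {
    q <- utils::read.delim(quality_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    names(q)[1] <- "sample_id"
    q
  }
  community_dataset(counts, taxonomy, tree, metadata, soil, quality)
}

# read.tree with a balance pre-check so parse failures name the offending
# token instead of failing opaquely
read_newick_checked <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (open != close)
    stop("malformed newick in ", path, ": unbalanced parentheses (",
         open, " '(' vs ", close, "')')", call. = FALSE)
  if (!grepl(";", txt, fixed = TRUE))
    stop("malformed newick in ", path, ": missing terminal ';'", call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("malformed newick in ", path, ": ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree))
    stop("malformed newick in ", path, call. = FALSE)
  tree
}

#' Write a community dataset to a directory
#'
#' Writes the same file layout [read_community_data()] reads: `counts.tsv`,
#' `taxonomy.tsv`, `tree.nwk`, `metadata.tsv` and, when present, `soil.tsv`
#' and `quality.tsv`.
#'
#' @param ds a `community_dataset`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_community_data <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  counts_df <- data.frame(sample_id = rownames(ds$counts), ds$counts,
                          check.names = FALSE)
  write_tsv(counts_df, file.path(dir, "counts.tsv"))
  write_tsv(ds$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_tsv(ds$metadata, file.path(dir, "metadata.tsv"))
  if (!is.null(ds$tree))
    ape::write.tree(ds$tree, file.path(dir, "tree.nwk"))
  if (!is.null(ds$soil))
    write_tsv(ds$soil, file.path(dir, "soil.tsv"))
  if (!is.null(ds$quality))
    write_tsv(ds$quality, file.path(dir, "quality.tsv"))
  invisible(dir)
}

#' Read a dataset from a directory written by [write_community_data()]
#' @param dir directory containing `counts.tsv` etc.
#' @return A validated `community_dataset`.
#' @export
read_community_dir <- function(dir) {
  p <- function(f) {
    fp <- file.path(dir, f)
    if (file.exists(fp)) fp else NULL
  }
  read_community_data(file.path(dir, "counts.tsv"),
                      file.path(dir, "taxonomy.tsv"),
                      p("tree.nwk"),
                      file.path(dir, "metadata.tsv"),
                      p("soil.tsv"), p("quality.tsv"))
}

#' Exclude ASVs assigned to unwanted lineages
#'
#' Drops every ASV whose lineage contains any of the excluded taxon names at
#' any rank. Matching is exact and case-sensitive on the name part of each
#' `rank:name` segment -- no substring matching, so e.g. excluding "Fungi"
#' cannot accidentally remove "Chytridiomycota_Fungi-like". The default set
#' removes the non-protist eukaryotes that 18S V9 amplicons co-capture.
#'
#' @param ds a `community_dataset`.
#' @param exclude_lineages character vector of taxon names.
#' @return The filtered dataset; the sample set is unchanged.
#' @export
filter_taxa <- function(ds,
                        exclude_lineages = c("Fungi", "Metazoa",
                                             "Embryophyta")) {
  if (length(exclude_lineages) == 0) return(ds)
  tx <- ds$taxonomy
  names_by_asv <- lapply(strsplit(tx$lineage, ";", fixed = TRUE),
                         function(seg) sub("^[^:]*:", "", seg))
  hit <- vapply(names_by_asv,
                function(nm) any(nm %in% exclude_lineages), logical(1))
  excluded <- tx$asv_id[hit]
  keep <- setdiff(colnames(ds$counts), excluded)
  if (length(keep) == 0)
    warning("all ASVs excluded by lineage filter", call. = FALSE)
  subset_dataset(ds, asvs = keep)
}

#' Remove singleton ASVs
#'
#' A singleton is an ASV whose total read count across all samples is exactly
#' one; such ASVs carry no abundance information and are commonly sequencing
#' artifacts, so they are dropped before normalization.
#'
#' @param ds a `community_dataset`.
#' @return Dataset without singleton ASVs.
#' @export
remove_singletons <- function(ds) {
  keep <- colnames(ds$counts)[colSums(ds$counts) != 1]
  subset_dataset(ds, asvs = keep)
}

#' Rarefy all samples to a common depth
#'
#' Subsamples each sample's reads uniformly without replacement (multivariate
#' hypergeometric, a single seeded draw) so every retained sample totals
#' exactly `depth`. Samples with fewer than `depth` reads are dropped with a
#' warning rather than kept unscaled, so all downstream sums stay comparable.
#'
#' @param ds a `community_dataset`.
#' @param depth target depth; the default is the normalization depth used
#'   for the lemon-farmland survey data.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return Rarefied dataset. ASVs that end up with zero total counts are kept
#'   as all-zero columns only if `drop_empty_asvs = FALSE`.
#' @param drop_empty_asvs drop ASVs with zero post-rarefaction total
#'   (default TRUE).
#' @export
rarefy_counts <- function(ds, depth = 18907, seed = NULL,
                          drop_empty_asvs = TRUE) {
  stop_if_not_scalar_count(depth, "depth", min = 1)
  totals <- rowSums(ds$counts)
  shallow <- rownames(ds$counts)[totals < depth]
  if (length(shallow)) {
    warning("dropping samples below depth ", depth, ": ",
            paste(shallow, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(rownames(ds$counts), shallow)
  if (length(keep) == 0) stop("no sample reaches depth ", depth, call. = FALSE)
  ds <- subset_dataset(ds, samples = keep)
  rare <- with_seed(seed, vegan::rrarefy(ds$counts, depth))
  storage.mode(rare) <- "double"
  ds$counts <- rare
  if (drop_empty_asvs) {
    ds <- subset_dataset(ds, asvs = colnames(rare)[colSums(rare) > 0])
  }
  ds
}

#' Standard table preparation
#'
#' The full preparation chain applied before any analysis: lineage exclusion,
#' singleton removal, then seeded rarefaction.
#'
#' @inheritParams filter_taxa
#' @inheritParams rarefy_counts
#' @return Prepared dataset.
#' @export
prepare_dataset <- function(ds,
                            exclude_lineages = c("Fungi", "Metazoa",
                                                 "Embryophyta"),
                            depth = 18907, seed = NULL) {
  ds <- filter_taxa(ds, exclude_lineages)
  ds <- remove_singletons(ds)
  rarefy_counts(ds, depth = depth, seed = seed)
}
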