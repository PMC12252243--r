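# rank vocabulary, most inclusive first; index = specificity
PR2_RANKS <- c("kingdom", "supergroup", "division", "class", "order",
               "family", "genus", "species")

#' Read a trophic trait map
#'
#' A trait map links taxon names (at a stated rank) to one of the three
#' protist trophic modes: `consumer`, `phototrophic`, `parasitic`. The file
#' is TSV with columns `taxon`, `rank`, `trait`. The same taxon+rank key may
#' not map to two different traits.
#'
#' @param path TSV file; defaults to the curated map shipped with the
#'   package, a small higher-rank subset covering common protist clades.
#'   Supply a full published matching table here to override it.
#' @return data.frame of class `trait_map` with columns `taxon`, `rank`,
#'   `trait`.
#' @export
read_trait_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "protist_trait_map.tsv",
                                package = "soilprotist", mustWork = TRUE)
  tm <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon", "rank", "trait")
  if (!all(need %in% names(tm)))
    stop("trait map needs columns taxon, rank, trait", call. = FALSE)
  bad_trait <- setdiff(unique(tm$trait),
                       c("consumer", "phototrophic", "parasitic"))
  if (length(bad_trait))
    stop("unknown trait labels: ", paste(bad_trait, collapse = ", "),
         call. = FALSE)
  bad_rank <- setdiff(unique(tm$rank), PR2_RANKS)
  if (length(bad_rank))
    stop("unknown ranks: ", paste(bad_rank, collapse = ", "), call. = FALSE)
  key <- paste(tm$taxon, tm$rank)
  dup <- duplicated(key)
  if (any(dup)) {
    conflict <- vapply(unique(key[dup]), function(k) {
      length(unique(tm$trait[key == k])) > 1
    }, logical(1))
    if (any(conflict))
      stop("conflicting duplicate trait-map keys: ",
           paste(unique(key[dup])[conflict], collapse = ", "), call. = FALSE)
    tm <- tm[!dup, , drop = FALSE]
  }
  structure(tm, class = c("trait_map", "data.frame"))
}

# split "rank:name" lineage strings into aligned rank/name vectors
parse_lineage <- function(lineage) {
  seg <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  has_rank <- grepl(":", seg, fixed = TRUE)
  list(rank = ifelse(has_rank, sub(":.*$", "", seg), NA_character_),
       name = sub("^[^:]*:", "", seg))
}

#' Assign trophic traits to ASVs
#'
#' Each ASV receives the trait of the most specific rank in its lineage that
#' matches a trait-map entry (rank and name both matching, case-sensitive);
#' lineages with no matching rank are labelled `unassigned`. The
#' most-specific-rank-wins rule lets a genus-level entry (e.g. a parasitic
#' genus inside an otherwise consumer division) override its higher ranks.
#'
#' @param taxonomy taxonomy data.frame (`asv_id`, `lineage`) or a
#'   `community_dataset`.
#' @param trait_map a `trait_map`; defaults to the packaged table.
#' @return Named character vector, trait per ASV.
#' @export
assign_traits <- function(taxonomy, trait_map = NULL) {
  if (inherits(taxonomy, "community_dataset")) taxonomy <- taxonomy$taxonomy
  trait_map <- trait_map %||% read_trait_map()
  map_key <- paste(trait_map$rank, trait_map$taxon)
  rank_level <- match(trait_map$rank, PR2_RANKS)
  out <- vapply(taxonomy$lineage, function(lin) {
    parsed <- parse_lineage(lin)
    hit <- match(paste(parsed$rank, parsed$name), map_key)
    hit <- hit[!is.na(hit)]
    if (!length(hit)) return("unassigned")
    trait_map$trait[hit[which.max(rank_level[hit])]]
  }, character(1), USE.NAMES = FALSE)
  stats::setNames(out, taxonomy$asv_id)
}

#' Per-sample trophic-group composition
#'
#' Sums relative abundances by trophic group, so each sample is summarized
#' as its consumer / phototrophic / parasitic / unassigned proportions
#' (rows sum to 1).
#'
#' @param ds a `community_dataset`.
#' @param assignment per-ASV trait vector from [assign_traits()]; computed
#'   with the packaged map when omitted.
#' @return Matrix samples x 4 groups of relative abundances.
#' @export
trait_composition <- function(ds, assignment = NULL) {
  assignment <- assignment %||% assign_traits(ds)
  counts <- ds$counts
  missing <- setdiff(colnames(counts), names(assignment))
  if (length(missing))
    stop("ASVs without a trait assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rel <- as_relative_abundance(counts)
  groups <- c("consumer", "phototrophic", "parasitic", "unassigned")
  f <- factor(assignment[colnames(counts)], levels = groups)
  out <- sapply(groups, function(g)
    rowSums(rel[, f == g, drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(rel), groups))
  out
}

#' Subset a dataset to the ASVs of one trophic group
#'
#' Used to rerun ordination/PERMANOVA per functional group.
#'
#' @param ds a `community_dataset`.
#' @param trait one of `consumer`, `phototrophic`, `parasitic`.
#' @param assignment optional precomputed assignment.
#' @return A `community_dataset` restricted to that group's ASVs; samples
#'   left empty by the subset are dropped with a warning.
#' @export
trait_subset <- function(ds, trait, assignment = NULL) {
  assignment <- assignment %||% assign_traits(ds)
  keep <- names(assignment)[assignment == trait]
  keep <- intersect(colnames(ds$counts), keep)
  if (!length(keep)) stop("no ASVs assigned to '", trait, "'", call. = FALSE)
  sub <- subset_dataset(ds, asvs = keep)
  empty <- rownames(sub$counts)[rowSums(sub$counts) == 0]
  if (length(empty)) {
    warning("samples empty after trait subset: ",
            paste(empty, collapse = ", "), call. = FALSE)
    sub <- subset_dataset(sub,
                          samples = setdiff(rownames(sub$counts), empty))
  }
  sub
}
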