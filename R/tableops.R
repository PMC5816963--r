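#' Canonicalize a Greengenes-style lineage string
#'
#' Taxonomy labels arrive in slightly different spellings across
#' pipelines: single- vs double-underscore rank prefixes
#' (`"p_Proteobacteria"` vs `"p__Proteobacteria"`) and stray whitespace
#' around the `";"` separators. Canonicalization makes "identical
#' taxonomy" well defined before collapsing and merging: whitespace is
#' stripped and every rank prefix is normalized to the double-underscore
#' Greengenes convention. Trailing empty ranks (`"g__;s__"`) are kept.
#'
#' @param raw character vector of taxonomy strings.
#' @return character vector of canonical lineages. Idempotent:
#'   `canonicalize_lineage(canonicalize_lineage(x)) == canonicalize_lineage(x)`.
#' @examples
#' canonicalize_lineage("k__Bacteria; p__Proteobacteria")
#' canonicalize_lineage("k_Bacteria;p_;c_;o_;f_;g_;s_")
#' @export
canonicalize_lineage <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  if (anyNA(raw) || any(!nzchar(trimws(raw))))
    stop("empty taxonomy string")
  vapply(as.character(raw), function(x) {
    parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    parts <- sub("^([A-Za-z])_{1,2}", "\\1__", parts)
    paste(parts, collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

# split a canonical lineage into rank parts; returns for each part the
# prefix letter (NA if unprefixed) and the name after the prefix
lineage_parts <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  has_prefix <- grepl("^[A-Za-z]__", parts)
  list(part = parts,
       prefix = ifelse(has_prefix, substr(parts, 1, 1), NA_character_),
       name = ifelse(has_prefix, substring(parts, 4), parts))
}

#' Collapse rows with identical taxonomy
#'
#' Rows whose canonical taxonomy labels agree are summed within each
#' sample, yielding one row per lineage. Per-sample column totals are
#' unchanged.
#'
#' @param table an [abundance_table()].
#' @return an `abundance_table` with unique taxonomy rows, in order of
#'   first appearance.
#' @export
collapse_by_taxonomy <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  canon <- canonicalize_lineage(table$taxonomy)
  collapsed <- rowsum(table$counts, group = canon, reorder = FALSE)
  abundance_table(collapsed, taxonomy = rownames(collapsed),
                  provenance = table$provenance)
}

#' Merge abundance tables on shared taxonomies
#'
#' Meta-analysis merge: the row set is the intersection of the tables'
#' canonical taxonomies (taxa absent from any table are dropped) and the
#' sample set is the concatenation of all tables' samples. Tables must
#' already be collapsed ([collapse_by_taxonomy()]) and have disjoint
#' sample ids.
#'
#' @param tables a list of collapsed `abundance_table`s (length >= 1).
#' @return the merged `abundance_table`; rows follow the first table's
#'   order.
#' @export
merge_tables <- function(tables) {
  if (inherits(tables, "abundance_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "abundance_table")))
  taxa <- lapply(tables, function(t) canonicalize_lineage(t$taxonomy))
  for (i in seq_along(tables)) {
    if (anyDuplicated(taxa[[i]]))
      stop(sprintf(
        "table %d has duplicated taxonomy; run collapse_by_taxonomy() first",
        i))
  }
  samples <- unlist(lapply(tables, sample_ids))
  if (anyDuplicated(samples))
    stop("duplicate sample id(s) across tables: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  shared <- Reduce(intersect, taxa)
  if (length(shared) == 0L)
    stop("no shared taxonomies across the input tables")
  mats <- lapply(seq_along(tables), function(i) {
    m <- tables[[i]]$counts
    rownames(m) <- taxa[[i]]
    m[shared, , drop = FALSE]
  })
  merged <- do.call(cbind, mats)
  abundance_table(merged, taxonomy = shared,
                  provenance = unlist(lapply(tables, `[[`, "provenance")))
}

#' Drop samples with low sequencing depth
#'
#' Removes samples whose total assigned counts fall below `min_depth`;
#' removals are reported via [message()] with the sample id and depth.
#'
#' @param table an `abundance_table`.
#' @param min_depth minimum column total a sample must reach to be kept.
#' @return the filtered `abundance_table`.
#' @export
filter_low_depth_samples <- function(table, min_depth) {
  stopifnot(inherits(table, "abundance_table"), min_depth >= 0)
  depth <- sample_sums(table)
  drop <- depth < min_depth
  if (all(drop))
    stop("all samples removed: every sample is below min_depth = ", min_depth)
  if (any(drop))
    message("removed low-depth sample(s): ",
            paste(sprintf("%s (%g)", names(depth)[drop], depth[drop]),
                  collapse = ", "))
  abundance_table(table$counts[, !drop, drop = FALSE],
                  taxonomy = table$taxonomy, provenance = table$provenance)
}

#' Normalize an abundance table
#'
#' @param table an `abundance_table`.
#' @param method `"none"` (identity), `"total_sum"` (each column divided
#'   by its sum, so columns sum to 1), or `"rarefy"` (seeded subsampling
#'   without replacement so each retained column sums exactly to `depth`;
#'   columns whose total is below `depth` are dropped with a warning).
#' @param depth target depth for `"rarefy"`.
#' @param seed integer seed making rarefaction reproducible; the global
#'   RNG state is restored afterwards.
#' @return a normalized `abundance_table`.
#' @export
normalize_table <- function(table, method = c("none", "total_sum", "rarefy"),
                            depth = NULL, seed = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  method <- match.arg(method)
  if (method == "none") return(table)
  if (method == "total_sum") {
    tot <- sample_sums(table)
    if (any(tot == 0))
      stop("total_sum normalization undefined for all-zero sample(s): ",
           paste(names(tot)[tot == 0], collapse = ", "))
    return(abundance_table(sweep(table$counts, 2, tot, "/"),
                           taxonomy = table$taxonomy,
                           provenance = table$provenance))
  }
  # rarefy
  if (is.null(depth) || depth <= 0)
    stop("rarefaction requires a positive 'depth'")
  if (any(table$counts != round(table$counts)))
    stop("rarefaction requires integer counts")
  tot <- sample_sums(table)
  drop <- tot < depth
  if (all(drop)) stop("all samples are below the rarefaction depth")
  if (any(drop))
    warning("dropped sample(s) below rarefaction depth: ",
            paste(sprintf("%s (%g)", names(tot)[drop], tot[drop]),
                  collapse = ", "))
  kept <- table$counts[, !drop, drop = FALSE]
  rare <- with_seed(seed, function() {
    t(vegan::rrarefy(t(kept), sample = depth))
  })
  dimnames(rare) <- dimnames(kept)
  abundance_table(rare, taxonomy = table$taxonomy,
                  provenance = table$provenance)
}

.rank_order <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                 family = "f", genus = "g", species = "s")

#' Collapse a table at a taxonomic rank
#'
#' Re-keys every row to its lineage truncated at `rank` and sums rows
#' sharing the truncated key, e.g. a phylum-level summary. Column totals
#' are preserved.
#'
#' @param table an `abundance_table`.
#' @param rank one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return an `abundance_table` keyed at the requested rank.
#' @export
collapse_at_rank <- function(table, rank) {
  stopifnot(inherits(table, "abundance_table"))
  rank <- match.arg(rank, names(.rank_order))
  target <- match(rank, names(.rank_order))
  canon <- canonicalize_lineage(table$taxonomy)
  truncated <- vapply(canon, function(x) {
    lp <- lineage_parts(x)
    pos <- match(lp$prefix, unname(.rank_order))
    # unprefixed parts inherit the next position after their predecessor
    for (i in seq_along(pos)) {
      if (is.na(pos[i])) pos[i] <- if (i == 1L) 1L else pos[i - 1L] + 1L
    }
    paste(lp$part[pos <= target], collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  collapsed <- rowsum(table$counts, group = truncated, reorder = FALSE)
  abundance_table(collapsed, taxonomy = rownames(collapsed),
                  provenance = table$provenance)
}

#' Binarize counts to presence/absence
#'
#' Converts counts to detected/not-detected per sample, discarding
#' abundance magnitude. The default `detection_threshold = 1` applies the
#' zero/nonzero rule: any nonzero value counts as present, which for
#' integer counts equals "count >= 1" and makes presence invariant to
#' sample-wise rescaling (e.g. total-sum normalization). A threshold
#' above 1 requires `count >= detection_threshold`.
#'
#' @param table an `abundance_table`.
#' @param detection_threshold minimum count treated as present (> 0).
#' @return an object of class `presence_matrix`: fields `present`
#'   (logical matrix), `taxonomy`, `detection_threshold`.
#' @export
binarize <- function(table, detection_threshold = 1) {
  stopifnot(inherits(table, "abundance_table"), detection_threshold > 0)
  present <- if (detection_threshold == 1) table$counts > 0
             else table$counts >= detection_threshold
  structure(list(present = present,
                 taxonomy = table$taxonomy,
                 detection_threshold = detection_threshold),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d taxa x %d samples (threshold %g)\n",
              nrow(x$present), ncol(x$present), x$detection_threshold))
  invisible(x)
}
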