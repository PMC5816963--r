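#' Construct an abundance table
#'
#' The universal exchange object of the package: a taxonomy-labelled
#' matrix of non-negative counts, rows = taxa, columns = samples.
#' Taxonomies may be duplicated (e.g. several OTUs assigned to the same
#' lineage); duplicates are only resolved by the explicit
#' [collapse_by_taxonomy()] step so that the collapse is observable.
#'
#' @param counts numeric matrix of non-negative values; column names are
#'   the (unique) sample ids.
#' @param taxonomy character vector of taxonomy labels, one per row.
#'   Defaults to `rownames(counts)`.
#' @param provenance source-file identifier(s) carried along for logging.
#' @return An object of class `abundance_table` with fields `counts`
#'   (matrix with unique internal rownames), `taxonomy` (one label per
#'   row, possibly duplicated) and `provenance`.
#' @examples
#' m <- matrix(c(0, 1, 2, 5, 0, 3), nrow = 2, byrow = TRUE,
#'             dimnames = list(NULL, c("S1", "S2", "S3")))
#' abundance_table(m, taxonomy = c("k__Bacteria;p__A", "k__Bacteria;p__B"))
#' @export
abundance_table <- function(counts, taxonomy = rownames(counts),
                            provenance = NA_character_) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix")
  if (is.null(colnames(counts)))
    stop("'counts' must have column names (sample ids)")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (is.null(taxonomy))
    stop("'taxonomy' is required when 'counts' has no rownames")
  taxonomy <- as.character(taxonomy)
  if (length(taxonomy) != nrow(counts))
    stop("length(taxonomy) != nrow(counts)")
  if (anyNA(counts))
    stop("counts contain NA")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at row %d ('%s'), sample '%s'",
                 bad[1], taxonomy[bad[1]], colnames(counts)[bad[2]]))
  }
  rownames(counts) <- make.unique(taxonomy, sep = "||dup")
  structure(list(counts = counts, taxonomy = taxonomy,
                 provenance = provenance),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (!all(is.na(x$provenance)))
    cat("  provenance:", paste(x$provenance, collapse = ", "), "\n")
  dups <- sum(duplicated(x$taxonomy))
  if (dups > 0)
    cat(sprintf("  %d duplicated taxonomy label(s) pending collapse\n", dups))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Sample ids of a table or presence matrix
#' @param x an `abundance_table` or `presence_matrix`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(x) {
  colnames(if (inherits(x, "presence_matrix")) x$present else x$counts)
}

#' Per-sample totals (sequencing depth) of an abundance table
#' @param x an `abundance_table`.
#' @return named numeric vector of column sums.
#' @export
sample_sums <- function(x) colSums(x$counts)

#' Construct a sample-to-group assignment
#'
#' Defines the interest in-group and out-group sample sets used by the
#' core test. Usually built by [read_mapping()]; this constructor exists
#' for programmatic use (e.g. the synthetic generator).
#'
#' @param interest_samples,outgroup_samples character vectors of sample
#'   ids; must be disjoint and non-empty.
#' @param group_column,interest_label,outgroup_labels metadata recording
#'   how the assignment was derived.
#' @param mapping optional data.frame of the full mapping file.
#' @return An object of class `group_map`.
#' @export
group_map <- function(interest_samples, outgroup_samples,
                      group_column = NA_character_,
                      interest_label = NA_character_,
                      outgroup_labels = NA_character_,
                      mapping = NULL) {
  interest_samples <- as.character(interest_samples)
  outgroup_samples <- as.character(outgroup_samples)
  if (length(interest_samples) == 0L) stop("in-group has zero samples")
  if (length(outgroup_samples) == 0L) stop("out-group has zero samples")
  both <- c(interest_samples, outgroup_samples)
  if (anyDuplicated(both))
    stop("sample(s) assigned to more than one group or duplicated: ",
         paste(unique(both[duplicated(both)]), collapse = ", "))
  if (!is.na(interest_label) && interest_label %in% outgroup_labels)
    stop("interest label cannot also be an out-group label")
  structure(list(interest = interest_samples, outgroup = outgroup_samples,
                 group_column = group_column,
                 interest_label = interest_label,
                 outgroup_labels = outgroup_labels,
                 mapping = mapping),
            class = "group_map")
}

#' @export
print.group_map <- function(x, ...) {
  cat(sprintf("group_map: %d in-group vs %d out-group samples\n",
              length(x$interest), length(x$outgroup)))
  if (!is.na(x$group_column))
    cat(sprintf("  column '%s': interest '%s' vs {%s}\n", x$group_column,
                x$interest_label, paste(x$outgroup_labels, collapse = ", ")))
  invisible(x)
}

# run fn() with a temporarily-seeded RNG, restoring global state after
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}
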