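#' Read a BIOM v1 (JSON) OTU table
#'
#' Reads a Biological Observation Matrix file (v1 JSON, dense or sparse
#' encoding) via the \pkg{biomformat} package and returns an
#' [abundance_table()] whose taxonomy labels come from the `"taxonomy"`
#' observation-metadata key (either a list of rank strings, joined with
#' `";"`, or a single semicolon-joined string). Labels are canonicalized
#' with [canonicalize_lineage()]. Counts are transcribed exactly; absent
#' cells of a sparse matrix become 0. Observations sharing a taxonomy are
#' NOT merged here — collapse is the explicit [collapse_by_taxonomy()]
#' step.
#'
#' BIOM v2 (HDF5) is not supported; files starting with the HDF5 magic
#' bytes are rejected with a clear error.
#'
#' @param path path to a BIOM v1 JSON file.
#' @return an `abundance_table`.
#' @export
read_biom_v1 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  magic <- readBin(path, "raw", n = 8L)
  hdf5_magic <- as.raw(c(0x89, 0x48, 0x44, 0x46, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(magic) == 8L && identical(magic, hdf5_magic))
    stop("'", path, "' is a BIOM v2 (HDF5) file; only BIOM v1 JSON is ",
         "supported - convert with 'biom convert --to-json'")
  ok <- jsonlite::validate(paste(readLines(path, warn = FALSE),
                                 collapse = "\n"))
  if (!isTRUE(ok))
    stop("malformed JSON in '", path, "': ", attr(ok, "err"))
  b <- biomformat::read_biom(path)
  counts <- as.matrix(biomformat::biom_data(b))
  obs_ids <- vapply(b$rows, function(r) r$id, character(1))
  smp_ids <- vapply(b$columns, function(s) s$id, character(1))
  # biom_data drops a 1 x n table to a column vector; restore orientation
  if (nrow(counts) != length(obs_ids) && ncol(counts) == length(obs_ids))
    counts <- t(counts)
  if (!all(dim(counts) == c(length(obs_ids), length(smp_ids))))
    stop("'", path, "' shape disagrees with its row/column entries")
  dimnames(counts) <- list(obs_ids, smp_ids)
  md <- biomformat::observation_metadata(b)
  tax_of <- function(id, entry) {
    if (is.null(entry) || length(entry) == 0L)
      stop("observation '", id, "' has no \"taxonomy\" metadata key")
    nm <- names(entry)
    if (is.data.frame(entry)) entry <- unlist(entry, use.names = TRUE)
    if (!is.null(nm) && !any(grepl("^taxonomy", nm)))
      stop("observation '", id, "' has no \"taxonomy\" metadata key")
    vals <- if (!is.null(nm)) entry[grepl("^taxonomy", nm)] else entry
    paste(unlist(vals, use.names = FALSE), collapse = ";")
  }
  taxonomy <- if (is.data.frame(md)) {
    keep <- grepl("^taxonomy", names(md))
    if (!any(keep))
      stop("observation '", obs_ids[1],
           "' has no \"taxonomy\" metadata key")
    apply(md[, keep, drop = FALSE], 1, paste, collapse = ";")
  } else {
    vapply(obs_ids, function(id) tax_of(id, md[[id]]), character(1))
  }
  taxonomy <- canonicalize_lineage(taxonomy)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count in '%s' at observation '%s', sample '%s'",
                 path, obs_ids[bad[1]], colnames(counts)[bad[2]]))
  }
  abundance_table(counts, taxonomy = taxonomy, provenance = path)
}

#' Write an abundance table as BIOM v1 (sparse JSON)
#'
#' The inverse of [read_biom_v1()]: taxonomy labels are stored under the
#' `"taxonomy"` observation-metadata key. Output is deterministic (no
#' timestamps), so identical tables produce byte-identical files.
#'
#' @param table an `abundance_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_biom_v1 <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  m <- table$counts
  nz <- which(m != 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
  data <- lapply(seq_len(nrow(nz)), function(k) {
    list(nz[k, 1] - 1L, nz[k, 2] - 1L, unname(m[nz[k, 1], nz[k, 2]]))
  })
  obj <- list(
    id = "coremic table",
    format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table",
    generated_by = "coremic",
    date = "",
    matrix_type = "sparse",
    matrix_element_type = if (all(m == round(m))) "int" else "float",
    shape = dim(m),
    rows = lapply(seq_len(nrow(m)), function(i) {
      list(id = sprintf("OTU_%d", i),
           metadata = list(taxonomy = table$taxonomy[i]))
    }),
    columns = lapply(colnames(m), function(s) {
      list(id = s, metadata = NULL)
    }),
    data = data
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                              digits = NA),
             path)
  invisible(path)
}

#' Read a tab-delimited OTU table
#'
#' Convenience alternative to BIOM: a TSV with a header row of sample
#' names and one taxonomy column.
#'
#' @param path path to the TSV file.
#' @param taxonomy_column name of the taxonomy column (default
#'   `"taxonomy"`).
#' @return an `abundance_table`.
#' @export
read_tsv_table <- function(path, taxonomy_column = "taxonomy") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", comment.char = "")
  if (nrow(df) == 0L) stop("no data rows in '", path, "'")
  if (!taxonomy_column %in% names(df))
    stop("taxonomy column '", taxonomy_column, "' not found; columns: ",
         paste(names(df), collapse = ", "))
  samples <- setdiff(names(df), taxonomy_column)
  if (length(samples) == 0L) stop("no sample columns in '", path, "'")
  if (anyDuplicated(samples))
    stop("duplicate sample name(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  m <- matrix(NA_real_, nrow(df), length(samples),
              dimnames = list(NULL, samples))
  for (s in samples) {
    v <- suppressWarnings(as.numeric(df[[s]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("non-numeric count '%s' at row %d, column '%s'",
                   df[[s]][i], i, s))
    }
    m[, s] <- v
  }
  taxonomy <- canonicalize_lineage(df[[taxonomy_column]])
  abundance_table(m, taxonomy = taxonomy, provenance = path)
}

#' Read a sample mapping file
#'
#' Tab-delimited per-sample metadata: first column is the sample id, the
#' remaining columns assign groups (treatment, location, ...). Lines
#' starting with `"#"` are ignored apart from an optional commented
#' header. Group matching is exact and case-sensitive so that mapping
#' mistakes surface instead of being silently folded.
#'
#' @param path path to the mapping file.
#' @param group_column name of the column holding the group labels.
#' @param interest label of the interest group.
#' @param outgroup character vector of out-group labels, or `"rest"`
#'   (default) to take every non-interest sample.
#' @return a [group_map()].
#' @export
read_mapping <- function(path, group_column, interest, outgroup = "rest") {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # QIIME-style mapping files comment the header line itself
  header_idx <- which(nzchar(lines))[1]
  if (is.na(header_idx)) stop("empty mapping file: ", path)
  lines[header_idx] <- sub("^#", "", lines[header_idx])
  lines <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("no sample rows in mapping file: ", path)
  if (!group_column %in% names(df))
    stop("group column '", group_column, "' not found; available columns: ",
         paste(names(df)[-1], collapse = ", "))
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate sample id(s) in mapping: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  grp <- df[[group_column]]
  in_samples <- ids[grp == interest]
  if (length(in_samples) == 0L)
    stop("interest label '", interest, "' matches zero samples in column '",
         group_column, "' (matching is case-sensitive); labels present: ",
         paste(unique(grp), collapse = ", "))
  if (identical(outgroup, "rest")) {
    out_samples <- ids[grp != interest]
    out_labels <- setdiff(unique(grp), interest)
  } else {
    if (interest %in% outgroup)
      stop("interest label cannot also be an out-group label")
    out_samples <- ids[grp %in% outgroup]
    out_labels <- outgroup
  }
  if (length(out_samples) == 0L)
    stop("out-group labels match zero samples")
  group_map(in_samples, out_samples, group_column = group_column,
            interest_label = interest, outgroup_labels = out_labels,
            mapping = df)
}

#' Write a group map as a tab-delimited mapping file
#'
#' @param groups a `group_map`.
#' @param path output path.
#' @param group_column,study optional: column name for the group labels
#'   and an optional per-sample study tag written as an extra column.
#' @return `path`, invisibly.
#' @export
write_mapping_tsv <- function(groups, path, group_column = NULL,
                              study = NULL) {
  stopifnot(inherits(groups, "group_map"))
  col <- group_column %||% groups$group_column
  if (is.na(col)) col <- "Group"
  ids <- c(groups$interest, groups$outgroup)
  labels <- c(rep(groups$interest_label %||% "interest",
                  length(groups$interest)),
              rep(groups$outgroup_labels[1] %||% "outgroup",
                  length(groups$outgroup)))
  df <- data.frame(`#SampleID` = ids, check.names = FALSE)
  df[[col]] <- labels
  if (!is.null(study)) df[["Study"]] <- study[ids]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

# format a numeric column for reports: full precision, no scientific-
# notation surprises across platforms
.fmt_num <- function(x) {
  vapply(x, function(v) format(v, digits = 15, scientific = NA),
         character(1))
}

#' Write core-test results to a TSV report
#'
#' One row per taxon, sorted by (q ascending, p ascending, taxonomy);
#' `is_core` is written as `true`/`false`.
#'
#' @param results a `coremic_results` data.frame from [identify_core()]
#'   (or any data.frame with the same columns). May be empty.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  cols <- c("taxonomy", "a", "b", "c", "d", "p_value", "q_value",
            "presence_in_pct", "presence_out_pct", "is_core")
  if (nrow(results) > 0) {
    o <- order(results$q_value, results$p_value, results$taxonomy)
    results <- results[o, , drop = FALSE]
  }
  out <- data.frame(
    taxonomy = results$taxonomy,
    a = results$a, b = results$b, c = results$c, d = results$d,
    p_value = .fmt_num(results$p_value),
    q_value = .fmt_num(results$q_value),
    presence_in_pct = .fmt_num(results$presence_in_pct),
    presence_out_pct = .fmt_num(results$presence_out_pct),
    is_core = ifelse(results$is_core, "true", "false"),
    stringsAsFactors = FALSE)
  if (nrow(results) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  utils::write.table(out[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
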