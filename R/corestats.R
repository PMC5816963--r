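#' Contingency counts for one taxon
#'
#' Tallies the 2x2 presence table underlying the core test: `a` in-group
#' samples with the taxon present, `b` in-group absent, `c` out-group
#' present, `d` out-group absent.
#'
#' @param presence a `presence_matrix` from [binarize()].
#' @param taxon a taxonomy label present in the matrix.
#' @param groups a [group_map()].
#' @return named integer vector `c(a, b, c, d)`.
#' @export
contingency_for_taxon <- function(presence, taxon, groups) {
  stopifnot(inherits(presence, "presence_matrix"),
            inherits(groups, "group_map"))
  idx <- which(presence$taxonomy == taxon)
  if (length(idx) == 0L) stop("taxon not found: ", taxon)
  if (length(idx) > 1L) stop("taxon label is ambiguous (collapse first): ",
                             taxon)
  missing <- setdiff(c(groups$interest, groups$outgroup),
                     colnames(presence$present))
  if (length(missing) > 0L)
    stop("sample(s) in group map missing from the presence matrix: ",
         paste(missing, collapse = ", "))
  p_in <- presence$present[idx, groups$interest]
  p_out <- presence$present[idx, groups$outgroup]
  c(a = sum(p_in), b = sum(!p_in), c = sum(p_out), d = sum(!p_out))
}

#' One-tailed Fisher's exact test for presence enrichment
#'
#' Exact p-value that the taxon's presence in the in-group is at least as
#' extreme as observed, under the null that presence is independent of
#' group: `P(X >= a)` where `X` is hypergeometric with population
#' `a+b+c+d`, `a+c` "present" successes and `a+b` in-group draws. The
#' tail is summed directly in log space (via `lchoose`), so the test is
#' overflow-free for any table size. The alternative is fixed as "greater
#' presence in the in-group"; to test the opposite direction, swap the
#' group labels.
#'
#' @param a,b,c,d non-negative integers: in-group present/absent,
#'   out-group present/absent.
#' @return the one-tailed p-value. A degenerate table with `a + c == 0`
#'   (taxon absent everywhere) gives `p = 1`.
#' @examples
#' fisher_one_tailed_p(10, 0, 0, 10)   # 1 / choose(20, 10)
#' fisher_one_tailed_p(0, 5, 5, 0)     # 1: observed a is the minimum
#' @export
fisher_one_tailed_p <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (anyNA(v) || any(v < 0) || any(v != round(v)))
    stop("contingency counts must be non-negative integers")
  N <- a + b + c + d
  K <- a + c        # samples with the taxon present
  n <- a + b        # in-group size
  hi <- min(n, K)
  if (a > hi) stop("impossible table: a exceeds its margins")
  if (a <= max(0, n + K - N)) return(1)  # tail covers the whole support
  x <- a:hi
  lg <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  m <- max(lg)
  min(1, exp(m) * sum(exp(lg - m)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up control of the false discovery rate: with p-values
#' sorted ascending, `q(i) = min over j >= i of p(j) * m / j`, clipped at
#' 1 and returned in the input order. Tied p-values share an identical q.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, same length and order; `q >= p`
#'   elementwise.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p_values) {
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  o <- order(p_values)
  terms <- (p_values[o] * m) / seq_len(m)
  q_sorted <- pmin(1, rev(cummin(rev(terms))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# half-up rounding (round() is half-even); used for displayed percentages
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Presence percentage within a group
#'
#' The percentage of a group's samples in which a taxon was detected,
#' rounded half-up to one decimal for reporting (core-criterion
#' comparisons elsewhere use the unrounded fraction).
#'
#' @param present_count number of samples with the taxon present.
#' @param group_size total samples in the group (> 0).
#' @return percentage in \[0, 100\], one decimal.
#' @examples
#' presence_fraction(28, 31)  # 90.3
#' @export
presence_fraction <- function(present_count, group_size) {
  if (any(group_size <= 0)) stop("group_size must be positive")
  if (any(present_count < 0) || any(present_count > group_size))
    stop("present_count must lie in [0, group_size]")
  round_half_up(100 * present_count / group_size, 1)
}

#' Is a lineage informative enough to report?
#'
#' Lineages classified no deeper than kingdom (e.g.
#' `"k__Bacteria;p__;c__;o__;f__;g__;s__"`) carry no usable identity and
#' are filtered from the core set. A lineage is informative when at least
#' `min_named_ranks` ranks have non-empty names; the default of 2 keeps
#' taxa resolved only to, say, order level while dropping kingdom-only
#' rows.
#'
#' @param lineage character vector of taxonomy strings (canonicalized
#'   internally).
#' @param min_named_ranks minimum number of named ranks (default 2).
#' @return logical vector.
#' @export
is_informative <- function(lineage, min_named_ranks = 2) {
  canon <- canonicalize_lineage(lineage)
  vapply(canon, function(x) {
    lp <- lineage_parts(x)
    sum(nzchar(lp$name)) >= min_named_ranks
  }, logical(1), USE.NAMES = FALSE)
}

#' Identify the core microbiome of an interest group
#'
#' End-to-end procedure: collapse each input table to unique taxonomy,
#' merge on shared taxa, optionally drop low-depth samples, apply the
#' chosen normalization, binarize to presence/absence, compute a
#' one-tailed Fisher's exact p-value per taxon for enrichment of presence
#' in the in-group, adjust ALL merged taxa together by Benjamini-Hochberg
#' (the FDR family is fixed before any presence filter), then flag as
#' core the taxa with `q < alpha`, in-group presence at or above
#' `min_in_pct`, out-group presence at or below `max_out_pct`, and an
#' informative lineage. Every merged taxon receives a result row whether
#' or not it passes.
#'
#' Presence-threshold comparisons use the exact unrounded fractions;
#' the percentages in the output are display-rounded to one decimal.
#'
#' @param tables an `abundance_table` or list of them (one per study).
#' @param groups a [group_map()].
#' @param alpha FDR threshold on the BH q-value (default 0.05).
#' @param min_in_pct minimum in-group presence percentage (default 90).
#' @param max_out_pct maximum out-group presence percentage (default 100,
#'   i.e. no ceiling).
#' @param detection_threshold minimum count treated as present (default
#'   1, the zero/nonzero rule).
#' @param normalization,norm_depth passed to [normalize_table()].
#' @param min_depth if > 0, samples with fewer total counts are dropped
#'   before normalization.
#' @param min_named_ranks passed to [is_informative()].
#' @param seed integer seed (used only by rarefaction).
#' @return a data.frame of class `coremic_results`, one row per merged
#'   taxon, with columns `taxonomy`, `a`, `b`, `c`, `d`, `p_value`,
#'   `q_value`, `presence_in_pct`, `presence_out_pct`, `informative`,
#'   `is_core`. Attributes `n_in`, `n_out`, `params` and `log` record the
#'   run.
#' @export
identify_core <- function(tables, groups, alpha = 0.05, min_in_pct = 90,
                          max_out_pct = 100, detection_threshold = 1,
                          normalization = "none", norm_depth = NULL,
                          min_depth = 0, min_named_ranks = 2, seed = NULL) {
  if (inherits(tables, "abundance_table")) tables <- list(tables)
  stopifnot(inherits(groups, "group_map"),
            alpha > 0, alpha <= 1,
            min_in_pct >= 0, min_in_pct <= 100,
            max_out_pct >= 0, max_out_pct <= 100)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  for (i in seq_along(tables))
    note("input table %d: %d taxa x %d samples (%s)", i,
         nrow(tables[[i]]$counts), ncol(tables[[i]]$counts),
         paste(tables[[i]]$provenance, collapse = ","))
  collapsed <- lapply(tables, collapse_by_taxonomy)
  for (i in seq_along(collapsed))
    note("collapsed table %d: %d unique taxonomies", i,
         nrow(collapsed[[i]]$counts))
  merged <- merge_tables(collapsed)
  note("merged table: %d shared taxa x %d samples",
       nrow(merged$counts), ncol(merged$counts))
  if (min_depth > 0) {
    before <- sample_ids(merged)
    kept_msgs <- character(0)
    withCallingHandlers(
      merged <- filter_low_depth_samples(merged, min_depth),
      message = function(m) {
        kept_msgs <<- c(kept_msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      })
    log <- c(log, trimws(kept_msgs))
    note("after depth filter (min_depth=%g): %d samples",
         min_depth, ncol(merged$counts))
    groups <- restrict_groups(groups,
                              dropped = setdiff(before, sample_ids(merged)))
  }
  before_norm <- sample_ids(merged)
  merged <- normalize_table(merged, method = normalization,
                            depth = norm_depth, seed = seed)
  note("normalization: %s", normalization)
  groups <- restrict_groups(groups,
                            dropped = setdiff(before_norm,
                                              sample_ids(merged)))
  n_in <- length(groups$interest)
  n_out <- length(groups$outgroup)
  if (n_in == 0L) stop("no in-group samples remain in the merged table")
  if (n_out == 0L) stop("no out-group samples remain in the merged table")
  note("groups: %d in-group vs %d out-group samples", n_in, n_out)
  pm <- binarize(merged, detection_threshold = detection_threshold)
  missing <- setdiff(c(groups$interest, groups$outgroup),
                     colnames(pm$present))
  if (length(missing) > 0L)
    stop("sample(s) in group map missing from the data: ",
         paste(missing, collapse = ", "))
  a <- rowSums(pm$present[, groups$interest, drop = FALSE])
  cc <- rowSums(pm$present[, groups$outgroup, drop = FALSE])
  b <- n_in - a
  d <- n_out - cc
  p <- mapply(fisher_one_tailed_p, a, b, cc, d)
  q <- bh_adjust(p)
  informative <- is_informative(pm$taxonomy,
                                min_named_ranks = min_named_ranks)
  # exact-arithmetic threshold comparisons (no rounding artifacts)
  pass_in <- 100 * a >= min_in_pct * n_in
  pass_out <- 100 * cc <= max_out_pct * n_out
  is_core <- (q < alpha) & pass_in & pass_out & informative
  note("core taxa: %d of %d tested", sum(is_core), length(is_core))
  res <- data.frame(
    taxonomy = pm$taxonomy,
    a = as.integer(a), b = as.integer(b),
    c = as.integer(cc), d = as.integer(d),
    p_value = unname(p), q_value = q,
    presence_in_pct = presence_fraction(a, n_in),
    presence_out_pct = presence_fraction(cc, n_out),
    informative = informative,
    is_core = is_core,
    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("coremic_results", "data.frame")
  attr(res, "n_in") <- n_in
  attr(res, "n_out") <- n_out
  attr(res, "params") <- list(alpha = alpha, min_in_pct = min_in_pct,
                              max_out_pct = max_out_pct,
                              detection_threshold = detection_threshold,
                              normalization = normalization,
                              norm_depth = norm_depth,
                              min_depth = min_depth,
                              min_named_ranks = min_named_ranks,
                              seed = seed)
  attr(res, "log") <- log
  res
}

# drop group-map samples removed by the depth filter; samples never seen
# in the data are kept so the mismatch is caught downstream as an error
restrict_groups <- function(groups, dropped) {
  if (length(dropped) == 0L) return(groups)
  group_map(setdiff(groups$interest, dropped),
            setdiff(groups$outgroup, dropped),
            group_column = groups$group_column,
            interest_label = groups$interest_label,
            outgroup_labels = groups$outgroup_labels,
            mapping = groups$mapping)
}

#' @export
print.coremic_results <- function(x, ...) {
  cat(sprintf("coremic_results: %d taxa tested (%d in-group vs %d out-group samples)\n",
              nrow(x), attr(x, "n_in"), attr(x, "n_out")))
  cat(sprintf("  core taxa: %d\n", sum(x$is_core)))
  if (sum(x$is_core) > 0) {
    core <- x[x$is_core, c("taxonomy", "q_value", "presence_in_pct")]
    core <- core[order(core$q_value, core$taxonomy), ]
    for (i in seq_len(nrow(core)))
      cat(sprintf("    %s  (q=%.3g, present %.1f%%)\n", core$taxonomy[i],
                  core$q_value[i], core$presence_in_pct[i]))
  }
  invisible(x)
}
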