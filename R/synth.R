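#' Specification of a synthetic two-study community
#'
#' Parameters of the seeded generator used to validate the pipeline.
#' The defaults emulate the structure of a two-study rhizosphere
#' meta-analysis: two sample groups of about 30 samples each split across
#' two studies with partially overlapping taxon sets and study-specific
#' sequencing depths, a small set of planted "core" taxa that occur with
#' high probability in the interest group and low probability in the
#' out-group, and a sparse background occurring at equal rates in both.
#'
#' @param n_in,n_out samples in the interest group and out-group.
#' @param n_core number of planted core taxa (present in every study's
#'   taxon set). May be 0 for null simulations.
#' @param n_background number of background taxa.
#' @param p_in,p_out per-sample occurrence probability of a planted taxon
#'   in the in-group / out-group; must satisfy `p_in > p_out` when
#'   `n_core > 0`.
#' @param p_bg occurrence probability of background taxa in both groups.
#' @param depth_mean per-study mean sequencing depth scale; its length
#'   sets the default `n_studies`. Unequal values emulate the platform
#'   depth differences typical of merged studies.
#' @param n_studies number of studies to split taxa and samples across.
#' @param overlap_fraction fraction of background taxa shared by all
#'   studies (planted taxa are always shared, so they survive the merge).
#' @param dispersion negative-binomial size parameter of the count law.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_in = 30, n_out = 30, n_core = 10,
                       n_background = 300, p_in = 0.95, p_out = 0.15,
                       p_bg = 0.5, depth_mean = c(2000, 10000),
                       n_studies = length(depth_mean),
                       overlap_fraction = 0.8, dispersion = 1, seed = 1) {
  probs <- c(p_in = p_in, p_out = p_out, p_bg = p_bg)
  if (any(probs < 0 | probs > 1))
    stop("occurrence probabilities must lie in [0, 1]")
  if (n_core > 0 && p_in <= p_out)
    stop("planted taxa require p_in > p_out")
  if (n_in < 1 || n_out < 1) stop("each group needs at least one sample")
  if (n_core < 0 || n_background < 1) stop("taxon counts must be positive")
  if (n_core + n_background < 1) stop("no taxa to generate")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must lie in [0, 1]")
  if (length(depth_mean) != n_studies)
    depth_mean <- rep_len(depth_mean, n_studies)
  if (any(depth_mean <= 0)) stop("depth_mean must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  structure(list(n_in = n_in, n_out = n_out, n_core = n_core,
                 n_background = n_background, p_in = p_in, p_out = p_out,
                 p_bg = p_bg, depth_mean = depth_mean,
                 n_studies = n_studies,
                 overlap_fraction = overlap_fraction,
                 dispersion = dispersion, seed = seed),
            class = "synth_spec")
}

.synth_phyla <- c("Proteobacteria", "Actinobacteria", "Bacteroidetes",
                  "Acidobacteria", "Firmicutes")

synth_lineage <- function(kind, i) {
  phy <- .synth_phyla[(i - 1L) %% length(.synth_phyla) + 1L]
  sprintf(
    "k__Bacteria;p__%s;c__%sia;o__%sales;f__%saceae;g__%s%03d;s__",
    phy, phy, phy, phy, kind, i)
}

#' Generate a synthetic multi-study dataset with planted core taxa
#'
#' Per taxon and sample, presence is drawn Bernoulli with the
#' group-appropriate probability (`p_in`/`p_out` for planted taxa,
#' `p_bg` for background); conditional on presence, the count is
#' `1 + NegBinom(size = dispersion, mu = depth_mean[study] / n_taxa)`,
#' i.e. a shifted positive count law whose scale tracks the study's
#' depth. Taxa receive synthetic Greengenes-style lineages with unique
#' genus names; each study's table contains every planted taxon, the
#' shared background and a study-specific remainder, so that the
#' intersection merge exercises real taxon loss.
#'
#' @param spec a [synth_spec()].
#' @return a list with components `tables` (list of `abundance_table`,
#'   one per study), `groups` (a [group_map()] labelling the interest
#'   group `"Swg"` and out-group `"NonSwg"`), `truth` (a `planted_truth`
#'   with the planted lineages and their realized per-group presence
#'   counts), and `study_of` (named vector mapping sample id to study).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, function() {
    in_ids <- sprintf("Swg_%02d", seq_len(spec$n_in))
    out_ids <- sprintf("NonSwg_%02d", seq_len(spec$n_out))
    study_of <- c(
      stats::setNames((seq_len(spec$n_in) - 1L) %% spec$n_studies + 1L,
                      in_ids),
      stats::setNames((seq_len(spec$n_out) - 1L) %% spec$n_studies + 1L,
                      out_ids))
    planted <- if (spec$n_core > 0)
      vapply(seq_len(spec$n_core), function(i) synth_lineage("Core", i),
             character(1)) else character(0)
    background <- vapply(seq_len(spec$n_background),
                         function(i) synth_lineage("Bg", i), character(1))
    n_shared_bg <- round(spec$overlap_fraction * spec$n_background)
    shared_bg <- background[seq_len(n_shared_bg)]
    specific <- background[setdiff(seq_len(spec$n_background),
                                   seq_len(n_shared_bg))]
    specific_of <- if (length(specific) > 0)
      (seq_along(specific) - 1L) %% spec$n_studies + 1L else integer(0)

    # realized presence is drawn once per taxon x sample and reused for
    # both the tables and the ground truth
    all_ids <- c(in_ids, out_ids)
    is_in <- c(rep(TRUE, spec$n_in), rep(FALSE, spec$n_out))
    taxa_all <- c(planted, background)
    prob <- matrix(spec$p_bg, length(taxa_all), length(all_ids),
                   dimnames = list(taxa_all, all_ids))
    if (spec$n_core > 0) {
      prob[planted, is_in] <- spec$p_in
      prob[planted, !is_in] <- spec$p_out
    }
    present <- matrix(stats::rbinom(length(prob), 1, prob) == 1,
                      nrow(prob), ncol(prob), dimnames = dimnames(prob))

    tables <- lapply(seq_len(spec$n_studies), function(s) {
      taxa_s <- c(planted, shared_bg, specific[specific_of == s])
      samples_s <- all_ids[study_of[all_ids] == s]
      mu <- spec$depth_mean[s] / length(taxa_s)
      pres_s <- present[taxa_s, samples_s, drop = FALSE]
      counts <- matrix(0, length(taxa_s), length(samples_s),
                       dimnames = list(NULL, samples_s))
      n_pres <- sum(pres_s)
      counts[pres_s] <- 1 + stats::rnbinom(n_pres, size = spec$dispersion,
                                           mu = mu)
      abundance_table(counts, taxonomy = taxa_s,
                      provenance = sprintf("study%d", s))
    })
    truth <- structure(
      list(taxa = planted,
           presence_in = rowSums(present[planted, is_in, drop = FALSE]),
           presence_out = rowSums(present[planted, !is_in, drop = FALSE])),
      class = "planted_truth")
    groups <- group_map(in_ids, out_ids, group_column = "Plant",
                        interest_label = "Swg", outgroup_labels = "NonSwg")
    list(tables = tables, groups = groups, truth = truth,
         study_of = study_of)
  })
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("planted_truth: %d planted core taxa\n", length(x$taxa)))
  invisible(x)
}

#' Score core-test results against the planted truth
#'
#' @param results a `coremic_results` data.frame from [identify_core()].
#' @param truth a `planted_truth` from [generate_dataset()].
#' @return a list of class `recovery_summary`: `sensitivity` (planted
#'   taxa flagged core / planted), `fdp` (non-planted flagged / flagged;
#'   0 when nothing is flagged), `n_flagged`, `n_planted`.
#' @export
evaluate_recovery <- function(results, truth) {
  stopifnot(inherits(truth, "planted_truth"))
  if (length(truth$taxa) == 0L) stop("empty planted truth")
  flagged <- results$taxonomy[results$is_core]
  sensitivity <- mean(truth$taxa %in% flagged)
  fdp <- if (length(flagged) == 0L) 0 else mean(!(flagged %in% truth$taxa))
  structure(list(sensitivity = sensitivity, fdp = fdp,
                 n_flagged = length(flagged),
                 n_planted = length(truth$taxa)),
            class = "recovery_summary")
}

#' Aggregate recovery summaries over replicate seeds
#'
#' @param summaries list of `recovery_summary` objects.
#' @return a list with the mean `sensitivity` and `fdp` and the number of
#'   replicates `n`.
#' @export
aggregate_recovery <- function(summaries) {
  stopifnot(length(summaries) > 0,
            all(vapply(summaries, inherits, logical(1),
                       "recovery_summary")))
  list(sensitivity = mean(vapply(summaries, `[[`, numeric(1),
                                 "sensitivity")),
       fdp = mean(vapply(summaries, `[[`, numeric(1), "fdp")),
       n = length(summaries))
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("recovery: sensitivity %.3f, FDP %.3f (%d flagged / %d planted)\n",
              x$sensitivity, x$fdp, x$n_flagged, x$n_planted))
  invisible(x)
}
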