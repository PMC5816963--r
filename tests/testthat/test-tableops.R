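test_that("lineage canonicalization normalizes prefixes and whitespace", {
  expect_identical(canonicalize_lineage("k__Bacteria; p__Proteobacteria"),
                   "k__Bacteria;p__Proteobacteria")
  expect_identical(canonicalize_lineage("k_Bacteria;p_;c_;o_;f_;g_;s_"),
                   "k__Bacteria;p__;c__;o__;f__;g__;s__")
  # idempotence over a spread of spellings
  raws <- c("k_Bacteria;p_X", " k__B ; p__Y", "p_Proteobacteria;c_Gamma",
            "k__Bacteria;p__;c__;o__;f__;g__;s__")
  once <- canonicalize_lineage(raws)
  expect_identical(canonicalize_lineage(once), once)
  expect_error(canonicalize_lineage(""), "empty")
})

test_that("collapse sums duplicate-taxonomy rows and conserves totals", {
  m <- matrix(c(1, 2, 3, 4, 0, 5), nrow = 3, byrow = TRUE,
              dimnames = list(NULL, c("S1", "S2")))
  tab <- abundance_table(m, taxonomy = c("k__B;p__L1", "k_B;p_L1",
                                         "k__B;p__L2"))
  col <- collapse_by_taxonomy(tab)
  expect_identical(col$taxonomy, c("k__B;p__L1", "k__B;p__L2"))
  expect_equal(unname(col$counts), matrix(c(4, 6, 0, 5), nrow = 2,
                                          byrow = TRUE))
  # already-unique tables pass through unchanged
  expect_equal(unname(collapse_by_taxonomy(col)$counts),
               unname(col$counts))
  # property: per-sample totals conserved on random tables with duplicates
  for (seed in 1:5) {
    rt <- rand_table(40, 8, seed = seed, dup_fraction = 0.4)
    expect_equal(sample_sums(collapse_by_taxonomy(rt)), sample_sums(rt))
  }
})

test_that("merge keeps the intersection of taxonomies across tables", {
  mk <- function(taxa, samples, seed) {
    set.seed(seed)
    abundance_table(
      matrix(rpois(length(taxa) * length(samples), 4),
             length(taxa), dimnames = list(NULL, samples)),
      taxonomy = taxa)
  }
  t1 <- mk(c("k__B;p__X", "k__B;p__Y", "k__B;p__Z"), c("S1", "S2"), 1)
  t2 <- mk(c("k__B;p__Y", "k__B;p__Z", "k__B;p__W"), c("S3", "S4"), 2)
  m12 <- merge_tables(list(t1, t2))
  expect_setequal(m12$taxonomy, c("k__B;p__Y", "k__B;p__Z"))
  expect_identical(sample_ids(m12), c("S1", "S2", "S3", "S4"))
  expect_lte(nrow(m12$counts), min(nrow(t1$counts), nrow(t2$counts)))

  # single-table identity
  m1 <- merge_tables(list(t1))
  expect_equal(unname(m1$counts), unname(t1$counts))

  # permutation equivalence: cell values agree regardless of table order
  m21 <- merge_tables(list(t2, t1))
  for (tax in m12$taxonomy) {
    i12 <- match(tax, m12$taxonomy)
    i21 <- match(tax, m21$taxonomy)
    expect_equal(m12$counts[i12, sample_ids(m12)],
                 m21$counts[i21, sample_ids(m12)])
  }

  t3 <- mk(c("k__B;p__Q"), c("S5"), 3)
  expect_error(merge_tables(list(t1, t3)), "no shared taxonomies")
  t4 <- mk(c("k__B;p__X"), c("S1"), 4)
  expect_error(merge_tables(list(t1, t4)), "duplicate sample")
  dup <- abundance_table(matrix(1:4, 2, dimnames = list(NULL, c("A", "B"))),
                         taxonomy = rep("k__B;p__X", 2))
  expect_error(merge_tables(list(dup)), "collapse_by_taxonomy")
})

test_that("low-depth samples are removed with logging", {
  m <- matrix(0, nrow = 1, ncol = 4,
              dimnames = list(NULL, sprintf("S%d", 1:4)))
  m[1, ] <- c(48, 75, 1200, 1500)
  tab <- abundance_table(m, taxonomy = "k__B;p__X")
  expect_message(kept <- filter_low_depth_samples(tab, 1150),
                 "S1 \\(48\\).*S2 \\(75\\)")
  expect_identical(sample_ids(kept), c("S3", "S4"))
  expect_identical(sample_ids(filter_low_depth_samples(tab, 0)),
                   sample_ids(tab))
  expect_error(filter_low_depth_samples(tab, 1e6), "all samples removed")
})

test_that("normalization: identity, total-sum, seeded rarefaction", {
  m <- matrix(c(2, 3, 5, 1, 0, 9), nrow = 3,
              dimnames = list(NULL, c("S1", "S2")))
  tab <- abundance_table(m, taxonomy = sprintf("k__B;p__%d", 1:3))
  expect_identical(normalize_table(tab, "none")$counts, tab$counts)

  ts <- normalize_table(tab, "total_sum")
  expect_equal(unname(ts$counts[, "S1"]), c(0.2, 0.3, 0.5))
  expect_equal(unname(colSums(ts$counts)), c(1, 1))
  zero <- abundance_table(matrix(c(1, 0), 1, dimnames = list(NULL, c("A", "B"))),
                          taxonomy = "k__B;p__X")
  expect_error(normalize_table(zero, "total_sum"), "all-zero")

  big <- rand_table(30, 6, seed = 9)
  depth <- min(sample_sums(big))
  r1 <- normalize_table(big, "rarefy", depth = depth, seed = 42)
  r2 <- normalize_table(big, "rarefy", depth = depth, seed = 42)
  expect_identical(r1$counts, r2$counts)
  expect_true(all(colSums(r1$counts) == depth))
  expect_error(normalize_table(big, "rarefy", depth = 0), "positive")
  expect_warning(
    shallow <- normalize_table(big, "rarefy",
                               depth = max(sample_sums(big)), seed = 1),
    "below rarefaction depth")
  expect_lt(ncol(shallow$counts), ncol(big$counts))
})

test_that("rank collapse sums sublineages and conserves totals", {
  m <- matrix(c(1, 2, 3, 4, 10, 0), nrow = 3, byrow = TRUE,
              dimnames = list(NULL, c("S1", "S2")))
  tab <- abundance_table(m, taxonomy = c(
    "k__Bacteria;p__Bacteroidetes;c__C1;o__O1;f__F1;g__G1;s__",
    "k__Bacteria;p__Bacteroidetes;c__C1;o__O1;f__F2;g__G2;s__",
    "k__Bacteria;p__Proteobacteria;c__C2;o__O2;f__F3;g__G3;s__"))
  phy <- collapse_at_rank(tab, "phylum")
  expect_identical(phy$taxonomy,
                   c("k__Bacteria;p__Bacteroidetes",
                     "k__Bacteria;p__Proteobacteria"))
  expect_equal(unname(phy$counts[1, ]), c(4, 6))
  expect_equal(sample_sums(phy), sample_sums(tab))
  # species-level collapse == plain taxonomy collapse
  expect_equal(collapse_at_rank(tab, "species")$counts,
               collapse_by_taxonomy(tab)$counts)
  for (seed in 1:3) {
    rt <- rand_table(25, 5, seed = seed)
    expect_equal(sample_sums(collapse_at_rank(rt, "class")),
                 sample_sums(rt))
  }
})

test_that("binarization follows the detection threshold and is idempotent", {
  m <- matrix(c(0, 1, 7), nrow = 1, dimnames = list(NULL, c("A", "B", "C")))
  tab <- abundance_table(m, taxonomy = "k__B;p__X")
  expect_equal(unname(binarize(tab)$present[1, ]), c(FALSE, TRUE, TRUE))
  expect_equal(unname(binarize(tab, 5)$present[1, ]),
               c(FALSE, FALSE, TRUE))
  expect_error(binarize(tab, 0))
  # reinterpreting a presence matrix as 0/1 counts reproduces itself
  pm <- binarize(tab)
  again <- binarize(abundance_table(pm$present * 1, taxonomy = pm$taxonomy))
  expect_identical(again$present, pm$present)
})

test_that("presence under threshold 1 is invariant to total-sum scaling", {
  rt <- rand_table(30, 8, seed = 5)
  if (any(colSums(rt$counts) == 0))
    rt$counts[1, colSums(rt$counts) == 0] <- 1
  raw <- binarize(rt)$present
  scaled <- normalize_table(rt, "total_sum")
  expect_identical(binarize(scaled)$present, raw)
})
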