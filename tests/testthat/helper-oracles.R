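# Independent oracles used to validate the package's own statistics.

# Brute-force one-tailed Fisher p: enumerate every table with the observed
# fixed margins and sum the hypergeometric probabilities of those at least
# as extreme as a. Uses choose()/division directly - a separate route from
# the package's log-space tail summation.
bf_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  N <- a + b + c + d
  xs <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- choose(r1, xs) * choose(N - r1, c1 - xs) / choose(N, c1)
  sum(probs[xs >= a])
}

# Textbook BH step-up: q(i) = min(1, min over j >= i of p(j)*m/j),
# computed per index rather than by cumulative minima.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(m), function(i) {
    min(1, min((ps[i:m] * m) / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- qs
  q
}

# random abundance table for property tests
rand_table <- function(n_taxa, n_samples, seed, dup_fraction = 0,
                       provenance = "rand") {
  set.seed(seed)
  lin <- sprintf("k__Bacteria;p__P%d;c__;o__;f__;g__G%03d;s__",
                 seq_len(n_taxa) %% 4 + 1, seq_len(n_taxa))
  if (dup_fraction > 0) {
    ndup <- ceiling(dup_fraction * n_taxa)
    lin[sample(n_taxa, ndup)] <- sample(lin, ndup, replace = TRUE)
  }
  m <- matrix(rpois(n_taxa * n_samples, 3) *
                rbinom(n_taxa * n_samples, 1, 0.6),
              n_taxa, n_samples,
              dimnames = list(NULL, sprintf("S%02d", seq_len(n_samples))))
  abundance_table(m, taxonomy = lin, provenance = provenance)
}

# write a minimal BIOM v1 JSON file; data is a base R matrix
write_tiny_biom <- function(path, counts, taxonomy,
                            matrix_type = c("sparse", "dense"),
                            taxonomy_as_list = FALSE,
                            drop_taxonomy_for = integer(0)) {
  matrix_type <- match.arg(matrix_type)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    md <- if (i %in% drop_taxonomy_for) {
      list(other = "x")
    } else if (taxonomy_as_list) {
      list(taxonomy = as.list(strsplit(taxonomy[i], ";", fixed = TRUE)[[1]]))
    } else {
      list(taxonomy = taxonomy[i])
    }
    list(id = sprintf("OTU_%d", i), metadata = md)
  })
  data <- if (matrix_type == "dense") {
    lapply(seq_len(nrow(counts)), function(i) as.list(unname(counts[i, ])))
  } else {
    nz <- which(counts != 0, arr.ind = TRUE)
    lapply(seq_len(nrow(nz)), function(k) {
      list(nz[k, 1] - 1L, nz[k, 2] - 1L,
           unname(counts[nz[k, 1], nz[k, 2]]))
    })
  }
  obj <- list(id = "tiny", format = "Biological Observation Matrix 1.0.0",
              format_url = "http://biom-format.org", type = "OTU table",
              generated_by = "test", date = "",
              matrix_type = matrix_type,
              matrix_element_type = "float", shape = dim(counts),
              rows = rows,
              columns = lapply(colnames(counts), function(s)
                list(id = s, metadata = NULL)),
              data = data)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                              digits = NA), path)
  path
}

write_tiny_mapping <- function(path, ids, groups, column = "Plant") {
  writeLines(c(paste0("#SampleID\t", column),
               paste(ids, groups, sep = "\t")), path)
  path
}
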