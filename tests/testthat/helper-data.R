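# Small builders shared across test files.

toy_sites <- function(p, chrom = "chr01", pos = seq_len(p) * 100L) {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
             stringsAsFactors = FALSE)
}

toy_geno <- function(dosage, labels = NULL, depth = NULL, chrom = "chr01",
                     pos = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("s%02d", seq_len(nrow(dosage)))
  }
  if (is.null(pos)) pos <- seq_len(ncol(dosage)) * 100L
  geno_matrix(dosage, toy_sites(ncol(dosage), chrom = chrom, pos = pos),
              labels = labels, depth = depth)
}

# A random genotype matrix (for round-trip / property loops).
random_geno <- function(n = 6L, p = 10L, missing_rate = 0.1,
                        with_depth = FALSE) {
  d <- matrix(sample(0:2, n * p, replace = TRUE), nrow = n)
  d[matrix(runif(n * p) < missing_rate, nrow = n)] <- NA_integer_
  depth <- if (with_depth) matrix(rpois(n * p, 12), nrow = n)
  rownames(d) <- sprintf("s%02d", seq_len(n))
  chrom <- sort(sample(sprintf("chr%02d", 1:3), p, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(p), chrom), function(i) {
    sort(sample.int(1e6L, length(i)))
  }), use.names = FALSE)
  geno_matrix(d, data.frame(chrom = sort(chrom), pos = pos,
                            ref = "A", alt = "G"),
              depth = depth)
}

# Default two-panel dataset used by several estimation tests; built once.
panels_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_dataset(synth_config(n_hybrids = 0L, seed = 101L))
    }
    cache
  }
})

# Curated (ancestral-MAF filtered + pruned) version of the fixture.
curated_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- panels_fixture()$geno
      anc <- c(which_label(g, "wild"), which_label(g, "vinifera"))
      g <- filter_by_maf(g, 0.10, samples = anc, strict = TRUE)
      cache <<- g[, window_prune(g)]
    }
    cache
  }
})
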