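#' Construct a genotype dosage matrix
#'
#' The central container of the package: an ordered set of samples genotyped
#' at an ordered set of biallelic sites, stored as a samples-by-sites matrix
#' of alternate-allele dosages (0, 1, 2, or `NA` for missing), with per-site
#' records, per-sample population labels and optional per-cell read depth.
#'
#' @param dosage Integer matrix, samples in rows, sites in columns. Values
#'   must be 0, 1, 2 or `NA`. Row names, if present, are used as sample ids.
#' @param sites Data frame with one row per site and columns `chrom`,
#'   `pos` (1-based bp), `ref` and `alt` (allele strings). A `variant_class`
#'   column (`"snp"` or `"indel"`) is recomputed from the alleles.
#' @param samples Character vector of unique sample ids; defaults to the
#'   dosage row names.
#' @param labels Character vector of population labels, one per sample, from
#'   `"wild"`, `"vinifera"`, `"hybrid"`, `"unknown"` (case-insensitive).
#'   Defaults to `"unknown"`.
#' @param depth Optional integer matrix of per-cell read depths, same
#'   dimensions as `dosage`.
#'
#' @return An object of class `geno_matrix`: a list with elements `dosage`,
#'   `sites`, `samples`, `labels` and (optionally) `depth`.
#' @export
#' @examples
#' g <- geno_matrix(
#'   dosage = rbind(s1 = c(0L, 1L), s2 = c(2L, NA)),
#'   sites = data.frame(chrom = "chr1", pos = c(100L, 200L),
#'                      ref = c("A", "T"), alt = c("G", "C"))
#' )
#' n_sites(g)
geno_matrix <- function(dosage, sites, samples = rownames(dosage),
                        labels = NULL, depth = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(samples)) {
    samples <- paste0("sample", seq_len(nrow(dosage)))
  }
  samples <- as.character(samples)
  if (anyDuplicated(samples)) {
    stop("sample ids must be unique", call. = FALSE)
  }
  if (length(samples) != nrow(dosage)) {
    stop("length(samples) must equal nrow(dosage)", call. = FALSE)
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols)) {
    stop("sites is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(sites) != ncol(dosage)) {
    stop("nrow(sites) must equal ncol(dosage)", call. = FALSE)
  }
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (any(sites$pos < 1L, na.rm = TRUE)) {
    stop("site positions must be >= 1", call. = FALSE)
  }
  sites$ref <- as.character(sites$ref)
  sites$alt <- as.character(sites$alt)
  # biallelic by construction: exactly one alt allele per record
  if (any(grepl(",", sites$alt, fixed = TRUE))) {
    stop("multi-allelic site in 'sites'; one alt allele per record",
         call. = FALSE)
  }
  sites$variant_class <- variant_class(sites$ref, sites$alt)
  rownames(sites) <- NULL
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("dosage values must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- rep("unknown", length(samples))
  }
  labels <- normalize_labels(labels)
  if (length(labels) != length(samples)) {
    stop("length(labels) must equal the number of samples", call. = FALSE)
  }
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    if (!identical(dim(depth), dim(dosage))) {
      stop("depth must have the same dimensions as dosage", call. = FALSE)
    }
    if (any(depth < 0L, na.rm = TRUE)) {
      stop("depth values must be >= 0", call. = FALSE)
    }
    dimnames(depth) <- list(samples, site_ids(sites))
  }
  dimnames(dosage) <- list(samples, site_ids(sites))
  structure(
    list(dosage = dosage, sites = sites, samples = samples,
         labels = labels, depth = depth),
    class = "geno_matrix"
  )
}

label_vocabulary <- c("wild", "vinifera", "hybrid", "unknown")

normalize_labels <- function(labels) {
  labels <- tolower(as.character(labels))
  bad <- setdiff(unique(labels), label_vocabulary)
  if (length(bad)) {
    stop("unknown label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(label_vocabulary, collapse = ", "),
         call. = FALSE)
  }
  labels
}

variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snp", "indel")
}

site_ids <- function(sites) {
  paste(sites$chrom, sites$pos, sep = ":")
}

#' @rdname geno_matrix
#' @param x A `geno_matrix`.
#' @export
n_samples <- function(x) length(x$samples)

#' @rdname geno_matrix
#' @export
n_sites <- function(x) nrow(x$sites)

#' Subset a genotype matrix
#'
#' Subsets samples (`i`) and/or sites (`j`), keeping dosage, depth, site
#' records and labels aligned.
#'
#' @param x A `geno_matrix`.
#' @param i Sample index (integer, logical, or sample ids).
#' @param j Site index (integer or logical).
#' @param ... Unused.
#' @return A `geno_matrix`.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_sites(x))
  if (is.character(i)) i <- match(i, x$samples)
  if (anyNA(i)) stop("unknown sample id in subset", call. = FALSE)
  geno_matrix(
    dosage = x$dosage[i, j, drop = FALSE],
    sites = x$sites[j, , drop = FALSE],
    samples = x$samples[i],
    labels = x$labels[i],
    depth = if (!is.null(x$depth)) x$depth[i, j, drop = FALSE]
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  tab <- table(factor(x$labels, levels = label_vocabulary))
  cls <- table(factor(x$sites$variant_class, levels = c("snp", "indel")))
  cat(sprintf("geno_matrix: %d samples x %d sites (%d SNPs, %d indels)\n",
              n_samples(x), n_sites(x), cls[["snp"]], cls[["indel"]]))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  missing: %.1f%%; depth: %s\n",
              100 * mean(is.na(x$dosage)),
              if (is.null(x$depth)) "absent" else "present"))
  invisible(x)
}

#' Per-sample and per-site missingness
#'
#' @param x A `geno_matrix`.
#' @return Numeric vector of missing fractions.
#' @export
sample_missingness <- function(x) rowMeans(is.na(x$dosage))

#' @rdname sample_missingness
#' @export
site_missingness <- function(x) colMeans(is.na(x$dosage))

#' Indices of samples carrying a given label
#' @param x A `geno_matrix`.
#' @param label Label(s) to match ("wild", "vinifera", "hybrid", "unknown").
#' @return Integer vector of sample indices.
#' @export
which_label <- function(x, label) {
  which(x$labels %in% normalize_labels(label))
}

# Run code with a temporarily seeded RNG; NULL seed leaves the RNG alone.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
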