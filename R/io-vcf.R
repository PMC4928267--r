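#' Read a VCF into a genotype dosage matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}), keeps biallelic records only and
#' decodes GT into alternate-allele dosages. Phased ("|") and unphased ("/")
#' genotypes are treated identically; half-calls (e.g. "./1") and "./." are
#' treated as missing. Per-genotype DP is captured when the FORMAT declares it.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param keep_indels Keep biallelic indel records? If `FALSE`, records where
#'   either allele is longer than one base are dropped.
#' @return A [geno_matrix] with all labels set to `"unknown"`.
#' @export
#' @seealso [write_vcf()], [read_labels()]
read_vcf <- function(path, keep_indels = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE),
    error = function(e) {
      stop("malformed VCF '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  if (ncol(vcf@gt) < 2L) {
    stop("VCF '", path, "' contains no sample columns", call. = FALSE)
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {   # single-record files come back as a vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & alt != "." & !grepl(",", alt, fixed = TRUE) &
    !grepl("<", alt, fixed = TRUE)
  if (!keep_indels) {
    keep <- keep & nchar(fix[, "REF"]) == 1L & nchar(alt) == 1L
  }
  if (!any(keep)) stop("no biallelic records in '", path, "'", call. = FALSE)
  vcf <- vcf[keep, ]
  fix <- fix[keep, , drop = FALSE]

  gt <- vcfR::extract.gt(vcf, element = "GT")
  dosage <- decode_gt(gt)
  depth <- NULL
  if (any(grepl("(^|:)DP(:|$)", vcf@gt[, "FORMAT"]))) {
    dp <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    )
    depth <- t(dp)
    storage.mode(depth) <- "integer"
  }
  sites <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  geno_matrix(dosage = t(dosage), sites = sites, samples = colnames(gt),
              depth = depth)
}

# GT strings (sites x samples) -> integer dosage matrix.
decode_gt <- function(gt) {
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  ok <- grepl("^[0-9.]+([/|][0-9.]+)?$", u)
  if (any(!ok)) {
    bad <- u[!ok][1]
    idx <- which(gt == bad, arr.ind = TRUE)[1, ]
    stop(sprintf("cannot decode GT '%s' (record %d, sample '%s')",
                 bad, idx[1], colnames(gt)[idx[2]]), call. = FALSE)
  }
  map <- vapply(u, function(g) {
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) != 2L || any(alleles == ".")) return(NA_integer_)
    a <- as.integer(alleles)
    if (any(a > 1L)) {
      stop("GT '", g, "' references a non-primary alternate allele in a ",
           "record kept as biallelic", call. = FALSE)
    }
    sum(a)
  }, integer(1))
  out <- matrix(map[match(as.vector(gt), u)], nrow = nrow(gt))
  dimnames(out) <- dimnames(gt)
  out
}

#' Write a genotype matrix as plain-text VCF 4.2
#'
#' Emits one biallelic record per site with a GT (and, when depth is present,
#' DP) FORMAT field. `read_vcf(write_vcf(x))` reproduces samples, sites,
#' dosage and depth exactly.
#'
#' @param x A [geno_matrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "geno_matrix"))
  if (n_sites(x) == 0L || n_samples(x) == 0L) {
    stop("refusing to write an empty genotype matrix", call. = FALSE)
  }
  gt_string <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow = n_samples(x), ncol = n_sites(x))
  obs <- !is.na(x$dosage)
  gt[obs] <- gt_string[as.character(x$dosage[obs])]
  has_dp <- !is.null(x$depth)
  if (has_dp) {
    dp <- ifelse(is.na(x$depth), ".", as.character(x$depth))
    gt <- matrix(paste(gt, dp, sep = ":"), nrow = n_samples(x))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=grapeAncestry",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_dp)
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  )
  body <- paste(
    x$sites$chrom, x$sites$pos, ".", x$sites$ref, x$sites$alt, ".", ".", ".",
    if (has_dp) "GT:DP" else "GT",
    apply(gt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
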