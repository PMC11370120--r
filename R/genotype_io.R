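#' Read a VCF file into a variant record table
#'
#' Thin wrapper over [vcfR::read.vcfR()] returning a column-oriented set
#' of variant records: one row per site with chromosome, position,
#' alleles, the GATK-style INFO annotations used by [hard_filter()]
#' (QD, MQ, FS, SOR, MQRankSum, ReadPosRankSum; `NA` when absent) and
#' per-individual ALT-dosages (`NA` for missing or uncalled genotypes).
#' Multi-allelic sites are retained and flagged; [qc_filter()] removes
#' them.
#'
#' @param path path to a VCF (v4.x) file, plain or bgzipped.
#' @return List of class `variant_records` with elements `sites` (data
#'   frame), `dosages` (sites x individuals matrix) and
#'   `individual_ids`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF '", path,
                                         "': ", conditionMessage(e)))
  if (nrow(v@fix) == 0L) {
    warning("VCF contains no variant records: ", path)
    return(empty_variant_records())
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ann <- sapply(c("QD", "MQ", "FS", "SOR", "MQRankSum", "ReadPosRankSum"),
                function(k) suppressWarnings(
                  as.numeric(vcfR::extract.info(v, element = k))))
  ann <- matrix(ann, nrow = nrow(fix),
                dimnames = list(NULL, c("QD", "MQ", "FS", "SOR",
                                        "MQRankSum", "ReadPosRankSum")))
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- gt_to_dosage(gt)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  sites <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID),
    ref = fix$REF, alt = fix$ALT, multiallelic = multi,
    stringsAsFactors = FALSE)
  sites <- cbind(sites, as.data.frame(ann))
  structure(list(sites = sites, dosages = dos,
                 individual_ids = colnames(gt)),
            class = "variant_records")
}

empty_variant_records <- function() {
  structure(list(sites = data.frame(chrom = character(), pos = integer(),
                                    id = character(), ref = character(),
                                    alt = character(),
                                    multiallelic = logical()),
                 dosages = matrix(NA_integer_, 0, 0),
                 individual_ids = character()),
            class = "variant_records")
}

# Diploid GT strings to ALT-dosage; any allele index > 1 (multi-allelic
# call) and any missing allele give NA -- such sites fall to qc_filter.
gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  num <- function(a) ifelse(a == "0", 0L, ifelse(a == "1", 1L, NA_integer_))
  d <- num(a1) + num(a2)
  matrix(d, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' @export
print.variant_records <- function(x, ...) {
  cat("variant_records:", nrow(x$sites), "sites x",
      length(x$individual_ids), "individuals\n")
  invisible(x)
}

# GATK-style hard-filter thresholds; a record fails if any *present*
# annotation violates its bound (absent annotations pass, following the
# VariantFiltration convention).
.hard_filter_rules <- list(
  SNP = list(QD = c("lt", 2.0), MQ = c("lt", 40.0), FS = c("gt", 60.0),
             SOR = c("gt", 3.0), MQRankSum = c("lt", -12.5),
             ReadPosRankSum = c("lt", -8.0)),
  InDel = list(QD = c("lt", 2.0), FS = c("gt", 200.0), SOR = c("gt", 10.0),
               MQRankSum = c("lt", -12.5), ReadPosRankSum = c("lt", -8.0))
)

#' Hard-filter variant records on INFO annotations
#'
#' Applies the GATK-style hard filters: SNPs are removed when QD < 2.0,
#' MQ < 40.0, FS > 60.0, SOR > 3.0, MQRankSum < -12.5 or
#' ReadPosRankSum < -8.0; InDels when QD < 2.0, FS > 200.0, SOR > 10.0,
#' MQRankSum < -12.5 or ReadPosRankSum < -8.0. A record with an absent
#' annotation passes that rule.
#'
#' @param records a `variant_records` object from [read_vcf()].
#' @param kind `"SNP"` or `"InDel"`: which ruleset to apply.
#' @return The filtered `variant_records`.
#' @export
hard_filter <- function(records, kind = c("SNP", "InDel")) {
  kind <- match.arg(kind)
  stopifnot(inherits(records, "variant_records"))
  rules <- .hard_filter_rules[[kind]]
  keep <- rep(TRUE, nrow(records$sites))
  for (nm in names(rules)) {
    v <- records$sites[[nm]]
    if (is.null(v)) next
    thr <- as.numeric(rules[[nm]][2])
    bad <- if (rules[[nm]][1] == "lt") v < thr else v > thr
    keep <- keep & !(bad %in% TRUE)  # NA annotation passes
  }
  subset_records(records, keep)
}

subset_records <- function(records, keep) {
  records$sites <- records$sites[keep, , drop = FALSE]
  records$dosages <- records$dosages[keep, , drop = FALSE]
  records
}

#' Classify markers as SNP or InDel
#'
#' A marker is a SNP iff both alleles are single bases; anything else
#' (length change, multi-base substitution) is treated as an InDel.
#'
#' @param ref,alt allele strings (vectorized).
#' @return Character vector of `"SNP"`/`"InDel"`.
#' @export
classify_marker <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt))) stop("empty allele string")
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "InDel")
}

#' Marker quality control
#'
#' Applies the four-rule marker QC: (i) biallelic sites only, (ii) 100%
#' genotyping rate (several downstream methods tolerate no missing
#' values), (iii) autosomal markers only, and (iv) InDel length
#' `max(nchar(ref), nchar(alt)) - 1` strictly below `max_indel_bp`.
#'
#' @param x a `variant_records` object or a [genotype_matrix()] (for
#'   matrix input the biallelic rule is structural).
#' @param autosomes chromosome whitelist; default `"1"`..`"26"` (sheep
#'   autosome count).
#' @param max_indel_bp InDel length bound (exclusive); default 50.
#' @return A [genotype_matrix()] with no missing dosages.
#' @export
qc_filter <- function(x, autosomes = as.character(1:26), max_indel_bp = 50L) {
  if (inherits(x, "variant_records")) {
    sites <- x$sites
    keep <- !sites$multiallelic &
      sites$chrom %in% autosomes &
      rowSums(is.na(x$dosages)) == 0L
    len <- pmax(nchar(sites$ref), nchar(sites$alt)) - 1L
    keep <- keep & (len == 0L | len < max_indel_bp)
    if (!any(keep)) stop("marker QC removed every marker")
    sites <- sites[keep, , drop = FALSE]
    gm <- genotype_matrix(t(x$dosages[keep, , drop = FALSE]),
                          sites[, c("id", "chrom", "pos", "ref", "alt")])
    ord <- order(chrom_key(gm$map$chrom), gm$map$pos)
    return(subset_genotypes(gm, markers = ord))
  }
  stopifnot(inherits(x, "genotype_matrix"))
  len <- pmax(nchar(x$map$ref), nchar(x$map$alt)) - 1L
  keep <- x$map$chrom %in% autosomes &
    colSums(is.na(x$dosages)) == 0L &
    (len == 0L | len < max_indel_bp)
  if (!any(keep)) stop("marker QC removed every marker")
  out <- subset_genotypes(x, markers = which(keep))
  ord <- order(chrom_key(out$map$chrom), out$map$pos)
  subset_genotypes(out, markers = ord)
}

#' Composite LD between two dosage vectors
#'
#' Squared Pearson correlation of genotype dosages (composite linkage
#' disequilibrium). A zero-variance vector yields r-squared 0 with a
#' warning.
#'
#' @param a,b equal-length dosage vectors.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    stop("dosage vectors must have equal length >= 2")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance dosage vector; r2 defined as 0")
    return(0)
  }
  stats::cor(a, b)^2
}

#' LD-prune a genotype matrix
#'
#' Removes markers so that no retained pair on the same chromosome
#' within `window_bp` has dosage r-squared at or above `r2_threshold`.
#' Pairs are scanned greedily in position order; of an offending pair
#' the member with the lower minor-allele frequency is removed (tie:
#' the later position).
#'
#' @param x a [genotype_matrix()] with map sorted by (chromosome,
#'   position) and no missing dosages.
#' @param r2_threshold LD threshold; default 0.2.
#' @param window_bp physical window in bp; default 500000.
#' @return The pruned `genotype_matrix`.
#' @export
ld_prune <- function(x, r2_threshold = 0.2, window_bp = 500000L) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (anyNA(x$dosages)) stop("ld_prune requires complete dosages; run qc_filter first")
  key <- chrom_key(x$map$chrom)
  ord <- order(key, x$map$pos)
  if (any(ord != seq_along(ord))) {
    stop("marker map must be sorted by (chromosome, position); sort before pruning")
  }
  d <- x$dosages
  maf <- pmin(colMeans(d) / 2, 1 - colMeans(d) / 2)
  keep <- rep(TRUE, ncol(d))
  pos <- x$map$pos
  for (ix in split(seq_len(ncol(d)), key)) {
    for (j in seq_along(ix)) {
      cj <- ix[j]
      if (!keep[cj]) next
      for (i in rev(seq_len(j - 1L))) {
        ci <- ix[i]
        if (pos[cj] - pos[ci] > window_bp) break
        if (!keep[ci]) next
        r2 <- suppressWarnings(ld_r2(d[, ci], d[, cj]))
        if (r2 >= r2_threshold) {
          if (maf[ci] < maf[cj]) keep[ci] <- FALSE else keep[cj] <- FALSE
          if (!keep[cj]) break
        }
      }
    }
  }
  subset_genotypes(x, markers = which(keep))
}

#' Merge SNP and InDel matrices into a jointly pruned SI set
#'
#' Column-concatenates the two matrices over the same individuals,
#' sorts by (chromosome, position) and re-applies [ld_prune()] with the
#' same threshold and window.
#'
#' @param snp,indel [genotype_matrix()] objects over identical
#'   individuals.
#' @param r2_threshold,window_bp passed to [ld_prune()].
#' @return The pruned combined `genotype_matrix`.
#' @export
merge_si <- function(snp, indel, r2_threshold = 0.2, window_bp = 500000L) {
  stopifnot(inherits(snp, "genotype_matrix"), inherits(indel, "genotype_matrix"))
  if (!identical(rownames(snp$dosages), rownames(indel$dosages))) {
    stop("SNP and InDel matrices must cover the same individuals in the same order")
  }
  d <- cbind(snp$dosages, indel$dosages)
  map <- rbind(snp$map, indel$map)
  labels <- snp$labels %||% indel$labels
  gm <- genotype_matrix(d, map, labels)
  ord <- order(chrom_key(gm$map$chrom), gm$map$pos, gm$map$id)
  gm <- subset_genotypes(gm, markers = ord)
  ld_prune(gm, r2_threshold = r2_threshold, window_bp = window_bp)
}

#' Write a genotype matrix to a minimal VCF
#'
#' Emits CHROM, POS, ID, REF, ALT, QUAL, FILTER, INFO and per-individual
#' GT fields (unphased; dosage 0 as `0/0`, 1 as `0/1`, 2 as `1/1`).
#' Round-trips through [read_vcf()] + [qc_filter()].
#'
#' @param x a [genotype_matrix()] without missing dosages.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (anyNA(x$dosages)) stop("cannot write missing genotypes")
  gt <- c("0/0", "0/1", "1/1")[t(x$dosages) + 1L]
  gt <- matrix(gt, nrow = ncol(x$dosages))
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(x$dosages)), collapse = "\t"),
    paste(x$map$chrom, x$map$pos, x$map$id, x$map$ref, x$map$alt,
          ".", "PASS", ".", "GT",
          apply(gt, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
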