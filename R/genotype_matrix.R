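#' Genotype matrix container
#'
#' Bundles an individuals-by-markers dosage matrix (counts of the ALT
#' allele, 0/1/2) with its marker map (chromosome, position, REF/ALT
#' alleles, SNP/InDel type) and optional per-individual breed labels.
#' This is the common currency of the whole pipeline: quality control,
#' LD pruning, the phylogenetic screen, genomic-breed-composition
#' estimation, marker selection and classification all consume and
#' return it.
#'
#' @param dosages integer matrix, individuals in rows, markers in
#'   columns; entries in \{0, 1, 2\} or `NA` for missing (missingness is
#'   only tolerated before [qc_filter()]).
#' @param map data frame with one row per marker and columns `id`,
#'   `chrom`, `pos`, `ref`, `alt`; a `type` column (`"SNP"`/`"InDel"`)
#'   is derived with [classify_marker()] when absent.
#' @param labels optional character vector of breed codes, one per
#'   individual.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, map, labels = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  bad <- !(dosages %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(map))
  if (length(miss)) stop("marker map lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(map) != ncol(dosages)) {
    stop("marker map has ", nrow(map), " rows but dosage matrix has ",
         ncol(dosages), " columns")
  }
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (any(map$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  if (is.null(map$type)) map$type <- classify_marker(map$ref, map$alt)
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("ind%03d", seq_len(nrow(dosages)))
  }
  colnames(dosages) <- map$id
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(dosages)) {
      stop("labels length (", length(labels), ") != number of individuals (",
           nrow(dosages), ")")
    }
    names(labels) <- rownames(dosages)
  }
  structure(list(dosages = dosages, map = map, labels = labels),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tt <- table(x$map$type)
  cat("genotype_matrix: ", nrow(x$dosages), " individuals x ",
      ncol(x$dosages), " markers (",
      paste(sprintf("%s %d", names(tt), tt), collapse = ", "), ")\n", sep = "")
  if (!is.null(x$labels)) {
    cat("breeds:", length(unique(x$labels)), "-",
        paste(utils::head(sort(unique(x$labels)), 8), collapse = " "),
        if (length(unique(x$labels)) > 8) "..." else "", "\n")
  }
  na <- sum(is.na(x$dosages))
  if (na > 0) cat("missing dosages:", na, "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param individuals row indices, logical mask or individual ids.
#' @param markers column indices, logical mask or marker ids.
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(x, individuals = NULL, markers = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  ri <- seq_len(nrow(x$dosages))
  ci <- seq_len(ncol(x$dosages))
  if (!is.null(individuals)) {
    ri <- if (is.character(individuals)) match(individuals, rownames(x$dosages)) else ri[individuals]
    if (anyNA(ri)) stop("unknown individual ids")
  }
  if (!is.null(markers)) {
    ci <- if (is.character(markers)) match(markers, x$map$id) else ci[markers]
    if (anyNA(ci)) {
      missing_ids <- if (is.character(markers)) markers[is.na(match(markers, x$map$id))] else "<index>"
      stop("markers not present in matrix: ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    }
  }
  genotype_matrix(x$dosages[ri, ci, drop = FALSE], x$map[ci, , drop = FALSE],
                  if (is.null(x$labels)) NULL else x$labels[ri])
}

#' Write/read a dosage matrix with marker map and labels
#'
#' Tab-separated interchange format: `<stem>.dosage.tsv` holds the
#' individuals-by-markers table (first column `individual_id`),
#' `<stem>.map.tsv` the marker map and `<stem>.labels.tsv` the
#' two-column (individual_id, breed_code) label table.
#'
#' @param x a [genotype_matrix()].
#' @param stem path stem for the three files.
#' @return `write_dosage_matrix` returns `stem` invisibly;
#'   `read_dosage_matrix` returns a `genotype_matrix`.
#' @export
write_dosage_matrix <- function(x, stem) {
  stopifnot(inherits(x, "genotype_matrix"))
  d <- data.frame(individual_id = rownames(x$dosages), x$dosages,
                  check.names = FALSE)
  utils::write.table(d, paste0(stem, ".dosage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$map, paste0(stem, ".map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(x$labels)) {
    utils::write.table(
      data.frame(individual_id = rownames(x$dosages), breed_code = x$labels),
      paste0(stem, ".labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(stem)
}

#' @rdname write_dosage_matrix
#' @export
read_dosage_matrix <- function(stem) {
  d <- utils::read.table(paste0(stem, ".dosage.tsv"), header = TRUE,
                         sep = "\t", check.names = FALSE)
  map <- utils::read.table(paste0(stem, ".map.tsv"), header = TRUE,
                           sep = "\t", colClasses = "character")
  map$pos <- as.integer(map$pos)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$individual_id
  labels <- NULL
  lab_path <- paste0(stem, ".labels.tsv")
  if (file.exists(lab_path)) {
    lt <- utils::read.table(lab_path, header = TRUE, sep = "\t",
                            colClasses = "character")
    labels <- lt$breed_code[match(d$individual_id, lt$individual_id)]
  }
  genotype_matrix(m, map, labels)
}
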