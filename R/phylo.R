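#' Pairwise p-distance matrix between individuals
#'
#' Allele-sharing p-distance from dosages:
#' d(i, j) = sum_m |g_im - g_jm| / (2 M), which lies in \[0, 1\] and is
#' a metric on dosage vectors (scaled Manhattan distance).
#'
#' @param x a [genotype_matrix()] with no missing dosages.
#' @return Symmetric numeric matrix with individual ids as dimnames.
#' @export
p_distance_matrix <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (ncol(x$dosages) == 0L) stop("no markers: cannot compute distances")
  if (anyNA(x$dosages)) stop("p-distance requires complete dosages")
  d <- as.matrix(stats::dist(x$dosages, method = "manhattan")) /
    (2 * ncol(x$dosages))
  dimnames(d) <- list(rownames(x$dosages), rownames(x$dosages))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj()]). Negative
#' branch lengths -- which NJ can produce on non-additive input -- are
#' clamped to zero with the deficit moved to the sibling edge, so path
#' lengths through the parent node are preserved.
#'
#' @param d symmetric distance matrix with at least 3 leaves.
#' @return An [ape::phylo] tree over the row names of `d`.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 leaves")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sib <- which(tr$edge[, 1] == parent & seq_len(nrow(tr$edge)) != e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sib)) {
      tr$edge.length[sib[1]] <- max(0, tr$edge.length[sib[1]] + deficit)
    }
  }
  tr
}

#' Flag individuals whose tree placement contradicts their breed label
#'
#' Operationalizes the visual "grouped in a branch of another breed"
#' screen: an individual is flagged when the majority breed label among
#' its `k` cophenetically nearest leaves differs from its own label
#' (ties are resolved in favor of the individual's own label, so only
#' clear misplacements are flagged).
#'
#' @param tree an [ape::phylo] tree whose tips are individual ids.
#' @param labels named character vector of breed codes (names =
#'   individual ids) or unnamed in tip order.
#' @param k neighborhood size; reduced to (smallest breed size - 1)
#'   when a breed is smaller than `k + 1`.
#' @return Character vector of flagged individual ids (possibly empty).
#' @export
flag_mislabeled <- function(tree, labels, k = 5L) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (is.null(names(labels))) {
    if (length(labels) != length(tips)) stop("labels must cover every leaf")
    names(labels) <- tips
  }
  if (!all(tips %in% names(labels))) stop("unlabeled leaves present")
  lab <- labels[tips]
  if (length(unique(lab)) < 2L) return(character(0))
  k <- min(k, min(table(lab)) - 1L)
  if (k < 1L) return(character(0))
  coph <- ape::cophenetic.phylo(tree)[tips, tips]
  flagged <- character(0)
  for (i in seq_along(tips)) {
    ord <- order(coph[i, -i])
    nn <- lab[-i][ord[seq_len(k)]]
    votes <- table(nn)
    own <- if (lab[i] %in% names(votes)) votes[[lab[i]]] else 0L
    if (own < max(votes)) flagged <- c(flagged, tips[i])
  }
  flagged
}

#' Write/read a PHYLIP square distance matrix
#'
#' @param d symmetric distance matrix with ids as dimnames.
#' @param path file path.
#' @return `write_phylip_dist` returns `path` invisibly;
#'   `read_phylip_dist` returns the matrix.
#' @export
write_phylip_dist <- function(d, path) {
  d <- as.matrix(d)
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i)
               paste(c(rownames(d)[i], sprintf("%.6f", d[i, ])),
                     collapse = "  "), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  parts <- strsplit(trimws(lines[1 + seq_len(n)]), "[[:space:]]+")
  ids <- vapply(parts, `[`, character(1), 1L)
  d <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
  dimnames(d) <- list(ids, ids)
  d
}
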