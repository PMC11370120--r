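#' Unclamped breed allele frequencies for informativeness statistics
#'
#' Same counting estimator as [estimate_breed_frequencies()] but without
#' clamping: the informativeness statistics want raw frequencies in
#' \[0, 1\] (a fixed difference should score FST = 1, In = log 2).
#'
#' @inheritParams estimate_breed_frequencies
#' @return Breeds-by-markers frequency matrix.
#' @export
breed_allele_frequencies <- function(x, labels = NULL) {
  estimate_breed_frequencies(x, labels, eps = NULL)
}

new_marker_scores <- function(map, score, method) {
  stopifnot(length(score) == nrow(map), all(is.finite(score)))
  structure(data.frame(id = map$id, chrom = map$chrom, pos = map$pos,
                       score = as.numeric(score), stringsAsFactors = FALSE),
            method = method, class = c("marker_scores", "data.frame"))
}

#' @export
print.marker_scores <- function(x, ...) {
  cat("marker_scores (", attr(x, "method"), "): ", nrow(x), " markers, ",
      "score range [", sprintf("%.4g", min(x$score)), ", ",
      sprintf("%.4g", max(x$score)), "]\n", sep = "")
  invisible(x)
}

# The frequency statistics accept either a labeled genotype_matrix (the
# frequencies are computed) or a breeds-by-markers frequency matrix
# directly. Returns the frequency matrix plus a marker map for
# deterministic tie-breaking.
freq_scores_input <- function(x, labels) {
  if (inherits(x, "genotype_matrix")) {
    f <- breed_allele_frequencies(x, labels)
    map <- x$map
  } else {
    f <- as.matrix(x)
    if (any(f < 0 | f > 1)) stop("allele frequencies must lie in [0, 1]")
    ids <- colnames(f) %||% sprintf("m%06d", seq_len(ncol(f)))
    map <- data.frame(id = ids, chrom = "0", pos = seq_len(ncol(f)),
                      stringsAsFactors = FALSE)
  }
  if (nrow(f) < 2L) stop("informativeness statistics need >= 2 breeds")
  list(f = f, map = map)
}

#' Delta score: largest pairwise allele-frequency difference
#'
#' delta_ab(m) = |p_am - p_bm| for a breed pair; the marker score is
#' the aggregate over all breed pairs (`"max"` by default: a marker
#' diagnostic for even one pair is assignment-relevant; `"mean"`
#' available).
#'
#' @param x a labeled [genotype_matrix()] or a breeds-by-markers allele
#'   frequency matrix.
#' @param labels breed codes (defaults to `x$labels`; ignored for
#'   frequency input).
#' @param aggregate `"max"` or `"mean"` over breed pairs.
#' @return A `marker_scores` data frame.
#' @export
delta_score <- function(x, labels = NULL, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  inp <- freq_scores_input(x, labels)
  s <- pairwise_aggregate(inp$f, function(pa, pb) abs(pa - pb), aggregate)
  new_marker_scores(inp$map, s, "delta")
}

#' Pairwise Wright's FST score
#'
#' For a breed pair, FST = (H_T - H_S) / H_T with pbar = (p_a + p_b)/2,
#' H_T = 2 pbar (1 - pbar) and H_S = p_a(1 - p_a) + p_b(1 - p_b)
#' (defined as 0 when H_T = 0); the marker score aggregates over breed
#' pairs (`"max"` default).
#'
#' @inheritParams delta_score
#' @return A `marker_scores` data frame.
#' @export
fst_score <- function(x, labels = NULL, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  inp <- freq_scores_input(x, labels)
  s <- pairwise_aggregate(inp$f, function(pa, pb) {
    pbar <- (pa + pb) / 2
    ht <- 2 * pbar * (1 - pbar)
    hs <- pa * (1 - pa) + pb * (1 - pb)
    ifelse(ht == 0, 0, (ht - hs) / ht)
  }, aggregate)
  new_marker_scores(inp$map, s, "fst")
}

pairwise_aggregate <- function(f, pairfun, aggregate) {
  pairs <- utils::combn(nrow(f), 2)
  vals <- matrix(0, ncol(pairs), ncol(f))
  for (p in seq_len(ncol(pairs))) {
    vals[p, ] <- pairfun(f[pairs[1, p], ], f[pairs[2, p], ])
  }
  if (aggregate == "max") apply(vals, 2, max) else colMeans(vals)
}

#' Rosenberg's informativeness for assignment (In)
#'
#' For a biallelic marker with breed frequencies p_1..p_K (alleles
#' j in \{ALT, REF\}, natural log, 0 log 0 = 0):
#' In = sum_j ( -pbar_j log pbar_j + (1/K) sum_i p_ij log p_ij ),
#' where pbar_j is the unweighted across-breed mean frequency of
#' allele j. Scores lie in \[0, log K\].
#'
#' @inheritParams delta_score
#' @return A `marker_scores` data frame.
#' @export
rosenberg_in_score <- function(x, labels = NULL) {
  inp <- freq_scores_input(x, labels)
  f <- inp$f
  K <- nrow(f)
  s <- numeric(ncol(f))
  for (al in list(f, 1 - f)) {           # ALT then REF allele frequencies
    pbar <- colMeans(al)
    s <- s + (-xlogx(pbar) + colSums(xlogx(al)) / K)
  }
  new_marker_scores(inp$map, pmax(s, 0), "in")
}

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' Mutual information between genotype category and breed label
#'
#' Empirical MI of the contingency table over dosage categories
#' \{0, 1, 2\} and breed labels, in nats:
#' MI = sum_g sum_b Phat(g, b) log\[ Phat(g, b) / (Phat(g) Phat(b)) \],
#' dropping 0 log 0 terms. Non-negative; 0 iff the empirical table
#' factorizes.
#'
#' @inheritParams delta_score
#' @return A `marker_scores` data frame.
#' @export
mutual_information_score <- function(x, labels = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  labels <- labels %||% x$labels
  if (is.null(labels)) stop("breed labels required")
  lab <- factor(labels)
  n <- nrow(x$dosages)
  s <- apply(x$dosages, 2, function(g) {
    tab <- table(factor(g, levels = 0:2), lab) / n
    pg <- rowSums(tab)
    pb <- colSums(tab)
    e <- outer(pg, pb)
    pos <- tab > 0
    sum(tab[pos] * log(tab[pos] / e[pos]))
  })
  new_marker_scores(x$map, pmax(s, 0), "mi")
}

#' Random-forest importance scores (MDA / MDG)
#'
#' Trains a random forest of `n_trees` trees on the dosage matrix with
#' the breed label as class and returns permutation importance
#' (`"mda"`, mean decrease in accuracy) or total impurity decrease
#' (`"mdg"`, mean decrease in Gini). Deterministic for a fixed seed.
#'
#' @inheritParams delta_score
#' @param measure `"mda"` or `"mdg"`.
#' @param n_trees ensemble size (default 500).
#' @param seed integer seed.
#' @return A `marker_scores` data frame.
#' @export
rf_importance_scores <- function(x, labels = NULL, measure = c("mda", "mdg"),
                                 n_trees = 500L, seed = NULL) {
  measure <- match.arg(measure)
  stopifnot(inherits(x, "genotype_matrix"))
  labels <- labels %||% x$labels
  if (is.null(labels)) stop("breed labels required")
  if (length(unique(labels)) < 2L) stop("need >= 2 breeds")
  imp_type <- if (measure == "mda") "permutation" else "impurity"
  fit <- ranger::ranger(x = x$dosages, y = factor(labels),
                        num.trees = n_trees,
                        mtry = floor(sqrt(ncol(x$dosages))),
                        importance = imp_type, num.threads = 1L,
                        seed = seed %||% 1L)
  new_marker_scores(x$map, fit$variable.importance, measure)
}

# Rank of every marker under a score vector: 1 = most informative.
# Ties broken by (chromosome, position) ascending, so rankings are a
# deterministic permutation.
score_ranks <- function(scores) {
  ord <- order(-scores$score, chrom_key(scores$chrom), scores$pos)
  r <- integer(nrow(scores))
  r[ord] <- seq_len(nrow(scores))
  r
}

new_marker_panel <- function(scores, take, method, n, provenance = NULL) {
  panel <- structure(
    data.frame(id = scores$id[take], chrom = scores$chrom[take],
               pos = scores$pos[take], stringsAsFactors = FALSE),
    method = method, n = n, class = c("marker_panel", "data.frame"))
  if (!is.null(provenance)) panel$source <- provenance
  panel
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("marker_panel (", attr(x, "method"), "): ", nrow(x), " markers\n",
      sep = "")
  invisible(x)
}

#' Top-N marker panel for one scoring method
#'
#' The `n` highest-scoring markers, ties broken by (chromosome,
#' position) ascending. Panels of the same scores nest: the top-200
#' panel is contained in the top-400 panel.
#'
#' @param scores a `marker_scores` data frame.
#' @param n panel size.
#' @return A `marker_panel` (ordered by rank).
#' @export
select_top_n <- function(scores, n) {
  stopifnot(inherits(scores, "marker_scores"))
  if (n > nrow(scores)) {
    stop("requested ", n, " markers but only ", nrow(scores), " available")
  }
  if (n < 1) stop("panel size must be positive")
  ord <- order(score_ranks(scores))
  new_marker_panel(scores, ord[seq_len(n)],
                   paste0("top-n(", attr(scores, "method"), ")"), n)
}

#' DFI intersection panel
#'
#' Combines the Delta, FST and In rankings by intersection: the
#' smallest depth t is found (binary search) such that the three top-t
#' lists share at least `n` markers; members are ordered by
#' (intersection entry depth = max of the three ranks, then rank sum,
#' then position) and the first `n` taken, so panels of increasing `n`
#' nest.
#'
#' @param delta,fst,in_ `marker_scores` over the same marker universe.
#' @param n panel size.
#' @return A `marker_panel` with a `source` column `"dfi"` and
#'   attribute `depth` (the depth t used).
#' @export
dfi_inter <- function(delta, fst, in_, n) {
  ranks <- dfi_ranks(delta, fst, in_, n)
  maxrank <- pmax(ranks[, 1], ranks[, 2], ranks[, 3])
  # smallest t with |{maxrank <= t}| >= n, by binary search on the
  # monotone count function
  lo <- n; hi <- nrow(ranks)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (sum(maxrank <= mid) >= n) hi <- mid else lo <- mid + 1
  }
  t_depth <- as.integer(lo)
  members <- which(maxrank <= t_depth)
  ranksum <- ranks[, 1] + ranks[, 2] + ranks[, 3]
  ord <- members[order(maxrank[members], ranksum[members],
                       chrom_key(delta$chrom[members]), delta$pos[members])]
  take <- ord[seq_len(n)]
  panel <- new_marker_panel(delta, take, "dfi_inter", n,
                            provenance = rep("dfi", n))
  attr(panel, "depth") <- t_depth
  panel
}

#' DFI union panel
#'
#' Combines the Delta, FST and In rankings by union: the smallest
#' common per-method depth k is found such that the union of the three
#' top-k lists reaches `n` unique markers; the union is ordered by the
#' best (minimum) rank across the three methods (ties by position) and
#' trimmed to exactly `n`. The deterministic trim order makes panels of
#' increasing `n` nest.
#'
#' @inheritParams dfi_inter
#' @return A `marker_panel` whose `source` column names the method(s)
#'   achieving each marker's best rank; attribute `depth` holds k.
#' @export
dfi_union <- function(delta, fst, in_, n) {
  ranks <- dfi_ranks(delta, fst, in_, n)
  minrank <- pmin(ranks[, 1], ranks[, 2], ranks[, 3])
  k <- as.integer(sort(minrank)[n])   # smallest k with |{minrank <= k}| >= n
  members <- which(minrank <= k)
  ord <- members[order(minrank[members], chrom_key(delta$chrom[members]),
                       delta$pos[members])]
  take <- ord[seq_len(n)]
  src <- apply(ranks[take, , drop = FALSE], 1, function(r)
    paste(c("delta", "fst", "in")[r == min(r)], collapse = "+"))
  panel <- new_marker_panel(delta, take, "dfi_union", n, provenance = src)
  attr(panel, "depth") <- k
  panel
}

dfi_ranks <- function(delta, fst, in_, n) {
  stopifnot(inherits(delta, "marker_scores"), inherits(fst, "marker_scores"),
            inherits(in_, "marker_scores"))
  if (!identical(delta$id, fst$id) || !identical(delta$id, in_$id)) {
    stop("score tables must cover the same marker universe in the same order")
  }
  if (n > nrow(delta)) {
    stop("requested ", n, " markers but the universe holds only ",
         nrow(delta), " (max achievable)")
  }
  if (n < 1) stop("panel size must be positive")
  cbind(score_ranks(delta), score_ranks(fst), score_ranks(in_))
}

#' Write a marker panel to a tab-separated file
#'
#' @param panel a `marker_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_panel <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
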