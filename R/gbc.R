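#' Reference-panel breed allele frequencies
#'
#' Per-breed ALT-allele frequencies f_km = (sum of dosages) / (2 n_k),
#' clamped to \[eps, 1 - eps\] so the admixture log-likelihood stays
#' finite for any genotype.
#'
#' @param x a [genotype_matrix()] with no missing dosages.
#' @param labels breed codes per individual (defaults to `x$labels`).
#' @param eps clamping bound; `NULL` or 0 disables clamping (used by
#'   the marker-informativeness statistics, which want raw \[0, 1\]
#'   frequencies).
#' @return Breeds-by-markers frequency matrix, breed codes as row
#'   names.
#' @export
estimate_breed_frequencies <- function(x, labels = NULL, eps = 1e-4) {
  stopifnot(inherits(x, "genotype_matrix"))
  labels <- labels %||% x$labels
  if (is.null(labels)) stop("breed labels required")
  if (anyNA(x$dosages)) stop("complete dosages required")
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts == 0)) {
    stop("breed with no reference individuals: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  }
  f <- rowsum(x$dosages, labels) / (2 * as.vector(counts[sort(unique(labels))]))
  f <- f[order(rownames(f)), , drop = FALSE]
  if (!is.null(eps) && eps > 0) f <- pmin(pmax(f, eps), 1 - eps)
  f
}

#' Estimate genomic breed composition of one individual
#'
#' Maximizes the supervised-admixture binomial log-likelihood
#' l(q) = sum_m \[ g_m log(sum_k q_k f_km) +
#'                (2 - g_m) log(sum_k q_k (1 - f_km)) \]
#' over the K-simplex by EM from a uniform start, with the reference
#' frequencies f held fixed (projection onto a purebred reference
#' panel). The EM update is multiplicative, keeps q on the simplex and
#' never decreases the log-likelihood.
#'
#' @param genotype dosage vector over the markers of `freqs` (named, or
#'   in matching column order).
#' @param freqs breeds-by-markers frequency matrix (clamped, from
#'   [estimate_breed_frequencies()]).
#' @param tol convergence tolerance on the log-likelihood gain.
#' @param max_iter iteration cap.
#' @return Named ancestry vector on the simplex with attributes
#'   `loglik` (final value), `loglik_trace` and `iterations`.
#' @export
estimate_gbc <- function(genotype, freqs, tol = 1e-6, max_iter = 2000L) {
  freqs <- as.matrix(freqs)
  K <- nrow(freqs)
  M <- ncol(freqs)
  if (!is.null(names(genotype)) && !is.null(colnames(freqs))) {
    if (!all(colnames(freqs) %in% names(genotype))) {
      stop("genotype lacks markers present in the reference frequencies")
    }
    genotype <- genotype[colnames(freqs)]
  }
  if (length(genotype) != M) stop("genotype/frequency marker mismatch")
  g <- as.numeric(genotype)
  if (K == 1L) {
    q <- stats::setNames(1, rownames(freqs))
    attr(q, "loglik") <- sum(g * log(freqs[1, ]) + (2 - g) * log(1 - freqs[1, ]))
    attr(q, "loglik_trace") <- attr(q, "loglik")
    attr(q, "iterations") <- 0L
    return(q)
  }
  q <- rep(1 / K, K)
  trace <- numeric(0)
  ll_old <- -Inf
  it <- 0L
  tF <- t(freqs)        # M x K
  tG <- 1 - tF
  repeat {
    a <- as.vector(tF %*% q)       # P(ALT allele | q) per marker
    b <- as.vector(tG %*% q)
    ll <- sum(g * log(a) + (2 - g) * log(b))
    trace <- c(trace, ll)
    if (!is.finite(ll)) stop("non-finite admixture likelihood")
    if (ll - ll_old < tol || it >= max_iter) break
    ll_old <- ll
    it <- it + 1L
    # EM: expected ancestry counts of the 2M sampled alleles
    q <- q * as.vector(crossprod(tF, g / a) + crossprod(tG, (2 - g) / b)) / (2 * M)
    q <- q / sum(q)
  }
  q <- stats::setNames(q, rownames(freqs))
  attr(q, "loglik") <- trace[length(trace)]
  attr(q, "loglik_trace") <- trace
  attr(q, "iterations") <- it
  q
}

#' Genomic breed composition for every individual
#'
#' Runs [estimate_gbc()] per individual against a fixed reference
#' frequency panel and assembles a GBC report with purebred flags
#' (labeled-breed GBC at or above `threshold`).
#'
#' @param x a [genotype_matrix()].
#' @param freqs reference frequencies; computed from `x` and its labels
#'   when `NULL`.
#' @param labels breed codes (defaults to `x$labels`); optional -- flags
#'   are `NA` without labels.
#' @param threshold purebred GBC threshold (default 0.90, inclusive).
#' @param ... passed to [estimate_gbc()].
#' @return Object of class `gbc_report`: list with `q` (individuals x
#'   breeds), `labels`, `purebred`, `threshold`.
#' @export
estimate_gbc_all <- function(x, freqs = NULL, labels = NULL, threshold = 0.9,
                             ...) {
  stopifnot(inherits(x, "genotype_matrix"))
  labels <- labels %||% x$labels
  if (is.null(freqs)) freqs <- estimate_breed_frequencies(x, labels)
  q <- t(apply(x$dosages, 1, function(g) as.vector(estimate_gbc(g, freqs, ...))))
  colnames(q) <- rownames(freqs)
  rownames(q) <- rownames(x$dosages)
  new_gbc_report(q, labels, threshold)
}

new_gbc_report <- function(q, labels, threshold) {
  purebred <- if (is.null(labels)) rep(NA, nrow(q)) else {
    q[cbind(seq_len(nrow(q)), match(labels, colnames(q)))] >= threshold
  }
  structure(list(q = q, labels = labels, purebred = purebred,
                 threshold = threshold),
            class = "gbc_report")
}

#' @export
print.gbc_report <- function(x, ...) {
  cat("gbc_report:", nrow(x$q), "individuals x", ncol(x$q), "breeds;",
      sum(x$purebred, na.rm = TRUE), "purebred at threshold",
      x$threshold, "\n")
  if (!is.null(x$labels)) {
    m <- mean_gbc_by_breed(x)
    cat("mean labeled-breed GBC:",
        sprintf("%.3f", mean(diag(m[, rownames(m), drop = FALSE]))), "\n")
  }
  invisible(x)
}

#' Per-breed mean GBC table
#'
#' Averages ancestry vectors within each labeled breed: rows are
#' labeled breeds, columns reference breeds (the diagonal is the mean
#' own-breed composition).
#'
#' @param report a `gbc_report` with labels.
#' @return Breeds-by-breeds matrix of mean GBC.
#' @export
mean_gbc_by_breed <- function(report) {
  stopifnot(inherits(report, "gbc_report"))
  if (is.null(report$labels)) stop("report has no breed labels")
  m <- rowsum(report$q, report$labels) /
    as.vector(table(report$labels)[sort(unique(report$labels))])
  m[order(rownames(m)), , drop = FALSE]
}

#' Purebred screen for the training population
#'
#' Retains individuals whose labeled-breed GBC is at or above the
#' threshold (inclusive) and who were not flagged by the phylogenetic
#' mislabel screen: the training population is the conjunction of both
#' checks.
#'
#' @param report a `gbc_report` with labels.
#' @param threshold GBC threshold (default taken from the report).
#' @param flagged ids flagged by [flag_mislabeled()]; excluded
#'   regardless of GBC.
#' @return Character vector of retained individual ids.
#' @export
screen_purebred <- function(report, threshold = NULL, flagged = character(0)) {
  stopifnot(inherits(report, "gbc_report"))
  if (is.null(report$labels)) stop("labels required for the purebred screen")
  threshold <- threshold %||% report$threshold
  ql <- report$q[cbind(seq_len(nrow(report$q)),
                       match(report$labels, colnames(report$q)))]
  ids <- rownames(report$q)
  ids[ql >= threshold & !(ids %in% flagged)]
}

#' Supervised admixture estimation for a test group
#'
#' Joint maximum-likelihood estimation in the supervised admixture
#' model: reference individuals keep their one-hot ancestry (their
#' labeled breed), test individuals get free ancestry vectors, and the
#' breed allele frequencies are re-estimated jointly from reference
#' and test individuals (the behavior of ADMIXTURE's supervised mode).
#' Joint frequency updates matter: frequencies estimated from a few
#' dozen reference animals carry sampling noise that a fixed-frequency
#' projection absorbs into spurious foreign ancestry, deflating
#' purebred GBC estimates by several percent.
#'
#' Because reference ancestry is one-hot, the reference contribution
#' to the EM frequency update reduces to fixed allele counts, so each
#' iteration costs only O(T K M) for T test individuals.
#'
#' @param x a labeled [genotype_matrix()].
#' @param test ids (or indices) of the individuals whose ancestry is
#'   estimated; everyone else is reference.
#' @param labels breed codes (defaults to `x$labels`).
#' @param eps frequency clamping bound.
#' @param tol EM convergence tolerance on the total log-likelihood.
#' @param max_iter iteration cap.
#' @return Matrix of test-individual ancestry vectors (rows on the
#'   simplex) with attribute `loglik_trace`.
#' @export
estimate_gbc_supervised <- function(x, test, labels = NULL, eps = 1e-4,
                                    tol = 1e-6, max_iter = 2000L) {
  stopifnot(inherits(x, "genotype_matrix"))
  labels <- labels %||% x$labels
  if (is.null(labels)) stop("breed labels required")
  if (is.character(test)) test <- match(test, rownames(x$dosages))
  if (anyNA(test)) stop("unknown test individual ids")
  ref <- setdiff(seq_len(nrow(x$dosages)), test)
  if (!length(ref)) stop("no reference individuals left")
  breeds <- sort(unique(labels[ref]))
  K <- length(breeds)
  M <- ncol(x$dosages)
  # fixed reference allele counts per breed
  cnt <- rowsum(x$dosages[ref, , drop = FALSE], labels[ref])[breeds, , drop = FALSE]
  n_k <- as.vector(table(labels[ref])[breeds])
  f <- pmin(pmax(cnt / (2 * n_k), eps), 1 - eps)
  gt <- x$dosages[test, , drop = FALSE]
  storage.mode(gt) <- "double"
  q <- matrix(1 / K, length(test), K,
              dimnames = list(rownames(x$dosages)[test], breeds))
  if (K == 1L) return(structure(q, loglik_trace = NA_real_))
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    p <- q %*% f
    pc <- 1 - p
    ll <- sum(gt * log(p) + (2 - gt) * log(pc)) +
      sum(cnt * log(f) + (2 * n_k - cnt) * log(1 - f))
    trace <- c(trace, ll)
    if (!is.finite(ll)) stop("non-finite admixture likelihood")
    if (ll - ll_old < tol) break
    ll_old <- ll
    a <- gt / p
    b <- (2 - gt) / pc
    q_new <- q * (a %*% t(f) + b %*% t(1 - f)) / (2 * M)
    q_new <- q_new / rowSums(q_new)
    alt_k <- f * crossprod(q, a)          # expected test ALT alleles per breed
    tot_k <- alt_k + (1 - f) * crossprod(q, b)
    f <- pmin(pmax((cnt + alt_k) / (2 * n_k + tot_k), eps), 1 - eps)
    q <- q_new
  }
  structure(q, loglik_trace = trace)
}

#' Tenfold cross-validated GBC estimation
#'
#' Randomly splits every breed into `folds` subsets; each subset in
#' turn is the test group, with the remaining subsets of every breed
#' as reference, so each individual's GBC is estimated exactly once,
#' never against a reference containing itself. The default engine is
#' the joint supervised estimator ([estimate_gbc_supervised()]);
#' `engine = "projection"` instead fixes the reference frequencies and
#' runs the per-individual EM of [estimate_gbc()].
#'
#' @param x a labeled [genotype_matrix()].
#' @param labels breed codes (defaults to `x$labels`).
#' @param folds fold count (default 10); reduced per breed with a
#'   warning when a breed is smaller.
#' @param threshold purebred threshold for the report.
#' @param seed integer seed controlling fold assignment.
#' @param engine `"supervised"` (joint frequency re-estimation) or
#'   `"projection"` (fixed reference frequencies).
#' @param ... passed to the engine.
#' @return A `gbc_report`.
#' @export
gbc_crossval <- function(x, labels = NULL, folds = 10L, threshold = 0.9,
                         seed = NULL, engine = c("supervised", "projection"),
                         ...) {
  engine <- match.arg(engine)
  stopifnot(inherits(x, "genotype_matrix"))
  labels <- labels %||% x$labels
  if (is.null(labels)) stop("breed labels required")
  fold_id <- assign_folds(labels, folds, seed)
  q <- NULL
  for (f in sort(unique(fold_id))) {
    test <- which(fold_id == f)
    ref <- which(fold_id != f)
    if (engine == "supervised") {
      qf <- estimate_gbc_supervised(x, test, labels = labels, ...)
    } else {
      freqs <- estimate_breed_frequencies(
        subset_genotypes(x, individuals = ref), labels[ref])
      qf <- t(apply(x$dosages[test, , drop = FALSE], 1,
                    function(g) as.vector(estimate_gbc(g, freqs, ...))))
      colnames(qf) <- rownames(freqs)
    }
    if (is.null(q)) {
      q <- matrix(NA_real_, nrow(x$dosages), ncol(qf),
                  dimnames = list(rownames(x$dosages), colnames(qf)))
    }
    q[test, ] <- qf
  }
  new_gbc_report(q, labels, threshold)
}

# Breed-stratified fold assignment; fold sizes within a breed differ by
# at most one. Breeds smaller than `folds` get one fold per individual,
# with a warning.
assign_folds <- function(labels, folds, seed = NULL) {
  with_seed(seed, {
    fold_id <- integer(length(labels))
    for (b in unique(labels)) {
      ix <- which(labels == b)
      fb <- folds
      if (length(ix) < folds) {
        warning("breed ", b, " has ", length(ix), " individuals < ", folds,
                " folds; using ", length(ix), " folds")
        fb <- length(ix)
      }
      fold_id[ix] <- sample(rep_len(seq_len(fb), length(ix)))
    }
    fold_id
  })
}

#' Correlation between panel-based and full-marker GBC
#'
#' Pearson correlation between the flattened individuals-by-breeds GBC
#' matrices of two reports over the same individuals, optionally
#' restricted to the purebred or non-purebred subset (per the full
#' report's flags).
#'
#' @param full,panel `gbc_report`s over identical individuals and
#'   breeds.
#' @param subset `"all"`, `"purebred"` or `"nonpurebred"`.
#' @return Pearson correlation (scalar).
#' @export
gbc_panel_correlation <- function(full, panel,
                                  subset = c("all", "purebred", "nonpurebred")) {
  subset <- match.arg(subset)
  stopifnot(inherits(full, "gbc_report"), inherits(panel, "gbc_report"))
  if (!identical(dimnames(full$q), dimnames(panel$q))) {
    stop("reports must cover identical individuals and breeds")
  }
  rows <- switch(subset,
                 all = rep(TRUE, nrow(full$q)),
                 purebred = full$purebred %in% TRUE,
                 nonpurebred = full$purebred %in% FALSE)
  a <- as.vector(full$q[rows, , drop = FALSE])
  b <- as.vector(panel$q[rows, , drop = FALSE])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("GBC correlation undefined: constant composition vector")
  }
  stats::cor(a, b)
}

#' Write a GBC report as a tab-separated table
#'
#' Columns: individual id, breed label, one column per reference breed
#' (ADMIXTURE .Q-style order with a header), purebred flag.
#'
#' @param report a `gbc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gbc_report <- function(report, path) {
  stopifnot(inherits(report, "gbc_report"))
  d <- data.frame(individual_id = rownames(report$q),
                  breed_code = report$labels %||% NA,
                  round(report$q, 6), purebred = report$purebred,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
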