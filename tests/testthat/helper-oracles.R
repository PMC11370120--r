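# Fixture builders and independent brute-force oracles used across the
# suite. The oracles are deliberately naive (explicit loops over
# alleles, pairs and depths) so they share no code path with the
# package implementations they check.

toy_map <- function(m, chrom = "1", start = 1L, step = 1000L,
                    ref = "A", alt = "C") {
  data.frame(id = sprintf("t%04d", seq_len(m)), chrom = chrom,
             pos = as.integer(seq(start, by = step, length.out = m)),
             ref = ref, alt = alt, stringsAsFactors = FALSE)
}

toy_gm <- function(dosages, labels = NULL, chrom = "1", step = 1000L) {
  dosages <- as.matrix(dosages)
  genotype_matrix(dosages, toy_map(ncol(dosages), chrom = chrom, step = step),
                  labels)
}

random_gm <- function(n, m, n_breeds = 2, seed = 1) {
  set.seed(seed)
  labels <- sort(rep_len(sprintf("B%02d", seq_len(n_breeds)), n))
  g <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  toy_gm(g, labels)
}

# --- brute-force statistics on a breeds x markers frequency matrix ---

oracle_delta <- function(f) {
  apply(f, 2, function(p) {
    best <- 0
    for (a in seq_along(p)) for (b in seq_along(p)) {
      if (a < b) best <- max(best, abs(p[a] - p[b]))
    }
    best
  })
}

oracle_fst <- function(f) {
  apply(f, 2, function(p) {
    best <- 0
    for (a in seq_along(p)) for (b in seq_along(p)) {
      if (a < b) {
        pbar <- (p[a] + p[b]) / 2
        ht <- 2 * pbar * (1 - pbar)
        hs <- p[a] * (1 - p[a]) + p[b] * (1 - p[b])
        v <- if (ht == 0) 0 else (ht - hs) / ht
        best <- max(best, v)
      }
    }
    best
  })
}

oracle_in <- function(f) {
  K <- nrow(f)
  plogp <- function(p) if (p > 0) p * log(p) else 0
  apply(f, 2, function(p) {
    total <- 0
    for (pj in list(p, 1 - p)) {           # the two alleles
      pbar <- mean(pj)
      term <- -plogp(pbar)
      for (i in seq_len(K)) term <- term + plogp(pj[i]) / K
      total <- total + term
    }
    total
  })
}

oracle_mi <- function(g, labels) {
  n <- length(g)
  total <- 0
  for (gv in 0:2) for (b in unique(labels)) {
    pgb <- sum(g == gv & labels == b) / n
    if (pgb > 0) {
      pg <- sum(g == gv) / n
      pb <- sum(labels == b) / n
      total <- total + pgb * log(pgb / (pg * pb))
    }
  }
  total
}

# --- linear depth-scan oracles for the DFI combiners -----------------

oracle_rank <- function(scores) {
  ord <- order(-scores$score, breedkit:::chrom_key(scores$chrom), scores$pos)
  r <- integer(nrow(scores)); r[ord] <- seq_along(ord); r
}

oracle_dfi_inter <- function(d, f, i, n) {
  r1 <- oracle_rank(d); r2 <- oracle_rank(f); r3 <- oracle_rank(i)
  for (t in seq(n, nrow(d))) {
    members <- which(r1 <= t & r2 <= t & r3 <= t)
    if (length(members) >= n) {
      mx <- pmax(r1, r2, r3)[members]
      rs <- (r1 + r2 + r3)[members]
      ord <- members[order(mx, rs, breedkit:::chrom_key(d$chrom[members]),
                           d$pos[members])]
      return(list(t = t, ids = d$id[ord[seq_len(n)]]))
    }
  }
  stop("unreachable for n <= universe")
}

oracle_dfi_union <- function(d, f, i, n) {
  r1 <- oracle_rank(d); r2 <- oracle_rank(f); r3 <- oracle_rank(i)
  for (k in seq_len(nrow(d))) {
    members <- which(r1 <= k | r2 <= k | r3 <= k)
    if (length(members) >= n) {
      mn <- pmin(r1, r2, r3)[members]
      ord <- members[order(mn, breedkit:::chrom_key(d$chrom[members]),
                           d$pos[members])]
      return(list(k = k, ids = d$id[ord[seq_len(n)]]))
    }
  }
  stop("unreachable for n <= universe")
}

random_scores <- function(m, seed) {
  set.seed(seed)
  map <- toy_map(m)
  list(
    d = breedkit:::new_marker_scores(map, stats::runif(m), "delta"),
    f = breedkit:::new_marker_scores(map, stats::runif(m), "fst"),
    i = breedkit:::new_marker_scores(map, stats::runif(m), "in"))
}

# --- least-squares topology oracle for 4-leaf neighbor joining -------

# All three unrooted 4-leaf topologies, as the leaf split {A, B} | {C, D}.
ls_fit_quartet <- function(d, split) {
  # For topology (a,b)|(c,d) with internal edge, path lengths are a
  # linear model in the 5 edge lengths; solve least squares.
  a <- split[1]; b <- split[2]; c <- split[3]; dd <- split[4]
  pairs <- utils::combn(4, 2)
  X <- matrix(0, 6, 5)  # columns: ea, eb, ec, ed, internal
  y <- numeric(6)
  leafcol <- integer(4); leafcol[c(a, b, c, dd)] <- 1:4
  for (p in seq_len(6)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    X[p, leafcol[i]] <- 1; X[p, leafcol[j]] <- 1
    same_side <- (i %in% c(a, b)) == (j %in% c(a, b))
    if (!same_side) X[p, 5] <- 1
    y[p] <- d[i, j]
  }
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), split = split)
}

oracle_best_quartet <- function(d) {
  splits <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  fits <- lapply(splits, function(s) ls_fit_quartet(d, s))
  best <- which.min(vapply(fits, `[[`, numeric(1), "rss"))
  fits[[best]]
}

# Which of the three quartet splits a (near-)additive 4x4 distance
# matrix supports, by the four-point condition: for split {a,b}|{c,d}
# the sum d(a,b) + d(c,d) is the smallest of the three pair-sums.
quartet_split_from_dist <- function(d) {
  sums <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
  list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))[[which.min(sums)]]
}

# Random additive (tree) metric over n leaves labeled t1..tn.
random_additive_dist <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) stats::runif(k, 0.05, 1))
  tr$tip.label <- sprintf("t%d", seq_len(n))
  d <- ape::cophenetic.phylo(tr)[sprintf("t%d", 1:n), sprintf("t%d", 1:n)]
  list(tree = tr, d = d)
}
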