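test_that("closed-form statistics hit their anchor values", {
  f2 <- rbind(c(1, 0.5, 0.9, 0.1), c(0, 0.5, 0.2, 0.5))
  expect_equal(fst_score(f2)$score[1], 1)          # fixed difference
  expect_equal(fst_score(f2)$score[2], 0)          # identical frequencies
  expect_equal(fst_score(rbind(0.8, 0.2))$score, 0.36)
  expect_equal(delta_score(f2)$score, c(1, 0, 0.7, 0.4))
  expect_equal(delta_score(rbind(0.1, 0.5, 0.9))$score, 0.8)  # max pair
  expect_equal(rosenberg_in_score(f2)$score[1], log(2))
  expect_equal(rosenberg_in_score(f2)$score[2], 0)

  # perfectly split two-class marker: MI = log 2
  gm <- toy_gm(cbind(c(0, 0, 2, 2), c(1, 1, 1, 1)),
               labels = c("A", "A", "B", "B"))
  mi <- mutual_information_score(gm)
  expect_equal(mi$score[1], log(2))
  expect_equal(mi$score[2], 0)                     # constant marker
})

test_that("statistics match brute-force oracles on random instances", {
  for (case in 1:100) {
    set.seed(case)
    K <- sample(2:6, 1)
    m <- sample(5:50, 1)
    f <- matrix(stats::runif(K * m), K, m)
    expect_equal(delta_score(f)$score, oracle_delta(f), tolerance = 1e-12)
    expect_equal(fst_score(f)$score, oracle_fst(f), tolerance = 1e-12)
    expect_equal(rosenberg_in_score(f)$score, oracle_in(f), tolerance = 1e-12)
  }
  for (case in 1:100) {
    set.seed(case)
    gm <- random_gm(n = 20, m = 8, n_breeds = sample(2:4, 1),
                    seed = 1000 + case)
    got <- mutual_information_score(gm)$score
    want <- apply(gm$dosages, 2, oracle_mi, labels = gm$labels)
    expect_equal(got, unname(want), tolerance = 1e-12)
  }
})

test_that("every statistic grows with simulated breed differentiation", {
  stat_means <- function(fst, seed) {
    ds <- simulate_dataset(sim_config(n_breeds = 3, n_per_breed = 40,
                                      n_markers = 100, fst = fst,
                                      admixed_fraction = 0, seed = seed))
    gm <- ds$genotypes
    c(delta = mean(delta_score(gm)$score),
      fst = mean(fst_score(gm)$score),
      inn = mean(rosenberg_in_score(gm)$score),
      mi = mean(mutual_information_score(gm)$score))
  }
  v <- vapply(c(0.02, 0.08, 0.2), stat_means, numeric(4), seed = 5)
  for (r in seq_len(nrow(v))) expect_true(all(diff(v[r, ]) > 0))
})

test_that("random-forest importances rank a diagnostic marker first", {
  set.seed(9)
  n <- 60
  labels <- rep(c("A", "B"), each = n / 2)
  noise <- matrix(sample(0:2, n * 50, replace = TRUE), n, 50)
  signal <- ifelse(labels == "A", 0L, 2L)
  gm <- toy_gm(cbind(signal, noise), labels = labels)

  top_hits <- 0L
  for (s in 1:20) {
    sc <- rf_importance_scores(gm, measure = "mdg", n_trees = 200, seed = s)
    if (which.max(sc$score) == 1L) top_hits <- top_hits + 1L
  }
  expect_gte(top_hits / 20, 0.95)

  # constant column has zero impurity importance, ~0 permutation importance
  gm2 <- toy_gm(cbind(signal, rep(1L, n), noise[, 1:10]), labels = labels)
  mdg <- rf_importance_scores(gm2, measure = "mdg", n_trees = 100, seed = 1)
  expect_equal(mdg$score[2], 0)
  mda <- rf_importance_scores(gm2, measure = "mda", n_trees = 100, seed = 1)
  expect_lt(abs(mda$score[2]), 1e-6)

  expect_identical(rf_importance_scores(gm, measure = "mda", seed = 4)$score,
                   rf_importance_scores(gm, measure = "mda", seed = 4)$score)
})

test_that("top-n selection orders by score with positional tie-break", {
  map <- toy_map(3)
  sc <- breedkit:::new_marker_scores(map, c(3, 1, 2), "delta")
  expect_identical(select_top_n(sc, 2)$id, map$id[c(1, 3)])
  expect_identical(select_top_n(sc, 3)$id, map$id[c(1, 3, 2)])
  expect_error(select_top_n(sc, 4), "only 3")

  # ties resolved by (chromosome, position) ascending
  tied <- breedkit:::new_marker_scores(toy_map(4), c(1, 1, 1, 1), "delta")
  expect_identical(select_top_n(tied, 2)$id, tied$id[1:2])
})

test_that("DFI combiners match linear depth-scan oracles", {
  for (case in 1:50) {
    sc <- random_scores(m = 60, seed = 2000 + case)
    n <- sample(5:30, 1)
    want_u <- oracle_dfi_union(sc$d, sc$f, sc$i, n)
    got_u <- dfi_union(sc$d, sc$f, sc$i, n)
    expect_identical(got_u$id, want_u$ids)
    expect_identical(attr(got_u, "depth"), want_u$k)

    want_i <- oracle_dfi_inter(sc$d, sc$f, sc$i, n)
    got_i <- dfi_inter(sc$d, sc$f, sc$i, n)
    expect_identical(got_i$id, want_i$ids)
    expect_identical(attr(got_i, "depth"), want_i$t)
  }
})

test_that("DFI combiners handle identical and disjoint rankings analytically", {
  map <- toy_map(30)
  set.seed(55)
  s <- stats::runif(30)
  same <- lapply(c("delta", "fst", "in"), function(m)
    breedkit:::new_marker_scores(map, s, m))
  # identical rankings: both combiners return the plain top-n at depth n
  top <- select_top_n(same[[1]], 10)
  u <- dfi_union(same[[1]], same[[2]], same[[3]], 10)
  i <- dfi_inter(same[[1]], same[[2]], same[[3]], 10)
  expect_setequal(u$id, top$id)
  expect_setequal(i$id, top$id)
  expect_identical(attr(u, "depth"), 10L)
  expect_identical(attr(i, "depth"), 10L)

  # three pairwise-disjoint top lists: per-method depth ceil(n/3)
  s1 <- c(rep(3, 10), rep(2, 10), rep(1, 10)) + seq(0.01, 0.3, by = 0.01)
  s2 <- c(rep(1, 10), rep(3, 10), rep(2, 10)) + seq(0.01, 0.3, by = 0.01)
  s3 <- c(rep(2, 10), rep(1, 10), rep(3, 10)) + seq(0.01, 0.3, by = 0.01)
  sc1 <- breedkit:::new_marker_scores(map, s1, "delta")
  sc2 <- breedkit:::new_marker_scores(map, s2, "fst")
  sc3 <- breedkit:::new_marker_scores(map, s3, "in")
  u9 <- dfi_union(sc1, sc2, sc3, 9)
  expect_identical(attr(u9, "depth"), 3L)
  expect_identical(nrow(u9), 9L)
  expect_error(dfi_union(sc1, sc2, sc3, 31), "universe")
  expect_error(dfi_inter(sc1, sc2, sc3, 31), "max achievable")
})

test_that("panels nest across the size ladder for every method", {
  ds <- simulate_dataset(sim_config(n_breeds = 5, n_per_breed = 20,
                                    n_markers = 800, fst = 0.08,
                                    admixed_fraction = 0, seed = 71))
  gm <- ds$genotypes
  sizes <- c(20L, 50L, 100L, 200L, 600L)
  d <- delta_score(gm); f <- fst_score(gm); i <- rosenberg_in_score(gm)
  mi <- mutual_information_score(gm)
  ladders <- list(
    topn_delta = lapply(sizes, function(n) select_top_n(d, n)),
    topn_mi = lapply(sizes, function(n) select_top_n(mi, n)),
    dfi_union = lapply(sizes, function(n) dfi_union(d, f, i, n)),
    dfi_inter = lapply(sizes, function(n) dfi_inter(d, f, i, n)))
  for (ladder in ladders) {
    for (k in seq_len(length(sizes) - 1)) {
      expect_true(all(ladder[[k]]$id %in% ladder[[k + 1]]$id))
    }
    expect_identical(vapply(ladder, nrow, 1L), sizes)
  }
  # each method contributes its own top markers to the union panel
  u <- dfi_union(d, f, i, 60)
  for (sc in list(d, f, i)) {
    expect_true(all(select_top_n(sc, 20)$id %in% u$id))
  }
})
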