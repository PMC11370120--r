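#' Simulation configuration for multi-breed genotype data
#'
#' Collects the knobs of the built-in generator. Defaults emulate a
#' sheep-style study design: 13 breeds with 17-39 animals each, a
#' SNP:InDel ratio of 5.3:1, markers spread over 26 autosomes, a
#' differentiation level `fst` of 0.1 and a ~10% minority of two-source
#' admixed individuals.
#'
#' @param n_breeds number of breeds K (>= 2).
#' @param n_per_breed integer vector of breed sizes (length 1 recycled,
#'   length K, or `NULL` to draw uniformly from `size_range`).
#' @param n_markers total marker count M.
#' @param fst Balding-Nichols differentiation parameter in (0, 1).
#' @param snp_indel_ratio SNPs per InDel; the map carries
#'   `round(M / (ratio + 1))` InDels.
#' @param admixed_fraction proportion of individuals given two-source
#'   admixed ancestry, in \[0, 1).
#' @param admix_alpha symmetric Dirichlet concentration for the two
#'   admixture proportions.
#' @param size_range inclusive range breed sizes are drawn from when
#'   `n_per_breed` is `NULL`.
#' @param n_chrom number of autosome labels positions are spread over.
#' @param chrom_bp autosome length in bp used to place positions.
#' @param seed integer seed; every draw of the generator is a
#'   deterministic function of it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_breeds = 13, n_per_breed = NULL, n_markers = 6000,
                       fst = 0.1, snp_indel_ratio = 5.3,
                       admixed_fraction = 0.1, admix_alpha = 0.5,
                       size_range = c(17L, 39L), n_chrom = 26L,
                       chrom_bp = 1e8, seed = 1L) {
  if (n_breeds < 2) stop("n_breeds must be >= 2")
  if (n_markers < 1) stop("n_markers must be >= 1")
  if (!(fst > 0 && fst < 1)) stop("fst must lie strictly in (0, 1)")
  if (snp_indel_ratio <= 0) stop("snp_indel_ratio must be positive")
  if (admixed_fraction < 0 || admixed_fraction >= 1) {
    stop("admixed_fraction must lie in [0, 1)")
  }
  if (!is.null(n_per_breed)) {
    if (length(n_per_breed) == 1L) n_per_breed <- rep(n_per_breed, n_breeds)
    if (length(n_per_breed) != n_breeds) {
      stop("n_per_breed must have length 1 or n_breeds")
    }
    if (any(n_per_breed < 1)) stop("breed sizes must be positive")
  }
  structure(list(n_breeds = as.integer(n_breeds), n_per_breed = n_per_breed,
                 n_markers = as.integer(n_markers), fst = fst,
                 snp_indel_ratio = snp_indel_ratio,
                 admixed_fraction = admixed_fraction,
                 admix_alpha = admix_alpha,
                 size_range = as.integer(size_range),
                 n_chrom = as.integer(n_chrom), chrom_bp = chrom_bp,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw breed allele frequencies under the Balding-Nichols model
#'
#' Each breed's frequency at a marker is drawn around the ancestral
#' frequency p from Beta(p(1-F)/F, (1-p)(1-F)/F), so that F is the
#' expected Wright's FST between breeds. Frequencies are clamped to
#' \[0.01, 0.99\] to avoid degenerate (fixed) markers.
#'
#' @param p_anc vector of ancestral allele frequencies, all in (0, 1).
#' @param fst differentiation parameter in (0, 1).
#' @param n_breeds number of breeds.
#' @param seed integer seed.
#' @return Matrix of breed-by-marker reference-allele frequencies.
#' @export
simulate_breed_frequencies <- function(p_anc, fst, n_breeds, seed = NULL) {
  if (any(p_anc <= 0 | p_anc >= 1)) {
    stop("ancestral frequencies must lie strictly in (0, 1)")
  }
  if (!(fst > 0 && fst < 1)) stop("fst must lie strictly in (0, 1)")
  if (n_breeds < 1) stop("n_breeds must be positive")
  m <- length(p_anc)
  scale <- (1 - fst) / fst
  f <- with_seed(seed, {
    draws <- stats::rbeta(n_breeds * m,
                          shape1 = rep(p_anc, each = n_breeds) * scale,
                          shape2 = rep(1 - p_anc, each = n_breeds) * scale)
    matrix(draws, nrow = n_breeds, ncol = m)
  })
  f <- pmin(pmax(f, 0.01), 0.99)
  rownames(f) <- sprintf("B%02d", seq_len(n_breeds))
  f
}

#' Simulate genotypes for individuals of given ancestry
#'
#' Draws each dosage independently as Binomial(2, sum_k q_k f_km): the
#' generative model the supervised admixture likelihood assumes.
#'
#' @param breed_freqs breeds-by-markers frequency matrix with entries
#'   strictly in (0, 1).
#' @param q ancestry vector over the breeds (rows of `breed_freqs`),
#'   non-negative, summing to 1 within 1e-8.
#' @param n number of individuals to draw.
#' @param seed integer seed.
#' @return Integer dosage matrix (n rows) with values in \{0, 1, 2\}.
#' @export
simulate_genotypes <- function(breed_freqs, q, n, seed = NULL) {
  breed_freqs <- as.matrix(breed_freqs)
  if (any(breed_freqs <= 0 | breed_freqs >= 1)) {
    stop("breed frequencies must lie strictly in (0, 1); clamp before sampling")
  }
  if (length(q) != nrow(breed_freqs)) stop("q length must match breed count")
  if (any(q < 0) || abs(sum(q) - 1) > 1e-8) {
    stop("q must be non-negative and sum to 1 (within 1e-8)")
  }
  p <- as.vector(crossprod(q, breed_freqs))  # marker-wise mixture frequency
  g <- with_seed(seed, {
    matrix(stats::rbinom(n * length(p), 2L, rep(p, each = n)),
           nrow = n, ncol = length(p))
  })
  storage.mode(g) <- "integer"
  colnames(g) <- colnames(breed_freqs)
  g
}

#' Simulate a complete multi-breed dataset
#'
#' Produces a labeled [genotype_matrix()] (purebreds plus a configurable
#' minority of two-source admixed individuals), the true ancestry matrix
#' of every individual, the breed allele frequencies used, and a marker
#' map with SNP/InDel types spread over autosome-labeled chromosomes at
#' positions compatible with 500-kb LD windowing.
#'
#' @param config a [sim_config()].
#' @return List of class `sim_dataset` with elements `genotypes`
#'   (genotype_matrix), `true_q` (individuals x breeds), `breed_freqs`
#'   and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  K <- config$n_breeds
  M <- config$n_markers
  seeds <- derive_seeds(config$seed, 6L)

  sizes <- config$n_per_breed
  if (is.null(sizes)) {
    sizes <- with_seed(seeds[[1]],
      sample(seq(config$size_range[1], config$size_range[2]), K, replace = TRUE))
  }
  breeds <- sprintf("B%02d", seq_len(K))
  labels <- rep(breeds, times = sizes)
  N <- length(labels)

  p_anc <- with_seed(seeds[[2]], stats::runif(M, 0.1, 0.9))
  f <- simulate_breed_frequencies(p_anc, config$fst, K, seed = seeds[[3]])

  # true ancestry: one-hot for purebreds; Dirichlet(alpha, alpha) over the
  # labeled breed and one random second source for the admixed minority,
  # with the labeled breed taking the larger component so labels stay
  # majority-correct.
  true_q <- matrix(0, N, K, dimnames = list(NULL, breeds))
  true_q[cbind(seq_len(N), match(labels, breeds))] <- 1
  n_admix <- round(config$admixed_fraction * N)
  if (n_admix > 0) {
    with_seed(seeds[[4]], {
      adm <- sample.int(N, n_admix)
      for (i in adm) {
        k <- match(labels[i], breeds)
        other <- sample(setdiff(seq_len(K), k), 1L)
        w <- stats::rbeta(1, config$admix_alpha, config$admix_alpha)
        w <- max(w, 1 - w)
        true_q[i, ] <- 0
        true_q[i, k] <- w
        true_q[i, other] <- 1 - w
      }
    })
  }

  map <- simulate_marker_map(M, config$snp_indel_ratio, config$n_chrom,
                             config$chrom_bp, seed = seeds[[5]])

  g <- with_seed(seeds[[6]], {
    p <- true_q %*% f  # N x M mixture frequencies
    matrix(stats::rbinom(N * M, 2L, p), nrow = N, ncol = M)
  })
  storage.mode(g) <- "integer"
  rownames(g) <- sprintf("%s_i%03d", labels, stats::ave(seq_len(N), labels,
                                                        FUN = seq_along))
  gm <- genotype_matrix(g, map, labels)
  rownames(true_q) <- rownames(gm$dosages)
  structure(list(genotypes = gm, true_q = true_q, breed_freqs = f,
                 config = config),
            class = "sim_dataset")
}

# Marker map: InDel count round(M / (ratio + 1)); markers spread over
# n_chrom chromosomes in contiguous blocks, sorted positions uniform on
# [1, chrom_bp]; random distinct REF/ALT bases for SNPs, multi-base
# REF or ALT (1-10 bp events) for InDels.
simulate_marker_map <- function(n_markers, snp_indel_ratio, n_chrom,
                                chrom_bp, seed = NULL) {
  with_seed(seed, {
    n_indel <- round(n_markers / (snp_indel_ratio + 1))
    type <- rep("SNP", n_markers)
    if (n_indel > 0) type[sample.int(n_markers, n_indel)] <- "InDel"
    chrom <- as.character(rep_len(rep(seq_len(n_chrom),
                                      each = ceiling(n_markers / n_chrom)),
                                  n_markers))
    pos <- unlist(lapply(split(seq_along(chrom), factor(chrom, levels = unique(chrom))),
                         function(ix) sort(sample.int(chrom_bp, length(ix)))),
                  use.names = FALSE)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_markers, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    is_ind <- type == "InDel"
    if (any(is_ind)) {
      ins <- is_ind & (stats::runif(n_markers) < 0.5)
      del <- is_ind & !ins
      ext <- function(n) vapply(sample.int(10, n, replace = TRUE), function(l)
        paste(sample(bases, l, replace = TRUE), collapse = ""), character(1))
      alt[ins] <- paste0(ref[ins], ext(sum(ins)))
      ref[del] <- paste0(ref[del], ext(sum(del)))
      alt[del] <- substr(ref[del], 1L, 1L)
    }
    data.frame(id = sprintf("m%06d", seq_len(n_markers)),
               chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
               type = type, stringsAsFactors = FALSE)
  })
}
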