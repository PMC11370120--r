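#' Pipeline configuration
#'
#' Validates and normalizes the configuration driving [run_pipeline()].
#' Either file inputs (`vcf` or `dosage_stem`) or a `simulate` block
#' (passed to [sim_config()]) must be given.
#'
#' @param ... configuration fields, or a single list (e.g. from
#'   [yaml::read_yaml()]). Recognized fields: `vcf`, `dosage_stem`,
#'   `simulate` (list), `marker_type` ("SNP"/"InDel"/"SI"),
#'   `detection` (delta/fst/in/mi/mda/mdg/dfi_inter/dfi_union),
#'   `classifier` (knn/svm/rf/ksr), `panel_sizes`, `purity_threshold`,
#'   `ld_r2`, `ld_window_bp`, `autosomes`, `folds`, `replicates`,
#'   `knn_k`, `seed`, `out_dir`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && is.null(names(args))) {
    args <- args[[1]]
  }
  cfg <- utils::modifyList(list(
    vcf = NULL, dosage_stem = NULL, simulate = NULL,
    marker_type = "SI", detection = "dfi_union", classifier = "ksr",
    panel_sizes = c(200L, 400L, 600L, 800L, 1000L, 2000L, 3000L, 4000L,
                    5000L, 6000L),
    labels_file = NULL,
    purity_threshold = 0.9, ld_r2 = 0.2, ld_window_bp = 500000L,
    autosomes = as.character(1:26), folds = 10L, replicates = 50L,
    knn_k = 1L, mislabel_k = 5L, seed = 1L, out_dir = "breedkit_run"),
    args)
  match1 <- function(v, choices, what) {
    if (!v %in% choices) stop("invalid ", what, " '", v, "'; choose one of: ",
                              paste(choices, collapse = ", "))
    v
  }
  cfg$marker_type <- match1(cfg$marker_type, c("SNP", "InDel", "SI"),
                            "marker_type")
  cfg$detection <- match1(cfg$detection,
                          c("delta", "fst", "in", "mi", "mda", "mdg",
                            "dfi_inter", "dfi_union"), "detection")
  cfg$classifier <- match1(cfg$classifier, c("knn", "svm", "rf", "ksr"),
                           "classifier")
  if (is.null(cfg$vcf) && is.null(cfg$dosage_stem) && is.null(cfg$simulate)) {
    stop("config needs an input: vcf, dosage_stem, or simulate block")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys as in [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

pipe_log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " | ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full breed-identification workflow
#'
#' Stages: load or simulate genotypes; marker QC; per-type LD pruning
#' (and SNP+InDel merge for the SI set); neighbor-joining mislabel
#' screen; GBC estimation and purebred screen to establish the
#' training population; breed-informative marker selection; replicated
#' tenfold cross-validated classification. Every stage logs its
#' marker/individual counts and writes its artifact into
#' `config$out_dir`. Stage seeds are derived deterministically from
#' `config$seed`, so reruns are byte-identical.
#'
#' @param config a [pipeline_config()] (or list coerced to one).
#' @return Invisibly, a list with the per-stage objects (`genotypes`,
#'   `pruned`, `tree`, `flagged`, `gbc`, `training_ids`, `panels`,
#'   `accuracy`) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(config$out_dir, "pipeline.log"), open = "wt")
  on.exit(close(log_con))
  seeds <- derive_seeds(config$seed, 5L)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  gm <- run_stage("input", {
    if (!is.null(config$simulate)) {
      sim <- do.call(sim_config, utils::modifyList(config$simulate,
                                                   list(seed = seeds[[1]])))
      simulate_dataset(sim)$genotypes
    } else if (!is.null(config$vcf)) {
      rec <- read_vcf(config$vcf)
      snp <- !rec$sites$multiallelic &
        classify_marker(rec$sites$ref, gsub(",.*", "", rec$sites$alt)) == "SNP"
      rec_f <- hard_filter(subset_records(rec, snp), "SNP")
      ind_f <- hard_filter(subset_records(rec, !snp), "InDel")
      merged <- list(sites = rbind(rec_f$sites, ind_f$sites),
                     dosages = rbind(rec_f$dosages, ind_f$dosages),
                     individual_ids = rec$individual_ids)
      class(merged) <- "variant_records"
      qc_filter(merged, autosomes = config$autosomes)
    } else {
      read_dosage_matrix(config$dosage_stem)
    }
  })
  if (!is.null(config$labels_file)) {
    lt <- utils::read.table(config$labels_file, header = TRUE, sep = "\t",
                            colClasses = "character")
    gm$labels <- stats::setNames(
      lt$breed_code[match(rownames(gm$dosages), lt$individual_id)],
      rownames(gm$dosages))
  }
  if (is.null(gm$labels)) {
    stop("breed labels required: provide labels_file or labeled input")
  }
  pipe_log(log_con, "input: ", nrow(gm$dosages), " individuals, ",
           ncol(gm$dosages), " markers, ", length(unique(gm$labels)),
           " breeds")

  gm <- run_stage("qc", qc_filter(gm, autosomes = config$autosomes))
  pipe_log(log_con, "qc: ", ncol(gm$dosages), " markers retained")
  utils::write.table(gm$map, file.path(config$out_dir, "qc_markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  pruned <- run_stage("prune", {
    snp <- subset_genotypes(gm, markers = which(gm$map$type == "SNP"))
    ind <- subset_genotypes(gm, markers = which(gm$map$type == "InDel"))
    snp_p <- ld_prune(snp, config$ld_r2, config$ld_window_bp)
    ind_p <- if (ncol(ind$dosages) > 0) {
      ld_prune(ind, config$ld_r2, config$ld_window_bp)
    } else ind
    si_p <- if (ncol(ind_p$dosages) > 0) {
      merge_si(snp_p, ind_p, config$ld_r2, config$ld_window_bp)
    } else snp_p
    list(SNP = snp_p, InDel = ind_p, SI = si_p)
  })
  pipe_log(log_con, "prune: SNP ", ncol(pruned$SNP$dosages), ", InDel ",
           ncol(pruned$InDel$dosages), ", SI ", ncol(pruned$SI$dosages))

  work <- pruned[[config$marker_type]]
  if (ncol(work$dosages) == 0L) stop("no markers of type ", config$marker_type)

  tree <- run_stage("tree", nj_tree(p_distance_matrix(pruned$SNP)))
  ape::write.tree(tree, file.path(config$out_dir, "nj_tree.nwk"))
  flagged <- run_stage("mislabel_screen",
                       flag_mislabeled(tree, work$labels, k = config$mislabel_k))
  writeLines(flagged, file.path(config$out_dir, "flagged_individuals.txt"))
  pipe_log(log_con, "mislabel screen: ", length(flagged), " flagged")

  gbc <- run_stage("gbc", gbc_crossval(work, folds = config$folds,
                                       threshold = config$purity_threshold,
                                       seed = seeds[[2]]))
  write_gbc_report(gbc, file.path(config$out_dir, "gbc_report.tsv"))
  training_ids <- run_stage("purebred_screen",
                            screen_purebred(gbc, flagged = flagged))
  pipe_log(log_con, "training population: ", length(training_ids), " of ",
           nrow(work$dosages), " individuals")
  train <- subset_genotypes(work, individuals = training_ids)

  panels <- run_stage("marker_selection", {
    sizes <- config$panel_sizes[config$panel_sizes <= ncol(train$dosages)]
    if (!length(sizes)) stop("every requested panel size exceeds the ",
                             ncol(train$dosages), " available markers")
    sel <- select_panels(train, config$detection, sizes, seed = seeds[[3]])
    for (i in seq_along(sel)) {
      write_marker_panel(sel[[i]], file.path(
        config$out_dir, sprintf("panel_%s_%d.tsv", config$detection,
                                attr(sel[[i]], "n"))))
    }
    sel
  })
  pipe_log(log_con, "panels (", config$detection, "): sizes ",
           paste(vapply(panels, attr, 1L, "n"), collapse = ", "))

  accuracy <- run_stage("classification", {
    out <- list()
    for (p in panels) {
      rep <- tenfold_cv(train, panel = p, method = config$classifier,
                        folds = config$folds, replicates = config$replicates,
                        params = list(k = config$knn_k), seed = seeds[[4]])
      write_accuracy_report(rep, file.path(
        config$out_dir, sprintf("cv_%s_%s_%d", config$classifier,
                                config$detection, attr(p, "n"))))
      pipe_log(log_con, "cv ", config$classifier, " n=", attr(p, "n"), ": ",
               sprintf("%.2f%%", rep$accuracy))
      out[[as.character(attr(p, "n"))]] <- rep
    }
    out
  })

  invisible(list(genotypes = gm, pruned = pruned, tree = tree,
                 flagged = flagged, gbc = gbc, training_ids = training_ids,
                 panels = panels, accuracy = accuracy,
                 out_dir = config$out_dir))
}

# Build nested panels of the requested sizes under one detection method.
select_panels <- function(train, detection, sizes, seed = NULL) {
  scorer <- function(method) switch(method,
    delta = delta_score(train),
    fst = fst_score(train),
    "in" = rosenberg_in_score(train),
    mi = mutual_information_score(train),
    mda = rf_importance_scores(train, measure = "mda", seed = seed),
    mdg = rf_importance_scores(train, measure = "mdg", seed = seed))
  if (detection %in% c("dfi_inter", "dfi_union")) {
    d <- scorer("delta"); f <- scorer("fst"); i <- scorer("in")
    builder <- if (detection == "dfi_inter") dfi_inter else dfi_union
    lapply(sizes, function(n) builder(d, f, i, n))
  } else {
    sc <- scorer(detection)
    lapply(sizes, function(n) select_top_n(sc, n))
  }
}

#' Accuracy grid over detection methods, classifiers and panel sizes
#'
#' Runs [tenfold_cv()] for every cell of the grid on an established
#' training population. All cells of a replicate share the same fold
#' randomization (the CV seed is common), so methods are compared on
#' identical splits.
#'
#' @param train a labeled [genotype_matrix()] (training population).
#' @param detections detection methods (see [pipeline_config()]).
#' @param classifiers classifier names.
#' @param sizes panel sizes.
#' @param folds,replicates,seed as in [tenfold_cv()].
#' @return Data frame with one row per grid cell: detection,
#'   classifier, size, accuracy (%).
#' @export
grid_run <- function(train, detections = c("dfi_inter", "dfi_union"),
                     classifiers = c("knn", "svm", "rf", "ksr"),
                     sizes = c(200L, 1000L), folds = 10L, replicates = 10L,
                     seed = 1L) {
  stopifnot(inherits(train, "genotype_matrix"))
  rows <- list()
  for (det in detections) {
    panels <- select_panels(train, det, sizes, seed = seed)
    for (p in panels) {
      for (cl in classifiers) {
        rep <- tenfold_cv(train, panel = p, method = cl, folds = folds,
                          replicates = replicates, seed = seed)
        rows[[length(rows) + 1L]] <- data.frame(
          detection = det, classifier = cl, size = attr(p, "n"),
          accuracy = rep$accuracy, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
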