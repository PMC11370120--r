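#' Train a classifier and predict breeds for test individuals
#'
#' Base learners: KNN (`class::knn`, k = 1 by default), linear SVM
#' (`e1071::svm`, C-classification, cost 1, no feature scaling --
#' dosages share a common scale) and random forest (`ranger`, 500
#' trees, mtry = floor(sqrt(M))). Test markers are aligned to the
#' training panel by marker id before prediction.
#'
#' @param method `"knn"`, `"svm"` or `"rf"`.
#' @param train a labeled [genotype_matrix()] (or dosage matrix when
#'   `labels` is given).
#' @param test a [genotype_matrix()] or dosage matrix over the same
#'   markers.
#' @param labels training breed codes (defaults to `train$labels`).
#' @param params optional list: `k` (KNN), `cost` (SVM), `n_trees`
#'   (RF).
#' @param seed integer seed for the stochastic learners.
#' @return Character vector of predicted breed codes, one per test
#'   individual.
#' @export
train_predict <- function(method = c("knn", "svm", "rf"), train, test,
                          labels = NULL, params = list(), seed = NULL) {
  method <- match.arg(method)
  if (inherits(train, "genotype_matrix")) {
    labels <- labels %||% train$labels
    train <- train$dosages
  }
  if (inherits(test, "genotype_matrix")) test <- test$dosages
  if (is.null(labels)) stop("training labels required")
  test <- align_markers(train, test)
  y <- factor(labels)
  if (nlevels(y) == 1L) return(rep(as.character(levels(y)), nrow(test)))
  pred <- switch(method,
    knn = with_seed(seed,
      class::knn(train, test, y, k = params$k %||% 1L)),
    svm = {
      fit <- with_seed(seed,
        e1071::svm(x = train, y = y, type = "C-classification",
                   kernel = "linear", cost = params$cost %||% 1,
                   scale = FALSE))
      stats::predict(fit, test)
    },
    rf = {
      fit <- ranger::ranger(x = train, y = y,
                            num.trees = params$n_trees %||% 500L,
                            mtry = floor(sqrt(ncol(train))),
                            num.threads = 1L, seed = seed %||% 1L)
      stats::predict(fit, data = test, num.threads = 1L)$predictions
    })
  as.character(pred)
}

# Align test columns with training columns by marker id; error listing
# the missing ids when alignment is impossible.
align_markers <- function(train, test) {
  if (is.null(colnames(train)) || is.null(colnames(test))) {
    if (ncol(train) != ncol(test)) stop("marker count mismatch between train and test")
    return(test)
  }
  miss <- setdiff(colnames(train), colnames(test))
  if (length(miss)) {
    stop("test set lacks training panel markers: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5) else "")
  }
  test[, colnames(train), drop = FALSE]
}

#' KSR ensemble rule
#'
#' Integrates KNN, SVM and RF predictions per individual: the breed
#' predicted by at least two of the three methods wins; when all three
#' disagree the KNN prediction is taken. Vectorized.
#'
#' @param knn_pred,svm_pred,rf_pred breed-code vectors of equal length.
#' @return Character vector of final breed calls.
#' @export
ksr_combine <- function(knn_pred, svm_pred, rf_pred) {
  knn_pred <- as.character(knn_pred)
  svm_pred <- as.character(svm_pred)
  rf_pred <- as.character(rf_pred)
  stopifnot(length(knn_pred) == length(svm_pred),
            length(knn_pred) == length(rf_pred))
  # any pair containing KNN already yields the KNN answer, so the only
  # way KNN is overruled is SVM agreeing with RF
  ifelse(svm_pred == rf_pred, svm_pred, knn_pred)
}

#' Assignment accuracy over replicates
#'
#' Accuracy = mean over replicates of N_T / (N_T + N_F) x 100, where
#' N_T (N_F) counts correctly (wrongly) assigned test individuals in a
#' replicate.
#'
#' @param assignments list with one character vector of predicted
#'   breeds per replicate (or a single vector).
#' @param truth true breed codes, recycled across replicates.
#' @return List: `accuracy` (mean %), `per_replicate` (%).
#' @export
assignment_accuracy <- function(assignments, truth) {
  if (!is.list(assignments)) assignments <- list(assignments)
  if (length(truth) == 0L) stop("empty test set")
  per <- vapply(assignments, function(p) {
    stopifnot(length(p) == length(truth))
    100 * sum(p == truth) / length(truth)
  }, numeric(1))
  list(accuracy = mean(per), per_replicate = per)
}

#' Replicated stratified tenfold cross-validation of breed assignment
#'
#' For each replicate, every breed is split into `folds` subsets
#' (sizes differing by at most one); each subset in turn is the
#' validation set and the rest the training set, restricted to the
#' markers of `panel`. Replicates differ only in their fold
#' randomization and learner seeds. For `method = "ksr"` the three
#' base learners are fitted once per fold and combined with
#' [ksr_combine()]; their individual predictions are kept in the
#' report.
#'
#' @param x a labeled [genotype_matrix()] (the established training
#'   population).
#' @param panel a `marker_panel` (or marker id vector); `NULL` uses
#'   all markers.
#' @param method `"knn"`, `"svm"`, `"rf"` or `"ksr"`.
#' @param labels breed codes (defaults to `x$labels`).
#' @param folds fold count, default 10.
#' @param replicates replicate count, default 50.
#' @param params passed to [train_predict()].
#' @param seed root seed; replicate seeds are derived from it.
#' @return Object of class `accuracy_report`: overall and per-breed
#'   accuracies (%), mean confusion matrix, per-replicate assignment
#'   tables.
#' @export
tenfold_cv <- function(x, panel = NULL, method = c("ksr", "knn", "svm", "rf"),
                       labels = NULL, folds = 10L, replicates = 50L,
                       params = list(), seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(x, "genotype_matrix"))
  labels <- labels %||% x$labels
  if (is.null(labels)) stop("breed labels required")
  if (!is.null(panel)) {
    ids <- if (inherits(panel, "data.frame")) panel$id else as.character(panel)
    x <- subset_genotypes(x, markers = ids)
  }
  d <- x$dosages
  base <- if (method == "ksr") c("knn", "svm", "rf") else method
  rep_seeds <- derive_seeds(seed, replicates)
  assignments <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    sub_seeds <- derive_seeds(rep_seeds[[r]], folds * length(base) + 1L)
    fold_id <- assign_folds(labels, folds, sub_seeds[[1]])
    pred <- matrix(NA_character_, nrow(d), length(base),
                   dimnames = list(rownames(d), base))
    si <- 1L
    for (f in sort(unique(fold_id))) {
      tr <- which(fold_id != f)
      te <- which(fold_id == f)
      for (b in base) {
        si <- si + 1L
        pred[te, b] <- train_predict(b, d[tr, , drop = FALSE],
                                     d[te, , drop = FALSE],
                                     labels = labels[tr], params = params,
                                     seed = sub_seeds[[si]])
      }
    }
    final <- if (method == "ksr") {
      ksr_combine(pred[, "knn"], pred[, "svm"], pred[, "rf"])
    } else pred[, method]
    assignments[[r]] <- data.frame(individual_id = rownames(d),
                                   truth = labels, pred,
                                   final = final, stringsAsFactors = FALSE)
  }
  build_accuracy_report(assignments, method)
}

build_accuracy_report <- function(assignments, method) {
  truth <- assignments[[1]]$truth
  breeds <- sort(unique(truth))
  per_rep <- vapply(assignments, function(a)
    100 * mean(a$final == a$truth), numeric(1))
  per_breed <- rowMeans(vapply(assignments, function(a)
    vapply(breeds, function(b)
      100 * mean(a$final[a$truth == b] == b), numeric(1)),
    numeric(length(breeds))))
  conf <- Reduce(`+`, lapply(assignments, function(a)
    unclass(table(factor(a$truth, breeds), factor(a$final, breeds))))) /
    length(assignments)
  structure(list(method = method, accuracy = mean(per_rep),
                 per_replicate = per_rep,
                 per_breed = stats::setNames(per_breed, breeds),
                 confusion = conf, assignments = assignments,
                 n_test = length(truth)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("accuracy_report (", x$method, "): ",
      sprintf("%.2f%%", x$accuracy), " over ",
      length(x$per_replicate), " replicate(s), ", x$n_test,
      " individuals\n", sep = "")
  worst <- which.min(x$per_breed)
  cat("per-breed range: ", sprintf("%.2f%%", min(x$per_breed)), " (",
      names(x$per_breed)[worst], ") - ",
      sprintf("%.2f%%", max(x$per_breed)), "\n", sep = "")
  invisible(x)
}

#' Mean confusion matrix of an accuracy report
#'
#' True breeds in rows, assigned breeds in columns; entries are mean
#' counts over replicates, so each row sums to that breed's test size.
#'
#' @param report an `accuracy_report`.
#' @return Numeric matrix.
#' @export
confusion_matrix <- function(report) {
  stopifnot(inherits(report, "accuracy_report"))
  report$confusion
}

#' Write accuracy report tables
#'
#' Emits `<stem>.accuracy.tsv` (overall and per-breed accuracies),
#' `<stem>.confusion.tsv` (mean confusion matrix) and
#' `<stem>.assignments.tsv` (per-replicate individual assignments).
#'
#' @param report an `accuracy_report`.
#' @param stem output path stem.
#' @return `stem`, invisibly.
#' @export
write_accuracy_report <- function(report, stem) {
  stopifnot(inherits(report, "accuracy_report"))
  acc <- data.frame(breed = c(names(report$per_breed), "Total"),
                    accuracy = c(report$per_breed, report$accuracy))
  utils::write.table(acc, paste0(stem, ".accuracy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(breed = rownames(report$confusion),
                                report$confusion, check.names = FALSE),
                     paste0(stem, ".confusion.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  asg <- do.call(rbind, lapply(seq_along(report$assignments), function(i)
    cbind(replicate = i, report$assignments[[i]])))
  utils::write.table(asg, paste0(stem, ".assignments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stem)
}
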