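#' Simulation configuration
#'
#' @param up_threshold ratio above which a gene is a positive example
#' @param split_fraction fraction of genes in the training half
#' @param ru undersampling ratio: fraction of negative training genes kept
#' @param c_grid,gamma_grid grids for the classifier's C (inverse
#'   regularization) and RBF gamma
#' @param cv_folds stratified cross-validation folds used in the grid search
#' @param seed integer seed driving split, undersampling, and folds
#' @return object of class `sim_config`
#' @export
sim_config <- function(up_threshold = 2.0, split_fraction = 0.5, ru = 1 / 16,
                       c_grid = 2^seq(-5, 15, by = 2),
                       gamma_grid = 2^seq(-15, 3, by = 2),
                       cv_folds = 5L, seed = 1L) {
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must be in (0, 1)")
  if (ru <= 0 || ru > 1) stop("ru must be in (0, 1]")
  if (up_threshold <= 1) stop("up_threshold must be > 1")
  structure(list(up_threshold = up_threshold, split_fraction = split_fraction,
                 ru = ru, c_grid = c_grid, gamma_grid = gamma_grid,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "sim_config")
}

#' Binary motif/pair presence feature matrix
#'
#' One binary column per upstream motif (presence in `upstream_region`), per
#' near-TSS motif (presence in `neartss_region`), and per selected pair
#' (both motifs present in `pair_region`).
#'
#' @param promoters a [promoter_set()]
#' @param upstream_motifs,neartss_motifs lists of `motif_group`
#' @param pairs data.frame from [select_enriched_pairs()] (needs the groups
#'   passed via `pair_groups`, a named list seed -> motif_group), or NULL
#' @param pair_groups named list of `motif_group` resolving pair motif names
#' @param upstream_region,neartss_region,pair_region TSS-relative windows
#' @return numeric matrix genes x features with 0/1 entries
#' @export
build_features <- function(promoters, upstream_motifs,
                           neartss_motifs = list(), pairs = NULL,
                           pair_groups = NULL,
                           upstream_region = c(-500L, 0L),
                           neartss_region = c(-50L, 150L),
                           pair_region = c(-500L, 150L)) {
  ids <- gene_ids(promoters)
  cols <- list()
  presence <- function(group, region) {
    as.numeric(ids %in% genes_with_motif(group, promoters, region))
  }
  for (g in upstream_motifs)
    cols[[paste0("up_", g$name)]] <- presence(g, upstream_region)
  for (g in neartss_motifs)
    cols[[paste0("tss_", g$name)]] <- presence(g, neartss_region)
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    if (is.null(pair_groups)) stop("pair_groups required when pairs are given")
    for (j in seq_len(nrow(pairs))) {
      a <- pair_groups[[pairs$motif_a[j]]]; b <- pair_groups[[pairs$motif_b[j]]]
      cols[[paste0("pair_", a$name, "_", b$name)]] <-
        presence(a, pair_region) * presence(b, pair_region)
    }
  }
  if (length(cols) == 0L) stop("empty feature space: no motifs supplied")
  if (anyDuplicated(names(cols))) stop("duplicate feature names")
  X <- do.call(cbind, cols)
  rownames(X) <- ids
  X
}

#' Up-regulation labels from expression ratios
#'
#' Strictly-greater comparison: ratio > threshold is +1, otherwise -1.
#'
#' @param expr an [expression_table()]
#' @param threshold up-regulation threshold (default twofold)
#' @return named vector of +1/-1
#' @export
make_labels <- function(expr, threshold = 2.0) {
  setNames(ifelse(as.numeric(expr) > threshold, 1L, -1L), names(expr))
}

#' Stratified random train/test split
#'
#' @param genes character vector of gene IDs
#' @param labels named +1/-1 vector covering `genes`
#' @param config a [sim_config()]
#' @return list(train, test) of gene ID vectors, both containing both classes
#' @export
split_train_test <- function(genes, labels, config = sim_config()) {
  y <- labels[genes]
  if (min(sum(y > 0), sum(y < 0)) < 2L)
    stop("each class needs at least 2 members to split")
  train <- character(0)
  set.seed(config$seed)
  for (cls in c(1L, -1L)) {
    g <- genes[y == cls]
    n_tr <- round(length(g) * config$split_fraction)
    n_tr <- min(max(n_tr, 1L), length(g) - 1L)   # both halves keep the class
    train <- c(train, sample(g, n_tr))
  }
  list(train = sort(train), test = sort(setdiff(genes, train)))
}

#' Random undersampling of negative training examples
#'
#' Keeps every positive and a uniform random fraction `ru` of the negatives
#' (rounded to nearest, at least 1).
#'
#' @param train character vector of training gene IDs
#' @param labels named +1/-1 vector
#' @param ru fraction of negatives retained
#' @param seed integer seed
#' @return reduced character vector of training genes
#' @export
undersample_negatives <- function(train, labels, ru = 1 / 16, seed = 1L) {
  if (ru <= 0 || ru > 1) stop("ru must be in (0, 1]")
  y <- labels[train]
  neg <- train[y < 0]
  if (ru == 1 || length(neg) == 0L) return(train)
  n_keep <- max(1L, round(ru * length(neg)))
  set.seed(seed)
  sort(c(train[y > 0], sample(neg, n_keep)))
}

# ---- RBF-kernel margin classifier (least-squares SVM) ----------------------
# No SVM library is available offline, so the module's classifier contract
# (binary margin classifier, RBF kernel, continuous decision values) is met
# by a least-squares SVM on +/-1 labels with a bias term:
#   [ 0  1' ] [ b     ]   [ 0 ]
#   [ 1  K + I/C ] [ alpha ] = [ y ],  decision f(x) = K(x, X) alpha + b.
# C keeps its meaning as the trade-off between training error and margin.

rbf_kernel <- function(X1, X2, gamma) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  exp(-gamma * pmax(d2, 0))
}

lssvm_solve <- function(K, y, C) {
  n <- nrow(K)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(1 / C, n)))
  sol <- solve(A, c(0, y))
  list(b = sol[1], alpha = sol[-1])
}

rls_train <- function(X, y, C, gamma) {
  K <- rbf_kernel(X, X, gamma)
  s <- lssvm_solve(K, y, C)
  structure(list(X = X, alpha = s$alpha, b = s$b, C = C, gamma = gamma),
            class = "mama_classifier")
}

#' Decision values of the trained classifier
#' @param model a trained classifier from [grid_search_train()]
#' @param X feature matrix to score
#' @return numeric vector of signed margins
#' @export
decision_values <- function(model, X) {
  as.numeric(rbf_kernel(X, model$X, model$gamma) %*% model$alpha) + model$b
}

# stratified fold assignment; redraws (new seed) if a training fold loses a
# class, at most 5 attempts
make_folds <- function(y, k, seed) {
  for (attempt in 0:4) {
    set.seed(child_seed(seed, attempt))
    fold <- integer(length(y))
    for (cls in c(1L, -1L)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[fold != f])) == 2L, logical(1)))
    if (ok) return(fold)
  }
  stop("could not build stratified folds with both classes after 5 attempts")
}

#' Grid search for C and gamma by cross-validated AUC-ROC
#'
#' For every (C, gamma) pair on the grids, estimates AUC-ROC by stratified
#' `cv_folds`-fold cross-validation on the (already undersampled) training
#' set, then refits the best pair on the full training set. Ties resolve to
#' the smallest C, then smallest gamma.
#'
#' @param X training feature matrix (rows = genes)
#' @param y +1/-1 labels aligned with rows of `X`
#' @param config a [sim_config()]
#' @return trained classifier with elements `best_c`, `best_gamma`, `cv_auc`
#' @export
grid_search_train <- function(X, y, config = sim_config()) {
  if (length(unique(y)) != 2L) stop("training data must contain both classes")
  k <- min(config$cv_folds, sum(y > 0), sum(y < 0))
  if (k < 2L) stop("too few examples per class for cross-validation")
  fold <- make_folds(y, k, config$seed)
  best <- NULL
  for (gamma in sort(config$gamma_grid)) {
    K_full <- rbf_kernel(X, X, gamma)
    for (C in sort(config$c_grid)) {
      scores <- numeric(length(y))
      for (f in seq_len(k)) {
        tr <- fold != f
        s <- lssvm_solve(K_full[tr, tr, drop = FALSE], y[tr], C)
        scores[!tr] <- as.numeric(K_full[!tr, tr, drop = FALSE] %*% s$alpha) +
          s$b
      }
      auc <- auc_roc(scores, y)
      if (is.null(best) || auc > best$auc + 1e-12) {
        best <- list(auc = auc, C = C, gamma = gamma)
      }
    }
  }
  model <- rls_train(X, y, best$C, best$gamma)
  model$best_c <- best$C
  model$best_gamma <- best$gamma
  model$cv_auc <- best$auc
  model
}

#' Evaluate a trained classifier on the untouched test half
#'
#' AUC-ROC from continuous decision values; accuracy at the sign threshold.
#'
#' @param model trained classifier
#' @param X_test,y_test test features and +1/-1 labels (both classes present)
#' @param seed seed recorded in the result
#' @return object of class `sim_result`: auc_roc, accuracy, n_test,
#'   n_correct, best_c, best_gamma, seed
#' @export
evaluate <- function(model, X_test, y_test, seed = NA_integer_) {
  if (length(unique(y_test)) != 2L) stop("test data must contain both classes")
  sc <- decision_values(model, X_test)
  pred <- ifelse(sc >= 0, 1L, -1L)
  n_correct <- sum(pred == y_test)
  structure(list(auc_roc = auc_roc(sc, y_test),
                 accuracy = n_correct / length(y_test),
                 n_test = length(y_test), n_correct = n_correct,
                 best_c = model$best_c %||% model$C,
                 best_gamma = model$best_gamma %||% model$gamma,
                 seed = seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: AUC-ROC %.4f, accuracy %.1f%% (%d/%d), C=%g gamma=%g\n",
              x$auc_roc, 100 * x$accuracy, x$n_correct, x$n_test,
              x$best_c, x$best_gamma))
  invisible(x)
}

#' End-to-end expression simulation on a feature matrix
#'
#' Split (stratified), undersample the training negatives, grid-search the
#' classifier, evaluate on the full test half.
#'
#' @param X feature matrix from [build_features()]
#' @param labels named +1/-1 vector from [make_labels()]
#' @param config a [sim_config()]
#' @return a `sim_result`
#' @export
run_expression_simulation <- function(X, labels, config = sim_config()) {
  genes <- rownames(X)
  sp <- split_train_test(genes, labels, config)
  train <- undersample_negatives(sp$train, labels, config$ru,
                                 seed = child_seed(config$seed, 1L))
  model <- grid_search_train(X[train, , drop = FALSE], labels[train], config)
  evaluate(model, X[sp$test, , drop = FALSE], labels[sp$test],
           seed = config$seed)
}
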