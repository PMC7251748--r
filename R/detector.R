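## Bagged decision-tree detector, repeated stratified k-fold evaluation,
## confusion-matrix metrics, trapezoidal AUC and per-feature significance.

POSITIVE_CLASS <- "PF"   # sensitivity = probability of catching a disorder

as_binary_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), CLASS_LABELS)
  if (length(bad))
    stop("labels must be PF or NS, got: ", paste(bad, collapse = ", "),
         call. = FALSE)
  as.numeric(labels == POSITIVE_CLASS)
}

#' Fit a bagged ensemble of decision trees
#'
#' `n_trees` CART trees (Gini impurity, unlimited depth by default), each
#' fit on a bootstrap sample of the training rows drawn with replacement
#' and of the same size as the training set. Deterministic given `seed`.
#'
#' @param x numeric feature matrix, one row per token.
#' @param labels character/factor vector of `"PF"`/`"NS"` labels.
#' @param n_trees number of base learners (default 30).
#' @param seed integer seed for the bootstrap stream.
#' @param bootstrap set `FALSE` to fit every tree on the full training set
#'   (useful for degenerate-ensemble tests).
#' @param max_depth optional depth cap for the trees.
#' @return object of class `pf_bagging`.
#' @export
fit_bagging <- function(x, labels, n_trees = 30L, seed = 1L,
                        bootstrap = TRUE, max_depth = Inf) {
  x <- as.matrix(x)
  y <- as_binary_labels(labels)
  if (nrow(x) < 2L)
    stop("need at least 2 training rows", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("degenerate-training error: both classes must be present",
         call. = FALSE)
  set.seed(as.integer(seed))
  n <- nrow(x)
  trees <- lapply(seq_len(n_trees), function(t) {
    idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    fit_tree(x[idx, , drop = FALSE], y[idx], max_depth = max_depth)
  })
  structure(list(trees = trees, n_trees = as.integer(n_trees),
                 seed = as.integer(seed), p = ncol(x)),
            class = "pf_bagging")
}

#' Predict with a bagged ensemble
#'
#' Majority vote over the trees. The vote fraction (proportion of trees
#' voting PF) doubles as the ranking score for ROC/AUC. An exactly split
#' vote is broken toward NS: at equivocal evidence the detector favours
#' "no disorder".
#'
#' @param object a `pf_bagging` model.
#' @param newdata feature matrix with the training dimensionality.
#' @param ... unused.
#' @return `data.frame` with columns `label` and `vote_pf`.
#' @export
predict.pf_bagging <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("shape error: expected ", object$p, " feature columns",
         call. = FALSE)
  votes <- vapply(object$trees, function(tr) predict_tree(tr, newdata),
                  numeric(nrow(newdata)))
  votes <- matrix(votes, nrow = nrow(newdata))
  frac <- rowMeans(votes)
  data.frame(label = ifelse(frac > 0.5, "PF", "NS"), vote_pf = frac,
             stringsAsFactors = FALSE)
}

#' Trapezoidal AUC from scores
#'
#' Area under the ROC curve via the midrank (Mann-Whitney) identity, which
#' equals the trapezoidal rule with ties averaged. Returned in percent.
#'
#' @param scores numeric scores, larger = more PF-like.
#' @param labels `"PF"`/`"NS"` labels.
#' @return AUC in \[0, 100\].
#' @export
auc_score <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC needs both classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  100 * (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusion_metrics <- function(truth, predicted) {
  tp <- sum(truth == "PF" & predicted == "PF")
  tn <- sum(truth == "NS" & predicted == "NS")
  fp <- sum(truth == "NS" & predicted == "PF")
  fn <- sum(truth == "PF" & predicted == "NS")
  c(accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

#' Repeated stratified k-fold cross-validation of the bagged detector
#'
#' Each repeat freshly shuffles a stratified k-fold partition (folds
#' balanced per class, mirroring the balanced clinical design), trains the
#' ensemble on k-1 folds and predicts the held-out fold, then computes
#' accuracy / sensitivity / specificity from the pooled confusion matrix
#' and AUC from the pooled vote fractions. Metrics are reported as mean
#' and standard deviation over the repeats (the spread flavour is SD).
#' Per-consonant metrics reuse the same pooled predictions restricted to
#' rows of each consonant type.
#'
#' @param x numeric feature matrix.
#' @param labels `"PF"`/`"NS"` per row.
#' @param consonants optional consonant type per row for the per-type table.
#' @param k folds (default 10).
#' @param repeats cross-validation repeats (default 10).
#' @param n_trees ensemble size (default 30).
#' @param seed master seed; repeat r uses derived seeds so repeat 1 is
#'   identical whether `repeats` is 1 or 10.
#' @param max_depth tree depth cap.
#' @return object of class `pf_cv`: `accuracy`, `sensitivity`,
#'   `specificity`, `auc` (each `c(mean, sd)`), `per_consonant`
#'   data.frame, `per_repeat` matrix.
#' @export
cross_validate <- function(x, labels, consonants = NULL, k = 10L,
                           repeats = 10L, n_trees = 30L, seed = 1L,
                           max_depth = Inf) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  y <- as_binary_labels(labels)
  if (min(table(labels)) < k)
    stop("config error: each class needs at least k rows", call. = FALSE)
  n <- nrow(x)
  per_repeat <- matrix(NA_real_, nrow = repeats, ncol = 4,
                       dimnames = list(NULL, c("accuracy", "sensitivity",
                                               "specificity", "auc")))
  cons_acc <- NULL
  if (!is.null(consonants)) {
    consonants <- as.character(consonants)
    cons_types <- sort(unique(consonants))
    cons_acc <- array(NA_real_, dim = c(repeats, length(cons_types), 4),
                      dimnames = list(NULL, cons_types,
                                      c("accuracy", "sensitivity",
                                        "specificity", "auc")))
  }
  for (r in seq_len(repeats)) {
    rep_seed <- (as.integer(seed) * 1009L + r * 7919L) %% .Machine$integer.max
    set.seed(rep_seed)
    fold <- integer(n)
    for (cl in CLASS_LABELS) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    pred <- character(n)
    vote <- numeric(n)
    for (f in seq_len(k)) {
      test <- fold == f
      model <- fit_bagging(x[!test, , drop = FALSE], labels[!test],
                           n_trees = n_trees,
                           seed = (rep_seed + f) %% .Machine$integer.max,
                           max_depth = max_depth)
      out <- predict(model, x[test, , drop = FALSE])
      pred[test] <- out$label
      vote[test] <- out$vote_pf
    }
    per_repeat[r, 1:3] <- confusion_metrics(labels, pred)
    per_repeat[r, 4] <- auc_score(vote, labels)
    if (!is.null(cons_acc)) {
      for (ct in dimnames(cons_acc)[[2]]) {
        rows <- consonants == ct
        if (length(unique(labels[rows])) == 2L) {
          cons_acc[r, ct, 1:3] <- confusion_metrics(labels[rows], pred[rows])
          cons_acc[r, ct, 4] <- auc_score(vote[rows], labels[rows])
        }
      }
    }
  }
  summarize <- function(v) c(mean = mean(v, na.rm = TRUE),
                             sd = stats::sd(v, na.rm = TRUE))
  per_consonant <- NULL
  if (!is.null(cons_acc)) {
    per_consonant <- do.call(rbind, lapply(dimnames(cons_acc)[[2]],
      function(ct) {
        m <- apply(cons_acc[, ct, , drop = FALSE], 3, mean, na.rm = TRUE)
        s <- apply(cons_acc[, ct, , drop = FALSE], 3, stats::sd,
                   na.rm = TRUE)
        data.frame(consonant = ct, metric = names(m), mean = unname(m),
                   sd = unname(s), stringsAsFactors = FALSE)
      }))
  }
  structure(list(accuracy = summarize(per_repeat[, "accuracy"]),
                 sensitivity = summarize(per_repeat[, "sensitivity"]),
                 specificity = summarize(per_repeat[, "specificity"]),
                 auc = summarize(per_repeat[, "auc"]),
                 per_consonant = per_consonant,
                 per_repeat = per_repeat,
                 k = k, repeats = repeats, n_trees = n_trees, seed = seed),
            class = "pf_cv")
}

#' @export
print.pf_cv <- function(x, ...) {
  cat(sprintf("<pf_cv> %dx%d-fold CV, %d trees\n", x$repeats, x$k,
              x$n_trees))
  for (m in c("accuracy", "sensitivity", "specificity", "auc"))
    cat(sprintf("  %-12s %5.1f +/- %.1f %%\n", m, x[[m]]["mean"],
                x[[m]]["sd"]))
  invisible(x)
}

#' Per-feature class-difference significance
#'
#' For each consonant type (and pooled over all rows), tests whether the
#' per-frame feature values of the PF and NS classes differ, using the same
#' test family as the cut-off search, at the 1 % level by default. Rows of
#' the feature matrix are flattened so every frame value enters the test.
#'
#' @param x numeric feature matrix (rows = tokens, columns = frame values).
#' @param labels `"PF"`/`"NS"` per row.
#' @param consonants optional consonant type per row; when given, one test
#'   per type is reported in addition to the pooled test.
#' @param alpha significance level (default 0.01).
#' @param method `"welch"` or `"wilcox"`.
#' @return `data.frame` with columns `consonant`, `p`, `H`. Strata missing
#'   a class are skipped with a warning.
#' @export
feature_significance <- function(x, labels, consonants = NULL,
                                 alpha = 0.01,
                                 method = c("welch", "wilcox")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  labels <- as.character(labels)
  strata <- list(all = rep(TRUE, nrow(x)))
  if (!is.null(consonants)) {
    consonants <- as.character(consonants)
    for (ct in sort(unique(consonants)))
      strata[[ct]] <- consonants == ct
  }
  out <- lapply(names(strata), function(nm) {
    rows <- strata[[nm]]
    a <- as.vector(x[rows & labels == "PF", , drop = FALSE])
    b <- as.vector(x[rows & labels == "NS", , drop = FALSE])
    if (length(a) < 2L || length(b) < 2L) {
      warning("stratum ", nm, " lacks a class; skipped", call. = FALSE)
      return(NULL)
    }
    res <- significance_flag(a, b, alpha = alpha, method = method)
    data.frame(consonant = nm, p = res$p, H = res$H,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
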