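#' Blocked k-fold assignment
#'
#' Divides `n_trials` consecutive trials into `k` contiguous blocks whose
#' sizes differ by at most one (larger blocks first). Blocked folds avoid
#' temporal leakage between training and test trials.
#'
#' @param n_trials number of trials.
#' @param k number of folds (at least 2).
#' @return integer vector of fold indices (1..k), one per trial.
#' @export
blocked_kfold <- function(n_trials, k) {
  if (k < 2L) stop("k must be at least 2")
  if (n_trials < k) stop(sprintf("n_trials (%d) must be at least k (%d)", n_trials, k))
  q <- n_trials %/% k
  r <- n_trials %% k
  sizes <- c(rep(q + 1L, r), rep(q, k - r))
  rep(seq_len(k), times = sizes)
}

#' Pearson correlation with strict input checks
#'
#' @param a,b numeric vectors of equal length (at least 2), each with
#'   non-zero variance.
#' @return the product-moment correlation in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length")
  if (length(a) < 2L) stop("need at least 2 samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(a, b)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement index `2 cov(a, b) / (var(a) + var(b) + (mean(a) - mean(b))^2)`
#' penalizing location and scale shifts as well as decorrelation, so
#' `|CCC| <= |r|` always.
#'
#' @inheritParams pearson_r
#' @return the CCC in `[-1, 1]`.
#' @export
ccc <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length")
  if (length(a) < 2L) stop("need at least 2 samples")
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 || vb == 0) stop("zero variance: concordance undefined")
  2 * stats::cov(a, b) / (va + vb + (mean(a) - mean(b))^2)
}

#' Cohen's kappa
#'
#' Chance-corrected classification agreement `(p_o - p_e) / (1 - p_e)`,
#' with the expected agreement `p_e` computed from the marginal label
#' frequencies.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @return kappa, at most 1.
#' @export
cohen_kappa <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("label vectors must have equal length")
  if (length(unique(y_true)) < 2L) stop("need at least 2 classes in y_true")
  lev <- union(unique(y_true), unique(y_pred))
  tt <- factor(y_true, levels = lev)
  pp <- factor(y_pred, levels = lev)
  n <- length(tt)
  p_o <- mean(tt == pp)
  p_e <- sum((table(tt) / n) * (table(pp) / n))
  if (1 - p_e <= 0) stop("degenerate marginals: expected agreement is 1")
  (p_o - p_e) / (1 - p_e)
}

#' Blocked cross-validation of the coherence decoder
#'
#' Runs blocked k-fold cross-validation independently per condition: in each
#' fold a [cohdecode()] model is fitted on the training blocks only (both
#' the spectral filters and the spatial weights) and evaluated on the
#' held-out block, scoring each test trial by Pearson r and CCC. Test trials
#' never influence any stage of fitting.
#'
#' @param x a [feature_tensor()].
#' @param y the paired [target_set()].
#' @param labels per-trial condition labels; defaults to `x$labels`.
#' @param k number of folds.
#' @param ... passed to [cohdecode()].
#' @return An object of class `cohdecode_cv`: `scores` data frame with
#'   columns `condition, fold, trial, r, ccc`; `folds`, a per-condition list
#'   of fold assignments; use `summary()` for fold/condition means.
#' @export
cross_validate <- function(x, y, labels = NULL, k = 5, ...) {
  if (is.null(labels)) labels <- x$labels
  conds <- unique(labels)
  rows <- list()
  folds <- list()
  for (cc in conds) {
    idx <- which(labels == cc)
    fold <- blocked_kfold(length(idx), k)
    folds[[cc]] <- fold
    for (f in seq_len(k)) {
      tr <- idx[fold != f]
      te <- idx[fold == f]
      if (length(tr) < 2L) stop(sprintf("training set of condition '%s' fold %d has < 2 trials", cc, f))
      fit <- cohdecode(subset_trials(x, tr), subset_trials(y, tr),
                       condition = cc, ...)
      pred <- predict(fit, subset_trials(x, te))
      for (i in seq_along(te)) {
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cc, fold = f, trial = te[i],
          r = pearson_r(pred$data[i, ], y$data[te[i], ]),
          ccc = ccc(pred$data[i, ], y$data[te[i], ]),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(scores = do.call(rbind, rows), folds = folds, k = k,
                 method = "coherence"),
            class = "cohdecode_cv")
}

#' @export
print.cohdecode_cv <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("<cohdecode_cv> %s, %d-fold blocked CV, %d test trials\n",
              x$method, x$k, nrow(x$scores)))
  print(s$per_condition, row.names = FALSE)
  cat(sprintf("overall mean r = %.3f, mean CCC = %.3f\n", s$mean_r, s$mean_ccc))
  invisible(x)
}

#' @export
summary.cohdecode_cv <- function(object, ...) {
  sc <- object$scores
  per_cond <- do.call(rbind, lapply(split(sc, sc$condition), function(d) {
    data.frame(condition = d$condition[1L], mean_r = mean(d$r),
               mean_ccc = mean(d$ccc), n_trials = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(per_cond) <- NULL
  list(per_condition = per_cond,
       mean_r = mean(per_cond$mean_r), mean_ccc = mean(per_cond$mean_ccc))
}

#' Per-fold, per-condition spatial-weight observations
#'
#' Fits a decoder per condition and fold and collects one importance value
#' per feature from each model, producing the observation matrix used by
#' [rank_electrodes()] and [lda_discriminability()].
#'
#' Two schemes are offered. `"blocks"` (default) trains each fold's model on
#' that fold's block only, so the k observations of one condition come from
#' disjoint trials and are exchangeable with other conditions' observations
#' under the null of identical spatial patterns — this makes the downstream
#' significance of the LDA analysis interpretable. `"cv"` trains each
#' fold's model on the complementary k-1 blocks (the models of ordinary
#' cross-validation); observations then share most of their training trials,
#' which inflates apparent discriminability even for identically coupled
#' conditions, and is provided for comparability only.
#'
#' @inheritParams cross_validate
#' @param measure per-feature importance: `"contribution"` (RMS of the
#'   feature's share of the training prediction; invariant to the scale
#'   split between filter and weight) or `"b"` (raw `|b_j|`).
#' @param scheme `"blocks"` or `"cv"`, see Details.
#' @return list with `W` (`(n_conditions * k) x n_features` matrix),
#'   `labels` (condition of each row) and `folds` (fold of each row).
#' @export
cv_weights <- function(x, y, labels = NULL, k = 5,
                       measure = c("contribution", "b"),
                       scheme = c("blocks", "cv"), ...) {
  measure <- match.arg(measure)
  scheme <- match.arg(scheme)
  if (is.null(labels)) labels <- x$labels
  conds <- unique(labels)
  W <- NULL
  wl <- character(0)
  wf <- integer(0)
  for (cc in conds) {
    idx <- which(labels == cc)
    fold <- blocked_kfold(length(idx), k)
    for (f in seq_len(k)) {
      tr <- if (scheme == "blocks") idx[fold == f] else idx[fold != f]
      fit <- cohdecode(subset_trials(x, tr), subset_trials(y, tr),
                       condition = cc, ...)
      v <- abs(if (measure == "b") fit$b else fit$contribution)
      W <- rbind(W, v)
      wl <- c(wl, cc)
      wf <- c(wf, f)
    }
  }
  rownames(W) <- NULL
  list(W = W, labels = wl, folds = wf)
}

#' Rank features by K-means separation of their weights
#'
#' For each feature (electrode), the per-condition/per-fold weight values
#' are clustered with K-means into `k_clusters` groups (one per condition in
#' the intended use) and the separation is scored as the between-cluster sum
#' of squares divided by the total sum of squares. Features whose weights
#' segregate cleanly by condition score near 1; features with identical
#' weights everywhere score 0. Ranking is by descending score, ties broken
#' by feature index.
#'
#' @param W numeric matrix of weight observations, rows = models
#'   (condition x fold), columns = features.
#' @param k_clusters number of clusters (the condition count).
#' @param seed integer seed for the K-means restarts.
#' @param nstart number of K-means restarts.
#' @return data frame with columns `feature`, `score`, ordered by rank.
#' @export
rank_electrodes <- function(W, k_clusters, seed = 1, nstart = 10) {
  if (nrow(W) < k_clusters) {
    stop(sprintf("need at least %d weight observations per feature, got %d",
                 k_clusters, nrow(W)))
  }
  set.seed(seed)
  score <- vapply(seq_len(ncol(W)), function(j) {
    v <- W[, j]
    tot <- sum((v - mean(v))^2)
    if (tot <= .Machine$double.eps * max(1, max(abs(v))^2)) return(0)
    if (length(unique(v)) < k_clusters) return(0)
    km <- stats::kmeans(v, centers = k_clusters, nstart = nstart)
    km$betweenss / km$totss
  }, 0)
  ord <- order(-score, seq_len(ncol(W)))
  data.frame(feature = if (is.null(colnames(W))) ord else colnames(W)[ord],
             index = ord, score = score[ord],
             stringsAsFactors = FALSE)
}

#' Condition discriminability of spatial weights via LDA
#'
#' Tests whether the fitted spatial weights differ systematically between
#' conditions: for each cross-validation fold, features are ranked by
#' [rank_electrodes()] on the training folds' observations only, the best
#' `n_selected` features are fed to a linear discriminant classifier trained
#' on the training folds, and the held-out fold's models are classified by
#' condition. Reports pooled held-out accuracy and Cohen's kappa.
#'
#' @param W weight observation matrix, as produced by [cv_weights()].
#' @param labels condition label of each row of `W`.
#' @param folds fold index of each row of `W`.
#' @param n_selected number of features to keep (`"all"` keeps every
#'   feature).
#' @param k_clusters clusters used in the ranking; defaults to the number of
#'   conditions.
#' @param seed seed for the K-means ranking.
#' @return An object of class `discriminability`: `accuracy`, `kappa`,
#'   per-fold selections, predicted and true labels.
#' @export
lda_discriminability <- function(W, labels, folds, n_selected = 2,
                                 k_clusters = length(unique(labels)),
                                 seed = 1) {
  stopifnot(nrow(W) == length(labels), nrow(W) == length(folds))
  keep_all <- identical(n_selected, "all")
  if (!keep_all && n_selected > ncol(W)) {
    stop("n_selected exceeds the number of features")
  }
  sel_list <- list()
  pred <- character(0)
  truth <- character(0)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    te <- folds == f
    if (length(unique(labels[tr])) < length(unique(labels))) {
      stop(sprintf("a class is absent from the training folds for fold %d", f))
    }
    sel <- if (keep_all) seq_len(ncol(W)) else {
      rank_electrodes(W[tr, , drop = FALSE], k_clusters = k_clusters,
                      seed = seed)$index[seq_len(n_selected)]
    }
    sel_list[[as.character(f)]] <- sel
    ld <- MASS::lda(W[tr, sel, drop = FALSE], grouping = factor(labels[tr]))
    p <- stats::predict(ld, W[te, sel, drop = FALSE])$class
    pred <- c(pred, as.character(p))
    truth <- c(truth, labels[te])
  }
  structure(list(accuracy = mean(pred == truth),
                 kappa = cohen_kappa(truth, pred),
                 selected = sel_list, predicted = pred, truth = truth,
                 n_selected = if (keep_all) "all" else n_selected),
            class = "discriminability")
}

#' @export
print.discriminability <- function(x, ...) {
  cat(sprintf("<discriminability> LDA on %s features: accuracy = %.1f%%, kappa = %.2f\n",
              if (identical(x$n_selected, "all")) "all" else sprintf("best %d", x$n_selected),
              100 * x$accuracy, x$kappa))
  invisible(x)
}
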