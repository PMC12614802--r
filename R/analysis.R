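# Mutual information between one continuous feature and a discrete
# label, nearest-neighbour estimator (Kraskov-style, discrete-target
# variant): with N samples, class sizes N_c, k-th same-class neighbour
# radius r_i and m_i points of any class strictly within r_i of point i,
#   MI = psi(N) - <psi(N_label(i))> + psi(k) - <psi(m_i)>
# A tiny seeded jitter breaks distance ties so the estimate is
# deterministic given the seed.
.mi_knn <- function(x, y, k = 3, jitter_sd = NULL) {
  n <- length(x)
  if (is.null(jitter_sd)) {
    scale <- stats::sd(x)
    jitter_sd <- if (is.finite(scale) && scale > 0) 1e-10 * scale else 1e-10
  }
  x <- x + stats::rnorm(n, 0, jitter_sd)
  y <- as.integer(factor(y))
  counts <- tabulate(y)
  r <- numeric(n)
  kk <- integer(n)
  for (c in seq_along(counts)) {
    idx <- which(y == c)
    m <- length(idx)
    if (m < 2) { r[idx] <- Inf; kk[idx] <- 0; next }
    kc <- min(k, m - 1)
    xs <- sort(x[idx])
    pos <- match(x[idx], xs)
    # k-th nearest neighbour distance in 1D via sliding windows of
    # kc+1 consecutive sorted points containing each point
    rc <- rep(Inf, m)
    for (a in 0:kc) {
      lo <- pos - a
      hi <- lo + kc
      ok <- lo >= 1 & hi <= m
      d <- pmax(xs[pmax(hi, 1)] - x[idx], x[idx] - xs[pmax(lo, 1)])
      rc[ok] <- pmin(rc[ok], d[ok])
    }
    r[idx] <- rc
    kk[idx] <- kc
  }
  valid <- is.finite(r) & kk > 0
  if (!any(valid)) return(0)
  xs_all <- sort(x)
  # m_i: points of any class strictly inside (x_i - r_i, x_i + r_i),
  # including the point itself
  m_i <- findInterval(x[valid] + r[valid], xs_all, left.open = TRUE) -
    findInterval(x[valid] - r[valid], xs_all)
  m_i <- pmax(m_i, 1)
  nx <- counts[y[valid]]
  mi <- digamma(n) - mean(digamma(nx)) + mean(digamma(kk[valid])) -
    mean(digamma(m_i))
  max(mi, 0)
}

#' Rank features by mutual information with a class label
#'
#' Scores every feature column against the discrete label with a
#' k-nearest-neighbour mutual-information estimate (nats, clipped at
#' zero) and returns the ranking. Deterministic for a fixed seed (the
#' seed controls only the tie-breaking jitter).
#'
#' @param table A \code{feature_table}, or a plain data.frame / matrix
#'   of numeric features.
#' @param labels Class label per row (taken from the table when
#'   attached).
#' @param k_neighbors Neighbour count of the estimator (default 3).
#' @param seed Integer seed.
#' @return data.frame of class \code{mi_ranking} with columns
#'   \code{feature}, \code{mi}, \code{rank}, ordered by decreasing MI
#'   (ties by feature name).
#' @export
mi_rank <- function(table, labels = NULL, k_neighbors = 3, seed = 1) {
  x <- .as_feature_matrix(table)
  if (is.null(labels) && inherits(table, "feature_table")) {
    labels <- table$labels
  }
  if (is.null(labels)) stop("labels are required")
  keep <- !is.na(labels)
  x <- x[keep, , drop = FALSE]
  labels <- labels[keep]
  if (length(unique(labels)) < 2) {
    stop("mutual information needs at least 2 classes")
  }
  set.seed(seed)
  mi <- vapply(seq_len(ncol(x)), function(j) {
    .mi_knn(x[, j], labels, k = k_neighbors)
  }, numeric(1))
  out <- data.frame(feature = colnames(x), mi = mi,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mi, out$feature), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("mi_ranking", "data.frame")
  out
}

.as_feature_matrix <- function(table) {
  if (inherits(table, "feature_table")) {
    df <- table$features
    as.matrix(df[, setdiff(colnames(df), "protein_id"), drop = FALSE])
  } else {
    m <- as.matrix(table)
    if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
    m
  }
}

#' Select the top-k features of a ranking
#'
#' @param ranking An \code{mi_ranking} from [mi_rank()].
#' @param k Number of features to keep (0 <= k <= feature count). Ties
#'   in MI are broken by lexicographic feature name.
#' @return Character vector of feature names.
#' @export
select_top <- function(ranking, k) {
  stopifnot(k >= 0, k <= nrow(ranking))
  ranking$feature[seq_len(k)]
}

# ---- classification metrics ------------------------------------------------

# Macro-averaged multiclass metrics plus Gorodkin's multiclass MCC,
# computed from the confusion matrix over the union of observed levels.
.class_metrics <- function(truth, pred) {
  lev <- sort(unique(c(truth, pred)))
  truth <- factor(truth, levels = lev)
  pred <- factor(pred, levels = lev)
  cm <- table(truth, pred)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- rowSums(cm) > 0  # macro-average over classes present in truth
  s <- sum(cm)
  c_ok <- sum(tp)
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  denom <- sqrt((s^2 - sum(p_k^2)) * (s^2 - sum(t_k^2)))
  mcc <- if (denom > 0) (c_ok * s - sum(p_k * t_k)) / denom else 0
  c(accuracy = c_ok / s,
    precision = mean(prec[present]),
    recall = mean(rec[present]),
    f1 = mean(f1[present]),
    mcc = mcc)
}

# ---- model zoo -------------------------------------------------------------

#' Built-in classifier specifications
#'
#' Classifiers honouring the \code{fit(x, y)} / \code{predict(model, x)}
#' contract used by [run_benchmark()]: \code{"rf"} (random forest via
#' ranger) and \code{"gbt"} (gradient-boosted trees via xgboost, the
#' histogram-based boosting family; requires the xgboost package).
#' Any user-supplied list with \code{fit} and \code{predict} functions
#' is accepted wherever a \code{model_spec} is expected.
#'
#' @param name One of \code{"rf"}, \code{"gbt"}.
#' @param seed Integer seed forwarded to the learner.
#' @return A model spec list.
#' @export
model_spec <- function(name = c("rf", "gbt"), seed = 1) {
  name <- match.arg(name)
  if (name == "rf") {
    list(
      name = "rf",
      fit = function(x, y) {
        ranger::ranger(x = x, y = factor(y), num.trees = 200,
                       seed = seed, num.threads = 1)
      },
      predict = function(model, x) {
        as.character(stats::predict(model, data = x,
                                    num.threads = 1)$predictions)
      }
    )
  } else {
    if (!requireNamespace("xgboost", quietly = TRUE)) {
      stop("the gbt model requires the xgboost package")
    }
    list(
      name = "gbt",
      fit = function(x, y) {
        yf <- factor(y)
        nc <- nlevels(yf)
        params <- list(objective = "multi:softmax", num_class = nc,
                       max_depth = 6, eta = 0.3, nthread = 1,
                       tree_method = "hist", seed = seed)
        m <- xgboost::xgboost(data = as.matrix(x),
                              label = as.integer(yf) - 1,
                              params = params, nrounds = 50, verbose = 0)
        list(model = m, levels = levels(yf))
      },
      predict = function(model, x) {
        p <- stats::predict(model$model, as.matrix(x))
        model$levels[p + 1]
      }
    )
  }
}

#' Leakage-safe classification benchmark
#'
#' Shuffles the rows with the given seed, holds out a test fraction
#' (stratified so every class appears in the training split), optionally
#' ranks features by mutual information \emph{on the training rows only}
#' and keeps the top \code{select_k}, fits the classifier on the
#' training split and evaluates on the held-out split.
#'
#' @param table \code{feature_table} or numeric matrix/data.frame.
#' @param labels Class labels (from the table when attached).
#' @param model A spec from [model_spec()] or any list with \code{fit}
#'   and \code{predict} functions.
#' @param test_fraction Held-out fraction (default 0.2).
#' @param select_k Number of MI-selected features; NULL uses all.
#' @param seed Integer seed controlling the shuffle, the selection
#'   jitter and the learner.
#' @param max_attempts Re-splits attempted when a class is missing from
#'   the training split before giving up.
#' @return List of class \code{benchmark_report}: \code{metrics}
#'   (accuracy, macro precision/recall/F1, MCC), \code{selected}
#'   (feature names used), \code{model_name}, \code{seed},
#'   \code{n_train}, \code{n_test}.
#' @export
run_benchmark <- function(table, labels = NULL, model = model_spec("rf"),
                          test_fraction = 0.2, select_k = NULL, seed = 1,
                          max_attempts = 10) {
  x <- .as_feature_matrix(table)
  if (is.null(labels) && inherits(table, "feature_table")) {
    labels <- table$labels
  }
  if (is.null(labels)) stop("labels are required")
  labels <- as.character(labels)
  keep <- !is.na(labels)
  x <- x[keep, , drop = FALSE]
  labels <- labels[keep]
  n <- nrow(x)
  n_test <- max(1, round(test_fraction * n))
  set.seed(seed)
  ok_split <- FALSE
  for (attempt in seq_len(max_attempts)) {
    ord <- sample.int(n)
    test_idx <- ord[seq_len(n_test)]
    train_idx <- ord[-seq_len(n_test)]
    if (setequal(unique(labels[train_idx]), unique(labels))) {
      ok_split <- TRUE
      break
    }
  }
  if (!ok_split) {
    stop("could not build a training split containing every class after ",
         max_attempts, " attempts")
  }
  selected <- colnames(x)
  if (!is.null(select_k)) {
    rk <- mi_rank(x[train_idx, , drop = FALSE], labels[train_idx],
                  seed = seed)
    selected <- select_top(rk, min(select_k, nrow(rk)))
    x <- x[, selected, drop = FALSE]
  }
  fitted <- model$fit(x[train_idx, , drop = FALSE], labels[train_idx])
  pred <- model$predict(fitted, x[test_idx, , drop = FALSE])
  structure(list(
    metrics = .class_metrics(labels[test_idx], pred),
    selected = selected,
    model_name = if (!is.null(model$name)) model$name else "custom",
    seed = seed,
    n_train = length(train_idx),
    n_test = n_test
  ), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark_report:", x$model_name, "| seed", x$seed, "|",
      x$n_train, "train /", x$n_test, "test |",
      length(x$selected), "features\n")
  print(round(x$metrics, 4))
  invisible(x)
}

# ---- grouped-importance enrichment -----------------------------------------

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped
#' at 1); thin wrapper over \code{stats::p.adjust}.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(is.finite(p)), all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Grouped-importance enrichment by two-sample KS test
#'
#' For each class, sums the per-protein importance (e.g. SHAP) values
#' over the features inside a group and over the remaining features,
#' yielding two per-protein samples, and compares their distributions
#' with a two-sided two-sample Kolmogorov-Smirnov test. P-values are
#' Benjamini-Hochberg adjusted across classes. A large statistic D
#' means the grouped features contribute very differently from the rest.
#'
#' @param shap_matrix Numeric matrix, proteins x features (column
#'   names required when \code{feature_groups} is a character vector).
#' @param feature_groups Logical vector per column (TRUE = in group) or
#'   character vector of in-group column names. Both the group and its
#'   complement must be non-empty.
#' @param class_partition Class label per row; a single shared label is
#'   allowed.
#' @return data.frame of class \code{ks_enrichment}: one row per class
#'   with \code{class}, \code{n}, \code{D}, \code{p}, \code{p_adj}.
#' @export
ks_enrichment <- function(shap_matrix, feature_groups, class_partition) {
  m <- as.matrix(shap_matrix)
  if (is.character(feature_groups)) {
    feature_groups <- colnames(m) %in% feature_groups
  }
  stopifnot(length(feature_groups) == ncol(m),
            length(class_partition) == nrow(m))
  if (!any(feature_groups) || all(feature_groups)) {
    stop("both the feature group and its complement must be non-empty")
  }
  sums_in <- rowSums(m[, feature_groups, drop = FALSE])
  sums_out <- rowSums(m[, !feature_groups, drop = FALSE])
  classes <- sort(unique(as.character(class_partition)))
  res <- lapply(classes, function(cl) {
    idx <- class_partition == cl
    ks <- suppressWarnings(
      stats::ks.test(sums_in[idx], sums_out[idx], exact = FALSE))
    data.frame(class = cl, n = sum(idx),
               D = unname(ks$statistic), p = ks$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  class(out) <- c("ks_enrichment", "data.frame")
  out
}
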