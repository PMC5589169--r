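#' Decision-support system for fluidity-pattern recognition
#'
#' Two per-channel pipelines (feature standardization, PCA retaining 99%
#' of the training variance, multi-class support vector machine) whose
#' per-image decisions are aggregated over each patient's z-stack by
#' majority and fused across the two emission channels by weighted
#' voting. Evaluation is leave-one-person-out (LOPO): every fold refits
#' standardizer, PCA, SVM and voting weights on the training patients
#' only, so no information from the held-out patient reaches any fitted
#' component.
#'
#' @name dss_classifier
NULL

group_factor <- function(labels) factor(labels, levels = GROUP_LEVELS)

# ---- standardization ------------------------------------------------------

fit_standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(std, X) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

# ---- PCA ------------------------------------------------------------------

#' Fit a PCA with a retained-variance threshold
#'
#' Principal components of the training matrix; the retained count `k` is
#' the smallest number of leading components whose cumulative explained
#' variance reaches `variance_threshold`. Refit inside every LOPO fold,
#' so `k` may vary across folds.
#'
#' @param X Numeric training matrix (rows = images).
#' @param variance_threshold Fraction of variance to retain, in (0, 1\];
#'   default 0.99.
#' @return A `gp_pca`: list with `center`, `loadings` (orthonormal
#'   columns, `k` of them), `explained_variance_ratio` (all components)
#'   and `k`.
#' @export
fit_pca <- function(X, variance_threshold = 0.99) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("PCA needs at least 2 rows", call. = FALSE)
  stopifnot(variance_threshold > 0, variance_threshold <= 1)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  var_ratio <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(var_ratio) >= variance_threshold - 1e-12)[1]
  structure(list(
    center = pc$center,
    loadings = pc$rotation[, seq_len(k), drop = FALSE],
    explained_variance_ratio = var_ratio,
    sdev = pc$sdev,
    k = k,
    variance_threshold = variance_threshold
  ), class = "gp_pca")
}

#' Project rows into a fitted PCA space
#'
#' @param pca A `gp_pca`.
#' @param X Matrix with the same columns as the training data.
#' @return Score matrix with `k` columns.
#' @export
pca_project <- function(pca, X) {
  stopifnot(inherits(pca, "gp_pca"))
  sweep(as.matrix(X), 2, pca$center, "-") %*% pca$loadings
}

# ---- per-channel pipeline -------------------------------------------------

#' Classifier configuration for the channel pipelines
#'
#' @param variance_threshold PCA retained-variance threshold.
#' @param kernel SVM kernel (`"linear"` default).
#' @param cost SVM regularization constant C.
#' @return A plain list.
#' @export
dss_config <- function(variance_threshold = 0.99, kernel = "linear",
                       cost = 1) {
  list(variance_threshold = variance_threshold, kernel = kernel,
       cost = cost)
}

#' Fit one channel's standardize / PCA / SVM pipeline
#'
#' The standardizer and PCA are fitted on the training rows only; the
#' multi-class maximum-margin classifier (one-vs-one, libsvm) is trained
#' on the projected rows. Deterministic given its inputs: no random
#' component anywhere in the stack.
#'
#' @param X Feature matrix (rows = training images).
#' @param labels Group labels, one per row.
#' @param config A [dss_config()] list.
#' @return A `channel_pipeline`.
#' @export
fit_channel_pipeline <- function(X, labels, config = dss_config()) {
  X <- as.matrix(X)
  y <- group_factor(labels)
  if (anyNA(y)) stop("labels outside {G0, G1, G2}", call. = FALSE)
  if (length(unique(as.character(y))) < 2L)
    stop("training set contains a single class", call. = FALSE)
  std <- fit_standardizer(X)
  Z <- apply_standardizer(std, X)
  pca <- fit_pca(Z, config$variance_threshold)
  proj <- pca_project(pca, Z)
  svm <- e1071::svm(x = proj, y = droplevels(y), kernel = config$kernel,
                    cost = config$cost, scale = FALSE)
  structure(list(standardizer = std, pca = pca, svm = svm,
                 config = config), class = "channel_pipeline")
}

#' Predict per-image labels with a channel pipeline
#'
#' Transform order is fixed: standardize, project, classify.
#'
#' @param object A `channel_pipeline`.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return Factor of predicted group labels (levels `G0 < G1 < G2`).
#' @export
predict.channel_pipeline <- function(object, newdata, ...) {
  Z <- apply_standardizer(object$standardizer, as.matrix(newdata))
  proj <- pca_project(object$pca, Z)
  pred <- stats::predict(object$svm, proj)
  factor(as.character(pred), levels = GROUP_LEVELS)
}

# per-class fraction of stack images voting each class
vote_fractions <- function(labels) {
  counts <- table(group_factor(labels))
  as.numeric(counts) / sum(counts)
}

# majority label over a stack; ties go to the lower class index
majority_label <- function(labels) {
  counts <- table(group_factor(labels))
  GROUP_LEVELS[which.max(counts)]
}

# stack majority with the tie rule used at patient level: a tie between
# classes is resolved by the weighted sum of both channels' vote
# fractions (the other channel's evidence), then by lower class index
stack_label <- function(frac_this, frac_other, w_this, w_other) {
  top <- which(frac_this == max(frac_this))
  if (length(top) == 1L) return(GROUP_LEVELS[top])
  combined <- w_this * frac_this + w_other * frac_other
  GROUP_LEVELS[top[which.max(combined[top])]]
}

#' Fuse the two channel decisions for one patient
#'
#' Each image of the stack gets a per-channel label; the per-channel
#' patient label is the majority over the stack (a tied majority is
#' resolved by the weighted sum of both channels' vote fractions); the
#' final label is the weighted vote of the two channel decisions. Vote
#' ties are broken toward the decision of the channel with the larger
#' weight (its training-fold accuracy), then toward the lower class
#' index.
#'
#' @param dss A `trained_dss` from [fit_dss()].
#' @param patient List with `blue` and `green` feature matrices (one row
#'   per image of the stack).
#' @return A group label string.
#' @export
classify_patient <- function(dss, patient) {
  stopifnot(inherits(dss, "trained_dss"))
  if (is.null(patient$blue) || nrow(patient$blue) == 0L)
    stop("empty image stack", call. = FALSE)
  w <- dss$channel_weights
  frac_b <- vote_fractions(predict(dss$blue_pipeline, patient$blue))
  frac_g <- vote_fractions(predict(dss$green_pipeline, patient$green))
  lab_b <- stack_label(frac_b, frac_g, w[1], w[2])
  lab_g <- stack_label(frac_g, frac_b, w[2], w[1])
  weighted_vote(lab_b, lab_g, w)
}

weighted_vote <- function(label_blue, label_green, weights) {
  stopifnot(length(weights) == 2L, all(weights >= 0), any(weights > 0))
  score <- setNames(numeric(3), GROUP_LEVELS)
  score[label_blue] <- score[label_blue] + weights[1]
  score[label_green] <- score[label_green] + weights[2]
  top <- which(score == max(score))
  if (length(top) == 1L) return(GROUP_LEVELS[top])
  # tie: side with the heavier channel if its vote is among the tied
  heavier <- if (weights[1] >= weights[2]) label_blue else label_green
  if (heavier %in% GROUP_LEVELS[top]) return(heavier)
  GROUP_LEVELS[top[1]]
}

#' Fit the full two-channel DSS on a set of training patients
#'
#' Fits both channel pipelines on the pooled training images and sets the
#' voting weights to each channel's mean patient-level accuracy over an
#' internal 3-fold split of the training patients (round-robin within
#' class, so the procedure is deterministic and uses no test
#' information). If the internal split is infeasible the weights fall
#' back to 0.5 / 0.5.
#'
#' @param patients List of patient entries (`id`, `group`, `blue`,
#'   `green` feature matrices), e.g. `feature_cohort$patients`.
#' @param config A [dss_config()].
#' @return A `trained_dss`.
#' @export
fit_dss <- function(patients, config = dss_config()) {
  stopifnot(length(patients) >= 2L)
  pool <- pool_images(patients)
  weights <- inner_fold_weights(patients, config)
  structure(list(
    blue_pipeline = fit_channel_pipeline(pool$blue, pool$labels, config),
    green_pipeline = fit_channel_pipeline(pool$green, pool$labels, config),
    channel_weights = weights
  ), class = "trained_dss")
}

pool_images <- function(patients) {
  list(
    blue = do.call(rbind, lapply(patients, `[[`, "blue")),
    green = do.call(rbind, lapply(patients, `[[`, "green")),
    labels = unlist(lapply(patients, function(p)
      rep(p$group, nrow(p$blue))))
  )
}

# deterministic stratified 3-fold assignment of patients (round-robin
# within class in list order)
stratified_folds <- function(groups, n_folds = 3L) {
  fold <- integer(length(groups))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    fold[idx] <- ((seq_along(idx) - 1L) %% n_folds) + 1L
  }
  fold
}

inner_fold_weights <- function(patients, config, n_folds = 3L) {
  groups <- vapply(patients, `[[`, "", "group")
  fold <- stratified_folds(groups, n_folds)
  acc <- matrix(NA_real_, n_folds, 2L)
  for (f in seq_len(n_folds)) {
    tr <- patients[fold != f]
    te <- patients[fold == f]
    if (length(te) == 0L || length(tr) < 2L) next
    tr_groups <- vapply(tr, `[[`, "", "group")
    if (length(unique(tr_groups)) < 2L) next
    pool <- pool_images(tr)
    pipes <- lapply(c("blue", "green"), function(ch) {
      fit_channel_pipeline(pool[[ch]], pool$labels, config)
    })
    # image-level accuracy over the held-in fold: finer-grained than
    # patient-level, so disagreeing channels rarely tie in the vote
    hits <- c(0, 0)
    tot <- 0L
    for (j in seq_along(te)) {
      for (c2 in 1:2) {
        ch <- c("blue", "green")[c2]
        pred <- predict(pipes[[c2]], te[[j]][[ch]])
        hits[c2] <- hits[c2] + sum(pred == te[[j]]$group)
      }
      tot <- tot + nrow(te[[j]]$blue)
    }
    acc[f, ] <- hits / tot
  }
  if (all(is.na(acc))) return(c(blue = 0.5, green = 0.5))
  w <- colMeans(acc, na.rm = TRUE)
  if (sum(w) == 0) w <- c(0.5, 0.5)
  c(blue = w[1], green = w[2])
}

#' Leave-one-person-out evaluation of the DSS
#'
#' For each patient: fit the complete DSS (standardizers, PCAs, SVMs,
#' voting weights) on all other patients, classify the held-out patient,
#' and accumulate the 3x3 confusion matrix (rows = predicted, columns =
#' true). Fold isolation is structural: the training list passed to
#' [fit_dss()] simply never contains the held-out patient; a
#' `fold_callback(holdout_id, training_ids)` hook lets tests instrument
#' every fold.
#'
#' @param patients List of patient feature entries (see [fit_dss()]).
#' @param config A [dss_config()].
#' @param fold_callback Optional function called per fold with the
#'   held-out id and the vector of training ids.
#' @return A `metrics_report` (see [compute_metrics()]) with a
#'   `predictions` data.frame (`patient`, `true`, `predicted`) and
#'   per-fold training ids attached.
#' @export
lopo_evaluate <- function(patients, config = dss_config(),
                          fold_callback = NULL) {
  groups <- vapply(patients, `[[`, "", "group")
  if (length(patients) < 2L)
    stop("LOPO needs at least 2 patients", call. = FALSE)
  if (length(unique(groups)) < 2L)
    stop("LOPO needs at least 2 classes in the cohort", call. = FALSE)
  preds <- character(length(patients))
  fold_train_ids <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    train <- patients[-i]
    fold_train_ids[[i]] <- vapply(train, `[[`, "", "id")
    if (!is.null(fold_callback))
      fold_callback(patients[[i]]$id, fold_train_ids[[i]])
    dss <- fit_dss(train, config)
    preds[i] <- classify_patient(dss, patients[[i]])
  }
  confusion <- confusion_matrix(preds, groups)
  rep <- compute_metrics(confusion)
  rep$predictions <- data.frame(
    patient = vapply(patients, `[[`, "", "id"),
    true = groups, predicted = preds, stringsAsFactors = FALSE
  )
  rep$fold_training_ids <- fold_train_ids
  rep
}

#' Build a 3x3 confusion matrix (rows = predicted, columns = true)
#'
#' @param predicted,true Group label vectors of equal length.
#' @return Integer matrix with dimnames `predicted` x `true`.
#' @export
confusion_matrix <- function(predicted, true) {
  tab <- table(predicted = group_factor(predicted),
               true = group_factor(true))
  matrix(as.integer(tab), 3, 3,
         dimnames = list(predicted = GROUP_LEVELS, true = GROUP_LEVELS))
}

# ---- Bayesian scalar baselines -------------------------------------------

#' Fit a Gaussian class-conditional classifier on a scalar biomarker
#'
#' Per-class Gaussian (sample mean and SD, SD floored at 1e-6) with class
#' priors equal to the training frequencies; prediction is the maximum
#' posterior, ties broken toward the lower class index. Used as the
#' HbA1c and mean-GP baselines against the image-based DSS.
#'
#' @param values Numeric scalar biomarker, one per patient.
#' @param labels Group labels.
#' @return A `bayes_scalar` model.
#' @export
fit_bayes_scalar <- function(values, labels) {
  y <- group_factor(labels)
  stopifnot(length(values) == length(y), !anyNA(y))
  classes <- GROUP_LEVELS[GROUP_LEVELS %in% as.character(y)]
  stats_ <- lapply(classes, function(g) {
    v <- values[y == g]
    sd_ <- if (length(v) >= 2L) stats::sd(v) else 0
    list(mean = mean(v), sd = max(sd_, 1e-6), prior = length(v) / length(y),
         n = length(v))
  })
  names(stats_) <- classes
  structure(list(classes = classes, stats = stats_), class = "bayes_scalar")
}

#' @export
#' @rdname fit_bayes_scalar
#' @param object A `bayes_scalar` model.
#' @param newdata Numeric vector of biomarker values to classify.
#' @param ... Unused.
predict.bayes_scalar <- function(object, newdata, ...) {
  post <- vapply(object$classes, function(g) {
    s <- object$stats[[g]]
    s$prior * stats::dnorm(newdata, s$mean, s$sd)
  }, numeric(length(newdata)))
  post <- matrix(post, nrow = length(newdata))
  object$classes[apply(post, 1, which.max)]
}

#' Leave-one-person-out evaluation of a scalar Bayes baseline
#'
#' @param values Scalar biomarker per patient.
#' @param labels Group labels per patient.
#' @param ids Optional patient ids for the predictions table.
#' @return A `metrics_report` with a `predictions` data.frame.
#' @export
lopo_bayes_scalar <- function(values, labels, ids = NULL) {
  n <- length(values)
  stopifnot(n >= 2L, length(labels) == n)
  if (is.null(ids)) ids <- sprintf("P%02d", seq_len(n))
  preds <- character(n)
  for (i in seq_len(n)) {
    model <- fit_bayes_scalar(values[-i], labels[-i])
    preds[i] <- predict(model, values[i])
  }
  rep <- compute_metrics(confusion_matrix(preds, labels))
  rep$predictions <- data.frame(patient = ids, true = labels,
                                predicted = preds,
                                stringsAsFactors = FALSE)
  rep
}

# ---- metrics --------------------------------------------------------------

#' Classification metrics from a 3-class confusion matrix
#'
#' With rows = predicted and columns = true: accuracy is the trace over
#' the total; per-class precision is the diagonal over its row sum
#' (everything classified as that class), recall is the diagonal over its
#' column sum (everything truly of that class), and F1 is their harmonic
#' mean. Ratios with a zero denominator are reported as 0 and flagged.
#'
#' @param confusion 3x3 non-negative integer matrix, rows = predicted,
#'   columns = true.
#' @return A `metrics_report`: list with `confusion`, `accuracy`,
#'   `precision`, `recall`, `f1` (named per class), `n`, and `undefined`
#'   (logical matrix flagging zero-denominator entries).
#' @export
compute_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(identical(dim(confusion), c(3L, 3L)),
            all(confusion >= 0), all(confusion == round(confusion)))
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  diagv <- diag(confusion)
  rs <- rowSums(confusion)
  cs <- colSums(confusion)
  precision <- ifelse(rs > 0, diagv / rs, 0)
  recall <- ifelse(cs > 0, diagv / cs, 0)
  pr <- precision + recall
  f1 <- ifelse(pr > 0, 2 * precision * recall / pr, 0)
  undefined <- rbind(precision = rs == 0, recall = cs == 0, f1 = pr == 0)
  colnames(undefined) <- GROUP_LEVELS
  names(precision) <- names(recall) <- names(f1) <- GROUP_LEVELS
  structure(list(
    confusion = confusion,
    accuracy = sum(diagv) / total,
    precision = precision, recall = recall, f1 = f1,
    n = total, undefined = undefined
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d, accuracy = %.3f\n", x$n, x$accuracy))
  print(x$confusion)
  m <- rbind(precision = x$precision, recall = x$recall, f1 = x$f1)
  print(round(m, 3))
  invisible(x)
}
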