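# SVM training, PeakDecoder scoring and FDR table construction.
#
# A radial-kernel binary SVM is fitted to the seven descriptors with
# standardization to zero mean / unit variance, 10-fold cross-validation and
# probability calibration (maximum-likelihood logistic fit to the decision
# values).  The calibrated target-class probability is the PeakDecoder
# score; sweeping it as a threshold over the labelled training set yields
# the (score threshold, estimated FDR) table.

#' Train the PeakDecoder SVM classifier
#'
#' @param descriptors data frame as returned by [descriptor_matrix()] (needs
#'   the seven descriptor columns plus `label` with values
#'   `"target"`/`"decoy"`); rows with non-finite descriptors are rejected
#'   with a message
#' @param seed integer seed for fold assignment and calibration internals
#' @param cost SVM cost parameter
#' @param gamma RBF kernel width; default 1/7 (one over the number of
#'   descriptors)
#' @param cross number of cross-validation folds
#' @return object of class `peakdecoder_model` with elements `svm` (fitted
#'   e1071 model, storing the per-descriptor centering/scaling), `cv_accuracy`
#'   (mean fold accuracy, percent), `seed`, `n_target`, `n_decoy`
#' @export
train_peakdecoder <- function(descriptors, seed = 1L, cost = 1,
                              gamma = 1 / 7, cross = 10) {
  stopifnot(all(.descriptor_names %in% names(descriptors)),
            "label" %in% names(descriptors))
  x <- as.matrix(descriptors[, .descriptor_names])
  ok <- apply(is.finite(x), 1, all)
  if (any(!ok)) {
    message(sum(!ok), " row(s) with non-finite descriptors rejected")
    x <- x[ok, , drop = FALSE]
  }
  lab <- descriptors$label[ok]
  if (length(unique(lab)) < 2)
    stop("training requires both target and decoy vectors")
  counts <- table(factor(lab, levels = c("decoy", "target")))
  if (any(counts < 50))
    warning("fewer than 50 vectors per class (",
            paste(names(counts), counts, sep = "=", collapse = ", "),
            "); FDR estimates may be unreliable")
  y <- factor(lab, levels = c("decoy", "target"))
  set.seed(as.integer(seed))
  fit <- e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
                    scale = TRUE, probability = TRUE, cross = cross)
  structure(list(svm = fit, cv_accuracy = mean(fit$accuracies),
                 seed = as.integer(seed),
                 n_target = as.integer(counts[["target"]]),
                 n_decoy = as.integer(counts[["decoy"]])),
            class = "peakdecoder_model")
}

#' @export
print.peakdecoder_model <- function(x, ...) {
  cat(sprintf(paste0("PeakDecoder model: RBF SVM on 7 descriptors\n",
                     "  training vectors: %d targets, %d decoys\n",
                     "  10-fold CV accuracy: %.2f%%  (seed %d)\n"),
              x$n_target, x$n_decoy, x$cv_accuracy, x$seed))
  invisible(x)
}

#' PeakDecoder score: calibrated target-class probability
#'
#' @param model a [train_peakdecoder()] model
#' @param descriptors data frame with the seven descriptor columns
#' @return numeric vector of scores in [0, 1]; rows with any missing
#'   descriptor get `NA` (unscorable), never 0
#' @export
peakdecoder_score <- function(model, descriptors) {
  stopifnot(inherits(model, "peakdecoder_model"))
  x <- as.matrix(descriptors[, .descriptor_names, drop = FALSE])
  out <- rep(NA_real_, nrow(x))
  ok <- apply(is.finite(x), 1, all)
  if (any(ok)) {
    pr <- stats::predict(model$svm, x[ok, , drop = FALSE],
                         probability = TRUE)
    out[ok] <- attr(pr, "probabilities")[, "target"]
  }
  out
}

#' Out-of-fold cross-validated PeakDecoder scores
#'
#' Scores every labelled vector with a model trained on the other folds
#' (stratified by class).  Unlike in-sample scores, out-of-fold scores are
#' not optimistically biased, so an FDR table built from them (see
#' [build_fdr_table()]) is better calibrated; the in-sample table tends to
#' underestimate the FDR roughly two-fold at the 1% operating point.
#'
#' @param descriptors labelled descriptor data frame (as for
#'   [train_peakdecoder()])
#' @param seed integer seed for the fold assignment
#' @param folds number of folds
#' @param cost,gamma SVM hyperparameters
#' @return numeric vector of scores aligned with `descriptors` rows (`NA`
#'   for rows with non-finite descriptors)
#' @export
crossval_scores <- function(descriptors, seed = 1L, folds = 10, cost = 1,
                            gamma = 1 / 7) {
  x <- as.matrix(descriptors[, .descriptor_names])
  lab <- descriptors$label
  ok <- apply(is.finite(x), 1, all)
  out <- rep(NA_real_, nrow(x))
  set.seed(as.integer(seed))
  fold <- integer(sum(ok))
  for (cl in unique(lab[ok])) {
    idx <- which(lab[ok] == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  xo <- x[ok, , drop = FALSE]
  yo <- factor(lab[ok], levels = c("decoy", "target"))
  sc <- rep(NA_real_, length(yo))
  for (k in seq_len(folds)) {
    tr <- fold != k
    fit <- e1071::svm(xo[tr, , drop = FALSE], yo[tr], kernel = "radial",
                      cost = cost, gamma = gamma, scale = TRUE,
                      probability = TRUE)
    pr <- stats::predict(fit, xo[!tr, , drop = FALSE], probability = TRUE)
    sc[!tr] <- attr(pr, "probabilities")[, "target"]
  }
  out[ok] <- sc
  out
}

#' False-discovery rate from confusion counts
#'
#' `FDR = FP / (TP + FP)`, with 0 when there are no discoveries.
#'
#' @param tp true positives at a score threshold (targets = positive class)
#' @param fp false positives (decoys classified as targets)
#' @return FDR as a fraction in [0, 1] (vectorized)
#' @export
compute_fdr <- function(tp, fp) {
  stopifnot(all(tp >= 0), all(fp >= 0))
  ifelse(tp + fp == 0, 0, fp / (tp + fp))
}

#' Build the (score threshold, estimated FDR) table
#'
#' Every distinct observed score is a candidate threshold; vectors are
#' classified positive when `score > threshold` and the FDR over the full
#' labelled set is computed at each.  A monotone envelope (the minimum FDR
#' over all thresholds at or below each row's, i.e. the q-value transform)
#' makes the FDR-to-score mapping well defined: rows are sorted by
#' descending threshold and FDR is non-decreasing down the table.
#'
#' @param model a [train_peakdecoder()] model
#' @param descriptors labelled descriptor data frame (training set)
#' @param scores optional precomputed scores aligned with `descriptors`
#' @return data frame with columns `score_threshold`, `fdr` (enveloped),
#'   `fdr_raw`, `tp`, `fp`
#' @export
build_fdr_table <- function(model, descriptors, scores = NULL) {
  if (is.null(scores)) scores <- peakdecoder_score(model, descriptors)
  ok <- !is.na(scores)
  s <- scores[ok]
  is_t <- descriptors$label[ok] == "target"
  ord <- order(-s)
  s <- s[ord]; is_t <- is_t[ord]
  # at threshold = s distinct value, accepted = scores strictly greater
  cum_t <- cumsum(is_t); cum_d <- cumsum(!is_t)
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each run
  thr <- s[last]
  # strictly-greater counts: everything before the first occurrence of thr
  first <- which(!duplicated(s))
  tp <- c(0L, cum_t)[first]
  fp <- c(0L, cum_d)[first]
  raw <- compute_fdr(tp, fp)
  env <- rev(cummin(rev(raw)))
  data.frame(score_threshold = thr, fdr = env, fdr_raw = raw,
             tp = tp, fp = fp)
}

#' Score threshold achieving a requested FDR
#'
#' Returns the smallest threshold whose enveloped FDR does not exceed
#' `fdr_target`.  When the target is unattainable, the threshold of the
#' minimum attainable (non-zero where possible) FDR is returned with a
#' warning.
#'
#' @param fdr_table data frame from [build_fdr_table()]
#' @param fdr_target requested FDR (fraction)
#' @return list with `score_threshold`, `fdr` (the estimated FDR at that
#'   threshold) and `attained` (logical)
#' @export
fdr_score_threshold <- function(fdr_table, fdr_target = 0.01) {
  # only thresholds that accept at least one discovery are operating points
  accepts <- if (all(c("tp", "fp") %in% names(fdr_table)))
    fdr_table$tp + fdr_table$fp > 0 else rep(TRUE, nrow(fdr_table))
  ok <- fdr_table$fdr <= fdr_target & accepts
  if (!any(ok)) {
    cand <- which(accepts)
    if (length(cand) == 0) cand <- seq_len(nrow(fdr_table))
    i <- cand[which.min(fdr_table$fdr[cand])]
    warning(sprintf(
      "FDR %.3g not attainable; minimum estimated FDR is %.3g",
      fdr_target, fdr_table$fdr[i]))
    return(list(score_threshold = fdr_table$score_threshold[i],
                fdr = fdr_table$fdr[i], attained = FALSE))
  }
  i <- max(which(ok))  # smallest threshold still within the target
  list(score_threshold = fdr_table$score_threshold[i],
       fdr = fdr_table$fdr[i], attained = TRUE)
}

#' Estimated FDR (q-value) at a given score
#'
#' @param fdr_table data frame from [build_fdr_table()]
#' @param score PeakDecoder score(s)
#' @return the enveloped FDR at the largest threshold below each score
#'   (`NA` for missing scores)
#' @export
fdr_at_score <- function(fdr_table, score) {
  vapply(score, function(s) {
    if (is.na(s)) return(NA_real_)
    ok <- which(fdr_table$score_threshold < s)
    if (length(ok) == 0) return(fdr_table$fdr[nrow(fdr_table)])
    fdr_table$fdr[min(ok)]
  }, 0)
}

#' Save / load a trained model
#'
#' The model is persisted as a single versioned archive; loading restores
#' scores bit-for-bit.
#'
#' @param model a `peakdecoder_model`
#' @param path file path
#' @return `path` invisibly (`save_peakdecoder`); the model
#'   (`load_peakdecoder`)
#' @export
save_peakdecoder <- function(model, path) {
  stopifnot(inherits(model, "peakdecoder_model"))
  saveRDS(list(format = "peakdecoder_model", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_peakdecoder
#' @export
load_peakdecoder <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "peakdecoder_model"))
    stop("not a peakdecoder model archive: ", path)
  obj$model
}
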