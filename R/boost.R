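#' Weighted round error
#'
#' AdaBoost round error: the total weight mass on misclassified examples,
#' `e_m = sum_i D(i) * [pred_i != label_i]`.
#'
#' @param predictions Predicted labels (+1/-1) on the full training set.
#' @param labels True labels, parallel.
#' @param D Weight distribution over the training set (sums to 1).
#' @return Error in `[0, 1]`.
#' @export
round_error <- function(predictions, labels, D) {
  stopifnot(length(predictions) == length(labels),
            length(labels) == length(D))
  if (abs(sum(D) - 1) > 1e-8) stop("weight vector D must sum to 1")
  sum(D[predictions != labels])
}

#' AdaBoost classifier weight
#'
#' `alpha = 0.5 * log((1 - e) / e)`: positive for better-than-chance
#' rounds, zero at e = 0.5, antisymmetric about chance.
#'
#' @param e_m Weighted round error, strictly inside (0, 1).
#' @return Classifier weight.
#' @export
round_alpha <- function(e_m) {
  if (any(e_m <= 0) || any(e_m >= 1))
    stop("round error must lie strictly inside (0, 1)")
  0.5 * log((1 - e_m) / e_m)
}

#' AdaBoost weight update
#'
#' Re-weights the training distribution: `D'(i) proportional to
#' D(i) * exp(-alpha * y_i * pred_i)`, renormalized to sum exactly 1.
#' Misclassified examples gain weight when alpha > 0.
#'
#' @param D Current weight distribution.
#' @param alpha_m Round weight.
#' @param predictions,labels Predicted and true labels (+1/-1).
#' @return Updated weight vector summing to 1.
#' @export
update_weights <- function(D, alpha_m, predictions, labels) {
  stopifnot(length(D) == length(labels), length(predictions) == length(labels))
  w <- D * exp(-alpha_m * labels * predictions)
  w / sum(w)
}

# deterministic fold assignment
.cv_folds <- function(n, folds, seed) {
  set.seed(as.integer(seed))
  sample(rep_len(seq_len(folds), n))
}

# Fit one RBF-SVM with Platt-style sigmoid calibration of decision values.
# Returns list(svm, calib, C, g). labels: +1/-1 integer.
.fit_svm_calibrated <- function(x, labels, C, g) {
  y <- factor(labels, levels = c(-1L, 1L))
  fit <- e1071::svm(x, y, kernel = "radial", cost = C, gamma = g,
                    scale = FALSE, probability = FALSE)
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")[, 1L]
  y01 <- as.integer(labels == 1L)
  calib <- suppressWarnings(
    stats::glm.fit(cbind(1, dv), y01,
                   family = stats::binomial()))$coefficients
  if (anyNA(calib)) calib <- c(0, 1)
  list(svm = fit, calib = calib, C = C, g = g)
}

# decision values of a fitted round on new rows
.round_decision <- function(round, x) {
  attr(stats::predict(round$svm, x, decision.values = TRUE),
       "decision.values")[, 1L]
}

# probability of the positive class under the calibrated sigmoid
.round_prob <- function(round, x) {
  dv <- .round_decision(round, x)
  stats::plogis(round$calib[1L] + round$calib[2L] * dv)
}

# hard +1/-1 labels from a round
.round_predict <- function(round, x) {
  p <- stats::predict(round$svm, x)
  ifelse(p == "1", 1L, -1L)
}

# ensemble vote: alpha-weighted sum of per-round probabilities.
# prob_matrix is rounds x candidates.
.combine_round_probs <- function(alpha, prob_matrix) {
  stopifnot(length(alpha) == nrow(prob_matrix))
  drop(crossprod(prob_matrix, alpha))
}

#' Train one probability-calibrated RBF-SVM round
#'
#' Fits a soft-margin SVM with radial-basis kernel
#' `K(x, x') = exp(-g * ||x - x'||^2)` on the (balanced) training subset,
#' choosing `(C, g)` from a grid by cross-validated accuracy on the subset,
#' and calibrates a sigmoid on the decision values so the round emits a
#' probability of being the true mature start.
#'
#' @param x Normalized feature matrix of the subset.
#' @param labels Integer labels +1/-1, both classes present.
#' @param grid_C,grid_g Candidate penalty and kernel-width values
#'   (defaults C in \{2, 8\}, g in \{0.5, 0.1\}).
#' @param cv_folds Folds for the grid search (>= 2); skipped when the grid
#'   has a single point.
#' @param seed Seed for fold assignment.
#' @return List with elements `svm`, `calib` (sigmoid intercept/slope),
#'   `C`, `g`.
#' @export
train_round <- function(x, labels, grid_C = c(2, 8), grid_g = c(0.5, 0.1),
                        cv_folds = 3L, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("training subset contains a single class")
  grid <- expand.grid(C = grid_C, g = grid_g)
  if (nrow(grid) == 0L) stop("empty (C, g) grid")
  best <- 1L
  if (nrow(grid) > 1L) {
    folds <- .cv_folds(length(labels), cv_folds, seed)
    acc <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      correct <- 0L
      for (f in seq_len(max(folds))) {
        tr <- folds != f; te <- folds == f
        if (length(unique(labels[tr])) < 2L || !any(te)) next
        fit <- e1071::svm(x[tr, , drop = FALSE],
                          factor(labels[tr], levels = c(-1L, 1L)),
                          kernel = "radial", cost = grid$C[gi],
                          gamma = grid$g[gi], scale = FALSE)
        pred <- stats::predict(fit, x[te, , drop = FALSE])
        correct <- correct + sum(pred == as.character(labels[te]))
      }
      acc[gi] <- correct / length(labels)
    }
    best <- which.max(acc)
  }
  .fit_svm_calibrated(x, labels, grid$C[best], grid$g[best])
}

#' Fit a boosted-SVM mature-start model
#'
#' The main fitting function. From annotated hairpins it enumerates all
#' sliding-window candidates, encodes the 110 features, normalizes them to
#' `[-1, 1]`, builds a balanced round-1 subset (all positives plus
#' k-means-centroid-nearest negatives), and trains up to `rounds`
#' AdaBoost-weighted RBF-SVM rounds. Each round is fit on the current
#' subset, evaluated on the full training set under the boosting weights
#' `D`, weighted by `alpha_m = 0.5 * log((1 - e_m) / e_m)`, and the next
#' subset is grown with the keys the round misclassified. Boosting aborts
#' (discarding the offending round) when `e_m >= 0.5`.
#'
#' @param hairpins Named list of annotated [hairpin()] objects (each needs
#'   `mature_start`); hairpins shorter than the window or with
#'   out-of-range annotation contribute negatives only or are skipped with
#'   a warning.
#' @param window_len Candidate window length in nt (default 22).
#' @param rounds Maximum boosting rounds M (default 10).
#' @param clusters Number of k-means clusters for negative undersampling
#'   (default 10).
#' @param grid_C,grid_g SVM parameter grid (defaults C in \{2, 8\},
#'   g in \{0.5, 0.1\}).
#' @param cv_folds Cross-validation folds for the per-round grid search.
#' @param method `"boosted"` (default) for the balanced boosted ensemble;
#'   `"single"` for one SVM trained on the full imbalanced training set
#'   (the no-rebalancing baseline).
#' @param seed Single integer seed; all stochastic steps (clustering
#'   initialization, CV folds) derive from it.
#' @return An object of class `"mirstart"`: list with `rounds` (each a
#'   calibrated SVM round), `alpha`, `normalization`, `window_len`,
#'   `round_log` (per-round subset size, error, weight, chosen C/g),
#'   `codebook_version`, `method`, `call`.
#' @examples
#' \donttest{
#' set.seed(1)
#' hp <- simulate_hairpins(n_hairpins = 40, seed = 7)
#' fit <- mirstart(hp, rounds = 2, seed = 7)
#' fit
#' predict(fit, hp[1:2], k = 3)
#' }
#' @export
mirstart <- function(hairpins, window_len = 22L, rounds = 10L,
                     clusters = 10L, grid_C = c(2, 8), grid_g = c(0.5, 0.1),
                     cv_folds = 3L, method = c("boosted", "single"),
                     seed = 1L) {
  method <- match.arg(method)
  cl <- match.call()
  seed <- as.integer(seed)
  if (is.null(names(hairpins)))
    names(hairpins) <- vapply(hairpins, `[[`, "", "id")

  annotated <- Filter(function(h) !is.null(h$mature_start), hairpins)
  if (length(annotated) == 0L) stop("no annotated hairpins to train on")
  if (length(annotated) < length(hairpins))
    warning(length(hairpins) - length(annotated),
            " unannotated hairpin(s) skipped")

  windows <- do.call(rbind, lapply(annotated, function(h)
    label_windows(generate_windows(h, window_len), h$mature_start)))
  x_raw <- feature_matrix(annotated, windows)
  labels <- windows$label
  norm <- fit_normalization(x_raw)
  x <- apply_normalization(x_raw, norm)
  keys <- rownames(x)
  pos_keys <- keys[labels == 1L]
  if (length(pos_keys) == 0L) stop("no positive training windows")

  if (method == "single") {
    rd <- train_round(x, labels, grid_C = grid_C, grid_g = grid_g,
                      cv_folds = cv_folds, seed = seed)
    pred <- .round_predict(rd, x)
    log <- data.frame(round = 1L, subset_size = nrow(x),
                      n_incorrect = sum(pred != labels),
                      e_m = mean(pred != labels), alpha_m = 1,
                      C = rd$C, g = rd$g)
    return(structure(list(rounds = list(rd), alpha = 1,
                          normalization = norm, window_len = window_len,
                          round_log = log,
                          codebook_version = CODEBOOK_VERSION,
                          method = method, call = cl),
                     class = "mirstart"))
  }

  subset_keys <- balanced_subset(x, labels, k = clusters, seed = seed,
                                 n_neg = length(pos_keys))
  D <- rep(1 / nrow(x), nrow(x))
  model_rounds <- list(); alpha <- numeric(0)
  log <- NULL
  for (m in seq_len(rounds)) {
    idx <- match(subset_keys, keys)
    rd <- train_round(x[idx, , drop = FALSE], labels[idx],
                      grid_C = grid_C, grid_g = grid_g,
                      cv_folds = cv_folds, seed = seed + m)
    pred <- .round_predict(rd, x)
    e_m <- round_error(pred, labels, D)
    if (e_m >= 0.5) {
      if (m == 1L)
        stop("no usable round: round-1 weighted error ", signif(e_m, 4),
             " >= 0.5")
      break
    }
    if (e_m == 0) e_m <- 0.5 / nrow(x)  # clamp: perfect round, finite alpha
    a_m <- round_alpha(e_m)
    model_rounds[[m]] <- rd
    alpha[m] <- a_m
    wrong <- keys[pred != labels]
    log <- rbind(log, data.frame(round = m,
                                 subset_size = length(subset_keys),
                                 n_incorrect = length(wrong),
                                 e_m = e_m, alpha_m = a_m,
                                 C = rd$C, g = rd$g))
    D <- update_weights(D, a_m, pred, labels)
    subset_keys <- assemble_round_subset(subset_keys, wrong, pos_keys)
  }
  structure(list(rounds = model_rounds, alpha = alpha, normalization = norm,
                 window_len = window_len, round_log = log,
                 codebook_version = CODEBOOK_VERSION, method = method,
                 call = cl),
            class = "mirstart")
}

#' Score and rank all candidate windows of a hairpin
#'
#' Every enumerable window is scored as the alpha-weighted sum of the
#' per-round calibrated probabilities,
#' `score(start) = sum_m alpha_m * p_m(start)`, and candidates are sorted
#' by decreasing score (ties: smaller start first).
#'
#' @param model A fitted [mirstart()] model.
#' @param h A [hairpin()] object.
#' @return Data frame with columns `hairpin_id`, `rank`, `start`, `end`,
#'   `score`, sorted by rank.
#' @export
score_candidates <- function(model, h) {
  stopifnot(inherits(model, "mirstart"), inherits(h, "hairpin"))
  if (!identical(model$codebook_version, CODEBOOK_VERSION))
    stop("model codebook version '", model$codebook_version,
         "' does not match library codebook '", CODEBOOK_VERSION, "'")
  windows <- generate_windows(h, model$window_len)
  x <- apply_normalization(
    feature_matrix(stats::setNames(list(h), h$id), windows),
    model$normalization)
  probs <- matrix(unlist(lapply(model$rounds,
                                function(rd) .round_prob(rd, x))),
                  nrow = length(model$rounds), ncol = nrow(x), byrow = TRUE)
  score <- .combine_round_probs(model$alpha, probs)
  ord <- order(-score, windows$start)
  data.frame(hairpin_id = h$id, rank = seq_len(nrow(x)),
             start = windows$start[ord],
             end = windows$start[ord] + model$window_len - 1L,
             score = score[ord], stringsAsFactors = FALSE)
}

#' Top-k candidate starts for a hairpin
#'
#' @param model A fitted [mirstart()] model.
#' @param h A [hairpin()] object.
#' @param k Number of candidates (default 5). When k exceeds the number of
#'   enumerable windows the full ranking is returned with a warning.
#' @return First k rows of [score_candidates()].
#' @export
predict_top_k <- function(model, h, k = 5L) {
  stopifnot(k >= 1L)
  ranked <- score_candidates(model, h)
  if (k > nrow(ranked)) {
    warning("k = ", k, " exceeds ", nrow(ranked), " windows for '",
            h$id, "'; returning all")
    k <- nrow(ranked)
  }
  ranked[seq_len(k), , drop = FALSE]
}

#' Predict mature start candidates for hairpins
#'
#' @param object A fitted [mirstart()] model.
#' @param newdata A `hairpin` or list of hairpins.
#' @param k Candidates per hairpin (default 5).
#' @param ... Unused.
#' @return Data frame of ranked candidates, `k` rows per hairpin. Hairpins
#'   shorter than the model window are reported with zero rows (warning).
#' @export
predict.mirstart <- function(object, newdata, k = 5L, ...) {
  if (inherits(newdata, "hairpin")) newdata <- list(newdata)
  out <- lapply(newdata, function(h) {
    if (nchar(h$sequence) < object$window_len) {
      warning("hairpin '", h$id, "' shorter than window; no candidates")
      return(NULL)
    }
    predict_top_k(object, h, k)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.mirstart <- function(x, ...) {
  cat("Boosted SVM mature-start model (", x$method, ")\n", sep = "")
  cat("  rounds: ", length(x$rounds), ", window: ", x$window_len,
      " nt\n", sep = "")
  if (!is.null(x$round_log)) {
    cat("  round log:\n")
    print(x$round_log, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.mirstart <- function(object, ...) {
  cat("Boosted RBF-SVM ensemble for 5' mature miRNA start prediction\n")
  cat("Call: "); print(object$call)
  cat("Method:", object$method, "\n")
  cat("Rounds:", length(object$rounds), " Window:", object$window_len,
      "nt\n")
  cat("Ensemble weights (alpha):",
      paste(signif(object$alpha, 4), collapse = ", "), "\n")
  if (!is.null(object$round_log)) print(object$round_log, row.names = FALSE)
  invisible(object)
}

#' @export
coef.mirstart <- function(object, ...) {
  stats::setNames(object$alpha,
                  paste0("round", seq_along(object$alpha)))
}

#' @export
plot.mirstart <- function(x, ...) {
  log <- x$round_log
  if (is.null(log)) stop("model has no round log to plot")
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(log$round, log$e_m, type = "b", xlab = "boosting round",
       ylab = expression(e[m]), main = "Weighted round error", ...)
  graphics::abline(h = 0.5, lty = 2)
  plot(log$round, log$alpha_m, type = "b", xlab = "boosting round",
       ylab = expression(alpha[m]), main = "Round weight", ...)
  invisible(x)
}

#' Save a fitted model bundle
#'
#' Persists the model (SVM rounds, alpha weights, normalization, window
#' length, codebook version) as a single self-describing archive.
#'
#' @param model A fitted [mirstart()] model.
#' @param path Destination file.
#' @export
save_mirstart <- function(model, path) {
  stopifnot(inherits(model, "mirstart"))
  validate_bundle(model)
  saveRDS(model, path)
  invisible(path)
}

#' Load a fitted model bundle
#'
#' Refuses to load archives whose feature-codebook version differs from
#' the library's, or whose contents fail validation.
#'
#' @param path File written by [save_mirstart()].
#' @return A `mirstart` model.
#' @export
load_mirstart <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  model <- tryCatch(readRDS(path),
                    error = function(e) stop("corrupted model file '", path,
                                             "': ", conditionMessage(e),
                                             call. = FALSE))
  if (!inherits(model, "mirstart"))
    stop("'", path, "' does not contain a mirstart model")
  if (!identical(model$codebook_version, CODEBOOK_VERSION))
    stop("model codebook version '", model$codebook_version,
         "' does not match library codebook '", CODEBOOK_VERSION,
         "'; refusing to load")
  validate_bundle(model)
  model
}

# structural checks shared by save/load
validate_bundle <- function(model) {
  if (length(model$rounds) < 1L) stop("model bundle has no rounds")
  if (any(!is.finite(model$alpha))) stop("model bundle has non-finite alpha")
  if (length(model$normalization$min) != 110L ||
      length(model$normalization$max) != 110L)
    stop("model bundle normalization must have exactly 110 entries, has ",
         length(model$normalization$min))
  invisible(model)
}
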