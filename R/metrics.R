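#' Accuracy at a position-deviation tolerance
#'
#' Fraction of hairpins whose predicted start deviates from the annotated
#' start by at most `pd` nucleotides (cumulative accuracy).
#'
#' @param pred_starts,true_starts Parallel vectors of 1-based positions.
#' @param pd Tolerated deviation in nt.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy_at_pd <- function(pred_starts, true_starts, pd = 0L) {
  if (length(pred_starts) == 0L) stop("no predictions to evaluate")
  stopifnot(length(pred_starts) == length(true_starts))
  mean(position_deviation(pred_starts, true_starts) <= pd)
}

#' Exact position-deviation distribution
#'
#' Histogram of exact deviations 0..`max_pd` plus an overflow bin, each
#' normalized so the masses sum to 1.
#'
#' @param pred_starts,true_starts Parallel vectors of 1-based positions.
#' @param max_pd Largest deviation binned exactly (default 5).
#' @return Named numeric vector `"0".."max_pd"`, `">max_pd"`.
#' @export
pd_distribution <- function(pred_starts, true_starts, max_pd = 5L) {
  if (length(pred_starts) == 0L) stop("no predictions to evaluate")
  d <- position_deviation(pred_starts, true_starts)
  masses <- vapply(0:max_pd, function(k) mean(d == k), 0)
  stats::setNames(c(masses, mean(d > max_pd)),
                  c(as.character(0:max_pd), paste0(">", max_pd)))
}

#' Average position deviation (APD)
#'
#' Mean absolute deviation between predicted and true starts, in nt.
#'
#' @param pred_starts,true_starts Parallel vectors of 1-based positions.
#' @return APD in nucleotides.
#' @export
apd <- function(pred_starts, true_starts) {
  if (length(pred_starts) == 0L) stop("no predictions to evaluate")
  mean(position_deviation(pred_starts, true_starts))
}

#' Top-k accuracy at a position-deviation tolerance
#'
#' Fraction of hairpins for which the best of the top-k ranked candidates
#' deviates from the annotated start by at most `pd` nt.
#'
#' @param ranked_lists List of integer vectors: the ranked candidate starts
#'   per hairpin (best first).
#' @param true_starts Annotated starts, parallel to `ranked_lists`.
#' @param k Candidates considered per hairpin.
#' @param pd Tolerated deviation in nt.
#' @return Fraction in `[0, 1]`.
#' @export
top_k_accuracy <- function(ranked_lists, true_starts, k = 5L, pd = 0L) {
  stopifnot(length(ranked_lists) == length(true_starts))
  if (any(lengths(ranked_lists) == 0L)) stop("empty ranked list")
  hits <- mapply(function(starts, truth) {
    kk <- min(k, length(starts))
    min(position_deviation(starts[seq_len(kk)], rep(truth, kk))) <= pd
  }, ranked_lists, true_starts)
  mean(hits)
}

#' Build an evaluation report
#'
#' Summarizes predictions against annotations: cumulative accuracy at
#' deviations 0..5 nt, the exact-deviation distribution, top-k accuracies
#' and the average position deviation.
#'
#' @param predictions Data frame from [predict.mirstart()] (columns
#'   `hairpin_id`, `rank`, `start`).
#' @param truth Data frame with columns `id`, `mature_start` (from
#'   [read_mature_tsv()] or annotated hairpins).
#' @param ks Values of k for top-k accuracy (default 1 and 5).
#' @param max_pd Largest deviation reported exactly (default 5).
#' @return Object of class `"mirstart_eval"`: list with `acc_by_pd`,
#'   `pd_distribution`, `top_k_acc` (matrix k x pd), `apd`, `n`.
#' @export
eval_report <- function(predictions, truth, ks = c(1L, 5L), max_pd = 5L) {
  ids <- intersect(unique(predictions$hairpin_id), truth$id)
  if (length(ids) == 0L)
    stop("no hairpin ids shared between predictions and truth")
  missing_pred <- setdiff(truth$id, unique(predictions$hairpin_id))
  ranked <- lapply(ids, function(i) {
    p <- predictions[predictions$hairpin_id == i, , drop = FALSE]
    p$start[order(p$rank)]
  })
  true_starts <- truth$mature_start[match(ids, truth$id)]
  first <- vapply(ranked, function(r) as.numeric(r[[1L]]), 0)
  acc <- vapply(0:max_pd, function(pd)
    accuracy_at_pd(first, true_starts, pd), 0)
  names(acc) <- paste0(0:max_pd, "nt")
  topk <- sapply(0:max_pd, function(pd)
    vapply(ks, function(k) top_k_accuracy(ranked, true_starts, k, pd), 0))
  dimnames(topk) <- list(paste0("top", ks), paste0(0:max_pd, "nt"))
  structure(list(acc_by_pd = acc,
                 pd_distribution = pd_distribution(first, true_starts,
                                                   max_pd),
                 top_k_acc = topk,
                 apd = apd(first, true_starts),
                 n = length(ids), missing = missing_pred),
            class = "mirstart_eval")
}

#' @export
print.mirstart_eval <- function(x, ...) {
  cat("Mature-start evaluation over", x$n, "hairpins\n")
  cat("Cumulative accuracy by position deviation:\n")
  print(round(x$acc_by_pd, 4))
  cat("Exact-deviation distribution:\n")
  print(round(x$pd_distribution, 4))
  cat("Top-k accuracy:\n")
  print(round(x$top_k_acc, 4))
  cat("APD:", round(x$apd, 2), "nt\n")
  if (length(x$missing))
    cat("(", length(x$missing), "annotated hairpins without predictions )\n")
  invisible(x)
}
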