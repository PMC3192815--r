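#' ROC curve and AUC over confidence thresholds
#'
#' Sweeps the decision threshold over every distinct confidence value (plus
#' sentinels) where a "positive" is a correct call and a "negative" an
#' incorrect one; at threshold `t` a call is predicted positive when its
#' confidence is `>= t`. The AUC is the trapezoidal area under the
#' (FPR, TPR) curve and equals the probability that a random correct call
#' outscores a random incorrect one, ties counting one half.
#'
#' @param confidence numeric vector of call confidences.
#' @param is_correct logical vector, same length.
#' @return list of class `rab_roc`: `points` (data.frame threshold, fpr, tpr)
#'   and `auc`.
#' @export
roc_auc <- function(confidence, is_correct) {
  stopifnot(length(confidence) == length(is_correct))
  ok <- !is.na(confidence) & !is.na(is_correct)
  confidence <- confidence[ok]; is_correct <- as.logical(is_correct[ok])
  n_pos <- sum(is_correct); n_neg <- sum(!is_correct)
  if (n_pos == 0L) stop("no positive (correct) calls: ROC undefined")
  if (n_neg == 0L) stop("no negative (incorrect) calls: ROC undefined")
  thr <- c(Inf, sort(unique(confidence), decreasing = TRUE))
  pts <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(!is_correct & confidence >= t), 1) / n_neg,
    tpr = vapply(thr, function(t) sum(is_correct & confidence >= t), 1) / n_pos)
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  structure(list(points = pts, auc = auc), class = "rab_roc")
}

#' Accuracy bookkeeping, overall and per organism
#'
#' Computes the two aggregate conventions — the overall fraction of correct
#' decisions (`sum(correct) / sum(total)`) and the unweighted mean of the
#' per-organism fractions — at both the family level (is it a Rab?) and the
#' subfamily level (is the named call right, among true Rabs correctly
#' identified as Rabs?).
#'
#' @param calls data.frame from [rabify_batch()].
#' @param truth data.frame with columns `query_id`, `is_rab` (logical),
#'   `subfamily` (the expected call; `"RabX"` for Rabs outside the reference
#'   subfamilies); every call must have a truth row.
#' @param organism named character vector or data.frame (query_id, organism)
#'   mapping queries to organisms; defaults to a single organism `"all"`.
#' @return list of class `rab_accuracy`: family (per_organism,
#'   overall_fraction, mean_per_organism), subfamily (idem), mode.
#' @export
accuracy_report <- function(calls, truth, organism = NULL) {
  if (nrow(calls) == 0L) stop("empty call set")
  m <- match(calls$query_id, truth$query_id)
  if (anyNA(m))
    stop("truth label missing for: ",
         paste(calls$query_id[is.na(m)], collapse = ", "))
  truth <- truth[m, , drop = FALSE]
  org <- if (is.null(organism)) rep("all", nrow(calls))
  else if (is.data.frame(organism))
    organism$organism[match(calls$query_id, organism$query_id)]
  else unname(organism[calls$query_id])
  if (anyNA(org)) stop("organism missing for some queries")

  fam_correct <- calls$is_rab == truth$is_rab
  agg <- function(correct, org) {
    per <- t(vapply(split(correct, org), function(x)
      c(n_correct = sum(x), n_total = length(x)), c(1, 1)))
    frac <- per[, "n_correct"] / per[, "n_total"]
    list(per_organism = per, overall_fraction = sum(correct) / length(correct),
         mean_per_organism = mean(frac))
  }
  fam <- agg(fam_correct, org)

  sub_ix <- which(truth$is_rab & calls$is_rab %in% TRUE)
  sub <- if (length(sub_ix)) {
    agg(calls$call[sub_ix] == truth$subfamily[sub_ix], org[sub_ix])
  } else list(per_organism = NULL, overall_fraction = NA_real_,
              mean_per_organism = NA_real_)
  structure(list(family = fam, subfamily = sub,
                 mode = if ("mode" %in% names(calls)) calls$mode[1] else NA),
            class = "rab_accuracy")
}

#' Write ROC points / accuracy report as TSV
#' @param roc `rab_roc` from [roc_auc()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roc_tsv <- function(roc, path) {
  pts <- roc$points
  pts$threshold[is.infinite(pts$threshold)] <- NA
  write_tsv(pts, path)
  invisible(path)
}

#' @rdname write_roc_tsv
#' @param report `rab_accuracy` from [accuracy_report()].
#' @export
write_accuracy_tsv <- function(report, path) {
  lv <- function(level, x) data.frame(
    level = level,
    organism = rownames(x$per_organism),
    n_correct = x$per_organism[, "n_correct"],
    n_total = x$per_organism[, "n_total"],
    stringsAsFactors = FALSE)
  rows <- lv("family", report$family)
  if (!is.null(report$subfamily$per_organism))
    rows <- rbind(rows, lv("subfamily", report$subfamily))
  summary <- data.frame(
    level = c("family", "family", "subfamily", "subfamily"),
    organism = c("_overall", "_mean_per_organism",
                 "_overall", "_mean_per_organism"),
    n_correct = NA_integer_, n_total = NA_integer_,
    stringsAsFactors = FALSE)
  summary$fraction <- c(report$family$overall_fraction,
                        report$family$mean_per_organism,
                        report$subfamily$overall_fraction,
                        report$subfamily$mean_per_organism)
  rows$fraction <- rows$n_correct / rows$n_total
  write_tsv(rbind(rows, summary), path)
  invisible(path)
}
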