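# Evaluation: plain accuracy, roll-up of species-level predictions to
# genus and family through the manifest taxonomy, per-class accuracy
# binning, and top-k ranked prediction.

#' Construct a prediction set
#'
#' @param true 0-based true class indices.
#' @param pred 0-based predicted class indices.
#' @param prob Optional N x K probability matrix (rows sum to 1 within
#'   1e-6).
#' @param record_id Optional record ids.
#' @param level Taxonomic level of the indices (default `"species"`).
#' @return An object of class `amcnn_predictions`.
#' @export
prediction_set <- function(true, pred, prob = NULL, record_id = NULL,
                           level = "species") {
  true <- as.integer(true)
  pred <- as.integer(pred)
  if (length(true) == 0L) stop("empty prediction set")
  if (length(pred) != length(true)) stop("true/pred length mismatch")
  if (!is.null(prob)) {
    if (nrow(prob) != length(true)) stop("prob rows must match predictions")
    if (any(abs(rowSums(prob) - 1) > 1e-6))
      stop("probability rows must sum to 1")
    if (any(pred < 0L) || any(pred >= ncol(prob)))
      stop("predicted index outside class range")
  }
  structure(list(true = true, pred = pred, prob = prob,
                 record_id = record_id, level = level),
            class = "amcnn_predictions")
}

#' @export
print.amcnn_predictions <- function(x, ...) {
  cat("Prediction set (", x$level, "): ", length(x$true), " records, accuracy ",
      sprintf("%.4f", accuracy(x)), "\n", sep = "")
  invisible(x)
}

#' Classification accuracy
#'
#' The exact ratio of correct predictions to the number of predictions; no
#' internal rounding.
#'
#' @param preds An [prediction_set()].
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(preds) {
  stopifnot(inherits(preds, "amcnn_predictions"))
  if (length(preds$true) == 0L) stop("empty prediction set")
  mean(preds$pred == preds$true)
}

# species index (0-based) -> index at `level`, from a manifest.
level_map <- function(manifest, level) {
  tax <- unique(manifest$records[, c("family", "genus", "species")])
  sp_idx <- manifest$class_index$species[tax$species]
  lv_idx <- manifest$class_index[[level]][tax[[level]]]
  out <- integer(length(sp_idx))
  out[sp_idx + 1L] <- lv_idx
  out
}

#' Roll species-level predictions up the taxonomy
#'
#' Maps predicted and true species indices upward to genus or family using
#' the manifest taxonomy, so accuracy can be reported per level; a correct
#' species prediction is by construction correct at every level, hence
#' accuracy is monotone non-decreasing going up the hierarchy.  Probability
#' columns, when present, are summed over the species of each upper-level
#' class.
#'
#' @param preds A species-level [prediction_set()].
#' @param manifest The manifest defining the taxonomy and class indices.
#' @param level Target level: `"family"`, `"genus"` or `"species"`.
#' @return A [prediction_set()] at the requested level.
#' @export
rollup <- function(preds, manifest, level = c("species", "genus", "family")) {
  level <- match.arg(level)
  stopifnot(inherits(preds, "amcnn_predictions"),
            inherits(manifest, "amcnn_manifest"))
  if (preds$level != "species")
    stop("rollup expects species-level predictions")
  if (level == "species") return(preds)
  K <- length(manifest$class_index$species)
  if (any(preds$true < 0L) || any(preds$true >= K) ||
      any(preds$pred < 0L) || any(preds$pred >= K))
    stop("mapping error: species index outside the manifest's class range")
  map <- level_map(manifest, level)
  prob <- NULL
  if (!is.null(preds$prob)) {
    grp <- map[seq_len(ncol(preds$prob))]          # 0-based group per column
    prob <- t(rowsum(t(preds$prob), grp))
    prob <- prob[, order(as.integer(colnames(prob))), drop = FALSE]
  }
  prediction_set(map[preds$true + 1L], map[preds$pred + 1L], prob,
                 preds$record_id, level)
}

#' Per-class accuracies of a prediction set
#'
#' @param preds An [prediction_set()].
#' @return Named numeric vector, one accuracy per true class present
#'   (names are 0-based class indices).
#' @export
per_class_accuracy <- function(preds) {
  stopifnot(inherits(preds, "amcnn_predictions"))
  correct <- preds$pred == preds$true
  vapply(split(correct, preds$true), mean, 0)
}

#' Bin per-class accuracies into three intervals
#'
#' The bins are `[0, e1)`, `[e1, e2]` and `(e2, 1]` with default edges 0.85
#' and 0.90 (the middle bin closed on both sides so the three bins are
#' exhaustive and disjoint).  Returns the fraction of classes per bin.
#'
#' @param per_class Numeric vector of per-class accuracies in `[0, 1]`.
#' @param edges Two increasing bin edges in (0, 1).
#' @return Named numeric vector `c(low, mid, high)` summing to 1.
#' @export
bin_per_class <- function(per_class, edges = c(0.85, 0.90)) {
  if (any(per_class < 0 | per_class > 1))
    stop("accuracies must lie in [0, 1]")
  if (length(edges) != 2L || edges[1L] >= edges[2L])
    stop("edges must be two increasing values")
  k <- length(per_class)
  if (k == 0L) stop("no classes to bin")
  c(low = sum(per_class < edges[1L]) / k,
    mid = sum(per_class >= edges[1L] & per_class <= edges[2L]) / k,
    high = sum(per_class > edges[2L]) / k)
}

#' Top-k ranked classes from a score vector
#'
#' Ranks classes by descending probability, breaking ties by ascending
#' class index, and returns exactly `k` rows.
#'
#' @param scores Numeric vector of class scores (typically probabilities);
#'   names are used as labels when present.
#' @param k Number of classes to return (default 3; must be
#'   `<= length(scores)`).
#' @return data.frame with columns `rank`, `class` (0-based index),
#'   `label` and `confidence`.
#' @export
top_k <- function(scores, k = 3L) {
  k <- as.integer(k)
  if (k < 1L || k > length(scores))
    stop("parameter error: k must lie in 1..n_classes")
  ord <- order(-scores, seq_along(scores))[seq_len(k)]
  labels <- if (!is.null(names(scores))) names(scores)[ord]
            else as.character(ord - 1L)
  data.frame(rank = seq_len(k), class = ord - 1L, label = labels,
             confidence = unname(scores[ord]), row.names = NULL)
}

#' Predict a manifest part as a prediction set
#'
#' @param fit An [amcnn_fit()] trained at species level.
#' @param manifest,split Manifest and split the fit was made on.
#' @param part Which part to predict (default `"test"`).
#' @param mask_provider Optional mask provider for attention weighting.
#' @param image_root Directory that record paths are relative to.
#' @return A species-level [prediction_set()].
#' @export
predict_set <- function(fit, manifest, split, part = "test",
                        mask_provider = NULL, image_root = NULL) {
  stopifnot(inherits(fit, "amcnn_fit"))
  recs <- split_records(manifest, split, part)
  if (nrow(recs) == 0L) stop("split part '", part, "' is empty")
  probs <- predict.amcnn_fit(fit, recs, type = "prob",
                             mask_provider = if (fit$use_masks) mask_provider else NULL,
                             image_root = image_root)
  true <- unname(fit$class_index[recs[[fit$level]]])
  pred <- max.col(probs, ties.method = "first") - 1L
  prediction_set(true, pred, probs, recs$record_id, fit$level)
}

#' Evaluate a fitted model with taxonomic roll-up
#'
#' Computes species/genus/family accuracy by rolling the species-level
#' predictions up the manifest taxonomy (mode `"rollup"`), together with
#' per-class accuracies and their three-bin fractions at every level.
#'
#' @inheritParams predict_set
#' @param edges Bin edges for [bin_per_class()].
#' @return An object of class `amcnn_report`: list with `mode`, `n`,
#'   `accuracy` (per level), `per_class`, `bins` and the species-level
#'   `predictions`.
#' @export
evaluate_model <- function(fit, manifest, split, part = "test",
                           mask_provider = NULL, image_root = NULL,
                           edges = c(0.85, 0.90)) {
  preds <- predict_set(fit, manifest, split, part, mask_provider, image_root)
  if (fit$level != "species")
    stop("roll-up evaluation needs a species-level fit")
  levels <- c("family", "genus", "species")
  acc <- numeric(0)
  per_class <- list()
  bins <- list()
  for (lv in levels) {
    p <- rollup(preds, manifest, lv)
    acc[lv] <- accuracy(p)
    per_class[[lv]] <- per_class_accuracy(p)
    bins[[lv]] <- bin_per_class(per_class[[lv]], edges)
  }
  structure(list(mode = "rollup", n = length(preds$true), part = part,
                 accuracy = acc, per_class = per_class, bins = bins,
                 edges = edges, predictions = preds),
            class = "amcnn_report")
}

#' @export
print.amcnn_report <- function(x, ...) {
  cat("Evaluation (", x$mode, ", ", x$part, " part, n = ", x$n, ")\n", sep = "")
  for (lv in names(x$accuracy)) {
    b <- x$bins[[lv]]
    cat(sprintf("  %-8s accuracy %.4f | class bins <%.0f%%: %.3f  [%.0f-%.0f%%]: %.3f  >%.0f%%: %.3f\n",
                lv, x$accuracy[[lv]], 100 * x$edges[1L], b[["low"]],
                100 * x$edges[1L], 100 * x$edges[2L], b[["mid"]],
                100 * x$edges[2L], b[["high"]]))
  }
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An [evaluate_model()] report.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "amcnn_report"))
  out <- list(mode = report$mode, part = report$part, n = report$n,
              accuracy = as.list(report$accuracy),
              bins = lapply(report$bins, as.list),
              per_class = lapply(report$per_class, as.list))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
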