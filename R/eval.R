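# Evaluation: confusion matrix, precision/recall/F-score, stratified
# k-fold cross-validation, automated-vs-manual count regression, and the
# proliferation score with its clinical categorization.
#
# Metric convention note: the source method's printed precision/recall
# formulas swap the FP and FN denominators relative to the standard
# definitions, yet its printed results (0.93 precision, 0.88 recall from
# the published confusion matrix) are only reproduced by the standard
# reading Pr = TP/(TP+FP), Re = TP/(TP+FN). The standard definitions are
# therefore the default; `convention = "as_printed"` exposes the swapped
# variant for auditability.

#' Tally a 2x2 confusion matrix
#'
#' Rows are actual, columns predicted; the positive class is
#' `"immunopositive"`.
#'
#' @param predicted,actual Vectors of class labels (from
#'   [nucleus_classes()]), equal length.
#' @return Object of class `confusion_matrix`: list with `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
compute_confusion <- function(predicted, actual) {
  predicted <- as.character(predicted); actual <- as.character(actual)
  if (length(predicted) != length(actual))
    stop("predicted and actual lengths differ", call. = FALSE)
  bad <- setdiff(unique(c(predicted, actual)), nucleus_classes())
  if (length(bad))
    stop(sprintf("unknown class label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  pos <- "immunopositive"
  confusion_matrix(tp = sum(actual == pos & predicted == pos),
                   fn = sum(actual == pos & predicted != pos),
                   fp = sum(actual != pos & predicted == pos),
                   tn = sum(actual != pos & predicted != pos))
}

#' @rdname compute_confusion
#' @param tp,fn,fp,tn Non-negative counts.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(v < 0)) stop("confusion counts must be >= 0", call. = FALSE)
  structure(as.list(v), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, byrow = TRUE,
              dimnames = list(actual = c("immunopositive", "immunonegative"),
                              predicted = c("immunopositive", "immunonegative")))
  print(m)
  invisible(x)
}

#' Precision, recall and F-score from a confusion matrix
#'
#' Standard definitions: precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F = harmonic mean of the unrounded precision and recall. Values are
#' proportions in `[0, 1]`; round only for presentation. An undefined
#' metric (zero denominator) is reported as `NA`, not 0.
#'
#' @param cm A [confusion_matrix()].
#' @param convention `"standard"` (default) or `"as_printed"` (the audit
#'   variant with FP/FN denominators swapped; see source note above).
#' @return List with `precision`, `recall`, `f_score`.
#' @examples
#' compute_metrics(confusion_matrix(17028, 2277, 1287, 15840))
#' @export
compute_metrics <- function(cm, convention = c("standard", "as_printed")) {
  convention <- match.arg(convention)
  stopifnot(inherits(cm, "confusion_matrix"))
  den_p <- if (convention == "standard") cm$tp + cm$fp else cm$tp + cm$fn
  den_r <- if (convention == "standard") cm$tp + cm$fn else cm$tp + cm$fp
  precision <- if (den_p > 0) cm$tp / den_p else NA_real_
  recall <- if (den_r > 0) cm$tp / den_r else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f_score = f)
}

#' Automated proliferation score (APS)
#'
#' `APS(%) = 100 * TIP / (TIP + TIN)` where TIP and TIN are the
#' immunopositive and immunonegative nucleus counts. The category follows
#' the clinical reference ranges low (< 15), average (16--30), high
#' (> 31); the unassigned boundary slivers are closed as
#' low < 15 <= average <= 30 < high.
#'
#' @param tip,tin Non-negative counts.
#' @return Object of class `proliferation_result`: `tip`, `tin`, `aps`
#'   (percentage, `NA` when no nuclei), `category` (`"low"`, `"average"`,
#'   `"high"` or `NA`).
#' @examples
#' compute_aps(13, 87)   # 13%, low
#' @export
compute_aps <- function(tip, tin) {
  stopifnot_scalar(tip, "tip", 0); stopifnot_scalar(tin, "tin", 0)
  if (tip + tin == 0) {
    return(structure(list(tip = 0L, tin = 0L, aps = NA_real_,
                          category = NA_character_),
                     class = "proliferation_result"))
  }
  aps <- 100 * tip / (tip + tin)
  structure(list(tip = as.integer(tip), tin = as.integer(tin), aps = aps,
                 category = aps_category(aps)),
            class = "proliferation_result")
}

#' @rdname compute_aps
#' @param aps APS percentage.
#' @export
aps_category <- function(aps) {
  ifelse(is.na(aps), NA_character_,
         ifelse(aps < 15, "low", ifelse(aps <= 30, "average", "high")))
}

#' @export
print.proliferation_result <- function(x, ...) {
  if (is.na(x$aps)) {
    cat("Proliferation score undefined: no nuclei detected\n")
  } else {
    cat(sprintf("APS = %.2f%% (%d immunopositive / %d total): %s proliferation\n",
                x$aps, x$tip, x$tip + x$tin, x$category))
  }
  invisible(x)
}

#' Category error between manual and automated scores
#'
#' Absolute difference between the mean of the manual (pathologist)
#' proliferation scores and the automated score, reported at two
#' decimals.
#'
#' @param manual Numeric vector of manual scores (percent), length >= 1.
#' @param automated Automated score (percent).
#' @return Absolute difference, rounded to two decimals.
#' @examples
#' category_error(c(12.87, 13.01), 13.00)  # 0.06
#' @export
category_error <- function(manual, automated) {
  if (!length(manual)) stop("need at least one manual score", call. = FALSE)
  round(abs(mean(manual) - automated), 2)
}

#' Ordinary least-squares regression of automated on manual counts
#'
#' @param automated,manual Paired per-image nucleus counts (>= 3 pairs).
#' @return List with `slope`, `intercept`, `r_squared` (`NA` with a
#'   warning when the manual counts have zero variance).
#' @export
count_regression <- function(automated, manual) {
  if (length(automated) != length(manual) || length(manual) < 3)
    stop("need >= 3 paired counts", call. = FALSE)
  if (stats::var(manual) == 0) {
    warning("manual counts have zero variance; R^2 undefined")
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_))
  }
  fit <- stats::lm(automated ~ manual)
  r2 <- if (stats::var(automated) == 0) 0 else
    1 - sum(stats::residuals(fit)^2) / sum((automated - mean(automated))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Stratified k-fold cross-validation of the patch classifier
#'
#' Splits patches into `k` stratified folds, trains on `k - 1` and
#' evaluates on the held-out fold, reporting per-fold and mean precision,
#' recall and F-score. Fold assignment, training and evaluation are all
#' reproducible from `rng_seed`.
#'
#' @param patches `size x size x 3 x N` array in `[0, 1]`.
#' @param labels Patch classes.
#' @param k Number of folds (>= 2; the reference protocol uses 5).
#' @param net_config,tc Network and training configuration (desk-scale
#'   defaults).
#' @param rng_seed Master seed.
#' @param classifier Optional function `(train_patches, train_labels,
#'   test_patches) -> predicted labels`, replacing network training (used
#'   for stub-based testing).
#' @return List: `folds` (assignment), `per_fold` (data.frame of fold,
#'   n_test, precision, recall, f_score), `mean` (list of averaged
#'   metrics).
#' @export
cross_validate <- function(patches, labels, k = 5L,
                           net_config = desk_network_config(),
                           tc = desk_train_config(), rng_seed = 1L,
                           classifier = NULL) {
  labels <- as.character(labels)
  fold <- build_splits(labels, k_folds = k, rng_seed = rng_seed)
  seeds <- derive_seeds(rng_seed + 1L, k)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    pred <- if (is.null(classifier)) {
      tcf <- tc; tcf$rng_seed <- seeds[f]
      net <- ndf_train(patches[, , , tr, drop = FALSE], labels[tr],
                       net_config, tcf)
      predict(net, patches[, , , te, drop = FALSE])$label
    } else {
      classifier(patches[, , , tr, drop = FALSE], labels[tr],
                 patches[, , , te, drop = FALSE])
    }
    m <- compute_metrics(compute_confusion(pred, labels[te]))
    rows[[f]] <- data.frame(fold = f, n_test = sum(te),
                            precision = m$precision, recall = m$recall,
                            f_score = m$f_score)
  }
  per_fold <- do.call(rbind, rows)
  list(folds = fold, per_fold = per_fold,
       mean = list(precision = mean(per_fold$precision),
                   recall = mean(per_fold$recall),
                   f_score = mean(per_fold$f_score)))
}

#' Score one image end-to-end
#'
#' Composition of the full pipeline: detect seed points, crop a patch
#' around each, classify every patch with the trained network, count the
#' classes and compute the proliferation score.
#'
#' @param image H x W x 3 array (0--255).
#' @param net A trained `ki67_net`.
#' @param config A [seed_detection_config()].
#' @param patch_size Patch side (default from the network input shape).
#' @return List: `result` (a [compute_aps()] object; APS `NA` when no
#'   nuclei detected), `nuclei` (per-nucleus data.frame: row, col,
#'   detected class, classified label, posteriors), `labels` (the pixel
#'   label map).
#' @export
score_image <- function(image, net, config = seed_detection_config(),
                        patch_size = NULL) {
  stopifnot(inherits(net, "ki67_net"))
  if (is.null(patch_size)) patch_size <- net$config$input_shape[1]
  det <- detect_seeds(image, config)
  if (!nrow(det$seeds)) {
    return(list(result = compute_aps(0, 0),
                nuclei = data.frame(), labels = det$labels))
  }
  cp <- crop_patches(image, det$seeds, size = patch_size,
                     boundary = "reflect")
  cls <- predict(net, cp$patches)
  nuclei <- cbind(det$seeds[cp$kept, c("row", "col", "class", "area")], cls)
  names(nuclei)[names(nuclei) == "class"] <- "detected_class"
  tip <- sum(cls$label == "immunopositive")
  tin <- sum(cls$label == "immunonegative")
  list(result = compute_aps(tip, tin), nuclei = nuclei, labels = det$labels)
}
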