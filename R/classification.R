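#' Extract scalar features from coefficient maps
#'
#' Crops a square ROI from each supplied map, reduces it by block
#' binning (default 2 x 2, halving the processing size), and averages to
#' one scalar feature per map. Because the mean is invariant to block
#' averaging, binning changes only the processing cost, not the feature
#' value, for fully valid ROIs.
#'
#' @param maps Named list of co-registered matrices (e.g.
#'   `list(mua = ..., musp = ...)` for the full-SFDI feature set, or
#'   `list(planar = ...)` for the planar-illumination set).
#' @param roi_origin ROI top-left corner as (row, col), 1-based.
#'   Default c(1, 1).
#' @param roi_size ROI edge, pixels. Default 400 (the bench protocol,
#'   26 mm at the bench pixel scale); must fit inside the maps.
#' @param bin Binning factor before averaging. Default 2.
#' @return Named numeric vector, one feature per map.
#' @export
extract_features <- function(maps, roi_origin = c(1L, 1L),
                             roi_size = 400L, bin = 2L) {
  stopifnot(is.list(maps), length(maps) >= 1L)
  vapply(maps, function(m) {
    m <- as.matrix(m)
    r0 <- roi_origin[1L]; c0 <- roi_origin[2L]
    if (r0 < 1L || c0 < 1L ||
        r0 + roi_size - 1L > nrow(m) || c0 + roi_size - 1L > ncol(m)) {
      stop("ROI out of bounds", call. = FALSE)
    }
    roi <- m[r0:(r0 + roi_size - 1L), c0:(c0 + roi_size - 1L)]
    mean(bin_image(roi, bin), na.rm = TRUE)
  }, numeric(1L))
}

#' Regroup four damage classes into three severity classes
#'
#' The four acquisition classes are A (normal), B (bruised),
#' C (scratched) and D (abraded). The three-class severity scheme keeps
#' normal, merges bruised and scratched into "minor" (both are shallow
#' damage with similar mean optical properties), and maps abraded to
#' "serious". The four-class scheme is the identity.
#'
#' @param labels Character or factor vector of class labels from
#'   `{"A", "B", "C", "D"}` (or the long names
#'   `{"normal", "bruised", "scratched", "abraded"}`).
#' @param scheme `"four"` (identity) or `"three"`.
#' @return Factor of regrouped labels.
#' @export
regroup_classes <- function(labels, scheme = c("four", "three")) {
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  long <- c(normal = "A", bruised = "B", scratched = "C", abraded = "D")
  labels <- ifelse(labels %in% names(long), long[labels], labels)
  if (!all(labels %in% c("A", "B", "C", "D"))) {
    stop("unknown class label", call. = FALSE)
  }
  if (scheme == "four") return(factor(labels, levels = c("A", "B", "C", "D")))
  map3 <- c(A = "normal", B = "minor", C = "minor", D = "serious")
  factor(unname(map3[labels]), levels = c("normal", "minor", "serious"))
}

#' Linear discriminant classification with stratified k-fold CV
#'
#' Fits a linear discriminant classifier and estimates accuracy by
#' stratified k-fold cross-validation with seeded fold assignment.
#' Every training fold must contain all classes.
#'
#' @param features Numeric matrix or data frame, one row per sample.
#' @param labels Class labels (factor or coercible).
#' @param k Number of folds (>= 2). Default 5.
#' @param seed Seed for the fold assignment. Default 1.
#' @return List with `accuracy` (percent), `confusion` (table,
#'   reference x predicted), `fold_accuracy` (per-fold percent).
#' @export
lda_crossval <- function(features, labels, k = 5L, seed = 1L) {
  x <- as.matrix(features)
  y <- factor(labels)
  stopifnot(nrow(x) == length(y))
  if (k < 2L) stop("k-fold cross-validation requires k >= 2", call. = FALSE)
  if (any(table(y) < k)) {
    warning("some class has fewer samples than folds; stratification is partial")
  }
  folds <- .with_seed(seed, function() {
    f <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (fold in seq_len(k)) {
    test <- folds == fold
    if (nlevels(droplevels(y[!test])) < nlevels(y)) {
      stop("a class is absent from a training fold; use fewer folds or more samples",
           call. = FALSE)
    }
    fit <- MASS::lda(x[!test, , drop = FALSE], grouping = y[!test])
    pred[test] <- stats::predict(fit, x[test, , drop = FALSE])$class
  }
  confusion <- table(reference = y, predicted = pred)
  fold_acc <- vapply(seq_len(k), function(fold) {
    test <- folds == fold
    100 * mean(pred[test] == y[test])
  }, numeric(1L))
  list(accuracy = 100 * mean(pred == y), confusion = confusion,
       fold_accuracy = fold_acc)
}

#' Simulate a labelled damage cohort and extract features
#'
#' Renders `n_per_class` damage scenes per class through the full
#' acquisition chain (simulate stacks, demodulate, calibrate, invert)
#' and extracts both feature sets: the full-SFDI features (mean mua,
#' mean musp over the ROI) and the planar features (mean calibrated
#' zero-frequency reflectance).
#'
#' @param n_per_class Scenes per class. Default 20.
#' @param fx_list Frequencies for the SFDI acquisition (must include 0
#'   for the planar feature). Default c(0, 0.042, 0.084, 0.14).
#' @param noise_sigma Camera noise fraction passed to the simulator.
#' @param size Scene size (rows, cols). Default c(48, 48).
#' @param bin Superpixel binning for the per-pixel inversion. Default 4.
#' @param seed Cohort seed; per-scene seeds are derived from it.
#' @return Data frame with columns `class` (A-D), `mean_mua`,
#'   `mean_musp`, `mean_planar`.
#' @export
simulate_damage_cohort <- function(n_per_class = 20L,
                                   fx_list = c(0, 0.042, 0.084, 0.14),
                                   noise_sigma = 0.01,
                                   size = c(48L, 48L), bin = 4L,
                                   seed = 1L) {
  stopifnot(0 %in% fx_list, length(fx_list) >= 3L)
  classes <- c(normal = "A", bruised = "B", scratched = "C", abraded = "D")
  rows <- list()
  scene_id <- 0L
  for (cl in names(classes)) {
    for (i in seq_len(n_per_class)) {
      scene_id <- scene_id + 1L
      s <- make_damage_scene(cl, seed = seed * 10000L + scene_id,
                             size = size)
      spec <- scene_spec(s$mua_map, s$musp_map, fx_list,
                         noise_sigma = noise_sigma,
                         seed = seed * 10000L + scene_id)
      stacks <- simulate_stack(spec)
      demod <- demodulate_acquisition(stacks$sample, stacks$reference,
                                      fx_list, rd_ref = spec$rd_ref)
      maps <- invert_map(demod$rd, fx_list, bin = bin,
                         medium = medium_constants(n = spec$n))
      planar <- demod$rd[[which(fx_list == 0)[1L]]]
      feats <- c(
        extract_features(list(mua = maps$mua, musp = maps$musp),
                         roi_size = nrow(maps$mua), bin = 1L),
        extract_features(list(planar = planar),
                         roi_size = min(dim(planar)), bin = 2L))
      rows[[scene_id]] <- data.frame(class = classes[[cl]],
                                     mean_mua = feats[["mua"]],
                                     mean_musp = feats[["musp"]],
                                     mean_planar = feats[["planar"]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
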