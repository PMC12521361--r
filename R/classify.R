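#' Compartment class labels
#'
#' Slices are classified into four compartments whose integer codes mirror
#' the proximal-to-distal anatomy: 0 = epiphyseal bone, 1 = growth plate,
#' 2 = primary spongiosa, 3 = secondary spongiosa.
#'
#' @format NULL
#' @export
COMPARTMENT_CLASSES <- c(epiphyseal_bone = 0L, growth_plate = 1L,
                         primary_spongiosa = 2L, secondary_spongiosa = 3L)

#' Aggregate multi-rater slice annotations by majority vote
#'
#' @param table data frame with columns `bone_id`, `slice_index`,
#'   `rater_id`, `repeat_id`, `label` (codes 0-3).
#' @return Data frame (`bone_id`, `slice_index`, `label`, `tie`) with the
#'   modal label per slice. Ties are broken toward the lowest class code
#'   (the most proximal compatible compartment) with a warning.
#' @export
majority_vote <- function(table) {
  need <- c("bone_id", "slice_index", "label")
  if (!all(need %in% names(table)))
    stopf("annotation table must have columns %s", paste(need, collapse = ", "))
  if (!all(table$label %in% 0:3)) stopf("labels must be codes 0..3")
  key <- paste(table$bone_id, table$slice_index, sep = "\r")
  groups <- split(table$label, key)
  if (any(lengths(groups) == 0)) stopf("empty slice group")
  ids <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  n_tie <- 0L
  lab <- vapply(groups, function(v) {
    tab <- table(factor(v, levels = 0:3))
    w <- which(tab == max(tab))
    if (length(w) > 1) n_tie <<- n_tie + 1L
    as.integer(names(tab)[w[1]])
  }, integer(1))
  tie <- vapply(groups, function(v) {
    tab <- table(factor(v, levels = 0:3))
    sum(tab == max(tab)) > 1
  }, logical(1))
  if (n_tie > 0)
    warnf("%d slice(s) had tied votes; broke toward the lower class code",
          n_tie)
  out <- data.frame(bone_id = ids[, 1],
                    slice_index = as.integer(ids[, 2]),
                    label = unname(lab), tie = unname(tie),
                    stringsAsFactors = FALSE)
  out[order(out$bone_id, out$slice_index), , drop = FALSE]
}

# ---- slice descriptors ------------------------------------------------------

shift_mat <- function(m, dx, dy) {
  n <- matrix(FALSE, nrow(m), ncol(m))
  xs <- seq_len(nrow(m)); ys <- seq_len(ncol(m))
  xd <- xs + dx; yd <- ys + dy
  ok_x <- xd >= 1 & xd <= nrow(m); ok_y <- yd >= 1 & yd <= ncol(m)
  n[xd[ok_x], yd[ok_y]] <- m[xs[ok_x], ys[ok_y]]
  n
}

#' Per-slice descriptors for the feature-baseline classifier
#'
#' Computes, per prepared slice: bone-area fraction, medullary bone-area
#' fraction (after removing the cortical shell), connected-component count,
#' a mean 2D object-thickness proxy, a low-attenuation band score capturing
#' non-calcified cartilage, and an 8-bin radial mean-intensity profile.
#'
#' @param slices list of `prepared_slice` objects (see [prepare_slices()]).
#' @param threshold bone/background threshold on the normalized scale; by
#'   default the Otsu threshold of the pooled slice intensities.
#' @return A numeric matrix (one row per slice) with named columns, and the
#'   threshold used as attribute `"threshold"`.
#' @export
slice_features <- function(slices, threshold = NULL) {
  thr <- threshold %||% {
    # pooled histogram threshold; a deterministic pixel subsample suffices
    px_sub <- unlist(lapply(slices, function(s)
      s$pixels[seq(1, length(s$pixels), by = 13L)]), use.names = FALSE)
    otsu_threshold(px_sub)
  }
  n_rad <- 8L
  d1 <- dim(slices[[1]]$pixels)
  Xc <- matrix(rep(seq_len(d1[1]), d1[2]), d1[1], d1[2])
  Yc <- matrix(rep(seq_len(d1[2]), each = d1[1]), d1[1], d1[2])
  feats <- t(vapply(slices, function(s) {
    px <- s$pixels
    bone <- px > thr
    if (!any(bone)) return(rep(0, 5 + n_rad))
    filled <- fill_holes_2d(bone)
    lab <- label_components(bone, 26L)
    ncomp <- attr(lab, "n_components")
    outer_bg <- !filled
    adj <- outer_bg
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
      adj <- adj | shift_mat(outer_bg, d[1], d[2])
    cortex_labels <- setdiff(unique(lab[adj & bone]), 0L)
    cortex <- matrix(lab %in% cortex_labels, nrow(lab), ncol(lab)) & bone
    medulla <- filled & !cortex
    n_med <- sum(medulla)
    med_bone <- if (n_med > 0) sum(bone & medulla) / n_med else 0
    d2 <- .cpp_edt_sq(array(bone, dim = c(dim(bone), 1L)),
                      c(dim(bone), 1L), TRUE)
    thick <- 2 * mean(sqrt(d2[bone])) / nrow(bone)
    band <- if (n_med > 0)
      sum(px[medulla] > 0.5 * thr & px[medulla] <= thr) / n_med else 0
    fx <- Xc[filled]; fy <- Yc[filled]
    rr <- sqrt((fx - mean(fx))^2 + (fy - mean(fy))^2)
    rmax <- max(rr, 1)
    bin <- pmin(floor(rr / rmax * n_rad) + 1L, n_rad)
    fv <- px[filled]
    rad <- vapply(seq_len(n_rad), function(b) {
      sel <- bin == b
      if (any(sel)) mean(fv[sel]) else 0
    }, numeric(1))
    c(mean(bone), med_bone, log1p(ncomp), thick, band, rad)
  }, numeric(5 + n_rad)))
  colnames(feats) <- c("bone_frac", "med_bone_frac", "log_ncomp",
                       "thickness_proxy", "cartilage_band",
                       paste0("radial_", seq_len(n_rad)))
  attr(feats, "threshold") <- thr
  feats
}

# ---- training ---------------------------------------------------------------

#' Training configuration
#'
#' Cross-entropy loss optimized by mini-batch stochastic gradient descent at
#' learning rate 1e-3 with batch size 64 (the standard recipe for this
#' classification task); the `feature_baseline` backbone is a multinomial
#' logistic model on the [slice_features()] descriptors and is fully
#' deterministic for a fixed seed.
#'
#' @param learning_rate SGD learning rate (> 0).
#' @param batch_size mini-batch size (>= 1).
#' @param epochs number of passes over the training set.
#' @param backbone only `"feature_baseline"` is built in; the interface
#'   accepts external backbones implementing `fit`/`logits`.
#' @param seed integer seed controlling batch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64L,
                         epochs = 300L, backbone = "feature_baseline",
                         seed = 1L) {
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  if (batch_size < 1) stopf("batch_size must be >= 1")
  structure(list(loss = "cross_entropy", optimizer = "sgd",
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), backbone = backbone,
                 seed = as.integer(seed)),
            class = "train_config")
}

softmax_rows <- function(L) {
  m <- apply(L, 1, max)
  E <- exp(L - m)
  E / rowSums(E)
}

#' Train the slice classifier
#'
#' Fits the configured backbone to labelled slices. The built-in
#' `feature_baseline` backbone standardizes the slice descriptors and fits a
#' 4-class softmax (multinomial logistic) model by mini-batch SGD with
#' cross-entropy loss.
#'
#' @param x either a list of `prepared_slice` objects or a precomputed
#'   feature matrix from [slice_features()].
#' @param labels integer class codes 0-3, one per slice.
#' @param config a [train_config()].
#' @return A `slice_classifier` object.
#' @export
train_classifier <- function(x, labels, config = train_config()) {
  if (!inherits(config, "train_config")) stopf("config must be a train_config")
  if (config$backbone != "feature_baseline")
    stopf("backbone '%s' is not built in; provide feature_baseline",
          config$backbone)
  feats <- if (is.matrix(x)) x else slice_features(x)
  labels <- as.integer(labels)
  if (nrow(feats) != length(labels)) stopf("labels/slices length mismatch")
  missing_cls <- setdiff(0:3, unique(labels))
  if (length(missing_cls) > 0)
    stopf("class(es) %s missing from the training set",
          paste(missing_cls, collapse = ", "))
  ctr <- colMeans(feats)
  scl <- apply(feats, 2, sd)
  scl[scl == 0] <- 1
  X <- cbind(1, sweep(sweep(feats, 2, ctr), 2, scl, "/"))
  Y <- matrix(0, nrow(X), 4)
  Y[cbind(seq_len(nrow(X)), labels + 1L)] <- 1
  W <- matrix(0, ncol(X), 4)
  n <- nrow(X)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      for (s in starts) {
        rows <- ord[s:min(s + config$batch_size - 1L, n)]
        Xb <- X[rows, , drop = FALSE]
        P <- softmax_rows(Xb %*% W)
        grad <- crossprod(Xb, P - Y[rows, , drop = FALSE]) / length(rows)
        W <- W - config$learning_rate * grad
      }
    }
  })
  structure(list(weights = W, center = ctr, scale = scl,
                 threshold = attr(feats, "threshold"),
                 config = config, classes = 0:3),
            class = "slice_classifier")
}

classifier_logits <- function(classifier, feats) {
  X <- cbind(1, sweep(sweep(feats, 2, classifier$center), 2,
                      classifier$scale, "/"))
  X %*% classifier$weights
}

#' Per-slice class probabilities
#'
#' Applies the classifier to prepared slices and passes the logits through a
#' softmax, yielding the class-probability profile along z (proximal to
#' distal).
#'
#' @param classifier a `slice_classifier`.
#' @param slices list of `prepared_slice` objects, ordered proximal to
#'   distal, or a precomputed feature matrix.
#' @param voxel_size_mm voxel size of the source volume.
#' @return A [probability_profile].
#' @export
predict_probabilities <- function(classifier, slices, voxel_size_mm) {
  feats <- if (is.matrix(slices)) slices
           else slice_features(slices, threshold = classifier$threshold)
  P <- softmax_rows(classifier_logits(classifier, feats))
  probability_profile(P, voxel_size_mm)
}

#' Bone-level k-fold split
#'
#' Partitions bones (not slices) into k folds so that all slices of a bone
#' stay on one side of each train/validation split; fold sizes differ by at
#' most one.
#'
#' @param bone_ids vector of bone identifiers (duplicates allowed; folds are
#'   over unique bones).
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @return List of k vectors of bone ids.
#' @export
kfold_split <- function(bone_ids, k = 5L, seed = 1L) {
  bones <- unique(bone_ids)
  if (k > length(bones)) stopf("k = %d exceeds the number of bones (%d)",
                               k, length(bones))
  with_seed(seed, {
    shuffled <- sample(bones)
    split(shuffled, rep_len(seq_len(k), length(shuffled)))
  })
}

#' Classification metrics
#'
#' Per-class precision (TP / (TP + FP)), recall (TP / (TP + FN)) and F1 (the
#' harmonic mean of precision and recall), plus the 4x4 confusion matrix
#' (rows = true, columns = predicted).
#'
#' Classes with zero support have undefined recall and are reported as `NA`,
#' not 0; a class with precision + recall = 0 has F1 = 0.
#'
#' @param true_labels,predicted_labels equal-length integer vectors of codes
#'   0-3.
#' @return A `classification_report`: list with `confusion` and `per_class`
#'   (data frame with precision, recall, f1, support).
#' @export
classification_report <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stopf("label sequences must have equal length")
  lv <- 0:3
  confusion <- table(factor(true_labels, levels = lv),
                     factor(predicted_labels, levels = lv))
  confusion <- unclass(confusion)
  dimnames(confusion) <- list(true = lv, predicted = lv)
  tp <- diag(confusion)
  support <- rowSums(confusion)
  pred_n <- colSums(confusion)
  precision <- ifelse(pred_n > 0, tp / pred_n, NA_real_)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  f1 <- f1_score(precision, recall)
  structure(list(confusion = confusion,
                 per_class = data.frame(class = lv, precision = precision,
                                        recall = recall, f1 = f1,
                                        support = as.integer(support),
                                        row.names = NULL)),
            class = "classification_report")
}

#' F1 score
#'
#' Harmonic mean of precision and recall: `2 P R / (P + R)`, defined as 0
#' when `P + R = 0`.
#'
#' @param precision,recall fractions in \[0, 1\] (vectorized).
#' @return F1 score(s).
#' @export
f1_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall), NA_real_,
         ifelse(precision + recall > 0,
                2 * precision * recall / (precision + recall), 0))
}
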