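# Box proposal, feature extraction and object classification. The proposal
# stage is parameter-free background subtraction (Otsu threshold on the
# intensity channel) followed by connected components; the classifier is a
# multinomial logistic model over a hand-built descriptor: 8x8 resampled
# grayscale patch, per-channel 8-bin color histogram, and area/aspect/
# eccentricity moments. Deterministic end to end.

FEATURE_LENGTH <- 64L + 24L + 3L

#' Propose object bounding boxes in a scene image
#'
#' Background subtraction: the background level is estimated by the median
#' intensity (the background dominates the frame), and foreground = pixels
#' darker than that level by more than `margin`. The median is robust where a
#' global Otsu split is not — with only a few percent foreground, Otsu's
#' between-class criterion tends to cut through the foreground's own modes
#' (e.g. between the yellow and black bands of a bee). Each 8-connected
#' foreground component (above a small area floor that suppresses isolated
#' noise pixels) yields the tight axis-aligned box of its pixels. Boxes are
#' sorted by (y, x) for determinism.
#'
#' @param image A `scene_image` or a numeric `h x w x 3` array in `[0, 1]`.
#' @param min_area Minimum component pixel count (default 6).
#' @param margin Intensity-unit separation from the background level
#'   (default 0.1, half the generator's noiseless separability margin).
#' @return Tibble of boxes (`x`, `y`, `w`, `h`), possibly empty.
#' @export
propose_boxes <- function(image, min_area = 6L, margin = 0.1) {
  pixels <- if (inherits(image, "scene_image")) image$pixels else image
  gray <- image_gray(pixels)
  bg <- stats::median(gray)
  fg <- matrix(as.numeric(gray < bg - margin), nrow = nrow(gray))
  if (!any(fg > 0)) {
    return(tibble(x = integer(), y = integer(), w = integer(), h = integer()))
  }
  lab <- EBImage::bwlabel(fg)
  nlab <- max(lab)
  if (nlab == 0) return(tibble(x = integer(), y = integer(), w = integer(), h = integer()))
  boxes <- map(seq_len(nlab), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_area) return(NULL)
    bounding_box(min(idx[, 2]) - 1L, min(idx[, 1]) - 1L,
                 max(idx[, 2]) - min(idx[, 2]) + 1L,
                 max(idx[, 1]) - min(idx[, 1]) + 1L)
  }) %>% bind_rows()
  if (nrow(boxes) == 0L) return(tibble(x = integer(), y = integer(), w = integer(), h = integer()))
  arrange(boxes, .data$y, .data$x)
}

#' Extract the descriptor of an image patch
#'
#' Concatenates (i) the 8x8 nearest-neighbour-resampled grayscale patch,
#' (ii) an 8-bin proportion histogram per color channel, and (iii) log-area,
#' aspect ratio and eccentricity of the darkness-weighted second moments.
#' Translation-invariant (the descriptor sees only the crop) and exactly
#' invariant under integer upscaling of the patch.
#'
#' @param image A `scene_image` or pixel array.
#' @param box A box within the image.
#' @return Numeric vector of length 91.
#' @export
extract_features <- function(image, box) {
  pixels <- if (inherits(image, "scene_image")) image$pixels else image
  patch <- crop_image(pixels, box)
  gray <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3
  block <- as.vector(resample_nearest(gray, 8L, 8L))
  hist_part <- unlist(map(1:3, function(ch) {
    v <- as.vector(patch[, , ch])
    counts <- tabulate(pmin(8L, floor(v * 8) + 1L), nbins = 8L)
    counts / length(v)
  }))
  wgt <- pmax(0, 1 - gray)  # darkness weights: foreground is darker than background
  s <- sum(wgt)
  if (s > 0) {
    cols <- matrix(rep(seq_len(ncol(gray)), each = nrow(gray)), nrow = nrow(gray))
    rows <- matrix(rep(seq_len(nrow(gray)), times = ncol(gray)), nrow = nrow(gray))
    mx <- sum(wgt * cols) / s; my <- sum(wgt * rows) / s
    mxx <- sum(wgt * (cols - mx)^2) / s
    myy <- sum(wgt * (rows - my)^2) / s
    mxy <- sum(wgt * (cols - mx) * (rows - my)) / s
    tr <- mxx + myy
    det_ <- mxx * myy - mxy^2
    disc <- sqrt(max(0, tr^2 / 4 - det_))
    l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
    ecc <- if (l1 > 1e-12) sqrt(max(0, 1 - l2 / l1)) else 0
  } else ecc <- 0
  shape <- c(log1p(as.numeric(box$w) * box$h) / 10, box$w / box$h, ecc)
  out <- c(block, hist_part, shape)
  stopifnot(length(out) == FEATURE_LENGTH, all(is.finite(out)))
  out
}

feature_matrix <- function(image, boxes) {
  if (nrow(boxes) == 0L) return(matrix(numeric(), 0L, FEATURE_LENGTH))
  t(vapply(seq_len(nrow(boxes)), function(i) extract_features(image, boxes[i, ]),
           numeric(FEATURE_LENGTH)))
}

# ---- multinomial logistic core ---------------------------------------------
# Full-batch gradient descent on the cross-entropy, zero-initialized (the
# objective is convex, so the optimum does not depend on initialization).
# Rows are canonically sorted before fitting, making the fit exactly
# invariant to the presentation order of the training data.

canonical_row_order <- function(X, y) {
  key <- apply(X, 1L, function(r) paste(format(r, digits = 10), collapse = ","))
  order(y, key)
}

softmax_fit <- function(X, y_idx, n_classes, lr = 0.5, epochs = 300L, l2 = 1e-4) {
  ord <- canonical_row_order(X, y_idx)
  X <- X[ord, , drop = FALSE]; y_idx <- y_idx[ord]
  n <- nrow(X); d <- ncol(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd); sdv[sdv < 1e-9] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  W <- matrix(0, n_classes, d); b <- rep(0, n_classes)
  Y <- matrix(0, n, n_classes); Y[cbind(seq_len(n), y_idx)] <- 1
  history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    P <- row_softmax(Xs %*% t(W) + matrix(b, n, n_classes, byrow = TRUE))
    history[e] <- -mean(log(pmax(P[cbind(seq_len(n), y_idx)], 1e-300)))
    G <- P - Y
    W <- W - lr * (t(G) %*% Xs / n + l2 * W)
    b <- b - lr * colMeans(G)
  }
  list(W = W, b = b, mu = mu, sd = sdv, history = history)
}

softmax_predict <- function(fit, X, temperature = 1) {
  Xs <- sweep(sweep(X, 2L, fit$mu), 2L, fit$sd, "/")
  logits <- Xs %*% t(fit$W) + matrix(fit$b, nrow(X), length(fit$b), byrow = TRUE)
  row_softmax(logits / temperature)
}

#' Train the object classifier on a generated dataset
#'
#' Crops every ground-truth box, extracts descriptors, and fits a multinomial
#' logistic model over the full 15-class vocabulary by full-batch gradient
#' descent on the cross-entropy. A seeded train/validation split is recorded;
#' the fit itself is exactly invariant to the presentation order of the data.
#'
#' @param dataset A `scene_dataset`.
#' @param holdout_frac Fraction of instances held out for validation.
#' @param epochs,lr Gradient-descent schedule.
#' @param seed Seed for the validation split.
#' @return An object of class `object_classifier`.
#' @export
train_object_classifier <- function(dataset, holdout_frac = 0.2, epochs = 300L,
                                    lr = 0.5, seed = 1L) {
  vocab <- load_vocabulary(attr(dataset, "config")$species)
  feats <- list(); labels <- character()
  for (i in seq_len(nrow(dataset))) {
    ann <- dataset$annotation[[i]]
    img <- dataset$image[[i]]
    if (nrow(ann$objects) == 0L) next
    feats[[length(feats) + 1L]] <- feature_matrix(img, ann$objects)
    labels <- c(labels, ann$objects$name)
  }
  X <- do.call(rbind, feats)
  classes <- vocab$objects$name
  y <- match(labels, classes)
  if (length(unique(y)) < 2L) abort("training data contains a single object class")
  ord <- canonical_row_order(X, y)
  X <- X[ord, , drop = FALSE]; y <- y[ord]
  n <- nrow(X)
  n_val <- max(1L, floor(holdout_frac * n))
  val_idx <- with_seed(seed, sample(n, n_val))
  tr <- setdiff(seq_len(n), val_idx)
  fit <- softmax_fit(X[tr, , drop = FALSE], y[tr], length(classes), lr, epochs)
  val_post <- softmax_predict(fit, X[val_idx, , drop = FALSE])
  val_acc <- mean(max.col(val_post, ties.method = "first") == y[val_idx])
  tr_post <- softmax_predict(fit, X[tr, , drop = FALSE])
  structure(list(fit = fit, classes = classes, species = vocab$species,
                 n_train = length(tr), n_val = n_val,
                 train_accuracy = mean(max.col(tr_post, ties.method = "first") == y[tr]),
                 val_accuracy = val_acc, epochs = as.integer(epochs), lr = lr,
                 seed = as.integer(seed)),
            class = "object_classifier")
}

#' @export
print.object_classifier <- function(x, ...) {
  cat(sprintf("<object_classifier: %s> %d classes, train acc %.3f, val acc %.3f (n=%d/%d)\n",
              x$species, length(x$classes), x$train_accuracy, x$val_accuracy,
              x$n_train, x$n_val))
  invisible(x)
}

#' Class posteriors for a set of feature vectors
#'
#' @param features Numeric matrix (rows = boxes) or single vector.
#' @param classifier An `object_classifier`.
#' @param temperature Softmax temperature; the infinite-temperature limit is
#'   the uniform distribution over the 15 classes.
#' @return Matrix of posteriors, one row per box, rows summing to 1.
#' @export
classify_objects <- function(features, classifier, temperature = 1) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != ncol(classifier$fit$W))
    abort(sprintf("descriptor length %d does not match classifier (%d)",
                  ncol(features), ncol(classifier$fit$W)))
  post <- softmax_predict(classifier$fit, features, temperature)
  colnames(post) <- classifier$classes
  post
}

#' Detect and classify objects in one image
#'
#' Runs [propose_boxes()], [extract_features()] and [classify_objects()] and
#' bundles boxes, descriptors and class posteriors.
#'
#' @param image A `scene_image` or pixel array.
#' @param classifier An `object_classifier`.
#' @return An object of class `detections`: list with `boxes` (tibble),
#'   `features` (matrix), `posteriors` (matrix), `classes`.
#' @export
detect_objects <- function(image, classifier) {
  boxes <- propose_boxes(image)
  feats <- feature_matrix(image, boxes)
  post <- if (nrow(boxes) > 0L) classify_objects(feats, classifier)
          else matrix(numeric(), 0L, length(classifier$classes),
                      dimnames = list(NULL, classifier$classes))
  structure(list(boxes = boxes, features = feats, posteriors = post,
                 classes = classifier$classes,
                 image = if (inherits(image, "scene_image")) image$pixels else image),
            class = "detections")
}

#' @export
print.detections <- function(x, ...) {
  cat(sprintf("<detections> %d boxes\n", nrow(x$boxes)))
  invisible(x)
}

#' Predicted class names of a detection set
#' @param det A `detections` object.
#' @return Character vector of argmax class names.
#' @export
detected_classes <- function(det) {
  if (nrow(det$boxes) == 0L) return(character())
  det$classes[max.col(det$posteriors, ties.method = "first")]
}

#' @method as_tibble detections
#' @export
as_tibble.detections <- function(x, ...) {
  if (nrow(x$boxes) == 0L)
    return(tibble(x = integer(), y = integer(), w = integer(), h = integer(),
                  class = character(), confidence = numeric()))
  cls <- max.col(x$posteriors, ties.method = "first")
  cls_name <- x$classes[cls]
  conf <- x$posteriors[cbind(seq_along(cls), cls)]
  x$boxes %>% mutate(class = cls_name, confidence = conf)
}
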