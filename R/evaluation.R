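# The staged evaluation protocol. S1 (object recognition): an image counts
# as correct when every ground-truth object is matched by a prediction of
# the same class at IoU >= 0.5. S2 (bounding boxes): the fraction of
# ground-truth boxes recovered at IoU >= 0.5 must strictly exceed 0.5 — for
# six boxes this is the published "at least four out of six" rule, with
# three of six (probability exactly 0.5) counted as failed. S3 (scene
# description): evaluated only on images where S1 and S2 both hold; the
# behavior-defining ground-truth predicate must be decoded positive
# (probability strictly above 0.5) and match; the accuracy denominator is
# the number of recognized images, not the dataset size.

IOU_MATCH <- 0.5

# One-to-one matching over the IoU >= threshold bipartite graph by
# augmenting paths (Kuhn's algorithm): always a maximum-cardinality
# matching, so it provably agrees with the exhaustive assignment oracle.
# Edges are explored in descending IoU for a deterministic, quality-first
# result.
match_boxes <- function(pred, truth, iou_min = IOU_MATCH, pred_class = NULL,
                        truth_class = NULL) {
  np <- nrow(pred); nt <- nrow(truth)
  empty <- tibble(pred_idx = integer(), truth_idx = integer(), iou = numeric())
  if (np == 0L || nt == 0L) return(empty)
  iou <- matrix(-1, np, nt)
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    if (!is.null(pred_class) && pred_class[i] != truth_class[j]) next
    v <- box_iou(pred[i, ], truth[j, ])
    if (v >= iou_min) iou[i, j] <- v
  }
  match_t <- integer(nt)  # truth j -> pred index (0 = free)
  vis <- logical(nt)      # shared per augmentation attempt
  try_augment <- function(i) {
    js <- which(iou[i, ] >= 0)
    for (j in js[order(-iou[i, js], js)]) {
      if (vis[j]) next
      vis[j] <<- TRUE
      if (match_t[j] == 0L || try_augment(match_t[j])) {
        match_t[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in seq_len(np)) {
    vis <- logical(nt)
    try_augment(i)
  }
  hit <- which(match_t > 0L)
  if (length(hit) == 0L) return(empty)
  tibble(pred_idx = match_t[hit], truth_idx = hit,
         iou = iou[cbind(match_t[hit], hit)]) %>%
    arrange(.data$pred_idx)
}

graph_boxes <- function(sg) {
  sg$objects %>% select("x", "y", "w", "h")
}

#' S1: object recognition accuracy
#'
#' An image verdict is correct iff every ground-truth object is matched
#' one-to-one by a predicted object of the same class at IoU >= 0.5.
#' Per-object recall is also reported.
#'
#' @param predicted List of predicted `scene_graph`s, one per image.
#' @param annotations List of ground-truth `image_annotation`s (aligned ids).
#' @return List of class `stage_eval`: `accuracy`, `verdicts` tibble,
#'   `object_recall`.
#' @export
eval_s1 <- function(predicted, annotations) {
  check_alignment(predicted, annotations)
  n_matched <- 0L; n_truth <- 0L
  verdicts <- map2(predicted, annotations, function(sg, ann) {
    m <- match_boxes(graph_boxes(sg), ann$objects, pred_class = sg$objects$name,
                     truth_class = ann$objects$name)
    n_matched <<- n_matched + nrow(m); n_truth <<- n_truth + nrow(ann$objects)
    tibble(image_id = ann$image_id, correct = nrow(m) == nrow(ann$objects))
  }) %>% bind_rows()
  structure(list(accuracy = mean(verdicts$correct), verdicts = verdicts,
                 object_recall = if (n_truth > 0L) n_matched / n_truth else NA_real_,
                 stage = "S1"),
            class = "stage_eval")
}

#' Bounding-box success rule
#'
#' `fraction = detected / total`; success iff the fraction strictly exceeds
#' 0.5. At total = 6 this reproduces the published threshold of 4: three of
#' six (probability exactly 0.5) fails, four or more succeed. Monotone in
#' `detected`.
#'
#' @param detected Number of ground-truth boxes recovered.
#' @param total Number of ground-truth boxes (>= 1).
#' @return List `(fraction, success)`.
#' @export
box_success <- function(detected, total) {
  detected <- as.integer(detected); total <- as.integer(total)
  if (is.na(total) || total < 1L) abort("total must be >= 1")
  if (is.na(detected) || detected < 0L || detected > total)
    abort("detected must lie in [0, total]")
  fraction <- detected / total
  list(fraction = fraction, success = fraction > 0.5)
}

#' S2: bounding-box accuracy
#'
#' Per image, counts the ground-truth boxes matched one-to-one at
#' IoU >= 0.5 (class-agnostic) and applies [box_success()].
#'
#' @param predicted List of predicted `scene_graph`s (or `detections`).
#' @param annotations Aligned ground-truth annotations.
#' @return `stage_eval` with per-image `detected`, `total`, `fraction`,
#'   `correct`.
#' @export
eval_s2 <- function(predicted, annotations) {
  check_alignment(predicted, annotations)
  verdicts <- map2(predicted, annotations, function(p, ann) {
    boxes <- if (inherits(p, "detections")) p$boxes else graph_boxes(p)
    m <- match_boxes(boxes, ann$objects)
    total <- nrow(ann$objects)
    bs <- box_success(nrow(m), max(1L, total))
    tibble(image_id = ann$image_id, detected = nrow(m), total = total,
           fraction = bs$fraction, correct = bs$success)
  }) %>% bind_rows()
  structure(list(accuracy = mean(verdicts$correct), verdicts = verdicts, stage = "S2"),
            class = "stage_eval")
}

#' Binary predicate verdict at the 0.5 decision threshold
#'
#' @param p Predicted probability in `[0, 1]`.
#' @return 1 if `p > 0.5` (strict), else 0.
#' @export
predicate_verdict <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) abort("probability outside [0, 1]")
  as.integer(p > 0.5)
}

#' S3: scene (textual description) accuracy
#'
#' Gated on S1 and S2: only images recognized by both stages are evaluated.
#' An image is correct iff the predicted graph contains the behavior-defining
#' ground-truth triplet — subject and object matched at IoU >= 0.5 with the
#' right classes, the right predicate, decoded positive at the strict 0.5
#' threshold. The accuracy denominator is the number of recognized images;
#' with none, the accuracy is NA (not applicable).
#'
#' @param predicted List of predicted `scene_graph`s with `prob` on relations.
#' @param annotations Aligned ground-truth annotations carrying `headline`.
#' @param s1,s2 `stage_eval` results from [eval_s1()] and [eval_s2()].
#' @return `stage_eval` with `accuracy`, per-image verdicts, `n_recognized`.
#' @export
eval_s3 <- function(predicted, annotations, s1, s2) {
  check_alignment(predicted, annotations)
  if (nrow(s1$verdicts) != length(predicted) || nrow(s2$verdicts) != length(predicted))
    abort("verdict vectors not aligned with predictions")
  recognized <- s1$verdicts$correct & s2$verdicts$correct
  rows <- map(seq_along(predicted), function(k) {
    ann <- annotations[[k]]
    if (!recognized[k] || is.null(ann$headline))
      return(tibble(image_id = ann$image_id, evaluated = FALSE, correct = NA))
    sg <- predicted[[k]]
    hl <- ann$headline
    sub_t <- ann$objects[hl$subject_idx, ]
    obj_t <- ann$objects[hl$object_idx, ]
    ok <- FALSE
    for (r in seq_len(nrow(sg$relations))) {
      if (sg$relations$predicate[r] != hl$predicate) next
      si <- sg$relations$subject_idx[r]; oi <- sg$relations$object_idx[r]
      p <- if ("prob" %in% names(sg$relations)) sg$relations$prob[r] else 1
      if (predicate_verdict(p) == 1L &&
          sg$objects$name[si] == sub_t$name &&
          sg$objects$name[oi] == obj_t$name &&
          box_iou(sg$objects[si, ], sub_t) >= IOU_MATCH &&
          box_iou(sg$objects[oi, ], obj_t) >= IOU_MATCH) {
        ok <- TRUE; break
      }
    }
    tibble(image_id = ann$image_id, evaluated = TRUE, correct = ok)
  }) %>% bind_rows()
  n_rec <- sum(rows$evaluated)
  structure(list(
    accuracy = if (n_rec > 0L) sum(rows$correct[rows$evaluated]) / n_rec else NA_real_,
    verdicts = rows, n_recognized = n_rec, stage = "S3"),
    class = "stage_eval")
}

#' @export
print.stage_eval <- function(x, ...) {
  acc <- if (is.na(x$accuracy)) "n/a" else sprintf("%.3f", x$accuracy)
  cat(sprintf("<stage_eval %s> accuracy %s over %d images\n", x$stage, acc, nrow(x$verdicts)))
  invisible(x)
}

check_alignment <- function(predicted, annotations) {
  if (length(predicted) != length(annotations))
    abort("prediction/annotation id mismatch: different lengths")
  invisible(TRUE)
}

#' Run the full pipeline on a dataset and evaluate all three stages
#'
#' @param dataset A `scene_dataset`.
#' @param model An `sgg_model` (its classifier is used for detection).
#' @return One-row tibble with `s1`, `s2`, `s3` accuracies plus counts.
#' @export
evaluate_pipeline <- function(dataset, model) {
  graphs <- map(seq_len(nrow(dataset)), function(i) {
    det <- detect_objects(dataset$image[[i]], model$classifier)
    classify_scene_graph(det, model, image_id = dataset$image_id[i])
  })
  anns <- dataset$annotation
  s1 <- eval_s1(graphs, anns)
  s2 <- eval_s2(graphs, anns)
  s3 <- eval_s3(graphs, anns, s1, s2)
  acc <- c(s1$accuracy, s2$accuracy, s3$accuracy)
  n_rec <- s3$n_recognized
  tibble(n_images = nrow(dataset), s1 = acc[1], s2 = acc[2], s3 = acc[3],
         n_recognized = n_rec)
}

#' Accuracy curve over a dataset series
#'
#' Generates a series of datasets of increasing size and reports S1/S2/S3
#' accuracies for each, mirroring the fifteen-dataset evaluation design
#' (first dataset 100 images, later ones larger). `predict_fun` maps
#' `(image, annotation)` to a `scene_graph`; [oracle_predictor()] gives the
#' ground-truth-reading model.
#'
#' @param predict_fun Function `(scene_image, image_annotation) -> scene_graph`.
#' @param species `"bee"` or `"ant"`.
#' @param sizes Integer vector of dataset sizes (default `seq(100, 1500, 100)`).
#' @param seed Master seed; dataset k uses a split of it.
#' @param noise_sd Rendering noise passed to the generator.
#' @return Tibble of class `eval_report`: dataset index, n_images, s1, s2, s3.
#' @export
accuracy_curve <- function(predict_fun, species = "bee",
                           sizes = seq(100L, 1500L, by = 100L), seed = 0L,
                           noise_sd = 0) {
  rows <- map(seq_along(sizes), function(k) {
    ds <- generate_dataset(scene_config(species, n_images = sizes[k],
                                        noise_sd = noise_sd,
                                        seed = split_seed(seed, k)))
    graphs <- map(seq_len(nrow(ds)), ~ predict_fun(ds$image[[.x]], ds$annotation[[.x]]))
    s1 <- eval_s1(graphs, ds$annotation)
    s2 <- eval_s2(graphs, ds$annotation)
    s3 <- eval_s3(graphs, ds$annotation, s1, s2)
    tibble(dataset = k, n_images = sizes[k], s1 = s1$accuracy, s2 = s2$accuracy,
           s3 = s3$accuracy)
  })
  out <- bind_rows(rows)
  class(out) <- c("eval_report", class(out))
  out
}

#' Ground-truth-reading predictor
#'
#' Returns the annotation's own scene graph; useful as the perfect-model
#' reference for protocol checks (a flat accuracy curve at 1.0).
#'
#' @return A predictor function for [accuracy_curve()].
#' @export
oracle_predictor <- function() {
  function(image, ann) annotation_to_scene_graph(ann)
}

#' Pipeline predictor from a trained model
#'
#' @param model An `sgg_model`.
#' @return A predictor function for [accuracy_curve()].
#' @export
pipeline_predictor <- function(model) {
  function(image, ann) {
    det <- detect_objects(image, model$classifier)
    classify_scene_graph(det, model, image_id = ann$image_id)
  }
}

#' Corrupt ground-truth object labels with nested noise
#'
#' Flips each annotated object's class with probability `eps`, using a
#' per-object uniform draw shared across `eps` values (the flipped set grows
#' with `eps`), so accuracy degradation is monotone in `eps` by construction
#' up to the resampled replacement labels.
#'
#' @param annotations List of `image_annotation`s.
#' @param eps Flip probability in `[0, 1]`.
#' @param vocab The species vocabulary (replacement classes).
#' @param seed Seed for the shared draws.
#' @return List of corrupted annotations.
#' @export
corrupt_labels <- function(annotations, eps, vocab, seed = 1L) {
  map(seq_along(annotations), function(k) {
    ann <- annotations[[k]]
    if (nrow(ann$objects) == 0L) return(ann)
    with_seed(split_seed(seed, k), {
      u <- runif(nrow(ann$objects))
      repl_idx <- sample.int(nrow(vocab$objects) - 1L, nrow(ann$objects), replace = TRUE)
      flip <- which(u < eps)
      for (i in flip) {
        others <- setdiff(seq_len(nrow(vocab$objects)),
                          match(ann$objects$name[i], vocab$objects$name))
        pick <- others[repl_idx[i] %% length(others) + 1L]
        ann$objects$name[i] <- vocab$objects$name[pick]
        ann$objects$synset[i] <- vocab$objects$synset[pick]
      }
      ann
    })
  })
}
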