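# Shared fixtures, generated in code and cached for the duration of a test
# run. Small sizes keep the suite fast; the acceptance tests use the full
# default configuration.

.fixture_cache <- new.env(parent = emptyenv())

fixture_dataset <- function(species = "bee", n = 8L, seed = 0L, noise_sd = 0) {
  key <- paste("ds", species, n, seed, noise_sd)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_dataset(
      scene_config(species, n_images = n, seed = seed, noise_sd = noise_sd))
  }
  .fixture_cache[[key]]
}

fixture_classifier <- function(species = "bee", n = 24L) {
  key <- paste("clf", species, n)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- train_object_classifier(fixture_dataset(species, n), seed = 1)
  }
  .fixture_cache[[key]]
}

fixture_model <- function(species = "bee", n = 24L) {
  key <- paste("sgg", species, n)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- train_sgg(fixture_dataset(species, n),
                                       fixture_classifier(species, n), seed = 1)
  }
  .fixture_cache[[key]]
}

# First image of a given behavior in a dataset, with its detections.
fixture_scene <- function(behavior, species = "bee", n = 24L) {
  ds <- fixture_dataset(species, n)
  i <- which(ds$behavior == behavior)[1]
  stopifnot(!is.na(i))
  list(image = ds$image[[i]], annotation = ds$annotation[[i]], index = i)
}

fixture_detections <- function(behavior, species = "bee", n = 24L) {
  sc <- fixture_scene(behavior, species, n)
  detect_objects(sc$image, fixture_classifier(species, n))
}

# A tiny hand-built annotation: two bees and a greeting triplet.
toy_annotation <- function() {
  objects <- tibble::tibble(
    object_id = 1:2, name = c("bee", "bee"), synset = c("bee.n.03", "bee.n.03"),
    x = c(10L, 40L), y = c(20L, 20L), w = c(12L, 12L), h = c(8L, 8L),
    attributes = list(c(Color = "Yellow"), c(Color = "Black")))
  regions <- tibble::tibble(
    region_id = 1L, x = 5L, y = 15L, w = 55L, h = 20L, phrase = "Bee Greeting",
    object_ids = list(1:2))
  rel <- tibble::tibble(subject_idx = 1L, predicate = "greeting", object_idx = 2L)
  qa <- tibble::tibble(qtype = c("what", "what"), scope = c("full_image", "region"),
                       question = c("What are the bees doing?", "What is shown in this region?"),
                       answer = c("Greeting", "Bee Greeting"), region_ref = c(NA_integer_, 1L))
  image_annotation(1L, 64L, 64L, regions, objects, rel, qa,
                   behavior = "greeting",
                   headline = list(subject_idx = 1L, predicate = "greeting", object_idx = 2L))
}

# Independent exhaustive enumeration of injective query->detection maps,
# used as the oracle against map_agreement (different algorithm: filters the
# full tuple grid for injectivity).
oracle_assignment_scores <- function(query, det, model) {
  nq <- nrow(query$objects); nd <- nrow(det$boxes)
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(nd)), nq)))
  keep <- apply(grid, 1L, function(r) length(unique(r)) == nq)
  grid <- grid[keep, , drop = FALSE]
  cls <- detected_classes(det)
  scores <- apply(grid, 1L, function(assign) {
    s <- 1
    for (q in seq_len(nq)) s <- s * det$posteriors[assign[q], query$objects$name[q]]
    for (k in seq_len(nrow(query$relations))) {
      row <- prior_row(model$prior, cls[assign[query$relations$subject_idx[k]]],
                       cls[assign[query$relations$object_idx[k]]])
      s <- s * row[[query$relations$predicate[k]]]
    }
    s
  })
  list(grid = grid, scores = scores)
}

# Independent maximum one-to-one box matching by exhaustive assignment
# enumeration (oracle for the greedy matcher inside eval_s1/eval_s2).
oracle_max_matching <- function(pred, truth, iou_min = 0.5,
                                pred_class = NULL, truth_class = NULL) {
  np <- nrow(pred); nt <- nrow(truth)
  iou <- matrix(0, np, nt)
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    ok <- is.null(pred_class) || pred_class[i] == truth_class[j]
    v <- box_iou(pred[i, ], truth[j, ])
    iou[i, j] <- if (ok && v >= iou_min) v else -1
  }
  best <- 0L
  k <- min(np, nt)
  if (k == 0L) return(0L)
  perm_rec <- function(rows, cols, count) {
    best <<- max(best, count)
    if (length(rows) == 0L || length(cols) == 0L) return()
    r <- rows[1]
    perm_rec(rows[-1], cols, count)  # leave r unmatched
    for (cc in cols) if (iou[r, cc] >= 0) perm_rec(rows[-1], setdiff(cols, cc), count + 1L)
  }
  perm_rec(seq_len(np), seq_len(nt), 0L)
  best
}
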