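test_that("box_success implements the strict majority rule", {
  r <- box_success(3, 6)
  expect_equal(r$fraction, 0.5)
  expect_false(r$success)                      # 3 of 6 is exactly 0.5: failed
  expect_true(box_success(4, 6)$success)       # the published threshold of 4
  expect_equal(box_success(6, 6)$fraction, 1)
  expect_true(box_success(6, 6)$success)
  # smallest succeeding count at total = 6 is 4
  first <- min(which(purrr::map_lgl(0:6, ~ box_success(.x, 6)$success))) - 1L
  expect_equal(first, 4L)
  # monotone: success at (d, t) implies success at (d + 1, t)
  for (t in 1:8) for (d in 0:(t - 1)) {
    if (box_success(d, t)$success) expect_true(box_success(d + 1, t)$success)
  }
  expect_error(box_success(7, 6), "detected")
  expect_error(box_success(1, 0), "total")
})

test_that("the predicate decision boundary is strictly 0.5", {
  expect_equal(predicate_verdict(0.6), 1L)
  expect_equal(predicate_verdict(0.5), 0L)
  expect_equal(predicate_verdict(0.0), 0L)
  expect_equal(predicate_verdict(1.0), 1L)
  expect_error(predicate_verdict(-0.1), "outside")
  expect_error(predicate_verdict(1.1), "outside")
})

test_that("S1 is perfect for oracle predictions and zero for empty ones", {
  ds <- fixture_dataset("bee", 6)
  oracle <- purrr::map(ds$annotation, annotation_to_scene_graph)
  s1 <- eval_s1(oracle, ds$annotation)
  expect_equal(s1$accuracy, 1)
  expect_equal(s1$object_recall, 1)
  empty <- purrr::map(ds$annotation, ~ scene_graph(image_id = .x$image_id))
  expect_equal(eval_s1(empty, ds$annotation)$accuracy, 0)
  expect_error(eval_s1(oracle[1:3], ds$annotation), "mismatch")
})

test_that("greedy matching equals the exhaustive one-to-one oracle on small cases", {
  set.seed(11)
  for (rep in 1:12) {
    nt <- sample(2:5, 1); np <- sample(2:5, 1)
    truth <- tibble::tibble(x = sample(0:40, nt), y = sample(0:40, nt),
                            w = sample(8:14, nt, replace = TRUE),
                            h = sample(8:14, nt, replace = TRUE))
    # predictions: jittered copies plus possible clutter
    pred <- truth[sample(nt, np, replace = TRUE), ] %>%
      dplyr::mutate(x = x + sample(-3:3, np, replace = TRUE),
                    y = y + sample(-3:3, np, replace = TRUE))
    cls_t <- sample(c("bee", "access"), nt, replace = TRUE)
    cls_p <- sample(c("bee", "access"), np, replace = TRUE)
    m <- nestsgg:::match_boxes(pred, truth, pred_class = cls_p, truth_class = cls_t)
    best <- oracle_max_matching(pred, truth, pred_class = cls_p, truth_class = cls_t)
    expect_equal(nrow(m), best)
    # one-to-one: no double counting on either side
    expect_false(anyDuplicated(m$pred_idx) > 0)
    expect_false(anyDuplicated(m$truth_idx) > 0)
  }
})

test_that("S2 applies the box-success rule per image", {
  ds <- fixture_dataset("bee", 6)
  oracle <- purrr::map(ds$annotation, annotation_to_scene_graph)
  s2 <- eval_s2(oracle, ds$annotation)
  expect_equal(s2$accuracy, 1)
  # an image with 6 truth boxes and only 3 recovered counts as failed
  ann6 <- render_scene("big_population", "bee", per_image_seed = 21, n_objects = 6)$annotation
  partial <- scene_graph(ann6$objects[1:3, c("name", "synset", "x", "y", "w", "h")])
  s2p <- eval_s2(list(partial), list(ann6))
  expect_equal(s2p$verdicts$detected, 3L)
  expect_equal(s2p$verdicts$total, 6L)
  expect_false(s2p$verdicts$correct)
  expect_equal(s2p$accuracy, 0)
})

test_that("S3 is gated on S1 and S2 and divides by recognized images only", {
  ds <- fixture_dataset("bee", 6)
  oracle <- purrr::map(ds$annotation, annotation_to_scene_graph)
  s1 <- eval_s1(oracle, ds$annotation)
  s2 <- eval_s2(oracle, ds$annotation)
  s3 <- eval_s3(oracle, ds$annotation, s1, s2)
  expect_equal(s3$accuracy, 1)
  expect_equal(s3$n_recognized, 6L)
  # all S1^S2 false -> not applicable
  empty <- purrr::map(ds$annotation, ~ scene_graph(image_id = .x$image_id))
  s1e <- eval_s1(empty, ds$annotation); s2e <- eval_s2(empty, ds$annotation)
  s3e <- eval_s3(empty, ds$annotation, s1e, s2e)
  expect_true(is.na(s3e$accuracy))
  expect_equal(s3e$n_recognized, 0L)
  # mixed: denominator is the count of recognized images, not N
  mixed <- oracle
  mixed[[2]] <- scene_graph(image_id = ds$annotation[[2]]$image_id)
  s1m <- eval_s1(mixed, ds$annotation); s2m <- eval_s2(mixed, ds$annotation)
  s3m <- eval_s3(mixed, ds$annotation, s1m, s2m)
  expect_equal(s3m$n_recognized, 5L)
  expect_equal(s3m$accuracy, 1)  # 5 correct / 5 recognized
})

test_that("accuracies are invariant to image ordering", {
  ds <- fixture_dataset("bee", 6)
  oracle <- purrr::map(ds$annotation, annotation_to_scene_graph)
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(eval_s1(oracle[perm], ds$annotation[perm])$accuracy,
               eval_s1(oracle, ds$annotation)$accuracy)
  expect_equal(eval_s2(oracle[perm], ds$annotation[perm])$accuracy,
               eval_s2(oracle, ds$annotation)$accuracy)
})

test_that("the accuracy curve is flat at 1.0 for the oracle and has one row per dataset", {
  sizes <- seq(6L, 20L, by = 1L)   # fifteen datasets, smallest first
  rep <- accuracy_curve(oracle_predictor(), "bee", sizes = sizes, seed = 1)
  expect_equal(nrow(rep), 15L)
  expect_equal(rep$s1, rep(1, 15))
  expect_equal(rep$s2, rep(1, 15))
  expect_equal(rep$s3, rep(1, 15))
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})

test_that("label noise degrades accuracy monotonically", {
  ds <- fixture_dataset("bee", 10)
  vocab <- load_vocabulary("bee")
  oracle <- purrr::map(ds$annotation, annotation_to_scene_graph)
  accs <- purrr::map_dbl(c(0, 0.25, 0.5, 0.9), function(eps) {
    noisy <- corrupt_labels(ds$annotation, eps, vocab, seed = 4)
    eval_s1(oracle, noisy)$accuracy
  })
  expect_equal(accs[1], 1)
  expect_true(all(diff(accs) <= 1e-12))
  expect_lt(accs[4], accs[1])
})

test_that("tidiers expose fits and verdicts as tibbles", {
  clf <- fixture_classifier("bee")
  expect_s3_class(tidy(clf), "tbl_df")
  g <- glance(clf)
  expect_equal(g$train_accuracy, 1)
  model <- fixture_model("bee")
  expect_equal(nrow(tidy(model)), 30L)
  expect_s3_class(glance(model), "tbl_df")
  ds <- fixture_dataset("bee", 6)
  oracle <- purrr::map(ds$annotation, annotation_to_scene_graph)
  s1 <- eval_s1(oracle, ds$annotation)
  expect_equal(nrow(tidy(s1)), 6L)
  expect_equal(glance(s1)$accuracy, 1)
})
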