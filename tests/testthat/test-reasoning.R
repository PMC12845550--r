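test_that("phrase detection emits the greeting triplet with a union box", {
  det <- fixture_detections("greeting", "bee")
  model <- fixture_model("bee")
  ph <- detect_phrases(det, model)
  expect_true("bee greeting bee" %in% ph$label)
  top <- ph[ph$label == "bee greeting bee", ][1, ]
  expect_gt(top$score, 0.5)
  # union box is the hull of the pair
  h <- box_hull(det$boxes[top$i, ], det$boxes[top$j, ])
  expect_equal(top$x, h$x); expect_equal(top$w, h$w)
  # sorted by score descending, ties by (i, j)
  expect_false(is.unsorted(rev(ph$score)))
  # deterministic
  expect_identical(ph, detect_phrases(det, model))
})

test_that("the interaction decision is strictly greater than the threshold", {
  det <- fixture_detections("greeting", "bee")
  model <- fixture_model("bee")
  ph <- detect_phrases(det, model)
  # raising the threshold to exactly the top score excludes that phrase
  ph2 <- detect_phrases(det, model, threshold = max(ph$score))
  expect_false(max(ph$score) %in% ph2$score)
  # single detection: no pairs at all
  single <- structure(list(
    boxes = det$boxes[1, ], features = det$features[1, , drop = FALSE],
    posteriors = det$posteriors[1, , drop = FALSE], classes = det$classes,
    image = det$image), class = "detections")
  expect_equal(nrow(detect_phrases(single, model)), 0L)
  expect_equal(nrow(classify_predicates(single, model)), 0L)
})

test_that("predicate classification skips i = j and ties break by vocabulary order", {
  det <- fixture_detections("carrying_food", "bee")
  model <- fixture_model("bee")
  pairs <- classify_predicates(det, model)
  expect_false(any(pairs$i == pairs$j))
  expect_equal(nrow(pairs), nrow(det$boxes) * (nrow(det$boxes) - 1L))
  expect_true(all(pairs$predicate %in% model$relations))
  # the ground-truth carrying pair decodes as carrying
  ann <- fixture_scene("carrying_food", "bee")$annotation
  hl <- ann$headline
  si <- which(det$boxes$x == ann$objects$x[hl$subject_idx])[1]
  oi <- which(det$boxes$x == ann$objects$x[hl$object_idx])[1]
  row <- pairs[pairs$i == si & pairs$j == oi, ]
  expect_true(row$interacts)
  expect_identical(row$predicate, "carrying")
})

test_that("scene-graph classification recovers the ground truth on noiseless scenes", {
  model <- fixture_model("bee")
  blank <- structure(list(image_id = 99L, pixels = array(0.9, c(64, 64, 3)),
                          species = "bee", seed = 0L), class = "scene_image")
  empty <- classify_scene_graph(detect_objects(blank, model$classifier), model)
  expect_equal(nrow(empty$objects), 0L)
  for (b in c("greeting", "intruder", "big_population")) {
    sc <- fixture_scene(b, "bee")
    det <- detect_objects(sc$image, model$classifier)
    sg <- classify_scene_graph(det, model, image_id = sc$annotation$image_id)
    gt <- sc$annotation$objects
    expect_equal(nrow(sg$objects), nrow(gt))
    for (k in seq_len(nrow(gt))) {
      ious <- purrr::map_dbl(seq_len(nrow(sg$objects)), ~ box_iou(sg$objects[.x, ], gt[k, ]))
      best <- which.max(ious)
      expect_gte(ious[best], 0.9)
      expect_identical(sg$objects$name[best], gt$name[k])
    }
    # the behavior-defining triplet is present with probability above 0.5
    hl <- sc$annotation$headline
    si <- which(sg$objects$x == gt$x[hl$subject_idx] & sg$objects$y == gt$y[hl$subject_idx])
    oi <- which(sg$objects$x == gt$x[hl$object_idx] & sg$objects$y == gt$y[hl$object_idx])
    hit <- sg$relations[sg$relations$subject_idx == si &
                          sg$relations$object_idx == oi &
                          sg$relations$predicate == hl$predicate, ]
    expect_equal(nrow(hit), 1L)
    expect_gt(hit$prob, 0.5)
    expect_lte(nrow(sg$relations), nrow(sg$objects)^2)
  }
})

test_that("MAP agreement equals exhaustive enumeration on small queries", {
  model <- fixture_model("bee")
  det <- fixture_detections("grouping", "bee")
  ann <- fixture_scene("grouping", "bee")$annotation
  # empty query scores 1 by convention
  expect_equal(map_agreement(scene_graph(), det, model)$value, 1)
  # single query object, single detection: normalization forces 1
  single <- structure(list(
    boxes = det$boxes[1, ], features = det$features[1, , drop = FALSE],
    posteriors = det$posteriors[1, , drop = FALSE], classes = det$classes,
    image = det$image), class = "detections")
  q1 <- scene_graph(tibble::tibble(name = "access", synset = "access.n.01",
                                   x = 0L, y = 0L, w = 10L, h = 10L))
  expect_equal(map_agreement(q1, single, model)$value, 1)
  # 2x2 and up to 4 query objects: compare against the independent oracle
  for (nq in 2:4) {
    qobj <- ann$objects[seq_len(nq), c("name", "synset", "x", "y", "w", "h")]
    qrel <- ann$relationships[ann$relationships$subject_idx <= nq &
                                ann$relationships$object_idx <= nq, , drop = FALSE]
    query <- scene_graph(qobj, if (nrow(qrel)) qrel else NULL)
    got <- map_agreement(query, det, model)
    orc <- oracle_assignment_scores(query, det, model)
    expect_equal(got$value, max(orc$scores) / sum(orc$scores), tolerance = 1e-12)
    # the returned assignment attains the maximum score (ties between
    # look-alike detections are legitimate)
    hit <- which(apply(orc$grid, 1L, function(r) all(r == got$assignment)))
    expect_equal(orc$scores[hit], max(orc$scores), tolerance = 1e-12)
  }
  expect_error(map_agreement(annotation_to_scene_graph(ann), single, model),
               "more query objects")
})

test_that("question answering follows the rule table over the closed vocabulary", {
  # empty graph: always unknown
  expect_identical(answer_question(scene_graph(), "Who is there?", "who"), "unknown")
  closed <- c("Intruder", "Bee", "Ant", "Big population", "Low population", "Free",
              "Greeting", "Grouping", "Crowding", "Accessing", "Carrying",
              "Approaching", "Carrying pollen", "Carrying food",
              "Type of bee", "Type of ant",
              "Bee Greeting", "Ant Greeting", "Bees Grouping", "Ants Grouping",
              "Carrying Pollen", "Carrying Food", "Intruder Detected",
              "Big Population", "Type of Bee", "Type of Ant",
              "At the beehive entrance", "At the anthill entrance", "unknown")
  for (sp in c("bee", "ant")) {
    ds <- fixture_dataset(sp, 8)
    for (i in seq_len(nrow(ds))) {
      ann <- ds$annotation[[i]]
      sg <- annotation_to_scene_graph(ann)
      for (k in seq_len(nrow(ann$qa))) {
        got <- answer_question(sg, ann$qa$question[k], ann$qa$qtype[k])
        expect_true(got %in% closed)
        # ground-truth graphs reproduce the generator's own answers
        expect_identical(got, ann$qa$answer[k])
      }
    }
  }
})

test_that("typed answers are graph-driven: who, how, why, where", {
  ann_i <- fixture_scene("intruder", "bee")$annotation
  sg_i <- annotation_to_scene_graph(ann_i)
  expect_identical(answer_question(sg_i, "Who is at the entrance of the hive?", "who"),
                   "Intruder")
  ann_b <- fixture_scene("big_population", "bee")$annotation
  sg_b <- annotation_to_scene_graph(ann_b)
  expect_identical(answer_question(sg_b, "How is the access to the beehive?", "how"),
                   "Big population")
  ann_c <- fixture_scene("carrying_food", "bee")$annotation
  sg_c <- annotation_to_scene_graph(ann_c)
  expect_identical(answer_question(sg_c, "Why are the bees working?", "why"),
                   "Carrying pollen")
  expect_identical(answer_question(sg_c, "Where is the bee?", "where"),
                   "At the beehive entrance")
  expect_identical(answer_question(sg_c, "When was this?", "when"), "unknown")
})
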