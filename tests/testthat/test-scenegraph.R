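test_that("a region graph links objects, attributes and relations", {
  sc <- fixture_scene("greeting", "bee")
  ann <- sc$annotation
  rg <- build_region_graph(ann$regions[1, ], ann$objects, ann$relationships,
                           image_id = ann$image_id)
  expect_equal(nrow(rg$objects), 2L)      # the two greeting bees
  expect_equal(nrow(rg$relations), 1L)
  expect_identical(rg$relations$predicate, "greeting")
  expect_gt(nrow(rg$attributes), 0L)      # bees carry Color/State/Position
  # single-object region -> single-node graph
  rg3 <- build_region_graph(ann$regions[3, ], ann$objects, ann$relationships)
  expect_equal(nrow(rg3$objects), 1L)
  expect_equal(nrow(rg3$relations), 0L)
  # dangling reference errors
  bad <- ann$regions[1, ]
  bad$object_ids <- list(99L)
  expect_error(build_region_graph(bad, ann$objects, ann$relationships), "missing object")
})

test_that("merging no regions gives the empty scene graph", {
  sg <- merge_region_graphs(list())
  expect_equal(scene_graph_summary(sg), tibble::tibble(n_objects = 0L, n_relations = 0L, n_edges = 0L))
})

test_that("merge equals brute-force union with dedup and is order invariant", {
  for (b in c("greeting", "big_population", "carrying_food")) {
    ann <- fixture_scene(b, "bee")$annotation
    rgs <- annotation_to_region_graphs(ann)
    sg <- merge_region_graphs(rgs)
    # oracle: unique canonical identities across all regions
    all_nodes <- dplyr::bind_rows(purrr::map(rgs, "objects"))
    key <- paste(all_nodes$synset, all_nodes$x, all_nodes$y, all_nodes$w, all_nodes$h)
    expect_equal(nrow(sg$objects), length(unique(key)))
    expect_setequal(paste(sg$objects$synset, sg$objects$x, sg$objects$y,
                          sg$objects$w, sg$objects$h), unique(key))
    # oracle for edges: unique triplets over global identities
    glob <- purrr::map(rgs, function(rg) {
      if (nrow(rg$relations) == 0L) return(NULL)
      k <- paste(rg$objects$synset, rg$objects$x, rg$objects$y, rg$objects$w, rg$objects$h)
      tibble::tibble(s = k[rg$relations$subject_idx], p = rg$relations$predicate,
                     o = k[rg$relations$object_idx])
    }) %>% dplyr::bind_rows() %>% dplyr::distinct()
    mkey <- paste(sg$objects$synset, sg$objects$x, sg$objects$y, sg$objects$w, sg$objects$h)
    got <- tibble::tibble(s = mkey[sg$relations$subject_idx], p = sg$relations$predicate,
                          o = mkey[sg$relations$object_idx])
    expect_setequal(paste(got$s, got$p, got$o), paste(glob$s, glob$p, glob$o))
    # order invariance and idempotence
    sg_rev <- merge_region_graphs(rev(rgs))
    expect_equal(sg$objects, sg_rev$objects)
    expect_equal(sg$relations, sg_rev$relations)
    sg_twice <- merge_region_graphs(c(rgs, rgs))
    expect_equal(sg$objects, sg_twice$objects)
    expect_equal(sg$relations, sg_twice$relations)
    # monotone: every region node appears in the merge
    expect_true(all(key %in% mkey))
    # provenance covers every contributing region
    shared <- which(purrr::map_int(sg$objects$provenance, length) > 1L)
    expect_gt(length(shared), 0L)  # the full-frame region shares all objects
  }
})

test_that("two regions sharing an instance merge to exactly one node for it", {
  ann <- toy_annotation()
  r1 <- ann$regions[1, ]
  r2 <- dplyr::mutate(r1, region_id = 2L, phrase = "Bees Together", object_ids = list(2:1))
  rgs <- list(build_region_graph(r1, ann$objects, ann$relationships, 1L),
              build_region_graph(r2, ann$objects, ann$relationships, 1L))
  sg <- merge_region_graphs(rgs)
  expect_equal(nrow(sg$objects), 2L)
  expect_equal(nrow(sg$relations), 1L)
  expect_equal(sort(sg$objects$provenance[[1]]), c(1L, 2L))
})

test_that("cross-image merges are refused", {
  ann <- toy_annotation()
  rg1 <- build_region_graph(ann$regions[1, ], ann$objects, ann$relationships, image_id = 1L)
  rg2 <- build_region_graph(ann$regions[1, ], ann$objects, ann$relationships, image_id = 2L)
  expect_error(merge_region_graphs(list(rg1, rg2)), "different images")
})

test_that("the n x n edge bound holds on every constructed graph", {
  ds <- fixture_dataset("bee", 8)
  for (ann in ds$annotation) {
    sg <- annotation_to_scene_graph(ann)
    s <- scene_graph_summary(sg)
    expect_lte(s$n_edges, s$n_objects^2)
    expect_equal(s$n_objects, nrow(ann$objects))  # full-frame region covers all
  }
  expect_error(scene_graph(toy_annotation()$objects,
                           tibble::tibble(subject_idx = 1L, predicate = "greeting",
                                          object_idx = 1L)),
               "self-relation")
})

test_that("near-duplicate fusion at IoU 0.9 is available but off by default", {
  objects <- tibble::tibble(
    object_id = 1:2, name = "bee", synset = "bee.n.03",
    x = c(10L, 10L), y = c(10L, 10L), w = c(20L, 21L), h = c(20L, 20L),
    attributes = list(character(), character()))
  reg <- tibble::tibble(region_id = 1:2, x = 0L, y = 0L, w = 64L, h = 64L,
                        phrase = c("Bee One", "Bee Two"),
                        object_ids = list(1L, 2L))
  rgs <- purrr::map(1:2, ~ build_region_graph(reg[.x, ], objects, NULL, 1L))
  expect_equal(nrow(merge_region_graphs(rgs)$objects), 2L)
  expect_equal(nrow(merge_region_graphs(rgs, iou_fuse = 0.9)$objects), 1L)
})

test_that("attribute conflicts keep both values and warn", {
  objects <- tibble::tibble(
    object_id = 1L, name = "bee", synset = "bee.n.03",
    x = 10L, y = 10L, w = 20L, h = 20L,
    attributes = list(c(Color = "Yellow")))
  objects2 <- dplyr::mutate(objects, attributes = list(c(Color = "Black")))
  reg <- tibble::tibble(region_id = 1L, x = 0L, y = 0L, w = 64L, h = 64L,
                        phrase = "A Bee", object_ids = list(1L))
  rgs <- list(build_region_graph(reg, objects, NULL, 1L),
              build_region_graph(dplyr::mutate(reg, region_id = 2L), objects2, NULL, 1L))
  expect_warning(sg <- merge_region_graphs(rgs), "attribute conflict")
  a <- sg$objects$attributes[[1]]
  expect_setequal(unname(a[names(a) == "Color"]), c("Yellow", "Black"))
})

test_that("DOT export wraps the graph under a presentation Root", {
  sg <- annotation_to_scene_graph(toy_annotation())
  dot <- sg_to_dot(sg)
  expect_match(dot, "digraph scene")
  expect_match(dot, "Root")
  expect_match(dot, "greeting")
})
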