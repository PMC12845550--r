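test_that("the prior reduces to counting: degenerate and smoothed cases", {
  v <- load_vocabulary("bee")
  ann <- toy_annotation()
  p0 <- fit_prior(list(ann), v, alpha = 0)
  expect_equal(unname(prior_row(p0, "bee", "bee")["greeting"]), 1)
  p1 <- fit_prior(list(ann), v, alpha = 1)
  expect_equal(unname(prior_row(p1, "intruder", "access")), rep(1 / 15, 15))  # unseen pair
  expect_equal(sum(prior_row(p1, "bee", "bee")), 1)
})

test_that("the prior matches brute-force tallying on a generated corpus", {
  ds <- fixture_dataset("bee", 8)
  v <- load_vocabulary("bee")
  pr <- fit_prior(ds, v, alpha = 1)
  # independent tally with base-R table over flattened triplets
  trip <- purrr::map(ds$annotation, function(ann) {
    r <- ann$relationships
    tibble::tibble(ci = ann$objects$name[r$subject_idx], p = r$predicate,
                   cj = ann$objects$name[r$object_idx])
  }) %>% dplyr::bind_rows()
  for (key in unique(paste(trip$ci, trip$cj))) {
    parts <- strsplit(key, " ")[[1]]
    sub <- trip[trip$ci == parts[1] & trip$cj == parts[2], ]
    n_pair <- nrow(sub)
    for (p in unique(sub$p)) {
      expected <- (sum(sub$p == p) + 1) / (n_pair + 15)
      expect_equal(unname(prior_row(pr, parts[1], parts[2])[p]), expected)
    }
  }
  # prior rows always sum to 1
  for (ci in c("bee", "access")) for (cj in c("bee", "pollen")) {
    expect_equal(sum(prior_row(pr, ci, cj)), 1, tolerance = 1e-12)
  }
})

test_that("smoothing is monotone: larger alpha moves rows toward uniform", {
  ds <- fixture_dataset("bee", 8)
  v <- load_vocabulary("bee")
  kl_unif <- function(p) sum(p * log(p * length(p)))
  kls <- purrr::map_dbl(c(0.5, 1, 2, 5, 20), function(a) {
    kl_unif(prior_row(fit_prior(ds, v, alpha = a), "bee", "bee"))
  })
  expect_true(all(diff(kls) <= 1e-12))
})

test_that("class-branch logits are log prior rows, marginalized over posteriors", {
  ds <- fixture_dataset("bee", 8)
  v <- load_vocabulary("bee")
  pr <- fit_prior(ds, v)
  expect_equal(predict_from_classes("bee", "bee", pr),
               unname(log(prior_row(pr, "bee", "bee"))))
  # uniform posteriors -> log of the plain average of all rows
  u <- rep(1 / 15, 15)
  avg <- rep(0, 15)
  for (a in v$objects$name) for (b in v$objects$name) {
    avg <- avg + prior_row(pr, a, b) / 225
  }
  expect_equal(predict_from_classes(u, u, pr), unname(log(avg)), tolerance = 1e-12)
  expect_error(predict_from_classes(numeric(), "bee", pr), "empty posterior")
  # ordered pairs require i != j at the pair level
  det <- fixture_detections("greeting", "bee")
  model <- fixture_model("bee")
  expect_error(pair_predicate_distribution(det, 1, 1, model), "i != j")
})

test_that("feature-branch logits equal the direct matrix product and are direction sensitive", {
  model <- fixture_model("bee")
  set.seed(3)
  xi <- runif(91); xj <- runif(91)
  got <- predict_from_features(xi, xj, model)
  vs <- (c(xi, xj) - model$mu_f) / model$sd_f
  expect_equal(got, as.numeric(model$W_f %*% vs + model$b_f), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(got, predict_from_features(xj, xi, model))))
  # zero weights give zero logits (uniform after softmax)
  zero <- list(W_f = matrix(0, 15, 182), b_f = rep(0, 15),
               mu_f = rep(0, 182), sd_f = rep(1, 182))
  expect_equal(predict_from_features(xi, xj, zero), rep(0, 15))
  expect_error(predict_from_features(xi[1:10], xj, model), "length")
})

test_that("the visual context is the descriptor of the joint-region hull", {
  sc <- fixture_scene("greeting", "bee")
  b1 <- sc$annotation$objects[2, ]
  b2 <- sc$annotation$objects[3, ]
  # identical boxes: the joint region is the box itself
  expect_equal(visual_context(sc$image, b1, b1), extract_features(sc$image, b1))
  # disjoint boxes: tight hull from corner coordinates
  h <- box_hull(b1, b2)
  expect_equal(h$x, min(b1$x, b2$x))
  expect_equal(h$y, min(b1$y, b2$y))
  expect_equal(h$x + h$w, max(b1$x + b1$w, b2$x + b2$w))
  expect_equal(h$y + h$h, max(b1$y + b1$h, b2$y + b2$h))
  expect_equal(visual_context(sc$image, b1, b2), extract_features(sc$image, h))
})

test_that("fusion is the softmax of summed logits, symmetric, and reduces per branch", {
  z <- rep(0, 15)
  expect_equal(fuse_branches(z, z, z), rep(1 / 15, 15))
  set.seed(8)
  a <- rnorm(15); b <- rnorm(15); cc <- rnorm(15)
  s <- exp(a + b + cc - max(a + b + cc)); s <- s / sum(s)
  expect_equal(fuse_branches(a, b, cc), s, tolerance = 1e-12)
  expect_equal(fuse_branches(a, b, cc), fuse_branches(cc, a, b))
  expect_equal(fuse_branches(a, z, z), exp(a - max(a)) / sum(exp(a - max(a))))
  expect_equal(sum(fuse_branches(a, b, cc)), 1, tolerance = 1e-9)
  expect_error(fuse_branches(a, b[1:3], cc), "mismatched")
})

test_that("the training loss has its closed forms and matches recomputation", {
  # perfect one-hot predictions -> 0
  P1 <- diag(3)[c(1, 2), ]
  expect_equal(training_loss(P1, P1, list(P1, P1, P1), c(1, 2), c(1, 2)), 0)
  # uniform predictions over C classes -> ln C per term
  C <- 15
  U <- matrix(1 / C, 2, C)
  expect_equal(training_loss(U, U, list(U, U, U), c(1, 5), c(2, 3)), 5 * log(C))
  # random case equals -sum(log p_true) by direct recomputation
  set.seed(4)
  P <- matrix(runif(4 * C), 4, C); P <- P / rowSums(P)
  y <- sample(C, 4, replace = TRUE)
  manual <- function(M) -mean(log(M[cbind(1:4, y)]))
  got <- training_loss(P, P, list(P, P, P), y, y)
  expect_equal(got, 5 * manual(P), tolerance = 1e-12)
  expect_gte(got, 0)
  expect_error(training_loss(P, P, list(P, P, P), y[1:2], y), "shape mismatch")
})

test_that("message passing: identity at K = 0, locality for isolated nodes", {
  model <- fixture_model("bee")
  sg <- scene_graph(
    tibble::tibble(name = c("bee", "bee", "pollen"), synset = "bee.n.03",
                   x = c(0L, 30L, 60L), y = 0L, w = 10L, h = 10L),
    tibble::tibble(subject_idx = 1L, predicate = "greeting", object_idx = 2L))
  set.seed(2)
  H0 <- matrix(rnorm(3 * 8), 3, 8)
  gp <- gnn_params(8, seed = 3, rounds = 3)
  expect_identical(gnn_embed(sg, H0, gp, K = 0), H0)
  H1 <- gnn_embed(sg, H0, gp, K = 1)
  # node 3 is isolated: one round equals the transition on its own feature
  expect_equal(H1[3, ], as.numeric(tanh(gp$W_self %*% H0[3, ] + gp$b)), tolerance = 1e-12)
  # connected nodes differ from their isolated transition
  expect_false(isTRUE(all.equal(H1[1, ], as.numeric(tanh(gp$W_self %*% H0[1, ] + gp$b)))))
})

test_that("message passing is permutation equivariant and respects automorphisms", {
  gp <- gnn_params(6, seed = 5, rounds = 2)
  set.seed(6)
  for (rep in 1:5) {
    n <- sample(3:5, 1)
    edges <- expand.grid(s = 1:n, o = 1:n)
    edges <- edges[edges$s < edges$o & runif(nrow(edges)) < 0.5, , drop = FALSE]
    obj <- tibble::tibble(name = "bee", synset = "bee.n.03",
                          x = as.integer(20 * (1:n)), y = 0L, w = 10L, h = 10L)
    rel <- if (nrow(edges) == 0L) NULL else
      tibble::tibble(subject_idx = edges$s, predicate = "greeting", object_idx = edges$o)
    sg <- scene_graph(obj, rel)
    H0 <- matrix(rnorm(n * 6), n, 6)
    H <- gnn_embed(sg, H0, gp, K = 2)
    perm <- sample(n)
    inv <- order(perm)
    obj_p <- obj[perm, ]
    obj_p$x <- obj$x  # keep canonical identities distinct
    rel_p <- if (is.null(rel)) NULL else
      dplyr::mutate(rel, subject_idx = inv[subject_idx], object_idx = inv[object_idx])
    sg_p <- scene_graph(obj_p, rel_p)
    H_p <- gnn_embed(sg_p, H0[perm, , drop = FALSE], gp, K = 2)
    expect_equal(H_p, H[perm, , drop = FALSE], tolerance = 1e-12)
  }
  # automorphism: a 4-cycle with equal features embeds all nodes equally
  cyc <- tibble::tibble(subject_idx = 1:4, predicate = "greeting",
                        object_idx = c(2L, 3L, 4L, 1L))
  obj <- tibble::tibble(name = "bee", synset = "bee.n.03",
                        x = as.integer(20 * (1:4)), y = 0L, w = 10L, h = 10L)
  sg <- scene_graph(obj, cyc)
  H0 <- matrix(rep(seq_len(6), each = 4), 4, 6)
  H <- gnn_embed(sg, H0, gnn_params(6, seed = 7), K = 3)
  for (r in 2:4) expect_equal(H[r, ], H[1, ], tolerance = 1e-12)
})

test_that("training is seeded-deterministic with a non-increasing loss", {
  ds <- fixture_dataset("bee", 8)
  clf <- fixture_classifier("bee")
  m1 <- train_sgg(ds, clf, epochs = 60, seed = 2)
  m2 <- train_sgg(ds, clf, epochs = 60, seed = 2)
  expect_identical(m1$W_f, m2$W_f)
  expect_identical(m1$W_c, m2$W_c)
  expect_identical(m1$history, m2$history)
  expect_true(all(diff(m1$history) <= 1e-8))
  expect_error(train_sgg(generate_dataset(scene_config("bee", n_images = 2, seed = 1,
                                                       behaviors = c(greeting = 1))),
                         clf, epochs = 5),
               "degenerate dataset")
})

test_that("the trained model beats the prior-only baseline on its training predicates", {
  ds <- fixture_dataset("bee", 24)
  model <- fixture_model("bee")
  clf <- fixture_classifier("bee")
  correct_fused <- 0L; correct_prior <- 0L; n <- 0L
  for (i in seq_len(nrow(ds))) {
    ann <- ds$annotation[[i]]
    det <- detect_objects(ds$image[[i]], clf)
    m <- nrow(det$boxes)
    for (k in seq_len(nrow(ann$relationships))) {
      s <- ann$relationships$subject_idx[k]; o <- ann$relationships$object_idx[k]
      # detections align with ground truth on noiseless scenes via box identity
      si <- which(det$boxes$x == ann$objects$x[s] & det$boxes$y == ann$objects$y[s])[1]
      oi <- which(det$boxes$x == ann$objects$x[o] & det$boxes$y == ann$objects$y[o])[1]
      if (is.na(si) || is.na(oi)) next
      fused <- pair_predicate_distribution(det, si, oi, model)
      prior_only <- prior_row(model$prior, ann$objects$name[s], ann$objects$name[o])
      truth <- ann$relationships$predicate[k]
      correct_fused <- correct_fused + (names(which.max(fused)) == truth)
      correct_prior <- correct_prior + (names(which.max(prior_only)) == truth)
      n <- n + 1L
    }
  }
  expect_gt(correct_fused / n, correct_prior / n)
  expect_gt(correct_fused / n, 0.95)
})
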