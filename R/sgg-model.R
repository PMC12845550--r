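# The predicate-inference model: three branches per ordered object pair
# (i, j), i != j —
#   class branch:   log P(predicate | subject class, object class) from a
#                   smoothed co-occurrence prior (marginalized over soft
#                   class posteriors when supplied);
#   feature branch: linear map on the concatenated pair descriptors [x_i, x_j];
#   context branch: linear map on the descriptor of the joint-region crop
#                   hull(b_i, b_j) — the stand-in for Convs(RoIAlign(...)).
# A fusion function combines the three branch logit vectors additively and
# maps them through the logistic link (softmax in the multiclass case), and
# auxiliary per-branch cross-entropies keep any single branch from dominating
# the fused logits. A message-passing graph network (transition function F =
# affine map + tanh, sum aggregation, applied identically at every node)
# provides structural node embeddings over scene graphs.

#' Fit the predicate co-occurrence prior
#'
#' Smoothed conditional distribution over the 15 relation types given the
#' (subject class, object class) pair:
#' `P(r | ci, cj) = (count(ci, r, cj) + alpha) / (count(ci, ., cj) + alpha * |C_rel|)`.
#' With `alpha = 1` an unseen pair yields the uniform distribution.
#'
#' @param annotations List of `image_annotation`s (or a `scene_dataset`).
#' @param vocab The species vocabulary.
#' @param alpha Additive smoothing count (default 1).
#' @return An object of class `predicate_prior`.
#' @export
fit_prior <- function(annotations, vocab, alpha = 1) {
  if (inherits(annotations, "scene_dataset")) annotations <- annotations$annotation
  if (length(annotations) == 0L) abort("empty corpus")
  cls <- vocab$objects$name
  rel <- vocab$relations
  counts <- array(0, dim = c(length(cls), length(cls), length(rel)),
                  dimnames = list(cls, cls, rel))
  for (ann in annotations) {
    r <- ann$relationships
    for (k in seq_len(nrow(r))) {
      ci <- ann$objects$name[r$subject_idx[k]]
      cj <- ann$objects$name[r$object_idx[k]]
      counts[ci, cj, r$predicate[k]] <- counts[ci, cj, r$predicate[k]] + 1
    }
  }
  structure(list(counts = counts, alpha = alpha, classes = cls, relations = rel),
            class = "predicate_prior")
}

#' @export
print.predicate_prior <- function(x, ...) {
  cat(sprintf("<predicate_prior> %d classes x %d relations, alpha=%g, %d observed triplets\n",
              length(x$classes), length(x$relations), x$alpha, sum(x$counts)))
  invisible(x)
}

#' Conditional predicate distribution for a hard class pair
#'
#' @param prior A `predicate_prior`.
#' @param ci,cj Subject and object class names.
#' @return Probability vector over the relation types (sums to 1).
#' @export
prior_row <- function(prior, ci, cj) {
  n <- prior$counts[ci, cj, ]
  (n + prior$alpha) / (sum(n) + prior$alpha * length(prior$relations))
}

as_posterior <- function(z, classes) {
  if (is.character(z)) {
    p <- setNames(rep(0, length(classes)), classes)
    if (!z %in% classes) abort(sprintf("class '%s' not in vocabulary", z))
    p[z] <- 1
    p
  } else {
    if (length(z) == 0L) abort("empty posterior")
    if (length(z) != length(classes)) abort("posterior length does not match class count")
    as.numeric(z)
  }
}

#' Class-branch logits
#'
#' Log prior row for hard classes; for soft class posteriors, the log of the
#' posterior-weighted average of prior rows (marginalization over the class
#' pair).
#'
#' @param zi,zj Subject/object class: a class name, or a posterior vector
#'   over the 15 classes.
#' @param prior A `predicate_prior`.
#' @return Logit vector over the relation types.
#' @export
predict_from_classes <- function(zi, zj, prior) {
  pi_ <- as_posterior(zi, prior$classes)
  pj <- as_posterior(zj, prior$classes)
  acc <- rep(0, length(prior$relations))
  nz_i <- which(pi_ > 0); nz_j <- which(pj > 0)
  for (a in nz_i) for (b in nz_j) {
    acc <- acc + pi_[a] * pj[b] * prior_row(prior, prior$classes[a], prior$classes[b])
  }
  unname(log(acc))
}

#' Feature-branch logits
#'
#' Linear map on the concatenated ordered pair `[x_i, x_j]`; direction
#' matters, so swapping the arguments generally changes the output.
#'
#' @param xi,xj Descriptor vectors of subject and object.
#' @param params A trained `sgg_model` (or a list with `W_f`, `b_f`,
#'   `mu_f`, `sd_f`).
#' @return Logit vector over the relation types.
#' @export
predict_from_features <- function(xi, xj, params) {
  v <- c(xi, xj)
  if (length(v) != ncol(params$W_f))
    abort(sprintf("pair descriptor length %d does not match model (%d)",
                  length(v), ncol(params$W_f)))
  vs <- (v - params$mu_f) / params$sd_f
  as.numeric(params$W_f %*% vs + params$b_f)
}

#' Visual-context descriptor of an ordered pair
#'
#' Descriptor (as in the detection module) of the crop of the joint region
#' `hull(b_i, b_j)`.
#'
#' @param image A `scene_image` or pixel array.
#' @param bi,bj Boxes of the pair.
#' @return Numeric descriptor vector.
#' @export
visual_context <- function(image, bi, bj) {
  joint <- box_hull(bi, bj)
  if (joint$w <= 0L || joint$h <= 0L) abort("degenerate joint box")
  extract_features(image, joint)
}

context_logits <- function(v, params) {
  vs <- (v - params$mu_c) / params$sd_c
  as.numeric(params$W_c %*% vs + params$b_c)
}

#' Fuse the three branch logit vectors into a predicate distribution
#'
#' Softmax of the elementwise sum — the logistic quantile (logit) link makes
#' additive branch logits coherent. Symmetric in branch order; reduces to the
#' single-branch softmax when the other two are zero.
#'
#' @param class_logits,feature_logits,context_logits Aligned logit vectors
#'   over the relation types.
#' @return Probability vector summing to 1.
#' @export
fuse_branches <- function(class_logits, feature_logits, context_logits) {
  if (length(feature_logits) != length(class_logits) ||
      length(context_logits) != length(class_logits))
    abort("branch logit vectors have mismatched lengths")
  softmax(class_logits + feature_logits + context_logits)
}

#' Training loss of the full model
#'
#' Sum of mean cross-entropies (natural log): object labels, fused predicate
#' distributions, and one auxiliary term per branch. Nonnegative; zero
#' exactly when every prediction is a point mass on the truth. Labels may be
#' class indices or, for soft targets, rows of a target matrix.
#'
#' @param object_posteriors Matrix of object class posteriors (rows sum to 1).
#' @param fused Matrix of fused predicate distributions.
#' @param branches List of three matrices of per-branch distributions.
#' @param object_labels Integer true class indices.
#' @param predicate_labels Integer true predicate indices.
#' @return Scalar loss.
#' @export
training_loss <- function(object_posteriors, fused, branches,
                          object_labels, predicate_labels) {
  ce <- function(P, y) {
    if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
    if (length(y) != nrow(P)) abort("label/prediction shape mismatch")
    -mean(log(pmax(P[cbind(seq_len(nrow(P)), y)], 1e-300)))
  }
  loss <- ce(object_posteriors, object_labels) + ce(fused, predicate_labels)
  for (B in branches) loss <- loss + ce(B, predicate_labels)
  loss
}

# ---- message-passing graph network -----------------------------------------

#' Initialize message-passing parameters
#'
#' The transition function F is an affine map plus tanh:
#' `h_v <- tanh(W_self h_v + W_msg sum_{u in N(v)} h_u + b)`, applied
#' identically ("symmetrically") at every node whatever its neighborhood
#' size. Weights are drawn from a seeded normal scaled by `1/sqrt(d)`.
#'
#' @param d Embedding dimension (equals the input feature length).
#' @param seed Seed for the weight draw.
#' @param rounds Default number of rounds K.
#' @return A list of class `gnn_params`.
#' @export
gnn_params <- function(d, seed = 1L, rounds = 3L) {
  with_seed(seed, {
    structure(list(
      W_self = matrix(rnorm(d * d, 0, 1 / sqrt(d)), d, d),
      W_msg = matrix(rnorm(d * d, 0, 1 / sqrt(d)), d, d),
      b = rep(0, d), d = as.integer(d), rounds = as.integer(rounds)
    ), class = "gnn_params")
  })
}

#' Message-passing node embeddings over a scene graph
#'
#' K rounds of the transition function with sum aggregation over graph
#' neighbours (relation edges taken as undirected for message flow, no self
#' loops). `K = 0` returns the initial features unchanged; an isolated node's
#' embedding depends only on its own feature.
#'
#' @param sg A `scene_graph` (only its relation edges are used).
#' @param features Numeric matrix, one row per graph object.
#' @param params A `gnn_params` whose `d` matches `ncol(features)`.
#' @param K Number of rounds (default `params$rounds`).
#' @return Matrix of embeddings, same shape as `features`.
#' @export
gnn_embed <- function(sg, features, params, K = params$rounds) {
  if (K < 0L) abort("K must be >= 0")
  n <- nrow(sg$objects)
  if (is.null(dim(features))) features <- matrix(features, nrow = n)
  stopifnot(nrow(features) == n, ncol(features) == params$d)
  if (K == 0L || n == 0L) return(features)
  A <- matrix(0, n, n)
  for (k in seq_len(nrow(sg$relations))) {
    i <- sg$relations$subject_idx[k]; j <- sg$relations$object_idx[k]
    A[i, j] <- 1; A[j, i] <- 1
  }
  H <- features
  for (r in seq_len(K)) {
    M <- A %*% H
    H <- tanh(H %*% t(params$W_self) + M %*% t(params$W_msg) +
                matrix(params$b, n, params$d, byrow = TRUE))
  }
  H
}

# ---- training ---------------------------------------------------------------

# Assemble the pair training set: ground-truth related pairs labelled with
# their predicate, plus (up to one per positive, per image) unrelated pairs
# given the uniform distribution as a soft target so non-interacting pairs
# stay below the interaction threshold.
build_pair_set <- function(dataset, n_rel, seed = 1L, neg_per_pos = 3L) {
  Xf <- list(); Xc <- list(); y <- integer(); soft <- logical()
  ci <- character(); cj <- character()
  rel_names <- load_vocabulary(attr(dataset, "config")$species)$relations
  for (i in seq_len(nrow(dataset))) {
    ann <- dataset$annotation[[i]]; img <- dataset$image[[i]]
    if (nrow(ann$relationships) == 0L || nrow(ann$objects) < 2L) next
    feats <- feature_matrix(img, ann$objects)
    boxes <- ann$objects
    pos_pairs <- ann$relationships
    for (k in seq_len(nrow(pos_pairs))) {
      s <- pos_pairs$subject_idx[k]; o <- pos_pairs$object_idx[k]
      Xf[[length(Xf) + 1L]] <- c(feats[s, ], feats[o, ])
      Xc[[length(Xc) + 1L]] <- visual_context(img, boxes[s, ], boxes[o, ])
      y <- c(y, match(pos_pairs$predicate[k], rel_names))
      soft <- c(soft, FALSE)
      ci <- c(ci, boxes$name[s]); cj <- c(cj, boxes$name[o])
    }
    # negatives: unrelated ordered pairs, deterministically subsampled
    n <- nrow(boxes)
    all_pairs <- expand.grid(s = seq_len(n), o = seq_len(n))
    all_pairs <- all_pairs[all_pairs$s != all_pairs$o, , drop = FALSE]
    pos_key <- paste(pos_pairs$subject_idx, pos_pairs$object_idx)
    neg <- all_pairs[!paste(all_pairs$s, all_pairs$o) %in% pos_key, , drop = FALSE]
    if (nrow(neg) > 0L) {
      take <- with_seed(split_seed(seed, i),
                        sample(nrow(neg), min(nrow(neg), neg_per_pos * nrow(pos_pairs))))
      for (t in take) {
        s <- neg$s[t]; o <- neg$o[t]
        Xf[[length(Xf) + 1L]] <- c(feats[s, ], feats[o, ])
        Xc[[length(Xc) + 1L]] <- visual_context(img, boxes[s, ], boxes[o, ])
        y <- c(y, 0L)  # soft uniform target
        soft <- c(soft, TRUE)
        ci <- c(ci, boxes$name[s]); cj <- c(cj, boxes$name[o])
      }
    }
  }
  list(Xf = do.call(rbind, Xf), Xc = do.call(rbind, Xc), y = y, soft = soft,
       ci = ci, cj = cj, relations = rel_names)
}

standardize_cols <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd); sdv[sdv < 1e-9] <- 1
  list(X = sweep(sweep(X, 2L, mu), 2L, sdv, "/"), mu = mu, sd = sdv)
}

#' Train the scene-graph predicate model
#'
#' Fits the co-occurrence prior by counting, then optimizes the feature- and
#' context-branch weights by full-batch gradient descent on the training
#' loss (fused cross-entropy plus the two auxiliary branch terms; the
#' class-branch logits are fixed by the prior, and the object term is carried
#' by the supplied classifier, whose parameters the predicate loss does not
#' touch). The sample order is canonicalized before fitting, so identical
#' data in any order with the same seed gives identical parameters.
#'
#' @param dataset A `scene_dataset` whose annotations validate.
#' @param classifier An `object_classifier` for the same species.
#' @param epochs,lr Gradient-descent schedule.
#' @param l2 Ridge penalty on the branch weights.
#' @param neg_per_pos Unrelated ordered pairs sampled per related pair and
#'   image, trained toward the uniform predicate distribution (keeps
#'   non-interacting pairs below the 0.5 interaction threshold).
#' @param seed Seed controlling negative-pair subsampling.
#' @return An object of class `sgg_model`.
#' @export
train_sgg <- function(dataset, classifier, epochs = 400L, lr = 0.2, l2 = 1e-4,
                      neg_per_pos = 3L, seed = 1L) {
  species <- attr(dataset, "config")$species
  vocab <- load_vocabulary(species)
  prior <- fit_prior(dataset, vocab)
  ps <- build_pair_set(dataset, length(vocab$relations), seed = seed,
                       neg_per_pos = neg_per_pos)
  if (length(unique(ps$y[!ps$soft])) < 2L)
    abort("degenerate dataset: fewer than two observed predicate classes")
  n <- length(ps$y); R <- length(ps$relations)
  # canonical order: positives by (label, class pair, features); negatives after
  key <- paste(ps$soft, ps$y, ps$ci, ps$cj,
               apply(ps$Xf, 1L, function(r) paste(format(r[1:8], digits = 8), collapse = ",")))
  ord <- order(key)
  ps$Xf <- ps$Xf[ord, , drop = FALSE]; ps$Xc <- ps$Xc[ord, , drop = FALSE]
  ps$y <- ps$y[ord]; ps$soft <- ps$soft[ord]
  ps$ci <- ps$ci[ord]; ps$cj <- ps$cj[ord]

  sf <- standardize_cols(ps$Xf); sc <- standardize_cols(ps$Xc)
  Lp <- t(vapply(seq_len(n), function(k) predict_from_classes(ps$ci[k], ps$cj[k], prior),
                 numeric(R)))
  Y <- matrix(1 / R, n, R)  # soft uniform targets for negatives
  hard <- which(!ps$soft)
  Y[hard, ] <- 0
  Y[cbind(hard, ps$y[hard])] <- 1

  W_f <- matrix(0, R, ncol(sf$X)); b_f <- rep(0, R)
  W_c <- matrix(0, R, ncol(sc$X)); b_c <- rep(0, R)
  history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    Lf <- sf$X %*% t(W_f) + matrix(b_f, n, R, byrow = TRUE)
    Lc <- sc$X %*% t(W_c) + matrix(b_c, n, R, byrow = TRUE)
    Pfu <- row_softmax(Lp + Lf + Lc)
    Pf <- row_softmax(Lf); Pc <- row_softmax(Lc)
    history[e] <- -mean(rowSums(Y * log(pmax(Pfu, 1e-300)))) -
      mean(rowSums(Y * log(pmax(Pf, 1e-300)))) -
      mean(rowSums(Y * log(pmax(Pc, 1e-300))))
    Gf <- (Pfu - Y) + (Pf - Y)
    Gc <- (Pfu - Y) + (Pc - Y)
    W_f <- W_f - lr * (t(Gf) %*% sf$X / n + l2 * W_f)
    b_f <- b_f - lr * colMeans(Gf)
    W_c <- W_c - lr * (t(Gc) %*% sc$X / n + l2 * W_c)
    b_c <- b_c - lr * colMeans(Gc)
  }
  structure(list(prior = prior, classifier = classifier,
                 W_f = W_f, b_f = b_f, mu_f = sf$mu, sd_f = sf$sd,
                 W_c = W_c, b_c = b_c, mu_c = sc$mu, sd_c = sc$sd,
                 relations = ps$relations, classes = vocab$objects$name,
                 species = species, history = history,
                 epochs = as.integer(epochs), lr = lr, seed = as.integer(seed),
                 n_pairs = n),
            class = "sgg_model")
}

#' @export
print.sgg_model <- function(x, ...) {
  cat(sprintf("<sgg_model: %s> %d relation types, %d training pairs, final loss %.4f\n",
              x$species, length(x$relations), x$n_pairs, tail(x$history, 1)))
  invisible(x)
}

#' Fused predicate distribution for one ordered detection pair
#'
#' Runs the three branches on detections `i` and `j` (class branch
#' marginalized over the class posteriors) and fuses them.
#'
#' @param det A `detections` object (with its source image attached).
#' @param i,j Ordered pair of detection indices, `i != j`.
#' @param model An `sgg_model`.
#' @return Named probability vector over the relation types.
#' @export
pair_predicate_distribution <- function(det, i, j, model) {
  if (i == j) abort("ordered pairs require i != j")
  m <- nrow(det$boxes)
  if (i < 1L || i > m || j < 1L || j > m) abort("detection index out of range")
  lp <- predict_from_classes(det$posteriors[i, ], det$posteriors[j, ], model$prior)
  lf <- predict_from_features(det$features[i, ], det$features[j, ], model)
  lc <- context_logits(visual_context(det$image, det$boxes[i, ], det$boxes[j, ]), model)
  setNames(fuse_branches(lp, lf, lc), model$relations)
}
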