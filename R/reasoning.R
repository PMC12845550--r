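# Graph reasoning over detections: phrase detection (textual
# subject-predicate-object labels with union boxes), predicate
# classification with the 0.5 interaction threshold, scene-graph
# classification, conditional-random-field MAP agreement scoring for
# retrieval, and rule-based question answering over a scene graph.

INTERACTION_THRESHOLD <- 0.5

#' Detect phrases (textual triplet labels)
#'
#' For every ordered detection pair whose fused max predicate probability
#' strictly exceeds the decision threshold, emits the label
#' "subject predicate object" with the union box of the pair. Sorted by
#' score descending, ties broken by (i, j).
#'
#' @param det A `detections` object with at least the boxes/features/
#'   posteriors of one image.
#' @param model An `sgg_model`.
#' @param threshold Decision threshold (default 0.5, strict).
#' @return Tibble with subject, predicate, object, label, score, i, j and the
#'   union box columns; zero rows when nothing interacts.
#' @export
detect_phrases <- function(det, model, threshold = INTERACTION_THRESHOLD) {
  pairs <- classify_predicates(det, model, threshold = threshold)
  hits <- pairs %>% filter(.data$interacts)
  if (nrow(hits) == 0L)
    return(tibble(subject = character(), predicate = character(), object = character(),
                  label = character(), score = numeric(), i = integer(), j = integer(),
                  x = integer(), y = integer(), w = integer(), h = integer()))
  cls <- detected_classes(det)
  rows <- map(seq_len(nrow(hits)), function(k) {
    i <- hits$i[k]; j <- hits$j[k]
    ub <- box_hull(det$boxes[i, ], det$boxes[j, ])
    tibble(subject = cls[i], predicate = hits$predicate[k], object = cls[j],
           label = paste(cls[i], hits$predicate[k], cls[j]),
           score = hits$prob[k], i = i, j = j, ub)
  }) %>% bind_rows()
  arrange(rows, desc(.data$score), .data$i, .data$j)
}

#' Classify the predicate of every ordered detection pair
#'
#' A pair interacts when its fused max predicate probability strictly
#' exceeds 0.5; the predicate is the argmax (ties broken by vocabulary
#' order). Pairs with i = j are skipped.
#'
#' @param det A `detections` object.
#' @param model An `sgg_model`.
#' @param threshold Interaction threshold (strict >).
#' @return Tibble with columns i, j, interacts, predicate, prob.
#' @export
classify_predicates <- function(det, model, threshold = INTERACTION_THRESHOLD) {
  m <- nrow(det$boxes)
  if (m < 2L)
    return(tibble(i = integer(), j = integer(), interacts = logical(),
                  predicate = character(), prob = numeric()))
  grid <- expand.grid(i = seq_len(m), j = seq_len(m))
  grid <- grid[grid$i != grid$j, , drop = FALSE]
  rows <- map(seq_len(nrow(grid)), function(k) {
    i <- grid$i[k]; j <- grid$j[k]
    p <- pair_predicate_distribution(det, i, j, model)
    best <- which.max(p)  # first max = vocabulary order tie-break
    tibble(i = i, j = j, interacts = unname(p[best]) > threshold,
           predicate = model$relations[best], prob = unname(p[best]))
  }) %>% bind_rows()
  arrange(rows, .data$i, .data$j)
}

#' Classify a full scene graph from detections
#'
#' Objects = argmax classes of the detections; relations = the interacting
#' pairs of [classify_predicates()] with their fused probabilities.
#'
#' @param det A `detections` object.
#' @param model An `sgg_model`.
#' @param image_id Optional image identifier for the graph.
#' @return A `scene_graph` whose relations carry a `prob` column.
#' @export
classify_scene_graph <- function(det, model, image_id = NA_integer_) {
  m <- nrow(det$boxes)
  if (m == 0L) return(scene_graph(image_id = image_id))
  cls <- detected_classes(det)
  syn <- load_vocabulary(model$species)$objects
  objects <- det$boxes %>%
    mutate(name = cls, synset = syn$synset[match(cls, syn$name)], .before = 1L)
  pairs <- classify_predicates(det, model) %>% filter(.data$interacts)
  relations <- if (nrow(pairs) == 0L) NULL else
    tibble(subject_idx = pairs$i, predicate = pairs$predicate,
           object_idx = pairs$j, prob = pairs$prob)
  scene_graph(objects, relations, image_id = image_id)
}

# ---- CRF MAP agreement ------------------------------------------------------

injective_assignments <- function(n_query, n_det) {
  # all injective maps query -> detections, as rows of a matrix
  if (n_query == 0L) return(matrix(integer(), 1L, 0L))
  rec <- function(free, k) {
    if (k == 0L) return(matrix(integer(), 1L, 0L))
    out <- list()
    for (d in free) {
      sub <- rec(setdiff(free, d), k - 1L)
      out[[length(out) + 1L]] <- cbind(d, sub)
    }
    do.call(rbind, out)
  }
  rec(seq_len(n_det), n_query)
}

assignment_score <- function(assign, query, det, model) {
  s <- 1
  for (q in seq_along(assign)) {
    s <- s * det$posteriors[assign[q], query$objects$name[q]]
  }
  cls <- detected_classes(det)
  for (k in seq_len(nrow(query$relations))) {
    qi <- query$relations$subject_idx[k]; qj <- query$relations$object_idx[k]
    row <- prior_row(model$prior, cls[assign[qi]], cls[assign[qj]])
    s <- s * row[query$relations$predicate[k]]
  }
  s
}

#' MAP agreement between a query graph and candidate detections
#'
#' Scores every injective assignment of query objects to detections by the
#' conditional-random-field potentials — unaries from the detection class
#' posteriors, pairwise terms from the predicate prior — and returns the
#' probability of the maximum a posteriori assignment (normalized over all
#' assignments) as the agreement score. Exhaustive up to `brute_cap` query
#' objects; beyond that a greedy best-first assignment is scored against its
#' single-swap neighbourhood unless `force_brute`.
#'
#' @param query A `scene_graph` (the structure to look for). An empty query
#'   scores 1 by convention (vacuous product).
#' @param det A `detections` object (the candidate image).
#' @param model An `sgg_model` providing the prior potentials.
#' @param brute_cap Maximum query size for exhaustive enumeration (default 4).
#' @param force_brute Enumerate exhaustively regardless of size.
#' @return List of class `agreement_score`: `value` in `[0, 1]` and
#'   `assignment` (detection index per query object).
#' @export
map_agreement <- function(query, det, model, brute_cap = 4L, force_brute = FALSE) {
  nq <- nrow(query$objects); nd <- nrow(det$boxes)
  if (nq == 0L)
    return(structure(list(value = 1, assignment = integer()), class = "agreement_score"))
  if (nq > nd) abort("more query objects than candidate detections")
  if (nq <= brute_cap || force_brute) {
    A <- injective_assignments(nq, nd)
    scores <- vapply(seq_len(nrow(A)), function(r) assignment_score(A[r, ], query, det, model),
                     numeric(1))
    tot <- sum(scores)
    best <- which.max(scores)
    val <- if (tot > 0) scores[best] / tot else 1 / nrow(A)
    structure(list(value = val, assignment = as.integer(A[best, ])),
              class = "agreement_score")
  } else {
    assign <- integer(nq); free <- seq_len(nd)
    for (q in seq_len(nq)) {
      u <- det$posteriors[free, query$objects$name[q]]
      pick <- free[which.max(u)]
      assign[q] <- pick; free <- setdiff(free, pick)
    }
    s_best <- assignment_score(assign, query, det, model)
    # local normalization over the single-swap neighbourhood
    neigh <- s_best
    for (q in seq_len(nq)) for (d in setdiff(seq_len(nd), assign)) {
      alt <- assign; alt[q] <- d
      neigh <- neigh + assignment_score(alt, query, det, model)
    }
    structure(list(value = if (neigh > 0) s_best / neigh else 0,
                   assignment = assign), class = "agreement_score")
  }
}

#' @export
print.agreement_score <- function(x, ...) {
  cat(sprintf("<agreement_score> %.4f (assignment: %s)\n", x$value,
              paste(x$assignment, collapse = ", ")))
  invisible(x)
}

# ---- question answering -----------------------------------------------------

INSECT_CLASSES <- c("bee", "mellifera_bee", "ant", "emmet")

# Strongest relation label: total fused probability per predicate when the
# graph carries probabilities (predicted graphs), plain counts otherwise.
dominant_predicate <- function(sg) {
  if (nrow(sg$relations) == 0L) return(NA_character_)
  wt <- if ("prob" %in% names(sg$relations)) sg$relations$prob else rep(1, nrow(sg$relations))
  tot <- tapply(wt, sg$relations$predicate, sum)
  names(tot)[order(-tot, names(tot))][1]
}

behavior_phrase_from_graph <- function(sg, species) {
  pred <- dominant_predicate(sg)
  if (is.na(pred)) return(NA_character_)
  insect <- title_word(species)
  switch(pred,
         greeting = paste(insect, "Greeting"),
         grouping = paste0(insect, "s Grouping"),
         carrying = {
           k <- which(sg$relations$predicate == "carrying")[1]
           cargo <- sg$objects$name[sg$relations$object_idx[k]]
           if (cargo == "pollen") "Carrying Pollen" else "Carrying Food"
         },
         approaching = "Intruder Detected",
         crowding = "Big Population",
         accessing = paste("Type of", insect),
         title_word(pred))
}

#' Answer a typed question from a scene graph
#'
#' Rule table keyed by question type: who -> the non-resident class if an
#' intruder node is present; how (access state) -> the access node's
#' population attribute (or a count-based inference when the graph carries no
#' attributes); what-doing -> the dominant relation label; what-is-in -> the
#' insect type; why -> the carrying activity; where -> the nest entrance when
#' occupied. Unanswerable questions return "unknown"; every answer comes from
#' the closed vocabulary plus "unknown".
#'
#' @param sg A `scene_graph` (ground truth or predicted).
#' @param question Question text.
#' @param qtype One of what, where, how, when, who, why.
#' @return Answer string.
#' @export
answer_question <- function(sg, question, qtype = c("what", "where", "how", "when", "who", "why")) {
  qtype <- match.arg(qtype)
  n <- nrow(sg$objects)
  if (n == 0L) return("unknown")
  species <- if (any(sg$objects$name %in% c("ant", "emmet"))) "ant" else "bee"
  insects <- which(sg$objects$name %in% INSECT_CLASSES)
  intr <- which(sg$objects$name == "intruder")
  acc <- which(sg$objects$name == "access")
  q <- tolower(question)
  if (qtype == "who") {
    if (length(intr) > 0L) return("Intruder")
    if (length(insects) > 0L) return(title_word(species))
    return("unknown")
  }
  if (qtype == "how") {
    if (length(acc) > 0L) {
      a <- sg$objects$attributes[[acc[1]]]
      state <- unname(a[names(a) == "Access"])[1]
      if (!is.na(state) && length(state) == 1L) {
        return(switch(state, Tumult = "Big population",
                      Occupied = "Low population", Free = "Free", "unknown"))
      }
      # predicted graphs carry no attributes: infer from crowding
      if (length(insects) >= 4L || "crowding" %in% sg$relations$predicate)
        return("Big population")
      if (length(insects) >= 1L || length(intr) >= 1L) return("Low population")
      return("Free")
    }
    return("unknown")
  }
  if (qtype == "what") {
    if (grepl("doing", q)) {
      pred <- dominant_predicate(sg)
      return(if (is.na(pred)) "unknown" else title_word(pred))
    }
    if (grepl("shown in this region", q)) {
      ph <- behavior_phrase_from_graph(sg, species)
      return(if (is.na(ph)) "unknown" else ph)
    }
    if (length(insects) > 0L) return(paste("Type of", species))
    if (length(intr) > 0L) return("Intruder")
    return("unknown")
  }
  if (qtype == "why") {
    k <- which(sg$relations$predicate == "carrying")
    if (length(k) > 0L) {
      cargo <- sg$objects$name[sg$relations$object_idx[k[1]]]
      return(if (cargo == "pollen") "Carrying pollen" else "Carrying food")
    }
    return("unknown")
  }
  if (qtype == "where") {
    if (length(acc) > 0L && (length(insects) > 0L || length(intr) > 0L))
      return(paste("At the", tolower(nest_word(species)), "entrance"))
    return("unknown")
  }
  "unknown"
}
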