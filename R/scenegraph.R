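# The SG = (O, R, E) data model. A scene graph holds object instances
# (class synset + box + attributes), directed predicate relations between
# pairs of instances, and provenance of which captioned regions contributed
# each node and edge. A region graph is the fragment describing one captioned
# region; the scene graph of an image is the union of its region graphs with
# nodes deduplicated by canonical identity (class synset + exact box; an
# optional IoU-based near-duplicate fusion can be enabled).

#' Construct a scene graph
#'
#' @param objects Tibble with columns `name`, `synset`, `x`, `y`, `w`, `h`,
#'   and optionally `attributes` (list of named character vectors) and
#'   `provenance` (list of integer region ids).
#' @param relations Tibble with columns `subject_idx`, `predicate`,
#'   `object_idx`, optionally `prob` and `provenance`.
#' @param image_id Optional image identifier.
#' @return An object of class `scene_graph`.
#' @export
scene_graph <- function(objects = NULL, relations = NULL, image_id = NA_integer_) {
  objects <- objects %||% tibble(name = character(), synset = character(),
                                 x = integer(), y = integer(), w = integer(), h = integer())
  relations <- relations %||% tibble(subject_idx = integer(), predicate = character(),
                                     object_idx = integer())
  objects <- as_tibble(objects); relations <- as_tibble(relations)
  if (!"attributes" %in% names(objects)) objects$attributes <- rep(list(character()), nrow(objects))
  if (!"provenance" %in% names(objects)) objects$provenance <- rep(list(integer()), nrow(objects))
  if (!"provenance" %in% names(relations)) relations$provenance <- rep(list(integer()), nrow(relations))
  n <- nrow(objects)
  if (nrow(relations) > 0L) {
    if (any(relations$subject_idx == relations$object_idx)) abort("self-relation in scene graph")
    if (any(relations$subject_idx < 1L | relations$subject_idx > n |
            relations$object_idx < 1L | relations$object_idx > n))
      abort("relation references a missing object")
    key <- paste(relations$subject_idx, relations$predicate, relations$object_idx)
    if (anyDuplicated(key)) abort("duplicate (subject, predicate, object) triplet")
  }
  if (nrow(relations) > n * n) abort("scene graph exceeds the n x n edge bound")
  okey <- paste(objects$synset, objects$x, objects$y, objects$w, objects$h)
  if (anyDuplicated(okey)) abort("duplicate object under canonical identity")
  structure(list(objects = objects, relations = relations,
                 image_id = as.integer(image_id)),
            class = "scene_graph")
}

#' @export
print.scene_graph <- function(x, ...) {
  s <- scene_graph_summary(x)
  cat(sprintf("<scene_graph> n=%d objects, %d relations (|E| <= n^2 = %d)\n",
              s$n_objects, s$n_relations, s$n_objects^2))
  invisible(x)
}

#' Build the graph of one captioned region
#'
#' One node per referenced object instance (each must lie center-in the
#' region box), one attribute node per attribute value linked to its owning
#' object, and one directed edge per relation whose endpoints both lie in the
#' region.
#'
#' @param region One-row regions tibble (`x`, `y`, `w`, `h`, `phrase`,
#'   `object_ids`).
#' @param objects Full objects tibble of the image.
#' @param relations Full relationships tibble of the image
#'   (`subject_idx`, `predicate`, `object_idx`).
#' @param image_id Image identifier for cross-image merge checks.
#' @return An object of class `region_graph` with local object indices.
#' @export
build_region_graph <- function(region, objects, relations = NULL, image_id = NA_integer_) {
  relations <- relations %||% tibble(subject_idx = integer(), predicate = character(),
                                     object_idx = integer())
  ids <- region$object_ids[[1]]
  sel <- match(ids, objects$object_id)
  if (anyNA(sel)) abort(sprintf("region references missing object id(s): %s",
                                paste(ids[is.na(sel)], collapse = ", ")))
  rbox <- bounding_box(region$x, region$y, region$w, region$h)
  for (i in sel) {
    ob <- bounding_box(objects$x[i], objects$y[i], objects$w[i], objects$h[i])
    if (!box_center_in(ob, rbox))
      abort(sprintf("object %d does not lie (center-in) within the region box", objects$object_id[i]))
  }
  local <- objects[sel, , drop = FALSE]
  attrs <- imap(local$attributes, function(a, i) {
    if (length(a) == 0L) return(NULL)
    tibble(object_local = i, facet = names(a) %||% rep("", length(a)), value = unname(a))
  }) %>% bind_rows()
  if (nrow(attrs) == 0L) attrs <- tibble(object_local = integer(), facet = character(), value = character())
  keep <- relations$subject_idx %in% sel & relations$object_idx %in% sel
  redges <- relations[keep, , drop = FALSE] %>%
    mutate(subject_idx = match(.data$subject_idx, sel),
           object_idx = match(.data$object_idx, sel))
  structure(list(region = as_tibble(region), objects = local,
                 attributes = attrs, relations = redges,
                 image_id = as.integer(image_id)),
            class = "region_graph")
}

#' @export
print.region_graph <- function(x, ...) {
  cat(sprintf("<region_graph \"%s\"> %d objects, %d attribute nodes, %d relation edges\n",
              x$region$phrase, nrow(x$objects), nrow(x$attributes), nrow(x$relations)))
  invisible(x)
}

#' All region graphs of an annotated image
#'
#' @param ann An `image_annotation`.
#' @return List of `region_graph` objects, one per region.
#' @export
annotation_to_region_graphs <- function(ann) {
  map(seq_len(nrow(ann$regions)),
      ~ build_region_graph(ann$regions[.x, ], ann$objects, ann$relationships,
                           image_id = ann$image_id))
}

#' Merge region graphs into a single scene graph
#'
#' Node set = union of the region nodes deduplicated by canonical identity
#' (class synset + exact box, or boxes at IoU >= `iou_fuse` when near-
#' duplicate fusion is enabled); edge set = union of edges deduplicated by
#' (subject, predicate, object); provenance records every contributing
#' region. The result is independent of region order, and re-merging a merged
#' graph's regions changes nothing. Attribute conflicts (same object, same
#' facet, different values) keep both values and emit a warning.
#'
#' @param regions List of `region_graph` objects from a single image.
#' @param iou_fuse Optional IoU threshold (e.g. 0.9) for fusing near-duplicate
#'   nodes of the same class; `NULL` (default) requires exact box identity.
#' @return A `scene_graph`.
#' @export
merge_region_graphs <- function(regions, iou_fuse = NULL) {
  if (length(regions) == 0L) return(scene_graph())
  imgs <- unique(map_int(regions, ~ .x$image_id))
  imgs <- imgs[!is.na(imgs)]
  if (length(imgs) > 1L) abort("cannot merge region graphs from different images")

  region_label <- function(rg, ri) {
    if ("region_id" %in% names(rg$region) && !is.na(rg$region$region_id[1]))
      rg$region$region_id[1] else ri
  }
  nodes <- imap(regions, function(rg, ri) {
    if (nrow(rg$objects) == 0L) return(NULL)
    rg$objects %>% mutate(.ri = ri, .region = region_label(rg, ri),
                          .local = dplyr::row_number())
  }) %>% bind_rows()
  img_id <- if (length(imgs) == 1L) imgs else NA_integer_
  if (is.null(nodes) || nrow(nodes) == 0L) return(scene_graph(image_id = img_id))

  key <- paste(nodes$synset, nodes$x, nodes$y, nodes$w, nodes$h)
  group <- match(key, key)  # canonical identity grouping
  if (!is.null(iou_fuse)) {
    # greedy transitive fusion of same-class near-duplicates, order-free via
    # canonical (y, x, w, h) ordering of group representatives
    reps <- sort(unique(group))
    ord <- reps[order(nodes$y[reps], nodes$x[reps], nodes$w[reps], nodes$h[reps])]
    for (i in seq_along(ord)) for (j in seq_len(i - 1L)) {
      a <- ord[i]; b <- ord[j]
      if (group[a] == group[b]) next
      if (nodes$synset[a] == nodes$synset[b] &&
          box_iou(nodes[a, ], nodes[b, ]) >= iou_fuse) {
        group[group == group[a]] <- group[b]
      }
    }
  }
  uid <- sort(unique(group))
  # canonical output order: by geometry then class, independent of region order
  rep_rows <- nodes[uid, , drop = FALSE]
  out_ord <- order(rep_rows$y, rep_rows$x, rep_rows$w, rep_rows$h, rep_rows$synset)
  uid <- uid[out_ord]
  objects <- map(uid, function(u) {
    members <- which(group == u)
    attrs <- list()
    for (m in members) {
      a <- nodes$attributes[[m]]
      for (f in names(a)) {
        prev <- attrs[[f]]
        if (!is.null(prev) && !a[[f]] %in% prev)
          warn(sprintf("attribute conflict on facet '%s': keeping both '%s' and '%s'",
                       f, paste(prev, collapse = "/"), a[[f]]))
        attrs[[f]] <- unique(c(prev, a[[f]]))
      }
    }
    flat <- unlist(unname(imap(attrs, function(v, f) setNames(v, rep(f, length(v)))))) %||% character()
    tibble(name = nodes$name[u], synset = nodes$synset[u],
           x = nodes$x[u], y = nodes$y[u], w = nodes$w[u], h = nodes$h[u],
           attributes = list(flat),
           provenance = list(sort(unique(nodes$.region[members]))))
  }) %>% bind_rows()

  node_of <- function(ri, local) {
    m <- which(nodes$.ri == ri & nodes$.local == local)
    match(group[m], group[uid])
  }
  edges <- imap(regions, function(rg, ri) {
    if (nrow(rg$relations) == 0L) return(NULL)
    rg$relations %>%
      mutate(subject_idx = map_int(.data$subject_idx, ~ node_of(ri, .x)),
             object_idx = map_int(.data$object_idx, ~ node_of(ri, .x)),
             .region = region_label(rg, ri))
  }) %>% bind_rows()
  if (!is.null(edges) && nrow(edges) > 0L) {
    edges <- edges %>%
      group_by(.data$subject_idx, .data$predicate, .data$object_idx) %>%
      summarise(provenance = list(sort(unique(.data$.region))), .groups = "drop") %>%
      arrange(.data$subject_idx, .data$object_idx, .data$predicate)
  } else {
    edges <- tibble(subject_idx = integer(), predicate = character(),
                    object_idx = integer(), provenance = list())
  }
  scene_graph(objects, edges, image_id = img_id)
}

#' Scene graph of an annotated image
#'
#' Ground-truth reading: merges the annotation's region graphs. Relations not
#' covered by any region are appended so the graph carries the full
#' relationship set.
#'
#' @param ann An `image_annotation`.
#' @param prob Probability attached to ground-truth relations (default 1).
#' @return A `scene_graph`.
#' @export
annotation_to_scene_graph <- function(ann, prob = 1) {
  sg <- merge_region_graphs(annotation_to_region_graphs(ann))
  # map annotation relations onto merged node set; regions may not cover all
  okey <- paste(sg$objects$synset, sg$objects$x, sg$objects$y, sg$objects$w, sg$objects$h)
  akey <- paste(ann$objects$synset, ann$objects$x, ann$objects$y, ann$objects$w, ann$objects$h)
  idx_map <- match(akey, okey)
  rel <- ann$relationships %>%
    mutate(subject_idx = idx_map[.data$subject_idx],
           object_idx = idx_map[.data$object_idx])
  have <- paste(sg$relations$subject_idx, sg$relations$predicate, sg$relations$object_idx)
  want <- paste(rel$subject_idx, rel$predicate, rel$object_idx)
  extra <- rel[!want %in% have & !is.na(rel$subject_idx) & !is.na(rel$object_idx), , drop = FALSE]
  rels <- bind_rows(sg$relations, extra %>% mutate(provenance = list(integer())))
  rels$prob <- rep(prob, nrow(rels))
  scene_graph(sg$objects, rels, image_id = ann$image_id)
}

#' Summary counts of a scene graph
#'
#' @param sg A `scene_graph`.
#' @return One-row tibble `(n_objects, n_relations, n_edges)`; asserts the
#'   `|E| <= n x n` bound.
#' @export
scene_graph_summary <- function(sg) {
  n <- nrow(sg$objects); e <- nrow(sg$relations)
  stopifnot(e <= n * n)
  tibble(n_objects = n, n_relations = length(unique(sg$relations$predicate)), n_edges = e)
}

#' GraphViz DOT export of a scene graph
#'
#' Writes object nodes, attribute leaves and predicate edges under a single
#' presentation "Root" node (the root is a figure artifact, not a graph
#' element).
#'
#' @param sg A `scene_graph`.
#' @return A single DOT document string.
#' @export
sg_to_dot <- function(sg) {
  lines <- c("digraph scene {", "  rankdir=TB;", "  Root [shape=box];")
  for (i in seq_len(nrow(sg$objects))) {
    lines <- c(lines, sprintf("  o%d [label=\"%s\"];", i, sg$objects$name[i]),
               sprintf("  Root -> o%d [style=dotted];", i))
    a <- sg$objects$attributes[[i]]
    for (j in seq_along(a)) {
      lines <- c(lines, sprintf("  o%d_a%d [label=\"%s\", shape=ellipse, style=dashed];", i, j, a[[j]]),
                 sprintf("  o%d -> o%d_a%d;", i, i, j))
    }
  }
  for (k in seq_len(nrow(sg$relations))) {
    lines <- c(lines, sprintf("  o%d -> o%d [label=\"%s\"];",
                              sg$relations$subject_idx[k], sg$relations$object_idx[k],
                              sg$relations$predicate[k]))
  }
  paste(c(lines, "}"), collapse = "\n")
}
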