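# The annotation bundle: per-image region descriptions, object instances with
# synsets and attributes, relationship triplets and question-answer pairs, in
# a Visual-Genome-dialect JSON document. All tables are tibbles; object
# attributes are a named character vector (facet -> value) per instance.

QA_TYPES <- c("what", "where", "how", "when", "who", "why")

#' Construct a per-image annotation
#'
#' @param image_id Integer or string image identifier.
#' @param width,height Image dimensions in pixels.
#' @param regions Tibble with columns `region_id`, `x`, `y`, `w`, `h`,
#'   `phrase` and a list-column `object_ids` of referenced instance ids.
#' @param objects Tibble with columns `object_id`, `name`, `synset`,
#'   `x`, `y`, `w`, `h` and a list-column `attributes` of named character
#'   vectors (facet -> value).
#' @param relationships Tibble with columns `subject_idx`, `predicate`,
#'   `object_idx` (1-based indices into `objects`).
#' @param qa Tibble with columns `qtype`, `scope`, `question`, `answer`,
#'   `region_ref`.
#' @param behavior Optional behavior label attached by the scene generator.
#' @param headline Optional list `(subject_idx, predicate, object_idx)` naming
#'   the behavior-defining ground-truth triplet.
#' @return An object of class `image_annotation`.
#' @export
image_annotation <- function(image_id, width, height, regions, objects,
                             relationships, qa, behavior = NA_character_,
                             headline = NULL) {
  ann <- structure(list(
    image_id = as.integer(image_id),
    width = as.integer(width), height = as.integer(height),
    regions = as_tibble(regions), objects = as_tibble(objects),
    relationships = as_tibble(relationships), qa = as_tibble(qa),
    behavior = behavior, headline = headline
  ), class = "image_annotation")
  check_annotation_structure(ann)
  ann
}

#' @export
print.image_annotation <- function(x, ...) {
  cat(sprintf("<image_annotation %d> %dx%d px, %d regions, %d objects, %d relationships, %d QA pairs\n",
              x$image_id, x$width, x$height, nrow(x$regions), nrow(x$objects),
              nrow(x$relationships), nrow(x$qa)))
  invisible(x)
}

# Hard structural invariants; violated files refuse to load.
check_annotation_structure <- function(ann) {
  ctx <- sprintf("image %s", ann$image_id)
  fail <- function(msg) abort(sprintf("invariant violation in %s: %s", ctx, msg))
  ob <- ann$objects
  if (nrow(ob) > 0L) {
    if (any(ob$w <= 0L | ob$h <= 0L)) fail("non-positive object box extents")
    if (!all(box_in_bounds(ob, ann$width, ann$height))) fail("object box outside image bounds")
  }
  rg <- ann$regions
  if (nrow(rg) > 0L) {
    if (any(rg$w <= 0L | rg$h <= 0L)) fail("non-positive region box extents")
    if (!all(box_in_bounds(rg, ann$width, ann$height))) fail("region box outside image bounds")
    wc <- phrase_word_count(rg$phrase)
    if (any(wc < 1L | wc > 16L)) fail("region phrase word count outside [1, 16]")
  }
  rel <- ann$relationships
  if (nrow(rel) > 0L) {
    if (any(rel$subject_idx == rel$object_idx)) fail("self-relation (subject_idx == object_idx)")
    if (any(rel$subject_idx < 1L | rel$subject_idx > nrow(ob) |
            rel$object_idx < 1L | rel$object_idx > nrow(ob)))
      fail("relationship references a missing object")
  }
  if (nrow(ann$qa) > 0L) {
    if (!all(ann$qa$qtype %in% QA_TYPES)) fail("unknown question type")
    reg_scope <- ann$qa$scope == "region"
    if (any(reg_scope & is.na(ann$qa$region_ref))) fail("region-scope QA without region_ref")
  }
  invisible(ann)
}

phrase_word_count <- function(phrase) {
  lengths(strsplit(trimws(phrase), "\\s+"))
}

#' Validate an annotation against a vocabulary
#'
#' Returns violations as data rather than raising, so a whole dataset can be
#' reported at once. A conforming image yields zero error-level rows: exactly
#' five regions, phrases of 1-16 words, in-bounds boxes, no self-relations,
#' classes/predicates/attribute values drawn from the vocabulary, and at least
#' one full-image and one region QA pair. Duplicate region descriptions are
#' flagged at warning level only (overlapping regions are legitimate when the
#' descriptions differ).
#'
#' @param ann An `image_annotation`.
#' @param vocab An `insect_vocabulary`.
#' @return Tibble with columns `level`, `code`, `message` (zero rows if clean).
#' @export
validate_annotation <- function(ann, vocab) {
  v <- list()
  add <- function(level, code, message) {
    v[[length(v) + 1L]] <<- tibble(level = level, code = code, message = message)
  }
  if (nrow(ann$regions) != 5L)
    add("error", "region-count", sprintf("expected 5 regions, found %d", nrow(ann$regions)))
  if (nrow(ann$regions) > 0L) {
    wc <- phrase_word_count(ann$regions$phrase)
    bad <- which(wc < 1L | wc > 16L)
    for (i in bad) add("error", "phrase-length",
                       sprintf("region %d phrase has %d words", i, wc[i]))
    if (anyDuplicated(ann$regions$phrase))
      add("warning", "duplicate-region-description", "identical phrases on multiple regions")
    oob <- which(!box_in_bounds(ann$regions, ann$width, ann$height))
    for (i in oob) add("error", "box-bounds", sprintf("region %d box out of bounds", i))
  }
  ob <- ann$objects
  if (nrow(ob) > 0L) {
    oob <- which(!box_in_bounds(ob, ann$width, ann$height) | ob$w <= 0L | ob$h <= 0L)
    for (i in oob) add("error", "box-bounds", sprintf("object %d box invalid", i))
    bad_cls <- which(!ob$synset %in% vocab$objects$synset)
    for (i in bad_cls) add("error", "unknown-class",
                           sprintf("object %d synset '%s' not in vocabulary", i, ob$synset[i]))
    ok_attr <- unique(c(vocab$attributes$value, vocab$object_attributes$value))
    for (i in seq_len(nrow(ob))) {
      a <- ob$attributes[[i]]
      bad <- setdiff(unname(a), ok_attr)
      for (b in bad) add("error", "unknown-attribute",
                         sprintf("object %d attribute value '%s' not in vocabulary", i, b))
    }
  }
  rel <- ann$relationships
  if (nrow(rel) > 0L) {
    self <- which(rel$subject_idx == rel$object_idx)
    for (i in self) add("error", "self-relation", sprintf("relationship %d relates an object to itself", i))
    bad_pred <- which(!rel$predicate %in% vocab$relations)
    for (i in bad_pred) add("error", "unknown-predicate",
                            sprintf("relationship %d predicate '%s' not in vocabulary", i, rel$predicate[i]))
    dangle <- which(rel$subject_idx < 1L | rel$subject_idx > nrow(ob) |
                    rel$object_idx < 1L | rel$object_idx > nrow(ob))
    for (i in dangle) add("error", "dangling-reference", sprintf("relationship %d references a missing object", i))
    if (nrow(rel) > nrow(ob)^2)
      add("error", "edge-bound", "more relationships than n x n")
  }
  if (sum(ann$qa$scope == "full_image") < 1L)
    add("error", "qa-missing", "no full-image QA pair")
  if (sum(ann$qa$scope == "region") < 1L)
    add("error", "qa-missing", "no region QA pair")
  if (nrow(ann$qa) > 0L) {
    bad_q <- which(!ann$qa$qtype %in% QA_TYPES)
    for (i in bad_q) add("error", "qa-type", sprintf("QA %d has unknown qtype '%s'", i, ann$qa$qtype[i]))
    bad_ref <- which(ann$qa$scope == "region" &
                       (is.na(ann$qa$region_ref) | ann$qa$region_ref < 1L |
                          ann$qa$region_ref > nrow(ann$regions)))
    for (i in bad_ref) add("error", "region-ref", sprintf("QA %d region_ref invalid", i))
  }
  if (length(v) == 0L) return(tibble(level = character(), code = character(), message = character()))
  bind_rows(v)
}

#' Are there no error-level violations?
#' @param violations Output of [validate_annotation()].
#' @return Logical scalar.
#' @export
is_clean <- function(violations) !any(violations$level == "error")

# ---- JSON dialect -----------------------------------------------------------

ann_to_list <- function(ann) {
  obj_list <- pmap(ann$objects, function(object_id, name, synset, x, y, w, h, attributes) {
    list(object_id = object_id, names = list(name), synsets = list(synset),
         x = x, y = y, w = w, h = h,
         attributes = as.list(attributes))
  })
  reg_list <- pmap(ann$regions, function(region_id, x, y, w, h, phrase, object_ids) {
    list(region_id = region_id, x = x, y = y, w = w, h = h, phrase = phrase,
         object_ids = as.list(as.integer(object_ids)))
  })
  rel_list <- pmap(ann$relationships, function(subject_idx, predicate, object_idx) {
    list(subject = subject_idx, predicate = predicate, object = object_idx)
  })
  qa_list <- pmap(ann$qa, function(qtype, scope, question, answer, region_ref) {
    out <- list(qtype = qtype, scope = scope, question = question, answer = answer)
    if (!is.na(region_ref)) out$region_ref <- as.integer(region_ref)
    out
  })
  meta <- list()
  if (!is.na(ann$behavior)) meta$behavior <- ann$behavior
  if (!is.null(ann$headline)) meta$headline <- ann$headline
  out <- list(image_id = ann$image_id, width = ann$width, height = ann$height,
              regions = reg_list, objects = obj_list,
              relationships = rel_list, qa = qa_list)
  if (length(meta) > 0L) out$meta <- meta
  out
}

list_to_ann <- function(rec) {
  as_int <- function(x) as.integer(x %||% NA_integer_)
  objects <- map(rec$objects, function(o) {
    tibble(object_id = as_int(o$object_id), name = o$names[[1]],
           synset = o$synsets[[1]], x = as_int(o$x), y = as_int(o$y),
           w = as_int(o$w), h = as_int(o$h),
           attributes = list(unlist(o$attributes) %||% character()))
  }) %>% bind_rows()
  if (nrow(objects) == 0L)
    objects <- tibble(object_id = integer(), name = character(), synset = character(),
                      x = integer(), y = integer(), w = integer(), h = integer(),
                      attributes = list())
  regions <- map(rec$regions, function(r) {
    tibble(region_id = as_int(r$region_id), x = as_int(r$x), y = as_int(r$y),
           w = as_int(r$w), h = as_int(r$h), phrase = r$phrase,
           object_ids = list(as.integer(unlist(r$object_ids))))
  }) %>% bind_rows()
  if (nrow(regions) == 0L)
    regions <- tibble(region_id = integer(), x = integer(), y = integer(),
                      w = integer(), h = integer(), phrase = character(),
                      object_ids = list())
  rels <- map(rec$relationships, function(r) {
    tibble(subject_idx = as_int(r$subject), predicate = r$predicate,
           object_idx = as_int(r$object))
  }) %>% bind_rows()
  if (nrow(rels) == 0L)
    rels <- tibble(subject_idx = integer(), predicate = character(), object_idx = integer())
  qa <- map(rec$qa, function(q) {
    tibble(qtype = q$qtype, scope = q$scope, question = q$question,
           answer = q$answer, region_ref = as_int(q$region_ref))
  }) %>% bind_rows()
  if (nrow(qa) == 0L)
    qa <- tibble(qtype = character(), scope = character(), question = character(),
                 answer = character(), region_ref = integer())
  headline <- NULL
  if (!is.null(rec$meta$headline))
    headline <- list(subject_idx = as_int(rec$meta$headline$subject_idx),
                     predicate = rec$meta$headline$predicate,
                     object_idx = as_int(rec$meta$headline$object_idx))
  image_annotation(rec$image_id, rec$width, rec$height, regions, objects, rels, qa,
                   behavior = rec$meta$behavior %||% NA_character_,
                   headline = headline)
}

#' Write an annotation bundle to JSON
#'
#' One JSON document per dataset, Visual-Genome field naming (objects with
#' `synsets`, relationships with `subject`/`predicate`/`object`). Output is
#' byte-deterministic for identical input.
#'
#' @param annotations List of `image_annotation` objects.
#' @param path Output file path.
#' @param species Species tag stored in the header.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, species = "bee") {
  for (ann in annotations) {
    check_annotation_structure(ann)  # refuses to write invalid structures
  }
  doc <- list(
    format = "nestsgg-annotations", version = "1.0", species = species,
    images = map(annotations, ~ list(image_id = .x$image_id, width = .x$width,
                                     height = .x$height)),
    annotations = map(annotations, ann_to_list)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read an annotation bundle from JSON
#'
#' Hard structural invariants (box bounds, phrase word counts, self-relations,
#' QA typing) are checked on load and raise an error naming the offending
#' image; full vocabulary conformance is checked separately with
#' [validate_annotation()]. Record order is preserved.
#'
#' @param path Path to a JSON file written by [write_annotations()].
#' @return List of `image_annotation` objects (with `species` attribute).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) abort(sprintf("parse error in %s: %s", path, conditionMessage(e))))
  if (!identical(doc$format, "nestsgg-annotations"))
    abort(sprintf("parse error in %s: not a nestsgg annotation bundle", path))
  anns <- map(doc$annotations, list_to_ann)
  attr(anns, "species") <- doc$species
  anns
}

#' Flatten annotations to a box table
#'
#' Convenience CSV-shaped view: one row per object instance.
#'
#' @param annotations List of `image_annotation` objects.
#' @return Tibble with image_id, object_id, name, synset, x, y, w, h.
#' @export
annotations_to_boxes <- function(annotations) {
  map(annotations, function(ann) {
    if (nrow(ann$objects) == 0L) return(NULL)
    ann$objects %>%
      select("object_id", "name", "synset", "x", "y", "w", "h") %>%
      mutate(image_id = ann$image_id, .before = 1L)
  }) %>% bind_rows()
}
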