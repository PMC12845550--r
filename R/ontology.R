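# Canonical vocabularies: object classes with synset identifiers, attribute
# facets, relation types, hypernym links and surface-name aliases. A small
# embedded synset table replaces a live WordNet query so that everything is
# deterministic and self-contained. Note that the sense numbering follows the
# field convention used for these datasets (bee.n.03 = generic bee, bee.n.01 =
# mellifera bee, with bee.n.01 a hypernym of bee.n.03), which is not identical
# to stock WordNet numbering.

#' Render a synset identifier
#'
#' Synsets are plain strings of the form `lemma.pos.sense` with the sense
#' zero-padded to two digits, e.g. `"bee.n.01"`.
#'
#' @param lemma Lowercase lemma.
#' @param pos Part-of-speech tag, one of `"n"`, `"v"`, `"a"`.
#' @param sense Positive integer sense number.
#' @return The rendered synset string.
#' @export
synset <- function(lemma, pos = "n", sense = 1L) {
  lemma <- tolower(trimws(lemma))
  if (!nzchar(lemma)) abort("synset lemma must be non-empty")
  if (!pos %in% c("n", "v", "a")) abort("synset pos must be one of n, v, a")
  sense <- as.integer(sense)
  if (is.na(sense) || sense < 1L) abort("synset sense must be a positive integer")
  sprintf("%s.%s.%02d", lemma, pos, sense)
}

#' Parse a synset identifier
#'
#' Inverse of [synset()]: `synset(parse_synset(s)$lemma, ...)` reproduces `s`.
#'
#' @param s A synset string such as `"bee.n.03"`.
#' @return A list with `lemma`, `pos`, `sense`.
#' @export
parse_synset <- function(s) {
  m <- regmatches(s, regexec("^([a-z_]+)\\.([nva])\\.([0-9]{2})$", s))[[1]]
  if (length(m) != 4L) abort(sprintf("not a synset identifier: '%s'", s))
  list(lemma = m[2], pos = m[3], sense = as.integer(m[4]))
}

norm_name <- function(x) gsub("[ _]+", " ", tolower(trimws(x)))

# Shared hypernym DAG over every synset either vocabulary uses. child -> parent.
hypernym_table <- function() {
  tribble_ <- function(...) {
    v <- c(...)
    tibble(child = v[seq(1, length(v), 2)], parent = v[seq(2, length(v), 2)])
  }
  tribble_(
    "bee.n.03", "bee.n.01",
    "bee.n.01", "insect.n.01",
    "ant.n.03", "ant.n.01",
    "ant.n.01", "insect.n.01",
    "intruder.n.01", "insect.n.01",
    "larva.n.01", "insect.n.01",
    "queen.n.01", "insect.n.01",
    "drone.n.01", "insect.n.01",
    "worker.n.01", "insect.n.01",
    "guard.n.01", "insect.n.01",
    "soldier.n.01", "insect.n.01",
    "insect.n.01", "entity.n.01",
    "access.n.01", "artifact.n.01",
    "platform.n.01", "artifact.n.01",
    "beehive.n.01", "artifact.n.01",
    "anthill.n.01", "artifact.n.01",
    "honeycomb.n.01", "artifact.n.01",
    "tunnel.n.01", "artifact.n.01",
    "trail.n.01", "artifact.n.01",
    "artifact.n.01", "entity.n.01",
    "pollen.n.01", "substance.n.01",
    "food.n.01", "substance.n.01",
    "honey.n.01", "substance.n.01",
    "substance.n.01", "entity.n.01",
    "flower.n.01", "plant.n.01",
    "seed.n.01", "plant.n.01",
    "leaf.n.01", "plant.n.01",
    "plant.n.01", "entity.n.01",
    "egg.n.01", "entity.n.01"
  )
}

bee_objects <- function() {
  tibble(
    name = c("bee", "mellifera_bee", "intruder", "access", "take_off_platform",
             "pollen", "food_source", "beehive", "flower", "queen", "drone",
             "worker", "guard", "larva", "honeycomb"),
    synset = c("bee.n.03", "bee.n.01", "intruder.n.01", "access.n.01",
               "platform.n.01", "pollen.n.01", "food.n.01", "beehive.n.01",
               "flower.n.01", "queen.n.01", "drone.n.01", "worker.n.01",
               "guard.n.01", "larva.n.01", "honeycomb.n.01")
  )
}

ant_objects <- function() {
  tibble(
    name = c("ant", "emmet", "intruder", "access", "anthill", "food", "seed",
             "leaf", "larva", "queen", "worker", "soldier", "egg", "trail",
             "tunnel"),
    synset = c("ant.n.03", "ant.n.01", "intruder.n.01", "access.n.01",
               "anthill.n.01", "food.n.01", "seed.n.01", "leaf.n.01",
               "larva.n.01", "queen.n.01", "worker.n.01", "soldier.n.01",
               "egg.n.01", "trail.n.01", "tunnel.n.01")
  )
}

# 15 relation types, shared by both species so predicate tables are comparable.
relation_types <- function() {
  c("greeting", "grouping", "carrying", "accessing", "leaving", "flying_over",
    "next_to", "loitering", "approaching", "guarding", "communicating",
    "crowding", "touching", "inspecting", "detaining")
}

attribute_facets <- function(species) {
  colors <- if (species == "bee") c("Yellow", "Black", "Grey") else c("Red", "Yellow", "Black")
  states <- if (species == "bee") c("Flying", "Accessing", "Leaving") else c("Walking", "Accessing", "Leaving")
  positions <- if (species == "bee") c("Raised wings", "Wings at rest", "Next to") else c("Raising antennas", "Detained and guarded", "Next to")
  tibble(
    facet = rep(c("Color", "State", "Position", "Access"), each = 3L),
    value = c(colors, states, positions, c("Free", "Occupied", "Tumult"))
  )
}

# Per-object attribute associations reproducing the published object/attribute
# tables (including entries, such as the intruder's Vigilant state, that sit
# outside the twelve counted facet values).
object_attribute_table <- function(species) {
  insect <- if (species == "bee") "bee" else "ant"
  facets <- attribute_facets(species)
  base <- facets %>%
    filter(.data$facet %in% c("Color", "State", "Position")) %>%
    mutate(object = insect, .before = 1L)
  intr <- tibble(
    object = "intruder",
    facet = c("Color", "State", "Position"),
    value = c("Grey", "Vigilant", "Raised wings")
  )
  occupant <- if (species == "bee") "bees" else "ants"
  acc <- tibble(
    object = "access",
    facet = rep(c("Access", "State", "Position"), times = c(3L, 3L, 1L)),
    value = c("Free", "Occupied", "Tumult",
              paste("Without", occupant), "Low population", "High population",
              "Vertical")
  )
  bind_rows(base, intr, acc)
}

alias_table <- function(species, objects) {
  al <- setNames(objects$synset, norm_name(objects$name))
  extra <- if (species == "bee") {
    c("bees" = "bee.n.03", "apis mellifera" = "bee.n.01",
      "mellifera bee" = "bee.n.01", "apis mellifera bee" = "bee.n.01",
      "beehive entrance" = "access.n.01", "entrance" = "access.n.01",
      "fly" = "intruder.n.01", "platform" = "platform.n.01")
  } else {
    c("ants" = "ant.n.03", "emmet ant" = "ant.n.01",
      "anthill entrance" = "access.n.01", "entrance" = "access.n.01",
      "fly" = "intruder.n.01")
  }
  c(al, extra)
}

#' Load the shipped vocabulary for a species
#'
#' Each vocabulary carries exactly 15 object classes (with synset identifiers),
#' 12 attribute values in four facets (Color, State, Position, Access), and 15
#' relation types, plus the hypernym links, per-object attribute associations
#' and the surface-name alias table used by [canonicalize()].
#'
#' @param species `"bee"` or `"ant"`.
#' @return An object of class `insect_vocabulary`.
#' @examples
#' v <- load_vocabulary("bee")
#' nrow(v$objects)      # 15
#' nrow(v$attributes)   # 12
#' length(v$relations)  # 15
#' @export
load_vocabulary <- function(species = c("bee", "ant")) {
  if (!is.character(species) || !species[1] %in% c("bee", "ant"))
    abort(sprintf("unknown species '%s' (expected \"bee\" or \"ant\")", species[1]))
  species <- species[1]
  objects <- if (species == "bee") bee_objects() else ant_objects()
  vocab <- structure(list(
    species = species,
    objects = objects,
    relations = relation_types(),
    attributes = attribute_facets(species),
    object_attributes = object_attribute_table(species),
    hypernyms = hypernym_table(),
    aliases = alias_table(species, objects)
  ), class = "insect_vocabulary")
  stopifnot(nrow(vocab$objects) == 15L, nrow(vocab$attributes) == 12L,
            length(vocab$relations) == 15L)
  vocab
}

#' @export
print.insect_vocabulary <- function(x, ...) {
  cat(sprintf("<insect_vocabulary: %s> %d object classes, %d attributes, %d relation types\n",
              x$species, nrow(x$objects), nrow(x$attributes), length(x$relations)))
  invisible(x)
}

#' Canonicalize a surface name to a synset identifier
#'
#' Case- and whitespace-insensitive lookup in the vocabulary alias table, e.g.
#' `"bee"` and `"BEE "` both map to `bee.n.03` and `"apis mellifera"` to
#' `bee.n.01`.
#'
#' @param name Surface name (non-empty string).
#' @param vocab An `insect_vocabulary`.
#' @return A synset identifier string.
#' @export
canonicalize <- function(name, vocab) {
  if (!is.character(name) || !nzchar(trimws(name[1]))) abort("name must be a non-empty string")
  key <- norm_name(name[1])
  hit <- vocab$aliases[key]
  if (is.na(hit)) {
    d <- utils::adist(key, names(vocab$aliases))
    near <- names(vocab$aliases)[order(d)][1:3]
    abort(sprintf("unknown name '%s'; nearest aliases: %s",
                  name[1], paste(near, collapse = ", ")))
  }
  unname(hit)
}

synset_ancestors <- function(s, hypernyms) {
  # distance-labelled ancestor set including the synset itself at distance 0
  out <- c(stats::setNames(0L, s))
  frontier <- s
  dist <- 0L
  while (length(frontier) > 0L) {
    dist <- dist + 1L
    parents <- unique(hypernyms$parent[hypernyms$child %in% frontier])
    parents <- setdiff(parents, names(out))
    if (length(parents) == 0L) break
    out <- c(out, stats::setNames(rep(dist, length(parents)), parents))
    frontier <- parents
  }
  out
}

#' Join two synsets at their nearest common ancestor
#'
#' Walks the vocabulary's hypernym links upward from both synsets and returns
#' the common ancestor minimizing the total hop count; `join_synsets(a, a)`
#' is `a`. Ties are broken by the smallest sense index, then lexicographically.
#' The canonical example: the generic `bee.n.03` and the mellifera `bee.n.01`
#' join to `bee.n.01`, its hypernym.
#'
#' @param a,b Synset identifiers present in the vocabulary's synset table.
#' @param vocab An `insect_vocabulary`.
#' @return The joined synset identifier.
#' @export
join_synsets <- function(a, b, vocab) {
  known <- unique(c(vocab$hypernyms$child, vocab$hypernyms$parent, vocab$objects$synset))
  for (s in c(a, b)) {
    parse_synset(s)
    if (!s %in% known) abort(sprintf("synset '%s' not in vocabulary", s))
  }
  if (identical(a, b)) return(a)
  aa <- synset_ancestors(a, vocab$hypernyms)
  bb <- synset_ancestors(b, vocab$hypernyms)
  common <- intersect(names(aa), names(bb))
  if (length(common) == 0L) abort(sprintf("no common ancestor of '%s' and '%s'", a, b))
  total <- aa[common] + bb[common]
  sense <- map_int(common, ~ parse_synset(.x)$sense)
  common[order(total, sense, common)][1]
}
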