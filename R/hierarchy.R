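#' The seven classification levels, root to leaf
#' @export
scop_levels <- function() {
  c("class", "fold", "superfamily", "family", "protein", "species", "domain")
}

level_codes <- c(class = "cl", fold = "cf", superfamily = "sf", family = "fa",
                 protein = "dm", species = "sp", domain = "px")

#' Build a classification hierarchy table
#'
#' One row per node of the seven-level hierarchy (class, fold,
#' superfamily, family, protein, species, domain). Every node carries a
#' stable integer `sunid`; domain leaves carry a 7-character `sid`;
#' family level and above carry the dotted concise classification
#' string `sccs` (e.g. "b.1.1.1"), which protein/species/domain nodes
#' inherit from their family.
#'
#' @param sunid integer ids, unique within a release.
#' @param level character, one of [scop_levels()].
#' @param sccs concise classification strings (NA where absent).
#' @param sid 7-char domain identifiers (NA except at domain level).
#' @param parent_sunid integer parent id; NA for root (class) nodes.
#' @param description free-text node description.
#' @return A `scop_hierarchy` data.frame.
#' @export
hierarchy_table <- function(sunid = integer(), level = character(),
                            sccs = character(), sid = character(),
                            parent_sunid = integer(),
                            description = character()) {
  h <- data.frame(sunid = as.integer(sunid),
                  level = as.character(level),
                  sccs = as.character(sccs),
                  sid = as.character(sid),
                  parent_sunid = as.integer(parent_sunid),
                  description = as.character(description),
                  stringsAsFactors = FALSE)
  class(h) <- c("scop_hierarchy", "data.frame")
  validate_hierarchy(h)
  h
}

validate_hierarchy <- function(h) {
  if (anyDuplicated(h$sunid)) {
    stop("duplicate sunid in hierarchy", call. = FALSE)
  }
  sids <- h$sid[!is.na(h$sid)]
  if (anyDuplicated(sids)) stop("duplicate sid in hierarchy", call. = FALSE)
  bad <- !h$level %in% scop_levels()
  if (any(bad)) {
    stop(sprintf("unknown hierarchy level '%s'", h$level[bad][1L]), call. = FALSE)
  }
  lv <- match(h$level, scop_levels())
  has_parent <- !is.na(h$parent_sunid)
  pi <- match(h$parent_sunid[has_parent], h$sunid)
  if (anyNA(pi)) {
    stop("parent_sunid references unknown node", call. = FALSE)
  }
  if (any(lv[has_parent] != lv[pi] + 1L)) {
    stop("child level must be exactly one step below its parent", call. = FALSE)
  }
  if (any(is.na(h$parent_sunid) & h$level != "class")) {
    stop("only class nodes may be roots", call. = FALSE)
  }
  invisible(h)
}

hier_row <- function(hierarchy, sunid) {
  i <- match(sunid, hierarchy$sunid)
  if (is.na(i)) stop(sprintf("unknown sunid %s", sunid), call. = FALSE)
  i
}

#' Ancestor of a node at a given level
#'
#' Walks parent links from `sunid` upward. If the node itself is at the
#' requested level it is returned; if the node lies above the requested
#' level, `NA` is returned.
#'
#' @param hierarchy a `scop_hierarchy` data.frame.
#' @param sunid node id (must exist).
#' @param level target level, one of [scop_levels()].
#' @return The ancestor's sunid, or `NA_integer_`.
#' @export
get_ancestor <- function(hierarchy, sunid, level) {
  stopifnot(level %in% scop_levels())
  target <- match(level, scop_levels())
  i <- hier_row(hierarchy, sunid)
  repeat {
    cur <- match(hierarchy$level[i], scop_levels())
    if (cur == target) return(hierarchy$sunid[i])
    if (cur < target) return(NA_integer_)
    p <- hierarchy$parent_sunid[i]
    if (is.na(p)) return(NA_integer_)
    i <- hier_row(hierarchy, p)
  }
}

#' Class letter of a node's sccs lineage
#'
#' The sccs class letter (e.g. "b" of "b.1.1.1") determines whether a
#' domain sits in one of the seven true structural classes (letters
#' a-g); letters beyond g mark entries such as ribosomal RNA-protein
#' complexes or synthetic constructs, which the confidence gate excludes.
#'
#' @param hierarchy a `scop_hierarchy` data.frame.
#' @param sunid node id.
#' @return Single lowercase letter, or `NA_character_` if unresolvable.
#' @export
sccs_class_letter <- function(hierarchy, sunid) {
  cl <- get_ancestor(hierarchy, sunid, "class")
  if (is.na(cl)) return(NA_character_)
  s <- hierarchy$sccs[hier_row(hierarchy, cl)]
  if (is.na(s)) return(NA_character_)
  substr(s, 1L, 1L)
}

#' Is a node inside the seven true classes (sccs letters a-g)?
#' @inheritParams sccs_class_letter
#' @return Logical.
#' @export
is_true_class <- function(hierarchy, sunid) {
  letter <- sccs_class_letter(hierarchy, sunid)
  !is.na(letter) && letter >= "a" && letter <= "g"
}

#' Children of a node
#' @param hierarchy a `scop_hierarchy` data.frame.
#' @param sunid parent id.
#' @return Integer vector of child sunids (sorted).
#' @export
hierarchy_children <- function(hierarchy, sunid) {
  sort(hierarchy$sunid[!is.na(hierarchy$parent_sunid) &
                         hierarchy$parent_sunid == sunid])
}
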