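new_prediction <- function(chain, hit, ranges) {
  structure(list(pdb_id = chain$pdb_id, chain_id = chain$chain_id,
                 ranges = ranges, target_sid = hit$target_sid,
                 hit = hit,
                 superfamily_sunid = NA_integer_, family_sunid = NA_integer_,
                 protein_sunid = NA_integer_, species_sunid = NA_integer_,
                 placement_mode = NA_character_),
            class = "domain_prediction")
}

#' @export
print.domain_prediction <- function(x, ...) {
  cat(sprintf("<prediction %s%s %s from %s (E=%.2g, %.1f%% id, %s)>\n",
              x$pdb_id, x$chain_id, format_ranges(x$ranges), x$target_sid,
              x$hit$e_value, x$hit$pct_id,
              ifelse(is.na(x$placement_mode), "unplaced", x$placement_mode)))
  invisible(x)
}

#' Assign domain boundaries from the top-ranked hit group
#'
#' One predicted domain per hit. Each boundary starts from the hit's
#' query range; if the nearest chain terminus or ATOM-record gap edge
#' lies within `params$extension_limit` residues beyond it, the
#' boundary is extended there (classifying every observed residue while
#' making it unlikely the extension crosses into another domain); the
#' result is then clipped to observed residues. A short unassigned
#' observed linker (at most `extension_limit` residues) strictly
#' between two predictions is appended to the preceding domain, up to
#' one residue before the following domain. Predictions are returned
#' sorted by start and non-overlapping.
#'
#' @param top_group a `hit_group` from [group_and_rank()] (non-empty).
#' @param chain the query [chain_record()].
#' @param params [default_params()].
#' @return List of `domain_prediction` objects.
#' @export
assign_domains <- function(top_group, chain, params = default_params()) {
  hits <- top_group$hits
  if (is.null(hits) || nrow(hits) == 0L) {
    stop("empty hit group", call. = FALSE)
  }
  if (any(hits$q_end > nchar(chain$seqres)) || any(hits$q_start < 1L)) {
    stop("hit lies outside the query SEQRES", call. = FALSE)
  }
  obs <- chain$observed_ranges
  hits <- hits[order(hits$q_start, hits$q_end), , drop = FALSE]
  lim <- params$extension_limit

  preds <- list()
  for (k in seq_len(nrow(hits))) {
    s <- hits$q_start[k]
    e <- hits$q_end[k]
    left_edges <- obs$start[obs$start <= s]
    if (length(left_edges) > 0L) {
      cand <- max(left_edges)
      if (s - cand <= lim) s <- cand
    }
    right_edges <- obs$end[obs$end >= e]
    if (length(right_edges) > 0L) {
      cand <- min(right_edges)
      if (cand - e <= lim) e <- cand
    }
    ranges <- intersect_ranges(residue_ranges(s, e), obs)
    if (range_union_size(ranges) == 0L) next
    preds[[length(preds) + 1L]] <- new_prediction(chain, hits[k, ], ranges)
  }
  if (length(preds) == 0L) return(preds)

  # resolve overlaps deterministically: later prediction yields
  preds <- preds[order(vapply(preds, function(p) p$ranges$start[1L], 1L))]
  kept <- list(preds[[1L]])
  for (p in preds[-1L]) {
    prev_end <- max(kept[[length(kept)]]$ranges$end)
    trimmed <- indices_to_ranges(range_indices(p$ranges)[
      range_indices(p$ranges) > prev_end])
    if (range_union_size(trimmed) == 0L) next
    p$ranges <- trimmed
    kept[[length(kept) + 1L]] <- p
  }
  preds <- kept

  # interior linkers: short observed gaps between adjacent predictions
  # join the preceding domain
  if (length(preds) > 1L) {
    for (k in seq_len(length(preds) - 1L)) {
      a <- max(preds[[k]]$ranges$end)
      b <- preds[[k + 1L]]$ranges$start[1L]
      if (b - a <= 1L) next
      linker <- intersect_ranges(residue_ranges(a + 1L, b - 1L), obs)
      n_link <- range_union_size(linker)
      if (n_link > 0L && n_link <= lim) {
        widened <- rbind(preds[[k]]$ranges, residue_ranges(a, b - 1L))
        preds[[k]]$ranges <- intersect_ranges(widened, obs)
      }
    }
  }
  preds
}

domain_is_whole_chain <- function(domain, chains) {
  if (domain$is_genetic) return(FALSE)
  ck <- chain_key(domain$pdb_id, domain$segments$chain_id[1L])
  if (!ck %in% names(chains)) return(FALSE)
  len <- nchar(chains[[ck]]$seqres)
  r <- normalize_ranges(domain_ranges(domain))
  nrow(r) == 1L && r$start == 1L && r$end == len
}

#' High-confidence gate for a chain's predictions
#'
#' Applies the acceptance criteria as independent predicates and
#' collects every violated one as a reason code; a chain is accepted
#' iff no code fires. Codes: `LOW_RESOLUTION` (resolution at or above
#' the cutoff, 3 Angstroms by default — inclusive), `RIBOSOMAL_OR_SYNTHETIC`
#' (top-group targets classified outside the seven true classes, or
#' entry description matching the exclusion keywords),
#' `GENETIC_DOMAIN_HOMOLOG` (any filtered hit targets a multi-chain
#' domain), `TARGET_NOT_WHOLE_CHAIN` (a single-domain prediction whose
#' target domain does not comprise its entire chain),
#' `MULTIDOMAIN_SHAPE` (multi-domain chains must have 100% SEQRES
#' identity with the target chain, or exactly two single-segment
#' domains), `UNASSIGNED_REGION` (an observed region longer than
#' `unassigned_limit` in no domain), `DUPLICATE_TARGET_DOMAIN` (two
#' predictions sharing one target domain), `NO_HITS`.
#'
#' @param predictions list from [assign_domains()] (possibly empty).
#' @param chain the query [chain_record()] (carries resolution and
#'   description metadata).
#' @param top_group the top-ranked `hit_group`, or `NULL`.
#' @param domain_db a [build_domain_db()] database.
#' @param params [default_params()].
#' @param all_hits all filtered hits for the chain across groups
#'   (defaults to the top group's hits); needed to detect homology to
#'   genetic domains, which are never grouped.
#' @return A `confidence_verdict`: `chain_key`, `accepted`,
#'   `reason_codes`.
#' @export
gate_confidence <- function(predictions, chain, top_group, domain_db,
                            params = default_params(), all_hits = NULL) {
  if (is.null(all_hits)) {
    all_hits <- if (is.null(top_group)) empty_hits() else top_group$hits
  }
  idx <- domain_db$index
  codes <- character()

  if (!is.na(chain$resolution) &&
      chain$resolution >= params$resolution_cutoff) {
    codes <- c(codes, "LOW_RESOLUTION")
  }

  outside <- FALSE
  if (!is.null(top_group) && nrow(top_group$hits) > 0L) {
    sccs <- idx$sccs[match(top_group$hits$target_sid, idx$sid)]
    letters1 <- substr(sccs, 1L, 1L)
    outside <- any(!is.na(letters1) & letters1 > "g")
  }
  kw <- any(vapply(params$exclusion_keywords, function(k) {
    grepl(k, chain$description, ignore.case = TRUE, fixed = FALSE)
  }, TRUE))
  if (outside || kw) codes <- c(codes, "RIBOSOMAL_OR_SYNTHETIC")

  if (nrow(all_hits) > 0L &&
      any(idx$is_genetic[match(all_hits$target_sid, idx$sid)])) {
    codes <- c(codes, "GENETIC_DOMAIN_HOMOLOG")
  }

  if (length(predictions) == 0L) {
    codes <- c(codes, "NO_HITS")
  } else if (length(predictions) == 1L) {
    target <- domain_db_domain(domain_db, predictions[[1L]]$target_sid)
    if (!domain_is_whole_chain(target, domain_db$chains)) {
      codes <- c(codes, "TARGET_NOT_WHOLE_CHAIN")
    }
  } else {
    tkey <- chain_key(top_group$pdb_id, top_group$chain_id)
    tchain <- domain_db$chains[[tkey]]
    identical_seq <- !is.null(tchain) &&
      identical(chain$seqres, tchain$seqres)
    two_contig <- length(predictions) == 2L &&
      all(vapply(predictions, function(p) nrow(p$ranges) == 1L, TRUE))
    if (!identical_seq && !two_contig) {
      codes <- c(codes, "MULTIDOMAIN_SHAPE")
    }
  }

  if (length(predictions) > 0L) {
    assigned <- do.call(rbind, lapply(predictions, `[[`, "ranges"))
    un <- setdiff_ranges(chain$observed_ranges, assigned)
    if (nrow(un) > 0L &&
        any(un$end - un$start + 1L > params$unassigned_limit)) {
      codes <- c(codes, "UNASSIGNED_REGION")
    }
    sids <- vapply(predictions, `[[`, "", "target_sid")
    if (anyDuplicated(sids)) codes <- c(codes, "DUPLICATE_TARGET_DOMAIN")
  }

  structure(list(chain_key = chain_key(chain$pdb_id, chain$chain_id),
                 accepted = length(codes) == 0L,
                 reason_codes = sort(unique(codes))),
            class = "confidence_verdict")
}

#' @export
print.confidence_verdict <- function(x, ...) {
  cat(sprintf("<verdict %s> %s%s\n", x$chain_key,
              if (x$accepted) "high confidence" else "rejected",
              if (length(x$reason_codes) > 0L)
                paste0(" [", paste(x$reason_codes, collapse = ","), "]")
              else ""))
  invisible(x)
}

domain_db_domain <- function(domain_db, sid) {
  d <- domain_db$domains[[sid]]
  if (is.null(d)) stop(sprintf("unknown target domain '%s'", sid), call. = FALSE)
  d
}

next_sunid <- function(hierarchy) max(hierarchy$sunid) + 1L

find_am_child <- function(hierarchy, parent_sunid, level) {
  kids <- hierarchy_children(hierarchy, parent_sunid)
  for (k in kids) {
    i <- hier_row(hierarchy, k)
    if (hierarchy$level[i] == level &&
        hierarchy$description[i] == "automated matches") {
      return(k)
    }
  }
  NA_integer_
}

ensure_am_node <- function(hierarchy, parent_sunid, level) {
  existing <- find_am_child(hierarchy, parent_sunid, level)
  if (!is.na(existing)) return(list(sunid = existing, hierarchy = hierarchy))
  pi <- hier_row(hierarchy, parent_sunid)
  sccs <- if (level == "family") {
    sibs <- hierarchy_children(hierarchy, parent_sunid)
    nums <- suppressWarnings(as.integer(sub(".*\\.", "", hierarchy$sccs[
      match(sibs, hierarchy$sunid)])))
    sprintf("%s.%d", hierarchy$sccs[pi],
            max(c(0L, nums[!is.na(nums)])) + 1L)
  } else {
    hierarchy$sccs[pi]
  }
  sunid <- next_sunid(hierarchy)
  row <- data.frame(sunid = sunid, level = level, sccs = sccs,
                    sid = NA_character_, parent_sunid = parent_sunid,
                    description = "automated matches",
                    stringsAsFactors = FALSE)
  h2 <- rbind(as.data.frame(hierarchy), row)
  class(h2) <- class(hierarchy)
  list(sunid = sunid, hierarchy = h2)
}

#' Place an accepted prediction in the hierarchy
#'
#' The superfamily is always inherited from the target domain. Below
#' it, heuristic thresholds decide how deep the inheritance reliably
#' goes: species requires 100% identity over the full target; protein
#' requires at least `params$protein_identity` percent identity with
#' full target coverage; family at least `params$family_identity`.
#' At the first unreliable level an "automated matches" node is reused
#' or created under the last reliable one, and `placement_mode` is set
#' to `"automated_matches"` (otherwise `"matched"`).
#'
#' @param prediction a `domain_prediction`.
#' @param hierarchy a `scop_hierarchy` (will gain fallback nodes as
#'   needed; the updated table is returned).
#' @param domain_db a [build_domain_db()] database.
#' @param params [default_params()].
#' @return List with elements `prediction` (placement filled) and
#'   `hierarchy` (possibly augmented).
#' @export
place_in_hierarchy <- function(prediction, hierarchy, domain_db,
                               params = default_params()) {
  i <- match(prediction$target_sid, domain_db$index$sid)
  if (is.na(i)) stop("unknown target domain", call. = FALSE)
  tsunid <- domain_db$index$sunid[i]
  if (!tsunid %in% hierarchy$sunid) {
    stop(sprintf("target domain %s (sunid %d) is not placed in the hierarchy",
                 prediction$target_sid, tsunid), call. = FALSE)
  }
  sf <- get_ancestor(hierarchy, tsunid, "superfamily")
  fa <- get_ancestor(hierarchy, tsunid, "family")
  dm <- get_ancestor(hierarchy, tsunid, "protein")
  sp <- get_ancestor(hierarchy, tsunid, "species")
  if (is.na(sf)) stop("target domain has no superfamily ancestor", call. = FALSE)

  full_cov <- prediction$hit$t_start == 1L &&
    prediction$hit$t_end == domain_db$index$length[i]
  pid_ok <- function(th) prediction$hit$pct_id >= th - 1e-9

  prediction$superfamily_sunid <- sf
  if (full_cov && pid_ok(100)) {
    prediction$family_sunid <- fa
    prediction$protein_sunid <- dm
    prediction$species_sunid <- sp
    prediction$placement_mode <- "matched"
    return(list(prediction = prediction, hierarchy = hierarchy))
  }
  prediction$placement_mode <- "automated_matches"
  if (full_cov && pid_ok(params$protein_identity)) {
    prediction$family_sunid <- fa
    prediction$protein_sunid <- dm
    am <- ensure_am_node(hierarchy, dm, "species")
  } else if (pid_ok(params$family_identity)) {
    prediction$family_sunid <- fa
    am <- ensure_am_node(hierarchy, fa, "protein")
    prediction$protein_sunid <- am$sunid
    am <- ensure_am_node(am$hierarchy, am$sunid, "species")
  } else {
    am <- ensure_am_node(hierarchy, sf, "family")
    prediction$family_sunid <- am$sunid
    am <- ensure_am_node(am$hierarchy, am$sunid, "protein")
    prediction$protein_sunid <- am$sunid
    am <- ensure_am_node(am$hierarchy, am$sunid, "species")
  }
  prediction$species_sunid <- am$sunid
  list(prediction = prediction, hierarchy = am$hierarchy)
}

#' Classify one chain end to end
#'
#' Composition of [search_hits()], [filter_hits()], [group_and_rank()],
#' [assign_domains()] on the top group, [gate_confidence()] and — for
#' accepted chains — [place_in_hierarchy()]. Deterministic for fixed
#' inputs and parameters.
#'
#' @param chain a [chain_record()] (query).
#' @param domain_db a [build_domain_db()] database.
#' @param hierarchy classification hierarchy (defaults to the one
#'   captured in `domain_db`).
#' @param params [default_params()].
#' @return List: `predictions` (placed if accepted), `verdict`
#'   (`confidence_verdict`), `hierarchy` (with any fallback nodes).
#' @export
classify_chain <- function(chain, domain_db, hierarchy = domain_db$hierarchy,
                           params = default_params()) {
  raw <- search_hits(chain$seqres, domain_db)
  hits <- filter_hits(raw, domain_db, params)
  groups <- group_and_rank(hits, domain_db)
  top <- if (length(groups) > 0L) groups[[1L]] else NULL
  preds <- if (is.null(top)) list() else assign_domains(top, chain, params)
  # genetic-domain homology is judged on significance alone: a single
  # chain can never cover most of a multi-chain domain, so the coverage
  # filter would mask exactly the hits this exclusion exists for
  sig <- raw[raw$e_value <= params$e_max, , drop = FALSE]
  verdict <- gate_confidence(preds, chain, top, domain_db, params,
                             all_hits = sig)
  if (verdict$accepted) {
    for (k in seq_along(preds)) {
      placed <- place_in_hierarchy(preds[[k]], hierarchy, domain_db, params)
      preds[[k]] <- placed$prediction
      hierarchy <- placed$hierarchy
    }
  }
  list(predictions = preds, verdict = verdict, hierarchy = hierarchy)
}

#' Tabular dump of predictions and verdict for one chain
#'
#' @param predictions list of `domain_prediction`s (possibly empty).
#' @param verdict the chain's `confidence_verdict`.
#' @return data.frame, one row per prediction (or a single hit-less row
#'   for rejected chains without predictions).
#' @export
prediction_dump <- function(predictions, verdict) {
  codes <- paste(verdict$reason_codes, collapse = ",")
  if (length(predictions) == 0L) {
    return(data.frame(chain = verdict$chain_key, ranges = "",
                      target_sid = "", e_value = NA_real_,
                      superfamily_sunid = NA_integer_,
                      family_sunid = NA_integer_,
                      protein_sunid = NA_integer_,
                      species_sunid = NA_integer_,
                      placement_mode = "", accepted = verdict$accepted,
                      reason_codes = codes, stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(predictions, function(p) {
    data.frame(chain = verdict$chain_key, ranges = format_ranges(p$ranges),
               target_sid = p$target_sid, e_value = p$hit$e_value,
               superfamily_sunid = p$superfamily_sunid,
               family_sunid = p$family_sunid,
               protein_sunid = p$protein_sunid,
               species_sunid = p$species_sunid,
               placement_mode = ifelse(is.na(p$placement_mode), "",
                                       p$placement_mode),
               accepted = verdict$accepted, reason_codes = codes,
               stringsAsFactors = FALSE)
  }))
}
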