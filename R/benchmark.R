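#' Pair predicted and curated domains by maximal residue overlap
#'
#' Greedy matching: the (predicted, curated) pair sharing the most
#' residues is paired first, both are removed, and the process repeats
#' while any overlap remains. Ties break toward the earlier-starting
#' prediction, then the earlier-starting curated domain, so pairing is
#' deterministic. Entries left over on either side are unmatched.
#'
#' @param predicted,curated lists of objects carrying a `ranges`
#'   element (`residue_ranges`), sorted by start.
#' @return List with `pairs` (list of `list(pred=, cur=)`),
#'   `unmatched_pred`, `unmatched_cur`.
#' @export
pair_domains <- function(predicted, curated) {
  np <- length(predicted)
  nc <- length(curated)
  if (np == 0L || nc == 0L) {
    return(list(pairs = list(), unmatched_pred = predicted,
                unmatched_cur = curated))
  }
  ov <- matrix(0L, np, nc)
  for (i in seq_len(np)) {
    for (j in seq_len(nc)) {
      ov[i, j] <- range_union_size(
        intersect_ranges(predicted[[i]]$ranges, curated[[j]]$ranges))
    }
  }
  pairs <- list()
  used_p <- used_c <- logical(0)
  taken_p <- rep(FALSE, np)
  taken_c <- rep(FALSE, nc)
  repeat {
    ov2 <- ov
    ov2[taken_p, ] <- -1L
    ov2[, taken_c] <- -1L
    if (max(ov2) <= 0L) break
    w <- which(ov2 == max(ov2), arr.ind = TRUE)
    w <- w[order(w[, 1L], w[, 2L]), , drop = FALSE]
    i <- w[1L, 1L]; j <- w[1L, 2L]
    pairs[[length(pairs) + 1L]] <- list(pred = predicted[[i]],
                                        cur = curated[[j]])
    taken_p[i] <- TRUE
    taken_c[j] <- TRUE
  }
  list(pairs = pairs,
       unmatched_pred = predicted[!taken_p],
       unmatched_cur = curated[!taken_c])
}

#' Compare one predicted domain with one curated domain
#'
#' A prediction is correct when it is placed in the same superfamily as
#' the curated domain and every paired segment boundary (start to
#' start, end to end, segments matched in order) deviates by at most
#' `tolerance` residues. Unequal segment counts are a boundary
#' mismatch with an infinite deviation sentinel.
#'
#' @param pred object with `ranges` and `superfamily_sunid`.
#' @param cur object with `ranges` and either `superfamily_sunid` or a
#'   domain `sunid` resolvable through `hierarchy`.
#' @param hierarchy `scop_hierarchy` used to resolve the curated
#'   domain's superfamily when only its sunid is known.
#' @param tolerance residues (default 10).
#' @return A one-row `benchmark_record` data.frame: `chain`,
#'   `predicted`, `curated`, `superfamily_match`, `max_boundary_dev`,
#'   `verdict` in correct/boundary_mismatch/superfamily_mismatch.
#' @export
compare_domains <- function(pred, cur, hierarchy, tolerance = 10L) {
  cur_sf <- cur$superfamily_sunid
  if (is.null(cur_sf) || is.na(cur_sf)) {
    cur_sf <- get_ancestor(hierarchy, cur$sunid, "superfamily")
  }
  sf_match <- !is.na(pred$superfamily_sunid) && !is.na(cur_sf) &&
    pred$superfamily_sunid == cur_sf
  pr <- normalize_ranges(pred$ranges)
  cr <- normalize_ranges(cur$ranges)
  if (nrow(pr) != nrow(cr)) {
    dev <- Inf
  } else {
    dev <- as.numeric(max(abs(pr$start - cr$start), abs(pr$end - cr$end)))
  }
  verdict <- if (!sf_match) {
    "superfamily_mismatch"
  } else if (dev <= tolerance) {
    "correct"
  } else {
    "boundary_mismatch"
  }
  data.frame(chain = chain_key(pred$pdb_id %||% "", pred$chain_id %||% ""),
             predicted = format_ranges(pr), curated = format_ranges(cr),
             superfamily_match = sf_match, max_boundary_dev = dev,
             verdict = verdict, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unmatched_record <- function(chain, predicted, curated) {
  data.frame(chain = chain, predicted = predicted, curated = curated,
             superfamily_match = FALSE, max_boundary_dev = Inf,
             verdict = "unmatched", stringsAsFactors = FALSE)
}

#' Format an error rate the way release notes print it
#'
#' Rates of 1% or more are shown with one decimal; rates below 1% with
#' one significant figure (so 62/80140 prints "0.08%" and 231/30660
#' prints "0.8%").
#'
#' @param n_errors,n_total integer counts.
#' @return Character scalar like `"0.08%"`, or `NA` when `n_total` is 0.
#' @export
format_error_rate <- function(n_errors, n_total) {
  if (n_total == 0L) return(NA_character_)
  pct <- 100 * n_errors / n_total
  if (pct >= 1) {
    sprintf("%.1f%%", pct)
  } else {
    paste0(format(signif(pct, 1L), scientific = FALSE, trim = TRUE), "%")
  }
}

#' Summarize a benchmark run
#'
#' @param records `benchmark_record` data.frame (rbind of
#'   [compare_domains()] rows and unmatched records).
#' @param attempted_chains character vector of chain keys the run
#'   attempted to classify.
#' @param classified_chains character vector of chain keys whose
#'   predictions passed the high-confidence gate.
#' @return A `benchmark_summary` list: domain counts, chain counts,
#'   `percent_classifiable`, numeric `error_rate_percent` and its
#'   printed form `error_rate_label` (`NA` when no domains were
#'   predicted).
#' @export
summarize_benchmark <- function(records, attempted_chains,
                                classified_chains = unique(records$chain)) {
  n_predicted <- sum(nzchar(records$predicted))
  n_correct <- sum(records$verdict == "correct")
  n_boundary <- sum(records$verdict == "boundary_mismatch" |
                      (records$verdict == "unmatched" &
                         nzchar(records$predicted)))
  n_att <- length(unique(attempted_chains))
  n_cls <- length(unique(classified_chains))
  structure(list(
    n_predicted = n_predicted,
    n_correct = n_correct,
    n_boundary_mismatch = n_boundary,
    n_chains_attempted = n_att,
    n_chains_classifiable = n_cls,
    percent_classifiable = if (n_att == 0L) NA_real_ else 100 * n_cls / n_att,
    error_rate_percent = if (n_predicted == 0L) NA_real_ else
      100 * n_boundary / n_predicted,
    error_rate_label = format_error_rate(n_boundary, n_predicted)),
    class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat(sprintf(paste0("<benchmark> %d/%d chains classifiable (%s); ",
                     "%d domains predicted, %d correct, error rate %s\n"),
              x$n_chains_classifiable, x$n_chains_attempted,
              ifelse(is.na(x$percent_classifiable), "NA",
                     sprintf("%.0f%%", x$percent_classifiable)),
              x$n_predicted, x$n_correct,
              ifelse(is.na(x$error_rate_label), "NA", x$error_rate_label)))
  invisible(x)
}

curated_domains_for_chain <- function(bundle, pdb_id, chain_id) {
  out <- list()
  for (d in bundle$domains) {
    if (d$is_genetic) next
    if (d$pdb_id == pdb_id && d$segments$chain_id[1L] == chain_id) {
      out[[length(out) + 1L]] <-
        list(sid = d$sid, sunid = d$sunid, pdb_id = pdb_id,
             chain_id = chain_id, ranges = domain_ranges(d))
    }
  }
  if (length(out) > 1L) {
    out <- out[order(vapply(out, function(d) d$ranges$start[1L], 1L))]
  }
  out
}

#' Benchmark a release pair
#'
#' Every chain present only in `new_release` is classified against
#' `old_release`'s domain database; high-confidence predictions are
#' scored against the curated domains of `new_release` (which shares
#' the stable identifier space).
#'
#' @param old_release,new_release [release_bundle()]s.
#' @param params [default_params()].
#' @return List: `records` (`benchmark_record` data.frame), `summary`
#'   ([summarize_benchmark()] result). Warns (and returns an empty run)
#'   when no new chains exist.
#' @export
benchmark_release_pair <- function(old_release, new_release,
                                   params = default_params()) {
  db <- build_domain_db(old_release)
  new_keys <- setdiff(names(new_release$chains), names(old_release$chains))
  if (length(new_keys) == 0L) {
    warning("no chains are unique to the new release; empty benchmark run")
  }
  records <- list()
  classified <- character()
  for (key in new_keys) {
    chain <- new_release$chains[[key]]
    res <- classify_chain(chain, db, params = params)
    if (!res$verdict$accepted || length(res$predictions) == 0L) next
    classified <- c(classified, key)
    curated <- curated_domains_for_chain(new_release, chain$pdb_id,
                                         chain$chain_id)
    paired <- pair_domains(res$predictions, curated)
    for (pr in paired$pairs) {
      records[[length(records) + 1L]] <-
        compare_domains(pr$pred, pr$cur, new_release$hierarchy,
                        params$benchmark_tolerance)
    }
    for (p in paired$unmatched_pred) {
      records[[length(records) + 1L]] <-
        unmatched_record(key, format_ranges(p$ranges), "")
    }
    for (cu in paired$unmatched_cur) {
      records[[length(records) + 1L]] <-
        unmatched_record(key, "", format_ranges(cu$ranges))
    }
  }
  records <- if (length(records) == 0L) {
    unmatched_record("x", "", "")[0L, ]
  } else {
    do.call(rbind, records)
  }
  list(records = records,
       summary = summarize_benchmark(records, new_keys, classified))
}

#' Change history between two releases
#'
#' Per-sunid comparison of two bundles: nodes present only in one are
#' `added`/`removed`; nodes whose parent changed are `moved`; domain
#' leaves whose region changed are `re-bounded`.
#'
#' @param a,b [release_bundle()]s sharing identifier space.
#' @return data.frame: `sunid`, `sid`, `change`, `old`, `new` (one row
#'   per changed node; zero rows for identical bundles).
#' @export
diff_releases <- function(a, b) {
  ha <- a$hierarchy
  hb <- b$hierarchy
  rows <- list()
  add_row <- function(sunid, sid, change, old, new) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sunid = sunid, sid = ifelse(is.na(sid), "-", sid), change = change,
      old = old, new = new, stringsAsFactors = FALSE)
  }
  for (s in setdiff(hb$sunid, ha$sunid)) {
    i <- match(s, hb$sunid)
    add_row(s, hb$sid[i], "added", "-", hb$description[i])
  }
  for (s in setdiff(ha$sunid, hb$sunid)) {
    i <- match(s, ha$sunid)
    add_row(s, ha$sid[i], "removed", ha$description[i], "-")
  }
  for (s in intersect(ha$sunid, hb$sunid)) {
    i <- match(s, ha$sunid)
    j <- match(s, hb$sunid)
    pa <- ha$parent_sunid[i]
    pb <- hb$parent_sunid[j]
    if (!identical(is.na(pa), is.na(pb)) ||
        (!is.na(pa) && pa != pb)) {
      add_row(s, ha$sid[i], "moved", as.character(pa), as.character(pb))
    }
    if (!is.na(ha$sid[i]) && ha$sid[i] %in% names(a$domains) &&
        ha$sid[i] %in% names(b$domains)) {
      ra <- region_string(a$domains[[ha$sid[i]]], a$chains)
      rb <- region_string(b$domains[[ha$sid[i]]], b$chains)
      if (!identical(ra, rb)) add_row(s, ha$sid[i], "re-bounded", ra, rb)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(sunid = integer(), sid = character(),
                      change = character(), old = character(),
                      new = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$sunid, out$change), , drop = FALSE]
}
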