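#' @importFrom Biostrings pairwiseAlignment pid score
NULL

# Gapped Karlin-Altschul parameters for BLOSUM62 with gap open 11 /
# extend 1 (the standard protein-search setting). E = K * m * n * exp(-lambda*S)
# with m the query length and n the total residue count of the database.
KA_LAMBDA <- 0.267
KA_K <- 0.041

aa_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' Build an in-memory domain sequence database
#'
#' Indexes every classified domain's SEQRES-based sequence for local
#' alignment. Multi-segment domains are indexed as their concatenated
#' sequence; hit target coordinates refer to that concatenation.
#' Genetic (multi-chain) domains are indexed and flagged — hits against
#' them never seed predictions, but the confidence gate uses them to
#' detect homology to genetic domains.
#'
#' @param bundle a [release_bundle()].
#' @return A `domain_db` list: `index` data.frame (sid, sunid, pdb_id,
#'   chain_id, length, sccs, is_genetic), `seqs` named character vector,
#'   `total_residues` database size for E-value scaling, and the source
#'   `chains`/`hierarchy` for gate checks.
#' @export
build_domain_db <- function(bundle) {
  doms <- bundle$domains[order(names(bundle$domains))]
  h <- bundle$hierarchy
  idx <- data.frame(
    sid = vapply(doms, `[[`, "", "sid"),
    sunid = vapply(doms, `[[`, 1L, "sunid"),
    pdb_id = vapply(doms, `[[`, "", "pdb_id"),
    chain_id = vapply(doms, function(d) {
      if (d$is_genetic) NA_character_ else d$segments$chain_id[1L]
    }, ""),
    length = vapply(doms, function(d) nchar(d$sequence), 1L),
    sccs = h$sccs[match(vapply(doms, `[[`, 1L, "sunid"), h$sunid)],
    is_genetic = vapply(doms, `[[`, TRUE, "is_genetic"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(index = idx,
                 domains = doms,
                 seqs = stats::setNames(vapply(doms, `[[`, "", "sequence"),
                                        idx$sid),
                 total_residues = sum(idx$length),
                 chains = bundle$chains,
                 hierarchy = h),
            class = "domain_db")
}

#' @export
print.domain_db <- function(x, ...) {
  cat(sprintf("<domain db> %d domains (%d genetic), %d residues\n",
              nrow(x$index), sum(x$index$is_genetic), x$total_residues))
  invisible(x)
}

karlin_altschul_evalue <- function(score, query_len, db_residues) {
  KA_K * query_len * db_residues * exp(-KA_LAMBDA * score)
}

empty_hits <- function() {
  data.frame(target_sid = character(), q_start = integer(), q_end = integer(),
             t_start = integer(), t_end = integer(), score = numeric(),
             e_value = numeric(), pct_id = numeric(),
             stringsAsFactors = FALSE)
}

# Best local alignment of a query window against one target; recurses
# into the unaligned query flanks so repeated matches of the same
# domain (e.g. tandem duplications) are also reported.
align_one <- function(query, offset, target_seq, sid, query_len, db_residues,
                      e_report, depth) {
  if (nchar(query) < 15L || depth > 4L) return(empty_hits())
  pa <- Biostrings::pairwiseAlignment(
    query, target_seq, type = "local", substitutionMatrix = aa_matrix(),
    gapOpening = 11, gapExtension = 1)
  s <- Biostrings::score(pa)
  ev <- karlin_altschul_evalue(s, query_len, db_residues)
  if (!is.finite(s) || ev > e_report) return(empty_hits())
  qs <- Biostrings::start(Biostrings::pattern(pa))
  qe <- Biostrings::end(Biostrings::pattern(pa))
  hit <- data.frame(target_sid = sid, q_start = offset + qs,
                    q_end = offset + qe,
                    t_start = Biostrings::start(Biostrings::subject(pa)),
                    t_end = Biostrings::end(Biostrings::subject(pa)),
                    score = s, e_value = ev,
                    pct_id = Biostrings::pid(pa, type = "PID1"),
                    stringsAsFactors = FALSE)
  left <- if (qs > 1L) {
    align_one(substr(query, 1L, qs - 1L), offset, target_seq, sid,
              query_len, db_residues, e_report, depth + 1L)
  } else empty_hits()
  right <- if (qe < nchar(query)) {
    align_one(substr(query, qe + 1L, nchar(query)), offset + qe, target_seq,
              sid, query_len, db_residues, e_report, depth + 1L)
  } else empty_hits()
  rbind(hit, left, right)
}

#' Local-alignment search of a query chain against the domain database
#'
#' Affine-gap Smith-Waterman (BLOSUM62, gap open 11 / extend 1) of the
#' query SEQRES against every indexed domain sequence, with
#' Karlin-Altschul E-values scaled to the database size. For each
#' target, the optimal local alignment is reported and the remaining
#' query flanks are searched recursively, so a query containing two
#' copies of a domain yields two hits to it.
#'
#' @param query_seqres amino-acid string (non-empty).
#' @param domain_db a [build_domain_db()] database.
#' @param e_report loose reporting ceiling on E-values; the
#'   significance threshold proper is applied later by [filter_hits()].
#' @return Hits data.frame: `target_sid`, `q_start`, `q_end` (query
#'   SEQRES range), `t_start`, `t_end` (range on the target's
#'   concatenated sequence), `score`, `e_value`, `pct_id` (percent
#'   identical positions over aligned columns).
#' @export
search_hits <- function(query_seqres, domain_db, e_report = 10) {
  if (!is.character(query_seqres) || length(query_seqres) != 1L ||
      is.na(query_seqres) || nchar(query_seqres) == 0L) {
    stop("query sequence must be a non-empty string", call. = FALSE)
  }
  qlen <- nchar(query_seqres)
  out <- lapply(seq_len(nrow(domain_db$index)), function(i) {
    align_one(query_seqres, 0L, domain_db$seqs[[i]],
              domain_db$index$sid[i], qlen, domain_db$total_residues,
              e_report, 1L)
  })
  hits <- do.call(rbind, c(out, list(empty_hits())))
  hits[order(hits$e_value, hits$target_sid, hits$q_start), , drop = FALSE]
}

#' Filter hits on significance and target coverage
#'
#' Keeps a hit only if its E-value is at least as significant as
#' `params$e_max` (inclusive) and the alignment covers most of the
#' target domain: it may miss at most `params$target_end_slack`
#' residues from each end of the target sequence.
#'
#' @param hits hits data.frame from [search_hits()].
#' @param domain_db the database the hits refer to.
#' @param params [default_params()].
#' @return Filtered hits data.frame (same columns).
#' @export
filter_hits <- function(hits, domain_db, params = default_params()) {
  if (nrow(hits) == 0L) return(hits)
  i <- match(hits$target_sid, domain_db$index$sid)
  if (anyNA(i)) {
    stop(sprintf("hit references unknown target domain '%s'",
                 hits$target_sid[which(is.na(i))[1L]]), call. = FALSE)
  }
  tlen <- domain_db$index$length[i]
  keep <- hits$e_value <= params$e_max &
    hits$t_start <= 1L + params$target_end_slack &
    hits$t_end >= tlen - params$target_end_slack
  hits[keep, , drop = FALSE]
}

#' Group hits by target chain and rank groups by query coverage
#'
#' Hits are grouped by the PDB chain their target domains belong to;
#' each group's coverage is the number of distinct query residues
#' covered by the union of its hits (overlaps counted once). Groups are
#' ranked by coverage descending, ties broken by smaller minimum
#' E-value, then lexicographic (pdb_id, chain_id). Hits against genetic
#' domains have no single owner chain and are never grouped (the gate
#' inspects them separately), so the union of group hits equals the
#' non-genetic input hits.
#'
#' @param hits filtered hits data.frame.
#' @param domain_db a [build_domain_db()] database.
#' @return List of `hit_group`s: `pdb_id`, `chain_id`, `hits`
#'   (data.frame), `coverage` (integer).
#' @export
group_and_rank <- function(hits, domain_db) {
  if (nrow(hits) == 0L) return(list())
  i <- match(hits$target_sid, domain_db$index$sid)
  if (anyNA(i)) stop("hit references unknown target domain", call. = FALSE)
  hits <- hits[!domain_db$index$is_genetic[i], , drop = FALSE]
  if (nrow(hits) == 0L) return(list())
  i <- match(hits$target_sid, domain_db$index$sid)
  key <- chain_key(domain_db$index$pdb_id[i], domain_db$index$chain_id[i])
  groups <- lapply(split(seq_len(nrow(hits)), key), function(rows) {
    g <- hits[rows, , drop = FALSE]
    j <- match(g$target_sid[1L], domain_db$index$sid)
    structure(list(pdb_id = domain_db$index$pdb_id[j],
                   chain_id = domain_db$index$chain_id[j],
                   hits = g,
                   coverage = range_union_size(
                     residue_ranges(g$q_start, g$q_end))),
              class = "hit_group")
  })
  cov <- vapply(groups, `[[`, 1L, "coverage")
  emin <- vapply(groups, function(g) min(g$hits$e_value), 1)
  groups[order(-cov, emin, names(groups))]
}
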