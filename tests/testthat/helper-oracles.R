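# Independent oracles used by the tests. These deliberately take the
# dumbest correct route (per-index membership, full DP matrices) so
# they share no code with the package implementation.

brute_union_size <- function(ranges) {
  idx <- integer()
  for (i in seq_len(nrow(ranges))) {
    idx <- c(idx, seq.int(ranges$start[i], ranges$end[i]))
  }
  length(unique(idx))
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Exhaustive affine-gap (Gotoh) local alignment. A gap of length g
# costs open + g * ext, matching the package's alignment settings.
# Returns the optimal score and the set of optimal end cells.
sw_oracle_ends <- function(a, b, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1) # gap in a (move along b)
  F <- matrix(-Inf, n + 1, m + 1) # gap in b (move along a)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + blosum62[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
    }
  }
  best <- max(H)
  w <- which(H == best, arr.ind = TRUE)
  list(score = best, ends = cbind(q = w[, 1] - 1L, t = w[, 2] - 1L))
}

rev_str <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")

# Optimal local-alignment start cells, via the same DP on the
# reversed sequences.
sw_oracle_starts <- function(a, b, open = 11, ext = 1) {
  r <- sw_oracle_ends(rev_str(a), rev_str(b), open, ext)
  list(score = r$score,
       starts = cbind(q = nchar(a) + 1L - r$ends[, "q"],
                      t = nchar(b) + 1L - r$ends[, "t"]))
}

random_aa <- function(n) {
  paste(sample(rownames(blosum62)[1:20], n, replace = TRUE), collapse = "")
}

# Minimal hand-built domain_db for unit tests that only need the index
# (filtering, grouping); lengths and chain keys are freely chosen.
toy_db <- function(sid, length, pdb_id = "1abc", chain_id = "A",
                   is_genetic = FALSE, sccs = "a.1.1.1") {
  idx <- data.frame(sid = sid, sunid = seq_along(sid),
                    pdb_id = rep_len(pdb_id, length(sid)),
                    chain_id = rep_len(chain_id, length(sid)),
                    length = as.integer(length),
                    sccs = rep_len(sccs, length(sid)),
                    is_genetic = rep_len(is_genetic, length(sid)),
                    stringsAsFactors = FALSE)
  structure(list(index = idx, domains = list(), seqs = character(),
                 total_residues = sum(idx$length), chains = list(),
                 hierarchy = NULL),
            class = "domain_db")
}

make_hits <- function(target_sid, q_start, q_end, t_start, t_end,
                      e_value, pct_id = 90) {
  data.frame(target_sid = target_sid, q_start = as.integer(q_start),
             q_end = as.integer(q_end), t_start = as.integer(t_start),
             t_end = as.integer(t_end),
             score = rep_len(100, length(target_sid)),
             e_value = e_value, pct_id = rep_len(pct_id, length(target_sid)),
             stringsAsFactors = FALSE)
}

make_prediction <- function(ranges, target_sid, pdb_id = "1abc",
                            chain_id = "A", pct_id = 95,
                            t_start = 1L, t_end = 100L) {
  structure(list(pdb_id = pdb_id, chain_id = chain_id, ranges = ranges,
                 target_sid = target_sid,
                 hit = make_hits(target_sid, ranges$start[1], ranges$end[1],
                                 t_start, t_end, 1e-30, pct_id),
                 superfamily_sunid = NA_integer_,
                 family_sunid = NA_integer_, protein_sunid = NA_integer_,
                 species_sunid = NA_integer_,
                 placement_mode = NA_character_),
            class = "domain_prediction")
}

# A successor release: every single-domain whole chain of `old` gains a
# derived homolog (new entry, new curated domain under the same
# species), emulating newly deposited structures between two releases.
derive_release <- function(old, mutation_rate = 0, seed = 1L,
                           boundary_shift = 0L) {
  h <- as.data.frame(old$hierarchy)
  domains <- old$domains
  chains <- old$chains
  set.seed(seed)
  next_id <- max(h$sunid) + 1L
  n <- 0L
  for (key in names(old$chains)) {
    src <- old$chains[[key]]
    cur <- scopclass:::curated_domains_for_chain(old, src$pdb_id, src$chain_id)
    if (length(cur) != 1L) next
    if (nrow(cur[[1]]$ranges) != 1L ||
        cur[[1]]$ranges$start != 1L ||
        cur[[1]]$ranges$end != nchar(src$seqres)) next
    n <- n + 1L
    q <- derive_query(src, mutation_rate, seed = seed + n,
                      pdb_id = sprintf("n%03d", n))
    chains[[paste0(q$pdb_id, q$chain_id)]] <- q
    sid <- sprintf("d%sa_", q$pdb_id)
    s <- max(1L, 1L + boundary_shift)
    e <- nchar(q$seqres) - max(0L, boundary_shift)
    species <- h$parent_sunid[match(cur[[1]]$sunid, h$sunid)]
    h <- rbind(h, data.frame(sunid = next_id, level = "domain",
                             sccs = h$sccs[match(cur[[1]]$sunid, h$sunid)],
                             sid = sid, parent_sunid = species,
                             description = sprintf("%s a:%d-%d", q$pdb_id,
                                                   s, e),
                             stringsAsFactors = FALSE))
    domains[[sid]] <- domain_definition(
      sid, next_id, q$pdb_id,
      data.frame(chain_id = q$chain_id, start = s, end = e),
      substr(q$seqres, s, e))
    next_id <- next_id + 1L
  }
  release_bundle(hierarchy_table(h$sunid, h$level, h$sccs, h$sid,
                                 h$parent_sunid, h$description),
                 domains, chains,
                 version_label = paste0(old$version_label, "-next"))
}
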