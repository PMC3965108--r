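AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit],
                         function(a) sample(setdiff(AA20, a), 1L), "")
  }
  paste(chars, collapse = "")
}

#' Specification for a synthetic release
#'
#' Sequences are drawn i.i.d. over the 20-letter alphabet; the members
#' of each family are generated by mutating a family ancestor at
#' `mutation_rate` substitutions per site, which guarantees that
#' within-family alignments are overwhelmingly significant at
#' desk-scale lengths while unrelated sequences are not.
#'
#' @param seed RNG seed; the generated bundle is a pure function of the
#'   spec.
#' @param n_superfamilies number of superfamilies (one fold and one
#'   family each).
#' @param domains_per_family classified domains per family.
#' @param chain_length_range inclusive range of per-domain sequence
#'   lengths.
#' @param mutation_rate substitutions/site between a family's ancestor
#'   and each member.
#' @param multidomain_fraction fraction of domains placed pairwise on
#'   two-domain chains (the rest are whole-chain single domains).
#' @param include_genetic add one genetic (two-chain) domain.
#' @param class_letter sccs class letter (use a letter beyond "g" to
#'   build a non-true-class release for gate tests).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_superfamilies = 3L,
                         domains_per_family = 2L,
                         chain_length_range = c(120L, 180L),
                         mutation_rate = 0.05,
                         multidomain_fraction = 0,
                         include_genetic = FALSE,
                         class_letter = "a") {
  stopifnot(n_superfamilies >= 0L, domains_per_family >= 0L,
            mutation_rate >= 0, mutation_rate <= 1,
            multidomain_fraction >= 0, multidomain_fraction <= 1,
            chain_length_range[1L] >= 20L,
            chain_length_range[2L] >= chain_length_range[1L],
            nchar(class_letter) == 1L)
  structure(list(seed = as.integer(seed),
                 n_superfamilies = as.integer(n_superfamilies),
                 domains_per_family = as.integer(domains_per_family),
                 chain_length_range = as.integer(chain_length_range),
                 mutation_rate = mutation_rate,
                 multidomain_fraction = multidomain_fraction,
                 include_genetic = include_genetic,
                 class_letter = class_letter),
            class = "fixture_spec")
}

#' Generate a synthetic classified release
#'
#' Builds a consistent [release_bundle()]: one class, one fold +
#' superfamily + family + protein + species per superfamily, and
#' `domains_per_family` domain leaves each. A `multidomain_fraction`
#' of the domains are placed pairwise on two-domain chains (the pair
#' drawn from different families); all other domains each comprise
#' their entire chain. Deterministic for a fixed spec.
#'
#' @param spec a [fixture_spec()].
#' @return A [release_bundle()].
#' @export
generate_release <- function(spec) {
  set.seed(spec$seed)
  sunid <- 0L
  nid <- function() {
    sunid <<- sunid + 1L
    sunid
  }
  rows <- list()
  push <- function(level, sccs, sid, parent, desc) {
    id <- nid()
    rows[[length(rows) + 1L]] <<- data.frame(
      sunid = id, level = level, sccs = sccs, sid = sid,
      parent_sunid = parent, description = desc, stringsAsFactors = FALSE)
    id
  }
  cl <- spec$class_letter
  cl_id <- push("class", cl, NA_character_, NA_integer_,
                sprintf("Synthetic class %s", cl))

  dom_seq <- character()
  dom_species <- integer()
  dom_sf <- integer()
  for (s in seq_len(spec$n_superfamilies)) {
    cf <- push("fold", sprintf("%s.%d", cl, s), NA_character_, cl_id,
               sprintf("Fold %d", s))
    sf <- push("superfamily", sprintf("%s.%d.1", cl, s), NA_character_, cf,
               sprintf("Superfamily %d", s))
    fa <- push("family", sprintf("%s.%d.1.1", cl, s), NA_character_, sf,
               sprintf("Family %d", s))
    dm <- push("protein", sprintf("%s.%d.1.1", cl, s), NA_character_, fa,
               sprintf("Protein %d", s))
    sp <- push("species", sprintf("%s.%d.1.1", cl, s), NA_character_, dm,
               sprintf("Species %d", s))
    len <- spec$chain_length_range[1L] +
      sample.int(diff(spec$chain_length_range) + 1L, 1L) - 1L
    ancestor <- random_protein(len)
    for (k in seq_len(spec$domains_per_family)) {
      dom_seq <- c(dom_seq, mutate_protein(ancestor, spec$mutation_rate))
      dom_species <- c(dom_species, sp)
      dom_sf <- c(dom_sf, sf)
    }
  }

  n_dom <- length(dom_seq)
  n_pairs <- floor(spec$multidomain_fraction * n_dom / 2)
  # pair across families so two-domain chains span two superfamilies
  ord <- order(rep(seq_len(spec$domains_per_family),
                   times = spec$n_superfamilies))
  paired_idx <- if (n_pairs > 0L) ord[seq_len(2L * n_pairs)] else integer()

  chains <- list()
  domains <- list()
  entry_no <- 0L
  add_chain_with <- function(dom_idx) {
    entry_no <<- entry_no + 1L
    pdb <- sprintf("s%03d", entry_no)
    seqres <- paste(dom_seq[dom_idx], collapse = "")
    ch <- chain_record(pdb, "a", seqres, resolution = 2.0,
                       description = sprintf("synthetic fixture entry %d",
                                             entry_no))
    chains[[chain_key(pdb, "a")]] <<- ch
    offset <- 0L
    for (j in seq_along(dom_idx)) {
      i <- dom_idx[j]
      suffix <- if (length(dom_idx) == 1L) "_" else as.character(j)
      sid <- sprintf("d%sa%s", pdb, suffix)
      len <- nchar(dom_seq[i])
      px <- push("domain", rows[[match(dom_species[i],
                                       vapply(rows, function(r) r$sunid, 1L))
                                 ]]$sccs,
                 sid, dom_species[i], sprintf("%s a:%d-%d", pdb,
                                              offset + 1L, offset + len))
      domains[[sid]] <<- domain_definition(
        sid, px, pdb,
        data.frame(chain_id = "a", start = offset + 1L, end = offset + len),
        dom_seq[i])
      offset <- offset + len
    }
  }
  if (length(paired_idx) > 0L) {
    for (p in seq_len(n_pairs)) {
      add_chain_with(paired_idx[c(2L * p - 1L, 2L * p)])
    }
  }
  for (i in setdiff(seq_len(n_dom), paired_idx)) add_chain_with(i)

  if (spec$include_genetic && spec$n_superfamilies > 0L) {
    entry_no <- entry_no + 1L
    pdb <- sprintf("s%03d", entry_no)
    half <- random_protein(60L)
    other <- random_protein(60L)
    chains[[chain_key(pdb, "a")]] <-
      chain_record(pdb, "a", half, resolution = 2.0,
                   description = "synthetic genetic-domain entry")
    chains[[chain_key(pdb, "b")]] <-
      chain_record(pdb, "b", other, resolution = 2.0,
                   description = "synthetic genetic-domain entry")
    sid <- sprintf("d%s.1", pdb)
    px <- push("domain", sprintf("%s.1.1.1", cl), sid, dom_species[1L],
               sprintf("%s a:,b:", pdb))
    domains[[sid]] <- domain_definition(
      sid, px, pdb,
      data.frame(chain_id = c("a", "b"), start = c(1L, 1L),
                 end = c(60L, 60L)),
      paste0(half, other))
  }

  hier <- do.call(rbind, rows)
  hierarchy <- hierarchy_table(hier$sunid, hier$level, hier$sccs, hier$sid,
                               hier$parent_sunid, hier$description)
  release_bundle(hierarchy, domains, chains,
                 version_label = sprintf("fixture-%d", spec$seed))
}

#' Derive a homologous query chain from a classified chain
#'
#' Emulates a newly deposited chain homologous to a classified one:
#' point mutations at `mutation_rate` substitutions per site, plus
#' specified unobserved regions. Ground truth for benchmarking (the
#' source chain key) is attached as attribute `source_key`.
#'
#' @param chain source [chain_record()].
#' @param mutation_rate substitutions/site in `[0, 1]`.
#' @param gap_spec `residue_ranges` of unobserved regions (must lie
#'   within the chain).
#' @param seed RNG seed.
#' @param pdb_id entry code for the derived chain (default `q` + last
#'   3 characters of the source id).
#' @return A [chain_record()] with attribute `source_key`.
#' @export
derive_query <- function(chain, mutation_rate = 0, gap_spec = residue_ranges(),
                         seed = 1L, pdb_id = NULL) {
  set.seed(seed)
  gap_spec <- normalize_ranges(gap_spec)
  len <- nchar(chain$seqres)
  if (nrow(gap_spec) > 0L &&
      (min(gap_spec$start) < 1L || max(gap_spec$end) > len)) {
    stop("gap outside chain", call. = FALSE)
  }
  if (is.null(pdb_id)) pdb_id <- paste0("q", substr(chain$pdb_id, 2L, 4L))
  observed <- setdiff_ranges(residue_ranges(1L, len), gap_spec)
  q <- chain_record(pdb_id, chain$chain_id,
                    mutate_protein(chain$seqres, mutation_rate),
                    observed_ranges = observed,
                    resolution = chain$resolution,
                    description = chain$description)
  attr(q, "source_key") <- chain_key(chain$pdb_id, chain$chain_id)
  q
}

#' The two-hit worked-example fixture
#'
#' A 554-residue query chain (1vj5, chain A) with residues 2-547
#' observed, two filtered hits at query residues 2-224 and 226-544
#' against two domains of the classified chain 1ek1A (itself 554
#' residues with observed regions 4-19, 48-66 and 90-544), and the
#' manually curated domains 2-223 and 224-547. Boundary assignment on
#' this fixture yields predicted domains 2-225 and 226-547.
#'
#' @param seed seed for the synthetic sequences (coordinates are fixed;
#'   sequences only carry lengths).
#' @return List: `chain` (query [chain_record()]), `top_group`
#'   (`hit_group` of the two filtered hits), `curated` (two curated
#'   domains with ranges and superfamily sunids), `bundle` (mini
#'   reference release holding 1ek1A), `db` (its domain database).
#' @export
worked_example_fixture <- function(seed = 42L) {
  set.seed(seed)
  query <- chain_record("1vj5", "A", random_protein(554L),
                        observed_ranges = residue_ranges(2L, 547L),
                        resolution = 1.9,
                        description = "query chain, two-domain hydrolase")

  target_seqres <- random_protein(554L)
  target <- chain_record("1ek1", "A", target_seqres,
                         observed_ranges = residue_ranges(
                           c(4L, 48L, 90L), c(19L, 66L, 544L)),
                         resolution = 1.8,
                         description = "classified two-domain chain")
  d1_seg <- data.frame(chain_id = "A", start = 2L, end = 224L)
  d2_seg <- data.frame(chain_id = "A", start = 226L, end = 544L)
  hierarchy <- hierarchy_table(
    sunid = 1:13,
    level = c("class", "fold", "superfamily", "family", "protein", "species",
              "fold", "superfamily", "family", "protein", "species",
              "domain", "domain"),
    sccs = c("c", "c.1", "c.1.1", "c.1.1.1", "c.1.1.1", "c.1.1.1",
             "c.2", "c.2.1", "c.2.1.1", "c.2.1.1", "c.2.1.1",
             "c.1.1.1", "c.2.1.1"),
    sid = c(rep(NA_character_, 11L), "d1ek1a1", "d1ek1a2"),
    parent_sunid = c(NA, 1L, 2L, 3L, 4L, 5L, 1L, 7L, 8L, 9L, 10L, 6L, 11L),
    description = c("alpha/beta class", "fold 1", "superfamily 1",
                    "family 1", "protein 1", "species 1", "fold 2",
                    "superfamily 2", "family 2", "protein 2", "species 2",
                    "1ek1 A:2-224", "1ek1 A:226-544"))

  domains <- list(
    d1ek1a1 = domain_definition("d1ek1a1", 12L, "1ek1", d1_seg,
                                substr(target_seqres, 2L, 224L)),
    d1ek1a2 = domain_definition("d1ek1a2", 13L, "1ek1", d2_seg,
                                substr(target_seqres, 226L, 544L)))
  bundle <- release_bundle(hierarchy, domains,
                           list(target), version_label = "fig-example")
  db <- build_domain_db(bundle)

  hits <- data.frame(
    target_sid = c("d1ek1a1", "d1ek1a2"),
    q_start = c(2L, 226L), q_end = c(224L, 544L),
    t_start = c(1L, 1L), t_end = c(223L, 319L),
    score = c(420, 600), e_value = c(1e-48, 1e-70),
    pct_id = c(42, 45), stringsAsFactors = FALSE)
  top_group <- structure(list(pdb_id = "1ek1", chain_id = "A", hits = hits,
                              coverage = range_union_size(
                                residue_ranges(hits$q_start, hits$q_end))),
                         class = "hit_group")

  curated <- list(
    list(sid = "manual1", sunid = 12L, pdb_id = "1vj5", chain_id = "A",
         superfamily_sunid = 3L, ranges = residue_ranges(2L, 223L)),
    list(sid = "manual2", sunid = 13L, pdb_id = "1vj5", chain_id = "A",
         superfamily_sunid = 8L, ranges = residue_ranges(224L, 547L)))

  list(chain = query, top_group = top_group, curated = curated,
       bundle = bundle, db = db)
}
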