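test_that("two-hit worked example: extension, clipping, interior linker", {
  fx <- worked_example_fixture()
  preds <- assign_domains(fx$top_group, fx$chain)
  expect_identical(length(preds), 2L)
  expect_identical(format_ranges(preds[[1]]$ranges), "2-225")
  expect_identical(format_ranges(preds[[2]]$ranges), "226-547")
})

one_hit_group <- function(q_start, q_end, sid = "dtoyaa_") {
  structure(list(pdb_id = "toya", chain_id = "A",
                 hits = make_hits(sid, q_start, q_end, 1, 100, 1e-30),
                 coverage = q_end - q_start + 1L),
            class = "hit_group")
}

test_that("boundaries extend to near termini and clip to observed residues", {
  set.seed(1)
  # clip start to observed, then extend end to the terminus 10 away
  ch <- chain_record("1qry", "A", random_aa(140),
                     observed_ranges = residue_ranges(10, 130))
  p <- assign_domains(one_hit_group(1, 120), ch)
  expect_identical(format_ranges(p[[1]]$ranges), "10-130")
  # terminus 15 residues past the hit end: no extension
  ch2 <- chain_record("1qry", "A", random_aa(140),
                      observed_ranges = residue_ranges(1, 105))
  p2 <- assign_domains(one_hit_group(1, 90), ch2)
  expect_identical(format_ranges(p2[[1]]$ranges), "1-90")
  # boundary exactly at the extension limit still extends
  ch3 <- chain_record("1qry", "A", random_aa(140),
                      observed_ranges = residue_ranges(1, 100))
  p3 <- assign_domains(one_hit_group(1, 90), ch3)
  expect_identical(format_ranges(p3[[1]]$ranges), "1-100")
  expect_error(assign_domains(one_hit_group(1, 500), ch), "outside")
  expect_error(assign_domains(structure(list(hits = make_hits(
    character(), integer(), integer(), integer(), integer(), numeric())),
    class = "hit_group"), ch), "empty")
})

test_that("extension stops at ATOM-record gap edges, not only termini", {
  set.seed(2)
  ch <- chain_record("1qry", "A", random_aa(200),
                     observed_ranges = residue_ranges(c(1, 80), c(60, 200)))
  # hit ends at 55; gap edge (observed end 60) is 5 away -> extend to 60
  p <- assign_domains(one_hit_group(5, 55), ch)
  expect_identical(format_ranges(p[[1]]$ranges), "1-60")
})

test_that("predicted ranges always lie within observed residues", {
  b <- generate_release(fixture_spec(seed = 13, n_superfamilies = 3,
                                     domains_per_family = 2))
  db <- build_domain_db(b)
  set.seed(14)
  for (rep in 1:8) {
    src <- b$chains[[sample(length(b$chains), 1)]]
    len <- nchar(src$seqres)
    gs <- sample(1:(len - 30), 1)
    q <- derive_query(src, mutation_rate = 0.05,
                      gap_spec = residue_ranges(gs, gs + sample(5:25, 1)),
                      seed = rep)
    res <- classify_chain(q, db)
    obs <- range_indices(q$observed_ranges)
    for (p in res$predictions) {
      expect_true(all(range_indices(p$ranges) %in% obs))
    }
  }
})

gate_db <- function() {
  fx <- worked_example_fixture()
  fx$db
}

test_that("the gate collects every violated criterion as a reason code", {
  fx <- worked_example_fixture()
  preds <- assign_domains(fx$top_group, fx$chain)
  ok <- gate_confidence(preds, fx$chain, fx$top_group, fx$db)
  expect_true(ok$accepted)
  expect_identical(ok$reason_codes, character(0))

  # resolution exactly at the cutoff is excluded (inclusive rule)
  low <- fx$chain
  low$resolution <- 3.0
  v <- gate_confidence(preds, low, fx$top_group, fx$db)
  expect_identical(v$reason_codes, "LOW_RESOLUTION")

  # both predictions to the same target domain
  dup <- preds
  dup[[2]]$target_sid <- preds[[1]]$target_sid
  dup[[2]]$hit$target_sid <- preds[[1]]$target_sid
  v <- gate_confidence(dup, fx$chain, fx$top_group, fx$db)
  expect_identical(v$reason_codes, "DUPLICATE_TARGET_DOMAIN")

  # an observed region of 11 unassigned residues blocks acceptance
  trimmed <- preds
  trimmed[[2]]$ranges <- residue_ranges(237, 547)
  v <- gate_confidence(trimmed, fx$chain, fx$top_group, fx$db)
  expect_identical(v$reason_codes, "UNASSIGNED_REGION")
  # ...but 10 unassigned residues do not
  trimmed[[2]]$ranges <- residue_ranges(236, 547)
  expect_true(gate_confidence(trimmed, fx$chain, fx$top_group,
                              fx$db)$accepted)

  # ribosomal/synthetic keyword on the entry description
  ribo <- fx$chain
  ribo$description <- "50S ribosomal protein L2"
  v <- gate_confidence(preds, ribo, fx$top_group, fx$db)
  expect_identical(v$reason_codes, "RIBOSOMAL_OR_SYNTHETIC")

  # violations accumulate independently of evaluation order
  low$description <- "synthetic construct"
  v <- gate_confidence(dup, low, fx$top_group, fx$db)
  expect_identical(v$reason_codes,
                   sort(c("LOW_RESOLUTION", "RIBOSOMAL_OR_SYNTHETIC",
                          "DUPLICATE_TARGET_DOMAIN")))

  # no predictions at all
  v <- gate_confidence(list(), fx$chain, NULL, fx$db)
  expect_false(v$accepted)
  expect_identical(v$reason_codes, "NO_HITS")
})

test_that("single-domain chains require a whole-chain target", {
  b <- generate_release(fixture_spec(seed = 17, n_superfamilies = 2,
                                     domains_per_family = 1,
                                     multidomain_fraction = 1))
  # the only chain holds two domains; a query matching just one of them
  # gets a single prediction whose target is not a whole chain
  db <- build_domain_db(b)
  two_dom <- b$chains[[1]]
  doms <- scopclass:::curated_domains_for_chain(b, two_dom$pdb_id,
                                                two_dom$chain_id)
  expect_identical(length(doms), 2L)
  part <- chain_record("1qry", "A",
                       substr(two_dom$seqres, doms[[1]]$ranges$start,
                              doms[[1]]$ranges$end),
                       resolution = 2.0)
  res <- classify_chain(part, db)
  expect_identical(length(res$predictions), 1L)
  expect_false(res$verdict$accepted)
  expect_true("TARGET_NOT_WHOLE_CHAIN" %in% res$verdict$reason_codes)

  # whereas a whole-chain self match is accepted
  b1 <- generate_release(fixture_spec(seed = 18, n_superfamilies = 2,
                                      domains_per_family = 1))
  db1 <- build_domain_db(b1)
  res1 <- classify_chain(b1$chains[[1]], db1)
  expect_true(res1$verdict$accepted)
  expect_identical(format_ranges(res1$predictions[[1]]$ranges),
                   sprintf("1-%d", nchar(b1$chains[[1]]$seqres)))
})

test_that("targets outside the seven true classes are gated out", {
  b <- generate_release(fixture_spec(seed = 19, n_superfamilies = 1,
                                     domains_per_family = 1,
                                     class_letter = "h"))
  db <- build_domain_db(b)
  res <- classify_chain(b$chains[[1]], db)
  expect_false(res$verdict$accepted)
  expect_true("RIBOSOMAL_OR_SYNTHETIC" %in% res$verdict$reason_codes)
})

test_that("homology to a genetic domain is gated out", {
  b <- generate_release(fixture_spec(seed = 23, n_superfamilies = 1,
                                     domains_per_family = 1,
                                     include_genetic = TRUE))
  db <- build_domain_db(b)
  gen <- Filter(function(d) d$is_genetic, b$domains)[[1]]
  ck <- paste0(gen$pdb_id, gen$segments$chain_id[1])
  res <- classify_chain(b$chains[[ck]], db)
  expect_true("GENETIC_DOMAIN_HOMOLOG" %in% res$verdict$reason_codes)
})

test_that("multi-domain shape rule admits identical chains or two contiguous domains", {
  fx <- worked_example_fixture()
  preds <- assign_domains(fx$top_group, fx$chain)
  # two contiguous single-segment domains: accepted regardless of identity
  expect_true(gate_confidence(preds, fx$chain, fx$top_group, fx$db)$accepted)
  # three predictions and no sequence identity with the target chain
  three <- c(preds, list(preds[[2]]))
  three[[2]]$ranges <- residue_ranges(226, 400)
  three[[3]]$ranges <- residue_ranges(401, 547)
  three[[3]]$target_sid <- "d1ek1a1"
  three[[3]]$hit$target_sid <- "d1ek1a1"
  v <- gate_confidence(three, fx$chain, fx$top_group, fx$db)
  expect_true("MULTIDOMAIN_SHAPE" %in% v$reason_codes)
  # identical SEQRES to the target chain lifts the shape restriction
  ident <- fx$db$chains[["1ek1A"]]
  q <- chain_record("1vj5", "A", ident$seqres,
                    observed_ranges = residue_ranges(1, 554),
                    resolution = 1.9)
  v2 <- gate_confidence(three, q, fx$top_group, fx$db)
  expect_false("MULTIDOMAIN_SHAPE" %in% v2$reason_codes)
})

test_that("hierarchy placement inherits as deep as identity supports", {
  b <- generate_release(fixture_spec(seed = 29, n_superfamilies = 2,
                                     domains_per_family = 1))
  db <- build_domain_db(b)
  h <- b$hierarchy
  sid <- db$index$sid[1]
  len <- db$index$length[1]
  target_sunid <- db$index$sunid[1]

  exact <- make_prediction(residue_ranges(1, len), sid, pct_id = 100,
                           t_end = len)
  placed <- place_in_hierarchy(exact, h, db)
  expect_identical(placed$prediction$placement_mode, "matched")
  expect_identical(placed$prediction$species_sunid,
                   get_ancestor(h, target_sunid, "species"))
  expect_identical(placed$prediction$superfamily_sunid,
                   get_ancestor(h, target_sunid, "superfamily"))
  expect_identical(nrow(placed$hierarchy), nrow(h))

  # 95% identity: protein inherited, species falls back
  close_hit <- make_prediction(residue_ranges(1, len), sid, pct_id = 95,
                               t_end = len)
  placed <- place_in_hierarchy(close_hit, h, db)
  expect_identical(placed$prediction$placement_mode, "automated_matches")
  expect_identical(placed$prediction$protein_sunid,
                   get_ancestor(h, target_sunid, "protein"))
  sp <- placed$prediction$species_sunid
  expect_identical(placed$hierarchy$description[
    match(sp, placed$hierarchy$sunid)], "automated matches")

  # 55% identity: family itself falls back under the superfamily
  far <- make_prediction(residue_ranges(1, len), sid, pct_id = 55,
                         t_end = len)
  placed2 <- place_in_hierarchy(far, h, db)
  fam <- placed2$prediction$family_sunid
  hh <- placed2$hierarchy
  expect_identical(hh$description[match(fam, hh$sunid)], "automated matches")
  expect_identical(hh$parent_sunid[match(fam, hh$sunid)],
                   get_ancestor(h, target_sunid, "superfamily"))
  expect_identical(placed2$prediction$superfamily_sunid,
                   get_ancestor(h, target_sunid, "superfamily"))

  # fallback nodes are reused, never duplicated
  placed3 <- place_in_hierarchy(far, placed2$hierarchy, db)
  expect_identical(placed3$prediction$family_sunid, fam)
  expect_identical(nrow(placed3$hierarchy), nrow(placed2$hierarchy))

  bad <- make_prediction(residue_ranges(1, 10), "nosuch01")
  expect_error(place_in_hierarchy(bad, h, db), "unknown target")
})

test_that("classification is deterministic and handles hit-less chains", {
  b <- generate_release(fixture_spec(seed = 37, n_superfamilies = 2,
                                     domains_per_family = 2))
  db <- build_domain_db(b)
  set.seed(38)
  none <- chain_record("1zzz", "A", random_aa(50), resolution = 2.0)
  res <- classify_chain(none, db)
  expect_identical(res$predictions, list())
  expect_identical(res$verdict$reason_codes, "NO_HITS")

  q <- derive_query(b$chains[[2]], mutation_rate = 0.08, seed = 5)
  r1 <- classify_chain(q, db)
  r2 <- classify_chain(q, db)
  expect_identical(prediction_dump(r1$predictions, r1$verdict),
                   prediction_dump(r2$predictions, r2$verdict))
})
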