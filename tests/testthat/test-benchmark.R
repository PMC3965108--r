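toy_dom <- function(start, end, sf = 3L, pdb = "1abc", chain = "A") {
  list(pdb_id = pdb, chain_id = chain, superfamily_sunid = sf,
       ranges = residue_ranges(start, end))
}

test_that("pairing matches by dominant overlap and reports leftovers", {
  p <- list(toy_dom(1, 150), toy_dom(160, 300))
  cur <- list(toy_dom(1, 155), toy_dom(156, 300))
  res <- pair_domains(p, cur)
  expect_identical(length(res$pairs), 2L)
  expect_identical(res$pairs[[1]]$pred$ranges$end, 150L)
  expect_identical(res$pairs[[1]]$cur$ranges$end, 155L)

  res2 <- pair_domains(p[1], cur)
  expect_identical(length(res2$pairs), 1L)
  expect_identical(length(res2$unmatched_cur), 1L)

  res3 <- pair_domains(p, p)
  expect_identical(length(res3$pairs), 2L)
  expect_identical(length(res3$unmatched_pred), 0L)
})

test_that("domain comparison scores the worked example as correct", {
  fx <- worked_example_fixture()
  pred <- list(toy_dom(2, 225, sf = 3L, pdb = "1vj5"),
               toy_dom(226, 547, sf = 8L, pdb = "1vj5"))
  rec1 <- compare_domains(pred[[1]], fx$curated[[1]], fx$bundle$hierarchy)
  rec2 <- compare_domains(pred[[2]], fx$curated[[2]], fx$bundle$hierarchy)
  expect_identical(rec1$max_boundary_dev, 2)
  expect_identical(rec2$max_boundary_dev, 2)
  expect_identical(rec1$verdict, "correct")
  expect_identical(rec2$verdict, "correct")
})

test_that("comparison applies the tolerance edge and superfamily rule", {
  h <- worked_example_fixture()$bundle$hierarchy
  base <- toy_dom(1, 100)
  expect_identical(compare_domains(toy_dom(1, 110), base, h)$verdict,
                   "correct")
  expect_identical(compare_domains(toy_dom(1, 111), base, h)$verdict,
                   "boundary_mismatch")
  off_sf <- compare_domains(toy_dom(1, 100, sf = 8L), base, h)
  expect_identical(off_sf$verdict, "superfamily_mismatch")
  # curated superfamily resolvable from the domain sunid
  cur <- list(sunid = 12L, ranges = residue_ranges(1, 100))
  expect_identical(compare_domains(toy_dom(1, 100, sf = 3L), cur, h)$verdict,
                   "correct")
  # unequal segment counts are a mismatch with an infinite sentinel
  multi <- toy_dom(1, 100)
  multi$ranges <- residue_ranges(c(1, 60), c(50, 100))
  expect_identical(compare_domains(multi, base, h)$max_boundary_dev, Inf)
})

test_that("deviation is symmetric under swapping predicted and curated", {
  h <- worked_example_fixture()$bundle$hierarchy
  set.seed(41)
  for (rep in 1:20) {
    a <- toy_dom(sample(1:20, 1), sample(100:140, 1))
    b <- toy_dom(sample(1:20, 1), sample(100:140, 1))
    expect_identical(compare_domains(a, b, h)$max_boundary_dev,
                     compare_domains(b, a, h)$max_boundary_dev)
  }
})

test_that("error rates print at the precision release notes use", {
  expect_identical(format_error_rate(62, 80140), "0.08%")
  expect_identical(format_error_rate(231, 30660), "0.8%")
  expect_identical(format_error_rate(5, 100), "5.0%")
  expect_identical(format_error_rate(0, 0), NA_character_)
})

test_that("summaries agree with brute-force recounts of the records", {
  recs <- rbind(
    data.frame(chain = "a001A", predicted = "1-100", curated = "1-100",
               superfamily_match = TRUE, max_boundary_dev = 0,
               verdict = "correct"),
    data.frame(chain = "a002A", predicted = "1-90", curated = "1-120",
               superfamily_match = TRUE, max_boundary_dev = 30,
               verdict = "boundary_mismatch"),
    data.frame(chain = "a003A", predicted = "", curated = "1-80",
               superfamily_match = FALSE, max_boundary_dev = Inf,
               verdict = "unmatched"))
  s <- summarize_benchmark(recs, attempted_chains = sprintf("a%03dA", 1:4),
                           classified_chains = c("a001A", "a002A", "a003A"))
  expect_identical(s$n_predicted, 2L)
  expect_identical(s$n_correct, sum(recs$verdict == "correct"))
  expect_identical(s$n_boundary_mismatch, 1L)
  expect_equal(s$percent_classifiable, 100 * 3 / 4)
  expect_equal(s$error_rate_percent, 100 * 1 / 2)
  empty <- summarize_benchmark(recs[0, ], character())
  expect_true(is.na(empty$error_rate_percent))
  expect_true(is.na(empty$percent_classifiable))
})

test_that("a release benchmarked against identical new chains is perfect", {
  old <- generate_release(fixture_spec(seed = 43, n_superfamilies = 3,
                                       domains_per_family = 1))
  new <- derive_release(old, mutation_rate = 0, seed = 1)
  res <- benchmark_release_pair(old, new)
  expect_gt(nrow(res$records), 0L)
  expect_true(all(res$records$verdict == "correct"))
  expect_true(all(res$records$max_boundary_dev == 0))
  expect_equal(res$summary$percent_classifiable, 100)
})

test_that("a chain without homologs counts as attempted, not classifiable", {
  old <- generate_release(fixture_spec(seed = 47, n_superfamilies = 2,
                                       domains_per_family = 1))
  new <- derive_release(old, mutation_rate = 0, seed = 1)
  set.seed(48)
  orphan <- chain_record("n999", "a", random_aa(80), resolution = 2.0)
  new$chains[["n999a"]] <- orphan
  res <- benchmark_release_pair(old, new)
  expect_identical(res$summary$n_chains_attempted, 3L)
  expect_identical(res$summary$n_chains_classifiable, 2L)
})

test_that("shifted curated boundaries flip with the tolerance", {
  old <- generate_release(fixture_spec(seed = 53, n_superfamilies = 2,
                                       domains_per_family = 1))
  new <- derive_release(old, mutation_rate = 0, seed = 1, boundary_shift = 5)
  loose <- benchmark_release_pair(old, new, default_params())
  tight <- benchmark_release_pair(old, new,
                                  default_params(benchmark_tolerance = 4))
  expect_true(all(loose$records$verdict == "correct"))
  expect_true(all(tight$records$verdict == "boundary_mismatch"))
  expect_true(all(loose$records$max_boundary_dev == 5))
})

test_that("release diffs report added, re-bounded and moved nodes", {
  a <- generate_release(fixture_spec(seed = 59, n_superfamilies = 2,
                                     domains_per_family = 2))
  expect_identical(nrow(diff_releases(a, a)), 0L)

  b <- derive_release(a, mutation_rate = 0, seed = 1)
  d <- diff_releases(a, b)
  expect_true(all(d$change == "added"))
  expect_identical(nrow(d), length(b$domains) - length(a$domains))

  # move one domain to the sibling species, shrink another by 3 residues
  h <- as.data.frame(a$hierarchy)
  doms <- a$domains
  px <- which(h$level == "domain")
  sp <- which(h$level == "species")
  other_sp <- h$sunid[setdiff(sp, match(h$parent_sunid[px[1]], h$sunid))][1]
  h$parent_sunid[px[1]] <- other_sp
  h$sccs[px[1]] <- h$sccs[match(other_sp, h$sunid)]
  moved_sid <- h$sid[px[1]]
  shrunk_sid <- h$sid[px[2]]
  dm <- doms[[shrunk_sid]]
  doms[[shrunk_sid]] <- domain_definition(
    dm$sid, dm$sunid, dm$pdb_id,
    data.frame(chain_id = dm$segments$chain_id,
               start = dm$segments$start, end = dm$segments$end - 3L),
    substr(dm$sequence, 1, nchar(dm$sequence) - 3L))
  c_rel <- release_bundle(hierarchy_table(h$sunid, h$level, h$sccs, h$sid,
                                          h$parent_sunid, h$description),
                          doms, a$chains, "moved")
  d2 <- diff_releases(a, c_rel)
  expect_setequal(d2$change, c("moved", "re-bounded"))
  expect_identical(d2$sid[d2$change == "moved"], moved_sid)
  expect_identical(d2$sid[d2$change == "re-bounded"], shrunk_sid)
})
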