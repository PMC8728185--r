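test_that("domain lengths sum over region segments through the RAF map", {
  set.seed(41)
  rec <- random_raf_record("9aaa", "A", 120, disorder_rate = 0)
  idx <- list("9aaaA" = rec)
  lp <- domain_lengths(list(sid = "d9aaaa_", pdb_id = "9aaa", region = "A:"),
                       idx)
  expect_equal(lp$seqres_len, 120L)
  expect_equal(lp$atom_len, 120L)

  # residues 10-20 unresolved inside A:1-50
  cells <- rec$cells
  cells$atom_aa[10:20] <- "."
  rec2 <- raf_record("9aab", "A", cells)
  idx2 <- list("9aabA" = rec2)
  lp2 <- domain_lengths(list(sid = "d9aaba_", pdb_id = "9aab",
                             region = "A:1-50"), idx2)
  expect_equal(lp2$seqres_len, 50L)
  expect_equal(lp2$atom_len, 39L)

  # additivity over two segments
  lp3 <- domain_lengths(list(sid = "d9aaba_", pdb_id = "9aab",
                             region = "A:1-50,A:61-120"), idx2)
  expect_equal(lp3$seqres_len, 50L + 60L)

  expect_error(domain_lengths(list(sid = "x", pdb_id = "9zzz", region = "A:"),
                              idx), "9zzzA")
})

test_that("KDE peak counting matches closed-form expectations", {
  expect_equal(kde_peak_count(rep(100, 50), bandwidth = 5), 1L)
  two <- c(rep(100, 25), rep(200, 25))
  expect_equal(kde_peak_count(two, bandwidth = 5),
               oracle_kde_peaks(two, 5))
  expect_equal(kde_peak_count(two, bandwidth = 5), 2L)
  expect_error(kde_peak_count(100, bandwidth = 5), "at least 2")
})

test_that("peak count never increases along a widening bandwidth sweep", {
  mix <- c(rep(100, 25), rep(200, 25))
  counts <- vapply(c(2, 5, 10, 20, 40, 80), function(bw)
    kde_peak_count(mix, bw), 0L)
  expect_true(all(diff(counts) <= 0L))
  expect_equal(counts[1], 2L)
  expect_equal(counts[length(counts)], 1L)
})

test_that("KDE peak counts agree with the brute-force oracle on random mixtures", {
  set.seed(43)
  for (i in 1:60) {
    lens <- random_length_instance()
    bw <- sample(2:10, 1)
    expect_equal(kde_peak_count(lens, bw), oracle_kde_peaks(lens, bw),
                 info = sprintf("instance %d", i))
  }
})

test_that("length ratio is max/min, permutation-invariant, and guards inputs", {
  expect_equal(length_ratio(c(100, 150)), 1.5)
  expect_equal(length_ratio(7), 1.0)
  set.seed(47)
  for (i in 1:20) {
    lens <- sample(50:400, sample(2:20, 1), replace = TRUE)
    expect_equal(length_ratio(lens), max(lens) / min(lens))
    expect_equal(length_ratio(sample(lens)), length_ratio(lens))
    expect_equal(length_ratio(c(lens, lens)), length_ratio(lens))
    expect_gte(length_ratio(lens), 1)
  }
  expect_error(length_ratio(c(10, 0)), "non-positive")
})

test_that("family flagging applies the routing, deficit, keyword and fragment rules", {
  cfg <- flag_config()
  homogeneous <- data.frame(sid = sprintf("d%04da_", 1:10),
                            seqres_len = rep(100L, 10),
                            atom_len = rep(100L, 10))
  rep1 <- flag_family("a.1.1.1", homogeneous, character(), cfg)
  expect_false(rep1$flagged)
  expect_length(rep1$reasons, 0L)
  expect_equal(rep1$peak_count, 1L)

  small <- data.frame(sid = c("d0001a_", "d0002a_", "d0003a_"),
                      seqres_len = c(100L, 100L, 210L),
                      atom_len = c(100L, 100L, 210L))
  rep2 <- flag_family("a.1.1.2", small, character(), cfg)
  expect_true(rep2$flagged)
  expect_equal(rep2$reasons, "ratio_exceeded")
  expect_equal(rep2$length_ratio, 2.1)
  # median 100: the fragment cut is 2/3 * 100; nobody falls below it
  expect_length(rep2$fragment_candidates, 0L)

  rep3 <- flag_family("a.1.1.3", homogeneous,
                      "family arose by gene DUPLICATION", cfg)
  expect_true(rep3$flagged)
  expect_equal(rep3$reasons, "keyword_hit")

  deficit <- data.frame(sid = c("d0001a_", "d0002a_"),
                        seqres_len = c(120L, 120L),
                        atom_len = c(120L, 60L))
  rep4 <- flag_family("a.1.1.4", deficit, character(), cfg)
  expect_true(rep4$flagged)
  expect_equal(rep4$reasons, "atom_deficit")
  expect_equal(rep4$atom_deficit_sids, "d0002a_")
  # 60 observed residues < 2/3 of the 120-residue median: fragment candidate
  expect_equal(rep4$fragment_candidates, "d0002a_")
})

test_that("raising the ratio threshold never adds the ratio reason", {
  set.seed(53)
  for (i in 1:20) {
    members <- data.frame(sid = sprintf("d%04da_", 1:4),
                          seqres_len = sample(60:240, 4),
                          atom_len = sample(60:240, 4))
    members$atom_len <- members$seqres_len
    flagged_at <- vapply(c(1.2, 1.5, 2, 3, 5), function(th)
      "ratio_exceeded" %in% flag_family("x.1.1.1", members, character(),
        flag_config(ratio_threshold = th))$reasons, NA)
    expect_true(all(diff(as.integer(flagged_at)) <= 0L))
  }
})

test_that("screening a synthetic release recovers exactly the planted families", {
  bundle <- generate_release(fixture_spec(seed = 59))
  reports <- screen_release(bundle$domains, bundle$raf_index,
                            bundle$descriptions)
  expect_length(attr(reports, "errors"), 0L)
  tab <- flag_report_table(reports)
  truth <- bundle$manifest$families
  expect_setequal(tab$sccs, truth$sccs)
  m <- merge(tab, truth, by = "sccs")
  expect_identical(m$flagged, m$expected_reason != "none")
  flagged <- m[m$flagged, ]
  expect_true(all(mapply(grepl, flagged$expected_reason, flagged$reasons)))

  again <- screen_release(bundle$domains, bundle$raf_index,
                          bundle$descriptions)
  expect_identical(flag_report_table(again), tab)

  empty <- screen_release(bundle$domains[0, ], bundle$raf_index)
  expect_length(empty, 0L)
})

test_that("a homogeneous, fully resolved, keyword-free family is never flagged", {
  set.seed(61)
  for (n in c(2L, 5L, 10L, 30L)) {
    len <- sample(60:300, 1)
    members <- data.frame(sid = sprintf("d%04da_", seq_len(n)),
                          seqres_len = rep(len, n), atom_len = rep(len, n))
    expect_false(flag_family("z.1.1.1", members, character())$flagged)
  }
})

test_that("new-entry validation warns on outliers and fragments only", {
  members <- data.frame(sid = sprintf("d%04da_", 1:5),
                        seqres_len = rep(100L, 5), atom_len = rep(100L, 5))
  rep0 <- flag_family("a.9.1.1", members)
  expect_length(validate_new_entry(list(sid = "dnew", seqres_len = 100L,
                                        atom_len = 100L), rep0), 0L)
  w <- validate_new_entry(list(sid = "dnew", seqres_len = 40L,
                               atom_len = 40L), rep0)
  expect_true(any(grepl("fragment", w)))
  expect_true(any(grepl("ratio", w)))

  het <- flag_family("a.9.1.2",
                     data.frame(sid = c("a", "b", "c"),
                                seqres_len = c(100L, 100L, 210L),
                                atom_len = c(100L, 100L, 210L)))
  w2 <- validate_new_entry(list(sid = "dnew", seqres_len = 110L,
                                atom_len = 110L), het)
  expect_true(any(grepl("flagged", w2)))
})

test_that("flagged families yield draft dir.inc rows that round-trip", {
  bundle <- generate_release(fixture_spec(seed = 67))
  reports <- screen_release(bundle$domains, bundle$raf_index)
  draft <- draft_inc(reports)
  expect_equal(sort(draft$sccs),
               sort(bundle$manifest$families$sccs[
                 bundle$manifest$families$expected_reason != "none"]))
  f <- withr::local_tempfile()
  write_inc(draft, f)
  back <- suppressWarnings(read_inc(f))
  expect_equal(back$sccs, draft$sccs)
})
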