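make_chain <- function(seqres, seqadv = NULL, dbref = NULL, pdb = "8aaa") {
  sa <- if (is.null(seqadv))
    data.frame(start = integer(), end = integer(), description = character())
  else seqadv
  chain_record(pdb, "A", seqres, seqadv = sa, dbref = dbref)
}

test_that("terminal SEQADV notes become calls, internal ones warnings", {
  set.seed(71)
  seqres <- paste(sample(AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                         150, replace = TRUE), collapse = "")
  ch <- make_chain(seqres, data.frame(start = 1L, end = 6L,
                                      description = "EXPRESSION TAG"))
  calls <- detect_tags_seqadv(ch)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$terminus, "N")
  expect_equal(c(calls$start, calls$end), c(1L, 6L))
  expect_equal(calls$evidence, "seqadv")

  internal <- make_chain(seqres, data.frame(start = 70L, end = 75L,
                                            description = "expression tag"))
  expect_warning(calls2 <- detect_tags_seqadv(internal), "not terminal")
  expect_equal(nrow(calls2), 0L)

  # conflict mutations are not in the vocabulary
  mut <- make_chain(seqres, data.frame(start = 1L, end = 2L,
                                       description = "ENGINEERED MUTATION"))
  expect_equal(nrow(detect_tags_seqadv(mut)), 0L)
})

test_that("adjacent qualifying SEQADV notes merge into one terminal call", {
  set.seed(73)
  seqres <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                         120, replace = TRUE), collapse = "")
  ch <- make_chain(seqres, data.frame(
    start = c(1L, 4L), end = c(3L, 8L),
    description = c("expression tag", "linker")))
  calls <- detect_tags_seqadv(ch)
  expect_equal(nrow(calls), 1L)
  expect_equal(c(calls$start, calls$end), c(1L, 8L))
  expect_match(calls$description, "expression tag; linker")
})

test_that("a mismatching His-tag is called and a matching terminus is not", {
  set.seed(79)
  g <- generate_chain_with_tag("8abc", "A", core_len = 60L, tag_len = 7L,
                               terminus = "N", accession = "P12345")
  calls <- detect_tags_by_uniprot(g$chain, g$uniprot[["P12345"]])
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$terminus, "N")
  expect_equal(c(calls$start, calls$end), c(1L, 7L))
  expect_equal(calls$evidence, "uniprot_compare")

  # chain exactly equal to its UniProt window: silence at both termini
  uni <- g$uniprot[["P12345"]]
  core <- substr(uni, 11, 70)
  plain <- make_chain(core, dbref = list(accession = "P12345",
                                         chain_start = 1L, chain_end = 60L,
                                         uniprot_start = 11L,
                                         uniprot_end = 70L))
  expect_equal(nrow(detect_tags_by_uniprot(plain, uni)), 0L)

  # flank-identical planted tag is undetectable by construction
  g2 <- generate_chain_with_tag("8abd", "A", core_len = 60L, tag_len = 5L,
                                terminus = "C", accession = "P12346",
                                detectable = FALSE)
  expect_equal(nrow(detect_tags_by_uniprot(g2$chain,
                                           g2$uniprot[["P12346"]])), 0L)
})

test_that("a 12-residue mismatching extension is rejected by the <10 rule", {
  set.seed(83)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  uni <- paste(sample(aa, 80, replace = TRUE), collapse = "")
  core <- substr(uni, 21, 70)
  ext <- paste(rep("W", 12), collapse = "")
  # force mismatch against positions 9-20 of the UniProt sequence
  ref <- substr(uni, 9, 20)
  ext <- paste(ifelse(strsplit(ext, "")[[1]] == strsplit(ref, "")[[1]], "Y", "W"),
               collapse = "")
  ch <- make_chain(paste0(ext, core),
                   dbref = list(accession = "P00001", chain_start = 13L,
                                chain_end = 62L, uniprot_start = 21L,
                                uniprot_end = 70L))
  calls <- detect_tags_by_uniprot(ch, uni)
  expect_equal(nrow(calls), 0L)
  expect_match(attr(calls, "diagnostics"), "exceeds the tag length bound")
})

test_that("an interior mismatch voids the DBREF check and suppresses calls", {
  set.seed(89)
  g <- generate_chain_with_tag("8abe", "A", core_len = 60L, tag_len = 4L,
                               terminus = "N", accession = "P22222")
  ch <- g$chain
  s <- strsplit(ch$seqres, "")[[1]]
  mid <- 30L
  s[mid] <- setdiff(c("A", "C"), s[mid])[1]  # engineered point mutation
  ch$seqres <- paste(s, collapse = "")
  calls <- detect_tags_by_uniprot(ch, g$uniprot[["P22222"]])
  expect_equal(nrow(calls), 0L)
  expect_match(attr(calls, "diagnostics"), "DBREF inconsistent")
})

test_that("planted tags of every length 1-9 are recovered exactly", {
  set.seed(97)
  n_called <- 0L
  for (tag_len in 1:9) {
    for (terminus in c("N", "C")) {
      g <- generate_chain_with_tag(sprintf("8%03d", tag_len), "A",
                                   core_len = sample(40:120, 1),
                                   tag_len = tag_len, terminus = terminus,
                                   accession = "P77777")
      calls <- detect_tags_by_uniprot(g$chain, g$uniprot[["P77777"]])
      expect_equal(nrow(calls), 1L)
      expect_equal(calls$terminus, terminus)
      expect_equal(c(calls$start, calls$end),
                   c(g$expected$start, g$expected$end))
      expect_lt(calls$end - calls$start + 1L, 10L)
      n_called <- n_called + 1L
    }
  }
  expect_equal(n_called, 18L)
})

test_that("overlapping calls from both evidence paths merge with joint evidence", {
  set.seed(101)
  g <- generate_chain_with_tag("8fff", "A", core_len = 60L, tag_len = 6L,
                               terminus = "N", accession = "P33333",
                               seqadv = TRUE)
  c1 <- detect_tags_seqadv(g$chain)
  c2 <- detect_tags_by_uniprot(g$chain, g$uniprot[["P33333"]])
  merged <- merge_tag_calls(c1, c2)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$evidence, "seqadv+uniprot_compare")
  expect_equal(c(merged$start, merged$end), c(1L, 6L))
})

test_that("trimming excises tags exactly and conserves SEQRES residues", {
  set.seed(103)
  for (i in 1:30) {
    tag_len_n <- sample(1:9, 1)
    tag_len_c <- sample(1:9, 1)
    core_len <- sample(40:120, 1)
    gN <- generate_chain_with_tag(sprintf("7%03d", i), "A", core_len,
                                  tag_len_n, "N", accession = "P55555")
    # append a C-tag to the same chain by hand
    uni <- gN$uniprot[["P55555"]]
    flank <- substr(uni, 11L + core_len, 10L + core_len + tag_len_c)
    ctag <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                         tag_len_c, replace = TRUE), collapse = "")
    ctag_v <- strsplit(ctag, "")[[1]]
    flank_v <- strsplit(flank, "")[[1]]
    ctag_v[ctag_v == flank_v] <- vapply(which(ctag_v == flank_v), function(j)
      setdiff(c("W", "Y"), flank_v[j])[1], "")
    ch <- chain_record(gN$chain$pdb_id, "A",
                       paste0(gN$chain$seqres, paste(ctag_v, collapse = "")),
                       dbref = gN$chain$dbref)
    n <- nchar(ch$seqres)
    aa <- strsplit(ch$seqres, "")[[1]]
    rec <- raf_record(ch$pdb_id, "A",
                      data.frame(residue_id = as.character(seq_len(n)),
                                 atom_aa = aa, seqres_aa = aa,
                                 stringsAsFactors = FALSE))
    idx <- stats::setNames(list(rec), raf_key(rec))
    calls <- detect_tags_by_uniprot(ch, uni)
    expect_equal(nrow(calls), 2L)
    dom <- list(sid = "d7aaaa_", pdb_id = ch$pdb_id, region = "A:",
                sccs = "b.1.1.1")
    tr <- trim_domain(dom, calls, idx)
    expect_length(tr$artifacts, 2L)
    trimmed_len <- domain_lengths(tr$trimmed, idx)$seqres_len
    art_len <- sum(vapply(tr$artifacts, `[[`, 0L, "seqres_len"))
    expect_equal(trimmed_len + art_len, n)
    expect_equal(trimmed_len, core_len)
    expect_true(all(vapply(tr$artifacts, function(a)
      startsWith(a$sccs, "l."), NA)))
  }

  # no calls: identity
  dom <- list(sid = "d7aaaa_", pdb_id = "7001", region = "A:",
              sccs = "b.1.1.1")
  no <- trim_domain(dom, detect_tags_seqadv(make_chain("MKLVAAAAAA")), list())
  expect_identical(no$trimmed, dom)
  expect_length(no$artifacts, 0L)
})

test_that("whole-chain N-tag trimming rewrites the region start residue", {
  aa <- strsplit("MHHHHHHKLMVAWYPQRSTV", "")[[1]]
  rec <- raf_record("7xyz", "A",
                    data.frame(residue_id = as.character(seq_along(aa)),
                               atom_aa = aa, seqres_aa = aa,
                               stringsAsFactors = FALSE))
  idx <- list("7xyzA" = rec)
  calls <- data.frame(chain_key = "7xyzA", terminus = "N", start = 1L,
                      end = 6L, evidence = "seqadv",
                      description = "his tag", stringsAsFactors = FALSE)
  dom <- list(sid = "d7xyza_", pdb_id = "7xyz", region = "A:", sccs = "a.1.1.1")
  tr <- trim_domain(dom, calls, idx)
  expect_equal(tr$trimmed$region, "A:7-20")
  expect_length(tr$artifacts, 1L)
  expect_equal(tr$artifacts[[1]]$region, "A:1-6")

  swallow <- data.frame(chain_key = "7xyzA", terminus = "N", start = 1L,
                        end = 20L, evidence = "seqadv", description = "x",
                        stringsAsFactors = FALSE)
  expect_error(trim_domain(dom, swallow, idx), "swallows")
})
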