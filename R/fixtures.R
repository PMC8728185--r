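# ---- Deterministic synthetic fixtures --------------------------------------
#
# Generates a small, fully cross-consistent synthetic release: dir.cla and
# dir.des tables, a RAF map covering every classified chain, a chain dump
# with planted terminal tags, matching UniProt sequences, a SIFTS-style
# mapping table, and a ground-truth manifest recording every planted
# anomaly.  Everything is a pure function of the seed, so identical specs
# produce byte-identical bundles.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.random_seq <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                                 collapse = "")

.mutate_to_mismatch <- function(seq, ref) {
  # force every position of seq to differ from the same position of ref
  s <- strsplit(seq, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  same <- which(s == r)
  for (i in same) s[i] <- sample(setdiff(AA_ALPHABET, r[i]), 1L)
  paste(s, collapse = "")
}

#' Fixture generation parameters
#'
#' Defaults describe a small release of 20 families: 14 structurally
#' homogeneous (unimodal SEQRES lengths, sd 3 residues), 3 with a planted
#' bimodal length distribution (modes 100 and 200 residues, sd 3 — a mode
#' gap far exceeding 4 kernel bandwidths), and 3 small families with one
#' planted ratio outlier (factor 2, above the 1.5 screening threshold).
#' Residues are unobserved (SEQRES-only) independently at rate 0.05, the
#' magnitude typical of short disordered loops.
#'
#' @param seed integer seed; fully determines the bundle.
#' @param n_families total number of families.
#' @param n_bimodal families with a planted bimodal length distribution.
#' @param n_ratio_outlier small families with one planted length outlier.
#' @param family_size inclusive size range for unimodal families.
#' @param unimodal_mean_range SEQRES length range from which each unimodal
#'   family's mean is drawn.
#' @param length_sd within-mode SEQRES length standard deviation (residues).
#' @param bimodal_modes the two planted modes (residues).
#' @param bimodal_size inclusive size range for bimodal families (kept at or
#'   above the KDE routing threshold).
#' @param ratio_factor planted outlier length multiplier.
#' @param ratio_family_size inclusive size range for ratio-outlier families
#'   (kept below the KDE routing threshold).
#' @param disorder_rate per-residue probability of being SEQRES-only.
#' @param n_tag_chains chains with a planted mismatching terminal tag.
#' @param n_undetectable_tags additional chains whose planted tag equals the
#'   UniProt flank and is therefore undetectable by design.
#' @param n_plain_chains chains with no tag at all.
#' @return list of class \code{"fixture_spec"}.
#' @export
fixture_spec <- function(seed = 1L,
                         n_families = 20L,
                         n_bimodal = 3L,
                         n_ratio_outlier = 3L,
                         family_size = c(3L, 15L),
                         unimodal_mean_range = c(80L, 250L),
                         length_sd = 3,
                         bimodal_modes = c(100L, 200L),
                         bimodal_size = c(12L, 16L),
                         ratio_factor = 2,
                         ratio_family_size = c(3L, 8L),
                         disorder_rate = 0.05,
                         n_tag_chains = 12L,
                         n_undetectable_tags = 2L,
                         n_plain_chains = 5L) {
  stopifnot(n_families >= n_bimodal + n_ratio_outlier,
            disorder_rate >= 0, disorder_rate < 1,
            ratio_factor > 1, length(bimodal_modes) == 2L)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a random RAF record
#'
#' Building block for format round-trip tests; uses the current RNG state.
#'
#' @param pdb_id,chain_id chain identity.
#' @param n_res number of SEQRES residues.
#' @param disorder_rate per-residue probability of being SEQRES-only.
#' @param version RAF format version; 0.02 records mark unobserved residues
#'   with the legacy B/M/E letters, 0.03 records keep numeric identifiers.
#' @return a \code{raf_record}.
#' @export
random_raf_record <- function(pdb_id, chain_id = "A", n_res = 100L,
                              disorder_rate = 0.05, version = "0.03") {
  aa <- sample(AA_ALPHABET, n_res, replace = TRUE)
  unobserved <- stats::runif(n_res) < disorder_rate
  ids <- as.character(seq_len(n_res))
  if (version == "0.02" && any(unobserved)) {
    observed <- which(!unobserved)
    first_obs <- if (length(observed)) observed[1] else n_res + 1L
    last_obs <- if (length(observed)) observed[length(observed)] else 0L
    ids[unobserved] <- vapply(which(unobserved), function(i) {
      if (i < first_obs) "B" else if (i > last_obs) "E" else "M"
    }, "")
  }
  cells <- data.frame(residue_id = ids,
                      atom_aa = ifelse(unobserved, ".", aa),
                      seqres_aa = aa,
                      stringsAsFactors = FALSE)
  raf_record(pdb_id, chain_id, cells, version = version)
}

.pdb_code <- function(prefix, i) sprintf("%s%03d", prefix, i)

# draw one integer from an inclusive range (safe when the range is a point)
.draw <- function(rng) if (rng[1] >= rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)

#' Generate one chain with a planted terminal tag
#'
#' The chain is a UniProt window with a tag of 1-9 residues prepended (N) or
#' appended (C); the DBREF record covers the core window.  The tag either
#' mismatches the flanking UniProt sequence at every position (detectable by
#' sequence comparison) or equals the flank exactly (undetectable by
#' design).
#'
#' @param pdb_id,chain_id chain identity.
#' @param core_len length of the UniProt-matching core (at least 10).
#' @param tag_len planted tag length, 1-9.
#' @param terminus \code{"N"} or \code{"C"}.
#' @param accession UniProt accession to synthesise.
#' @param detectable plant a mismatching (TRUE) or flank-identical (FALSE)
#'   tag.
#' @param seqadv also record the tag in a SEQADV note.
#' @return list with \code{chain} (a \code{chain_record}), \code{uniprot}
#'   (named character vector of length 1), \code{expected} (tag-call
#'   data.frame; zero rows when the tag is undetectable) and
#'   \code{detectable}.
#' @export
generate_chain_with_tag <- function(pdb_id, chain_id = "A", core_len = 80L,
                                    tag_len = 6L, terminus = c("N", "C"),
                                    accession = "P90001",
                                    detectable = TRUE, seqadv = FALSE) {
  terminus <- match.arg(terminus)
  if (tag_len < 1L || tag_len > 9L)
    stop("planted tag length must be between 1 and 9 residues")
  if (core_len < 10L)
    stop("core shorter than 10 residues cannot anchor a DBREF window")
  margin <- 10L
  uni <- .random_seq(core_len + 2L * margin)
  u1 <- margin + 1L
  core <- substr(uni, u1, u1 + core_len - 1L)
  if (terminus == "N") {
    flank <- substr(uni, u1 - tag_len, u1 - 1L)
    tag <- if (detectable) .mutate_to_mismatch(.random_seq(tag_len), flank)
           else flank
    seqres <- paste0(tag, core)
    dbref <- list(accession = accession,
                  chain_start = tag_len + 1L, chain_end = tag_len + core_len,
                  uniprot_start = u1, uniprot_end = u1 + core_len - 1L)
    iv <- c(1L, tag_len)
  } else {
    flank <- substr(uni, u1 + core_len, u1 + core_len + tag_len - 1L)
    tag <- if (detectable) .mutate_to_mismatch(.random_seq(tag_len), flank)
           else flank
    seqres <- paste0(core, tag)
    dbref <- list(accession = accession,
                  chain_start = 1L, chain_end = core_len,
                  uniprot_start = u1, uniprot_end = u1 + core_len - 1L)
    iv <- c(core_len + 1L, core_len + tag_len)
  }
  sa <- if (seqadv)
    data.frame(start = iv[1], end = iv[2], description = "EXPRESSION TAG",
               stringsAsFactors = FALSE)
  else data.frame(start = integer(), end = integer(),
                  description = character())
  chain <- chain_record(pdb_id, chain_id, seqres, seqadv = sa, dbref = dbref)
  expected <- if (detectable)
    data.frame(chain_key = chain_key(chain), terminus = terminus,
               start = iv[1], end = iv[2], evidence = "uniprot_compare",
               description = "planted", stringsAsFactors = FALSE)
  else
    data.frame(chain_key = character(), terminus = character(),
               start = integer(), end = integer(), evidence = character(),
               description = character(), stringsAsFactors = FALSE)
  list(chain = chain, uniprot = stats::setNames(uni, accession),
       expected = expected, detectable = detectable)
}

#' Generate a synthetic release bundle
#'
#' @param spec a [fixture_spec()].
#' @param out_dir optional directory; when given, the bundle is written as
#'   \code{dir.cla.txt}, \code{dir.des.txt}, \code{raf.txt},
#'   \code{chains.json}, \code{uniprot.fasta}, \code{sifts.tsv} and
#'   \code{manifest.json}.
#' @return list with components \code{domains} (dir.cla table),
#'   \code{descriptions} (named character by sccs), \code{raf_index} (named
#'   list of RAF records), \code{chains} (list of \code{chain_record}s),
#'   \code{uniprot} (named character vector), \code{sifts} (mapping table)
#'   and \code{manifest} (ground truth: per-family model and expected flag
#'   reason; per-chain planted tag with terminus, extent and detectability).
#' @export
generate_release <- function(spec = fixture_spec(), out_dir = NULL) {
  set.seed(spec$seed)
  models <- c(rep("bimodal", spec$n_bimodal),
              rep("ratio_outlier", spec$n_ratio_outlier),
              rep("unimodal", spec$n_families - spec$n_bimodal -
                    spec$n_ratio_outlier))
  class_letters <- rep(letters[1:7], length.out = spec$n_families)
  domains <- NULL
  raf_index <- list()
  descriptions <- character()
  fam_truth <- data.frame(sccs = character(), model = character(),
                          expected_reason = character(),
                          stringsAsFactors = FALSE)
  sunid_counter <- 100000L
  chain_counter <- 0L
  for (f in seq_len(spec$n_families)) {
    model <- models[f]
    sccs <- sprintf("%s.%d.1.1", class_letters[f], 100L + f)
    lengths <- switch(model,
      unimodal = {
        n <- .draw(spec$family_size)
        mu <- .draw(spec$unimodal_mean_range)
        pmax(20L, round(mu + pmax(pmin(stats::rnorm(n, 0, spec$length_sd),
                                       3 * spec$length_sd),
                                  -3 * spec$length_sd)))
      },
      bimodal = {
        n <- .draw(spec$bimodal_size)
        half <- n %/% 2L
        mode_of <- c(rep(1L, half), rep(2L, n - half))
        pmax(20L, round(spec$bimodal_modes[mode_of] +
                          pmax(pmin(stats::rnorm(n, 0, spec$length_sd),
                                    3 * spec$length_sd),
                               -3 * spec$length_sd)))
      },
      ratio_outlier = {
        n <- .draw(spec$ratio_family_size)
        base <- sample(80:200, 1L)
        l <- pmax(20L, round(base + pmax(pmin(stats::rnorm(n, 0, spec$length_sd),
                                              3 * spec$length_sd),
                                         -3 * spec$length_sd)))
        l[n] <- round(base * spec$ratio_factor)
        l
      })
    expected <- switch(model,
      unimodal = "none",
      bimodal = "kde_multimodal",
      ratio_outlier = "ratio_exceeded")
    fam_truth <- rbind(fam_truth, data.frame(
      sccs = sccs, model = model, expected_reason = expected,
      stringsAsFactors = FALSE))
    descriptions[sccs] <- sprintf("Synthetic family %s", sccs)
    lin_base <- sunid_counter
    sunid_counter <- sunid_counter + 7L
    for (m in seq_along(lengths)) {
      chain_counter <- chain_counter + 1L
      pdb <- .pdb_code("9", chain_counter)
      rec <- random_raf_record(pdb, "A", lengths[m],
                               disorder_rate = spec$disorder_rate,
                               version = "0.03")
      raf_index[[raf_key(rec)]] <- rec
      sunid_counter <- sunid_counter + 1L
      row <- data.frame(sid = paste0("d", pdb, "a_"), pdb_id = pdb,
                        region = "A:", sccs = sccs, sunid = sunid_counter,
                        stringsAsFactors = FALSE)
      for (j in seq_along(LINEAGE_CODES))
        row[[LINEAGE_CODES[j]]] <- if (j < 7L) lin_base + j else sunid_counter
      domains <- rbind(domains, row)
    }
  }
  attr(domains, "header") <- sprintf("# synthetic dir.cla (seed %d)",
                                     spec$seed)

  chains <- list()
  uniprot <- character()
  tag_truth <- data.frame(chain_key = character(), terminus = character(),
                          start = integer(), end = integer(),
                          length = integer(), detectable = logical(),
                          seqadv = logical(), stringsAsFactors = FALSE)
  n_tagged <- spec$n_tag_chains + spec$n_undetectable_tags
  for (i in seq_len(n_tagged + spec$n_plain_chains)) {
    pdb <- .pdb_code("8", i)
    accession <- sprintf("P9%04d", i)
    core_len <- sample(50:150, 1L)
    if (i <= n_tagged) {
      detectable <- i <= spec$n_tag_chains
      tag_len <- sample(1:9, 1L)
      terminus <- sample(c("N", "C"), 1L)
      with_seqadv <- detectable && (i %% 2L == 0L)
      g <- generate_chain_with_tag(pdb, "A", core_len, tag_len, terminus,
                                   accession, detectable = detectable,
                                   seqadv = with_seqadv)
      chains[[chain_key(g$chain)]] <- g$chain
      uniprot[accession] <- unname(g$uniprot)
      iv <- if (terminus == "N") c(1L, tag_len)
            else c(core_len + 1L, core_len + tag_len)
      tag_truth <- rbind(tag_truth, data.frame(
        chain_key = chain_key(g$chain), terminus = terminus,
        start = iv[1], end = iv[2], length = tag_len,
        detectable = detectable, seqadv = with_seqadv,
        stringsAsFactors = FALSE))
    } else {
      uni <- .random_seq(core_len + 20L)
      core <- substr(uni, 11L, 10L + core_len)
      chain <- chain_record(pdb, "A", core,
                            dbref = list(accession = accession,
                                         chain_start = 1L,
                                         chain_end = core_len,
                                         uniprot_start = 11L,
                                         uniprot_end = 10L + core_len))
      chains[[chain_key(chain)]] <- chain
      uniprot[accession] <- uni
    }
    # RAF coverage for every chain in the dump
    ch <- chains[[length(chains)]]
    n <- nchar(ch$seqres)
    aa <- strsplit(ch$seqres, "")[[1]]
    unobserved <- stats::runif(n) < spec$disorder_rate
    raf_index[[chain_key(ch)]] <- raf_record(
      ch$pdb_id, ch$chain_id,
      data.frame(residue_id = as.character(seq_len(n)),
                 atom_aa = ifelse(unobserved, ".", aa),
                 seqres_aa = aa, stringsAsFactors = FALSE))
  }

  # SIFTS rows: every dumped chain maps its DBREF core to UniProt
  sifts <- do.call(rbind, lapply(chains, function(ch) {
    idx <- ch$dbref$chain_start:ch$dbref$chain_end
    data.frame(accession = ch$dbref$accession,
               chain_key = chain_key(ch),
               uniprot_pos = ch$dbref$uniprot_start +
                 (idx - ch$dbref$chain_start),
               seqres_index = idx, stringsAsFactors = FALSE)
  }))
  rownames(sifts) <- NULL

  manifest <- list(seed = spec$seed, families = fam_truth, tags = tag_truth)
  bundle <- list(domains = domains, descriptions = descriptions,
                 raf_index = raf_index, chains = chains, uniprot = uniprot,
                 sifts = sifts, manifest = manifest)
  if (!is.null(out_dir)) write_release(bundle, out_dir)
  bundle
}

#' Write a fixture bundle to disk
#' @param bundle list from [generate_release()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the output directory.
#' @export
write_release <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cla(bundle$domains, file.path(out_dir, "dir.cla.txt"))
  writeLines(sprintf("%s\t%s", names(bundle$descriptions),
                     unname(bundle$descriptions)),
             file.path(out_dir, "dir.des.txt"))
  write_raf(bundle$raf_index, file.path(out_dir, "raf.txt"))
  write_chain_dump(bundle$chains, file.path(out_dir, "chains.json"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(bundle$uniprot),
                              file.path(out_dir, "uniprot.fasta"))
  write_sifts(bundle$sifts, file.path(out_dir, "sifts.tsv"))
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out_dir)
}

#' Write chain records as a JSON chain dump
#' @param chains list of \code{chain_record}s.
#' @param file output path.
#' @export
write_chain_dump <- function(chains, file) {
  payload <- lapply(unname(chains), function(ch) {
    out <- list(pdb_id = ch$pdb_id, chain_id = ch$chain_id,
                seqres = ch$seqres)
    out$seqadv <- if (nrow(ch$seqadv)) ch$seqadv else list()
    if (!is.null(ch$dbref)) out$dbref <- ch$dbref
    out
  })
  jsonlite::write_json(payload, file, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Read a JSON chain dump
#' @param file path written by [write_chain_dump()].
#' @return named list of \code{chain_record}s keyed by chain key.
#' @export
read_chain_dump <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = FALSE)
  chains <- lapply(payload, function(p) {
    sa <- if (length(p$seqadv))
      do.call(rbind, lapply(p$seqadv, function(x)
        data.frame(start = x$start, end = x$end,
                   description = x$description, stringsAsFactors = FALSE)))
    else data.frame(start = integer(), end = integer(),
                    description = character())
    dbref <- if (!is.null(p$dbref)) lapply(p$dbref, identity)
    chain_record(p$pdb_id, p$chain_id, p$seqres, seqadv = sa, dbref = dbref)
  })
  stats::setNames(chains, vapply(chains, chain_key, ""))
}

#' Read UniProt sequences from a FASTA file
#' @param file FASTA path.
#' @return named character vector keyed by accession.
#' @export
read_uniprot_fasta <- function(file) {
  set <- Biostrings::readAAStringSet(file)
  stats::setNames(as.character(set), names(set))
}
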