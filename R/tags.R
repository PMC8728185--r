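# ---- Terminal cloning / expression / purification tag detection ------------
#
# Two independent evidence paths identify non-natural terminal segments:
#   * SEQADV metadata: PDB annotations whose description names an expression
#     tag, cloning artifact, purification tag or linker, anchored at a chain
#     terminus (adjacent qualifying notes are merged first).
#   * UniProt comparison: for chains with a DBREF cross-reference, a terminal
#     run that mismatches the aligned UniProt canonical sequence is a
#     putative tag when it is shorter than 10 residues AND the remaining
#     (non-tag) SEQRES matches the corresponding UniProt subsequence exactly,
#     which verifies the DBREF record itself.
# Detected tags can then be excised from classified domains, with the
# excised pieces re-filed as artifact-class (l.) domain records.

#' Construct a chain record
#'
#' A neutral representation of one PDB chain: its SEQRES sequence, SEQADV
#' difference annotations, and an optional DBREF cross-reference to a
#' UniProt entry.
#'
#' @param pdb_id 4-character PDB entry id.
#' @param chain_id single chain character.
#' @param seqres one-letter SEQRES sequence string.
#' @param seqadv data.frame with columns \code{start}, \code{end} (1-based
#'   inclusive SEQRES interval) and \code{description}; may be empty.
#' @param dbref optional list with \code{accession}, \code{chain_start},
#'   \code{chain_end} (SEQRES interval) and \code{uniprot_start},
#'   \code{uniprot_end} (UniProt interval of equal length).
#' @return object of class \code{"chain_record"}.
#' @export
chain_record <- function(pdb_id, chain_id, seqres,
                         seqadv = data.frame(start = integer(),
                                             end = integer(),
                                             description = character()),
                         dbref = NULL) {
  stopifnot(nchar(pdb_id) == 4L, nchar(chain_id) == 1L, nzchar(seqres))
  n <- nchar(seqres)
  if (nrow(seqadv) &&
      (any(seqadv$start < 1L) || any(seqadv$end > n) ||
       any(seqadv$start > seqadv$end)))
    stop("SEQADV interval outside sequence bounds")
  if (!is.null(dbref)) {
    stopifnot(all(c("accession", "chain_start", "chain_end",
                    "uniprot_start", "uniprot_end") %in% names(dbref)))
    if (dbref$chain_start < 1L || dbref$chain_end > n ||
        dbref$chain_start > dbref$chain_end)
      stop("DBREF chain range outside sequence bounds")
    if (dbref$chain_end - dbref$chain_start !=
        dbref$uniprot_end - dbref$uniprot_start)
      stop("DBREF chain and UniProt ranges differ in length")
  }
  structure(list(pdb_id = pdb_id, chain_id = chain_id, seqres = seqres,
                 seqadv = seqadv, dbref = dbref),
            class = "chain_record")
}

#' Chain key of a chain record
#' @param chain a \code{chain_record}.
#' @return 5-character chain key.
#' @export
chain_key <- function(chain) paste0(chain$pdb_id, chain$chain_id)

#' Default SEQADV tag vocabulary
#'
#' Description phrases accepted as evidence for a non-natural terminal
#' segment.  The initiator methionine is a natural residue and deliberately
#' absent.
#'
#' @return character vector of phrases (matched case-insensitively as
#'   substrings).
#' @export
tag_vocabulary <- function() {
  c("expression tag", "cloning artifact", "purification tag", "linker")
}

.tag_call <- function(chain_key = character(), terminus = character(),
                      start = integer(), end = integer(),
                      evidence = character(), description = character()) {
  data.frame(chain_key = chain_key, terminus = terminus,
             start = start, end = end, evidence = evidence,
             description = description, stringsAsFactors = FALSE)
}

#' Detect terminal tags from SEQADV metadata
#'
#' A SEQADV note yields a call when its description matches the vocabulary
#' and the note (after merging adjacent qualifying notes) touches position 1
#' (N terminus) or the last SEQRES position (C terminus).  Qualifying notes
#' in the chain interior are reported with a warning, never called.
#'
#' @param chain a [chain_record()].
#' @param vocabulary phrases accepted as tag evidence, see [tag_vocabulary()].
#' @return data.frame of tag calls with columns \code{chain_key},
#'   \code{terminus} (\code{"N"}/\code{"C"}), \code{start}, \code{end},
#'   \code{evidence} (\code{"seqadv"}), \code{description}.
#' @export
detect_tags_seqadv <- function(chain, vocabulary = tag_vocabulary()) {
  n <- nchar(chain$seqres)
  sa <- chain$seqadv
  if (!nrow(sa)) return(.tag_call())
  qual <- vapply(sa$description, function(d)
    any(vapply(vocabulary, function(v) grepl(v, d, ignore.case = TRUE), NA)),
    NA, USE.NAMES = FALSE)
  sa <- sa[qual, , drop = FALSE]
  if (!nrow(sa)) return(.tag_call())
  sa <- sa[order(sa$start), , drop = FALSE]
  # merge adjacent/overlapping qualifying notes
  merged <- list(list(start = sa$start[1], end = sa$end[1],
                      description = sa$description[1]))
  for (k in seq_len(nrow(sa))[-1]) {
    last <- merged[[length(merged)]]
    if (sa$start[k] <= last$end + 1L) {
      last$end <- max(last$end, sa$end[k])
      last$description <- paste(unique(c(last$description,
                                         sa$description[k])),
                                collapse = "; ")
      merged[[length(merged)]] <- last
    } else {
      merged <- c(merged, list(list(start = sa$start[k], end = sa$end[k],
                                    description = sa$description[k])))
    }
  }
  calls <- .tag_call()
  for (m in merged) {
    if (m$start == 1L) {
      calls <- rbind(calls, .tag_call(chain_key(chain), "N", m$start, m$end,
                                      "seqadv", m$description))
    } else if (m$end == n) {
      calls <- rbind(calls, .tag_call(chain_key(chain), "C", m$start, m$end,
                                      "seqadv", m$description))
    } else {
      warning(sprintf(
        "chain %s: internal SEQADV note [%d,%d] '%s' matches tag vocabulary but is not terminal",
        chain_key(chain), m$start, m$end, m$description))
    }
  }
  calls
}

# UniProt position implied for each SEQRES position by extending the DBREF
# offset; positions before 1 or past the end of the UniProt sequence have no
# correspondence and automatically mismatch.
.implied_uniprot_pos <- function(chain) {
  n <- nchar(chain$seqres)
  chain$dbref$uniprot_start + (seq_len(n) - chain$dbref$chain_start)
}

#' Detect terminal tags by comparison to the UniProt canonical sequence
#'
#' For each terminus, the maximal terminal run of SEQRES residues that fall
#' outside, or mismatch, the DBREF-aligned UniProt sequence is a putative
#' tag when its length is between 1 and 9 residues.  The call is made only
#' if the interior (non-tag) SEQRES matches the corresponding UniProt
#' subsequence exactly; any interior mismatch invalidates the DBREF
#' consistency check and suppresses all calls, with a diagnostic attached as
#' the \code{"diagnostics"} attribute.  A mismatching terminal run of 10 or
#' more residues is likewise reported as a diagnostic, never called.
#'
#' @param chain a [chain_record()] with a DBREF cross-reference.
#' @param uniprot_seq canonical sequence of the referenced UniProt entry.
#' @return data.frame of tag calls (evidence \code{"uniprot_compare"}).
#' @export
detect_tags_by_uniprot <- function(chain, uniprot_seq) {
  if (is.null(chain$dbref)) stop("chain has no DBREF cross-reference")
  n <- nchar(chain$seqres)
  nu <- nchar(uniprot_seq)
  if (chain$dbref$uniprot_end > nu)
    stop(sprintf("DBREF UniProt range [%d,%d] exceeds sequence length %d",
                 chain$dbref$uniprot_start, chain$dbref$uniprot_end, nu))
  upos <- .implied_uniprot_pos(chain)
  chain_aa <- strsplit(chain$seqres, "")[[1]]
  uni_aa <- strsplit(uniprot_seq, "")[[1]]
  in_uni <- upos >= 1L & upos <= nu
  match_v <- in_uni & chain_aa == ifelse(in_uni, uni_aa[pmax(upos, 1L)], "")
  n_run <- if (all(!match_v)) n else which(match_v)[1] - 1L
  c_run <- if (all(!match_v)) 0L else n - max(which(match_v))
  diagnostics <- character()
  interior <- setdiff(seq_len(n), c(seq_len(n_run), seq_len(c_run) + n - c_run))
  if (length(interior) && !all(match_v[interior])) {
    diagnostics <- sprintf(
      "chain %s: non-tag SEQRES mismatches UniProt %s at %d position(s); DBREF inconsistent, no calls made",
      chain_key(chain), chain$dbref$accession, sum(!match_v[interior]))
    calls <- .tag_call()
    attr(calls, "diagnostics") <- diagnostics
    return(calls)
  }
  calls <- .tag_call()
  for (t in c("N", "C")) {
    run <- if (t == "N") n_run else c_run
    if (run == 0L) next
    iv <- if (t == "N") c(1L, run) else c(n - run + 1L, n)
    if (run >= 10L) {
      diagnostics <- c(diagnostics, sprintf(
        "chain %s: %s-terminal mismatching run of %d residues exceeds the tag length bound (<10); not called",
        chain_key(chain), t, run))
    } else {
      calls <- rbind(calls, .tag_call(
        chain_key(chain), t, iv[1], iv[2], "uniprot_compare",
        sprintf("%d-residue %s-terminal segment absent from %s",
                run, t, chain$dbref$accession)))
    }
  }
  attr(calls, "diagnostics") <- diagnostics
  calls
}

#' Merge tag calls from both evidence paths
#'
#' Calls on the same chain and terminus with overlapping intervals are
#' collapsed into one call covering their union, with the evidence values
#' concatenated.
#'
#' @param ... tag-call data.frames.
#' @return merged tag-call data.frame.
#' @export
merge_tag_calls <- function(...) {
  calls <- do.call(rbind, lapply(list(...), function(x) {
    attr(x, "diagnostics") <- NULL
    x
  }))
  if (is.null(calls) || !nrow(calls)) return(.tag_call())
  out <- .tag_call()
  for (key in unique(paste(calls$chain_key, calls$terminus))) {
    grp <- calls[paste(calls$chain_key, calls$terminus) == key, , drop = FALSE]
    out <- rbind(out, .tag_call(
      grp$chain_key[1], grp$terminus[1], min(grp$start), max(grp$end),
      paste(sort(unique(grp$evidence)), collapse = "+"),
      paste(unique(grp$description), collapse = "; ")))
  }
  out[order(out$chain_key, out$terminus), , drop = FALSE]
}

#' Excise tag segments from a classified domain
#'
#' Removes the called tag intervals from the domain's region (exact residue
#' bookkeeping through the chain's RAF record) and returns the excised
#' pieces as artifact-class domain records (sccs \code{"l.1.1.1"}).
#'
#' @param domain list or one-row data.frame with \code{sid}, \code{pdb_id},
#'   \code{region}, \code{sccs}.
#' @param calls tag-call data.frame; calls must lie on chains covered by the
#'   domain's region, and a call must not straddle a region boundary in the
#'   middle of a segment.
#' @param raf_index named list of \code{raf_record}s keyed by chain key.
#' @return list with \code{trimmed} (the domain with tag residues excluded;
#'   region rewritten with explicit residue-id bounds) and \code{artifacts}
#'   (list of artifact domain records, one per excised interval).
#' @export
trim_domain <- function(domain, calls, raf_index) {
  region <- domain$region
  if (is.character(region)) region <- parse_region(region)
  if (!nrow(calls))
    return(list(trimmed = domain, artifacts = list()))
  new_chain <- region$chain
  new_start <- region$start
  new_end <- region$end
  artifacts <- list()
  for (ci in seq_len(nrow(calls))) {
    call <- calls[ci, ]
    rec <- raf_index[[call$chain_key]]
    if (is.null(rec)) stop("no RAF record for chain ", call$chain_key)
    seg <- which(vapply(seq_len(nrow(region)), function(k) {
      r <- .segment_record(region$chain[k], domain$pdb_id, raf_index)
      raf_key(r) == call$chain_key
    }, NA))
    if (!length(seg))
      stop("tag call on chain ", call$chain_key,
           " not covered by the domain's region")
    seg <- seg[1]
    rng <- .segment_cells(rec, new_start[seg], new_end[seg])
    sq_cells <- which(rec$cells$seqres_aa != ".")
    # SEQRES-index span of the (current) segment
    s1 <- which(sq_cells >= rng[1])[1]
    s2 <- max(which(sq_cells <= rng[2]))
    if (call$end < s1 || call$start > s2) next  # tag outside the domain
    if (call$terminus == "N") {
      if (call$start > s1)
        stop("N-terminal call [", call$start, ",", call$end,
             "] starts inside the segment: overlaps a region boundary")
      if (call$end >= s2)
        stop("tag call [", call$start, ",", call$end,
             "] swallows the whole segment")
      excised <- c(s1, call$end)
      new_start[seg] <- rec$cells$residue_id[sq_cells[call$end + 1L]]
      if (is.na(new_end[seg])) new_end[seg] <- rec$cells$residue_id[rng[2]]
    } else {
      if (call$end < s2)
        stop("C-terminal call [", call$start, ",", call$end,
             "] ends inside the segment: overlaps a region boundary")
      if (call$start <= s1)
        stop("tag call [", call$start, ",", call$end,
             "] swallows the whole segment")
      excised <- c(call$start, s2)
      new_end[seg] <- rec$cells$residue_id[sq_cells[call$start - 1L]]
      if (is.na(new_start[seg])) new_start[seg] <- rec$cells$residue_id[rng[1]]
    }
    new_chain[seg] <- rec$chain_id
    art_region <- .region_spec(rec$chain_id,
                               rec$cells$residue_id[sq_cells[excised[1]]],
                               rec$cells$residue_id[sq_cells[excised[2]]])
    artifacts <- c(artifacts, list(list(
      sid = sprintf("%s_%s%d", domain$sid, tolower(call$terminus), ci),
      pdb_id = domain$pdb_id,
      region = format_region(art_region),
      sccs = "l.1.1.1",
      source_sid = domain$sid,
      evidence = call$evidence,
      seqres_len = excised[2] - excised[1] + 1L
    )))
  }
  trimmed <- domain
  trimmed$region <- format_region(.region_spec(new_chain, new_start, new_end))
  list(trimmed = trimmed, artifacts = artifacts)
}
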