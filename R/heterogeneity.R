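# ---- Family-level structural-heterogeneity flagging ------------------------
#
# If every domain in a family has essentially the same structure, the domain
# lengths should be near-identical.  The screen therefore collects, per
# domain, the SEQRES length (genetically encoded) and the ATOM length
# (experimentally observed), and flags families whose length distribution is
# suspicious: multimodal SEQRES lengths (large families, Gaussian KDE peak
# count), an excessive longest/shortest ratio (small families), domains with
# a large SEQRES-vs-ATOM deficit, or free-text metadata containing keywords
# that hint at duplication/fragmentation.  Flags are input to manual review;
# assigning one of the eleven heterogeneity labels stays with the curator.

#' Configuration for the heterogeneity screen
#'
#' @param large_family_min family size at or above which the KDE peak test is
#'   used; smaller families use the longest/shortest ratio test.
#' @param kde_bandwidth Gaussian kernel bandwidth in residues; \code{NULL}
#'   (default) adapts per family to 10\% of the median SEQRES length, floored
#'   at 3 residues.
#' @param kde_grid_step evaluation grid step in residues; \code{NULL} uses
#'   bandwidth / 10.
#' @param ratio_threshold families whose longest/shortest SEQRES ratio is at
#'   or above this are flagged.
#' @param atom_deficit_fraction a domain whose ATOM length falls below
#'   (1 - fraction) of its SEQRES length is reported as having a significant
#'   SEQRES-vs-ATOM discrepancy.
#' @param fragment_fraction a domain missing at least this fraction of the
#'   family's reference (median) SEQRES length, in sequence or in structure,
#'   is a fragment candidate.
#' @param keywords free-text metadata containing any of these (case-
#'   insensitive substring match) flags the family.
#' @return list of class \code{"flag_config"}.
#' @export
flag_config <- function(large_family_min = 10L,
                        kde_bandwidth = NULL,
                        kde_grid_step = NULL,
                        ratio_threshold = 1.5,
                        atom_deficit_fraction = 1 / 3,
                        fragment_fraction = 1 / 3,
                        keywords = c("duplication", "repeat", "swap",
                                     "fragment", "circular permut")) {
  stopifnot(large_family_min >= 2L, ratio_threshold > 1,
            atom_deficit_fraction > 0, atom_deficit_fraction < 1,
            fragment_fraction > 0, fragment_fraction < 1,
            is.null(kde_bandwidth) || kde_bandwidth > 0,
            is.null(kde_grid_step) || kde_grid_step > 0)
  structure(list(large_family_min = as.integer(large_family_min),
                 kde_bandwidth = kde_bandwidth,
                 kde_grid_step = kde_grid_step,
                 ratio_threshold = ratio_threshold,
                 atom_deficit_fraction = atom_deficit_fraction,
                 fragment_fraction = fragment_fraction,
                 keywords = keywords),
            class = "flag_config")
}

.family_bandwidth <- function(lengths, config) {
  if (!is.null(config$kde_bandwidth)) return(config$kde_bandwidth)
  max(3, 0.1 * stats::median(lengths))
}

#' SEQRES and ATOM lengths of a classified domain
#'
#' Sums, over the segments of the domain's region, the number of SEQRES
#' residues and the number of experimentally observed (ATOM) residues, using
#' the chain's RAF record for the residue bookkeeping.
#'
#' @param domain a list or one-row data.frame with elements \code{sid},
#'   \code{pdb_id} and \code{region} (concise region string or
#'   \code{region_spec}).
#' @param raf_index named list of \code{raf_record}s keyed by chain key.
#' @return list with \code{sid}, \code{seqres_len}, \code{atom_len}.
#' @export
domain_lengths <- function(domain, raf_index) {
  region <- domain$region
  if (is.character(region)) region <- parse_region(region)
  seqres_len <- 0L
  atom_len <- 0L
  for (k in seq_len(nrow(region))) {
    rec <- .segment_record(region$chain[k], domain$pdb_id, raf_index)
    rng <- .segment_cells(rec, region$start[k], region$end[k])
    cells <- rec$cells[rng[1]:rng[2], , drop = FALSE]
    seqres_len <- seqres_len + sum(cells$seqres_aa != ".")
    atom_len <- atom_len + sum(cells$atom_aa != ".")
  }
  list(sid = domain$sid, seqres_len = seqres_len, atom_len = atom_len)
}

#' Count the peaks of a Gaussian kernel density estimate of domain lengths
#'
#' The density is evaluated exactly (no binning) on a regular grid spanning
#' \code{[min - 3 bw, max + 3 bw]}.  A peak is a strict local maximum on the
#' grid, with plateau runs collapsed to a single candidate; candidates whose
#' rise above the adjacent minima is below 1\% of the maximum density are
#' discarded as numerical ripple.
#'
#' @param lengths integer vector of SEQRES lengths (at least 2 values).
#' @param bandwidth Gaussian kernel bandwidth in residues.
#' @param grid_step evaluation grid step; default bandwidth / 10.
#' @return integer peak count.
#' @export
kde_peak_count <- function(lengths, bandwidth, grid_step = bandwidth / 10) {
  if (length(lengths) < 2L)
    stop("kde_peak_count needs at least 2 lengths; ",
         "route small families to the ratio test")
  stopifnot(bandwidth > 0, grid_step > 0)
  grid <- seq(min(lengths) - 3 * bandwidth, max(lengths) + 3 * bandwidth,
              by = grid_step)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, lengths, bandwidth)),
                 0)
  count_grid_peaks(dens)
}

#' Count peaks in a densely evaluated curve
#'
#' Shared peak definition for the KDE screen: plateau runs are collapsed,
#' strict local maxima are candidates, and a candidate survives only if it
#' rises by at least \code{min_prominence} times the curve maximum above the
#' higher of its two neighbouring minima (curve endpoints count as minima).
#'
#' @param dens numeric vector of density values on a regular grid.
#' @param min_prominence minimum rise as a fraction of \code{max(dens)}.
#' @return integer peak count.
#' @export
count_grid_peaks <- function(dens, min_prominence = 0.01) {
  r <- rle(dens)
  v <- r$values
  m <- length(v)
  if (m == 1L) return(0L)
  thresh <- min_prominence * max(dens)
  n_peaks <- 0L
  for (j in seq_len(m)) {
    left <- if (j > 1L) v[j - 1L] else -Inf
    right <- if (j < m) v[j + 1L] else -Inf
    if (v[j] > left && v[j] > right) {
      # walk outward to the neighbouring minima
      lo_l <- if (j > 1L) .valley(v, j, -1L) else v[j]
      lo_r <- if (j < m) .valley(v, j, +1L) else v[j]
      drop <- v[j] - max(lo_l, lo_r)
      if (drop >= thresh) n_peaks <- n_peaks + 1L
    }
  }
  n_peaks
}

# lowest value between position j and the next higher-or-equal value in the
# given direction (or the end of the curve)
.valley <- function(v, j, dir) {
  lo <- v[j]
  i <- j + dir
  while (i >= 1L && i <= length(v) && v[i] < v[j]) {
    lo <- min(lo, v[i])
    i <- i + dir
  }
  lo
}

#' Longest-to-shortest SEQRES length ratio of a family
#' @param lengths vector of positive lengths.
#' @return max(lengths) / min(lengths).
#' @export
length_ratio <- function(lengths) {
  if (!length(lengths)) stop("empty length vector")
  if (any(lengths <= 0)) stop("non-positive length(s)")
  max(lengths) / min(lengths)
}

#' Screen one family for structural heterogeneity
#'
#' Applies the KDE peak test (families of at least
#' \code{config$large_family_min} members) or the longest/shortest ratio test
#' (smaller families), plus the per-domain SEQRES-vs-ATOM deficit rule and
#' the metadata keyword rule, and lists fragment candidates relative to the
#' family's median SEQRES length.
#'
#' @param sccs family identifier.
#' @param members data.frame with columns \code{sid}, \code{seqres_len},
#'   \code{atom_len}.
#' @param metadata character vector of free-text clade names / comments.
#' @param config a [flag_config()].
#' @return list of class \code{"family_flag_report"} with fields \code{sccs},
#'   \code{n_domains}, \code{peak_count}, \code{length_ratio},
#'   \code{median_seqres}, \code{flagged}, \code{reasons},
#'   \code{atom_deficit_sids}, \code{fragment_candidates}, \code{details}.
#' @export
flag_family <- function(sccs, members, metadata = character(), config = flag_config()) {
  stopifnot(nrow(members) >= 1L)
  n <- nrow(members)
  seqres <- members$seqres_len
  med <- stats::median(seqres)
  reasons <- character()
  peak_count <- NA_integer_
  ratio <- NA_real_
  if (n >= config$large_family_min) {
    bw <- .family_bandwidth(seqres, config)
    step <- if (is.null(config$kde_grid_step)) bw / 10 else config$kde_grid_step
    peak_count <- kde_peak_count(seqres, bw, step)
    if (peak_count > 1L) reasons <- c(reasons, "kde_multimodal")
  } else {
    ratio <- length_ratio(seqres)
    if (ratio >= config$ratio_threshold) reasons <- c(reasons, "ratio_exceeded")
  }
  deficit <- members$atom_len < (1 - config$atom_deficit_fraction) * seqres
  if (any(deficit)) reasons <- c(reasons, "atom_deficit")
  if (length(metadata)) {
    hit <- vapply(config$keywords, function(kw)
      any(grepl(kw, metadata, ignore.case = TRUE, fixed = FALSE)), NA)
    if (any(hit)) reasons <- c(reasons, "keyword_hit")
  }
  frag_cut <- (1 - config$fragment_fraction) * med
  frag <- seqres < frag_cut | members$atom_len < frag_cut
  structure(list(
    sccs = sccs, n_domains = n, peak_count = peak_count,
    length_ratio = ratio, median_seqres = med,
    flagged = length(reasons) > 0L, reasons = reasons,
    atom_deficit_sids = members$sid[deficit],
    fragment_candidates = members$sid[frag],
    details = members
  ), class = "family_flag_report")
}

#' @export
print.family_flag_report <- function(x, ...) {
  cat(sprintf("family %s (%d domains): %s\n", x$sccs, x$n_domains,
              if (x$flagged) paste("FLAGGED:", paste(x$reasons, collapse = ", "))
              else "ok"))
  invisible(x)
}

#' Screen a whole release for structurally heterogeneous families
#'
#' Groups the classified domains by family, computes SEQRES/ATOM lengths
#' through the RAF maps, and applies [flag_family()] to every family.
#'
#' @param domains data.frame from [read_cla()].
#' @param raf_index named list of \code{raf_record}s keyed by chain key.
#' @param descriptions named character vector of free-text metadata keyed by
#'   sccs (family names, curator comments).
#' @param config a [flag_config()].
#' @return list of \code{family_flag_report}s ordered by sccs.  Families with
#'   unresolvable domains (no RAF coverage) are reported in the
#'   \code{"errors"} attribute rather than aborting the screen.
#' @export
screen_release <- function(domains, raf_index, descriptions = character(),
                           config = flag_config()) {
  fams <- suppressWarnings(group_by_family(domains))
  errors <- character()
  reports <- list()
  for (sccs in sort(names(fams))) {
    fam <- fams[[sccs]]
    lp <- vector("list", nrow(fam))
    ok <- logical(nrow(fam))
    for (k in seq_len(nrow(fam))) {
      lp[[k]] <- tryCatch(domain_lengths(fam[k, ], raf_index),
                          error = function(e) conditionMessage(e))
      ok[k] <- is.list(lp[[k]])
    }
    if (any(!ok))
      errors <- c(errors, sprintf("%s: %s", fam$sid[!ok],
                                  unlist(lp[!ok])))
    if (!any(ok)) next
    members <- do.call(rbind, lapply(lp[ok], function(x)
      data.frame(sid = x$sid, seqres_len = x$seqres_len,
                 atom_len = x$atom_len, stringsAsFactors = FALSE)))
    meta <- unname(descriptions[names(descriptions) == sccs])
    reports[[sccs]] <- flag_family(sccs, members, meta, config)
  }
  attr(reports, "errors") <- errors
  reports
}

#' Summarise screen reports as a table
#' @param reports list of reports from [screen_release()].
#' @return data.frame with one row per family.
#' @export
flag_report_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(sccs = r$sccs, n_domains = r$n_domains,
               peak_count = r$peak_count, length_ratio = r$length_ratio,
               flagged = r$flagged,
               reasons = paste(r$reasons, collapse = ","),
               n_fragment_candidates = length(r$fragment_candidates),
               stringsAsFactors = FALSE)))
}

#' Sanity-check a newly classified entry against its family
#'
#' Guards manual classification (e.g. typo'd region bounds) by comparing a
#' candidate domain's lengths to the family's established length profile.
#'
#' @param candidate list with \code{sid}, \code{seqres_len}, \code{atom_len}.
#' @param family_report report from [flag_family()] on the existing members.
#' @param config a [flag_config()].
#' @return character vector of warnings (empty when the candidate looks
#'   consistent).
#' @export
validate_new_entry <- function(candidate, family_report,
                               config = flag_config()) {
  warnings <- character()
  med <- family_report$median_seqres
  r <- max(candidate$seqres_len, med) / min(candidate$seqres_len, med)
  if (r >= config$ratio_threshold)
    warnings <- c(warnings, sprintf(
      "length %d deviates from family median %g by ratio %.2f (threshold %.2f)",
      candidate$seqres_len, med, r, config$ratio_threshold))
  frag_cut <- (1 - config$fragment_fraction) * med
  if (candidate$seqres_len < frag_cut || candidate$atom_len < frag_cut)
    warnings <- c(warnings, sprintf(
      "candidate covers less than %d%% of the family median length: possible fragment",
      round(100 * (1 - config$fragment_fraction))))
  if (isTRUE(family_report$flagged))
    warnings <- c(warnings, sprintf(
      "note: family %s is itself flagged (%s)", family_report$sccs,
      paste(family_report$reasons, collapse = ", ")))
  warnings
}

#' Draft dir.inc rows for flagged families
#'
#' Emits one provisional annotation per flagged family, using the code
#' \code{"fr"} for fragment candidates and leaving other flag reasons with
#' an empty sid list for the curator to label.
#'
#' @param reports list of reports from [screen_release()].
#' @return data.frame in [read_inc()] layout (possibly zero rows).
#' @export
draft_inc <- function(reports) {
  rows <- Filter(Negate(is.null), lapply(reports, function(r) {
    if (!r$flagged) return(NULL)
    sids <- if (length(r$fragment_candidates)) list(r$fragment_candidates)
            else list(character(0))
    code <- if (length(r$fragment_candidates)) "fr" else "dv"
    out <- data.frame(sccs = r$sccs, code = code, stringsAsFactors = FALSE)
    out$sids <- sids
    out
  }))
  if (!length(rows)) {
    out <- data.frame(sccs = character(), code = character(),
                      stringsAsFactors = FALSE)
    out$sids <- list()
    return(out)
  }
  do.call(rbind, rows)
}
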