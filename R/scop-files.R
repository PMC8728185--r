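# ---- SCOPe parseable files: dir.cla, dir.inc, dir.rep ----------------------
#
# All dir.* dialects are tab-delimited, UTF-8, LF-terminated, with
# '#'-prefixed comment/header lines.  Readers keep the header lines in an
# attribute so that write_*(read_*(f)) reproduces a canonically formatted
# file byte-for-byte.

LINEAGE_CODES <- c("cl", "cf", "sf", "fa", "dm", "sp", "px")

.read_source <- function(file) {
  if (inherits(file, "connection")) {
    readLines(file, warn = FALSE)
  } else if (is.character(file) && length(file) == 1L &&
             !grepl("[\t\n]", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    as.character(file)
  }
}

.is_comment <- function(lines) startsWith(lines, "#")

.valid_sid <- function(sid) grepl("^[dge][0-9a-z_.]{6}$", sid)
.valid_sccs <- function(sccs) grepl("^[a-l](\\.[0-9]+){0,3}$", sccs)

#' Number of dot-separated components in an sccs string
#'
#' A 4-component sccs (e.g. \code{"b.1.2.1"}) names a family, 3 components a
#' superfamily, 2 a fold and 1 a class.
#'
#' @param sccs character vector of sccs identifiers.
#' @return integer vector of component counts.
#' @export
sccs_depth <- function(sccs) {
  lengths(strsplit(sccs, ".", fixed = TRUE))
}

#' Read a dir.cla classification file
#'
#' Parses the classic SCOP/SCOPe tab-delimited classification file: one line
#' per domain with sid, PDB id, region, sccs, sunid and the
#' \code{cl=...,cf=...} lineage field.
#'
#' @param file path, connection, or character vector of lines.
#' @return A data.frame with one row per domain and columns \code{sid},
#'   \code{pdb_id}, \code{region}, \code{sccs}, \code{sunid} plus one integer
#'   column per lineage level (\code{cl}, \code{cf}, \code{sf}, \code{fa},
#'   \code{dm}, \code{sp}, \code{px}).  Comment lines are preserved in the
#'   \code{"header"} attribute.  Input order is preserved.
#' @export
#' @examples
#' d <- read_cla(paste("d1dlwa_\t1dlw\tA:\ta.1.1.1\t14982",
#'   "cl=46456,cf=46457,sf=46458,fa=46459,dm=46460,sp=46461,px=14982",
#'   sep = "\t"))
#' d$sid
read_cla <- function(file) {
  lines <- .read_source(file)
  header <- lines[.is_comment(lines)]
  body_idx <- which(!.is_comment(lines) & nzchar(lines))
  n <- length(body_idx)
  out <- data.frame(
    sid = character(n), pdb_id = character(n), region = character(n),
    sccs = character(n), sunid = integer(n),
    stringsAsFactors = FALSE
  )
  for (lv in LINEAGE_CODES) out[[lv]] <- integer(n)
  for (k in seq_len(n)) {
    i <- body_idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 6L)
      stop(sprintf("dir.cla line %d: expected 6 tab-delimited fields, got %d",
                   i, length(f)))
    if (!.valid_sid(f[1]))
      stop(sprintf("dir.cla line %d: malformed sid '%s'", i, f[1]))
    if (!.valid_sccs(f[4]))
      stop(sprintf("dir.cla line %d: malformed sccs '%s'", i, f[4]))
    sunid <- suppressWarnings(as.integer(f[5]))
    if (is.na(sunid))
      stop(sprintf("dir.cla line %d: non-integer sunid '%s'", i, f[5]))
    # validates the region syntax; result discarded, the string is stored
    tryCatch(parse_region(f[3]), error = function(e)
      stop(sprintf("dir.cla line %d: unparseable region '%s' (%s)",
                   i, f[3], conditionMessage(e))))
    lin <- .parse_lineage(f[6], i)
    out$sid[k] <- f[1]; out$pdb_id[k] <- f[2]; out$region[k] <- f[3]
    out$sccs[k] <- f[4]; out$sunid[k] <- sunid
    for (lv in LINEAGE_CODES) out[[lv]][k] <- lin[[lv]]
  }
  attr(out, "header") <- header
  out
}

.parse_lineage <- function(txt, line_no) {
  pairs <- strsplit(txt, ",", fixed = TRUE)[[1]]
  kv <- strsplit(pairs, "=", fixed = TRUE)
  codes <- vapply(kv, `[`, "", 1L)
  vals <- suppressWarnings(as.integer(vapply(kv, `[`, "", 2L)))
  if (!identical(codes, LINEAGE_CODES) || anyNA(vals))
    stop(sprintf("dir.cla line %d: lineage field must contain exactly %s",
                 line_no, paste(LINEAGE_CODES, collapse = ",")))
  stats::setNames(as.list(vals), codes)
}

#' Write a dir.cla classification file
#'
#' Inverse of [read_cla()]: emits the header lines stored in the
#' \code{"header"} attribute followed by one tab-delimited line per domain.
#'
#' @param domains data.frame as returned by [read_cla()].
#' @param file path or connection.
#' @export
write_cla <- function(domains, file) {
  lineage <- vapply(seq_len(nrow(domains)), function(k) {
    paste(sprintf("%s=%d", LINEAGE_CODES,
                  unlist(domains[k, LINEAGE_CODES])), collapse = ",")
  }, "")
  body <- sprintf("%s\t%s\t%s\t%s\t%d\t%s",
                  domains$sid, domains$pdb_id, domains$region,
                  domains$sccs, domains$sunid, lineage)
  writeLines(c(attr(domains, "header"), body), file)
}

#' Registry of two-letter structural-heterogeneity codes
#'
#' Eleven categories of structural heterogeneity are recognised in dir.inc
#' annotations.  The released files do not document which two-letter code the
#' curators assigned to each category, so this registry carries a default
#' mapping that can be replaced wholesale from a two-column tab-delimited
#' file (code, label) once authoritative codes are available; no code changes
#' are needed.
#'
#' @param file optional path to a two-column TSV overriding the defaults.
#' @return data.frame with columns \code{code} and \code{label}.
#' @export
heterogeneity_codes <- function(file = NULL) {
  if (!is.null(file)) {
    tab <- utils::read.delim(file, header = FALSE, comment.char = "#",
                             col.names = c("code", "label"),
                             stringsAsFactors = FALSE)
    stopifnot(all(nchar(tab$code) == 2L))
    return(tab)
  }
  data.frame(
    code = c("dv", "sd", "ie", "fr", "ms", "ae", "me", "nd", "hf", "nt", "ri"),
    label = c(
      "multiple alternative domain divisions",
      "additional (sub)domain(s)",
      "additional insertion(s)/extension(s)",
      "fragment",
      "missing some secondary structure(s)",
      "additional element(s)",
      "missing element(s)",
      "different number of (sub)domains",
      "heterogeneous fold",
      "not a true fold",
      "repeat and inconsistent"),
    stringsAsFactors = FALSE
  )
}

#' Read a dir.inc structural-heterogeneity file
#'
#' Three tab-delimited columns: the sccs of the heterogeneous clade, a
#' two-letter heterogeneity code, and a comma-delimited list of affected sid
#' identifiers (empty when the code applies to the whole clade).
#'
#' @param file path, connection, or character vector of lines.
#' @param codes code registry, see [heterogeneity_codes()].  Unknown codes
#'   are preserved but reported with a warning.
#' @return data.frame with columns \code{sccs}, \code{code} and list-column
#'   \code{sids}; comment lines preserved in the \code{"header"} attribute.
#' @export
read_inc <- function(file, codes = heterogeneity_codes()) {
  lines <- .read_source(file)
  header <- lines[.is_comment(lines)]
  body_idx <- which(!.is_comment(lines) & nzchar(lines))
  sccs <- character(length(body_idx))
  code <- character(length(body_idx))
  sids <- vector("list", length(body_idx))
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    # a trailing empty third column is dropped by strsplit; restore it
    if (length(f) == 2L && grepl("\t$", lines[i])) f <- c(f, "")
    if (length(f) != 3L)
      stop(sprintf("dir.inc line %d: expected 3 tab-delimited columns, got %d",
                   i, length(f)))
    if (!.valid_sccs(f[1]))
      stop(sprintf("dir.inc line %d: malformed sccs '%s'", i, f[1]))
    sccs[k] <- f[1]
    code[k] <- f[2]
    sids[[k]] <- if (nzchar(f[3])) strsplit(f[3], ",", fixed = TRUE)[[1]]
                 else character(0)
  }
  unknown <- setdiff(unique(code), codes$code)
  if (length(unknown))
    warning("unknown heterogeneity code(s): ", paste(unknown, collapse = ", "))
  out <- data.frame(sccs = sccs, code = code, stringsAsFactors = FALSE)
  out$sids <- sids
  attr(out, "header") <- header
  out
}

#' Write a dir.inc structural-heterogeneity file
#' @param annotations data.frame as returned by [read_inc()].
#' @param file path or connection.
#' @export
write_inc <- function(annotations, file) {
  body <- sprintf("%s\t%s\t%s", annotations$sccs, annotations$code,
                  vapply(annotations$sids, paste, "", collapse = ","))
  writeLines(c(attr(annotations, "header"), body), file)
}

#' Read a dir.rep tandem-repeat-unit file
#'
#' Three tab-delimited columns: the family sccs, the sid of the domain in
#' which the canonical repeat unit is defined, and the unit extent written as
#' \code{start-end} in author residue numbering (insertion codes allowed).
#'
#' @param file path, connection, or character vector of lines.
#' @return data.frame with columns \code{sccs}, \code{sid},
#'   \code{unit_start}, \code{unit_end}.
#' @export
read_rep <- function(file) {
  lines <- .read_source(file)
  header <- lines[.is_comment(lines)]
  body_idx <- which(!.is_comment(lines) & nzchar(lines))
  out <- data.frame(sccs = character(length(body_idx)),
                    sid = character(length(body_idx)),
                    unit_start = character(length(body_idx)),
                    unit_end = character(length(body_idx)),
                    stringsAsFactors = FALSE)
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3L)
      stop(sprintf("dir.rep line %d: expected 3 tab-delimited columns, got %d",
                   i, length(f)))
    m <- regmatches(f[3], regexec("^([0-9]+[A-Za-z]?)-([0-9]+[A-Za-z]?)$", f[3]))[[1]]
    if (length(m) != 3L)
      stop(sprintf("dir.rep line %d: malformed unit extent '%s'", i, f[3]))
    out$sccs[k] <- f[1]; out$sid[k] <- f[2]
    out$unit_start[k] <- m[2]; out$unit_end[k] <- m[3]
  }
  attr(out, "header") <- header
  out
}

#' Write a dir.rep tandem-repeat-unit file
#'
#' Residue identifiers with negative author numbering cannot be serialised
#' unambiguously in the \code{start-end} column and are rejected.
#'
#' @param annotations data.frame as returned by [read_rep()].
#' @param file path or connection.
#' @export
write_rep <- function(annotations, file) {
  if (any(grepl("-", c(annotations$unit_start, annotations$unit_end),
                fixed = TRUE)))
    stop("negative residue identifiers cannot be written to dir.rep")
  body <- sprintf("%s\t%s\t%s-%s", annotations$sccs, annotations$sid,
                  annotations$unit_start, annotations$unit_end)
  writeLines(c(attr(annotations, "header"), body), file)
}

# ---- region specifications -------------------------------------------------

#' Parse a SCOP concise region specification
#'
#' Understands the classic dialect: \code{"A:"} (whole chain), \code{"A:1-100"}
#' (bounded segment, author numbering with optional insertion codes, e.g.
#' \code{"A:100A-200"}), comma-joined multi-segment regions, and \code{"-"}
#' for the whole single-chain entry.
#'
#' @param text a single region string.
#' @return A data.frame of class \code{"region_spec"} with one row per
#'   segment and character columns \code{chain}, \code{start}, \code{end}
#'   (\code{NA} = absent bound / absent chain id).
#' @export
parse_region <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  if (text == "-") {
    return(.region_spec(NA_character_, NA_character_, NA_character_))
  }
  parts <- strsplit(text, ",", fixed = TRUE)[[1]]
  chain <- start <- end <- character(length(parts))
  res <- "(-?[0-9]+[A-Za-z]?)"
  for (k in seq_along(parts)) {
    p <- parts[k]
    if (grepl("^[0-9A-Za-z]:$", p)) {
      chain[k] <- sub(":$", "", p); start[k] <- NA; end[k] <- NA
    } else if (grepl(paste0("^[0-9A-Za-z]:", res, "-", res, "$"), p)) {
      m <- regmatches(p, regexec(paste0("^([0-9A-Za-z]):", res, "-", res, "$"), p))[[1]]
      chain[k] <- m[2]; start[k] <- m[3]; end[k] <- m[4]
    } else if (grepl(paste0("^", res, "-", res, "$"), p) && !startsWith(p, "-")) {
      m <- regmatches(p, regexec(paste0("^", res, "-", res, "$"), p))[[1]]
      chain[k] <- NA; start[k] <- m[2]; end[k] <- m[3]
    } else {
      stop(sprintf("unparseable region segment '%s'", p))
    }
    if (!is.na(start[k])) {
      s_num <- as.integer(sub("[A-Za-z]$", "", start[k]))
      e_num <- as.integer(sub("[A-Za-z]$", "", end[k]))
      if (s_num > e_num)
        stop(sprintf("region segment '%s': start follows end", p))
    }
  }
  .region_spec(chain, start, end)
}

.region_spec <- function(chain, start, end) {
  out <- data.frame(chain = chain, start = start, end = end,
                    stringsAsFactors = FALSE)
  class(out) <- c("region_spec", "data.frame")
  out
}

#' Format a region specification back to its concise string
#' @param spec a \code{region_spec} as returned by [parse_region()].
#' @return a single region string.
#' @export
format_region <- function(spec) {
  segs <- vapply(seq_len(nrow(spec)), function(k) {
    ch <- spec$chain[k]
    if (is.na(ch)) {
      if (is.na(spec$start[k])) "-" else
        sprintf("%s-%s", spec$start[k], spec$end[k])
    } else if (is.na(spec$start[k])) {
      paste0(ch, ":")
    } else {
      sprintf("%s:%s-%s", ch, spec$start[k], spec$end[k])
    }
  }, "")
  paste(segs, collapse = ",")
}

#' Group classified domains by family
#'
#' @param domains data.frame as returned by [read_cla()].
#' @return A named list mapping each 4-component (family-level) sccs to the
#'   data.frame of its member domains, in stable input order.  Domains whose
#'   sccs has fewer than 4 components are excluded; their sids are attached
#'   as the \code{"excluded"} attribute and reported with a warning.
#' @export
group_by_family <- function(domains) {
  depth <- sccs_depth(domains$sccs)
  excl <- domains$sid[depth < 4L]
  if (length(excl))
    warning(sprintf("%d domain(s) without family-level sccs excluded: %s",
                    length(excl), paste(excl, collapse = ", ")))
  keep <- domains[depth == 4L, , drop = FALSE]
  fams <- split(keep, factor(keep$sccs, levels = unique(keep$sccs)))
  attr(fams, "excluded") <- excl
  fams
}

#' Census of a classification release
#'
#' Counts the distinct domain and PDB-entry identifiers in a dir.cla table
#' and, when a dir.inc table is supplied, the number of annotated clades at
#' family level (4-component sccs) and fold level (2-component sccs).
#'
#' @param domains data.frame from [read_cla()].
#' @param inc optional data.frame from [read_inc()].
#' @return list with \code{n_sids}, \code{n_pdb_ids} and, if \code{inc} is
#'   given, \code{n_family_clades} and \code{n_fold_clades}.
#' @export
release_census <- function(domains, inc = NULL) {
  out <- list(n_sids = length(unique(domains$sid)),
              n_pdb_ids = length(unique(domains$pdb_id)))
  if (!is.null(inc)) {
    depth <- sccs_depth(inc$sccs)
    out$n_family_clades <- length(unique(inc$sccs[depth == 4L]))
    out$n_fold_clades <- length(unique(inc$sccs[depth == 2L]))
  }
  out
}
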