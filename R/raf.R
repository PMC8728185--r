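# ---- RAF: Rapid Access Format SEQRES <-> ATOM residue maps -----------------
#
# One body line per chain summarises, in SEQRES order, the correspondence
# between the genetically encoded sequence (SEQRES) and the experimentally
# observed residues (ATOM records).  Version 0.02 marks SEQRES residues
# missing from the ATOM records with the placeholder letters B/M/E
# (beginning/middle/end gap); version 0.03 instead carries the PDB-assigned
# residue identifier for every cell.
#
# The byte layout is declared in one table so it can be adjusted to match a
# released raf file without touching any parsing or query logic.

.RAF_LAYOUT <- list(
  key_width   = 5L,   # 4-char PDB id + 1-char chain id
  flags_width = 2L,   # index-origin / completeness flags
  cell_width  = 7L,   # 5-char right-justified residue id + atom aa + seqres aa
  resid_width = 5L
)

.raf_prefix_width <- function() {
  .RAF_LAYOUT$key_width + 1L + .RAF_LAYOUT$flags_width + 1L
}

RAF_LEGACY_LETTERS <- c("B", "M", "E")

#' Construct a RAF record
#'
#' @param pdb_id 4-character PDB entry id.
#' @param chain_id single chain character.
#' @param cells data.frame with character columns \code{residue_id} (author
#'   residue identifier, possibly with insertion code; the legacy letters
#'   B/M/E in version 0.02), \code{atom_aa} and \code{seqres_aa} (one-letter
#'   amino-acid codes, \code{"."} when the residue is absent from the ATOM or
#'   SEQRES records respectively), in SEQRES order.
#' @param version format version, \code{"0.02"} or \code{"0.03"}.
#' @param flags two-character header flag field.
#' @return object of class \code{"raf_record"}.
#' @export
raf_record <- function(pdb_id, chain_id, cells, version = "0.03",
                       flags = "01") {
  stopifnot(nchar(pdb_id) == 4L, nchar(chain_id) == 1L,
            version %in% c("0.02", "0.03"),
            nchar(flags) == .RAF_LAYOUT$flags_width,
            is.data.frame(cells),
            all(c("residue_id", "atom_aa", "seqres_aa") %in% names(cells)))
  bad <- cells$atom_aa == "." & cells$seqres_aa == "."
  if (any(bad))
    stop("cell(s) with neither ATOM nor SEQRES residue: positions ",
         paste(which(bad), collapse = ", "))
  if (version == "0.03" &&
      any(cells$residue_id %in% RAF_LEGACY_LETTERS & cells$atom_aa == "."))
    stop("version 0.03 records may not contain legacy B/M/E identifiers")
  structure(list(pdb_id = pdb_id, chain_id = chain_id, version = version,
                 flags = flags, cells = cells),
            class = "raf_record")
}

#' Chain key of a RAF record (PDB id + chain id)
#' @param record a \code{raf_record}.
#' @return 5-character chain key, e.g. \code{"101mA"}.
#' @export
raf_key <- function(record) paste0(record$pdb_id, record$chain_id)

#' @export
print.raf_record <- function(x, ...) {
  cat(sprintf("RAF %s record %s: %d cells (%d SEQRES, %d resolved)\n",
              x$version, raf_key(x), nrow(x$cells),
              sum(x$cells$seqres_aa != "."), sum(x$cells$atom_aa != ".")))
  invisible(x)
}

#' Parse a RAF map file
#'
#' The file header declares the format version (\code{# RAF version 0.03});
#' each body line holds the chain key, the header flags, and fixed-width
#' residue cells.
#'
#' @param file path, connection, or character vector of lines.
#' @return Named list of [raf_record()] objects keyed by chain key, in input
#'   order.
#' @export
parse_raf <- function(file) {
  lines <- .read_source(file)
  ver_line <- grep("^# RAF version ", lines, value = TRUE)
  if (!length(ver_line))
    stop("RAF file lacks a '# RAF version' header")
  version <- sub("^# RAF version +", "", ver_line[1])
  if (!version %in% c("0.02", "0.03"))
    stop("unsupported RAF version '", version, "'")
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  pw <- .raf_prefix_width()
  cw <- .RAF_LAYOUT$cell_width
  out <- vector("list", length(body))
  keys <- character(length(body))
  for (k in seq_along(body)) {
    ln <- body[k]
    key <- substr(ln, 1L, .RAF_LAYOUT$key_width)
    flags <- substr(ln, .RAF_LAYOUT$key_width + 2L, pw - 1L)
    rest <- substring(ln, pw + 1L)
    if (nchar(rest) %% cw != 0L)
      stop(sprintf("chain %s: body width %d not a multiple of cell width %d",
                   key, nchar(rest), cw))
    n <- nchar(rest) %/% cw
    starts <- (seq_len(n) - 1L) * cw + 1L
    cells <- data.frame(
      residue_id = trimws(substring(rest, starts,
                                    starts + .RAF_LAYOUT$resid_width - 1L)),
      atom_aa = substring(rest, starts + 5L, starts + 5L),
      seqres_aa = substring(rest, starts + 6L, starts + 6L),
      stringsAsFactors = FALSE
    )
    out[[k]] <- raf_record(substr(key, 1L, 4L), substr(key, 5L, 5L),
                           cells, version = version, flags = flags)
    keys[k] <- key
  }
  stats::setNames(out, keys)
}

#' Write a RAF map file
#'
#' Inverse of [parse_raf()].  All records must share one format version.
#'
#' @param records list of \code{raf_record} objects.
#' @param file path or connection.
#' @export
write_raf <- function(records, file) {
  versions <- unique(vapply(records, `[[`, "", "version"))
  if (length(versions) > 1L)
    stop("records mix RAF versions: ", paste(versions, collapse = ", "))
  version <- if (length(versions)) versions else "0.03"
  body <- vapply(records, function(r) {
    cells <- sprintf("%*s%s%s", .RAF_LAYOUT$resid_width,
                     r$cells$residue_id, r$cells$atom_aa, r$cells$seqres_aa)
    sprintf("%s %s %s", raf_key(r), r$flags, paste(cells, collapse = ""))
  }, "")
  writeLines(c(sprintf("# RAF version %s", version), body), file)
}

#' Convert a RAF record from version 0.02 to 0.03
#'
#' Replaces the legacy B/M/E placeholders of SEQRES residues missing from
#' the ATOM records with the residue identifiers now assigned by the PDB.
#'
#' @param record a version-0.02 \code{raf_record} (a record already free of
#'   legacy letters is passed through with its version bumped).
#' @param assigned_ids named character vector mapping the 1-based SEQRES
#'   index of each legacy cell to its PDB-assigned residue identifier.
#' @return the converted \code{raf_record}, version \code{"0.03"}.
#' @export
convert_v2_to_v3 <- function(record, assigned_ids = character()) {
  cells <- record$cells
  seqres_idx <- cumsum(cells$seqres_aa != ".")
  legacy <- cells$residue_id %in% RAF_LEGACY_LETTERS & cells$atom_aa == "."
  need <- as.character(seqres_idx[legacy])
  missing <- setdiff(need, names(assigned_ids))
  if (length(missing))
    stop("no assigned identifier for SEQRES index(es): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(assigned_ids), need)
  if (length(extra))
    warning("assigned identifiers for non-legacy SEQRES index(es) ignored: ",
            paste(extra, collapse = ", "))
  cells$residue_id[legacy] <- unname(assigned_ids[need])
  raf_record(record$pdb_id, record$chain_id, cells,
             version = "0.03", flags = record$flags)
}

#' Map a SEQRES index to its ATOM residue identifier
#'
#' @param record a \code{raf_record}.
#' @param seqres_index 1-based index into the SEQRES sequence.
#' @return A list with \code{resolved} (logical) and \code{residue_id}: the
#'   author residue identifier when the residue appears in the ATOM records;
#'   otherwise an unresolved marker whose \code{residue_id} carries the
#'   PDB-assigned identifier for version 0.03 records and \code{NA} for
#'   version 0.02.
#' @export
seqres_to_atom <- function(record, seqres_index) {
  cells <- record$cells
  sq <- which(cells$seqres_aa != ".")
  if (seqres_index < 1L || seqres_index > length(sq))
    stop(sprintf("SEQRES index %d out of range [1, %d] for chain %s",
                 seqres_index, length(sq), raf_key(record)))
  i <- sq[seqres_index]
  if (cells$atom_aa[i] != ".") {
    list(resolved = TRUE, residue_id = cells$residue_id[i])
  } else {
    list(resolved = FALSE,
         residue_id = if (record$version == "0.03") cells$residue_id[i]
                      else NA_character_)
  }
}

#' SEQRES sequence of a RAF record
#' @param record a \code{raf_record}.
#' @return one-letter sequence string of the genetically encoded chain.
#' @export
seqres_sequence <- function(record) {
  paste(record$cells$seqres_aa[record$cells$seqres_aa != "."], collapse = "")
}

#' ATOM sequence of a RAF record
#' @param record a \code{raf_record}.
#' @return one-letter sequence string of the experimentally observed residues.
#' @export
atom_sequence <- function(record) {
  paste(record$cells$atom_aa[record$cells$atom_aa != "."], collapse = "")
}

# Cell index range of a region segment within a RAF record.  Absent bounds
# denote the whole chain.  Bounds are author residue identifiers and must
# match a cell; the range is clipped to the chain's cells by construction.
.segment_cells <- function(record, start, end) {
  n <- nrow(record$cells)
  i1 <- if (is.na(start)) 1L else match(start, record$cells$residue_id)
  i2 <- if (is.na(end)) n else match(end, record$cells$residue_id)
  if (is.na(i1) || is.na(i2))
    stop(sprintf("chain %s: region bound %s not found among residue ids",
                 raf_key(record),
                 paste(c(start, end)[is.na(c(i1, i2))], collapse = ", ")))
  if (i1 > i2)
    stop(sprintf("chain %s: segment %s-%s reversed in SEQRES order",
                 raf_key(record), start, end))
  c(i1, i2)
}

# Resolve the RAF record for one region segment.  A segment with an absent
# chain id refers to the single chain of the entry; ambiguous when the entry
# has several chains.
.segment_record <- function(chain, pdb_id, raf_index) {
  if (!is.na(chain)) {
    key <- paste0(pdb_id, chain)
    rec <- raf_index[[key]]
    if (is.null(rec)) stop("no RAF record for chain ", key)
    return(rec)
  }
  hits <- raf_index[startsWith(names(raf_index), pdb_id)]
  if (length(hits) == 0L) stop("no RAF record for entry ", pdb_id)
  if (length(hits) > 1L)
    stop("whole-entry region is ambiguous: entry ", pdb_id,
         " has ", length(hits), " chains")
  hits[[1]]
}
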