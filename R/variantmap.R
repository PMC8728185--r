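# ---- Variant-to-structure residue mapping ----------------------------------
#
# Offline core of the variant-interpretation chain: a protein-level variant
# position (UniProt canonical numbering) is translated to a PDB SEQRES index
# via a SIFTS-style per-residue mapping table, then to an ATOM residue
# identifier via the chain's RAF record.  Positions falling in structurally
# uncharacterized (disordered) regions are reported with their nearest
# resolved neighbours; classified domains covering the position supply
# evolutionary context.

#' Read a SIFTS-style per-residue mapping table
#'
#' Minimal 4-column tab-delimited dialect: \code{accession}, \code{chain_key}
#' (PDB id + chain), \code{uniprot_pos}, \code{seqres_index}.  Within each
#' (accession, chain) pair the mapping must be strictly increasing in both
#' coordinates (no crossing alignments); rows may appear in any order on
#' disk and are sorted before validation.
#'
#' @param file path, connection, or character vector of lines.
#' @return data.frame with the four columns above, sorted by accession,
#'   chain_key and uniprot_pos.
#' @export
read_sifts <- function(file) {
  lines <- .read_source(file)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 4L)
  if (length(bad))
    stop("SIFTS line ", bad[1], ": expected 4 tab-delimited columns")
  out <- data.frame(
    accession = vapply(f, `[`, "", 1L),
    chain_key = vapply(f, `[`, "", 2L),
    uniprot_pos = as.integer(vapply(f, `[`, "", 3L)),
    seqres_index = as.integer(vapply(f, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$uniprot_pos) || anyNA(out$seqres_index))
    stop("non-integer coordinate in SIFTS table")
  out <- out[order(out$accession, out$chain_key, out$uniprot_pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  for (grp in split(out, paste(out$accession, out$chain_key))) {
    if (any(diff(grp$uniprot_pos) <= 0L) || any(diff(grp$seqres_index) <= 0L))
      stop("SIFTS mapping for ", grp$accession[1], "/", grp$chain_key[1],
           " is not strictly increasing in both coordinates")
  }
  out
}

#' Write a SIFTS-style mapping table
#' @param sifts data.frame as returned by [read_sifts()].
#' @param file path or connection.
#' @export
write_sifts <- function(sifts, file) {
  writeLines(sprintf("%s\t%s\t%d\t%d", sifts$accession, sifts$chain_key,
                     sifts$uniprot_pos, sifts$seqres_index), file)
}

#' Nearest resolved residues to a SEQRES position
#'
#' @param record a \code{raf_record}.
#' @param seqres_index 1-based SEQRES index.
#' @return data.frame with columns \code{residue_id} and \code{distance}
#'   (absolute SEQRES-index distance): the resolved residue(s) minimising
#'   the distance, both reported on an upstream/downstream tie; the queried
#'   residue itself at distance 0 when it is resolved; zero rows for a chain
#'   with no resolved residues.
#' @export
nearest_resolved <- function(record, seqres_index) {
  cells <- record$cells
  sq <- which(cells$seqres_aa != ".")
  if (seqres_index < 1L || seqres_index > length(sq))
    stop(sprintf("SEQRES index %d out of range [1, %d]",
                 seqres_index, length(sq)))
  resolved <- which(cells$atom_aa[sq] != ".")
  if (!length(resolved))
    return(data.frame(residue_id = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  d <- abs(resolved - seqres_index)
  hits <- resolved[d == min(d)]
  data.frame(residue_id = cells$residue_id[sq[hits]],
             distance = abs(hits - seqres_index),
             stringsAsFactors = FALSE)
}

# Does a classified domain's region contain the given SEQRES index of the
# given chain?
.region_contains <- function(domain, record, seqres_index, raf_index) {
  region <- parse_region(domain$region)
  sq <- which(record$cells$seqres_aa != ".")
  cell <- sq[seqres_index]
  for (k in seq_len(nrow(region))) {
    rec_k <- tryCatch(.segment_record(region$chain[k], domain$pdb_id,
                                      raf_index),
                      error = function(e) NULL)
    if (is.null(rec_k) || raf_key(rec_k) != raf_key(record)) next
    rng <- .segment_cells(record, region$start[k], region$end[k])
    if (cell >= rng[1] && cell <= rng[2]) return(TRUE)
  }
  FALSE
}

#' Map a UniProt protein position to a structure residue
#'
#' Translates a protein-level position to a PDB SEQRES index through the
#' SIFTS pairs, then to an ATOM residue identifier through the RAF record.
#' A position in a disordered region is returned unresolved together with
#' its nearest resolved neighbours; a position outside the mapped interval
#' is returned as unmapped rather than raising an error.
#'
#' @param uniprot_pos 1-based position in the UniProt canonical sequence.
#' @param sifts data.frame from [read_sifts()], already restricted or
#'   restrictable to the record's chain via its \code{chain_key} column.
#' @param record the chain's \code{raf_record}.
#' @param domains optional data.frame from [read_cla()] used to report the
#'   classified domains containing the position.
#' @param raf_index optional named list of RAF records (defaults to just
#'   \code{record}) used for region resolution of multi-chain domains.
#' @return list of class \code{"structure_position"} with fields
#'   \code{chain_key}, \code{uniprot_pos}, \code{mapped}, \code{seqres_index},
#'   \code{resolved}, \code{residue_id}, \code{nearest_resolved} (data.frame,
#'   see [nearest_resolved()]) and \code{domains} (character vector of sids).
#' @export
map_protein_position <- function(uniprot_pos, sifts, record, domains = NULL,
                                 raf_index = NULL) {
  key <- raf_key(record)
  if (is.null(raf_index)) raf_index <- stats::setNames(list(record), key)
  pairs <- sifts[sifts$chain_key == key, , drop = FALSE]
  hit <- which(pairs$uniprot_pos == uniprot_pos)
  out <- list(chain_key = key, uniprot_pos = uniprot_pos, mapped = FALSE,
              seqres_index = NA_integer_, resolved = FALSE,
              residue_id = NA_character_,
              nearest_resolved = data.frame(residue_id = character(),
                                            distance = integer(),
                                            stringsAsFactors = FALSE),
              domains = character())
  class(out) <- "structure_position"
  if (!length(hit)) return(out)
  out$mapped <- TRUE
  out$seqres_index <- pairs$seqres_index[hit[1]]
  atom <- seqres_to_atom(record, out$seqres_index)
  out$resolved <- atom$resolved
  if (atom$resolved) {
    out$residue_id <- atom$residue_id
    out$nearest_resolved <- data.frame(residue_id = atom$residue_id,
                                       distance = 0L,
                                       stringsAsFactors = FALSE)
  } else {
    out$residue_id <- NA_character_
    out$nearest_resolved <- nearest_resolved(record, out$seqres_index)
  }
  if (!is.null(domains) && nrow(domains)) {
    cand <- domains[domains$pdb_id == record$pdb_id, , drop = FALSE]
    inside <- vapply(seq_len(nrow(cand)), function(k)
      .region_contains(cand[k, ], record, out$seqres_index, raf_index), NA)
    out$domains <- cand$sid[inside]
  }
  out
}

#' @export
print.structure_position <- function(x, ...) {
  if (!x$mapped) {
    cat(sprintf("UniProt position %d: unmapped on chain %s\n",
                x$uniprot_pos, x$chain_key))
  } else if (x$resolved) {
    cat(sprintf("UniProt position %d -> chain %s SEQRES %d -> residue %s\n",
                x$uniprot_pos, x$chain_key, x$seqres_index, x$residue_id))
  } else {
    cat(sprintf(
      "UniProt position %d -> chain %s SEQRES %d: unresolved; nearest resolved: %s\n",
      x$uniprot_pos, x$chain_key, x$seqres_index,
      paste(sprintf("%s (|d|=%d)", x$nearest_resolved$residue_id,
                    x$nearest_resolved$distance), collapse = ", ")))
  }
  if (length(x$domains))
    cat("  in domain(s): ", paste(x$domains, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evolutionary context of a mapped structure position
#'
#' For each classified domain containing the position, lists the other
#' members of its family (and optionally superfamily) from the
#' classification.
#'
#' @param position a \code{structure_position} from [map_protein_position()].
#' @param classification data.frame from [read_cla()].
#' @param superfamily also list superfamily-level siblings.
#' @return list, one element per containing domain, each with \code{sid},
#'   \code{sccs}, \code{family_siblings} and (optionally)
#'   \code{superfamily_siblings}.
#' @export
domain_context <- function(position, classification, superfamily = FALSE) {
  lapply(position$domains, function(sid) {
    row <- classification[classification$sid == sid, , drop = FALSE]
    sccs <- row$sccs[1]
    fam <- classification$sid[classification$sccs == sccs &
                                classification$sid != sid]
    out <- list(sid = sid, sccs = sccs, family_siblings = fam)
    if (superfamily) {
      sf <- sub("\\.[0-9]+$", "", sccs)
      sf_members <- classification$sid[
        startsWith(classification$sccs, paste0(sf, ".")) &
          classification$sid != sid]
      out$superfamily_siblings <- sf_members
    }
    out
  })
}
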