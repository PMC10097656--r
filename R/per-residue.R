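# ---------------------------------------------------------------------------
# Per-residue cross-reference table: the `_pdbx_sifts_xref_db` rows.  Rows
# are restricted to residues covered by best-mapping segments; unmapped
# residues (tags, linkers) get no row at all.
# ---------------------------------------------------------------------------

#' Expand best-mapping segments to per-residue cross-reference rows
#'
#' One row per residue covered by a best-mapping UniProt segment, carrying
#' dual numbering, observedness, the sequence-conflict flag, and one column
#' per external resource (Pfam/SCOP2/CATH) filled where a domain segment
#' covers the residue.
#'
#' @param unp_segments Segments of the chain (only `best_mapping` rows are
#'   expanded), with `instance_id`/`segment_id` assigned.
#' @param xref_segments Domain segments from [project_domains()] (may be
#'   empty).
#' @param chain The `polymer_chain`.
#' @param pairs Residue pairs of the best mapping(s), for the UniProt
#'   residue letters.
#' @return data.frame of class `xref_residues` with columns `asym_id`,
#'   `auth_asym_id`, `seq_id`, `auth_seq_id`, `icode`, `comp_one_letter`,
#'   `unp_acc`, `unp_num`, `unp_one_letter`, `observed`, `conflict`,
#'   `pfam_acc`, `scop2_id`, `cath_id`; ordered by (`asym_id`, `seq_id`).
#' @export
expand_residues <- function(unp_segments, xref_segments, chain, pairs) {
  stopifnot(inherits(chain, "polymer_chain"))
  empty <- data.frame(asym_id = character(0), auth_asym_id = character(0),
                      seq_id = integer(0), auth_seq_id = character(0),
                      icode = character(0), comp_one_letter = character(0),
                      unp_acc = character(0), unp_num = integer(0),
                      unp_one_letter = character(0), observed = logical(0),
                      conflict = logical(0), pfam_acc = character(0),
                      scop2_id = character(0), cath_id = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("xref_residues", "data.frame")
  segs <- unp_segments[unp_segments$best_mapping %in% TRUE, , drop = FALSE]
  if (!nrow(segs)) return(empty)
  mon <- chain$monomers
  rows <- list()
  pair_key <- paste(pairs$unp_acc, pairs$label_seq_id)
  for (s in seq_len(nrow(segs))) {
    ids <- segs$seq_id_start[s]:segs$seq_id_end[s]
    # collinearity within a segment fixes unp numbering
    unp <- segs$unp_start[s] + (ids - segs$seq_id_start[s])
    mi <- match(ids, mon$label_seq_id)
    if (anyNA(mi))
      stop("segment references label_seq_id outside chain ",
           chain$label_asym_id)
    pk <- match(paste(segs$unp_acc[s], ids), pair_key)
    if (anyNA(pk))
      stop("segment residue without a residue pair in chain ",
           chain$label_asym_id, " (collinearity violated)")
    if (any(pairs$unp_num[pk] != unp))
      stop("segment collinearity violated in chain ", chain$label_asym_id)
    rows[[s]] <- data.frame(
      asym_id = chain$label_asym_id,
      auth_asym_id = chain$auth_asym_id,
      seq_id = ids,
      auth_seq_id = mon$auth_seq_id[mi],
      icode = mon$icode[mi],
      comp_one_letter = mon$one_letter[mi],
      unp_acc = segs$unp_acc[s],
      unp_num = unp,
      unp_one_letter = pairs$unp_one_letter[pk],
      observed = mon$observed[mi],
      conflict = mon$one_letter[mi] != pairs$unp_one_letter[pk],
      pfam_acc = NA_character_, scop2_id = NA_character_,
      cath_id = NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$seq_id))
    stop("residue covered by two best-mapping segments in chain ",
         chain$label_asym_id)
  # fill resource columns from covering domain segments
  if (!is.null(xref_segments) && nrow(xref_segments)) {
    col_of <- c(Pfam = "pfam_acc", SCOP2 = "scop2_id", CATH = "cath_id")
    xs <- xref_segments[xref_segments$asym_id == chain$label_asym_id, ,
                        drop = FALSE]
    for (r in seq_len(nrow(xs))) {
      cn <- col_of[[xs$resource[r]]]
      hit <- out$seq_id >= xs$seq_id_start[r] & out$seq_id <= xs$seq_id_end[r]
      clash <- hit & !is.na(out[[cn]]) & out[[cn]] != xs$xref_acc[r]
      if (any(clash))
        stop("residue covered by two ", xs$resource[r],
             " segments in chain ", chain$label_asym_id)
      out[[cn]][hit] <- xs$xref_acc[r]
    }
  }
  out <- out[order(out$asym_id, out$seq_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("xref_residues", "data.frame")
  out
}

#' Look up a residue row by author numbering
#'
#' Resolves author chain id, author residue number and insertion code to
#' the per-residue cross-reference row.
#'
#' @param table An `xref_residues` data.frame (rows of one or more chains).
#' @param auth_asym_id Author chain identifier.
#' @param auth_seq_id Author residue number (text).
#' @param icode Insertion code; `""` for none.
#' @return The matching one-row data.frame, or `NULL` when the residue has
#'   no cross-reference row (e.g. expression tags) or does not exist.
#' @export
residue_query <- function(table, auth_asym_id, auth_seq_id, icode = "") {
  hit <- table$auth_asym_id == auth_asym_id &
    table$auth_seq_id == as.character(auth_seq_id) &
    table$icode == icode
  n <- sum(hit)
  if (n == 0L) return(NULL)
  if (n > 1L)
    stop("ambiguous author residue key: ", auth_asym_id, " ",
         auth_seq_id, if (nzchar(icode)) paste0("(", icode, ")") else "")
  table[hit, , drop = FALSE]
}
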