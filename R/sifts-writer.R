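# ---------------------------------------------------------------------------
# Serialization of the four SIFTS-specific mmCIF categories and the
# augmented _atom_site items, plus the reverse parse for round-trip checks.
#
# All seq_id items reference label_seq_id, never author numbering.
# ---------------------------------------------------------------------------

SIFTS_CATEGORIES <- c("pdbx_sifts_unp_segments", "pdbx_sifts_xref_db_segments",
                      "pdbx_sifts_xref_db")
SIFTS_ATOM_ITEMS <- c("pdbx_sifts_xref_db_acc", "pdbx_sifts_xref_db_name",
                      "pdbx_sifts_xref_db_num", "pdbx_label_index")

#' Schema of the SIFTS-specific categories
#'
#' One row per data item of the three new categories and the extended
#' `_atom_site` items.  `paper_attested` marks item names that are fixed by
#' the format description (`.instance_id`, `.segment_id`, `.seq_id`,
#' `.seq_id_start`, `.seq_id_end`, `pdbx_label_index`); the remaining names
#' are declared here so they can be reconciled against the public wwPDB
#' dictionary extension without code changes.
#'
#' @return data.frame with columns `category`, `item`, `paper_attested`.
#' @export
sifts_schema <- function() {
  rbind(
    data.frame(category = "pdbx_sifts_unp_segments",
               item = c("asym_id", "unp_acc", "instance_id", "segment_id",
                        "seq_id_start", "seq_id_end", "unp_start", "unp_end",
                        "identity", "best_mapping"),
               paper_attested = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                                  FALSE, FALSE, FALSE, FALSE)),
    data.frame(category = "pdbx_sifts_xref_db_segments",
               item = c("xref_db", "xref_db_acc", "asym_id", "instance_id",
                        "segment_id", "seq_id_start", "seq_id_end"),
               paper_attested = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)),
    data.frame(category = "pdbx_sifts_xref_db",
               item = c("asym_id", "auth_asym_id", "seq_id", "auth_seq_id",
                        "ins_code", "mon_id_one_letter", "unp_acc", "unp_num",
                        "unp_one_letter", "observed", "conflict",
                        "pfam_acc", "scop2_id", "cath_id"),
               paper_attested = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                                  FALSE, FALSE, FALSE, FALSE, FALSE,
                                  FALSE, FALSE, FALSE)),
    data.frame(category = "atom_site",
               item = SIFTS_ATOM_ITEMS,
               paper_attested = c(FALSE, FALSE, FALSE, TRUE)))
}

fmt_int <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE,
                                                    trim = TRUE))
fmt_chr <- function(x) ifelse(is.na(x) | !nzchar(x), ".", x)
fmt_flag <- function(x) ifelse(x, "Y", "N")
fmt_ident <- function(x) ifelse(is.na(x), ".", sprintf("%.4f", x))

#' Emit the `_pdbx_sifts_unp_segments` category
#'
#' @param segments UniProt segments with instance/segment ids assigned.
#' @return A character data.frame (category table) named per the schema, or
#'   `NULL` for an empty segment list (no empty categories are written).
#' @export
emit_unp_segments <- function(segments) {
  if (is.null(segments) || !nrow(segments)) return(NULL)
  stopifnot(all(c("instance_id", "segment_id") %in% names(segments)))
  if (any(segments$seq_id_start > segments$seq_id_end))
    stop("segment with seq_id_start > seq_id_end refused")
  if (any((segments$unp_end - segments$unp_start) !=
          (segments$seq_id_end - segments$seq_id_start)))
    stop("non-collinear segment refused")
  o <- order(segments$asym_id, segments$unp_acc, segments$instance_id,
             segments$segment_id)
  s <- segments[o, , drop = FALSE]
  data.frame(asym_id = s$asym_id, unp_acc = s$unp_acc,
             instance_id = fmt_int(s$instance_id),
             segment_id = fmt_int(s$segment_id),
             seq_id_start = fmt_int(s$seq_id_start),
             seq_id_end = fmt_int(s$seq_id_end),
             unp_start = fmt_int(s$unp_start),
             unp_end = fmt_int(s$unp_end),
             identity = fmt_ident(s$identity),
             best_mapping = fmt_flag(s$best_mapping),
             stringsAsFactors = FALSE)
}

#' Emit the `_pdbx_sifts_xref_db_segments` category
#'
#' @param xref_segments Domain segments from [project_domains()].
#' @return Category table, or `NULL` when empty.
#' @export
emit_xref_segments <- function(xref_segments) {
  if (is.null(xref_segments) || !nrow(xref_segments)) return(NULL)
  if (any(xref_segments$seq_id_start > xref_segments$seq_id_end))
    stop("segment with seq_id_start > seq_id_end refused")
  key <- paste(xref_segments$asym_id, xref_segments$resource,
               xref_segments$xref_acc, xref_segments$instance_id,
               xref_segments$segment_id)
  if (anyDuplicated(key))
    stop("duplicate (resource, accession, instance, segment) refused")
  o <- order(xref_segments$asym_id, xref_segments$resource,
             xref_segments$xref_acc, xref_segments$instance_id,
             xref_segments$segment_id)
  s <- xref_segments[o, , drop = FALSE]
  data.frame(xref_db = s$resource, xref_db_acc = s$xref_acc,
             asym_id = s$asym_id,
             instance_id = fmt_int(s$instance_id),
             segment_id = fmt_int(s$segment_id),
             seq_id_start = fmt_int(s$seq_id_start),
             seq_id_end = fmt_int(s$seq_id_end),
             stringsAsFactors = FALSE)
}

#' Emit the `_pdbx_sifts_xref_db` category
#'
#' @param rows An `xref_residues` data.frame.
#' @return Category table, or `NULL` when empty.
#' @export
emit_xref_db <- function(rows) {
  if (is.null(rows) || !nrow(rows)) return(NULL)
  o <- order(rows$asym_id, rows$seq_id)
  r <- rows[o, , drop = FALSE]
  data.frame(asym_id = r$asym_id, auth_asym_id = r$auth_asym_id,
             seq_id = fmt_int(r$seq_id),
             auth_seq_id = fmt_chr(r$auth_seq_id),
             ins_code = fmt_chr(r$icode),
             mon_id_one_letter = r$comp_one_letter,
             unp_acc = r$unp_acc, unp_num = fmt_int(r$unp_num),
             unp_one_letter = r$unp_one_letter,
             observed = fmt_flag(r$observed),
             conflict = fmt_flag(r$conflict),
             pfam_acc = fmt_chr(r$pfam_acc),
             scop2_id = fmt_chr(r$scop2_id),
             cath_id = fmt_chr(r$cath_id),
             stringsAsFactors = FALSE)
}

#' Augment the `_atom_site` category with SIFTS items
#'
#' Every atom row gains `pdbx_sifts_xref_db_acc`, `pdbx_sifts_xref_db_name`
#' (one-letter residue), `pdbx_sifts_xref_db_num` and `pdbx_label_index`.
#' Atoms of unmapped residues and non-polymer components get `?` for the
#' three cross-reference items but always a valid `pdbx_label_index`.  No
#' pre-existing item or value is altered.
#'
#' @param entry A `sifts_entry`.
#' @param residues `xref_residues` rows of the best mapping (may be empty).
#' @param label_index Index table from [compute_label_index()].
#' @return The entry's `cif_doc` with the extended `atom_site` category.
#' @export
augment_atom_site <- function(entry, residues, label_index) {
  stopifnot(inherits(entry, "sifts_entry"))
  doc <- entry$doc
  as_ <- doc$categories$atom_site
  atoms <- entry$atoms
  stopifnot(nrow(as_) == nrow(atoms))
  poly <- !is.na(atoms$label_seq_id)

  acc <- rep("?", nrow(as_))
  aa <- rep("?", nrow(as_))
  num <- rep("?", nrow(as_))
  if (!is.null(residues) && nrow(residues)) {
    mi <- match(paste(atoms$label_asym_id, atoms$label_seq_id),
                paste(residues$asym_id, residues$seq_id))
    hit <- !is.na(mi)
    acc[hit] <- residues$unp_acc[mi[hit]]
    aa[hit] <- residues$unp_one_letter[mi[hit]]
    num[hit] <- as.character(residues$unp_num[mi[hit]])
  }

  idx <- rep(NA_character_, nrow(as_))
  pk <- paste(label_index$asym_id, label_index$label_seq_id)
  mi <- match(paste(atoms$label_asym_id, atoms$label_seq_id)[poly], pk)
  idx[poly] <- as.character(label_index$index[mi])
  if (any(!poly)) {
    npk <- paste(label_index$asym_id, label_index$comp_id,
                 label_index$auth_seq_id, label_index$icode)[
                   is.na(label_index$label_seq_id)]
    npi <- label_index$index[is.na(label_index$label_seq_id)]
    mi2 <- match(paste(atoms$label_asym_id, atoms$comp_id,
                       atoms$auth_seq_id, atoms$icode)[!poly], npk)
    idx[!poly] <- as.character(npi[mi2])
  }
  if (anyNA(idx)) stop("atom without a pdbx_label_index assignment")

  as_ <- as_[, setdiff(names(as_), SIFTS_ATOM_ITEMS), drop = FALSE]
  as_$pdbx_sifts_xref_db_acc <- acc
  as_$pdbx_sifts_xref_db_name <- aa
  as_$pdbx_sifts_xref_db_num <- num
  as_$pdbx_label_index <- idx
  doc$categories$atom_site <- as_
  doc
}

#' Write an updated (`_updated.cif`-style) mmCIF file
#'
#' Serializes the entry with the SIFTS categories appended after all
#' existing categories.  SIFTS categories already present are replaced
#' wholesale, so re-running the augmentation is idempotent.
#'
#' @param doc A `cif_doc` (typically from [augment_atom_site()]).
#' @param tables Named list with any of `unp_segments`, `xref_segments`,
#'   `xref_db` category tables (as emitted by the `emit_*` functions);
#'   `NULL` entries are omitted.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_updated_cif <- function(doc, tables, path) {
  stopifnot(inherits(doc, "cif_doc"))
  doc$categories <- doc$categories[setdiff(names(doc$categories),
                                           SIFTS_CATEGORIES)]
  nm <- c(unp_segments = "pdbx_sifts_unp_segments",
          xref_segments = "pdbx_sifts_xref_db_segments",
          xref_db = "pdbx_sifts_xref_db")
  for (k in names(nm)) {
    tb <- tables[[k]]
    if (!is.null(tb) && nrow(tb)) doc$categories[[nm[[k]]]] <- tb
  }
  cif_write(doc, path)
}

#' Parse the SIFTS categories back from an updated mmCIF file
#'
#' Reconstructs typed segment, domain-segment and per-residue tables from
#' a written file; used for round-trip validation.  Unknown extra items are
#' preserved opaquely in the returned raw tables.
#'
#' @param path Path to an mmCIF file containing at least one SIFTS category.
#' @return List with elements `unp_segments`, `xref_segments`, `residues`
#'   (typed data.frames or `NULL`), `atom_items` (data.frame of the four
#'   `_atom_site` SIFTS items, or `NULL`) and `raw` (the verbatim category
#'   tables).
#' @export
parse_sifts_categories <- function(path) {
  doc <- cif_read(path)
  cats <- doc$categories
  if (!any(SIFTS_CATEGORIES %in% names(cats)))
    stop("no SIFTS category present in ", path)
  req <- function(df, items, cat) {
    miss <- setdiff(items, names(df))
    if (length(miss))
      stop("category _", cat, " missing mandatory item(s): ",
           paste(miss, collapse = ", "))
  }
  unp <- cats[["pdbx_sifts_unp_segments"]]
  if (!is.null(unp)) {
    req(unp, c("asym_id", "unp_acc", "instance_id", "segment_id",
               "seq_id_start", "seq_id_end", "unp_start", "unp_end",
               "identity", "best_mapping"), "pdbx_sifts_unp_segments")
    unp_typed <- data.frame(
      unp_acc = unp$unp_acc, asym_id = unp$asym_id,
      seq_id_start = as.integer(unp$seq_id_start),
      seq_id_end = as.integer(unp$seq_id_end),
      unp_start = as.integer(unp$unp_start),
      unp_end = as.integer(unp$unp_end),
      identity = as.numeric(unp$identity),
      best_mapping = unp$best_mapping == "Y",
      instance_id = as.integer(unp$instance_id),
      segment_id = as.integer(unp$segment_id),
      stringsAsFactors = FALSE)
  } else unp_typed <- NULL
  xs <- cats[["pdbx_sifts_xref_db_segments"]]
  if (!is.null(xs)) {
    req(xs, c("xref_db", "xref_db_acc", "asym_id", "instance_id",
              "segment_id", "seq_id_start", "seq_id_end"),
        "pdbx_sifts_xref_db_segments")
    xs_typed <- data.frame(
      resource = xs$xref_db, xref_acc = xs$xref_db_acc,
      asym_id = xs$asym_id, instance_id = as.integer(xs$instance_id),
      segment_id = as.integer(xs$segment_id),
      seq_id_start = as.integer(xs$seq_id_start),
      seq_id_end = as.integer(xs$seq_id_end), stringsAsFactors = FALSE)
  } else xs_typed <- NULL
  xr <- cats[["pdbx_sifts_xref_db"]]
  if (!is.null(xr)) {
    req(xr, c("asym_id", "seq_id", "auth_seq_id", "ins_code",
              "mon_id_one_letter", "unp_acc", "unp_num", "unp_one_letter",
              "observed", "conflict"), "pdbx_sifts_xref_db")
    xr_typed <- data.frame(
      asym_id = xr$asym_id,
      auth_asym_id = if (!is.null(xr$auth_asym_id)) xr$auth_asym_id
        else xr$asym_id,
      seq_id = as.integer(xr$seq_id),
      auth_seq_id = xr$auth_seq_id,
      icode = ifelse(xr$ins_code == ".", "", xr$ins_code),
      comp_one_letter = xr$mon_id_one_letter,
      unp_acc = xr$unp_acc, unp_num = as.integer(xr$unp_num),
      unp_one_letter = xr$unp_one_letter,
      observed = xr$observed == "Y", conflict = xr$conflict == "Y",
      pfam_acc = if (!is.null(xr$pfam_acc)) cif_null(xr$pfam_acc)
        else NA_character_,
      scop2_id = if (!is.null(xr$scop2_id)) cif_null(xr$scop2_id)
        else NA_character_,
      cath_id = if (!is.null(xr$cath_id)) cif_null(xr$cath_id)
        else NA_character_,
      stringsAsFactors = FALSE)
    class(xr_typed) <- c("xref_residues", "data.frame")
  } else xr_typed <- NULL
  as_ <- cats[["atom_site"]]
  atom_items <- if (!is.null(as_) && all(SIFTS_ATOM_ITEMS %in% names(as_)))
    as_[, SIFTS_ATOM_ITEMS] else NULL
  list(unp_segments = unp_typed, xref_segments = xs_typed,
       residues = xr_typed, atom_items = atom_items,
       raw = cats[intersect(SIFTS_CATEGORIES, names(cats))])
}
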