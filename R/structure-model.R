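# ---------------------------------------------------------------------------
# In-memory model of an mmCIF entry: polymer chains with SEQRES-derived
# monomer lists carrying dual numbering (label_seq_id / auth_seq_id + insert
# code) and observed flags, non-polymer components, and atom records.
# ---------------------------------------------------------------------------

#' Three-letter to one-letter residue translation table
#'
#' Standard amino acids plus common modified residues translated to the
#' one-letter code of their parent amino acid.  Unknown components map to
#' `X` downstream.
#'
#' @return Named character vector: `comp_id` -> one-letter code.
#' @export
aa_parent_table <- function() {
  c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
    GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
    LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
    SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
    # modified residues -> parent
    MSE = "M", FME = "M", SEP = "S", TPO = "T", PTR = "Y",
    CSO = "C", CME = "C", OCS = "C", CSD = "C", SEC = "C",
    HYP = "P", MLY = "K", M3L = "K", ALY = "K", KCX = "K",
    PCA = "Q", CGU = "E", HIC = "H", NEP = "H", MLZ = "K")
}

#' Read an mmCIF entry into the structure model
#'
#' Builds polymer chains from the SEQRES-level categories
#' (`entity_poly_seq` and/or `pdbx_poly_seq_scheme`), so that unobserved
#' residues (present in the sequence but absent from `atom_site`) are
#' retained with `observed = FALSE`.  Author numbering and insertion codes
#' are taken from `pdbx_poly_seq_scheme` when present, otherwise from the
#' atom records.
#'
#' @param path Path to an mmCIF file containing `atom_site` and a polymer
#'   sequence category.
#' @param parent_table Translation table as from [aa_parent_table()].
#' @return An object of class `sifts_entry` with elements `entry_id`,
#'   `chains` (named list of `polymer_chain`), `nonpoly` (data.frame of
#'   non-polymer/solvent component instances), `atoms` (data.frame) and
#'   `doc` (the parsed `cif_doc`, kept for augmentation).
#' @export
read_entry <- function(path, parent_table = aa_parent_table()) {
  doc <- cif_read(path)
  cats <- doc$categories
  if (is.null(cats$atom_site))
    stop("entry has no atom_site category: ", path)
  has_seq <- !is.null(cats$entity_poly_seq) || !is.null(cats$pdbx_poly_seq_scheme)
  if (!has_seq)
    stop("entry has no polymer sequence category ",
         "(entity_poly_seq or pdbx_poly_seq_scheme): ", path)

  as_ <- cats$atom_site
  need <- c("label_asym_id", "label_comp_id", "label_seq_id", "label_atom_id",
            "Cartn_x", "Cartn_y", "Cartn_z")
  miss <- setdiff(need, names(as_))
  if (length(miss))
    stop("atom_site missing item(s): ", paste(miss, collapse = ", "))
  atoms <- data.frame(
    serial = if (!is.null(as_$id)) as_$id else as.character(seq_len(nrow(as_))),
    label_asym_id = as_$label_asym_id,
    label_seq_id = suppressWarnings(as.integer(cif_null(as_$label_seq_id))),
    auth_asym_id = if (!is.null(as_$auth_asym_id)) as_$auth_asym_id else as_$label_asym_id,
    auth_seq_id = if (!is.null(as_$auth_seq_id)) as_$auth_seq_id else as_$label_seq_id,
    icode = if (!is.null(as_$pdbx_PDB_ins_code))
      ifelse(is.na(cif_null(as_$pdbx_PDB_ins_code)), "", as_$pdbx_PDB_ins_code)
      else "",
    comp_id = as_$label_comp_id,
    atom_id = as_$label_atom_id,
    x = as.numeric(as_$Cartn_x), y = as.numeric(as_$Cartn_y),
    z = as.numeric(as_$Cartn_z),
    model_num = if (!is.null(as_$pdbx_PDB_model_num))
      as.integer(as_$pdbx_PDB_model_num) else 1L,
    stringsAsFactors = FALSE)

  # entity -> asym mapping
  struct_asym <- cats$struct_asym
  poly_entities <- character(0)
  if (!is.null(cats$entity_poly)) {
    poly_entities <- cats$entity_poly$entity_id
  } else if (!is.null(cats$entity_poly_seq)) {
    poly_entities <- unique(cats$entity_poly_seq$entity_id)
  } else if (!is.null(cats$pdbx_poly_seq_scheme)) {
    poly_entities <- unique(cats$pdbx_poly_seq_scheme$entity_id)
  }

  scheme <- cats$pdbx_poly_seq_scheme
  eps <- cats$entity_poly_seq
  # chain inventory: from scheme if present, else struct_asym x entity_poly_seq
  if (!is.null(scheme)) {
    inv <- unique(scheme[, c("asym_id", "entity_id")])
  } else if (!is.null(struct_asym)) {
    inv <- struct_asym[struct_asym$entity_id %in% poly_entities,
                       c("id", "entity_id")]
    names(inv) <- c("asym_id", "entity_id")
  } else {
    stop("cannot determine polymer chain inventory ",
         "(need pdbx_poly_seq_scheme or struct_asym): ", path)
  }

  taxids <- entity_taxids(cats)
  observed_key <- unique(paste(atoms$label_asym_id[!is.na(atoms$label_seq_id)],
                               atoms$label_seq_id[!is.na(atoms$label_seq_id)]))
  # auth numbering observed in atom records (first atom of each residue)
  pa <- atoms[!is.na(atoms$label_seq_id), ]
  pa_first <- pa[!duplicated(paste(pa$label_asym_id, pa$label_seq_id)), ]

  chains <- list()
  for (r in seq_len(nrow(inv))) {
    asym <- inv$asym_id[r]
    ent <- inv$entity_id[r]
    if (!is.null(scheme)) {
      sc <- scheme[scheme$asym_id == asym, , drop = FALSE]
      seq_num <- as.integer(sc$seq_id)
      comp <- sc$mon_id
      auth <- cif_null(if (!is.null(sc$pdb_seq_num)) sc$pdb_seq_num
                       else if (!is.null(sc$auth_seq_num)) sc$auth_seq_num
                       else rep(NA_character_, nrow(sc)))
      ic <- if (!is.null(sc$pdb_ins_code))
        ifelse(is.na(cif_null(sc$pdb_ins_code)), "", sc$pdb_ins_code)
        else rep("", nrow(sc))
      auth_asym <- if (!is.null(sc$pdb_strand_id)) sc$pdb_strand_id[1L] else asym
    } else {
      ee <- eps[eps$entity_id == ent, , drop = FALSE]
      seq_num <- as.integer(ee$num)
      comp <- ee$mon_id
      auth <- rep(NA_character_, nrow(ee))
      ic <- rep("", nrow(ee))
      auth_asym <- asym
    }
    o <- order(seq_num)
    seq_num <- seq_num[o]; comp <- comp[o]; auth <- auth[o]; ic <- ic[o]
    # microheterogeneity: alternative components at one position; keep first
    if (anyDuplicated(seq_num)) {
      warning("microheterogeneity in chain ", asym,
              ": first listed component used", call. = FALSE)
      keep <- !duplicated(seq_num)
      seq_num <- seq_num[keep]; comp <- comp[keep]
      auth <- auth[keep]; ic <- ic[keep]
    }
    if (!length(seq_num)) next
    if (!identical(seq_num, seq_len(length(seq_num))))
      stop("chain ", asym, ": label_seq_id must run 1..N without gaps")
    # fill auth numbering from atom records where the scheme lacked it
    pa_c <- pa_first[pa_first$label_asym_id == asym, , drop = FALSE]
    if (nrow(pa_c)) {
      mi <- match(seq_num, pa_c$label_seq_id)
      take <- is.na(auth) & !is.na(mi)
      auth[take] <- pa_c$auth_seq_id[mi[take]]
      ic[take] <- pa_c$icode[mi[take]]
      if (is.null(scheme)) auth_asym <- pa_c$auth_asym_id[1L]
      bad <- pa_c$label_seq_id > length(seq_num)
      if (any(bad))
        stop("chain ", asym, ": atom_site label_seq_id ",
             max(pa_c$label_seq_id), " exceeds SEQRES length ", length(seq_num))
    }
    auth[is.na(auth)] <- as.character(seq_num[is.na(auth)])
    one <- unname(parent_table[comp])
    one[is.na(one)] <- "X"
    mon <- data.frame(comp_id = comp, one_letter = one,
                      label_seq_id = seq_num, auth_seq_id = auth,
                      icode = ic,
                      observed = paste(asym, seq_num) %in% observed_key,
                      stringsAsFactors = FALSE)
    if (anyDuplicated(paste(mon$auth_seq_id, mon$icode)))
      stop("chain ", asym, ": duplicate (auth_seq_id, icode)")
    chains[[asym]] <- structure(
      list(entry_id = doc$block, entity_id = ent, label_asym_id = asym,
           auth_asym_id = auth_asym, monomers = mon,
           taxid = if (!is.na(match(ent, names(taxids)))) taxids[[ent]] else NA_character_),
      class = "polymer_chain")
  }

  np <- atoms[is.na(atoms$label_seq_id), , drop = FALSE]
  nonpoly <- if (nrow(np)) {
    u <- np[!duplicated(paste(np$label_asym_id, np$comp_id,
                              np$auth_seq_id, np$icode)), ]
    data.frame(asym_id = u$label_asym_id, comp_id = u$comp_id,
               auth_seq_id = u$auth_seq_id, icode = u$icode,
               stringsAsFactors = FALSE)
  } else {
    data.frame(asym_id = character(0), comp_id = character(0),
               auth_seq_id = character(0), icode = character(0),
               stringsAsFactors = FALSE)
  }

  known_asym <- c(names(chains), unique(nonpoly$asym_id))
  if (!all(atoms$label_asym_id %in% known_asym))
    stop("atom_site references unknown asym_id: ",
         paste(setdiff(unique(atoms$label_asym_id), known_asym), collapse = ", "))

  structure(list(entry_id = doc$block, chains = chains, nonpoly = nonpoly,
                 atoms = atoms, doc = doc),
            class = "sifts_entry")
}

# source-organism taxids per entity, from the src categories when present
entity_taxids <- function(cats) {
  out <- character(0)
  grab <- function(df, ent_item, tax_item) {
    if (is.null(df) || is.null(df[[tax_item]])) return(NULL)
    v <- cif_null(df[[tax_item]])
    names(v) <- df[[ent_item]]
    v[!is.na(v)]
  }
  for (v in list(grab(cats$entity_src_gen, "entity_id",
                      "pdbx_gene_src_ncbi_taxonomy_id"),
                 grab(cats$entity_src_nat, "entity_id",
                      "pdbx_ncbi_taxonomy_id"),
                 grab(cats$pdbx_entity_src_syn, "entity_id",
                      "ncbi_taxonomy_id"))) {
    if (!is.null(v)) out <- c(out, v[setdiff(names(v), names(out))])
  }
  out
}

#' @export
print.sifts_entry <- function(x, ...) {
  cat("mmCIF entry ", x$entry_id, ": ", length(x$chains),
      " polymer chain(s), ", nrow(x$nonpoly), " non-polymer component(s), ",
      nrow(x$atoms), " atoms\n", sep = "")
  for (ch in x$chains)
    cat("  chain ", ch$label_asym_id, " (auth ", ch$auth_asym_id, "): ",
        nrow(ch$monomers), " residues, ", sum(ch$monomers$observed),
        " observed\n", sep = "")
  invisible(x)
}

#' One-letter sequence of a polymer chain
#'
#' Concatenates the parent one-letter codes of all SEQRES monomers; unknown
#' chemical components degrade to `X`.
#'
#' @param chain A `polymer_chain`.
#' @param parent_table Translation table as from [aa_parent_table()].
#' @return Single string of length `nrow(chain$monomers)`.
#' @export
chain_sequence <- function(chain, parent_table = aa_parent_table()) {
  stopifnot(inherits(chain, "polymer_chain"))
  if (!nrow(chain$monomers)) stop("empty chain")
  one <- unname(parent_table[chain$monomers$comp_id])
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Unique per-component index for `_atom_site.pdbx_label_index`
#'
#' Within each `label_asym_id`, polymer residues are numbered 1..N in
#' `label_seq_id` order; non-polymer and solvent component instances are
#' numbered 1..N in file order.  `(label_asym_id, index)` is unique
#' entry-wide.
#'
#' @param entry A `sifts_entry`.
#' @return data.frame with columns `asym_id`, `label_seq_id` (NA for
#'   non-polymer components), `comp_id`, `auth_seq_id`, `icode`, `index`.
#' @export
compute_label_index <- function(entry) {
  stopifnot(inherits(entry, "sifts_entry"))
  parts <- list()
  for (ch in entry$chains) {
    m <- ch$monomers
    parts[[length(parts) + 1L]] <- data.frame(
      asym_id = ch$label_asym_id, label_seq_id = m$label_seq_id,
      comp_id = m$comp_id, auth_seq_id = m$auth_seq_id, icode = m$icode,
      index = seq_len(nrow(m)), stringsAsFactors = FALSE)
  }
  np <- entry$nonpoly
  if (nrow(np)) {
    for (asym in unique(np$asym_id)) {
      u <- np[np$asym_id == asym, , drop = FALSE]
      parts[[length(parts) + 1L]] <- data.frame(
        asym_id = asym, label_seq_id = NA_integer_, comp_id = u$comp_id,
        auth_seq_id = u$auth_seq_id, icode = u$icode,
        index = seq_len(nrow(u)), stringsAsFactors = FALSE)
    }
  }
  if (!length(parts))
    return(data.frame(asym_id = character(0), label_seq_id = integer(0),
                      comp_id = character(0), auth_seq_id = character(0),
                      icode = character(0), index = integer(0)))
  do.call(rbind, parts)
}
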