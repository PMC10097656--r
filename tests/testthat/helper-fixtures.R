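# Shared helpers: tiny hand-built mmCIF entries, data.frame comparison, and
# the full-pipeline ground-truth check used by the recovery tests.

write_lines_cif <- function(lines) {
  f <- tempfile(fileext = ".cif")
  writeLines(lines, f)
  f
}

# a 10-residue chain (A) with atoms for residues 1-4 and 7-10 only, plus a
# water chain (B) with 5 HOH molecules
mini_entry_cif <- function() {
  seq3 <- c("MET", "LYS", "VAL", "LEU", "GLN", "ALA", "GLY", "SER",
            "THR", "TRP")
  obs <- c(1:4, 7:10)
  lines <- c(
    "data_MINI",
    "loop_", "_entity.id", "_entity.type",
    "1 polymer", "2 water",
    "loop_", "_entity_poly.entity_id", "_entity_poly.type",
    "1 'polypeptide(L)'",
    "loop_", "_entity_poly_seq.entity_id", "_entity_poly_seq.num",
    "_entity_poly_seq.mon_id",
    paste("1", seq_len(10), seq3),
    "loop_", "_struct_asym.id", "_struct_asym.entity_id",
    "A 1", "B 2",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.label_atom_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.auth_seq_id", "_atom_site.auth_asym_id",
    "_atom_site.pdbx_PDB_model_num",
    paste("ATOM", seq_along(obs), "CA", seq3[obs], "A", obs, "?",
          sprintf("%.3f", 3.8 * obs), "0.000", "0.000", obs + 100L, "A", 1L),
    paste("HETATM", 8L + 1:5, "O", "HOH", "B", ".", "?",
          sprintf("%.3f", -5 * (1:5)), "0.000", "0.000", 501:505, "A", 1L))
  write_lines_cif(lines)
}

sorted_equal <- function(a, b) {
  if (is.null(a) || !nrow(a)) return(is.null(b) || nrow(b) == 0L)
  if (is.null(b) || !nrow(b)) return(FALSE)
  a <- a[do.call(order, a), , drop = FALSE]
  b <- b[do.call(order, b), , drop = FALSE]
  rownames(a) <- rownames(b) <- NULL
  isTRUE(all.equal(a, b, check.attributes = FALSE))
}

# run the full pipeline on one generated fixture and compare every output
# against the generator's ground truth; returns TRUE or a description
check_fixture_recovery <- function(preset, seed) {
  d <- tempfile()
  dir.create(d)
  on.exit(unlink(d, recursive = TRUE))
  fx <- fixture_preset(preset, seed = seed, dir = d)
  entry <- read_entry(fx$cif)
  cur <- utils::read.delim(fx$curated, colClasses = "character")
  doms <- read_domain_definitions(fx$domains)
  aug <- suppressMessages(suppressWarnings(
    augment_entry(entry, fx$records, cur, fx$tree, doms)))
  tr <- fx$truth

  best_acc <- sort(unname(vapply(aug$best[[tr$asym_id]], `[[`,
                                 character(1), "accession")))
  if (!identical(as.character(best_acc), sort(tr$expected_best)))
    return(sprintf("%s seed %d: best {%s} != expected {%s}", preset, seed,
                   paste(best_acc, collapse = ","),
                   paste(tr$expected_best, collapse = ",")))

  cols <- c("unp_acc", "seq_id_start", "seq_id_end", "unp_start", "unp_end",
            "instance_id", "segment_id")
  bs <- if (!is.null(aug$segments))
    aug$segments[aug$segments$best_mapping, cols] else NULL
  ts <- tr$segments[tr$segments$unp_acc %in% tr$expected_best, cols]
  if (!sorted_equal(bs, ts))
    return(sprintf("%s seed %d: best segments differ", preset, seed))

  trr <- tr$residue[!is.na(tr$residue$accession) &
                      tr$residue$accession %in% tr$expected_best, ]
  r <- aug$residues
  if (length(tr$expected_best)) {
    r <- r[order(r$seq_id), ]
    ok <- identical(nrow(r), nrow(trr)) &&
      all(r$seq_id == trr$label_seq_id) &&
      all(r$unp_acc == trr$accession) &&
      all(r$unp_num == trr$unp_num) &&
      all(r$observed == trr$observed) &&
      all(r$conflict == trr$conflict)
    if (!ok) return(sprintf("%s seed %d: per-residue rows differ",
                            preset, seed))
  } else if (!is.null(r) && nrow(r)) {
    return(sprintf("%s seed %d: residues emitted without a best mapping",
                   preset, seed))
  }

  xcols <- c("resource", "xref_acc", "instance_id", "segment_id",
             "seq_id_start", "seq_id_end")
  if (length(tr$expected_best)) {
    xs <- aug$xref_segments
    if (!sorted_equal(if (!is.null(xs)) xs[, xcols] else NULL,
                      tr$xref[, xcols]))
      return(sprintf("%s seed %d: domain segments differ", preset, seed))
  }

  # decoys must never be selected
  decoys <- attr(fx$records, "decoys")
  if (any(best_acc %in% decoys))
    return(sprintf("%s seed %d: decoy selected as best", preset, seed))
  TRUE
}

fixture_presets <- function() c("tag", "repeat", "split", "chimera",
                                "insertcode", "mutant", "missing", "lowid")

# hand-built candidate with a prescribed identity fraction
fake_candidate <- function(acc, identity, n = 100L, tax_ok = TRUE,
                           canonical = !grepl("-", acc)) {
  n_id <- round(identity * n)
  structure(list(asym_id = "A", accession = acc,
                 canonical_accession = sub("-.*", "", acc),
                 is_canonical = canonical,
                 identity = n_id / n, n_identical = n_id, n_aligned = n,
                 taxonomy_ok = tax_ok,
                 pairs = data.frame(asym_id = "A",
                                    label_seq_id = seq_len(n),
                                    unp_acc = acc, unp_num = seq_len(n),
                                    unp_one_letter = "A",
                                    chain_one_letter = "A",
                                    identical = c(rep(TRUE, n_id),
                                                  rep(FALSE, n - n_id))),
                 is_best = FALSE),
            class = "candidate_mapping")
}
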