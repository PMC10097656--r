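augmented_fixture <- function(preset = "tag", seed = 5) {
  d <- tempfile()
  dir.create(d)
  fx <- fixture_preset(preset, seed = seed, dir = d)
  entry <- read_entry(fx$cif)
  cur <- utils::read.delim(fx$curated, colClasses = "character")
  doms <- read_domain_definitions(fx$domains)
  aug <- suppressMessages(suppressWarnings(
    augment_entry(entry, fx$records, cur, fx$tree, doms)))
  list(dir = d, fx = fx, entry = entry, aug = aug)
}

test_that("category emission respects names, ordering and flags", {
  f <- augmented_fixture("repeat")
  on.exit(unlink(f$dir, recursive = TRUE))
  tab <- emit_unp_segments(f$aug$segments)
  expect_true(all(c("asym_id", "unp_acc", "instance_id", "segment_id",
                    "seq_id_start", "seq_id_end", "unp_start", "unp_end",
                    "identity", "best_mapping") %in% names(tab)))
  expect_true(all(tab$best_mapping %in% c("Y", "N")))
  # tandem repeat: the best accession appears with instance ids 1 and 2
  best <- tab[tab$best_mapping == "Y", ]
  expect_setequal(best$instance_id, c("1", "2"))
  # ordering: (asym, acc, instance, segment)
  o <- order(tab$asym_id, tab$unp_acc, as.integer(tab$instance_id),
             as.integer(tab$segment_id))
  expect_equal(o, seq_len(nrow(tab)))
  # empty inputs emit no category at all
  expect_null(emit_unp_segments(NULL))
  expect_null(emit_xref_segments(f$aug$xref_segments[0, ]))
  expect_null(emit_xref_db(NULL))
  # invariant violations are refused
  bad <- f$aug$segments
  bad$unp_end[1] <- bad$unp_end[1] + 1L
  expect_error(emit_unp_segments(bad), "collinear")
})

test_that("atom_site augmentation is value-preserving and complete", {
  f <- augmented_fixture("tag")
  on.exit(unlink(f$dir, recursive = TRUE))
  before <- f$entry$doc$categories$atom_site
  after <- f$aug$doc$categories$atom_site
  # no pre-existing item or value altered
  expect_identical(after[, names(before)], before)
  # every atom gains the four items; label index is always set
  expect_true(all(c("pdbx_sifts_xref_db_acc", "pdbx_sifts_xref_db_name",
                    "pdbx_sifts_xref_db_num", "pdbx_label_index")
                  %in% names(after)))
  expect_false(any(after$pdbx_label_index %in% c(".", "?")))
  # tag residue atoms carry '?' for the three xref items
  tag_ids <- f$fx$truth$residue$label_seq_id[
    is.na(f$fx$truth$residue$accession)]
  tag_rows <- after$label_seq_id %in% as.character(tag_ids)
  expect_true(all(after$pdbx_sifts_xref_db_acc[tag_rows] == "?"))
  # mapped residues agree row-for-row with the per-residue table
  res <- f$aug$residues
  mi <- match(after$label_seq_id, as.character(res$seq_id))
  hit <- !is.na(mi) & after$label_asym_id == "A"
  expect_equal(after$pdbx_sifts_xref_db_acc[hit], res$unp_acc[mi[hit]])
  expect_equal(after$pdbx_sifts_xref_db_num[hit],
               as.character(res$unp_num[mi[hit]]))
})

test_that("written files are re-parseable, greppable and fixpoints", {
  f <- augmented_fixture("split")
  on.exit(unlink(f$dir, recursive = TRUE))
  out1 <- file.path(f$dir, "u1.cif")
  write_updated_cif(f$aug$doc, f$aug$tables, out1)
  txt <- readLines(out1)
  for (cat in c("_pdbx_sifts_unp_segments", "_pdbx_sifts_xref_db_segments",
                "_pdbx_sifts_xref_db", "_atom_site.pdbx_label_index"))
    expect_true(any(grepl(cat, txt, fixed = TRUE)), info = cat)
  # write -> read -> write fixpoint
  out2 <- file.path(f$dir, "u2.cif")
  cif_write(cif_read(out1), out2)
  out3 <- file.path(f$dir, "u3.cif")
  cif_write(cif_read(out2), out3)
  expect_identical(readLines(out2), readLines(out3))
  # parse_sifts_categories reconstructs the emitted tables
  parsed <- parse_sifts_categories(out1)
  expect_equal(nrow(parsed$unp_segments), nrow(f$aug$segments))
  expect_equal(nrow(parsed$residues), nrow(f$aug$residues))
  got_best <- parsed$unp_segments[parsed$unp_segments$best_mapping, ]
  want_best <- f$aug$segments[f$aug$segments$best_mapping, ]
  expect_setequal(paste(got_best$unp_acc, got_best$seq_id_start,
                        got_best$seq_id_end, got_best$instance_id,
                        got_best$segment_id),
                  paste(want_best$unp_acc, want_best$seq_id_start,
                        want_best$seq_id_end, want_best$instance_id,
                        want_best$segment_id))
  # cross-category referential integrity: every seq_id resolves to a chain
  ch <- f$entry$chains[["A"]]
  expect_true(all(parsed$residues$seq_id %in% ch$monomers$label_seq_id))
  expect_true(all(parsed$unp_segments$seq_id_start %in%
                    ch$monomers$label_seq_id))
})

test_that("hand-written and extended SIFTS categories parse", {
  f <- write_lines_cif(c(
    "data_H",
    "loop_",
    "_pdbx_sifts_unp_segments.asym_id",
    "_pdbx_sifts_unp_segments.unp_acc",
    "_pdbx_sifts_unp_segments.instance_id",
    "_pdbx_sifts_unp_segments.segment_id",
    "_pdbx_sifts_unp_segments.seq_id_start",
    "_pdbx_sifts_unp_segments.seq_id_end",
    "_pdbx_sifts_unp_segments.unp_start",
    "_pdbx_sifts_unp_segments.unp_end",
    "_pdbx_sifts_unp_segments.identity",
    "_pdbx_sifts_unp_segments.best_mapping",
    "_pdbx_sifts_unp_segments.extra_item",
    "A P12345 1 1 1 50 10 59 0.9800 Y opaque"))
  parsed <- parse_sifts_categories(f)
  expect_equal(nrow(parsed$unp_segments), 1L)
  expect_equal(parsed$unp_segments$unp_start, 10L)
  expect_true(parsed$unp_segments$best_mapping)
  # unknown extra item preserved opaquely in the raw table
  expect_equal(parsed$raw$pdbx_sifts_unp_segments$extra_item, "opaque")
  # missing mandatory item -> schema error naming the item
  f2 <- write_lines_cif(c(
    "data_H",
    "loop_",
    "_pdbx_sifts_unp_segments.asym_id",
    "_pdbx_sifts_unp_segments.unp_acc",
    "A P12345"))
  expect_error(parse_sifts_categories(f2), "instance_id")
  # a file without any SIFTS category is rejected
  expect_error(parse_sifts_categories(mini_entry_cif()), "no SIFTS category")
})

test_that("the schema table pins the paper-attested item names", {
  sch <- sifts_schema()
  fixed <- sch$item[sch$paper_attested]
  expect_true(all(c("instance_id", "segment_id", "seq_id", "seq_id_start",
                    "seq_id_end", "pdbx_label_index") %in% fixed))
  expect_setequal(unique(sch$category),
                  c("pdbx_sifts_unp_segments", "pdbx_sifts_xref_db_segments",
                    "pdbx_sifts_xref_db", "atom_site"))
})
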