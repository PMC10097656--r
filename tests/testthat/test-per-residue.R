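expand_mini <- function() {
  entry <- read_entry(mini_entry_cif())
  ch <- entry$chains[["A"]] # MKVLQAGSTW, residues 5-6 unobserved
  pairs <- data.frame(asym_id = "A", label_seq_id = 3:10, unp_acc = "P1",
                      unp_num = 1:8, unp_one_letter = c("V", "L", "Q", "A",
                                                        "G", "A", "T", "W"),
                      chain_one_letter = c("V", "L", "Q", "A", "G", "S",
                                           "T", "W"),
                      identical = c(rep(TRUE, 5), FALSE, TRUE, TRUE),
                      stringsAsFactors = FALSE)
  segs <- assign_instances(build_unp_segments(pairs, identity = 7 / 8,
                                              best_mapping = TRUE))
  list(entry = entry, ch = ch, pairs = pairs, segs = segs)
}

test_that("per-residue rows cover exactly the best segments", {
  f <- expand_mini()
  res <- expand_residues(f$segs, NULL, f$ch, f$pairs)
  # row count equals the summed best-segment length
  expect_equal(nrow(res), sum(f$segs$seq_id_end - f$segs$seq_id_start + 1L))
  expect_equal(res$seq_id, 3:10)
  # residues 5-6 are unobserved but still carry UniProt numbering
  expect_equal(res$observed, c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE,
                               TRUE, TRUE))
  expect_false(any(is.na(res$unp_num)))
  # the point mutation is the single conflict row
  expect_equal(sum(res$conflict), 1L)
  expect_equal(res$seq_id[res$conflict], 8L)
  # conflicts equal the non-identical pairs inside best segments
  expect_equal(sum(res$conflict), sum(!f$pairs$identical))
  # every row's unp_num lies inside its covering segment
  expect_true(all(res$unp_num >= f$segs$unp_start &
                    res$unp_num <= f$segs$unp_end))
  # non-best segments are not expanded
  segs2 <- f$segs
  segs2$best_mapping <- FALSE
  expect_equal(nrow(expand_residues(segs2, NULL, f$ch, f$pairs)), 0L)
})

test_that("resource columns are filled from covering domain segments", {
  f <- expand_mini()
  xs <- data.frame(resource = c("Pfam", "CATH"),
                   xref_acc = c("PF00001", "1.10.8.10"), asym_id = "A",
                   instance_id = 1L, segment_id = 1L,
                   seq_id_start = c(3L, 5L), seq_id_end = c(6L, 10L),
                   stringsAsFactors = FALSE)
  res <- expand_residues(f$segs, xs, f$ch, f$pairs)
  expect_equal(res$pfam_acc, c("PF00001", "PF00001", "PF00001", "PF00001",
                               NA, NA, NA, NA))
  expect_equal(res$cath_id, c(NA, NA, "1.10.8.10", "1.10.8.10", "1.10.8.10",
                              "1.10.8.10", "1.10.8.10", "1.10.8.10"))
  # two segments of one resource covering one residue is an integrity error
  xs2 <- rbind(xs, data.frame(resource = "Pfam", xref_acc = "PF00002",
                              asym_id = "A", instance_id = 1L,
                              segment_id = 1L, seq_id_start = 4L,
                              seq_id_end = 5L))
  expect_error(expand_residues(f$segs, xs2, f$ch, f$pairs), "two Pfam")
})

test_that("author-key queries resolve insertion codes", {
  d <- tempfile(); dir.create(d); on.exit(unlink(d, recursive = TRUE))
  fx <- fixture_preset("insertcode", seed = 3, dir = d)
  entry <- read_entry(fx$cif)
  cur <- utils::read.delim(fx$curated, colClasses = "character")
  aug <- suppressMessages(suppressWarnings(
    augment_entry(entry, fx$records, cur, fx$tree, NULL)))
  res <- aug$residues
  # find the anchor author number shared by three residues (icode '', A, B)
  anchor <- res$auth_seq_id[res$icode == "A"]
  expect_length(anchor, 1L)
  plain <- residue_query(res, "A", anchor, "")
  ins_a <- residue_query(res, "A", anchor, "A")
  ins_b <- residue_query(res, "A", anchor, "B")
  expect_equal(ins_a$seq_id, plain$seq_id + 1L)
  expect_equal(ins_b$seq_id, plain$seq_id + 2L)
  # queries outside the chain or on unmapped residues return NULL
  expect_null(residue_query(res, "A", "99999", ""))
  expect_null(residue_query(res, "Z", anchor, ""))
})

test_that("tag residues have no cross-reference row", {
  d <- tempfile(); dir.create(d); on.exit(unlink(d, recursive = TRUE))
  fx <- fixture_preset("tag", seed = 3, dir = d)
  entry <- read_entry(fx$cif)
  cur <- utils::read.delim(fx$curated, colClasses = "character")
  aug <- suppressMessages(suppressWarnings(
    augment_entry(entry, fx$records, cur, fx$tree, NULL)))
  tag_ids <- fx$truth$residue$label_seq_id[is.na(fx$truth$residue$accession)]
  expect_true(length(tag_ids) >= 3L)
  expect_false(any(aug$residues$seq_id %in% tag_ids))
  # query by the tag residue's author number returns NULL
  ch <- entry$chains[["A"]]
  tag_auth <- ch$monomers$auth_seq_id[tag_ids[1]]
  expect_null(residue_query(aug$residues, "A", tag_auth, ""))
})
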