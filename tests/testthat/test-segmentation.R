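mk_pairs <- function(seq_ids, unp_nums, acc = "P1", identical = TRUE) {
  data.frame(asym_id = "A", label_seq_id = as.integer(seq_ids),
             unp_acc = acc, unp_num = as.integer(unp_nums),
             unp_one_letter = "A", chain_one_letter = "A",
             identical = identical, stringsAsFactors = FALSE)
}

test_that("contiguous collinear runs become single segments", {
  segs <- build_unp_segments(mk_pairs(1:50, 10:59), identity = 0.98,
                             best_mapping = TRUE)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$seq_id_start, 1L)
  expect_equal(segs$seq_id_end, 50L)
  expect_equal(segs$unp_start, 10L)
  expect_equal(segs$unp_end, 59L)
  # collinearity invariant
  expect_equal(segs$unp_end - segs$unp_start,
               segs$seq_id_end - segs$seq_id_start)
})

test_that("jumps in either numbering or accession changes split segments", {
  # internal unaligned linker -> two segments around it
  p <- rbind(mk_pairs(1:20, 1:20), mk_pairs(26:40, 21:35))
  segs <- build_unp_segments(p)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$seq_id_start, c(1L, 26L))
  # unp jump alone also splits (insert domain on the reference side)
  p2 <- rbind(mk_pairs(1:20, 1:20), mk_pairs(21:40, 121:140))
  expect_equal(nrow(build_unp_segments(p2)), 2L)
  # accession change splits
  p3 <- rbind(mk_pairs(1:20, 1:20, acc = "P1"),
              mk_pairs(21:40, 21:40, acc = "P2"))
  expect_equal(nrow(build_unp_segments(p3)), 2L)
})

test_that("unobserved residues do not break segments", {
  # segments are sequence-defined: pairs exist for unobserved residues too,
  # so a missing-residue stretch leaves one contiguous segment
  d <- tempfile(); dir.create(d); on.exit(unlink(d, recursive = TRUE))
  fx <- fixture_preset("missing", seed = 4, dir = d)
  entry <- read_entry(fx$cif)
  cur <- utils::read.delim(fx$curated, colClasses = "character")
  aug <- suppressMessages(suppressWarnings(
    augment_entry(entry, fx$records, cur, fx$tree, NULL)))
  best <- aug$segments[aug$segments$best_mapping, ]
  expect_equal(nrow(best), 1L)
  expect_true(sum(!aug$residues$observed) > 0)
})

test_that("instance and segment ids follow the advance/regression rule", {
  # two successive full-length copies -> instances 1 and 2
  two_copies <- data.frame(unp_acc = "P1", asym_id = "A",
                           seq_id_start = c(1L, 61L), seq_id_end = c(50L, 110L),
                           unp_start = c(1L, 1L), unp_end = c(50L, 50L))
  got <- assign_instances(two_copies)
  expect_equal(got$instance_id, c(1L, 2L))
  expect_equal(got$segment_id, c(1L, 1L))
  # split domain: advancing numbering -> same instance, segment 2
  split_dom <- data.frame(unp_acc = "P1", asym_id = "A",
                          seq_id_start = c(5L, 277L), seq_id_end = c(182L, 337L),
                          unp_start = c(5L, 277L), unp_end = c(182L, 337L))
  got2 <- assign_instances(split_dom)
  expect_equal(got2$instance_id, c(1L, 1L))
  expect_equal(got2$segment_id, c(1L, 2L))
  # single segment -> (1, 1)
  got3 <- assign_instances(two_copies[1, ])
  expect_equal(got3$instance_id, 1L)
  expect_equal(got3$segment_id, 1L)
  # numbering is dense: 1..K instances, 1..Mk segments
  mixed <- data.frame(unp_acc = "P1", asym_id = "A",
                      seq_id_start = c(1L, 40L, 80L, 120L),
                      seq_id_end = c(30L, 70L, 110L, 150L),
                      unp_start = c(1L, 45L, 1L, 45L),
                      unp_end = c(30L, 74L, 30L, 74L))
  got4 <- assign_instances(mixed)
  expect_equal(got4$instance_id, c(1L, 1L, 2L, 2L))
  expect_equal(got4$segment_id, c(1L, 2L, 1L, 2L))
})

test_that("domain projection shifts, repeats and splits correctly", {
  entry <- read_entry(mini_entry_cif())
  ch <- entry$chains[["A"]]
  # coordinate shift: unp 10-59 domain over chain 1-50 mapped to 10-59
  defs <- data.frame(resource = "Pfam", xref_acc = "PF00069",
                     coordinate_system = "unp", target = "P1",
                     start = 10L, end = 59L, stringsAsFactors = FALSE)
  xs <- project_domains(defs, mk_pairs(1:50, 10:59), ch)
  expect_equal(nrow(xs), 1L)
  expect_equal(xs$seq_id_start, 1L)
  expect_equal(xs$seq_id_end, 50L)
  expect_equal(xs$instance_id, 1L)
  # tandem repeat: one domain definition, two copies -> instances 1, 2
  rep_pairs <- rbind(mk_pairs(1:50, 10:59), mk_pairs(56:105, 10:59))
  xs2 <- project_domains(defs, rep_pairs, ch)
  expect_equal(xs2$instance_id, c(1L, 2L))
  expect_equal(xs2$segment_id, c(1L, 1L))
  # pdb_label definition split into two ranges -> one instance, two segments
  defs3 <- data.frame(resource = "CATH", xref_acc = "1.10.8.10",
                      coordinate_system = "pdb_label", target = "A",
                      start = c(1L, 7L), end = c(4L, 10L),
                      stringsAsFactors = FALSE)
  xs3 <- project_domains(defs3, mk_pairs(1:10, 1:10), ch)
  expect_equal(xs3$instance_id, c(1L, 1L))
  expect_equal(xs3$segment_id, c(1L, 2L))
  # unmapped target accession is skipped with a notice
  defs4 <- data.frame(resource = "Pfam", xref_acc = "PF1",
                      coordinate_system = "unp", target = "NOPE",
                      start = 1L, end = 10L, stringsAsFactors = FALSE)
  expect_message(out <- project_domains(defs4, mk_pairs(1:10, 1:10), ch),
                 "skipped")
  expect_equal(nrow(out), 0L)
})
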