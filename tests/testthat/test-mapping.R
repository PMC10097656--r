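make_records <- function() {
  df <- data.frame(
    accession = c("P1", "P1-2", "P1-3", "Q9"),
    canonical_accession = c("P1", "P1", "P1", "Q9"),
    is_canonical = c(TRUE, FALSE, FALSE, TRUE),
    sequence = c("MKVLQWREAY", "MKVLQ", "MKVQWREAY", "AYAYAYAYAY"),
    taxid = c("T40", "T40", "T40", "S32"),
    name = letters[1:4], stringsAsFactors = FALSE)
  class(df) <- c("uniprot_records", "data.frame")
  df
}

test_that("isoform expansion returns canonical-first accession groups", {
  rec <- make_records()
  got <- expand_isoforms("P1", rec)
  expect_equal(got$accession, c("P1", "P1-2", "P1-3"))
  expect_equal(expand_isoforms(character(0), rec)$accession, character(0))
  both <- expand_isoforms(c("P1", "Q9"), rec)
  expect_setequal(both$accession, c("P1", "P1-2", "P1-3", "Q9"))
  expect_error(expand_isoforms("Z0", rec), "Z0")
})

test_that("the taxonomy rule matches an exhaustive ancestor-walk oracle", {
  tree <- make_taxonomy(1)
  pairs <- attr(tree, "pairs")
  # independent oracle: full ancestor chains, truncated after a species
  # node, cut to max_levels steps; compatible iff the sets intersect
  chain_of <- function(t, max_levels) {
    nodes <- tree$nodes
    out <- t
    cur <- t
    for (s in seq_len(max_levels)) {
      if (nodes$rank[nodes$taxid == cur] == "species") break
      p <- nodes$parent_taxid[nodes$taxid == cur]
      if (p == cur) break
      out <- c(out, p)
      cur <- p
    }
    out
  }
  for (r in seq_len(nrow(pairs))) {
    got <- taxonomy_compatible(pairs$taxid_a[r], pairs$taxid_b[r], tree, 2L)
    oracle <- pairs$taxid_a[r] == pairs$taxid_b[r] ||
      length(intersect(chain_of(pairs$taxid_a[r], 2L),
                       chain_of(pairs$taxid_b[r], 2L))) > 0
    expect_equal(got, oracle, info = paste(pairs$taxid_a[r], pairs$taxid_b[r]))
    expect_equal(got, pairs$compatible[r],
                 info = paste("label", pairs$taxid_a[r], pairs$taxid_b[r]))
  }
  expect_error(taxonomy_compatible("T40", "NOPE", tree), "unknown taxid")
  expect_warning(ok <- taxonomy_compatible(NA, "T40", tree), "absent")
  expect_true(ok)
})

test_that("best-mapping selection conjoins taxonomy, threshold and ties", {
  # taxonomy failure beats higher identity
  got <- select_best(list(fake_candidate("P1", 0.95),
                          fake_candidate("P2", 0.97, tax_ok = FALSE)))
  expect_equal(got$accession, "P1")
  expect_true(got$is_best)
  # the 90% boundary is inclusive; 0.8999 is rejected
  expect_equal(select_best(list(fake_candidate("P1", 0.90)))$accession, "P1")
  expect_null(select_best(list(fake_candidate("P1", 0.89))))
  expect_null(select_best(list()))
  # canonical-first tie-break, then lexicographic accession
  tie <- select_best(list(fake_candidate("P1-2", 0.93),
                          fake_candidate("P1", 0.93)))
  expect_equal(tie$accession, "P1")
  tie2 <- select_best(list(fake_candidate("P1-3", 0.93, canonical = FALSE),
                           fake_candidate("P1-2", 0.93, canonical = FALSE)))
  expect_equal(tie2$accession, "P1-2")
  # exhaustive comparator check against a brute-force pick
  set.seed(5)
  for (k in 1:50) {
    cands <- lapply(seq_len(sample(1:5, 1)), function(i)
      fake_candidate(paste0("P", i), sample(85:100, 1) / 100,
                     tax_ok = sample(c(TRUE, FALSE), 1)))
    got <- select_best(cands)
    elig <- Filter(function(cm) cm$taxonomy_ok && cm$identity >= 0.9, cands)
    if (!length(elig)) {
      expect_null(got)
    } else {
      ids <- vapply(elig, `[[`, 0, "identity")
      expect_equal(got$identity, max(ids))
    }
  }
})

test_that("candidate generation reports every isoform without filtering", {
  entry <- read_entry(mini_entry_cif())
  ch <- entry$chains[["A"]] # MKVLQAGSTW
  rec <- make_records()
  # the mini entry records no source organism: the curated mapping is
  # trusted (one warning per record, silenced here)
  cands <- suppressWarnings(
    candidate_mappings(ch, expand_isoforms("P1", rec), make_taxonomy(1),
                       mapping_params(min_segment_length = 3L)))
  expect_length(cands, 3L)
  expect_equal(vapply(cands, `[[`, "", "accession"), c("P1", "P1-2", "P1-3"))
  # chain MKVLQ prefix is identical to the P1 prefix
  expect_equal(cands[[2]]$identity, 1.0)
  expect_equal(cands[[2]]$n_aligned, 5L)
})

test_that("chimera resolution partitions claimed residues", {
  a <- fake_candidate("PA", 1.0, n = 50L)
  b <- fake_candidate("PB", 1.0, n = 50L)
  b$pairs$label_seq_id <- 51:100
  got <- resolve_chimera(list(a, b))
  expect_equal(unname(got[as.character(1:50)]), rep("PA", 50))
  expect_equal(unname(got[as.character(51:100)]), rep("PB", 50))
  # single accession -> identity assignment
  solo <- resolve_chimera(list(a))
  expect_equal(unname(solo), rep("PA", 50))
  # 3-residue overlap at equal support -> left-flanking accession wins
  a2 <- fake_candidate("PA", 1.0, n = 50L)
  b2 <- fake_candidate("PB", 1.0, n = 50L)
  b2$pairs$label_seq_id <- 48:97
  got2 <- resolve_chimera(list(a2, b2))
  expect_equal(unname(got2[as.character(48:50)]), rep("PA", 3))
  # brute-force oracle: per residue, max support then left start then name
  claims <- list(list(acc = "PA", ids = 1:50, sup = 50, start = 1),
                 list(acc = "PB", ids = 48:97, sup = 50, start = 48))
  for (res in 1:97) {
    cl <- Filter(function(c) res %in% c$ids, claims)
    o <- order(-vapply(cl, `[[`, 0, "sup"),
               vapply(cl, `[[`, 0, "start"),
               vapply(cl, `[[`, "", "acc"))
    expect_equal(unname(got2[as.character(res)]), cl[[o[1]]]$acc)
  }
  # no residue is ever assigned twice (it is a named vector partition)
  expect_false(anyDuplicated(names(got2)) > 0)
})
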