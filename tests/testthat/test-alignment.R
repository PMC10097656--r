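test_that("DP score equals exhaustive enumeration on short sequences", {
  set.seed(7)
  alph <- c("A", "C", "G", "T")
  for (k in 1:300) {
    a <- paste(sample(alph, sample(1:8, 1), TRUE), collapse = "")
    b <- paste(sample(alph, sample(1:8, 1), TRUE), collapse = "")
    p <- alignment_params(end_gaps_free = k %% 2 == 0)
    expect_equal(align_global(a, b, p)$score, align_enumerate(a, b, p))
    expect_equal(align_local(a, b, p)$score,
                 align_enumerate(a, b, p, local = TRUE))
  }
})

test_that("DP score matches Biostrings pairwiseAlignment on longer pairs", {
  skip_if_not_installed("Biostrings")
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  mat <- matrix(-1, 20, 20, dimnames = list(aa, aa))
  diag(mat) <- 1
  set.seed(11)
  for (k in 1:25) {
    a <- paste(sample(aa, sample(20:80, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(20:80, 1), TRUE), collapse = "")
    free <- k %% 2 == 0
    # Biostrings charges a gap of length L as gapOpening + L*gapExtension
    ref <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = mat, gapOpening = 10, gapExtension = 1,
      type = if (free) "overlap" else "global", scoreOnly = TRUE)
    got <- align_global(a, b, alignment_params(end_gaps_free = free))$score
    expect_equal(got, ref)
  }
})

test_that("worked examples behave as specified", {
  p <- alignment_params()
  a1 <- align_global("MKV", "MKV", p)
  expect_equal(a1$n_aligned, 3L)
  expect_equal(a1$n_identical, 3L)
  expect_equal(alignment_identity(a1), 1.0)

  a2 <- align_global("GSHMKVLQ", "MKVLQ", p)
  expect_equal(a2$pairs$pos_a, 4:8)
  expect_equal(a2$pairs$pos_b, 1:5)
  expect_equal(a2$n_identical, 5L)

  a3 <- align_global("AAAA", "TTTT", alignment_params(end_gaps_free = FALSE))
  expect_equal(a3$n_aligned, 4L)
  expect_equal(a3$n_identical, 0L)
  expect_equal(alignment_identity(a3), 0)

  expect_error(align_global("", "MKV", p), "non-empty")
})

test_that("identity uses aligned columns and rejects empty alignments", {
  a <- align_global("MKVLQWRE", "MKVLQWRA",
                    alignment_params(end_gaps_free = FALSE))
  expect_equal(a$n_aligned, 8L)
  expect_equal(a$n_identical, 7L)
  expect_equal(alignment_identity(a), 7 / 8)
  empty <- structure(list(n_aligned = 0L, n_identical = 0L),
                     class = "sifts_alignment")
  expect_error(alignment_identity(empty), "undefined")
})

test_that("pairs are strictly monotone and the score is symmetric", {
  set.seed(3)
  aa <- c("A","R","N","D","C","Q","E","G","H","I")
  for (k in 1:50) {
    a <- paste(sample(aa, sample(5:40, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(5:40, 1), TRUE), collapse = "")
    al <- align_global(a, b)
    if (nrow(al$pairs) > 1L) {
      expect_true(all(diff(al$pairs$pos_a) > 0))
      expect_true(all(diff(al$pairs$pos_b) > 0))
    }
    expect_equal(al$score, align_global(b, a)$score)
  }
})

test_that("X positions align but never count as identical", {
  a <- align_global("MKXLQ", "MKXLQ", alignment_params(end_gaps_free = FALSE))
  expect_equal(a$n_aligned, 5L)
  expect_equal(a$n_identical, 4L)
})

test_that("residue pairs carry conflicts and skip unaligned tags", {
  entry <- read_entry(mini_entry_cif())
  ch <- entry$chains[["A"]] # MKVLQAGSTW
  unp <- "VLQAGSTW" # chain residues 1-2 (MK) behave like a tag
  a <- align_global(chain_sequence(ch), unp)
  rp <- residue_pairs(a, ch, "P99999", unp)
  expect_equal(rp$label_seq_id, 3:10)
  expect_equal(rp$unp_num, 1:8)
  expect_true(all(rp$identical))
  # single substitution -> exactly one non-identical pair
  unp2 <- "VLQAGATW"
  rp2 <- residue_pairs(align_global(chain_sequence(ch), unp2), ch,
                       "P99998", unp2)
  expect_equal(sum(!rp2$identical), 1L)
  expect_equal(rp2$label_seq_id[!rp2$identical], 8L)
})
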