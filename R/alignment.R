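# ---------------------------------------------------------------------------
# Pairwise semi-global alignment between a chain sequence and a UniProtKB
# sequence.  Identity scoring (no substitution matrix): SIFTS pairs are
# near-identical by construction, so the alignment's job is locating the
# construct on the reference, not detecting homology.
# ---------------------------------------------------------------------------

#' Alignment parameters
#'
#' @param match Score for an identical aligned pair (default +1).
#' @param mismatch Score for a non-identical pair, including any pair
#'   involving `X` (default -1).
#' @param gap_open Cost of a gap run of length 1 (default -11).
#' @param gap_extend Cost per additional gapped position (default -1); a run
#'   of length L costs `gap_open + (L-1)*gap_extend`.
#' @param end_gaps_free If `TRUE` (default) terminal gaps in either sequence
#'   cost nothing (semi-global alignment), so expression tags and construct
#'   overhangs do not depress identity.
#' @return Object of class `alignment_params`.
#' @export
alignment_params <- function(match = 1, mismatch = -1,
                             gap_open = -11, gap_extend = -1,
                             end_gaps_free = TRUE) {
  if (!(gap_open <= gap_extend && gap_extend <= 0))
    stop("require gap_open <= gap_extend <= 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, end_gaps_free = end_gaps_free),
            class = "alignment_params")
}

#' Optimal affine-gap pairwise alignment
#'
#' Computes the optimal global (or, with free end gaps, semi-global)
#' alignment of two sequences over the amino-acid alphabet plus `X`.
#' Traceback tie-breaking is deterministic: diagonal first, then gap in
#' `seq_b`, then gap in `seq_a`; with free end gaps, ties among terminal
#' cells prefer the full-length corner, then the last column bottom-up,
#' then the last row right-to-left.
#'
#' @param seq_a,seq_b Non-empty character strings.
#' @param params An [alignment_params()] object.
#' @return Object of class `sifts_alignment`: list with `pairs` (data.frame
#'   `pos_a`, `pos_b`, both strictly increasing), `score`, `n_identical`,
#'   `n_aligned`, and the input sequences.  An `X` position never counts as
#'   identical.
#' @export
align_global <- function(seq_a, seq_b, params = alignment_params()) {
  if (!is.character(seq_a) || !is.character(seq_b) ||
      length(seq_a) != 1L || length(seq_b) != 1L ||
      !nzchar(seq_a) || !nzchar(seq_b))
    stop("seq_a and seq_b must be non-empty strings")
  r <- gotoh_align_cpp(seq_a, seq_b, params$match, params$mismatch,
                       params$gap_open, params$gap_extend,
                       if (params$end_gaps_free) 1L else 0L)
  structure(list(pairs = data.frame(pos_a = r$pos_a, pos_b = r$pos_b),
                 score = r$score, n_identical = r$n_identical,
                 n_aligned = r$n_aligned, seq_a = seq_a, seq_b = seq_b,
                 params = params),
            class = "sifts_alignment")
}

#' Local affine-gap alignment (anchor search)
#'
#' Same scoring scheme as [align_global()], but the alignment may start and
#' end at any matched pair (terminal residues of both sequences are free).
#' This is the anchor search used by the mapping module for constructs
#' whose genuine region is an interior fraction of the chain (insert
#' domains, fusion partners); internal gaps remain penalized.
#'
#' @inheritParams align_global
#' @return A `sifts_alignment` (see [align_global()]).
#' @export
align_local <- function(seq_a, seq_b, params = alignment_params()) {
  if (!is.character(seq_a) || !is.character(seq_b) ||
      length(seq_a) != 1L || length(seq_b) != 1L ||
      !nzchar(seq_a) || !nzchar(seq_b))
    stop("seq_a and seq_b must be non-empty strings")
  r <- gotoh_align_cpp(seq_a, seq_b, params$match, params$mismatch,
                       params$gap_open, params$gap_extend, 2L)
  structure(list(pairs = data.frame(pos_a = r$pos_a, pos_b = r$pos_b),
                 score = r$score, n_identical = r$n_identical,
                 n_aligned = r$n_aligned, seq_a = seq_a, seq_b = seq_b,
                 params = params),
            class = "sifts_alignment")
}

#' @export
print.sifts_alignment <- function(x, ...) {
  cat("alignment: ", nchar(x$seq_a), " x ", nchar(x$seq_b), " residues, ",
      x$n_aligned, " aligned columns, ", x$n_identical, " identical (",
      if (x$n_aligned > 0) sprintf("%.1f%%", 100 * x$n_identical / x$n_aligned)
      else "NA", "), score ", x$score, "\n", sep = "")
  invisible(x)
}

#' Exhaustive-enumeration alignment score (reference implementation)
#'
#' Enumerates every monotone matching between the two sequences and returns
#' the best achievable score under the same scoring scheme as
#' [align_global()].  Exponential in sequence length; intended as an
#' independent oracle for short sequences (length <= ~10), never for
#' production alignment.
#'
#' @inheritParams align_global
#' @param local Score under the local (anchor-search) semantics of
#'   [align_local()] instead of global/overlap.
#' @return Optimal score (numeric scalar).
#' @export
align_enumerate <- function(seq_a, seq_b, params = alignment_params(),
                            local = FALSE) {
  if (nchar(seq_a) > 12L || nchar(seq_b) > 12L)
    stop("enumeration reference is restricted to sequences of length <= 12")
  mode <- if (local) 2L else if (params$end_gaps_free) 1L else 0L
  enum_align_score_cpp(seq_a, seq_b, params$match, params$mismatch,
                       params$gap_open, params$gap_extend, mode)
}

#' Sequence identity of an alignment
#'
#' Identical aligned pairs divided by aligned (non-gap) columns.
#'
#' @param a A `sifts_alignment`.
#' @return Fraction in `[0, 1]`.
#' @export
alignment_identity <- function(a) {
  stopifnot(inherits(a, "sifts_alignment"))
  if (a$n_aligned == 0L)
    stop("identity undefined: alignment has no aligned columns")
  a$n_identical / a$n_aligned
}

#' Per-residue correspondence rows from an alignment
#'
#' One row per aligned column; unaligned chain positions (expression tags,
#' linkers, insertions) yield no row.
#'
#' @param a A `sifts_alignment` built from `chain_sequence(chain)` and
#'   `unp_seq`.
#' @param chain The `polymer_chain` the alignment was computed for.
#' @param accession UniProtKB accession of `unp_seq`.
#' @param unp_seq The UniProtKB sequence aligned (canonical or isoform; the
#'   reported `unp_num` refers to positions in this sequence).
#' @return data.frame with columns `asym_id`, `label_seq_id`, `unp_acc`,
#'   `unp_num`, `unp_one_letter`, `chain_one_letter`, `identical`.
#' @export
residue_pairs <- function(a, chain, accession, unp_seq) {
  stopifnot(inherits(a, "sifts_alignment"), inherits(chain, "polymer_chain"))
  ca <- strsplit(a$seq_a, "")[[1]]
  cb <- strsplit(unp_seq, "")[[1]]
  p <- a$pairs
  la <- ca[p$pos_a]
  lb <- cb[p$pos_b]
  data.frame(asym_id = chain$label_asym_id,
             label_seq_id = p$pos_a,
             unp_acc = accession,
             unp_num = p$pos_b,
             unp_one_letter = lb,
             chain_one_letter = la,
             identical = la == lb & la != "X",
             stringsAsFactors = FALSE)
}
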