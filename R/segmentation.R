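# ---------------------------------------------------------------------------
# Decompose per-residue correspondences into contiguous, collinear segments;
# assign instance_id (repeat copies) and segment_id (split-domain parts);
# project external Pfam/SCOP2/CATH domain definitions onto the structure.
# ---------------------------------------------------------------------------

#' Build UniProt segments from residue pairs
#'
#' Maximal runs in which both `label_seq_id` and `unp_num` increment by
#' exactly 1 become one segment; a jump in either numbering, or a change of
#' accession, starts a new segment.  Unobserved residues do not break
#' segments: segments are defined on the sequence, and observedness is
#' carried per-residue instead.
#'
#' @param pairs data.frame of residue pairs (as from [residue_pairs()] or a
#'   `candidate_mapping`), sorted by `label_seq_id`.
#' @param assignment Optional named vector from [resolve_chimera()]; when
#'   given, pairs whose residue is assigned to a different accession are
#'   dropped first.
#' @param identity Whole-alignment identity to report on each segment.
#' @param best_mapping Logical flag copied onto each segment.
#' @return data.frame with columns `unp_acc`, `asym_id`, `seq_id_start`,
#'   `seq_id_end`, `unp_start`, `unp_end`, `identity`, `best_mapping`
#'   (instance/segment ids are added by [assign_instances()]).
#' @export
build_unp_segments <- function(pairs, assignment = NULL,
                               identity = NA_real_, best_mapping = FALSE) {
  empty <- data.frame(unp_acc = character(0), asym_id = character(0),
                      seq_id_start = integer(0), seq_id_end = integer(0),
                      unp_start = integer(0), unp_end = integer(0),
                      identity = numeric(0), best_mapping = logical(0),
                      stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(empty)
  if (is.unsorted(pairs$label_seq_id))
    pairs <- pairs[order(pairs$label_seq_id), , drop = FALSE]
  if (!is.null(assignment)) {
    keep <- assignment[as.character(pairs$label_seq_id)] == pairs$unp_acc
    keep[is.na(keep)] <- FALSE
    pairs <- pairs[keep, , drop = FALSE]
    if (!nrow(pairs)) return(empty)
  }
  brk <- c(1L, which(diff(pairs$label_seq_id) != 1L |
                       diff(pairs$unp_num) != 1L |
                       pairs$unp_acc[-1L] != pairs$unp_acc[-nrow(pairs)]) + 1L)
  run <- rep(seq_along(brk), diff(c(brk, nrow(pairs) + 1L)))
  segs <- lapply(split(seq_len(nrow(pairs)), run), function(g) {
    data.frame(unp_acc = pairs$unp_acc[g[1L]],
               asym_id = pairs$asym_id[g[1L]],
               seq_id_start = pairs$label_seq_id[g[1L]],
               seq_id_end = pairs$label_seq_id[g[length(g)]],
               unp_start = pairs$unp_num[g[1L]],
               unp_end = pairs$unp_num[g[length(g)]],
               identity = identity, best_mapping = best_mapping,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Assign instance and segment identifiers
#'
#' Within one accession (or domain accession) on one chain, segments are
#' scanned in `seq_id_start` order.  A segment whose reference numbering
#' still advances (`unp_start` greater than the previous segment's
#' `unp_end`) continues the current instance as an additional split part
#' (`segment_id + 1`); a regression or overlap of the reference numbering
#' starts a new copy (`instance_id + 1`, `segment_id` reset to 1).  This
#' single rule yields both tandem-repeat copies (instances 1, 2, ...) and
#' split domains (one instance, segments 1, 2, ...).
#'
#' @param segments data.frame of segments of one accession on one chain,
#'   with `seq_id_start` and reference columns `unp_start`/`unp_end` (for
#'   domain segments lacking reference numbering, each discontinuity is a
#'   new split part of one instance).
#' @return `segments` with integer columns `instance_id` and `segment_id`.
#' @export
assign_instances <- function(segments) {
  n <- nrow(segments)
  if (!n) {
    segments$instance_id <- integer(0)
    segments$segment_id <- integer(0)
    return(segments)
  }
  segments <- segments[order(segments$seq_id_start), , drop = FALSE]
  inst <- integer(n)
  segid <- integer(n)
  inst[1L] <- 1L
  segid[1L] <- 1L
  has_ref <- all(c("unp_start", "unp_end") %in% names(segments)) &&
    !anyNA(segments$unp_start)
  if (n > 1L) for (k in 2L:n) {
    advancing <- if (has_ref)
      segments$unp_start[k] > segments$unp_end[k - 1L] else TRUE
    if (advancing) {
      inst[k] <- inst[k - 1L]
      segid[k] <- segid[k - 1L] + 1L
    } else {
      inst[k] <- inst[k - 1L] + 1L
      segid[k] <- 1L
    }
  }
  segments$instance_id <- inst
  segments$segment_id <- segid
  rownames(segments) <- NULL
  segments
}

#' Read domain definitions
#'
#' @param path Tab-separated file with columns `resource` (Pfam, SCOP2 or
#'   CATH), `xref_acc`, `coordinate_system` (`unp` or `pdb_label`), `target`
#'   (UniProt accession for `unp`, label_asym_id for `pdb_label`), `start`,
#'   `end`; repeated rows describe discontinuous definitions.
#' @return data.frame of class `domain_definitions`.
#' @export
read_domain_definitions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("resource", "xref_acc", "coordinate_system", "target",
            "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("domain definition table missing column(s): ",
         paste(miss, collapse = ", "))
  if (!all(df$resource %in% c("Pfam", "SCOP2", "CATH")))
    stop("resource must be one of Pfam, SCOP2, CATH")
  if (!all(df$coordinate_system %in% c("unp", "pdb_label")))
    stop("coordinate_system must be 'unp' or 'pdb_label'")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start > df$end)) stop("domain range with start > end")
  class(df) <- c("domain_definitions", "data.frame")
  df
}

#' Project domain definitions into structure segments
#'
#' UniProt-coordinate definitions are carried through the residue pairs of
#' the target accession; `pdb_label` definitions apply directly to the
#' chain.  Each definition's ranges are intersected with the mapped (or
#' existing) residues; the resulting runs get instance and segment ids by
#' the same advance/regression rule as [assign_instances()].
#'
#' @param defs A `domain_definitions` data.frame.
#' @param pairs Residue pairs of the chain's best mapping(s) (data.frame
#'   with `unp_acc`, `label_seq_id`, `unp_num`).
#' @param chain The `polymer_chain`.
#' @return data.frame with columns `resource`, `xref_acc`, `asym_id`,
#'   `instance_id`, `segment_id`, `seq_id_start`, `seq_id_end`.
#' @export
project_domains <- function(defs, pairs, chain) {
  stopifnot(inherits(chain, "polymer_chain"))
  out <- list()
  empty <- data.frame(resource = character(0), xref_acc = character(0),
                      asym_id = character(0), instance_id = integer(0),
                      segment_id = integer(0), seq_id_start = integer(0),
                      seq_id_end = integer(0), stringsAsFactors = FALSE)
  if (is.null(defs) || !nrow(defs)) return(empty)
  key <- paste(defs$resource, defs$xref_acc, defs$coordinate_system,
               defs$target)
  for (g in split(seq_len(nrow(defs)), key)) {
    d <- defs[g, , drop = FALSE]
    cs <- d$coordinate_system[1L]
    if (cs == "unp") {
      if (is.null(pairs) || !nrow(pairs)) {
        message("domain ", d$xref_acc[1L], " targets unmapped accession ",
                d$target[1L], "; skipped")
        next
      }
      p <- pairs[pairs$unp_acc == d$target[1L], , drop = FALSE]
      if (!nrow(p)) {
        message("domain ", d$xref_acc[1L], " targets unmapped accession ",
                d$target[1L], "; skipped")
        next
      }
      inrange <- rep(FALSE, nrow(p))
      for (r in seq_len(nrow(d)))
        inrange <- inrange | (p$unp_num >= d$start[r] & p$unp_num <= d$end[r])
      p <- p[inrange, , drop = FALSE]
      if (!nrow(p)) next
      p <- p[order(p$label_seq_id), , drop = FALSE]
      brk <- c(1L, which(diff(p$label_seq_id) != 1L |
                           diff(p$unp_num) != 1L) + 1L)
      run <- rep(seq_along(brk), diff(c(brk, nrow(p) + 1L)))
      segs <- do.call(rbind, lapply(split(seq_len(nrow(p)), run), function(gg)
        data.frame(resource = d$resource[1L], xref_acc = d$xref_acc[1L],
                   asym_id = chain$label_asym_id,
                   seq_id_start = p$label_seq_id[gg[1L]],
                   seq_id_end = p$label_seq_id[gg[length(gg)]],
                   unp_start = p$unp_num[gg[1L]],
                   unp_end = p$unp_num[gg[length(gg)]],
                   stringsAsFactors = FALSE)))
    } else {
      if (d$target[1L] != chain$label_asym_id) next
      nres <- nrow(chain$monomers)
      segs <- do.call(rbind, lapply(seq_len(nrow(d)), function(r) {
        lo <- max(1L, d$start[r]); hi <- min(nres, d$end[r])
        if (lo > hi) return(NULL)
        data.frame(resource = d$resource[1L], xref_acc = d$xref_acc[1L],
                   asym_id = chain$label_asym_id,
                   seq_id_start = lo, seq_id_end = hi,
                   unp_start = NA_integer_, unp_end = NA_integer_,
                   stringsAsFactors = FALSE)
      }))
      if (is.null(segs)) next
    }
    segs <- assign_instances(segs)
    out[[length(out) + 1L]] <-
      segs[, c("resource", "xref_acc", "asym_id", "instance_id",
               "segment_id", "seq_id_start", "seq_id_end")]
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$resource, res$xref_acc, res$instance_id,
                   res$segment_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
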