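# ---------------------------------------------------------------------------
# Chain -> UniProtKB mapping: isoform expansion, taxonomy compatibility,
# identity threshold, best-mapping selection, chimera resolution.
# ---------------------------------------------------------------------------

#' Mapping parameters
#'
#' @param identity_threshold Minimum sequence identity for a best mapping;
#'   the boundary is inclusive ("at least 90%"), default 0.90.
#' @param max_ancestor_levels Maximum ancestor-walk steps for taxonomy
#'   compatibility (default 2: common ancestor within one or two levels,
#'   truncated at the species rank).
#' @param min_segment_length Minimum aligned length for a secondary
#'   (repeat-copy) alignment pass to be accepted, in residues (default 10).
#' @param min_coverage Minimum aligned-column count of a best-mapping
#'   candidate, as a fraction of the largest aligned-column count in its
#'   candidate group (default 0.5).  A candidate explaining only a small
#'   sub-region of what another candidate explains cannot be the best
#'   mapping, however locally identical that sub-region is.
#' @return Object of class `mapping_params`.
#' @export
mapping_params <- function(identity_threshold = 0.90,
                           max_ancestor_levels = 2L,
                           min_segment_length = 10L,
                           min_coverage = 0.5) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            max_ancestor_levels >= 0, min_segment_length >= 1,
            min_coverage >= 0, min_coverage <= 1)
  structure(list(identity_threshold = identity_threshold,
                 max_ancestor_levels = as.integer(max_ancestor_levels),
                 min_segment_length = as.integer(min_segment_length),
                 min_coverage = min_coverage),
            class = "mapping_params")
}

#' Read UniProtKB candidate records
#'
#' @param fasta_path FASTA file; the accession must be the first token of
#'   each header.
#' @param meta_path Tab-separated metadata with columns `accession`,
#'   `canonical_accession`, `taxid`, `name`.
#' @return data.frame of class `uniprot_records` with columns `accession`,
#'   `canonical_accession`, `is_canonical`, `sequence`, `taxid`, `name`.
#' @export
read_uniprot_set <- function(fasta_path, meta_path) {
  seqs <- read_fasta(fasta_path)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  need <- c("accession", "canonical_accession", "taxid", "name")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("uniprot metadata missing column(s): ", paste(miss, collapse = ", "))
  mi <- match(names(seqs), meta$accession)
  if (anyNA(mi))
    stop("no metadata for accession(s): ",
         paste(names(seqs)[is.na(mi)], collapse = ", "))
  out <- data.frame(accession = names(seqs),
                    canonical_accession = meta$canonical_accession[mi],
                    is_canonical = names(seqs) == meta$canonical_accession[mi],
                    sequence = unname(seqs),
                    taxid = meta$taxid[mi],
                    name = meta$name[mi],
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$sequence))) stop("empty sequence in ", fasta_path)
  class(out) <- c("uniprot_records", "data.frame")
  out
}

# FASTA -> named character vector; the accession is the first
# whitespace-delimited token of the header
read_fasta <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  if (!length(s)) stop("no FASTA records in ", path)
  acc <- sub("^\\s*(\\S+).*$", "\\1", names(s))
  stats::setNames(toupper(as.character(s)), acc)
}

#' Read a taxonomy table
#'
#' @param path Tab-separated file with columns `taxid`, `parent_taxid`,
#'   `rank` (and optionally `name`).  The root node has itself (or empty)
#'   as parent.
#' @return Object of class `taxonomy_tree`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  miss <- setdiff(c("taxid", "parent_taxid", "rank"), names(df))
  if (length(miss))
    stop("taxonomy table missing column(s): ", paste(miss, collapse = ", "))
  taxonomy_tree(df)
}

#' Construct a taxonomy tree
#'
#' @param nodes data.frame with columns `taxid`, `parent_taxid`, `rank`.
#' @return Object of class `taxonomy_tree`.
#' @export
taxonomy_tree <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  nodes$taxid <- as.character(nodes$taxid)
  nodes$parent_taxid <- as.character(nodes$parent_taxid)
  if (anyDuplicated(nodes$taxid)) stop("duplicate taxid in taxonomy table")
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$taxid)
  # cycle/termination check: every parent chain must reach a root
  for (t in nodes$taxid) {
    seen <- character(0)
    cur <- t
    repeat {
      if (cur %in% seen) stop("taxonomy cycle at taxid ", cur)
      seen <- c(seen, cur)
      p <- nodes$parent_taxid[idx[[cur]]]
      if (is.na(p) || !nzchar(p) || p == cur) break
      if (is.na(idx[p])) stop("parent taxid ", p, " of ", cur, " not in table")
      cur <- p
    }
  }
  structure(list(nodes = nodes, index = idx), class = "taxonomy_tree")
}

#' Taxonomy compatibility of two source organisms
#'
#' Two taxa are compatible when they are identical, or when the ancestor
#' walks of both — self plus up to `max_levels` ancestors, truncated once a
#' node of rank `species` is reached — intersect.
#'
#' @param taxid_a,taxid_b Taxonomy identifiers; `NA` on either side returns
#'   `TRUE` with a warning (the curated mapping is trusted when the source
#'   organism is unrecorded).
#' @param tree A `taxonomy_tree`.
#' @param max_levels Maximum ancestor steps (default 2).
#' @return Logical scalar.
#' @export
taxonomy_compatible <- function(taxid_a, taxid_b, tree, max_levels = 2L) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  if (is.na(taxid_a) || is.na(taxid_b)) {
    warning("source organism absent; accepting curated mapping", call. = FALSE)
    return(TRUE)
  }
  taxid_a <- as.character(taxid_a)
  taxid_b <- as.character(taxid_b)
  for (t in c(taxid_a, taxid_b))
    if (is.na(tree$index[t])) stop("unknown taxid: ", t)
  if (taxid_a == taxid_b) return(TRUE)
  length(intersect(ancestor_walk(taxid_a, tree, max_levels),
                   ancestor_walk(taxid_b, tree, max_levels))) > 0L
}

# self plus up to max_levels ancestors; the walk stops once a species-rank
# node has been included (levels are counted up to the species level)
ancestor_walk <- function(taxid, tree, max_levels) {
  nodes <- tree$nodes
  idx <- tree$index
  walk <- taxid
  cur <- taxid
  steps <- 0L
  while (steps < max_levels) {
    if (identical(nodes$rank[idx[[cur]]], "species")) break
    p <- nodes$parent_taxid[idx[[cur]]]
    if (is.na(p) || !nzchar(p) || p == cur) break
    walk <- c(walk, p)
    cur <- p
    steps <- steps + 1L
  }
  walk
}

#' Expand curated canonical accessions to all their isoforms
#'
#' @param curated Character vector of canonical accessions.
#' @param records A `uniprot_records` data.frame.
#' @return The subset of `records` belonging to the curated accession
#'   groups: canonical record first, then isoforms by accession text.
#' @export
expand_isoforms <- function(curated, records) {
  stopifnot(inherits(records, "uniprot_records") || is.data.frame(records))
  curated <- unique(curated)
  if (!length(curated)) return(records[0L, , drop = FALSE])
  missing_acc <- setdiff(curated, records$canonical_accession)
  if (length(missing_acc))
    stop("curated accession(s) not in records: ",
         paste(missing_acc, collapse = ", "))
  parts <- lapply(curated, function(acc) {
    grp <- records[records$canonical_accession == acc, , drop = FALSE]
    grp[order(!grp$is_canonical, grp$accession), , drop = FALSE]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Candidate chain-to-UniProt mappings
#'
#' Aligns the chain sequence against every expanded record.  To support
#' tandem repeats (several copies of one accession in a single chain), the
#' unaligned flanks left by the primary alignment are re-aligned recursively
#' against the same record; a secondary pass is kept only when it aligns at
#' least `min_segment_length` residues at or above the identity threshold.
#' No filtering is applied across records: every isoform alignment is
#' reported (filtering happens in [select_best()]).
#'
#' @param chain A `polymer_chain`.
#' @param records Records from [expand_isoforms()].
#' @param tree A `taxonomy_tree`, or `NULL` to skip the taxonomy check.
#' @param params A [mapping_params()] object.
#' @param align_params An [alignment_params()] object.
#' @return List of `candidate_mapping` objects.
#' @export
candidate_mappings <- function(chain, records, tree = NULL,
                               params = mapping_params(),
                               align_params = alignment_params()) {
  stopifnot(inherits(chain, "polymer_chain"))
  seq_c <- chain_sequence(chain)
  lapply(seq_len(nrow(records)), function(r) {
    rec <- records[r, ]
    hits <- map_iterative(seq_c, rec$sequence, params, align_params)
    tax_ok <- if (is.null(tree)) TRUE else
      taxonomy_compatible(chain$taxid, rec$taxid, tree,
                          params$max_ancestor_levels)
    pr <- if (nrow(hits)) {
      ca <- strsplit(seq_c, "")[[1]]
      cb <- strsplit(rec$sequence, "")[[1]]
      la <- ca[hits$pos_a]; lb <- cb[hits$pos_b]
      data.frame(asym_id = chain$label_asym_id, label_seq_id = hits$pos_a,
                 unp_acc = rec$accession, unp_num = hits$pos_b,
                 unp_one_letter = lb, chain_one_letter = la,
                 identical = la == lb & la != "X", stringsAsFactors = FALSE)
    } else {
      data.frame(asym_id = character(0), label_seq_id = integer(0),
                 unp_acc = character(0), unp_num = integer(0),
                 unp_one_letter = character(0), chain_one_letter = character(0),
                 identical = logical(0), stringsAsFactors = FALSE)
    }
    n_al <- nrow(pr)
    n_id <- sum(pr$identical)
    structure(list(asym_id = chain$label_asym_id,
                   accession = rec$accession,
                   canonical_accession = rec$canonical_accession,
                   is_canonical = rec$is_canonical,
                   identity = if (n_al > 0L) n_id / n_al else 0,
                   n_identical = n_id, n_aligned = n_al,
                   taxonomy_ok = tax_ok, pairs = pr, is_best = FALSE),
              class = "candidate_mapping")
  })
}

# Maximal-scoring contiguous column run of an alignment (Kadane over the
# alignment path: columns score match/mismatch, jumps between consecutive
# columns cost their gap runs).  Semi-global alignments of constructs align
# foreign regions (tags, linkers, fusion partners) as cheap mismatch
# columns; the trim recovers the genuine anchor region.  Ties prefer the
# shortest, leftmost run, so chance matches in foreign residues are not
# absorbed.
trim_to_anchor <- function(a, params) {
  p <- a$pairs
  n <- nrow(p)
  if (n == 0L) return(p)
  la <- strsplit(a$seq_a, "")[[1]][p$pos_a]
  lb <- strsplit(a$seq_b, "")[[1]][p$pos_b]
  colscore <- ifelse(la == lb & la != "X", params$match, params$mismatch)
  rc <- function(L) ifelse(L > 0L, params$gap_open + (L - 1L) *
                             params$gap_extend, 0)
  gap <- if (n > 1L) rc(diff(p$pos_a) - 1L) + rc(diff(p$pos_b) - 1L)
         else numeric(0)
  best <- -Inf; bs <- be <- 1L
  cur <- 0; cs <- 1L
  for (k in seq_len(n)) {
    ext <- if (k > 1L) cur + gap[k - 1L] else -Inf
    if (ext > 0) {
      cur <- ext + colscore[k]
    } else {
      cur <- colscore[k]
      cs <- k
    }
    if (cur > best) { best <- cur; bs <- cs; be <- k }
  }
  p[bs:be, , drop = FALSE]
}

# Local anchor alignment, anchor trim, then recursive re-alignment of the
# remaining chain flanks against the full record sequence (tandem repeat
# and insert-domain support).  The primary anchor must reach the minimum
# segment length; secondary anchors must additionally meet the identity
# threshold.
map_iterative <- function(seq_c, seq_u, params, align_params) {
  n <- nchar(seq_c)
  cu <- strsplit(seq_c, "")[[1]]
  ub <- strsplit(seq_u, "")[[1]]
  empty <- data.frame(pos_a = integer(0), pos_b = integer(0))
  rec_align <- function(lo, hi, primary) {
    if (hi - lo + 1L < params$min_segment_length) return(empty)
    a <- align_local(substr(seq_c, lo, hi), seq_u, align_params)
    if (a$n_aligned == 0L) return(empty)
    anchor <- trim_to_anchor(a, align_params)
    if (nrow(anchor) < params$min_segment_length) return(empty)
    if (!primary) {
      ident <- cu[anchor$pos_a + lo - 1L] == ub[anchor$pos_b]
      if (mean(ident) < params$identity_threshold) return(empty)
    }
    p <- data.frame(pos_a = anchor$pos_a + lo - 1L, pos_b = anchor$pos_b)
    left <- rec_align(lo, min(p$pos_a) - 1L, FALSE)
    right <- rec_align(max(p$pos_a) + 1L, hi, FALSE)
    rbind(left, p, right)
  }
  out <- rec_align(1L, n, TRUE)
  out[order(out$pos_a), , drop = FALSE]
}

#' @export
print.candidate_mapping <- function(x, ...) {
  cat(sprintf("chain %s -> %s: identity %.3f over %d residues, taxonomy %s%s\n",
              x$asym_id, x$accession, x$identity, x$n_aligned,
              if (x$taxonomy_ok) "ok" else "incompatible",
              if (x$is_best) " [best]" else ""))
  invisible(x)
}

#' Select the best mapping among candidates of one chain
#'
#' Among taxonomy-compatible candidates whose identity meets the inclusive
#' threshold, the maximum-identity candidate wins; ties prefer the canonical
#' record, then lexicographically smaller accession.
#'
#' @param candidates List of `candidate_mapping` objects for one chain.
#' @param params A [mapping_params()] object.
#' @return The winning `candidate_mapping` with `is_best = TRUE`, or `NULL`
#'   if no candidate qualifies.
#' @export
select_best <- function(candidates, params = mapping_params()) {
  if (!length(candidates)) return(NULL)
  max_aligned <- max(vapply(candidates, `[[`, 0L, "n_aligned"))
  ok <- vapply(candidates, function(cm)
    cm$taxonomy_ok && cm$n_aligned > 0L &&
      cm$n_aligned >= params$min_coverage * max_aligned &&
      cm$identity >= params$identity_threshold, TRUE)
  if (!any(ok)) return(NULL)
  cand <- candidates[ok]
  ident <- vapply(cand, `[[`, 0, "identity")
  canon <- vapply(cand, `[[`, TRUE, "is_canonical")
  acc <- vapply(cand, `[[`, "", "accession")
  o <- order(-ident, !canon, acc)
  best <- cand[[o[1L]]]
  best$is_best <- TRUE
  best
}

#' Assign chimera residues to a single accession each
#'
#' For a chain mapped to more than one accession (chimeric construct), every
#' residue claimed by at least one best candidate is assigned to exactly one
#' accession: the claiming aligned run with the greater identical-pair count
#' wins; at equal support the run starting further left (the left-flanking
#' segment's accession) wins, then the lexicographically smaller accession.
#'
#' @param per_accession_best List of best `candidate_mapping`s, one per
#'   curated accession group of one chain.
#' @return Named character vector: `label_seq_id` (as name) -> accession.
#' @export
resolve_chimera <- function(per_accession_best) {
  per_accession_best <- per_accession_best[!vapply(per_accession_best,
                                                   is.null, TRUE)]
  if (!length(per_accession_best)) return(stats::setNames(character(0), NULL))
  claims <- list()
  for (cm in per_accession_best) {
    p <- cm$pairs
    if (!nrow(p)) next
    run <- cumsum(c(1L, (diff(p$label_seq_id) != 1L) |
                      (diff(p$unp_num) != 1L)))
    for (g in split(seq_len(nrow(p)), run)) {
      claims[[length(claims) + 1L]] <- list(
        accession = cm$accession,
        seq_ids = p$label_seq_id[g],
        start = min(p$label_seq_id[g]),
        support = sum(p$identical[g]))
    }
  }
  if (!length(claims)) return(stats::setNames(character(0), NULL))
  all_ids <- sort(unique(unlist(lapply(claims, `[[`, "seq_ids"))))
  assign <- stats::setNames(rep(NA_character_, length(all_ids)),
                            as.character(all_ids))
  sup <- stats::setNames(rep(-Inf, length(all_ids)), as.character(all_ids))
  st <- stats::setNames(rep(Inf, length(all_ids)), as.character(all_ids))
  for (cl in claims) {
    k <- as.character(cl$seq_ids)
    better <- cl$support > sup[k] |
      (cl$support == sup[k] & cl$start < st[k]) |
      (cl$support == sup[k] & cl$start == st[k] &
         (is.na(assign[k]) | cl$accession < assign[k]))
    assign[k][better] <- cl$accession
    sup[k][better] <- cl$support
    st[k][better] <- cl$start
  }
  assign
}
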