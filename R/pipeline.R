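# ---------------------------------------------------------------------------
# End-to-end augmentation: read entry -> map chains -> segment -> expand ->
# write `<id>_updated.cif`, with per-entry reporting.
# ---------------------------------------------------------------------------

#' Run configuration for the augmentation pipeline
#'
#' @param cif Character vector of input mmCIF paths.
#' @param uniprot_fasta,uniprot_meta UniProt candidate records (FASTA +
#'   metadata TSV).
#' @param taxonomy Taxonomy TSV path, or `NULL` to skip the taxonomy check.
#' @param curated Curated-mapping TSV (`entry_id`, `label_asym_id`,
#'   `canonical_accession`; repeated rows for chimeras).
#' @param domains Domain-definition TSV path(s), or `NULL`.
#' @param out_dir Output directory for the `_updated.cif` files.
#' @param mapping A [mapping_params()] object.
#' @param alignment An [alignment_params()] object.
#' @param emit_tsv Also write the per-residue table as TSV.
#' @param strict Stop on the first entry failure instead of isolating it.
#' @return Object of class `sifts_run_config`.
#' @export
run_config <- function(cif, uniprot_fasta, uniprot_meta, curated,
                       taxonomy = NULL, domains = NULL, out_dir = ".",
                       mapping = mapping_params(),
                       alignment = alignment_params(),
                       emit_tsv = FALSE, strict = FALSE) {
  for (p in c(cif, uniprot_fasta, uniprot_meta, curated, taxonomy, domains))
    if (!is.null(p) && !file.exists(p)) stop("no such file: ", p)
  structure(list(cif = cif, uniprot_fasta = uniprot_fasta,
                 uniprot_meta = uniprot_meta, curated = curated,
                 taxonomy = taxonomy, domains = domains, out_dir = out_dir,
                 mapping = mapping, alignment = alignment,
                 emit_tsv = emit_tsv, strict = strict),
            class = "sifts_run_config")
}

#' Augment one parsed entry
#'
#' The core per-entry computation: candidate mappings per curated accession
#' group, best-mapping selection, chimera resolution, segmentation with
#' instance/segment ids, domain projection, per-residue expansion, and
#' `_atom_site` augmentation.  Chains without a curated accession are
#' skipped (they still receive `pdbx_label_index`).
#'
#' @param entry A `sifts_entry`.
#' @param records A `uniprot_records` data.frame.
#' @param curated data.frame (`entry_id`, `label_asym_id`,
#'   `canonical_accession`).
#' @param tree A `taxonomy_tree` or `NULL`.
#' @param domains A `domain_definitions` data.frame or `NULL`.
#' @param mapping,alignment Parameter objects.
#' @return List with `doc` (augmented `cif_doc`), `tables` (category
#'   tables), `segments`, `xref_segments`, `residues`, `best` (list of best
#'   candidates per chain), and `report` (one-row data.frame).
#' @export
augment_entry <- function(entry, records, curated, tree = NULL,
                          domains = NULL, mapping = mapping_params(),
                          alignment = alignment_params()) {
  stopifnot(inherits(entry, "sifts_entry"))
  label_index <- compute_label_index(entry)
  all_segments <- list()
  all_xref <- list()
  all_residues <- list()
  best_by_chain <- list()
  n_skipped <- 0L

  # alignments are computed once per entity and reused across its chains
  entity_cache <- new.env(parent = emptyenv())

  for (ch in entry$chains) {
    cur <- curated[curated$entry_id == entry$entry_id &
                     curated$label_asym_id == ch$label_asym_id, , drop = FALSE]
    if (!nrow(cur)) {
      message("chain ", ch$label_asym_id, ": no curated accession; skipped")
      n_skipped <- n_skipped + 1L
      next
    }
    groups <- unique(cur$canonical_accession)
    cache_key <- paste0(ch$entity_id, "|", paste(sort(groups), collapse = ","))
    if (!is.null(entity_cache[[cache_key]])) {
      per_group <- entity_cache[[cache_key]]
      # re-key candidates onto this chain
      per_group <- lapply(per_group, function(g) {
        lapply(g, function(cm) {
          cm$asym_id <- ch$label_asym_id
          if (nrow(cm$pairs)) cm$pairs$asym_id <- ch$label_asym_id
          cm
        })
      })
    } else {
      per_group <- lapply(groups, function(g) {
        recs <- expand_isoforms(g, records)
        candidate_mappings(ch, recs, tree, mapping, alignment)
      })
      names(per_group) <- groups
      entity_cache[[cache_key]] <- per_group
    }

    bests <- lapply(per_group, select_best, params = mapping)
    assignment <- resolve_chimera(bests)
    best_ok <- bests[!vapply(bests, is.null, TRUE)]
    best_by_chain[[ch$label_asym_id]] <- best_ok

    # segments: every candidate of every group is reported; best-mapping
    # candidates have their pairs restricted by the chimera assignment
    chain_segs <- list()
    for (g in per_group) for (cm in g) {
      is_best_cm <- any(vapply(best_ok, function(b)
        identical(b$accession, cm$accession), TRUE))
      segs <- build_unp_segments(cm$pairs,
                                 assignment = if (is_best_cm) assignment,
                                 identity = cm$identity,
                                 best_mapping = is_best_cm)
      if (!nrow(segs)) next
      segs <- assign_instances(segs)
      chain_segs[[length(chain_segs) + 1L]] <- segs
    }
    if (length(chain_segs)) {
      seg_df <- do.call(rbind, chain_segs)
      all_segments[[ch$label_asym_id]] <- seg_df

      best_pairs <- do.call(rbind, lapply(best_ok, function(b) {
        keep <- assignment[as.character(b$pairs$label_seq_id)] ==
          b$pairs$unp_acc
        keep[is.na(keep)] <- FALSE
        b$pairs[keep, , drop = FALSE]
      }))
      xs <- project_domains(domains, best_pairs, ch)
      if (nrow(xs)) all_xref[[ch$label_asym_id]] <- xs
      res <- expand_residues(seg_df, xs, ch, best_pairs)
      if (nrow(res)) all_residues[[ch$label_asym_id]] <- res
    }
  }

  segments <- if (length(all_segments)) do.call(rbind, all_segments)
  xref_segments <- if (length(all_xref)) do.call(rbind, all_xref)
  residues <- if (length(all_residues)) do.call(rbind, all_residues)
  if (!is.null(residues)) rownames(residues) <- NULL

  doc <- augment_atom_site(entry, residues, label_index)
  tables <- list(unp_segments = emit_unp_segments(segments),
                 xref_segments = emit_xref_segments(xref_segments),
                 xref_db = emit_xref_db(residues))
  report <- data.frame(
    entry_id = entry$entry_id,
    chains = length(entry$chains),
    chains_skipped = n_skipped,
    accessions = length(unique(unlist(lapply(best_by_chain, function(b)
      vapply(b, `[[`, "", "accession"))))),
    segments = if (is.null(segments)) 0L else nrow(segments),
    xref_segments = if (is.null(xref_segments)) 0L else nrow(xref_segments),
    residues = if (is.null(residues)) 0L else nrow(residues),
    conflicts = if (is.null(residues)) 0L else sum(residues$conflict),
    stringsAsFactors = FALSE)
  list(doc = doc, tables = tables, segments = segments,
       xref_segments = xref_segments, residues = residues,
       best = best_by_chain, report = report)
}

#' Run the augmentation pipeline
#'
#' Processes every input entry: reads it, computes the mappings, writes
#' `<id>_updated.cif` into the output directory, and reports per-entry
#' totals.  SIFTS categories already present in an input are replaced
#' wholesale, so the run is idempotent.
#'
#' @param config A [run_config()] object.
#' @return data.frame report, one row per entry (with an `output` column);
#'   attribute `failures` lists entries that failed (non-strict mode).
#' @export
run_augment <- function(config) {
  stopifnot(inherits(config, "sifts_run_config"))
  records <- read_uniprot_set(config$uniprot_fasta, config$uniprot_meta)
  curated <- utils::read.delim(config$curated, stringsAsFactors = FALSE,
                               colClasses = "character")
  tree <- if (!is.null(config$taxonomy)) read_taxonomy(config$taxonomy)
  domains <- if (!is.null(config$domains)) {
    do.call(rbind, lapply(config$domains, read_domain_definitions))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- list()
  failures <- character(0)
  for (path in config$cif) {
    res <- tryCatch({
      entry <- read_entry(path)
      aug <- augment_entry(entry, records, curated, tree, domains,
                           config$mapping, config$alignment)
      out <- file.path(config$out_dir,
                       paste0(entry$entry_id, "_updated.cif"))
      write_updated_cif(aug$doc, aug$tables, out)
      if (config$emit_tsv && !is.null(aug$residues))
        utils::write.table(aug$residues,
                           file.path(config$out_dir,
                                     paste0(entry$entry_id, "_xref.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      rep <- aug$report
      rep$output <- out
      rep
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (config$strict) stop("entry ", path, " failed: ",
                              conditionMessage(res))
      warning("entry ", path, " failed: ", conditionMessage(res),
              call. = FALSE)
      failures <- c(failures, path)
      next
    }
    reports[[length(reports) + 1L]] <- res
  }
  out <- if (length(reports)) do.call(rbind, reports) else
    data.frame(entry_id = character(0))
  attr(out, "failures") <- failures
  out
}
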