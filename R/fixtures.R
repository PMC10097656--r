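# ---------------------------------------------------------------------------
# Deterministic synthetic fixtures: toy UniProt records with isoforms and
# decoys, a small ranked taxonomy, domain definitions, and mmCIF entries
# built from construct specifications (tags, truncations, point mutations,
# chimeras, tandem repeats, insert domains, unobserved residues, insertion
# codes) with fully known ground truth.
# ---------------------------------------------------------------------------

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

#' Generate a toy UniProtKB record set
#'
#' Builds canonical records with isoforms (an internal deletion and a
#' C-terminal truncation) plus decoy records verified by alignment to be
#' below 60% identity to every non-decoy sequence.  Deterministic for a
#' fixed seed.
#'
#' @param seed Integer seed.
#' @param n_records Number of non-decoy canonical records (>= 1).
#' @param n_isoforms Isoforms per canonical record (0, 1 or 2).
#' @param length_range Canonical sequence length range.
#' @param n_decoys Number of decoy records.
#' @param dir If non-`NULL`, the FASTA and metadata TSV are written here.
#' @return A `uniprot_records` data.frame; attributes `decoys` (accessions)
#'   and, when written, `fasta` and `meta` (paths).
#' @export
make_uniprot_set <- function(seed, n_records = 2L, n_isoforms = 2L,
                             length_range = c(150L, 220L), n_decoys = 1L,
                             dir = NULL) {
  stopifnot(n_records >= 1L, n_isoforms %in% 0:2)
  with_seed(seed, {
    taxpool <- c("T40", "T41") # strains of species S30 (see make_taxonomy)
    rows <- list()
    shared <- list() # canonical positions covered by every isoform of a group
    for (k in seq_len(n_records)) {
      acc <- sprintf("P%05d", 10000L + k)
      len <- sample(length_range[1L]:length_range[2L], 1L)
      seqk <- random_aa(len)
      cov <- seq_len(len)
      rows[[length(rows) + 1L]] <- data.frame(
        accession = acc, canonical_accession = acc, is_canonical = TRUE,
        sequence = seqk, taxid = taxpool[(k - 1L) %% 2L + 1L],
        name = sprintf("Synthetic protein %d", k), stringsAsFactors = FALSE)
      if (n_isoforms >= 1L) { # internal exon-skip deletion
        del_start <- floor(len * 0.40)
        del_len <- floor(len * 0.15)
        iso <- paste0(substr(seqk, 1L, del_start - 1L),
                      substr(seqk, del_start + del_len, len))
        cov <- setdiff(cov, del_start:(del_start + del_len - 1L))
        rows[[length(rows) + 1L]] <- data.frame(
          accession = paste0(acc, "-2"), canonical_accession = acc,
          is_canonical = FALSE, sequence = iso,
          taxid = taxpool[(k - 1L) %% 2L + 1L],
          name = sprintf("Synthetic protein %d isoform 2", k),
          stringsAsFactors = FALSE)
      }
      if (n_isoforms >= 2L) { # alternative (shortened) C-terminus
        cut <- floor(len * 0.80)
        iso <- substr(seqk, 1L, cut)
        cov <- cov[cov <= cut]
        rows[[length(rows) + 1L]] <- data.frame(
          accession = paste0(acc, "-3"), canonical_accession = acc,
          is_canonical = FALSE, sequence = iso,
          taxid = taxpool[(k - 1L) %% 2L + 1L],
          name = sprintf("Synthetic protein %d isoform 3", k),
          stringsAsFactors = FALSE)
      }
      # mutable positions: covered by every isoform AND interior to every
      # isoform's coverage runs (a mutation at a coverage-run edge is
      # terminal to that isoform's alignment and silently dropped by it,
      # handing the isoform a higher identity than the canonical record)
      run_interior <- function(pos) {
        if (!length(pos)) return(integer(0))
        brk <- cumsum(c(1L, diff(pos) != 1L))
        unlist(lapply(split(pos, brk), function(g)
          if (length(g) >= 5L) g[3:(length(g) - 2L)] else integer(0)),
          use.names = FALSE)
      }
      shared[[acc]] <- run_interior(cov)
    }
    nondecoy <- vapply(rows, function(r) r$sequence, "")
    decoys <- character(0)
    for (k in seq_len(n_decoys)) {
      acc <- sprintf("Q%05d", 90000L + k)
      len <- sample(length_range[1L]:length_range[2L], 1L)
      for (try in 1:50) {
        cand <- random_aa(len)
        ids <- vapply(nondecoy, function(s) {
          a <- align_global(cand, s)
          if (a$n_aligned == 0L) 0 else alignment_identity(a)
        }, 0)
        if (all(ids < 0.60)) break
      }
      decoys <- c(decoys, acc)
      rows[[length(rows) + 1L]] <- data.frame(
        accession = acc, canonical_accession = acc, is_canonical = TRUE,
        sequence = cand, taxid = "S32", # different genus: incompatible
        name = sprintf("Synthetic decoy %d", k), stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    class(out) <- c("uniprot_records", "data.frame")
    attr(out, "decoys") <- decoys
    attr(out, "shared_coverage") <- shared
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      fa <- file.path(dir, "uniprot.fasta")
      writeLines(unlist(lapply(seq_len(nrow(out)), function(r)
        c(paste0(">", out$accession[r], " ", out$name[r]),
          gsub("(.{60})", "\\1\n", out$sequence[r])))), fa)
      mt <- file.path(dir, "uniprot_meta.tsv")
      utils::write.table(
        out[, c("accession", "canonical_accession", "taxid", "name")],
        mt, sep = "\t", quote = FALSE, row.names = FALSE)
      attr(out, "fasta") <- fa
      attr(out, "meta") <- mt
    }
    out
  })
}

#' Generate the toy taxonomy
#'
#' A fixed small tree with ranks family/genus/species/strain/isolate plus a
#' table of labelled compatible and incompatible pairs at 1, 2 and 3
#' ancestor levels.
#'
#' @param seed Unused (the tree is fixed); kept for interface symmetry.
#' @param dir If non-`NULL`, a taxonomy TSV is written here.
#' @return A `taxonomy_tree`; attribute `pairs` holds the labelled pair
#'   table (`taxid_a`, `taxid_b`, `compatible`, `levels`), attribute `path`
#'   the TSV path when written.
#' @export
make_taxonomy <- function(seed = 1L, dir = NULL) {
  nodes <- data.frame(
    taxid  = c("R1", "F10", "G20", "G21", "S30", "S31", "S32",
               "T40", "T41", "T42", "U50", "V60"),
    parent_taxid = c("R1", "R1", "F10", "F10", "G20", "G20", "G21",
                     "S30", "S30", "S31", "T40", "U50"),
    rank   = c("no rank", "family", "genus", "genus", "species", "species",
               "species", "strain", "strain", "strain", "isolate", "isolate"),
    name   = c("root", "Synthetaceae", "Synthus", "Mockus",
               "Synthus exemplaris", "Synthus alter", "Mockus decoyi",
               "strain A", "strain B", "strain C", "isolate A1",
               "isolate A1a"),
    stringsAsFactors = FALSE)
  pairs <- data.frame(
    taxid_a = c("T40", "T40", "T40", "U50", "V60", "S30", "T40", "S30"),
    taxid_b = c("T40", "T41", "S30", "T41", "T41", "S31", "T42", "S32"),
    compatible = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    levels = c(0L, 1L, 1L, 2L, 3L, 2L, 2L, 4L),
    stringsAsFactors = FALSE)
  tree <- taxonomy_tree(nodes)
  attr(tree, "pairs") <- pairs
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(dir, "taxonomy.tsv")
    utils::write.table(nodes, p, sep = "\t", quote = FALSE, row.names = FALSE)
    attr(tree, "path") <- p
  }
  tree
}

#' Construct specification for a synthetic entry
#'
#' Describes one synthetic protein construct: which UniProt region(s) the
#' chain is built from and which experimental artefacts to emulate.
#'
#' @param seed Integer seed driving all random draws of this fixture.
#' @param accession Base (canonical) accession the chain is built from.
#' @param entry_id Entry identifier (data block code).
#' @param truncation `c(start, end)` of the base accession used, or `NULL`
#'   for the full sequence.
#' @param tag N-terminal expression tag sequence (`""` for none).
#' @param repeat_count Number of tandem copies of the base region (>= 1).
#' @param linker Linker sequence between repeats/partners.
#' @param chimera_partners List of `list(accession =, range = c(s, e))`
#'   fused after the base region.
#' @param insert_partner `list(accession =, range =, at =)`: a partner
#'   domain inserted after relative position `at` of the base region,
#'   splitting it in two (requires `repeat_count = 1`).
#' @param mutation_rate Per-residue point-mutation probability over
#'   interior mapped positions.
#' @param min_mutation_fraction Floor on the realized mutation count, as a
#'   fraction of the mapped region (default 0).  Used by constructs that
#'   must be engineered below the identity threshold: without the floor, a
#'   lucky binomial draw could leave the construct above 90% identity.
#' @param missing_fraction Fraction of residues left unobserved (no atoms).
#' @param insert_codes Emulate author insertion codes mid-chain.
#' @param use_mse Replace the first interior mapped Met by MSE
#'   (selenomethionine) to exercise modified-residue translation.
#' @param with_ligand Add a non-polymer component and waters.
#' @param auth_offset Author numbering offset relative to label numbering.
#' @return Object of class `construct_spec`.
#' @export
construct_spec <- function(seed, accession, entry_id = "SYN1",
                           truncation = NULL, tag = "",
                           repeat_count = 1L, linker = "",
                           chimera_partners = list(),
                           insert_partner = NULL,
                           mutation_rate = 0, min_mutation_fraction = 0,
                           missing_fraction = 0,
                           insert_codes = FALSE, use_mse = FALSE,
                           with_ligand = FALSE, auth_offset = 10L) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1,
            min_mutation_fraction >= 0, min_mutation_fraction <= 1,
            missing_fraction >= 0, missing_fraction <= 1,
            repeat_count >= 1L)
  if (!is.null(insert_partner) && repeat_count > 1L)
    stop("insert_partner requires repeat_count = 1")
  structure(list(seed = seed, accession = accession, entry_id = entry_id,
                 truncation = truncation, tag = tag,
                 repeat_count = as.integer(repeat_count), linker = linker,
                 chimera_partners = chimera_partners,
                 insert_partner = insert_partner,
                 mutation_rate = mutation_rate,
                 min_mutation_fraction = min_mutation_fraction,
                 missing_fraction = missing_fraction,
                 insert_codes = insert_codes, use_mse = use_mse,
                 with_ligand = with_ligand,
                 auth_offset = as.integer(auth_offset)),
            class = "construct_spec")
}

#' Build a synthetic mmCIF entry with ground truth
#'
#' Emits a valid mmCIF file (SEQRES categories including unobserved
#' residues, author numbering with optional insertion codes, extended-chain
#' C-alpha coordinates at 3.8 Angstrom spacing with seeded jitter), a
#' curated-mapping TSV, a domain-definition TSV, and the fully populated
#' ground truth of the construct.
#'
#' @param spec A [construct_spec()].
#' @param records A `uniprot_records` data.frame containing all referenced
#'   accessions.
#' @param dir Output directory.
#' @return List with `cif`, `curated`, `domains` (paths) and `truth` (list:
#'   `residue` per-residue data.frame, `segments`, `xref`, `expected_best`,
#'   `n_conflicts`, `asym_id`, `entry_id`).
#' @export
make_entry <- function(spec, records, dir) {
  stopifnot(inherits(spec, "construct_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  get_seq <- function(acc) {
    i <- match(acc, records$accession)
    if (is.na(i)) stop("accession ", acc, " not in records")
    records$sequence[i]
  }
  base_seq <- get_seq(spec$accession)
  rng <- if (is.null(spec$truncation)) c(1L, nchar(base_seq))
         else as.integer(spec$truncation)
  if (rng[1L] < 1L || rng[2L] > nchar(base_seq) || rng[1L] > rng[2L])
    stop("truncation outside base sequence")

  with_seed(spec$seed, {
    asm <- assemble_construct(spec, rng, get_seq)
    ltr <- asm$ltr; acc <- asm$acc; unp <- asm$unp
    n <- length(ltr)

    # --- point mutations (interior of mapped runs only: terminal
    # mismatches are not alignable evidence) ------------------------------
    mapped <- !is.na(acc)
    run_id <- cumsum(c(TRUE, diff(mapped) != 0L |
                         (acc[-1L] != acc[-n]) %in% TRUE |
                         (diff(unp) != 1L) %in% TRUE))
    interior <- rep(FALSE, n)
    for (g in split(seq_len(n), run_id)) {
      if (!mapped[g[1L]] || length(g) < 7L) next
      interior[g[3:(length(g) - 2L)]] <- TRUE
    }
    # mutations are restricted to positions covered by every isoform of the
    # accession's group: a mutation outside one isoform's coverage would
    # hand that isoform a strictly higher identity than the generating
    # canonical record, making the intended best mapping unrecoverable
    shared_cov <- attr(records, "shared_coverage")
    eligible <- interior
    if (!is.null(shared_cov)) {
      for (p in which(interior)) {
        cov <- shared_cov[[acc[p]]]
        if (!is.null(cov) && !(unp[p] %in% cov)) eligible[p] <- FALSE
      }
    }
    n_mut <- stats::rbinom(1L, sum(eligible), spec$mutation_rate)
    if (spec$min_mutation_fraction > 0) {
      floor_n <- min(sum(eligible),
                     ceiling(spec$min_mutation_fraction * sum(mapped)))
      n_mut <- max(n_mut, floor_n)
    }
    mut_pos <- sort(sample(which(eligible), n_mut))
    for (p in mut_pos) ltr[p] <- sample(setdiff(AA20, ltr[p]), 1L)
    conflict <- seq_len(n) %in% mut_pos

    # --- comp_ids, MSE, observedness, author numbering -------------------
    comp <- unname(AA_THREE[ltr])
    if (spec$use_mse) {
      cand <- which(ltr == "M" & interior & !conflict)
      if (length(cand)) comp[cand[1L]] <- "MSE"
    }
    observed <- rep(TRUE, n)
    if (spec$missing_fraction > 0) {
      n_miss <- min(n - 3L, round(spec$missing_fraction * n))
      if (n_miss > 0L) observed[sample(n, n_miss)] <- FALSE
    }
    auth <- as.character(seq_len(n) + spec$auth_offset)
    icode <- rep("", n)
    if (spec$insert_codes && n >= 12L) {
      k <- floor(n / 2L)
      anchor <- as.integer(auth[k])
      icode[k + 1L] <- "A"
      icode[k + 2L] <- "B"
      auth[k + 1L] <- as.character(anchor)
      auth[k + 2L] <- as.character(anchor)
      if (k + 3L <= n) auth[(k + 3L):n] <- as.character(
        seq_len(n - k - 2L) + anchor)
    }

    # --- ground truth ----------------------------------------------------
    residue <- data.frame(label_seq_id = seq_len(n), accession = acc,
                          unp_num = unp, observed = observed,
                          conflict = conflict, stringsAsFactors = FALSE)
    truth_segments <- local({
      segs <- list()
      for (g in split(seq_len(n), run_id)) {
        if (!mapped[g[1L]]) next
        segs[[length(segs) + 1L]] <- data.frame(
          unp_acc = acc[g[1L]], seq_id_start = g[1L],
          seq_id_end = g[length(g)], unp_start = unp[g[1L]],
          unp_end = unp[g[length(g)]], stringsAsFactors = FALSE)
      }
      df <- do.call(rbind, segs)
      parts <- lapply(split(df, df$unp_acc), function(d) {
        d <- d[order(d$seq_id_start), , drop = FALSE]
        inst <- segid <- integer(nrow(d))
        inst[1L] <- segid[1L] <- 1L
        if (nrow(d) > 1L) for (r in 2L:nrow(d)) {
          if (d$unp_start[r] > d$unp_end[r - 1L]) {
            inst[r] <- inst[r - 1L]; segid[r] <- segid[r - 1L] + 1L
          } else {
            inst[r] <- inst[r - 1L] + 1L; segid[r] <- 1L
          }
        }
        d$instance_id <- inst; d$segment_id <- segid
        d
      })
      out <- do.call(rbind, parts)
      rownames(out) <- NULL
      out
    })

    # --- domain definitions + expected projection ------------------------
    dom_rows <- list()
    xref_truth <- list()
    pf <- "PF00001"
    dom_rows[[1L]] <- data.frame(resource = "Pfam", xref_acc = pf,
                                 coordinate_system = "unp",
                                 target = spec$accession,
                                 start = rng[1L], end = rng[2L],
                                 stringsAsFactors = FALSE)
    base_segs <- truth_segments[truth_segments$unp_acc == spec$accession, ]
    xref_truth[[1L]] <- data.frame(
      resource = "Pfam", xref_acc = pf,
      instance_id = base_segs$instance_id, segment_id = base_segs$segment_id,
      seq_id_start = base_segs$seq_id_start, seq_id_end = base_segs$seq_id_end,
      stringsAsFactors = FALSE)
    ca <- "C1.10.8"
    dom_rows[[2L]] <- data.frame(resource = "CATH", xref_acc = ca,
                                 coordinate_system = "pdb_label",
                                 target = "A",
                                 start = base_segs$seq_id_start,
                                 end = base_segs$seq_id_end,
                                 stringsAsFactors = FALSE)
    xref_truth[[2L]] <- data.frame(
      resource = "CATH", xref_acc = ca, instance_id = 1L,
      segment_id = seq_len(nrow(base_segs)),
      seq_id_start = base_segs$seq_id_start,
      seq_id_end = base_segs$seq_id_end, stringsAsFactors = FALSE)
    domains <- do.call(rbind, dom_rows)
    xref_expect <- do.call(rbind, xref_truth)

    # --- expected best mappings ------------------------------------------
    used_acc <- unique(acc[!is.na(acc)])
    per_acc_identity <- vapply(used_acc, function(a) {
      msk <- acc == a & !is.na(acc)
      1 - sum(conflict[msk]) / sum(msk)
    }, 0)
    expected_best <- used_acc[per_acc_identity >= 0.90]

    # --- write mmCIF ------------------------------------------------------
    doc <- build_fixture_doc(spec, n, comp, auth, icode, observed)
    cif <- file.path(dir, paste0(spec$entry_id, ".cif"))
    cif_write(doc, cif)
    lines <- readLines(cif)
    writeLines(c(lines[1L], paste0("# construct seed: ", spec$seed),
                 lines[-1L]), cif)

    curated_acc <- unique(c(spec$accession,
                            vapply(spec$chimera_partners, `[[`, "",
                                   "accession"),
                            if (!is.null(spec$insert_partner))
                              spec$insert_partner$accession,
                            attr(records, "decoys")))
    curated <- file.path(dir, paste0(spec$entry_id, "_curated.tsv"))
    utils::write.table(
      data.frame(entry_id = spec$entry_id, label_asym_id = "A",
                 canonical_accession = curated_acc),
      curated, sep = "\t", quote = FALSE, row.names = FALSE)
    dom_path <- file.path(dir, paste0(spec$entry_id, "_domains.tsv"))
    utils::write.table(domains, dom_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    list(cif = cif, curated = curated, domains = dom_path,
         truth = list(entry_id = spec$entry_id, asym_id = "A",
                      residue = residue, segments = truth_segments,
                      xref = xref_expect, expected_best = expected_best,
                      n_conflicts = n_mut, seed = spec$seed))
  })
}

# Would a semi-global aligner profitably (or neutrally) extend an aligned
# region into adjacent foreign residues?  chain_next / ref_next are the
# letters walking outward from the junction; an extension is flagged when
# any prefix has at least as many matches as mismatches.
ext_profitable <- function(chain_next, ref_next) {
  w <- min(length(chain_next), length(ref_next), 8L)
  if (w == 0L) return(FALSE)
  s <- cumsum(ifelse(chain_next[seq_len(w)] == ref_next[seq_len(w)], 1L, -1L))
  any(s >= 0L)
}

# Assemble the construct as (letter, accession, unp_num) triples.  Element
# boundaries are deterministically trimmed until no junction admits a
# spurious (profitable or score-neutral) alignment extension into
# tag/linker/partner residues, so the constructed mapping is exactly
# recoverable.  Split-interior boundaries (the two halves of an insert
# construct) are frozen — trimming them would punch a hole into the
# reference numbering that a cheap mismatch bridge could exploit — so the
# trim always falls on the junction's other side.
assemble_construct <- function(spec, rng, get_seq) {
  split_chars <- function(s) strsplit(s, "")[[1]]
  elems <- list()
  add_fixed <- function(s) {
    if (nzchar(s))
      elems[[length(elems) + 1L]] <<- list(type = "fixed",
                                           letters = split_chars(s))
  }
  add_mapped <- function(accession, from, to, frozen_from = FALSE,
                         frozen_to = FALSE)
    elems[[length(elems) + 1L]] <<- list(type = "mapped",
                                         accession = accession,
                                         from = as.integer(from),
                                         to = as.integer(to),
                                         frozen_from = frozen_from,
                                         frozen_to = frozen_to)
  add_fixed(spec$tag)
  if (is.null(spec$insert_partner)) {
    for (k in seq_len(spec$repeat_count)) {
      if (k > 1L) add_fixed(spec$linker)
      add_mapped(spec$accession, rng[1L], rng[2L])
    }
  } else {
    ip <- spec$insert_partner
    at <- rng[1L] + as.integer(ip$at) - 1L
    stopifnot(at >= rng[1L], at < rng[2L])
    add_mapped(spec$accession, rng[1L], at, frozen_to = TRUE)
    add_mapped(ip$accession, ip$range[1L], ip$range[2L])
    add_mapped(spec$accession, at + 1L, rng[2L], frozen_from = TRUE)
  }
  for (cp in spec$chimera_partners) {
    add_fixed(spec$linker)
    add_mapped(cp$accession, cp$range[1L], cp$range[2L])
  }

  elem_letters <- function(e) {
    if (e$type == "fixed") e$letters
    else split_chars(substr(get_seq(e$accession), e$from, e$to))
  }
  # trim one chain letter at a junction: k = element index, side = "head"
  # (drop first letter / advance from) or "tail"; returns TRUE if trimmed
  trim_elem <- function(k, side) {
    e <- elems[[k]]
    if (e$type == "fixed") {
      if (!length(e$letters)) return(FALSE)
      elems[[k]]$letters <<- if (side == "head") e$letters[-1L]
                             else e$letters[-length(e$letters)]
      return(TRUE)
    }
    if (side == "head") {
      if (isTRUE(e$frozen_from)) return(FALSE)
      elems[[k]]$from <<- e$from + 1L
    } else {
      if (isTRUE(e$frozen_to)) return(FALSE)
      elems[[k]]$to <<- e$to - 1L
    }
    if (elems[[k]]$to - elems[[k]]$from < 20L)
      stop("junction sanitisation shrank a region below 20 residues")
    TRUE
  }
  for (iter in 1:80) {
    dirty <- FALSE
    lets <- lapply(elems, elem_letters)
    for (k in seq_along(elems)) {
      e <- elems[[k]]
      if (e$type != "mapped") next
      refs <- split_chars(get_seq(e$accession))
      before <- rev(unlist(lets[seq_len(k - 1L)]))
      ref_before <- if (e$from > 1L) refs[(e$from - 1L):1L] else character(0)
      if (ext_profitable(before, ref_before)) {
        # offending chain letters live in the preceding element
        ok <- (k > 1L && trim_elem(k - 1L, "tail")) ||
          trim_elem(k, "head")
        if (!ok) stop("cannot sanitise junction before element ", k)
        dirty <- TRUE
        break
      }
      after <- unlist(lets[-seq_len(k)])
      ref_after <- if (e$to < length(refs))
        refs[(e$to + 1L):length(refs)] else character(0)
      if (ext_profitable(after, ref_after)) {
        ok <- (k < length(elems) && trim_elem(k + 1L, "head")) ||
          trim_elem(k, "tail")
        if (!ok) stop("cannot sanitise junction after element ", k)
        dirty <- TRUE
        break
      }
    }
    if (!dirty) break
    if (iter == 80L) stop("could not sanitise construct junctions")
  }
  elems <- Filter(function(e) e$type != "fixed" || length(e$letters) > 0L,
                  elems)

  ltr <- character(0); acc <- character(0); unp <- integer(0)
  for (e in elems) {
    l <- elem_letters(e)
    ltr <- c(ltr, l)
    if (e$type == "fixed") {
      acc <- c(acc, rep(NA_character_, length(l)))
      unp <- c(unp, rep(NA_integer_, length(l)))
    } else {
      acc <- c(acc, rep(e$accession, length(l)))
      unp <- c(unp, e$from:e$to)
    }
  }
  list(ltr = ltr, acc = acc, unp = unp)
}

# assemble the cif_doc of a fixture entry (one polymer chain A, optional
# ligand chain B + waters C)
build_fixture_doc <- function(spec, n, comp, auth, icode, observed) {
  cats <- list()
  cats$entry <- data.frame(id = spec$entry_id, stringsAsFactors = FALSE)
  ent_ids <- c("1", if (spec$with_ligand) c("2", "3"))
  cats$entity <- data.frame(
    id = ent_ids,
    type = c("polymer", if (spec$with_ligand) c("non-polymer", "water")),
    stringsAsFactors = FALSE)
  cats$entity_poly <- data.frame(entity_id = "1",
                                 type = "polypeptide(L)",
                                 stringsAsFactors = FALSE)
  cats$entity_src_gen <- data.frame(
    entity_id = "1", pdbx_gene_src_ncbi_taxonomy_id = "S30",
    stringsAsFactors = FALSE)
  cats$entity_poly_seq <- data.frame(entity_id = "1",
                                     num = as.character(seq_len(n)),
                                     mon_id = comp, stringsAsFactors = FALSE)
  asyms <- c("A", if (spec$with_ligand) c("B", "C"))
  cats$struct_asym <- data.frame(id = asyms,
                                 entity_id = ent_ids[seq_along(asyms)],
                                 stringsAsFactors = FALSE)
  cats$pdbx_poly_seq_scheme <- data.frame(
    asym_id = "A", entity_id = "1", seq_id = as.character(seq_len(n)),
    mon_id = comp, pdb_seq_num = auth,
    pdb_ins_code = ifelse(nzchar(icode), icode, "."),
    pdb_strand_id = "A", stringsAsFactors = FALSE)

  jitter <- function(k) stats::rnorm(k, 0, 0.1)
  obs_idx <- which(observed)
  atom <- data.frame(
    group_PDB = "ATOM", id = as.character(seq_along(obs_idx)),
    label_atom_id = "CA", label_alt_id = ".", label_comp_id = comp[obs_idx],
    label_asym_id = "A", label_entity_id = "1",
    label_seq_id = as.character(obs_idx),
    pdbx_PDB_ins_code = ifelse(nzchar(icode[obs_idx]), icode[obs_idx], "?"),
    Cartn_x = sprintf("%.3f", 3.8 * obs_idx + jitter(length(obs_idx))),
    Cartn_y = sprintf("%.3f", jitter(length(obs_idx))),
    Cartn_z = sprintf("%.3f", jitter(length(obs_idx))),
    occupancy = "1.00",
    auth_seq_id = auth[obs_idx], auth_asym_id = "A",
    pdbx_PDB_model_num = "1", stringsAsFactors = FALSE)
  if (spec$with_ligand) {
    het <- data.frame(
      group_PDB = "HETATM",
      id = as.character(nrow(atom) + 1:5),
      label_atom_id = c("C1", "C1", "O", "O", "O"),
      label_alt_id = ".",
      label_comp_id = c("LIG", "LIG", "HOH", "HOH", "HOH"),
      label_asym_id = c("B", "B", "C", "C", "C"),
      label_entity_id = c("2", "2", "3", "3", "3"),
      label_seq_id = ".",
      pdbx_PDB_ins_code = "?",
      Cartn_x = sprintf("%.3f", seq(-5, -25, length.out = 5L)),
      Cartn_y = sprintf("%.3f", jitter(5L)),
      Cartn_z = sprintf("%.3f", jitter(5L)),
      occupancy = "1.00",
      auth_seq_id = as.character(501:505), auth_asym_id = "A",
      pdbx_PDB_model_num = "1", stringsAsFactors = FALSE)
    atom <- rbind(atom, het)
  }
  cats$atom_site <- atom
  structure(list(block = spec$entry_id, categories = cats), class = "cif_doc")
}

#' Preset fixture scenarios
#'
#' One-call construction of the named scenario: UniProt set, taxonomy,
#' construct and entry files, all derived from one seed.
#'
#' Presets: `tag` (N-terminal GSH tag, MSE, ligand), `repeat` (two tandem
#' copies), `split` (partner domain inserted mid-range, splitting the base
#' domain), `chimera` (two-protein fusion), `insertcode` (author insertion
#' codes), `mutant` (2% point mutations), `missing` (20% unobserved
#' residues), `lowid` (25% mutations: engineered below the identity
#' threshold, expected to yield no best mapping).
#'
#' @param preset One of the names above.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return As [make_entry()], plus `records`, `tree`, `spec`.
#' @export
fixture_preset <- function(preset = c("tag", "repeat", "split", "chimera",
                                      "insertcode", "mutant", "missing",
                                      "lowid"),
                           seed, dir) {
  preset <- match.arg(preset)
  records <- make_uniprot_set(seed, n_records = 2L, n_decoys = 1L, dir = dir)
  tree <- make_taxonomy(seed, dir = dir)
  acc1 <- records$accession[records$is_canonical &
                              !records$accession %in% attr(records, "decoys")]
  base <- acc1[1L]
  partner <- acc1[2L]
  len1 <- nchar(records$sequence[match(base, records$accession)])
  len2 <- nchar(records$sequence[match(partner, records$accession)])
  sp <- switch(preset,
    tag = construct_spec(seed, base, entry_id = "SYNT",
                         truncation = c(11L, min(140L, len1)), tag = "GSH",
                         use_mse = TRUE, with_ligand = TRUE),
    "repeat" = construct_spec(seed, base, entry_id = "SYNR",
                              truncation = c(21L, 100L), repeat_count = 2L,
                              linker = "GSGSG"),
    split = construct_spec(seed, base, entry_id = "SYNS",
                           truncation = c(11L, min(150L, len1)),
                           insert_partner = list(accession = partner,
                                                 range = c(31L, min(90L, len2)),
                                                 at = 70L)),
    chimera = construct_spec(seed, base, entry_id = "SYNC",
                             truncation = c(1L, 80L),
                             chimera_partners = list(
                               list(accession = partner,
                                    range = c(41L, min(130L, len2))))),
    insertcode = construct_spec(seed, base, entry_id = "SYNI",
                                truncation = c(11L, min(140L, len1)),
                                insert_codes = TRUE, with_ligand = TRUE),
    mutant = construct_spec(seed, base, entry_id = "SYNM",
                            truncation = c(11L, min(200L, len1)),
                            mutation_rate = 0.02),
    missing = construct_spec(seed, base, entry_id = "SYNU",
                             truncation = c(11L, min(140L, len1)),
                             missing_fraction = 0.20),
    lowid = construct_spec(seed, base, entry_id = "SYNL",
                           truncation = c(11L, min(140L, len1)),
                           mutation_rate = 0.25,
                           min_mutation_fraction = 0.12))
  out <- make_entry(sp, records, dir)
  out$records <- records
  out$tree <- tree
  out$spec <- sp
  out
}
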