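# Synthetic-data generators: ortholog alignments with controlled
# per-segment divergence and spontaneous-report tables with independence
# background plus multiplicatively spiked drug-AE pairs. Every generator is
# a pure function of (config, seed): the caller's RNG state is saved and
# restored around each call.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# substitution target distribution for residue x: softmax over the raw
# matrix row, identity excluded. Respects biochemical similarity without a
# full Markov substitution model.
.substitution_probs <- function(raw) {
  probs <- list()
  for (x in raw$alphabet) {
    w <- exp(raw$scores[x, ])
    w[x] <- 0
    probs[[x]] <- w / sum(w)
  }
  probs
}

#' Simulate ortholog sequences with per-segment divergence
#'
#' Starting from a human reference sequence, generates one ortholog per
#' species: each position is substituted with its segment's probability
#' `p_sub` (replacement drawn from a softmax over the raw substitution-matrix
#' row, identity excluded) and suffers an indel with probability `p_indel`
#' (equal odds of deleting the residue or inserting one uniform-random
#' residue after it). Because the simulation knows the true homology, the
#' emitted multiple alignment is exact: deletions become gaps in the
#' ortholog row and insertions become extra columns gapped in all other
#' rows.
#'
#' @param reference Ungapped human reference sequence (character scalar over
#'   the 20-letter alphabet).
#' @param annotation A `segment_annotation` for the reference (positions in
#'   reference coordinates).
#' @param species Character vector of species labels (at least one).
#' @param p_sub Per-segment substitution probability: single value, or named
#'   vector keyed by segment name (missing segments fall back to
#'   `p_sub_default`).
#' @param p_indel Per-segment indel probability, same conventions.
#' @param p_sub_default,p_indel_default Rates for positions outside any
#'   annotated segment (and unnamed segments).
#' @param raw Raw substitution matrix driving replacement choice; defaults
#'   to the bundled BLOSUM90.
#' @param subunit_id Subunit name for the emitted alignment.
#' @param seed Integer seed; same (config, seed) gives identical output.
#' @return List with `alignment` (a `subunit_alignment`; human reference row
#'   id `<subunit>|Homo_sapiens|ref`), `annotation` (the input), and `truth`
#'   (data.frame per species x segment: `n_positions`, `n_substituted`,
#'   `realized_p_sub`).
#' @export
simulate_orthologs <- function(reference, annotation, species,
                               p_sub = 0.05, p_indel = 0.01,
                               p_sub_default = NULL, p_indel_default = NULL,
                               raw = NULL, subunit_id = annotation$subunit_id,
                               seed = NULL) {
  if (nchar(reference) == 0L) stop("empty reference sequence")
  stopifnot(inherits(annotation, "segment_annotation"),
            length(species) >= 1L)
  ref <- strsplit(reference, "")[[1L]]
  if (!all(ref %in% AA_STANDARD)) {
    stop("reference contains non-standard residues")
  }
  if (is.null(raw)) raw <- read_raw_matrix(blosum90_path())
  if (is.null(p_sub_default)) {
    p_sub_default <- if (is.null(names(p_sub))) p_sub[1L] else 0
  }
  if (is.null(p_indel_default)) {
    p_indel_default <- if (is.null(names(p_indel))) p_indel[1L] else 0
  }

  # per-position rates from segment membership
  segs <- annotation$segments
  pos_seg <- rep(NA_character_, length(ref))
  for (i in seq_len(nrow(segs))) {
    pos_seg[segs$start[i]:segs$end[i]] <- segs$segment_name[i]
  }
  rate_at <- function(rates, default) {
    if (is.null(names(rates))) return(rep(rates[1L], length(ref)))
    r <- rates[pos_seg]
    r[is.na(r)] <- default
    unname(r)
  }
  p_sub_pos <- rate_at(p_sub, p_sub_default)
  p_indel_pos <- rate_at(p_indel, p_indel_default)
  stopifnot(all(p_sub_pos >= 0 & p_sub_pos <= 1),
            all(p_indel_pos >= 0 & p_indel_pos <= 1))

  sub_probs <- .substitution_probs(raw)

  .with_seed(seed, {
    # per-species event draws
    events <- lapply(species, function(sp) {
      res <- ref
      do_sub <- stats::runif(length(ref)) < p_sub_pos
      for (i in which(do_sub)) {
        res[i] <- sample(raw$alphabet, 1L, prob = sub_probs[[ref[i]]])
      }
      do_indel <- stats::runif(length(ref)) < p_indel_pos
      is_del <- do_indel & (stats::runif(length(ref)) < 0.5)
      is_ins <- do_indel & !is_del
      ins_res <- rep(NA_character_, length(ref))
      ins_res[is_ins] <- sample(AA_STANDARD, sum(is_ins), replace = TRUE)
      list(species = sp, residues = res, substituted = do_sub,
           deleted = is_del, inserted = ins_res)
    })

    # assemble the exact joint alignment: one column per reference
    # position; each insertion gets its own extra column
    human_row <- character(0L)
    sp_rows <- stats::setNames(rep(list(character(0L)), length(species)),
                               species)
    for (i in seq_along(ref)) {
      human_row <- c(human_row, ref[i])
      for (ev in events) {
        sp_rows[[ev$species]] <- c(sp_rows[[ev$species]],
                                   if (ev$deleted[i]) GAP_CHAR
                                   else ev$residues[i])
      }
      for (ev in events) {
        if (!is.na(ev$inserted[i])) {
          human_row <- c(human_row, GAP_CHAR)
          for (sp in species) {
            sp_rows[[sp]] <- c(sp_rows[[sp]],
                               if (sp == ev$species) ev$inserted[i]
                               else GAP_CHAR)
          }
        }
      }
    }

    ids <- c(paste0(subunit_id, "|Homo_sapiens|ref"),
             paste0(subunit_id, "|", species, "|sim"))
    seqs <- c(paste(human_row, collapse = ""),
              vapply(sp_rows, paste, character(1L), collapse = ""))
    names(seqs) <- ids
    aln <- subunit_alignment(subunit_id, seqs,
                             species = c("Homo_sapiens", species),
                             human_reference_id = ids[1L])

    truth <- do.call(rbind, lapply(events, function(ev) {
      do.call(rbind, lapply(seq_len(nrow(segs)), function(j) {
        pos <- segs$start[j]:segs$end[j]
        data.frame(species = ev$species,
                   segment_name = segs$segment_name[j],
                   n_positions = length(pos),
                   n_substituted = sum(ev$substituted[pos]),
                   realized_p_sub = mean(ev$substituted[pos]),
                   stringsAsFactors = FALSE)
      }))
    }))
    list(alignment = aln, annotation = annotation, truth = truth)
  })
}

#' Simulate a spontaneous-report count table with spiked signals
#'
#' The expected count of pair (i, j) is `N * p_i * q_j * lambda_ij / Z`
#' where `lambda_ij = 1` except for spiked pairs and `Z` renormalizes the
#' cell probabilities to 1; counts are drawn from one multinomial. Under all
#' `lambda = 1` the table satisfies reporting independence, so PRR tends to
#' 1 for every pair.
#'
#' @param n_reports Total number of reports `N`.
#' @param p_drug Drug marginal probabilities (must sum to 1 within 1e-9);
#'   names become drug labels, default `drug01..`.
#' @param p_term Term marginal probabilities, same conventions, default
#'   `term01..`.
#' @param spikes data.frame with columns `drug`, `ae_term`, `lambda`
#'   (relative reporting ratio > 0) or NULL for a pure-independence table.
#' @param seed Integer seed.
#' @return List with `table` (a count-mode `report_table`) and `truth`
#'   (the spikes data.frame, possibly empty).
#' @export
simulate_reports <- function(n_reports, p_drug, p_term, spikes = NULL,
                             seed = NULL) {
  stopifnot(n_reports >= 1L)
  if (abs(sum(p_drug) - 1) > 1e-9) stop("drug marginals must sum to 1")
  if (abs(sum(p_term) - 1) > 1e-9) stop("term marginals must sum to 1")
  if (is.null(names(p_drug))) {
    names(p_drug) <- sprintf("drug%02d", seq_along(p_drug))
  }
  if (is.null(names(p_term))) {
    names(p_term) <- sprintf("term%02d", seq_along(p_term))
  }
  lambda <- matrix(1, nrow = length(p_drug), ncol = length(p_term),
                   dimnames = list(names(p_drug), names(p_term)))
  if (!is.null(spikes) && nrow(spikes) > 0L) {
    stopifnot(all(c("drug", "ae_term", "lambda") %in% names(spikes)),
              all(spikes$lambda > 0))
    for (i in seq_len(nrow(spikes))) {
      lambda[spikes$drug[i], spikes$ae_term[i]] <- spikes$lambda[i]
    }
  } else {
    spikes <- data.frame(drug = character(0L), ae_term = character(0L),
                         lambda = numeric(0L))
  }
  prob <- outer(p_drug, p_term) * lambda
  prob <- prob / sum(prob)
  counts <- .with_seed(seed, {
    stats::rmultinom(1L, size = n_reports, prob = as.vector(prob))[, 1L]
  })
  df <- data.frame(drug = rep(rownames(prob), times = ncol(prob)),
                   ae_term = rep(colnames(prob), each = nrow(prob)),
                   count = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[df$count > 0L, , drop = FALSE]
  rownames(df) <- NULL
  list(table = report_table(df, mode = "count"), truth = spikes)
}

#' Expand a count-mode table into single-drug single-term records
#'
#' Each count becomes that many one-mention reports, which keeps the
#' multinomial truth exact in record mode.
#'
#' @param table A count-mode `report_table`.
#' @return A record-mode `report_table` with synthetic report ids.
#' @export
expand_to_records <- function(table) {
  stopifnot(inherits(table, "report_table"), table$mode == "count")
  d <- table$data
  n <- sum(d$count)
  df <- data.frame(report_id = sprintf("r%07d", seq_len(n)),
                   drug = rep(d$drug, d$count),
                   ae_term = rep(d$ae_term, d$count),
                   stringsAsFactors = FALSE)
  report_table(df, mode = "record")
}

# fixed fixture-bundle study design --------------------------------------

.bundle_segments <- function() {
  data.frame(
    segment_name = c("A", "B", "C", "D", "E", "F", "G",
                     "TM1", "TM2", "TM3", "TM4"),
    start = c(8L, 20L, 32L, 44L, 52L, 62L, 72L, 81L, 91L, 101L, 111L),
    end = c(14L, 26L, 38L, 48L, 58L, 68L, 78L, 90L, 100L, 110L, 120L),
    stringsAsFactors = FALSE)
}

.bundle_reference <- function(seed) {
  .with_seed(seed, {
    ref <- sample(AA_STANDARD, 120L, replace = TRUE)
    ref[55L] <- "C"  # cys-loop first cysteine
    ref[68L] <- "C"  # cys-loop second cysteine: the coordinate anchor
    paste(ref, collapse = "")
  })
}

.bundle_seizure_terms <- function() {
  c("Seizure", "Generalised tonic-clonic seizure", "Partial seizures",
    "Status epilepticus")
}

#' Write a self-contained desk-scale fixture bundle
#'
#' Generates and writes, reproducibly from one seed, everything both
#' pipelines need end-to-end: one simulated subunit alignment (3 species,
#' 120-residue reference, loops A-G and TM1-TM4 annotated), a count-mode
#' report table (10 drugs x 8 terms, 4 seizure terms, 2 drug-AE pairs
#' spiked at relative reporting ratio 8 in a 5000-report table), the seizure
#' term-group file, an in-silico hit-flag table, the bundled BLOSUM90 copy
#' and a YAML run configuration pointing at all of them.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; the same seed reproduces every file
#'   byte-identically.
#' @return Named list of written file paths (invisibly includes `truth`:
#'   the spiked pairs and per-segment substitution truth).
#' @export
make_fixture_bundle <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create bundle directory: ", dir)

  ref <- .bundle_reference(seed)
  ann <- segment_annotation("GABRA1", .bundle_segments(),
                            ecd_end = 80L, anchor_residue = 68L,
                            human_seq = ref)
  sim_aln <- simulate_orthologs(
    reference = ref, annotation = ann,
    species = c("Mus_musculus", "Rattus_norvegicus", "Danio_rerio"),
    p_sub = c(A = 0.02, B = 0.02, C = 0.05, D = 0.05, E = 0.1, F = 0.1,
              G = 0.2, TM1 = 0.02, TM2 = 0.05, TM3 = 0.1, TM4 = 0.2),
    p_indel = 0.01, p_sub_default = 0.1, p_indel_default = 0.01,
    seed = seed + 1L)

  seizure_terms <- .bundle_seizure_terms()
  other_terms <- c("Nausea", "Headache", "Dizziness", "Fatigue")
  terms <- c(seizure_terms, other_terms)
  drugs <- sprintf("drug%02d", 1:10)
  spikes <- data.frame(drug = c("drug01", "drug02"),
                       ae_term = c("Seizure", "Status epilepticus"),
                       lambda = c(8, 8), stringsAsFactors = FALSE)
  sim_rep <- simulate_reports(
    n_reports = 5000L,
    p_drug = stats::setNames(rep(0.1, 10L), drugs),
    p_term = stats::setNames(rep(0.125, 8L), terms),
    spikes = spikes, seed = seed + 2L)

  paths <- list(
    alignment = file.path(dir, "GABRA1_alignment.fasta"),
    annotations = file.path(dir, "segment_annotations.tsv"),
    matrix = file.path(dir, "BLOSUM90.txt"),
    reports = file.path(dir, "reports_counts.tsv"),
    term_group = file.path(dir, "seizure_terms.txt"),
    hits = file.path(dir, "insilico_hits.tsv"),
    config = file.path(dir, "config.yaml"))

  write_alignment_fasta(sim_aln$alignment, paths$alignment)
  write_segment_annotations(list(GABRA1 = ann), paths$annotations)
  file.copy(blosum90_path(), paths$matrix, overwrite = TRUE)
  utils::write.table(sim_rep$table$data, paths$reports, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c("# seizure-category adverse-event terms (flat MedDRA-style list)",
               seizure_terms), paths$term_group)
  hits <- data.frame(drug = c("drug01", "drug05", "drug05"),
                     model = c("GABA-A-Channel-LB", "GABA-A-Channel-LB",
                               "GABA-A-PAM"),
                     fit_score = c(0.8, 0.5, 0.6))
  utils::write.table(hits, paths$hits, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- list(seed = seed,
              conservation = list(alignments = "GABRA1_alignment.fasta",
                                  matrix = "BLOSUM90.txt",
                                  annotations = "segment_annotations.tsv",
                                  reference_subunit = "GABRA1"),
              signals = list(reports = "reports_counts.tsv",
                             term_group = "seizure_terms.txt",
                             prr_min = 2, min_reports = 5),
              burden = list(k = 10, coverage = 0.98),
              integrate = list(hits = "insilico_hits.tsv"))
  yaml::write_yaml(cfg, paths$config)

  out <- lapply(paths, normalizePath)
  out$truth <- list(spikes = sim_rep$truth, segments = sim_aln$truth)
  invisible(out)
}
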