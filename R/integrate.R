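# Red-flag integration of pharmacovigilance alerts with externally supplied
# in-silico hit flags, and the run-all pipeline driver with its manifest.

#' Read an in-silico hit-flag table
#'
#' TSV with columns `drug`, `model`, and optionally `fit_score`. The fit
#' score is treated as an opaque ordinal value (larger = better fit);
#' (drug, model) pairs must be unique.
#'
#' @param path Hit TSV.
#' @return data.frame of hits.
#' @export
read_hit_flags <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("drug", "model") %in% names(df))) {
    stop("hit table needs columns: drug, model")
  }
  if (!"fit_score" %in% names(df)) df$fit_score <- NA_real_
  if (any(!is.na(df$fit_score) & df$fit_score < 0)) {
    stop("fit_score must be >= 0 when present")
  }
  key <- paste(tolower(trimws(df$drug)), df$model)
  if (anyDuplicated(key)) {
    stop("duplicate (drug, model) rows in hit table: ",
         key[duplicated(key)][1L])
  }
  df
}

#' Combine pharmacovigilance alerts and in-silico hits into a red-flag report
#'
#' A drug is pharmacovigilance-alerted when it has at least one retained
#' signal. Flag levels: `dual-source` (PV alert AND at least one in-silico
#' model hit), `single-source` (one of the two), `none`. Drug names are
#' matched exactly after case-folding and whitespace trimming; no fuzzy
#' matching.
#'
#' @param signals A `pv_signals` object (or data.frame with `drug`,
#'   `retained`).
#' @param hits Hit data.frame from [read_hit_flags()] (or NULL for none).
#' @param burden Optional `burden_summary` supplying per-drug burden ranks.
#' @return Object of class `red_flag_report`: data.frame with columns
#'   `drug`, `has_pv_alert`, `burden_rank`, `n_models_hit`, `models_hit`,
#'   `flag_level`, sorted by flag level then burden rank.
#' @export
integrate_flags <- function(signals, hits = NULL, burden = NULL) {
  sig <- as.data.frame(signals)
  alerted <- unique(sig$drug[sig$retained])
  canon <- function(x) tolower(trimws(x))
  if (is.null(hits)) {
    hits <- data.frame(drug = character(0L), model = character(0L),
                       fit_score = numeric(0L))
  }
  key <- paste(canon(hits$drug), hits$model)
  if (anyDuplicated(key)) stop("duplicate (drug, model) rows in hit table")

  all_drugs <- unique(c(sig$drug, hits$drug))
  ck <- canon(all_drugs)
  keep <- !duplicated(ck)
  all_drugs <- all_drugs[keep]
  ck <- ck[keep]

  pv <- ck %in% canon(alerted)
  models <- vapply(ck, function(k) {
    paste(sort(hits$model[canon(hits$drug) == k]), collapse = ";")
  }, character(1L))
  n_models <- vapply(ck, function(k) sum(canon(hits$drug) == k), integer(1L))

  rank_map <- rep(NA_integer_, length(all_drugs))
  if (!is.null(burden)) {
    stopifnot(inherits(burden, "burden_summary"))
    d <- burden$drug_stats
    ord <- order(-d$burden_pct, d$drug)
    ranks <- stats::setNames(seq_along(ord), canon(d$drug[ord]))
    rank_map <- unname(ranks[ck])
  }

  level <- ifelse(pv & n_models > 0L, "dual-source",
                  ifelse(pv | n_models > 0L, "single-source", "none"))
  out <- data.frame(drug = all_drugs, has_pv_alert = pv,
                    burden_rank = rank_map, n_models_hit = n_models,
                    models_hit = models, flag_level = level,
                    stringsAsFactors = FALSE, row.names = NULL)
  lev <- match(out$flag_level, c("dual-source", "single-source", "none"))
  out <- out[order(lev, out$burden_rank, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("red_flag_report", "data.frame"))
}

#' @export
print.red_flag_report <- function(x, ...) {
  n_dual <- sum(x$flag_level == "dual-source")
  cat("Red-flag report: ", nrow(x), " drugs, ", n_dual,
      " dual-source flag(s)\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline into an output directory
#'
#' Stages: (optional) simulate a fixture bundle, conservation profiling,
#' signal detection, burden summarization, red-flag integration. Every
#' output table is written as TSV and listed, with its MD5 content hash, in
#' a JSON run manifest; re-running with the same config and seed reproduces
#' all hashes (the manifest timestamp is the only varying field). A failing
#' stage aborts with a stage-named error and leaves a `FAILED` marker file
#' naming the stage next to any partial outputs.
#'
#' @param out_dir Output directory (created).
#' @param simulate When TRUE, inputs are generated with
#'   [make_fixture_bundle()] under `out_dir/inputs`; otherwise `config`
#'   must point at existing inputs.
#' @param seed Integer seed used for simulation.
#' @param config Either the path to a YAML config (as written by the fixture
#'   bundle: per-stage sections with file paths relative to the config file)
#'   or an equivalent named list with absolute paths. Ignored when
#'   `simulate = TRUE` except for threshold overrides.
#' @param make_plots Also write conservation track plots (PNG). Default
#'   FALSE: the tabular outputs are the primary artifact.
#' @return Invisibly, a list with the manifest (as a list) and the paths of
#'   all written files.
#' @export
run_all <- function(out_dir, simulate = FALSE, seed = 1L, config = NULL,
                    make_plots = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(name, file.path(out_dir, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  written <- character(0L)
  cfg <- stage("config", {
    if (simulate) {
      bundle_dir <- file.path(out_dir, "inputs")
      bundle <- make_fixture_bundle(bundle_dir, seed = seed)
      written <- c(written,
                    unlist(bundle[setdiff(names(bundle), "truth")],
                           use.names = FALSE))
      list(cfg = yaml::read_yaml(bundle$config), dir = bundle_dir)
    } else if (is.character(config)) {
      list(cfg = yaml::read_yaml(config), dir = dirname(config))
    } else if (is.list(config)) {
      list(cfg = config, dir = ".")
    } else {
      stop("need either simulate = TRUE or a config")
    }
  })
  pth <- function(p) {
    if (file.exists(p)) p else file.path(cfg$dir, p)
  }

  message("stage conservation")
  cons <- stage("conservation", {
    cc <- cfg$cfg$conservation
    aln_spec <- pth(cc$alignments)
    fasta_files <- if (dir.exists(aln_spec)) {
      list.files(aln_spec, pattern = "\\.fa(sta)?$", full.names = TRUE)
    } else {
      unlist(lapply(cc$alignments, pth))
    }
    alignments <- list()
    for (f in fasta_files) {
      a <- read_alignment_fasta(f)
      alignments[[a$subunit_id]] <- a
    }
    if (length(alignments) == 0L) stop("no alignment files found")
    annotations <- read_segment_annotations(pth(cc$annotations),
                                            alignments = alignments)
    sm <- build_scoring_matrix(read_raw_matrix(pth(cc$matrix)))
    prof <- conservation_profile(alignments, annotations, sm,
                                 reference_subunit_id =
                                   cc$reference_subunit)
    written <- c(written,
                  .write_tsv(tracks_table(prof),
                             file.path(out_dir, "conservation_tracks.tsv")))
    seg <- do.call(rbind, lapply(prof$tracks, function(tr) {
      s <- summarize_segments(tr, annotations[[tr$subunit_id]],
                              alignments[[tr$subunit_id]])
      cbind(data.frame(subunit_id = tr$subunit_id, species = tr$species,
                       stringsAsFactors = FALSE), s)
    }))
    rownames(seg) <- NULL
    written <- c(written,
                  .write_tsv(seg, file.path(out_dir,
                                            "conservation_segments.tsv")))
    if (make_plots) {
      written <- c(written,
                    plot_tracks(prof, file.path(out_dir, "conservation")))
    }
    prof
  })

  message("stage signals")
  sig <- stage("signals", {
    sc <- cfg$cfg$signals
    tab <- read_reports(pth(sc$reports))
    grp <- read_term_group(pth(sc$term_group))
    s <- pv_signals(tab, group = grp,
                    prr_min = if (is.null(sc$prr_min)) 2 else sc$prr_min,
                    min_reports = if (is.null(sc$min_reports)) 5
                                  else sc$min_reports)
    written <- c(written,
                  write_signals(s, file.path(out_dir, "signals.tsv")))
    s
  })

  message("stage burden")
  bs <- stage("burden", {
    bc <- cfg$cfg$burden
    b <- burden_summary(sig,
                        k = if (is.null(bc$k)) 10 else bc$k,
                        coverage = if (is.null(bc$coverage)) 0.98
                                   else bc$coverage)
    written <- c(written,
                  .write_tsv(b$drug_stats,
                             file.path(out_dir, "burden_drugs.tsv")),
                  .write_tsv(b$ae_stats,
                             file.path(out_dir, "burden_terms.tsv")))
    ranks <- data.frame(
      rank = seq_along(b$top_by_burden),
      top_by_burden = b$top_by_burden,
      top_by_pool_share = b$top_by_pool_share[seq_along(b$top_by_burden)],
      stringsAsFactors = FALSE)
    written <- c(written,
                  .write_tsv(ranks, file.path(out_dir, "rankings.tsv")))
    b
  })

  message("stage integrate")
  report <- stage("integrate", {
    ic <- cfg$cfg$integrate
    hits <- if (!is.null(ic$hits)) read_hit_flags(pth(ic$hits)) else NULL
    r <- integrate_flags(sig, hits, burden = bs)
    written <- c(written,
                  .write_tsv(as.data.frame(r),
                             file.path(out_dir, "red_flags.tsv")))
    r
  })

  manifest <- list(
    package = "seizurescope",
    version = as.character(utils::packageVersion("seizurescope")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    simulate = simulate,
    parameters = cfg$cfg,
    files = lapply(stats::setNames(written, basename(written)), function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, files = written,
                 signals = sig, burden = bs, red_flags = report,
                 conservation = cons))
}
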