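# Shared fixtures: cached scoring matrix, toy alignment builders and the
# brute-force tabulation oracle used to cross-check aggregate_counts().

.fixture_env <- new.env(parent = emptyenv())

blosum90_raw <- function() {
  if (is.null(.fixture_env$raw)) {
    .fixture_env$raw <- read_raw_matrix(blosum90_path())
  }
  .fixture_env$raw
}

blosum90_scoring <- function() {
  if (is.null(.fixture_env$sm)) {
    .fixture_env$sm <- build_scoring_matrix(blosum90_raw())
  }
  .fixture_env$sm
}

# two-row alignment with a human reference, for column-scoring tests
toy_alignment <- function(human, other, subunit_id = "GABRA1") {
  seqs <- c(human, other)
  names(seqs) <- c(paste0(subunit_id, "|Homo_sapiens|h"),
                   paste0(subunit_id, "|Mus_musculus|m"))
  subunit_alignment(subunit_id, seqs,
                    species = c("Homo_sapiens", "Mus_musculus"),
                    human_reference_id = names(seqs)[1])
}

# minimal annotation over a human sequence; anchor defaults to its first C
toy_annotation <- function(human_seq, ecd_end, segments = NULL,
                           anchor = NULL, subunit_id = "GABRA1") {
  if (is.null(anchor)) {
    anchor <- regexpr("C", human_seq, fixed = TRUE)[1]
  }
  if (is.null(segments)) {
    segments <- data.frame(segment_name = "A", start = 1L,
                           end = min(2L, nchar(human_seq)))
  }
  segment_annotation(subunit_id, segments, ecd_end = ecd_end,
                     anchor_residue = anchor, human_seq = human_seq)
}

# independent oracle: per-report loop over record-mode data
brute_force_counts <- function(records) {
  d <- unique(records[, c("report_id", "drug", "ae_term")])
  reports <- split(d, d$report_id)
  N <- length(reports)
  pairs <- unique(d[, c("drug", "ae_term")])
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    dg <- pairs$drug[i]; tm <- pairs$ae_term[i]
    a <- b <- cc <- dd <- 0L
    for (rep in reports) {
      has_d <- dg %in% rep$drug
      has_t <- tm %in% rep$ae_term
      if (has_d && has_t) a <- a + 1L
      else if (has_d) b <- b + 1L
      else if (has_t) cc <- cc + 1L
      else dd <- dd + 1L
    }
    data.frame(drug = dg, ae_term = tm, a = a, b = b, c = cc, d = dd,
               n_total = N, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$drug, out$ae_term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exact-independence count table: counts = N * p_i * q_j with exact division
exact_independence_table <- function(drug_tot, ae_tot) {
  N <- sum(drug_tot)
  stopifnot(sum(ae_tot) == N)
  grid <- expand.grid(drug = names(drug_tot), ae_term = names(ae_tot),
                      stringsAsFactors = FALSE)
  grid$count <- drug_tot[grid$drug] * ae_tot[grid$ae_term] / N
  stopifnot(all(grid$count == round(grid$count)))
  report_table(grid, mode = "count")
}
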