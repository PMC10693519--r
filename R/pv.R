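# Pharmacovigilance disproportionality analysis over drug x adverse-event
# report tables: 2x2 tabulation, PRR, shrinkage information component with
# its 95% credibility lower bound, retention criteria, term-group
# restriction and burden summaries.

#' Construct a report table
#'
#' Two modes. `"count"`: one row per (drug, adverse-event) pair with a
#' non-negative integer count of reports. `"record"`: one row per
#' (report id, drug, term) mention; a report may list several drugs and
#' terms, and each unique (drug, term) pair within a report counts once.
#'
#' @param data data.frame. Count mode needs columns `drug`, `ae_term`,
#'   `count`; record mode needs `report_id`, `drug`, `ae_term`.
#' @param mode `"count"` or `"record"`; inferred from the columns when
#'   missing.
#' @return Object of class `report_table`.
#' @export
report_table <- function(data, mode = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(mode)) {
    mode <- if ("count" %in% names(data)) "count" else "record"
  }
  mode <- match.arg(mode, c("count", "record"))
  if (mode == "count") {
    need <- c("drug", "ae_term", "count")
    if (!all(need %in% names(data))) {
      stop("count mode needs columns: ", paste(need, collapse = ", "))
    }
    if (any(data$count < 0) || any(data$count != round(data$count))) {
      stop("counts must be non-negative integers")
    }
    data$count <- as.integer(data$count)
  } else {
    need <- c("report_id", "drug", "ae_term")
    if (!all(need %in% names(data))) {
      stop("record mode needs columns: ", paste(need, collapse = ", "))
    }
  }
  structure(list(mode = mode, data = data), class = "report_table")
}

#' @export
print.report_table <- function(x, ...) {
  if (x$mode == "count") {
    cat("Report table (count mode): ", nrow(x$data), " drug-AE cells, ",
        sum(x$data$count), " reports\n", sep = "")
  } else {
    cat("Report table (record mode): ", nrow(x$data), " mentions, ",
        length(unique(x$data$report_id)), " reports\n", sep = "")
  }
  invisible(x)
}

#' Read a report table from TSV
#'
#' Record TSV has columns `report_id`, `drug`, `ae_term`; count TSV has
#' `drug`, `ae_term`, `count`. The mode is inferred from the header.
#'
#' @param path TSV file path.
#' @return A `report_table`.
#' @export
read_reports <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  report_table(df)
}

#' Build 2x2 contingency counts for every observed drug-AE pair
#'
#' For each pair: `a` = reports with the drug AND the term, `b` = reports
#' with the drug without the term, `c` = reports with the term without the
#' drug, `d` = neither; `n_total = a+b+c+d`. In record mode the report is
#' the counting unit and duplicate (drug, term) mentions within one report
#' are collapsed first.
#'
#' @param table A `report_table`.
#' @return data.frame with columns `drug`, `ae_term`, `a`, `b`, `c`, `d`,
#'   `n_total`, one row per observed pair.
#' @export
aggregate_counts <- function(table) {
  stopifnot(inherits(table, "report_table"))
  if (table$mode == "count") {
    d <- table$data
    d <- stats::aggregate(count ~ drug + ae_term, data = d, FUN = sum)
    drug_tot <- tapply(d$count, d$drug, sum)
    ae_tot <- tapply(d$count, d$ae_term, sum)
    N <- sum(d$count)
    a <- d$count
    pairs <- data.frame(drug = d$drug, ae_term = d$ae_term,
                        a = a,
                        b = as.integer(drug_tot[d$drug]) - a,
                        c = as.integer(ae_tot[d$ae_term]) - a,
                        stringsAsFactors = FALSE)
    pairs$d <- N - pairs$a - pairs$b - pairs$c
    pairs$n_total <- N
  } else {
    # a report listing several drugs and several terms contributes each
    # (drug, term) combination once: drugs and terms are report-level sets
    d0 <- table$data
    drug_rep0 <- unique(d0[, c("report_id", "drug")])
    ae_rep0 <- unique(d0[, c("report_id", "ae_term")])
    d <- merge(drug_rep0, ae_rep0, by = "report_id")
    N <- length(unique(d0$report_id))
    # report-level incidence of each drug and each term
    drug_rep <- unique(d[, c("report_id", "drug")])
    ae_rep <- unique(d[, c("report_id", "ae_term")])
    drug_tot <- table(drug_rep$drug)
    ae_tot <- table(ae_rep$ae_term)
    key <- paste(d$drug, d$ae_term, sep = "\r")
    a_tab <- table(key)
    u <- !duplicated(key)
    pairs <- data.frame(drug = d$drug[u], ae_term = d$ae_term[u],
                        a = as.integer(a_tab[key[u]]),
                        stringsAsFactors = FALSE)
    pairs$b <- as.integer(drug_tot[pairs$drug]) - pairs$a
    pairs$c <- as.integer(ae_tot[pairs$ae_term]) - pairs$a
    pairs$d <- N - pairs$a - pairs$b - pairs$c
    pairs$n_total <- N
  }
  pairs <- pairs[order(pairs$drug, pairs$ae_term), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Proportional reporting ratio
#'
#' `PRR = (a / (a+b)) / (c / (c+d))`: the term's reporting proportion for
#' the drug relative to all other drugs. Undefined (returned as `NA`) when
#' the drug has no reports, no other drug reports the term (`c = 0`), or
#' there are no other reports at all; such pairs can never be retained.
#'
#' @param a,b,c,d 2x2 cell counts (vectorized).
#' @return Numeric vector of PRR values, `NA` where undefined.
#' @export
prr <- function(a, b, c, d) {
  num <- a / (a + b)
  den <- c / (c + d)
  out <- num / den
  out[a + b == 0 | c == 0 | c + d == 0] <- NA_real_
  out
}

#' Shrinkage information component and its 95% credibility lower bound
#'
#' `IC = log2((a + 0.5) / (E + 0.5))` with expectation
#' `E = (a+b)(a+c)/N`, and the standard credibility-interval approximation
#' `IC025 = IC - 3.3 (a+0.5)^(-1/2) - 2 (a+0.5)^(-3/2)`.
#'
#' @param a Observed pair count (vectorized).
#' @param expected Expected count `E` under independence (vectorized).
#' @return data.frame with columns `ic`, `ic025`.
#' @export
ic_with_bound <- function(a, expected) {
  if (any(expected < 0)) stop("expected counts must be non-negative")
  ic <- log2((a + 0.5) / (expected + 0.5))
  ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
  data.frame(ic = ic, ic025 = ic025)
}

#' Read an adverse-event term group file
#'
#' One term per line; lines starting with `#` are comments. Stands in for a
#' flat export of a MedDRA class and its descendants (here: seizures
#' including subtypes).
#'
#' @param path Term file path.
#' @param name Group name; defaults to the file name.
#' @param case_insensitive Match terms case-insensitively (default TRUE).
#' @return Object of class `term_group`: list with `name`, `terms`,
#'   `case_insensitive`.
#' @export
read_term_group <- function(path, name = NULL, case_insensitive = TRUE) {
  if (!file.exists(path)) stop("term group file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("term group file is empty: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  term_group(name, lines, case_insensitive)
}

#' Construct a term group
#' @param name Group name.
#' @param terms Character vector of AE terms (non-empty).
#' @param case_insensitive Match case-insensitively (default TRUE).
#' @return Object of class `term_group`.
#' @export
term_group <- function(name, terms, case_insensitive = TRUE) {
  terms <- unique(trimws(terms))
  if (length(terms) == 0L) stop("term group must be non-empty")
  structure(list(name = name, terms = terms,
                 case_insensitive = case_insensitive),
            class = "term_group")
}

#' Restrict pair statistics to an AE term group
#'
#' @param pairs data.frame with an `ae_term` column (e.g. from
#'   [aggregate_counts()] or [pv_signals()]).
#' @param group A `term_group`.
#' @return The subset of rows whose term belongs to the group.
#' @export
restrict_to_group <- function(pairs, group) {
  stopifnot(inherits(group, "term_group"))
  terms <- trimws(pairs$ae_term)
  gterms <- group$terms
  if (group$case_insensitive) {
    keep <- tolower(terms) %in% tolower(gterms)
  } else {
    keep <- terms %in% gterms
  }
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Disproportionality signal statistics with retention flags
#'
#' Tabulates 2x2 counts for every drug-AE pair, computes PRR, IC and IC025,
#' and flags pairs meeting the retention criteria: `PRR >= prr_min`
#' (inclusive), `IC025 > 0` (strict) and at least `min_reports` reports for
#' the pair. Pairs with undefined PRR are never retained. Optionally
#' restricts to an AE term group first.
#'
#' @param table A `report_table` (or a data.frame accepted by
#'   [report_table()]).
#' @param group Optional `term_group` to restrict the AE terms.
#' @param prr_min PRR threshold (default 2, inclusive).
#' @param require_ic025_positive Require IC025 > 0 (default TRUE).
#' @param min_reports Minimum pair report count (default 5, inclusive).
#' @return Object of class `pv_signals`: a data.frame with columns `drug`,
#'   `ae_term`, `a`, `b`, `c`, `d`, `n_total`, `expected`, `prr`, `ic`,
#'   `ic025`, `retained`, plus the thresholds as attributes.
#' @examples
#' tbl <- report_table(data.frame(
#'   drug = c("X", "X", "Y", "Y"),
#'   ae_term = c("Seizure", "Nausea", "Seizure", "Nausea"),
#'   count = c(30, 70, 10, 890)))
#' sig <- pv_signals(tbl)
#' sig[sig$retained, c("drug", "ae_term", "prr", "ic025")]
#' @export
pv_signals <- function(table, group = NULL, prr_min = 2,
                       require_ic025_positive = TRUE, min_reports = 5) {
  if (is.data.frame(table)) table <- report_table(table)
  pairs <- aggregate_counts(table)
  if (!is.null(group)) pairs <- restrict_to_group(pairs, group)
  pairs$expected <- (pairs$a + pairs$b) * (pairs$a + pairs$c) / pairs$n_total
  pairs$prr <- prr(pairs$a, pairs$b, pairs$c, pairs$d)
  icb <- ic_with_bound(pairs$a, pairs$expected)
  pairs$ic <- icb$ic
  pairs$ic025 <- icb$ic025
  pairs$retained <- filter_signals(pairs, prr_min = prr_min,
                                   require_ic025_positive =
                                     require_ic025_positive,
                                   min_reports = min_reports)
  structure(pairs, prr_min = prr_min,
            require_ic025_positive = require_ic025_positive,
            min_reports = min_reports,
            class = c("pv_signals", "data.frame"))
}

#' Apply the retention criteria to signal statistics
#'
#' @param stats data.frame with columns `prr`, `ic025`, `a`.
#' @param prr_min PRR threshold (inclusive).
#' @param require_ic025_positive Require IC025 strictly positive.
#' @param min_reports Minimum pair report count (inclusive).
#' @return Logical vector: TRUE where the pair is retained.
#' @export
filter_signals <- function(stats, prr_min = 2,
                           require_ic025_positive = TRUE, min_reports = 5) {
  ok <- !is.na(stats$prr) & stats$prr >= prr_min & stats$a >= min_reports
  if (require_ic025_positive) ok <- ok & stats$ic025 > 0
  ok
}

#' @export
print.pv_signals <- function(x, ...) {
  cat("Disproportionality signals: ", nrow(x), " drug-AE pairs, ",
      sum(x$retained), " retained (PRR >= ", attr(x, "prr_min"),
      ", IC025 > 0, a >= ", attr(x, "min_reports"), ")\n", sep = "")
  if (sum(x$retained) > 0L) {
    top <- x[x$retained, , drop = FALSE]
    top <- top[order(-top$prr), , drop = FALSE]
    print(utils::head(as.data.frame(top)[, c("drug", "ae_term", "a", "prr",
                                             "ic", "ic025")], 10L),
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @method summary pv_signals
#' @export
summary.pv_signals <- function(object, ...) {
  ret <- object[object$retained, , drop = FALSE]
  structure(list(n_pairs = nrow(object),
                 n_retained = nrow(ret),
                 n_drugs_alerted = length(unique(ret$drug)),
                 group_total = sum(ret$a)),
            class = "summary.pv_signals")
}

#' @export
print.summary.pv_signals <- function(x, ...) {
  cat("pairs tested:   ", x$n_pairs, "\n",
      "pairs retained: ", x$n_retained, "\n",
      "drugs alerted:  ", x$n_drugs_alerted, "\n",
      "retained report total: ", x$group_total, "\n", sep = "")
  invisible(x)
}

# deterministic ranking: descending value, ties broken by name
.rank_names <- function(values, names, k) {
  ord <- order(-values, names)
  utils::head(names[ord], k)
}

#' Burden summary over retained seizure signals
#'
#' All percentage denominators use retained records only. Per pair,
#' `drug_ae_pct = a / drug total reports * 100` and
#' `pool_share_pct = a / group total * 100` where the group total is the sum
#' of retained pair counts (computed, never supplied). Per drug, the burden
#' is the cumulative seizure-AE fraction of the drug's reports and the pool
#' share the drug's fraction of all retained seizure records; per AE, the
#' pie share is the term's fraction of the pool. `top_coverage_terms` is the
#' smallest prefix of terms (sorted by descending total count, ties
#' lexicographic) whose cumulative share reaches `coverage`.
#'
#' @param signals A `pv_signals` object (its retained rows are used) or a
#'   data.frame of already-retained pair statistics with columns `drug`,
#'   `ae_term`, `a`, `b`.
#' @param k Size of the top lists (default 10).
#' @param coverage Cumulative share (fraction) for the top-coverage AE set
#'   (default 0.98).
#' @return Object of class `burden_summary`: list with `pair_stats` (with
#'   `drug_ae_pct`, `pool_share_pct`), `drug_stats` (`burden_pct`,
#'   `pool_share_pct`), `ae_stats` (`pie_share_pct`), `top_coverage_terms`,
#'   `top_by_burden`, `top_by_pool_share`, `intersection`, `group_total`,
#'   `k`, `coverage`.
#' @export
burden_summary <- function(signals, k = 10, coverage = 0.98) {
  if (inherits(signals, "pv_signals")) {
    ret <- as.data.frame(signals)[signals$retained, , drop = FALSE]
  } else {
    ret <- as.data.frame(signals)
  }
  if (nrow(ret) == 0L) stop("nothing to summarize: no retained signals")
  group_total <- sum(ret$a)

  pair <- data.frame(drug = ret$drug, ae_term = ret$ae_term, a = ret$a,
                     drug_total = ret$a + ret$b,
                     stringsAsFactors = FALSE)
  pair$drug_ae_pct <- pair$a / pair$drug_total * 100
  pair$pool_share_pct <- pair$a / group_total * 100

  drug_a <- tapply(pair$a, pair$drug, sum)
  drug_tot <- tapply(pair$drug_total, pair$drug, max)
  drug <- data.frame(drug = names(drug_a),
                     burden_pct = as.numeric(drug_a / drug_tot * 100),
                     pool_share_pct = as.numeric(drug_a / group_total * 100),
                     stringsAsFactors = FALSE)

  ae_a <- tapply(pair$a, pair$ae_term, sum)
  ae <- data.frame(ae_term = names(ae_a),
                   total_reports = as.integer(ae_a),
                   pie_share_pct = as.numeric(ae_a / group_total * 100),
                   stringsAsFactors = FALSE)

  ord <- order(-ae$total_reports, ae$ae_term)
  cum <- cumsum(ae$total_reports[ord]) / group_total
  n_cov <- which(cum >= coverage)[1L]
  top_terms <- ae$ae_term[ord][seq_len(n_cov)]

  top_burden <- .rank_names(drug$burden_pct, drug$drug, k)
  top_pool <- .rank_names(drug$pool_share_pct, drug$drug, k)

  structure(list(pair_stats = pair, drug_stats = drug, ae_stats = ae,
                 top_coverage_terms = top_terms,
                 top_by_burden = top_burden,
                 top_by_pool_share = top_pool,
                 intersection = sort(intersect(top_burden, top_pool)),
                 group_total = group_total, k = k, coverage = coverage),
            class = "burden_summary")
}

#' @export
print.burden_summary <- function(x, ...) {
  cat("Seizure-AE burden summary over ", x$group_total,
      " retained records\n", sep = "")
  cat("  top-", length(x$top_coverage_terms), " AEs cover >= ",
      x$coverage * 100, "% of records\n", sep = "")
  cat("  top-", x$k, " by within-drug burden:   ",
      paste(x$top_by_burden, collapse = ", "), "\n", sep = "")
  cat("  top-", x$k, " by pool share:           ",
      paste(x$top_by_pool_share, collapse = ", "), "\n", sep = "")
  cat("  in both lists (", length(x$intersection), "): ",
      paste(x$intersection, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Intersection of the two top-k drug rankings
#'
#' Drugs ranked top-k both by within-drug seizure-AE burden and by share of
#' the retained seizure-record pool. Tie-breaking is deterministic
#' (descending value, then drug name).
#'
#' @param summary A `burden_summary`.
#' @param k Top-list size; defaults to the summary's `k`.
#' @return Sorted character vector of drugs present in both top-k lists.
#' @export
rank_and_intersect <- function(summary, k = summary$k) {
  stopifnot(inherits(summary, "burden_summary"))
  d <- summary$drug_stats
  tb <- .rank_names(d$burden_pct, d$drug, k)
  tp <- .rank_names(d$pool_share_pct, d$drug, k)
  sort(intersect(tb, tp))
}

#' Write signal statistics to TSV
#' @param signals A `pv_signals` object.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_signals <- function(signals, path) {
  utils::write.table(as.data.frame(signals), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
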