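# 2x2 tabulation, PRR, IC/IC025, retention criteria, term-group
# restriction and burden summaries.

test_that("tabulation matches the brute-force per-report oracle", {
  # degenerate single record
  one <- report_table(data.frame(report_id = "r1", drug = "drugX",
                                 ae_term = "termY"))
  cc <- aggregate_counts(one)
  expect_equal(cc[, c("a", "b", "c", "d", "n_total")],
               data.frame(a = 1L, b = 0L, c = 0L, d = 0L, n_total = 1L))

  # random multi-drug multi-term reports, duplicates included on purpose
  set.seed(21)
  recs <- data.frame(
    report_id = sample(sprintf("r%03d", 1:100), 400, replace = TRUE),
    drug = sample(sprintf("drug%02d", 1:6), 400, replace = TRUE),
    ae_term = sample(sprintf("term%02d", 1:5), 400, replace = TRUE),
    stringsAsFactors = FALSE)
  recs <- rbind(recs, recs[1:20, ])  # duplicated mentions collapse
  got <- aggregate_counts(report_table(recs))
  want <- brute_force_counts(recs)
  expect_equal(got, want)

  # margin identities hold for every pair
  drug_tot <- tapply(got$a, got$drug, function(x) x)  # a+b constant per drug
  expect_true(all(got$a + got$b + got$c + got$d == got$n_total))
  for (dg in unique(got$drug)) {
    expect_equal(unique(got$a[got$drug == dg] + got$b[got$drug == dg]),
                 want$a[want$drug == dg][1] + want$b[want$drug == dg][1])
  }
  expect_error(report_table(data.frame(drug = "x", ae_term = "y",
                                       count = -1)),
               "non-negative")
})

test_that("PRR follows its defining ratio and flags undefined pairs", {
  expect_equal(prr(5, 95, 50, 950), 1.0)
  expect_equal(prr(10, 90, 10, 890), 9.0)
  # scale invariance of a ratio of proportions
  expect_equal(prr(3 * 10, 3 * 90, 3 * 10, 3 * 890), prr(10, 90, 10, 890))
  # undefined when no other drug reports the term, or the drug is empty
  expect_true(is.na(prr(5, 5, 0, 100)))
  expect_true(is.na(prr(0, 0, 10, 100)))
})

test_that("IC matches the shrinkage formulas and its bound sits below it", {
  # a = E gives log of 1
  expect_equal(ic_with_bound(7, 7)$ic, 0)
  # absent pair with positive expectation: negative IC, bound below it
  z <- ic_with_bound(0, 4)
  expect_lt(z$ic, 0)
  expect_lt(z$ic025, z$ic)
  # arithmetic oracle evaluated separately from the implementation
  z <- ic_with_bound(20, 5)
  ic_exp <- log(20.5 / 5.5) / log(2)
  pen <- 3.3 / sqrt(20.5) + 2 / sqrt(20.5)^3
  expect_equal(z$ic, ic_exp, tolerance = 1e-12)
  expect_equal(z$ic025, ic_exp - pen, tolerance = 1e-12)
  expect_equal(round(z$ic, 3), 1.898)
  expect_equal(round(z$ic025, 3), 1.148)
  # ic025 < ic strictly on a wide grid of counts and expectations
  a <- rep(c(0:50, 100, 1000, 10000), times = 4)
  E <- rep(c(0.5, 3, 40, 800), each = 54)
  z <- ic_with_bound(a, E)
  expect_true(all(z$ic025 < z$ic))
})

test_that("retention applies the three criteria with stated strictness", {
  stats <- data.frame(
    prr = c(2.0, 50, 3, NA, 1.99, 3),
    ic025 = c(0.3, 2, 0, 5, 1, 1e-9),
    a = c(7L, 4L, 10L, 100L, 10L, 5L))
  keep <- filter_signals(stats)
  # PRR = 2.0 is inclusive; a = 4 excluded; ic025 = 0 excluded (strict);
  # undefined PRR never retained; PRR below 2 excluded; 5 reports inclusive
  expect_identical(keep, c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(filter_signals(stats[0, ]), logical(0))
})

test_that("retention is monotone in the pair count at fixed margins", {
  # with the drug and term margins fixed, raising a never flips a retained
  # pair back to excluded
  a <- 0:100
  tab <- data.frame(drug = "X", ae_term = "t", a = a, b = 100L - a,
                    c = 50L, d = 5000L, n_total = 5150L)
  tab$prr <- prr(tab$a, tab$b, tab$c, tab$d)
  z <- ic_with_bound(tab$a,
                     (tab$a + tab$b) * (tab$a + tab$c) / tab$n_total)
  tab$ic025 <- z$ic025
  keep <- filter_signals(tab)
  expect_true(all(diff(as.integer(keep)) >= 0))
  expect_false(keep[1])
  expect_true(keep[length(keep)])
})

test_that("term-group restriction matches per the case flag", {
  pairs <- data.frame(drug = "X",
                      ae_term = c("Seizure", "SEIZURE ", "Nausea"),
                      a = 1:3)
  grp <- term_group("seizures", c("seizure"))
  expect_equal(restrict_to_group(pairs, grp)$a, 1:2)
  grp_cs <- term_group("seizures", c("Seizure"), case_insensitive = FALSE)
  expect_equal(restrict_to_group(pairs, grp_cs)$a, 1L)
  # identity and empty cases
  all_grp <- term_group("all", pairs$ae_term)
  expect_equal(nrow(restrict_to_group(pairs, all_grp)), 3L)
  none <- term_group("none", "Rash")
  expect_equal(nrow(restrict_to_group(pairs, none)), 0L)
  expect_error(term_group("empty", character(0)), "non-empty")
})

test_that("burden percentages follow the stated formulas", {
  # one drug, 200 total reports, one retained AE with a = 50
  ret <- data.frame(drug = "X", ae_term = "Seizure", a = 50L, b = 150L)
  b <- burden_summary(ret, k = 10)
  expect_equal(b$pair_stats$drug_ae_pct, 25.0)
  expect_equal(b$drug_stats$pool_share_pct, 100.0)
  expect_equal(b$ae_stats$pie_share_pct, 100.0)
  expect_equal(b$group_total, 50L)

  # coverage: one dominant term already covers 98%
  ret <- data.frame(drug = c("X", "X"), ae_term = c("t1", "t2"),
                    a = c(99L, 1L), b = c(0L, 98L))
  b <- burden_summary(ret, coverage = 0.98)
  expect_equal(b$top_coverage_terms, "t1")

  # pool and pie shares always sum to 100
  set.seed(5)
  ret <- data.frame(drug = sample(LETTERS[1:6], 30, TRUE),
                    ae_term = sample(paste0("t", 1:7), 30, TRUE),
                    a = sample(5:80, 30, TRUE), b = sample(0:400, 30, TRUE))
  ret <- ret[!duplicated(ret[, 1:2]), ]
  b <- burden_summary(ret)
  expect_equal(sum(b$drug_stats$pool_share_pct), 100, tolerance = 1e-9)
  expect_equal(sum(b$ae_stats$pie_share_pct), 100, tolerance = 1e-9)
  expect_true(all(b$intersection %in% b$top_by_burden))
  expect_true(all(b$intersection %in% b$top_by_pool_share))

  expect_error(burden_summary(ret[0, ]), "nothing to summarize")
})

test_that("top-list intersection recovers engineered overlapping leaders", {
  # three drugs lead both rankings by construction: huge seizure fraction
  # AND huge pool share; the rest are low on at least one axis
  lead <- data.frame(drug = c("amox", "bupro", "clozap"),
                     ae_term = "Seizure", a = c(900L, 850L, 800L),
                     b = c(100L, 150L, 200L))
  # high pool share but tiny within-drug fraction
  bulk <- data.frame(drug = paste0("bulk", 1:3), ae_term = "Seizure",
                     a = c(700L, 650L, 600L), b = 90000L)
  # decent fraction (but below the leaders') and negligible pool share
  rare <- data.frame(drug = paste0("rare", 1:3), ae_term = "Seizure",
                     a = c(7L, 6L, 5L), b = 3L)
  ret <- rbind(lead, bulk, rare)
  b <- burden_summary(ret, k = 3)
  # brute-force both rankings
  frac <- ret$a / (ret$a + ret$b)
  pool <- ret$a / sum(ret$a)
  top_frac <- ret$drug[order(-frac, ret$drug)][1:3]
  top_pool <- ret$drug[order(-pool, ret$drug)][1:3]
  expect_equal(sort(intersect(top_frac, top_pool)),
               c("amox", "bupro", "clozap"))
  expect_equal(rank_and_intersect(b, 3), c("amox", "bupro", "clozap"))
  # identical rankings intersect completely; disjoint ones not at all
  expect_equal(length(rank_and_intersect(burden_summary(lead, k = 3), 3)),
               3L)
  two <- rbind(data.frame(drug = "hi_frac", ae_term = "Seizure",
                          a = 9L, b = 1L),
               data.frame(drug = "hi_pool", ae_term = "Seizure",
                          a = 1000L, b = 99000L))
  expect_equal(length(rank_and_intersect(burden_summary(two, k = 1), 1)),
               0L)
})

test_that("the full signal pipeline flags an engineered association", {
  tbl <- report_table(data.frame(
    drug = c("X", "X", "Y", "Y"),
    ae_term = c("Seizure", "Nausea", "Seizure", "Nausea"),
    count = c(30L, 70L, 10L, 890L)))
  sig <- pv_signals(tbl, group = term_group("sz", "Seizure"))
  expect_s3_class(sig, "pv_signals")
  expect_equal(nrow(sig), 2L)  # restricted to the seizure term
  expect_equal(sig$retained, sig$drug == "X")
  sm <- summary(sig)
  expect_equal(sm$n_retained, 1L)
  expect_equal(sm$n_drugs_alerted, 1L)
})
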