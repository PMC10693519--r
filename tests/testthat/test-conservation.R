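# Column scoring, ECD / non-ECD domain labels, cys-loop anchoring,
# segment summaries and track plots.

test_that("column scoring applies the three column rules", {
  sm <- blosum90_scoring()
  d <- function(x) sm$normalized_scores[x, x]

  aln <- toy_alignment("ACG", "ACG")
  tr <- score_track(aln, names(aln$seqs)[2], sm)
  expect_equal(tr$scores, c(d("A"), d("C"), d("G")))

  aln <- toy_alignment("AC-G", "A-CG")
  tr <- score_track(aln, names(aln$seqs)[2], sm)
  expect_equal(tr$scores, c(d("A"), -0.5, -0.5, d("G")))

  aln <- toy_alignment("A-", "--")
  tr <- score_track(aln, names(aln$seqs)[2], sm)
  expect_equal(tr$scores, c(-0.5, 0))

  # track length always equals alignment width and every value comes from
  # the table or the two gap scores
  expect_length(tr$scores, aln$n_columns)
  aln <- toy_alignment("AC-GW-", "A--GWY")
  tr <- score_track(aln, names(aln$seqs)[2], sm)
  ok <- vapply(tr$scores, function(s) {
    s %in% c(sm$normalized_scores, sm$indel_score, sm$dual_gap_score)
  }, logical(1))
  expect_true(all(ok))
})

test_that("scoring rejects self-comparison and unknown characters", {
  sm <- blosum90_scoring()
  aln <- toy_alignment("ACG", "ACG")
  expect_error(score_track(aln, aln$human_reference_id, sm),
               "differ from the human reference")
  expect_error(toy_alignment("ACG", "AJG"), "outside the alphabet")
})

test_that("self-scoring yields the residue-composition diagonal mean", {
  sm <- blosum90_scoring()
  set.seed(3)
  seq <- paste(sample(seizurescope:::AA_STANDARD, 80, TRUE), collapse = "")
  seqs <- c(h = seq, m = seq)
  names(seqs) <- c("GABRA1|Homo_sapiens|h", "GABRA1|Mus_musculus|m")
  aln <- subunit_alignment("GABRA1", seqs, c("Homo_sapiens", "Mus_musculus"),
                           names(seqs)[1])
  tr <- score_track(aln, names(seqs)[2], sm)
  comp <- table(strsplit(seq, "")[[1]])
  closed_form <- sum(diag(sm$normalized_scores)[names(comp)] * comp) /
    sum(comp)
  expect_equal(mean(tr$scores), closed_form)
})

test_that("domain labels split on the human sequence, gaps inherit", {
  # whole sequence extracellular
  aln <- toy_alignment("ACDEG", "ACDEG")
  ann <- toy_annotation("ACDEG", ecd_end = 5)
  expect_true(all(label_domains(aln, ann) == "ECD"))

  # boundary immediately after the column of human residue ecd_end;
  # the gap column inherits the preceding (ECD) region
  aln <- toy_alignment("AC-GD", "ACWGD")
  ann <- toy_annotation("ACGD", ecd_end = 2)
  expect_equal(label_domains(aln, ann),
               c("ECD", "ECD", "ECD", "non-ECD", "non-ECD"))

  # leading gap columns are ECD
  aln <- toy_alignment("--CGD", "WWCGD")
  ann <- toy_annotation("CGD", ecd_end = 1)
  expect_equal(label_domains(aln, ann),
               c("ECD", "ECD", "ECD", "non-ECD", "non-ECD"))

  # invalid boundaries are rejected
  expect_error(toy_annotation("ACGD", ecd_end = 0), "ecd_end")
  expect_error(toy_annotation("ACGD", ecd_end = 9), "exceeds")
})

test_that("anchoring gives every alignment the reference's anchor number", {
  sm <- blosum90_scoring()
  # three alignments whose human anchors sit at columns 3, 2 and 5
  mk <- function(su, human, other) {
    seqs <- c(human, other)
    names(seqs) <- c(paste0(su, "|Homo_sapiens|h"),
                     paste0(su, "|Mus_musculus|m"))
    subunit_alignment(su, seqs, c("Homo_sapiens", "Mus_musculus"),
                      names(seqs)[1])
  }
  alns <- list(GABRR1 = mk("GABRR1", "AWCDEFG", "AWCDEFG"),
               GABRA1 = mk("GABRA1", "WC-DEFG", "WCADEFG"),
               GABRB2 = mk("GABRB2", "--A-CDEF", "WWAWCDEF"))
  anns <- list(
    GABRR1 = toy_annotation("AWCDEFG", ecd_end = 5, subunit_id = "GABRR1"),
    GABRA1 = toy_annotation("WCDEFG", ecd_end = 4, subunit_id = "GABRA1"),
    GABRB2 = toy_annotation("ACDEF", ecd_end = 3, subunit_id = "GABRB2"))
  map <- anchor_coordinates(alns, anns, "GABRR1")
  expect_s3_class(map, "coordinate_map")
  ref_anchor <- map$anchor_column[map$subunit_id == "GABRR1"]
  expect_equal(ref_anchor, 3L)
  expect_equal(map$ecd_offset[map$subunit_id == "GABRR1"], 0L)
  # after applying offsets, all anchors share one coordinate
  expect_true(all(map$anchor_column + map$ecd_offset == ref_anchor))
  # forced by the rule: offset = reference anchor - own anchor column
  expect_equal(map$ecd_offset[map$subunit_id == "GABRA1"], 3L - 2L)
  expect_equal(map$ecd_offset[map$subunit_id == "GABRB2"], 3L - 5L)

  # non-ECD numbering restarts at 1 in every alignment
  for (su in names(alns)) {
    px <- plot_coordinates(alns[[su]], anns[[su]], map)
    dom <- label_domains(alns[[su]], anns[[su]])
    expect_equal(min(px[dom == "non-ECD"]), 1L)
    expect_true(all(diff(px[dom == "ECD"]) > 0))
    expect_true(all(diff(px[dom == "non-ECD"]) > 0))
  }
})

test_that("absent reference falls back to the longest human sequence", {
  alns <- list(GABRA1 = toy_alignment("AWCDE", "AWCDE", "GABRA1"),
               GABRB2 = toy_alignment("AWCDEFG", "AWCDEFG", "GABRB2"))
  anns <- list(GABRA1 = toy_annotation("AWCDE", 4, subunit_id = "GABRA1"),
               GABRB2 = toy_annotation("AWCDEFG", 6, subunit_id = "GABRB2"))
  expect_message(map <- anchor_coordinates(alns, anns, "GABRR1"),
                 "longest")
  expect_equal(attr(map, "reference_subunit_id"), "GABRB2")
})

test_that("segment summaries average the right columns in canonical order", {
  sm <- blosum90_scoring()
  d <- function(x) sm$normalized_scores[x, x]
  human <- "ACDEFGHIKL"
  aln <- toy_alignment(human, human)
  segs <- data.frame(segment_name = c("TM1", "A"),
                     start = c(7L, 2L), end = c(9L, 4L))
  ann <- toy_annotation(human, ecd_end = 6, segments = segs)
  tr <- score_track(aln, names(aln$seqs)[2], sm)
  s <- summarize_segments(tr, ann, aln)
  # deterministic ordering A..G then TM1..TM4, regardless of input order
  expect_equal(s$segment_name, c("A", "TM1"))
  expect_equal(s$mean_score[1], mean(c(d("C"), d("D"), d("E"))))
  expect_equal(s$mean_score[2], mean(c(d("H"), d("I"), d("K"))))
  expect_equal(s$n_columns, c(3L, 3L))

  # a segment fully deleted in the other sequence scores the indel value
  aln2 <- toy_alignment("ACDEFGHIKL", "A---FGHIKL")
  tr2 <- score_track(aln2, names(aln2$seqs)[2], sm)
  s2 <- summarize_segments(tr2, ann, aln2)
  expect_equal(s2$mean_score[s2$segment_name == "A"], -0.5)

  # segments beyond the alignment are rejected
  bad <- toy_annotation(human, ecd_end = 6,
                        segments = data.frame(segment_name = "A",
                                              start = 2L, end = 4L))
  bad$segments$end <- 99L
  expect_error(summarize_segments(tr, bad, aln), "past the alignment")
  expect_error(segment_annotation("X", data.frame(segment_name = "A",
                                                  start = 5L, end = 3L),
                                  ecd_end = 6, anchor_residue = 1),
               "invalid segment")
})

test_that("track plots write one panel per domain part", {
  sm <- blosum90_scoring()
  alns <- list(GABRA1 = toy_alignment("AWCDEFGHIK", "AWCDEFGHIK"))
  anns <- list(GABRA1 = toy_annotation("AWCDEFGHIK", ecd_end = 6,
                                       segments = data.frame(
                                         segment_name = c("A", "TM1"),
                                         start = c(2L, 7L),
                                         end = c(4L, 9L))))
  prof <- conservation_profile(alns, anns, sm, "GABRA1")
  out <- plot_tracks(prof, file.path(tempdir(), "trk"))
  expect_length(out, 2L)
  expect_true(all(file.exists(out)))
  unlink(out)

  empty <- prof
  empty$tracks <- list()
  expect_error(plot_tracks(empty, tempfile()), "no tracks")
})
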