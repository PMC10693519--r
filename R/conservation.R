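# Per-position conservation scoring of non-human orthologs against the
# human reference, the anchored ECD / non-ECD coordinate system, and
# per-segment summaries.

# cumulative human residue index at each alignment column (0 before the
# first residue)
.human_residue_index <- function(alignment) {
  chars <- strsplit(alignment$seqs[[alignment$human_reference_id]], "")[[1L]]
  cumsum(chars != GAP_CHAR)
}

# alignment column holding human residue `pos` (1-based sequence coordinate)
.column_of_residue <- function(alignment, pos) {
  idx <- .human_residue_index(alignment)
  chars <- strsplit(alignment$seqs[[alignment$human_reference_id]], "")[[1L]]
  hit <- which(idx == pos & chars != GAP_CHAR)
  if (length(hit) != 1L) {
    stop("human residue ", pos, " not found in alignment ",
         alignment$subunit_id)
  }
  hit
}

#' Score one non-human row against the human reference, column by column
#'
#' For every alignment column: two residues score the normalized substitution
#' value, exactly one gap (in either row) scores the indel value, and two
#' gaps score the dual-gap value.
#'
#' @param alignment A `subunit_alignment`.
#' @param other_id Row id of the non-human sequence (must differ from the
#'   human reference).
#' @param matrix A `scoring_matrix` from [build_scoring_matrix()].
#' @return Object of class `position_score_track`: list with `subunit_id`,
#'   `sequence_id`, `species`, `scores` (numeric, one per column).
#' @export
score_track <- function(alignment, other_id, matrix) {
  stopifnot(inherits(alignment, "subunit_alignment"),
            inherits(matrix, "scoring_matrix"))
  if (identical(other_id, alignment$human_reference_id)) {
    stop("other_id must differ from the human reference")
  }
  if (!other_id %in% names(alignment$seqs)) {
    stop("row '", other_id, "' not in alignment")
  }
  h <- strsplit(alignment$seqs[[alignment$human_reference_id]], "")[[1L]]
  o <- strsplit(alignment$seqs[[other_id]], "")[[1L]]
  scores <- numeric(length(h))
  for (k in seq_along(h)) {
    hg <- h[k] == GAP_CHAR
    og <- o[k] == GAP_CHAR
    if (hg && og) {
      scores[k] <- matrix$dual_gap_score
    } else if (hg || og) {
      scores[k] <- matrix$indel_score
    } else {
      if (!h[k] %in% matrix$alphabet || !o[k] %in% matrix$alphabet) {
        stop("character outside alphabet at column ", k, ": '",
             h[k], "' vs '", o[k], "'")
      }
      scores[k] <- matrix$normalized_scores[h[k], o[k]]
    }
  }
  structure(list(subunit_id = alignment$subunit_id,
                 sequence_id = other_id,
                 species = unname(alignment$species[other_id]),
                 scores = scores),
            class = "position_score_track")
}

#' @export
print.position_score_track <- function(x, ...) {
  cat("Score track ", x$subunit_id, " / ", x$sequence_id, ": ",
      length(x$scores), " columns, mean score ",
      format(mean(x$scores), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Label alignment columns as ECD or non-ECD
#'
#' The split is defined on the human sequence only: a column is ECD when the
#' human residue at or before it has sequence position `<= ecd_end`. Gap
#' columns inherit the label of the nearest preceding human residue; leading
#' gaps are ECD.
#'
#' @param alignment A `subunit_alignment`.
#' @param annotation Matching `segment_annotation`.
#' @return Character vector of `"ECD"` / `"non-ECD"`, one per column.
#' @export
label_domains <- function(alignment, annotation) {
  stopifnot(inherits(alignment, "subunit_alignment"),
            inherits(annotation, "segment_annotation"))
  n_res <- nchar(human_sequence(alignment))
  if (annotation$ecd_end > n_res) {
    stop("ecd_end (", annotation$ecd_end,
         ") exceeds human sequence length (", n_res, ")")
  }
  idx <- .human_residue_index(alignment)
  ifelse(idx <= annotation$ecd_end, "ECD", "non-ECD")
}

#' Anchor ECD coordinates of several subunit alignments to one reference
#'
#' ECD columns of the reference alignment are numbered 1..n; every other
#' alignment receives an integer offset so that the column holding its
#' cys-loop second cysteine gets the same number as the reference's.
#' Non-ECD columns of every alignment are numbered from 1 independently.
#'
#' @param alignments Named list of `subunit_alignment` (names = subunit ids).
#' @param annotations Named list of matching `segment_annotation`.
#' @param reference_subunit_id Subunit whose alignment defines the ECD
#'   numbering. When absent from `alignments`, the subunit with the longest
#'   ungapped human sequence is used instead (with a message).
#' @return Object of class `coordinate_map`: data.frame with one row per
#'   subunit (`subunit_id`, `anchor_column`, `anchor_number`, `ecd_offset`)
#'   plus attribute `reference_subunit_id`.
#' @export
anchor_coordinates <- function(alignments, annotations,
                               reference_subunit_id) {
  stopifnot(length(alignments) >= 1L,
            all(names(alignments) %in% names(annotations)))
  if (!reference_subunit_id %in% names(alignments)) {
    lens <- vapply(alignments, function(a) nchar(human_sequence(a)),
                   integer(1L))
    reference_subunit_id <- names(which.max(lens))
    message("reference subunit not supplied; using the longest human ",
            "sequence: ", reference_subunit_id)
  }
  anchor_cols <- vapply(names(alignments), function(su) {
    .column_of_residue(alignments[[su]], annotations[[su]]$anchor_residue)
  }, integer(1L))
  ref_anchor <- anchor_cols[[reference_subunit_id]]
  map <- data.frame(subunit_id = names(alignments),
                    anchor_column = unname(anchor_cols),
                    anchor_number = ref_anchor,
                    ecd_offset = ref_anchor - unname(anchor_cols),
                    stringsAsFactors = FALSE)
  structure(map, reference_subunit_id = reference_subunit_id,
            class = c("coordinate_map", "data.frame"))
}

#' Plotting coordinates for every column of an alignment
#'
#' ECD columns get `column index + ecd_offset` (anchored numbering);
#' non-ECD columns are renumbered 1..m within the alignment.
#'
#' @param alignment A `subunit_alignment`.
#' @param annotation Matching `segment_annotation`.
#' @param map A `coordinate_map` covering the alignment's subunit.
#' @return Integer vector of plot coordinates, one per column.
#' @export
plot_coordinates <- function(alignment, annotation, map) {
  stopifnot(inherits(map, "coordinate_map"))
  row <- map[map$subunit_id == alignment$subunit_id, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("subunit ", alignment$subunit_id, " not in coordinate map")
  }
  dom <- label_domains(alignment, annotation)
  x <- integer(alignment$n_columns)
  is_ecd <- dom == "ECD"
  x[is_ecd] <- which(is_ecd) + row$ecd_offset
  x[!is_ecd] <- seq_len(sum(!is_ecd))
  x
}

#' Full conservation profile for a set of subunit alignments
#'
#' Runs the whole conservation pipeline: scores every non-human row of every
#' alignment against its same-subunit human reference, labels columns
#' ECD / non-ECD, anchors ECD coordinates across alignments and attaches
#' plotting coordinates.
#'
#' @param alignments Named list of `subunit_alignment`.
#' @param annotations Named list of `segment_annotation`.
#' @param matrix A `scoring_matrix`.
#' @param reference_subunit_id Reference subunit for ECD anchoring.
#' @return Object of class `conservation_profile`: list with `tracks`
#'   (list of `position_score_track`, each augmented with `domain_labels`
#'   and `plot_x`), `map` (the `coordinate_map`), `annotations`,
#'   `alignments`.
#' @export
conservation_profile <- function(alignments, annotations, matrix,
                                 reference_subunit_id) {
  map <- anchor_coordinates(alignments, annotations, reference_subunit_id)
  tracks <- list()
  for (su in names(alignments)) {
    aln <- alignments[[su]]
    ann <- annotations[[su]]
    dom <- label_domains(aln, ann)
    px <- plot_coordinates(aln, ann, map)
    others <- setdiff(names(aln$seqs), aln$human_reference_id)
    for (id in others) {
      tr <- score_track(aln, id, matrix)
      tr$domain_labels <- dom
      tr$plot_x <- px
      tracks[[paste(su, id, sep = "/")]] <- tr
    }
  }
  structure(list(tracks = tracks, map = map, annotations = annotations,
                 alignments = alignments),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("Conservation profile: ", length(x$tracks), " track(s) across ",
      nrow(x$map), " subunit alignment(s); reference ",
      attr(x$map, "reference_subunit_id"), "\n", sep = "")
  for (tr in x$tracks) {
    cat("  ", tr$subunit_id, " / ", tr$species, ": mean score ",
        format(mean(tr$scores), digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Summarize a score track per annotated segment
#'
#' Segment coordinates (human sequence positions) are converted to alignment
#' columns via the human row, including interleaved gap columns. Means are
#' taken over columns where at least one of the two rows has a residue
#' (dual-gap columns are excluded). Rows are ordered A..G then TM1..TM4.
#'
#' @param track A `position_score_track` (with or without annotations
#'   attached).
#' @param annotation The subunit's `segment_annotation`.
#' @param alignment The source `subunit_alignment`.
#' @return data.frame with columns `segment_name`, `mean_score`,
#'   `min_score`, `n_columns`.
#' @export
summarize_segments <- function(track, annotation, alignment) {
  stopifnot(inherits(track, "position_score_track"),
            inherits(annotation, "segment_annotation"))
  h <- strsplit(alignment$seqs[[alignment$human_reference_id]], "")[[1L]]
  o <- strsplit(alignment$seqs[[track$sequence_id]], "")[[1L]]
  segs <- annotation$segments
  ord <- order(match(segs$segment_name, SEGMENT_ORDER))
  segs <- segs[ord, , drop = FALSE]
  n_res <- nchar(human_sequence(alignment))
  out <- lapply(seq_len(nrow(segs)), function(i) {
    if (segs$end[i] > n_res) {
      stop("segment ", segs$segment_name[i], " extends past the alignment")
    }
    c1 <- .column_of_residue(alignment, segs$start[i])
    c2 <- .column_of_residue(alignment, segs$end[i])
    cols <- c1:c2
    keep <- cols[h[cols] != GAP_CHAR | o[cols] != GAP_CHAR]
    sc <- track$scores[keep]
    data.frame(segment_name = segs$segment_name[i],
               mean_score = mean(sc),
               min_score = min(sc),
               n_columns = length(keep),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Export score tracks as a tidy table
#'
#' @param profile A `conservation_profile`.
#' @return data.frame with columns `subunit_id`, `sequence_id`, `species`,
#'   `column`, `plot_x`, `domain`, `score`.
#' @export
tracks_table <- function(profile) {
  stopifnot(inherits(profile, "conservation_profile"))
  do.call(rbind, lapply(profile$tracks, function(tr) {
    data.frame(subunit_id = tr$subunit_id,
               sequence_id = tr$sequence_id,
               species = tr$species,
               column = seq_along(tr$scores),
               plot_x = tr$plot_x,
               domain = tr$domain_labels,
               score = tr$scores,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Plot score tracks in the anchored coordinate system
#'
#' One panel per domain part (ECD on anchored coordinates, non-ECD numbered
#' from 1), one line per non-human sequence, annotated segments drawn as
#' labelled bands.
#'
#' @param profile A `conservation_profile` with at least one track.
#' @param out_path Output file stem; `_ECD.png` and `_nonECD.png` are
#'   appended.
#' @param width,height Device size in pixels.
#' @return Character vector of written file paths.
#' @export
plot_tracks <- function(profile, out_path, width = 1400, height = 500) {
  stopifnot(inherits(profile, "conservation_profile"))
  if (length(profile$tracks) == 0L) stop("no tracks to plot")
  written <- character(0L)
  for (part in c("ECD", "non-ECD")) {
    fn <- paste0(out_path, "_", gsub("-", "", part), ".png")
    grDevices::png(fn, width = width, height = height)
    tryCatch({
      xs <- lapply(profile$tracks, function(tr) tr$plot_x[tr$domain_labels == part])
      ys <- lapply(profile$tracks, function(tr) tr$scores[tr$domain_labels == part])
      xr <- range(unlist(xs))
      graphics::plot(NA, xlim = xr, ylim = c(-0.6, 1.1),
                     xlab = paste(part, "alignment position"),
                     ylab = "substitution score",
                     main = paste("Conservation,", part))
      cols <- grDevices::rainbow(length(profile$tracks))
      for (i in seq_along(profile$tracks)) {
        graphics::lines(xs[[i]], ys[[i]], col = cols[i])
      }
      # segment bands from each subunit's annotation, in plot coordinates
      for (su in names(profile$alignments)) {
        aln <- profile$alignments[[su]]
        ann <- profile$annotations[[su]]
        px <- plot_coordinates(aln, ann, profile$map)
        dom <- label_domains(aln, ann)
        segs <- ann$segments
        in_part <- if (part == "ECD") segs$end <= ann$ecd_end
                   else segs$start > ann$ecd_end
        for (i in which(in_part)) {
          c1 <- .column_of_residue(aln, segs$start[i])
          c2 <- .column_of_residue(aln, segs$end[i])
          if (dom[c1] != part) next
          graphics::rect(px[c1], 1.02, px[c2], 1.08, col = "grey85",
                         border = "grey40")
          graphics::text((px[c1] + px[c2]) / 2, 1.05,
                         segs$segment_name[i], cex = 0.7)
        }
      }
      graphics::legend("bottomright",
                       legend = vapply(profile$tracks, function(tr)
                         paste(tr$subunit_id, tr$species, sep = "/"),
                         character(1L)),
                       col = cols, lty = 1, cex = 0.7)
    }, finally = grDevices::dev.off())
    written <- c(written, fn)
  }
  written
}

#' @method plot conservation_profile
#' @export
plot.conservation_profile <- function(x, out_path = tempfile("tracks"), ...) {
  plot_tracks(x, out_path, ...)
}
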