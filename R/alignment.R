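# Subunit multiple alignments and segment annotations.
#
# Aligned FASTA headers follow `>SUBUNIT|SPECIES|ACCESSION` (pipe-separated;
# the first two fields are mandatory). Alignments are consumed, never
# computed: the aligner (e.g. MUSCLE) is an external, upstream step.

#' Construct a subunit alignment object
#'
#' @param subunit_id Subunit name (e.g. `"GABRA1"`).
#' @param seqs Named character vector of aligned sequences (rows); names are
#'   sequence ids. All rows must have equal length; allowed characters are
#'   the 20 standard residues plus the gap `-`.
#' @param species Character vector of species labels, parallel to `seqs`.
#' @param human_reference_id Name of the human reference row.
#' @return Object of class `subunit_alignment`.
#' @export
subunit_alignment <- function(subunit_id, seqs, species, human_reference_id) {
  stopifnot(is.character(seqs), length(seqs) >= 1L,
            !is.null(names(seqs)), length(species) == length(seqs))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows have unequal lengths: ",
         paste(unique(widths), collapse = ", "))
  }
  if (!human_reference_id %in% names(seqs)) {
    stop("human reference '", human_reference_id,
         "' not among alignment rows")
  }
  allowed <- c(AA_STANDARD, GAP_CHAR)
  for (id in names(seqs)) {
    chars <- unique(strsplit(seqs[[id]], "")[[1L]])
    bad <- setdiff(chars, allowed)
    if (length(bad) > 0L) {
      stop("row '", id, "' contains characters outside the alphabet: ",
           paste(bad, collapse = ""))
    }
  }
  structure(list(subunit_id = subunit_id,
                 seqs = seqs,
                 species = stats::setNames(species, names(seqs)),
                 human_reference_id = human_reference_id,
                 n_columns = unname(widths[1L])),
            class = "subunit_alignment")
}

#' @export
print.subunit_alignment <- function(x, ...) {
  cat("Subunit alignment ", x$subunit_id, ": ", length(x$seqs),
      " rows x ", x$n_columns, " columns (reference: ",
      x$human_reference_id, ")\n", sep = "")
  invisible(x)
}

#' Read one aligned FASTA file as a subunit alignment
#'
#' @param path Aligned FASTA file; all records must belong to one subunit.
#' @param human_species Species label identifying the human reference row
#'   (matched case-insensitively against the second header field).
#' @return A `subunit_alignment`.
#' @export
read_alignment_fasta <- function(path, human_species = "Homo_sapiens") {
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) stop("no sequences in ", path)
  headers <- names(aa)
  fields <- strsplit(headers, "|", fixed = TRUE)
  bad <- vapply(fields, length, integer(1L)) < 2L
  if (any(bad)) {
    stop("FASTA header lacks SUBUNIT|SPECIES fields: ",
         headers[which(bad)[1L]])
  }
  subunit <- vapply(fields, `[`, character(1L), 1L)
  species <- vapply(fields, `[`, character(1L), 2L)
  if (length(unique(subunit)) != 1L) {
    stop("alignment file mixes subunits: ",
         paste(unique(subunit), collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  names(seqs) <- headers
  is_human <- tolower(species) == tolower(human_species)
  if (sum(is_human) != 1L) {
    stop("expected exactly one row with species '", human_species,
         "' in ", path, ", found ", sum(is_human))
  }
  subunit_alignment(subunit_id = unique(subunit), seqs = seqs,
                    species = species,
                    human_reference_id = headers[is_human])
}

#' Write a subunit alignment as aligned FASTA
#'
#' @param alignment A `subunit_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  stopifnot(inherits(alignment, "subunit_alignment"))
  out <- character(0L)
  for (id in names(alignment$seqs)) {
    out <- c(out, paste0(">", id), alignment$seqs[[id]])
  }
  writeLines(out, path)
  invisible(path)
}

#' Ungapped human reference sequence of an alignment
#' @param alignment A `subunit_alignment`.
#' @return Character scalar, gaps removed.
#' @export
human_sequence <- function(alignment) {
  gsub(GAP_CHAR, "", alignment$seqs[[alignment$human_reference_id]],
       fixed = TRUE)
}

SEGMENT_ORDER <- c("A", "B", "C", "D", "E", "F", "G",
                   "TM1", "TM2", "TM3", "TM4")

#' Construct a segment annotation
#'
#' Coordinates are human 1-based inclusive sequence positions (not alignment
#' columns). `ecd_end` is the last extracellular-domain residue (the residue
#' before TM1); `anchor_residue` is the position of the second conserved
#' cysteine of the cys-loop, the coordinate anchor.
#'
#' @param subunit_id Subunit name.
#' @param segments data.frame with columns `segment_name`, `start`, `end`.
#'   Segment names come from loops A-G and TM1-TM4.
#' @param ecd_end Human position of the last ECD residue.
#' @param anchor_residue Human position of the cys-loop second cysteine.
#' @param human_seq Optional ungapped human sequence; when given, the
#'   annotation is validated against it (lengths, anchor residue is `C`).
#' @return Object of class `segment_annotation`.
#' @export
segment_annotation <- function(subunit_id, segments, ecd_end, anchor_residue,
                               human_seq = NULL) {
  stopifnot(is.data.frame(segments),
            all(c("segment_name", "start", "end") %in% names(segments)))
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  if (any(segments$start < 1L) || any(segments$start > segments$end)) {
    stop("invalid segment coordinates (need 1 <= start <= end)")
  }
  ecd_end <- as.integer(ecd_end)
  anchor_residue <- as.integer(anchor_residue)
  if (ecd_end < 1L) stop("ecd_end must be >= 1")
  if (anchor_residue > ecd_end) {
    stop("anchor residue (", anchor_residue,
         ") must lie inside the ECD (ecd_end = ", ecd_end, ")")
  }
  if (!is.null(human_seq)) {
    n <- nchar(human_seq)
    if (ecd_end > n) stop("ecd_end (", ecd_end,
                          ") exceeds human sequence length (", n, ")")
    if (any(segments$end > n)) stop("segment extends past human sequence")
    if (substr(human_seq, anchor_residue, anchor_residue) != "C") {
      stop("residue at anchor position ", anchor_residue,
           " is not a cysteine")
    }
  }
  structure(list(subunit_id = subunit_id, segments = segments,
                 ecd_end = ecd_end, anchor_residue = anchor_residue),
            class = "segment_annotation")
}

#' Read segment annotations from TSV
#'
#' Expected columns: `subunit_id`, `segment_name`, `start`, `end`. Ordinary
#' rows define segments (A-G, TM1-TM4); rows with `segment_name` equal to
#' `ECD_END` or `CYS_ANCHOR` carry the ECD boundary and cys-loop anchor in
#' their `start` column.
#'
#' @param path Annotation TSV.
#' @param alignments Optional named list of `subunit_alignment` objects used
#'   to validate each annotation against its human sequence.
#' @return Named list of `segment_annotation`, one per subunit.
#' @export
read_segment_annotations <- function(path, alignments = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subunit_id", "segment_name", "start", "end")
  if (!all(need %in% names(df))) {
    stop("annotation TSV needs columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (su in unique(df$subunit_id)) {
    d <- df[df$subunit_id == su, , drop = FALSE]
    ecd <- d$start[d$segment_name == "ECD_END"]
    anc <- d$start[d$segment_name == "CYS_ANCHOR"]
    if (length(ecd) != 1L || length(anc) != 1L) {
      stop("subunit ", su, ": need exactly one ECD_END and one CYS_ANCHOR row")
    }
    segs <- d[!d$segment_name %in% c("ECD_END", "CYS_ANCHOR"), , drop = FALSE]
    hseq <- if (!is.null(alignments) && su %in% names(alignments)) {
      human_sequence(alignments[[su]])
    } else NULL
    out[[su]] <- segment_annotation(su, segs[, c("segment_name", "start",
                                                 "end")],
                                    ecd_end = ecd, anchor_residue = anc,
                                    human_seq = hseq)
  }
  out
}

#' Write segment annotations to TSV
#' @param annotations Named list of `segment_annotation`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_segment_annotations <- function(annotations, path) {
  rows <- lapply(annotations, function(a) {
    rbind(data.frame(subunit_id = a$subunit_id,
                     segment_name = a$segments$segment_name,
                     start = a$segments$start, end = a$segments$end,
                     stringsAsFactors = FALSE),
          data.frame(subunit_id = a$subunit_id,
                     segment_name = c("ECD_END", "CYS_ANCHOR"),
                     start = c(a$ecd_end, a$anchor_residue),
                     end = c(a$ecd_end, a$anchor_residue),
                     stringsAsFactors = FALSE))
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
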