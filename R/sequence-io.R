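#' Construct an element sequence
#'
#' An element sequence holds the onset (and optionally offset) times, in
#' seconds, of the elements — syllables, calls or clicks — of one
#' vocalization or click train, together with identifying metadata. Onsets
#' must be strictly increasing; all downstream rhythm statistics are
#' computed from them.
#'
#' @param onsets Numeric vector of onset times in seconds, strictly
#'   increasing, length >= 1.
#' @param offsets Optional numeric vector of offset times; must have the
#'   same length as `onsets` with `offsets[i] > onsets[i]`. Offsets are
#'   carried through but unused by the rhythm statistics, which are defined
#'   on onsets only.
#' @param labels Optional character vector of element-type tags.
#' @param sequence_id,individual_id,species Identifying metadata strings.
#' @return An object of class `"element_sequence"`.
#' @seealso [compute_iois()], [ioi_sequence()]
#' @export
element_sequence <- function(onsets, offsets = NULL, labels = NULL,
                             sequence_id = "seq1", individual_id = "ind1",
                             species = "unknown") {
  onsets <- as.numeric(onsets)
  if (length(onsets) < 1L) stop("element_sequence needs at least one onset")
  if (any(!is.finite(onsets))) stop("onsets must be finite")
  if (is.unsorted(onsets, strictly = TRUE))
    stop("onsets must be strictly increasing")
  if (!is.null(offsets)) {
    offsets <- as.numeric(offsets)
    if (length(offsets) != length(onsets))
      stop("offsets must have the same length as onsets")
    if (any(offsets <= onsets))
      stop("each offset must be greater than its onset")
  }
  if (!is.null(labels) && length(labels) != length(onsets))
    stop("labels must have the same length as onsets")
  structure(
    list(onsets = onsets, offsets = offsets, labels = labels,
         sequence_id = as.character(sequence_id),
         individual_id = as.character(individual_id),
         species = as.character(species)),
    class = "element_sequence")
}

#' Construct an inter-onset-interval sequence
#'
#' An IOI sequence holds the ordered, strictly positive inter-onset
#' intervals (seconds) of one vocalization or click train. An IOI spans
#' from one element's onset to the next element's onset, i.e. the element
#' duration plus the following gap.
#'
#' @param iois Numeric vector of IOIs in seconds, all > 0.
#' @inheritParams element_sequence
#' @return An object of class `"ioi_sequence"`.
#' @export
ioi_sequence <- function(iois, sequence_id = "seq1", individual_id = "ind1",
                         species = "unknown") {
  iois <- as.numeric(iois)
  if (any(!is.finite(iois)) || any(iois <= 0))
    stop("all IOIs must be finite and > 0")
  structure(
    list(iois = iois, sequence_id = as.character(sequence_id),
         individual_id = as.character(individual_id),
         species = as.character(species)),
    class = "ioi_sequence")
}

#' Bundle sequences into a dataset
#'
#' @param sequences List of [ioi_sequence()] and/or [element_sequence()]
#'   objects. Sequence ids must be unique within the dataset.
#' @param name Dataset label.
#' @return An object of class `"rhythm_dataset"`.
#' @export
rhythm_dataset <- function(sequences, name = "dataset") {
  if (!is.list(sequences) || length(sequences) == 0L)
    stop("sequences must be a non-empty list")
  ok <- vapply(sequences, inherits, logical(1),
               what = c("ioi_sequence", "element_sequence"))
  if (!all(ok))
    stop("all sequences must be ioi_sequence or element_sequence objects")
  ids <- vapply(sequences, `[[`, character(1), "sequence_id")
  if (anyDuplicated(ids))
    stop("sequence_ids must be unique within a dataset: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(name = as.character(name), sequences = sequences),
            class = "rhythm_dataset")
}

#' @export
print.element_sequence <- function(x, ...) {
  cat(sprintf("<element_sequence> %s | %s | %s: %d onsets spanning %.4g s\n",
              x$species, x$individual_id, x$sequence_id, length(x$onsets),
              diff(range(x$onsets))))
  invisible(x)
}

#' @export
print.ioi_sequence <- function(x, ...) {
  cat(sprintf("<ioi_sequence> %s | %s | %s: %d IOIs, mean %.4g s\n",
              x$species, x$individual_id, x$sequence_id, length(x$iois),
              mean(x$iois)))
  invisible(x)
}

#' @export
print.rhythm_dataset <- function(x, ...) {
  sp <- vapply(x$sequences, `[[`, character(1), "species")
  cat(sprintf("<rhythm_dataset> '%s': %d sequences (%s)\n", x$name,
              length(x$sequences),
              paste(sprintf("%s: %d", names(table(sp)), table(sp)),
                    collapse = "; ")))
  invisible(x)
}

#' @export
length.rhythm_dataset <- function(x) length(x$sequences)

#' Read a tab-separated element label file
#'
#' Reads one label file per sequence in the format exported by common
#' bioacoustic labelling software: one row per element with numeric onset
#' and offset columns (seconds) and an optional element-type label, with or
#' without a header line.
#'
#' Field label files are often hand-edited, so the default mode is lenient:
#' out-of-order rows are sorted by onset with a warning. With
#' `strict = TRUE` non-monotone onsets are an error instead.
#'
#' @param path Path to a tab-separated file.
#' @param strict Logical; error (rather than sort + warn) on out-of-order
#'   onsets.
#' @param unit `"s"` or `"ms"`; times are converted to seconds on ingest.
#' @inheritParams element_sequence
#' @return An [element_sequence()].
#' @export
read_label_file <- function(path, strict = FALSE, unit = c("s", "ms"),
                            sequence_id = NULL, individual_id = "ind1",
                            species = "unknown") {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("cannot read label file: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0L) stop("label file is empty: ", path)
  fields <- strsplit(raw, "\t", fixed = TRUE)
  # header detection: first row non-numeric in column 1
  first <- suppressWarnings(as.numeric(fields[[1]][1]))
  if (is.na(first)) {
    fields <- fields[-1]
    if (length(fields) == 0L) stop("label file has a header but no rows: ", path)
  }
  n <- length(fields)
  onsets <- offsets <- numeric(n)
  labels <- character(n)
  has_labels <- FALSE
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 2L)
      stop(sprintf("parse error in %s, row %d: expected at least onset<TAB>offset",
                   path, i))
    on <- suppressWarnings(as.numeric(f[1]))
    off <- suppressWarnings(as.numeric(f[2]))
    if (is.na(on) || is.na(off))
      stop(sprintf("parse error in %s, row %d: non-numeric onset/offset", path, i))
    if (off < on)
      stop(sprintf("parse error in %s, row %d: offset %.6g < onset %.6g",
                   path, i, off, on))
    onsets[i] <- on; offsets[i] <- off
    if (length(f) >= 3L && nzchar(f[3])) { labels[i] <- f[3]; has_labels <- TRUE }
  }
  if (unit == "ms") { onsets <- onsets / 1000; offsets <- offsets / 1000 }
  if (is.unsorted(onsets, strictly = TRUE)) {
    if (strict) stop("onsets are not strictly increasing in ", path)
    ord <- order(onsets)
    onsets <- onsets[ord]; offsets <- offsets[ord]; labels <- labels[ord]
    warning("onsets were not sorted in ", path, "; sorted by onset time")
    if (is.unsorted(onsets, strictly = TRUE))
      stop("duplicate onset times in ", path)
  }
  if (is.null(sequence_id))
    sequence_id <- tools::file_path_sans_ext(basename(path))
  element_sequence(onsets, offsets = offsets,
                   labels = if (has_labels) labels else NULL,
                   sequence_id = sequence_id, individual_id = individual_id,
                   species = species)
}

#' Read a long-format IOI table into a dataset
#'
#' Reads a CSV/TSV table with one row per IOI, carrying species, individual,
#' sequence id and the IOI in seconds, and assembles a [rhythm_dataset()] of
#' [ioi_sequence()] objects. Column names are configurable because published
#' IOI tables vary in layout.
#'
#' @param path Path to a delimited text file with a header row.
#' @param columns Named character vector mapping the roles `species`,
#'   `individual`, `sequence`, `ioi` to column names in the file.
#' @param sep Field separator; guessed from the file extension when `NULL`
#'   (`.csv` comma, otherwise tab).
#' @param unit `"s"` or `"ms"`; IOIs converted to seconds on ingest.
#' @param name Dataset label.
#' @return A [rhythm_dataset()].
#' @export
read_ioi_table <- function(path,
                           columns = c(species = "species",
                                       individual = "individual",
                                       sequence = "sequence_id",
                                       ioi = "ioi_s"),
                           sep = NULL, unit = c("s", "ms"),
                           name = basename(path)) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("cannot read IOI table: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("species", "individual", "sequence", "ioi")
  if (!all(need %in% names(columns)))
    stop("columns must map the roles: ", paste(need, collapse = ", "))
  missing_cols <- setdiff(unname(columns[need]), names(df))
  if (length(missing_cols))
    stop("IOI table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  ioi <- as.numeric(df[[columns[["ioi"]]]])
  if (unit == "ms") ioi <- ioi / 1000
  bad <- which(!is.finite(ioi) | ioi <= 0)
  if (length(bad))
    stop("non-positive or non-numeric IOI in rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  key <- paste(df[[columns[["species"]]]], df[[columns[["individual"]]]],
               df[[columns[["sequence"]]]], sep = "\r")
  idx <- split(seq_along(ioi), factor(key, levels = unique(key)))
  seqs <- lapply(idx, function(i) {
    ioi_sequence(ioi[i],
                 sequence_id = as.character(df[[columns[["sequence"]]]][i[1]]),
                 individual_id = as.character(df[[columns[["individual"]]]][i[1]]),
                 species = as.character(df[[columns[["species"]]]][i[1]]))
  })
  names(seqs) <- NULL
  rhythm_dataset(seqs, name = name)
}

#' Write a dataset as a normalized long-format IOI table
#'
#' @param ds A [rhythm_dataset()]; element sequences are converted to IOIs.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_ioi_table <- function(ds, path) {
  stopifnot(inherits(ds, "rhythm_dataset"))
  rows <- lapply(ds$sequences, function(s) {
    if (inherits(s, "element_sequence")) s <- compute_iois(s)
    data.frame(species = s$species, individual = s$individual_id,
               sequence_id = s$sequence_id,
               ioi_index = seq_along(s$iois), ioi_s = s$iois,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive inter-onset intervals from an element sequence
#'
#' @param seq An [element_sequence()] with at least two onsets.
#' @return An [ioi_sequence()] with `length(onsets) - 1` intervals,
#'   `iois[i] = onsets[i+1] - onsets[i]`.
#' @export
compute_iois <- function(seq) {
  stopifnot(inherits(seq, "element_sequence"))
  if (length(seq$onsets) < 2L)
    stop("need at least 2 onsets to compute IOIs")
  ioi_sequence(diff(seq$onsets), sequence_id = seq$sequence_id,
               individual_id = seq$individual_id, species = seq$species)
}

#' Reconstruct onsets from inter-onset intervals
#'
#' The first onset is placed at t = 0; all rhythm statistics here are
#' translation-invariant, so the absolute start time is immaterial.
#' Round-trips with [compute_iois()].
#'
#' @param iois An [ioi_sequence()] (or bare numeric vector of positive IOIs).
#' @return An [element_sequence()] with `length(iois) + 1` onsets.
#' @export
onsets_from_iois <- function(iois) {
  if (is.numeric(iois)) iois <- ioi_sequence(iois)
  stopifnot(inherits(iois, "ioi_sequence"))
  v <- iois$iois
  if (length(v) == 0L) {
    warning("empty IOI list: returning a single onset at 0")
    onsets <- 0
  } else {
    onsets <- c(0, cumsum(v))
  }
  element_sequence(onsets, sequence_id = iois$sequence_id,
                   individual_id = iois$individual_id, species = iois$species)
}

# Internal: coerce any supported input to a bare onset vector.
as_onsets <- function(x) {
  if (inherits(x, "element_sequence")) return(x$onsets)
  if (inherits(x, "ioi_sequence")) return(onsets_from_iois(x)$onsets)
  if (is.numeric(x)) return(as.numeric(x))
  stop("cannot interpret input as onsets")
}

# Internal: coerce any supported input to a bare IOI vector.
as_iois <- function(x) {
  if (inherits(x, "ioi_sequence")) return(x$iois)
  if (inherits(x, "element_sequence")) return(compute_iois(x)$iois)
  if (is.numeric(x)) return(as.numeric(x))
  stop("cannot interpret input as IOIs")
}
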