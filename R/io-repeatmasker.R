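#' Read a RepeatMasker annotation table
#'
#' Parses the classic whitespace-delimited RepeatMasker `.out` dialect
#' (15 columns; the two header lines and blank lines are tolerated). Each
#' alignment row becomes one repeat hit. The transposable-element class is
#' mapped from the class/family string: `LTR`, `LINE` and `SINE` elements are
#' class I (retrotransposons), `DNA` elements are class II, everything else
#' (simple repeats, low complexity, unknown) is `other`.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return A tibble of repeat hits with columns `chrom`, `start`, `end`
#'   (1-based inclusive), `length`, `sw_score`, `repeat_name`, `family`
#'   (the class/family string, e.g. `"LTR/Gypsy"`) and `repeat_class`
#'   (`"I"`, `"II"` or `"other"`).
#' @export
read_repeatmasker_out <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("RepeatMasker file not found: ", path), class = "mycomine_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  data_rows <- lines[grepl("^[0-9]", lines)]
  if (length(data_rows) == 0L) {
    return(empty_repeat_hits())
  }
  fields <- strsplit(data_rows, "\\s+")
  nf <- lengths(fields)
  if (any(nf < 14L)) {
    abort(paste0("malformed RepeatMasker row (fewer than 14 fields): line ",
                 which(nf < 14L)[1]),
          class = "mycomine_io_error")
  }
  get <- function(i) vapply(fields, `[`, character(1), i)
  sw_score <- suppressWarnings(as.integer(get(1)))
  start <- suppressWarnings(as.integer(get(6)))
  end <- suppressWarnings(as.integer(get(7)))
  if (anyNA(sw_score) || anyNA(start) || anyNA(end) || any(end < start)) {
    abort("malformed RepeatMasker row (non-numeric or inverted coordinates)",
          class = "mycomine_io_error")
  }
  tibble(
    chrom = get(5),
    start = start,
    end = end,
    length = end - start + 1L,
    sw_score = sw_score,
    repeat_name = get(10),
    family = get(11),
    repeat_class = repeat_class_of(get(11))
  )
}

#' Map RepeatMasker class/family strings to transposable-element classes
#'
#' @param family Character vector of RepeatMasker class/family strings.
#' @return Character vector over `"I"`, `"II"`, `"other"`.
#' @export
repeat_class_of <- function(family) {
  dplyr::case_when(
    grepl("^(LTR|LINE|SINE)", family, ignore.case = TRUE) ~ "I",
    grepl("^DNA", family, ignore.case = TRUE) ~ "II",
    TRUE ~ "other"
  )
}

empty_repeat_hits <- function() {
  tibble(
    chrom = character(), start = integer(), end = integer(),
    length = integer(), sw_score = integer(),
    repeat_name = character(), family = character(), repeat_class = character()
  )
}

#' Write repeat hits in the RepeatMasker `.out` layout
#'
#' Writes the standard 15-column body (with the conventional two header lines)
#' so that simulator output can be re-read by [read_repeatmasker_out()].
#'
#' @param hits Repeat-hit tibble (see [read_repeatmasker_out()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(hits, path) {
  header <- c(
    "   SW  perc perc perc  query     position in query     matching repeat       position in repeat",
    "score  div. del. ins.  sequence  begin end    (left)   repeat   class/family begin end (left) ID",
    ""
  )
  rows <- sprintf(
    "%d 1.0 0.0 0.0 %s %d %d (0) + %s %s 1 %d (0) %d",
    hits$sw_score, hits$chrom, hits$start, hits$end,
    hits$repeat_name, hits$family, hits$length, seq_len(nrow(hits))
  )
  writeLines(c(header, rows), path)
  invisible(path)
}
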