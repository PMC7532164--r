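#' @name icd10
#' @title ICD-10 level-3 code handling and chapter mapping
#'
#' @description Helpers for working with three-character ("level-3") ICD-10
#' codes: truncation of national dialect codes to the level-3 core, the
#' standard 22-chapter letter/number range table, and chapter-based event
#' filtering. The reserved code `Y99` marks death and is handled specially
#' throughout the package.
NULL

#' Reserved diagnosis code marking death
#'
#' Appended to a patient's event history at the death date by
#' [inject_death_events()]; only ever appears as the terminal code of a pair
#' or trajectory.
#' @export
DEATH_CODE <- "Y99"

## Chapter table: roman label, code range (letter + 2-digit start/end).
## Ranges follow the WHO ICD-10 chapter index; chapters XIX and XX span two
## letters and are encoded as multiple rows sharing a label.
icd10_chapter_table <- function() {
  dt <- data.table::data.table(
    chapter = c("I", "I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX",
                "X", "XI", "XII", "XIII", "XIV", "XV", "XVI", "XVII",
                "XVIII", "XIX", "XIX", "XX", "XX", "XX", "XX", "XXI", "XXII"),
    letter = c("A", "B", "C", "D", "E", "F", "G", "H", "H", "I",
               "J", "K", "L", "M", "N", "O", "P", "Q",
               "R", "S", "T", "V", "W", "X", "Y", "Z", "U"),
    lo = c(0L, 0L, 0L, 50L, 0L, 0L, 0L, 0L, 60L, 0L,
           0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
           0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),
    hi = c(99L, 99L, 48L, 89L, 90L, 99L, 99L, 59L, 95L, 99L,
           99L, 93L, 99L, 99L, 99L, 99L, 96L, 99L,
           99L, 99L, 98L, 99L, 99L, 99L, 99L, 99L, 85L)
  )
  ## chapter II runs C00-D48, chapter III D50-D89: C handled above, D split
  dt <- rbind(dt, data.table::data.table(chapter = "II", letter = "D",
                                         lo = 0L, hi = 48L))
  dt
}

#' Truncate a raw diagnosis code to its ICD-10 level-3 core
#'
#' Extracts the three-character code (one letter, two digits). A leading
#' single-letter national prefix (the Danish convention prepends "D", so
#' `DI10` means `I10`) is stripped when the string starts with two letters;
#' anything after the level-3 core (sub-level digits, a dot and decimals) is
#' dropped. Idempotent on codes already at level 3.
#'
#' @param raw_code character vector of diagnosis codes.
#' @return character vector of level-3 codes (letter + two digits).
#' @examples
#' truncate_to_level3(c("I10", "DI109", "Q90.1"))
#' @export
truncate_to_level3 <- function(raw_code) {
  if (length(raw_code) == 0L) return(character(0))
  x <- toupper(trimws(as.character(raw_code)))
  if (anyNA(x) || any(!nzchar(x)))
    stop("empty or missing diagnosis code", call. = FALSE)
  ## strip one leading letter when the string starts with two letters
  two_letter <- grepl("^[A-Z][A-Z]", x)
  x[two_letter] <- sub("^[A-Z]", "", x[two_letter])
  core <- regmatches(x, regexpr("^[A-Z][0-9]{2}", x))
  ok <- grepl("^[A-Z][0-9]{2}", x)
  if (!all(ok)) {
    bad <- unique(raw_code[!ok])
    stop("malformed diagnosis code(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  out <- character(length(x))
  out[ok] <- core
  out
}

#' Map level-3 codes to ICD-10 chapter labels
#'
#' @param code character vector of level-3 codes.
#' @return character vector of roman-numeral chapter labels ("I" ... "XXII");
#'   `NA` for codes outside every chapter range.
#' @export
icd10_chapter <- function(code) {
  tab <- icd10_chapter_table()
  letter <- substr(code, 1L, 1L)
  num <- suppressWarnings(as.integer(substr(code, 2L, 3L)))
  out <- rep(NA_character_, length(code))
  for (i in seq_len(nrow(tab))) {
    hit <- letter == tab$letter[i] & !is.na(num) &
      num >= tab$lo[i] & num <= tab$hi[i]
    out[hit & is.na(out)] <- tab$chapter[i]
  }
  out
}

#' Default chapter exclusions
#'
#' Chapters dropped before pair mining: perinatal conditions (XVI), symptoms
#' and abnormal findings (XVIII), injury and poisoning (XIX), external causes
#' (XX) and factors influencing health status (XXI).
#' @export
DEFAULT_EXCLUDED_CHAPTERS <- c("XVI", "XVIII", "XIX", "XX", "XXI")

#' Filter diagnosis events by ICD-10 chapter
#'
#' Removes events whose code falls in an excluded chapter. The death code
#' `Y99` sits inside chapter XX's letter range but is always retained: death
#' must stay visible to the mining stages regardless of chapter exclusions.
#'
#' @param events a `data.table` of diagnosis events (column `code`).
#' @param excluded_chapters character vector of roman chapter labels.
#' @return the retained events (a subset of the input rows).
#' @export
filter_chapters <- function(events,
                            excluded_chapters = DEFAULT_EXCLUDED_CHAPTERS) {
  events <- data.table::as.data.table(events)
  if (length(excluded_chapters) == 0L) return(events[])
  valid <- unique(icd10_chapter_table()$chapter)
  unknown <- setdiff(excluded_chapters, valid)
  if (length(unknown))
    stop("unknown ICD-10 chapter label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ch <- icd10_chapter(events$code)
  keep <- !(ch %in% excluded_chapters) | events$code == DEATH_CODE
  events[keep][]
}
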