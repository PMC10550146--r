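#' Construct a longitudinal tumor-volume study dataset
#'
#' Validates and wraps a table of caliper-derived tumor volume measurements:
#' one row per animal per measurement day. Rows are sorted by
#' `(animal_id, time)`; within an animal, times must be strictly increasing
#' after sorting (no duplicated measurement days) and every animal must
#' contribute at least two records.
#'
#' @param measurements data.frame with columns `animal_id`, `time` (days since
#'   inoculation, >= 0), `tv` (mm^3, > 0) and optionally `cell_line`,
#'   `tumor_type`.
#' @param upper_limit Ethical upper tumor size limit in mm^3 (animals are
#'   sacrificed once the measured volume exceeds it), or `NULL` if unknown.
#' @return An object of class `study_dataset`: list with `measurements`
#'   (sorted data.frame), `upper_limit`, `n_animals`, `n_obs`.
#' @export
study_dataset <- function(measurements, upper_limit = NULL) {
  req <- c("animal_id", "time", "tv")
  miss <- setdiff(req, names(measurements))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- as.data.frame(measurements, stringsAsFactors = FALSE)
  if (!"cell_line" %in% names(m)) m$cell_line <- NA_character_
  if (!"tumor_type" %in% names(m)) m$tumor_type <- NA_character_
  m <- m[, c("animal_id", "time", "tv", "cell_line", "tumor_type")]
  m$animal_id <- as.character(m$animal_id)
  m$time <- as.numeric(m$time)
  m$tv <- as.numeric(m$tv)

  bad <- which(!is.finite(m$tv) | m$tv <= 0)
  if (length(bad))
    stop("validation error: non-positive or missing tumor volume at row ",
         bad[1], " (animal ", m$animal_id[bad[1]], ", time ", m$time[bad[1]],
         ")", call. = FALSE)
  bad <- which(!is.finite(m$time) | m$time < 0)
  if (length(bad))
    stop("validation error: negative or missing time at row ", bad[1],
         " (animal ", m$animal_id[bad[1]], ")", call. = FALSE)

  ord <- order(m$animal_id, m$time)
  m <- m[ord, , drop = FALSE]
  rownames(m) <- NULL
  dup <- which(duplicated(m[, c("animal_id", "time")]))
  if (length(dup))
    stop("validation error: duplicate (animal_id, time) at row ", dup[1],
         " (animal ", m$animal_id[dup[1]], ", time ", m$time[dup[1]], ")",
         call. = FALSE)
  cnt <- table(m$animal_id)
  if (any(cnt < 2))
    stop("validation error: animal(s) with fewer than 2 records: ",
         paste(names(cnt)[cnt < 2], collapse = ", "), call. = FALSE)
  if (!is.null(upper_limit)) {
    if (!is.numeric(upper_limit) || length(upper_limit) != 1L || upper_limit <= 0)
      stop("upper_limit must be a single positive number", call. = FALSE)
  }
  structure(list(measurements = m,
                 upper_limit = upper_limit,
                 n_animals = length(cnt),
                 n_obs = nrow(m)),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("study_dataset:", x$n_animals, "animals,", x$n_obs, "observations\n")
  cl <- unique(x$measurements$cell_line)
  tt <- unique(x$measurements$tumor_type)
  if (!all(is.na(cl)))
    cat("  cell lines:", length(cl), "| tumor types:", length(tt[!is.na(tt)]), "\n")
  cat("  time span (days):", paste(range(x$measurements$time), collapse = " - "), "\n")
  cat("  upper limit (mm^3):",
      if (is.null(x$upper_limit)) "none" else x$upper_limit, "\n")
  invisible(x)
}

#' Split a dataset into per-animal profiles
#' @param dataset A [study_dataset()].
#' @return Named list of data.frames, one per animal, ordered by time.
#' @export
split_animals <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  split(dataset$measurements, dataset$measurements$animal_id)
}

# NONMEM-style column convention used on disk
.dialect_default <- list(sep = ",",
                         col_id = "ID", col_time = "TIME", col_tv = "DV",
                         col_cell_line = "CELL_LINE",
                         col_tumor_type = "TUMOR_TYPE")

#' Read a longitudinal tumor-volume dataset from delimited text
#'
#' The default dialect is a comma-separated file with a header row and
#' NONMEM-style columns `ID,TIME,DV,CELL_LINE,TUMOR_TYPE` (TIME in days, DV in
#' mm^3); `CELL_LINE` and `TUMOR_TYPE` are optional.
#'
#' @param path File path.
#' @param dialect Named list overriding any of `sep`, `col_id`, `col_time`,
#'   `col_tv`, `col_cell_line`, `col_tumor_type`.
#' @param upper_limit Optional ethical limit (mm^3) to attach.
#' @return A [study_dataset()].
#' @export
read_dataset <- function(path, dialect = list(), upper_limit = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::modifyList(.dialect_default, dialect)
  raw <- utils::read.table(path, header = TRUE, sep = d$sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(d$col_id, d$col_time, d$col_tv))
    if (!col %in% names(raw))
      stop("format error: column '", col, "' not found in ", path, call. = FALSE)
  m <- data.frame(animal_id = raw[[d$col_id]],
                  time = raw[[d$col_time]],
                  tv = raw[[d$col_tv]],
                  stringsAsFactors = FALSE)
  if (d$col_cell_line %in% names(raw)) m$cell_line <- raw[[d$col_cell_line]]
  if (d$col_tumor_type %in% names(raw)) m$tumor_type <- raw[[d$col_tumor_type]]
  study_dataset(m, upper_limit = upper_limit)
}

#' Write a dataset to delimited text (inverse of [read_dataset()])
#' @param dataset A [study_dataset()].
#' @param path Output file path.
#' @param dialect As in [read_dataset()].
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, dialect = list()) {
  stopifnot(inherits(dataset, "study_dataset"))
  d <- utils::modifyList(.dialect_default, dialect)
  m <- dataset$measurements
  out <- data.frame(m$animal_id, m$time, m$tv, m$cell_line, m$tumor_type,
                    stringsAsFactors = FALSE)
  names(out) <- c(d$col_id, d$col_time, d$col_tv, d$col_cell_line,
                  d$col_tumor_type)
  utils::write.table(out, path, sep = d$sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tumor volume from caliper length and width
#'
#' Ovoid approximation used for subcutaneous xenografts:
#' volume = length x width^2 / 2. If `width > length` the two are swapped
#' with a warning (caliper readings are order-agnostic).
#'
#' @param length,width Caliper readings in mm, > 0.
#' @return Volume in mm^3.
#' @export
caliper_volume <- function(length, width) {
  if (any(!is.finite(length)) || any(!is.finite(width)) ||
      any(length <= 0) || any(width <= 0))
    stop("length and width must be positive", call. = FALSE)
  swap <- width > length
  if (any(swap)) {
    warning("width > length for ", sum(swap),
            " measurement(s); swapping", call. = FALSE)
    tmp <- length[swap]
    length[swap] <- width[swap]
    width[swap] <- tmp
  }
  length * width^2 / 2
}

#' Transform a per-animal tumor volume profile
#'
#' Two transformations put animals on a comparable scale before empirical
#' oscillation screening: the natural logarithm, and unit normalization
#' (division by the animal's maximum observed volume, so the maximum maps
#' exactly to 1).
#'
#' @param tv Positive volumes of one animal.
#' @param mode `"log"` (natural log) or `"unit"`.
#' @return Transformed numeric vector.
#' @export
transform_profile <- function(tv, mode = c("unit", "log")) {
  mode <- match.arg(mode)
  if (length(tv) == 0L) stop("empty profile", call. = FALSE)
  if (any(!is.finite(tv) | tv <= 0))
    stop("all tumor volumes must be positive", call. = FALSE)
  switch(mode, log = log(tv), unit = tv / max(tv))
}
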