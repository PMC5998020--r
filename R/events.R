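#' Event lists and localization sets
#'
#' SMLM acquisition software exports one row per *blink*: a single localized
#' emission event with X/Y/Z coordinates. `event_list()` is the in-memory
#' container for such a table; all coordinates are held in nanometres.
#' After multi-blink correction (see [merge_blinks()]) the points become
#' *localizations* — predicted molecule positions — held in a
#' `localization_set`, which additionally records how many raw blinks each
#' localization absorbed.
#'
#' @param points numeric matrix with 3 columns (x, y, z) in nm, or a
#'   data.frame with columns `x`, `y`, `z`.
#' @param frame optional integer vector of acquisition frame indices, one per
#'   point (non-negative).
#' @param source_label free-text identifier (cell / experiment id).
#' @return An object of class `event_list`: a list with elements `points`
#'   (n x 3 numeric matrix with columns x, y, z), `frame` (or `NULL`) and
#'   `source_label`.
#' @examples
#' ev <- event_list(cbind(c(0, 10), c(0, 0), c(0, 0)))
#' n_points(ev)
#' @export
event_list <- function(points, frame = NULL, source_label = "") {
  pts <- as_points(points)
  if (!all(is.finite(pts))) stop("event_list: coordinates must be finite")
  if (!is.null(frame)) {
    frame <- as.integer(frame)
    if (length(frame) != nrow(pts))
      stop("event_list: 'frame' must have one entry per point")
    if (any(frame < 0L, na.rm = TRUE))
      stop("event_list: frame indices must be non-negative")
  }
  structure(list(points = pts, frame = frame,
                 source_label = as.character(source_label)[1]),
            class = "event_list")
}

#' @param merged_from positive integer vector: number of original blinks
#'   absorbed into each localization.
#' @rdname event_list
#' @export
localization_set <- function(points, merged_from = NULL, source_label = "") {
  pts <- as_points(points)
  if (is.null(merged_from)) merged_from <- rep(1L, nrow(pts))
  merged_from <- as.integer(merged_from)
  if (length(merged_from) != nrow(pts) || any(merged_from < 1L))
    stop("localization_set: 'merged_from' must be positive, one per point")
  structure(list(points = pts, merged_from = merged_from,
                 source_label = as.character(source_label)[1]),
            class = "localization_set")
}

# Coerce anything point-like to an n x 3 numeric matrix (nm).
as_points <- function(x) {
  if (inherits(x, c("event_list", "localization_set", "roi"))) return(x$points)
  if (is.data.frame(x)) {
    cn <- tolower(names(x))
    if (all(c("x", "y", "z") %in% cn)) {
      x <- as.matrix(x[, match(c("x", "y", "z"), cn), drop = FALSE])
    } else x <- as.matrix(x)
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  x <- unname(as.matrix(x))
  storage.mode(x) <- "double"
  if (ncol(x) != 3) stop("points must have 3 columns (x, y, z)")
  colnames(x) <- c("x", "y", "z")
  x
}

#' @rdname event_list
#' @param x an `event_list` or `localization_set`.
#' @export
n_points <- function(x) nrow(as_points(x))

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list> %d blinks%s%s\n", n_points(x),
              if (!is.null(x$frame)) " (+frame)" else "",
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]") else ""))
  invisible(x)
}

#' @export
print.localization_set <- function(x, ...) {
  cat(sprintf("<localization_set> %d localizations from %d blinks\n",
              n_points(x), sum(x$merged_from)))
  invisible(x)
}

#' Column dialects for tabular event lists
#'
#' A dialect maps file columns to coordinate roles and declares the unit scale
#' applied at read time so that the in-memory representation is always in nm.
#' The default dialect matches a plain `x,y,z[,frame]` CSV already in nm.
#' The `"leica-gsd"` dialect documents the assumption used for Leica GSD 3D
#' exports: pixel-indexed X/Y at 20 nm/px and Z at 25 nm/px (the acquisition
#' pixel sizes); the exact export schema is instrument-configurable, so the
#' mapping is declarative and user-overridable.
#'
#' @param name one of `"xyz-nm"` (default) or `"leica-gsd"`, or leave and pass
#'   fields directly.
#' @param columns named character vector mapping roles `x`, `y`, `z` (and
#'   optionally `frame`) to file column names.
#' @param scale numeric length-3 (x, y, z): multiply file values by this to
#'   obtain nm.
#' @param sep field separator (`","` or `"\t"`).
#' @return a list of class `event_dialect`.
#' @export
event_dialect <- function(name = "xyz-nm", columns = NULL, scale = NULL,
                          sep = ",") {
  defaults <- list(
    "xyz-nm"    = list(columns = c(x = "x", y = "y", z = "z", frame = "frame"),
                       scale = c(1, 1, 1)),
    "leica-gsd" = list(columns = c(x = "x", y = "y", z = "z", frame = "frame"),
                       scale = c(20, 20, 25)))
  if (!name %in% names(defaults))
    stop("unknown dialect '", name, "'")
  d <- defaults[[name]]
  if (!is.null(columns)) d$columns[names(columns)] <- columns
  if (!is.null(scale)) d$scale <- scale
  structure(list(name = name, columns = d$columns, scale = as.numeric(d$scale),
                 sep = sep), class = "event_dialect")
}

#' Read an SMLM event list from tabular text
#'
#' One blink per data row; header required. Units are converted to nm using
#' the dialect's scale factors. Row order is preserved.
#'
#' @param path file path.
#' @param dialect an [event_dialect()] (or its name as a string).
#' @param source_label optional label stored on the result.
#' @return an [event_list()].
#' @export
read_event_list <- function(path, dialect = event_dialect(),
                            source_label = basename(path)) {
  if (is.character(dialect)) dialect <- event_dialect(dialect)
  if (!file.exists(path)) stop("read_event_list: no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  need <- dialect$columns[c("x", "y", "z")]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("read_event_list: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0)
    return(event_list(matrix(numeric(0), ncol = 3), source_label = source_label))
  coords <- sapply(seq_along(need), function(k) {
    v <- suppressWarnings(as.numeric(df[[need[k]]]))
    bad <- which(is.na(v) & !is.na(df[[need[k]]]))
    if (length(bad))
      stop(sprintf("read_event_list: non-numeric %s coordinate at data row %d",
                   c("x", "y", "z")[k], bad[1]))
    v * dialect$scale[k]
  })
  coords <- matrix(coords, ncol = 3)
  frame <- NULL
  fcol <- dialect$columns["frame"]
  if (!is.na(fcol) && fcol %in% names(df))
    frame <- as.integer(as.numeric(df[[fcol]]))
  event_list(coords, frame = frame, source_label = source_label)
}

#' Write an event list (or localization set) to tabular text
#'
#' Writes a headered CSV with `x,y,z` columns in nm, plus `frame` if present
#' on an event list and `merged_from` if given a localization set.
#'
#' @param ev an [event_list()] or [localization_set()].
#' @param path destination path.
#' @param digits decimal places retained (default 4; ~0.1 pm, far below any
#'   physical precision here).
#' @return `path`, invisibly.
#' @export
write_event_list <- function(ev, path, digits = 4) {
  pts <- as_points(ev)
  df <- as.data.frame(round(pts, digits))
  if (inherits(ev, "event_list") && !is.null(ev$frame)) df$frame <- ev$frame
  if (inherits(ev, "localization_set")) df$merged_from <- ev$merged_from
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("write_event_list: cannot write to ", path, ": ",
         conditionMessage(ok))
  invisible(path)
}
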