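.POINT_COLS <- c("pole_id", "structure_id", "label", "x_nm", "y_nm")

#' Read a point table of motor/relic annotations
#'
#' Point tables carry the per-structure 2D positions on cell poles that the
#' spatial analysis consumes: one row per structure with columns `pole_id`,
#' `structure_id`, `label` (`motor` or `relic`), `x_nm`, `y_nm`. Row order
#' is preserved.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`; the default guesses from the file
#'   extension (`.csv` means csv, anything else tsv).
#' @return a data.frame with the five canonical columns.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' df <- data.frame(pole_id = "p1", structure_id = c("s1", "s2"),
#'                  label = c("motor", "relic"), x_nm = c(0, 50),
#'                  y_nm = c(0, 10))
#' writePointTable(df, f)
#' readPointTable(f)
#' @export
readPointTable <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  missing <- setdiff(.POINT_COLS, names(df))
  if (length(missing))
    stop("point table is missing required column(s): ",
         paste(missing, collapse = ", "))
  df <- df[, .POINT_COLS]
  bad <- !df$label %in% .LABELS
  if (any(bad))
    stop(sprintf("unknown label '%s' in row %d; allowed labels: %s",
                 df$label[which(bad)[1]], which(bad)[1],
                 paste(.LABELS, collapse = ", ")))
  for (col in c("x_nm", "y_nm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    badrow <- which(is.na(v) | !is.finite(v))
    if (length(badrow))
      stop(sprintf("non-numeric %s value '%s' in row %d",
                   col, df[[col]][badrow[1]], badrow[1]))
    df[[col]] <- v
  }
  df
}

#' @rdname readPointTable
#' @param df data.frame with the five canonical columns.
#' @export
writePointTable <- function(df, path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  missing <- setdiff(.POINT_COLS, names(df))
  if (length(missing))
    stop("cannot write point table; missing column(s): ",
         paste(missing, collapse = ", "))
  utils::write.table(df[, .POINT_COLS], path,
                     sep = if (dialect == "csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert between point tables and PolePattern lists
#'
#' `polePatterns` splits a point table into one [PolePattern-class] per
#' pole (order of first appearance preserved); `patternsToTable` is the
#' inverse.
#'
#' @param df point table data.frame.
#' @param cringDiameter C-ring diameter in nm attached to each pattern.
#' @return `polePatterns`: named list of `PolePattern`; `patternsToTable`:
#'   a point table data.frame.
#' @export
polePatterns <- function(df, cringDiameter = 45) {
  ids <- unique(df$pole_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$pole_id == id, , drop = FALSE]
    PolePattern(id, sub$x_nm, sub$y_nm, sub$label, cringDiameter)
  })
  names(out) <- ids
  out
}

#' @rdname polePatterns
#' @param patterns list of [PolePattern-class] objects.
#' @export
patternsToTable <- function(patterns) {
  do.call(rbind, lapply(patterns, function(p) {
    xy <- poleCoords(p)
    data.frame(pole_id = poleId(p),
               structure_id = sprintf("%s_s%d", poleId(p), seq_len(nrow(xy))),
               label = structureLabels(p),
               x_nm = xy[, 1], y_nm = xy[, 2],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
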