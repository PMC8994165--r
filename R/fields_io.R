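# Visual-field records: one row per test, metadata columns followed by one
# sensitivity (dB) column per grid location, in the grid's stable order.
# This mirrors the layout perimetric analysis packages use and keeps a whole
# cohort or longitudinal series in a single data frame.

vf_meta_cols <- c("id", "eye", "date", "age", "duration",
                  "fpr", "fnr", "fl", "grid")

#' Assemble a visual-field table
#'
#' @param id subject identifier(s).
#' @param eye `"OD"` or `"OS"` per row.
#' @param date test date(s) (`Date` or ISO-8601 string).
#' @param age age in decimal years.
#' @param duration test duration in seconds.
#' @param fpr,fnr,fl false-positive, false-negative and fixation-loss rates
#'   in `[0, 1]`.
#' @param grid name of the grid the sensitivity columns refer to.
#' @param sensitivities numeric matrix (rows = tests, columns = grid
#'   locations, dB); `NA` marks missing values (blind spots may be missing).
#' @return a data frame of class `vf` with columns `id, eye, date, age,
#'   duration, fpr, fnr, fl, grid, l1...lN`.
#' @export
vf_table <- function(id, eye, date, age, duration = 0, fpr = 0, fnr = 0,
                     fl = 0, grid, sensitivities) {
  sens <- as.matrix(sensitivities)
  n <- nrow(sens)
  gname <- if (inherits(grid, "vf_grid")) grid$name else as.character(grid)
  if (inherits(grid, "vf_grid") && ncol(sens) != nrow(grid$locations))
    stop_perisim("sensitivity columns (", ncol(sens), ") do not match grid size (",
                 nrow(grid$locations), ")")
  eye <- rep_len(eye, n)
  if (!all(eye %in% c("OD", "OS"))) stop_perisim("eye must be OD or OS")
  out <- data.frame(id = rep_len(as.character(id), n),
                    eye = eye,
                    date = rep_len(as.Date(date), n),
                    age = rep_len(as.numeric(age), n),
                    duration = rep_len(as.numeric(duration), n),
                    fpr = rep_len(as.numeric(fpr), n),
                    fnr = rep_len(as.numeric(fnr), n),
                    fl = rep_len(as.numeric(fl), n),
                    grid = rep_len(gname, n),
                    stringsAsFactors = FALSE)
  colnames(sens) <- paste0("l", seq_len(ncol(sens)))
  out <- cbind(out, as.data.frame(sens))
  class(out) <- c("vf", "data.frame")
  out
}

vf_sens_cols <- function(vf) grep("^l[0-9]+$", names(vf), value = TRUE)

#' Extract the sensitivity matrix from a field table
#'
#' @param vf a `vf` table.
#' @return numeric matrix, rows = tests, columns = grid locations (dB).
#' @export
vf_sens_matrix <- function(vf) {
  as.matrix(vf[, vf_sens_cols(vf), drop = FALSE])
}

#' @export
print.vf <- function(x, ...) {
  cat(sprintf("Visual field table: %d test(s) on grid '%s' (%d locations)\n",
              nrow(x), x$grid[1], length(vf_sens_cols(x))))
  NextMethod()
}

#' Read visual-field records from CSV
#'
#' The schema has one header row `id,eye,date,age,duration,fpr,fnr,fl,grid,
#' l1,...,lN` with the sensitivity columns in the grid's stable location
#' order, dates in ISO 8601, and missing sensitivities (e.g. blind spots) as
#' empty cells. Every row's grid must be registered (the built-in `"24-2"`
#' or one added with [register_grid()]) and must match the file's column
#' count; violations raise an error naming the offending row.
#'
#' @param path CSV file path.
#' @return a `vf` table.
#' @export
read_vf_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  need <- vf_meta_cols
  if (!identical(names(raw)[seq_along(need)], need))
    stop_perisim("CSV header must start with ", paste(need, collapse = ","))
  lcols <- names(raw)[-seq_along(need)]
  if (!identical(lcols, paste0("l", seq_along(lcols))))
    stop_perisim("sensitivity columns must be named l1..lN in order")
  nloc <- length(lcols)
  for (r in seq_len(nrow(raw))) {
    g <- tryCatch(build_standard_grid(raw$grid[r]), error = function(e) NULL)
    if (is.null(g))
      stop_perisim("row ", r, ": unregistered grid '", raw$grid[r], "'")
    if (nrow(g$locations) != nloc)
      stop_perisim("row ", r, ": grid '", raw$grid[r], "' has ",
                   nrow(g$locations), " locations but file has ", nloc,
                   " sensitivity columns")
    if (!raw$eye[r] %in% c("OD", "OS"))
      stop_perisim("row ", r, ": eye must be OD or OS, got '", raw$eye[r], "'")
    if (is.na(as.Date(raw$date[r], format = "%Y-%m-%d")))
      stop_perisim("row ", r, ": unparseable date '", raw$date[r],
                   "' (expected YYYY-MM-DD)")
    for (cc in c("fpr", "fnr", "fl")) {
      v <- suppressWarnings(as.numeric(raw[[cc]][r]))
      if (is.na(v) || v < 0 || v > 1)
        stop_perisim("row ", r, ": ", cc, " = '", raw[[cc]][r],
                     "' outside [0, 1]")
    }
  }
  sens <- vapply(raw[lcols], function(col) {
    col[col == ""] <- NA_character_
    as.numeric(col)
  }, numeric(nrow(raw)))
  sens <- matrix(sens, nrow = nrow(raw),
                 dimnames = list(NULL, lcols))
  vf_table(id = raw$id, eye = raw$eye, date = as.Date(raw$date),
           age = as.numeric(raw$age), duration = as.numeric(raw$duration),
           fpr = as.numeric(raw$fpr), fnr = as.numeric(raw$fnr),
           fl = as.numeric(raw$fl), grid = raw$grid[1], sensitivities = sens)
}

#' Write visual-field records to CSV
#'
#' Sensitivities are serialized with two decimal places (trailing zeros
#' trimmed) and missing values as empty cells; dates as ISO 8601. A write
#' followed by [read_vf_csv()] reproduces every representable field (dB
#' values with at most two decimals) bit-exactly, preserving row order.
#'
#' @param vf a `vf` table.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_vf_csv <- function(vf, path) {
  sens <- vf_sens_matrix(vf)
  fmt <- function(x) {
    out <- ifelse(is.na(x), "", sub("\\.?0+$", "", sprintf("%.2f", x)))
    out[out == "-0"] <- "0"
    out
  }
  meta <- data.frame(id = vf$id, eye = vf$eye,
                     date = format(vf$date, "%Y-%m-%d"),
                     age = vf$age, duration = vf$duration, fpr = vf$fpr,
                     fnr = vf$fnr, fl = vf$fl, grid = vf$grid,
                     stringsAsFactors = FALSE)
  sf <- as.data.frame(matrix(fmt(sens), nrow = nrow(sens),
                             dimnames = dimnames(sens)),
                      stringsAsFactors = FALSE)
  utils::write.csv(cbind(meta, sf), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}
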