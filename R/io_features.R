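# Feature tables: tab-separated values plus a JSON sidecar (<path>.layout.json)
# that is the authoritative schema for the block layout.

#' Write a feature matrix with its layout
#'
#' The matrix is stored as TSV (one row per segment, full precision) and the
#' layout as a JSON sidecar at `<path>.layout.json` describing the named
#' blocks `(name, start, length)` and the montage id.
#'
#' @param x numeric matrix, columns matching `layout`.
#' @param layout a [feature_layout()] (or any object with `blocks` and
#'   `montage`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, layout, path) {
  x <- as.matrix(x)
  if (ncol(x) != layout_total(layout))
    stop("matrix has ", ncol(x), " columns but layout totals ",
         layout_total(layout))
  con <- file(path, "w")
  writeLines(paste0("n_features\t", ncol(x)), con)
  if (nrow(x)) {
    utils::write.table(format(x, digits = 17, trim = TRUE, scientific = TRUE),
                       con, sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  close(con)
  jsonlite::write_json(
    list(montage = layout$montage, blocks = layout$blocks),
    paste0(path, ".layout.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a feature matrix and its layout
#' @param path a TSV written by [write_feature_table()]; the
#'   `<path>.layout.json` sidecar must be present.
#' @return List with elements `x` (matrix) and `layout`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  side <- paste0(path, ".layout.json")
  if (!file.exists(side)) stop("missing layout sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  layout <- feature_layout_from_blocks(as.data.frame(meta$blocks), meta$montage)
  lines <- readLines(path)
  if (length(lines) < 1L || !grepl("^n_features\t[0-9]+$", lines[1L]))
    stop("corrupted feature-table header in ", path)
  nf <- as.integer(sub("^n_features\t", "", lines[1L]))
  if (nf != layout_total(layout))
    stop("feature table declares ", nf, " features but layout totals ",
         layout_total(layout))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (!length(body)) {
    x <- matrix(numeric(0), nrow = 0L, ncol = nf)
  } else {
    x <- as.matrix(utils::read.table(text = body, sep = "\t", header = FALSE,
                                     colClasses = "numeric"))
    dimnames(x) <- NULL
    if (ncol(x) != nf) stop("feature-table rows have ", ncol(x),
                            " fields, expected ", nf)
  }
  list(x = x, layout = layout)
}
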