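#' Construct a parcellation hierarchy
#'
#' A parcellation hierarchy maps every region label of the finest resolution
#' to a label at each coarser resolution, the structure used to derive
#' low-resolution braingraphs from the finest-resolution consensus graph by
#' vertex contraction (as in the nested Lausanne-style atlases with
#' 1015 down to 86 regions).
#'
#' @param table data frame with one row per finest-level label and one
#'   column per level, finest first (column names are the level names).
#' @return an object of class `parcellation_hierarchy` with elements
#'   `levels` (character vector, finest first), `sizes` (label counts per
#'   level) and `table`.
#' @details Invariants enforced: finest labels unique; every label mapped at
#'   every level (totality); level sizes strictly decreasing; the map
#'   between any two consecutive levels is a well-defined function (a label
#'   never maps to two different coarser labels), which makes composition
#'   from the finest to every coarser level well-defined.
#' @export
parcellation_hierarchy <- function(table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (ncol(table) < 2)
    stop_input("hierarchy needs at least two levels, got %d column(s)", ncol(table))
  for (j in seq_len(ncol(table))) table[[j]] <- as.character(table[[j]])
  levels <- names(table)
  if (anyDuplicated(levels)) stop_input("duplicate level name(s) in header")
  if (any(vapply(table, function(col) any(is.na(col) | !nzchar(col)), TRUE)))
    stop_input("totality violated: empty or missing label in hierarchy table")
  finest <- table[[1]]
  if (anyDuplicated(finest))
    stop_input("duplicate finest-level label(s): %s",
               paste(unique(finest[duplicated(finest)]), collapse = ", "))
  sizes <- vapply(table, function(col) length(unique(col)), 0L)
  if (any(diff(sizes) >= 0))
    stop_input("level sizes must be strictly decreasing, got [%s]",
               paste(sizes, collapse = ", "))
  # consecutive-level maps must be functions
  for (j in seq_len(ncol(table) - 1)) {
    pairs <- unique(table[, c(j, j + 1)])
    if (anyDuplicated(pairs[[1]]))
      stop_input(
        "label(s) at level '%s' map to more than one label at level '%s': %s",
        levels[j], levels[j + 1],
        paste(unique(pairs[[1]][duplicated(pairs[[1]])]), collapse = ", "))
  }
  structure(list(levels = levels, sizes = unname(sizes), table = table),
            class = "parcellation_hierarchy")
}

#' Read a parcellation hierarchy from a delimited text file
#'
#' The file must have a header row of level names (finest level first) and
#' one row per finest-level label. The delimiter is taken from the file
#' extension (`.tsv` = tab, otherwise comma) unless given.
#'
#' @param path path to a CSV/TSV file.
#' @param sep field separator; `NULL` to infer from the extension.
#' @return a [parcellation_hierarchy()].
#' @export
read_hierarchy <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  parcellation_hierarchy(df)
}

#' Label map between two hierarchy levels
#'
#' @param hierarchy a [parcellation_hierarchy()].
#' @param from,to level names; `from` must be at least as fine as `to`.
#' @return named character vector: `from`-level label -> `to`-level label.
#' @export
level_map <- function(hierarchy, from, to) {
  i_from <- match(from, hierarchy$levels)
  i_to <- match(to, hierarchy$levels)
  if (is.na(i_from)) stop_input("unknown level '%s'", from)
  if (is.na(i_to)) stop_input("unknown level '%s'", to)
  if (i_to < i_from)
    stop_input("cannot map from level '%s' to the finer level '%s'", from, to)
  pairs <- unique(hierarchy$table[, c(i_from, i_to)])
  stats::setNames(pairs[[2]], pairs[[1]])
}

#' @export
print.parcellation_hierarchy <- function(x, ...) {
  cat(sprintf("parcellation hierarchy: %d levels (%s)\n", length(x$levels),
              paste(sprintf("%s=%d", x$levels, x$sizes), collapse = " > ")))
  invisible(x)
}
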