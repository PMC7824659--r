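#' Read an origin-destination flow table
#'
#' Two dialects are accepted. Long format has header
#' \code{origin,dest,count}, one row per zone pair; zone ids are opaque
#' strings kept in first-appearance order (origins scanned before
#' destinations), missing pairs are zero flows, and duplicate pairs are
#' summed with a warning. Wide format is a square table whose first
#' column holds origin ids and whose remaining column names are the
#' destination ids, taken in column order.
#'
#' @param path CSV file path.
#' @param dialect \code{"auto"} (default; long is recognised by its
#'   header), \code{"long"} or \code{"wide"}.
#' @param window_years window length recorded on the result.
#' @return a [flow_matrix].
#' @export
read_flows <- function(path, dialect = c("auto", "long", "wide"),
                       window_years = 1L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    hdr <- tolower(trimws(strsplit(readLines(path, n = 1L), ",")[[1]]))
    dialect <- if (identical(hdr, c("origin", "dest", "count"))) "long"
               else "wide"
  }
  if (dialect == "long") {
    df <- utils::read.csv(path, colClasses = c("character", "character",
                                               "numeric"))
    names(df) <- tolower(names(df))
    if (!identical(names(df), c("origin", "dest", "count"))) {
      stop("long dialect needs header origin,dest,count")
    }
    if (any(df$count < 0)) stop("negative counts in ", path)
    ids <- unique(c(df$origin, df$dest))
    n <- length(ids)
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    if (anyDuplicated(df[c("origin", "dest")])) {
      warning("duplicate origin-dest pairs summed")
    }
    for (r in seq_len(nrow(df))) {
      m[df$origin[r], df$dest[r]] <- m[df$origin[r], df$dest[r]] + df$count[r]
    }
    flow_matrix(m, window_years = window_years, zone_ids = ids)
  } else {
    df <- utils::read.csv(path, check.names = FALSE,
                          colClasses = "character")
    origins <- df[[1L]]
    dests <- names(df)[-1L]
    vals <- suppressWarnings(
      vapply(df[-1L], as.numeric, numeric(nrow(df))))
    m <- matrix(as.numeric(vals), nrow(df), length(dests))
    if (any(!is.finite(m))) stop("non-numeric or ragged wide matrix in ", path)
    if (nrow(m) != ncol(m) || !setequal(origins, dests)) {
      stop("wide matrix must be square with matching origin/destination ids")
    }
    dimnames(m) <- list(origins, dests)
    m <- m[, origins, drop = FALSE]   # align column order to row order
    if (any(m < 0)) stop("negative counts in ", path)
    flow_matrix(m, window_years = window_years, zone_ids = origins)
  }
}

#' Read a per-zone population table
#'
#' @param path CSV file with header \code{zone,population}.
#' @return a [population_vector], zones in file order.
#' @export
read_population <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  names(df) <- tolower(names(df))
  if (!identical(names(df), c("zone", "population"))) {
    stop("population file needs header zone,population")
  }
  population_vector(df$population, zone_ids = df$zone)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a matrix or vector as diff-able CSV
#'
#' Matrices go out wide: first column \code{origin} with zone ids, then
#' one column per destination, numbers printed with 17 significant
#' digits so that \code{read_flows()} round-trips exactly. Vectors go
#' out as \code{zone,value} rows; an optional matrix of per-component
#' columns can ride along (the \code{zone,population_eq,component_k}
#' layout of equilibrium output).
#'
#' @param path output file path.
#' @param object matrix ([flow_matrix], [spatial_kernel], or plain with
#'   dimnames) / named vector or [population_vector].
#' @param value_name column name for the vector value column.
#' @param extra optional named list of further per-zone columns.
#' @return the path, invisibly.
#' @export
write_matrix <- function(path, object) {
  m <- if (inherits(object, "flow_matrix")) unclass_flow(object)
       else if (is_spatial_kernel(object)) unclass_matrix(object)
       else as.matrix(object)
  if (length(m) == 0L) stop("empty object")
  ids <- resolve_zone_ids(NULL, m)
  lines <- c(paste(c("origin", ids), collapse = ","),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(ids[i], fmt17(m[i, ])), collapse = ",")
             }, character(1)))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

#' @rdname write_matrix
#' @export
write_vector <- function(path, object, value_name = "value", extra = NULL) {
  v <- as.numeric(object)
  if (length(v) == 0L) stop("empty object")
  ids <- names(object)
  if (is.null(ids)) ids <- paste0("z", seq_along(v))
  cols <- c(list(v), unname(extra))
  hdr <- paste(c("zone", value_name, names(extra)), collapse = ",")
  rows <- vapply(seq_along(v), function(i) {
    paste(c(ids[i], vapply(cols, function(cc) fmt17(cc[i]), character(1))),
          collapse = ",")
  }, character(1))
  tryCatch(writeLines(c(hdr, rows), path),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}
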