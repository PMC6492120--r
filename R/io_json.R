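# JSON serialization of result objects. Matrices are written as
# {dim, dimnames, data} records so shapes and labels survive the
# round-trip exactly; doubles are written at full precision.

.ser_value <- function(x) {
  if (is.matrix(x)) {
    list(.matrix = TRUE, dim = dim(x),
         rownames = rownames(x), colnames = colnames(x),
         data = as.vector(x))
  } else {
    x
  }
}

.deser_value <- function(x) {
  if (is.list(x) && isTRUE(x$.matrix)) {
    m <- matrix(as.numeric(unlist(x$data)), nrow = x$dim[[1]], ncol = x$dim[[2]])
    rn <- unlist(x$rownames); cn <- unlist(x$colnames)
    if (length(rn) == nrow(m)) rownames(m) <- rn
    if (length(cn) == ncol(m)) colnames(m) <- cn
    return(m)
  }
  if (is.list(x)) return(lapply(x, .deser_value))
  x
}

#' Write an analysis result to JSON
#'
#' Serializes a [fit_2bpls()], [fit_rrr()] or [mantel_test()] result (or
#' any tagged list) with full double precision, so that
#' [read_results()] reproduces every field to within 1e-12.
#'
#' @param result result object.
#' @param path output file path.
#' @export
write_results <- function(result, path) {
  type <- class(result)[1]
  payload <- lapply(unclass(result), .ser_value)
  payload <- payload[!vapply(payload, is.null, logical(1))]
  payload <- c(list(.type = type), payload)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an analysis result written by [write_results()]
#'
#' @param path JSON file path.
#' @return the restored result object, with its original class.
#' @export
read_results <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyMatrix = FALSE, simplifyDataFrame = FALSE)
  type <- raw$.type
  raw$.type <- NULL
  out <- lapply(raw, function(v) {
    v <- .deser_value(v)
    if (is.list(v) && !is.matrix(v) && all(vapply(v, is.numeric, logical(1))) &&
        all(lengths(v) == 1L) && is.null(names(v))) {
      v <- unlist(v)
    }
    v
  })
  class(out) <- type
  out
}
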