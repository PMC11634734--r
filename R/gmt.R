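#' Read and write gene-set collections in GMT format
#'
#' GMT is the tab-delimited gene-set format: one set per line with the set
#' name, a description field, then the member identifiers.
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of character vectors;
#'   descriptions are kept in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) abort("malformed GMT line: need name, description, members")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "descriptions") <-
    setNames(vapply(parts, `[[`, character(1), 2), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
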