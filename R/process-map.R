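#' Biological-process gene sets (GMT)
#'
#' A process map names the biological-process gene sets used for reporting
#' which parts of the network a regulator reaches (e.g. "jasmonic acid
#' biosynthetic process" -> member gene ids). Sets may overlap; membership
#' is a set (duplicates within one process are collapsed). Computing the
#' enrichment that produced such sets is out of scope; the map is consumed
#' as given.
#'
#' @param sets Named list of character vectors of gene ids.
#' @return A named list of class `"ProcessMap"`; each element is a sorted,
#'   unique character vector.
#' @examples
#' process_map(list(JA = c("G1", "G2"), ROS = "G2"))
#' @export
process_map <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stopf("sets must be a named list of gene-id vectors")
  }
  assert_character_ids(names(sets), "process names")
  out <- lapply(sets, function(v) sort(unique(as.character(v))))
  empty <- names(out)[lengths(out) == 0L]
  if (length(empty) > 0L) {
    stopf("process '%s' has no member genes", empty[1L])
  }
  structure(out, class = "ProcessMap")
}

#' @export
print.ProcessMap <- function(x, ...) {
  cat(sprintf(
    "ProcessMap: %d processes, %d distinct genes\n",
    length(x), length(unique(unlist(x)))
  ))
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Empty member lists
#' are rejected. On write, the description field holds `"na"`.
#'
#' @param path File path.
#' @return [read_process_map()]: a [process_map()].
#' @export
read_process_map <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[`, "", 1L)
  sets <- lapply(parts, function(p) {
    members <- p[-(1:2)]
    members[nzchar(members)]
  })
  names(sets) <- names_
  for (i in seq_along(sets)) {
    if (length(sets[[i]]) == 0L) {
      stopf("process '%s' has no member genes in %s", names_[i], path)
    }
  }
  process_map(sets)
}

#' @rdname read_process_map
#' @param pm A [process_map()] to serialize.
#' @export
write_process_map <- function(pm, path) {
  lines <- vapply(names(pm), function(nm) {
    paste(c(nm, "na", pm[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
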