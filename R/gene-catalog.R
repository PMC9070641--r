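#' Gene catalog: regulator vs structural roles
#'
#' The algorithm partitions genes into two groups before building anything:
#' regulatory genes (TF-encoding genes, the candidate edge sources) and
#' structural genes (enzyme-encoding and other effector genes, the bottom
#' layer). A catalog records that partition, optionally with a TF family
#' label (ERF, NAC, MADS, WRKY, ...) on regulator genes.
#'
#' Accepted role tokens (case-insensitive): `regulator`, `tf`,
#' `transcription_factor` map to the regulator role; `structural`,
#' `structure`, `target` map to the structural role.
#'
#' @param gene_id Character vector of unique gene ids.
#' @param role Character vector of role tokens, recycled rules not applied;
#'   must match `gene_id` in length.
#' @param family Optional TF family labels; only allowed on regulator genes.
#' @return A data frame of class `"GeneCatalog"` with columns `gene_id`,
#'   `role` (factor-free character, `"regulator"` or `"structural"`) and
#'   `family`.
#' @examples
#' gene_catalog(c("G1", "G2"), c("TF", "structural"))
#' @export
gene_catalog <- function(gene_id, role, family = NULL) {
  gene_id <- as.character(gene_id)
  role <- normalize_role(role)
  if (length(role) != length(gene_id)) {
    stopf("gene_id and role must have equal length")
  }
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup) > 0L) {
    # A gene listed twice with the same role is harmless; conflicting roles
    # are a real error and must name the offender.
    for (g in dup) {
      if (length(unique(role[gene_id == g])) > 1L) {
        stopf("gene '%s' is listed with conflicting roles", g)
      }
    }
    keep <- !duplicated(gene_id)
    if (!is.null(family)) family <- family[keep]
    role <- role[keep]
    gene_id <- gene_id[keep]
  }
  if (is.null(family)) {
    family <- rep(NA_character_, length(gene_id))
  } else {
    family <- as.character(family)
    family[!nzchar(family) | family == "NA"] <- NA_character_
    bad <- !is.na(family) & role != "regulator"
    if (any(bad)) {
      stopf(
        "family labels are only allowed on regulator genes (offender: '%s')",
        gene_id[which(bad)[1L]]
      )
    }
  }
  structure(
    data.frame(
      gene_id = gene_id, role = role, family = family,
      stringsAsFactors = FALSE
    ),
    class = c("GeneCatalog", "data.frame")
  )
}

ROLE_ALIASES <- c(
  regulator = "regulator", tf = "regulator",
  transcription_factor = "regulator",
  structural = "structural", structure = "structural", target = "structural"
)

normalize_role <- function(role) {
  key <- tolower(as.character(role))
  out <- unname(ROLE_ALIASES[key])
  if (anyNA(out)) {
    bad <- unique(key[is.na(out)])
    stopf(
      "unknown role token(s): %s (accepted: %s)",
      paste(bad, collapse = ", "),
      paste(names(ROLE_ALIASES), collapse = ", ")
    )
  }
  out
}

#' @export
print.GeneCatalog <- function(x, ...) {
  cat(sprintf(
    "GeneCatalog: %d genes (%d regulator, %d structural)\n",
    nrow(x), sum(x$role == "regulator"), sum(x$role == "structural")
  ))
  invisible(x)
}

#' Regulator / structural gene ids of a catalog
#' @param catalog A [gene_catalog()].
#' @return Character vector of gene ids, sorted.
#' @export
regulator_genes <- function(catalog) {
  sort(catalog$gene_id[catalog$role == "regulator"])
}

#' @rdname regulator_genes
#' @export
structural_genes <- function(catalog) {
  sort(catalog$gene_id[catalog$role == "structural"])
}

#' Read / write a gene catalog TSV
#'
#' Two or three tab-separated columns: `gene_id`, `role`, optional
#' `family`. `#` comment lines are skipped. A header line is optional and
#' detected by the literal column name `gene_id`.
#'
#' @param path File path.
#' @return [read_gene_catalog()]: a [gene_catalog()].
#' @export
read_gene_catalog <- function(path) {
  if (!file.exists(path)) stopf("catalog file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stopf("catalog file is empty: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(parts[[1L]][1L], "gene_id")) parts <- parts[-1L]
  ids <- vapply(parts, `[`, "", 1L)
  roles <- vapply(parts, function(p) p[2L] %||% NA_character_, "")
  if (anyNA(roles)) stopf("catalog line without a role column in %s", path)
  fams <- vapply(parts, function(p) {
    if (length(p) >= 3L) p[3L] else NA_character_
  }, "")
  gene_catalog(ids, roles, fams)
}

#' @rdname read_gene_catalog
#' @param catalog A [gene_catalog()] to serialize.
#' @export
write_gene_catalog <- function(catalog, path) {
  utils::write.table(
    as.data.frame(catalog), path,
    sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
  invisible(path)
}
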