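#' Construct an OTU table
#'
#' The central exchange object of the package: a non-negative integer count
#' matrix (samples x OTUs) together with a per-OTU taxonomy string (seven
#' semicolon-delimited ranks, possibly partially unassigned) and a per-sample
#' metadata table mapping samples to host species, genus, tribe and replicate.
#'
#' @param counts integer matrix, samples in rows, OTUs in columns; both
#'   dimensions must carry unique names.
#' @param taxonomy named character vector of lineage strings, one per OTU.
#'   Defaults to fully unassigned lineages.
#' @param metadata data.frame with a `sample_id` column covering every sample
#'   and (at least) a `host_species` column; `genus`, `tribe` and `replicate`
#'   are carried when present.
#' @return An object of class `otu_table`: a list with elements `counts`,
#'   `taxonomy`, `metadata`.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 3L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("otu1", "otu2")))
#' md <- data.frame(sample_id = c("s1", "s2"), host_species = c("sp1", "sp1"))
#' otu_table(m, metadata = md)
#' @export
otu_table <- function(counts, taxonomy = NULL, metadata = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .stopf("`counts` must have sample row names and OTU column names")
  if (anyDuplicated(rownames(counts)))
    .stopf("duplicated sample identifiers: %s",
           paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                 collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    .stopf("duplicated OTU identifiers: %s",
           paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                 collapse = ", "))
  if (anyNA(counts) || any(counts < 0L))
    .stopf("counts must be non-negative integers")
  if (is.null(taxonomy)) {
    taxonomy <- stats::setNames(rep(strrep(";", 6L), ncol(counts)),
                                colnames(counts))
  }
  if (is.null(names(taxonomy)) ||
      !setequal(names(taxonomy), colnames(counts)))
    .stopf("taxonomy must be named and cover exactly the table's OTU ids")
  taxonomy <- taxonomy[colnames(counts)]
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = rownames(counts),
                           host_species = rownames(counts),
                           stringsAsFactors = FALSE)
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(metadata) ||
      !"host_species" %in% names(metadata))
    .stopf("metadata needs `sample_id` and `host_species` columns")
  missing <- setdiff(rownames(counts), metadata$sample_id)
  if (length(missing))
    .stopf("samples missing from metadata: %s", paste(missing, collapse = ", "))
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  host species: %s\n",
              paste(unique(x$metadata$host_species), collapse = ", ")))
  cat(sprintf("  total reads: %d (per-sample range %d-%d)\n",
              sum(x$counts),
              if (nrow(x$counts)) min(rowSums(x$counts)) else 0L,
              if (nrow(x$counts)) max(rowSums(x$counts)) else 0L))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Sample identifiers of an OTU table
#' @param t an `otu_table`.
#' @return character vector of sample ids, in table order.
#' @export
sample_ids <- function(t) rownames(t$counts)

#' OTU identifiers of an OTU table
#' @param t an `otu_table`.
#' @return character vector of OTU ids, in table order.
#' @export
otu_ids <- function(t) colnames(t$counts)

# subset an otu_table by sample/otu index or name, keeping it consistent
.subset_table <- function(t, samples = NULL, otus = NULL) {
  counts <- t$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(otus)) counts <- counts[, otus, drop = FALSE]
  otu_table(counts, t$taxonomy[colnames(counts)],
            t$metadata[t$metadata$sample_id %in% rownames(counts), ,
                       drop = FALSE])
}

#' Read an OTU table and its sample metadata from TSV files
#'
#' Two table dialects are accepted and auto-detected from the header: the
#' QIIME-classic layout (first header cell `#OTU ID`, OTUs as rows, optional
#' trailing `taxonomy` column) and a plain samples-as-rows layout (first
#' column sample ids, one column per OTU). The returned object is always
#' oriented samples x OTUs.
#'
#' @param table_path path to the tab-separated count table.
#' @param metadata_path path to a TSV with columns `sample_id`,
#'   `host_species` and optionally `genus`, `tribe`, `replicate`.
#' @return an [otu_table].
#' @export
read_otu_table <- function(table_path, metadata_path) {
  first <- readLines(table_path, n = 2L)
  first <- first[!startsWith(first, "# Constructed")]
  header <- strsplit(first[1L], "\t", fixed = TRUE)[[1L]]
  qiime <- identical(header[1L], "#OTU ID")
  raw <- utils::read.delim(table_path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE,
                           skip = if (startsWith(first[1L], "# Constructed")) 1L else 0L)
  taxonomy <- NULL
  if (qiime) {
    ids <- as.character(raw[[1L]])
    raw <- raw[, -1L, drop = FALSE]
    if (tolower(names(raw)[ncol(raw)]) == "taxonomy") {
      taxonomy <- stats::setNames(as.character(raw[[ncol(raw)]]), ids)
      raw <- raw[, -ncol(raw), drop = FALSE]
    }
    m <- .numeric_count_matrix(raw, ids, table_path)
    m <- t(m)  # OTUs were rows
  } else {
    ids <- as.character(raw[[1L]])
    raw <- raw[, -1L, drop = FALSE]
    m <- .numeric_count_matrix(raw, ids, table_path)
  }
  metadata <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                                check.names = FALSE, comment.char = "",
                                stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(metadata))
    names(metadata)[1L] <- "sample_id"
  extra <- setdiff(rownames(m), metadata$sample_id)
  if (length(extra))
    .stopf("samples present in table but absent from metadata: %s",
           paste(extra, collapse = ", "))
  otu_table(m, taxonomy, metadata)
}

.numeric_count_matrix <- function(df, row_ids, path) {
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) | v != round(v))
    if (length(bad))
      .stopf("non-integer count in %s at row '%s', column '%s'",
             path, row_ids[bad[1L]], names(df)[j])
    df[[j]] <- as.integer(v)
  }
  m <- as.matrix(df)
  rownames(m) <- row_ids
  m
}

#' Write an OTU table (and optionally its metadata) to TSV
#'
#' @param t an [otu_table].
#' @param table_path output path for the count table.
#' @param metadata_path optional output path for the metadata TSV.
#' @param dialect `"qiime"` (OTUs as rows, `#OTU ID` header, trailing
#'   `taxonomy` column) or `"samples"` (samples as rows, no taxonomy).
#' @return invisibly, `t`.
#' @export
write_otu_table <- function(t, table_path, metadata_path = NULL,
                            dialect = c("qiime", "samples")) {
  dialect <- match.arg(dialect)
  if (dialect == "qiime") {
    m <- t(t$counts)
    df <- data.frame(`#OTU ID` = rownames(m), m,
                     taxonomy = unname(t$taxonomy[rownames(m)]),
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- data.frame(sample_id = rownames(t$counts), t$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
  }
  utils::write.table(df, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.table(t$metadata, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(t)
}

#' Read a labeled square distance matrix from TSV
#'
#' Expects the QIIME distance-matrix layout: first row and first column are
#' labels, body is a square symmetric numeric matrix with zero diagonal.
#' @param path input TSV path.
#' @return symmetric numeric matrix with matching dimnames.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  validate_distance_matrix(m)
}

#' Write a labeled square distance matrix to TSV
#' @param dm symmetric labeled matrix.
#' @param path output path.
#' @return invisibly, `dm`.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(id = rownames(dm), dm, check.names = FALSE)
  names(df)[1L] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dm)
}

#' Validate a distance matrix
#'
#' Checks squareness, matching labels, symmetry, finiteness, non-negativity
#' and a zero diagonal (to `tol`).
#' @param m matrix to validate.
#' @param tol numeric tolerance for symmetry/diagonal checks.
#' @return the matrix, invisibly symmetrized to remove rounding fuzz.
#' @export
validate_distance_matrix <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    .stopf("distance matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    .stopf("distance matrix row and column labels must match")
  if (any(!is.finite(m))) .stopf("distance matrix has non-finite entries")
  if (any(m < -tol)) .stopf("distance matrix has negative entries")
  if (max(abs(m - t(m))) > tol) .stopf("distance matrix is not symmetric")
  if (any(abs(diag(m)) > tol)) .stopf("distance matrix diagonal is not zero")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}
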