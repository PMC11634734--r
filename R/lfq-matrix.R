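#' Construct an LFQ intensity matrix
#'
#' Container for a label-free quantification protein-group matrix: a
#' proteins-by-samples intensity matrix (NA = missing), a sample annotation
#' table, a per-protein contaminant flag, and an explicit scale state
#' (`"linear"` or `"log2"`) so transformation steps can guard against being
#' applied twice.
#'
#' @param intensities Numeric matrix, proteins in rows (rownames = protein
#'   IDs), samples in columns (colnames = sample IDs). Missing values `NA`.
#' @param annotations Tibble with columns `sample_id` (matching the matrix
#'   columns) and `group`, optionally `sex`, `region`.
#' @param scale `"linear"` or `"log2"`.
#' @param contaminant Logical vector per protein (default all `FALSE`).
#' @return An object of class `lfq_matrix`.
#' @export
lfq_matrix <- function(intensities, annotations, scale = c("linear", "log2"),
                       contaminant = NULL) {
  scale <- match.arg(scale)
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities))) {
    rownames(intensities) <- sprintf("P%05d", seq_len(nrow(intensities)))
  }
  if (is.null(colnames(intensities))) {
    colnames(intensities) <- sprintf("S%02d", seq_len(ncol(intensities)))
  }
  annotations <- as_tibble(annotations)
  if (!all(c("sample_id", "group") %in% names(annotations))) {
    abort("`annotations` needs columns sample_id and group")
  }
  if (!setequal(annotations$sample_id, colnames(intensities)) ||
      nrow(annotations) != ncol(intensities)) {
    abort("annotations must cover exactly the matrix columns")
  }
  annotations <- annotations[match(colnames(intensities),
                                   annotations$sample_id), ]
  if (scale == "linear" && any(intensities <= 0, na.rm = TRUE)) {
    abort("linear-scale intensities must be positive where present")
  }
  contaminant <- contaminant %||% rep(FALSE, nrow(intensities))
  if (length(contaminant) != nrow(intensities)) {
    abort("`contaminant` must flag every protein")
  }
  structure(
    list(intensities = intensities, annotations = annotations,
         scale = scale, contaminant = as.logical(contaminant)),
    class = "lfq_matrix"
  )
}

#' @export
print.lfq_matrix <- function(x, ...) {
  cat(sprintf("<lfq_matrix> %d proteins x %d samples (%s scale)\n",
              nrow(x$intensities), ncol(x$intensities), x$scale))
  cat(sprintf("missing: %.1f%%; contaminants flagged: %d\n",
              100 * mean(is.na(x$intensities)), sum(x$contaminant)))
  grp <- table(x$annotations$group)
  cat("groups:", paste(sprintf("%s=%d", names(grp), as.integer(grp)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.lfq_matrix <- function(x) dim(x$intensities)

#' Long-format view of an LFQ matrix
#'
#' @param x An `lfq_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `protein_id`, `sample_id`, `intensity`,
#'   joined with the sample annotations.
#' @export
as_tibble.lfq_matrix <- function(x, ...) {
  long <- tibble(
    protein_id = rep(rownames(x$intensities), times = ncol(x$intensities)),
    sample_id = rep(colnames(x$intensities), each = nrow(x$intensities)),
    intensity = as.vector(x$intensities)
  )
  left_join(long, x$annotations, by = "sample_id")
}

group_columns <- function(lfq) {
  split(seq_len(ncol(lfq$intensities)), lfq$annotations$group)
}

#' Write / read an LFQ matrix as TSV
#'
#' The intensity TSV has a `protein_id` column then one column per sample
#' (empty cell = missing, emulating a DIA-NN protein-group matrix export),
#' plus an `is_contaminant` 0/1 column; the annotation TSV has `sample_id`,
#' `group` and any further columns.
#'
#' @param lfq An [lfq_matrix()].
#' @param matrix_tsv,annotations_tsv File paths.
#' @param scale Scale flag to assume when reading.
#' @return `write_lfq()` returns `lfq` invisibly; `read_lfq()` an
#'   [lfq_matrix()].
#' @export
write_lfq <- function(lfq, matrix_tsv, annotations_tsv) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  out <- as_tibble(as.data.frame(lfq$intensities))
  out <- bind_cols(tibble(protein_id = rownames(lfq$intensities),
                          is_contaminant = as.integer(lfq$contaminant)), out)
  readr::write_tsv(out, matrix_tsv, na = "")
  readr::write_tsv(lfq$annotations, annotations_tsv)
  invisible(lfq)
}

#' @rdname write_lfq
#' @export
read_lfq <- function(matrix_tsv, annotations_tsv,
                     scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  tab <- readr::read_tsv(matrix_tsv, show_col_types = FALSE)
  ann <- readr::read_tsv(annotations_tsv, show_col_types = FALSE)
  contaminant <- rep(FALSE, nrow(tab))
  if ("is_contaminant" %in% names(tab)) {
    contaminant <- tab$is_contaminant == 1
  }
  m <- as.matrix(tab[setdiff(names(tab), c("protein_id", "is_contaminant"))])
  rownames(m) <- tab$protein_id
  lfq_matrix(m, ann, scale = scale, contaminant = contaminant)
}
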