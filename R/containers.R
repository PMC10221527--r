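#' Construct a taxa abundance table
#'
#' Container for a samples x taxa abundance matrix from one gut location,
#' either sequencing counts or relative abundances (proportions), together
#' with the taxonomic level and an optional taxonomy lineage map.
#'
#' @param abundance numeric matrix, samples in rows, taxa in columns; row
#'   and column names are the sample and taxon identifiers. All entries
#'   must be non-negative.
#' @param location gut location label, one of `"ileum"`, `"cecum"`,
#'   `"faeces"`.
#' @param level taxonomic level of the columns: `"ASV"`, `"genus"` or
#'   `"species"`.
#' @param taxonomy optional named character vector mapping taxon id to a
#'   lineage string.
#' @return an object of class `taxa_table` (a list with elements
#'   `abundance`, `location`, `level`, `taxonomy`).
#' @export
taxa_table <- function(abundance,
                       location = c("ileum", "cecum", "faeces"),
                       level = c("ASV", "genus", "species"),
                       taxonomy = NULL) {
  location <- match.arg(location)
  level <- match.arg(level)
  abundance <- as.matrix(abundance)
  if (!is.numeric(abundance)) {
    stop("'abundance' must be a numeric matrix")
  }
  if (any(abundance < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative")
  }
  if (is.null(rownames(abundance))) {
    rownames(abundance) <- sprintf("S%03d", seq_len(nrow(abundance)))
  }
  if (anyDuplicated(rownames(abundance))) {
    stop("sample ids (row names) must be unique")
  }
  if (is.null(colnames(abundance))) {
    colnames(abundance) <- sprintf("T%04d", seq_len(ncol(abundance)))
  }
  structure(
    list(abundance = abundance, location = location, level = level,
         taxonomy = taxonomy),
    class = "taxa_table"
  )
}

#' @export
print.taxa_table <- function(x, ...) {
  cat(sprintf("taxa_table: %d samples x %d taxa (%s, %s level)\n",
              nrow(x$abundance), ncol(x$abundance), x$location, x$level))
  kind <- if (is_proportions(x)) "relative abundances" else "counts"
  cat(sprintf("  values: %s\n", kind))
  invisible(x)
}

#' @export
dim.taxa_table <- function(x) dim(x$abundance)

# TRUE when every non-empty row sums to ~1, i.e. the table already holds
# relative abundances rather than counts.
is_proportions <- function(x) {
  rs <- rowSums(x$abundance)
  rs <- rs[rs > 0]
  length(rs) > 0 && all(abs(rs - 1) < 1e-6)
}

# Convert a taxa_table's matrix to per-sample proportions.
as_proportions <- function(x) {
  m <- x$abundance
  rs <- rowSums(m)
  if (any(rs == 0)) {
    stop("cannot convert to proportions: sample(s) with zero total: ",
         paste(rownames(m)[rs == 0], collapse = ", "))
  }
  sweep(m, 1, rs, "/")
}

#' Construct a serum metabolite feature matrix
#'
#' Container for an LC-MS feature intensity matrix with the per-sample
#' injection metadata the QC procedures need. An intensity of exactly 0
#' encodes a missing value.
#'
#' @param intensity numeric matrix, samples (study + QC injections) in
#'   rows, metabolite features in columns; non-negative.
#' @param injection_order integer vector, one unique value per row, the
#'   position of that sample in the acquisition run.
#' @param is_qc logical vector flagging pooled-QC injections.
#' @param annotation optional data.frame with columns `feature_id`,
#'   `compound`, `msi_level` (1, 2, 3, 4 or NA for unannotated) and
#'   `ion_mode` (`"positive"`/`"negative"`).
#' @return an object of class `metabo_matrix`.
#' @export
metabo_matrix <- function(intensity, injection_order, is_qc,
                          annotation = NULL) {
  intensity <- as.matrix(intensity)
  if (any(intensity < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative (0 encodes missing)")
  }
  n <- nrow(intensity)
  if (length(injection_order) != n || length(is_qc) != n) {
    stop("'injection_order' and 'is_qc' must have one entry per sample row")
  }
  if (anyDuplicated(injection_order)) {
    stop("injection orders must be unique")
  }
  if (is.null(rownames(intensity))) {
    rownames(intensity) <- sprintf("S%03d", seq_len(n))
  }
  if (is.null(colnames(intensity))) {
    colnames(intensity) <- sprintf("M%04d", seq_len(ncol(intensity)))
  }
  if (!is.null(annotation)) {
    stopifnot(is.data.frame(annotation), "feature_id" %in% names(annotation))
    annotation <- annotation[match(colnames(intensity),
                                   annotation$feature_id), , drop = FALSE]
  }
  structure(
    list(intensity = intensity,
         injection_order = as.integer(injection_order),
         is_qc = as.logical(is_qc),
         annotation = annotation),
    class = "metabo_matrix"
  )
}

#' @export
print.metabo_matrix <- function(x, ...) {
  cat(sprintf("metabo_matrix: %d samples (%d QC) x %d features\n",
              nrow(x$intensity), sum(x$is_qc), ncol(x$intensity)))
  if (!is.null(x$annotation)) {
    lv <- x$annotation$msi_level
    cat(sprintf("  annotated (MSI level 1-2): %d features\n",
                sum(lv %in% c(1, 2))))
  }
  invisible(x)
}

#' @export
dim.metabo_matrix <- function(x) dim(x$intensity)

# Subset a metabo_matrix by feature index/names, keeping metadata aligned.
subset_features <- function(m, keep) {
  m$intensity <- m$intensity[, keep, drop = FALSE]
  if (!is.null(m$annotation)) {
    m$annotation <- m$annotation[
      match(colnames(m$intensity), m$annotation$feature_id), , drop = FALSE]
  }
  m
}

# Non-QC (study sample) part of the intensity matrix.
study_intensity <- function(m) m$intensity[!m$is_qc, , drop = FALSE]

# QC part of the intensity matrix.
qc_intensity <- function(m) m$intensity[m$is_qc, , drop = FALSE]
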