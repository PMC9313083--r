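#' Construct a per-study expression dataset
#'
#' Container for one study's log2 expression matrix together with its
#' case/control labels and a disease-group tag. This is the unit the
#' meta-analysis consumes: each dataset is analysed separately and only its
#' per-gene calls are compared across datasets, so no cross-dataset
#' normalisation is performed (or needed).
#'
#' @param values Numeric matrix, genes in rows, samples in columns, log2
#'   intensity units. Row and column names are required and must be unique.
#' @param sample_class Character vector, one of `"case"`/`"control"` per
#'   sample, in column order (or named by sample id).
#' @param dataset_id Single string identifying the study.
#' @param disease_group One of `"LC"`, `"BC"`, `"LK"`, `"OTHER"`.
#'
#' @details Values on an apparently linear scale (any entry above 30) trigger
#' a warning but are never transformed silently. At least two case and two
#' control samples are required, and all values must be finite.
#'
#' @return An object of class `expression_dataset`.
#' @export
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- expression_dataset(m, c("control", "control", "case", "case"),
#'                          "toy", "LC")
#' dim(ds)
expression_dataset <- function(values, sample_class, dataset_id,
                               disease_group = c("LC", "BC", "LK", "OTHER")) {
  disease_group <- match.arg(disease_group)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids in expression matrix", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("expression values must all be finite", call. = FALSE)
  }
  if (!is.null(names(sample_class))) {
    missing_lab <- setdiff(colnames(values), names(sample_class))
    if (length(missing_lab)) {
      stop("samples without a class label: ",
           paste(missing_lab, collapse = ", "), call. = FALSE)
    }
    sample_class <- unname(sample_class[colnames(values)])
  }
  if (length(sample_class) != ncol(values)) {
    stop("`sample_class` must label every sample", call. = FALSE)
  }
  if (!all(sample_class %in% c("case", "control"))) {
    stop("sample classes must be 'case' or 'control'", call. = FALSE)
  }
  if (sum(sample_class == "case") < 2 || sum(sample_class == "control") < 2) {
    stop("need at least 2 case and 2 control samples", call. = FALSE)
  }
  if (any(values > 30)) {
    warning("values > 30 detected; matrix may be on a linear, not log2, scale",
            call. = FALSE)
  }
  structure(
    list(values = values,
         sample_class = sample_class,
         dataset_id = as.character(dataset_id),
         disease_group = disease_group),
    class = "expression_dataset"
  )
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s [%s]: %d genes x %d samples (%d case / %d control)\n",
              x$dataset_id, x$disease_group, nrow(x$values), ncol(x$values),
              sum(x$sample_class == "case"), sum(x$sample_class == "control")))
  invisible(x)
}

#' Gene ids of an expression dataset
#' @param ds An `expression_dataset`.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(ds) rownames(ds$values)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Long-form view of an expression dataset
#'
#' @param x An `expression_dataset`.
#' @param ... Unused.
#' @return A tibble with one row per (gene, sample) cell: `dataset_id`,
#'   `disease_group`, `gene_id`, `sample_id`, `class`, `value`.
#' @export
tidy.expression_dataset <- function(x, ...) {
  tibble::tibble(
    dataset_id = x$dataset_id,
    disease_group = x$disease_group,
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    class = rep(x$sample_class, each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' Read a per-study expression matrix from TSV
#'
#' Expects a UTF-8 TSV whose first column holds feature (gene or probe) ids
#' and whose first row holds sample ids; all remaining cells numeric. Rows
#' containing any non-finite value are dropped with a message giving the
#' count.
#'
#' @param path Path to the TSV file.
#' @param dataset_id,disease_group Passed to [expression_dataset()].
#' @param class_labels Either a named character vector (`sample_id -> class`)
#'   or a two-column data frame (`sample_id`, `class`) covering every sample.
#' @return An `expression_dataset`.
#' @export
read_expression_matrix <- function(path, dataset_id, disease_group,
                                   class_labels) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  if (ncol(raw) < 2) stop("expression TSV needs an id column plus samples",
                          call. = FALSE)
  ids <- raw[[1]]
  num <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  if (nrow(raw) == 1L) num <- matrix(num, nrow = 1)
  bad <- which(!is.finite(num) & !(raw[-1] == "NA" | raw[-1] == "" |
                                     is.na(raw[-1])), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("malformed numeric cell at row '%s', column '%s'",
                 ids[bad[1, 1]], colnames(raw)[-1][bad[1, 2]]), call. = FALSE)
  }
  keep <- apply(num, 1, function(r) all(is.finite(r)))
  if (any(!keep)) {
    message(sum(!keep), " row(s) with non-finite values dropped")
  }
  num <- num[keep, , drop = FALSE]
  rownames(num) <- ids[keep]
  colnames(num) <- colnames(raw)[-1]
  if (is.data.frame(class_labels)) {
    class_labels <- stats::setNames(as.character(class_labels[[2]]),
                                    as.character(class_labels[[1]]))
  }
  expression_dataset(num, class_labels, dataset_id, disease_group)
}

#' Write an expression dataset as TSV
#'
#' Round-trips with [read_expression_matrix()]: first column `gene_id`, then
#' one column per sample. Values are written at full precision.
#'
#' @param ds An `expression_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(ds, path) {
  df <- data.frame(gene_id = rownames(ds$values), ds$values,
                   check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
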