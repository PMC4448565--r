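#' @title Expression-matrix and label file formats
#'
#' @description
#' Readers and writers for the plain TSV/CSV layout (gene ids in the first
#' column, sample names in the header) and for the Broad dialects used by
#' the Global Cancer Map distribution: GCT (versioned matrix), RES (matrix
#' with per-value Absent/Present call columns) and CLS (class labels).
#' Parsers fail fast with line numbers: a wrapper selection run has no
#' imputation step, so a missing or non-numeric cell is an input error,
#' never something to coerce silently.  Duplicate gene identifiers are
#' rejected because chromosomes index genes positionally.
#'
#' @name data_io
NULL

split_fields <- function(line, sep) strsplit(line, sep, fixed = TRUE)[[1]]

parse_numeric_row <- function(cells, line_no, first_col) {
  vals <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(vals) | cells == "")
  if (length(bad)) {
    b <- bad[1]
    stop("line ", line_no, ", column ", first_col + b - 1,
         ": non-numeric or missing expression value ",
         deparse(cells[b]), call. = FALSE)
  }
  vals
}

#' Read an expression matrix
#'
#' @param path Path to the matrix file.
#' @param format One of `"tsv"`, `"csv"`, `"gct"`, `"res"`.
#' @param samples_as_rows For tsv/csv only: set `TRUE` when the file stores
#'   samples in rows and genes in columns; the matrix is transposed to the
#'   canonical genes-by-samples orientation.
#' @return An unlabeled `expression_dataset` (attach labels with
#'   [set_labels()]).
#' @export
read_expression <- function(path, format = c("tsv", "csv", "gct", "res"),
                            samples_as_rows = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  switch(format,
         tsv = read_delim_matrix(lines, "\t", samples_as_rows),
         csv = read_delim_matrix(lines, ",", samples_as_rows),
         gct = read_gct(lines),
         res = read_res(lines))
}

read_delim_matrix <- function(lines, sep, samples_as_rows) {
  if (length(lines) < 2L) stop("matrix file needs a header and data rows")
  header <- split_fields(lines[1], sep)
  col_names <- header[-1]
  n_col <- length(col_names)
  ids <- character(length(lines) - 1L)
  M <- matrix(NA_real_, length(lines) - 1L, n_col)
  for (i in seq_along(ids)) {
    cells <- split_fields(lines[i + 1L], sep)
    if (length(cells) != n_col + 1L)
      stop("line ", i + 1L, ": expected ", n_col + 1L, " fields, found ",
           length(cells), call. = FALSE)
    ids[i] <- cells[1]
    M[i, ] <- parse_numeric_row(cells[-1], i + 1L, 2L)
  }
  rownames(M) <- ids
  colnames(M) <- col_names
  if (samples_as_rows) M <- t(M)
  expression_dataset(M, require_labels = FALSE)
}

read_gct <- function(lines) {
  if (length(lines) < 4L || !startsWith(lines[1], "#1.2"))
    stop("not a GCT 1.2 file: expected '#1.2' on line 1", call. = FALSE)
  dims <- suppressWarnings(as.integer(split_fields(lines[2], "\t")))
  if (length(dims) < 2L || anyNA(dims[1:2]))
    stop("line 2: expected '<n_genes>\\t<n_samples>'", call. = FALSE)
  header <- split_fields(lines[3], "\t")
  if (length(header) < 3L || tolower(header[1]) != "name")
    stop("line 3: expected 'Name\\tDescription\\t<samples...>'",
         call. = FALSE)
  samples <- header[-(1:2)]
  if (length(samples) != dims[2])
    stop("line 3: header lists ", length(samples),
         " samples but line 2 declares ", dims[2], call. = FALSE)
  body <- lines[-(1:3)]
  if (length(body) != dims[1])
    stop("found ", length(body), " data rows but line 2 declares ", dims[1],
         call. = FALSE)
  ids <- character(dims[1])
  M <- matrix(NA_real_, dims[1], dims[2])
  for (i in seq_len(dims[1])) {
    cells <- split_fields(body[i], "\t")
    if (length(cells) != dims[2] + 2L)
      stop("line ", i + 3L, ": expected ", dims[2] + 2L, " fields, found ",
           length(cells), call. = FALSE)
    ids[i] <- cells[1]
    M[i, ] <- parse_numeric_row(cells[-(1:2)], i + 3L, 3L)
  }
  rownames(M) <- ids
  colnames(M) <- samples
  expression_dataset(M, require_labels = FALSE)
}

read_res <- function(lines) {
  if (length(lines) < 4L)
    stop("not a RES file: too short", call. = FALSE)
  header <- split_fields(lines[1], "\t")
  if (length(header) < 3L || tolower(header[1]) != "description")
    stop("line 1: expected 'Description\\tAccession\\t<samples...>'",
         call. = FALSE)
  # sample names occupy every second field after the two id columns (a
  # blank call-column placeholder follows each name)
  rest <- header[-(1:2)]
  samples <- rest[rest != ""]
  n_genes_declared <- suppressWarnings(as.integer(lines[3]))
  if (is.na(n_genes_declared))
    stop("line 3: expected the number of genes", call. = FALSE)
  body <- lines[-(1:3)]
  if (length(body) != n_genes_declared)
    stop("found ", length(body), " data rows but line 3 declares ",
         n_genes_declared, call. = FALSE)
  n_s <- length(samples)
  ids <- character(n_genes_declared)
  M <- matrix(NA_real_, n_genes_declared, n_s)
  for (i in seq_len(n_genes_declared)) {
    cells <- split_fields(body[i], "\t")
    if (length(cells) < 2L + 2L * n_s)
      stop("line ", i + 3L, ": expected ", 2L + 2L * n_s,
           " fields (value/call pairs), found ", length(cells),
           call. = FALSE)
    ids[i] <- cells[2] # accession column carries the gene id
    vals <- cells[2L + 2L * seq_len(n_s) - 1L] # skip the call columns
    M[i, ] <- parse_numeric_row(vals, i + 3L, 3L)
  }
  rownames(M) <- ids
  colnames(M) <- samples
  expression_dataset(M, require_labels = FALSE)
}

#' Write an expression matrix
#'
#' @param x An `expression_dataset` or a genes-by-samples numeric matrix.
#' @param path Output path.
#' @param format One of `"tsv"`, `"csv"`, `"gct"`, `"res"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "csv", "gct", "res")) {
  format <- match.arg(format)
  M <- if (inherits(x, "expression_dataset")) x$matrix else as.matrix(x)
  if (is.null(colnames(M))) colnames(M) <- paste0("S", seq_len(ncol(M)))
  ids <- rownames(M)
  fmt_vals <- function(v) format(v, digits = 15, trim = TRUE,
                                 scientific = FALSE)
  lines <- switch(format,
    tsv = c(paste(c("gene_id", colnames(M)), collapse = "\t"),
            vapply(seq_len(nrow(M)), function(i)
              paste(c(ids[i], fmt_vals(M[i, ])), collapse = "\t"),
              character(1))),
    csv = c(paste(c("gene_id", colnames(M)), collapse = ","),
            vapply(seq_len(nrow(M)), function(i)
              paste(c(ids[i], fmt_vals(M[i, ])), collapse = ","),
              character(1))),
    gct = c("#1.2",
            paste(nrow(M), ncol(M), sep = "\t"),
            paste(c("Name", "Description", colnames(M)), collapse = "\t"),
            vapply(seq_len(nrow(M)), function(i)
              paste(c(ids[i], "na", fmt_vals(M[i, ])), collapse = "\t"),
              character(1))),
    res = c(paste(c("Description", "Accession",
                    as.vector(rbind(colnames(M), ""))), collapse = "\t"),
            paste(rep("", 2L + 2L * ncol(M)), collapse = "\t"),
            as.character(nrow(M)),
            vapply(seq_len(nrow(M)), function(i)
              paste(c("na", ids[i],
                      as.vector(rbind(fmt_vals(M[i, ]), "P"))),
                    collapse = "\t"),
              character(1))))
  writeLines(lines, path)
  invisible(path)
}

#' Read per-sample class labels
#'
#' The CLS dialect has a `<n_samples> <n_classes> 1` header, a `#`-prefixed
#' class-name line, and a final line of labels.  Numeric label tokens are
#' mapped to class names by order of first appearance (the first distinct
#' token on the label line is the first name on the `#` line); string
#' tokens are used directly.
#'
#' @param path Path to the label file.
#' @param format `"cls"` or `"plain"` (one label per line).
#' @param n_samples Optional expected sample count; mismatch is an error.
#' @return Character vector of labels.
#' @export
read_labels <- function(path, format = c("cls", "plain"), n_samples = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[lines != ""]
  labels <- if (format == "plain") {
    lines
  } else {
    if (length(lines) < 3L)
      stop("CLS file needs 3 lines (header, names, labels)", call. = FALSE)
    hdr <- suppressWarnings(as.integer(strsplit(lines[1], "[ \t]+")[[1]]))
    if (length(hdr) < 2L || anyNA(hdr[1:2]))
      stop("line 1: expected '<n_samples> <n_classes> 1'", call. = FALSE)
    if (!startsWith(lines[2], "#"))
      stop("line 2: expected '# <class names...>'", call. = FALSE)
    names_ <- strsplit(sub("^#[ \t]*", "", lines[2]), "[ \t]+")[[1]]
    toks <- strsplit(lines[3], "[ \t]+")[[1]]
    if (length(toks) != hdr[1])
      stop("label line has ", length(toks), " entries but header declares ",
           hdr[1], call. = FALSE)
    if (length(names_) != hdr[2])
      stop("name line has ", length(names_),
           " classes but header declares ", hdr[2], call. = FALSE)
    if (all(grepl("^-?[0-9]+$", toks))) {
      names_[match(toks, unique(toks))]
    } else {
      unknown <- setdiff(unique(toks), names_)
      if (length(unknown))
        stop("label(s) not on the name line: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      toks
    }
  }
  if (!is.null(n_samples) && length(labels) != n_samples)
    stop("label count (", length(labels),
         ") does not match sample count (", n_samples, ")")
  labels
}

#' Write labels in CLS or plain format
#'
#' @param labels Character vector of class labels.
#' @param path Output path.
#' @param format `"cls"` or `"plain"`.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, format = c("cls", "plain")) {
  format <- match.arg(format)
  labels <- as.character(labels)
  lines <- if (format == "plain") labels else {
    classes <- unique(labels)
    c(paste(length(labels), length(classes), 1),
      paste("#", paste(classes, collapse = " ")),
      paste(labels, collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load a labeled dataset from a matrix file plus a label file
#'
#' @param expression_path,labels_path Input files.
#' @param format Matrix format (see [read_expression()]).
#' @param labels_format Label format (see [read_labels()]).
#' @param samples_as_rows Passed to [read_expression()].
#' @return A labeled `expression_dataset`.
#' @export
read_dataset <- function(expression_path, labels_path,
                         format = c("tsv", "csv", "gct", "res"),
                         labels_format = c("cls", "plain"),
                         samples_as_rows = FALSE) {
  ds <- read_expression(expression_path, match.arg(format), samples_as_rows)
  labels <- read_labels(labels_path, match.arg(labels_format),
                        n_samples = ncol(ds$matrix))
  set_labels(ds, labels)
}

#' Write a selection report: gene list plus JSON run record
#'
#' Produces `genes.tsv` (rank and gene id, in order of appearance on the
#' chromosome) and `report.json` (mean and per-split accuracies, selected
#' count, fitness, and the echoed configuration and seeds so the run can
#' be replayed exactly).
#'
#' @param gene_ids Selected gene identifiers.
#' @param fitness A `fitness_result` for the selection.
#' @param out_dir Output directory (created if absent).
#' @param config Arbitrary configuration echo stored under `"config"`.
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_gene_list <- function(gene_ids, fitness, out_dir, config = list()) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  genes_path <- file.path(out_dir, "genes.tsv")
  report_path <- file.path(out_dir, "report.json")
  writeLines(c("rank\tgene_id",
               paste(seq_along(gene_ids), gene_ids, sep = "\t")),
             genes_path)
  report <- list(
    n_selected = fitness$n_selected,
    mean_accuracy = fitness$mean_accuracy,
    fitness = fitness$fitness,
    per_split_accuracies = fitness$per_split_accuracies,
    gene_ids = gene_ids,
    config = config)
  jsonlite::write_json(report, report_path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(genes = genes_path, report = report_path))
}
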