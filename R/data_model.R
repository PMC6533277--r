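# Core data containers and tab-delimited readers/writers.
#
# The pipeline works on three plain-text inputs: a log10-scale expression
# matrix (genes x samples, TSV), a sample metadata table describing the
# tetrad-matched design, and gene sets in GMT format. Values are required to
# be complete and finite at this layer; users of real data must pre-impute.

REGION_LEVELS    <- c("DLPFC", "HIP", "STR")
DIAGNOSIS_LEVELS <- c("CTRL", "SCZ", "BD", "MDD")
SEX_LEVELS       <- c("M", "F")
TOBACCO_LEVELS   <- c("yes", "no")
MANNER_LEVELS    <- c("accidental", "natural", "suicide")

SAMPLE_TABLE_COLUMNS <- c("subject_id", "tetrad_id", "region", "diagnosis",
                          "age", "sex", "tobacco", "manner_of_death",
                          "pmi", "ph")

#' Construct a validated sample metadata table
#'
#' One row per profiled sample (subject within region). Each tetrad is a
#' matched quartet holding at most one subject per diagnosis; a subject
#' carries identical covariates across regions.
#'
#' @param df A data.frame with columns `subject_id`, `tetrad_id`, `region`,
#'   `diagnosis`, `age`, `sex`, `tobacco`, `manner_of_death`, `pmi`, `ph`.
#' @return The validated data.frame with class `"sample_table"`.
#' @export
sample_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SAMPLE_TABLE_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop_listing("sample table is missing required columns", missing_cols)

  check_levels <- function(col, levels) {
    bad <- setdiff(unique(as.character(df[[col]])), levels)
    if (length(bad) > 0)
      stop(sprintf("unknown %s level(s) %s; allowed: %s", col,
                   paste(sQuote(bad), collapse = ", "),
                   paste(levels, collapse = ", ")), call. = FALSE)
  }
  check_levels("region", REGION_LEVELS)
  check_levels("diagnosis", DIAGNOSIS_LEVELS)
  check_levels("sex", SEX_LEVELS)
  check_levels("tobacco", TOBACCO_LEVELS)
  check_levels("manner_of_death", MANNER_LEVELS)

  for (col in c("age", "pmi", "ph")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(!is.finite(v)))
      stop(sprintf("column %s must be finite numeric", col), call. = FALSE)
    df[[col]] <- v
  }

  # One subject per (tetrad, diagnosis): a tetrad is a matched quartet.
  key <- paste(df$tetrad_id, df$diagnosis)
  n_subj <- tapply(df$subject_id, key, function(s) length(unique(s)))
  if (any(n_subj > 1))
    stop_listing("tetrad has more than one subject of the same diagnosis",
                 names(n_subj)[n_subj > 1])
  dup <- duplicated(paste(df$tetrad_id, df$diagnosis, df$region))
  if (any(dup))
    stop_listing("duplicated (tetrad, diagnosis, region) rows",
                 paste(df$tetrad_id, df$diagnosis, df$region)[dup])

  # A subject's covariates do not change across regions.
  cov_sig <- paste(df$tetrad_id, df$diagnosis, df$age, df$sex, df$tobacco,
                   df$manner_of_death, df$pmi, df$ph)
  n_sig <- tapply(cov_sig, df$subject_id, function(s) length(unique(s)))
  if (any(n_sig > 1))
    stop_listing("subject has inconsistent covariates across rows",
                 names(n_sig)[n_sig > 1])

  class(df) <- c("sample_table", "data.frame")
  df
}

#' Bind an expression matrix to its sample metadata
#'
#' @param expr Numeric matrix, genes in rows (log10 scale), samples in
#'   columns; dimnames required, unique, no missing or non-finite values.
#' @param metadata A [sample_table()] (or coercible data.frame) whose
#'   `subject_id` values cover `colnames(expr)` exactly once each.
#' @return An object of class `"expression_study"`: a list with elements
#'   `expr`, `gene_ids`, `sample_ids`, `metadata` (rows ordered as samples).
#' @export
expression_study <- function(expr, metadata) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expr must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expr must carry gene (row) and sample (column) names", call. = FALSE)
  if (anyDuplicated(rownames(expr)))
    stop_listing("duplicated gene identifier(s)",
                 rownames(expr)[duplicated(rownames(expr))])
  if (anyDuplicated(colnames(expr)))
    stop_listing("duplicated sample identifier(s)",
                 colnames(expr)[duplicated(colnames(expr))])
  if (any(!is.finite(expr)))
    stop("expression values must be finite; missing values are not allowed",
         call. = FALSE)
  if (!inherits(metadata, "sample_table")) metadata <- sample_table(metadata)
  idx <- match(colnames(expr), metadata$subject_id)
  if (any(is.na(idx)))
    stop_listing("samples absent from metadata",
                 colnames(expr)[is.na(idx)])
  if (anyDuplicated(metadata$subject_id))
    stop("metadata must have exactly one row per sample; got repeated subject_id (subset to one region first)",
         call. = FALSE)
  structure(list(expr = expr,
                 gene_ids = rownames(expr),
                 sample_ids = colnames(expr),
                 metadata = metadata[idx, , drop = FALSE]),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d samples\n",
              nrow(x$expr), ncol(x$expr)))
  cat("regions:", paste(unique(x$metadata$region), collapse = ", "), "\n")
  cat("diagnoses:", paste(table(x$metadata$diagnosis)[
    unique(as.character(x$metadata$diagnosis))], collapse = "/"),
    paste0("(", paste(unique(as.character(x$metadata$diagnosis)),
                      collapse = "/"), ")"), "\n")
  invisible(x)
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' First column holds gene identifiers, header row holds sample identifiers.
#' Duplicated identifiers and non-numeric cells are rejected with the
#' offending coordinates.
#'
#' @param path Path to a tab-delimited text file.
#' @return Numeric matrix with gene row names and sample column names.
#' @export
read_expression_matrix <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("expression file needs a gene column plus at least one sample column")
  genes <- raw[[1]]
  if (anyDuplicated(genes))
    stop_listing("duplicated gene identifier(s)", genes[duplicated(genes)])
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples))
    stop_listing("duplicated sample identifier(s)", samples[duplicated(samples)])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric value %s at gene row %s, sample column %s",
                 sQuote(vals[bad[1, 1], bad[1, 2]]), genes[bad[1, 1]],
                 samples[bad[1, 2]]), call. = FALSE)
  if (any(is.na(num)))
    stop("missing values are not allowed in the expression matrix", call. = FALSE)
  dimnames(num) <- list(genes, samples)
  num
}

#' Write an expression matrix as TSV at full double precision
#'
#' Values are written with 17 significant digits so a write/read round trip
#' is bitwise exact.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat),
                   apply(mat, 2, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' @param path Path to a tab-delimited file with the columns listed in
#'   [sample_table()].
#' @return A validated `sample_table`.
#' @export
read_sample_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  sample_table(df)
}

#' Write a sample metadata table as TSV
#'
#' @param meta A `sample_table` (or data.frame with the same columns).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample_table <- function(meta, path) {
  out <- as.data.frame(meta)[, SAMPLE_TABLE_COLUMNS]
  for (col in c("age", "pmi", "ph")) out[[col]] <- sprintf("%.17g", out[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene identifiers.
#'   Duplicates within a set are dropped.
#' @param universe Optional explicit background gene list; when supplied,
#'   every scored set is intersected with it before testing.
#' @return Object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) && length(sets) > 0)
    stop("gene sets must be named", call. = FALSE)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(list(sets = sets,
                 universe = if (is.null(universe)) NULL else unique(as.character(universe))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %s)\n", length(x$sets),
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-") else "-"))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then one or more member genes, all
#' tab-separated. Duplicate members within a set are de-duplicated with a
#' message.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(gene_set_collection(list()))
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has %d field(s); need set name, description and at least one gene",
                   i, length(fields)), call. = FALSE)
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members))
      message(sprintf("GMT set %s: %d duplicate member(s) dropped", fields[1],
                      sum(duplicated(members))))
    sets[[fields[1]]] <- unique(members)
  }
  gene_set_collection(sets)
}

#' Write a gene-set collection in GMT format
#'
#' @param gsc A [gene_set_collection()].
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gsc, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(gsc$sets))
  lines <- vapply(seq_along(gsc$sets), function(i) {
    paste(c(names(gsc$sets)[i], descriptions[i], gsc$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
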