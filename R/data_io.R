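## Readers/writers for the tab-delimited formats the pipeline touches, plus
## the validators that turn raw files into the shared domain containers:
## an expression matrix (genes x samples), a gene set collection (named list)
## and a clinical table (data.frame).

#' Validate a genes-by-samples expression matrix
#'
#' Checks the invariants every downstream stage relies on: unique gene and
#' sample identifiers, all values finite and non-negative (the pipeline
#' assumes RSEM-like normalized expression, never raw counts), and at least
#' two genes and two samples.
#'
#' @param mat Numeric matrix with gene IDs as rownames and sample IDs as
#'   colnames.
#' @return The validated matrix, invisibly unchanged.
#' @export
validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix must carry gene rownames and sample colnames")
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("expression matrix needs at least 2 genes and 2 samples")
  dup_g <- rownames(mat)[duplicated(rownames(mat))]
  if (length(dup_g))
    stop("duplicated gene ID(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- colnames(mat)[duplicated(colnames(mat))]
  if (length(dup_s))
    stop("duplicated sample ID(s): ", paste(unique(dup_s), collapse = ", "))
  bad <- which(!is.finite(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-finite or negative expression value for gene '%s' in sample '%s'",
      rownames(mat)[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]]))
  }
  invisible(mat)
}

#' Read a genes-by-samples expression TSV
#'
#' The file must have a header row of sample IDs and gene IDs in the first
#' column. Values are RSEM-like non-negative normalized expression; the
#' reader validates but never re-normalizes. Row and column order are
#' preserved.
#'
#' @param path Path to a tab-delimited text file.
#' @return A validated numeric matrix (genes x samples).
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("expression TSV needs a gene column and >= 2 samples")
  genes <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  non_num <- !vapply(vals, is.numeric, logical(1L))
  if (any(non_num)) {
    smp <- names(vals)[which(non_num)[1L]]
    col <- vals[[which(non_num)[1L]]]
    row <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
    stop(sprintf("non-numeric expression value for gene '%s' in sample '%s'",
                 genes[if (is.na(row)) 1L else row], smp))
  }
  mat <- as.matrix(vals)
  rownames(mat) <- genes
  validate_expression_matrix(mat)
  mat
}

#' Write an expression matrix as TSV
#'
#' @param mat Genes-by-samples numeric matrix.
#' @param path Output path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene set file
#'
#' Standard GMT: one set per line, fields tab-separated as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are removed with a warning. Empty trailing fields are ignored.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene IDs; the per-set
#'   descriptions are attached as the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    nm <- fields[[1L]]
    genes <- fields[-c(1L, 2L)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': duplicate gene IDs removed", nm))
      genes <- unique(genes)
    }
    if (nm %in% names(sets))
      stop(sprintf("GMT set name '%s' duplicated at line %d", nm, i))
    sets[[nm]] <- genes
    desc[[nm]] <- fields[[2L]]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a gene set collection as GMT
#'
#' @param sets Named list of gene-ID character vectors.
#' @param path Output path.
#' @param description Optional named character vector of per-set
#'   descriptions; defaults to the set name.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(description) && nm %in% names(description))
      description[[nm]] else nm
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

.required_clinical_cols <- c("sample_id", "os_days", "event", "age_years",
                             "sex", "stage", "egfr_status", "kras_status",
                             "tissue")

#' Collapse sub-staged labels to stage I-IV
#'
#' Labels such as "IA"/"IIIB" collapse to their Roman prefix. Anything that
#' does not start with I/II/III/IV becomes missing (NA) with a warning.
#'
#' @param stage Character vector of stage labels.
#' @return Factor with levels I, II, III, IV (NA for unparseable values).
#' @export
collapse_stage <- function(stage) {
  stage <- toupper(trimws(as.character(stage)))
  out <- rep(NA_character_, length(stage))
  ## longest prefix first so "IIIA" maps to III, not I
  for (lev in c("IV", "III", "II", "I")) {
    hit <- is.na(out) & startsWith(stage, lev)
    out[hit] <- lev
  }
  sub_staged <- !is.na(out) & out != stage & !is.na(stage)
  if (any(sub_staged))
    warning(sprintf("%d sub-staged label(s) collapsed to stage I-IV",
                    sum(sub_staged)))
  unparseable <- is.na(out) & !is.na(stage) & nzchar(stage) & stage != "NA"
  if (any(unparseable))
    warning(sprintf("%d unparseable stage label(s) set to missing",
                    sum(unparseable)))
  factor(out, levels = c("I", "II", "III", "IV"))
}

#' Read and validate a clinical TSV
#'
#' Required columns: sample_id, os_days, event, age_years, sex, stage,
#' egfr_status, kras_status, tissue; an optional paired_sample_id column
#' links tumor and normal tissue from the same patient. Unknown columns are
#' passed through. Sub-staged labels (IA, IIB, ...) collapse to I-IV.
#'
#' @param path Path to a tab-delimited clinical table.
#' @return A data.frame with typed columns.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  missing_cols <- setdiff(.required_clinical_cols, names(df))
  if (length(missing_cols))
    stop("clinical table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in clinical table: ",
         df$sample_id[duplicated(df$sample_id)][1L])
  df$os_days <- as.numeric(df$os_days)
  if (any(!is.na(df$os_days) & df$os_days < 0))
    stop("os_days must be >= 0 (sample ",
         df$sample_id[which(df$os_days < 0)[1L]], ")")
  df$event <- as.logical(df$event)
  df$age_years <- as.numeric(df$age_years)
  df$stage <- collapse_stage(df$stage)
  df$tissue <- tolower(as.character(df$tissue))
  if (!all(df$tissue %in% c("tumor", "normal")))
    stop("tissue must be 'tumor' or 'normal'")
  for (col in c("egfr_status", "kras_status")) {
    v <- tolower(as.character(df[[col]]))
    ok <- v %in% c("mutation", "non-mutation", "unknown") | is.na(v)
    if (any(!ok)) {
      warning(sprintf("%d unparseable %s value(s) set to 'unknown'",
                      sum(!ok), col))
      v[!ok] <- "unknown"
    }
    df[[col]] <- factor(v, levels = c("non-mutation", "mutation", "unknown"))
  }
  if ("paired_sample_id" %in% names(df)) {
    pid <- as.character(df$paired_sample_id)
    has <- !is.na(pid) & nzchar(pid)
    if (any(has)) {
      idx <- match(pid[has], df$sample_id)
      if (anyNA(idx))
        stop("paired_sample_id references unknown sample: ",
             pid[has][which(is.na(idx))[1L]])
      same <- df$tissue[has] == df$tissue[idx]
      if (any(same))
        stop("paired_sample_id must link samples of opposite tissue (sample ",
             df$sample_id[has][which(same)[1L]], ")")
    }
    df$paired_sample_id <- pid
  }
  df
}

#' Write a results table deterministically
#'
#' Writes a TSV with header, floats at 6 significant digits, rows sorted by
#' the first (primary-key) column so repeated runs are byte-identical.
#'
#' @param records A data.frame (possibly empty) whose rows share a schema.
#' @param path Output path.
#' @export
write_results_table <- function(records, path) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) > 1L)
    records <- records[order(records[[1L]]), , drop = FALSE]
  is_dbl <- vapply(records, is.double, logical(1L))
  for (j in which(is_dbl)) {
    records[[j]] <- formatC(signif(records[[j]], 6L), format = "g",
                            digits = 6L)
    records[[j]][records[[j]] %in% c("NA", " NA")] <- NA
  }
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
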