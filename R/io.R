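# File formats: tab-separated with header (expression, sample sheet, probe
# map, annotations, network, results), comma-separated for clinical/Ct
# tables, GMT for gene sets, JSON for truth/reports.  Readers validate and
# fail with the offending record; writers round-trip exactly.

read_tsv_checked <- function(path, required, id_col = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(basename(path), ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(id_col) && anyDuplicated(df[[id_col]])) {
    dup <- df[[id_col]][duplicated(df[[id_col]])][1]
    stop(basename(path), ": duplicate ", id_col, " '", dup, "'",
         call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an expression matrix as TSV
#'
#' First column `probe_id` (or any identifier), one column per sample.
#' Missing or nonpositive values fail at load (linear scale expected).
#'
#' @param path file path.
#' @param scale scale tag to attach on read ("linear" or "log2").
#' @return numeric matrix with a scale attribute.
#' @export
read_expression_tsv <- function(path, scale = "linear") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop(basename(path), ": no sample columns", call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop(basename(path), ": duplicate row id '",
         ids[duplicated(ids)][1], "'", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop(basename(path), ": non-numeric cell", call. = FALSE)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(basename(path), ": missing value at row ", ids[bad[1]],
         ", column ", colnames(m)[bad[2]], call. = FALSE)
  }
  if (scale == "linear" && any(m <= 0)) {
    stop(basename(path), ": nonpositive intensity on the linear scale",
         call. = FALSE)
  }
  rownames(m) <- ids
  set_expr_scale(m, scale)
}

#' @rdname read_expression_tsv
#' @param matrix matrix to write (row names become the first column).
#' @param id_name header of the identifier column.
#' @export
write_expression_tsv <- function(matrix, path, id_name = "probe_id") {
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  write_tsv(df, path)
}

#' Read / write the sample sheet (sample_id, group, sex, batch)
#' @param path file path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  read_tsv_checked(path, c("sample_id", "group", "sex", "batch"),
                   id_col = "sample_id")
}

#' @rdname read_sample_sheet
#' @param samples sample sheet to write.
#' @export
write_sample_sheet <- function(samples, path) write_tsv(samples, path)

#' Read / write the probe-to-gene map (probe_id, gene)
#' @param path file path.
#' @return data.frame.
#' @export
read_probe_map <- function(path) {
  df <- read_tsv_checked(path, c("probe_id", "gene"), id_col = "probe_id")
  df$probe_id <- as.character(df$probe_id)
  df$gene <- as.character(df$gene)
  df
}

#' @rdname read_probe_map
#' @param probe_map map to write.
#' @export
write_probe_map <- function(probe_map, path) write_tsv(probe_map, path)

#' Read / write the gene annotation table (gene, location, type, vascular)
#' @param path file path.
#' @return data.frame with `vascular` coerced to integer 0/1.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_checked(path, c("gene", "location", "type", "vascular"),
                         id_col = "gene")
  df$vascular <- as.integer(df$vascular)
  df
}

#' @rdname read_annotations
#' @param annotations table to write.
#' @export
write_annotations <- function(annotations, path) write_tsv(annotations, path)

#' Read / write the signed regulator network (regulator, target, sign)
#' @param path file path.
#' @return data.frame with signs validated to be +1/-1.
#' @export
read_network <- function(path) {
  df <- read_tsv_checked(path, c("regulator", "target", "sign"))
  df$sign <- as.numeric(df$sign)
  check_network(df)
  df
}

#' @rdname read_network
#' @param network edge list to write.
#' @export
write_network <- function(network, path) write_tsv(network, path)

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then the member genes, all
#' tab-separated.  A line with fewer than 3 fields (i.e. no members) is an
#' error naming the line number.
#'
#' @param path file path.
#' @return named list of character vectors; each carries a `description`
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop(basename(path), ": line ", i, " has no member genes",
           call. = FALSE)
    }
    if (parts[1] %in% names(sets)) {
      stop(basename(path), ": duplicate set name '", parts[1], "' (line ",
           i, ")", call. = FALSE)
    }
    members <- parts[-(1:2)]
    attr(members, "description") <- parts[2]
    sets[[parts[1]]] <- members
  }
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors (optional `description`
#'   attributes).
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% "na"
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write the clinical cohort table (CSV)
#' @param path file path.
#' @return data.frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"group" %in% names(df)) {
    stop(basename(path), ": missing 'group' column", call. = FALSE)
  }
  df
}

#' @rdname read_cohort_csv
#' @param cohort table to write.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the long qPCR Ct table (CSV)
#' @param path file path.
#' @return data.frame (sample_id, group, gene, ct).
#' @export
read_ct_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "group", "gene", "ct"), names(df))
  if (length(miss)) {
    stop(basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(df$ct <= 0)) {
    stop(basename(path), ": Ct values must be positive", call. = FALSE)
  }
  df
}

#' @rdname read_ct_csv
#' @param ct table to write.
#' @export
write_ct_csv <- function(ct, path) {
  utils::write.csv(ct, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the truth table / a report bundle as JSON
#' @param x list or data.frame.
#' @param path file path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
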