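#' OTU count table
#'
#' The universal input container: a samples x OTUs matrix of non-negative
#' counts with unique sample and OTU identifiers and an optional taxonomy
#' map (OTU id -> lineage string).
#'
#' @param counts numeric matrix, rows = samples, columns = OTUs.
#' @param sample_ids character vector of unique sample identifiers.
#' @param otu_ids character vector of unique OTU identifiers.
#' @param taxonomy optional named character vector of lineage strings, names
#'   are OTU ids.
#' @param check_integer require integral counts (the raw-count invariant).
#'   Averaged rarefied tables set this to \code{FALSE}.
#' @return an object of class \code{otu_table}: a list with elements
#'   \code{sample_ids}, \code{otu_ids}, \code{counts} (dimnamed matrix) and
#'   \code{taxonomy}.
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts), taxonomy = NULL,
                      check_integer = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(otu_ids))
    stop("sample_ids and otu_ids are required (or set as dimnames)")
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (nrow(counts) != length(sample_ids) || ncol(counts) != length(otu_ids))
    stop("counts dimensions (", nrow(counts), " x ", ncol(counts),
         ") do not match ids (", length(sample_ids), " x ", length(otu_ids), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU ids: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("negative count at sample '", sample_ids[bad[1]], "', OTU '",
         otu_ids[bad[2]], "'")
  }
  if (check_integer) {
    if (any(abs(counts - round(counts)) > 1e-8)) {
      bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
      stop("non-integral count at sample '", sample_ids[bad[1]], "', OTU '",
           otu_ids[bad[2]], "'")
    }
    if (max(counts) <= .Machine$integer.max) storage.mode(counts) <- "integer"
  }
  dimnames(counts) <- list(sample_ids, otu_ids)
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[names(taxonomy) %in% otu_ids]
    if (!length(taxonomy)) taxonomy <- NULL
  }
  structure(list(sample_ids = sample_ids, otu_ids = otu_ids,
                 counts = counts, taxonomy = taxonomy),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table:", length(x$sample_ids), "samples x", length(x$otu_ids),
      "OTUs; total count", sum(x$counts),
      if (!is.null(x$taxonomy)) "; taxonomy present" else "", "\n")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Subset an OTU table by sample and/or OTU ids (or logical/integer index)
#' @param table an \code{otu_table}.
#' @param samples,otus index vectors; \code{NULL} keeps all.
#' @return an \code{otu_table}.
#' @export
subset_otu_table <- function(table, samples = NULL, otus = NULL) {
  stopifnot(inherits(table, "otu_table"))
  m <- table$counts
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  if (!is.null(otus)) m <- m[, otus, drop = FALSE]
  otu_table(m, taxonomy = table$taxonomy, check_integer = FALSE)
}

split_fields <- function(line) strsplit(line, "\t", fixed = TRUE)[[1]]

parse_count_block <- function(lines, path, first_data_line) {
  rows <- lapply(lines, split_fields)
  n_fields <- lengths(rows)
  if (length(unique(n_fields)) > 1) {
    bad <- which(n_fields != n_fields[1])[1]
    stop("ragged row at line ", first_data_line + bad - 1, " of ", path)
  }
  rows
}

#' Read an OTU table from a tab-separated file
#'
#' Two dialects are accepted. \code{plain_tsv}: rows are samples, the first
#' header field names the sample-id column and the remaining header fields
#' are OTU ids. \code{biom_tsv}: the classic BIOM TSV dialect with rows =
#' OTUs, a \code{#OTU ID} header (an optional leading \code{# ...} comment
#' line is skipped), sample columns, and an optional trailing
#' \code{taxonomy} column; the matrix is transposed to the in-memory
#' samples-by-OTUs orientation on read.
#'
#' @param path file path.
#' @param dialect \code{"plain_tsv"} or \code{"biom_tsv"}.
#' @return a validated \code{otu_table}.
#' @export
read_otu_table <- function(path, dialect = c("plain_tsv", "biom_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty file: ", path)
  skipped <- 0L
  if (dialect == "biom_tsv") {
    while (length(lines) && grepl("^#", lines[1]) &&
           !grepl("^#OTU ID", lines[1])) {
      lines <- lines[-1]
      skipped <- skipped + 1L
    }
    if (!length(lines) || !grepl("^#OTU ID", lines[1]))
      stop("malformed biom_tsv header in ", path, ": expected '#OTU ID'")
  }
  header <- split_fields(lines[1])
  body <- lines[-1]
  if (!length(body)) stop("no data rows in ", path)
  rows <- parse_count_block(body, path, first_data_line = skipped + 2L)
  if (any(lengths(rows) != length(header)))
    stop("row width does not match header in ", path)

  parse_num <- function(fields, line_no) {
    x <- suppressWarnings(as.numeric(fields))
    if (anyNA(x))
      stop("non-numeric count '", fields[which(is.na(x))[1]], "' at line ",
           line_no, " of ", path)
    x
  }

  if (dialect == "plain_tsv") {
    otu_ids <- header[-1]
    sample_ids <- vapply(rows, `[`, "", 1L)
    counts <- do.call(rbind, lapply(seq_along(rows), function(i)
      parse_num(rows[[i]][-1], skipped + 1L + i)))
    taxonomy <- NULL
  } else {
    has_tax <- tolower(header[length(header)]) == "taxonomy"
    sample_ids <- header[-1]
    if (has_tax) sample_ids <- sample_ids[-length(sample_ids)]
    otu_ids <- vapply(rows, `[`, "", 1L)
    counts <- do.call(rbind, lapply(seq_along(rows), function(i) {
      f <- rows[[i]][-1]
      if (has_tax) f <- f[-length(f)]
      parse_num(f, skipped + 1L + i)
    }))
    counts <- t(counts)
    taxonomy <- if (has_tax)
      stats::setNames(vapply(rows, function(r) r[length(r)], ""), otu_ids)
  }
  tab <- tryCatch(
    otu_table(counts, sample_ids, otu_ids, taxonomy = taxonomy),
    error = function(e) stop("invalid OTU table in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  tab
}

#' Write an OTU table
#' @param table an \code{otu_table}.
#' @param path output file.
#' @param dialect output dialect, see \code{\link{read_otu_table}}.
#' @export
write_otu_table <- function(table, path, dialect = c("plain_tsv", "biom_tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "otu_table"))
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  if (dialect == "plain_tsv") {
    out <- c(paste(c("sample_id", table$otu_ids), collapse = "\t"),
             vapply(seq_along(table$sample_ids), function(i)
               paste(c(table$sample_ids[i], fmt(table$counts[i, ])),
                     collapse = "\t"), ""))
  } else {
    has_tax <- !is.null(table$taxonomy)
    hdr <- c("#OTU ID", table$sample_ids, if (has_tax) "taxonomy")
    out <- c(paste(hdr, collapse = "\t"),
             vapply(seq_along(table$otu_ids), function(j)
               paste(c(table$otu_ids[j], fmt(table$counts[, j]),
                       if (has_tax) unname(table$taxonomy[table$otu_ids[j]])),
                     collapse = "\t"), ""))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with columns \code{sample_id}, \code{group}, and optionally
#' \code{subject}, \code{timepoint} (integer day, treatment day-0
#' convention) and \code{housing}.
#'
#' @param path file path.
#' @param groups optional declared set of allowed group labels.
#' @return a data.frame with class \code{sample_metadata}.
#' @export
read_sample_metadata <- function(path, groups = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  sample_metadata(df, groups = groups)
}

#' Validate a sample metadata data.frame
#' @param df data.frame with at least \code{sample_id} and \code{group}.
#' @param groups optional allowed group labels.
#' @return the validated data.frame, class \code{sample_metadata}.
#' @export
sample_metadata <- function(df, groups = NULL) {
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("metadata needs 'sample_id' and 'group' columns")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!is.null(groups) && !all(df$group %in% groups))
    stop("group labels outside declared set: ",
         paste(setdiff(df$group, groups), collapse = ", "))
  if ("timepoint" %in% names(df)) df$timepoint <- as.numeric(df$timepoint)
  class(df) <- c("sample_metadata", "data.frame")
  df
}

match_meta <- function(table, meta) {
  i <- match(table$sample_ids, meta$sample_id)
  if (anyNA(i))
    stop("samples missing from metadata: ",
         paste(table$sample_ids[is.na(i)], collapse = ", "))
  meta[i, , drop = FALSE]
}
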