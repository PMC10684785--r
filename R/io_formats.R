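# Tabular IO. Canonical dialect: TSV, UTF-8, '.' decimal. CSV via format =
# "csv". Gene matrices are MAG rows x gene columns; abundance tables are day
# rows x MAG columns; coverage tables are long (day, mag_id, mapped_reads,
# genome_length_bp, total_mapped).

io_sep <- function(format) {
  format <- match.arg(format, c("tsv", "csv"))
  if (format == "tsv") "\t" else ","
}

read_table_checked <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected an id column plus data columns in ", path, call. = FALSE)
  df
}

# coerce the data body of a read data.frame to numeric, reporting the first
# offending cell by row label and column name
body_as_numeric <- function(df, what) {
  ids <- as.character(df[[1L]])
  col_ids <- colnames(df)[-1L]  # before subsetting: `[.data.frame` dedupes names
  body <- df[, -1L, drop = FALSE]
  m <- matrix(NA_real_, nrow(body), ncol(body),
              dimnames = list(ids, col_ids))
  for (j in seq_len(ncol(body))) {
    col <- body[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad)) {
      stop(what, ": non-numeric cell at row '", ids[bad[1L]],
           "', column '", col_ids[j], "' (value '", col[bad[1L]], "')",
           call. = FALSE)
    }
    m[, j] <- num
  }
  m
}

#' Read a MAG-by-gene presence/absence matrix
#'
#' The first column holds MAG identifiers and the header row holds gene
#' identifiers. Cells must parse as numbers; count-valued tables (e.g. gene
#' copy numbers from an annotation pipeline) are binarized as \code{> 0} with
#' a warning, since all downstream computations use presence/absence only.
#'
#' @param path path to a TSV (or CSV, see \code{format}) file.
#' @param format \code{"tsv"} (default) or \code{"csv"}.
#' @return a validated binary integer matrix, row and column order as in the
#'   file.
#' @seealso [write_gene_matrix()], [pairwise_jaccard()]
#' @export
read_gene_matrix <- function(path, format = "tsv") {
  df <- read_table_checked(path, io_sep(format))
  m <- body_as_numeric(df, "gene matrix")
  if (any(m != 0 & m != 1)) {
    warning("gene matrix contains counts; binarizing as presence (> 0)",
            call. = FALSE)
    m[] <- as.numeric(m > 0)
  }
  validate_gene_matrix(m)
}

#' Write a gene-repertoire matrix
#'
#' @param m validated gene matrix (see [validate_gene_matrix()]).
#' @param path output path.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @return invisibly, \code{path}.
#' @export
write_gene_matrix <- function(m, path, format = "tsv") {
  m <- validate_gene_matrix(m)
  write_with_id(m, path, id_name = "mag_id", sep = io_sep(format))
}

#' Read a time-by-MAG relative-abundance table
#'
#' Rows are time points (first column, numeric day), columns are MAGs.
#' Rows must already sum to 1 within 1e-9 unless \code{normalize = TRUE},
#' in which case each row is closed to the simplex by dividing by its sum.
#' Negative cells and all-zero rows are rejected either way.
#'
#' @param path input file.
#' @param normalize close rows to the simplex instead of requiring unit sums.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @return a validated abundance matrix (day rownames, MAG colnames).
#' @export
read_abundance_table <- function(path, normalize = FALSE, format = "tsv") {
  df <- read_table_checked(path, io_sep(format))
  a <- body_as_numeric(df, "abundance table")
  if (any(a < 0)) stop("abundance table contains negative values", call. = FALSE)
  rs <- rowSums(a)
  zero <- which(rs == 0)
  if (length(zero)) {
    stop("all-zero abundance row at day ", rownames(a)[zero[1L]], call. = FALSE)
  }
  if (normalize) a <- a / rs
  validate_abundance_table(a)
}

#' Write an abundance table
#'
#' @param a validated abundance matrix.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @return invisibly, \code{path}.
#' @export
write_abundance_table <- function(a, path, format = "tsv") {
  a <- validate_abundance_table(a)
  write_with_id(a, path, id_name = "day", sep = io_sep(format))
}

#' Read a long-format coverage table
#'
#' Expected columns: \code{day}, \code{mag_id}, \code{mapped_reads},
#' \code{genome_length_bp}, \code{total_mapped}. \code{total_mapped} is the
#' per-day library size (reads mapped to anything, not only to MAGs), so it
#' may exceed the per-day sum of \code{mapped_reads}.
#'
#' @param path input file.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @return a data.frame with the five columns above.
#' @seealso [relative_abundance_from_coverage()]
#' @export
read_coverage_table <- function(path, format = "tsv") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = io_sep(format), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("day", "mag_id", "mapped_reads", "genome_length_bp", "total_mapped")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop("coverage table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[need]
  if (any(df$genome_length_bp <= 0)) stop("genome_length_bp must be positive", call. = FALSE)
  if (any(df$mapped_reads < 0) || any(df$total_mapped < 0)) {
    stop("read counts must be nonnegative", call. = FALSE)
  }
  df
}

#' Write a per-time-point series to TSV
#'
#' One row per time point; undefined values are written as \code{NA}.
#' Numeric cells are written with 15 significant digits so a read/write
#' round trip preserves values well beyond 12 significant digits.
#'
#' @param series a data.frame, e.g. from [overlap_series()] or
#'   [dynamics_series()].
#' @param path output path.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @return invisibly, \code{path}.
#' @export
write_series <- function(series, path, format = "tsv") {
  if (!is.data.frame(series) || nrow(series) < 1L) {
    stop("series must be a nonempty data.frame", call. = FALSE)
  }
  out <- series
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(v) {
        if (is.na(v)) NA_character_ else format(v, digits = 15)
      }, character(1L))
    }
  }
  utils::write.table(out, path, sep = io_sep(format), quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a series written by [write_series()]
#'
#' @param path input file.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @return a data.frame with \code{NA} for undefined cells.
#' @export
read_series <- function(path, format = "tsv") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = io_sep(format), header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
}

write_with_id <- function(m, path, id_name, sep) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_name
  for (j in seq(2L, ncol(df))) {
    if (is.double(df[[j]])) df[[j]] <- vapply(df[[j]], format, character(1L), digits = 15)
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
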