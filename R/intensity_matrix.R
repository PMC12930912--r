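#' Protein intensity matrix
#'
#' The central data container of the package: a proteins x samples abundance
#' matrix with `NA` marking missing quantifications and a scale flag recording
#' whether values are raw (strictly positive) intensities or log2 intensities.
#'
#' @param values Numeric matrix, proteins in rows, samples in columns. Row and
#'   column names are required and must be unique. `NA` marks missing cells.
#' @param scale Either `"raw"` (strictly positive intensities, the native
#'   DIA-NN protein-group output scale) or `"log2"`.
#'
#' @return An object of class `intensity_matrix`: a list with elements
#'   `values` (the matrix) and `scale`.
#' @export
#' @examples
#' m <- matrix(2^rnorm(6, 20), 3, 2,
#'             dimnames = list(paste0("P", 1:3), c("s1", "s2")))
#' im <- intensity_matrix(m, "raw")
#' n_missing(im)
intensity_matrix <- function(values, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry protein row names and sample column names",
         call. = FALSE)
  dup_p <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_p))
    stop("duplicate protein identifiers: ", paste(dup_p, collapse = ", "),
         call. = FALSE)
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  if (scale == "raw" && any(values <= 0, na.rm = TRUE))
    stop("raw-scale intensities must be strictly positive", call. = FALSE)
  structure(list(values = values, scale = scale), class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("intensity_matrix: %d proteins x %d samples (%s scale)\n",
              nrow(v), ncol(v), x$scale))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(v)),
              100 * mean(is.na(v))))
  invisible(x)
}

#' @export
as.matrix.intensity_matrix <- function(x, ...) x$values

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Accessors for intensity matrices
#'
#' `proteins()` and `samples()` return the identifier vectors; `n_missing()`
#' counts masked cells; `missing_mask()` returns the logical mask.
#'
#' @param x An `intensity_matrix`.
#' @return Character vector, integer, or logical matrix respectively.
#' @export
proteins <- function(x) rownames(x$values)

#' @rdname proteins
#' @export
samples <- function(x) colnames(x$values)

#' @rdname proteins
#' @export
n_missing <- function(x) sum(is.na(x$values))

#' @rdname proteins
#' @export
missing_mask <- function(x) is.na(x$values)

#' Log2-transform a raw-scale intensity matrix
#'
#' Missing cells stay missing; calling this on a matrix already on the log2
#' scale is an error, so the transform is applied exactly once per analysis.
#'
#' @param x An `intensity_matrix` on the raw scale.
#' @return An `intensity_matrix` on the log2 scale.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (x$scale == "log2")
    stop("matrix is already on the log2 scale", call. = FALSE)
  intensity_matrix(log2(x$values), "log2")
}

# tokens treated as missing in input files
.na_tokens <- c("", "NA", "NaN", "nan", "na", "NULL")

.read_table_raw <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    colClasses = "character", quote = "\"",
                    comment.char = "", stringsAsFactors = FALSE)
}

# DIA-NN pg_matrix annotation columns; Protein.Group is the identifier
.diann_annot_cols <- c("Protein.Group", "Protein.Ids", "Protein.Names",
                       "Genes", "First.Protein.Description")

#' Read a wide protein intensity table
#'
#' Reads a proteins-in-rows TSV/CSV matrix. Two dialects are supported:
#' `generic_wide` (first column holds protein identifiers, every other column
#' is a sample) and `diann_pg_matrix` (DIA-NN protein-group matrix: the
#' `Protein.Group` column is the identifier, other annotation columns are
#' dropped, and `0` is read as missing, since DIA-NN writes blanks/zeros for
#' quantities absent from a run). In the generic dialect only empty/NA/NaN
#' tokens are treated as missing, so legitimate zeros in user data survive.
#'
#' @param path Path to a `.tsv` (tab) or `.csv` (comma) file.
#' @param dialect `"generic_wide"` or `"diann_pg_matrix"`.
#' @return An `intensity_matrix` on the raw scale.
#' @export
read_intensity_table <- function(path,
                                 dialect = c("generic_wide", "diann_pg_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- .read_table_raw(path)
  if (ncol(df) < 2) stop("table needs an id column plus sample columns",
                         call. = FALSE)
  # duplicate check on the raw header: data.frame subsetting would mangle it
  sample_names <- if (dialect == "diann_pg_matrix")
    setdiff(names(df), .diann_annot_cols) else names(df)[-1L]
  dup_s <- unique(sample_names[duplicated(sample_names)])
  if (length(dup_s))
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  if (dialect == "diann_pg_matrix") {
    if (!"Protein.Group" %in% names(df))
      stop("diann_pg_matrix dialect requires a 'Protein.Group' column",
           call. = FALSE)
    ids <- df[["Protein.Group"]]
    df <- df[, !(names(df) %in% .diann_annot_cols), drop = FALSE]
  } else {
    ids <- df[[1L]]
    df <- df[, -1L, drop = FALSE]
  }
  names(df) <- sample_names
  dup_p <- unique(ids[duplicated(ids)])
  if (length(dup_p))
    stop("duplicate protein identifiers: ", paste(dup_p, collapse = ", "),
         call. = FALSE)
  vals <- matrix(NA_real_, nrow(df), ncol(df),
                 dimnames = list(ids, names(df)))
  for (j in seq_len(ncol(df))) {
    cell <- df[[j]]
    is_na <- cell %in% .na_tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_na & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d (protein %s), column '%s'",
                   cell[bad[1L]], bad[1L], ids[bad[1L]], names(df)[j]),
           call. = FALSE)
    num[is_na] <- NA_real_
    vals[, j] <- num
  }
  if (dialect == "diann_pg_matrix") vals[!is.na(vals) & vals == 0] <- NA_real_
  intensity_matrix(vals, "raw")
}

#' Write a wide protein intensity table
#'
#' Values are written with 17 significant digits so that a
#' `write_intensity_table()` / [read_intensity_table()] round-trip reproduces
#' values bit-exactly; missing cells are written as empty fields.
#'
#' @param x An `intensity_matrix`.
#' @param path Output path; `.csv` selects comma separation, anything else tab.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(x, path) {
  stopifnot(inherits(x, "intensity_matrix"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  v <- x$values
  chr <- matrix(sprintf("%.17g", v), nrow(v), ncol(v))
  chr[is.na(v)] <- ""
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("protein", colnames(v)), collapse = sep), con)
  writeLines(paste(rownames(v), apply(chr, 1L, paste, collapse = sep),
                   sep = sep), con)
  invisible(path)
}

#' Read a sample metadata table
#'
#' The table must carry `sample_id` and `group` columns; further columns
#' (age, sex, ...) are carried along but unused by the statistics. When an
#' `intensity_matrix` is supplied the metadata are restricted and reordered to
#' its samples; a sample present in the matrix but absent from the metadata is
#' a hard error, while metadata-only samples are dropped and counted in the
#' `"n_metadata_only"` attribute.
#'
#' @param path Path to a TSV/CSV file.
#' @param matrix Optional `intensity_matrix` to align against.
#' @return A data.frame with at least `sample_id` and `group` columns.
#' @export
read_sample_metadata <- function(path, matrix = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- .read_table_raw(path)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("metadata must have 'sample_id' and 'group' columns", call. = FALSE)
  if (any(df$group %in% .na_tokens))
    stop("missing group label for sample(s): ",
         paste(df$sample_id[df$group %in% .na_tokens], collapse = ", "),
         call. = FALSE)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("duplicate sample identifiers in metadata: ",
         paste(dup, collapse = ", "), call. = FALSE)
  align_metadata(df, matrix)
}

#' Align metadata to an intensity matrix
#'
#' @param metadata Data.frame with `sample_id` and `group`.
#' @param matrix Optional `intensity_matrix`; if `NULL` the metadata are
#'   returned unchanged (with `n_metadata_only = 0`).
#' @return The metadata restricted and ordered to the matrix samples, with an
#'   attribute `n_metadata_only` counting dropped metadata-only samples.
#' @export
align_metadata <- function(metadata, matrix = NULL) {
  if (is.null(matrix)) {
    attr(metadata, "n_metadata_only") <- 0L
    return(metadata)
  }
  stopifnot(inherits(matrix, "intensity_matrix"))
  sm <- samples(matrix)
  absent <- setdiff(sm, metadata$sample_id)
  if (length(absent))
    stop("samples in matrix but not in metadata: ",
         paste(absent, collapse = ", "), call. = FALSE)
  extra <- setdiff(metadata$sample_id, sm)
  out <- metadata[match(sm, metadata$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_metadata_only") <- length(extra)
  if (length(extra))
    message(length(extra), " metadata-only sample(s) dropped")
  out
}

#' Read a GMT gene-set file
#'
#' Broad-dialect GMT: one set per line, tab-separated `name`, `description`,
#' then members. Duplicate members within a set are removed.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: a named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); at least 3 required",
                   i, length(f)), call. = FALSE)
    nm[i] <- f[1L]
    desc[i] <- f[2L]
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("GMT line %d (%s) has no members", i, f[1L]), call. = FALSE)
    sets[[i]] <- members
  }
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicate set names in GMT: ", paste(dup, collapse = ", "),
         call. = FALSE)
  names(sets) <- nm
  names(desc) <- nm
  structure(sets, descriptions = desc, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d set(s)\n", length(x)))
  if (length(x)) {
    sz <- lengths(x)
    cat(sprintf("  sizes: min %d, median %g, max %d\n",
                min(sz), stats::median(sz), max(sz)))
  }
  invisible(x)
}
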