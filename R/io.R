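#' Read an expression matrix from a delimited text file
#'
#' Reads a TSV or CSV table with a header row and a first column of
#' identifiers, and returns a numeric matrix oriented genes x samples.
#' The delimiter is chosen from the file extension (`.tsv` = tab,
#' `.csv` = comma); there is no content sniffing.
#'
#' @param path Path to a `.tsv` or `.csv` file.
#' @param orientation Either `"genes_in_rows"` (default) or
#'   `"samples_in_rows"`; the returned matrix is always genes x samples.
#' @return Numeric matrix with gene ids as rownames and sample ids as
#'   colnames. Values are kept on the scale of the file (linear scale
#'   throughout this package).
#' @export
read_expression <- function(path, orientation = c("genes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  sep <- .delim_for(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("expression file must have an identifier column plus >= 1 data column: ", path)
  ids <- df[[1L]]
  cols <- colnames(df)[-1L]
  if (anyDuplicated(cols)) {
    stop("duplicate column ids in ", path, ": ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  }
  m <- matrix(NA_real_, nrow = nrow(df), ncol = length(cols),
              dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) & !(df[[j + 1L]] %in% c("NA", "")))
    if (length(bad)) {
      stop("non-numeric value in ", path, " at row '", ids[bad[1L]],
           "', column '", cols[j], "': '", df[[j + 1L]][bad[1L]], "'")
    }
    m[, j] <- v
  }
  if (orientation == "samples_in_rows") m <- t(m)
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  m
}

#' Write an expression matrix to a delimited text file
#'
#' Inverse of [read_expression()]: writes a genes x samples matrix with an
#' identifier first column named `gene_id`. Round-trips value-exactly
#' (full precision).
#'
#' @param expr Numeric matrix, genes x samples, with dimnames.
#' @param path Output path; `.tsv` or `.csv` selects the delimiter.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(gene_id = rownames(expr),
                   format(expr, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .delim_for(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

.delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, tsv = "\t", txt = "\t", csv = ",",
         stop("unrecognized extension '", ext, "' (use .tsv or .csv): ", path))
}

#' Collapse expression rows to gene symbols
#'
#' Maps source identifiers (probes, transcripts) to target gene symbols and
#' collapses duplicates: when several source rows map to one symbol, each
#' sample's value is the per-sample median over those rows (midpoint rule for
#' even counts; missing values dropped before the median). Unmapped source
#' ids are dropped, never guessed.
#'
#' @param expr Genes x samples numeric matrix keyed by source identifiers.
#' @param map Two-column data.frame (`source`, `target`) or a named character
#'   vector `source -> target`. Many-to-one is allowed; empty targets are
#'   invalid.
#' @return Genes x samples matrix keyed by unique target symbols.
#' @export
collapse_gene_ids <- function(expr, map) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (is.data.frame(map)) {
    src <- as.character(map[[1L]]); tgt <- as.character(map[[2L]])
  } else {
    src <- names(map); tgt <- as.character(map)
  }
  if (any(!nzchar(tgt))) stop("gene id map contains empty target symbols")
  lut <- stats::setNames(tgt, src)
  hit <- rownames(expr) %in% src
  if (!any(hit)) stop("no gene ids map to a symbol; output would be empty")
  sub <- expr[hit, , drop = FALSE]
  sym <- unname(lut[rownames(sub)])
  groups <- split(seq_len(nrow(sub)), sym)
  out <- matrix(NA_real_, nrow = length(groups), ncol = ncol(expr),
                dimnames = list(names(groups), colnames(expr)))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    if (length(rows) == 1L) {
      out[g, ] <- sub[rows, ]
    } else {
      out[g, ] <- apply(sub[rows, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
    }
  }
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#' Duplicate genes within a set are deduplicated (first occurrence kept).
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (one per set); set descriptions
#'   are kept in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("GMT line ", which(nf < 3L)[1L], " has fewer than 3 fields in ", path)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate set names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(vapply(fields, `[[`, "", 2L), nm)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read sample metadata
#'
#' Reads a CSV/TSV metadata table and validates the study-design contract:
#' unique sample ids, and every non-control sample's `control_group_key`
#' matching at least one control sample.
#'
#' @param path Path to a metadata table with columns `sample_id`, `compound`,
#'   `dose_group`, `time_h`, `replicate`, `is_control`, `control_group_key`,
#'   and optionally `alt` plus hematology analyte columns.
#' @return Validated data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  df$is_control <- as.logical(df$is_control)
  validate_metadata(df)
}

#' Validate a sample metadata table
#'
#' @param meta Data.frame of per-sample study metadata.
#' @return `meta`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_metadata <- function(meta) {
  need <- c("sample_id", "compound", "dose_group", "time_h", "replicate",
            "is_control", "control_group_key")
  miss <- setdiff(need, colnames(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  if (any(meta$time_h < 0)) stop("time_h must be non-negative")
  if (any(meta$replicate < 1)) stop("replicate must be >= 1")
  ctrl_keys <- unique(meta$control_group_key[meta$is_control])
  orphans <- unique(meta$control_group_key[!meta$is_control &
                                           !(meta$control_group_key %in% ctrl_keys)])
  if (length(orphans)) {
    stop("non-control samples with no matching control group: ",
         paste(orphans, collapse = ", "))
  }
  meta
}

#' Write sample metadata
#'
#' @param meta Metadata data.frame.
#' @param path Output path (`.csv` or `.tsv`).
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = .delim_for(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}
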