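# Reading, validation and serialization of intensity tables, sample sheets
# and GMT gene-set collections; protein-inclusion filters and the
# human/mouse organism partition.

INTENSITY_META_COLS <- c(accession = "accession", gene = "gene",
                         organism = "organism",
                         unique_peptides = "unique_peptides")

#' Read a protein intensity table
#'
#' Parses a tab-separated protein table whose leading columns carry per-protein
#' annotations (accession, gene symbol, organism, unique-peptide count) and
#' whose remaining columns are raw sample intensities, with zero encoding "not
#' detected". Rows that are zero across every sample carry no information for
#' any downstream route and are dropped with a message.
#'
#' @param path Path to the TSV file.
#' @param col_map Named character vector mapping the canonical annotation
#'   fields (`accession`, `gene`, `organism`, `unique_peptides`) to the
#'   column names used in the file.
#' @return List with `intensity` (numeric matrix, accessions x sample ids)
#'   and `annotations` (data frame).
#' @export
read_intensity_table <- function(path, col_map = INTENSITY_META_COLS) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(names(col_map)) || !all(names(INTENSITY_META_COLS) %in% names(col_map))) {
    stop_config("col_map", "must name accession, gene, organism and unique_peptides")
  }
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(col_map), names(raw))
  if (length(missing_cols)) {
    stop("format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  annotations <- data.frame(
    accession = as.character(raw[[col_map[["accession"]]]]),
    gene = as.character(raw[[col_map[["gene"]]]]),
    organism = as.character(raw[[col_map[["organism"]]]]),
    unique_peptides = raw[[col_map[["unique_peptides"]]]],
    stringsAsFactors = FALSE
  )
  dup <- annotations$accession[duplicated(annotations$accession)]
  if (length(dup)) {
    stop("validation error: duplicate accession(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  sample_cols <- setdiff(names(raw), unname(col_map))
  if (!length(sample_cols)) stop("format error: no sample columns found", call. = FALSE)

  intensity <- matrix(NA_real_, nrow(raw), length(sample_cols),
                      dimnames = list(annotations$accession, sample_cols))
  for (j in seq_along(sample_cols)) {
    v <- raw[[sample_cols[j]]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "NA")
    if (length(bad)) {
      stop(sprintf("format error: non-numeric intensity at row %d, column '%s'",
                   bad[1], sample_cols[j]), call. = FALSE)
    }
    intensity[, j] <- num
  }
  neg <- which(intensity < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("validation error: negative intensity at protein '%s', sample '%s'",
                 rownames(intensity)[neg[1, 1]], colnames(intensity)[neg[1, 2]]),
         call. = FALSE)
  }
  all_zero <- rowSums(intensity != 0, na.rm = TRUE) == 0
  if (any(all_zero)) {
    message(sum(all_zero), " all-zero protein row(s) dropped at ingest")
    intensity <- intensity[!all_zero, , drop = FALSE]
    annotations <- annotations[!all_zero, , drop = FALSE]
    rownames(annotations) <- NULL
  }
  list(intensity = intensity, annotations = annotations)
}

#' Write a protein intensity table
#'
#' Inverse of [read_intensity_table()]: annotations first, then one column per
#' sample; missing values are written as 0 ("not detected").
#'
#' @param intensity Numeric matrix (accessions x samples).
#' @param annotations Annotation data frame covering all rows.
#' @param path Output TSV path.
#' @export
write_intensity_table <- function(intensity, annotations, path) {
  stopifnot(identical(rownames(intensity), annotations$accession))
  out <- intensity
  out[is.na(out)] <- 0
  df <- cbind(annotations, as.data.frame(out, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' CSV with columns `sample_id,treatment,duration,replicate,included`.
#' Treatments must be si-NT or si-hVDAC1 and durations short or long; the
#' four design groups must all be present among included samples.
#'
#' @param path CSV path.
#' @return Sample sheet data frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
  sheet$included <- as.logical(sheet$included)
  sheet
}

#' @rdname read_sample_sheet
#' @param sheet Sample sheet data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_sample_sheet <- function(sheet) {
  needed <- c("sample_id", "treatment", "duration", "replicate", "included")
  missing_cols <- setdiff(needed, names(sheet))
  if (length(missing_cols)) {
    stop("format error: sample sheet missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("validation error: duplicate sample ids", call. = FALSE)
  }
  if (!all(sheet$treatment %in% TREATMENTS)) {
    stop("validation error: treatment must be one of ",
         paste(TREATMENTS, collapse = ", "), call. = FALSE)
  }
  if (!all(sheet$duration %in% DURATIONS)) {
    stop("validation error: duration must be one of ",
         paste(DURATIONS, collapse = ", "), call. = FALSE)
  }
  inc <- sheet[as.logical(sheet$included), , drop = FALSE]
  if (!all(design_groups() %in% group_id(inc$treatment, inc$duration))) {
    stop("validation error: included samples must span all four design groups",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Protein-inclusion filter
#'
#' Retains proteins of the requested organism with at least
#' `min_unique_peptides` unique peptides — the inclusion rule applied to the
#' quantified human proteome (organism `"human"`, at least one unique
#' peptide) before any statistics. Row order is preserved; the filter is a
#' pure row predicate and therefore idempotent.
#'
#' @param intensity Intensity matrix (accessions x samples).
#' @param annotations Annotation data frame covering all rows.
#' @param organism Organism tag to keep, or `"*"` for any.
#' @param min_unique_peptides Minimum unique-peptide count (default 1).
#' @return List with filtered `intensity` and `annotations`.
#' @export
filter_proteins <- function(intensity, annotations, organism = "human",
                            min_unique_peptides = 1L) {
  stopifnot(identical(rownames(intensity), annotations$accession))
  min_unique_peptides <- check_count(min_unique_peptides, "min_unique_peptides", min = 0L)
  keep <- (organism == "*" | annotations$organism == organism) &
    annotations$unique_peptides >= min_unique_peptides
  if (!any(keep)) warning("protein filter retained zero rows", call. = FALSE)
  list(intensity = intensity[keep, , drop = FALSE],
       annotations = {a <- annotations[keep, , drop = FALSE]; rownames(a) <- NULL; a})
}

#' Partition a table by organism
#'
#' Splits a protein table into disjoint per-organism tables whose union of
#' rows equals the input — used to analyze human (tumor) and mouse
#' (microenvironment) proteins separately.
#'
#' @inheritParams filter_proteins
#' @return Named list (one element per organism present) of
#'   `list(intensity, annotations)`.
#' @export
partition_by_organism <- function(intensity, annotations) {
  stopifnot(identical(rownames(intensity), annotations$accession))
  lapply(split(seq_len(nrow(annotations)), annotations$organism), function(idx) {
    list(intensity = intensity[idx, , drop = FALSE],
         annotations = {a <- annotations[idx, , drop = FALSE]; rownames(a) <- NULL; a})
  })
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated `term`, `description`, then
#' member gene symbols. Duplicate members within a term are de-duplicated with
#' a message.
#'
#' @param path GMT path.
#' @return A `gene_set_db` (see [simulate_gene_sets()]).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("format error: GMT line %d has fewer than 3 fields", short[1]),
         call. = FALSE)
  }
  n_dup <- 0L
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    u <- unique(members)
    n_dup <<- n_dup + (length(members) - length(u))
    u
  })
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (n_dup > 0) message(n_dup, " duplicate member(s) de-duplicated across terms")
  if (anyDuplicated(names(sets))) {
    stop("validation error: duplicate term ids in GMT", call. = FALSE)
  }
  info <- data.frame(term = names(sets),
                     description = vapply(fields, `[[`, "", 2L),
                     stringsAsFactors = FALSE)
  structure(list(sets = sets, info = info), class = "gene_set_db")
}

#' @rdname read_gene_sets
#' @param db A `gene_set_db`.
#' @export
write_gene_sets <- function(db, path) {
  stopifnot(inherits(db, "gene_set_db"))
  desc <- db$info$description[match(names(db$sets), db$info$term)]
  desc[is.na(desc)] <- "na"
  lines <- vapply(seq_along(db$sets), function(i) {
    paste(c(names(db$sets)[i], desc[i], db$sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
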