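# Core data containers and readers/writers.
#
# The unit consumed by every stage is the `omics_block`: a log2
# feature-by-sample intensity matrix (NA marks a masked cell), per-feature
# metadata, and the ordered sample ids matching a sample sheet.

NA_TOKENS <- c("", "NA", "NaN")

#' Construct an omics block
#'
#' @param values numeric matrix, rows = features, columns = samples, on the
#'   log2 scale; `NA` encodes a missing (masked) cell.
#' @param feature_meta data.frame with one row per feature; must contain a
#'   `feature_id` column. For histone PTM blocks a `precursor_group` column
#'   identifies co-measured modified forms of one precursor peptide; for
#'   plasma blocks a `protein` column carries the leading protein name.
#' @param sample_ids character vector of column labels; defaults to
#'   `colnames(values)`.
#' @return An object of class `omics_block` with elements `values`,
#'   `feature_meta`, `sample_ids`.
#' @export
omics_block <- function(values, feature_meta = NULL, sample_ids = colnames(values)) {
  .assert(is.matrix(values) && is.numeric(values), "values must be a numeric matrix")
  if (is.null(feature_meta)) {
    .assert(!is.null(rownames(values)), "feature ids required (rownames or feature_meta)")
    feature_meta <- data.frame(feature_id = rownames(values), stringsAsFactors = FALSE)
  }
  .assert(is.data.frame(feature_meta) && "feature_id" %in% names(feature_meta),
          "feature_meta must be a data.frame with a feature_id column")
  .assert(nrow(feature_meta) == nrow(values),
          "feature_meta rows must match matrix rows")
  .assert(!anyDuplicated(feature_meta$feature_id),
          "duplicated feature id(s)")
  .assert(length(sample_ids) == ncol(values), "sample_ids must match matrix columns")
  .assert(!anyDuplicated(sample_ids), "duplicated sample id(s)")
  ok <- is.na(values) | is.finite(values)
  .assert(all(ok), "all present values must be finite")
  rownames(values) <- feature_meta$feature_id
  colnames(values) <- sample_ids
  structure(list(values = values, feature_meta = feature_meta,
                 sample_ids = as.character(sample_ids)),
            class = "omics_block")
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("omics_block: %d features x %d samples (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_block <- function(x) dim(x$values)

#' Read and validate a sample sheet
#'
#' A sample sheet names each measured sample and places it in the paired
#' design: participant, timepoint (BT = before therapy, AT = after therapy),
#' sample type (buccal, pbmc, plasma) and acquisition batch.
#'
#' @param path CSV file with columns `sample_id`, `participant_id`,
#'   `timepoint`, `sample_type`, `batch`.
#' @return A validated data.frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  as_sample_sheet(df)
}

#' Validate a data.frame as a sample sheet
#' @param df data.frame with the sample-sheet columns.
#' @rdname read_sample_sheet
#' @export
as_sample_sheet <- function(df) {
  need <- c("sample_id", "participant_id", "timepoint", "sample_type", "batch")
  miss <- setdiff(need, names(df))
  .assert(length(miss) == 0, paste("sample sheet missing column(s):", paste(miss, collapse = ", ")))
  dup <- df$sample_id[duplicated(df$sample_id)]
  .assert(length(dup) == 0, paste("duplicated sample_id:", paste(unique(dup), collapse = ", ")))
  .assert(all(df$timepoint %in% c("BT", "AT")),
          "timepoint must be BT or AT")
  .assert(all(df$sample_type %in% c("buccal", "pbmc", "plasma")),
          "sample_type must be buccal, pbmc or plasma")
  .assert(all(nzchar(df$batch)), "every batch label must be non-empty")
  key <- paste(df$participant_id, df$sample_type, df$timepoint)
  dupk <- key[duplicated(key)]
  .assert(length(dupk) == 0,
          paste("more than one sample per (participant, type, timepoint):",
                paste(unique(dupk), collapse = "; ")))
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read and validate a participant sheet
#'
#' Carries lifestyle categories (exercise, diet, BMI class), ordinal response
#' categories (performance; back-pain self-assessment) and agility metrics
#' (flexion, extension, rotation; isometric maximum strength, arbitrary force
#' units) at BT and AT.
#'
#' @param path CSV file; columns `participant_id`, `exercise_class`,
#'   `diet_class`, `bmi_class`, `performance`, `self_assessment` and
#'   `<metric>_bt` / `<metric>_at` for flexion, extension, rotation.
#' @return A validated data.frame of class `participant_sheet`.
#' @export
read_participant_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_participant_sheet(df)
}

#' @rdname read_participant_sheet
#' @param df data.frame with the participant-sheet columns.
#' @export
as_participant_sheet <- function(df) {
  metrics <- c("flexion", "extension", "rotation")
  need <- c("participant_id", "exercise_class", "diet_class", "bmi_class",
            "performance", "self_assessment",
            paste0(metrics, "_bt"), paste0(metrics, "_at"))
  miss <- setdiff(need, names(df))
  .assert(length(miss) == 0,
          paste("participant sheet missing column(s):", paste(miss, collapse = ", ")))
  .assert(!anyDuplicated(df$participant_id), "duplicated participant_id")
  .assert(all(df$performance %in% c("moderate", "intermediate", "max")),
          "performance must be moderate/intermediate/max")
  .assert(all(df$self_assessment %in%
                c("improving", "unimpaired", "stagnating", "worsening")),
          "self_assessment must be improving/unimpaired/stagnating/worsening")
  ag <- as.matrix(df[, c(paste0(metrics, "_bt"), paste0(metrics, "_at"))])
  .assert(all(is.finite(ag)) && all(ag > 0), "agility values must be positive")
  class(df) <- c("participant_sheet", "data.frame")
  df
}

#' Read an intensity matrix into an omics block
#'
#' @param matrix_path TSV with feature ids in the first column and sample ids
#'   in the header; cells are log2 intensities or one of the accepted NA
#'   tokens (`""`, `"NA"`, `"NaN"`). Any other non-numeric cell is an error —
#'   never a silent drop.
#' @param feature_meta_path optional TSV of per-feature metadata with a
#'   `feature_id` column covering every feature id in the matrix.
#' @param sheet a `sample_sheet`; every matrix sample must appear in it.
#' @param linear set `TRUE` if the file stores linear-scale intensities; they
#'   are then log2-transformed on read (zeros become missing).
#' @return An `omics_block`.
#' @export
read_block <- function(matrix_path, feature_meta_path = NULL, sheet = NULL,
                       linear = FALSE) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  .assert(ncol(raw) >= 2, "matrix file needs a feature column plus sample columns")
  fid <- raw[[1]]
  dup <- fid[duplicated(fid)]
  .assert(length(dup) == 0,
          paste("duplicated feature id:", paste(unique(dup), collapse = ", ")))
  cells <- as.matrix(raw[, -1, drop = FALSE])
  # read.delim already maps the "NA" token to R's NA in character mode
  is_na_tok <- matrix(is.na(cells) | trimws(cells) %in% NA_TOKENS,
                      nrow = nrow(cells))
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(!is_na_tok & is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell '%s' at feature %s, sample %s",
                 cells[bad[1, , drop = FALSE]], fid[bad[1, 1]],
                 colnames(raw)[-1][bad[1, 2]]), call. = FALSE)
  }
  num[is_na_tok] <- NA_real_
  rownames(num) <- fid
  colnames(num) <- colnames(raw)[-1]
  if (linear) {
    .assert(all(num >= 0, na.rm = TRUE), "linear intensities must be nonnegative")
    num[num == 0] <- NA_real_
    num <- log2(num)
  }
  if (!is.null(sheet)) {
    unknown <- setdiff(colnames(num), sheet$sample_id)
    .assert(length(unknown) == 0,
            paste("sample(s) in matrix absent from sheet:",
                  paste(unknown, collapse = ", ")))
  }
  meta <- NULL
  if (!is.null(feature_meta_path)) {
    meta <- utils::read.delim(feature_meta_path, stringsAsFactors = FALSE)
    .assert("feature_id" %in% names(meta), "feature meta needs a feature_id column")
    uncov <- setdiff(fid, meta$feature_id)
    .assert(length(uncov) == 0,
            paste("feature(s) missing from meta:", paste(utils::head(uncov, 5), collapse = ", ")))
    meta <- meta[match(fid, meta$feature_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  omics_block(num, feature_meta = meta)
}

#' Write an omics block to TSV
#'
#' Inverse of [read_block()]: missing cells are written as `NA`, full numeric
#' precision is kept so that read-after-write is the identity on values, mask
#' and labels.
#'
#' @param block an `omics_block`.
#' @param matrix_path output TSV path.
#' @param feature_meta_path optional output TSV for the feature metadata.
#' @export
write_block <- function(block, matrix_path, feature_meta_path = NULL) {
  v <- block$values
  out <- data.frame(feature_id = rownames(v),
                    format(v, digits = 17, trim = TRUE, scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  if (!is.null(feature_meta_path)) {
    utils::write.table(block$feature_meta, feature_meta_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  invisible(matrix_path)
}

#' Build the paired BT/AT design from a sample sheet
#'
#' Pairs every participant that has both a BT and an AT sample of a given
#' type; participants with only one timepoint are listed as unpaired.
#'
#' @param sheet a `sample_sheet`.
#' @return An object of class `paired_design`: a list with per-sample-type
#'   data.frames `pairs` (`participant_id`, `bt`, `at`) and `unpaired`
#'   (`participant_id`, `sample_id`, `timepoint`).
#' @export
build_paired_design <- function(sheet) {
  sheet <- as_sample_sheet(as.data.frame(sheet))
  out <- list()
  for (ty in unique(sheet$sample_type)) {
    s <- sheet[sheet$sample_type == ty, , drop = FALSE]
    bt <- s[s$timepoint == "BT", ]
    at <- s[s$timepoint == "AT", ]
    common <- intersect(bt$participant_id, at$participant_id)
    pairs <- data.frame(
      participant_id = common,
      bt = bt$sample_id[match(common, bt$participant_id)],
      at = at$sample_id[match(common, at$participant_id)],
      stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$participant_id), , drop = FALSE]
    rownames(pairs) <- NULL
    lone <- s[!(s$participant_id %in% common), c("participant_id", "sample_id", "timepoint")]
    rownames(lone) <- NULL
    out[[ty]] <- list(pairs = pairs, unpaired = lone)
  }
  structure(out, class = "paired_design")
}

#' @export
print.paired_design <- function(x, ...) {
  for (ty in names(x)) {
    cat(sprintf("%s: %d pairs, %d unpaired samples\n",
                ty, nrow(x[[ty]]$pairs), nrow(x[[ty]]$unpaired)))
  }
  invisible(x)
}

# Restrict a design to pairs fully present in a block's samples.
design_pairs <- function(design, type, block = NULL) {
  .assert(type %in% names(design), paste("no design for sample type", type))
  p <- design[[type]]$pairs
  if (!is.null(block)) {
    keep <- p$bt %in% block$sample_ids & p$at %in% block$sample_ids
    p <- p[keep, , drop = FALSE]
  }
  p
}

#' Write a result object to disk
#'
#' Record-like results go to JSON with deterministic field order, matrices to
#' TSV (square affinity matrices keep identical row and column labels), and
#' edge lists to GraphML with `r` and `sign` edge attributes.
#'
#' @param obj a result: data.frame/list (JSON), matrix (TSV), or an edge-list
#'   data.frame with columns `from`, `to`, `r`, `sign` (GraphML when `path`
#'   ends in `.graphml`).
#' @param path output path; the extension selects the format (`.json`,
#'   `.tsv`, `.graphml`).
#' @export
write_results <- function(obj, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "graphml") {
    .assert(is.data.frame(obj) && all(c("from", "to", "r", "sign") %in% names(obj)),
            "GraphML output expects an edge list with from/to/r/sign")
    g <- igraph::graph_from_data_frame(obj[, c("from", "to")], directed = FALSE)
    igraph::E(g)$r <- obj$r
    igraph::E(g)$sign <- obj$sign
    igraph::write_graph(g, path, format = "graphml")
  } else if (ext == "tsv") {
    .assert(is.matrix(obj) || is.data.frame(obj), "TSV output expects a matrix or data.frame")
    if (is.matrix(obj)) {
      obj <- data.frame(id = rownames(obj) %||% seq_len(nrow(obj)), obj,
                        check.names = FALSE, stringsAsFactors = FALSE)
    }
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (ext == "json") {
    payload <- list(schema_version = "1.0", data = obj)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    stop("unsupported result extension: ", ext, call. = FALSE)
  }
  invisible(path)
}
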