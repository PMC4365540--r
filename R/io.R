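# Readers and writers for the tab-delimited interchange formats: expression
# matrices, clinical tables, centroid matrices and baseline-percentile tables.
# All formats are UTF-8 TSV, genes as rows where applicable, with optional
# "#"-prefixed provenance comment lines at the top of a file. Numeric fields
# are written with 17 significant digits so write -> read round-trips are
# lossless.

MISSING_TOKENS <- c("", "na", "nan")

.formatNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, header = TRUE, sep = "\t", quote = "", comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE,
             colClasses = "character", na.strings = NULL)
}

.writeTsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    body <- do.call(paste, c(unname(as.list(df)), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

.parseNumericCells <- function(chr, rows, cols, what) {
  # chr: character matrix. Returns numeric matrix; missing tokens -> NA;
  # any other non-numeric cell is a parse error with coordinates.
  low <- tolower(trimws(chr))
  miss <- low %in% MISSING_TOKENS
  num <- suppressWarnings(as.numeric(chr))
  bad <- is.na(num) & !miss
  if (any(bad)) {
    idx <- which(bad)[1L]
    r <- ((idx - 1L) %% length(rows)) + 1L
    c <- ((idx - 1L) %/% length(rows)) + 1L
    stop(what, ": non-numeric value '", chr[idx], "' at gene '", rows[r],
         "', sample '", cols[c], "'")
  }
  num[miss] <- NA_real_
  matrix(num, nrow = length(rows), dimnames = list(rows, cols))
}

#' Read a gene-expression matrix from TSV
#'
#' Expects a tab-delimited file with gene ids in the first column (header
#' `gene_id`), sample ids as the remaining column headers, and log-scale
#' expression values in the body. Empty cells and the tokens `NA` / `NaN`
#' (case-insensitive) are read as missing values.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, genes x samples, with `NA` for missing cells.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeExpression(matrix(1:4, 2, dimnames = list(c("g1", "g2"),
#'                                                c("s1", "s2"))), f)
#' readExpression(f)
#' @seealso [writeExpression()], [alignToSignature()]
#' @export
readExpression <- function(path) {
  df <- .readTsv(path)
  if (ncol(df) < 2L) stop("expression file needs gene_id plus >= 1 sample")
  genes <- df[[1L]]
  samples <- names(df)[-1L]
  dupg <- unique(genes[duplicated(genes)])
  if (length(dupg)) {
    stop("duplicated gene id(s) in ", path, ": ", paste(dupg, collapse = ", "))
  }
  dups <- unique(samples[duplicated(samples)])
  if (length(dups)) {
    stop("duplicated sample id(s) in ", path, ": ",
         paste(dups, collapse = ", "))
  }
  chr <- as.matrix(df[, -1L, drop = FALSE])
  mat <- .parseNumericCells(chr, genes, samples, path)
  validateExpression(mat)
  mat
}

#' Write a gene-expression matrix to TSV
#'
#' @param x numeric matrix (genes x samples) or a [CenteringResult] /
#'   [SyntheticCohort]; missing values are written as `NA`.
#' @param path output path.
#' @param comments optional character vector of provenance lines, written as
#'   `#`-prefixed comments before the header.
#' @return `path`, invisibly.
#' @seealso [readExpression()]
#' @export
writeExpression <- function(x, path, comments = character()) {
  mat <- asExpressionMatrix(x)
  validateExpression(mat)
  df <- data.frame(gene_id = rownames(mat), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mat))) df[[colnames(mat)[j]]] <- .formatNum(mat[, j])
  .writeTsv(df, path, comments)
}

.ER_POSITIVE_TOKENS <- c("positive", "pos", "er+", "+", "erpos", "er positive")
.ER_NEGATIVE_TOKENS <- c("negative", "neg", "er-", "-", "erneg", "er negative")
.TRUE_TOKENS <- c("true", "t", "yes", "y", "1", "tnbc")
.FALSE_TOKENS <- c("false", "f", "no", "n", "0")

.normalizeLabels <- function(x, positive, negative, column) {
  low <- tolower(trimws(x))
  out <- rep("unknown", length(x))
  out[low %in% positive] <- if (column == "tnbc") "true" else "positive"
  out[low %in% negative] <- if (column == "tnbc") "false" else "negative"
  out[low %in% c("unknown", MISSING_TOKENS)] <- "unknown"
  unrec <- !(low %in% c(positive, negative, "unknown", MISSING_TOKENS))
  if (any(unrec)) {
    warning("unrecognized ", column, " label(s) mapped to 'unknown': ",
            paste(unique(x[unrec]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a clinical annotation table from TSV
#'
#' Requires a `sample_id` column; recognises optional `er_status`, `tnbc`, and
#' `prototypic_subtype` columns. Label vocabulary is case-insensitive
#' (`"ER+"`, `"positive"`, `"pos"` all map to `positive`); unrecognised
#' tokens map to `unknown` with a warning. A sample flagged TNBC but
#' ER-positive raises a validation warning (inconsistent labels are reported,
#' never auto-corrected).
#'
#' @param path path to the TSV file.
#' @return `data.frame` with columns `sample_id`, `er_status`
#'   (`positive`/`negative`/`unknown`), `tnbc` (`true`/`false`/`unknown`),
#'   `prototypic_subtype` (subtype name or `NA`).
#' @seealso [writeClinical()], [subgroupSpec()]
#' @export
readClinical <- function(path) {
  df <- .readTsv(path)
  if (!"sample_id" %in% names(df)) {
    stop("clinical file ", path, " lacks the required 'sample_id' column")
  }
  out <- data.frame(sample_id = df$sample_id, stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id)) {
    stop("duplicated sample_id in ", path, ": ",
         paste(unique(out$sample_id[duplicated(out$sample_id)]),
               collapse = ", "))
  }
  out$er_status <- if ("er_status" %in% names(df)) {
    .normalizeLabels(df$er_status, .ER_POSITIVE_TOKENS, .ER_NEGATIVE_TOKENS,
                     "er_status")
  } else "unknown"
  out$tnbc <- if ("tnbc" %in% names(df)) {
    .normalizeLabels(df$tnbc, .TRUE_TOKENS, .FALSE_TOKENS, "tnbc")
  } else "unknown"
  out$prototypic_subtype <- if ("prototypic_subtype" %in% names(df)) {
    .normalizeSubtype(df$prototypic_subtype)
  } else NA_character_
  validateClinical(out)
  out
}

.normalizeSubtype <- function(x) {
  low <- tolower(trimws(x))
  map <- c("basal-like" = "Basal-like", "basal" = "Basal-like",
           "her2-enriched" = "HER2-enriched", "her2" = "HER2-enriched",
           "luma" = "LumA", "luminal a" = "LumA",
           "lumb" = "LumB", "luminal b" = "LumB",
           "normal-like" = "Normal-like", "normal" = "Normal-like")
  out <- unname(map[low])
  miss <- low %in% c(MISSING_TOKENS, "unknown")
  unrec <- is.na(out) & !miss
  if (any(unrec)) {
    warning("unrecognized prototypic_subtype label(s) mapped to NA: ",
            paste(unique(x[unrec]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Validate a clinical table
#'
#' Checks the label vocabulary and flags (without correcting) samples labelled
#' both TNBC and ER-positive.
#'
#' @param clinical `data.frame` as returned by [readClinical()].
#' @return `clinical`, invisibly.
#' @export
validateClinical <- function(clinical) {
  if (!is.data.frame(clinical) || !"sample_id" %in% names(clinical)) {
    stop("clinical must be a data.frame with a 'sample_id' column")
  }
  if (anyDuplicated(clinical$sample_id)) stop("duplicated sample_id values")
  if ("er_status" %in% names(clinical)) {
    bad <- setdiff(unique(clinical$er_status),
                   c("positive", "negative", "unknown"))
    if (length(bad)) stop("invalid er_status value(s): ",
                          paste(bad, collapse = ", "))
  }
  if ("tnbc" %in% names(clinical)) {
    bad <- setdiff(unique(clinical$tnbc), c("true", "false", "unknown"))
    if (length(bad)) stop("invalid tnbc value(s): ", paste(bad, collapse = ", "))
  }
  if (all(c("er_status", "tnbc") %in% names(clinical))) {
    inconsistent <- clinical$tnbc == "true" & clinical$er_status == "positive"
    if (any(inconsistent)) {
      warning("sample(s) labelled TNBC but ER-positive: ",
              paste(clinical$sample_id[inconsistent], collapse = ", "),
              call. = FALSE)
    }
  }
  invisible(clinical)
}

#' Write a clinical table to TSV
#'
#' @param clinical `data.frame` with `sample_id` and any of `er_status`,
#'   `tnbc`, `prototypic_subtype`.
#' @param path output path.
#' @param comments optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
writeClinical <- function(clinical, path, comments = character()) {
  validateClinical(clinical)
  df <- clinical
  if ("prototypic_subtype" %in% names(df)) {
    df$prototypic_subtype[is.na(df$prototypic_subtype)] <- "NA"
  }
  .writeTsv(df, path, comments)
}

#' Read a centroid matrix from TSV
#'
#' Expects `gene_id` plus one column per subtype.
#'
#' @param path path to the TSV file.
#' @return a [CentroidMatrix].
#' @seealso [writeCentroids()], [trainCentroids()]
#' @export
readCentroids <- function(path) {
  df <- .readTsv(path)
  if (ncol(df) < 3L) stop("centroid file needs gene_id plus >= 2 subtypes")
  genes <- df[[1L]]
  subtypes <- names(df)[-1L]
  mat <- .parseNumericCells(as.matrix(df[, -1L, drop = FALSE]), genes,
                            subtypes, path)
  if (any(is.na(mat))) stop("centroid file ", path, " has missing values")
  new("CentroidMatrix", values = mat)
}

#' Write a centroid matrix to TSV
#'
#' @param centroids a [CentroidMatrix].
#' @param path output path.
#' @param comments optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
writeCentroids <- function(centroids, path, comments = character()) {
  stopifnot(is(centroids, "CentroidMatrix"))
  mat <- centroidValues(centroids)
  df <- data.frame(gene_id = rownames(mat), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mat))) df[[colnames(mat)[j]]] <- .formatNum(mat[, j])
  .writeTsv(df, path, comments)
}

#' Read a baseline-percentile table from TSV
#'
#' Expects columns `gene_id`, `subgroup`, `mu_gene`, `q_gene`,
#' `baseline_method`. Percentiles outside `[0, 100]` are a validation error.
#'
#' @param path path to the TSV file.
#' @return a [PercentileTable].
#' @seealso [writePercentileTable()], [subgroupCenter()]
#' @export
readPercentileTable <- function(path) {
  df <- .readTsv(path)
  need <- c("gene_id", "subgroup", "mu_gene", "q_gene", "baseline_method")
  missingCols <- setdiff(need, names(df))
  if (length(missingCols)) {
    stop("percentile table ", path, " lacks column(s): ",
         paste(missingCols, collapse = ", "))
  }
  mu <- suppressWarnings(as.numeric(df$mu_gene))
  q <- suppressWarnings(as.numeric(df$q_gene))
  if (any(is.na(mu)) || any(is.na(q))) {
    stop("percentile table ", path, " has non-numeric mu_gene/q_gene cells")
  }
  if (any(q < 0 | q > 100)) {
    stop("percentile table ", path, " has q_gene outside [0, 100]")
  }
  method <- unique(df$baseline_method)
  if (length(method) != 1L) {
    stop("percentile table ", path, " mixes baseline methods: ",
         paste(method, collapse = ", "))
  }
  new("PercentileTable",
      table = data.frame(gene_id = df$gene_id, subgroup = df$subgroup,
                         mu_gene = mu, q_gene = q, stringsAsFactors = FALSE),
      baselineMethod = method)
}

#' Write a baseline-percentile table to TSV
#'
#' @param table a [PercentileTable].
#' @param path output path.
#' @param comments optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
writePercentileTable <- function(table, path, comments = character()) {
  stopifnot(is(table, "PercentileTable"))
  df <- as.data.frame(table)
  df$mu_gene <- .formatNum(df$mu_gene)
  df$q_gene <- .formatNum(df$q_gene)
  .writeTsv(df, path, comments)
}

#' Restrict an expression matrix to a centroid signature
#'
#' Intersects the matrix's genes with the centroid genes and reorders the
#' result to centroid order. Fails when the intersection covers less than
#' `minCoverage` of the signature.
#'
#' @param expr numeric matrix (genes x samples), a [CenteringResult], or a
#'   [SyntheticCohort].
#' @param centroids a [CentroidMatrix].
#' @param minCoverage minimum fraction of centroid genes that must be present
#'   (in `(0, 1]`; default 0.5).
#' @return numeric matrix restricted to the shared genes, in centroid order.
#' @examples
#' \dontrun{aligned <- alignToSignature(expr, centroids, minCoverage = 0.5)}
#' @export
alignToSignature <- function(expr, centroids, minCoverage = 0.5) {
  stopifnot(is(centroids, "CentroidMatrix"))
  if (length(minCoverage) != 1L || minCoverage <= 0 || minCoverage > 1) {
    stop("'minCoverage' must lie in (0, 1]")
  }
  mat <- asExpressionMatrix(expr)
  validateExpression(mat)
  sig <- geneIds(centroids)
  shared <- sig[sig %in% rownames(mat)]
  if (length(shared) / length(sig) < minCoverage) {
    stop("signature coverage too low: ", length(shared), "/", length(sig),
         " centroid genes present (minimum coverage ", minCoverage, ")")
  }
  mat[shared, , drop = FALSE]
}
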