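#' Read a triad definition table
#'
#' A triad binds one A-, one B- and one D-subgenome homeolog under a single
#' triad identifier. The file is tab-separated with a header and columns
#' \code{triad_id}, \code{gene_a}, \code{gene_b}, \code{gene_d} and an
#' optional \code{syntenic} (0/1) flag. Gene IDs are treated as opaque,
#' case-sensitive strings; subgenome membership comes from the column, never
#' from parsing the ID.
#'
#' @param path Path to a tab-separated triad table.
#' @return A data frame of class \code{triad_set} with columns
#'   \code{triad_id}, \code{gene_a}, \code{gene_b}, \code{gene_d},
#'   \code{syntenic} (logical). Row order follows the file.
#' @export
read_triad_table <- function(path) {
  df <- read_tsv_checked(path, c("triad_id", "gene_a", "gene_b", "gene_d"))
  if (nrow(df) == 0L) {
    warning("triad table '", path, "' contains a header but no triads")
  }
  if (is.null(df$syntenic)) {
    df$syntenic <- rep(NA, nrow(df))
  }
  df$syntenic <- as.logical(df$syntenic)
  validate_triad_set(df[c("triad_id", "gene_a", "gene_b", "gene_d", "syntenic")])
}

#' Construct and validate a triad set from a data frame
#'
#' @param df Data frame with columns \code{triad_id}, \code{gene_a},
#'   \code{gene_b}, \code{gene_d} and optionally \code{syntenic}.
#' @return The validated data frame with class \code{triad_set}.
#' @export
validate_triad_set <- function(df) {
  for (col in c("triad_id", "gene_a", "gene_b", "gene_d")) {
    df[[col]] <- as.character(df[[col]])
    if (anyNA(df[[col]]) || any(!nzchar(df[[col]]))) {
      stop("column '", col, "' contains empty or missing values")
    }
  }
  if (anyDuplicated(df$triad_id)) {
    dup <- unique(df$triad_id[duplicated(df$triad_id)])
    stop("duplicate triad_id: ", paste(dup, collapse = ", "))
  }
  genes <- c(df$gene_a, df$gene_b, df$gene_d)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop("gene ID assigned to more than one homeolog slot: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (is.null(df$syntenic)) df$syntenic <- rep(NA, nrow(df))
  rownames(df) <- NULL
  class(df) <- c("triad_set", "data.frame")
  df
}

#' Read a gene-by-sample expression matrix
#'
#' First column is the gene ID; every remaining column is one sample. Values
#' must be non-negative and complete. The unit (raw counts vs TPM) cannot be
#' inferred from the numbers, so the caller must declare it.
#'
#' @param path Path to a tab-separated expression table.
#' @param unit Either \code{"TPM"} or \code{"counts"}.
#' @return Numeric matrix (genes x samples) with a \code{"unit"} attribute.
#' @export
read_expression_matrix <- function(path, unit = c("TPM", "counts")) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a gene column plus >= 1 sample")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene ID in expression matrix: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (anyDuplicated(colnames(m))) stop("duplicate sample IDs in expression matrix")
  bad <- which(is.na(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("negative or missing expression value at gene '",
         rownames(m)[bad[1L, 1L]], "', sample '", colnames(m)[bad[1L, 2L]], "'")
  }
  attr(m, "unit") <- unit
  m
}

#' Read a sample sheet
#'
#' Columns: \code{sample_id}, \code{tissue}, \code{condition} (one of
#' \code{control}/\code{stress}), \code{replicate} (integer >= 1).
#'
#' @param path Path to a tab-separated sample sheet.
#' @return Data frame of class \code{sample_sheet}.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "tissue", "condition", "replicate"))
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param df Data frame with the sample-sheet columns.
#' @export
validate_sample_sheet <- function(df) {
  df$sample_id <- as.character(df$sample_id)
  df$tissue <- as.character(df$tissue)
  df$condition <- as.character(df$condition)
  allowed <- c("control", "stress")
  bad <- setdiff(unique(df$condition), allowed)
  if (length(bad) > 0L) {
    stop("unknown condition label(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "))
  }
  df$replicate <- as.integer(df$replicate)
  if (anyNA(df$replicate) || any(df$replicate < 1L)) {
    stop("replicate must be an integer >= 1")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a differential-expression results table
#'
#' Requires \code{gene_id} plus \code{fold_change} (stress/control) and/or
#' \code{log2fc}, and the p-value columns \code{pvalue}, \code{padj}. When
#' both fold-change encodings are present they must agree
#' (\code{log2fc == log2(fold_change)} within tolerance); when one is absent
#' it is derived from the other.
#'
#' @param path Path to a tab-separated DE table.
#' @param tol Consistency tolerance between \code{log2fc} and
#'   \code{log2(fold_change)}.
#' @return Data frame of class \code{de_records} with columns
#'   \code{gene_id}, \code{fold_change}, \code{log2fc}, \code{pvalue},
#'   \code{padj}.
#' @export
read_de_table <- function(path, tol = 1e-6) {
  df <- read_tsv_checked(path, "gene_id")
  df$gene_id <- as.character(df$gene_id)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in DE table")
  has_fc <- !is.null(df$fold_change)
  has_l2 <- !is.null(df$log2fc)
  if (!has_fc && !has_l2) stop("DE table needs fold_change and/or log2fc")
  if (has_fc && any(df$fold_change < 0, na.rm = TRUE)) {
    stop("fold_change must be non-negative")
  }
  if (has_fc && has_l2) {
    ok <- is.na(df$fold_change) | is.na(df$log2fc) |
      (df$fold_change == 0 & df$log2fc == -Inf) |
      abs(df$log2fc - log2(df$fold_change)) <= tol
    if (!all(ok)) {
      stop("log2fc inconsistent with log2(fold_change) for gene ",
           df$gene_id[which(!ok)[1L]])
    }
  } else if (has_fc) {
    df$log2fc <- log2(df$fold_change)
  } else {
    df$fold_change <- 2^df$log2fc
  }
  for (col in c("pvalue", "padj")) {
    if (!is.null(df[[col]])) {
      v <- df[[col]]
      if (any(v < 0 | v > 1, na.rm = TRUE)) stop(col, " must lie in [0, 1]")
    }
  }
  keep <- intersect(c("gene_id", "fold_change", "log2fc", "pvalue", "padj"),
                    names(df))
  df <- df[keep]
  rownames(df) <- NULL
  class(df) <- c("de_records", "data.frame")
  df
}

#' Read gene sets from a two-column TSV
#'
#' @param path TSV with columns \code{set_name}, \code{gene_id}.
#' @return Named list of unique gene-ID character vectors.
#' @export
read_gene_sets <- function(path) {
  df <- read_tsv_checked(path, c("set_name", "gene_id"))
  sets <- split(as.character(df$gene_id), as.character(df$set_name))
  lapply(sets, unique)
}

#' Read a solute concentration table
#'
#' Wide format: a \code{solute} column followed by one column per replicate
#' measurement named \code{<condition>_<replicate>} (e.g. \code{control_1},
#' \code{stress_3}); units are umol per g dry weight.
#'
#' @param path Path to a tab-separated solute table.
#' @return Long data frame of class \code{solute_profile} with columns
#'   \code{solute}, \code{condition}, \code{replicate}, \code{concentration}.
#' @export
read_solute_table <- function(path) {
  df <- read_tsv_checked(path, "solute")
  reps <- setdiff(names(df), "solute")
  parsed <- regmatches(reps, regexec("^(control|stress)_([0-9]+)$", reps))
  bad <- reps[lengths(parsed) == 0L]
  if (length(bad) > 0L) {
    stop("replicate columns must be named <condition>_<replicate> with ",
         "condition control or stress; offending: ", paste(bad, collapse = ", "))
  }
  out <- do.call(rbind, lapply(seq_along(reps), function(i) {
    data.frame(solute = as.character(df$solute),
               condition = parsed[[i]][2L],
               replicate = as.integer(parsed[[i]][3L]),
               concentration = as.numeric(df[[reps[i]]]),
               stringsAsFactors = FALSE)
  }))
  if (any(out$concentration < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  rownames(out) <- NULL
  class(out) <- c("solute_profile", "data.frame")
  out
}

#' Read a qPCR Ct table
#'
#' @param path TSV with columns \code{gene}, \code{sample}, \code{ct}.
#' @return Data frame with those columns; Ct values must be finite.
#' @export
read_ct_table <- function(path) {
  df <- read_tsv_checked(path, c("gene", "sample", "ct"))
  df$gene <- as.character(df$gene)
  df$sample <- as.character(df$sample)
  df$ct <- as.numeric(df$ct)
  if (any(!is.finite(df$ct))) stop("Ct values must be finite")
  df
}

#' Write a table as TSV
#'
#' Writes any of the package's tabular objects (or a plain data frame /
#' expression matrix) tab-separated with a header, so that the matching
#' reader reproduces the object. Logical columns are serialized as 0/1.
#'
#' @param x Data frame or matrix.
#' @param path Output path.
#' @param id_column Column name for matrix row names (default
#'   \code{"gene_id"}).
#' @return Invisibly, the path.
#' @export
write_tsv <- function(x, path, id_column = "gene_id") {
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1L] <- id_column
    x <- df
  }
  x <- as.data.frame(x)
  for (col in names(x)) {
    if (is.logical(x[[col]])) x[[col]] <- as.integer(x[[col]])
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Shared TSV reader: header mandatory, required columns checked by name.
read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing required column(s) in '", path, "': ",
         paste(missing, collapse = ", "))
  }
  df
}
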