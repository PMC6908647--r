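## Readers and writers for the pipeline's tabular inputs. All files are
## TSV with a header row; beta matrices use empty cells for missing values.

.read_table <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "", ...)
}

.check_unique <- function(ids, what, path) {
  d <- ids[duplicated(ids)]
  if (length(d))
    stop("duplicate ", what, " id(s) in ", path, ": ",
         paste(unique(d), collapse = ", "))
}

#' Read / write a beta-value matrix
#'
#' A beta matrix is a numeric matrix of methylation fractions in \[0, 1\]
#' with probes as rows and samples as columns; missing values are empty
#' cells on disk and `NA` in memory. Writing then reading preserves ids
#' exactly and values to full precision.
#'
#' @param path file path; TSV with a header row, first column `probe_id`.
#' @return `read_beta_matrix`: a numeric matrix with probe rownames and
#'   sample colnames.
#' @export
read_beta_matrix <- function(path) {
  df <- .read_table(path, colClasses = "character")
  if (ncol(df) < 2L) stop("beta matrix needs a probe_id column and >=1 sample")
  probes <- df[[1L]]
  .check_unique(probes, "probe", path)
  samples <- colnames(df)[-1L]
  .check_unique(samples, "sample", path)
  m <- matrix(NA_real_, length(probes), length(samples),
              dimnames = list(probes, samples))
  for (j in seq_along(samples)) {
    raw <- df[[j + 1L]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(v))
    if (length(bad))
      stop("non-numeric beta value '", raw[bad[1L]], "' at probe ",
           probes[bad[1L]], ", sample ", samples[j])
    m[, j] <- v
  }
  .validate_beta(m)
  m
}

.validate_beta <- function(m) {
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad))
    stop("beta value out of [0,1] at probe ", rownames(m)[bad[1L, 1L]],
         ", sample ", colnames(m)[bad[1L, 2L]], ": ",
         m[bad[1L, 1L], bad[1L, 2L]])
  invisible(m)
}

#' @rdname read_beta_matrix
#' @param beta numeric matrix as returned by [read_beta_matrix()].
#' @export
write_beta_matrix <- function(beta, path) {
  .validate_beta(beta)
  df <- data.frame(probe_id = rownames(beta),
                   format(beta, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  df[-1L][is.na(beta)] <- ""
  colnames(df) <- c("probe_id", colnames(beta))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a probe annotation manifest
#'
#' Columns: `probe_id`, `chromosome`, `position` (1-based), `gene`
#' (semicolon-joined symbols, may be empty), `gene_region`
#' (semicolon-joined, parallel to `gene`, values from [GENE_REGIONS]),
#' `cgi_relation` (one of [CGI_RELATIONS]) and `snp_flag` (TRUE/FALSE).
#'
#' @param path TSV path.
#' @return a data.frame with the columns above.
#' @export
read_manifest <- function(path) {
  df <- .read_table(path)
  need <- c("probe_id", "chromosome", "position", "gene", "gene_region",
            "cgi_relation", "snp_flag")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         "; expected header: ", paste(need, collapse = ", "))
  .check_unique(df$probe_id, "probe", path)
  if (any(df$position < 1, na.rm = TRUE)) stop("positions must be >= 1")
  df$gene[is.na(df$gene)] <- ""
  df$gene_region[is.na(df$gene_region)] <- ""
  regions <- unlist(strsplit(df$gene_region[df$gene_region != ""], ";"))
  bad <- setdiff(regions, GENE_REGIONS)
  if (length(bad))
    stop("unknown gene_region value(s): ", paste(unique(bad), collapse = ", "))
  bad <- setdiff(df$cgi_relation, CGI_RELATIONS)
  if (length(bad))
    stop("unknown cgi_relation value(s): ", paste(unique(bad), collapse = ", "))
  df$snp_flag <- as.logical(df$snp_flag)
  if (anyNA(df$snp_flag)) stop("snp_flag must be TRUE/FALSE")
  df
}

#' @rdname read_manifest
#' @param ann manifest data.frame.
#' @export
write_manifest <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expand a manifest into one row per probe-gene link
#'
#' Semicolon-joined gene / gene_region fields become parallel rows.
#'
#' @param ann manifest data.frame (see [read_manifest()]).
#' @return data.frame with columns `probe_id`, `gene`, `gene_region`.
#' @export
probe_gene_links <- function(ann) {
  keep <- ann$gene != "" & !is.na(ann$gene)
  genes <- strsplit(ann$gene[keep], ";")
  regions <- strsplit(ann$gene_region[keep], ";")
  n <- lengths(genes)
  if (!all(n == lengths(regions)))
    stop("gene and gene_region lists differ in length for some probe")
  data.frame(probe_id = rep(ann$probe_id[keep], n),
             gene = unlist(genes), gene_region = unlist(regions),
             stringsAsFactors = FALSE)
}

#' Read / write a read-count matrix
#'
#' Genes as rows, samples as columns; entries must be non-negative
#' integers.
#'
#' @param path TSV path, first column `gene_id`.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- .read_table(path)
  if (ncol(df) < 2L) stop("count matrix needs a gene_id column and >=1 sample")
  genes <- as.character(df[[1L]])
  .check_unique(genes, "gene", path)
  m <- as.matrix(df[-1L])
  if (!is.numeric(m)) stop("counts must be numeric")
  if (anyNA(m)) stop("counts may not be missing")
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(m != round(m)))
    stop("counts must be integers; first offender: ",
         m[which(m != round(m))[1L]])
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' @rdname read_counts
#' @param counts integer matrix.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' Mandatory columns `sample_id` (unique) and `condition`
#' (`tumor`/`normal`); optional `cancer_type`, `histology`, `hpv_status`,
#' `hpv_clade`.
#'
#' @param path TSV path.
#' @return data.frame, `condition` a factor with levels normal, tumor.
#' @export
read_sample_sheet <- function(path) {
  df <- .read_table(path)
  need <- c("sample_id", "condition")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         "; expected at least: ", paste(need, collapse = ", "))
  .check_unique(df$sample_id, "sample", path)
  df$condition <- .as_condition(df$condition)
  df
}

#' @rdname read_sample_sheet
#' @param samples sample sheet data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
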