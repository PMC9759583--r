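#' Construct a genus abundance table
#'
#' A samples-by-genera matrix of sequencing counts or closed relative
#' abundances, the basic container consumed by the diversity and
#' classification functions.
#'
#' @param values Numeric matrix, rows = samples, columns = genera, with
#'   row and column names set to the sample and genus identifiers.
#' @param mode `"counts"` (non-negative integers) or `"relative"`
#'   (non-negative, rows summing to 1 within 1e-9).
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if ((is.null(rownames(values)) && nrow(values) > 0) ||
      is.null(colnames(values)))
    stop("`values` must carry sample ids (rownames) and genus ids (colnames)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate genus ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative value at sample '%s', genus '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
  if (mode == "counts") {
    if (any(abs(values - round(values)) > 1e-8))
      stop("counts mode requires integer values")
    storage.mode(values) <- "double"
  } else {
    rs <- rowSums(values)
    bad <- which(abs(rs - 1) > 1e-9)
    if (length(bad) > 0)
      stop(sprintf("relative mode: rows must sum to 1 (row '%s' sums to %.6g)",
                   rownames(values)[bad[1]], rs[bad[1]]))
  }
  structure(list(values = values, mode = mode), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d genera (%s mode)\n",
              nrow(x$values), ncol(x$values), x$mode))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Convert a count table to closed relative abundances
#'
#' @param table An `abundance_table` in counts mode.
#' @return An `abundance_table` in relative mode (rows sum to 1).
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode == "relative") return(table)
  tot <- rowSums(table$values)
  if (any(tot == 0)) stop("cannot close a sample with zero total count")
  abundance_table(table$values / tot, mode = "relative")
}

#' Read / write abundance tables as TSV
#'
#' Tab-separated, samples as rows; first column `sample_id`, remaining
#' columns one per genus. A write followed by a read is the identity
#' (up to float formatting below 1e-12).
#'
#' @param path File path.
#' @param mode `"counts"` or `"relative"`.
#' @return An `abundance_table`.
#' @export
read_abundance <- function(path, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("abundance file needs a sample_id column plus genus columns")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric abundance values in ", path)
  rownames(m) <- ids
  abundance_table(m, mode = mode)
}

#' @rdname read_abundance
#' @param table An `abundance_table` to serialize.
#' @export
write_abundance <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(sample_id = rownames(table$values),
                   table$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop samples with low sequencing depth
#'
#' Retains exactly the samples whose total assigned read count is at least
#' `min_total` (the study's QC cutoff of 5000 reads); sample order is
#' preserved and the operation is idempotent.
#'
#' @param table An `abundance_table` in counts mode.
#' @param min_total Minimum row total retained (default 5000).
#' @return The filtered `abundance_table`.
#' @export
filter_low_depth <- function(table, min_total = 5000) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode != "counts")
    stop("depth filtering applies to counts mode only")
  keep <- rowSums(table$values) >= min_total
  if (!any(keep)) warning("all samples fall below the depth cutoff")
  abundance_table(table$values[keep, , drop = FALSE], mode = "counts")
}

#' Homeostatic model assessment of insulin resistance
#'
#' Matthews formula on conventional units:
#' HOMA-IR = glucose (mg/dL) x insulin (uIU/mL) / 405.
#'
#' @param glucose Fasting glucose, mg/dL (> 0).
#' @param insulin Fasting insulin, uIU/mL (> 0).
#' @return HOMA-IR (vectorized).
#' @export
compute_homa_ir <- function(glucose, insulin) {
  if (any(glucose <= 0) || any(insulin <= 0))
    stop("glucose and insulin must be positive")
  glucose * insulin / 405
}

#' Assign insulin-resistance status and study subgroup
#'
#' Samples are insulin resistant (IR) when HOMA-IR is strictly above the
#' sex-specific cutoff (1.8 for men, 2.2 for women by default); crossing
#' IR/IS with the ultrasonography fatty-liver label yields the four
#' subgroups ISNF, ISFL, IRNF, IRFL.
#'
#' @param records Data frame with columns `sex` ("M"/"F"), `glucose`,
#'   `insulin`, `fl_label` ("NF"/"FL").
#' @param cutoffs Named numeric vector `c(M = , F = )` of HOMA-IR cutoffs.
#' @return Data frame with columns `homa_ir`, `ir_status`, `subgroup`.
#' @export
assign_groups <- function(records, cutoffs = c(M = 1.8, F = 2.2)) {
  req <- c("sex", "glucose", "insulin", "fl_label")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(is.na(records$sex)) || !all(records$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F' for every record")
  if (!all(records$fl_label %in% c("NF", "FL")))
    stop("fl_label must be 'NF' or 'FL'")
  homa <- compute_homa_ir(records$glucose, records$insulin)
  ir <- homa > unname(cutoffs[records$sex])
  ir_status <- ifelse(ir, "IR", "IS")
  subgroup <- paste0(ir_status, records$fl_label)
  data.frame(homa_ir = homa, ir_status = ir_status, subgroup = subgroup,
             stringsAsFactors = FALSE)
}

#' Drop clinical records with missing required fields
#'
#' The cohort QC excluded participants with missing data; the rule here is
#' explicit: a sample is dropped when any of `fields` is NA, and the count
#' of dropped samples is reported via a message.
#'
#' @param records Clinical data frame.
#' @param fields Character vector of required columns.
#' @return The complete-case subset.
#' @export
drop_incomplete <- function(records,
                            fields = c("sex", "glucose", "insulin", "fl_label")) {
  miss <- setdiff(fields, names(records))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  ok <- stats::complete.cases(records[, fields, drop = FALSE])
  if (any(!ok)) message(sum(!ok), " record(s) dropped for missing data")
  records[ok, , drop = FALSE]
}
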