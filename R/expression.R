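## Expression linkage: median-of-ratios normalization, per-gene fold
## changes (M/A values), and the test of whether exclusive H3K27ac classes
## stratify expression change.

#' Median-of-ratios size factors
#'
#' Reference is the per-gene geometric mean over samples, computed on
#' genes positive in all samples; each sample's factor is the median ratio
#' of its counts to the reference.
#'
#' @param counts numeric matrix or data.frame, genes x samples (>= 2
#'   samples), non-negative counts. A `gene_id` column is tolerated and
#'   ignored.
#' @return named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  m <- as.matrix(counts)
  if (!is.null(colnames(m)) && "gene_id" %in% colnames(m)) {
    m <- m[, setdiff(colnames(m), "gene_id"), drop = FALSE]
  }
  storage.mode(m) <- "numeric"
  if (ncol(m) < 2L) stop("need at least 2 samples")
  if (any(m < 0)) stop("counts must be non-negative")
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) stop("no gene has positive counts in all samples")
  logm <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(logm)
  apply(logm, 2L, function(x) exp(stats::median(x - ref)))
}

#' Normalized counts and log2 fold changes
#'
#' Genes with a zero normalized control count are flagged incalculable
#' and carry NA fold changes, mirroring the exclusion of genes without
#' reads in the control sample.
#'
#' @param counts data.frame with `gene_id` and two count columns (control
#'   first, experimental second) or a 2-column matrix.
#' @param factors size factors from [size_factors()] (recomputed when
#'   missing).
#' @param control,experimental column indices among the count columns.
#' @return data.frame with `gene_id`, raw and normalized counts,
#'   `calculable`, `log2_fc` (M), `mean_expr` (A, log2 mean of normalized
#'   counts).
#' @export
fold_changes <- function(counts, factors = NULL, control = 1L,
                         experimental = 2L) {
  has_gid <- !is.null(colnames(counts)) && "gene_id" %in% colnames(counts)
  gid <- if (has_gid) counts$gene_id else rownames(counts)
  m <- as.matrix(counts)
  if (has_gid) m <- m[, setdiff(colnames(m), "gene_id"), drop = FALSE]
  storage.mode(m) <- "numeric"
  if (is.null(factors)) factors <- size_factors(m)
  norm <- sweep(m, 2L, factors, "/")
  ctrl <- norm[, control]
  expt <- norm[, experimental]
  calculable <- ctrl > 0
  log2_fc <- ifelse(calculable, log2(expt / ctrl), NA_real_)
  data.frame(gene_id = gid,
             count_ctrl = m[, control], count_expt = m[, experimental],
             norm_ctrl = ctrl, norm_expt = expt,
             calculable = calculable, log2_fc = log2_fc,
             mean_expr = log2((ctrl + expt) / 2),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Test whether exclusive H3K27ac classes stratify expression change
#'
#' Joins fold changes to exclusive class labels, drops empty classes with
#' a warning, and runs a Kruskal-Wallis omnibus test followed by Dunn's
#' pairwise comparisons on the calculable genes.
#'
#' @param records output of [fold_changes()].
#' @param labels data.frame with `gene_id` and `exclusive_class` (as from
#'   [label_lcred_content()]); genes without an exclusive class are
#'   excluded.
#' @return list with `by_class` (n, median, IQR per class), `omnibus`
#'   (Kruskal-Wallis H, df, p), `pairwise` (Dunn z and p), `groups` (the
#'   per-class fold-change vectors).
#' @export
class_expression_test <- function(records, labels) {
  lab <- labels[!is.na(labels$exclusive_class), , drop = FALSE]
  d <- merge(records[records$calculable, c("gene_id", "log2_fc")],
             lab[, c("gene_id", "exclusive_class")], by = "gene_id")
  groups <- split(d$log2_fc, d$exclusive_class)
  empty <- names(groups)[lengths(groups) == 0L]
  if (length(empty) > 0L) {
    warning("dropping empty class(es): ", paste(empty, collapse = ", "))
    groups <- groups[lengths(groups) > 0L]
  }
  if (length(groups) < 2L) stop("need at least 2 nonempty classes")
  kd <- kruskal_dunn(groups)
  by_class <- data.frame(
    class = names(groups), n = lengths(groups),
    median_log2_fc = vapply(groups, stats::median, numeric(1)),
    iqr_log2_fc = vapply(groups, stats::IQR, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(by_class = by_class, omnibus = kd$omnibus, pairwise = kd$pairwise,
       groups = groups)
}
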