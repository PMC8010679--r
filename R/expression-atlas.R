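#' Median-of-ratios library size factors
#'
#' The median-count-ratio approach: a per-gene reference is the geometric
#' mean of the gene's counts across columns, computed over genes with
#' strictly positive counts everywhere; each column's size factor is the
#' median over those genes of count / reference.
#'
#' @param counts Non-negative numeric matrix, genes in rows, libraries
#'   (sample x replicate) in columns.
#' @return Named positive numeric vector, one factor per column.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), ncol(counts) >= 1)
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable)) {
    stop("no gene has positive counts in every column; ",
         "median-of-ratios reference is undefined (pseudo-reference ",
         "fallback is disabled)")
  }
  apply(counts, 2, function(col) {
    exp(median(log(col[usable]) - log_geo[usable]))
  })
}

#' Normalize a count matrix by library size factors
#'
#' @param counts Count matrix (genes x columns).
#' @param factors Positive per-column size factors, e.g. from
#'   [size_factors()].
#' @return Matrix of normalized expression values (counts / factor).
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  counts <- as.matrix(counts)
  stopifnot(length(factors) == ncol(counts), all(factors > 0))
  sweep(counts, 2, factors, "/")
}

# Split "SAMPLE.REP" column names into sample and replicate.
.parse_columns <- function(col_names) {
  if (any(!grepl("^.+\\.[0-9]+$", col_names))) {
    bad <- col_names[!grepl("^.+\\.[0-9]+$", col_names)][1]
    stop("column name '", bad, "' is not of the form SAMPLE.REP")
  }
  data.frame(column = col_names,
             sample = sub("\\.[0-9]+$", "", col_names),
             replicate = sub("^.*\\.", "", col_names),
             stringsAsFactors = FALSE)
}

#' Average replicate columns into per-sample means
#'
#' @param normalized Normalized matrix with `SAMPLE.REP` column names.
#' @return Matrix genes x samples of replicate-averaged values.
#' @export
replicate_means <- function(normalized) {
  meta <- .parse_columns(colnames(normalized))
  samples <- unique(meta$sample)
  out <- vapply(samples, function(s) {
    rowMeans(normalized[, meta$sample == s, drop = FALSE])
  }, numeric(nrow(normalized)))
  dimnames(out) <- list(rownames(normalized), samples)
  out
}

#' Call genes expressed per sample
#'
#' A gene is expressed in a sample when its normalized count reaches the
#' threshold (inclusive) in both biological replicates of that sample.
#'
#' @param normalized Normalized matrix with `SAMPLE.REP` column names and
#'   exactly two replicates per sample.
#' @param threshold Normalized-count threshold (default 5).
#' @return List with `calls` (logical matrix genes x samples) and `summary`
#'   (data.frame: n_genes, expressed_any, expressed_all, expressed_none,
#'   pct_expressed_any).
#' @export
call_expressed <- function(normalized, threshold = 5) {
  meta <- .parse_columns(colnames(normalized))
  reps_per_sample <- table(meta$sample)
  if (any(reps_per_sample != 2)) {
    bad <- names(reps_per_sample)[reps_per_sample != 2][1]
    stop("sample '", bad, "' does not have exactly 2 replicates")
  }
  samples <- unique(meta$sample)
  calls <- vapply(samples, function(s) {
    sub <- normalized[, meta$sample == s, drop = FALSE]
    rowSums(sub >= threshold) == ncol(sub)
  }, logical(nrow(normalized)))
  dimnames(calls) <- list(rownames(normalized), samples)
  n_any <- sum(rowSums(calls) >= 1)
  summary <- data.frame(
    n_genes = nrow(calls),
    expressed_any = n_any,
    expressed_all = sum(rowSums(calls) == ncol(calls)),
    expressed_none = sum(rowSums(calls) == 0),
    pct_expressed_any = 100 * n_any / nrow(calls))
  list(calls = calls, summary = summary)
}

#' Shannon-entropy expression breadth
#'
#' For each gene the replicate-averaged sample means are rescaled to a
#' distribution p_s over samples and summarized by the Shannon entropy
#' H = -sum p_s log2 p_s (with 0 log 0 = 0).  H is 0 for a gene expressed
#' in a single sample and log2(S) for perfectly uniform expression over S
#' samples; genes with zero total expression get NA.
#'
#' @param normalized Normalized matrix with `SAMPLE.REP` column names.
#' @param calls Optional expressed-gene calls from [call_expressed()]; when
#'   given, the per-gene count of expressed samples is included.
#' @return data.frame with gene_id, entropy_bits and (when `calls` is
#'   given) n_samples_expressed.
#' @export
expression_breadth <- function(normalized, calls = NULL) {
  means <- replicate_means(normalized)
  tot <- rowSums(means)
  H <- rep(NA_real_, nrow(means))
  pos <- tot > 0
  if (any(pos)) {
    p <- means[pos, , drop = FALSE] / tot[pos]
    plogp <- ifelse(p > 0, p * log2(p), 0)
    H[pos] <- -rowSums(plogp)
  }
  out <- data.frame(gene_id = rownames(means), entropy_bits = H,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(calls)) {
    out$n_samples_expressed <- rowSums(calls$calls)[match(out$gene_id,
                                                          rownames(calls$calls))]
  }
  out
}

#' SD/mean expression stability ranking
#'
#' Ranks genes by the coefficient of variation of their expression
#' (standard deviation divided by mean): low values mark stably expressed
#' genes, candidates for qRT-PCR references.  By default the SD is the
#' population SD (divisor n) over replicate-averaged sample values; both
#' choices are configurable.
#'
#' @param normalized Normalized matrix with `SAMPLE.REP` column names.
#' @param thresholds SD/mean cutoffs for which gene counts are reported.
#' @param sd_type "population" (divisor n, default) or "sample"
#'   (divisor n - 1).
#' @param replicate_average Average replicates into per-sample values
#'   before computing SD/mean (default TRUE); FALSE uses all columns.
#' @return List with `scores` (data.frame gene_id, mean, sd_over_mean,
#'   sorted ascending; zero-mean genes excluded and listed in `excluded`),
#'   `threshold_counts` (named counts below each cutoff) and `excluded`.
#' @export
stability_ranking <- function(normalized, thresholds = c(0.2, 0.25, 0.3),
                              sd_type = c("population", "sample"),
                              replicate_average = TRUE) {
  sd_type <- match.arg(sd_type)
  values <- if (replicate_average) replicate_means(normalized) else normalized
  mu <- rowMeans(values)
  excluded <- rownames(values)[mu == 0]
  keep <- mu > 0
  values <- values[keep, , drop = FALSE]
  mu <- mu[keep]
  n <- ncol(values)
  sds <- apply(values, 1, sd)                 # divisor n - 1
  if (sd_type == "population") sds <- sds * sqrt((n - 1) / n)
  ratio <- sds / mu
  ord <- order(ratio)
  scores <- data.frame(gene_id = rownames(values)[ord], mean = mu[ord],
                       sd_over_mean = ratio[ord],
                       stringsAsFactors = FALSE, row.names = NULL)
  threshold_counts <- vapply(thresholds, function(t) sum(ratio < t),
                             integer(1))
  names(threshold_counts) <- paste0("<", thresholds)
  list(scores = scores, threshold_counts = threshold_counts,
       excluded = excluded)
}

#' Correlation-based distance between samples
#'
#' Replicates are averaged per sample and the distance between two samples
#' is 1 - r^2, the complement of the squared Pearson correlation of their
#' expression profiles.
#'
#' @param normalized Normalized matrix with `SAMPLE.REP` column names.
#' @return Symmetric samples x samples distance matrix with zero diagonal,
#'   values in \[0, 1\].
#' @export
sample_distance <- function(normalized) {
  means <- replicate_means(normalized)
  if (ncol(means) < 2) stop("need at least 2 samples")
  vars <- apply(means, 2, stats::var)
  if (any(vars == 0)) {
    stop("zero-variance sample '", colnames(means)[vars == 0][1],
         "': correlation undefined")
  }
  r <- cor(means)
  d <- 1 - r^2
  diag(d) <- 0
  d
}

#' Hierarchical clustering of atlas samples
#'
#' Agglomerative clustering of the sample distance matrix (average linkage
#' by default), returned as a phylogenetic tree that can be written to
#' newick with [ape::write.tree()].
#'
#' @param distance Symmetric distance matrix, e.g. from [sample_distance()].
#' @param linkage Linkage passed to [stats::hclust()] (default "average",
#'   i.e. UPGMA).
#' @return An [ape::as.phylo()] tree over the sample labels.
#' @export
cluster_samples <- function(distance, linkage = "average") {
  distance <- as.matrix(distance)
  if (!isSymmetric(unname(distance), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  hc <- hclust(as.dist(distance), method = linkage)
  ape::as.phylo(hc)
}

#' Full atlas-statistics pipeline
#'
#' Normalizes a count matrix by median-of-ratios size factors, then
#' computes expressed-gene calls, entropy breadth, SD/mean stability and
#' the sample dendrogram.  When `out_dir` is given, every table is written
#' as TSV and the dendrogram as newick.
#'
#' @param counts Count matrix (genes x `SAMPLE.REP` columns) or a path to a
#'   counts TSV readable by [read_counts_tsv()].
#' @param threshold Expressed-gene threshold on normalized counts.
#' @param stability_thresholds SD/mean cutoffs to report.
#' @param out_dir Optional output directory.
#' @return List with `size_factors`, `normalized`, `expressed`, `breadth`,
#'   `stability`, `distance` and `tree`.
#' @export
atlas_stats <- function(counts, threshold = 5,
                        stability_thresholds = c(0.2, 0.25, 0.3),
                        out_dir = NULL) {
  if (is.character(counts)) counts <- read_counts_tsv(counts)
  sf <- size_factors(counts)
  norm <- normalize_counts(counts, sf)
  expressed <- call_expressed(norm, threshold)
  breadth <- expression_breadth(norm, expressed)
  stability <- stability_ranking(norm, stability_thresholds)
  d <- sample_distance(norm)
  tree <- cluster_samples(d)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_table(data.frame(column = names(sf), size_factor = sf),
                    file.path(out_dir, "size_factors.tsv"))
    write_counts_tsv(round(norm, 4), file.path(out_dir, "normalized.tsv"),
                     integer_counts = FALSE)
    write_tsv_table(data.frame(gene_id = rownames(expressed$calls),
                               expressed$calls, check.names = FALSE),
                    file.path(out_dir, "expressed_calls.tsv"))
    write_tsv_table(expressed$summary,
                    file.path(out_dir, "expressed_summary.tsv"))
    write_tsv_table(breadth, file.path(out_dir, "breadth.tsv"))
    write_tsv_table(stability$scores, file.path(out_dir, "stability.tsv"))
    write_tsv_table(data.frame(sample = rownames(d), d, check.names = FALSE),
                    file.path(out_dir, "sample_distance.tsv"))
    ape::write.tree(tree, file.path(out_dir, "sample_clustering.nwk"))
  }
  list(size_factors = sf, normalized = norm, expressed = expressed,
       breadth = breadth, stability = stability, distance = d, tree = tree)
}
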