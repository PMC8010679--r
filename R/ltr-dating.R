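#' An annotated LTR retroelement with its two long terminal repeats
#'
#' Minimal in-memory representation of one full or partial LTR
#' retrotransposon: the 5' and 3' LTR sequences (on the element's own
#' orientation), a family label and the set of retroelement protein domains
#' detected in the internal region.
#'
#' @param element_id Identifier.
#' @param ltr5,ltr3 Non-empty nucleotide strings over A, C, G, T, N.
#' @param family Family label; defaults to "unclassified".
#' @param superfamily Optional superfamily label (e.g. "Ty3/Gypsy").
#' @param domains_present Character subset of GAG, RT, RH, AP, INT.
#' @return Object of class `ltr_element`.
#' @export
ltr_element <- function(element_id, ltr5, ltr3, family = "unclassified",
                        superfamily = NA_character_,
                        domains_present = character()) {
  stopifnot(is.character(ltr5), is.character(ltr3),
            nzchar(ltr5), nzchar(ltr3), nzchar(family))
  structure(list(element_id = as.character(element_id),
                 family = family, superfamily = superfamily,
                 ltr5 = ltr5, ltr3 = ltr3,
                 domains_present = unique(as.character(domains_present))),
            class = "ltr_element")
}

#' The five protein domains of an intact LTR retroelement
#' @export
FULL_LENGTH_DOMAINS <- c("GAG", "RT", "RH", "AP", "INT")

#' Keep only full-length elements
#'
#' Retains exactly the elements whose detected protein domains include all
#' five of GAG, RT, RH, AP and INT; everything else is considered truncated
#' or degenerate and excluded from dating.
#'
#' @param elements List of [ltr_element()] objects.
#' @return Filtered list.
#' @export
filter_full_length <- function(elements) {
  keep <- vapply(elements,
                 function(e) all(FULL_LENGTH_DOMAINS %in% e$domains_present),
                 logical(1))
  elements[keep]
}

#' Alignment scoring parameters
#'
#' Scores for the global dynamic-programming aligner.  A gap run of length
#' L costs `gap_open + L * gap_extend`.
#'
#' @param match,mismatch Per-column substitution scores.
#' @param gap_open,gap_extend Gap penalties (both must be negative).
#' @return Object of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 2, mismatch = -1,
                              gap_open = -5, gap_extend = -1) {
  stopifnot(gap_open < 0, gap_extend < 0, match > mismatch)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_scoring")
}

.PURINES <- c("A", "G")
.PYRIMIDINES <- c("C", "T")

# Classify each column of an alignment as match / transition / transversion /
# gap / ambiguous.
.classify_columns <- function(a1, a2) {
  b1 <- strsplit(a1, "", fixed = TRUE)[[1]]
  b2 <- strsplit(a2, "", fixed = TRUE)[[1]]
  cls <- character(length(b1))
  gap <- b1 == "-" | b2 == "-"
  amb <- !gap & (b1 == "N" | b2 == "N")
  same <- !gap & !amb & b1 == b2
  ts <- !gap & !amb & !same &
    ((b1 %in% .PURINES & b2 %in% .PURINES) |
     (b1 %in% .PYRIMIDINES & b2 %in% .PYRIMIDINES))
  cls[gap] <- "gap"
  cls[amb] <- "ambiguous"
  cls[same] <- "match"
  cls[ts] <- "transition"
  cls[!gap & !amb & !same & !ts] <- "transversion"
  cls
}

#' Globally align the two LTRs of an element
#'
#' End-to-end (Needleman-Wunsch) alignment of the 5' vs 3' LTR under affine
#' gap costs, with every column classified as match, transition,
#' transversion, gap or ambiguous (N).  Ties in the dynamic program are
#' broken deterministically.
#'
#' @param element An [ltr_element()], or a length-2 character vector of the
#'   two sequences.
#' @param scoring An [alignment_scoring()].
#' @return Object of class `ltr_alignment` with fields `aligned1`,
#'   `aligned2`, `score` and `columns` (per-column classification).
#' @export
align_ltr_pair <- function(element, scoring = alignment_scoring()) {
  if (inherits(element, "ltr_element")) {
    s1 <- element$ltr5; s2 <- element$ltr3
  } else {
    stopifnot(is.character(element), length(element) == 2L)
    s1 <- element[1]; s2 <- element[2]
  }
  if (!nzchar(s1) || !nzchar(s2)) stop("empty LTR sequence")
  if (grepl("[^ACGTN]", s1) || grepl("[^ACGTN]", s2)) {
    stop("LTR sequences must be over the alphabet A, C, G, T, N")
  }
  res <- .nw_align_cpp(s1, s2, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)
  structure(list(aligned1 = res$aligned1, aligned2 = res$aligned2,
                 score = res$score,
                 columns = .classify_columns(res$aligned1, res$aligned2)),
            class = "ltr_alignment")
}

#' Transition and transversion frequencies of an aligned LTR pair
#'
#' Counts compared sites (columns with a nucleotide in both rows; gap and N
#' columns are pairwise-deleted) and returns the transition frequency p and
#' the transversion frequency q over those sites.
#'
#' @param alignment An `ltr_alignment` from [align_ltr_pair()].
#' @return List with `p`, `q` and `n_sites`.
#' @export
substitution_frequencies <- function(alignment) {
  stopifnot(inherits(alignment, "ltr_alignment"))
  cls <- alignment$columns
  n_sites <- sum(cls %in% c("match", "transition", "transversion"))
  if (n_sites == 0L) {
    stop("no comparable sites: p and q are undefined for this pair")
  }
  list(p = sum(cls == "transition") / n_sites,
       q = sum(cls == "transversion") / n_sites,
       n_sites = n_sites)
}

#' Kimura two-parameter distance between two LTRs
#'
#' K = -1/2 * ln\[(1 - 2p - q) * sqrt(1 - 2q)\] with p the transition and q
#' the transversion frequency.  When either logarithm argument is
#' non-positive the pair is saturated: divergence is beyond the range the
#' two-parameter correction can invert, and the estimate is flagged rather
#' than reported.
#'
#' @param p Transition frequency (fraction of compared sites).
#' @param q Transversion frequency.
#' @param n_sites Number of compared sites (bookkeeping only).
#' @return Object of class `k2p_estimate` with fields `p`, `q`, `n_sites`,
#'   `K` (NA when saturated) and `saturated`.
#' @export
k2p_distance <- function(p, q, n_sites = NA_integer_) {
  stopifnot(p >= 0, q >= 0, p + q <= 1)
  w1 <- 1 - 2 * p - q
  w2 <- 1 - 2 * q
  saturated <- w1 <= 0 || w2 <= 0
  K <- if (saturated) NA_real_ else -0.5 * log(w1 * sqrt(w2))
  structure(list(p = p, q = q, n_sites = n_sites, K = K,
                 saturated = saturated),
            class = "k2p_estimate")
}

#' Insertion time from LTR divergence
#'
#' The two LTRs are identical at insertion and diverge independently
#' afterwards, so the element age is T = K / (2 r) with K the distance
#' between the LTRs and r the substitution rate per site per year.
#'
#' @param K K2P distance (>= 0), e.g. from [k2p_distance()].
#' @param rate_r Substitution rate (default the plant nuclear clock
#'   1.3e-8 subs/site/year).
#' @param threshold_years Recency threshold; elements strictly younger are
#'   flagged recent (default 0.5 My).
#' @param element_id Optional identifier carried through.
#' @return Object of class `insertion_time_estimate` with fields
#'   `element_id`, `T_years`, `r_used`, `recent`, `threshold_years`.
#' @export
insertion_time <- function(K, rate_r = 1.3e-8, threshold_years = 5e5,
                           element_id = NA_character_) {
  if (rate_r <= 0) stop("rate_r must be > 0")
  stopifnot(K >= 0)
  T_years <- K / (2 * rate_r)
  # strict T < threshold on the exact value: ages within one part in 1e8 of
  # the threshold are boundary cases and classify as old
  tol <- threshold_years * sqrt(.Machine$double.eps)
  structure(list(element_id = element_id, T_years = T_years,
                 r_used = rate_r, recent = T_years < threshold_years - tol,
                 threshold_years = threshold_years),
            class = "insertion_time_estimate")
}

#' Date a set of LTR elements
#'
#' Runs the full per-element dating pipeline: global LTR alignment,
#' substitution frequencies, K2P distance and insertion time.  Saturated
#' pairs (divergence beyond the K2P correction's range) get NA ages and are
#' counted in the `saturated` column rather than dropped silently.
#'
#' @param elements List of [ltr_element()] objects.
#' @param scoring An [alignment_scoring()].
#' @param rate_r Substitution rate per site per year.
#' @param threshold_years Recency threshold in years.
#' @return data.frame with element_id, family, p, q, n_sites, K, T_years,
#'   recent, saturated.
#' @export
date_elements <- function(elements, scoring = alignment_scoring(),
                          rate_r = 1.3e-8, threshold_years = 5e5) {
  rows <- lapply(elements, function(e) {
    aln <- align_ltr_pair(e, scoring)
    fr <- substitution_frequencies(aln)
    est <- k2p_distance(fr$p, fr$q, fr$n_sites)
    if (est$saturated) {
      data.frame(element_id = e$element_id, family = e$family,
                 p = fr$p, q = fr$q, n_sites = fr$n_sites,
                 K = NA_real_, T_years = NA_real_, recent = NA,
                 saturated = TRUE, stringsAsFactors = FALSE)
    } else {
      it <- insertion_time(est$K, rate_r, threshold_years, e$element_id)
      data.frame(element_id = e$element_id, family = e$family,
                 p = fr$p, q = fr$q, n_sites = fr$n_sites,
                 K = est$K, T_years = it$T_years, recent = it$recent,
                 saturated = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  n_sat <- sum(out$saturated)
  if (n_sat > 0) {
    warning(n_sat, " saturated pair(s) excluded from dating")
  }
  out
}

#' Cross-genome 2x2 table of recent vs old insertions
#'
#' @param times_a,times_b Logical vectors of recency flags (or data.frames
#'   with a `recent` column, e.g. from [date_elements()]; NA entries from
#'   saturated pairs are dropped).
#' @param labels Genome labels for the row names.
#' @return 2x2 integer matrix (genomes x recent/old) of class
#'   `recency_table`.
#' @export
recency_contingency <- function(times_a, times_b,
                                labels = c("genome_a", "genome_b")) {
  get_flags <- function(x) {
    if (is.data.frame(x)) x <- x$recent
    x[!is.na(x)]
  }
  fa <- get_flags(times_a); fb <- get_flags(times_b)
  if (length(fa) == 0L || length(fb) == 0L) {
    stop("both genomes need at least one dated element")
  }
  tab <- matrix(c(sum(fa), sum(!fa), sum(fb), sum(!fb)),
                nrow = 2, byrow = TRUE,
                dimnames = list(labels, c("recent", "old")))
  structure(tab, class = c("recency_table", class(tab)))
}

#' Two-sided exact Fisher test for a 2x2 table
#'
#' Conditional on both margins, the cell count follows a hypergeometric
#' distribution; the two-sided p-value is the sum of the probabilities of
#' all tables with the same margins whose point probability does not
#' exceed that of the observed table (within relative tolerance 1e-7, the
#' minimum-likelihood definition).
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return The two-sided p-value in (0, 1].
#' @export
fisher_exact <- function(table) {
  tab <- unclass(as.matrix(table))
  stopifnot(identical(dim(tab), c(2L, 2L)) || all(dim(tab) == 2))
  if (any(tab < 0)) stop("negative cell count")
  if (any(tab != round(tab))) stop("cell counts must be integers")
  m1 <- tab[1, 1] + tab[1, 2]   # row margins
  m2 <- tab[2, 1] + tab[2, 2]
  n1 <- tab[1, 1] + tab[2, 1]   # first column margin
  if (m1 == 0 || m2 == 0 || n1 == 0 || (tab[1, 2] + tab[2, 2]) == 0) {
    stop("all margins must be positive")
  }
  support <- max(0, n1 - m2):min(n1, m1)
  probs <- dhyper(support, m1, m2, n1)
  p_obs <- dhyper(tab[1, 1], m1, m2, n1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Per-family copy numbers and fold ratios across two genomes
#'
#' @param families_a,families_b Character vectors of family labels, one per
#'   element, for the two genomes.
#' @param labels Genome labels used in the column names.
#' @return data.frame with one row per family present in either genome:
#'   counts, within-genome fractions and the A/B fold ratio (NA when the
#'   family is absent from B).
#' @export
family_copy_summary <- function(families_a, families_b,
                                labels = c("a", "b")) {
  fams <- sort(unique(c(families_a, families_b)))
  n_a <- vapply(fams, function(f) sum(families_a == f), integer(1))
  n_b <- vapply(fams, function(f) sum(families_b == f), integer(1))
  out <- data.frame(
    family = fams, count_a = n_a, count_b = n_b,
    fraction_a = if (length(families_a)) n_a / length(families_a) else NA,
    fraction_b = if (length(families_b)) n_b / length(families_b) else NA,
    fold_ratio = ifelse(n_b > 0, n_a / n_b, NA_real_),
    stringsAsFactors = FALSE, row.names = NULL)
  names(out) <- c("family", paste0("count_", labels),
                  paste0("fraction_", labels), "fold_ratio")
  out
}

#' Cumulative insertion-age curve
#'
#' Fraction of elements at least as old-or-younger than each grid age:
#' value at grid point g is the fraction of elements with T <= g.  With
#' `families` given, one curve per family.
#'
#' @param times Numeric insertion times in years (NA dropped).
#' @param grid Ascending vector of ages in years.
#' @param families Optional per-element family labels.
#' @return data.frame with columns family ("all" when no labels given),
#'   age_years and cumulative_fraction.
#' @export
cumulative_age_curve <- function(times, grid, families = NULL) {
  stopifnot(!is.unsorted(grid))
  if (is.null(families)) families <- rep("all", length(times))
  keep <- !is.na(times)
  times <- times[keep]; families <- families[keep]
  if (length(times) == 0L) stop("no dated elements")
  rows <- lapply(sort(unique(families)), function(f) {
    tf <- times[families == f]
    data.frame(family = f, age_years = grid,
               cumulative_fraction = vapply(grid,
                                            function(g) mean(tf <= g),
                                            numeric(1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Renormalize repeat genome fractions after organelle-cluster removal
#'
#' Read clusters flagged as organelle DNA are removed and every remaining
#' cluster's genome fraction is recomputed against the reduced read total;
#' fractions are then aggregated by annotation label.
#'
#' @param clusters data.frame with columns `cluster`, `annotation`, `reads`
#'   and `organelle` (logical).
#' @param total_reads Total read count of the clustering run; defaults to
#'   the sum of the cluster read counts.
#' @return data.frame with columns annotation and genome_fraction, plus an
#'   attribute `retained_reads`.
#' @export
repeat_fraction_renormalize <- function(clusters,
                                        total_reads = sum(clusters$reads)) {
  stopifnot(all(c("cluster", "annotation", "reads", "organelle") %in%
                  names(clusters)),
            all(clusters$reads >= 0), total_reads >= sum(clusters$reads))
  org_reads <- sum(clusters$reads[clusters$organelle])
  denom <- total_reads - org_reads
  if (denom <= 0) stop("organelle clusters account for all reads")
  kept <- clusters[!clusters$organelle, , drop = FALSE]
  frac <- tapply(kept$reads / denom, kept$annotation, sum)
  out <- data.frame(annotation = names(frac),
                    genome_fraction = as.numeric(frac),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "retained_reads") <- denom
  out
}

#' @export
print.recency_table <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}
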