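#' Scoring configuration for candidate gene models
#'
#' Evidence weights for model scoring: a small bonus per RNA-seq-supported
#' intron or exon, homology bonuses proportional to hit significance and
#' ordered by database tier (arabidopsis > swissprot > nr), and large
#' negative penalties for intersecting a repeat region or hitting a
#' transposable element.
#'
#' @param bonus_per_supported_feature Bonus per supported intron/exon (> 0).
#' @param tier_weights Named weights for homology tiers; must satisfy
#'   arabidopsis > swissprot > nr > 0.
#' @param repeat_penalty,te_penalty Penalties (< 0).
#' @return Object of class `scoring_config`.
#' @export
scoring_config <- function(bonus_per_supported_feature = 1,
                           tier_weights = c(arabidopsis = 10, swissprot = 5,
                                            nr = 2),
                           repeat_penalty = -100, te_penalty = -100) {
  stopifnot(bonus_per_supported_feature > 0,
            all(c("arabidopsis", "swissprot", "nr") %in% names(tier_weights)),
            tier_weights[["arabidopsis"]] > tier_weights[["swissprot"]],
            tier_weights[["swissprot"]] > tier_weights[["nr"]],
            tier_weights[["nr"]] > 0,
            repeat_penalty < 0, te_penalty < 0)
  structure(list(bonus_per_supported_feature = bonus_per_supported_feature,
                 tier_weights = tier_weights,
                 repeat_penalty = repeat_penalty, te_penalty = te_penalty),
            class = "scoring_config")
}

#' Normalized blastp significance from an e-value
#'
#' Maps an e-value to a significance in \[0, 1\]: min(1, -log10(e) / 20),
#' so e-values of 1e-20 or better saturate at 1.
#'
#' @param evalue Non-negative e-value(s).
#' @return Significance score(s) in \[0, 1\].
#' @export
evalue_significance <- function(evalue) {
  stopifnot(all(evalue >= 0))
  pmin(1, pmax(0, -log10(pmax(evalue, .Machine$double.xmin)) / 20))
}

# Parse "tier:sig;tier:sig" hit strings into a data.frame.
.parse_hits <- function(hits) {
  if (is.na(hits) || !nzchar(hits)) {
    return(data.frame(tier = character(), significance = numeric()))
  }
  parts <- strsplit(strsplit(hits, "[;|]")[[1]], ":", fixed = TRUE)
  data.frame(tier = vapply(parts, `[`, "", 1L),
             significance = as.numeric(vapply(parts, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

#' Score one candidate gene model
#'
#' score = bonus_per_supported_feature * (introns_supported +
#' exons_supported) + sum over homology hits of tier_weight * significance
#' + repeat_penalty \[if repeat overlap\] + te_penalty \[if TE hit\].
#'
#' @param candidate List or one-row data.frame with fields
#'   `introns_supported`, `exons_supported`, `hits` (either a data.frame
#'   with columns tier/significance or a `tier:sig;...` string),
#'   `repeat_overlap`, `te_hit`.
#' @param config A [scoring_config()].
#' @return List with `score` and `breakdown` (named per-term vector:
#'   rnaseq_support, homology, repeat_penalty, te_penalty).
#' @export
score_candidate <- function(candidate, config = scoring_config()) {
  hits <- candidate$hits
  if (is.data.frame(candidate) && nrow(candidate) == 1L &&
      is.character(hits)) {
    hits <- hits[[1]]
  }
  if (!is.data.frame(hits)) hits <- .parse_hits(hits)
  if (nrow(hits) > 0) {
    unknown <- setdiff(hits$tier, names(config$tier_weights))
    if (length(unknown)) stop("unknown homology tier '", unknown[1], "'")
    stopifnot(all(hits$significance >= 0))
  }
  breakdown <- c(
    rnaseq_support = config$bonus_per_supported_feature *
      (candidate$introns_supported + candidate$exons_supported),
    homology = if (nrow(hits)) {
      sum(config$tier_weights[hits$tier] * hits$significance)
    } else 0,
    repeat_penalty = if (isTRUE(as.logical(candidate$repeat_overlap))) {
      config$repeat_penalty
    } else 0,
    te_penalty = if (isTRUE(as.logical(candidate$te_hit))) {
      config$te_penalty
    } else 0)
  list(score = sum(breakdown), breakdown = breakdown)
}

#' Score a table of candidate gene models
#'
#' @param candidates data.frame of candidates (see
#'   [simulate_gene_model_candidates()] for the column layout).
#' @param config A [scoring_config()].
#' @return The input with a `score` column and one column per score term.
#' @export
score_candidates <- function(candidates, config = scoring_config()) {
  scored <- lapply(seq_len(nrow(candidates)), function(i) {
    s <- score_candidate(candidates[i, , drop = FALSE], config)
    c(score = s$score, s$breakdown)
  })
  cbind(candidates, do.call(rbind, scored))
}

#' Greedy selection of non-overlapping gene models
#'
#' Candidates are visited in descending score order (ties broken by longer
#' span, then lexicographic model id) and accepted unless their genomic
#' span shares at least one base with an already accepted model on the same
#' contig and strand.  The rejection log names the accepted model that
#' blocked each rejected candidate.
#'
#' @param scored data.frame with columns model_id, contig, strand, start,
#'   end and score (e.g. from [score_candidates()]).
#' @return List with `selected` (data.frame of accepted rows, in acceptance
#'   order) and `rejections` (data.frame model_id, score, blocked_by).
#' @export
select_models <- function(scored) {
  stopifnot(all(c("model_id", "contig", "strand", "start", "end", "score")
                %in% names(scored)),
            all(scored$start <= scored$end))
  span <- scored$end - scored$start + 1
  ord <- order(-scored$score, -span, scored$model_id)
  scored <- scored[ord, , drop = FALSE]

  accepted <- logical(nrow(scored))
  blocked_by <- rep(NA_character_, nrow(scored))
  for (i in seq_len(nrow(scored))) {
    prev <- which(accepted &
                    scored$contig == scored$contig[i] &
                    scored$strand == scored$strand[i])
    hit <- prev[scored$start[prev] <= scored$end[i] &
                  scored$end[prev] >= scored$start[i]]
    if (length(hit) == 0L) {
      accepted[i] <- TRUE
    } else {
      blocked_by[i] <- scored$model_id[hit[1L]]
    }
  }
  list(selected = scored[accepted, , drop = FALSE],
       rejections = data.frame(model_id = scored$model_id[!accepted],
                               score = scored$score[!accepted],
                               blocked_by = blocked_by[!accepted],
                               stringsAsFactors = FALSE))
}

#' Summary metrics of a model selection
#'
#' @param selection Result of [select_models()].
#' @param candidates The full candidate table the selection was made from.
#' @return data.frame with n_candidates, n_selected, n_rejected,
#'   fraction_rnaseq_supported, plus one `n_source_<label>` column per
#'   predictor.
#' @export
selection_report <- function(selection, candidates) {
  sel <- selection$selected
  base <- data.frame(
    n_candidates = nrow(candidates),
    n_selected = nrow(sel),
    n_rejected = nrow(selection$rejections),
    fraction_rnaseq_supported = if (nrow(sel)) {
      mean(sel$introns_supported + sel$exons_supported > 0)
    } else 0)
  for (src in sort(unique(candidates$source))) {
    base[[paste0("n_source_", src)]] <- sum(sel$source == src)
  }
  base
}

#' Score-and-select pipeline for candidate gene models
#'
#' @param candidates Candidate data.frame or path to a candidate GFF3
#'   readable by [read_candidate_gff3()].
#' @param config A [scoring_config()].
#' @param out_dir Optional directory for selected/rejection/report TSVs.
#' @return List with `scored`, `selection` and `report`.
#' @export
rank_models <- function(candidates, config = scoring_config(),
                        out_dir = NULL) {
  if (is.character(candidates)) candidates <- read_candidate_gff3(candidates)
  scored <- score_candidates(candidates, config)
  selection <- select_models(scored)
  report <- selection_report(selection, candidates)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_table(selection$selected,
                    file.path(out_dir, "selected_models.tsv"))
    write_tsv_table(selection$rejections,
                    file.path(out_dir, "rejections.tsv"))
    write_tsv_table(report, file.path(out_dir, "selection_report.tsv"))
  }
  list(scored = scored, selection = selection, report = report)
}
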