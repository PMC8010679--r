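#' Specification of a two-parameter substitution process for one LTR pair
#'
#' Bundles the parameters under which an LTR sequence diverges from its
#' ancestral copy: the per-year substitution rate, the
#' transition/transversion rate ratio and the age of the element.  The
#' default rate is the plant nuclear clock of 1.3e-8 substitutions per site
#' per year used throughout the dating stage.
#'
#' @param rate_r Substitution rate in substitutions/site/year (> 0).
#' @param kappa Transition/transversion rate ratio (> 0).  The dating model
#'   itself does not need kappa; it only shapes simulated divergence.
#' @param age_years Age of the element in years (>= 0).
#' @param seed Integer seed controlling all randomness of a mutation call.
#' @return An object of class `evolution_spec`.
#' @export
evolution_spec <- function(rate_r = 1.3e-8, kappa = 2, age_years = 0,
                           seed = 1L) {
  stopifnot(is.numeric(rate_r), length(rate_r) == 1L, rate_r > 0,
            is.numeric(kappa), length(kappa) == 1L, kappa > 0,
            is.numeric(age_years), length(age_years) == 1L, age_years >= 0,
            is.finite(rate_r * age_years))
  structure(list(rate_r = rate_r, kappa = kappa, age_years = age_years,
                 seed = as.integer(seed)),
            class = "evolution_spec")
}

#' Closed-form substitution probabilities of the two-parameter model
#'
#' Probability that a site has undergone an apparent transition or an
#' apparent transversion after evolving for a branch length of `d` expected
#' substitutions per site, with transition/transversion rate ratio `kappa`.
#' With the per-event rates normalized so that alpha + 2 beta = 1
#' (alpha = kappa beta), the standard spectral solution gives
#' P(transition) = 1/4 - 1/2 exp(-2(alpha+beta) d) + 1/4 exp(-4 beta d) and
#' P(transversion) = 1/2 (1 - exp(-4 beta d)).
#'
#' @param d Expected substitutions per site (branch length, >= 0).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @return Named numeric vector with components `identity`, `transition`
#'   and `transversion` (the latter summed over both transversion targets).
#' @export
k2p_site_probs <- function(d, kappa) {
  stopifnot(d >= 0, kappa > 0)
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  p <- 0.25 - 0.5 * exp(-2 * (alpha + beta) * d) + 0.25 * exp(-4 * beta * d)
  q <- 0.5 * (1 - exp(-4 * beta * d))
  c(identity = 1 - p - q, transition = p, transversion = q)
}

# Mutate a character vector of bases in place under the current RNG state.
# Used by both the public wrapper and the library simulator.
.mutate_bases_k2p <- function(bases, d, kappa) {
  pr <- k2p_site_probs(d, kappa)
  n <- length(bases)
  u <- runif(n)
  is_ts <- u < pr[["transition"]]
  is_tv <- !is_ts & u < pr[["transition"]] + pr[["transversion"]]
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv2 <- c(A = "T", G = "T", C = "G", T = "G")
  out <- bases
  if (any(is_ts)) out[is_ts] <- ts_map[bases[is_ts]]
  if (any(is_tv)) {
    pick_first <- runif(sum(is_tv)) < 0.5
    tv_bases <- bases[is_tv]
    out[is_tv] <- ifelse(pick_first, tv1[tv_bases], tv2[tv_bases])
  }
  out
}

#' Mutate a nucleotide sequence under the two-parameter substitution model
#'
#' Applies the exact closed-form site substitution probabilities of the
#' Kimura two-parameter process at total branch length
#' d = rate_r * age_years.  Each site is substituted independently; no
#' indels are introduced.  The inverse of the K2P distance estimator, so a
#' round trip (mutate, then estimate) recovers the planted divergence.
#'
#' @param sequence Single string over the alphabet A, C, G, T.
#' @param spec An [evolution_spec()].
#' @return Mutated sequence as a single string; identical to the input when
#'   `age_years` is 0, and deterministic given `spec$seed`.
#' @export
mutate_sequence_k2p <- function(sequence, spec) {
  stopifnot(inherits(spec, "evolution_spec"),
            is.character(sequence), length(sequence) == 1L)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!bases %in% c("A", "C", "G", "T"))
  if (length(bad) > 0L) {
    stop("non-ACGT character '", bases[bad[1L]], "' at position ", bad[1L])
  }
  d <- spec$rate_r * spec$age_years
  if (d == 0) return(sequence)
  withr::with_seed(spec$seed,
    paste(.mutate_bases_k2p(bases, d, spec$kappa), collapse = ""))
}

.random_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

#' Age sampler mixing recent and old insertions
#'
#' Returns a sampler drawing element ages from a two-component uniform
#' mixture: with probability `recent_fraction` an age uniform on
#' `recent_range`, otherwise uniform on `old_range`.  Emulates a genome in
#' which a known fraction of elements inserted within the recency window.
#'
#' @param recent_fraction Probability of a "recent" age, in \[0, 1\].
#' @param recent_range,old_range Age intervals in years (recent below the
#'   classification threshold, old above it).
#' @return A function of `n` returning `n` ages in years, using the caller's
#'   RNG state.
#' @export
mixture_age_sampler <- function(recent_fraction,
                                recent_range = c(0, 5e5),
                                old_range = c(5e5, 5e6)) {
  stopifnot(recent_fraction >= 0, recent_fraction <= 1)
  force(recent_range); force(old_range)
  function(n) {
    recent <- runif(n) < recent_fraction
    ifelse(recent,
           runif(n, recent_range[1], recent_range[2]),
           runif(n, old_range[1], old_range[2]))
  }
}

#' Simulate a library of LTR retroelements with known insertion ages
#'
#' Builds one synthetic contig carrying `n_elements` LTR retrotransposons.
#' For each element an ancestral LTR is drawn uniformly over A/C/G/T and
#' copied to the 5' and 3' ends; each copy is then mutated independently
#' under the two-parameter model for the element's sampled age, so the
#' expected divergence between the two LTRs is 2 * rate_r * age.  Elements
#' are separated by random spacer sequence.
#'
#' @param n_elements Number of elements (>= 1).
#' @param ltr_length LTR length in bases (>= 50; shorter LTRs give unstable
#'   frequency estimates).
#' @param age_sampler Function of `n` returning ages in years, e.g.
#'   [mixture_age_sampler()]; the default draws uniform ages on 0--5 My.
#' @param families Named probability vector over family labels.
#' @param rate_r,kappa Substitution process parameters (see
#'   [evolution_spec()]).
#' @param internal_length Length of the internal (between-LTR) region.
#' @param spacer Length of random sequence between consecutive elements.
#' @param recent_threshold Age in years below which the truth table flags
#'   an element as recent.
#' @param seed Integer seed; output is byte-identical across calls with the
#'   same arguments and seed.
#' @return List with `genome` (a [Biostrings::DNAStringSet] of one contig),
#'   `features` (a [GenomicRanges::GRanges] with `LTR_retrotransposon`
#'   parents and two `long_terminal_repeat` children each, carrying `ID`,
#'   `Family` and `Complete` attributes) and `truth` (data.frame with
#'   element_id, family, true_age_years, recent).
#' @export
simulate_ltr_library <- function(n_elements, ltr_length = 1000,
                                 age_sampler = function(n) runif(n, 0, 5e6),
                                 families = c(Athila = 0.42, Tekay = 0.20,
                                              Ale = 0.10, SIRE = 0.10,
                                              TAR = 0.08, Ikeros = 0.05,
                                              Tork = 0.03, CRM = 0.02),
                                 rate_r = 1.3e-8, kappa = 2,
                                 internal_length = 300, spacer = 100,
                                 recent_threshold = 5e5, seed = 1L) {
  stopifnot(n_elements >= 1)
  if (ltr_length < 50) {
    stop("ltr_length must be >= 50 (too short for stable frequency estimates)")
  }
  withr::with_seed(as.integer(seed), {
    ages <- age_sampler(n_elements)
    stopifnot(length(ages) == n_elements, all(ages >= 0))
    fam <- sample(names(families), n_elements, replace = TRUE,
                  prob = as.numeric(families))
    ids <- sprintf("RTE%05d", seq_len(n_elements))

    pieces <- character(2L * n_elements + 1L)
    pieces[1L] <- paste(.random_bases(spacer), collapse = "")
    elem_len <- 2L * ltr_length + internal_length
    starts <- spacer + (seq_len(n_elements) - 1L) * (elem_len + spacer) + 1L

    for (i in seq_len(n_elements)) {
      anc <- .random_bases(ltr_length)
      d <- rate_r * ages[i]
      ltr5 <- if (d > 0) .mutate_bases_k2p(anc, d, kappa) else anc
      ltr3 <- if (d > 0) .mutate_bases_k2p(anc, d, kappa) else anc
      internal <- .random_bases(internal_length)
      pieces[2L * i] <- paste(c(ltr5, internal, ltr3), collapse = "")
      pieces[2L * i + 1L] <- paste(.random_bases(spacer), collapse = "")
    }
    genome <- Biostrings::DNAStringSet(
      stats::setNames(paste(pieces, collapse = ""), "chr1"))

    ends <- starts + elem_len - 1L
    parent <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(starts, ends), strand = "+",
      type = "LTR_retrotransposon", ID = ids, Family = fam,
      Complete = rep("true", n_elements))
    ltr5_gr <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(starts, starts + ltr_length - 1L),
      strand = "+", type = "long_terminal_repeat",
      ID = paste0(ids, "_LTR5"), Family = NA_character_,
      Complete = NA_character_)
    ltr3_gr <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(ends - ltr_length + 1L, ends),
      strand = "+", type = "long_terminal_repeat",
      ID = paste0(ids, "_LTR3"), Family = NA_character_,
      Complete = NA_character_)
    S4Vectors::mcols(parent)$Parent <- NA_character_
    S4Vectors::mcols(ltr5_gr)$Parent <- ids
    S4Vectors::mcols(ltr3_gr)$Parent <- ids
    features <- c(parent, ltr5_gr, ltr3_gr)
    features <- features[order(GenomicRanges::start(features),
                               match(features$type,
                                     c("LTR_retrotransposon",
                                       "long_terminal_repeat")))]

    truth <- data.frame(element_id = ids, family = fam,
                        true_age_years = ages,
                        recent = ages < recent_threshold,
                        stringsAsFactors = FALSE)
    list(genome = genome, features = features, truth = truth)
  })
}

#' Specification of a synthetic count-matrix experiment
#'
#' Describes a negative-binomial read-count simulation with planted
#' expression classes, emulating a bulk transcriptome atlas with two
#' biological replicates per sample.
#'
#' Planted classes: `broad` genes are expressed everywhere with
#' between-sample lognormal variation of the mean; `specific` genes are
#' expressed in exactly one sample; `stable` genes have a constant mean in
#' every sample; `silent` genes are all zero.
#'
#' @param n_genes Number of genes.
#' @param samples Character vector of sample labels.
#' @param n_replicates Replicates per sample (the atlas design uses 2).
#' @param library_size_factors Positive per-column scaling factors (length
#'   `length(samples) * n_replicates`), or NULL to draw them lognormal with
#'   geometric mean 1.
#' @param dispersion Negative-binomial dispersion (scalar or per gene);
#'   variance is mu + dispersion * mu^2.
#' @param class_probs Named probabilities for classes broad, specific,
#'   stable, silent; must sum to 1.
#' @param mean_broad,mean_specific,mean_stable Baseline expression means.
#' @param broad_sdlog Lognormal SD of the between-sample variation of broad
#'   gene means.
#' @param seed Integer seed.
#' @return An object of class `count_sim_spec`.
#' @export
count_sim_spec <- function(n_genes = 2000,
                           samples = sprintf("S%02d", 1:46),
                           n_replicates = 2,
                           library_size_factors = NULL,
                           dispersion = 0.05,
                           class_probs = c(broad = 0.77, specific = 0.15,
                                           stable = 0.05, silent = 0.03),
                           mean_broad = 100, mean_specific = 500,
                           mean_stable = 200, broad_sdlog = 0.5,
                           seed = 1L) {
  stopifnot(n_genes >= 1, length(samples) >= 2, n_replicates >= 1,
            all(dispersion > 0),
            abs(sum(class_probs) - 1) < 1e-8, all(class_probs >= 0),
            setequal(names(class_probs),
                     c("broad", "specific", "stable", "silent")))
  n_cols <- length(samples) * n_replicates
  if (!is.null(library_size_factors)) {
    stopifnot(length(library_size_factors) == n_cols,
              all(library_size_factors > 0))
  }
  structure(list(n_genes = n_genes, samples = samples,
                 n_replicates = n_replicates,
                 library_size_factors = library_size_factors,
                 dispersion = dispersion, class_probs = class_probs,
                 mean_broad = mean_broad, mean_specific = mean_specific,
                 mean_stable = mean_stable, broad_sdlog = broad_sdlog,
                 seed = as.integer(seed)),
            class = "count_sim_spec")
}

#' Simulate a read-count matrix with planted expression classes
#'
#' Draws counts gene by gene from a negative binomial around class-determined
#' means scaled by the per-column library size factors (see
#' [count_sim_spec()] for the class definitions).
#'
#' @param spec A [count_sim_spec()].
#' @return List with `counts` (integer matrix, rownames gene ids, colnames
#'   `SAMPLE.REP`), `truth` (data.frame with gene_id, class,
#'   specific_sample) and `size_factors` (the true per-column factors).
#' @export
simulate_count_matrix <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  withr::with_seed(spec$seed, {
    n_samples <- length(spec$samples)
    n_cols <- n_samples * spec$n_replicates
    col_sample <- rep(seq_len(n_samples), each = spec$n_replicates)
    col_names <- paste(spec$samples[col_sample],
                       rep(seq_len(spec$n_replicates), times = n_samples),
                       sep = ".")
    sf <- spec$library_size_factors
    if (is.null(sf)) {
      sf <- rlnorm(n_cols, 0, 0.3)
      sf <- sf / exp(mean(log(sf)))
    }
    classes <- sample(names(spec$class_probs), spec$n_genes, replace = TRUE,
                      prob = as.numeric(spec$class_probs))
    gene_ids <- sprintf("g%05d", seq_len(spec$n_genes))
    specific_sample <- rep(NA_character_, spec$n_genes)

    mu <- matrix(0, spec$n_genes, n_samples)
    for (i in seq_len(spec$n_genes)) {
      mu[i, ] <- switch(classes[i],
        broad = rlnorm(1, log(spec$mean_broad), 1.2) *
          rlnorm(n_samples, 0, spec$broad_sdlog),
        specific = {
          s <- sample.int(n_samples, 1L)
          specific_sample[i] <- spec$samples[s]
          v <- numeric(n_samples); v[s] <- rlnorm(1, log(spec$mean_specific), 0.3)
          v
        },
        stable = rep(rlnorm(1, log(spec$mean_stable), 0.3), n_samples),
        silent = numeric(n_samples))
    }
    size <- 1 / rep_len(spec$dispersion, spec$n_genes)
    counts <- matrix(0L, spec$n_genes, n_cols,
                     dimnames = list(gene_ids, col_names))
    for (j in seq_len(n_cols)) {
      m <- mu[, col_sample[j]] * sf[j]
      pos <- m > 0
      if (any(pos)) {
        counts[pos, j] <- rnbinom(sum(pos), mu = m[pos], size = size[pos])
      }
    }
    truth <- data.frame(gene_id = gene_ids, class = classes,
                        specific_sample = specific_sample,
                        stringsAsFactors = FALSE)
    list(counts = counts, truth = truth,
         size_factors = stats::setNames(sf, col_names))
  })
}

#' Specification of a synthetic candidate gene-model pool
#'
#' Describes the simulation of overlapping candidate gene models from
#' several predictors at a set of loci, with one designated winner per
#' locus receiving strictly dominant evidence.
#'
#' `evidence_rates` are Bernoulli probabilities: `rnaseq_winner` /
#' `rnaseq_other` of a candidate having RNA-seq-supported features,
#' `homology_winner` / `homology_other` of carrying a protein homology hit
#' (winners draw from the arabidopsis tier, others from swissprot/nr) and
#' `repeat_winner` / `repeat_other` of overlapping a repeat.  At the extreme
#' setting (winner rates 1/1/0, other rates 0/0/1) the winner dominates
#' every competitor by construction.
#'
#' @param n_loci Number of loci.
#' @param predictors Source labels to draw candidates from.
#' @param candidates_per_locus Overlapping candidates at each locus (>= 1).
#' @param evidence_rates Named list of the six probabilities above.
#' @param seed Integer seed.
#' @return An object of class `model_sim_spec`.
#' @export
model_sim_spec <- function(n_loci = 50,
                           predictors = c("augustus_ara", "augustus_tom",
                                          "genemark"),
                           candidates_per_locus = 3,
                           evidence_rates = list(rnaseq_winner = 1,
                                                 rnaseq_other = 0.3,
                                                 homology_winner = 1,
                                                 homology_other = 0.2,
                                                 repeat_winner = 0,
                                                 repeat_other = 0.5),
                           seed = 1L) {
  rates <- unlist(evidence_rates)
  stopifnot(n_loci >= 1, candidates_per_locus >= 1,
            all(rates >= 0), all(rates <= 1),
            all(c("rnaseq_winner", "rnaseq_other", "homology_winner",
                  "homology_other", "repeat_winner", "repeat_other") %in%
                  names(rates)))
  structure(list(n_loci = n_loci, predictors = predictors,
                 candidates_per_locus = candidates_per_locus,
                 evidence_rates = as.list(rates), seed = as.integer(seed)),
            class = "model_sim_spec")
}

#' Simulate overlapping candidate gene models with a known best model
#'
#' At each locus, `candidates_per_locus` mutually overlapping candidate
#' models from distinct predictors are generated; one designated winner is
#' given strictly better evidence than its competitors (more supported
#' features and a top-tier homology hit when its rates fire, never a repeat
#' overlap when `repeat_winner` is 0).  Loci do not overlap each other.
#'
#' @param spec A [model_sim_spec()].
#' @return List with `candidates` (data.frame: model_id, contig, strand,
#'   start, end, exons, source, introns_supported, exons_supported, hits
#'   encoded as `tier:significance` pairs separated by `;`, repeat_overlap,
#'   te_hit) and `truth` (data.frame: locus, winner_id).
#' @export
simulate_gene_model_candidates <- function(spec) {
  stopifnot(inherits(spec, "model_sim_spec"))
  r <- spec$evidence_rates
  withr::with_seed(spec$seed, {
    k <- spec$candidates_per_locus
    rows <- vector("list", spec$n_loci * k)
    winners <- character(spec$n_loci)
    locus_pitch <- 10000L
    for (l in seq_len(spec$n_loci)) {
      locus_start <- (l - 1L) * locus_pitch + 1L
      strand <- sample(c("+", "-"), 1L)
      win <- sample.int(k, 1L)
      base_len <- 1500L
      for (j in seq_len(k)) {
        id <- sprintf("m%04d_%d", l, j)
        is_win <- j == win
        if (is_win) winners[l] <- id
        start <- locus_start + (j - 1L) * 200L
        end <- start + base_len + sample.int(500L, 1L) - 1L
        # 2 exons inside the span
        mid <- start + (end - start) %/% 2L
        exons <- sprintf("%d-%d,%d-%d", start, mid - 50L, mid + 50L, end)
        p_rna <- if (is_win) r$rnaseq_winner else r$rnaseq_other
        p_hom <- if (is_win) r$homology_winner else r$homology_other
        p_rep <- if (is_win) r$repeat_winner else r$repeat_other
        n_sup <- if (runif(1) < p_rna) (if (is_win) 5L else 1L) else 0L
        hits <- if (runif(1) < p_hom) {
          if (is_win) sprintf("arabidopsis:%.3f", runif(1, 0.8, 1))
          else sprintf("%s:%.3f", sample(c("swissprot", "nr"), 1L),
                       runif(1, 0.1, 0.5))
        } else ""
        rep_ov <- runif(1) < p_rep
        rows[[(l - 1L) * k + j]] <- data.frame(
          model_id = id, contig = "ctg1", strand = strand,
          start = start, end = end, exons = exons,
          source = spec$predictors[((j - 1L) %% length(spec$predictors)) + 1L],
          introns_supported = n_sup, exons_supported = n_sup,
          hits = hits, repeat_overlap = rep_ov, te_hit = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    candidates <- do.call(rbind, rows)
    truth <- data.frame(locus = seq_len(spec$n_loci), winner_id = winners,
                        stringsAsFactors = FALSE)
    list(candidates = candidates, truth = truth)
  })
}
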