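# Shared fixtures and independent oracles used across test files.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent solution of the two-parameter substitution model: build the
# 4x4 rate matrix (transitions at rate alpha, transversions at rate beta,
# normalized to one expected substitution per unit branch length) and
# exponentiate it by eigendecomposition.  Returns the transition-probability
# matrix after branch length d.
k2p_matrix_oracle <- function(d, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  states <- c("A", "G", "C", "T")
  Q <- matrix(beta, 4, 4, dimnames = list(states, states))
  Q["A", "G"] <- alpha; Q["G", "A"] <- alpha
  Q["C", "T"] <- alpha; Q["T", "C"] <- alpha
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  e <- eigen(Q)
  P <- e$vectors %*% diag(exp(e$values * d)) %*% solve(e$vectors)
  dimnames(P) <- list(states, states)
  P
}

# All global alignments of two short character vectors (monotone paths;
# never a gap against a gap).  Each alignment is a list of two equal-length
# character vectors with "-" for gaps.
enumerate_alignments <- function(a, b) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(list(list(character(0), character(0))))
    out <- list()
    if (i > 0 && j > 0) {
      for (al in rec(i - 1, j - 1)) {
        out <- c(out, list(list(c(al[[1]], a[i]), c(al[[2]], b[j]))))
      }
    }
    if (i > 0) {
      for (al in rec(i - 1, j)) {
        out <- c(out, list(list(c(al[[1]], a[i]), c(al[[2]], "-"))))
      }
    }
    if (j > 0) {
      for (al in rec(i, j - 1)) {
        out <- c(out, list(list(c(al[[1]], "-"), c(al[[2]], b[j]))))
      }
    }
    out
  }
  rec(length(a), length(b))
}

# Score one explicit alignment under the package's affine convention:
# a gap run of length L costs gap_open + L * gap_extend.
score_alignment_brute <- function(a1, a2, scoring) {
  both <- a1 != "-" & a2 != "-"
  col_scores <- ifelse(a1[both] == "N" | a2[both] == "N", 0,
                       ifelse(a1[both] == a2[both],
                              scoring$match, scoring$mismatch))
  gap_cost <- function(v) {
    r <- rle(v == "-")
    runs <- r$lengths[r$values]
    sum(scoring$gap_open + runs * scoring$gap_extend)
  }
  sum(col_scores) + gap_cost(a1) + gap_cost(a2)
}

best_alignment_score_brute <- function(s1, s2, scoring) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  max(vapply(enumerate_alignments(a, b),
             function(al) score_alignment_brute(al[[1]], al[[2]], scoring),
             numeric(1)))
}

# Brute-force two-sided Fisher p-value by enumerating every table with the
# observed margins; point probabilities from log-binomial coefficients.
fisher_brute <- function(tab) {
  m1 <- tab[1, 1] + tab[1, 2]
  m2 <- tab[2, 1] + tab[2, 2]
  n1 <- tab[1, 1] + tab[2, 1]
  N <- m1 + m2
  support <- max(0, n1 - m2):min(n1, m1)
  lp <- lchoose(m1, support) + lchoose(m2, n1 - support) - lchoose(N, n1)
  probs <- exp(lp)
  p_obs <- probs[support == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Tiny hand-built candidate table for selection tests.
toy_candidates <- function(ids, scores, starts, ends,
                           contig = "c1", strand = "+") {
  data.frame(model_id = ids, contig = contig, strand = strand,
             start = starts, end = ends, score = scores,
             stringsAsFactors = FALSE)
}
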