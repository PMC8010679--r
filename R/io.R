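#' Read a FASTA file of nucleotide sequences
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet]; empty for an empty file.  Duplicate
#'   record identifiers are an error.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  non_empty <- which(nzchar(trimws(lines)))
  if (length(non_empty) == 0L) return(Biostrings::DNAStringSet())
  if (!startsWith(lines[non_empty[1]], ">")) {
    stop("malformed FASTA header at line ", non_empty[1],
         ": expected '>'")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifier '", ids[duplicated(ids)][1], "'")
  }
  names(seqs) <- ids
  seqs
}

#' Write nucleotide sequences to FASTA (60-column wrap)
#'
#' @param records A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) records <- Biostrings::DNAStringSet(records)
  Biostrings::writeXStringSet(records, path, width = 60L)
  invisible(path)
}

# Feature types the element GFF3 dialect knows about.
.ELEMENT_TYPES <- c("LTR_retrotransposon", "long_terminal_repeat")

#' Read an LTR-element GFF3 file
#'
#' Parses a GFF3 of `LTR_retrotransposon` features, each with two
#' `long_terminal_repeat` children (1-based inclusive coordinates,
#' attributes ID / Parent / Family / Complete).  Validation: element
#' features must be stranded (+ or -), children must lie within their
#' parent's span, and unknown feature types produce a warning and are
#' passed through.
#'
#' @param path GFF3 path.
#' @return A [GenomicRanges::GRanges] of the features.
#' @export
read_element_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  unknown <- setdiff(unique(type), .ELEMENT_TYPES)
  if (length(unknown)) {
    warning("unknown feature type(s) passed through: ",
            paste(unknown, collapse = ", "))
  }
  is_parent <- type == "LTR_retrotransposon"
  if (any(as.character(GenomicRanges::strand(gr))[is_parent] == "*")) {
    stop("LTR_retrotransposon features must be stranded (+ or -)")
  }
  parent_of <- function(x) {
    p <- x$Parent
    vapply(p, function(v) if (length(v)) as.character(v)[1] else
      NA_character_, character(1))
  }
  kids <- which(type == "long_terminal_repeat")
  if (length(kids)) {
    par_ids <- parent_of(gr[kids])
    idx <- match(par_ids, gr$ID)
    if (anyNA(idx)) {
      stop("long_terminal_repeat with missing parent: ",
           par_ids[is.na(idx)][1])
    }
    inside <- GenomicRanges::start(gr[kids]) >= GenomicRanges::start(gr[idx]) &
      GenomicRanges::end(gr[kids]) <= GenomicRanges::end(gr[idx])
    if (!all(inside)) {
      stop("long_terminal_repeat outside its parent span: ",
           gr$ID[kids][!inside][1])
    }
  }
  gr
}

#' Write LTR-element features to GFF3
#'
#' @param features A [GenomicRanges::GRanges] as produced by
#'   [simulate_ltr_library()] or [read_element_gff3()].
#' @param path Output path.
#' @export
write_element_gff3 <- function(features, path) {
  rtracklayer::export(features, path, format = "gff3")
  invisible(path)
}

#' Assemble LTR elements from a GFF3 annotation and a genome FASTA
#'
#' For every `LTR_retrotransposon` feature the sequences of its two
#' `long_terminal_repeat` children are extracted from the genome (reverse
#' complemented for minus-strand elements, so both LTRs are reported on the
#' element's own orientation).  A `Complete=true` attribute marks the
#' element as carrying all five retroelement protein domains.
#'
#' @param gff_path Element GFF3 path (or a GRanges already read).
#' @param fasta_path Genome FASTA path (or a DNAStringSet).
#' @return List of [ltr_element()] objects.
#' @export
read_ltr_elements <- function(gff_path, fasta_path) {
  gr <- if (is.character(gff_path)) read_element_gff3(gff_path) else gff_path
  genome <- if (is.character(fasta_path)) read_fasta(fasta_path) else fasta_path
  type <- as.character(gr$type)
  parents <- gr[type == "LTR_retrotransposon"]
  kids <- gr[type == "long_terminal_repeat"]
  kid_parent <- vapply(kids$Parent, function(v) as.character(v)[1],
                       character(1))
  lapply(seq_along(parents), function(i) {
    pid <- parents$ID[i]
    mine <- kids[kid_parent == pid]
    if (length(mine) != 2L) {
      stop("element ", pid, " has ", length(mine),
           " long_terminal_repeat children (need exactly 2)")
    }
    mine <- mine[order(GenomicRanges::start(mine))]
    chrom <- as.character(GenomicRanges::seqnames(parents)[i])
    get_seq <- function(f) {
      s <- Biostrings::subseq(genome[[chrom]],
                              GenomicRanges::start(f),
                              GenomicRanges::end(f))
      as.character(s)
    }
    minus <- as.character(GenomicRanges::strand(parents)[i]) == "-"
    seqs <- c(get_seq(mine[1]), get_seq(mine[2]))
    if (minus) {
      seqs <- rev(as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs))))
    }
    complete <- identical(tolower(as.character(parents$Complete[i])), "true")
    ltr_element(pid, ltr5 = seqs[1], ltr3 = seqs[2],
                family = if (is.na(parents$Family[i])) "unclassified"
                         else parents$Family[i],
                domains_present = if (complete) FULL_LENGTH_DOMAINS
                                  else character())
  })
}

#' Read candidate gene models from GFF3
#'
#' Expects `gene` features carrying the evidence attributes
#' `introns_supported`, `exons_supported`, `hits` (`tier:significance`
#' pairs separated by `|`), `repeat_overlap` and `te_hit`, each with `exon`
#' children validated to lie within the gene span.
#'
#' @param path GFF3 path.
#' @return Candidate data.frame as used by [score_candidates()].
#' @export
read_candidate_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  exons <- gr[type == "exon"]
  exon_parent <- vapply(exons$Parent, function(v) as.character(v)[1],
                        character(1))
  exon_str <- vapply(genes$ID, function(id) {
    mine <- exons[exon_parent == id]
    mine <- mine[order(GenomicRanges::start(mine))]
    paste(sprintf("%d-%d", GenomicRanges::start(mine),
                  GenomicRanges::end(mine)), collapse = ",")
  }, character(1))
  g_idx <- match(exon_parent, genes$ID)
  if (anyNA(g_idx)) stop("exon with unknown parent gene")
  ok <- GenomicRanges::start(exons) >= GenomicRanges::start(genes)[g_idx] &
    GenomicRanges::end(exons) <= GenomicRanges::end(genes)[g_idx]
  if (!all(ok)) {
    stop("exon outside its gene span: parent ", exon_parent[!ok][1])
  }
  opt_chr <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  data.frame(
    model_id = as.character(genes$ID),
    contig = as.character(GenomicRanges::seqnames(genes)),
    strand = as.character(GenomicRanges::strand(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    exons = unname(exon_str),
    source = as.character(genes$source),
    introns_supported = as.integer(genes$introns_supported),
    exons_supported = as.integer(genes$exons_supported),
    hits = ifelse(is.na(opt_chr(genes$hits)), "", opt_chr(genes$hits)),
    repeat_overlap = as.logical(genes$repeat_overlap),
    te_hit = as.logical(genes$te_hit),
    stringsAsFactors = FALSE)
}

#' Write candidate gene models to GFF3
#'
#' @param candidates Candidate data.frame (see
#'   [simulate_gene_model_candidates()]).
#' @param path Output path.
#' @export
write_candidate_gff3 <- function(candidates, path) {
  gene_gr <- GenomicRanges::GRanges(
    candidates$contig,
    IRanges::IRanges(candidates$start, candidates$end),
    strand = candidates$strand,
    type = "gene",
    source = candidates$source,
    ID = candidates$model_id,
    introns_supported = as.character(candidates$introns_supported),
    exons_supported = as.character(candidates$exons_supported),
    hits = candidates$hits,
    repeat_overlap = tolower(as.character(candidates$repeat_overlap)),
    te_hit = tolower(as.character(candidates$te_hit)))
  exon_rows <- lapply(seq_len(nrow(candidates)), function(i) {
    spans <- strsplit(candidates$exons[i], ",", fixed = TRUE)[[1]]
    if (length(spans) == 0L || !nzchar(spans[1])) return(NULL)
    bounds <- do.call(rbind, strsplit(spans, "-", fixed = TRUE))
    GenomicRanges::GRanges(
      candidates$contig[i],
      IRanges::IRanges(as.integer(bounds[, 1]), as.integer(bounds[, 2])),
      strand = candidates$strand[i],
      type = "exon", source = candidates$source[i],
      ID = paste0(candidates$model_id[i], ".e", seq_len(nrow(bounds))),
      introns_supported = NA_character_, exons_supported = NA_character_,
      hits = NA_character_, repeat_overlap = NA_character_,
      te_hit = NA_character_)
  })
  exon_gr <- do.call(c, c(list(GenomicRanges::GRanges()),
                          Filter(Negate(is.null), exon_rows)))
  if (length(exon_gr)) {
    S4Vectors::mcols(exon_gr)$Parent <- sub("\\.e[0-9]+$", "", exon_gr$ID)
    S4Vectors::mcols(gene_gr)$Parent <- NA_character_
  }
  rtracklayer::export(c(gene_gr, exon_gr), path, format = "gff3")
  invisible(path)
}

#' Read a gene-level count table
#'
#' TSV with a header row: a gene id column followed by one `SAMPLE.REP`
#' column per library.  Counts must be non-negative integers when
#' `integer_counts` is TRUE.
#'
#' @param path TSV path.
#' @param integer_counts Enforce integer counts (default TRUE).
#' @return Numeric matrix with gene ids as rownames.
#' @export
read_counts_tsv <- function(path, integer_counts = TRUE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("counts table needs a gene id column plus data")
  .parse_columns(names(df)[-1])
  gene_ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    bad_row <- which(is.na(suppressWarnings(as.numeric(df[[bad + 1]]))))[1]
    stop("non-numeric count for gene '", gene_ids[bad_row],
         "' in column '", names(df)[bad + 1], "'")
  }
  if (any(mat < 0)) {
    idx <- which(mat < 0, arr.ind = TRUE)[1, ]
    stop("negative count for gene '", gene_ids[idx[1]], "' in column '",
         colnames(mat)[idx[2]], "'")
  }
  if (integer_counts && any(mat != round(mat))) {
    idx <- which(mat != round(mat), arr.ind = TRUE)[1, ]
    stop("non-integer count for gene '", gene_ids[idx[1]],
         "' in column '", colnames(mat)[idx[2]], "'")
  }
  rownames(mat) <- gene_ids
  mat
}

#' Write a count (or normalized-expression) matrix as TSV
#'
#' @param counts Matrix with gene ids as rownames and `SAMPLE.REP` column
#'   names.
#' @param path Output path.
#' @param integer_counts Write as integers (default TRUE).
#' @export
write_counts_tsv <- function(counts, path, integer_counts = TRUE) {
  df <- data.frame(gene_id = rownames(counts),
                   if (integer_counts) {
                     matrix(as.integer(counts), nrow(counts),
                            dimnames = dimnames(counts))
                   } else counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data.frame as a TSV with header
#'
#' @param rows data.frame.
#' @param path Output path.
#' @export
write_tsv_table <- function(rows, path) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with header
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
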