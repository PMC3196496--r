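# RNA-seq quantification with mappability correction. Gene length for the
# RPMK denominator is the number of 32-mers unique to the gene across the
# whole transcriptome; reads hitting more than one gene are discarded.
# Differential expression between two pooled groups uses a binomial
# generalized likelihood-ratio test with BH FDR control.

# enumerate all k-mers of a sequence (empty when shorter than k)
.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

#' Precompute the k-mer to gene lookup used by quantification
#'
#' Named character vector over every k-mer occurring in the transcriptome:
#' the owning gene for k-mers unique to one gene, NA for k-mers shared by
#' several genes. Computing this once and passing it to [effective_length()]
#' and [assign_reads()] avoids rebuilding it per sample.
#'
#' @param transcripts transcript sequences.
#' @param gene_of gene id per transcript.
#' @param k k-mer length.
#' @return named character vector (k-mer -> gene id or NA).
#' @export
kmer_gene_map <- function(transcripts, gene_of, k = 32) {
  .kmer_gene_map(as.character(transcripts), gene_of, k)
}

# map k-mer -> gene for k-mers unique to one gene; multi-gene k-mers -> NA
.kmer_gene_map <- function(transcripts, gene_of, k) {
  stopifnot(length(transcripts) == length(gene_of))
  per_gene <- lapply(split(transcripts, gene_of), function(seqs) {
    unique(unlist(lapply(seqs, .kmers, k = k), use.names = FALSE))
  })
  genes <- rep(names(per_gene), lengths(per_gene))
  kmers <- unlist(per_gene, use.names = FALSE)
  multi <- unique(kmers[duplicated(kmers)])
  gene <- ifelse(kmers %in% multi, NA_character_, genes)
  first <- !duplicated(kmers)
  stats::setNames(gene[first], kmers[first])
}

#' Mappability-corrected effective gene length
#'
#' Generates all k-mers (default 32, the read length) from each gene's
#' transcripts and counts how many occur in that gene's transcripts and in
#' no other gene's. This unique-k-mer count is the modified gene length used
#' as the RPMK denominator; genes whose sequence is wholly shared (or
#' shorter than k) get length 0.
#'
#' @param transcripts character vector (or DNAStringSet) of transcript
#'   sequences.
#' @param gene_of gene id per transcript.
#' @param k k-mer/read length (default 32).
#' @param map optional precomputed [kmer_gene_map()].
#' @return data.frame with `gene_id`, `effective_length` (unique k-mers),
#'   and `k`.
#' @export
effective_length <- function(transcripts, gene_of, k = 32, map = NULL) {
  if (k < 1) stop("k must be >= 1")
  transcripts <- as.character(transcripts)
  map <- map %||% .kmer_gene_map(transcripts, gene_of, k)
  uniq <- table(map[!is.na(map)])
  genes <- sort(unique(as.character(gene_of)))
  data.frame(gene_id = genes,
             effective_length = as.integer(ifelse(genes %in% names(uniq),
                                                  uniq[genes], 0L)),
             k = as.integer(k), stringsAsFactors = FALSE)
}

#' Assign fixed-length reads to genes by exact unique match
#'
#' A read is counted for gene g iff its sequence (or, by default, its
#' reverse complement) occurs in g's transcripts and in no other gene's
#' transcripts. Reads hitting k-mers shared by several genes, reads whose
#' forward and reverse-complement hits disagree, and reads matching nothing
#' are discarded. Conservation: assigned + multi-gene + unmatched = input.
#'
#' @param reads character vector of reads, all exactly length `k`.
#' @param transcripts transcript sequences.
#' @param gene_of gene id per transcript.
#' @param k read length (default 32).
#' @param revcomp also match the reverse complement (default TRUE).
#' @param map optional precomputed [kmer_gene_map()].
#' @return list with `counts` (named integer vector per gene, zero-filled),
#'   `total` (assigned reads), `n_multi`, `n_unmatched`.
#' @export
assign_reads <- function(reads, transcripts, gene_of, k = 32, revcomp = TRUE,
                         map = NULL) {
  reads <- as.character(reads)
  if (length(reads) && !all(nchar(reads) == k))
    stop("all reads must be exactly ", k, " nt")
  map <- map %||% .kmer_gene_map(as.character(transcripts), gene_of, k)
  hit_f <- map[reads]
  known_f <- reads %in% names(map)
  if (revcomp) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(reads)))
    hit_r <- map[rc]
    known_r <- rc %in% names(map)
    gene <- ifelse(known_f & !known_r, hit_f,
            ifelse(known_r & !known_f, hit_r,
            ifelse(known_f & known_r,
                   ifelse(!is.na(hit_f) & !is.na(hit_r) & hit_f == hit_r,
                          hit_f, NA_character_),
                   NA_character_)))
    known <- known_f | known_r
  } else {
    gene <- hit_f
    known <- known_f
  }
  assigned <- known & !is.na(gene)
  genes <- sort(unique(as.character(gene_of)))
  counts <- table(factor(gene[assigned], levels = genes))
  list(counts = stats::setNames(as.integer(counts), genes),
       total = sum(assigned),
       n_multi = sum(known & !assigned),
       n_unmatched = sum(!known))
}

#' Read count per million mapped reads per kilobase of mappable length
#'
#' @param count read count(s) for the gene.
#' @param effective_length_bp unique-k-mer (mappable) length in bases; must
#'   be positive (zero-length genes are excluded upstream).
#' @param total_mapped total assigned reads in the sample.
#' @return RPMK value(s).
#' @export
rpmk <- function(count, effective_length_bp, total_mapped) {
  if (any(effective_length_bp <= 0)) stop("effective length must be positive")
  if (any(total_mapped <= 0)) stop("total mapped reads must be positive")
  count / (total_mapped / 1e6) / (effective_length_bp / 1e3)
}

#' Exclude duplicated genes with too short a mappable region
#'
#' Genes created by duplication (DNA-level duplicates and retrogenes) whose
#' unique mappable length is below `min_bp` are excluded; de novo genes are
#' never excluded by this filter, so that their typically longer mappable
#' regions cannot create a spurious contrast.
#'
#' @param catalog gene catalog with `gene_id` and `mechanism`
#'   (dna_duplicate / retrogene / de_novo / unknown).
#' @param lengths output of [effective_length()].
#' @param min_bp threshold (default 30; strict `<` excludes).
#' @return list with `retained` and `excluded` gene id vectors.
#' @export
filter_short_mappable <- function(catalog, lengths, min_bp = 30) {
  miss <- setdiff(catalog$gene_id, lengths$gene_id)
  if (length(miss)) stop("effective lengths missing for: ",
                         paste(utils::head(miss, 5), collapse = ","))
  len <- lengths$effective_length[match(catalog$gene_id, lengths$gene_id)]
  dup <- catalog$mechanism %in% c("dna_duplicate", "retrogene")
  drop <- dup & len < min_bp
  list(retained = catalog$gene_id[!drop], excluded = catalog$gene_id[drop])
}

# binomial log-likelihood with 0*log(0) == 0
.binll <- function(x, n, p) {
  t1 <- ifelse(x == 0, 0, x * log(p))
  t2 <- ifelse(n - x == 0, 0, (n - x) * log1p(-p))
  t1 + t2
}

#' Binomial two-group generalized likelihood-ratio test
#'
#' Tests whether a gene's read count arises at the same per-read rate in two
#' pooled samples. Under H0 both groups share p0 = (x1+x2)/(N1+N2); under H1
#' each group has its own MLE x/N. Lambda = 2 (l1 - l0) is referred to a
#' chi-square with 1 df (upper tail). Vectorised over genes.
#'
#' @param x1,x2 gene read counts in groups 1 and 2.
#' @param N1,N2 total mapped reads per group.
#' @return data.frame with `lambda` and `p`.
#' @export
lrt_de <- function(x1, N1, x2, N2) {
  if (any(N1 <= 0) || any(N2 <= 0)) stop("group totals must be positive")
  if (any(x1 < 0) || any(x2 < 0) || any(x1 > N1) || any(x2 > N2))
    stop("counts must satisfy 0 <= x <= N")
  p0 <- (x1 + x2) / (N1 + N2)
  l0 <- .binll(x1, N1, p0) + .binll(x2, N2, p0)
  l1 <- .binll(x1, N1, x1 / N1) + .binll(x2, N2, x2 / N2)
  lambda <- pmax(0, 2 * (l1 - l0))
  data.frame(lambda = lambda, p = stats::pchisq(lambda, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values (monotone, capped at 1).
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-group differential expression calls from a count matrix
#'
#' Samples within each group are pooled (summed) before testing; each gene
#' is then tested with [lrt_de()] and q-values are BH-adjusted. Direction is
#' the group with the larger per-read rate for genes with q below the FDR
#' cutoff; genes at or above the cutoff (or with exactly equal rates) are
#' unbiased.
#'
#' @param counts gene x sample integer matrix (rownames = gene ids).
#' @param groups group label per sample (exactly two distinct labels).
#' @param totals per-sample total mapped reads (default: column sums).
#' @param fdr FDR cutoff (default 0.05).
#' @return data.frame with per-group pooled counts/totals, `lambda`, `p`,
#'   `q`, and `bias` (group label or `"unbiased"`).
#' @export
de_test <- function(counts, groups, totals = colSums(counts), fdr = 0.05) {
  stopifnot(is.matrix(counts), length(groups) == ncol(counts),
            length(totals) == ncol(counts))
  gl <- unique(groups)
  if (length(gl) != 2) stop("exactly two groups required")
  x1 <- rowSums(counts[, groups == gl[1], drop = FALSE])
  x2 <- rowSums(counts[, groups == gl[2], drop = FALSE])
  N1 <- sum(totals[groups == gl[1]])
  N2 <- sum(totals[groups == gl[2]])
  lr <- lrt_de(x1, N1, x2, N2)
  q <- bh_fdr(lr$p)
  r1 <- x1 / N1; r2 <- x2 / N2
  bias <- ifelse(q < fdr & r1 > r2, gl[1],
          ifelse(q < fdr & r2 > r1, gl[2], "unbiased"))
  data.frame(gene_id = rownames(counts), x1 = x1, N1 = N1, x2 = x2, N2 = N2,
             lambda = lr$lambda, p = lr$p, q = q, bias = bias,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Partition samples into two groups by expression clustering
#'
#' Hierarchical clustering (average linkage) on 1 - Pearson correlation
#' between sample expression profiles, cut into exactly two clusters; used
#' to pool samples into e.g. fetal and adult groups before testing.
#'
#' @param expr gene x sample numeric matrix with >= 2 samples.
#' @return integer vector of cluster labels (1/2) named by sample.
#' @export
group_samples <- function(expr) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 2) stop("need at least 2 samples")
  if (ncol(expr) == 2)
    return(stats::setNames(c(1L, 2L), colnames(expr)))
  d <- 1 - stats::cor(expr)
  if (max(d, na.rm = TRUE) < 1e-12)
    stop("all pairwise distances are zero; no defensible split")
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  stats::cutree(hc, k = 2)
}
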