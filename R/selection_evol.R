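# Sequence-evolution layer: Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor
# correction and the study's filters, McDonald-Kreitman 2x2 statistics
# (FET, neutrality index, alpha), and a per-gene Poisson-random-field
# maximum-likelihood estimator of the scaled selection intensity gamma=2Ns.

.genetic_code <- function() {
  b <- c("T", "C", "A", "G")
  eg <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  codons <- paste0(eg$p1, eg$p2, eg$p3)  # third position varies fastest
  # aa in TCAG order by position (standard code), '*' = stop
  aa <- unlist(strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), ""))
  stats::setNames(aa, codons)
}

.CODE <- .genetic_code()
.BASES <- c("A", "C", "G", "T")

# per-codon synonymous site count: sum over positions of the fraction of
# the three possible changes that preserve the amino acid (changes to or
# from stop count as nonsynonymous), so syn + nonsyn sites == 3 per codon
.syn_sites_codon <- function(codon) {
  aa <- .CODE[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (nb in setdiff(.BASES, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nb
      if (.CODE[[mut]] == aa && aa != "*") s <- s + 1 / 3
    }
  }
  s
}

# pathway-averaged (syn, nonsyn) difference counts between two codons; all
# substitution orderings weighted equally, steps via stop codons count as
# nonsynonymous
.codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(syn = 0, nonsyn = 0))
  paths <- if (nd == 1) list(pos) else
    lapply(asplit(do.call(rbind, .permutations(pos)), 1), as.vector)
  acc <- c(syn = 0, nonsyn = 0)
  for (ord in paths) {
    cur <- c1
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (.CODE[[cur]] != "*" && .CODE[[nxt]] != "*" &&
          .CODE[[cur]] == .CODE[[nxt]]) {
        acc["syn"] <- acc["syn"] + 1
      } else {
        acc["nonsyn"] <- acc["nonsyn"] + 1
      }
      cur <- nxt
    }
  }
  acc / length(paths)
}

.permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .permutations(v[-i]))
      out <- c(out, list(c(v[i], rest)))
  out
}

#' Nei-Gojobori Ka/Ks for a pairwise codon alignment
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon (averaged
#' between the two sequences), pathway-averaged difference counts (Sd, Nd),
#' proportions pS = Sd/S and pN = Nd/N, and Jukes-Cantor corrected rates
#' d = -(3/4) ln(1 - 4p/3). Alignments covering at most `min_codons` codons
#' or with fewer than one estimated synonymous substitution (Ks * S < 1)
#' fail the filters; the ratio is additionally trimmed to 1 for plotting.
#'
#' @param seq1,seq2 gap-free in-frame nucleotide sequences of equal length
#'   divisible by 3 (ACGT alphabet, no internal stops).
#' @param min_codons alignment-length filter: pass requires codons strictly
#'   greater than this (default 100).
#' @return list with `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `Ka`, `Ks`, `ratio`,
#'   `ratio_trimmed`, `n_codons`, `pass` and `fail_reason` (NA when `pass`),
#'   plus `undefined` flags when a JC correction does not exist (p >= 3/4).
#' @export
ng86_kaks <- function(seq1, seq2, min_codons = 100) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) stop("sequences must have equal length")
  if (nchar(seq1) %% 3 != 0) stop("length must be divisible by 3")
  if (grepl("[^ACGT]", seq1) || grepl("[^ACGT]", seq2))
    stop("sequences must be gap-free ACGT")
  nc <- nchar(seq1) / 3
  starts <- seq(1, nchar(seq1), by = 3)
  cod1 <- substring(seq1, starts, starts + 2)
  cod2 <- substring(seq2, starts, starts + 2)
  if (any(.CODE[cod1] == "*") || any(.CODE[cod2] == "*"))
    stop("internal stop codon")
  s1 <- vapply(cod1, .syn_sites_codon, numeric(1))
  s2 <- vapply(cod2, .syn_sites_codon, numeric(1))
  S <- (sum(s1) + sum(s2)) / 2
  N <- 3 * nc - S
  d <- mapply(function(a, b) .codon_diffs(a, b), cod1, cod2)
  Sd <- sum(d["syn", ]); Nd <- sum(d["nonsyn", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log1p(-4 * p / 3)
  Ks <- jc(pS); Ka <- jc(pN)
  undefined <- is.na(Ks) || is.na(Ka)
  ratio <- if (!undefined && Ks > 0) Ka / Ks else NA_real_
  fail <- if (nc <= min_codons) "short_alignment"
          else if (undefined) "jc_undefined"
          else if (Ks * S < 1) "too_few_synonymous"
          else NA_character_
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN, Ka = Ka, Ks = Ks,
       ratio = ratio,
       ratio_trimmed = if (is.na(ratio)) NA_real_ else min(ratio, 1),
       n_codons = nc, pass = is.na(fail), fail_reason = fail,
       undefined = undefined)
}

#' McDonald-Kreitman test statistics for one gene
#'
#' Two-sided Fisher exact test on the 2x2 table `[[ds, ps], [dn, pn]]` of
#' fixed/polymorphic x synonymous/nonsynonymous counts, with the neutrality
#' index NI = (pn/ps)/(dn/ds) and alpha = 1 - (ds*pn)/(dn*ps). NI and alpha
#' are NA (flagged, no error) when a denominator is zero.
#'
#' @param ds,ps,dn,pn fixed synonymous, polymorphic synonymous, fixed
#'   nonsynonymous, polymorphic nonsynonymous counts.
#' @return list with `p`, `NI`, `alpha`, `NI_defined`, `alpha_defined`.
#' @export
mk_fet <- function(ds, ps, dn, pn) {
  cnt <- c(ds, ps, dn, pn)
  if (any(cnt < 0) || any(cnt != round(cnt))) stop("counts must be nonnegative integers")
  if (sum(cnt) == 0) stop("all-zero MK table")
  tab <- matrix(c(ds, ps, dn, pn), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  NI <- if (ps > 0 && dn > 0 && ds > 0) (pn / ps) / (dn / ds) else NA_real_
  alpha <- if (dn > 0 && ps > 0) 1 - (ds * pn) / (dn * ps) else NA_real_
  list(p = p, NI = NI, alpha = alpha,
       NI_defined = !is.na(NI), alpha_defined = !is.na(alpha))
}

#' PRF fixation-rate factor G(gamma) = 2 gamma / (1 - exp(-2 gamma))
#'
#' Relative fixation rate of a new mutation with scaled selection intensity
#' gamma = 2Ns, normalised so G(0) = 1.
#'
#' @param gamma scaled selection intensity (vectorised).
#' @return numeric vector.
#' @export
prf_G <- function(gamma) {
  ifelse(abs(gamma) < 1e-8,
         1 + gamma,  # first-order series; exact limit 1 at gamma = 0
         2 * gamma / (1 - exp(-2 * gamma)))
}

#' PRF expected polymorphism factor L(gamma, n)
#'
#' Expected number of segregating sites (per unit mutation rate) visible in
#' a sample of `n` chromosomes under selection intensity gamma:
#' the integral over population frequency q of the stationary PRF density
#' times the probability that the site is polymorphic in the sample,
#' `L(gamma, n) = int_0^1 [(1 - e^(-2 gamma (1-q))) / ((1 - e^(-2 gamma))
#' q (1-q))] (1 - q^n - (1-q)^n) dq`. At gamma = 0 this reduces to the
#' harmonic sum `sum_{i=1}^{n-1} 1/i`.
#'
#' @param gamma scaled selection intensity.
#' @param n sample size in chromosomes (>= 2).
#' @return numeric scalar.
#' @export
prf_L <- function(gamma, n) {
  stopifnot(n >= 2)
  if (abs(gamma) < 1e-8)
    return(stats::integrate(function(q) (1 - q^n - (1 - q)^n) / q,
                            0, 1, rel.tol = 1e-10)$value)
  f <- function(q) {
    (1 - exp(-2 * gamma * (1 - q))) / ((1 - exp(-2 * gamma)) * q * (1 - q)) *
      (1 - q^n - (1 - q)^n)
  }
  stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
}

# NI expected under the PRF model: R(gamma) = [L(gamma,n)/L(0,n)] / G(gamma),
# strictly decreasing in gamma
.prf_R <- function(gamma, n, L0 = prf_L(0, n)) prf_L(gamma, n) / L0 / prf_G(gamma)

#' Estimate the scaled selection intensity gamma from MK counts
#'
#' Poisson-random-field model: E[ps] = theta_s L(0,n), E[ds] = theta_s tau,
#' E[pn] = theta_r L(gamma,n), E[dn] = theta_r tau G(gamma). The observed
#' neutrality index then identifies gamma through the strictly decreasing
#' map R(gamma) = [L(gamma,n)/L(0,n)]/G(gamma); the MLE gamma-hat solves
#' R(gamma) = NI by monotone root finding (starting bracket [-30, 30],
#' doubled up to [-200, 200] before flagging a boundary). The test of
#' gamma = 0 is a likelihood-ratio test between the full (saturated) Poisson
#' fit and the gamma = 0 fit, referred to chi-square(1); with gamma free the
#' null fit is the 2x2 independence fit, so the LRT coincides with the
#' G-test of the MK table.
#'
#' @param ds,ps,dn,pn MK counts (all four must be positive for a point
#'   estimate; otherwise estimation is declined with a reason).
#' @param n_sample chromosomes sampled in the polymorphism data (default 40).
#' @return list with `gamma`, `p` (LRT, chi-square(1) upper tail),
#'   `lambda` (LRT statistic), `NI`, `boundary` (logical), `reason`
#'   (NA when estimated).
#' @export
prf_gamma <- function(ds, ps, dn, pn, n_sample = 40) {
  decline <- function(reason) list(gamma = NA_real_, p = NA_real_,
                                   lambda = NA_real_, NI = NA_real_,
                                   boundary = FALSE, reason = reason)
  if (any(c(ds, ps, dn, pn) < 0)) stop("counts must be nonnegative")
  if (min(ds, ps, dn, pn) <= 0) return(decline("zero count: NI undefined"))
  NI <- (pn / ps) / (dn / ds)
  L0 <- prf_L(0, n_sample)
  g <- function(x) .prf_R(x, n_sample, L0) - NI
  lo <- -30; hi <- 30
  while (g(lo) < 0 || g(hi) > 0) {   # R decreasing: need g(lo) > 0 > g(hi)
    lo <- lo * 2; hi <- hi * 2
    if (hi > 200) {
      gamma_hat <- if (NI < 1) 200 else -200
      lam <- .prf_lrt_stat(ds, ps, dn, pn)
      return(list(gamma = gamma_hat,
                  p = stats::pchisq(lam, 1, lower.tail = FALSE),
                  lambda = lam, NI = NI, boundary = TRUE,
                  reason = NA_character_))
    }
  }
  gamma_hat <- if (abs(NI - 1) < 1e-12) 0 else
    stats::uniroot(g, c(lo, hi), tol = 1e-9)$root
  lam <- .prf_lrt_stat(ds, ps, dn, pn, gamma_hat, n_sample, L0)
  list(gamma = gamma_hat, p = stats::pchisq(lam, 1, lower.tail = FALSE),
       lambda = lam, NI = NI, boundary = FALSE, reason = NA_character_)
}

# LRT statistic: full Poisson fit (theta_s, theta_r, tau, gamma-hat; exact
# fit of all four counts) versus the gamma = 0 fit (independence margins)
.prf_lrt_stat <- function(ds, ps, dn, pn, gamma_hat = NULL, n_sample = 40,
                          L0 = prf_L(0, n_sample)) {
  obs <- c(ps = ps, ds = ds, pn = pn, dn = dn)
  pois_ll <- function(mu) sum(stats::dpois(obs, pmax(mu, 1e-300), log = TRUE))
  if (!is.null(gamma_hat)) {
    theta_s <- ps / L0
    tau <- ds / theta_s
    theta_r <- pn / prf_L(gamma_hat, n_sample)
    mu_full <- c(theta_s * L0, theta_s * tau,
                 theta_r * prf_L(gamma_hat, n_sample),
                 theta_r * tau * prf_G(gamma_hat))
  } else {
    mu_full <- obs  # saturated
  }
  # gamma = 0: mu = (theta_s L0, theta_s tau, theta_r L0, theta_r tau);
  # Poisson MLE = independence fit of the 2x2 (rows syn/rep, cols poly/div)
  tot <- sum(obs)
  mu0 <- c((ps + ds) * (ps + pn), (ps + ds) * (ds + dn),
           (pn + dn) * (ps + pn), (pn + dn) * (ds + dn)) / tot
  max(0, 2 * (pois_ll(mu_full) - pois_ll(mu0)))
}

#' Run MK + PRF analysis over a table of genes
#'
#' @param mk data.frame with columns `gene_id` (or `symbol`), `ds`, `ps`,
#'   `dn`, `pn`, and optionally `n` (sample size; default `n_sample`).
#' @param n_sample default chromosomes sampled.
#' @return data.frame with FET p, NI, alpha, gamma-hat and LRT p per gene.
#' @export
mk_analyze <- function(mk, n_sample = 40) {
  id <- mk$gene_id %||% mk$symbol
  n <- if ("n" %in% names(mk)) mk$n else rep(n_sample, nrow(mk))
  rows <- lapply(seq_len(nrow(mk)), function(i) {
    f <- mk_fet(mk$ds[i], mk$ps[i], mk$dn[i], mk$pn[i])
    g <- prf_gamma(mk$ds[i], mk$ps[i], mk$dn[i], mk$pn[i], n_sample = n[i])
    data.frame(gene_id = id[i], ds = mk$ds[i], ps = mk$ps[i],
               dn = mk$dn[i], pn = mk$pn[i],
               fet_p = f$p, NI = f$NI, alpha = f$alpha,
               gamma = g$gamma, lrt_p = g$p, boundary = g$boundary,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flag positively selected genes at a p-value threshold
#'
#' @param results data.frame with a p column.
#' @param threshold strict threshold (default 0.1): rows with `p < threshold`
#'   are returned.
#' @param p_col name of the p column (default `"p"`).
#' @return the flagged subset of `results`.
#' @export
classify_positively_selected <- function(results, threshold = 0.1, p_col = "p") {
  if (!p_col %in% names(results)) stop("missing p column '", p_col, "'")
  results[results[[p_col]] < threshold, , drop = FALSE]
}

#' Compare proportions of positively selected genes between two gene sets
#'
#' @param set_a,set_b vectors/lists giving `(selected, total)` per set.
#' @param alternative passed to [stats::fisher.test()] (default two-sided).
#' @return Fisher exact p-value.
#' @export
selection_enrichment <- function(set_a, set_b, alternative = "two.sided") {
  a <- as.numeric(unlist(set_a)[1:2]); b <- as.numeric(unlist(set_b)[1:2])
  if (a[2] < a[1] || b[2] < b[1]) stop("total must be >= selected")
  if (a[2] == 0 || b[2] == 0) stop("zero totals")
  tab <- matrix(c(a[1], a[2] - a[1], b[1], b[2] - b[1]), 2, byrow = TRUE)
  stats::fisher.test(tab, alternative = alternative)$p.value
}
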