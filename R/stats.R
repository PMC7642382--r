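#' Required read depth for one-sided binomial detection power
#'
#' Gaussian-approximated power calculation for detecting an elevated junction
#' allele fraction `j1` against a null fraction `j0` with a one-sided binomial
#' test:
#' \deqn{R \ge \left(\frac{Z_{1-\alpha}\sqrt{J_0(1-J_0)} +
#'   Z_{1-\beta}\sqrt{J_1(1-J_1)}}{J_1 - J_0}\right)^2}
#' The default Z-scores 1.645 and 0.84 correspond to a 5% type-I rate and 80%
#' power. With the defaults and `j1 = 0.10` the smallest sufficient depth is
#' 150x.
#'
#' @param j0 Null junction allele fraction, in (0, 1).
#' @param j1 Alternative junction allele fraction, in (j0, 1).
#' @param z_alpha Type-I error Z-score.
#' @param z_beta Power Z-score.
#'
#' @return Smallest integer depth satisfying the inequality.
#' @export
#' @examples
#' required_depth(0.05, 0.10) # 150
required_depth <- function(j0 = 0.05, j1, z_alpha = 1.645, z_beta = 0.84) {
  stopifnot(is.finite(z_alpha), is.finite(z_beta))
  if (!(j0 > 0 && j0 < 1 && j1 > 0 && j1 < 1)) {
    stop("j0 and j1 must lie in (0, 1)", call. = FALSE)
  }
  if (j1 <= j0) stop("j1 must exceed j0", call. = FALSE)
  r <- ((z_alpha * sqrt(j0 * (1 - j0)) + z_beta * sqrt(j1 * (1 - j1))) /
          (j1 - j0))^2
  as.integer(ceiling(r))
}

#' Depth-vs-detectable-JAF power table
#'
#' Tabulates [required_depth()] over a grid of alternative junction allele
#' fractions, reproducing the familiar coverage-vs-JAF power curves.
#'
#' @inheritParams required_depth
#' @param j1 Vector of alternative fractions.
#' @return A tibble with columns `j0`, `j1`, `required_depth`.
#' @export
power_table <- function(j1 = seq(0.06, 0.5, by = 0.01), j0 = 0.05,
                        z_alpha = 1.645, z_beta = 0.84) {
  depths <- vapply(j1, function(a) required_depth(j0, a, z_alpha, z_beta),
                   integer(1))
  tibble::tibble(j0 = j0, j1 = j1, required_depth = depths)
}

#' Expected number of artifactual supporting reads
#'
#' At depth `depth` with mean base/alignment quality `q` (Phred scale), the
#' expected number of reads supporting a junction purely through error is
#' `depth * 10^(-q/10)`; e.g. 200x at Q20 gives 2 reads.
#'
#' @param depth Read depth (non-negative).
#' @param q Mean Phred quality.
#' @return Expected artifact read count.
#' @export
#' @examples
#' expected_artifact_reads(200, 20) # 2
expected_artifact_reads <- function(depth, q) {
  stopifnot(depth >= 0, q >= 0)
  depth * 10^(-q / 10)
}

#' Poisson upper-tail probability
#'
#' `P(X >= m)` for `X ~ Poisson(lambda)`. Used to justify the minimum
#' supporting-read threshold: with an expected 2 artifact reads, seeing 5 or
#' more by chance has probability ~5%.
#'
#' @param lambda Poisson mean (>= 0).
#' @param m Threshold count (>= 0).
#' @return Upper-tail probability.
#' @export
#' @examples
#' poisson_tail(2, 5) # ~0.053
poisson_tail <- function(lambda, m) {
  stopifnot(lambda >= 0, m >= 0)
  if (m == 0) return(1)
  stats::ppois(m - 1, lambda, lower.tail = FALSE)
}

#' Probability that an intron can host a new exon
#'
#' A new exon requires a 9-nt donor and a 23-nt acceptor motif separated by an
#' exon-sized gap `E` — a joint 32-nt event with per-placement probability
#' 4^-32 (~1e-19) that can occur in about `L - E - 31` positions within an
#' intron of length `L`. The exact form is `1 - (1 - 4^-32)^(L - E - 31)`,
#' evaluated with `expm1`/`log1p` to survive the tiny per-placement
#' probability; `linear = TRUE` returns the first-order expansion
#' `(L - E - 31) * 4^-32`.
#'
#' @param L Intron length (bp).
#' @param E Exon length (bp).
#' @param linear Use the linearised approximation.
#' @return Probability (0 when `L < E + 31`, with a warning).
#' @export
new_exon_probability <- function(L, E, linear = FALSE) {
  n <- L - E - 31
  if (any(n < 0)) {
    warning("intron shorter than E + 31: no placement possible, returning 0")
  }
  n <- pmax(n, 0)
  p <- 4^-32
  if (linear) n * p else -expm1(n * log1p(-p))
}

#' Long- versus short-intron bias for new-exon creation
#'
#' Under the placement-count model of [new_exon_probability()], the relative
#' propensity of a long intron (`long_len`) versus a short intron
#' (`short_len`) to host a new exon of size `exon_len` is
#' `(L_L - E - 31) / (L_S - E - 31)`: about 10-fold for 30 kb vs 3 kb introns,
#' and ~40-fold for a 200 bp exon in a 1 kb intron.
#'
#' @param long_len,short_len Intron lengths in bp (`long_len >= short_len`).
#' @param exon_len Exon length in bp.
#' @return The fold-bias ratio.
#' @export
#' @examples
#' intron_bias_ratio(30000, 3000)        # ~10
#' intron_bias_ratio(30000, 1000, 200)   # ~40
intron_bias_ratio <- function(long_len, short_len, exon_len = 0) {
  if (long_len < short_len) stop("long_len must be >= short_len", call. = FALSE)
  denom <- short_len - exon_len - 31
  if (denom <= 0) {
    stop("short intron leaves no room for the exon plus motifs", call. = FALSE)
  }
  (long_len - exon_len - 31) / denom
}

#' Tukey outlier score for one expression value against a cohort
#'
#' Computes `(x - Q3)/IQR` when `x` lies above the third quartile and
#' `(x - Q1)/IQR` below the first quartile (0 and tail `"none"` in between);
#' `|score| > 1.5` flags an expression outlier. Quartiles use linear
#' interpolation (`quantile` type 7). Expression values are expected on a
#' log2 scale (e.g. log2 RSEM).
#'
#' @param x Expression value of the sample of interest.
#' @param cohort Numeric vector of cohort expression values (length >= 4).
#' @param fence Outlier fence on the score scale (default 1.5).
#' @return One-row tibble: `x`, `q1`, `q3`, `iqr`, `score`, `tail`,
#'   `outlier`, `degenerate`, `p`. `p` maps the score through a normal model
#'   centred at the median with sigma = IQR/1.349, a reconstruction of the
#'   conventional score-to-p conversion (one-sided by tail).
#' @export
#' @examples
#' tukey_outlier(10, c(2, 3, 4, 5, 6))
tukey_outlier <- function(x, cohort, fence = 1.5) {
  if (length(cohort) < 4) stop("cohort must have >= 4 values", call. = FALSE)
  qs <- stats::quantile(cohort, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  q1 <- qs[1]; med <- qs[2]; q3 <- qs[3]
  iqr <- q3 - q1
  degenerate <- iqr <= 0
  if (degenerate) {
    score <- NA_real_; tail <- "none"; p <- NA_real_
  } else if (x > q3) {
    score <- (x - q3) / iqr; tail <- "upper"
    p <- stats::pnorm(x, med, iqr / 1.349, lower.tail = FALSE)
  } else if (x < q1) {
    score <- (x - q1) / iqr; tail <- "lower"
    p <- stats::pnorm(x, med, iqr / 1.349)
  } else {
    score <- 0; tail <- "none"; p <- NA_real_
  }
  tibble::tibble(
    x = x, q1 = q1, q3 = q3, iqr = iqr, score = score, tail = tail,
    outlier = !degenerate && is.finite(score) && abs(score) > fence,
    degenerate = degenerate, p = p
  )
}

#' Expression outliers across genes
#'
#' Applies [tukey_outlier()] gene-by-gene: for each gene the value of
#' `sample` is scored against the remaining cohort samples, and p-values are
#' BH-corrected across genes.
#'
#' @param expr A data frame with one row per gene/sample pair.
#' @param sample Sample identifier to score.
#' @param gene_col,sample_col,value_col Column names (strings) holding gene
#'   id, sample id and log2 expression.
#' @param fence Outlier fence (default 1.5).
#' @return Tibble with one row per gene: the [tukey_outlier()] columns plus
#'   `gene_id`, `sample_id` and BH-adjusted `q`.
#' @export
expression_outliers <- function(expr, sample,
                                gene_col = "gene_id",
                                sample_col = "sample_id",
                                value_col = "value",
                                fence = 1.5) {
  stopifnot(is.data.frame(expr),
            all(c(gene_col, sample_col, value_col) %in% names(expr)))
  df <- tibble::tibble(
    gene_id = expr[[gene_col]],
    sample_id = expr[[sample_col]],
    value = expr[[value_col]]
  )
  res <- df |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(g, key) {
      xi <- g$value[g$sample_id == sample]
      cohort <- g$value[g$sample_id != sample]
      if (length(xi) != 1 || length(cohort) < 4) {
        return(tibble::tibble(
          x = if (length(xi) == 1) xi else NA_real_,
          q1 = NA_real_, q3 = NA_real_, iqr = NA_real_,
          score = NA_real_, tail = "none", outlier = FALSE,
          degenerate = TRUE, p = NA_real_
        ))
      }
      tukey_outlier(xi, cohort, fence = fence)
    }) |>
    dplyr::ungroup()
  res$sample_id <- sample
  res$q <- bh_fdr(res$p)
  dplyr::relocate(res, "gene_id", "sample_id")
}

#' Fisher enrichment of splice-creating mutations in a gene class
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' `[[n1, n2], [t1, t2]]` where `n1`/`n2` are non-cancer / cancer genes
#' carrying splice-site-creating mutations and `t1`/`t2` the genome-wide
#' tallies. The p-value is the conventional sum over all tables with the same
#' margins whose probability does not exceed the observed table's. The odds
#' ratio reported is the direct ratio `(n2/n1) / (t2/t1)`.
#'
#' @param n1,n2,t1,t2 Non-negative integer cell counts.
#' @return One-row tibble with `odds_ratio` and `p`.
#' @export
#' @examples
#' fisher_enrichment(202, 17, 19376, 624)
fisher_enrichment <- function(n1, n2, t1, t2) {
  cells <- c(n1, n2, t1, t2)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  if ((n1 + n2) == 0 || (t1 + t2) == 0 || (n1 + t1) == 0 || (n2 + t2) == 0) {
    stop("a margin of the table is zero; the test is undefined", call. = FALSE)
  }
  tab <- matrix(c(n1, n2, t1, t2), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or <- (n2 / n1) / (t2 / t1)
  tibble::tibble(odds_ratio = or, p = min(p, 1))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment in input order; `NA` p-values yield `NA` q-values
#' and do not count towards the number of tests.
#'
#' @param p Vector of p-values in \[0, 1\] (NAs allowed).
#' @return Vector of q-values, same order and length.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Exact one-sided binomial upper-tail p-value
#'
#' `P(X >= n_supporting)` for `X ~ Binomial(depth, null_jaf)` — the
#' proportion-test p-value for a junction with `n_supporting` of `depth`
#' reads under a null junction allele fraction.
#'
#' @param n_supporting Supporting read count.
#' @param depth Total read depth (> 0).
#' @param null_jaf Null junction allele fraction in (0, 1).
#' @return Upper-tail p-value.
#' @export
binomial_upper_p <- function(n_supporting, depth, null_jaf) {
  if (any(null_jaf <= 0 | null_jaf >= 1)) {
    stop("null_jaf must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(all(depth > 0), all(n_supporting >= 0),
            all(n_supporting <= depth))
  ifelse(n_supporting == 0, 1,
         stats::pbinom(n_supporting - 1, depth, null_jaf, lower.tail = FALSE))
}
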