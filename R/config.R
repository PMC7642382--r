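#' Pipeline configuration
#'
#' Bundles the tunable thresholds of the discovery pipeline. Defaults follow
#' the published parameterisation: at least `min_supporting_reads` (M = 5)
#' junction reads each with mapping quality at least `min_mapq` (Q = 20),
#' a mutation-to-junction window of `window` bp (N = 20), a case/control
#' top fraction `control_top_fraction` (k = 0.05), a minimum junction allele
#' fraction `min_jaf` of 0.05 for the heuristic coverage filter, and a 30%
#' minimum mutant fraction among junction reads for spliced-in mutations.
#'
#' @param min_supporting_reads Minimum junction-supporting reads (M).
#' @param min_mapq Minimum read mapping quality (Q).
#' @param window Maximum mutation-to-junction distance in bp (N).
#' @param control_top_fraction Case/control top fraction (k): the case count
#'   must exceed the counts of all but less than this fraction of controls.
#' @param min_jaf Minimum junction allele fraction for the heuristic filter.
#' @param min_spliced_in_fraction Minimum fraction of mutation-covering
#'   junction reads that must carry the alternate allele when the mutation is
#'   spliced in.
#' @param batch_size Mutations per batch for parallel processing.
#' @param mode Coverage/JAF filter mode: `"heuristic"` (JAF cut-off) or
#'   `"proportion"` (exact binomial proportion test with BH correction).
#' @param null_jaf Null junction allele fraction for the proportion test.
#' @param alpha FDR level for the proportion-test mode.
#' @param new_exon_size Plausible new-exon length bounds (bp) used when
#'   pairing a primary splice site with an activated mate site.
#' @param seed Integer seed used by any stochastic helper.
#'
#' @return A list of class `"splice_config"`.
#' @export
#' @examples
#' splice_config(window = 25)
splice_config <- function(min_supporting_reads = 5L,
                          min_mapq = 20L,
                          window = 20L,
                          control_top_fraction = 0.05,
                          min_jaf = 0.05,
                          min_spliced_in_fraction = 0.30,
                          batch_size = 200L,
                          mode = c("heuristic", "proportion"),
                          null_jaf = 0.05,
                          alpha = 0.05,
                          new_exon_size = c(15L, 600L),
                          seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(
    min_supporting_reads >= 1, min_mapq >= 0, window >= 1,
    control_top_fraction > 0, control_top_fraction < 1,
    min_jaf >= 0, min_jaf <= 1,
    min_spliced_in_fraction >= 0, min_spliced_in_fraction <= 1,
    batch_size >= 1,
    null_jaf > 0, null_jaf < 1, alpha > 0, alpha <= 1,
    length(new_exon_size) == 2, new_exon_size[1] <= new_exon_size[2]
  )
  structure(
    list(
      min_supporting_reads = as.integer(min_supporting_reads),
      min_mapq = as.integer(min_mapq),
      window = as.integer(window),
      control_top_fraction = control_top_fraction,
      min_jaf = min_jaf,
      min_spliced_in_fraction = min_spliced_in_fraction,
      batch_size = as.integer(batch_size),
      mode = mode,
      null_jaf = null_jaf,
      alpha = alpha,
      new_exon_size = as.integer(new_exon_size),
      seed = as.integer(seed)
    ),
    class = "splice_config"
  )
}

#' @export
print.splice_config <- function(x, ...) {
  cat("<splice_config>\n")
  cat(sprintf("  M = %d supporting reads, Q >= %d, N = %d bp, k = %.3g\n",
              x$min_supporting_reads, x$min_mapq, x$window,
              x$control_top_fraction))
  cat(sprintf("  coverage filter: %s (min JAF %.3g / null %.3g, alpha %.3g)\n",
              x$mode, x$min_jaf, x$null_jaf, x$alpha))
  cat(sprintf("  spliced-in fraction >= %.2f, batch %d, seed %d\n",
              x$min_spliced_in_fraction, x$batch_size, x$seed))
  invisible(x)
}
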