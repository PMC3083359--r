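#' Diagnostic plots
#'
#' Optional figures mirroring the usual survey summaries: read-length
#' distribution, per-hit identity distribution, and the microsatellite
#' motif census. Plots are presentation artifacts only; no computation
#' consumes them.
#'
#' @param reads A [bes_reads] tibble.
#' @param binwidth Histogram bin width (bp).
#' @return A ggplot object.
#' @export
plot_read_lengths <- function(reads, binwidth = 50) {
  df <- tibble(len = nchar(reads$seq))
  ggplot2::ggplot(df, ggplot2::aes(x = len)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "grey30") +
    ggplot2::labs(x = "Read length (bp)", y = "Reads") +
    ggplot2::theme_minimal()
}

#' @rdname plot_read_lengths
#' @param idsum Result of [identity_summary()].
#' @export
plot_identity_histogram <- function(idsum) {
  ggplot2::ggplot(idsum$histogram,
                  ggplot2::aes(x = bin_lo, y = n)) +
    ggplot2::geom_col(fill = "steelblue", colour = "grey30") +
    ggplot2::labs(x = "Percent identity", y = "BES") +
    ggplot2::theme_minimal()
}

#' @rdname plot_read_lengths
#' @param census An `ssr_census`.
#' @param top_n How many motifs to show.
#' @export
plot_ssr_census <- function(census, top_n = 15) {
  df <- head(census$by_motif, top_n)
  df$canonical <- factor(df$canonical, levels = rev(df$canonical))
  ggplot2::ggplot(df, ggplot2::aes(x = canonical, y = n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "Canonical motif", y = "Microsatellites") +
    ggplot2::theme_minimal()
}
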