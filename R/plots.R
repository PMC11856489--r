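# ggplot2 helpers for the main result types.

#' Stacked RSCU bars per genome
#' @param rscu_tbl output of [rscu()] (multiple genomes stack by facet)
#' @return a ggplot
#' @export
plot_rscu <- function(rscu_tbl) {
  ggplot2::ggplot(rscu_tbl,
                  ggplot2::aes(x = .data$amino_acid, y = .data$rscu,
                               fill = .data$codon)) +
    ggplot2::geom_col(position = "stack", show.legend = FALSE) +
    ggplot2::facet_wrap(~species_id) +
    ggplot2::labs(x = "amino acid", y = "RSCU") +
    ggplot2::theme_minimal()
}

#' Per-gene distributions of pairwise K2P, Ka and Ks
#' @param rates output of [pairwise_gene_rates()]
#' @return a ggplot (boxplots, genes ordered by median K2P)
#' @export
plot_gene_rates <- function(rates) {
  long <- rates |>
    dplyr::select("gene", "d_k2p", "ka", "ks") |>
    tidyr::pivot_longer(c("d_k2p", "ka", "ks"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(is.finite(.data$value))
  ord <- rates |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(m = stats::median(.data$d_k2p, na.rm = TRUE)) |>
    dplyr::arrange(dplyr::desc(.data$m))
  long$gene <- factor(long$gene, levels = ord$gene)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Base-frequency profile around intron insertion sites
#' @param profile output of [flank_profile()]
#' @return a ggplot (per-position base frequencies, -window..+window)
#' @export
plot_flank_profile <- function(profile) {
  ggplot2::ggplot(profile$freq,
                  ggplot2::aes(x = .data$position, y = .data$freq,
                               colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "position relative to insertion site (nt)",
                  y = "base frequency") +
    ggplot2::theme_minimal()
}

#' Intron length histogram per species
#' @param introns intron tibble (see [extract_introns()])
#' @param binwidth histogram bin width in nt
#' @return a ggplot
#' @export
plot_intron_lengths <- function(introns, binwidth = 500) {
  ggplot2::ggplot(introns, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey40") +
    ggplot2::facet_wrap(~species_id) +
    ggplot2::labs(x = "intron length (nt)", y = "count") +
    ggplot2::theme_minimal()
}
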