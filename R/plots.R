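#' Plot a prioritization as a genotype heat map
#'
#' Tiles sites by samples, filling by zygosity, with the site verdict as a
#' left-hand annotation strip. Candidate sites sort to the top.
#'
#' @param object A `pkd_prioritization` from [prioritize()].
#' @param table The `variant_table` the prioritization came from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pkd_prioritization <- function(object, table, ...) {
  samples <- vt_samples(table)
  long <- tidyr::pivot_longer(
    dplyr::left_join(
      tidy(object),
      tibble::as_tibble(unclass(table)[c("assay_id", samples)]),
      by = "assay_id"
    ),
    cols = dplyr::all_of(samples),
    names_to = "sample", values_to = "genotype"
  )
  long$zygosity <- ifelse(
    vapply(long$genotype, is_heterozygous, logical(1)),
    "heterozygous", "homozygous"
  )
  long$assay_id <- factor(long$assay_id, levels = rev(object$assay_id))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$sample, y = .data$assay_id, fill = .data$zygosity)
  ) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$genotype), size = 2.4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$verdict),
      scales = "free_y", space = "free_y"
    ) +
    ggplot2::scale_fill_manual(
      values = c(heterozygous = "#fdd49e", homozygous = "#d9d9d9")
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot phased haplotypes
#'
#' One tile per (haplotype, site), coloured by allele token, mirroring the
#' dash-joined haplotype strings.
#'
#' @param object A `pkd_phasing` from [min_parsimony_phase()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pkd_phasing <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$site, y = .data$label, fill = .data$allele)
  ) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$allele), size = 2.2) +
    ggplot2::labs(x = "site index", y = NULL, fill = "allele") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(legend.position = "none")
}
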