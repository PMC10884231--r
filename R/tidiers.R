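# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a Reference Set build
#'
#' @param x an `ig_reference_build` from [build_reference_set()].
#' @param ... unused.
#' @return the Reference Set entry tibble with list-columns flattened to
#'   semicolon-joined strings.
#' @method tidy ig_reference_build
#' @export
tidy.ig_reference_build <- function(x, ...) {
  x$reference_set %>%
    mutate(
      paralogs = semicolon_join(.data$paralogs),
      aliases = semicolon_join(.data$aliases)
    )
}

#' @rdname tidy.ig_reference_build
#' @return `glance()` returns a one-row tibble of build-level counts.
#' @method glance ig_reference_build
#' @export
glance.ig_reference_build <- function(x, ...) {
  tibble(
    version_label = x$version_label,
    n_source = x$source_size,
    n_reference = nrow(x$reference_set),
    n_collapsed = x$source_size - nrow(x$reference_set),
    n_extended = sum(x$reference_set$extension_donor != "none"),
    n_paralog_groups = sum(map_int(x$reference_set$paralogs, length) > 0)
  )
}

#' Tidy a set comparison
#'
#' @param x an `ig_set_comparison` from [compare_sets()].
#' @param ... unused.
#' @return a tibble with one row per sequence and its partition.
#' @method tidy ig_set_comparison
#' @export
tidy.ig_set_comparison <- function(x, ...) {
  bind_rows(
    mutate(x$shared, partition = "shared"),
    mutate(x$built_only, partition = "built_only"),
    mutate(x$comparator_only, partition = "comparator_only")
  )
}

#' @rdname tidy.ig_set_comparison
#' @return `glance()` returns the three partition counts.
#' @method glance ig_set_comparison
#' @export
glance.ig_set_comparison <- function(x, ...) {
  tibble(
    shared = x$shared_n,
    built_only = x$built_only_n,
    comparator_only = x$comparator_only_n
  )
}

#' Plot per-gene expression frequencies against the proximal/distal bands
#'
#' @param object an `ig_frequency_classification` from
#'   [classify_proximal_distal()].
#' @param config the [curation_config()] whose bands to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ig_frequency_classification
#' @export
autoplot.ig_frequency_classification <- function(object,
                                                 config = curation_config(),
                                                 ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$gene, y = .data$median_frequency, fill = .data$classification
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = config$proximal_freq_hi, linetype = 2) +
    ggplot2::geom_hline(yintercept = config$distal_freq_lo, linetype = 3) +
    ggplot2::labs(
      x = NULL, y = "median % of productive VJ repertoire",
      title = "Expression frequency vs proximal/distal bands"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot anchored read counts behind a haplotype assignment
#'
#' @param object an `ig_haplotype_assignment` from
#'   [haplotype_individual()] or [haplotype_all()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ig_haplotype_assignment
#' @export
autoplot.ig_haplotype_assignment <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    c("count_on_anchor1", "count_on_anchor2"),
    names_to = "anchor", values_to = "reads"
  ) %>%
    mutate(anchor = ifelse(.data$anchor == "count_on_anchor1",
                           .data$anchor_allele_1, .data$anchor_allele_2))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$v_allele, y = .data$reads, fill = .data$anchor
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~individual_id, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "anchored reads",
                  title = "V-allele phasing by anchor-J heterozygosity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
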