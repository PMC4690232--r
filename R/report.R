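# Summary tables and demo plots: per-type counts and lengths, size
# spectrum, ancestral-state and mechanism proportions by size bin.

size_bins <- function(len) {
  cut(pmax(len, 1),
      breaks = c(0, 10, 100, 1000, 10000, 100000, Inf),
      labels = c("1-10", "10-100", "100-1k", "1k-10k", "10k-100k", ">100k"))
}

variant_len <- function(v) {
  pmax(nchar(v$ref), nchar(v$alt)) - 1L
}

#' Summarize a variant record set
#'
#' Per variant type: total Number, total Length, Min_length, Max_length,
#' the mean per-individual load and the across-individual SDs of number and
#' length; plus a log-spaced size-spectrum histogram and, when the
#' annotations are present, ancestral-state and mechanism proportions per
#' size bin. Every value is re-derivable from the records by one-pass
#' tabulation.
#'
#' @param records record tibble (needs `ref`, `alt`, `category`; optionally
#'   `carriers`, `aa_state`, `mechanism`).
#' @return list of tibbles: `by_type`, `size_spectrum`, `ancestral`,
#'   `mechanism` (the latter two NULL without annotations).
#' @export
summarize_variants <- function(records) {
  v <- as_tibble(records)
  if (nrow(v) == 0) {
    return(list(by_type = tibble(category = character(), n = integer(),
                                 length = integer(), min_length = integer(),
                                 max_length = integer(),
                                 individual_load = numeric(),
                                 sd_number = numeric(), sd_length = numeric()),
                size_spectrum = tibble(), ancestral = NULL, mechanism = NULL))
  }
  v$len <- variant_len(v)
  v$len[v$category == "SNP"] <- 1L
  per_ind <- NULL
  if ("carriers" %in% names(v)) {
    per_ind <- tidyr::unnest(v[c("category", "len", "carriers")],
                             cols = "carriers") |>
      dplyr::group_by(.data$category, .data$carriers) |>
      dplyr::summarise(n = dplyr::n(), length = sum(.data$len),
                       .groups = "drop")
  }
  by_type <- v |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n = dplyr::n(), length = sum(.data$len),
                     min_length = min(.data$len), max_length = max(.data$len),
                     .groups = "drop")
  if (!is.null(per_ind)) {
    load <- per_ind |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(individual_load = mean(.data$n),
                       sd_number = stats::sd(.data$n),
                       sd_length = stats::sd(.data$length), .groups = "drop")
    by_type <- dplyr::left_join(by_type, load, by = "category")
  }
  spectrum <- v |>
    dplyr::filter(.data$category != "SNP") |>
    dplyr::mutate(bin = size_bins(.data$len),
                  type = ifelse(nchar(.data$alt) >= nchar(.data$ref),
                                "INS", "DEL")) |>
    dplyr::count(.data$type, .data$bin, .drop = FALSE)
  anc <- mech <- NULL
  if ("aa_state" %in% names(v)) {
    anc <- v |>
      dplyr::filter(!is.na(.data$aa_state), .data$category != "SNP") |>
      dplyr::mutate(bin = size_bins(.data$len)) |>
      dplyr::count(.data$bin, .data$aa_state) |>
      dplyr::group_by(.data$bin) |>
      dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  }
  if ("mechanism" %in% names(v)) {
    mech <- v |>
      dplyr::filter(!is.na(.data$mechanism), .data$category != "SNP") |>
      dplyr::mutate(bin = size_bins(.data$len)) |>
      dplyr::count(.data$bin, .data$mechanism) |>
      dplyr::group_by(.data$bin) |>
      dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  }
  list(by_type = by_type, size_spectrum = spectrum, ancestral = anc,
       mechanism = mech)
}

#' Size-spectrum demo plot
#'
#' Log-spaced size bins on the x axis, counts on a log y axis, deletions
#' and insertions side by side.
#'
#' @param records record tibble.
#' @return a ggplot object.
#' @export
plot_size_spectrum <- function(records) {
  sp <- summarize_variants(records)$size_spectrum
  ggplot2::ggplot(sp, ggplot2::aes(.data$bin, .data$n, fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "size bin (bp)", y = "count", fill = NULL)
}

#' Stacked proportions of ancestral states or mechanisms by size bin
#'
#' @param records annotated record tibble.
#' @param what `"ancestral"` or `"mechanism"`.
#' @return a ggplot object.
#' @export
plot_annotation_spectrum <- function(records, what = c("ancestral", "mechanism")) {
  what <- match.arg(what)
  tab <- summarize_variants(records)[[what]]
  if (is.null(tab) || nrow(tab) == 0) abort("records carry no such annotation")
  fillcol <- if (what == "ancestral") "aa_state" else "mechanism"
  ggplot2::ggplot(tab, ggplot2::aes(.data$bin, .data$proportion,
                                    fill = .data[[fillcol]])) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "size bin (bp)", y = "proportion", fill = NULL)
}

#' Discover and merge variants across a population of assemblies
#'
#' Runs [discover_individual()] for every individual in a block table and
#' merges the normalized calls into population records.
#'
#' @param blocks block tibble covering several individuals.
#' @param ref_seqs reference sequences.
#' @param assemblies tibble `individual`, `name`, `sequence` (scaffolds).
#' @param prior optional prior call set (see [merge_population()]).
#' @param ... passed to [call_between_blocks()].
#' @return list: `records` (merged, double-hit-flagged), `per_individual`
#'   (long variant tibble), `unaligned`, `ref_gaps`.
#' @export
discover_population <- function(blocks, ref_seqs, assemblies, prior = NULL,
                                ...) {
  per_ind <- list(); unal <- list(); gaps <- list()
  for (ind in unique(assemblies$individual)) {
    scafs <- assemblies[assemblies$individual == ind, c("name", "sequence")]
    bl <- blocks[blocks$q_name %in% scafs$name, , drop = FALSE]
    res <- discover_individual(bl, ref_seqs, scafs, individual = ind, ...)
    per_ind[[ind]] <- res$variants
    unal[[ind]] <- dplyr::mutate(res$unaligned, individual = ind)
    gaps[[ind]] <- dplyr::mutate(res$ref_gaps, individual = ind)
  }
  all_vars <- dplyr::bind_rows(unname(per_ind))
  records <- find_double_hits(merge_population(all_vars, prior))
  list(records = records, per_individual = all_vars,
       unaligned = dplyr::bind_rows(unname(unal)),
       ref_gaps = dplyr::bind_rows(unname(gaps)))
}
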