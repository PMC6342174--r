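# Plot-data builders and static renderers: stacked bar chart of record
# frequencies per chromosome number (colored by species) and the
# percentage heatmap. Plot *data* is the tested surface; rendering is
# a thin deterministic layer over ggplot2.

#' Build stacked-bar plot data from a frequency table
#'
#' One bar per distinct chromosome number; within a bar, one segment
#' per species with height equal to its record frequency, stacked in
#' fixed species sort order with a deterministic color index. A species
#' recorded at several counts appears in several bars — the visual
#' signature of a polyploid series.
#'
#' @param freq A `chrom_freq` tibble from [count_frequencies()].
#' @return An object of class `stacked_bar_data`: list with `segments`
#'   (tibble `count`, `species`, `n_records`, ordered by count then
#'   species) and `legend` (tibble `species`, `color_index`).
#' @export
stacked_bar_data <- function(freq) {
  stopifnot(is.data.frame(freq))
  if (!nrow(freq)) {
    rlang::abort("empty frequency table", class = "chromcurate_validation_error")
  }
  segments <- freq |>
    dplyr::select("count", "species", "n_records") |>
    dplyr::arrange(.data$count, .data$species)
  legend <- tibble::tibble(species = sort(unique(segments$species)))
  legend$color_index <- seq_len(nrow(legend))
  structure(list(segments = segments, legend = legend),
            class = "stacked_bar_data")
}

#' @export
print.stacked_bar_data <- function(x, ...) {
  cat(sprintf("<stacked_bar_data> %d bars, %d species, %d records\n",
              dplyr::n_distinct(x$segments$count), nrow(x$legend),
              sum(x$segments$n_records)))
  print(x$segments, ...)
  invisible(x)
}

#' Export stacked-bar data as JSON
#'
#' Schema: `{"bars": [{"count": c, "segments": [{"species": s,
#' "n_records": n}, ...]}, ...]}` — the same structure an interactive
#' front end would consume for a hover plot.
#'
#' @param data A `stacked_bar_data` object.
#' @param path Optional file path; if `NULL`, the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
stacked_bar_json <- function(data, path = NULL) {
  stopifnot(inherits(data, "stacked_bar_data"))
  bars <- data$segments |>
    dplyr::group_by(count = .data$count) |>
    dplyr::group_map(function(seg, key) {
      list(count = key$count,
           segments = purrr::map2(seg$species, seg$n_records,
                                  ~list(species = .x, n_records = .y)))
    })
  js <- jsonlite::toJSON(list(bars = bars), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path, useBytes = TRUE)
  invisible(js)
}

.species_palette <- function(n) {
  base <- c("#4477AA", "#EE6677", "#228833", "#CCBB44", "#66CCEE",
            "#AA3377", "#BBBBBB", "#999933", "#882255", "#44AA99")
  rep_len(base, n)
}

#' ggplot of the stacked bar chart
#'
#' @param x A `stacked_bar_data` object or a `chrom_freq` tibble.
#' @param ... Unused.
#' @return A ggplot object: record frequency per chromosome number,
#'   stacked and colored by species.
#' @export
plot_stacked_bar <- function(x, ...) {
  data <- if (inherits(x, "stacked_bar_data")) x else stacked_bar_data(x)
  seg <- data$segments
  seg$species <- factor(seg$species, levels = data$legend$species)
  ggplot2::ggplot(seg, ggplot2::aes(x = factor(.data$count),
                                    y = .data$n_records,
                                    fill = .data$species)) +
    ggplot2::geom_col(position = ggplot2::position_stack(reverse = TRUE),
                      color = "grey20", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = .species_palette(nrow(data$legend)),
                               name = "Species") +
    ggplot2::labs(x = "Chromosome number", y = "Number of records") +
    ggplot2::theme_minimal()
}

#' @rdname plot_stacked_bar
#' @param object A `chrom_freq` tibble.
#' @method autoplot chrom_freq
#' @export
autoplot.chrom_freq <- function(object, ...) plot_stacked_bar(object, ...)

.check_percent_matrix <- function(m, tol = 1e-6) {
  if (!is.matrix(m) || !nrow(m) || is.null(rownames(m))) {
    rlang::abort("need a species x count percentage matrix with rownames",
                 class = "chromcurate_validation_error")
  }
  if (any(abs(rowSums(m) - 100) > tol)) {
    rlang::abort("heatmap rows must each sum to 100 (per-species percentages)",
                 class = "chromcurate_validation_error")
  }
  invisible(m)
}

#' ggplot of the percentage heatmap
#'
#' @param m A species x count percentage matrix from
#'   [heatmap_percentages()] (per-species normalization: rows sum to
#'   100).
#' @param ... Unused.
#' @return A ggplot object; zero cells are drawn (lightest fill), so
#'   they remain distinct from species absent from the matrix.
#' @export
plot_count_heatmap <- function(m, ...) {
  .check_percent_matrix(m)
  df <- tibble::as_tibble(m, rownames = "species") |>
    tidyr::pivot_longer(-"species", names_to = "count",
                        values_to = "percent")
  df$count <- factor(df$count, levels = sort(unique(as.integer(df$count))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$species,
                                   fill = .data$percent)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_gradient(low = "#F7FBFF", high = "#08306B",
                                 limits = c(0, 100),
                                 name = "% of records") +
    ggplot2::labs(x = "Chromosome number", y = NULL) +
    ggplot2::theme_minimal()
}

.render <- function(p, path, width, height) {
  force(p) # validate the plot before any file is touched
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext,
    png = function(f) grDevices::png(f, width = width, height = height,
                                     units = "in", res = 150),
    svg = function(f) grDevices::svg(f, width = width, height = height),
    pdf = function(f) grDevices::pdf(f, width = width, height = height),
    rlang::abort(sprintf("unsupported image format '.%s' (png/svg/pdf)", ext),
                 class = "chromcurate_validation_error")
  )
  dev(path)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}

#' Render the stacked bar chart to an image file
#'
#' @param data A `stacked_bar_data` object (or `chrom_freq` tibble).
#' @param path Output path; format from the extension (png/svg/pdf).
#' @param width,height Figure size in inches.
#' @return `path`, invisibly.
#' @export
render_stacked_bar <- function(data, path, width = 7, height = 4.5) {
  .render(plot_stacked_bar(data), path, width, height)
}

#' Render the percentage heatmap to an image file
#'
#' @param m Percentage matrix (see [plot_count_heatmap()]).
#' @param path Output path; format from the extension (png/svg/pdf).
#' @param width,height Figure size in inches.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(m, path, width = 7, height = 4.5) {
  .render(plot_count_heatmap(m), path, width, height)
}
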