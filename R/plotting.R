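# PDF rendering of average-profile plots and clustered heatmaps. Every
# render also writes a JSON manifest next to the PDF (row order, color
# and axis limits, labels) so the visual output is testable without
# image diffing.

#' Configure a plot
#'
#' @param kind `"profile"` or `"heatmap"`
#' @param title,x_label,y_label text; sensible defaults per kind
#' @param y_min,y_max optional fixed y-axis limits (profile)
#' @param color_map character vector of line colors (profile) or a
#'   2+ color gradient for heatmaps (low -> high); defaults: a
#'   qualitative palette / white-to-blue
#' @param error_band `"none"`, `"se"` or `"ci95"` (profile ribbons)
#' @param heatmap_clip quantile pair `(lo, hi)` clipping the heatmap
#'   color scale per panel; the default (0.01, 0.99) keeps coverage
#'   outliers from flattening the gradient
#' @param width,height device size in inches
#' @return a `PlotSpec` object
#' @export
plot_spec <- function(kind = c("profile", "heatmap"), title = NULL,
                      x_label = NULL, y_label = NULL,
                      y_min = NULL, y_max = NULL, color_map = NULL,
                      error_band = c("ci95", "se", "none"),
                      heatmap_clip = c(0.01, 0.99),
                      width = 7, height = 5) {
  kind <- match.arg(kind)
  error_band <- match.arg(error_band)
  if (!is.null(y_min) && !is.null(y_max) && !(y_min < y_max))
    stopf("y_min must be < y_max")
  stopifnot(length(heatmap_clip) == 2, heatmap_clip[1] >= 0,
            heatmap_clip[1] < heatmap_clip[2], heatmap_clip[2] <= 1)
  structure(list(kind = kind, title = title,
                 x_label = x_label %||% "Position relative to anchor [bp]",
                 y_label = y_label %||%
                   if (kind == "profile") "Mean signal" else "Feature",
                 y_min = y_min, y_max = y_max,
                 color_map = color_map, error_band = error_band,
                 heatmap_clip = heatmap_clip,
                 width = width, height = height),
            class = "PlotSpec")
}

default_line_colors <- function(n) {
  pal <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
           "#A65628", "#F781BF", "#999999")
  rep_len(pal, n)
}

manifest_path <- function(pdf_path) sub("\\.pdf$", ".manifest.json", pdf_path)

write_manifest <- function(pdf_path, manifest) {
  jsonlite::write_json(manifest, manifest_path(pdf_path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

summary_label <- function(s) {
  paste0(attr(s, "signal_label") %||% "signal", " @ ",
         attr(s, "feature_label") %||% "features")
}

#' Plot average profiles with error bands
#'
#' One line per summary (legend label `"signal @ feature"`), optional
#' translucent ribbon (`+/- se` or the 95% band), x axis in bp relative
#' to the anchor with 0 marked. When autoscaled, the y range contains
#' the full extent of the drawn bands.
#'
#' @param summaries a `ProfileSummary` or list of them, sharing bin
#'   offsets
#' @param spec a [plot_spec()] of kind `"profile"`
#' @param pdf_path output PDF; a JSON manifest is written alongside
#' @return `pdf_path`, invisibly
#' @export
plot_profile <- function(summaries, spec = plot_spec("profile"), pdf_path) {
  if (inherits(summaries, "ProfileSummary")) summaries <- list(summaries)
  offs <- lapply(summaries, `[[`, "offset")
  if (length(unique(vapply(offs, paste, character(1), collapse = ","))) != 1)
    stopf("summaries have mismatched bin offsets")
  labels <- vapply(summaries, summary_label, character(1))
  cols <- spec$color_map %||% default_line_colors(length(summaries))
  df <- do.call(rbind, Map(function(s, lab) {
    d <- as.data.frame(s)
    d$label <- lab
    d
  }, summaries, labels))
  df$label <- factor(df$label, levels = labels)
  band <- spec$error_band
  if (band == "se") {
    df$lo <- df$mean - df$se
    df$hi <- df$mean + df$se
  } else if (band == "ci95") {
    df$lo <- df$ci_lo
    df$hi <- df$ci_hi
  }
  ylim <- c(spec$y_min, spec$y_max)
  if (is.null(spec$y_min) || is.null(spec$y_max)) {
    lo_all <- if (band == "none") df$mean else pmin(df$lo, df$mean, na.rm = TRUE)
    hi_all <- if (band == "none") df$mean else pmax(df$hi, df$mean, na.rm = TRUE)
    ylim <- c(spec$y_min %||% min(lo_all, na.rm = TRUE),
              spec$y_max %||% max(hi_all, na.rm = TRUE))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$mean,
                                        color = .data$label))
  if (band != "none")
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi, fill = .data$label),
      alpha = 0.25, color = NA)
  p <- p +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        color = "grey40") +
    ggplot2::geom_line(linewidth = 0.7, na.rm = TRUE) +
    ggplot2::scale_color_manual(values = cols, name = NULL) +
    ggplot2::scale_fill_manual(values = cols, guide = "none") +
    ggplot2::coord_cartesian(ylim = ylim) +
    ggplot2::labs(title = spec$title, x = spec$x_label, y = spec$y_label) +
    ggplot2::theme_classic()
  ggplot2::ggsave(pdf_path, p, width = spec$width, height = spec$height,
                  device = grDevices::pdf, useDingbats = FALSE)
  write_manifest(pdf_path, list(
    kind = "profile", labels = as.list(labels),
    colors = as.list(cols[seq_along(labels)]),
    error_band = band,
    x_range = range(df$offset), y_range = ylim,
    n_pages = 1))
  invisible(pdf_path)
}

#' Plot clustered heatmaps
#'
#' One panel per matrix, all sharing the row order of the
#' `ClusterResult`; horizontal separators mark cluster boundaries and
#' cluster ids are labelled. Each panel's color scale is clipped at the
#' `heatmap_clip` quantiles of its own non-missing values; missing cells
#' render in a distinct neutral color.
#'
#' @param matrices a `ProfileMatrix` or list of them, row-aligned
#' @param result a `ClusterResult` (or `NULL` for file order)
#' @param spec a [plot_spec()] of kind `"heatmap"`
#' @param pdf_path output PDF; a JSON manifest is written alongside
#' @return `pdf_path`, invisibly
#' @export
plot_heatmap <- function(matrices, result = NULL,
                         spec = plot_spec("heatmap"), pdf_path) {
  if (inherits(matrices, "ProfileMatrix")) matrices <- list(matrices)
  n <- nrow(matrices[[1]]$values)
  for (m in matrices) if (nrow(m$values) != n)
    stopf("heatmap matrices are not row-aligned")
  if (is.null(result)) result <- sort_rows(
    assemble_cluster_input(matrices), sort_within = FALSE)
  if (length(result$labels) != n)
    stopf("cluster result has %d rows but matrices have %d",
          length(result$labels), n)
  ord <- result$order
  grad <- spec$color_map %||% c("#FFFFFF", "#08306B")
  limits <- list()
  panels <- lapply(matrices, function(m) {
    v <- m$values[ord, , drop = FALSE]
    qs <- stats::quantile(v, probs = spec$heatmap_clip, na.rm = TRUE,
                          names = FALSE)
    if (qs[1] == qs[2]) qs[2] <- qs[1] + 1e-9
    limits[[length(limits) + 1]] <<- qs
    df <- expand.grid(rank = seq_len(n), bin = seq_along(m$bin_centers))
    df$offset <- m$bin_centers[df$bin]
    df$value <- pmin(pmax(as.vector(v), qs[1]), qs[2])
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$rank,
                                          fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradientn(colors = grad, limits = qs,
                                    na.value = "grey80", name = NULL) +
      ggplot2::scale_y_reverse(expand = c(0, 0)) +
      ggplot2::scale_x_continuous(expand = c(0, 0)) +
      ggplot2::labs(title = m$signal_label, x = spec$x_label, y = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                     panel.grid = ggplot2::element_blank())
    if (length(result$boundaries) > 0)
      p <- p + ggplot2::geom_hline(yintercept = result$boundaries + 0.5,
                                   color = "black", linewidth = 0.4)
    p
  })
  # cluster id labels on the left margin of the first panel
  labs_df <- data.frame(
    cluster = unique(result$labels[ord]),
    at = vapply(unique(result$labels[ord]), function(cl)
      mean(which(result$labels[ord] == cl)), numeric(1)))
  panels[[1]] <- panels[[1]] +
    ggplot2::annotate("text", x = min(matrices[[1]]$bin_centers),
                      y = labs_df$at, label = paste0("C", labs_df$cluster),
                      hjust = 0, size = 3)
  combined <- patchwork::wrap_plots(panels, nrow = 1)
  if (!is.null(spec$title))
    combined <- combined + patchwork::plot_annotation(title = spec$title)
  ggplot2::ggsave(pdf_path, combined, width = spec$width,
                  height = spec$height, device = grDevices::pdf,
                  useDingbats = FALSE)
  write_manifest(pdf_path, list(
    kind = "heatmap",
    panels = lapply(matrices, `[[`, "signal_label"),
    row_ids = as.list(matrices[[1]]$feature_ids[ord]),
    cluster_labels = result$labels[ord],
    boundaries = result$boundaries,
    color_limits = limits,
    n_pages = 1))
  invisible(pdf_path)
}

#' Check that a file is a renderable PDF
#'
#' @param path file path
#' @return `TRUE` if the file starts with the PDF magic bytes and
#'   contains at least one page object
#' @export
is_pdf <- function(path) {
  if (!file.exists(path)) return(FALSE)
  head <- readBin(path, "raw", n = 5)
  if (!identical(rawToChar(head), "%PDF-")) return(FALSE)
  pdf_page_count(path) >= 1
}

#' Number of pages in a PDF file
#' @param path PDF path
#' @return integer page count
#' @export
pdf_page_count <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  raw[raw > 0x7f | raw == 0x00] <- as.raw(0x20)
  txt <- rawToChar(raw)
  hits <- gregexpr("/Type\\s*/Page[^s]", txt)[[1]]
  if (identical(hits[1], -1L)) 0L else length(hits)
}
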