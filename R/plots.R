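# ---- pure data-extraction layer (unit-testable without any device) ----

#' Data behind a dot plot: top sets per direction
#'
#' Selects the \code{top_n} lowest-p upregulated and \code{top_n} lowest-p
#' downregulated records and computes the plotting channels: the signed
#' significance score \code{-log10(pvalue)} (positive for UP, negative for
#' DOWN), the dot-size channel \code{pct_sig_genes}, and a flag for
#' orthology-derived sets so pathways discovered only through human
#' annotation can be highlighted.
#'
#' @param res an \code{enrichment_result} containing UP and/or DOWN rows.
#' @param top_n sets to keep per direction (default 10).
#' @return data.frame with columns \code{set_id}, \code{set_name},
#'   \code{direction}, \code{score}, \code{pct_sig_genes},
#'   \code{via_orthology}, ordered by score.
#' @export
dot_plot_data <- function(res, top_n = 10L) {
  stopifnot(inherits(res, "enrichment_result"), top_n >= 1L)
  df <- as.data.frame(res)
  pick <- function(dir) {
    sub <- df[df$direction == dir, , drop = FALSE]
    if (!nrow(sub)) {
      message("no ", dir, " records; panel omitted")
      return(sub)
    }
    sub <- sub[order(sub$pvalue, sub$set_id, method = "radix"), ,
               drop = FALSE]
    utils::head(sub, top_n)
  }
  sel <- rbind(pick("UP"), pick("DOWN"))
  if (!nrow(sel)) stop("no directional (UP/DOWN) records to plot",
                       call. = FALSE)
  out <- data.frame(
    set_id = sel$set_id, set_name = sel$set_name,
    direction = sel$direction,
    score = -log10(sel$pvalue) * ifelse(sel$direction == "UP", 1, -1),
    pct_sig_genes = sel$pct_sig_genes,
    via_orthology = sel$annotation_organism == "HUMAN_VIA_ORTHOLOGY",
    stringsAsFactors = FALSE)
  out[order(out$score), , drop = FALSE]
}

#' Data behind a bar chart: record counts per group
#'
#' @param res an \code{enrichment_result}.
#' @param group_by \code{"direction"} or \code{"source_db"}.
#' @return data.frame with columns \code{group}, \code{count}; counts sum
#'   to \code{nrow(res)}, and levels observed nowhere get a zero row.
#' @export
bar_chart_data <- function(res, group_by = c("direction", "source_db")) {
  stopifnot(inherits(res, "enrichment_result"))
  if (!nrow(res)) stop("empty enrichment table", call. = FALSE)
  group_by <- match.arg(group_by)
  v <- as.character(as.data.frame(res)[[group_by]])
  levels <- unique(v)
  # zero-height bars are retained: a directional analysis always shows
  # both panels even when one direction produced no record
  if (group_by == "direction" && attr(res, "direction") == "BOTH")
    levels <- union(levels, c("UP", "DOWN"))
  tab <- table(factor(v, levels = sort(levels)))
  data.frame(group = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Data behind a volcano plot
#'
#' x is the effect on a log scale — \code{log(odds ratio)} for Fisher
#' results, the slope \code{beta} for logistic results — and y is
#' \code{-log10(pvalue)}.
#'
#' @param res an \code{enrichment_result}.
#' @return data.frame with columns \code{set_id}, \code{x}, \code{y},
#'   \code{direction}.
#' @export
volcano_data <- function(res) {
  stopifnot(inherits(res, "enrichment_result"))
  if (!nrow(res)) stop("empty enrichment table", call. = FALSE)
  df <- as.data.frame(res)
  x <- ifelse(df$method == "FISHER", log(df$effect), df$effect)
  data.frame(set_id = df$set_id, x = x, y = -log10(df$pvalue),
             direction = df$direction, stringsAsFactors = FALSE)
}

# ---- rendering ----

open_device <- function(path, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdf = grDevices::pdf(path, width = width, height = height),
         svg = grDevices::svg(path, width = width, height = height),
         png = grDevices::png(path, width = width * 100,
                              height = height * 100, res = 100),
         stop("unsupported figure format '", ext,
              "'; use pdf, svg or png", call. = FALSE))
}

# diverging palette anchored at score 0, so up/down are visually symmetric
score_colors <- function(score) {
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  m <- max(abs(score), 1e-9)
  pal[round(50 + 50 * score / m) + 1L]
}

#' Dot plot of the top up- and downregulated sets
#'
#' One dot per selected set: position encodes the signed significance
#' score, size the percentage of significant genes in the set, color a
#' diverging scale anchored at zero. Orthology-derived sets are drawn with
#' a ring and an asterisk after the name, highlighting pathways only
#' testable through human annotation.
#'
#' @param res an \code{enrichment_result} with UP/DOWN rows (run
#'   \code{direction = "both"}).
#' @param top_n sets per direction.
#' @param file output path (\code{.pdf}, \code{.svg} or \code{.png});
#'   \code{NULL} draws on the current device.
#' @return The plotted data (from \code{\link{dot_plot_data}}),
#'   invisibly.
#' @export
dot_plot <- function(res, top_n = 10L, file = NULL) {
  dat <- dot_plot_data(res, top_n)
  if (!is.null(file)) {
    open_device(file, width = 7, height = max(3, 0.35 * nrow(dat) + 1.5))
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mar = c(4.5, 14, 2.5, 5), xpd = NA)
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  yy <- seq_len(nrow(dat))
  cex <- 0.8 + 2.2 * dat$pct_sig_genes / max(dat$pct_sig_genes, 1)
  lab <- paste0(dat$set_name, ifelse(dat$via_orthology, " *", ""))
  graphics::plot(dat$score, yy, axes = FALSE, xlab = "signed -log10 p",
                 ylab = "", pch = 21, cex = cex,
                 bg = score_colors(dat$score),
                 col = ifelse(dat$via_orthology, "black", "grey40"),
                 lwd = ifelse(dat$via_orthology, 2, 1),
                 xlim = range(dat$score) + c(-0.5, 0.5),
                 main = "Top enriched gene sets")
  graphics::axis(1)
  graphics::axis(2, at = yy, labels = lab, las = 2, cex.axis = 0.7,
                 tick = FALSE)
  graphics::abline(v = 0, lty = 3, col = "grey60", xpd = FALSE)
  graphics::mtext("* via human orthology; dot size = % significant genes",
                  side = 1, line = 3.3, cex = 0.7)
  invisible(dat)
}

#' Bar chart of enrichment-record counts per category
#'
#' @inheritParams bar_chart_data
#' @param file output path or \code{NULL} for the current device.
#' @return The plotted data, invisibly.
#' @export
bar_chart <- function(res, group_by = "direction", file = NULL) {
  dat <- bar_chart_data(res, group_by)
  if (!is.null(file)) {
    open_device(file)
    on.exit(grDevices::dev.off())
  }
  graphics::barplot(stats::setNames(dat$count, dat$group),
                    ylab = "gene sets", col = "grey70",
                    main = paste("Gene sets by", group_by))
  invisible(dat)
}

#' Volcano plot of effect versus significance
#'
#' @param res an \code{enrichment_result}.
#' @param alpha significance threshold drawn as a horizontal line.
#' @param file output path or \code{NULL} for the current device.
#' @return The plotted data, invisibly.
#' @export
volcano_plot <- function(res, alpha = 0.05, file = NULL) {
  dat <- volcano_data(res)
  if (!is.null(file)) {
    open_device(file)
    on.exit(grDevices::dev.off())
  }
  xlab <- if (attr(res, "method") == "FISHER") "log odds ratio" else
    "logistic slope (beta)"
  graphics::plot(dat$x, dat$y, pch = 19, cex = 0.7,
                 col = ifelse(dat$y > -log10(alpha), "#B2182B", "grey60"),
                 xlab = xlab, ylab = "-log10 p", main = "Enrichment volcano")
  graphics::abline(h = -log10(alpha), lty = 2, col = "grey40")
  graphics::abline(v = 0, lty = 3, col = "grey70")
  invisible(dat)
}

#' Plot method for enrichment results
#'
#' Dispatches to \code{\link{dot_plot}}, \code{\link{bar_chart}} or
#' \code{\link{volcano_plot}}.
#'
#' @param x an \code{enrichment_result}.
#' @param type \code{"dot"}, \code{"bar"} or \code{"volcano"}.
#' @param ... passed to the chosen plotting function.
#' @return The plotted data, invisibly.
#' @export
plot.enrichment_result <- function(x, type = c("dot", "bar", "volcano"),
                                   ...) {
  switch(match.arg(type),
         dot = dot_plot(x, ...),
         bar = bar_chart(x, ...),
         volcano = volcano_plot(x, ...))
}
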