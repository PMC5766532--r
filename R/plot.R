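#' Plot benchmark metrics against missing proportion
#'
#' Writes one line chart per metric in the report (methods as series,
#' missing proportion on the x axis), mirroring the usual presentation of
#' imputation benchmarks.
#'
#' @param report An `evaluation_report` from [run_benchmark()].
#' @param out_dir Output directory (created if absent).
#' @param format `"png"` or `"svg"`.
#' @param width,height Figure size in inches.
#' @return Character vector of the files written, invisibly.
#' @export
plot_report <- function(report, out_dir, format = c("png", "svg"),
                        width = 6, height = 4) {
  if (!inherits(report, "evaluation_report") || !nrow(report)) {
    stop("report must be a non-empty evaluation_report", call. = FALSE)
  }
  format <- match.arg(format)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  for (metric in unique(report$metric)) {
    d <- report[report$metric == metric, ]
    gg <- ggplot2::ggplot(
      d, ggplot2::aes(x = .data$proportion, y = .data$value,
                      colour = .data$method)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 1.5) +
      ggplot2::labs(x = "missing proportion", y = metric,
                    colour = "method",
                    title = sprintf("%s by missing proportion", metric)) +
      ggplot2::theme_minimal()
    f <- file.path(out_dir, sprintf("benchmark_%s.%s", metric, format))
    ggplot2::ggsave(f, gg, width = width, height = height, dpi = 150)
    files <- c(files, f)
  }
  invisible(files)
}

#' @importFrom rlang .data
NULL
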