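#' Run a full fusion method comparison
#'
#' Fuses one co-registered pair with every requested method — the proposed
#' wavelet max-selection method expanded to one row per level in
#' `level_min:level_max` — evaluates the seven quality metrics for each
#' fused image against the two sources, and returns the comparison table
#' (the layout of a standard fusion benchmark table: one row per method,
#' columns Q, MI, E, SD, BSSIM, SF, AG).
#'
#' A failure in one method is reported as a warning with its method/level
#' context and does not abort the remaining methods.
#'
#' @param image_a,image_b Co-registered `image2d` inputs.
#' @param methods Character vector from `"proposed"`, `"average"`, `"pca"`,
#'   `"gp"`, `"cp"`, `"rp"`, `"sidwt-haar"`. Default: the proposed method
#'   plus the five classic baselines.
#' @param level_min,level_max Level sweep for the proposed method.
#' @param wavelet Wavelet for the proposed method (default `"db3"`).
#' @param boundary_mode Boundary handling for the proposed method.
#' @param approximation_rule Approximation-band rule, see
#'   [fuse_pyramids_max()].
#' @param baseline_levels Pyramid / undecimated-transform depth for the
#'   gp/cp/rp/sidwt baselines (clamped to the dyadic capacity).
#' @param bins,window,constants Metric settings, see [evaluate_metrics()].
#' @param output_dir Optional directory: every fused image is saved there
#'   as an 8-bit PNG with a systematic name.
#' @return A tibble with columns `method`, `level`, `Q`, `MI`, `E`, `SD`,
#'   `BSSIM`, `SF`, `AG`.
#' @export
run_comparison <- function(image_a, image_b,
                           methods = c("proposed", "gp", "cp", "rp", "pca", "sidwt-haar"),
                           level_min = 2L, level_max = NULL,
                           wavelet = "db3", boundary_mode = "periodic",
                           approximation_rule = "max",
                           baseline_levels = 4L,
                           bins = 256L, window = 8L, constants = q_constants(),
                           output_dir = NULL) {
  hb <- harmonize_ranges(image_a, image_b)
  a <- hb$a; b <- hb$b
  problems <- character(0)
  if (!identical(dim(a), dim(b)))
    problems <- c(problems, "input images must share dimensions")
  lmax <- max_decomposition_level(nrow(a), ncol(a))
  if (is.null(level_max)) level_max <- lmax
  known <- c("proposed", "average", "pca", "gp", "cp", "rp", "sidwt-haar")
  bad <- setdiff(methods, known)
  if (length(bad))
    problems <- c(problems, sprintf("unknown method(s): %s", paste(bad, collapse = ", ")))
  if ("proposed" %in% methods && (level_min < 1 || level_max > lmax || level_min > level_max))
    problems <- c(problems, sprintf("level range %d:%d outside capacity [1, %d]",
                                    level_min, level_max, lmax))
  if (bins < 2) problems <- c(problems, "bins must be >= 2")
  if (window < 1) problems <- c(problems, "window must be >= 1")
  if (length(problems))
    stop(paste(c("invalid comparison configuration:", paste(" -", problems)),
               collapse = "\n"), call. = FALSE)

  blev <- min(baseline_levels, lmax)
  tasks <- list()
  if ("proposed" %in% methods)
    for (l in seq.int(level_min, level_max))
      tasks[[length(tasks) + 1L]] <- list(
        label = sprintf("proposed level %d", l), level = l,
        fn = local({ ll <- l; function() fuse_images(a, b, ll, wavelet, boundary_mode,
                                                     approximation_rule)$fused_image }))
  baseline_fns <- list(
    "average" = function() fuse_average(a, b),
    "pca" = function() fuse_pca(a, b),
    "gp" = function() fuse_pyramid(a, b, "gradient", blev),
    "cp" = function() fuse_pyramid(a, b, "contrast", blev),
    "rp" = function() fuse_pyramid(a, b, "ratio", blev),
    "sidwt-haar" = function() fuse_sidwt_haar(a, b, blev))
  for (m in intersect(methods, names(baseline_fns)))
    tasks[[length(tasks) + 1L]] <- list(label = m, level = NA_integer_,
                                        fn = baseline_fns[[m]])

  rows <- list()
  for (t in tasks) {
    row <- tryCatch({
      f <- t$fn()
      if (!is.null(output_dir)) {
        if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
        fname <- file.path(output_dir,
                           paste0(gsub("[^a-z0-9]+", "_", t$label), ".png"))
        write_image(f, fname, bit_depth = 8L)
      }
      evaluate_metrics(a, b, f, bins = bins, window = window,
                       constants = constants,
                       method_label = t$label, level = t$level)
    }, error = function(e) {
      warning(sprintf("method '%s' failed: %s", t$label, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

#' Write a fusion comparison report
#'
#' Serializes a [run_comparison()] table to CSV or JSON with the canonical
#' column order (method, level, Q, MI, E, SD, BSSIM, SF, AG); output bytes
#' are deterministic for a fixed table.
#'
#' @param report Tibble from [run_comparison()] or [evaluate_metrics()].
#' @param path Destination file.
#' @param format `"csv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  cols <- c("method", "level", "Q", "MI", "E", "SD", "BSSIM", "SF", "AG")
  report <- report[, intersect(cols, names(report))]
  if (format == "csv") {
    utils::write.csv(report, path, row.names = FALSE)
  } else {
    jsonlite::write_json(report, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Plot a fusion comparison report
#'
#' One panel per metric, methods on the x axis — a quick visual of which
#' fusion method dominates on which criterion.
#'
#' @param report Tibble from [run_comparison()].
#' @return A ggplot object.
#' @export
plot_fusion_report <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_fusion_report() needs the ggplot2 package", call. = FALSE)
  metrics <- c("Q", "MI", "E", "SD", "BSSIM", "SF", "AG")
  long <- do.call(rbind, lapply(metrics, function(m)
    data.frame(method = report$method, metric = factor(m, levels = metrics),
               value = report[[m]])))
  long$method <- factor(long$method, levels = unique(report$method))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
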