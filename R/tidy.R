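#' Tidy an evaluation into one row per read
#'
#' @param x A `skelmap_eval` from [evaluate_mapping()].
#' @param ... Unused.
#' @return Per-read tibble (`read_id`, `mapped`, `coverage`, `cmr`,
#'   `cmb`, truth and alignment coordinates).
#' @export
tidy.skelmap_eval <- function(x, ...) {
  dplyr::select(x$per_read, "read_id", "chrom", "strand", "read_len",
                "ref_start", "ref_end", "mapped", "aln_strand",
                "aln_start", "aln_end", "coverage", "cmr", "cmb")
}

#' One-row summary of an evaluation
#'
#' @inheritParams tidy.skelmap_eval
#' @return The metrics tibble: read/base counts, aligned coverage,
#'   sensitivity, precision, consecutiveness percentages.
#' @export
glance.skelmap_eval <- function(x, ...) x$metrics

#' Plot an evaluation: consecutiveness and coverage
#'
#' Bar panel of consecutive-alignment percentages at the configured
#' thresholds, next to the aligned-coverage distribution of mapped reads.
#'
#' @inheritParams tidy.skelmap_eval
#' @param object A `skelmap_eval`.
#' @return A ggplot object.
#' @export
autoplot.skelmap_eval <- function(object, ...) {
  m <- object$metrics
  cons <- dplyr::select(m, dplyr::starts_with("consec_"))
  df <- tibble(
    threshold = sub("^consec_c([0-9.]+)_pct$", "\\1%", names(cons)),
    pct = as.numeric(cons[1, ]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = "coverage threshold",
                  y = "consecutive alignments (%)",
                  title = sprintf(
                    "%d/%d mapped; sensitivity %.2f%%, precision %.2f%%",
                    m$n_mapped, m$n_reads, m$sensitivity_pct,
                    m$precision_pct)) +
    ggplot2::theme_minimal()
}

#' Anchor/skeleton diagnostics for one read
#'
#' Runs the seeding and chaining stages only and returns the anchors with
#' their chain scores, flagged by membership in the initial and refined
#' skeleton — the input for a classic mapping dot-plot.
#'
#' @param read One-row tibble (`id`, `seq`).
#' @param index A `kmer_index`.
#' @param cfg A [map_config()].
#' @return Tibble of class `skelmap_chain` (anchors + `score`,
#'   `in_skeleton`, `in_refined`).
#' @export
chain_diagnostics <- function(read, index, cfg = map_config()) {
  anchors <- extract_anchors(index, read)
  d <- compute_d(nchar(read$seq[[1]]), cfg$lam)
  dp <- chain_scores(anchors, d, cfg$alpha)
  skel <- backtrack_skeleton(dp)
  wl <- if (is.null(cfg$window)) nchar(read$seq[[1]]) else cfg$window
  ref <- refine_skeleton(skel, wl)
  key <- function(tb) paste(tb$chrom, tb$ref_pos, tb$read_pos)
  out <- dplyr::mutate(dp, in_skeleton = key(dp) %in% key(skel),
                       in_refined = key(dp) %in% key(ref))
  class(out) <- c("skelmap_chain", class(out))
  out
}

#' Dot-plot of anchors and the chained skeleton
#'
#' @param object A `skelmap_chain` from [chain_diagnostics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.skelmap_chain <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$ref_pos, y = .data$read_pos)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_refined),
                        size = 0.8) +
    ggplot2::geom_path(
      data = object[object$in_refined, , drop = FALSE],
      colour = "firebrick", linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
      name = "refined skeleton") +
    ggplot2::labs(x = "reference position", y = "read position") +
    ggplot2::theme_minimal()
}
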