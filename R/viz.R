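#' Radar-plot data for one screened reference
#'
#' Six axes in fixed order (pearson, spearman, cosine, wtcs, css, xsum),
#' each carrying the reference's directional percentile rank (0-100) for
#' that method within the screen. References not gated into WTCS show a 0
#' axis with `gated = FALSE`, so the heterogeneous score scales remain
#' comparable.
#'
#' @param report a `screen_report`.
#' @param sig_id reference to display.
#' @return a `plot_data` object (`kind = "radar"`); `$tables$axes` is a
#'   data.frame of method / percentile / vote / gated.
#' @export
radar_data <- function(report, sig_id) {
  .assert(inherits(report, "screen_report"), "not a screen_report")
  row <- report$results[report$results$sig_id == sig_id, , drop = FALSE]
  .assert(nrow(row) == 1L, "unknown sig_id in report: ", sig_id)
  axes <- data.frame(
    method = ALL_METHODS,
    percentile = as.numeric(row[, paste0("pct_", ALL_METHODS)]),
    vote = as.integer(row[, paste0("vote_", ALL_METHODS)]),
    gated = c(TRUE, TRUE, TRUE, row$gated_wtcs, TRUE, TRUE),
    stringsAsFactors = FALSE)
  structure(list(kind = "radar", sig_id = sig_id,
                 meta_score = row$meta_score,
                 tables = list(axes = axes)),
            class = "plot_data")
}

#' GSEA running-sum data for a query's extreme sets against one reference
#'
#' Per-position running-sum values and hit positions for the up and the down
#' extreme set, walking the reference ranking (z descending). The reported
#' enrichment scores equal the signed maximum-magnitude deviations of the
#' emitted running sums and agree with [enrichment_score()].
#'
#' @param extremes a [select_extreme_genes()] result.
#' @param ref reference [signature_record()].
#' @param weight_exponent hit-weight exponent (default 1).
#' @return a `plot_data` (`kind = "gsea"`); `$tables$running` has columns
#'   position, running_up, running_down; `$tables$hits` the hit positions;
#'   `$es` the two enrichment scores.
#' @export
gsea_data <- function(extremes, ref, weight_exponent = 1) {
  .assert(is_extreme_set(extremes), "extremes must be an extreme_gene_set")
  .assert(is_signature(ref), "ref must be a signature_record")
  ord <- order(-ref$z, ref$gene_ids, method = "radix")
  ranked_genes <- ref$gene_ids[ord]
  w <- abs(ref$z[ord])^weight_exponent
  n <- length(ranked_genes)
  one_set <- function(set) {
    hit <- ranked_genes %in% set
    denom <- sum(w[hit])
    .assert(denom > 0, "all set genes have zero reference weight")
    running <- cumsum(ifelse(hit, w / denom, -1 / (n - length(set))))
    list(running = running, hit = which(hit),
         es = running[which.max(abs(running))])
  }
  up <- one_set(extremes$up)
  dn <- one_set(extremes$down)
  structure(
    list(kind = "gsea",
         tables = list(
           running = data.frame(position = seq_len(n),
                                running_up = up$running,
                                running_down = dn$running),
           hits = data.frame(
             set = rep(c("up", "down"), c(length(up$hit), length(dn$hit))),
             position = c(up$hit, dn$hit))),
         es = c(up = up$es, down = dn$es)),
    class = "plot_data")
}

#' Venn data over method vote sets
#'
#' Membership sets are the references receiving each selected method's vote;
#' all `2^m - 1` region counts are emitted (inclusion-exclusion complete).
#'
#' @param report a `screen_report`.
#' @param methods 2-6 of the six method names.
#' @return a `plot_data` (`kind = "venn"`); `$tables$regions` lists each
#'   region (methods joined by `&`) with its exclusive count; `$sets` the
#'   per-method membership vectors.
#' @export
venn_data <- function(report, methods = c("css", "xsum", "wtcs")) {
  .assert(inherits(report, "screen_report"), "not a screen_report")
  methods <- match.arg(methods, ALL_METHODS, several.ok = TRUE)
  m <- length(methods)
  .assert(m >= 2L && m <= 6L, "select between 2 and 6 methods")
  res <- report$results
  sets <- lapply(methods, function(x) res$sig_id[res[[paste0("vote_", x)]] == 1L])
  names(sets) <- methods
  membership <- vapply(methods, function(x)
    res[[paste0("vote_", x)]] == 1L, logical(nrow(res)))
  pattern <- apply(membership, 1L, function(b) paste(as.integer(b), collapse = ""))
  all_patterns <- apply(
    as.matrix(expand.grid(rep(list(0:1), m)))[, seq_len(m), drop = FALSE],
    1L, paste, collapse = "")
  all_patterns <- setdiff(all_patterns, strrep("0", m))
  counts <- vapply(all_patterns, function(p) sum(pattern == p), integer(1))
  label <- vapply(all_patterns, function(p) {
    paste(methods[strsplit(p, "")[[1L]] == "1"], collapse = "&")
  }, character(1))
  structure(
    list(kind = "venn",
         tables = list(regions = data.frame(region = label, pattern = all_patterns,
                                            count = as.integer(counts),
                                            stringsAsFactors = FALSE)),
         sets = sets),
    class = "plot_data")
}

#' @export
print.plot_data <- function(x, ...) {
  cat("<plot data> kind=", x$kind, "\n", sep = "")
  invisible(x)
}

#' Render plot data to an image file
#'
#' Base-graphics renderings of the three plot kinds; the tables in the
#' `plot_data` object remain the contract — images are side effects.
#'
#' @param pd a `plot_data` from [radar_data()], [gsea_data()] or
#'   [venn_data()].
#' @param file output path; device chosen from the extension
#'   (`.png` or `.svg`). `NULL` draws on the current device.
#' @param ... ignored.
#' @return `file`, invisibly.
#' @export
plot_connectivity <- function(pd, file = NULL, ...) {
  .assert(inherits(pd, "plot_data"), "pd must be a plot_data")
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = 800, height = 800),
           svg = grDevices::svg(file, width = 8, height = 8),
           stop("unsupported image extension: ", ext, call. = FALSE))
    on.exit(grDevices::dev.off())
  }
  switch(pd$kind,
         radar = .draw_radar(pd),
         gsea = .draw_gsea(pd),
         venn = .draw_venn(pd))
  invisible(file)
}

.draw_radar <- function(pd) {
  axes <- pd$tables$axes
  m <- nrow(axes)
  theta <- pi / 2 - 2 * pi * (seq_len(m) - 1L) / m
  graphics::plot.new()
  graphics::plot.window(c(-1.3, 1.3), c(-1.3, 1.3), asp = 1)
  for (r in c(0.25, 0.5, 0.75, 1))
    graphics::polygon(r * cos(theta), r * sin(theta), border = "grey80")
  graphics::segments(0, 0, cos(theta), sin(theta), col = "grey80")
  v <- axes$percentile / 100
  graphics::polygon(v * cos(theta), v * sin(theta),
                    col = grDevices::adjustcolor("steelblue", 0.4),
                    border = "steelblue", lwd = 2)
  lab <- ifelse(axes$gated, axes$method, paste0(axes$method, " (ungated)"))
  graphics::text(1.18 * cos(theta), 1.18 * sin(theta), lab, cex = 0.9)
  graphics::title(main = sprintf("%s  (meta-score %d)", pd$sig_id,
                                 pd$meta_score))
}

.draw_gsea <- function(pd) {
  run <- pd$tables$running
  hits <- pd$tables$hits
  ylim <- range(run$running_up, run$running_down, 0)
  graphics::plot(run$position, run$running_up, type = "l", col = "firebrick",
                 lwd = 2, xlab = "rank in reference signature",
                 ylab = "running enrichment", ylim = ylim)
  graphics::lines(run$position, run$running_down, col = "navy", lwd = 2)
  graphics::abline(h = 0, col = "grey60")
  graphics::rug(hits$position[hits$set == "up"], col = "firebrick")
  graphics::rug(hits$position[hits$set == "down"], col = "navy",
                side = 3)
  graphics::legend("topright",
                   legend = sprintf("%s set (ES %.3f)", c("up", "down"),
                                    pd$es), col = c("firebrick", "navy"),
                   lwd = 2, bty = "n")
}

.draw_venn <- function(pd) {
  regions <- pd$tables$regions
  sets <- pd$sets
  m <- length(sets)
  if (m <= 3L) {
    centers <- switch(m,
                      NULL,
                      list(c(-0.35, 0), c(0.35, 0)),
                      list(c(-0.35, -0.2), c(0.35, -0.2), c(0, 0.4)))
    graphics::plot.new()
    graphics::plot.window(c(-1.2, 1.2), c(-1.2, 1.2), asp = 1)
    cols <- c("firebrick", "navy", "darkgreen")
    ang <- seq(0, 2 * pi, length.out = 200)
    for (i in seq_len(m)) {
      graphics::polygon(centers[[i]][1] + 0.6 * cos(ang),
                        centers[[i]][2] + 0.6 * sin(ang),
                        border = cols[i],
                        col = grDevices::adjustcolor(cols[i], 0.15))
      graphics::text(centers[[i]][1] * 1.9, centers[[i]][2] * 1.9,
                     sprintf("%s (%d)", names(sets)[i], length(sets[[i]])),
                     col = cols[i])
    }
    graphics::title(main = "method vote overlap")
  } else {
    graphics::barplot(regions$count, names.arg = regions$region, las = 2,
                      cex.names = 0.6, ylab = "references",
                      main = "method vote overlap (region counts)")
  }
}
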