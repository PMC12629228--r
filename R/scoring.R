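#' Full-vector similarity scores
#'
#' The three whole-gene-list connectivity methods: product-moment (Pearson)
#' correlation, Spearman rank correlation (average ranks on ties) and cosine
#' similarity, evaluated over gene-matched query/reference z vectors.
#'
#' @param q_z,r_z numeric vectors matched gene-for-gene.
#' @return a single value in `[-1, 1]`.
#' @export
pearson_score <- function(q_z, r_z) {
  .check_vec_pair(q_z, r_z, min_len = 3L)
  .assert(sd(q_z) > 0 && sd(r_z) > 0,
          "zero-variance vector: degenerate signature for correlation")
  cor(q_z, r_z, method = "pearson")
}

#' @rdname pearson_score
#' @export
spearman_score <- function(q_z, r_z) {
  .check_vec_pair(q_z, r_z, min_len = 3L)
  qr <- rank(q_z, ties.method = "average")
  rr <- rank(r_z, ties.method = "average")
  .assert(sd(qr) > 0 && sd(rr) > 0,
          "zero-variance ranks: degenerate signature for correlation")
  cor(qr, rr, method = "pearson")
}

#' @rdname pearson_score
#' @export
cosine_score <- function(q_z, r_z) {
  .check_vec_pair(q_z, r_z, min_len = 2L)
  nq <- sqrt(sum(q_z^2)); nr <- sqrt(sum(r_z^2))
  .assert(nq > 0 && nr > 0, "zero-norm vector in cosine similarity")
  sum(q_z * r_z) / (nq * nr)
}

.check_vec_pair <- function(q_z, r_z, min_len) {
  .assert(is.numeric(q_z) && is.numeric(r_z), "inputs must be numeric")
  .assert(length(q_z) == length(r_z), "vectors must be gene-matched (equal length)")
  .assert(length(q_z) >= min_len, "need at least ", min_len, " shared genes")
  .assert(all(is.finite(q_z)) && all(is.finite(r_z)), "non-finite values")
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' GSEA-style running-sum statistic of a gene set against a reference
#' signature ranked by z descending. Walking the ranking, a hit at gene g
#' adds `|z_ref(g)|^w / sum_set(|z_ref|^w)` and a miss adds `-1/(N - m)`
#' where m is the set size. The score is the maximum-magnitude deviation of
#' the running sum, signed; at an exact magnitude tie the deviation occurring
#' earliest in the ranking is taken (deterministic). Reference rank ties in z
#' are broken lexicographically by gene id.
#'
#' @param gene_set character vector of genes, all present in `ref`,
#'   `1 <= length(gene_set) < N`.
#' @param ref a [signature_record()].
#' @param weight_exponent exponent w on `|z_ref|` hit weights (default 1).
#' @return enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(gene_set, ref, weight_exponent = 1) {
  .assert(is_signature(ref), "ref must be a signature_record")
  gene_set <- as.character(gene_set)
  .assert(!anyDuplicated(gene_set), "duplicate genes in gene_set")
  missing <- setdiff(gene_set, ref$gene_ids)
  .assert(length(missing) == 0L,
          "gene_set members absent from reference: ",
          paste(head(missing, 5), collapse = ", "))
  n <- length(ref$gene_ids); m <- length(gene_set)
  .assert(m >= 1L && m < n,
          "gene_set size must satisfy 1 <= |set| < N (set equal to the whole ",
          "gene list is disallowed)")
  ord <- order(-ref$z, ref$gene_ids, method = "radix")
  hit <- ref$gene_ids[ord] %in% gene_set
  w <- abs(ref$z[ord])^weight_exponent
  denom <- sum(w[hit])
  .assert(denom > 0, "all gene_set members have zero reference weight")
  incr <- ifelse(hit, w / denom, -1 / (n - m))
  running <- cumsum(incr)
  running[which.max(abs(running))]
}

#' Weighted connectivity score (WTCS)
#'
#' Two enrichment scores — the query's up set and down set against the
#' reference ranking — combined as `(ES_up - ES_down) / 2` when the two have
#' strictly opposite signs, and 0 otherwise (components that agree in sign
#' indicate no coherent connection).
#'
#' @param extremes an [select_extreme_genes()] result.
#' @param ref reference [signature_record()]; must contain all extreme genes.
#' @param weight_exponent passed to [enrichment_score()].
#' @return a `method_score` list with fields `method`, `value`, `es_up`,
#'   `es_down`, `support`.
#' @export
wtcs <- function(extremes, ref, weight_exponent = 1) {
  .assert(is_extreme_set(extremes), "extremes must be an extreme_gene_set")
  es_up <- enrichment_score(extremes$up, ref, weight_exponent)
  es_down <- enrichment_score(extremes$down, ref, weight_exponent)
  value <- if (es_up * es_down < 0) (es_up - es_down) / 2 else 0
  method_score("wtcs", value, es_up = es_up, es_down = es_down,
               support = 2L * extremes$K)
}

#' Signed-rank connection strength score (CSS)
#'
#' Reference genes receive signed ranks `R_ref(g) = rank(|z_ref|, ascending
#' over all N universe genes) * sign(z_ref(g))`; the 2K query extreme genes
#' receive signed ranks `R_q(g) = rank(|z_q|, ascending over the 2K) *
#' sign(z_q(g))`. The raw strength is `c = sum_g R_ref(g) R_q(g)` over the 2K
#' genes, normalized by `c_max`, which pairs the 2K largest `|R_ref|` of the
#' universe with the 2K query rank magnitudes, largest with largest. Ties in
#' `|z|` receive average signed ranks.
#'
#' @inheritParams wtcs
#' @return a `method_score` with value in `[-1, 1]`.
#' @export
css <- function(extremes, ref) {
  .assert(is_extreme_set(extremes), "extremes must be an extreme_gene_set")
  genes <- c(extremes$up, extremes$down)
  missing <- setdiff(genes, ref$gene_ids)
  .assert(length(missing) == 0L, "extreme genes absent from reference: ",
          paste(head(missing, 5), collapse = ", "))
  r_ref <- css_reference_ranks(ref$z)
  qz <- c(extremes$up_z, extremes$down_z)
  r_q <- rank(abs(qz), ties.method = "average") * sign(qz)
  c_raw <- sum(r_ref[match(genes, ref$gene_ids)] * r_q)
  c_max <- css_cmax(r_ref, sort(abs(r_q), decreasing = TRUE))
  method_score("css", c_raw / c_max, support = length(genes))
}

# Signed |z| ranks over the whole universe (average ranks on |z| ties).
css_reference_ranks <- function(ref_z) {
  rank(abs(ref_z), ties.method = "average") * sign(ref_z)
}

# Maximal attainable raw strength: sorted pairing of the 2K largest |R_ref|
# with the query rank magnitudes (rearrangement bound).
css_cmax <- function(r_ref, q_mags_desc) {
  top <- sort(abs(r_ref), decreasing = TRUE)[seq_along(q_mags_desc)]
  sum(top * q_mags_desc)
}

#' eXtreme Sum score (XSum)
#'
#' Reference z-scores are truncated to the reference's own extremes: the
#' top `ref_extreme_n` and bottom `ref_extreme_n` genes by z keep their z,
#' all other genes are zeroed. The score is the truncated-z sum over the
#' query's up genes minus the sum over its down genes; positive values
#' indicate mimicry, negative values reversal. Unbounded.
#'
#' @inheritParams wtcs
#' @param ref_extreme_n reference-side extreme count (default: the query K).
#' @return a `method_score` (unbounded real value).
#' @export
xsum <- function(extremes, ref, ref_extreme_n = extremes$K) {
  .assert(is_extreme_set(extremes), "extremes must be an extreme_gene_set")
  genes <- c(extremes$up, extremes$down)
  missing <- setdiff(genes, ref$gene_ids)
  .assert(length(missing) == 0L, "extreme genes absent from reference: ",
          paste(head(missing, 5), collapse = ", "))
  zs <- xsum_truncated_z(ref$z, ref$gene_ids, ref_extreme_n)
  method_score("xsum",
               sum(zs[match(extremes$up, ref$gene_ids)]) -
                 sum(zs[match(extremes$down, ref$gene_ids)]),
               support = length(genes))
}

# z with everything outside the reference's own top/bottom m genes zeroed.
xsum_truncated_z <- function(ref_z, ref_genes, m) {
  n <- length(ref_z)
  .assert(m >= 1L && 2L * m <= n,
          "ref_extreme_n must satisfy 2 * ref_extreme_n <= universe size")
  ord <- order(-ref_z, ref_genes, method = "radix")
  keep <- c(ord[seq_len(m)], ord[seq.int(n - m + 1L, n)])
  zs <- numeric(n)
  zs[keep] <- ref_z[keep]
  zs
}

method_score <- function(method, value, es_up = NA_real_, es_down = NA_real_,
                         support = NA_integer_) {
  structure(list(method = method, value = value, es_up = es_up,
                 es_down = es_down, support = support),
            class = "method_score")
}

#' @export
print.method_score <- function(x, ...) {
  cat("<", x$method, "> ", sprintf("%.4f", x$value), sep = "")
  if (!is.na(x$es_up))
    cat(sprintf("  (ES_up %.4f, ES_down %.4f)", x$es_up, x$es_down))
  cat("\n")
  invisible(x)
}

ALL_METHODS <- c("pearson", "spearman", "cosine", "wtcs", "css", "xsum")

#' Score one query-reference pair with any subset of the six methods
#'
#' Full-vector methods use all genes shared by `query` and `ref`; extreme
#' methods use [select_extreme_genes()] of the (aligned) query.
#'
#' @param query query [signature_record()], aligned to the reference universe
#'   (see [align_query()]).
#' @param ref reference [signature_record()].
#' @param config a [screen_config()]; supplies K and `ref_extreme_n`.
#' @param methods subset of
#'   `c("pearson","spearman","cosine","wtcs","css","xsum")`.
#' @return a data.frame, one row per method: `method`, `value`, `es_up`,
#'   `es_down`, `support`.
#' @export
score_pair <- function(query, ref, config = screen_config(),
                       methods = ALL_METHODS) {
  methods <- match.arg(methods, ALL_METHODS, several.ok = TRUE)
  shared <- intersect(query$gene_ids, ref$gene_ids)
  .assert(length(shared) >= 3L, "query and reference share < 3 genes")
  qz <- query$z[match(shared, query$gene_ids)]
  rz <- ref$z[match(shared, ref$gene_ids)]
  extremes <- NULL
  if (any(methods %in% c("wtcs", "css", "xsum"))) {
    aligned <- signature_record(query$sig_id, shared, qz)
    extremes <- select_extreme_genes(aligned, config$K)
  }
  rows <- lapply(methods, function(m) {
    s <- tryCatch(switch(m,
      pearson  = method_score("pearson", pearson_score(qz, rz),
                              support = length(shared)),
      spearman = method_score("spearman", spearman_score(qz, rz),
                              support = length(shared)),
      cosine   = method_score("cosine", cosine_score(qz, rz),
                              support = length(shared)),
      wtcs     = wtcs(extremes, ref),
      css      = css(extremes, ref),
      xsum     = xsum(extremes, ref, config$ref_extreme_n)
    ), error = function(e) stop("method '", m, "': ", conditionMessage(e),
                                call. = FALSE))
    data.frame(method = s$method, value = s$value, es_up = s$es_up,
               es_down = s$es_down, support = s$support,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
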