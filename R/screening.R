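#' Assign top-quantile votes for one method across a screen
#'
#' A reference receives a method's vote (1) iff its directional effective
#' score ranks within the top `ceiling(vote_quantile * S)` of all S screened
#' references for that method. For negative (reversal) screens the effective
#' score is the negated score. When one-sided empirical p-values are
#' available (CSS/XSum), smaller p ranks first, with the directional score
#' breaking p ties; remaining ties break by sig_id (stable).
#'
#' @param scores numeric vector of raw method scores, one per reference.
#' @param sig_ids parallel character vector of reference ids.
#' @param direction `"positive"` or `"negative"`.
#' @param vote_quantile vote fraction (default 0.05).
#' @param p optional parallel vector of one-sided p-values in the screen
#'   direction.
#' @param eligible optional logical vector; ineligible references (e.g.
#'   references not gated into WTCS) never receive a vote.
#' @return integer 0/1 vector parallel to `scores`.
#' @export
method_votes <- function(scores, sig_ids, direction = c("negative", "positive"),
                         vote_quantile = 0.05, p = NULL, eligible = NULL) {
  direction <- match.arg(direction)
  s <- length(scores)
  .assert(s >= 1L && length(sig_ids) == s, "scores and sig_ids must be parallel")
  if (s < ceiling(1 / vote_quantile))
    warning(sprintf(paste0("only %d references screened; fewer than 1/%.3g -- ",
                           "top-quantile votes are degenerate"), s, vote_quantile),
            call. = FALSE)
  eff <- if (direction == "positive") scores else -scores
  if (!is.null(eligible)) eff[!eligible] <- -Inf
  ord <- if (is.null(p)) order(-eff, sig_ids, method = "radix")
         else order(p, -eff, sig_ids, method = "radix")
  n_top <- ceiling(vote_quantile * s)
  votes <- integer(s)
  votes[ord[seq_len(n_top)]] <- 1L
  if (!is.null(eligible)) votes[!eligible] <- 0L
  votes
}

#' Consensus meta-score
#'
#' The count of connectivity methods (out of six) that place a
#' query-reference pair within the top 5% of a screen, each method
#' contributing a binary vote. Ranges 0 (no method) to 6 (all methods).
#'
#' @param votes exactly six 0/1 values.
#' @return integer in 0..6.
#' @export
meta_score <- function(votes) {
  .assert(length(votes) == 6L, "meta_score requires exactly six votes, got ",
          length(votes))
  .assert(all(votes %in% c(0L, 1L)), "votes must be 0 or 1")
  as.integer(sum(votes))
}

#' Gate references into the WTCS computation
#'
#' WTCS is the costliest method, so it is evaluated only for references
#' already significant by at least one of the other five methods.
#'
#' @param flags logical matrix (references x five methods) of per-method
#'   significance.
#' @return logical vector: TRUE for gated-in references.
#' @export
wtcs_gate <- function(flags) {
  .assert(is.matrix(flags) && ncol(flags) == 5L,
          "flags must be a references x 5 methods matrix")
  rowSums(flags) >= 1L
}

# two-sided t-approximation p for a correlation coefficient
.cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(t), df = n - 2)
}

#' Screen a query signature against a whole repository
#'
#' The full pipeline: (1) align the query to the repository universe;
#' (2) compute Pearson, Spearman, cosine, CSS and XSum for every reference;
#' (3) convert CSS/XSum to one-sided empirical p-values against their
#' permutation backgrounds (precomputed store, or built on the fly from the
#' config seed); (4) determine per-method significance and gate WTCS to
#' references significant by at least one of the five; (5) assign top-5%
#' votes and the 0-6 meta-score; (6) order by (meta-score desc, consensus
#' directional percentile desc, sig_id asc) and assign ranks 1..S.
#'
#' With `direction = "negative"` the screen looks for reversal (candidate
#' therapeutics); with `"positive"`, for mimicry (shared mechanism of
#' action).
#'
#' @param query a [signature_record()].
#' @param repo a `sig_repository`.
#' @param config a [screen_config()].
#' @param backgrounds `NULL` (build CSS/XSum nulls on the fly), a store
#'   directory written by [background_store_write()], or a list of
#'   `perm_background` objects covering (every sig_id) x (css, xsum) at
#'   `config$K` and `config$n_perm`.
#' @return an object of class `screen_report`: `direction`, `config`,
#'   `query_id`, `results` (data.frame ordered by rank) and `summary`
#'   (screened / gated / significant counts).
#' @export
run_screen <- function(query, repo, config = screen_config(),
                       backgrounds = NULL) {
  .assert(is_repository(repo), "repo must be a sig_repository")
  ids <- repo_sig_ids(repo)
  s_count <- length(ids)
  .assert(s_count >= 1L, "empty repository")
  aligned <- align_query(query, repo, config$min_overlap_frac)
  shared <- aligned$gene_ids
  qz <- aligned$z
  zs <- repo$zmat[shared, , drop = FALSE]
  n_shared <- length(shared)
  .assert(n_shared >= 3L, "query shares < 3 genes with the repository")

  ## full-vector methods, vectorized over the repository
  pearson <- as.vector(cor(qz, zs))
  qr <- rank(qz, ties.method = "average")
  zr <- apply(zs, 2L, rank, ties.method = "average")
  spearman <- as.vector(cor(qr, zr))
  cosine <- as.vector((qz %*% zs) / (sqrt(sum(qz^2)) * sqrt(colSums(zs^2))))

  ## extreme-gene methods over the full universe
  extremes <- select_extreme_genes(aligned, config$K)
  uni <- repo$gene_universe
  idx_up <- match(extremes$up, uni)
  idx_dn <- match(extremes$down, uni)
  qz_ext <- c(extremes$up_z, extremes$down_z)
  r_q <- rank(abs(qz_ext), ties.method = "average") * sign(qz_ext)
  q_mags_desc <- sort(abs(r_q), decreasing = TRUE)
  idx_2k <- c(idx_up, idx_dn)
  css_obs <- xsum_obs <- numeric(s_count)
  for (j in seq_len(s_count)) {
    rz <- repo$zmat[, j]
    r_ref <- css_reference_ranks(rz)
    css_obs[j] <- sum(r_ref[idx_2k] * r_q) / css_cmax(r_ref, q_mags_desc)
    zst <- xsum_truncated_z(rz, uni, config$ref_extreme_n)
    xsum_obs[j] <- sum(zst[idx_up]) - sum(zst[idx_dn])
  }

  ## permutation p-values (one-sided in the screen direction)
  tail <- if (config$direction == "positive") "upper" else "lower"
  get_bg <- .background_getter(backgrounds, repo, config)
  pv <- .per_reference(ids, config$threads, function(i) {
    id <- ids[i]
    c(css = empirical_pvalue(css_obs[i], get_bg(id, "css"), tail),
      xsum = empirical_pvalue(xsum_obs[i], get_bg(id, "xsum"), tail))
  })
  p_css <- vapply(pv, `[[`, numeric(1), "css")
  p_xsum <- vapply(pv, `[[`, numeric(1), "xsum")
  p_pearson <- .cor_pvalue(pearson, n_shared)
  p_spearman <- .cor_pvalue(spearman, n_shared)

  ## votes for the five cheap methods
  vq <- config$vote_quantile
  dirn <- config$direction
  v_pearson <- method_votes(pearson, ids, dirn, vq)
  v_spearman <- method_votes(spearman, ids, dirn, vq)
  v_cosine <- method_votes(cosine, ids, dirn, vq)
  v_css <- method_votes(css_obs, ids, dirn, vq, p = p_css)
  v_xsum <- method_votes(xsum_obs, ids, dirn, vq, p = p_xsum)

  ## WTCS gate: significant by any of the five
  flags <- if (config$sig_rule == "pvalue") {
    cbind(p_pearson <= 0.05, p_spearman <= 0.05, v_cosine == 1L,
          p_css <= 0.05, p_xsum <= 0.05)
  } else {
    cbind(v_pearson, v_spearman, v_cosine, v_css, v_xsum) == 1L
  }
  gated <- wtcs_gate(flags)
  wtcs_val <- es_up <- es_down <- rep(NA_real_, s_count)
  gate_idx <- which(gated)
  wres <- .per_reference(ids[gated], config$threads, function(i) {
    ref <- repo_signature(repo, ids[gate_idx[i]])
    sc <- wtcs(extremes, ref)
    c(sc$value, sc$es_up, sc$es_down)
  })
  for (i in seq_along(gate_idx)) {
    wtcs_val[gate_idx[i]] <- wres[[i]][1]
    es_up[gate_idx[i]] <- wres[[i]][2]
    es_down[gate_idx[i]] <- wres[[i]][3]
  }
  ## the top-5% cutoff for WTCS keeps the full S as denominator; ungated
  ## references are non-candidates and always vote 0
  wtcs_for_vote <- ifelse(gated, wtcs_val, if (dirn == "positive") -Inf else Inf)
  v_wtcs <- method_votes(wtcs_for_vote, ids, dirn, vq, eligible = gated)

  votes <- cbind(pearson = v_pearson, spearman = v_spearman,
                 cosine = v_cosine, wtcs = v_wtcs, css = v_css, xsum = v_xsum)
  meta <- as.integer(rowSums(votes))

  ## directional percentile ranks (0-100; 100 = strongest in direction);
  ## ungated WTCS pinned to 0
  pct <- function(scores, p = NULL, eligible = NULL) {
    eff <- if (dirn == "positive") scores else -scores
    if (!is.null(eligible)) eff[!eligible] <- -Inf
    ord <- if (is.null(p)) order(-eff, ids, method = "radix")
           else order(p, -eff, ids, method = "radix")
    r <- integer(s_count); r[ord] <- seq_len(s_count)
    out <- if (s_count == 1L) 100 else 100 * (s_count - r) / (s_count - 1)
    if (!is.null(eligible)) out[!eligible] <- 0
    out
  }
  pcts <- cbind(pearson = pct(pearson), spearman = pct(spearman),
                cosine = pct(cosine),
                wtcs = pct(wtcs_for_vote, eligible = gated),
                css = pct(css_obs, p = p_css),
                xsum = pct(xsum_obs, p = p_xsum))
  consensus_pct <- rowMeans(pcts)

  results <- data.frame(
    sig_id = ids, stringsAsFactors = FALSE)
  for (f in c("compound", "cell_line", "dose", "time", "pert_type"))
    results[[f]] <- if (f %in% names(repo$meta)) repo$meta[[f]] else NA_character_
  results$pearson <- pearson; results$spearman <- spearman
  results$cosine <- cosine; results$wtcs <- wtcs_val
  results$es_up <- es_up; results$es_down <- es_down
  results$css <- css_obs; results$xsum <- xsum_obs
  results$p_pearson <- p_pearson; results$p_spearman <- p_spearman
  results$p_css <- p_css; results$p_xsum <- p_xsum
  for (m in colnames(votes)) results[[paste0("vote_", m)]] <- votes[, m]
  for (m in colnames(pcts)) results[[paste0("pct_", m)]] <- pcts[, m]
  results$gated_wtcs <- gated
  results$meta_score <- meta
  results$consensus_pct <- consensus_pct

  ord <- order(-meta, -consensus_pct, ids, method = "radix")
  results <- results[ord, , drop = FALSE]
  results$rank <- seq_len(s_count)
  rownames(results) <- NULL

  structure(
    list(direction = dirn, config = config, query_id = query$sig_id,
         query_retained_frac = attr(aligned, "retained_frac"),
         results = results,
         summary = list(screened = s_count, gated_for_wtcs = sum(gated),
                        significant = sum(meta >= 1L))),
    class = "screen_report"
  )
}

# resolve the backgrounds argument into a lookup closure
.background_getter <- function(backgrounds, repo, config) {
  K <- config$K; n_perm <- config$n_perm
  if (is.null(backgrounds)) {
    function(id, method) {
      build_background(repo_signature(repo, id), method, K = K,
                       n_perm = n_perm, seed = config$seed,
                       ref_extreme_n = config$ref_extreme_n)
    }
  } else if (is.character(backgrounds) && length(backgrounds) == 1L) {
    function(id, method)
      background_store_read(backgrounds, id, method, K, n_perm = n_perm)
  } else if (is.list(backgrounds)) {
    key <- vapply(backgrounds, function(b)
      paste(b$sig_id, b$method, b$K, sep = "\r"), character(1))
    function(id, method) {
      hit <- which(key == paste(id, method, K, sep = "\r"))
      .assert(length(hit) == 1L,
              sprintf("no background supplied for (sig_id=%s, method=%s, K=%d)",
                      id, method, K))
      bg <- backgrounds[[hit]]
      .assert(bg$n_perm == n_perm,
              sprintf("background for %s has n_perm=%d, config wants %d",
                      id, bg$n_perm, n_perm))
      bg
    }
  } else stop("backgrounds must be NULL, a store directory, or a list",
              call. = FALSE)
}

# deterministic per-reference map, optionally forked; scheduling never
# changes results because each unit is self-contained
.per_reference <- function(ids, threads, fn) {
  if (length(ids) == 0L) return(list())
  idx <- seq_along(ids)
  if (threads > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(idx, fn, mc.cores = threads)
  else lapply(idx, fn)
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen report> direction=", x$direction, ", query=", x$query_id,
      "\n  screened ", x$summary$screened, " references; ",
      x$summary$gated_for_wtcs, " gated for WTCS; ",
      x$summary$significant, " with meta-score >= 1\n", sep = "")
  top <- head(x$results[, c("rank", "sig_id", "meta_score", "consensus_pct")], 5)
  print(top, row.names = FALSE)
  invisible(x)
}

#' Convenience wrappers for the two screen directions
#'
#' `run_negative_screen` searches for reference signatures that reverse the
#' query (drug-repurposing candidates); `run_positive_screen` for signatures
#' that mimic it (mechanism-of-action / side-effect inference).
#'
#' @inheritParams run_screen
#' @param ... passed to [screen_config()].
#' @return a `screen_report`.
#' @export
run_negative_screen <- function(query, repo, backgrounds = NULL, ...) {
  run_screen(query, repo, screen_config(direction = "negative", ...),
             backgrounds)
}

#' @rdname run_negative_screen
#' @export
run_positive_screen <- function(query, repo, backgrounds = NULL, ...) {
  run_screen(query, repo, screen_config(direction = "positive", ...),
             backgrounds)
}
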